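test_that("a minimal one-individual file reads into a valid cohort", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tiny_cohort(), f)
  ch <- read_cohort(f)
  expect_s3_class(ch, "cohort")
  expect_equal(cohort_size(ch), 1L)
  expect_equal(max(ch$age), 3L)
})

test_that("cohort validation rejects rule-breaking records by name", {
  base <- data.frame(individual_id = "x", sex = "undetermined",
                     age = 0:2, stage = c("egg", "egg", "L1"),
                     alive = TRUE, eggs = 0L)
  skipper <- base
  skipper$stage <- c("egg", "L1", "L3")
  expect_error(cohort(skipper), "stage skipping")
  expect_s3_class(cohort(skipper, allow_stage_skip = TRUE), "cohort")

  gap <- base
  gap$age <- c(0L, 2L, 3L)
  expect_error(cohort(gap), "consecutive")

  reenter <- base
  reenter$stage <- c("L1", "L1", "egg")
  expect_error(cohort(reenter), "non-decreasing")

  male_layer <- data.frame(individual_id = "m", sex = "male", age = 0:6,
                           stage = c("egg", "L1", "L2", "L3", "L4",
                                     "pupa", "adult"),
                           alive = TRUE, eggs = c(rep(0L, 6), 2L))
  expect_error(cohort(male_layer), "adult females")

  undet_pupa <- data.frame(individual_id = "u", sex = "undetermined",
                           age = 0:5,
                           stage = c("egg", "L1", "L2", "L3", "L4", "pupa"),
                           alive = TRUE, eggs = 0L)
  expect_error(cohort(undet_pupa), "undetermined only for pre-pupal")

  expect_error(cohort(base[0, ]), "at least one individual")
})

test_that("read/write round trip is the identity on simulated cohorts", {
  ch <- simulate_cohort(simulation_preset("control", N = 100), seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, f)
  back <- read_cohort(f, label = attr(ch, "label"))
  expect_equal(as.data.frame(back), as.data.frame(ch))
  expect_identical(attr(back, "stage_order"), attr(ch, "stage_order"))
  # and the writer is byte-stable
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("canonical CSV output matches the frozen golden file", {
  ch <- simulate_cohort(simulation_preset("control", N = 2), seed = 42)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, f)
  expect_identical(readLines(f), c(
    "individual_id,sex,age,stage,alive,eggs",
    "ind001,undetermined,0,egg,TRUE,0",
    "ind001,undetermined,1,egg,TRUE,0",
    "ind001,undetermined,2,egg,TRUE,0",
    "ind001,undetermined,3,egg,TRUE,0",
    "ind001,undetermined,4,egg,TRUE,0",
    "ind001,undetermined,5,L1,TRUE,0",
    "ind001,undetermined,6,L1,TRUE,0",
    "ind002,undetermined,0,egg,TRUE,0",
    "ind002,undetermined,1,egg,TRUE,0",
    "ind002,undetermined,2,egg,TRUE,0",
    "ind002,undetermined,3,egg,TRUE,0",
    "ind002,undetermined,4,egg,TRUE,0",
    "ind002,undetermined,5,L1,TRUE,0",
    "ind002,undetermined,6,L1,TRUE,0",
    "ind002,undetermined,7,L2,TRUE,0",
    "ind002,undetermined,8,L2,TRUE,0",
    "ind002,undetermined,9,L3,TRUE,0",
    "ind002,undetermined,10,L3,TRUE,0",
    "ind002,undetermined,11,L3,TRUE,0",
    "ind002,undetermined,12,L3,TRUE,0"))
})

test_that("bioassay tables validate counts and monotonicity", {
  ok <- data.frame(strain = "s", concentration = 1e7, replicate = 1L,
                   day = 1:3, n_total = 10L, n_dead_cum = c(0L, 2L, 5L))
  expect_s3_class(bioassay_table(ok), "bioassay_table")

  over <- ok; over$n_dead_cum <- c(0L, 11L, 11L)
  expect_error(bioassay_table(over), "exceed")

  dec <- ok; dec$n_dead_cum <- c(5L, 2L, 6L)
  expect_error(bioassay_table(dec), "decreases")

  # published endpoint summaries re-entered as a 5 x 3 table parse fine
  tbl2 <- expand.grid(day = c(3L, 7L, 14L),
                      concentration = 10^(4:8))
  tbl2$strain <- "Bb1Bm"; tbl2$replicate <- 1L; tbl2$n_total <- 80L
  pct <- c(2.5, 5.63, 18.13, 5, 21.25, 33.75, 5, 29.38, 38.75,
           7.5, 34.38, 57.5, 10, 61.25, 85)
  tbl2 <- tbl2[order(tbl2$concentration, tbl2$day), ]
  tbl2$n_dead_cum <- as.integer(round(80 * pct / 100))
  expect_s3_class(bioassay_table(tbl2), "bioassay_table")

  f <- withr::local_tempfile(fileext = ".csv")
  sim <- simulate_bioassay(1e6, 0.8, 40L, 10^(4:8), seed = 3)
  write_bioassay(sim, f)
  expect_equal(as.data.frame(read_bioassay(f)), as.data.frame(sim))
})

test_that("age-stage counts equal a brute-force recount of raw records", {
  ch <- simulate_cohort(simulation_preset("bbfs", N = 80), seed = 5)
  counts <- age_stage_counts(ch)
  expect_identical(counts, brute_force_counts(ch))
  expect_equal(sum(counts[1L, ]), cohort_size(ch))
  # no resurrection: total alive is non-increasing in age
  expect_true(all(diff(rowSums(counts)) <= 0))
})

test_that("hand cohort counts place individuals where the records say", {
  counts <- age_stage_counts(hand_cohort())
  expect_equal(counts["0", "egg"], 4L)
  expect_equal(counts["2", "larva"], 4L)
  expect_equal(counts["4", "adult_female"], 1L)
  expect_equal(counts["4", "adult_male"], 1L)
  expect_equal(unname(rowSums(counts)), c(4L, 4L, 4L, 3L, 3L, 3L, 1L))
})
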