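test_that("survival matrix and l_x reproduce raw alive fractions", {
  ch <- simulate_cohort(simulation_preset("control", N = 60), seed = 2)
  counts <- age_stage_counts(ch)
  N <- cohort_size(ch)
  s <- survival_matrix(counts, N)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(sum(s[1L, ]), 1)
  lx <- age_specific_survival(s)
  live <- ch[ch$alive, ]
  alive_frac <- as.numeric(table(factor(live$age, levels = names(lx))) / N)
  expect_equal(unname(lx), alive_frac)
  expect_true(all(diff(lx) <= 1e-12))
  expect_error(survival_matrix(counts, 0), "positive")
})

test_that("fecundity schedule and R0 agree with hand-computed values", {
  ch <- hand_cohort()
  s <- survival_matrix(age_stage_counts(ch), 4)
  fs <- fecundity_schedule(ch, s)
  expect_equal(fs$mx[["5"]], 8 / 3)
  expect_equal(fs$mx[["6"]], 7)
  expect_equal(net_reproductive_rate(fs), 3.75)
  # R0 = total eggs / N, the exact two-sex identity
  expect_equal(net_reproductive_rate(fs), sum(ch$eggs) / 4)
})

test_that("cohorts without reproduction have m_x = 0 and undefined r", {
  ch <- tiny_cohort()
  s <- survival_matrix(age_stage_counts(ch), 1)
  fs <- fecundity_schedule(ch, s)
  expect_true(all(fs$mx == 0))
  expect_equal(net_reproductive_rate(fs), 0)
  expect_error(intrinsic_rate(fs), "undefined")
})

test_that("Euler-Lotka solution matches closed forms", {
  # l_x m_x = e concentrated at x = 4: exp(-5r) * e = 1 => r = 0.2
  fs <- list(lxmx = c(0, 0, 0, 0, exp(1)))
  expect_equal(intrinsic_rate(fs), 0.2, tolerance = 1e-10)
  # R0 = 1 concentrated anywhere => r = 0
  expect_equal(intrinsic_rate(list(lxmx = c(0, 0, 1))), 0,
               tolerance = 1e-10)
  # declining schedule, R0 < 1 => r < 0
  expect_lt(intrinsic_rate(list(lxmx = c(0, 0.5, 0.3))), 0)
})

test_that("Euler-Lotka solution matches a dense grid-search oracle", {
  set.seed(99)
  for (i in 1:5) {
    lxmx <- c(rep(0, 3 + i), stats::runif(6) * i)
    r_pkg <- intrinsic_rate(list(lxmx = lxmx))
    r_grid <- grid_search_r(lxmx)
    expect_equal(r_pkg, r_grid, tolerance = 1e-6)
    xs <- seq_along(lxmx) - 1
    expect_lt(abs(sum(exp(-r_pkg * (xs + 1)) * lxmx) - 1), 1e-9)
  }
})

test_that("finite rate and generation time follow their definitions", {
  expect_equal(finite_rate(0), 1)
  expect_equal(round(finite_rate(0.15), 2), 1.16)
  expect_equal(round(finite_rate(0.12), 2), 1.13)
  expect_equal(mean_generation_time(exp(1), 1), 1)
  expect_error(mean_generation_time(0, 0.1), "R0 > 0")
  tg <- mean_generation_time(1, 0)
  expect_true(is.na(tg))
  expect_equal(attr(tg, "reason"), "r = 0")
})

test_that("preadult survival counts individuals ever reaching adulthood", {
  expect_equal(preadult_survival(tiny_cohort()), 0)
  expect_equal(preadult_survival(hand_cohort()), 0.75)
  zero_mort <- simulate_cohort(
    simulation_params(N = 20, daily_survival = 1, stage_cv = 0), seed = 1)
  expect_equal(preadult_survival(zero_mort), 1)
  ch <- simulate_cohort(simulation_preset("control", N = 80), seed = 8)
  direct <- mean(tapply(ch$stage == "adult" & ch$alive,
                        ch$individual_id, any))
  expect_equal(preadult_survival(ch), direct)
})

test_that("population parameters are invariant to collapsing instars", {
  ch7 <- simulate_cohort(simulation_preset("control", N = 100), seed = 13)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch7, f)
  df <- utils::read.csv(f, colClasses = c(individual_id = "character"))
  df$stage[df$stage %in% c("L1", "L2", "L3", "L4")] <- "larva"
  ch3 <- cohort(df, stage_order = c("egg", "larva", "pupa", "adult"),
                label = "collapsed")
  lt7 <- life_table(ch7)
  lt3 <- life_table(ch3)
  for (p in c("R0", "r", "lambda", "T", "preadult_survival")) {
    expect_equal(lt3$params[[p]], lt7$params[[p]], tolerance = 1e-12)
  }
})

test_that("R0 responds monotonically to edits of the raw records", {
  ch <- simulate_cohort(simulation_preset("control", N = 40), seed = 21)
  R0 <- life_table(ch)$params[["R0"]]
  # adding one egg to an existing laying day weakly increases R0
  df <- as.data.frame(ch)
  lay <- which(df$eggs > 0)[1L]
  df$eggs[lay] <- df$eggs[lay] + 1L
  ch_plus <- cohort(df, stage_order = attr(ch, "stage_order"))
  expect_equal(life_table(ch_plus)$params[["R0"]], R0 + 1 / 40)
  # removing a never-reproducing individual strictly increases R0
  per_id <- tapply(df$eggs, df$individual_id, sum)
  barren <- names(per_id)[per_id == 0][1L]
  ch_minus <- cohort(df[df$individual_id != barren, ],
                     stage_order = attr(ch, "stage_order"))
  expect_gt(life_table(ch_minus)$params[["R0"]], R0)
})
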