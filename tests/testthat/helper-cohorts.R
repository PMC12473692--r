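# Small deterministic cohorts built by hand for exact-value checks.

# One individual: egg ages 0..2, L1 at 3, then dies.
tiny_cohort <- function() {
  cohort(data.frame(
    individual_id = "a", sex = "undetermined", age = 0:3,
    stage = c("egg", "egg", "egg", "L1"), alive = TRUE, eggs = 0L))
}

# A fully hand-specified 4-individual cohort with 3 stages:
#  - f1: female, egg 0-1, larva 2-3, adult 4-6, lays 3 + 7 eggs
#  - f2: female, egg 0-1, larva 2-4, adult 5, lays 5 eggs
#  - m1: male,   egg 0-1, larva 2-3, adult 4-5
#  - d1: dies as larva at age 2 (sex undetermined)
hand_cohort <- function() {
  mk <- function(id, sex, stages, eggs) {
    data.frame(individual_id = id, sex = sex,
               age = seq_along(stages) - 1L, stage = stages,
               alive = TRUE, eggs = eggs)
  }
  cohort(rbind(
    mk("f1", "female", c("egg", "egg", "larva", "larva",
                         "adult", "adult", "adult"),
       c(0L, 0L, 0L, 0L, 0L, 3L, 7L)),
    mk("f2", "female", c("egg", "egg", "larva", "larva", "larva", "adult"),
       c(0L, 0L, 0L, 0L, 0L, 5L)),
    mk("m1", "male", c("egg", "egg", "larva", "larva", "adult", "adult"),
       rep(0L, 6)),
    mk("d1", "undetermined", c("egg", "egg", "larva"), rep(0L, 3))),
    stage_order = c("egg", "larva", "adult"), label = "hand")
}

# Deterministic clone cohort: n identical females, useful for zero-variance
# bootstrap checks.
clone_cohort <- function(n = 6L, eggs_at_4 = 10L) {
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(individual_id = sprintf("c%02d", i), sex = "female",
               age = 0:4,
               stage = c("egg", "egg", "larva", "pupa", "adult"),
               alive = TRUE, eggs = c(0L, 0L, 0L, 0L, eggs_at_4))
  }))
  cohort(rows, stage_order = c("egg", "larva", "pupa", "adult"),
         label = "clones")
}

# Independent brute-force recount of n_xj straight from the raw rows.
brute_force_counts <- function(ch) {
  so <- attr(ch, "stage_order")
  adult <- so[length(so)]
  live <- ch[ch$alive, ]
  cols <- c(so[-length(so)], "adult_female", "adult_male")
  m <- matrix(0L, max(live$age) + 1L, length(cols),
              dimnames = list(age = 0:max(live$age), stage = cols))
  for (i in seq_len(nrow(live))) {
    st <- if (live$stage[i] == adult) {
      if (live$sex[i] == "female") "adult_female" else "adult_male"
    } else live$stage[i]
    m[live$age[i] + 1L, st] <- m[live$age[i] + 1L, st] + 1L
  }
  m
}

# Dense grid-search oracle for the Euler-Lotka root, independent of the
# bracketing solver.
grid_search_r <- function(lxmx, lo = -2, hi = 2, tol = 1e-6) {
  xs <- seq_along(lxmx) - 1
  resid <- function(r) abs(sum(exp(-r * (xs + 1)) * lxmx) - 1)
  grid <- seq(lo, hi, length.out = 401L)
  best <- grid[which.min(vapply(grid, resid, numeric(1)))]
  width <- (hi - lo) / 400
  while (width > tol / 10) {
    grid <- seq(best - width, best + width, length.out = 81L)
    best <- grid[which.min(vapply(grid, resid, numeric(1)))]
    width <- 2 * width / 80
  }
  best
}
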