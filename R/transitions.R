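#' Empirical age-stage transition model
#'
#' Tallies, for every occupied age-stage cell `(x, j)`, the observed
#' frequencies of the three fates an individual can meet by the next daily
#' census: remain in stage `j`, develop into the next stage (pupae develop
#' into adult females or adult males, tracked separately), or die.  These
#' frequencies are the machinery behind the age-stage life expectancy and
#' reproductive value matrices: propagating a unit of probability forward
#' through them reproduces the cohort's observed flows exactly, because
#' transitions only ever go from a stage to itself or to its successor.
#'
#' @param counts matrix from [age_stage_counts()]
#' @param x the [cohort()] the counts came from
#' @return object of class `transition_model`: list with `P`, a 3-d array
#'   `[age, from, to]` of transition probabilities (death is the
#'   complement of each row-slice sum), `counts`, and `states` (column
#'   names, adult split by sex).
#' @export
transition_model <- function(counts, x) {
  stopifnot(inherits(x, "cohort"))
  stage_order <- attr(x, "stage_order")
  adult <- stage_order[length(stage_order)]
  states <- colnames(counts)
  A <- nrow(counts)
  S <- length(states)
  tally <- array(0, dim = c(A, S, S),
                 dimnames = list(age = rownames(counts), from = states,
                                 to = states))

  live <- x[x$alive, , drop = FALSE]
  state_of <- function(stage, sex) {
    ifelse(stage == adult,
           ifelse(sex == "female", "adult_female", "adult_male"), stage)
  }
  live$state <- match(state_of(live$stage, live$sex), states)
  for (rows in split(seq_len(nrow(live)), live$individual_id)) {
    st <- live$state[rows][order(live$age[rows])]
    k <- length(st)
    if (k >= 2L) {
      for (i in seq_len(k - 1L)) {
        tally[i, st[i], st[i + 1L]] <- tally[i, st[i], st[i + 1L]] + 1
      }
    }
  }
  occ <- counts
  P <- tally
  for (j in seq_len(S)) {
    n <- occ[, j]
    nz <- n > 0
    P[nz, j, ] <- tally[nz, j, , drop = FALSE] / n[nz]
    P[!nz, j, ] <- NA_real_
  }
  structure(list(P = P, counts = occ, states = states),
            class = "transition_model")
}

# Propagate an occupancy distribution forward from age x0 through the
# empirical transition probabilities.  init is a vector over states at age
# x0; returns a matrix over ages x0..A-1 by states.
propagate_occupancy <- function(tm, x0, init) {
  P <- tm$P
  A <- dim(P)[1L]
  S <- dim(P)[2L]
  ages <- x0:(A - 1L)
  occ <- matrix(0, nrow = length(ages), ncol = S,
                dimnames = list(age = ages, state = tm$states))
  occ[1L, ] <- init
  if (length(ages) >= 2L) {
    for (i in seq_len(length(ages) - 1L)) {
      Pi <- P[ages[i] + 1L, , , drop = TRUE]  # rows age 1-indexed
      Pi[is.na(Pi)] <- 0
      occ[i + 1L, ] <- drop(occ[i, ] %*% Pi)
    }
  }
  occ
}

#' Age-stage life expectancy
#'
#' `e_xj` is the number of further days an individual currently at age `x`
#' in stage `j` is expected to live, computed by setting a unit of
#' occupancy at `(x, j)` and propagating it through the empirical
#' transition model; the sum of all occupancy over the remaining ages and
#' stages is the expectancy.  The current day counts as one: an individual
#' censused alive on its last day has `e = 1`, and `e` at age 0 in the
#' first stage equals the mean observed lifespan of the cohort.
#'
#' @param tm a [transition_model()]
#' @return matrix aligned with the count matrix; cells never occupied are
#'   `NA` (masked, not zero)
#' @export
life_expectancy <- function(tm) {
  cnt <- tm$counts
  A <- nrow(cnt); S <- ncol(cnt)
  e <- matrix(NA_real_, A, S, dimnames = dimnames(cnt))
  for (x0 in seq_len(A) - 1L) {
    for (j in seq_len(S)) {
      if (cnt[x0 + 1L, j] > 0L) {
        init <- numeric(S); init[j] <- 1
        e[x0 + 1L, j] <- sum(propagate_occupancy(tm, x0, init))
      }
    }
  }
  e
}

#' Age-stage reproductive value
#'
#' `v_xj` measures the contribution an individual at age `x` in stage `j`
#' makes to future population growth, discounting future offspring at the
#' intrinsic rate:
#' `v_xj = exp(r (x+1)) / s_xj * sum_{i >= x} exp(-r (i+1))
#'   sum_y s'_iy f_iy`,
#' where `s'` is the occupancy propagated forward from `s'_xj = s_xj`.
#' At age 0 in the first stage this reduces algebraically to the finite
#' rate `lambda`, which the engine exploits as a self-consistency check.
#'
#' @param tm a [transition_model()]
#' @param fs a [fecundity_schedule()]
#' @param r intrinsic rate of increase
#' @param s matrix from [survival_matrix()]
#' @return matrix aligned with `s`; unoccupied cells are `NA`
#' @export
reproductive_value <- function(tm, fs, r, s) {
  cnt <- tm$counts
  A <- nrow(cnt); S <- ncol(cnt)
  f <- fs$f
  v <- matrix(NA_real_, A, S, dimnames = dimnames(cnt))
  for (x0 in seq_len(A) - 1L) {
    for (j in seq_len(S)) {
      sxj <- s[x0 + 1L, j]
      if (sxj > 0) {
        init <- numeric(S); init[j] <- sxj
        occ <- propagate_occupancy(tm, x0, init)
        ages <- x0:(A - 1L)
        disc <- exp(-r * (ages + 1))
        future <- sum(disc * rowSums(occ * f[ages + 1L, , drop = FALSE]))
        v[x0 + 1L, j] <- exp(r * (x0 + 1)) / sxj * future
      }
    }
  }
  v
}
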