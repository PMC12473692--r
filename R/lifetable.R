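#' Age-stage survival matrix
#'
#' `s_xj = n_xj / N`: the probability that a newborn egg is alive and in
#' stage `j` at age `x`.  This matrix is the backbone of the two-sex
#' framework: unlike a female-only life table it keeps males and
#' stage-structure explicit, so developmental asynchrony between
#' individuals shows up as overlapping stage curves.
#'
#' @param counts integer matrix from [age_stage_counts()]
#' @param N cohort size (number of eggs at age 0)
#' @return matrix of proportions with class `age_stage_survival`; attribute
#'   `N` carries the cohort size.
#' @export
survival_matrix <- function(counts, N) {
  if (N <= 0) stop("cohort size N must be positive", call. = FALSE)
  if (sum(counts[1L, ]) != N) {
    stop("counts at age 0 must sum to the cohort size", call. = FALSE)
  }
  s <- counts / N
  structure(s, N = N, class = c("age_stage_survival", class(s)))
}

#' Age-specific survival curve
#'
#' `l_x = sum_j s_xj`: the probability of being alive at age `x`
#' regardless of stage; `l_0 = 1` by construction.
#'
#' @param s matrix from [survival_matrix()]
#' @return numeric vector indexed by age (names give the age)
#' @export
age_specific_survival <- function(s) {
  lx <- rowSums(s)
  names(lx) <- rownames(s)
  lx
}

#' Age-stage fecundity and the age-specific schedule
#'
#' `f_xj` is the mean number of eggs laid per day by an individual of age
#' `x` in stage `j` (nonzero only in the adult-female column), and
#' `m_x = sum_j s_xj f_xj / sum_j s_xj` its population-weighted
#' age-specific mean.  Ages at which nobody is alive have `m_x = 0`.
#'
#' @param x a [cohort()]
#' @param s matrix from [survival_matrix()] for the same cohort
#' @return list of class `fecundity_schedule` with elements `f` (matrix
#'   aligned with `s`), `lx`, `mx`, and `lxmx = lx * mx`
#' @export
fecundity_schedule <- function(x, s) {
  stopifnot(inherits(x, "cohort"))
  stage_order <- attr(x, "stage_order")
  adult <- stage_order[length(stage_order)]
  N <- attr(s, "N")

  f <- matrix(0, nrow = nrow(s), ncol = ncol(s), dimnames = dimnames(s))
  laid <- x[x$alive & x$eggs > 0L & x$stage == adult &
              x$sex == "female", , drop = FALSE]
  if (nrow(laid) > 0L) {
    eggs_by_age <- tapply(laid$eggs, factor(laid$age, levels = rownames(s)),
                          sum, default = 0)
    nf <- s[, "adult_female"] * N
    f[, "adult_female"] <- ifelse(nf > 0, eggs_by_age / nf, 0)
  }
  lx <- age_specific_survival(s)
  weighted <- rowSums(s * f)
  mx <- ifelse(lx > 0, weighted / lx, 0)
  structure(list(f = f, lx = lx, mx = mx, lxmx = lx * mx),
            class = "fecundity_schedule")
}

#' Net reproductive rate
#'
#' `R0 = sum_x l_x m_x`: the expected lifetime offspring per newborn.  In
#' the two-sex framework this equals (adult females / N) times the mean
#' lifetime fecundity per adult female, exactly.
#'
#' @param fs a [fecundity_schedule()]
#' @return scalar `R0 >= 0`
#' @export
net_reproductive_rate <- function(fs) sum(fs$lxmx)

#' Intrinsic rate of increase from the Euler-Lotka equation
#'
#' Solves `sum_x exp(-r (x+1)) l_x m_x = 1` for `r`, with age indexed from
#' 0 (the Goodman convention used by TWOSEX-MSChart: a female aged `x` at
#' the end-of-day census contributes offspring discounted by `x + 1`
#' days).  The left-hand side is strictly decreasing in `r`, so the root
#' is unique whenever `R0 > 0`; it is found by bracket expansion and
#' [stats::uniroot()].  `r < 0` is legitimate when `0 < R0 < 1`.
#'
#' @param fs a [fecundity_schedule()] (or any list with a `lxmx` vector)
#' @param tol absolute tolerance on the Euler residual
#' @return scalar `r` (per day)
#' @export
intrinsic_rate <- function(fs, tol = 1e-12) {
  lxmx <- fs$lxmx
  if (any(!is.finite(lxmx))) stop("non-finite fecundity schedule",
                                  call. = FALSE)
  if (sum(lxmx) <= 0) {
    stop("intrinsic rate undefined: net reproductive rate is zero",
         call. = FALSE)
  }
  xs <- seq_along(lxmx) - 1  # age 0-based
  euler <- function(r) sum(exp(-r * (xs + 1)) * lxmx) - 1
  lo <- -5; hi <- 5
  while (euler(lo) < 0) lo <- lo * 2
  while (euler(hi) > 0) hi <- hi * 2
  root <- stats::uniroot(euler, c(lo, hi), tol = 1e-14)$root
  if (abs(euler(root)) > tol) {
    # polish with a few Newton steps if uniroot's tolerance fell short
    for (i in 1:50) {
      g <- -sum((xs + 1) * exp(-root * (xs + 1)) * lxmx)
      root <- root - euler(root) / g
      if (abs(euler(root)) <= tol) break
    }
  }
  root
}

#' Finite rate of increase
#'
#' `lambda = exp(r)`: the factor by which the population multiplies per
#' day at the stable age-stage distribution.
#'
#' @param r intrinsic rate of increase (per day)
#' @return scalar `lambda`
#' @export
finite_rate <- function(r) exp(r)

#' Mean generation time
#'
#' `T = ln(R0) / r`: the time a population needs to grow `R0`-fold at the
#' stable age-stage distribution.
#'
#' @param R0 net reproductive rate (> 0)
#' @param r intrinsic rate of increase
#' @return scalar days; `NA` with attribute `reason = "r = 0"` when the
#'   population is exactly stationary
#' @export
mean_generation_time <- function(R0, r) {
  if (R0 <= 0) stop("mean generation time requires R0 > 0", call. = FALSE)
  if (r == 0) return(structure(NA_real_, reason = "r = 0"))
  log(R0) / r
}

#' Preadult survival
#'
#' Fraction of the cohort's eggs that ever reach the adult stage.
#'
#' @param x a [cohort()]
#' @return proportion in `[0, 1]`
#' @export
preadult_survival <- function(x) {
  stopifnot(inherits(x, "cohort"))
  stage_order <- attr(x, "stage_order")
  adult <- stage_order[length(stage_order)]
  reached <- tapply(x$alive & x$stage == adult, x$individual_id, any)
  mean(reached)
}

#' Full age-stage two-sex life table for a cohort
#'
#' One call computing the survival matrix, the `l_x`/`f_xj`/`m_x`
#' schedules, the population parameters (`R0`, `r`, `lambda`, `T`,
#' preadult survival), the empirical transition model, and the age-stage
#' life expectancy `e_xj` and reproductive value `v_xj` matrices.
#'
#' @param x a [cohort()]
#' @param tol Euler residual tolerance passed to [intrinsic_rate()]
#' @return object of class `lifetable`: a list with elements `s`, `f`,
#'   `lx`, `mx`, `exj`, `vxj`, `params` (named vector: `R0`, `r`,
#'   `lambda`, `T`, `preadult_survival`), `transitions`, `N`, `label`.
#' @examples
#' p <- simulation_preset("control", N = 50)
#' ch <- simulate_cohort(p, seed = 1)
#' lt <- life_table(ch)
#' lt$params
#' @export
life_table <- function(x, tol = 1e-12) {
  stopifnot(inherits(x, "cohort"))
  counts <- age_stage_counts(x)
  N <- cohort_size(x)
  s <- survival_matrix(counts, N)
  fs <- fecundity_schedule(x, s)
  R0 <- net_reproductive_rate(fs)
  if (R0 > 0) {
    r <- intrinsic_rate(fs, tol = tol)
    lam <- finite_rate(r)
    Tg <- mean_generation_time(R0, r)
  } else {
    r <- NA_real_; lam <- NA_real_; Tg <- NA_real_
  }
  tm <- transition_model(counts, x)
  exj <- life_expectancy(tm)
  vxj <- if (is.finite(r)) reproductive_value(tm, fs, r, s) else NULL
  params <- c(R0 = R0, r = r, lambda = lam, T = Tg,
              preadult_survival = preadult_survival(x))
  structure(list(s = s, f = fs$f, lx = fs$lx, mx = fs$mx,
                 lxmx = fs$lxmx, exj = exj, vxj = vxj, params = params,
                 transitions = tm, N = N, label = attr(x, "label")),
            class = "lifetable")
}

#' @export
print.lifetable <- function(x, ...) {
  cat(sprintf("Age-stage two-sex life table: '%s' (N = %d, %d ages)\n",
              x$label, x$N, nrow(x$s)))
  p <- x$params
  cat(sprintf("  R0 = %.3f offspring/newborn\n", p[["R0"]]))
  if (is.finite(p[["r"]])) {
    cat(sprintf("  r  = %.4f /day   lambda = %.4f /day   T = %.2f days\n",
                p[["r"]], p[["lambda"]], p[["T"]]))
  } else {
    cat("  r, lambda, T undefined (no reproduction observed)\n")
  }
  cat(sprintf("  preadult survival = %.1f%%\n",
              100 * p[["preadult_survival"]]))
  invisible(x)
}
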