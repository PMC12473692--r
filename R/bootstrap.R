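# Per-individual reduction of a cohort.  The population parameters are
# functionals of l_x and l_x m_x only, both of which are means over
# individuals of per-individual age profiles, so bootstrap replicates can
# be computed from these matrices without rebuilding a cohort object.
cohort_reduction <- function(x) {
  stopifnot(inherits(x, "cohort"))
  stage_order <- attr(x, "stage_order")
  adult <- stage_order[length(stage_order)]
  live <- x[x$alive, , drop = FALSE]
  ids <- unique(x$individual_id)
  N <- length(ids)
  A <- max(live$age) + 1L
  alive <- matrix(0, N, A, dimnames = list(ids, 0:(A - 1L)))
  eggs <- matrix(0, N, A, dimnames = list(ids, 0:(A - 1L)))
  i <- match(live$individual_id, ids)
  alive[cbind(i, live$age + 1L)] <- 1
  eggs[cbind(i, live$age + 1L)] <- live$eggs
  reached <- tapply(x$alive & x$stage == adult, x$individual_id, any)
  list(alive = alive, eggs = eggs,
       adult = as.logical(reached[ids]), N = N, A = A)
}

# Population parameters for a resample (vector of row indices, with
# repetition) of the reduction.  Undefined parameters come back NA.
reduction_params <- function(red, idx, tol = 1e-10) {
  lxmx <- colMeans(red$eggs[idx, , drop = FALSE])
  R0 <- sum(lxmx)
  pre <- mean(red$adult[idx])
  if (R0 > 0) {
    r <- intrinsic_rate(list(lxmx = lxmx), tol = tol)
    c(R0 = R0, r = r, lambda = exp(r),
      T = log(R0) / r, preadult_survival = pre)
  } else {
    c(R0 = 0, r = NA_real_, lambda = NA_real_, T = NA_real_,
      preadult_survival = pre)
  }
}

#' Bootstrap standard errors for the population parameters
#'
#' Resamples `N` individuals with replacement from the cohort — the
#' resampling unit is the individual egg with its complete life history,
#' the standard two-sex bootstrap — and recomputes `R0`, `r`, `lambda`,
#' `T` and preadult survival for each replicate.  Replicates in which no
#' resampled female reproduces have `R0 = 0` and undefined `r`, `lambda`
#' and `T`; these are recorded as missing, counted, and excluded from the
#' summaries of the affected parameters.
#'
#' Each replicate draws its indices from a stream sub-seeded by
#' `(seed, replicate index)`, so two cohorts bootstrapped with the same
#' `seed` and `B` have aligned replicate streams and can be compared with
#' [paired_bootstrap_test()].
#'
#' @param x a [cohort()]
#' @param B number of bootstrap iterations (the study-scale default is
#'   100,000; smaller values are appropriate for exploration)
#' @param seed integer RNG seed
#' @return object of class `bootstrap_result`: list with `estimates`
#'   (point estimates from the full cohort), `samples` (`B` x 5 matrix),
#'   `se` (standard deviation of the replicates, the conventional
#'   TWOSEX-style SE), `ci` (2.5/97.5 percentiles), `n_undefined`, `B`,
#'   `seed`, `label`.
#' @export
bootstrap_parameters <- function(x, B = 100000L, seed = 1L) {
  stopifnot(inherits(x, "cohort"), B >= 1L)
  red <- cohort_reduction(x)
  est <- reduction_params(red, seq_len(red$N), tol = 1e-12)
  pnames <- names(est)
  samples <- matrix(NA_real_, nrow = B, ncol = length(pnames),
                    dimnames = list(NULL, pnames))
  for (b in seq_len(B)) {
    set.seed((seed + b) %% 2147483647L)
    idx <- sample.int(red$N, red$N, replace = TRUE)
    samples[b, ] <- reduction_params(red, idx)
  }
  se <- apply(samples, 2L, stats::sd, na.rm = TRUE)
  ci <- apply(samples, 2L, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE, names = FALSE)
  rownames(ci) <- c("2.5%", "97.5%")
  structure(list(estimates = est, samples = samples, se = se, ci = ci,
                 n_undefined = sum(is.na(samples[, "r"])), B = B,
                 seed = seed, label = attr(x, "label")),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap (B = %d, seed = %d) for '%s'\n",
              x$B, x$seed, x$label))
  tab <- data.frame(estimate = x$estimates, se = x$se,
                    lo95 = x$ci[1L, ], hi95 = x$ci[2L, ])
  print(round(tab, 4))
  if (x$n_undefined > 0L) {
    cat(sprintf("  (%d replicate(s) with R0 = 0: r/lambda/T undefined)\n",
                x$n_undefined))
  }
  invisible(x)
}

#' Paired bootstrap comparison of two cohorts
#'
#' Compares each population parameter between two bootstrapped cohorts by
#' pairing replicates by index: `d_b = a_b - b_b`.  The two-sided p-value
#' is percentile-based with add-one smoothing,
#' `p = 2 min((#\{d <= 0\} + 1), (#\{d >= 0\} + 1)) / (B + 1)`, capped at
#' 1.  A normal-approximation alternative (`d / se(d)` against the
#' standard normal) is available via `method`.
#'
#' @param a,b [bootstrap_parameters()] results with identical `B`
#' @param method `"percentile"` (default) or `"normal"`
#' @param alpha significance level used for the `significant` flag
#' @return data.frame of class `paired_bootstrap_test`: one row per
#'   parameter with the difference estimate (`a - b`), bootstrap SE of the
#'   difference, p-value, and significance flag; replicate pairs where
#'   either side is undefined are dropped and counted in `n_dropped`.
#' @export
paired_bootstrap_test <- function(a, b, method = c("percentile", "normal"),
                                  alpha = 0.05) {
  stopifnot(inherits(a, "bootstrap_result"), inherits(b, "bootstrap_result"))
  method <- match.arg(method)
  if (a$B != b$B) {
    stop("paired bootstrap test requires equal replicate counts B",
         call. = FALSE)
  }
  pnames <- colnames(a$samples)
  out <- data.frame(parameter = pnames,
                    estimate = a$estimates[pnames] - b$estimates[pnames],
                    se = NA_real_, p = NA_real_, n_dropped = NA_integer_,
                    row.names = NULL)
  for (k in seq_along(pnames)) {
    d <- a$samples[, k] - b$samples[, k]
    drop <- is.na(d)
    d <- d[!drop]
    out$n_dropped[k] <- sum(drop)
    out$se[k] <- stats::sd(d)
    if (length(d) == 0L) next
    if (method == "percentile") {
      p <- 2 * min(sum(d <= 0) + 1, sum(d >= 0) + 1) / (length(d) + 1)
      out$p[k] <- min(1, p)
    } else {
      s <- stats::sd(d)
      z <- if (s > 0) mean(d) / s else 0
      out$p[k] <- if (s > 0) 2 * stats::pnorm(-abs(z)) else 1
    }
  }
  out$significant <- !is.na(out$p) & out$p < alpha
  class(out) <- c("paired_bootstrap_test", "data.frame")
  out
}

#' Letter display from all-pairs paired bootstrap tests
#'
#' For more than two cohorts, performs every pairwise
#' [paired_bootstrap_test()], Holm-adjusts each parameter's pairwise
#' p-values, and assigns compact letters (groups sharing a letter do not
#' differ at level `alpha`); the cohort with the larger estimate gets the
#' earlier letter.
#'
#' @param boots named list of [bootstrap_parameters()] results (same `B`)
#' @param alpha significance level
#' @param method p-value construction, as in [paired_bootstrap_test()]
#' @return data.frame: parameter, group, estimate, se, letter
#' @export
bootstrap_letters <- function(boots, alpha = 0.05,
                              method = c("percentile", "normal")) {
  method <- match.arg(method)
  stopifnot(length(boots) >= 2L, !is.null(names(boots)))
  groups <- names(boots)
  pnames <- colnames(boots[[1L]]$samples)
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  rows <- list()
  for (param in pnames) {
    praw <- vapply(pairs, function(pr) {
      tst <- paired_bootstrap_test(boots[[pr[1L]]], boots[[pr[2L]]],
                                   method = method, alpha = alpha)
      tst$p[tst$parameter == param]
    }, numeric(1L))
    padj <- stats::p.adjust(praw, method = "holm")
    means <- vapply(boots, function(bb) bb$estimates[[param]], numeric(1L))
    sig <- matrix(FALSE, length(groups), length(groups),
                  dimnames = list(groups, groups))
    for (i in seq_along(pairs)) {
      pr <- pairs[[i]]
      sig[pr[1L], pr[2L]] <- sig[pr[2L], pr[1L]] <-
        !is.na(padj[i]) && padj[i] < alpha
    }
    letters_out <- compact_letters(means, sig)
    rows[[param]] <- data.frame(
      parameter = param, group = groups, estimate = unname(means),
      se = vapply(boots, function(bb) bb$se[[param]], numeric(1L)),
      letter = letters_out[groups], row.names = NULL)
  }
  do.call(rbind, rows)
}
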