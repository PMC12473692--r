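#' Abbott's correction for control mortality
#'
#' Adjusts an observed treatment mortality for the background mortality of
#' the untreated control:
#' `corrected % = 100 (p_treat - p_control) / (1 - p_control)`.
#' The corrected value is monotone increasing in the treatment mortality
#' and, below 100% treatment mortality, decreasing in the control
#' mortality.  A treatment killing fewer insects than the control yields a
#' negative value; it is reported as-is with a warning rather than clamped.
#'
#' @param p_treat,p_control mortality proportions in `[0, 1]`;
#'   `p_control < 1`
#' @return corrected mortality as a percentage
#' @export
abbott_correction <- function(p_treat, p_control) {
  stopifnot(all(p_treat >= 0 & p_treat <= 1),
            all(p_control >= 0 & p_control <= 1))
  if (any(p_control == 1)) {
    stop("Abbott correction undefined: control mortality is 100%",
         call. = FALSE)
  }
  out <- 100 * (p_treat - p_control) / (1 - p_control)
  if (any(out < 0)) {
    warning("treatment mortality below control: negative corrected value")
  }
  out
}

#' Three-parameter logistic time-mortality fit
#'
#' Fits `Y = K / (1 + exp(a - b X))` to a series of (day, cumulative
#' mortality %) points by least squares, where `K` is the mortality
#' asymptote (%), `b` the per-day slope and `a/b` the inflection day.
#' Virulence assays routinely plateau below 100% mortality, which is why
#' the asymptote is a free parameter; when the plateau sits at or below
#' 50% the median lethal time does not exist (see [lt50()]).
#'
#' Starting values: `K0` is the maximum observed mortality (nudged above
#' it), `b0` comes from a log-linearization of the interior points, and
#' `a0 = b0 * X` at half-`K`.  Fitting uses Levenberg-Marquardt with `K`
#' bounded in `(0, 100]`.
#'
#' @param day numeric vector of days (>= 4 points)
#' @param mortality cumulative mortality, percent, non-decreasing
#' @return object of class `time_mortality_fit`: list with `K`, `a`, `b`,
#'   `r2`, `vcov` (3 x 3 covariance of `(K, a, b)`), `fitted`, `data`
#' @export
fit_time_mortality <- function(day, mortality) {
  stopifnot(length(day) == length(mortality), length(day) >= 4L)
  if (is.unsorted(mortality[order(day)], strictly = FALSE) &&
      any(diff(mortality[order(day)]) < -1e-8)) {
    stop("cumulative mortality must be non-decreasing in time",
         call. = FALSE)
  }
  if (max(mortality) <= 0) {
    stop("fit failure: no mortality observed (flat series)", call. = FALSE)
  }
  K0 <- min(100, max(mortality) * 1.05 + 1e-6)
  # log-linearize: log(K0/Y - 1) = a - bX on interior points
  interior <- mortality > 0.01 * K0 & mortality < 0.999 * K0
  if (sum(interior) >= 2L) {
    z <- log(pmax(K0 / mortality[interior] - 1, 1e-8))
    cf <- stats::coef(stats::lm(z ~ day[interior]))
    a0 <- cf[[1L]]; b0 <- max(-cf[[2L]], 1e-3)
  } else {
    b0 <- 0.5; a0 <- b0 * stats::median(day)
  }
  df <- data.frame(X = day, Y = mortality)
  do_fit <- function(start) {
    minpack.lm::nlsLM(Y ~ K / (1 + exp(a - b * X)), data = df,
                      start = start,
                      lower = c(K = 1e-6, a = -Inf, b = 1e-8),
                      upper = c(K = 100, a = Inf, b = Inf))
  }
  # a start sitting exactly on a zero-residual optimum trips a
  # singular-gradient stop in the LM machinery; fall back to a jittered
  # restart, then to direct bounded least squares
  fit <- tryCatch(
    do_fit(list(K = K0, a = a0, b = b0)),
    error = function(e) tryCatch(
      do_fit(list(K = max(1e-3, K0 * 0.9), a = a0 + 0.3,
                  b = b0 * 1.2 + 0.01)),
      error = function(e2) NULL))
  if (is.null(fit)) {
    ssq <- function(p) {
      sum((mortality - p[1L] / (1 + exp(p[2L] - p[3L] * day)))^2)
    }
    opt <- stats::optim(c(K0, a0, b0), ssq, method = "L-BFGS-B",
                        lower = c(1e-6, -50, 1e-8),
                        upper = c(100, 50, 50))
    if (opt$convergence != 0 && opt$value > 1e-6) {
      stop("time-mortality fit failed to converge: ", opt$message,
           call. = FALSE)
    }
    cf <- c(K = opt$par[1L], a = opt$par[2L], b = opt$par[3L])
    fitted_y <- cf[["K"]] / (1 + exp(cf[["a"]] - cf[["b"]] * day))
    vc <- NULL
  } else {
    cf <- stats::coef(fit)
    fitted_y <- stats::fitted(fit)
    vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  }
  ss_res <- sum((mortality - fitted_y)^2)
  ss_tot <- sum((mortality - mean(mortality))^2)
  time_mortality_fit(K = cf[["K"]], a = cf[["a"]], b = cf[["b"]],
                     r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                     vcov = vc,
                     data = df, fitted = as.numeric(fitted_y))
}

#' @rdname fit_time_mortality
#' @param K,a,b logistic coefficients (e.g. re-entered from a published
#'   table) from which to build a fit object directly
#' @param r2 optional goodness of fit
#' @param vcov optional coefficient covariance matrix
#' @param data,fitted optional original points and fitted values
#' @export
time_mortality_fit <- function(K, a, b, r2 = NA_real_, vcov = NULL,
                               data = NULL, fitted = NULL) {
  stopifnot(K > 0, K <= 100)
  structure(list(K = K, a = a, b = b, r2 = r2, vcov = vcov, data = data,
                 fitted = fitted),
            class = "time_mortality_fit")
}

#' @export
print.time_mortality_fit <- function(x, ...) {
  cat(sprintf("Y = %.3f/(1 + Exp(%.3f - %.3fX))", x$K, x$a, x$b))
  if (is.finite(x$r2)) cat(sprintf("   R^2 = %.3f", x$r2))
  cat("\n")
  lt <- lt50(x)
  if (is.na(lt$lt50)) {
    cat("LT50: undefined,", lt$reason, "\n")
  } else {
    cat(sprintf("LT50 = %.2f days\n", lt$lt50))
  }
  invisible(x)
}

#' Median lethal time from a logistic time-mortality fit
#'
#' Solves `K / (1 + exp(a - b X)) = 50` in closed form:
#' `LT50 = (a - ln(K/50 - 1)) / b`.  When the mortality asymptote `K`
#' does not exceed 50% the curve never crosses half-mortality and the
#' LT50 does not exist; the result is then undefined with the reason
#' `"asymptote <= 50%"` — the situation a published table marks with a
#' dash when cumulative mortality stays too low for the median to be
#' reached.
#'
#' A 95% confidence interval is computed by the delta method on the
#' `(K, a, b)` covariance when the fit carries one.
#'
#' @param fit a [fit_time_mortality()] / [time_mortality_fit()] object
#' @return list with `lt50` (days, or `NA`), `reason` (`NA` or why it is
#'   undefined), and `ci` (length-2 vector or `NULL`)
#' @export
lt50 <- function(fit) {
  stopifnot(inherits(fit, "time_mortality_fit"))
  K <- fit$K; a <- fit$a; b <- fit$b
  if (K <= 50) {
    return(list(lt50 = NA_real_, reason = "asymptote <= 50%", ci = NULL))
  }
  if (b <= 0) {
    return(list(lt50 = NA_real_, reason = "non-positive slope", ci = NULL))
  }
  x50 <- (a - log(K / 50 - 1)) / b
  ci <- NULL
  if (!is.null(fit$vcov)) {
    # delta method: gradient of x50 w.r.t. (K, a, b);
    # d/dK log(K/50 - 1) = (1/50)/(K/50 - 1)
    g <- c(K = -(1 / 50) / ((K / 50 - 1) * b),
           a = 1 / b,
           b = -x50 / b)
    v <- drop(t(g) %*% fit$vcov %*% g)
    if (is.finite(v) && v >= 0) {
      ci <- x50 + c(-1, 1) * stats::qnorm(0.975) * sqrt(v)
    }
  }
  list(lt50 = x50, reason = NA_character_, ci = ci)
}

#' Probit dose-response fit and LC50
#'
#' Maximum-likelihood probit regression of mortality on
#' `log10(concentration)`, the canonical analysis of an endpoint
#' dose-mortality assay.  The median lethal concentration is
#' `LC50 = 10^(-intercept/slope)`, with a 95% confidence interval by
#' Fieller's theorem on the ratio of coefficients (falling back to
#' undefined limits when the slope is too poorly determined, i.e. the
#' Fieller `g >= 1`).  Pearson's chi-square against the fitted probits is
#' reported as the heterogeneity statistic.
#'
#' @param concentration dose per observation unit (e.g. spores/mL); >= 3
#'   distinct positive values
#' @param n_total number exposed at each concentration
#' @param n_dead number dead at the endpoint
#' @return object of class `dose_response_fit`: list with `intercept`,
#'   `slope` (per log10 concentration), `lc50`, `lc50_ci`, `chi2_gof`,
#'   `df`, `valid` (FALSE when slope <= 0), `glm`
#' @export
fit_dose_response <- function(concentration, n_total, n_dead) {
  stopifnot(length(concentration) == length(n_total),
            length(n_total) == length(n_dead),
            all(concentration > 0), all(n_dead <= n_total))
  if (length(unique(concentration)) < 3L) {
    stop("probit fit requires >= 3 concentrations", call. = FALSE)
  }
  if (all(n_dead == 0L) || all(n_dead == n_total)) {
    stop("complete separation: no mortality gradient across doses",
         call. = FALSE)
  }
  x <- log10(concentration)
  fit <- stats::glm(cbind(n_dead, n_total - n_dead) ~ x,
                    family = stats::binomial(link = "probit"))
  cf <- stats::coef(fit)
  intercept <- cf[[1L]]; slope <- cf[[2L]]
  valid <- is.finite(slope) && slope > 0
  lc50 <- if (valid) 10^(-intercept / slope) else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (valid) {
    V <- stats::vcov(fit)
    m <- -intercept / slope
    z2 <- stats::qnorm(0.975)^2
    # Fieller: roots of (alpha - m b)^2 = z^2 Var(alpha - m b),
    # alpha = -intercept
    va <- V[1L, 1L]; vb <- V[2L, 2L]; vab <- -V[1L, 2L]
    A <- slope^2 - z2 * vb
    Bq <- -2 * (-intercept * slope - z2 * vab)
    Cq <- intercept^2 - z2 * va
    disc <- Bq^2 - 4 * A * Cq
    if (A > 0 && disc >= 0) {
      roots <- sort((-Bq + c(-1, 1) * sqrt(disc)) / (2 * A))
      ci <- 10^roots
    }
  }
  chi2 <- sum(stats::residuals(fit, type = "pearson")^2)
  structure(list(intercept = intercept, slope = slope, lc50 = lc50,
                 lc50_ci = ci, chi2_gof = chi2,
                 df = length(unique(x)) - 2L, valid = valid, glm = fit),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Probit fit: probit(p) = %.3f + %.3f log10(dose)\n",
              x$intercept, x$slope))
  if (x$valid) {
    cat(sprintf("LC50 = %.3g (95%% CI %.3g - %.3g), heterogeneity chi2 = %.2f on %d df\n",
                x$lc50, x$lc50_ci[1L], x$lc50_ci[2L], x$chi2_gof, x$df))
  } else {
    cat("invalid fit: non-positive slope\n")
  }
  invisible(x)
}

#' Endophytic colonization rate
#'
#' `100 * positives / total`: the percentage of plants from which the
#' inoculated fungus was re-isolated after surface sterilization.
#'
#' @param positives number of fungal-positive plants
#' @param total number of plants tested (> 0)
#' @return percentage
#' @export
colonization_rate <- function(positives, total) {
  if (any(total <= 0)) stop("total plants tested must be > 0", call. = FALSE)
  stopifnot(all(positives >= 0), all(positives <= total))
  100 * positives / total
}

#' One-way ANOVA of percentage data with LSD letters
#'
#' The standard analysis of replicate mortality or colonization
#' percentages: an arcsine square-root transform to stabilize binomial
#' variance, one-way ANOVA, all-pairs least-significant-difference t-tests
#' on the transformed scale using the pooled error mean square, Holm
#' correction of the pairwise p-values, and a compact letter display at
#' level `alpha`.
#'
#' @param values numeric vector of percentages (0-100) or proportions
#' @param group factor or character vector of group labels
#' @param transform apply the arcsine square-root transform (default
#'   `TRUE`); values are interpreted as percentages when any exceed 1
#' @param alpha significance level for the letters
#' @return list of class `group_comparison`: `anova` (data.frame with F,
#'   df, p), `pairwise` (data.frame of pairwise differences and Holm
#'   p-values), `letters` (named character), `means` (group means on the
#'   original scale)
#' @export
compare_groups <- function(values, group, transform = TRUE, alpha = 0.05) {
  group <- factor(group)
  stopifnot(length(values) == length(group), nlevels(group) >= 2L)
  if (any(table(group) < 2L)) {
    stop("each group needs >= 2 replicates", call. = FALSE)
  }
  y <- values
  if (transform) {
    p <- if (any(values > 1)) values / 100 else values
    if (any(p < 0 | p > 1)) {
      stop("percentages must lie in [0, 100] for the arcsine transform",
           call. = FALSE)
    }
    y <- asin(sqrt(p))
  }
  if (stats::sd(y) == 0) {
    stop("degenerate ANOVA: zero variance everywhere", call. = FALSE)
  }
  fit <- stats::aov(y ~ group)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  gm <- tapply(y, group, mean)
  gn <- tapply(y, group, length)
  lev <- levels(group)
  pairs <- utils::combn(lev, 2L, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    d <- gm[[pr[1L]]] - gm[[pr[2L]]]
    sed <- sqrt(mse * (1 / gn[[pr[1L]]] + 1 / gn[[pr[2L]]]))
    tval <- if (sed > 0) d / sed else 0
    data.frame(group1 = pr[1L], group2 = pr[2L], diff = d, t = tval,
               p = 2 * stats::pt(-abs(tval), df_err))
  }))
  pw$p_holm <- stats::p.adjust(pw$p, method = "holm")
  sig <- matrix(FALSE, nlevels(group), nlevels(group),
                dimnames = list(lev, lev))
  for (i in seq_len(nrow(pw))) {
    sig[pw$group1[i], pw$group2[i]] <- sig[pw$group2[i], pw$group1[i]] <-
      pw$p_holm[i] < alpha
  }
  means_orig <- tapply(values, group, mean)
  letters_out <- compact_letters(stats::setNames(as.numeric(gm), lev), sig)
  structure(list(
    anova = data.frame(F = an["group", "F value"],
                       df1 = an["group", "Df"], df2 = df_err,
                       p = an["group", "Pr(>F)"]),
    pairwise = pw,
    letters = letters_out,
    means = stats::setNames(as.numeric(means_orig), lev)),
    class = "group_comparison")
}

# Compact letter display by the sweep (insert-absorb) method: groups
# sorted by decreasing mean; each joins every existing letter-class whose
# members it does not differ from, else founds a new class.
compact_letters <- function(means, sig) {
  groups <- names(means)
  ord <- groups[order(-means)]
  classes <- list()
  for (g in ord) {
    joined <- FALSE
    for (i in seq_along(classes)) {
      if (!any(sig[g, classes[[i]]])) {
        classes[[i]] <- c(classes[[i]], g)
        joined <- TRUE
      }
    }
    if (!joined) classes[[length(classes) + 1L]] <- g
  }
  out <- stats::setNames(character(length(groups)), groups)
  for (i in seq_along(classes)) {
    for (g in classes[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}
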