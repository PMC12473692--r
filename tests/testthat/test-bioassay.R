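test_that("Abbott correction matches direct arithmetic", {
  expect_equal(abbott_correction(0.57, 0), 57)
  expect_equal(abbott_correction(0.5, 0.2), 37.5)
  expect_equal(abbott_correction(0.3, 0.3), 0)
  expect_warning(neg <- abbott_correction(0.1, 0.2), "negative")
  expect_lt(neg, 0)
  expect_error(abbott_correction(0.5, 1), "100%")
})

test_that("Abbott correction is monotone in both arguments", {
  p_treat <- seq(0.05, 0.95, by = 0.1)
  for (pc in c(0, 0.1, 0.3)) {
    vals <- suppressWarnings(abbott_correction(p_treat, pc))
    expect_true(all(diff(vals) > 0))
  }
  for (pt in c(0.3, 0.6, 0.9)) {
    vals <- vapply(c(0, 0.05, 0.1, 0.2), function(pc)
      abbott_correction(pt, pc), numeric(1))
    expect_true(all(diff(vals) < 0))
  }
})

test_that("time-mortality fit recovers noiseless logistic curves", {
  days <- 1:14
  for (truth in list(c(K = 58.781, a = 3.142, b = 0.560),
                     c(K = 100, a = 0, b = 1))) {
    y <- truth[["K"]] / (1 + exp(truth[["a"]] - truth[["b"]] * days))
    fit <- fit_time_mortality(days, y)
    expect_equal(fit$K, truth[["K"]], tolerance = 1e-6)
    expect_equal(fit$a, truth[["a"]], tolerance = 1e-6)
    expect_equal(fit$b, truth[["b"]], tolerance = 1e-6)
    expect_gt(fit$r2, 0.999999)
    # lt50 of the fit equals the coefficient-implied closed form
    lt_fit <- lt50(fit)$lt50
    lt_true <- (truth[["a"]] - log(truth[["K"]] / 50 - 1)) / truth[["b"]]
    expect_equal(lt_fit, lt_true, tolerance = 1e-5)
  }
})

test_that("degenerate time series are rejected with diagnostics", {
  expect_error(fit_time_mortality(1:6, rep(0, 6)), "flat series")
  expect_error(fit_time_mortality(1:3, c(0, 10, 20)), "length")
  expect_error(fit_time_mortality(1:5, c(30, 20, 10, 5, 0)),
               "non-decreasing")
})

test_that("lt50 is undefined exactly when the asymptote is at most 50%", {
  low <- time_mortality_fit(K = 49.349, a = 3.677, b = 0.719)
  res <- lt50(low)
  expect_true(is.na(res$lt50))
  expect_equal(res$reason, "asymptote <= 50%")
  ok <- time_mortality_fit(K = 50.001, a = 3, b = 0.5)
  expect_false(is.na(lt50(ok)$lt50))
})

test_that("probit fit recovers a symmetric LC50 exactly", {
  conc <- 10^(4:8)
  n <- rep(100L, 5)
  dead <- c(2L, 16L, 50L, 84L, 98L)  # symmetric around 1e6
  fit <- fit_dose_response(conc, n, dead)
  expect_true(fit$valid)
  expect_equal(log10(fit$lc50), 6, tolerance = 1e-6)
  expect_true(fit$lc50_ci[1] < fit$lc50 & fit$lc50 < fit$lc50_ci[2])
})

test_that("LC50 is equivariant under rescaling all doses", {
  conc <- 10^(4:8)
  dead <- c(5L, 20L, 55L, 80L, 95L)
  f1 <- fit_dose_response(conc, rep(100L, 5), dead)
  f10 <- fit_dose_response(conc * 10, rep(100L, 5), dead)
  expect_equal(f10$lc50, 10 * f1$lc50, tolerance = 1e-8)
  expect_equal(f10$slope, f1$slope, tolerance = 1e-8)
})

test_that("separation and too-few doses raise errors", {
  expect_error(fit_dose_response(10^(4:8), rep(10L, 5), rep(0L, 5)),
               "separation")
  expect_error(fit_dose_response(10^(4:8), rep(10L, 5), rep(10L, 5)),
               "separation")
  expect_error(fit_dose_response(c(1e4, 1e5), c(10L, 10L), c(1L, 9L)),
               ">= 3 concentrations")
})

test_that("colonization rate is a plain percentage", {
  expect_equal(colonization_rate(3, 6), 50)
  expect_equal(colonization_rate(0, 6), 0)
  expect_equal(colonization_rate(45, 60), 75)
  expect_error(colonization_rate(1, 0), "> 0")
})

test_that("group comparison matches brute-force sums of squares", {
  vals <- c(12, 15, 14, 22, 25, 23, 31, 35, 33)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- compare_groups(vals, grp, transform = FALSE)
  # brute-force one-way ANOVA F
  gm <- tapply(vals, grp, mean)
  ssb <- sum(3 * (gm - mean(vals))^2)
  ssw <- sum((vals - gm[grp])^2)
  f_direct <- (ssb / 2) / (ssw / 6)
  expect_equal(res$anova$F, f_direct, tolerance = 1e-10)
  expect_equal(res$anova$df1, 2)
  expect_equal(res$anova$df2, 6)
  # clearly separated groups earn distinct letters, ordered by mean
  expect_equal(unname(res$letters[c("c", "b", "a")]), c("a", "b", "c"))
})

test_that("identical groups share a letter with F near zero", {
  vals <- c(10, 12, 11, 10, 12, 11)
  grp <- rep(c("g1", "g2"), each = 3)
  res <- compare_groups(vals, grp, transform = FALSE)
  expect_equal(res$anova$F, 0, tolerance = 1e-12)
  expect_gt(res$anova$p, 0.99)
  expect_equal(unname(res$letters), c("a", "a"))
})

test_that("letters are invariant under group relabeling", {
  set.seed(8)
  vals <- c(rnorm(4, 20), rnorm(4, 50), rnorm(4, 52))
  grp1 <- rep(c("x", "y", "z"), each = 4)
  grp2 <- rep(c("z", "x", "y"), each = 4)  # same partition, new names
  r1 <- compare_groups(vals, grp1)
  r2 <- compare_groups(vals, grp2)
  expect_equal(unname(r1$letters[c("x", "y", "z")]),
               unname(r2$letters[c("z", "x", "y")]))
})

test_that("arcsine transform handles the 0% and 100% endpoints", {
  vals <- c(0, 0, 100, 100, 50, 52)
  grp <- rep(c("lo", "hi", "mid"), each = 2)
  res <- compare_groups(vals, grp, transform = TRUE)
  expect_true(is.finite(res$anova$F))
  expect_equal(sort(unique(unname(res$means))),
               c(0, 51, 100))
})
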