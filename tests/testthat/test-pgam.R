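test_that("a constant response collapses to an intercept-only fit", {
  set.seed(1)
  dat <- data.frame(pos = rep(12L, 120), x = runif(120), u = rnorm(120))
  fit <- pgam(cbind(pos, 24 - pos) ~ s(x) + s(u), data = dat)
  sm <- summary(fit)
  expect_true(all(sm$smooth_table$edf_nonlinear < 0.1))
  expect_equal(unname(coef(fit)[1]), qlogis(0.5), tolerance = 1e-6)
  expect_true(all(abs(fitted(fit) - 0.5) < 1e-6))
})

test_that("a simulated SIC effect is recovered with calibrated intervals", {
  set.seed(7)
  n <- 400
  sic <- runif(n)
  pos <- rbinom(n, 24, plogis(-1 + 2 * sic))
  dat <- data.frame(pos = pos, sic = sic)
  fit <- pgam(cbind(pos, 24 - pos) ~ s(sic), data = dat)
  grid <- seq(0.1, 0.9, length.out = 50)
  pr <- predict(fit, newdata = data.frame(sic = grid), se.fit = TRUE)
  expect_true(all(diff(pr$fit) > 0))           # monotone increasing
  truth <- -1 + 2 * grid
  covered <- truth >= pr$fit - 1.96 * pr$se.fit &
             truth <= pr$fit + 1.96 * pr$se.fit
  expect_gte(mean(covered), 0.9)
  expect_gt(fit$dispersion, 0.8); expect_lt(fit$dispersion, 1.2)
})

test_that("dispersion is near one for binomial data", {
  set.seed(99)
  n <- 400
  x <- runif(n)
  pos <- rbinom(n, 24, plogis(0.5 * sin(2 * pi * x)))
  fit <- pgam(cbind(pos, 24 - pos) ~ s(x), data = data.frame(pos, x))
  expect_gt(fit$dispersion, 0.8); expect_lt(fit$dispersion, 1.2)
})

test_that("partial effects are centered at the covariate mean", {
  set.seed(5)
  n <- 300
  x <- runif(n)
  pos <- rbinom(n, 24, plogis(sin(2 * pi * x)))
  fit <- pgam(cbind(pos, 24 - pos) ~ s(x), data = data.frame(pos, x))
  ef <- spline_effect(fit, "x", grid = mean(x))
  expect_lt(abs(ef$effect), 1e-6)
  ## intervals contain the estimated curve
  ef2 <- spline_effect(fit, "x")
  expect_true(all(ef2$lo <= ef2$effect & ef2$effect <= ef2$hi))
  expect_error(spline_effect(fit, "nope"), "no smooth term")
})

test_that("confidence bands tighten as the sample doubles", {
  width <- function(n, seed) {
    set.seed(seed)
    x <- runif(n)
    pos <- rbinom(n, 24, plogis(sin(2 * pi * x)))
    fit <- pgam(cbind(pos, 24 - pos) ~ s(x), data = data.frame(pos, x))
    ef <- spline_effect(fit, "x", grid = seq(0.2, 0.8, length.out = 25))
    mean(ef$hi - ef$lo)
  }
  expect_lt(width(800, 42), width(200, 42))
})

test_that("a linear truth stays within the interval of the fitted curve", {
  set.seed(19)
  n <- 500
  x <- runif(n)
  pos <- rbinom(n, 24, plogis(-0.5 + 1.5 * x))
  fit <- pgam(cbind(pos, 24 - pos) ~ s(x), data = data.frame(pos, x))
  ef <- spline_effect(fit, "x", grid = seq(min(x) + 0.05, max(x) - 0.05,
                                           length.out = 40))
  ## deviation of the fit from its own best linear approximation is
  ## smaller than the interval half-width almost everywhere
  lfit <- lm(effect ~ x, data = ef)
  dev <- abs(resid(lfit))
  halfw <- (ef$hi - ef$lo) / 2
  expect_gte(mean(dev <= pmax(halfw, 1e-8)), 0.95)
})

test_that("fits are invariant to affine rescaling of covariates", {
  set.seed(8)
  n <- 250
  x <- runif(n); u <- rnorm(n)
  pos <- rbinom(n, 24, plogis(sin(2 * pi * x) - 0.3 * u))
  d1 <- data.frame(pos = pos, x = x, u = u)
  d2 <- data.frame(pos = pos, x = 1000 * x - 3, u = u / 50 + 2)
  f1 <- pgam(cbind(pos, 24 - pos) ~ s(x) + s(u), data = d1)
  f2 <- pgam(cbind(pos, 24 - pos) ~ s(x) + s(u), data = d2)
  expect_equal(fitted(f1), fitted(f2), tolerance = 1e-6)
})

test_that("the fit tracks an established GAM implementation", {
  set.seed(11)
  n <- 400
  x1 <- runif(n); x2 <- runif(n)
  pos <- rbinom(n, 24, plogis(sin(2 * pi * x1) + 0.5 * x2))
  dat <- data.frame(pos = pos, x1 = x1, x2 = x2)
  fit <- pgam(cbind(pos, 24 - pos) ~ s(x1) + s(x2), data = dat)
  ref <- mgcv::gam(cbind(pos, 24 - pos) ~ s(x1) + s(x2),
                   family = quasibinomial(), data = dat, method = "REML")
  expect_gt(cor(fitted(fit), fitted(ref)), 0.999)
  expect_lt(abs(fit$dispersion - ref$scale), 0.1)
})

test_that("proportion + trials interface matches the two-column one", {
  set.seed(2)
  n <- 150
  x <- runif(n)
  rec <- sample(20:24, n, replace = TRUE)
  pos <- rbinom(n, rec, plogis(1.2 * x))
  d <- data.frame(prop = pos / rec, pos = pos, rec = rec, x = x)
  f1 <- pgam(prop ~ s(x), data = d, weights = rec)
  f2 <- pgam(cbind(pos, rec - pos) ~ s(x), data = d)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("invalid responses and weights are rejected", {
  d <- data.frame(y = c(0.5, 1.2, 0.3), x = 1:3 + 0.5)
  expect_error(pgam(y ~ s(x), data = d, weights = rep(24, 3)), "\\[0, 1\\]")
  d2 <- data.frame(y = c(0.5, 0.2, 0.3), x = 1:3)
  expect_error(pgam(y ~ s(x), data = d2, weights = rep(0.5, 3)), ">= 1")
})

test_that("backward selection drops a pure-noise covariate", {
  set.seed(4)
  n <- 300
  x <- runif(n); junk <- rnorm(n)
  pos <- rbinom(n, 24, plogis(-1 + 2 * x))
  dat <- data.frame(pos = pos, fail = 24 - pos, x = x, junk = junk)
  sel <- pgam_select(cbind(pos, fail) ~ s(x) + s(junk), data = dat)
  labs <- vapply(sel$smooths, `[[`, "", "label")
  expect_true("x" %in% labs)
  expect_false("junk" %in% labs)
})

test_that("residual types are consistent with the fitted quasi-binomial", {
  set.seed(6)
  n <- 200
  x <- runif(n)
  pos <- rbinom(n, 24, plogis(x))
  fit <- pgam(cbind(pos, 24 - pos) ~ s(x), data = data.frame(pos, x))
  rp <- residuals(fit, "pearson")
  expect_equal(sum(rp^2) / (fit$n - fit$edf_total), fit$dispersion,
               tolerance = 1e-8)
  rd <- residuals(fit, "deviance")
  expect_equal(sum(rd^2), fit$deviance, tolerance = 1e-6)
  expect_equal(residuals(fit, "response"), fit$y - fitted(fit))
})
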