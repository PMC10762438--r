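## Quasi-binomial penalized-spline additive models, from first
## principles: low-rank thin-plate-type spline bases, penalized IRLS with
## a logit link, and smoothing parameters chosen by an outer REML-type
## criterion on the converged working model.

#' Smooth term marker
#'
#' Marks a covariate in a [pgam()] formula as a penalized thin-plate-type
#' spline, e.g. `y ~ s(sic) + s(sst, k = 8)`.
#'
#' @param x covariate.
#' @param k basis dimension (default 10): one unpenalized linear column
#'   plus `k - 2` penalized columns.
#' @return the evaluated covariate with basis metadata attached.
#' @export
s <- function(x, k = 10) {
  structure(list(x = x, k = k, label = deparse(substitute(x))),
            class = "pgam_smooth_spec")
}

## Low-rank 1-D thin-plate spline basis (radial basis |x - x_k|^3 / 12,
## null space {1, x}): eigen-truncation of the penalty-defining radial
## matrix to rank k, absorption of the null-space orthogonality
## constraint, then reparameterization so the wiggliness penalty is the
## identity on the retained columns.
tprs_setup <- function(x, k = 10) {
  ux <- sort(unique(x))
  m <- min(length(ux), max(20, 2 * k))
  xk <- if (length(ux) <= m) ux else
    unique(quantile(ux, seq(0, 1, length.out = m), names = FALSE, type = 7))
  m <- length(xk)
  if (k > m) k <- m
  if (k < 4) stopf("basis dimension too small (k = %d after deduplication)", k)
  E <- abs(outer(xk, xk, "-"))^3 / 12
  eg <- eigen(E, symmetric = TRUE)
  sel <- order(abs(eg$values), decreasing = TRUE)[seq_len(k)]
  Uk <- eg$vectors[, sel, drop = FALSE]
  Dk <- eg$values[sel]
  Tmat <- cbind(1, xk)
  ## columns spanning the null space of t(Tmat) %*% Uk (the constraint)
  Ct <- crossprod(Uk, Tmat)                     # k x 2
  qc <- qr(Ct)
  Z <- qr.Q(qc, complete = TRUE)[, (qc$rank + 1):k, drop = FALSE]
  S <- crossprod(Z, Dk * Z)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  pos <- es$values > max(es$values) * 1e-9
  M <- Uk %*% Z %*% es$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(es$values[pos]), sum(pos))
  list(knots = xk, M = M, q = sum(pos))
}

tprs_eval <- function(basis, x) {
  (abs(outer(x, basis$knots, "-"))^3 / 12) %*% basis$M
}

#' Fit a quasi-binomial penalized-spline additive model
#'
#' Models a daily presence proportion (successes out of a known number of
#' trials, e.g. positive hours out of recorded hours) as a sum of smooth
#' functions of covariates on the logit scale. Each `s()` term gets a
#' low-rank thin-plate-type spline basis whose wiggliness is penalized;
#' coefficients are estimated by penalized iteratively reweighted least
#' squares and the smoothing parameters by minimizing a REML-type
#' criterion of the converged working model (outer optimization over log
#' smoothing parameters). The dispersion is estimated from Pearson
#' residuals, so over- or under-dispersed binomial responses are handled
#' quasi-likelihood style. Covariates are standardized internally, making
#' the fit invariant to affine rescaling of predictors.
#'
#' @param formula e.g. `prop ~ s(sic) + s(sst, k = 8) + month`; the
#'   response is a proportion in `[0, 1]` (supply `weights` = trials) or
#'   a two-column matrix `cbind(successes, failures)`. Non-`s()` terms
#'   enter as unpenalized linear terms.
#' @param data data.frame holding the variables. Rows with any missing
#'   value are dropped listwise (a message reports how many).
#' @param weights binomial trial counts per row (default 1).
#' @param control list: `maxit` (IRLS iterations, 50), `tol` (deviance
#'   convergence, 1e-8), `rho_bound` (|log lambda| box, 18),
#'   `optim_maxit` (outer iterations, 200).
#' @return object of class `pgam`; see [summary.pgam()],
#'   [predict.pgam()], [spline_effect()], [plot.pgam()].
#' @export
pgam <- function(formula, data, weights = NULL, control = list()) {
  ctrl <- modifyList(list(maxit = 50, tol = 1e-8, rho_bound = 18,
                          optim_maxit = 200), control)
  env <- environment(formula)
  tf <- terms(formula)
  labels <- attr(tf, "term.labels")
  is_sm <- grepl("^s\\(", labels)

  resp <- eval(formula[[2]], data, env)
  w <- eval(substitute(weights), data, parent.frame())
  if (is.matrix(resp) && ncol(resp) == 2) {
    w <- resp[, 1] + resp[, 2]
    y <- ifelse(w > 0, resp[, 1] / w, 0)
  } else {
    y <- as.numeric(resp)
    if (is.null(w)) w <- rep(1, length(y))
  }
  if (any(y < -1e-12 | y > 1 + 1e-12, na.rm = TRUE))
    stopf("response proportions must lie in [0, 1]")
  if (any(w < 1, na.rm = TRUE)) stopf("trial weights must be >= 1")

  vals <- lapply(labels, function(lb) eval(parse(text = lb)[[1]], data, env))
  xs <- lapply(seq_along(labels), function(i) {
    if (is_sm[i]) vals[[i]]$x else as.numeric(vals[[i]])
  })
  ok <- complete.cases(do.call(cbind, c(list(y, w), xs)))
  if (any(!ok)) message(sprintf("dropped %d row(s) with missing values",
                                sum(!ok)))
  y <- y[ok]; w <- w[ok]
  xs <- lapply(xs, `[`, ok)
  n <- length(y)

  ## design: intercept | linear terms | per smooth: linear + penalized
  X <- matrix(1, n, 1)
  colnames(X) <- "(Intercept)"
  pen_group <- integer(0)         # 0 = unpenalized, j = smooth j
  smooths <- list()
  par_scale <- list()
  sm_id <- 0L
  for (i in seq_along(labels)) {
    xi <- xs[[i]]
    mu_x <- mean(xi); sd_x <- sd(xi)
    if (sd_x == 0) stopf("term '%s' is constant", labels[i])
    xstd <- (xi - mu_x) / sd_x
    if (!is_sm[i]) {
      X <- cbind(X, xstd)
      colnames(X)[ncol(X)] <- labels[i]
      pen_group <- c(pen_group, 0L)
      par_scale[[labels[i]]] <- c(mu_x, sd_x)
      next
    }
    sm_id <- sm_id + 1L
    spec <- vals[[i]]
    basis <- tprs_setup(xstd, spec$k)
    B <- cbind(xstd, tprs_eval(basis, xstd))
    centers <- colMeans(B)
    B <- sweep(B, 2, centers)
    idx <- ncol(X) + seq_len(ncol(B))
    X <- cbind(X, B)
    colnames(X)[idx] <- paste0("s(", spec$label, ").", seq_along(idx))
    pen_group <- c(pen_group, 0L, rep(sm_id, basis$q))
    smooths[[sm_id]] <- list(label = spec$label, term = labels[i],
                             expr = parse(text = spec$label)[[1]],
                             mean = mu_x, sd = sd_x, basis = basis,
                             centers = centers, idx = idx, q = basis$q,
                             x = xi)
  }
  pen_group <- c(0L, pen_group)   # intercept
  p <- ncol(X)
  nsm <- length(smooths)
  Mp <- sum(pen_group == 0L)

  dev_fun <- function(mu) {
    t1 <- ifelse(y > 0, y * log(y / mu), 0)
    t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)
    2 * sum(w * (t1 + t2))
  }

  fit_irls <- function(lambda, eta = NULL) {
    svec <- numeric(p)
    for (j in seq_len(nsm)) svec[pen_group == j] <- lambda[j]
    if (is.null(eta)) {
      mu <- (w * y + 0.5) / (w + 1)
      eta <- qlogis(mu)
    }
    dev_old <- Inf; beta <- NULL; ch <- NULL; Wv <- NULL; z <- NULL
    conv <- FALSE
    for (it in seq_len(ctrl$maxit)) {
      mu <- plogis(eta)
      mu <- pmin(pmax(mu, 1e-8), 1 - 1e-8)
      Wv <- w * mu * (1 - mu)
      z <- eta + (y - mu) / (mu * (1 - mu))
      H <- crossprod(X, X * Wv) + diag(svec + 1e-10, p)
      ch <- tryCatch(chol(H), error = function(e) NULL)
      if (is.null(ch)) stopf("singular penalized system in IRLS")
      beta <- backsolve(ch, forwardsolve(t(ch), crossprod(X, Wv * z)))
      eta <- drop(X %*% beta)
      dev <- dev_fun(pmin(pmax(plogis(eta), 1e-8), 1 - 1e-8))
      if (abs(dev - dev_old) < ctrl$tol * (abs(dev) + 0.1)) {
        conv <- TRUE; dev_old <- dev; break
      }
      dev_old <- dev
    }
    mu <- pmin(pmax(plogis(eta), 1e-8), 1 - 1e-8)
    list(beta = drop(beta), eta = eta, mu = mu, Wv = Wv, z = z, ch = ch,
         svec = svec, dev = dev_old, converged = conv, iters = it)
  }

  reml_score <- function(rho) {
    pen_rho <- sum(pmax(abs(rho) - ctrl$rho_bound, 0)^2)
    rho <- pmin(pmax(rho, -ctrl$rho_bound), ctrl$rho_bound)
    f <- fit_irls(exp(rho))
    rss <- sum(f$Wv * (f$z - f$eta)^2)
    pen <- sum(f$svec * f$beta^2)
    Dp <- rss + pen
    phi <- max(Dp / max(n - 2 * Mp, 1), 1e-10)
    ldetH <- 2 * sum(log(diag(f$ch)))
    ldetS <- sum(vapply(seq_len(nsm), function(j)
      sum(pen_group == j) * rho[j], numeric(1)))
    Dp / (2 * phi) + (ldetH - ldetS) / 2 - (Mp / 2) * log(phi) +
      ((n - Mp) / 2) * log(2 * pi * phi) + 100 * pen_rho
  }

  if (nsm > 0) {
    ## data-driven start: penalty on the scale of the information matrix
    mu0 <- (w * y + 0.5) / (w + 1)
    W0 <- w * mu0 * (1 - mu0)
    xtwx_d <- colSums(X^2 * W0)
    rho0 <- vapply(seq_len(nsm), function(j)
      log(mean(xtwx_d[pen_group == j]) + 1), numeric(1))
    if (nsm == 1) {
      opt <- optimize(function(r) reml_score(r),
                      interval = c(-ctrl$rho_bound, ctrl$rho_bound),
                      tol = 1e-6)
      rho <- opt$minimum
      reml <- opt$objective
    } else {
      opt <- optim(rho0, reml_score, method = "Nelder-Mead",
                   control = list(maxit = ctrl$optim_maxit, reltol = 1e-7))
      rho <- pmin(pmax(opt$par, -ctrl$rho_bound), ctrl$rho_bound)
      reml <- opt$value
    }
    lambda <- exp(rho)
  } else {
    lambda <- numeric(0); rho <- numeric(0)
    reml <- NA_real_
  }

  final <- fit_irls(lambda)
  if (!final$converged)
    stopf("IRLS failed to converge in %d iterations (deviance %.4g)",
          ctrl$maxit, final$dev)
  if (any(abs(final$eta) > 15))
    warnf("very large linear predictor: possible separation")

  XtWX <- crossprod(X, X * final$Wv)
  Hinv <- chol2inv(final$ch)
  Amat <- Hinv %*% XtWX
  edf <- diag(Amat)
  edf_total <- sum(edf)
  pearson <- sum(w * (y - final$mu)^2 / (final$mu * (1 - final$mu)))
  dispersion <- pearson / (n - edf_total)
  Vb <- Hinv * dispersion
  mu_null <- sum(w * y) / sum(w)
  null_dev <- dev_fun(rep(pmin(pmax(mu_null, 1e-8), 1 - 1e-8), n))

  structure(list(
    coefficients = setNames(final$beta, colnames(X)),
    Vb = Vb, edf = setNames(edf, colnames(X)), edf_total = edf_total,
    lambda = lambda, rho = rho, reml = reml,
    dispersion = dispersion, deviance = final$dev, null_deviance = null_dev,
    fitted.values = final$mu, linear.predictors = final$eta,
    y = y, prior_weights = w, X = X, pen_group = pen_group,
    smooths = smooths, parametric = labels[!is_sm], par_scale = par_scale,
    formula = formula, terms = tf, n = n, iters = final$iters,
    call = match.call()
  ), class = "pgam")
}

## design matrix for new covariate values (one smooth term)
smooth_design <- function(sm, xnew) {
  xstd <- (xnew - sm$mean) / sm$sd
  B <- cbind(xstd, tprs_eval(sm$basis, xstd))
  sweep(B, 2, sm$centers)
}

#' @export
print.pgam <- function(x, ...) {
  cat("Quasi-binomial penalized-spline additive model (logit link)\n")
  cat(deparse(x$formula), "\n")
  if (length(x$smooths)) {
    ed <- vapply(x$smooths, function(s) sum(x$edf[s$idx]), numeric(1))
    cat(sprintf("Smooth terms: %s\n",
                paste(sprintf("s(%s) edf=%.2f",
                              vapply(x$smooths, `[[`, "", "label"), ed),
                      collapse = ", ")))
  }
  cat(sprintf("n = %d, dispersion = %.3f, deviance explained = %.1f%%\n",
              x$n, x$dispersion,
              100 * (1 - x$deviance / x$null_deviance)))
  invisible(x)
}

#' Summary of a pgam fit
#'
#' Per-smooth effective degrees of freedom and approximate Wald tests
#' (pseudo-F using the quasi-binomial dispersion), parametric
#' coefficients, dispersion and deviance explained. The nonlinear edf of
#' a smooth excludes its unpenalized linear column, so a smooth shrunk to
#' a straight line reports nonlinear edf near 0.
#'
#' @param object a `pgam`.
#' @param ... unused.
#' @return object of class `summary.pgam`.
#' @export
summary.pgam <- function(object, ...) {
  sm_tab <- NULL
  if (length(object$smooths)) {
    rows <- lapply(object$smooths, function(s) {
      idx <- s$idx
      b <- object$coefficients[idx]
      V <- object$Vb[idx, idx, drop = FALSE]
      ev <- eigen(V, symmetric = TRUE)
      r <- sum(ev$values > max(ev$values) * 1e-7)
      Tstat <- sum((crossprod(ev$vectors[, seq_len(r), drop = FALSE], b))^2 /
                     ev$values[seq_len(r)])
      Fst <- Tstat / r
      pv <- pf(Fst, r, object$n - object$edf_total, lower.tail = FALSE)
      data.frame(term = sprintf("s(%s)", s$label),
                 edf = sum(object$edf[idx]),
                 edf_nonlinear = sum(object$edf[idx[-1]]),
                 F = Fst, p_value = pv)
    })
    sm_tab <- do.call(rbind, rows)
  }
  par_idx <- which(object$pen_group == 0L &
                     !(seq_along(object$coefficients) %in%
                         unlist(lapply(object$smooths, function(s) s$idx))))
  pt <- data.frame(
    estimate = object$coefficients[par_idx],
    se = sqrt(diag(object$Vb)[par_idx])
  )
  pt$t <- pt$estimate / pt$se
  pt$p_value <- 2 * pt(abs(pt$t), object$n - object$edf_total,
                       lower.tail = FALSE)
  structure(list(smooth_table = sm_tab, parametric_table = pt,
                 dispersion = object$dispersion,
                 dev_explained = 1 - object$deviance / object$null_deviance,
                 n = object$n, formula = object$formula),
            class = "summary.pgam")
}

#' @export
print.summary.pgam <- function(x, ...) {
  cat(deparse(x$formula), "\n\nParametric coefficients:\n")
  print(round(x$parametric_table, 4))
  if (!is.null(x$smooth_table)) {
    cat("\nApproximate significance of smooth terms:\n")
    st <- x$smooth_table
    st[, -1] <- round(st[, -1], 4)
    print(st, row.names = FALSE)
  }
  cat(sprintf("\nDispersion = %.3f, deviance explained = %.1f%%, n = %d\n",
              x$dispersion, 100 * x$dev_explained, x$n))
  invisible(x)
}

#' @export
coef.pgam <- function(object, ...) object$coefficients

#' @export
fitted.pgam <- function(object, ...) object$fitted.values

#' @export
residuals.pgam <- function(object,
                           type = c("deviance", "pearson", "working",
                                    "response"), ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted.values; w <- object$prior_weights
  switch(type,
    response = y - mu,
    working = (y - mu) / (mu * (1 - mu)),
    pearson = (y - mu) * sqrt(w / (mu * (1 - mu))),
    deviance = {
      t1 <- ifelse(y > 0, y * log(y / mu), 0)
      t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)
      sign(y - mu) * sqrt(pmax(2 * w * (t1 + t2), 0))
    })
}

#' Predict from a pgam fit
#'
#' @param object a `pgam`.
#' @param newdata data.frame of covariates (default: training data).
#' @param type `"link"` (logit scale) or `"response"` (probability).
#' @param se.fit also return standard errors (link scale, transformed by
#'   the delta method for `type = "response"`).
#' @param ... unused.
#' @return vector of predictions, or `list(fit, se.fit)`.
#' @export
predict.pgam <- function(object, newdata = NULL,
                         type = c("link", "response"), se.fit = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    Xp <- object$X
  } else {
    env <- environment(object$formula)
    n_new <- nrow(newdata)
    Xp <- matrix(1, n_new, 1)
    sm_terms <- vapply(object$smooths, `[[`, "", "term")
    for (lb in object$parametric) {
      xi <- as.numeric(eval(parse(text = lb)[[1]], newdata, env))
      ## parametric columns were standardized with training moments
      tr <- object$par_scale[[lb]]
      Xp <- cbind(Xp, (xi - tr[1]) / tr[2])
    }
    for (s in object$smooths) {
      xi <- as.numeric(eval(s$expr, newdata, env))
      Xp <- cbind(Xp, smooth_design(s, xi))
    }
  }
  fit <- drop(Xp %*% object$coefficients)
  if (se.fit) {
    se <- sqrt(pmax(rowSums((Xp %*% object$Vb) * Xp), 0))
    if (type == "response") {
      mu <- plogis(fit)
      return(list(fit = mu, se.fit = se * mu * (1 - mu)))
    }
    return(list(fit = fit, se.fit = se))
  }
  if (type == "response") plogis(fit) else fit
}

#' Centered partial effect of one smooth
#'
#' The fitted spline of one covariate on the link (logit) scale, centered
#' so the effect at the observed covariate mean is exactly zero, with
#' pointwise 95% confidence intervals from the Bayesian posterior
#' covariance of the coefficients (interval of the contrast
#' `f(x) - f(mean(x))`, hence zero-width at the mean).
#'
#' @param fit a `pgam`.
#' @param term covariate name as given inside `s()`.
#' @param grid evaluation points (default: 100 points over the observed
#'   range).
#' @param level confidence level.
#' @return data.frame: `x`, `effect`, `lo`, `hi`.
#' @export
spline_effect <- function(fit, term, grid = NULL, level = 0.95) {
  stopifnot(inherits(fit, "pgam"))
  labs <- vapply(fit$smooths, `[[`, "", "label")
  j <- match(term, labs)
  if (is.na(j)) stopf("no smooth term s(%s) in the fit", term)
  sm <- fit$smooths[[j]]
  if (is.null(grid))
    grid <- seq(min(sm$x), max(sm$x), length.out = 100)
  B <- smooth_design(sm, grid)
  B0 <- smooth_design(sm, mean(sm$x))
  C <- sweep(B, 2, drop(B0))
  b <- fit$coefficients[sm$idx]
  V <- fit$Vb[sm$idx, sm$idx, drop = FALSE]
  eff <- drop(C %*% b)
  se <- sqrt(pmax(rowSums((C %*% V) * C), 0))
  zq <- qnorm(1 - (1 - level) / 2)
  data.frame(x = grid, effect = eff, lo = eff - zq * se, hi = eff + zq * se)
}

#' Spline panel plot
#'
#' One panel per smooth term: centered effect with shaded confidence
#' band and a covariate rug.
#'
#' @param x a `pgam`.
#' @param level confidence level.
#' @param ... passed to `plot`.
#' @export
plot.pgam <- function(x, level = 0.95, ...) {
  nsm <- length(x$smooths)
  if (!nsm) stopf("no smooth terms to plot")
  op <- par(mfrow = c(ceiling(nsm / 2), min(nsm, 2)),
            mar = c(4, 4, 1, 1))
  on.exit(par(op))
  for (s in x$smooths) {
    ef <- spline_effect(x, s$label, level = level)
    plot(ef$x, ef$effect, type = "n", ylim = range(ef$lo, ef$hi),
         xlab = s$label, ylab = sprintf("s(%s)", s$label), ...)
    polygon(c(ef$x, rev(ef$x)), c(ef$lo, rev(ef$hi)),
            col = adjustcolor("steelblue", 0.3), border = NA)
    lines(ef$x, ef$effect, lwd = 2)
    rug(s$x)
  }
  invisible(x)
}

#' Quasi-AIC of a pgam fit
#'
#' `deviance / dispersion + 2 * (total edf)`, the AIC-style score used
#' for term selection under quasi-likelihood. The dispersion should come
#' from the richest model under comparison.
#'
#' @param fit a `pgam`.
#' @param dispersion dispersion to penalize with (default: the fit's
#'   own).
#' @return numeric QAIC.
#' @export
pgam_qaic <- function(fit, dispersion = fit$dispersion) {
  fit$deviance / dispersion + 2 * fit$edf_total
}

#' Backward term selection for pgam
#'
#' Starting from the full model, repeatedly drops the smooth term whose
#' removal most improves the quasi-AIC (computed with the full model's
#' dispersion), stopping when no drop improves it: only predictors that
#' improve the fit are retained.
#'
#' @param formula full-model formula (smooth terms only are candidates
#'   for dropping).
#' @param data,weights as in [pgam()].
#' @return the selected `pgam` fit, with a `selection` attribute logging
#'   the path.
#' @export
pgam_select <- function(formula, data, weights = NULL) {
  w <- eval(substitute(weights), data, parent.frame())
  resp <- deparse(formula[[2]])
  labels <- attr(terms(formula), "term.labels")
  fit_with <- function(labs) {
    f <- reformulate(labs, response = resp)
    environment(f) <- environment(formula)
    pgam(f, data, weights = w)
  }
  current <- fit_with(labels)
  phi <- current$dispersion
  log <- data.frame(step = "full", qaic = pgam_qaic(current, phi))
  repeat {
    sm_labels <- labels[grepl("^s\\(", labels)]
    if (length(labels) < 2 || !length(sm_labels)) break
    qaics <- vapply(sm_labels, function(lb) {
      pgam_qaic(fit_with(setdiff(labels, lb)), phi)
    }, numeric(1))
    best <- which.min(qaics)
    if (qaics[best] >= pgam_qaic(current, phi) - 1e-8) break
    labels <- setdiff(labels, sm_labels[best])
    current <- fit_with(labels)
    log <- rbind(log, data.frame(step = paste("dropped", sm_labels[best]),
                                 qaic = qaics[best]))
  }
  attr(current, "selection") <- log
  current
}
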