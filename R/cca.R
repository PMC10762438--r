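## Constrained correspondence analysis, implemented from the chi-square
## standardization + weighted projection + SVD definition.

#' Constrained correspondence analysis
#'
#' Relates a non-negative community matrix (here: days x species daily
#' positive hours) to environmental predictors. The algorithm is the
#' standard one: chi-square residual matrix
#' `Q = D_r^{-1/2} (P - r c') D_c^{-1/2}` with `P` the relative-total
#' matrix and `r`, `c` its margins; weighted (by `r`) least-squares
#' projection of `Q` onto the predictor space; singular value
#' decomposition of the projected matrix. Constrained eigenvalues are the
#' squared singular values; the residual of the projection carries the
#' unconstrained ones, and the two sets sum to the total inertia
#' `sum(Q^2)`.
#'
#' Scores use a species-focused scaling (type 2): species scores
#' `D_c^{-1/2} V diag(d)`, linear-combination (constrained) site scores
#' `D_r^{-1/2} Q_hat V diag(1/d)`, weighted-average site scores
#' `D_r^{-1/2} Q V diag(1/d)`. Biplot arrows are the weighted
#' correlations of the predictors with the constrained site scores.
#'
#' @param Y community matrix (n sites x m species), non-negative, no
#'   all-zero row or column.
#' @param X predictors: numeric data.frame or matrix with n rows.
#' @return object of class `pam_cca` with elements `eig` (constrained
#'   eigenvalues), `eig_resid`, `total_inertia`, `prop_explained`,
#'   `species_scores`, `site_scores` (weighted averages), `site_lc`,
#'   `biplot`.
#' @export
cca_fit <- function(Y, X) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stopf("community matrix must be non-negative")
  rs <- rowSums(Y); cs <- colSums(Y)
  if (any(rs == 0))
    stopf("all-zero row(s): %s",
          paste(head(rownames(Y)[rs == 0] %||% which(rs == 0), 5),
                collapse = ", "))
  if (any(cs == 0))
    stopf("all-zero column(s): %s",
          paste(colnames(Y)[cs == 0] %||% which(cs == 0), collapse = ", "))
  X <- as.matrix(X)
  if (!is.numeric(X)) stopf("predictors must be numeric")
  n <- nrow(Y)
  if (nrow(X) != n) stopf("Y and X must have the same number of rows")
  if (n <= ncol(X)) stopf("need more sites than predictors")

  P <- Y / sum(Y)
  r <- rowSums(P); cc <- colSums(P)
  Qbar <- (P - tcrossprod(r, cc)) / tcrossprod(sqrt(r), sqrt(cc))

  ## weighted projection of Q's rows onto the predictor space
  xm <- colSums(X * r)
  Xc <- sweep(X, 2, xm)
  Xw <- Xc * sqrt(r)
  qrX <- qr(Xw)
  Qhat <- if (qrX$rank == 0) matrix(0, nrow(Qbar), ncol(Qbar)) else
    qr.fitted(qrX, Qbar)
  Qres <- Qbar - Qhat

  tol <- 1e-12
  sv <- svd(Qhat)
  keep <- sv$d^2 > tol * max(sv$d^2, 1)
  d <- sv$d[keep]; U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  svr <- svd(Qres)
  eig_resid <- svr$d[svr$d^2 > tol]^2

  total <- sum(Qbar^2)
  species <- (V %*% diag(d, length(d))) / sqrt(cc)
  site_lc <- (Qhat %*% V %*% diag(1 / d, length(d))) / sqrt(r)
  site_wa <- (Qbar %*% V %*% diag(1 / d, length(d))) / sqrt(r)
  ## weighted correlation of predictors with constrained site scores
  wcor <- function(x, y) {
    xm <- sum(r * x); ym <- sum(r * y)
    sum(r * (x - xm) * (y - ym)) /
      sqrt(sum(r * (x - xm)^2) * sum(r * (y - ym)^2))
  }
  ax <- if (length(d)) paste0("CCA", seq_along(d)) else character(0)
  biplot <- matrix(NA_real_, ncol(X), length(d),
                   dimnames = list(colnames(X) %||% paste0("x", seq_len(ncol(X))),
                                   ax))
  for (j in seq_len(ncol(X)))
    for (k in seq_along(d))
      biplot[j, k] <- wcor(X[, j], site_lc[, k])

  dimnames(species) <- list(colnames(Y), ax)
  dimnames(site_lc) <- list(rownames(Y), ax)
  dimnames(site_wa) <- list(rownames(Y), ax)
  structure(list(eig = stats::setNames(d^2, ax), eig_resid = eig_resid,
                 total_inertia = total,
                 prop_explained = d^2 / total,
                 species_scores = species, site_scores = site_wa,
                 site_lc = site_lc, biplot = biplot,
                 call = match.call()),
            class = "pam_cca")
}

#' @export
print.pam_cca <- function(x, ...) {
  cat("Constrained correspondence analysis\n")
  cat(sprintf("Total inertia: %.4f; constrained: %.4f (%.1f%%)\n",
              x$total_inertia, sum(x$eig),
              100 * sum(x$eig) / x$total_inertia))
  cat("Constrained eigenvalues:\n")
  print(round(x$eig, 4))
  invisible(x)
}

#' @export
summary.pam_cca <- function(object, ...) {
  cat("Eigenvalues and proportion explained:\n")
  print(rbind(eigenvalue = round(object$eig, 4),
              proportion = round(object$prop_explained, 4)))
  cat("\nSpecies scores:\n"); print(round(object$species_scores, 3))
  cat("\nBiplot arrows:\n"); print(round(object$biplot, 3))
  invisible(object)
}

#' CCA biplot
#'
#' Species scores as labels, predictors as arrows, on the first two
#' constrained axes.
#'
#' @param x a `pam_cca`.
#' @param arrow_scale multiplier applied to the arrow coordinates.
#' @param ... passed to `plot`.
#' @export
plot.pam_cca <- function(x, arrow_scale = NULL, ...) {
  if (length(x$eig) < 2) stopf("need at least two constrained axes to plot")
  sp <- x$species_scores[, 1:2]
  if (is.null(arrow_scale))
    arrow_scale <- 0.8 * max(abs(sp)) / max(abs(x$biplot[, 1:2]))
  ar <- x$biplot[, 1:2] * arrow_scale
  lim <- range(c(sp, ar)) * 1.15
  plot(sp, type = "n", xlim = lim, ylim = lim,
       xlab = sprintf("CCA1 (%.1f%%)", 100 * x$prop_explained[1]),
       ylab = sprintf("CCA2 (%.1f%%)", 100 * x$prop_explained[2]), ...)
  abline(h = 0, v = 0, col = "grey80", lty = 3)
  text(sp, labels = rownames(sp), col = "grey20")
  arrows(0, 0, ar[, 1], ar[, 2], length = 0.08, col = "red3")
  text(ar * 1.08, labels = rownames(ar), col = "red3", cex = 0.9)
  invisible(x)
}
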