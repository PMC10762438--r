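## Variance inflation factors, computed from the definition.

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from the ordinary
#' least-squares regression of predictor j on all the others (intercept
#' included). An exactly collinear predictor is reported as `Inf` with a
#' warning. As a reading guide, values near 1 indicate little
#' collinearity, around 5 moderate, above 10 strong.
#'
#' @param predictors data.frame or matrix of numeric predictors
#'   (>= 2 columns, more rows than columns).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(predictors) {
  X <- as.matrix(predictors)
  if (!is.numeric(X)) stopf("predictors must be numeric")
  p <- ncol(X)
  if (p < 2) stopf("need at least 2 predictors")
  if (nrow(X) <= p) stopf("need more observations than predictors")
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X) %||% paste0("x", seq_len(p))
  if (any(is.infinite(out)))
    warnf("exact collinearity: infinite VIF for %s",
          paste(names(out)[is.infinite(out)], collapse = ", "))
  out
}
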