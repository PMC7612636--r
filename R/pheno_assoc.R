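# Observational phenotype modelling: multivariable regression of diastolic
# traits on risk factors, LASSO with stability selection, and collinearity
# diagnostics.

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j) from regressing predictor j on the others.
#' Perfect collinearity is reported as `Inf`.
#'
#' @param X numeric matrix or data frame with at least 2 predictors.
#' @return named numeric vector of VIFs (all >= 1).
#' @export
collinearity_diagnostics <- function(X) {
  X <- as.matrix(as.data.frame(X))
  if (ncol(X) < 2) stop("need at least 2 predictors")
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else max(1, 1 / (1 - r2))
  }, numeric(1))
  stats::setNames(vif, colnames(X))
}

#' Multivariable regression of a diastolic trait on risk factors
#'
#' All continuous variables (trait included) are standardized so
#' coefficients are in standard-deviation units; binary predictors (0/1)
#' are left as indicators. P-values are Benjamini-Hochberg adjusted across
#' the predictors, and variance inflation factors are reported.
#'
#' @param tt trait table data frame (a `bsa` column is derived from weight
#'   and height via [du_bois_bsa()] when absent).
#' @param trait trait column name.
#' @param predictors predictor column names.
#' @param conf_level confidence level of the reported intervals.
#' @return a `regression_report` data frame: predictor, beta, ci_lower,
#'   ci_upper, p_value, p_adj, vif; attributes `r_squared` and `n`.
#' @export
multivariable_model <- function(tt, trait,
                                predictors = c("age", "sex", "bsa", "sbp",
                                               "pulse", "diabetes"),
                                conf_level = 0.95) {
  if ("bsa" %in% predictors && is.null(tt$bsa))
    tt$bsa <- du_bois_bsa(tt$weight, tt$height)
  X <- as.matrix(tt[, predictors, drop = FALSE])
  dup <- which(duplicated(t(X)))
  if (length(dup)) {
    partner <- which(vapply(seq_len(dup[1] - 1), function(j)
      isTRUE(all.equal(X[, j], X[, dup[1]], check.attributes = FALSE)),
      logical(1)))[1]
    stop("exactly collinear predictors: ",
         paste(predictors[c(partner, dup[1])], collapse = " and "))
  }
  is_binary <- apply(X, 2, function(v) all(v %in% c(0, 1)))
  Xs <- X
  Xs[, !is_binary] <- apply(X[, !is_binary, drop = FALSE], 2, std1)
  y <- std1(tt[[trait]])
  qrX <- qr(cbind(1, Xs))
  if (qrX$rank < ncol(Xs) + 1) {
    bad <- predictors[setdiff(seq_len(ncol(Xs)),
                              qrX$pivot[seq_len(qrX$rank)] - 1L)]
    stop("exactly collinear predictors: ", paste(bad, collapse = ", "))
  }
  fit <- stats::lm(y ~ Xs)
  sm <- summary(fit)
  cf <- sm$coefficients[-1, , drop = FALSE]
  zq <- stats::qt(1 - (1 - conf_level) / 2, fit$df.residual)
  out <- data.frame(predictor = predictors,
                    beta = cf[, 1],
                    ci_lower = cf[, 1] - zq * cf[, 2],
                    ci_upper = cf[, 1] + zq * cf[, 2],
                    p_value = cf[, 4],
                    p_adj = stats::p.adjust(cf[, 4], method = "BH"),
                    vif = if (ncol(Xs) >= 2) collinearity_diagnostics(Xs)
                          else stats::setNames(1, predictors),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "r_squared") <- sm$r.squared
  attr(out, "n") <- nrow(X)
  class(out) <- c("regression_report", "data.frame")
  out
}

#' LASSO with stability selection
#'
#' For each of `B` subsamples (drawn without replacement, size
#' `subsample_fraction * n`), fits an L1-penalized linear path over
#' `lambda_grid`; the selection frequency of a predictor is the fraction of
#' subsamples in which it has a nonzero coefficient at any grid point, and
#' it is selected when that frequency reaches `threshold`. By default the
#' per-subsample path is truncated once more than `q` variables are active
#' (q = ceiling(sqrt(0.8 p)) unless given), which bounds the number of
#' variables entering per subsample and keeps the selection frequency of
#' pure-noise predictors near zero; a fixed `lambda_grid` can be supplied
#' instead.
#'
#' @param X predictor matrix (standardized internally by glmnet).
#' @param y response vector.
#' @param B number of subsamples.
#' @param subsample_fraction subsample size as a fraction of n, in (0, 1).
#' @param threshold selection-frequency threshold in `[0, 1]`.
#' @param lambda_grid optional decreasing lambda sequence (overrides the
#'   q-bounded path).
#' @param q cap on the number of active variables per subsample path.
#' @param seed integer seed.
#' @return a `stability_selection_report` data frame: predictor, frequency,
#'   selected; subsampling metadata as attributes.
#' @export
lasso_stability <- function(X, y, B = 100, subsample_fraction = 0.5,
                            threshold = 0.6, lambda_grid = NULL,
                            q = NULL, seed = 1) {
  X <- as.matrix(as.data.frame(X))
  n <- nrow(X)
  if (n <= 10) stop("need more than 10 observations")
  if (subsample_fraction <= 0 || subsample_fraction >= 1)
    stop("subsample_fraction must lie strictly inside (0, 1)")
  if (!is.null(lambda_grid) && !length(lambda_grid)) stop("empty lambda grid")
  q <- q %||% ceiling(sqrt(0.8 * ncol(X)))
  cols <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  hits <- matrix(FALSE, B, ncol(X))
  withr::with_seed(child_seed(seed, 11L), {
    for (b in seq_len(B)) {
      idx <- sample.int(n, floor(subsample_fraction * n))
      if (is.null(lambda_grid)) {
        fit <- glmnet::glmnet(X[idx, , drop = FALSE], y[idx], dfmax = q,
                              nlambda = 30, standardize = TRUE)
        nz <- as.matrix(fit$beta) != 0
        keep <- colSums(nz) <= q
        hits[b, ] <- rowSums(nz[, keep, drop = FALSE]) > 0
      } else {
        fit <- glmnet::glmnet(X[idx, , drop = FALSE], y[idx],
                              lambda = lambda_grid, standardize = TRUE)
        hits[b, ] <- rowSums(as.matrix(fit$beta) != 0) > 0
      }
    }
  })
  freq <- colMeans(hits)
  out <- data.frame(predictor = cols, frequency = freq,
                    selected = freq >= threshold,
                    stringsAsFactors = FALSE)
  attr(out, "meta") <- list(B = B, subsample_fraction = subsample_fraction,
                            threshold = threshold, q = q, seed = seed,
                            lambda_grid = lambda_grid)
  class(out) <- c("stability_selection_report", "data.frame")
  out
}
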