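#' Natural-log (x + 1) transform
#'
#' The variance-stabilising transform applied to every count entering
#' the supply-demand regression: response (author counts) and
#' predictors (species richness, policy counts).
#'
#' @param v non-negative numeric vector.
#' @return `log(v + 1)`, elementwise.
#' @export
log1p_transform <- function(v) {
  if (!is.numeric(v)) stop("input must be numeric", call. = FALSE)
  if (any(v < 0)) stop("negative entries are not allowed", call. = FALSE)
  log1p(v)
}

#' Fitting configuration for the robust linear model
#'
#' @param huber_c Huber tuning constant; 1.345 gives 95 per cent
#'   efficiency at the Gaussian model.
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on the max absolute coefficient
#'   change.
#' @return a `fit_config` list.
#' @export
fit_config <- function(huber_c = 1.345, max_iter = 50, tol = 1e-8) {
  stopifnot(huber_c > 0, max_iter >= 1, tol > 0)
  structure(list(huber_c = huber_c, max_iter = max_iter, tol = tol),
            class = "fit_config")
}

#' Robust linear regression with Huber's T norm
#'
#' M-estimation by iteratively reweighted least squares. Residuals are
#' scaled each iteration by the normalised MAD (median absolute
#' deviation divided by 0.6745); observations with scaled residual
#' inside the tuning constant `c` get weight 1, outliers get weight
#' `c / |r/sigma|`. Iteration stops when the largest coefficient change
#' falls below the tolerance. Standard errors use the standard Huber
#' sandwich estimate
#' `sigma^2 * [sum psi(u)^2 / (n - p)] / [mean psi'(u)]^2 * (X'X)^{-1}`,
#' with p-values from the asymptotic normal distribution.
#'
#' An exactly-interpolating fit (zero residual scale) short-circuits
#' with unit weights. With `huber_c = Inf` the fit is ordinary least
#' squares.
#'
#' @param X design matrix (include the intercept column yourself, or
#'   use [regression_dataset()]); must have more rows than columns and
#'   full column rank.
#' @param y response vector.
#' @param config a [fit_config()].
#' @return a `huber_rlm` object: list with `coefficients`,
#'   `standardErrors`, `pValues`, `scale`, `weights`, `residuals`,
#'   `fitted`, `converged`, `nIterations`, plus `X`, `y`, `config`.
#' @export
fit_huber_rlm <- function(X, y, config = fit_config()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than parameters", call. = FALSE)
  if (qr(X)$rank < p) stop("design matrix is rank deficient", call. = FALSE)

  cc <- config$huber_c
  beta <- qr.solve(X, y)
  w <- rep(1, n)
  sigma <- 0
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    r <- y - drop(X %*% beta)
    sigma <- stats::mad(r)          # median-centred, constant 1/0.6745
    if (sigma < 1e-12) { w <- rep(1, n); converged <- TRUE; break }
    u <- r / sigma
    w <- ifelse(abs(u) <= cc, 1, cc / abs(u))
    sw <- sqrt(w)
    beta_new <- qr.solve(X * sw, y * sw)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < config$tol) { converged <- TRUE; break }
    if (iter >= config$max_iter) break
  }
  if (!converged) {
    warning("IRLS did not converge in ", config$max_iter, " iterations",
            call. = FALSE)
  }

  r <- y - drop(X %*% beta)
  if (sigma > 1e-12) {
    u <- r / sigma
    psi <- pmax(pmin(u, cc), -cc)
    psip <- as.numeric(abs(u) <= cc)
    xtx_inv <- chol2inv(chol(crossprod(X)))
    kappa <- (sum(psi^2) / (n - p)) / mean(psip)^2
    se <- sqrt(pmax(0, sigma^2 * kappa * diag(xtx_inv)))
  } else {
    se <- rep(0, p)
  }
  z <- ifelse(se > 0, beta / se, Inf * sign(beta))
  pvals <- 2 * pnorm(-abs(z))

  structure(
    list(coefficients = stats::setNames(drop(beta), colnames(X)),
         standardErrors = stats::setNames(se, colnames(X)),
         pValues = stats::setNames(pvals, colnames(X)),
         scale = sigma, weights = w, residuals = r,
         fitted = drop(X %*% beta), converged = converged,
         nIterations = iter, X = X, y = y, config = config),
    class = "huber_rlm"
  )
}

#' @export
print.huber_rlm <- function(x, ...) {
  cat("Huber robust linear model (c =", x$config$huber_c, ")\n")
  print(cbind(estimate = x$coefficients, se = x$standardErrors,
              p = x$pValues))
  cat("scale:", format(x$scale), " iterations:", x$nIterations,
      if (!x$converged) "(not converged)" else "", "\n")
  invisible(x)
}

#' Robust F-test comparing nested model fits
#'
#' Tests whether the predictors present only in the full model improve
#' it, using weighted residual sums of squares with the full model's
#' final IRLS weights applied to both fits:
#' `F = [(RSS_r - RSS_f)/df1] / [RSS_f/(n - p_f)]`. When all weights
#' are one this is the textbook nested-model F-test. Identical models
#' give F = 0, p = 1.
#'
#' @param full,reduced `huber_rlm` fits on the same rows; the reduced
#'   model's (named) columns must be a subset of the full model's.
#' @return list with `fStatistic`, `dfNumerator`, `dfDenominator`,
#'   `pValue`.
#' @export
compare_models_f <- function(full, reduced) {
  stopifnot(inherits(full, "huber_rlm"), inherits(reduced, "huber_rlm"))
  if (nrow(full$X) != nrow(reduced$X)) {
    stop("models were fitted on different rows", call. = FALSE)
  }
  if (!all(colnames(reduced$X) %in% colnames(full$X))) {
    stop("models are not nested: reduced columns must be a subset",
         call. = FALSE)
  }
  n <- nrow(full$X)
  p_full <- ncol(full$X)
  df1 <- p_full - ncol(reduced$X)
  df2 <- n - p_full
  w <- full$weights
  rss_full <- sum(w * full$residuals^2)
  rss_red <- sum(w * reduced$residuals^2)
  fstat <- if (df1 == 0) 0 else max(0, (rss_red - rss_full) / df1 /
                                      (rss_full / df2))
  pval <- if (df1 == 0) 1 else pf(fstat, df1, df2, lower.tail = FALSE)
  list(fStatistic = fstat, dfNumerator = df1, dfDenominator = df2,
       pValue = pval)
}

#' Durbin-Watson statistic
#'
#' `sum(diff(e)^2) / sum(e^2)`; lies in [0, 4], with 2 indicating no
#' first-order autocorrelation of the residual sequence.
#'
#' @param residuals numeric vector, length >= 2, not all zero.
#' @return the statistic.
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2) stop("need at least two residuals", call. = FALSE)
  if (all(residuals == 0)) stop("undefined for all-zero residuals", call. = FALSE)
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' Breusch-Pagan test for heteroscedasticity
#'
#' Lagrange-multiplier form: `n * R^2` from the auxiliary OLS
#' regression of squared residuals on the design matrix (intercept
#' included), referred to a chi-squared distribution with one degree of
#' freedom per non-intercept predictor. This is the studentised
#' (Koenker) version, robust to non-normal errors.
#'
#' @param residuals residual vector.
#' @param X design matrix used in the original fit; an intercept column
#'   is added if none is present.
#' @return list with `statistic` and `pValue`.
#' @export
breusch_pagan <- function(residuals, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(residuals) != n) stop("length mismatch", call. = FALSE)
  has_intercept <- any(apply(X, 2, function(col) all(col == 1)))
  if (!has_intercept) X <- cbind(`(Intercept)` = 1, X)
  if (qr(X)$rank < ncol(X)) stop("degenerate design matrix", call. = FALSE)
  u2 <- residuals^2
  fit <- stats::lm.fit(X, u2)
  tss <- sum((u2 - mean(u2))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(fit$residuals^2) / tss
  stat <- n * r2
  df <- ncol(X) - 1
  list(statistic = stat, pValue = pchisq(stat, df, lower.tail = FALSE))
}

#' Shapiro-Wilk normality test of residuals
#'
#' Thin wrapper over the reference implementation in \pkg{stats};
#' errors on constant input (zero variance) and on sample sizes outside
#' 3..5000.
#'
#' @param residuals numeric vector.
#' @return list with `W` and `pValue`.
#' @export
shapiro_wilk <- function(residuals) {
  n <- length(residuals)
  if (n < 3 || n > 5000) stop("sample size out of range [3, 5000]", call. = FALSE)
  if (stats::sd(residuals) == 0) stop("zero-variance residuals", call. = FALSE)
  ht <- stats::shapiro.test(residuals)
  list(W = unname(ht$statistic), pValue = ht$p.value)
}

#' Flag outlier observations of a robust fit
#'
#' Rows whose standardised residual (residual divided by the fit's
#' robust scale) exceeds the threshold in absolute value, sorted by
#' descending magnitude.
#'
#' @param fit a `huber_rlm`.
#' @param threshold standardised-residual threshold (default 3).
#' @param row_labels optional labels; defaults to row names of the
#'   design matrix or row numbers.
#' @return tibble with `rowLabel`, `standardizedResidual`.
#' @export
flag_outliers <- function(fit, threshold = 3, row_labels = NULL) {
  stopifnot(inherits(fit, "huber_rlm"))
  if (fit$scale <= 0) stop("fit has zero scale; outliers undefined",
                           call. = FALSE)
  labels <- row_labels %||% rownames(fit$X) %||% as.character(seq_along(fit$y))
  std <- fit$residuals / fit$scale
  idx <- which(abs(std) > threshold)
  idx <- idx[order(-abs(std[idx]))]
  tibble::tibble(rowLabel = labels[idx], standardizedResidual = std[idx])
}

#' Taxonomists per described species
#'
#' @param author_count number of authors publishing on the order.
#' @param richness accepted species richness of the order.
#' @return the ratio, rounded to three decimals; `NA` (with a warning)
#'   when richness is zero.
#' @export
taxonomists_per_species <- function(author_count, richness) {
  if (richness == 0) {
    warning("richness is zero; ratio undefined, reported as missing",
            call. = FALSE)
    return(NA_real_)
  }
  round(author_count / richness, 3)
}

#' Pearson correlation with t-transform p-value
#'
#' @param x,y numeric vectors of equal length >= 3, both with positive
#'   variance.
#' @return list with `r` and `pValue` (two-sided).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors of length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), pValue = ht$p.value)
}

#' Assemble the regression dataset from a demand matrix
#'
#' Applies the ln(x + 1) transform to the response (author counts) and
#' predictors (species richness and the nine policy counts) and builds
#' the full and species-only design matrices, both with intercept.
#'
#' @param matrix_tbl tibble from [build_policy_matrix()] (or the
#'   synthetic regression generator): columns `order`,
#'   `speciesRichness`, the nine policy counts, `authorCount`.
#' @return list with `y`, `X_full`, `X_reduced`, `rowLabels`.
#' @export
regression_dataset <- function(matrix_tbl) {
  needed <- c("order", "speciesRichness", policy_ids(), "authorCount")
  missing_cols <- setdiff(needed, names(matrix_tbl))
  if (length(missing_cols) > 0) {
    stop("matrix lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  y <- log1p_transform(matrix_tbl$authorCount)
  preds <- c("speciesRichness", policy_ids())
  Xp <- vapply(preds, function(cn) log1p_transform(matrix_tbl[[cn]]),
               numeric(nrow(matrix_tbl)))
  X_full <- cbind(`(Intercept)` = 1, Xp)
  rownames(X_full) <- matrix_tbl$order
  list(y = y,
       X_full = X_full,
       X_reduced = X_full[, c("(Intercept)", "speciesRichness"), drop = FALSE],
       rowLabels = matrix_tbl$order)
}
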