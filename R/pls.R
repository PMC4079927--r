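# NIPALS PLS1 with leave-one-out cross-validation and jackknife variable
# selection.

pls_core <- function(xs, fs, n_components) {
  p <- ncol(xs)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(xs), n_components)
  q <- numeric(n_components)
  E <- xs; f <- fs
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) rlang::abort("PLS: residual X carries no covariance with y; reduce n_components.")
    w <- w / nw
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) rlang::abort("PLS: degenerate score vector; reduce n_components.")
    p_a <- drop(crossprod(E, t_a)) / tt
    q_a <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p_a)
    f <- f - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
  }
  # scaled-space regression vector for each component count (cumulative)
  coef_path <- lapply(seq_len(n_components), function(a) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    drop(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)]))
  })
  list(W = W, P = P, T = Tm, q = q, coef_path = coef_path)
}

#' Fit a PLS1 regression (NIPALS)
#'
#' Univariate-response partial least squares by NIPALS deflation. Inputs are
#' autoscaled internally (mean zero, unit variance); regression coefficients
#' are back-transformed to the original scale. Deterministic: no random
#' initialization. With `n_components` equal to the rank of the autoscaled
#' predictor matrix the fit reproduces ordinary least squares.
#'
#' @param x Predictor matrix/data frame (rows = subjects).
#' @param y Numeric response vector.
#' @param n_components Number of latent variables (1 <= A <= rank of scaled x).
#' @return Object of class `pls_model` with scaling parameters, weights
#'   `W`, loadings `P`, scores `T`, y-loadings `q`, `coefficients`
#'   (original scale, with intercept), `fitted`, and `r_squared`.
#' @export
pls_fit <- function(x, y, n_components) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (nrow(x) != length(y)) rlang::abort("`x` rows and `y` length differ.")
  sx <- autoscale(x)
  sy <- autoscale(matrix(y, ncol = 1, dimnames = list(NULL, "y")))
  rk <- qr(sx$x)$rank
  if (n_components < 1 || n_components > rk) {
    rlang::abort(sprintf("`n_components` must lie in 1..rank(X) = %d.", rk))
  }
  core <- pls_core(sx$x, drop(sy$x), n_components)
  b_scaled <- core$coef_path[[n_components]]
  b <- b_scaled * sy$scales / sx$scales
  intercept <- sy$means - sum(b * sx$means)
  fitted <- drop(as.matrix(x[, names(sx$means), drop = FALSE]) %*% b) + intercept
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  structure(list(
    x_means = sx$means, x_scales = sx$scales, x_dropped = sx$dropped,
    y_mean = sy$means, y_scale = sy$scales,
    n_components = n_components,
    W = core$W, P = core$P, T = core$T, q = core$q,
    coef_path_scaled = core$coef_path,
    coefficients = c(`(Intercept)` = unname(intercept), stats::setNames(b, names(sx$means))),
    fitted = fitted, y = y, r_squared = r2
  ), class = "pls_model")
}

#' Predict from a PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Predictor matrix/data frame with the training columns.
#' @param n_components Component count to use (default: as fitted).
#' @param ... Unused.
#' @return Numeric predictions on the original response scale.
#' @export
predict.pls_model <- function(object, newdata, n_components = object$n_components, ...) {
  if (n_components < 1 || n_components > length(object$coef_path_scaled)) {
    rlang::abort("`n_components` outside the fitted component path.")
  }
  nd <- as.matrix(newdata)
  if (is.null(colnames(nd))) {
    if (ncol(nd) != length(object$x_means) + length(object$x_dropped)) {
      rlang::abort("unnamed `newdata` must match the training columns.")
    }
    colnames(nd) <- paste0("X", seq_len(ncol(nd)))
  }
  nd <- nd[, names(object$x_means), drop = FALSE]
  xs <- scale(nd, center = object$x_means, scale = object$x_scales)
  bs <- object$coef_path_scaled[[n_components]]
  drop(xs %*% bs) * object$y_scale + object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS1 model: %d component(s), %d predictor(s), n = %d\n",
              x$n_components, length(x$x_means), length(x$y)))
  cat(sprintf("  R^2 = %.3f\n", x$r_squared))
  if (!is.null(x$cv)) {
    cat(sprintf("  LOO Q^2 (selected A = %d) = %.3f\n",
                x$n_components, x$cv$q2[x$cv$n_components == x$n_components]))
  }
  if (!is.null(x$jackknife)) {
    cat(sprintf("  jackknife-selected variables: %d\n", sum(x$jackknife$selected)))
  }
  invisible(x)
}

#' Leave-one-out cross-validation for PLS1
#'
#' For every left-out subject the model is refit from scratch on the
#' remaining subjects (including re-autoscaling on the training fold) and the
#' left-out response predicted at each component count.
#' `Q^2(A) = 1 - PRESS(A)/TSS`; the selected component count maximizes Q^2,
#' ties resolved toward fewer components. LOO is the only feasible scheme at
#' the small n of intervention cohorts, at the price of optimism.
#'
#' @param x Predictor matrix/data frame (n >= 3 rows).
#' @param y Numeric response.
#' @param max_components Largest component count to evaluate; capped at
#'   n - 2 (with a warning) and at the training-fold rank.
#' @return List with `q2` tibble (`n_components`, `press`, `q2`),
#'   `n_components` (selected), and `fold_coefficients` (matrix of
#'   original-scale coefficients per fold, used by the jackknife).
#' @export
loo_cv <- function(x, y, max_components = 2) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 3) rlang::abort("LOO cross-validation needs at least 3 rows.")
  if (max_components >= n - 1) {
    rlang::warn(sprintf("max_components capped at n - 2 = %d.", n - 2))
    max_components <- n - 2
  }
  a_max <- max(1L, as.integer(max_components))
  preds <- matrix(NA_real_, n, a_max)
  fold_coefs <- vector("list", n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; ytr <- y[-i]
    rk <- suppressWarnings(qr(autoscale(xtr)$x)$rank)
    a_i <- min(a_max, rk)
    fit <- suppressWarnings(pls_fit(xtr, ytr, a_i))
    for (a in seq_len(a_i)) preds[i, a] <- predict(fit, x[i, , drop = FALSE], a)
    if (a_i < a_max) preds[i, (a_i + 1):a_max] <- preds[i, a_i]
    cf <- fit$coefficients[-1]
    full_cf <- stats::setNames(numeric(ncol(x)), colnames(x))
    full_cf[names(cf)] <- cf
    fold_coefs[[i]] <- full_cf
  }
  tss <- sum((y - mean(y))^2)
  press <- colSums((y - preds)^2)
  q2 <- 1 - press / tss
  sel <- which.max(q2)  # which.max takes the first maximum: fewer components on ties
  list(
    q2 = tibble::tibble(n_components = seq_len(a_max), press = press, q2 = q2),
    n_components = as.integer(sel),
    fold_coefficients = do.call(rbind, fold_coefs)
  )
}

#' Jackknife variable selection for PLS1
#'
#' Tukey jackknife on the leave-one-out refits: for each predictor the
#' jackknife standard error of its (original-scale) PLS coefficient is
#' `sqrt((n-1)/n * sum((b_i - mean(b_i))^2))` over the n folds; the variable
#' is kept when `|b_full| / SE` exceeds the two-sided t critical value at
#' `alpha` with n - 1 degrees of freedom. A coefficient that is identical and
#' nonzero across all folds (SE = 0) is kept.
#'
#' @param x,y Training data (as in [pls_fit()]).
#' @param n_components Component count for the full fit.
#' @param alpha Two-sided selection level (default 0.05).
#' @param cv Optional precomputed [loo_cv()] result (must match `x`, `y`).
#' @return Tibble with `variable`, `coefficient`, `se`, `statistic`,
#'   `critical`, `selected`.
#' @export
jackknife_select <- function(x, y, n_components, alpha = 0.05, cv = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 3) rlang::abort("jackknife selection needs at least 3 rows.")
  if (is.null(cv)) cv <- loo_cv(x, y, max_components = n_components)
  full <- suppressWarnings(pls_fit(x, y, n_components))
  b_full <- stats::setNames(numeric(ncol(x)), colnames(x))
  b_full[names(full$coefficients[-1])] <- full$coefficients[-1]
  bc <- cv$fold_coefficients
  se <- apply(bc, 2, function(col) sqrt((n - 1) / n * sum((col - mean(col))^2)))
  stat <- ifelse(se == 0, ifelse(b_full != 0, Inf, 0), abs(b_full) / se)
  crit <- stats::qt(1 - alpha / 2, df = n - 1)
  tibble::tibble(variable = colnames(x), coefficient = unname(b_full),
                 se = unname(se), statistic = unname(stat),
                 critical = crit, selected = unname(stat > crit))
}

#' Full PLS analysis: cross-validated fit plus jackknife selection
#'
#' Runs [loo_cv()] to pick the component count (by maximal Q^2), fits the
#' final model on all subjects, and attaches the jackknife variable-selection
#' table. This is the model runner used for each configured response
#' (e.g. a genus abundance change against all host-parameter changes).
#'
#' @inheritParams loo_cv
#' @param alpha Jackknife selection level.
#' @return A `pls_model` with extra elements `cv` (Q^2 table + selection) and
#'   `jackknife` (selection tibble).
#' @export
pls_analysis <- function(x, y, max_components = 2, alpha = 0.05) {
  x <- as.matrix(x); y <- as.numeric(y)
  cv <- loo_cv(x, y, max_components)
  fit <- suppressWarnings(pls_fit(x, y, cv$n_components))
  fit$cv <- cv[c("q2", "n_components")]
  # jackknife refits LOO at the *selected* component count so fold
  # coefficients match the final model
  fit$jackknife <- if (cv$n_components == nrow(cv$q2)) {
    jackknife_select(x, y, cv$n_components, alpha, cv = cv)
  } else {
    jackknife_select(x, y, cv$n_components, alpha)
  }
  fit
}
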