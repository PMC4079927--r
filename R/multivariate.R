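# Multivariate layer: autoscaling and the RV matrix correlation.

#' Autoscale a data matrix
#'
#' Centers every column to mean zero and scales to unit sample variance
#' (n - 1 denominator). Zero-variance columns carry no correlation
#' information; they are dropped with a warning and recorded.
#'
#' @param x Numeric matrix or data frame (>= 2 rows).
#' @return List with `x` (scaled matrix), `means`, `scales`, and `dropped`
#'   (names of zero-variance columns).
#' @export
autoscale <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("X", seq_len(ncol(m)))
  if (nrow(m) < 2) rlang::abort("autoscale needs at least 2 rows.")
  mns <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  dropped <- colnames(m)[sds == 0]
  if (length(dropped) == ncol(m)) rlang::abort("all columns are constant.")
  if (length(dropped)) {
    rlang::warn(paste0("autoscale: dropped constant column(s): ",
                       paste(dropped, collapse = ", ")))
  }
  keep <- sds > 0
  list(x = scale(m[, keep, drop = FALSE], center = mns[keep], scale = sds[keep]),
       means = mns[keep], scales = sds[keep], dropped = dropped)
}

# Undo autoscaling (round-trip inverse of autoscale on the kept columns).
unscale <- function(x_scaled, means, scales) {
  sweep(sweep(x_scaled, 2, scales, `*`), 2, means, `+`)
}

#' RV coefficient between two data blocks
#'
#' Multivariate generalization of the (squared) Pearson correlation between
#' two matrices sharing rows: `RV = trace(XX'YY') /
#' sqrt(trace((XX')^2) * trace((YY')^2))` on column-centered matrices, between
#' 0 and 1. For single-column blocks it reduces to the squared Pearson
#' correlation; it is invariant to orthogonal rotation of either block.
#'
#' @param x,y Numeric matrices/data frames with the same number of rows.
#' @return RV coefficient between 0 and 1.
#' @export
rv_coefficient <- function(x, y) {
  xm <- as.matrix(x); ym <- as.matrix(y)
  if (nrow(xm) != nrow(ym)) rlang::abort("`x` and `y` must have the same number of rows.")
  xc <- scale(xm, center = TRUE, scale = FALSE)
  yc <- scale(ym, center = TRUE, scale = FALSE)
  if (all(xc == 0) || all(yc == 0)) rlang::abort("zero matrix after centering.")
  cxy <- crossprod(xc, yc)
  cxx <- crossprod(xc)
  cyy <- crossprod(yc)
  sum(cxy^2) / sqrt(sum(cxx^2) * sum(cyy^2))
}
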