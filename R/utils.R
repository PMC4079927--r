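# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Derive a child seed deterministically from a master seed. Keeps the result
# inside the 32-bit integer range R's RNG accepts.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + offset * 7919) %% 2147483646) + 1L
}

# Evaluate `code` under `seed` and restore the caller's RNG state afterwards,
# so package functions never clobber a user's random stream.
with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Row-wise softmax on a numeric matrix (log-abundances -> compositions).
softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# Convert a wide tibble (first column = id) to a numeric matrix with rownames.
tbl_to_matrix <- function(tbl, id_col = 1L) {
  ids <- as.character(tbl[[id_col]])
  m <- as.matrix(tbl[, -id_col, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

# Inverse of tbl_to_matrix.
matrix_to_tbl <- function(m, id_name) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(!!id_name := rownames(m)), out)
  out
}

stop_config <- function(msg) rlang::abort(msg, class = "microdelta_config_error")

check_positive_int <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 1 || x != floor(x)) {
    stop_config(sprintf("`%s` must be a single positive integer (got %s).",
                        name, paste(format(x), collapse = ", ")))
  }
  invisible(as.integer(x))
}

check_positive_real <- function(x, name, strict = TRUE) {
  ok <- length(x) == 1 && is.numeric(x) && !is.na(x) && (if (strict) x > 0 else x >= 0)
  if (!ok) stop_config(sprintf("`%s` must be a single %s real number.",
                               name, if (strict) "positive" else "non-negative"))
  invisible(as.numeric(x))
}
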