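# Readers and writers for the TSV/JSON dialect shared by all stages.
# TSV is canonical; CSV is accepted by sniffing the delimiter.

sniff_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) rlang::abort(paste0("empty file: ", path))
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

read_table_checked <- function(path) {
  delim <- sniff_delim(path)
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  probs <- readr::problems(tbl)
  if (nrow(probs)) {
    rlang::abort(paste0("malformed table ", path, ": ",
                        paste(sprintf("line %d: %s", probs$row, probs$expected),
                              collapse = "; ")))
  }
  if (nrow(tbl) == 0) rlang::abort(paste0("no data rows in ", path))
  ids <- as.character(tbl[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    rlang::abort(paste0("duplicate id(s) in ", path, ": ", paste(dup, collapse = ", ")))
  }
  tbl
}

#' Read a sample-by-taxon abundance table
#'
#' TSV (or CSV) with a header row; first column is the sample id, remaining
#' columns are numeric taxon abundances. Negative values are rejected with
#' the offending cell named.
#'
#' @param path File path.
#' @return Abundance tibble.
#' @export
read_abundance_table <- function(path) {
  tbl <- read_table_checked(path)
  m <- suppressWarnings(tbl_to_matrix(tbl))
  if (any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("non-numeric or missing abundance at sample '%s', taxon '%s' in %s",
                         rownames(m)[bad[1]], colnames(m)[bad[2]], path))
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("negative count at sample '%s', taxon '%s' in %s",
                         rownames(m)[bad[1]], colnames(m)[bad[2]], path))
  }
  tbl
}

#' Read a subject-by-parameter host table
#'
#' Non-numeric cells (e.g. "NA", "<LOD") become missing values; the number of
#' coerced cells is reported via a message and the `"n_missing"` attribute.
#'
#' @param path File path.
#' @return Host tibble (first column subject id, numeric columns).
#' @export
read_host_table <- function(path) {
  tbl <- read_table_checked(path)
  id <- tbl[1]
  vals <- tbl[-1]
  pre_na <- sum(is.na(vals))
  vals <- dplyr::mutate(vals, dplyr::across(dplyr::everything(),
                                            ~ suppressWarnings(as.numeric(.x))))
  n_coerced <- sum(is.na(vals)) - pre_na
  if (n_coerced > 0) {
    rlang::inform(paste0("read_host_table: ", n_coerced,
                         " non-numeric cell(s) set to missing."))
  }
  out <- dplyr::bind_cols(id, vals)
  attr(out, "n_missing") <- sum(is.na(vals))
  out
}

#' Read a taxonomy table
#'
#' Accepts either the wide layout (`taxon_id`, `phylum`, ..., `genus`) or a
#' two-column layout with semicolon-delimited lineage strings
#' (`p__X;c__Y;o__Z;f__W;g__V`).
#'
#' @param path File path.
#' @return Taxonomy tibble in the wide layout.
#' @export
read_taxonomy <- function(path) {
  tbl <- read_table_checked(path)
  if (all(taxonomic_ranks %in% names(tbl))) return(tbl)
  if (ncol(tbl) == 2) {
    lin <- strsplit(as.character(tbl[[2]]), ";", fixed = TRUE)
    if (any(lengths(lin) != 5)) {
      rlang::abort("lineage strings must have 5 semicolon-separated fields (phylum..genus).")
    }
    parts <- do.call(rbind, lin)
    parts <- sub("^[pcofg]__", "", parts)
    return(tibble::tibble(taxon_id = as.character(tbl[[1]]),
                          phylum = parts[, 1], class = parts[, 2], order = parts[, 3],
                          family = parts[, 4], genus = parts[, 5]))
  }
  rlang::abort("unrecognized taxonomy layout.")
}

#' Write tables in the canonical TSV dialect
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @name write_tables
#' @export
write_abundance_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_tables
#' @export
write_host_table <- write_abundance_table

#' @rdname write_tables
#' @export
write_taxonomy <- function(x, path) {
  out <- tibble::tibble(
    taxon_id = x$taxon_id,
    lineage = sprintf("p__%s;c__%s;o__%s;f__%s;g__%s",
                      x$phylum, x$class, x$order, x$family, x$genus)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write ground truth as JSON
#'
#' @param truth A `cohort_truth` object.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  cfg <- truth$config
  cfg$planted_links <- NULL
  jsonlite::write_json(list(links = truth$links, config = unclass(cfg)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a distance matrix as square TSV
#'
#' @param dm Symmetric matrix with ids as dimnames.
#' @param path Output path.
#' @export
write_distance_matrix <- function(dm, path) {
  readr::write_tsv(matrix_to_tbl(dm, "sample_id"), path)
  invisible(path)
}
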