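#' Read a summary-statistic table
#'
#' Reads a delimited file with a header containing an `id` column and
#' either an `xty` column (scores \eqn{X^\top Y}) or a `z` column
#' (marginal Z-scores, converted through [zscores_to_summary()]).
#' Optional `chr`/`pos` columns are carried as opaque metadata. `n` and
#' `yty` may be columns (constant) or supplied as arguments.
#'
#' @param path File path (whitespace- or comma-delimited, autodetected).
#' @param n,yty Sample size and \eqn{\|Y\|_2^2}; required unless present
#'   as columns (`yty` unnecessary for the Z-score dialect).
#' @param expected_p Optional dimension check (e.g. `nrow(sigma)`).
#' @return A `summary_stats` object; metadata columns are attached as
#'   attribute `"meta"`.
#' @export
read_summary_table <- function(path, n = NULL, yty = NULL,
                               expected_p = NULL) {
  sep <- if (grepl(",", readLines(path, n = 1))) "," else ""
  tab <- read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
  if (!"id" %in% names(tab)) stop("summary table needs an 'id' column")
  if ("n" %in% names(tab)) {
    if (is.null(n)) n <- tab$n[1]
  }
  if (is.null(n)) stop("sample size n not found in table or arguments")
  if ("xty" %in% names(tab)) {
    if (!is.numeric(tab$xty)) stop("'xty' column must be numeric")
    if (is.null(yty)) stop("the xty dialect requires yty")
    out <- summary_stats(zs = tab$xty, yty = yty, n = n, ids = tab$id)
  } else if ("z" %in% names(tab)) {
    if (!is.numeric(tab$z)) stop("'z' column must be numeric")
    out <- zscores_to_summary(tab$z, n = n, ids = tab$id)
  } else {
    stop("summary table needs an 'xty' or 'z' column")
  }
  if (!is.null(expected_p) && out$p != expected_p) {
    stop("summary table has p = ", out$p,
         " rows but the covariance matrix has dimension ", expected_p)
  }
  meta_cols <- intersect(c("chr", "pos"), names(tab))
  if (length(meta_cols)) attr(out, "meta") <- tab[meta_cols]
  out
}

#' Read a symmetric matrix
#'
#' Dense whitespace/comma-delimited text (optionally lower- or
#' upper-triangle only, mirrored on read) or an `.rds` container.
#' Asymmetry up to `1e-6` is averaged away; beyond that it is an error.
#'
#' @param path File path; `.rds` is read with [readRDS()], anything else
#'   as delimited text.
#' @param expected_dim Optional dimension check.
#' @return Symmetric numeric matrix.
#' @export
read_matrix <- function(path, expected_dim = NULL) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    mat <- as.matrix(readRDS(path))
  } else {
    sep <- if (grepl(",", readLines(path, n = 1))) "," else ""
    mat <- as.matrix(read.table(path, header = FALSE, sep = sep))
  }
  dimnames(mat) <- NULL
  if (nrow(mat) != ncol(mat)) stop("matrix is not square")
  lower_only <- all(is.na(mat[upper.tri(mat)]) | mat[upper.tri(mat)] == 0) &&
    any(mat[lower.tri(mat)] != 0)
  upper_only <- all(is.na(mat[lower.tri(mat)]) | mat[lower.tri(mat)] == 0) &&
    any(mat[upper.tri(mat)] != 0)
  if (xor(lower_only, upper_only)) {
    tri <- if (lower_only) mat[lower.tri(mat)] else t(mat)[lower.tri(mat)]
    full <- diag(diag(mat))
    full[lower.tri(full)] <- tri
    full <- full + t(full) - diag(diag(mat))
    mat <- full
  } else {
    mat[is.na(mat)] <- 0
    asym <- max(abs(mat - t(mat)))
    if (asym > 1e-6 * max(1, max(abs(mat)))) {
      stop("matrix is asymmetric beyond tolerance (max |A - A'| = ",
           format(asym), ")")
    }
    mat <- (mat + t(mat)) / 2
  }
  if (!is.null(expected_dim) && nrow(mat) != expected_dim) {
    stop("matrix has dimension ", nrow(mat), ", expected ", expected_dim)
  }
  mat
}

#' Write a selection result to a delimited table
#'
#' Tab-separated output with columns `index, id, W, selected, T, q,
#' method, seed`; an infinite threshold is serialized as the string
#' `"inf"`. Row order follows the input statistics, so re-running with
#' the same seed reproduces the file byte for byte.
#'
#' @param sel A `selection` object.
#' @param path Output path.
#' @param ids Optional variable labels (defaults to those recorded in
#'   `sel`, else `V1..Vp`).
#' @param seed Seed to record (optional).
#' @return Invisibly, the written data frame.
#' @export
write_selection <- function(sel, path, ids = NULL, seed = NA) {
  p <- length(sel$W)
  if (is.null(ids)) ids <- sel$ids
  if (is.null(ids)) ids <- paste0("V", seq_len(p))
  df <- data.frame(
    index = seq_len(p), id = ids, W = sel$W,
    selected = as.integer(seq_len(p) %in% sel$selected),
    T = if (is.finite(sel$threshold)) format(sel$threshold) else "inf",
    q = sel$q,
    method = if (is.null(sel$method)) NA_character_ else sel$method,
    seed = seed)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
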