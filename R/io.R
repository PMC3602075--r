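# File formats: plain whitespace-delimited genotype matrices, the vcftools
# "--012" dialect, and ADMIXTURE-style .P/.Q text outputs.

#' Read a genotype matrix from a text file
#'
#' Two dialects are supported.  `"matrix"` is a plain whitespace-delimited
#' integer matrix, by default loci in rows and individuals in columns.
#' `"z012"` is the output of `vcftools --012`: individuals in rows, a
#' leading individual-index column, and -1 marking missing genotypes; it is
#' transposed to loci-by-individuals on load.  Missing entries (-1) are an
#' error by default, or imputed with the rounded locus mean of the observed
#' genotypes under `missing_policy = "mean_impute"`.
#'
#' @param path file to read.
#' @param format `"matrix"` or `"z012"`.
#' @param orientation for `"matrix"` files only: `"loci-by-individuals"`
#'   (default) or `"individuals-by-loci"` (transposed on load).
#' @param missing_policy `"error"` or `"mean_impute"`.
#' @return M x N genotype matrix with entries in \{0, 1, 2\}.
#' @export
read_genotypes <- function(path, format = c("matrix", "z012"),
                           orientation = c("loci-by-individuals",
                                           "individuals-by-loci"),
                           missing_policy = c("error", "mean_impute")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop(sprintf("no data in %s", path), call. = FALSE)
  toks <- strsplit(trimws(lines), "[ \t]+")
  nfield <- lengths(toks)
  if (length(unique(nfield)) != 1L) {
    bad <- which(nfield != nfield[1L])[1L]
    stop(sprintf("ragged rows in %s: line %d has %d fields, expected %d",
                 path, bad, nfield[bad], nfield[1L]), call. = FALSE)
  }
  flat <- unlist(toks, use.names = FALSE)
  nonint <- !grepl("^-?[0-9]+$", flat)
  if (any(nonint)) {
    i <- which(nonint)[1L]
    stop(sprintf("non-integer token '%s' in %s at line %d, column %d",
                 flat[i], path, (i - 1L) %/% nfield[1L] + 1L,
                 (i - 1L) %% nfield[1L] + 1L), call. = FALSE)
  }
  X <- matrix(as.integer(flat), nrow = length(lines), byrow = TRUE)
  col_offset <- 0L
  if (format == "z012") {
    if (ncol(X) < 2L)
      stop(sprintf("z012 file %s must have an index column plus loci", path),
           call. = FALSE)
    X <- X[, -1L, drop = FALSE]  # leading individual-index column
    col_offset <- 1L
  }
  # range and missingness checks, located in file coordinates
  locate <- function(mask) which(matrix(mask, nrow(X)), arr.ind = TRUE)[1L, ]
  out_of_range <- !(X %in% c(-1L, 0L, 1L, 2L))
  if (any(out_of_range)) {
    idx <- locate(out_of_range)
    stop(sprintf("genotype %d in %s at line %d, column %d is outside {-1, 0, 1, 2}",
                 X[idx[1L], idx[2L]], path, idx[1L], idx[2L] + col_offset),
         call. = FALSE)
  }
  if (any(X == -1L) && missing_policy == "error") {
    idx <- locate(X == -1L)
    stop(sprintf("missing genotype (-1) in %s at line %d, column %d (set missing_policy = \"mean_impute\" to impute)",
                 path, idx[1L], idx[2L] + col_offset), call. = FALSE)
  }
  if (format == "z012" || orientation == "individuals-by-loci")
    X <- t(X)
  if (any(X == -1L)) {
    for (l in which(rowSums(X == -1L) > 0L)) {
      obs <- X[l, X[l, ] != -1L]
      if (!length(obs))
        stop(sprintf("locus %d has no observed genotypes to impute from", l),
             call. = FALSE)
      X[l, X[l, ] == -1L] <- as.integer(round(mean(obs)))
    }
  }
  genotype_matrix(X)
}

#' Write fitted P and Q in the conventional .P/.Q layout
#'
#' Writes `<prefix>.P` (M rows by K space-delimited frequencies) and
#' `<prefix>.Q` (N rows by K proportions; Q is transposed on write so rows
#' are individuals, matching the conventional layout).  Values are printed
#' with six decimals, so a round trip through [read_pq()] agrees to 5e-7.
#'
#' @param prefix output path prefix.
#' @param P M x K allele-frequency matrix.
#' @param Q K x N admixture matrix.
#' @return invisibly, the two file paths written.
#' @export
write_pq <- function(prefix, P, Q) {
  P <- as.matrix(P)
  Q <- as.matrix(Q)
  fmt_rows <- function(X)
    apply(X, 1L, function(r) paste(sprintf("%.6f", r), collapse = " "))
  p_path <- paste0(prefix, ".P")
  q_path <- paste0(prefix, ".Q")
  writeLines(fmt_rows(P), p_path)
  writeLines(fmt_rows(t(Q)), q_path)
  invisible(c(P = p_path, Q = q_path))
}

read_real_matrix <- function(path) {
  X <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(X) <- NULL
  X
}

#' Read .P/.Q files written by [write_pq()]
#'
#' @param prefix path prefix of the `.P` and `.Q` files.
#' @return list with `P` (M x K) and `Q` (K x N; transposed back from the
#'   individuals-in-rows file layout).
#' @export
read_pq <- function(prefix) {
  list(P = read_real_matrix(paste0(prefix, ".P")),
       Q = t(read_real_matrix(paste0(prefix, ".Q"))))
}

#' Write a genotype matrix as plain text
#'
#' Loci in rows, individuals in columns, space-delimited integers; the
#' format read back by `read_genotypes(format = "matrix")`.
#'
#' @param path output file.
#' @param G M x N genotype matrix.
#' @return invisibly, the path written.
#' @export
write_genotypes <- function(path, G) {
  G <- genotype_matrix(G)
  writeLines(apply(G, 1L, paste, collapse = " "), path)
  invisible(path)
}
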