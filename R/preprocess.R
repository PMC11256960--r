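# Normalization chain turning raw count/intensity matrices into the
# approximately Gaussian inputs the factor model assumes.

#' Map a sample column onto standard-normal quantiles
#'
#' Rank-based inverse-normal transform: the value with (1-based) rank r,
#' ties resolved by average rank, maps to qnorm((r - 0.5) / m). The
#' transform is order-preserving and makes each sample's marginal
#' distribution approximately standard normal.
#'
#' @param column Numeric vector (one sample across markers).
#' @return Numeric vector of the same length.
#' @export
quantile_normalize_sample <- function(column) {
  stopifnot(is.numeric(column), length(column) >= 1L)
  m <- length(column)
  r <- rank(column, ties.method = "average")
  stats::qnorm((r - 0.5) / m)
}

#' Normalize a raw expression matrix
#'
#' Applies, in order: (1) per-sample scaling to counts-per-million
#' (library-size standardization), (2) elementwise `log(1 + x)`,
#' (3) per-sample rank-based mapping to standard-normal quantiles
#' ([quantile_normalize_sample()]), and (4) per-marker z-scoring across
#' samples (sample standard deviation, n - 1 denominator). Markers that
#' are constant after step (3) are set to zero with a warning rather than
#' dividing by zero.
#'
#' @param raw Numeric matrix, markers in rows and samples in columns,
#'   non-negative, no missing values. Row and column names are preserved.
#' @return The normalized matrix with attribute `stage = "normalized"`.
#' @export
normalize_matrix <- function(raw) {
  stopifnot(is.matrix(raw), is.numeric(raw))
  if (anyNA(raw)) stop("raw matrix contains missing values")
  if (any(raw < 0)) stop("raw matrix contains negative values")
  cs <- colSums(raw)
  if (any(cs == 0)) {
    bad <- if (!is.null(colnames(raw))) colnames(raw)[cs == 0][1L] else which(cs == 0)[1L]
    stop("sample with zero column sum: ", bad)
  }
  cpm <- sweep(raw, 2L, cs, "/") * 1e6
  lg <- log1p(cpm)
  qn <- apply(lg, 2L, quantile_normalize_sample)
  dimnames(qn) <- dimnames(raw)
  mu <- rowMeans(qn)
  sd <- apply(qn, 1L, stats::sd)
  zero_var <- sd == 0 | !is.finite(sd)
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance marker(s) set to zero after z-scoring")
    sd[zero_var] <- 1
  }
  z <- (qn - mu) / sd
  z[zero_var, ] <- 0
  attr(z, "stage") <- "normalized"
  z
}

#' Read a marker-by-sample expression matrix from TSV
#'
#' First column holds marker identifiers, the header row sample
#' identifiers.
#'
#' @param path Path to a tab-separated matrix file.
#' @return Numeric matrix with marker row names and sample column names.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' Write a marker-by-sample expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; round-trips bit-identically for
#' integer raw inputs.
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(is.matrix(x))
  df <- data.frame(marker = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
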