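#' Quantile-normalize a raw expression matrix across samples
#'
#' Classic rank-mean quantile normalization: the reference distribution is
#' the mean, across samples, of the per-sample sorted intensities; every
#' sample's values are replaced by the reference value of their rank. Ties
#' within a sample receive the mean of the reference values of the ranks the
#' tie run spans, so tied inputs stay tied and within-column order is
#' preserved. The output remains on the raw scale; log2 transformation is a
#' separate, subsequent step ([log2_transform()]).
#'
#' @param m an [expr_matrix()] with `scale_tag = "raw"` and at least two
#'   samples.
#' @return A list with `matrix` (the normalized [expr_matrix()]) and
#'   `report` (a `normalization_report`: `n_probes`, `n_samples`, and the
#'   non-decreasing `reference_distribution`).
#' @export
quantile_normalize <- function(m) {
  if (m$scale_tag != "raw")
    abort("quantile_normalize expects a raw-scale matrix", "state_error")
  x <- m$values
  if (ncol(x) < 2L)
    abort("quantile normalization needs at least two samples",
          "precondition_error")
  ref <- unname(rowMeans(apply(x, 2L, sort, method = "radix")))
  csum <- c(0, cumsum(ref))
  out <- x
  for (j in seq_len(ncol(x))) {
    rmin <- rank(x[, j], ties.method = "min")
    rmax <- rank(x[, j], ties.method = "max")
    # mean of the reference values over the rank span of each tie run
    out[, j] <- (csum[rmax + 1L] - csum[rmin]) / (rmax - rmin + 1)
  }
  report <- structure(list(n_probes = nrow(x), n_samples = ncol(x),
                           reference_distribution = ref),
                      class = "normalization_report")
  list(matrix = expr_matrix(out, m$groups, scale_tag = "raw"),
       report = report)
}

#' Log2-transform a raw expression matrix
#'
#' Maps every intensity v to log2(v + offset). The default offset is 0
#' (microarray intensities are strictly positive); a small positive offset
#' guards against exact zeros in synthetic or background-subtracted data.
#'
#' @param m an [expr_matrix()] with `scale_tag = "raw"`.
#' @param offset small non-negative pseudocount added before the logarithm.
#' @return An [expr_matrix()] with `scale_tag = "log2"`.
#' @export
log2_transform <- function(m, offset = 0) {
  if (m$scale_tag != "raw")
    abort("matrix is already log2-transformed", "state_error")
  if (offset < 0)
    abort("offset must be non-negative", "argument_error")
  structure(list(values = log2(m$values + offset), groups = m$groups,
                 scale_tag = "log2"), class = "expr_matrix")
}
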