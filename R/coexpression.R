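#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]: errors (with a typed
#' condition) on zero-variance input instead of returning `NA`, so pipeline
#' callers can skip degenerate probes explicitly.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    abort("vectors must have equal length >= 3", "precondition_error")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    abort("zero variance input", "degenerate_error")
  stats::cor(x, y)
}

#' Two-sided p value for a Pearson correlation
#'
#' Uses the exact t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom; `|r| = 1` gives p = 0.
#'
#' @param r correlation coefficient(s) in \[-1, 1\] (vectorized).
#' @param n number of paired observations, >= 3.
#' @return Two-sided p value(s).
#' @export
corr_p_value <- function(r, n) {
  if (any(n < 3))
    abort("correlation p value needs n >= 3", "precondition_error")
  if (any(abs(r) > 1 + 1e-12))
    abort("|r| must not exceed 1", "argument_error")
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) == 1, 0,
              2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2))
  p
}

#' Screen differentially expressed lncRNA-mRNA pairs for co-expression
#'
#' Computes the Pearson correlation of every (differentially expressed
#' lncRNA) x (differentially expressed mRNA) pair over the selected samples
#' and retains pairs with `|r| > r_threshold` (strictly) and
#' `p < p_threshold`. `sample_scope = "all"` uses both groups (default);
#' `"case_only"` restricts to the case group — note that with 5 case
#' samples p < 0.05 at 3 degrees of freedom already requires |r| above
#' about 0.878, which is stricter than the 0.7 cut. Probes with zero
#' variance over the selected samples are skipped with a warning. The full
#' pre-filter correlation grid (lncRNA rows x mRNA columns) is returned for
#' heat-map display.
#'
#' @param m an [expr_matrix()] with `scale_tag = "log2"`.
#' @param de output of [differential_expression()]; only rows with
#'   `status != "ns"` enter the screen.
#' @param sample_scope `"all"` or `"case_only"`.
#' @param case_label group label used when `sample_scope = "case_only"`.
#' @param r_threshold correlation magnitude cut, exceeded strictly
#'   (default 0.7).
#' @param p_threshold p value cut (default 0.05).
#' @return A list with `pairs` (data.frame `lnc_probe`, `lnc_symbol`,
#'   `mrna_probe`, `mrna_symbol`, `r`, `p_value`, `n`, sorted by |r|
#'   descending then symbols) and `grid` (numeric matrix of r values).
#' @export
coexpression_screen <- function(m, de, sample_scope = c("all", "case_only"),
                                case_label = NULL, r_threshold = 0.7,
                                p_threshold = 0.05) {
  sample_scope <- match.arg(sample_scope)
  de_sig <- de[de$status != "ns", , drop = FALSE]
  lnc <- de_sig[de_sig$biotype == "lncRNA", , drop = FALSE]
  mrna <- de_sig[de_sig$biotype == "mRNA", , drop = FALSE]
  if (!nrow(lnc) || !nrow(mrna))
    abort("need at least one DE lncRNA and one DE mRNA",
          "precondition_error")
  samples <- if (sample_scope == "all") sample_ids(m) else {
    if (is.null(case_label))
      abort("case_label required for case_only scope", "argument_error")
    group_samples(m, case_label)
  }
  if (length(samples) < 3L)
    abort("co-expression needs at least three samples in scope",
          "precondition_error")
  n <- length(samples)
  X <- t(m$values[lnc$probe_id, samples, drop = FALSE])
  Y <- t(m$values[mrna$probe_id, samples, drop = FALSE])
  sd0x <- apply(X, 2L, stats::sd) == 0
  sd0y <- apply(Y, 2L, stats::sd) == 0
  if (any(sd0x) || any(sd0y)) {
    warning(sprintf("skipping %d zero-variance probes in co-expression",
                    sum(sd0x) + sum(sd0y)))
    X <- X[, !sd0x, drop = FALSE]; Y <- Y[, !sd0y, drop = FALSE]
    lnc <- lnc[!sd0x, , drop = FALSE]; mrna <- mrna[!sd0y, , drop = FALSE]
  }
  grid <- stats::cor(X, Y)
  rownames(grid) <- lnc$probe_id; colnames(grid) <- mrna$probe_id
  hit <- which(abs(grid) > r_threshold &
                 corr_p_value(as.vector(grid), n) < p_threshold,
               arr.ind = TRUE)
  pairs <- data.frame(lnc_probe = lnc$probe_id[hit[, 1L]],
                      lnc_symbol = lnc$gene_symbol[hit[, 1L]],
                      mrna_probe = mrna$probe_id[hit[, 2L]],
                      mrna_symbol = mrna$gene_symbol[hit[, 2L]],
                      r = grid[hit],
                      p_value = corr_p_value(grid[hit], n),
                      n = if (nrow(hit)) n else integer(0),
                      stringsAsFactors = FALSE)
  ord <- order(-abs(pairs$r), pairs$lnc_symbol, pairs$mrna_symbol,
               method = "radix")
  list(pairs = pairs[ord, , drop = FALSE], grid = grid)
}
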