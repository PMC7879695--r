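#' Pooled-variance two-sample Student's t test
#'
#' Classical Student's t with pooled variance and `length(x)+length(y)-2`
#' degrees of freedom, two-sided p from the t distribution. The degenerate
#' zero-pooled-variance case is given a fixed convention: equal means give
#' `t = 0, p = 1`; unequal means give a signed infinite t and `p = 0`. Both
#' are flagged so downstream consumers can recognize them.
#'
#' @param x,y numeric vectors, each of length >= 2 (case and control).
#' @return A list with `t_stat`, `p_value`, `df` and `degenerate_flag`.
#' @seealso [differential_expression()] for the vectorized per-probe version.
#' @export
t_test_two_group <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    abort("each group needs at least two observations", "precondition_error")
  df <- nx + ny - 2
  delta <- mean(x) - mean(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  if (sp2 == 0) {
    if (delta == 0)
      return(list(t_stat = 0, p_value = 1, df = df, degenerate_flag = TRUE))
    return(list(t_stat = sign(delta) * Inf, p_value = 0, df = df,
                degenerate_flag = TRUE))
  }
  t_stat <- delta / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t_stat = t_stat, p_value = 2 * stats::pt(-abs(t_stat), df),
       df = df, degenerate_flag = FALSE)
}

## row-wise pooled t over a matrix; same conventions as t_test_two_group
row_t_test <- function(values, case_idx, ctrl_idx) {
  nx <- length(case_idx); ny <- length(ctrl_idx)
  xc <- values[, case_idx, drop = FALSE]
  yc <- values[, ctrl_idx, drop = FALSE]
  mx <- rowMeans(xc); my <- rowMeans(yc)
  vx <- rowSums((xc - mx)^2) / (nx - 1)
  vy <- rowSums((yc - my)^2) / (ny - 1)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
  delta <- mx - my
  t_stat <- delta / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- 2 * stats::pt(-abs(t_stat), df)
  degen <- sp2 == 0
  if (any(degen)) {
    eq <- degen & delta == 0
    t_stat[eq] <- 0; p[eq] <- 1
    ne <- degen & delta != 0
    t_stat[ne] <- sign(delta[ne]) * Inf; p[ne] <- 0
  }
  list(mean_case = mx, mean_control = my, log2fc = delta, t_stat = t_stat,
       p_value = p, degenerate_flag = degen)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"` after validating the input).
#'
#' @param p_values numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    abort("p values must lie in [0, 1]", "argument_error")
  stats::p.adjust(p_values, method = "BH")
}

#' Two-group differential expression of mRNAs and lncRNAs
#'
#' One pooled Student's t test per probe on log2 intensities;
#' `log2fc = mean(case) - mean(control)`. A probe is called `up` when
#' `log2fc > lfc_threshold` and its p value is below `p_threshold`, `down`
#' when `log2fc < -lfc_threshold` with the same p criterion, otherwise `ns`
#' — strict inequalities at both boundaries (fold change > 2 means strictly
#' greater). The default significance criterion is the raw p value; set
#' `use_adjusted = TRUE` to gate on the Benjamini-Hochberg adjusted p
#' instead. Results carry gene symbol and biotype from the annotation so the
#' lncRNA and mRNA volcano classifications can be separated.
#'
#' @param m an [expr_matrix()] with `scale_tag = "log2"`.
#' @param ann a `probe_annotation` covering every probe of `m`.
#' @param case_label,control_label the two group labels; "up" means higher
#'   in the case group.
#' @param lfc_threshold absolute log2 fold-change threshold (default 1,
#'   i.e. fold change 2).
#' @param p_threshold significance threshold (default 0.05).
#' @param use_adjusted gate the status rule on `adj_p` instead of raw p.
#' @return A `data.frame` with columns `probe_id`, `gene_symbol`, `biotype`,
#'   `mean_case`, `mean_control`, `log2fc`, `t_stat`, `p_value`, `adj_p`,
#'   `status`, `degenerate_flag`.
#' @export
differential_expression <- function(m, ann, case_label, control_label,
                                    lfc_threshold = 1, p_threshold = 0.05,
                                    use_adjusted = FALSE) {
  if (m$scale_tag != "log2")
    abort("differential expression expects a log2-scale matrix",
          "state_error")
  case_s <- group_samples(m, case_label)
  ctrl_s <- group_samples(m, control_label)
  if (length(case_s) < 2L || length(ctrl_s) < 2L)
    abort("each group needs at least two samples", "precondition_error")
  missing <- setdiff(probe_ids(m), ann$probe_id)
  if (length(missing))
    abort(sprintf("%d probes missing from the annotation (first: %s)",
                  length(missing), missing[1L]), "validation_error")
  tt <- row_t_test(m$values, match(case_s, sample_ids(m)),
                   match(ctrl_s, sample_ids(m)))
  adj <- bh_adjust(tt$p_value)
  crit_p <- if (use_adjusted) adj else tt$p_value
  status <- rep("ns", nrow(m$values))
  status[tt$log2fc > lfc_threshold & crit_p < p_threshold] <- "up"
  status[tt$log2fc < -lfc_threshold & crit_p < p_threshold] <- "down"
  idx <- match(probe_ids(m), ann$probe_id)
  data.frame(probe_id = probe_ids(m),
             gene_symbol = ann$gene_symbol[idx],
             biotype = ann$biotype[idx],
             mean_case = unname(tt$mean_case),
             mean_control = unname(tt$mean_control),
             log2fc = unname(tt$log2fc),
             t_stat = unname(tt$t_stat),
             p_value = unname(tt$p_value),
             adj_p = adj,
             status = status,
             degenerate_flag = unname(tt$degenerate_flag),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Volcano-plot coordinate table
#'
#' Per-probe (log2 fold change, -log10 p, status) for volcano-style display.
#' Zero p values (the degenerate-test sentinel) are capped at a finite
#' -log10 value so the table stays plottable.
#'
#' @param results output of [differential_expression()].
#' @param cap value substituted for `-log10(0)` (default 350, just below
#'   the double-precision limit of ~1e-308).
#' @return A data.frame with `probe_id`, `gene_symbol`, `biotype`, `log2fc`,
#'   `neg_log10_p`, `status`.
#' @export
volcano_table <- function(results, cap = 350) {
  y <- -log10(results$p_value)
  y[results$p_value == 0] <- cap
  y <- pmin(y, cap)
  data.frame(probe_id = results$probe_id, gene_symbol = results$gene_symbol,
             biotype = results$biotype, log2fc = results$log2fc,
             neg_log10_p = y, status = results$status,
             stringsAsFactors = FALSE)
}
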