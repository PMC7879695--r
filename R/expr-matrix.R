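#' @keywords internal
"_PACKAGE"

## Typed conditions: every user-facing failure carries a class so callers
## (and the test suite) can distinguish format, validation, coordinate,
## state and argument errors from plain R errors.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("lncnet_", class), "lncnet_error")))
}

#' Construct an expression matrix with group labels
#'
#' The central container of the pipeline: a probe x sample intensity grid
#' together with a sample-to-group mapping and a scale tag recording whether
#' values are raw intensities or log2-transformed. Raw-scale matrices must be
#' non-negative; at most two distinct group labels are allowed (the pipeline
#' performs a two-group comparison).
#'
#' @param values numeric matrix, probes in rows, samples in columns. Row and
#'   column names are the probe and sample identifiers.
#' @param groups named character vector mapping every sample id to its group
#'   label.
#' @param scale_tag `"raw"` or `"log2"`.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `groups` and `scale_tag`.
#' @export
expr_matrix <- function(values, groups, scale_tag = c("raw", "log2")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    abort("'values' must be a numeric matrix", "format_error")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort("'values' must carry probe row names and sample column names",
          "format_error")
  if (anyDuplicated(rownames(values)))
    abort("duplicate probe identifiers", "format_error")
  if (anyDuplicated(colnames(values)))
    abort("duplicate sample identifiers", "format_error")
  if (anyNA(values))
    abort("expression values contain missing entries", "format_error")
  groups <- vapply(groups, as.character, character(1))
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    abort(paste0("samples without a group assignment: ",
                 paste(missing, collapse = ", ")), "validation_error")
  groups <- groups[colnames(values)]
  if (length(unique(groups)) > 2)
    abort("more than two group labels", "validation_error")
  if (scale_tag == "raw" && any(values < 0))
    abort("raw-scale intensities must be non-negative", "validation_error")
  structure(list(values = values, groups = groups, scale_tag = scale_tag),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  cat("groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                               table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

probe_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

## samples belonging to one group label, erroring if the label is absent
group_samples <- function(m, label) {
  idx <- which(m$groups == label)
  if (!length(idx))
    abort(paste0("group label not present among samples: ", label),
          "argument_error")
  names(m$groups)[idx]
}
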