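## Readers and writers for every external representation the pipeline
## touches. All tables are UTF-8, tab-delimited, "." decimal mark.

#' Read a raw expression matrix and its sample-group mapping
#'
#' The matrix file is tab-delimited with probe identifiers in the first
#' column and sample identifiers in the header row; the groups file is a
#' two-column (sample_id, group) tab-delimited table without header.
#' Values are validated as raw-scale intensities (non-negative), probe and
#' sample identifiers must be unique, every sample needs a group label, and
#' at most two distinct labels are allowed.
#'
#' @param matrix_path path to the probe x sample intensity table.
#' @param groups_path path to the sample-to-group table.
#' @param scale_tag scale of the stored values: `"raw"` (default; values
#'   must be non-negative) or `"log2"` for re-reading normalized output.
#' @return A validated [expr_matrix()] with the given `scale_tag`.
#' @export
read_expression <- function(matrix_path, groups_path,
                            scale_tag = c("raw", "log2")) {
  scale_tag <- match.arg(scale_tag)
  header <- strsplit(readLines(matrix_path, n = 1L), "\t", fixed = TRUE)[[1]]
  raw <- utils::read.table(matrix_path, sep = "\t", header = TRUE,
                           row.names = NULL, check.names = FALSE,
                           colClasses = c("character",
                                          rep("numeric", length(header) - 1L)),
                           quote = "", comment.char = "")
  if (anyDuplicated(raw[[1L]]))
    abort(paste0("duplicate probe identifier: ",
                 raw[[1L]][duplicated(raw[[1L]])][1L]), "format_error")
  values <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(values) || anyNA(values))
    abort("non-numeric or missing expression cell", "format_error")
  rownames(values) <- raw[[1L]]
  grp <- utils::read.table(groups_path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(grp) != 2L)
    abort("groups file must have exactly two columns", "format_error")
  groups <- stats::setNames(grp[[2L]], grp[[1L]])
  if (length(unique(groups)) > 2L)
    abort("groups file lists more than two distinct labels",
          "validation_error")
  expr_matrix(values, groups, scale_tag = scale_tag)
}

#' Write an expression matrix (and optionally its groups) to TSV
#'
#' Inverse of [read_expression()]: full-precision decimal representations are
#' used so that a read-back reproduces values exactly.
#'
#' @param m an [expr_matrix()].
#' @param matrix_path output path for the intensity table.
#' @param groups_path optional output path for the sample-group table.
#' @export
write_expression <- function(m, matrix_path, groups_path = NULL) {
  con <- file(matrix_path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("probe_id", sample_ids(m)), collapse = "\t"), con)
  # %.17g round-trips IEEE doubles exactly through read.table
  body <- apply(m$values, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(paste(probe_ids(m), body, sep = "\t"), con)
  if (!is.null(groups_path))
    utils::write.table(data.frame(sample = names(m$groups),
                                  group = unname(m$groups)),
                       groups_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(matrix_path)
}

#' Read a probe annotation table
#'
#' Tab-delimited columns: probe_id, gene_symbol, biotype, chrom, start, end,
#' strand (with header). Loci follow the BED convention (0-based start,
#' half-open end); the four locus columns may be empty, in which case the
#' probe has no locus and is excluded from cis/trans classification (but not
#' from differential expression or correlation). Biotype strings are
#' normalized case-insensitively to `mRNA` / `lncRNA`; anything else is a
#' format error.
#'
#' @param path path to the annotation TSV.
#' @return A `data.frame` of class `probe_annotation` with columns
#'   `probe_id`, `gene_symbol`, `biotype`, `chrom`, `start`, `end`, `strand`
#'   (locus columns `NA` when absent).
#' @export
read_annotation <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "", na.strings = "")
  needed <- c("probe_id", "gene_symbol", "biotype", "chrom", "start", "end",
              "strand")
  if (!all(needed %in% names(ann)))
    abort(paste0("annotation must have columns: ",
                 paste(needed, collapse = ", ")), "format_error")
  probe_annotation(ann$probe_id, ann$gene_symbol, ann$biotype,
                   ann$chrom, suppressWarnings(as.numeric(ann$start)),
                   suppressWarnings(as.numeric(ann$end)), ann$strand)
}

#' Construct a validated probe annotation
#'
#' @param probe_id,gene_symbol,biotype,chrom,start,end,strand parallel
#'   vectors; `chrom`/`start`/`end`/`strand` may be `NA` (locus absent).
#' @return A `probe_annotation` data.frame.
#' @export
probe_annotation <- function(probe_id, gene_symbol, biotype,
                             chrom = NA_character_, start = NA_real_,
                             end = NA_real_, strand = NA_character_) {
  n <- length(probe_id)
  if (anyDuplicated(probe_id))
    abort("duplicate probe identifier in annotation", "format_error")
  canon <- c(mrna = "mRNA", lncrna = "lncRNA")
  biotype <- canon[tolower(biotype)]
  if (anyNA(biotype))
    abort("biotype must be one of mRNA, lncRNA", "format_error")
  ann <- data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                    biotype = unname(biotype),
                    chrom = rep_len(chrom, n),
                    start = rep_len(as.numeric(start), n),
                    end = rep_len(as.numeric(end), n),
                    strand = rep_len(strand, n),
                    stringsAsFactors = FALSE)
  has_locus <- !is.na(ann$chrom)
  if (any(has_locus & (is.na(ann$start) | is.na(ann$end))))
    abort("locus with chromosome but missing coordinates", "format_error")
  bad <- has_locus & !(ann$start >= 0 & ann$start < ann$end)
  if (any(bad))
    abort(paste0("invalid coordinates (need 0 <= start < end) for probe ",
                 ann$probe_id[bad][1L]), "coordinate_error")
  okstrand <- is.na(ann$strand) | ann$strand %in% c("+", "-", ".")
  if (!all(okstrand))
    abort("strand must be one of +, -, .", "format_error")
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Write a probe annotation table
#' @param ann a `probe_annotation`.
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  out <- as.data.frame(ann)
  out$start <- ifelse(is.na(out$start), "", format(out$start, scientific = FALSE, trim = TRUE))
  out$end <- ifelse(is.na(out$end), "", format(out$end, scientific = FALSE, trim = TRUE))
  out$chrom[is.na(out$chrom)] <- ""
  out$strand[is.na(out$strand)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-delimited fields
#' name, description, member... (at least one member). Members are
#' de-duplicated within a set preserving first occurrence; duplicate set
#' names are a format error.
#'
#' @param path path to the GMT file.
#' @return A named list of class `gene_set_collection`; each element is a
#'   list with `description` and `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    abort(sprintf("GMT line %d has fewer than 3 fields", which(short)[1L]),
          "format_error")
  names_ <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names_))
    abort(paste0("duplicate gene-set name: ",
                 names_[duplicated(names_)][1L]), "format_error")
  sets <- lapply(fields, function(f)
    list(description = f[[2L]], members = unique(f[-c(1L, 2L)])))
  names(sets) <- names_
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#' @param sets a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$members), collapse = "\t"),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write regulatory pairs as a SIF edge list
#'
#' Simple interaction format consumed by Cytoscape-style network tools:
#' one line per pair, `<lncRNA symbol> TAB <cis|trans> TAB <mRNA symbol>`,
#' in input order. An empty pair table yields an empty file.
#'
#' @param pairs a data.frame of regulatory pairs (see [classify_cis_trans()]).
#' @param path output path.
#' @export
write_pairs_sif <- function(pairs, path) {
  lines <- character(0)
  if (nrow(pairs))
    lines <- paste(pairs$lnc_symbol, pairs$regulation, pairs$mrna_symbol,
                   sep = "\t")
  tryCatch(writeLines(lines, path, useBytes = TRUE),
           error = function(e) abort(conditionMessage(e), "io_error"))
  invisible(path)
}

## generic tab-separated results writer used by the pipeline stages
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
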