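## Full-chain driver: (simulate | ingest) -> preprocess -> diffexpr ->
## coexpression -> regulation network -> enrichment, under one config,
## with per-stage counts and a reproducible JSON manifest.

default_config <- function() {
  list(case_label = "tibetan", control_label = "han",
       log2_offset = 0, sample_scope = "all", use_adjusted = FALSE,
       mnc_neighborhood = "open",
       thresholds = list(lfc = 1, p = 0.05, r = 0.7,
                         window_bp = 300000, top_k = 100))
}

## fill unset keys recursively from the defaults
merge_config <- function(cfg, defaults = default_config()) {
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]))
      cfg[[k]] <- merge_config(cfg[[k]], defaults[[k]])
  }
  cfg
}

require_key <- function(cfg, key, where) {
  if (is.null(cfg[[key]]))
    abort(sprintf("configuration is missing required key '%s' in '%s'",
                  key, where), "config_error")
  cfg[[key]]
}

## stage output helper: files are written under a .partial suffix and only
## renamed to their final names when the stage completes, so an aborted run
## leaves its incomplete outputs clearly marked
stage_files <- function(out_dir, names) {
  final <- file.path(out_dir, names)
  stats::setNames(paste0(final, ".partial"), names)
}

finalize_stage <- function(partial) {
  final <- sub("\\.partial$", "", partial)
  ok <- file.rename(partial, final)
  if (!all(ok)) abort("could not finalize stage outputs", "io_error")
  stats::setNames(final, names(partial))
}

run_stage <- function(name, manifest, fun) {
  res <- tryCatch(fun(), error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          "stage_error")
  })
  files <- if (length(res$files)) finalize_stage(res$files) else character(0)
  manifest$stages[[name]] <- list(
    name = name,
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      names(files))),
    counts = res$counts)
  message(sprintf("[%s] %s", name,
                  paste(sprintf("%s=%s", names(res$counts),
                                unlist(res$counts)), collapse = " ")))
  list(manifest = manifest, value = res$value)
}

#' Run the full lncRNA-mRNA analysis pipeline from one configuration
#'
#' Orchestrates the whole chain behind a single configuration (a YAML file
#' or an equivalent nested list): either a `simulate` block (a
#' [sim_config()] argument list plus the top-level `seed`) or an `inputs`
#' block (`matrix`, `groups`, `annotation`, `gmt` paths); then quantile
#' normalization and log2 transformation, two-group differential
#' expression, lncRNA-mRNA co-expression screening, cis/trans
#' classification with trans-network hub scoring and top-k selection, and
#' over-representation analysis of the DE mRNAs. Every threshold of the
#' analysis (|log2FC| > 1, p < 0.05, |r| > 0.7, 300,000 bp window, top 100)
#' is a named config key with that default. All stage tables are written to
#' `out_dir`; the JSON run manifest (config snapshot, per-stage output
#' digests and counts, package version, seed) is written last. Re-running
#' with an identical config reproduces byte-identical outputs and digests.
#'
#' @param config path to a YAML configuration or a named list.
#' @return The run manifest, invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- merge_config(cfg)
  out_dir <- require_key(cfg, "out_dir", "top level")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- cfg$thresholds
  manifest <- list(config = cfg,
                   tool_version = as.character(utils::packageVersion("lncnet")),
                   seed = cfg$seed, stages = list())

  ## stage 1: simulate or ingest
  st <- run_stage("input", manifest, function() {
    if (!is.null(cfg$simulate)) {
      args <- cfg$simulate
      args$seed <- require_key(cfg, "seed", "top level")
      if (!is.null(args$corr_pairs))
        args$corr_pairs <- as.data.frame(args$corr_pairs)
      ds <- generate_dataset(do.call(sim_config, args))
      files <- stage_files(out_dir, c("matrix.tsv", "groups.tsv",
                                      "annotation.tsv", "sets.gmt",
                                      "truth.tsv", "truth_pairs.tsv"))
      write_expression(ds$expr, files[["matrix.tsv"]],
                       files[["groups.tsv"]])
      write_annotation(ds$annotation, files[["annotation.tsv"]])
      write_gmt(ds$gene_sets, files[["sets.gmt"]])
      write_tsv(ds$truth$de_status, files[["truth.tsv"]])
      write_tsv(ds$truth$corr_pairs, files[["truth_pairs.tsv"]])
      list(files = files,
           counts = list(probes = nrow(ds$expr$values),
                         samples = ncol(ds$expr$values)),
           value = list(expr = ds$expr, ann = ds$annotation,
                        sets = ds$gene_sets))
    } else {
      inp <- require_key(cfg, "inputs", "top level")
      expr <- read_expression(require_key(inp, "matrix", "inputs"),
                              require_key(inp, "groups", "inputs"))
      ann <- read_annotation(require_key(inp, "annotation", "inputs"))
      sets <- read_gmt(require_key(inp, "gmt", "inputs"))
      list(files = character(0),
           counts = list(probes = nrow(expr$values),
                         samples = ncol(expr$values)),
           value = list(expr = expr, ann = ann, sets = sets))
    }
  })
  manifest <- st$manifest
  expr <- st$value$expr; ann <- st$value$ann; sets <- st$value$sets

  ## stage 2: quantile normalization + log2
  st <- run_stage("preprocess", manifest, function() {
    qn <- quantile_normalize(expr)
    norm <- log2_transform(qn$matrix, offset = cfg$log2_offset)
    files <- stage_files(out_dir, "norm_log2.tsv")
    write_expression(norm, files[["norm_log2.tsv"]])
    list(files = files,
         counts = list(probes = qn$report$n_probes,
                       samples = qn$report$n_samples),
         value = norm)
  })
  manifest <- st$manifest
  norm <- st$value

  ## stage 3: differential expression
  st <- run_stage("diffexpr", manifest, function() {
    de <- differential_expression(norm, ann, cfg$case_label,
                                  cfg$control_label,
                                  lfc_threshold = th$lfc,
                                  p_threshold = th$p,
                                  use_adjusted = cfg$use_adjusted)
    files <- stage_files(out_dir, c("de.tsv", "volcano.tsv"))
    write_tsv(de, files[["de.tsv"]])
    write_tsv(volcano_table(de), files[["volcano.tsv"]])
    tab <- table(factor(de$status, c("up", "down")),
                 factor(de$biotype, c("lncRNA", "mRNA")))
    list(files = files,
         counts = list(up_lnc = unname(tab["up", "lncRNA"]),
                       down_lnc = unname(tab["down", "lncRNA"]),
                       up_mrna = unname(tab["up", "mRNA"]),
                       down_mrna = unname(tab["down", "mRNA"])),
         value = de)
  })
  manifest <- st$manifest
  de <- st$value

  ## stage 4: co-expression screen
  st <- run_stage("coexpr", manifest, function() {
    cx <- coexpression_screen(norm, de, sample_scope = cfg$sample_scope,
                              case_label = cfg$case_label,
                              r_threshold = th$r, p_threshold = th$p)
    files <- stage_files(out_dir, c("coexpr_pairs.tsv", "coexpr_grid.tsv"))
    write_tsv(cx$pairs, files[["coexpr_pairs.tsv"]])
    grid_df <- data.frame(lnc_probe = rownames(cx$grid),
                          as.data.frame(cx$grid), check.names = FALSE)
    write_tsv(grid_df, files[["coexpr_grid.tsv"]])
    list(files = files,
         counts = list(pairs_retained = nrow(cx$pairs)),
         value = cx$pairs)
  })
  manifest <- st$manifest
  pairs <- st$value

  ## stage 5: cis/trans classification, trans network, hubs, top-k
  st <- run_stage("regnet", manifest, function() {
    reg <- classify_cis_trans(pairs, ann, window_bp = th$window_bp)
    g <- build_trans_network(reg)
    scores <- mnc_scores(g, neighborhood = cfg$mnc_neighborhood)
    topk <- top_k_pairs(reg, k = th$top_k, class_filter = "trans")
    files <- stage_files(out_dir, c("regulation_pairs.tsv",
                                    "node_scores.tsv", "trans_top.tsv",
                                    "trans_network.sif"))
    write_tsv(reg, files[["regulation_pairs.tsv"]])
    write_tsv(scores, files[["node_scores.tsv"]])
    write_tsv(topk, files[["trans_top.tsv"]])
    write_pairs_sif(reg[reg$regulation != "unclassified", , drop = FALSE],
                    files[["trans_network.sif"]])
    cnt <- table(factor(reg$regulation, c("cis", "trans", "unclassified")))
    list(files = files,
         counts = list(cis = unname(cnt[["cis"]]),
                       trans = unname(cnt[["trans"]]),
                       unclassified = unname(cnt[["unclassified"]]),
                       top_k_size = nrow(topk)),
         value = reg)
  })
  manifest <- st$manifest

  ## stage 6: over-representation of the DE mRNAs
  st <- run_stage("enrich", manifest, function() {
    de_mrna <- de$gene_symbol[de$biotype == "mRNA" & de$status != "ns"]
    universe <- ann$gene_symbol[ann$biotype == "mRNA"]
    enr <- ora(de_mrna, sets, universe)
    files <- stage_files(out_dir, "enrichment.tsv")
    write_tsv(enr, files[["enrichment.tsv"]])
    list(files = files, counts = list(sets_tested = nrow(enr)),
         value = enr)
  })
  manifest <- st$manifest

  json <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}
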