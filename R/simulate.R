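#' Simulation configuration
#'
#' Defines a two-group microarray dataset with planted structure. Defaults
#' mirror the study design the pipeline targets: 5 case (Tibetan-analog) vs
#' 3 control (Han-analog) cartilage samples on an array carrying 32,776
#' mRNA and 17,438 lncRNA probes, with 49/68 up/down lncRNAs and 158/139
#' up/down mRNAs planted at a log2 effect of 3.0 over residual noise of
#' 0.5 SD on the log2 scale, and probe baselines uniform on \[4, 12\].
#'
#' Correlated lncRNA-mRNA pairs are planted through a shared latent factor:
#' both probes load sqrt(|rho|) on a common standard-normal factor (the
#' mRNA loading carries the sign of rho) with independent residuals scaled
#' so the noise component keeps variance `noise_sd^2`; the expected Pearson
#' correlation of the noise components is then exactly rho. Each planted
#' pair carries a locus geometry class: `cis_near` (same-chromosome gap
#' 100,000 bp), `cis_boundary` (gap exactly 300,000 bp, pinning the
#' inclusive cis boundary), `trans_far` (gap 500,000 bp, same chromosome)
#' or `trans_diffchrom` (different chromosomes).
#'
#' Planted probes occupy fixed leading positions and annotation loci are
#' deterministic functions of probe index, so changing the seed changes
#' values but never dimensions, truth structure, or annotation.
#'
#' @param n_case,n_control samples per group (>= 2 each).
#' @param n_mrna,n_lnc probe counts per biotype.
#' @param n_up_lnc,n_down_lnc,n_up_mrna,n_down_mrna planted DE counts.
#' @param effect_log2fc planted group-mean shift on the log2 scale.
#' @param noise_sd residual SD on the log2 scale.
#' @param baseline_log2_range range of the uniform probe baselines.
#' @param corr_pairs data.frame with columns `lnc_index`, `mrna_index`
#'   (1-based indices into the lncRNA / mRNA probe panels), `rho` in
#'   (-1, 1) and `geometry`; `NULL` plants a default set of eight pairs
#'   (two per geometry class) on the leading up-regulated probes, the cis
#'   pairs at correlations 0.805-0.857.
#' @param missing_locus_every every k-th unplanted probe is emitted without
#'   a locus (annotation incompleteness); 0 disables.
#' @param seed RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_case = 5, n_control = 3,
                       n_mrna = 32776, n_lnc = 17438,
                       n_up_lnc = 49, n_down_lnc = 68,
                       n_up_mrna = 158, n_down_mrna = 139,
                       effect_log2fc = 3.0, noise_sd = 0.5,
                       baseline_log2_range = c(4, 12),
                       corr_pairs = NULL, missing_locus_every = 50,
                       seed = 1) {
  if (n_case < 2 || n_control < 2)
    abort("each group needs at least two samples", "config_error")
  if (n_up_lnc + n_down_lnc > n_lnc || n_up_mrna + n_down_mrna > n_mrna)
    abort("planted DE counts exceed probe counts", "config_error")
  if (noise_sd < 0) abort("noise_sd must be non-negative", "config_error")
  if (abs(effect_log2fc) >= diff(baseline_log2_range))
    abort("effect_log2fc must be smaller than the baseline range width",
          "config_error")
  if (is.null(corr_pairs)) {
    geoms <- rep(c("cis_near", "cis_boundary", "trans_far",
                   "trans_diffchrom"), each = 2L)
    corr_pairs <- data.frame(
      lnc_index = seq_len(8L), mrna_index = seq_len(8L),
      rho = c(0.805, 0.857, 0.833, 0.833, 0.95, -0.9, 0.92, 0.88),
      geometry = geoms, stringsAsFactors = FALSE)
    corr_pairs <- corr_pairs[seq_len(min(8L, min(n_up_lnc, n_up_mrna))), ,
                             drop = FALSE]
  }
  if (nrow(corr_pairs)) {
    if (any(abs(corr_pairs$rho) >= 1))
      abort("every planted rho must lie strictly inside (-1, 1)",
            "config_error")
    if (any(corr_pairs$lnc_index > n_lnc | corr_pairs$mrna_index > n_mrna))
      abort("planted pair index out of range", "config_error")
    if (anyDuplicated(corr_pairs$lnc_index) ||
        anyDuplicated(corr_pairs$mrna_index))
      abort("each probe may join at most one planted pair", "config_error")
    ok <- corr_pairs$geometry %in% c("cis_near", "cis_boundary",
                                     "trans_far", "trans_diffchrom")
    if (!all(ok)) abort("unknown planted geometry class", "config_error")
  }
  structure(list(n_case = n_case, n_control = n_control, n_mrna = n_mrna,
                 n_lnc = n_lnc, n_up_lnc = n_up_lnc,
                 n_down_lnc = n_down_lnc, n_up_mrna = n_up_mrna,
                 n_down_mrna = n_down_mrna, effect_log2fc = effect_log2fc,
                 noise_sd = noise_sd,
                 baseline_log2_range = baseline_log2_range,
                 corr_pairs = corr_pairs,
                 missing_locus_every = missing_locus_every, seed = seed),
            class = "sim_config")
}

## deterministic (seed-independent) locus for an unplanted probe
.default_locus <- function(i) {
  chrom <- paste0("chr", (i %% 22L) + 1L)
  start <- (i * 131071) %% 150000000
  list(chrom = chrom, start = start, end = start + 20000)
}

.geometry_gap <- c(cis_near = 100000, cis_boundary = 300000,
                   trans_far = 500000)

#' Generate a seeded synthetic dataset with known ground truth
#'
#' Builds the log2-scale signal as probe baseline + group effect
#' (+/- `effect_log2fc` on planted probes in the case group) + correlated
#' latent component (planted pairs) + independent Gaussian noise, then
#' exports it on the raw intensity scale as 2^signal so the pipeline's
#' normalize-then-log2 path is exercised on its real input regime. The
#' accompanying annotation realizes each planted pair's geometry class
#' exactly (gaps of 100,000 / 300,000 / 500,000 bp or different
#' chromosomes), and the gene-set collection contains one set drawn 80%
#' from the planted DE mRNAs plus ten uniform-random sets. Identical
#' configuration and seed give bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @return A list with `expr` (raw-scale [expr_matrix()]), `annotation`
#'   (`probe_annotation`), `gene_sets` (`gene_set_collection`), `truth`
#'   (list: `de_status`, `corr_pairs`, `enriched_set_names`) and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ns <- cfg$n_case + cfg$n_control
  sample_id <- c(sprintf("TIB%d", seq_len(cfg$n_case)),
                 sprintf("HAN%d", seq_len(cfg$n_control)))
  groups <- stats::setNames(rep(c("tibetan", "han"),
                                c(cfg$n_case, cfg$n_control)), sample_id)
  case_col <- seq_len(cfg$n_case)

  lnc_probe <- sprintf("P_LNC_%05d", seq_len(cfg$n_lnc))
  mrna_probe <- sprintf("P_MRNA_%05d", seq_len(cfg$n_mrna))
  lnc_sym <- sprintf("LNC%05d", seq_len(cfg$n_lnc))
  mrna_sym <- sprintf("GENE%05d", seq_len(cfg$n_mrna))

  status_of <- function(n, n_up, n_down)
    rep(c("up", "down", "ns"), c(n_up, n_down, n - n_up - n_down))
  lnc_status <- status_of(cfg$n_lnc, cfg$n_up_lnc, cfg$n_down_lnc)
  mrna_status <- status_of(cfg$n_mrna, cfg$n_up_mrna, cfg$n_down_mrna)
  status <- c(lnc_status, mrna_status)
  probe_id <- c(lnc_probe, mrna_probe)
  np <- length(probe_id)

  lo <- cfg$baseline_log2_range[1L]; hi <- cfg$baseline_log2_range[2L]
  baseline <- stats::runif(np, lo, hi)
  ## planted probes keep their shifted group mean inside the global
  ## intensity range: quantile normalization presumes comparable
  ## distributions across samples, and a shift leaving the array's dynamic
  ## range would be destroyed by normalization itself, not by noise
  shrink <- (hi - lo - cfg$effect_log2fc) / (hi - lo)
  up_i <- status == "up"; down_i <- status == "down"
  baseline[up_i] <- lo + (baseline[up_i] - lo) * shrink
  baseline[down_i] <- hi - (hi - baseline[down_i]) * shrink
  effect <- ifelse(status == "up", cfg$effect_log2fc,
                   ifelse(status == "down", -cfg$effect_log2fc, 0))
  signal <- matrix(baseline, np, ns)
  signal[, case_col] <- signal[, case_col] + effect

  noise <- matrix(stats::rnorm(np * ns), np, ns)
  cp <- cfg$corr_pairs
  if (nrow(cp)) {
    for (t in seq_len(nrow(cp))) {
      z <- stats::rnorm(ns)
      a <- sqrt(abs(cp$rho[t])); b <- sqrt(1 - abs(cp$rho[t]))
      li <- cp$lnc_index[t]; mi <- cfg$n_lnc + cp$mrna_index[t]
      noise[li, ] <- a * z + b * stats::rnorm(ns)
      noise[mi, ] <- sign(cp$rho[t]) * a * z + b * stats::rnorm(ns)
    }
  }
  signal <- signal + cfg$noise_sd * noise
  values <- 2 ^ signal
  dimnames(values) <- list(probe_id, sample_id)
  expr <- expr_matrix(values, groups, scale_tag = "raw")

  ## annotation: deterministic loci; planted pairs get exact geometry
  loc <- lapply(seq_len(np), .default_locus)
  chrom <- vapply(loc, `[[`, character(1), "chrom")
  start <- vapply(loc, `[[`, numeric(1), "start")
  end <- vapply(loc, `[[`, numeric(1), "end")
  if (cfg$missing_locus_every > 0) {
    drop <- seq_len(np) %% cfg$missing_locus_every == 0
    chrom[drop] <- NA; start[drop] <- NA; end[drop] <- NA
  }
  if (nrow(cp)) {
    for (t in seq_len(nrow(cp))) {
      li <- cp$lnc_index[t]; mi <- cfg$n_lnc + cp$mrna_index[t]
      base <- 10000000 + t * 5000000
      width <- 10000
      if (cp$geometry[t] == "trans_diffchrom") {
        chrom[li] <- "chr1"; chrom[mi] <- "chr2"
        start[c(li, mi)] <- base; end[c(li, mi)] <- base + width
      } else {
        gap <- .geometry_gap[[cp$geometry[t]]]
        chrom[c(li, mi)] <- paste0("chr", (t %% 22L) + 1L)
        start[li] <- base; end[li] <- base + width
        start[mi] <- base + width + gap; end[mi] <- start[mi] + width
      }
    }
  }
  strand <- ifelse(is.na(chrom), NA_character_,
                   c("+", "-")[(seq_len(np) %% 2L) + 1L])
  ann <- probe_annotation(probe_id, c(lnc_sym, mrna_sym),
                          rep(c("lncRNA", "mRNA"),
                              c(cfg$n_lnc, cfg$n_mrna)),
                          chrom, start, end, strand)

  ## gene sets: one planted enriched set (80% planted DE mRNAs), ten random
  de_mrna_sym <- mrna_sym[mrna_status != "ns"]
  null_mrna_sym <- mrna_sym[mrna_status == "ns"]
  set_size <- min(50L, cfg$n_mrna)
  n_hit <- min(length(de_mrna_sym), round(0.8 * set_size))
  n_fill <- min(set_size - n_hit, length(null_mrna_sym))
  planted_members <- c(sample(de_mrna_sym, n_hit),
                       sample(null_mrna_sym, n_fill))
  sets <- list(PLANTED_SET = list(description = "planted enriched set",
                                  members = planted_members))
  for (s in seq_len(10L))
    sets[[sprintf("RANDOM_SET_%02d", s)]] <-
      list(description = "uniform random set",
           members = sample(mrna_sym, set_size))
  sets <- structure(sets, class = "gene_set_collection")

  truth_pairs <- if (nrow(cp))
    data.frame(lnc_probe = lnc_probe[cp$lnc_index],
               mrna_probe = mrna_probe[cp$mrna_index],
               rho = cp$rho, geometry = cp$geometry,
               stringsAsFactors = FALSE)
  else data.frame(lnc_probe = character(0), mrna_probe = character(0),
                  rho = numeric(0), geometry = character(0))

  list(expr = expr, annotation = ann, gene_sets = sets,
       truth = list(de_status = data.frame(probe_id = probe_id,
                                           biotype = rep(c("lncRNA", "mRNA"),
                                                         c(cfg$n_lnc, cfg$n_mrna)),
                                           status = status,
                                           stringsAsFactors = FALSE),
                    corr_pairs = truth_pairs,
                    enriched_set_names = "PLANTED_SET"),
       config = cfg)
}

#' Packaged replica recovery fixture
#'
#' A fixed configuration used by the end-to-end recovery tests: it plants
#' 49 up- and 68 down-regulated lncRNAs and 158 up- and 139 down-regulated
#' mRNAs (the reported scale of the comparison the pipeline emulates) at a
#' log2 effect of 3.0 and noise SD 0.5, over 5 case vs 3 control samples,
#' on an array of 250 lncRNA and 750 mRNA probes. The array is deliberately
#' smaller than a full production chip so that the expected number of null
#' probes crossing the |log2FC| > 1 & p < 0.05 rule by chance stays well
#' below the planted class counts — a recovery fixture is only informative
#' when false positives cannot mask the planted truth (see the methods
#' vignette for the sizing calculation).
#'
#' @param seed RNG seed (default 42, the packaged seed).
#' @param dir optional directory; when given, the dataset files are written
#'   there via [write_dataset()].
#' @return As [generate_dataset()], plus `files` when `dir` is given.
#' @export
replica_fixture <- function(seed = 42, dir = NULL) {
  cfg <- sim_config(n_case = 5, n_control = 3, n_mrna = 750, n_lnc = 250,
                    n_up_lnc = 49, n_down_lnc = 68, n_up_mrna = 158,
                    n_down_mrna = 139, effect_log2fc = 3.0, noise_sd = 0.5,
                    seed = seed)
  ds <- generate_dataset(cfg)
  if (!is.null(dir)) ds$files <- write_dataset(ds, dir)
  ds
}

#' Write a generated dataset to a directory
#'
#' Emits `matrix.tsv`, `groups.tsv`, `annotation.tsv`, `sets.gmt`,
#' `truth.tsv` (probe-level planted status), `truth_pairs.tsv` and
#' `truth_sets.tsv` in the pipeline's input dialects.
#'
#' @param ds output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             groups = file.path(dir, "groups.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             gmt = file.path(dir, "sets.gmt"),
             truth = file.path(dir, "truth.tsv"),
             truth_pairs = file.path(dir, "truth_pairs.tsv"),
             truth_sets = file.path(dir, "truth_sets.tsv"))
  write_expression(ds$expr, paths[["matrix"]], paths[["groups"]])
  write_annotation(ds$annotation, paths[["annotation"]])
  write_gmt(ds$gene_sets, paths[["gmt"]])
  write_tsv(ds$truth$de_status, paths[["truth"]])
  write_tsv(ds$truth$corr_pairs, paths[["truth_pairs"]])
  write_tsv(data.frame(enriched_set = ds$truth$enriched_set_names),
            paths[["truth_sets"]])
  paths
}
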