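small_cfg <- function(seed = 1, ...) {
  defaults <- list(n_case = 5, n_control = 3, n_lnc = 40, n_mrna = 120,
                   n_up_lnc = 4, n_down_lnc = 4, n_up_mrna = 10,
                   n_down_mrna = 10, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

test_that("identical seed gives bit-identical datasets", {
  a <- generate_dataset(small_cfg(seed = 9))
  b <- generate_dataset(small_cfg(seed = 9))
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(as.data.frame(a$annotation), as.data.frame(b$annotation))
  expect_identical(unclass(a$gene_sets), unclass(b$gene_sets))
  expect_identical(a$truth, b$truth)
})

test_that("changing the seed changes values but not structure", {
  a <- generate_dataset(small_cfg(seed = 1))
  b <- generate_dataset(small_cfg(seed = 2))
  expect_false(identical(a$expr$values, b$expr$values))
  expect_identical(dim(a$expr$values), dim(b$expr$values))
  expect_identical(a$truth$de_status, b$truth$de_status)
  expect_identical(a$truth$corr_pairs, b$truth$corr_pairs)
  expect_identical(as.data.frame(a$annotation), as.data.frame(b$annotation))
})

test_that("planted log2 effects average to the configured magnitude", {
  devs <- unlist(lapply(1:10, function(s) {
    ds <- generate_dataset(small_cfg(seed = s))
    sig <- log2(ds$expr$values)
    up <- ds$truth$de_status$status == "up"
    rowMeans(sig[up, 1:5, drop = FALSE]) -
      rowMeans(sig[up, 6:8, drop = FALSE])
  }))
  expect_equal(mean(devs), 3.0, tolerance = 0.1)
})

test_that("planted correlations converge to rho in the diagnostic regime", {
  cfg <- small_cfg(seed = 4, n_case = 250, n_control = 250,
                   n_up_lnc = 0, n_down_lnc = 0, n_up_mrna = 0,
                   n_down_mrna = 0,
                   corr_pairs = data.frame(
                     lnc_index = 1:3, mrna_index = 1:3,
                     rho = c(0.9, -0.8, 0.85),
                     geometry = c("cis_near", "trans_far",
                                  "trans_diffchrom")))
  ds <- generate_dataset(cfg)
  sig <- log2(ds$expr$values)
  tp <- ds$truth$corr_pairs
  for (i in seq_len(nrow(tp))) {
    r <- cor(sig[tp$lnc_probe[i], ], sig[tp$mrna_probe[i], ])
    expect_lt(abs(r - tp$rho[i]), 0.05)
  }
})

test_that("planted geometry is realized exactly in the annotation", {
  ds <- generate_dataset(small_cfg(seed = 6, n_up_lnc = 8, n_up_mrna = 8))
  tp <- ds$truth$corr_pairs
  expect_equal(nrow(tp), 8L)
  ann <- ds$annotation
  li <- match(tp$lnc_probe, ann$probe_id)
  mi <- match(tp$mrna_probe, ann$probe_id)
  gap <- interval_gap(ann$chrom[li], ann$start[li], ann$end[li],
                      ann$chrom[mi], ann$start[mi], ann$end[mi])
  expect_equal(gap[tp$geometry == "cis_near"], rep(100000, 2))
  expect_equal(gap[tp$geometry == "cis_boundary"], rep(300000, 2))
  expect_equal(gap[tp$geometry == "trans_far"], rep(500000, 2))
  expect_true(all(is.na(gap[tp$geometry == "trans_diffchrom"])))
})

test_that("dataset round-trips through the on-disk dialects", {
  ds <- generate_dataset(small_cfg(seed = 12))
  dir <- file.path(tempdir(), "simds")
  paths <- write_dataset(ds, dir)
  back <- read_expression(paths[["matrix"]], paths[["groups"]])
  expect_identical(back$values, ds$expr$values)
  ann <- read_annotation(paths[["annotation"]])
  expect_equal(ann$biotype, ds$annotation$biotype)
  expect_equal(ann$start, ds$annotation$start)
  sets <- read_gmt(paths[["gmt"]])
  expect_identical(unclass(sets)$PLANTED_SET$members,
                   ds$gene_sets$PLANTED_SET$members)
})

test_that("the replica fixture carries the reported planted scale", {
  ds <- replica_fixture(seed = 42)
  counts <- table(ds$truth$de_status$status, ds$truth$de_status$biotype)
  expect_equal(unname(counts["up", "lncRNA"]), 49L)
  expect_equal(unname(counts["down", "lncRNA"]), 68L)
  expect_equal(unname(counts["up", "mRNA"]), 158L)
  expect_equal(unname(counts["down", "mRNA"]), 139L)
  expect_equal(sum(ds$truth$de_status$status != "ns"), 49 + 68 + 158 + 139)
  again <- replica_fixture(seed = 42)
  expect_identical(ds$expr$values, again$expr$values)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_case = 1), class = "lncnet_config_error")
  expect_error(small_cfg(n_up_lnc = 50), class = "lncnet_config_error")
  expect_error(small_cfg(corr_pairs = data.frame(
    lnc_index = 1, mrna_index = 1, rho = 1, geometry = "cis_near")),
    class = "lncnet_config_error")
  expect_error(small_cfg(corr_pairs = data.frame(
    lnc_index = 999, mrna_index = 1, rho = 0.5, geometry = "cis_near")),
    class = "lncnet_config_error")
  expect_error(small_cfg(corr_pairs = data.frame(
    lnc_index = 1, mrna_index = 1, rho = 0.5, geometry = "sideways")),
    class = "lncnet_config_error")
  expect_error(small_cfg(effect_log2fc = 9), class = "lncnet_config_error")
})
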