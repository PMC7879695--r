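test_that("interval gap follows the half-open convention and is symmetric", {
  expect_equal(interval_gap("chr1", 100, 200, "chr1", 150, 300), 0)
  expect_equal(interval_gap("chr1", 100, 200, "chr1", 500, 600), 300)
  expect_equal(interval_gap("chr1", 100, 200, "chr1", 200, 300), 0) # touching
  expect_true(is.na(interval_gap("chr1", 100, 200, "chr2", 100, 200)))
  set.seed(9)
  for (i in 1:50) {
    a <- sort(sample(1e6, 2)); b <- sort(sample(1e6, 2))
    expect_equal(interval_gap("chr3", a[1], a[2], "chr3", b[1], b[2]),
                 interval_gap("chr3", b[1], b[2], "chr3", a[1], a[2]))
  }
})

test_that("interval gap agrees with the GenomicRanges distance oracle", {
  set.seed(17)
  starts_a <- sample(1e6, 40); starts_b <- sample(1e6, 40)
  w_a <- sample(1e4, 40); w_b <- sample(1e4, 40)
  got <- interval_gap("chr1", starts_a, starts_a + w_a,
                      "chr1", starts_b, starts_b + w_b)
  gr_a <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(starts_a + 1, starts_a + w_a))
  gr_b <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(starts_b + 1, starts_b + w_b))
  expect_equal(got, GenomicRanges::distance(gr_a, gr_b))
})

reg_pairs <- function(lnc_chrom, lnc_start, mrna_chrom, mrna_start,
                      width = 1000) {
  n <- length(lnc_start)
  ann <- probe_annotation(
    c(sprintf("L%d", 1:n), sprintf("M%d", 1:n)),
    c(sprintf("lncG%d", 1:n), sprintf("mG%d", 1:n)),
    rep(c("lncRNA", "mRNA"), each = n),
    chrom = c(lnc_chrom, mrna_chrom),
    start = c(lnc_start, mrna_start),
    end = c(lnc_start, mrna_start) + width,
    strand = "+")
  pairs <- data.frame(lnc_probe = sprintf("L%d", 1:n),
                      lnc_symbol = sprintf("lncG%d", 1:n),
                      mrna_probe = sprintf("M%d", 1:n),
                      mrna_symbol = sprintf("mG%d", 1:n),
                      r = 0.9, p_value = 0.01, n = 8)
  list(pairs = pairs, ann = ann)
}

test_that("cis/trans classification pins the 300 kb boundary", {
  x <- reg_pairs(rep("chr1", 4), rep(0, 4),
                 c("chr1", "chr1", "chr1", "chr2"),
                 c(101000, 301000, 301001, 1000))
  ## gaps: 100000 (cis), exactly 300000 (cis), 300001 (trans), diff chrom
  out <- classify_cis_trans(x$pairs, x$ann)
  expect_equal(out$regulation, c("cis", "cis", "trans", "trans"))
  expect_equal(out$distance_bp, c(100000, 300000, 300001, NA))

  ## missing locus -> unclassified, and the partition is exhaustive
  ann2 <- x$ann; ann2$chrom[1] <- NA; ann2$start[1] <- NA; ann2$end[1] <- NA
  out2 <- classify_cis_trans(x$pairs, ann2)
  expect_equal(out2$regulation[1], "unclassified")
  expect_true(all(out2$regulation %in% c("cis", "trans", "unclassified")))
  expect_equal(nrow(out2), nrow(x$pairs))
})

test_that("trans network is bipartite with role-tagged, weighted edges", {
  x <- reg_pairs(rep("chr1", 3), rep(0, 3), rep("chr2", 3), rep(0, 3))
  x$pairs$lnc_symbol <- "hubL"   # star: one lncRNA, three mRNAs
  reg <- classify_cis_trans(x$pairs, x$ann)
  g <- build_trans_network(reg)
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)
  expect_equal(max(igraph::degree(g)), 3)
  expect_equal(sort(unique(igraph::V(g)$role)), c("lncRNA", "mRNA"))
  expect_true(igraph::is_bipartite(
    igraph::set_vertex_attr(g, "type", value = igraph::V(g)$role == "mRNA")))

  empty <- build_trans_network(reg[0, ])
  expect_equal(igraph::vcount(empty), 0L)

  one <- build_trans_network(reg[1, ])
  expect_equal(igraph::vcount(one), 2L)
  expect_equal(igraph::ecount(one), 1L)

  ## same symbol on both sides gets a role suffix
  x2 <- reg_pairs("chr1", 0, "chr2", 0)
  x2$pairs$lnc_symbol <- "SHARED"; x2$pairs$mrna_symbol <- "SHARED"
  g2 <- build_trans_network(classify_cis_trans(x2$pairs, x2$ann))
  expect_setequal(igraph::V(g2)$name, c("SHARED:lncRNA", "SHARED:mRNA"))
})

test_that("MNC scores reproduce the hand-checked structures", {
  tri <- adj_to_igraph(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3,
                              dimnames = rep(list(c("a", "b", "c")), 2)))
  expect_true(all(mnc_scores(tri, "open")$mnc == 2L))
  expect_true(all(mnc_scores(tri, "closed")$mnc == 3L))

  star <- igraph::make_star(4, mode = "undirected", center = 1)
  star <- igraph::set_vertex_attr(star, "name",
                                  value = c("hub", "l1", "l2", "l3"))
  open <- mnc_scores(star, "open")
  expect_equal(open$mnc[open$node_symbol == "hub"], 1L)
  closed <- mnc_scores(star, "closed")
  expect_equal(closed$mnc[closed$node_symbol == "hub"], 4L)
  expect_true(all(closed$mnc[closed$node_symbol != "hub"] == 2L))

  lone <- igraph::make_empty_graph(1, directed = FALSE)
  lone <- igraph::set_vertex_attr(lone, "name", value = "solo")
  expect_equal(mnc_scores(lone, "open")$mnc, 0L)
  expect_equal(mnc_scores(lone, "closed")$mnc, 1L)
})

test_that("MNC matches the brute-force oracle on random graphs", {
  set.seed(23)
  for (i in 1:50) {
    adj <- random_adj(sample(2:12, 1), runif(1, 0.1, 0.7))
    g <- adj_to_igraph(adj)
    for (mode in c("open", "closed")) {
      got <- mnc_scores(g, mode)
      want <- vapply(seq_len(nrow(adj)), oracle_mnc, integer(1),
                     adj = adj, mode = mode)
      expect_equal(got$mnc[match(rownames(adj), got$node_symbol)], want)
    }
  }
})

test_that("open-neighborhood MNC on a bipartite graph never exceeds 1", {
  set.seed(31)
  for (i in 1:20) {
    nl <- sample(2:6, 1); nm <- sample(2:6, 1)
    inc <- matrix(rbinom(nl * nm, 1, 0.5), nl, nm)
    adj <- rbind(cbind(matrix(0L, nl, nl), inc),
                 cbind(t(inc), matrix(0L, nm, nm)))
    dimnames(adj) <- rep(list(sprintf("n%d", seq_len(nl + nm))), 2)
    scores <- mnc_scores(adj_to_igraph(adj), "open")
    expect_true(all(scores$mnc <= 1L))
  }
})

test_that("top-k selection ranks by |r|, then p, then symbols", {
  x <- reg_pairs(rep("chr1", 3), rep(0, 3), rep("chr2", 3), rep(0, 3))
  reg <- classify_cis_trans(x$pairs, x$ann)
  reg$r <- c(0.9, -0.9, 0.8)
  reg$p_value <- c(0.02, 0.01, 0.001)
  top <- top_k_pairs(reg, k = 2)
  expect_equal(top$lnc_probe, c("L2", "L1"))  # tie on |r|: smaller p first
  expect_equal(nrow(top_k_pairs(reg, k = 100)), 3L)

  set.seed(71)
  reg150 <- reg[rep(1, 150), ]
  reg150$r <- runif(150, -1, 1)
  reg150$lnc_symbol <- sprintf("l%03d", 1:150)
  got <- top_k_pairs(reg150, k = 100)
  expect_equal(got$r, reg150$r[order(-abs(reg150$r))][1:100])

  expect_error(top_k_pairs(reg, k = 0), class = "lncnet_argument_error")
})

test_that("mRNA-mRNA edges break bipartiteness for hub scoring", {
  x <- reg_pairs(rep("chr1", 2), rep(0, 2), rep("chr2", 2), rep(0, 2))
  x$pairs$lnc_symbol <- "hubL"
  reg <- classify_cis_trans(x$pairs, x$ann)
  extra <- data.frame(sym_a = "mG1", sym_b = "mG2", r = 0.95)
  g <- build_trans_network(reg, mrna_edges = extra)
  expect_equal(igraph::ecount(g), 3L)
  open <- mnc_scores(g, "open")
  expect_equal(open$mnc[open$node_symbol == "hubL"], 2L)
})
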