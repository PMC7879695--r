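test_that("pearson_r evaluates the product-moment formula", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_r(c(2, 4, 6), c(6, 4, 2)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8,
               tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)),
               class = "lncnet_degenerate_error")
  expect_error(pearson_r(c(1, 2), c(1, 2)),
               class = "lncnet_precondition_error")
})

test_that("correlation p value follows the t transform", {
  expect_equal(corr_p_value(0, 5), 1)
  expect_equal(corr_p_value(1, 5), 0)
  expect_equal(corr_p_value(-1, 4), 0)
  expect_equal(corr_p_value(0.8, 8), 0.01712, tolerance = 1e-10)
  expect_error(corr_p_value(0.5, 2), class = "lncnet_precondition_error")

  set.seed(77)
  for (i in 1:1000) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n) + runif(1, -1, 1) * x
    ref <- cor.test(x, y)
    expect_equal(corr_p_value(cor(x, y), n), ref$p.value,
                 tolerance = 1e-10)
  }
})

test_that("pearson r equals the signed square root of the regression R2", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    x <- rnorm(n); y <- rnorm(n) + runif(1, -2, 2) * x
    fit <- lm(y ~ x)
    r <- pearson_r(x, y)
    expect_equal(abs(r), sqrt(summary(fit)$r.squared), tolerance = 1e-12)
    expect_equal(sign(r), sign(coef(fit)[["x"]]))
  }
})

de_frame <- function(probes, biotype, symbols = probes) {
  data.frame(probe_id = probes, gene_symbol = symbols, biotype = biotype,
             status = "up", stringsAsFactors = FALSE)
}

test_that("co-expression screen retains pairs by strict thresholds", {
  s <- seq_len(8)
  vals <- rbind(L1 = s, M1 = 2 * s + 3, M2 = c(5, 2, 8, 1, 9, 3, 7, 4))
  colnames(vals) <- sprintf("S%d", 1:8)
  m <- make_expr(vals, scale_tag = "log2",
                 groups = setNames(rep(c("tibetan", "han"), c(5, 3)),
                                   colnames(vals)))
  de <- de_frame(c("L1", "M1", "M2"), c("lncRNA", "mRNA", "mRNA"))
  out <- coexpression_screen(m, de)
  expect_equal(nrow(out$pairs), 1L)
  expect_equal(out$pairs$r, 1)
  expect_equal(out$pairs$n, 8L)
  expect_equal(dim(out$grid), c(1L, 2L))   # full grid kept for the heat map

  ## a pair whose |r| equals the threshold exactly is NOT retained
  r_m2 <- cor(vals["L1", ], vals["M2", ])
  at_boundary <- coexpression_screen(m, de, r_threshold = abs(r_m2))
  expect_false("M2" %in% at_boundary$pairs$mrna_probe)

  below <- coexpression_screen(m, de, r_threshold = 0.999999)
  expect_equal(nrow(below$pairs), 1L)      # only the perfect pair survives
})

test_that("sample scope restricts to the case group when asked", {
  set.seed(5)
  vals <- matrix(rnorm(4 * 8), 4, 8,
                 dimnames = list(c("L1", "L2", "M1", "M2"),
                                 sprintf("S%d", 1:8)))
  m <- make_expr(vals, scale_tag = "log2",
                 groups = setNames(rep(c("tibetan", "han"), c(5, 3)),
                                   colnames(vals)))
  de <- de_frame(rownames(vals), c("lncRNA", "lncRNA", "mRNA", "mRNA"))
  all_scope <- coexpression_screen(m, de, r_threshold = 0, p_threshold = 1)
  expect_true(all(all_scope$pairs$n == 8L))
  case_scope <- coexpression_screen(m, de, sample_scope = "case_only",
                                    case_label = "tibetan",
                                    r_threshold = 0, p_threshold = 1)
  expect_true(all(case_scope$pairs$n == 5L))
  expect_equal(case_scope$grid[1, 1],
               cor(vals["L1", 1:5], vals["M1", 1:5]))
  expect_error(coexpression_screen(m, de, sample_scope = "case_only"),
               class = "lncnet_argument_error")
})

test_that("zero-variance probes are skipped with a warning, not an abort", {
  vals <- rbind(L1 = c(1, 2, 3, 4, 5, 6, 7, 8), L2 = rep(2, 8),
                M1 = c(8, 7, 6, 5, 4, 3, 2, 1))
  colnames(vals) <- sprintf("S%d", 1:8)
  m <- make_expr(vals, scale_tag = "log2")
  de <- de_frame(rownames(vals), c("lncRNA", "lncRNA", "mRNA"))
  expect_warning(out <- coexpression_screen(m, de), "zero-variance")
  expect_equal(nrow(out$pairs), 1L)
  expect_equal(out$pairs$r, -1)
})

test_that("retained pairs come sorted by |r| then symbols, deterministically", {
  set.seed(40)
  n <- 8
  vals <- matrix(rnorm(12 * n), 12, n,
                 dimnames = list(c(sprintf("L%d", 1:6), sprintf("M%d", 1:6)),
                                 sprintf("S%d", seq_len(n))))
  m <- make_expr(vals, scale_tag = "log2")
  de <- de_frame(rownames(vals), rep(c("lncRNA", "mRNA"), each = 6))
  out <- coexpression_screen(m, de, r_threshold = 0, p_threshold = 1)
  expect_equal(nrow(out$pairs), 36L)
  expect_true(all(diff(abs(out$pairs$r)) <= 1e-15))
  again <- coexpression_screen(m, de, r_threshold = 0, p_threshold = 1)
  expect_identical(out$pairs, again$pairs)
})
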