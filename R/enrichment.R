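#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ hypergeometric(N, K, n): drawing `n` genes from a
#' universe of `N` of which `K` belong to the set, the probability of an
#' overlap at least as large as the one observed. Computed by exact
#' summation of the point masses in log space (numerically safe for large
#' universes).
#'
#' @param k observed overlap.
#' @param K set size within the universe.
#' @param n gene-list size within the universe.
#' @param N universe size.
#' @return The upper-tail probability in (0, 1\].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (K > N || n > N || k < 0 || k > min(K, n))
    abort("inconsistent hypergeometric counts", "argument_error")
  if (k == 0) return(1)
  i <- k:min(K, n)
  lp <- stats::dhyper(i, K, N - K, n, log = TRUE)
  m <- max(lp)
  min(1, exp(m) * sum(exp(lp - m)))
}

#' Over-representation analysis of a gene list against gene sets
#'
#' Local one-sided (over-representation) hypergeometric test of a
#' differentially expressed gene list against every set of a GMT
#' collection, with Benjamini-Hochberg adjustment across the tested sets.
#' Genes outside the declared universe are dropped from both list and sets
#' (with a message of the dropped count), so results depend only on
#' intersections with the universe. Sets with no member in the universe are
#' not tested.
#'
#' @param de_symbols character vector of gene symbols (the DE list).
#' @param sets a `gene_set_collection` from [read_gmt()].
#' @param universe background gene symbols (conventionally all mRNA symbols
#'   on the array).
#' @return A data.frame sorted by p ascending with columns `set_name`,
#'   `k_overlap`, `K_set`, `n_list`, `N_universe`, `p_value`, `adj_p`,
#'   `gene_ratio`, `overlap_symbols` (comma-joined).
#' @export
ora <- function(de_symbols, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) abort("empty universe", "argument_error")
  de0 <- unique(de_symbols)
  de <- intersect(de0, universe)
  dropped <- length(de0) - length(de)
  if (dropped)
    message(sprintf("ora: %d DE symbols outside the universe dropped",
                    dropped))
  if (!length(de)) {
    warning("ora: empty DE list after intersecting with the universe")
    return(data.frame(set_name = character(0), k_overlap = integer(0),
                      K_set = integer(0), n_list = integer(0),
                      N_universe = integer(0), p_value = numeric(0),
                      adj_p = numeric(0), gene_ratio = numeric(0),
                      overlap_symbols = character(0)))
  }
  N <- length(universe); n <- length(de)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]]$members, universe)
    K <- length(members)
    if (!K) return(NULL)
    hits <- intersect(members, de)
    data.frame(set_name = nm, k_overlap = length(hits), K_set = K,
               n_list = n, N_universe = N,
               p_value = hypergeom_upper_tail(length(hits), K, n, N),
               gene_ratio = length(hits) / n,
               overlap_symbols = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) abort("no gene set overlaps the universe",
                          "argument_error")
  out$adj_p <- bh_adjust(out$p_value)
  out <- out[, c("set_name", "k_overlap", "K_set", "n_list", "N_universe",
                 "p_value", "adj_p", "gene_ratio", "overlap_symbols")]
  out[order(out$p_value, out$set_name, method = "radix"), , drop = FALSE]
}
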