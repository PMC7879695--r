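## Independent brute-force oracles and small fixture builders shared by the
## unit and acceptance tests. Everything here is deliberately naive and kept
## separate from the package's own code paths.

## step-up false-discovery-rate adjustment, written out longhand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  cummin(pmin(1, m / (m:1) * p[o]))[ro]
}

## pooled two-sample t via stats::t.test (the reference implementation)
oracle_t <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t_stat = unname(tt$statistic), p_value = tt$p.value)
}

## neighborhood-component score by exhaustive search on an adjacency matrix
oracle_mnc <- function(adj, v, mode = c("open", "closed")) {
  mode <- match.arg(mode)
  nb <- which(adj[v, ] != 0)
  if (mode == "closed") nb <- sort(unique(c(nb, v)))
  if (!length(nb)) return(0L)
  sub <- adj[nb, nb, drop = FALSE]
  seen <- rep(FALSE, length(nb))
  best <- 0L
  for (s in seq_along(nb)) {
    if (seen[s]) next
    stack <- s; comp <- 0L
    while (length(stack)) {
      u <- stack[[1L]]; stack <- stack[-1L]
      if (seen[u]) next
      seen[u] <- TRUE; comp <- comp + 1L
      stack <- c(stack, which(sub[u, ] != 0 & !seen))
    }
    best <- max(best, comp)
  }
  best
}

## hypergeometric upper tail by enumerating every draw of n items from N
oracle_hyper_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

## random undirected graph as an adjacency matrix with named vertices
random_adj <- function(n, p_edge = 0.3) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- stats::rbinom(n * (n - 1) / 2, 1L, p_edge)
  adj <- adj + t(adj)
  dimnames(adj) <- list(sprintf("N%02d", seq_len(n)),
                        sprintf("N%02d", seq_len(n)))
  adj
}

adj_to_igraph <- function(adj)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")

## small in-memory expression matrix with two groups
make_expr <- function(values, scale_tag = "raw",
                      groups = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%d", seq_len(ncol(values)))
  if (is.null(groups)) {
    half <- ceiling(ncol(values) / 2)
    groups <- stats::setNames(rep(c("tibetan", "han"),
                                  c(half, ncol(values) - half)),
                              colnames(values))
  }
  expr_matrix(values, groups, scale_tag = scale_tag)
}

## minimal annotation for probes P1..Pn alternating biotypes
make_ann <- function(n, biotype = rep(c("lncRNA", "mRNA"), length.out = n)) {
  probe_annotation(sprintf("P%d", seq_len(n)),
                   sprintf("G%d", seq_len(n)), biotype,
                   chrom = "chr1", start = seq_len(n) * 1e6,
                   end = seq_len(n) * 1e6 + 1000, strand = "+")
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
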