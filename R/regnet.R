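#' Genomic gap between two loci
#'
#' Loci are BED-style half-open intervals. Different chromosomes give `NA`
#' (no finite distance); overlapping or touching intervals give 0; otherwise
#' the number of bases strictly between the intervals. Symmetric in its
#' arguments and strand-blind.
#'
#' @param chrom_a,start_a,end_a first locus (0-based start, half-open end).
#' @param chrom_b,start_b,end_b second locus.
#' @return Gap in base pairs, or `NA` for different chromosomes
#'   (vectorized).
#' @export
interval_gap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  gap <- pmax(0, pmax(start_a, start_b) - pmin(end_a, end_b))
  gap[chrom_a != chrom_b] <- NA_real_
  gap
}

#' Classify co-expressed pairs as cis or trans by genomic distance
#'
#' A significant lncRNA-mRNA pair is *cis* when both loci lie on the same
#' chromosome with a gap of at most `window_bp` (the mRNA locus inside a
#' window extending `window_bp` up- and downstream of the lncRNA; the
#' boundary gap equal to the window is cis, because trans is defined by a
#' distance strictly larger than the window). It is *trans* when the loci
#' sit on different chromosomes or farther apart than the window. Pairs for
#' which either probe lacks a locus are `unclassified`. The distance is the
#' minimal gap between the whole gene intervals, not TSS-to-TSS;
#' `anchor = "tss"` switches to the distance between transcription start
#' sites (strand-aware 5' ends).
#'
#' @param pairs the `pairs` data.frame from [coexpression_screen()].
#' @param ann a `probe_annotation`.
#' @param window_bp cis window in base pairs (default 300000).
#' @param anchor `"interval"` (minimal gap, default) or `"tss"`.
#' @return The input with columns `regulation` (`cis`/`trans`/
#'   `unclassified`) and `distance_bp` (`NA` for different chromosomes or
#'   missing loci) appended.
#' @export
classify_cis_trans <- function(pairs, ann, window_bp = 300000,
                               anchor = c("interval", "tss")) {
  anchor <- match.arg(anchor)
  li <- match(pairs$lnc_probe, ann$probe_id)
  mi <- match(pairs$mrna_probe, ann$probe_id)
  if (anyNA(li) || anyNA(mi))
    abort("pair probe missing from annotation", "validation_error")
  has <- !is.na(ann$chrom[li]) & !is.na(ann$chrom[mi])
  dist <- rep(NA_real_, nrow(pairs))
  if (anchor == "interval") {
    dist[has] <- interval_gap(ann$chrom[li][has], ann$start[li][has],
                              ann$end[li][has], ann$chrom[mi][has],
                              ann$start[mi][has], ann$end[mi][has])
  } else {
    tss <- function(i) ifelse(!is.na(ann$strand[i]) & ann$strand[i] == "-",
                              ann$end[i] - 1, ann$start[i])
    d <- abs(tss(li)[has] - tss(mi)[has])
    d[ann$chrom[li][has] != ann$chrom[mi][has]] <- NA_real_
    dist[has] <- d
  }
  samechr <- has & ann$chrom[li] == ann$chrom[mi]
  regulation <- rep("unclassified", nrow(pairs))
  regulation[has & !samechr] <- "trans"
  regulation[samechr & dist <= window_bp] <- "cis"
  regulation[samechr & dist > window_bp] <- "trans"
  out <- pairs
  out$regulation <- regulation
  out$distance_bp <- dist
  out
}

#' Build the undirected bipartite trans-regulation network
#'
#' Nodes are gene symbols tagged with their role (lncRNA or mRNA); edges are
#' the trans pairs, weighted by |r|. A symbol occurring as both a lncRNA and
#' an mRNA is disambiguated with a role suffix (`sym:lncRNA`, `sym:mRNA`).
#'
#' Open-neighborhood MNC is degenerate on a strictly bipartite graph (every
#' score is at most 1); to obtain an informative hub ranking either use the
#' closed neighborhood in [mnc_scores()] or supply `mrna_edges`, mRNA-mRNA
#' co-expression edges above the same correlation threshold, which break
#' the bipartite structure.
#'
#' @param pairs output of [classify_cis_trans()]; only rows with
#'   `regulation == "trans"` contribute edges.
#' @param mrna_edges optional data.frame with columns `sym_a`, `sym_b`, `r`
#'   of mRNA-mRNA co-expression edges to add.
#' @return An [igraph][igraph::graph_from_data_frame] graph with vertex
#'   attribute `role` and edge attribute `weight`.
#' @export
build_trans_network <- function(pairs, mrna_edges = NULL) {
  tp <- pairs[pairs$regulation == "trans", , drop = FALSE]
  if (!nrow(tp) && is.null(mrna_edges))
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  lsym <- tp$lnc_symbol; msym <- tp$mrna_symbol
  clash <- intersect(unique(lsym), unique(msym))
  if (length(clash)) {
    lsym[lsym %in% clash] <- paste0(lsym[lsym %in% clash], ":lncRNA")
    msym[msym %in% clash] <- paste0(msym[msym %in% clash], ":mRNA")
  }
  edges <- data.frame(from = lsym, to = msym, weight = abs(tp$r))
  if (!is.null(mrna_edges) && nrow(mrna_edges)) {
    ma <- mrna_edges$sym_a; mb <- mrna_edges$sym_b
    ma[ma %in% clash] <- paste0(ma[ma %in% clash], ":mRNA")
    mb[mb %in% clash] <- paste0(mb[mb %in% clash], ":mRNA")
    msym <- c(msym, ma, mb)
    edges <- rbind(edges, data.frame(from = ma, to = mb,
                                     weight = abs(mrna_edges$r)))
  }
  verts <- rbind(data.frame(name = unique(lsym), role = "lncRNA"),
                 data.frame(name = setdiff(unique(msym), unique(lsym)),
                            role = "mRNA"))
  ## parallel edges (same symbol pair via several probes) collapse to the
  ## strongest correlation
  edges <- edges[order(-edges$weight, method = "radix"), ]
  edges <- edges[!duplicated(paste(edges$from, edges$to, sep = "\r")), ]
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Maximum-neighborhood-component hub scores
#'
#' For every node v the MNC score is the order of the largest connected
#' component of the subgraph induced by v's neighborhood: the open
#' neighborhood N(v) (the cytoHubba definition, default) or the closed
#' neighborhood N(v) + v. An isolated node scores 0 (open) or 1 (closed).
#' On a strictly bipartite graph the open-neighborhood score is at most 1
#' for every node (neighbors of a node all lie on the other side and are
#' mutually non-adjacent), which is why the closed mode is offered for
#' ranking bipartite lncRNA-mRNA networks.
#'
#' @param g an igraph graph with vertex attribute `role` (as produced by
#'   [build_trans_network()]; plain graphs get role `NA`).
#' @param neighborhood `"open"` (default) or `"closed"`.
#' @return A data.frame `node_symbol`, `role`, `degree`, `mnc`, sorted by
#'   `mnc` descending with ties broken by symbol.
#' @export
mnc_scores <- function(g, neighborhood = c("open", "closed")) {
  neighborhood <- match.arg(neighborhood)
  nv <- igraph::vcount(g)
  if (!nv)
    return(data.frame(node_symbol = character(0), role = character(0),
                      degree = integer(0), mnc = integer(0)))
  syms <- igraph::V(g)$name
  roles <- if ("role" %in% igraph::vertex_attr_names(g))
    igraph::V(g)$role else rep(NA_character_, nv)
  deg <- igraph::degree(g)
  mnc <- vapply(seq_len(nv), function(v) {
    nb <- as.integer(igraph::neighbors(g, v))
    if (neighborhood == "closed") nb <- unique(c(nb, v))
    if (!length(nb)) return(0L)
    sub <- igraph::induced_subgraph(g, nb)
    as.integer(max(igraph::components(sub)$csize))
  }, integer(1))
  out <- data.frame(node_symbol = syms, role = roles,
                    degree = as.integer(deg), mnc = mnc,
                    stringsAsFactors = FALSE)
  out[order(-out$mnc, out$node_symbol, method = "radix"), , drop = FALSE]
}

#' Select the top-k regulatory pairs by correlation strength
#'
#' Pairs of the requested regulation class ranked by |r| descending, ties
#' broken by p ascending then by (lncRNA symbol, mRNA symbol); the first
#' `min(k, available)` are returned. The default reproduces a "top 100
#' trans interactions" table.
#'
#' @param pairs output of [classify_cis_trans()].
#' @param k number of pairs to keep (default 100).
#' @param class_filter `"trans"` (default), `"cis"` or `"any"`.
#' @return The selected rows, re-ranked.
#' @export
top_k_pairs <- function(pairs, k = 100, class_filter = c("trans", "cis", "any")) {
  class_filter <- match.arg(class_filter)
  if (k < 1) abort("k must be >= 1", "argument_error")
  sel <- if (class_filter == "any") pairs
         else pairs[pairs$regulation == class_filter, , drop = FALSE]
  ord <- order(-abs(sel$r), sel$p_value, sel$lnc_symbol, sel$mrna_symbol,
               method = "radix")
  utils::head(sel[ord, , drop = FALSE], k)
}
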