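# Independent oracles used across the suite.

# Naive substring-scanning de Bruijn graph builder: every quantity is
# recomputed by brute-force string scans, independently of the package's
# construction path.
naive_dbg <- function(reads, k, min_support = 1L) {
  reads <- toupper(reads)
  reads <- reads[nchar(reads) >= k]
  all_kmers <- character(0)
  for (r in reads) {
    for (i in seq_len(nchar(r) - k + 1L)) {
      all_kmers <- c(all_kmers, substr(r, i, i + k - 1L))
    }
  }
  vertices <- unique(all_kmers)
  support <- vapply(vertices, function(v) {
    sum(vapply(reads, function(r) grepl(v, r, fixed = TRUE), logical(1)))
  }, integer(1))
  edges <- character(0)
  for (r in reads) {
    if (nchar(r) < k + 1L) next
    for (i in seq_len(nchar(r) - k)) {
      edges <- c(edges, paste(substr(r, i, i + k - 1L),
                              substr(r, i + 1L, i + k), sep = ">"))
    }
  }
  edges <- unique(edges)
  keep <- vertices[support >= min_support]
  ef <- sub(">.*", "", edges); et <- sub(".*>", "", edges)
  list(vertices = sort(keep),
       support = support[keep],
       edges = sort(edges[ef %in% keep & et %in% keep]))
}

# Exhaustive simple-path enumeration between vertex sets via igraph,
# filtered by the same structural rules as the alternative-path search.
igraph_alt_paths <- function(diff, ref) {
  skip_if_not_installed("igraph")
  if (nrow(diff$edges) == 0L) return(character(0))
  g <- igraph::graph_from_data_frame(diff$edges, directed = TRUE)
  vs <- igraph::V(g)$name
  outdeg <- igraph::degree(g, mode = "out")
  indeg <- igraph::degree(g, mode = "in")
  in_ref <- stats::setNames(vs %in% ref$vertices, vs)
  starts <- vs[outdeg > 0 & (in_ref[vs] | indeg == 0)]
  ends <- vs[indeg > 0 & (in_ref[vs] | outdeg == 0)]
  seqs <- character(0)
  for (s in starts) {
    for (e in ends) {
      if (s == e) next
      ps <- suppressWarnings(
        igraph::all_simple_paths(g, from = s, to = e, mode = "out"))
      for (p in ps) {
        nm <- names(p)
        interior <- nm[-c(1L, length(nm))]
        if (any(in_ref[interior])) next
        # terminal vertices must be path-terminal per the split rule: a
        # non-reference end must be a true tip (no outgoing edge)
        if (!in_ref[nm[length(nm)]] && outdeg[nm[length(nm)]] > 0) next
        if (!in_ref[nm[1L]] && indeg[nm[1L]] > 0) next
        seqs <- c(seqs, spell(nm))
      }
    }
  }
  sort(unique(seqs))
}
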