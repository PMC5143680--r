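# Explicit-edge colored de Bruijn graphs over reference sequences and reads.
#
# Vertices are k-mers; an edge (v, w) exists only when the spelled (k+1)-mer
# v + last(w) occurs in at least one source sequence ("explicit" edges), so
# every walk in the graph spells a sequence present in the input.

#' Decompose a sequence into its ordered k-mers
#'
#' Returns the `nchar(sequence) - k + 1` substrings of length `k`, in order.
#' Consecutive k-mers overlap by `k - 1` characters.
#'
#' @param sequence A single DNA string (A/C/G/T; case-insensitive).
#' @param k K-mer length, an integer `>= 2`.
#' @param on_invalid How to treat non-ACGT characters: `"split"` (default)
#'   drops every k-mer window that spans an invalid character, so k-mers come
#'   only from clean segments; `"drop"` returns `character(0)`; `"error"`
#'   aborts.
#' @return Character vector of k-mers (possibly empty). A sequence shorter
#'   than `k` yields `character(0)` with a warning.
#' @examples
#' kmerize("CGATTTGAA", 3)
#' @export
kmerize <- function(sequence, k, on_invalid = c("split", "drop", "error")) {
  on_invalid <- match.arg(on_invalid)
  check_k(k)
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  sequence <- toupper(sequence)
  if (nchar(sequence) < k) {
    warning("sequence shorter than k (", nchar(sequence), " < ", k,
            "); skipping", call. = FALSE)
    return(character(0))
  }
  if (grepl("[^ACGT]", sequence)) {
    if (on_invalid == "error") {
      stop("sequence contains non-ACGT characters", call. = FALSE)
    }
    if (on_invalid == "drop") return(character(0))
  }
  unlist(kmer_segments(sequence, k), use.names = FALSE)
}

# Split a sequence at non-ACGT characters and k-merize each clean segment.
# Returns a list of k-mer vectors; consecutive k-mers within one element are
# consecutive in the read (needed for edge construction), k-mers in different
# elements are not.
kmer_segments <- function(sequence, k) {
  segs <- strsplit(toupper(sequence), "[^ACGT]+")[[1]]
  segs <- segs[nchar(segs) >= k]
  lapply(segs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  })
}

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 2 || k != round(k)) {
    stop("k must be a single integer >= 2", call. = FALSE)
  }
  invisible(as.integer(k))
}

#' Spell the sequence of a walk
#'
#' Concatenates a walk of overlapping k-mers back into the DNA string it
#' encodes: the first k-mer followed by the last character of each subsequent
#' one. `kmerize(spell(p), k)` reproduces `p`.
#'
#' @param path Character vector of k-mers forming a walk (consecutive k-mers
#'   must overlap by `k - 1` characters).
#' @return A single DNA string of length `k + length(path) - 1`.
#' @examples
#' spell(c("TTC", "TCA", "CAA", "AAC"))
#' @export
spell <- function(path) {
  stopifnot(is.character(path), length(path) >= 1L)
  k <- nchar(path[1L])
  if (any(nchar(path) != k)) stop("all k-mers must have equal length", call. = FALSE)
  if (length(path) > 1L) {
    ok <- substring(path[-length(path)], 2L, k) == substring(path[-1L], 1L, k - 1L)
    if (!all(ok)) {
      stop("path is not a walk: consecutive k-mers must overlap by k-1",
           call. = FALSE)
    }
  }
  paste0(path[1L], paste(substring(path[-1L], k, k), collapse = ""))
}

# Shared constructor: vertices/edges/adjacency from a list of per-sequence
# k-mer segment lists. `per_source` is a list (one element per source) of
# lists of k-mer runs.
dbg_core <- function(per_source, k) {
  edge_from <- character(0)
  edge_to <- character(0)
  for (runs in per_source) {
    for (run in runs) {
      if (length(run) >= 2L) {
        edge_from <- c(edge_from, run[-length(run)])
        edge_to <- c(edge_to, run[-1L])
      }
    }
  }
  key <- paste(edge_from, edge_to, sep = ">")
  dup <- duplicated(key)
  list(
    vertices = unique(unlist(per_source, use.names = FALSE)),
    edges = data.frame(from = edge_from[!dup], to = edge_to[!dup],
                       stringsAsFactors = FALSE)
  )
}

adjacency <- function(edges) {
  if (nrow(edges) == 0L) return(list())
  lapply(split(edges$to, edges$from), unique)
}

#' Build the reference graph
#'
#' Constructs an explicit-edge colored de Bruijn graph from one or more
#' labeled reference sequences (e.g. splicing variants plus known-SNP
#' haplotypes). Each vertex records the set of reference labels ("colors")
#' whose sequence contains its k-mer, and each reference corresponds to a
#' walk through vertices carrying its label.
#'
#' @param references Named character vector of reference sequences (names are
#'   the labels), or an unnamed vector (labels `ref1`, `ref2`, ...).
#' @param k K-mer length.
#' @param primary Label of the coordinate backbone used to position variants;
#'   defaults to the first reference.
#' @return An object of class `reference_graph` with elements `k`, `vertices`,
#'   `edges`, `adj` (out-adjacency), `labels` (vertex -> label set),
#'   `sequences`, `walks` (per-reference k-mer walks) and `primary`.
#' @export
build_reference_graph <- function(references, k, primary = NULL) {
  k <- check_k(k)
  if (length(references) == 0L) stop("empty reference set", call. = FALSE)
  references <- toupper(unlist(references))
  if (is.null(names(references)) || any(names(references) == "")) {
    names(references) <- paste0("ref", seq_along(references))
  }
  if (any(nchar(references) < k)) {
    stop("every reference sequence must be at least k long", call. = FALSE)
  }
  if (is.null(primary)) primary <- names(references)[1L]
  if (!primary %in% names(references)) {
    stop("primary label not among reference names", call. = FALSE)
  }
  per_source <- lapply(references, kmer_segments, k = k)
  core <- dbg_core(per_source, k)
  lab_df <- unique(data.frame(
    kmer = unlist(per_source, use.names = FALSE),
    label = rep(names(references),
                vapply(per_source, function(r) sum(lengths(r)), integer(1))),
    stringsAsFactors = FALSE
  ))
  g <- list(
    k = k,
    vertices = core$vertices,
    edges = core$edges,
    adj = adjacency(core$edges),
    labels = split(lab_df$label, lab_df$kmer),
    sequences = references,
    walks = lapply(per_source, function(r) unlist(r, use.names = FALSE)),
    primary = primary
  )
  class(g) <- c("reference_graph", "colored_dbg")
  g
}

#' Build a sample graph from sequencing reads
#'
#' Constructs the single-color explicit-edge de Bruijn graph of one sample's
#' read set. The read support `r(v)` of a vertex is the number of reads its
#' k-mer appears in (each read counted at most once). Vertices with
#' `r(v) < min_support` are removed together with their incident edges, which
#' discards most singleton sequencing errors.
#'
#' @param reads Character vector of read sequences (assumed forward-oriented;
#'   see [orient_reads()]).
#' @param k K-mer length.
#' @param min_support Minimum read support for a vertex to be retained
#'   (default 2).
#' @param sample_id Optional sample label stored on the object.
#' @return An object of class `sample_graph` with elements `k`, `vertices`,
#'   `support` (named integer vector), `edges`, `adj`, `reads` (the retained
#'   read sequences), `min_support`, `sample_id`.
#' @export
build_sample_graph <- function(reads, k, min_support = 2, sample_id = NULL) {
  k <- check_k(k)
  stopifnot(is.character(reads), length(reads) >= 1L)
  reads <- toupper(reads)
  short <- nchar(reads) < k
  if (all(short)) stop("all reads are shorter than k", call. = FALSE)
  if (any(short)) {
    warning(sum(short), " read(s) shorter than k dropped", call. = FALSE)
    reads <- reads[!short]
  }
  per_read <- lapply(reads, kmer_segments, k = k)
  per_read_unique <- lapply(per_read, function(r) unique(unlist(r, use.names = FALSE)))
  support_tab <- table(unlist(per_read_unique, use.names = FALSE))
  support <- as.integer(support_tab)
  names(support) <- names(support_tab)
  core <- dbg_core(per_read, k)
  keep <- names(support)[support >= min_support]
  edges <- core$edges[core$edges$from %in% keep & core$edges$to %in% keep, ,
                      drop = FALSE]
  rownames(edges) <- NULL
  g <- list(
    k = k,
    vertices = keep,
    support = support[keep],
    edges = edges,
    adj = adjacency(edges),
    reads = reads,
    min_support = min_support,
    sample_id = sample_id
  )
  class(g) <- c("sample_graph", "colored_dbg")
  g
}

#' Read support of a vertex
#'
#' @param sample A `sample_graph`.
#' @param v A k-mer string.
#' @return Number of retained reads containing `v` (0 if the vertex was
#'   removed or never seen).
#' @export
vertex_support <- function(sample, v) {
  stopifnot(inherits(sample, "sample_graph"))
  s <- sample$support[v]
  s[is.na(s)] <- 0L
  unname(s)
}

#' Read support of a path
#'
#' A read supports a path iff it contains all consecutive k-mers of the path
#' in order, which is equivalent to containing the path's spelled sequence as
#' a contiguous substring.
#'
#' @param sample A `sample_graph`.
#' @param path Character vector of k-mers forming a walk.
#' @return Integer count of supporting reads.
#' @export
path_read_support <- function(sample, path) {
  stopifnot(inherits(sample, "sample_graph"))
  if (length(path) == 0L) stop("empty path", call. = FALSE)
  seq_read_support(sample$reads, spell(path))
}

# Substring-based support of a spelled sequence in a read vector.
seq_read_support <- function(reads, seq) {
  sum(grepl(seq, reads, fixed = TRUE))
}

#' Orient reads against a reference
#'
#' Reverse-complements a read when it shares more k-mers with the primary
#' reference after reverse complement than before (shared-k-mer voting). Reads
#' from protocols that report both strands can be passed through this before
#' graph construction.
#'
#' @param reads Character vector of reads.
#' @param reference A single reference sequence (or a `reference_graph`, whose
#'   primary sequence is used).
#' @param k K-mer length used for the vote.
#' @return Character vector of oriented reads.
#' @export
orient_reads <- function(reads, reference, k) {
  k <- check_k(k)
  if (inherits(reference, "reference_graph")) {
    reference <- reference$sequences[[reference$primary]]
  }
  ref_kmers <- unique(kmerize(reference, k))
  vapply(reads, function(r) {
    fwd <- sum(unique(unlist(kmer_segments(r, k))) %in% ref_kmers)
    rc <- revcomp(r)
    rev <- sum(unique(unlist(kmer_segments(rc, k))) %in% ref_kmers)
    if (rev > fwd) rc else toupper(r)
  }, character(1), USE.NAMES = FALSE)
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) {
           paste(rev(strsplit(toupper(s), "")[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

#' Export a graph as GFA1
#'
#' Writes one S-line per k-mer vertex and one L-line per edge (k-1 overlap),
#' for inspection in graph viewers.
#'
#' @param graph A `sample_graph` or `reference_graph`.
#' @param path Output file path.
#' @return Invisibly, the output path.
#' @export
export_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "colored_dbg"))
  ids <- seq_along(graph$vertices)
  names(ids) <- graph$vertices
  s_lines <- paste("S", ids, graph$vertices, sep = "\t")
  l_lines <- character(0)
  if (nrow(graph$edges) > 0L) {
    l_lines <- paste("L", ids[graph$edges$from], "+", ids[graph$edges$to], "+",
                     paste0(graph$k - 1L, "M"), sep = "\t")
  }
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines), path)
  invisible(path)
}

#' @export
print.colored_dbg <- function(x, ...) {
  kind <- if (inherits(x, "reference_graph")) "reference" else "sample"
  cat(sprintf("%s de Bruijn graph (k = %d): %d vertices, %d edges\n",
              kind, x$k, length(x$vertices), nrow(x$edges)))
  if (inherits(x, "reference_graph")) {
    cat(sprintf("  %d reference sequence(s); primary: %s\n",
                length(x$sequences), x$primary))
  } else {
    cat(sprintf("  %d read(s); min_support = %d\n",
                length(x$reads), x$min_support))
  }
  invisible(x)
}

#' Walk length between two reference vertices
#'
#' Number of edges on the shortest directed walk from `from` to `to` in the
#' reference graph (breadth-first search), as used by the tip-anchoring
#' heuristic.
#'
#' @param ref A `reference_graph`.
#' @param from,to K-mer vertices.
#' @return Integer edge count, or `NA` if no walk exists.
#' @export
reference_walk_distance <- function(ref, from, to) {
  stopifnot(inherits(ref, "reference_graph"))
  if (!from %in% ref$vertices || !to %in% ref$vertices) return(NA_integer_)
  if (from == to) return(0L)
  dist <- c(stats::setNames(0L, from))
  frontier <- from
  while (length(frontier) > 0L) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in ref$adj[[v]]) {
        if (!w %in% names(dist)) {
          dist[w] <- dist[[v]] + 1L
          if (w == to) return(unname(dist[w]))
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  NA_integer_
}
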