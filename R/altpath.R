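# Alternative-path search: difference graph, path enumeration, tip anchoring,
# reference-path choice, atomic decomposition into edit operations, and
# mapping of alterations onto the primary reference.

#' Difference graph between a sample and the reference
#'
#' The difference graph has vertex set `V* = V_s` union `V_ref` and edge set
#' `E* = E_s \ E_ref`: exactly the sample edges that the reference does not
#' explain. Shared k-mers with no alternative edge remain as singleton
#' vertices.
#'
#' @param sample A `sample_graph`.
#' @param ref A `reference_graph` built with the same `k`.
#' @return An object of class `difference_graph` with `k`, `vertices`,
#'   `edges`, `adj`, and logical lookups `in_ref`, `in_sample` (named by
#'   vertex).
#' @export
difference_graph <- function(sample, ref) {
  stopifnot(inherits(sample, "sample_graph"), inherits(ref, "reference_graph"))
  if (sample$k != ref$k) {
    stop("sample and reference graphs were built with different k", call. = FALSE)
  }
  ref_keys <- paste(ref$edges$from, ref$edges$to, sep = ">")
  smp_keys <- paste(sample$edges$from, sample$edges$to, sep = ">")
  edges <- sample$edges[!smp_keys %in% ref_keys, , drop = FALSE]
  rownames(edges) <- NULL
  vertices <- union(sample$vertices, ref$vertices)
  in_ref <- stats::setNames(vertices %in% ref$vertices, vertices)
  in_sample <- stats::setNames(vertices %in% sample$vertices, vertices)
  g <- list(k = sample$k, vertices = vertices, edges = edges,
            adj = adjacency(edges), in_ref = in_ref, in_sample = in_sample)
  class(g) <- "difference_graph"
  g
}

#' @export
print.difference_graph <- function(x, ...) {
  cat(sprintf("difference graph (k = %d): %d vertices, %d alternative edges\n",
              x$k, length(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Enumerate alternative paths in a difference graph
#'
#' Walks the alternative edges `E*` depth-first and returns every simple path
#' that (i) starts at a vertex with positive out-degree in `E*` which is
#' either a reference vertex or a tip (no incoming alternative edge), (ii)
#' ends at a reference vertex or at a vertex with no outgoing alternative
#' edge (a tip), and (iii) has no interior reference vertex. Composite paths
#' are split at interior reference vertices: the continuation is enumerated
#' as its own path. Paths whose simple-path extension would exceed `max_len`
#' edges are truncated out (counted in the `dropped` attribute), as are
#' dead ends closed by cycles.
#'
#' @param diff A `difference_graph`.
#' @param ref The `reference_graph` used to build it.
#' @param sample The `sample_graph`, used to compute read support.
#' @param max_len Maximum path length in edges (default `10 * k`).
#' @param max_paths Safety cap on the number of emitted paths.
#' @return A data.frame with one row per alternative path: `seq` (spelled
#'   sequence), `start`, `end`, `n_edges`, `tip_start`, `tip_end`, `support`;
#'   the list of vertex vectors is attached as attribute `"vertices"`.
#' @export
find_alternative_paths <- function(diff, ref, sample, max_len = NULL,
                                   max_paths = 100000L) {
  stopifnot(inherits(diff, "difference_graph"))
  if (is.null(max_len)) max_len <- 10L * diff$k
  if (max_len < 2) stop("max_len must be >= 2", call. = FALSE)
  adj <- diff$adj
  in_ref <- diff$in_ref
  outdeg <- stats::setNames(integer(length(diff$vertices)), diff$vertices)
  outdeg[names(adj)] <- lengths(adj)
  indeg <- stats::setNames(integer(length(diff$vertices)), diff$vertices)
  if (nrow(diff$edges) > 0L) {
    tb <- table(diff$edges$to)
    indeg[names(tb)] <- as.integer(tb)
  }
  starts <- diff$vertices[outdeg > 0L & (in_ref[diff$vertices] |
                                           indeg[diff$vertices] == 0L)]
  acc <- new.env(parent = emptyenv())
  acc$paths <- vector("list", 256L)
  acc$n <- 0L
  acc$dropped <- 0L
  emit <- function(path, tip_end) {
    if (acc$n >= max_paths) {
      acc$dropped <- acc$dropped + 1L
      return(invisible())
    }
    acc$n <- acc$n + 1L
    if (acc$n > length(acc$paths)) {
      acc$paths <- c(acc$paths, vector("list", length(acc$paths)))
    }
    acc$paths[[acc$n]] <- list(vertices = path, tip_end = tip_end)
  }
  walk <- function(path) {
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w %in% path) next  # simple paths only; cyclic closures dropped
      if (in_ref[[w]]) {
        emit(c(path, w), tip_end = FALSE)
      } else if (outdeg[[w]] == 0L) {
        emit(c(path, w), tip_end = TRUE)
      } else if (length(path) <= max_len) {
        walk(c(path, w))
      } else {
        acc$dropped <- acc$dropped + 1L
      }
    }
  }
  for (s in starts) walk(s)
  paths <- acc$paths[seq_len(acc$n)]
  if (length(paths) == 0L) {
    out <- data.frame(seq = character(0), start = character(0),
                      end = character(0), n_edges = integer(0),
                      tip_start = logical(0), tip_end = logical(0),
                      support = integer(0), stringsAsFactors = FALSE)
    attr(out, "vertices") <- list()
    attr(out, "dropped") <- acc$dropped
    return(out)
  }
  verts <- lapply(paths, `[[`, "vertices")
  seqs <- vapply(verts, spell, character(1))
  out <- data.frame(
    seq = seqs,
    start = vapply(verts, function(p) p[1L], character(1)),
    end = vapply(verts, function(p) p[length(p)], character(1)),
    n_edges = lengths(verts) - 1L,
    tip_start = !in_ref[vapply(verts, function(p) p[1L], character(1))],
    tip_end = vapply(paths, `[[`, logical(1), "tip_end"),
    support = vapply(seqs, function(s) seq_read_support(sample$reads, s),
                     integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "vertices") <- verts
  attr(out, "dropped") <- acc$dropped
  out
}

#' Tips of a set of alternative paths
#'
#' A tip is an alternative-path endpoint absent from the reference graph;
#' tips arise from truncated reads, alterations at read extremities, or the
#' removal of low-support vertices from the sample graph.
#'
#' @param paths Result of [find_alternative_paths()].
#' @param ref A `reference_graph`.
#' @return `paths` with `tip_start`/`tip_end` recomputed against `ref`;
#'   the unique tip vertices are attached as attribute `"tips"`.
#' @export
detect_tips <- function(paths, ref) {
  stopifnot(inherits(ref, "reference_graph"))
  paths$tip_start <- !paths$start %in% ref$vertices
  paths$tip_end <- !paths$end %in% ref$vertices
  attr(paths, "tips") <- unique(c(paths$start[paths$tip_start],
                                  paths$end[paths$tip_end]))
  paths
}

#' Anchor a tip onto the reference graph
#'
#' Replaces an endpoint that is absent from the reference graph by the most
#' plausible reference vertex. Candidates are the vertices lying on the
#' reference walks between the relevant reference terminus and the path's
#' other endpoint (`companion`); among them the one minimizing the Levenshtein
#' distance to the tip k-mer is chosen, ties broken by the candidate whose
#' walk length in edges to the companion is closest to the alternative path's
#' edge count, then by shortest walk, then lexicographically.
#'
#' @param tip The tip k-mer (not in the reference graph).
#' @param direction `"start"` if the tip begins the path (candidates lie
#'   upstream of `companion`), `"end"` if it ends it (downstream).
#' @param companion The path's other endpoint, resolvable in the reference.
#' @param ref A `reference_graph`.
#' @param alt_edges The alternative path's length in edges.
#' @return A list with `anchor`, `lev` (edit distance to the tip) and `dist`
#'   (edges between anchor and companion), or `NULL` when no candidate
#'   exists (the caller then discards the path).
#' @export
anchor_tip <- function(tip, direction = c("start", "end"), companion, ref,
                       alt_edges) {
  direction <- match.arg(direction)
  stopifnot(inherits(ref, "reference_graph"))
  if (!companion %in% ref$vertices) {
    stop("companion endpoint is not a reference vertex", call. = FALSE)
  }
  cand <- character(0)
  dist <- integer(0)
  for (w in ref$walks) {
    occ <- which(w == companion)
    for (j in occ) {
      if (direction == "start" && j > 1L) {
        idx <- seq_len(j - 1L)
        cand <- c(cand, w[idx]); dist <- c(dist, j - idx)
      } else if (direction == "end" && j < length(w)) {
        idx <- (j + 1L):length(w)
        cand <- c(cand, w[idx]); dist <- c(dist, idx - j)
      }
    }
  }
  if (length(cand) == 0L) return(NULL)
  # minimal companion distance per unique candidate vertex
  dist <- vapply(split(dist, cand), min, integer(1))
  cand <- names(dist)
  lev <- vapply(cand, function(v) lev_distance(tip, v), integer(1))
  best <- which(lev == min(lev))
  if (length(best) > 1L) {
    gap <- abs(dist[best] - alt_edges)
    best <- best[gap == min(gap)]
  }
  if (length(best) > 1L) best <- best[dist[best] == min(dist[best])]
  if (length(best) > 1L) best <- best[order(cand[best])[1L]]
  best <- best[1L]
  list(anchor = cand[best], lev = unname(lev[best]), dist = unname(dist[best]))
}

#' Best reference path between two anchors
#'
#' Enumerates the simple reference paths from `v_s` to `v_e` (up to `max_len`
#' edges) and retains the one with the largest read support measured in the
#' sample: every read supporting a candidate reference path contains both
#' anchor k-mers, so this maximizes the overlap with the reads covering the
#' alternative path's anchor context. Ties are broken by the path length
#' closest to the alternative path's, then by lexicographic spelled sequence.
#'
#' @param v_s,v_e Reference vertices (possibly anchor-substituted endpoints).
#' @param ref A `reference_graph`.
#' @param sample The `sample_graph` in which support is counted.
#' @param alt_edges Alternative path length in edges (tie-break target).
#' @param max_len Maximum reference path length in edges (default `10 * k`).
#' @param max_paths Cap on enumerated candidates (guards haplotype blow-up).
#' @return A list with `vertices`, `seq`, `support`, `n_edges`, or `NULL`
#'   when no reference path connects the anchors.
#' @export
best_reference_path <- function(v_s, v_e, ref, sample, alt_edges,
                                max_len = NULL, max_paths = 1000L) {
  stopifnot(inherits(ref, "reference_graph"))
  if (is.null(max_len)) max_len <- 10L * ref$k
  if (!v_s %in% ref$vertices || !v_e %in% ref$vertices) {
    stop("anchors must be reference vertices", call. = FALSE)
  }
  acc <- new.env(parent = emptyenv())
  acc$paths <- list()
  walk <- function(path) {
    if (length(acc$paths) >= max_paths) return(invisible())
    v <- path[length(path)]
    for (w in ref$adj[[v]]) {
      if (w %in% path) next
      if (w == v_e) {
        acc$paths[[length(acc$paths) + 1L]] <- c(path, w)
      } else if (length(path) <= max_len) {
        walk(c(path, w))
      }
    }
  }
  walk(v_s)
  if (length(acc$paths) == 0L) return(NULL)
  seqs <- vapply(acc$paths, spell, character(1))
  supp <- vapply(seqs, function(s) seq_read_support(sample$reads, s), integer(1))
  best <- which(supp == max(supp))
  if (length(best) > 1L) {
    gap <- abs((lengths(acc$paths)[best] - 1L) - alt_edges)
    best <- best[gap == min(gap)]
  }
  if (length(best) > 1L) best <- best[order(seqs[best])[1L]]
  best <- best[1L]
  list(vertices = acc$paths[[best]], seq = unname(seqs[best]),
       support = unname(supp[best]), n_edges = length(acc$paths[[best]]) - 1L)
}

#' Count ratio of an alternative path
#'
#' `c = r_alt / (r_alt + r_ref)`: the fraction of local read support carried
#' by the alternative path versus its reference path. Always in `(0, 1]`;
#' equals 1 exactly when the reference path has no support in the sample.
#'
#' @param r_alt Read support of the alternative path (must be `>= 1`).
#' @param r_ref Read support of the reference path in the sample (`>= 0`).
#' @return The count ratio.
#' @examples
#' count_ratio(8, 3)  # 8 / 11
#' @export
count_ratio <- function(r_alt, r_ref) {
  if (any(r_alt < 1)) stop("unsupported alternative path (r_alt = 0)", call. = FALSE)
  if (any(r_ref < 0)) stop("r_ref must be >= 0", call. = FALSE)
  r_alt / (r_alt + r_ref)
}

# ---- Levenshtein machinery ---------------------------------------------

# Plain DP edit distance (unit costs). Used internally; tests check it
# against utils::adist.
lev_distance <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j] + (av[i] != bv[j]),
                         prev[j + 1L] + 1L,
                         cur[j] + 1L)
    }
    prev <- cur
  }
  as.integer(prev[m + 1L])
}

#' Decompose an alternative sequence into atomic edit operations
#'
#' Computes a minimal-cost Levenshtein alignment (unit costs) transforming
#' `ref_seq` into `alt_seq`, then merges maximal runs of adjacent same-type
#' single-character operations into block alterations, so that a multi-
#' nucleotide indel counts as one alteration. Blocks are left-normalized
#' (shifted to their leftmost equivalent placement, as VCF does) and re-merged
#' until stable, which makes the decomposition independent of arbitrary
#' tie-breaks in the alignment. Each operation defines one atomic alternative
#' path carrying exactly one alteration.
#'
#' @param alt_seq Spelled sequence of the alternative path.
#' @param ref_seq Spelled sequence of the reference path.
#' @return A data.frame of operations with columns `type` (`"X"`
#'   substitution, `"D"` deletion, `"I"` insertion), `pos` (1-based position
#'   in `ref_seq` of the first affected base; for insertions, the number of
#'   reference bases preceding the inserted material, 0 allowed), `ref`
#'   (replaced/deleted bases, `""` for insertions) and `alt` (replacement/
#'   inserted bases, `""` for deletions). Identical sequences give zero rows.
#'   `apply_edits(ref_seq, ops)` reproduces `alt_seq`.
#' @examples
#' atomic_decomposition("CGAGTAGAA", "CGATTCATGGAA")
#' @export
atomic_decomposition <- function(alt_seq, ref_seq) {
  stopifnot(nchar(alt_seq) > 0, nchar(ref_seq) > 0)
  empty <- data.frame(type = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE)
  if (alt_seq == ref_seq) return(empty)
  rv <- strsplit(ref_seq, "")[[1]]
  av <- strsplit(alt_seq, "")[[1]]
  n <- length(rv); m <- length(av)
  # Three-state DP. The primary objective is the unit edit count (weight W),
  # so the op count equals the Levenshtein distance; the secondary objective
  # (+1) minimizes gap openings among minimal alignments, so a multi-nt
  # indel aligns as one contiguous block even when its content partially
  # matches the flanking reference.
  W <- 1000000L
  INF <- .Machine$integer.max %/% 4L
  M <- matrix(INF, n + 1L, m + 1L)
  I <- matrix(INF, n + 1L, m + 1L)
  D <- matrix(INF, n + 1L, m + 1L)
  M[1L, 1L] <- 0L
  if (m > 0L) I[1L, 2L:(m + 1L)] <- W * seq_len(m) + 1L
  if (n > 0L) D[2L:(n + 1L), 1L] <- W * seq_len(n) + 1L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1L, j + 1L] <- min(M[i, j], I[i, j], D[i, j]) +
        W * (rv[i] != av[j])
      I[i + 1L, j + 1L] <- min(I[i + 1L, j] + W,
                               min(M[i + 1L, j], D[i + 1L, j]) + W + 1L)
      D[i + 1L, j + 1L] <- min(D[i, j + 1L] + W,
                               min(M[i, j + 1L], I[i, j + 1L]) + W + 1L)
    }
  }
  # backtrace; ties prefer match/substitution, then deletion, then insertion
  i <- n; j <- m
  scores <- c(M[i + 1L, j + 1L], D[i + 1L, j + 1L], I[i + 1L, j + 1L])
  state <- c("M", "D", "I")[which.min(scores)]
  n_unit <- min(scores) %/% W
  type <- character(0); pos <- integer(0); rb <- character(0); ab <- character(0)
  push <- function(t, p, r, a) {
    type <<- c(t, type); pos <<- c(p, pos); rb <<- c(r, rb); ab <<- c(a, ab)
  }
  while (i > 0L || j > 0L) {
    if (state == "M") {
      if (rv[i] != av[j]) push("X", i, rv[i], av[j])
      prev <- c(M[i, j], I[i, j], D[i, j])
      state <- c("M", "I", "D")[which.min(prev)]
      i <- i - 1L; j <- j - 1L
    } else if (state == "D") {
      push("D", i, rv[i], "")
      if (i > 1L || j > 0L) {
        here <- D[i + 1L, j + 1L]
        state <- if (D[i, j + 1L] + W == here) "D"
                 else if (M[i, j + 1L] + W + 1L == here) "M" else "I"
      }
      i <- i - 1L
    } else {
      push("I", i, "", av[j])
      if (j > 1L || i > 0L) {
        here <- I[i + 1L, j + 1L]
        state <- if (I[i + 1L, j] + W == here) "I"
                 else if (M[i + 1L, j] + W + 1L == here) "M" else "D"
      }
      j <- j - 1L
    }
  }
  ops <- merge_op_runs(data.frame(type = type, pos = pos, ref = rb, alt = ab,
                                  stringsAsFactors = FALSE))
  repeat {
    merged <- merge_op_runs(normalize_op_blocks(ops, rv))
    if (identical(merged, ops)) break
    ops <- merged
  }
  attr(ops, "n_unit_ops") <- length(type)
  rownames(ops) <- NULL
  ops
}

# Merge maximal runs of adjacent same-type single-character (or block)
# operations: deletions at contiguous reference positions, insertions at the
# same reference gap, substitutions at contiguous positions. Mixed types are
# never merged.
merge_op_runs <- function(ops) {
  if (nrow(ops) <= 1L) return(ops)
  ord <- order(ops$pos, match(ops$type, c("X", "D", "I")))
  ops <- ops[ord, , drop = FALSE]
  out <- ops[1L, , drop = FALSE]
  for (r in 2L:nrow(ops)) {
    cur <- ops[r, ]
    last <- out[nrow(out), ]
    joinable <-
      cur$type == last$type &&
      ((cur$type == "I" && cur$pos == last$pos) ||
         (cur$type %in% c("D", "X") &&
            cur$pos == last$pos + nchar(last$ref)))
    if (joinable) {
      out$ref[nrow(out)] <- paste0(last$ref, cur$ref)
      out$alt[nrow(out)] <- paste0(last$alt, cur$alt)
    } else {
      out <- rbind(out, cur)
    }
  }
  rownames(out) <- NULL
  out
}

# Shift indel blocks to their leftmost equivalent placement without crossing
# the previous block.
normalize_op_blocks <- function(ops, rv) {
  if (nrow(ops) == 0L) return(ops)
  lower <- 0L
  for (r in seq_len(nrow(ops))) {
    t <- ops$type[r]
    if (t == "D") {
      p <- ops$pos[r]; l <- nchar(ops$ref[r])
      while (p - 1L > lower && rv[p - 1L] == rv[p + l - 1L]) p <- p - 1L
      ops$pos[r] <- p
      ops$ref[r] <- paste(rv[p:(p + l - 1L)], collapse = "")
      lower <- p + l - 1L
    } else if (t == "I") {
      p <- ops$pos[r]
      a <- strsplit(ops$alt[r], "")[[1]]
      while (p > lower && rv[p] == a[length(a)]) {
        a <- c(a[length(a)], a[-length(a)])
        p <- p - 1L
      }
      ops$pos[r] <- p
      ops$alt[r] <- paste(a, collapse = "")
      lower <- max(lower, p)
    } else {
      lower <- ops$pos[r] + nchar(ops$ref[r]) - 1L
    }
  }
  ops
}

#' Apply edit operations to a sequence
#'
#' Replays a set of operations (as produced by [atomic_decomposition()])
#' on `ref_seq`. Applying all operations of a decomposition reproduces the
#' alternative sequence; applying a single one spells the corresponding
#' atomic alternative path.
#'
#' @param ref_seq Reference sequence the operation positions refer to.
#' @param ops Data.frame with columns `type`, `pos`, `ref`, `alt`.
#' @return The edited sequence.
#' @export
apply_edits <- function(ref_seq, ops) {
  rv <- strsplit(ref_seq, "")[[1]]
  if (nrow(ops) == 0L) return(ref_seq)
  ops <- ops[order(ops$pos, decreasing = TRUE), , drop = FALSE]
  for (r in seq_len(nrow(ops))) {
    p <- ops$pos[r]
    if (ops$type[r] == "X") {
      l <- nchar(ops$ref[r])
      rv <- c(rv[seq_len(p - 1L)], strsplit(ops$alt[r], "")[[1]],
              rv[seq_len(length(rv) - p - l + 1L) + p + l - 1L])
    } else if (ops$type[r] == "D") {
      l <- nchar(ops$ref[r])
      rv <- rv[-(p:(p + l - 1L))]
    } else {
      rv <- append(rv, strsplit(ops$alt[r], "")[[1]], after = p)
    }
  }
  paste(rv, collapse = "")
}

# ---- Coordinate mapping -------------------------------------------------

#' Normalize a variant against a reference sequence
#'
#' Trims shared prefix/suffix bases and left-aligns indels (VCF convention),
#' producing a canonical minimal representation.
#'
#' @param pos 1-based position of the first base of `ref` on `seq` (for pure
#'   insertions, the position after which material is inserted; 0 allowed).
#' @param ref,alt Reference and alternative allele strings (either may be
#'   `""`).
#' @param seq The reference sequence providing left-shift context.
#' @return A list with normalized `pos`, `ref`, `alt` and `type` (`"X"`,
#'   `"D"`, `"I"`).
#' @export
normalize_variant <- function(pos, ref, alt, seq) {
  sv <- strsplit(seq, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  # trim common suffix
  while (length(r) > 0L && length(a) > 0L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  # trim common prefix
  while (length(r) > 0L && length(a) > 0L && r[1L] == a[1L]) {
    r <- r[-1L]; a <- a[-1L]; pos <- pos + 1L
  }
  if (length(r) == 0L && length(a) == 0L) {
    return(list(pos = pos, ref = "", alt = "", type = "none"))
  }
  if (length(r) > 0L && length(a) > 0L) {
    return(list(pos = pos, ref = paste(r, collapse = ""),
                alt = paste(a, collapse = ""), type = "X"))
  }
  if (length(a) == 0L) { # deletion of r at pos
    l <- length(r)
    while (pos > 1L && sv[pos - 1L] == sv[pos + l - 1L]) pos <- pos - 1L
    return(list(pos = pos, ref = paste(sv[pos:(pos + l - 1L)], collapse = ""),
                alt = "", type = "D"))
  }
  # insertion of a after `pos` reference bases; if ref was non-empty the
  # prefix trim above advanced pos past the anchored bases
  ins_pos <- if (nchar(ref) > 0L) pos - 1L else pos
  while (ins_pos > 0L && sv[ins_pos] == a[length(a)]) {
    a <- c(a[length(a)], a[-length(a)])
    ins_pos <- ins_pos - 1L
  }
  list(pos = ins_pos, ref = "", alt = paste(a, collapse = ""), type = "I")
}

# Anchored VCF representation of a normalized minimal variant.
vcf_fields <- function(pos, ref, alt, type, seq) {
  sv <- strsplit(seq, "")[[1]]
  if (type == "X") {
    return(list(pos = pos, ref = ref, alt = alt))
  }
  if (type == "D") {
    l <- nchar(ref)
    if (pos > 1L) {
      return(list(pos = pos - 1L,
                  ref = paste(sv[(pos - 1L):(pos + l - 1L)], collapse = ""),
                  alt = sv[pos - 1L]))
    }
    # deletion at the very start: anchor on the following base
    return(list(pos = 1L, ref = paste(sv[1L:(l + 1L)], collapse = ""),
                alt = sv[l + 1L]))
  }
  if (pos >= 1L) {
    return(list(pos = pos, ref = sv[pos], alt = paste0(sv[pos], alt)))
  }
  list(pos = 1L, ref = sv[1L], alt = paste0(alt, sv[1L]))
}

#' Map an edit operation onto the primary reference
#'
#' Locates the chosen reference path's spelled sequence on the primary
#' reference sequence and translates an operation's position accordingly,
#' returning both the normalized minimal representation and the anchored
#' VCF-style fields (left-aligned, anchor base prepended for indels).
#'
#' @param op One row of an [atomic_decomposition()] result (list or
#'   single-row data.frame with `type`, `pos`, `ref`, `alt`).
#' @param ref_path_seq Spelled sequence of the reference path the operation
#'   positions refer to.
#' @param ref A `reference_graph` (its primary sequence is searched).
#' @return A list with `pos`, `ref`, `alt`, `type` (normalized, on the
#'   primary reference; `pos` is `NA` when the path sequence does not occur)
#'   and `vcf_pos`, `vcf_ref`, `vcf_alt`.
#' @export
map_to_reference_coordinates <- function(op, ref_path_seq, ref) {
  stopifnot(inherits(ref, "reference_graph"))
  primary <- unname(ref$sequences[[ref$primary]])
  hits <- gregexpr(ref_path_seq, primary, fixed = TRUE)[[1]]
  if (hits[1L] == -1L) {
    warning("reference path sequence not found on the primary reference",
            call. = FALSE)
    return(list(pos = NA_integer_, ref = op$ref, alt = op$alt, type = op$type,
                vcf_pos = NA_integer_, vcf_ref = op$ref, vcf_alt = op$alt))
  }
  if (length(hits) > 1L) {
    warning("reference path sequence occurs ", length(hits),
            " times on the primary reference; using the first occurrence",
            call. = FALSE)
  }
  offset <- hits[1L] - 1L
  nv <- normalize_variant(op$pos + offset, op$ref, op$alt, primary)
  vf <- vcf_fields(nv$pos, nv$ref, nv$alt, nv$type, primary)
  list(pos = nv$pos, ref = nv$ref, alt = nv$alt, type = nv$type,
       vcf_pos = vf$pos, vcf_ref = vf$ref, vcf_alt = vf$alt)
}

#' All atomic alterations of a sample versus the reference
#'
#' Runs the full alternative-path stage for one sample: difference graph,
#' path enumeration, tip anchoring, best-reference-path selection, atomic
#' decomposition and coordinate mapping. Paths with both endpoints
#' unanchorable, no connecting reference path, or zero read support are
#' discarded (with a message when `verbose`). Atomic records inherit the read
#' support of their parent path; duplicated variants arising from several
#' parents keep the best-supported record.
#'
#' @param sample A `sample_graph`.
#' @param ref A `reference_graph` (same `k`).
#' @param max_len Maximum path length in edges (default `10 * k`).
#' @param verbose Emit messages about discarded paths.
#' @return A data.frame of alteration records with columns `parent_seq`,
#'   `ref_seq`, `type`, `pos`, `ref`, `alt` (normalized, primary reference
#'   coordinates), `vcf_pos`, `vcf_ref`, `vcf_alt`, `r_alt`, `r_ref`, `c`,
#'   `tip_start`, `tip_end`.
#' @export
sample_alterations <- function(sample, ref, max_len = NULL, verbose = FALSE) {
  diff <- difference_graph(sample, ref)
  paths <- find_alternative_paths(diff, ref, sample, max_len = max_len)
  empty <- data.frame(
    parent_seq = character(0), ref_seq = character(0), type = character(0),
    pos = integer(0), ref = character(0), alt = character(0),
    vcf_pos = integer(0), vcf_ref = character(0), vcf_alt = character(0),
    r_alt = integer(0), r_ref = integer(0), c = numeric(0),
    tip_start = logical(0), tip_end = logical(0), stringsAsFactors = FALSE)
  if (nrow(paths) == 0L) return(empty)
  recs <- vector("list", nrow(paths))
  n_skip <- 0L
  for (idx in seq_len(nrow(paths))) {
    p <- paths[idx, ]
    if (p$support < 1L) { n_skip <- n_skip + 1L; next }
    if (p$tip_start && p$tip_end) { n_skip <- n_skip + 1L; next }
    v_s <- p$start; v_e <- p$end
    if (p$tip_start) {
      a <- anchor_tip(v_s, "start", companion = v_e, ref = ref,
                      alt_edges = p$n_edges)
      if (is.null(a)) { n_skip <- n_skip + 1L; next }
      v_s <- a$anchor
    }
    if (p$tip_end) {
      a <- anchor_tip(v_e, "end", companion = v_s, ref = ref,
                      alt_edges = p$n_edges)
      if (is.null(a)) { n_skip <- n_skip + 1L; next }
      v_e <- a$anchor
    }
    rp <- best_reference_path(v_s, v_e, ref, sample, alt_edges = p$n_edges,
                              max_len = max_len)
    if (is.null(rp)) { n_skip <- n_skip + 1L; next }
    ops <- atomic_decomposition(p$seq, rp$seq)
    if (nrow(ops) == 0L) { n_skip <- n_skip + 1L; next }
    cc <- count_ratio(p$support, rp$support)
    rows <- vector("list", nrow(ops))
    for (o in seq_len(nrow(ops))) {
      mp <- suppressWarnings(
        map_to_reference_coordinates(ops[o, ], rp$seq, ref))
      rows[[o]] <- data.frame(
        parent_seq = p$seq, ref_seq = rp$seq, type = mp$type,
        pos = mp$pos, ref = mp$ref, alt = mp$alt,
        vcf_pos = mp$vcf_pos, vcf_ref = mp$vcf_ref, vcf_alt = mp$vcf_alt,
        r_alt = p$support, r_ref = rp$support, c = cc,
        tip_start = p$tip_start, tip_end = p$tip_end,
        stringsAsFactors = FALSE)
    }
    recs[[idx]] <- do.call(rbind, rows)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (verbose && n_skip > 0L) {
    message(n_skip, " alternative path(s) discarded (unanchorable, ",
            "unsupported, or without reference path)")
  }
  if (length(recs) == 0L) return(empty)
  out <- do.call(rbind, recs)
  key <- paste(out$type, out$pos, out$ref, out$alt)
  out <- out[order(key, -out$r_alt, -out$c), , drop = FALSE]
  out <- out[!duplicated(paste(out$type, out$pos, out$ref, out$alt)), ,
             drop = FALSE]
  out <- out[order(out$pos, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}
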