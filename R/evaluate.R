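# Scoring calls against truth tables: per-sample TP/FP/FN with outcome
# classes, and cohort-level alteration hotspot aggregation.

# Canonical key of a variant after left-normalization on `refseq`.
variant_key <- function(pos, ref, alt, refseq) {
  nv <- normalize_variant(pos, ref, alt, refseq)
  paste(nv$type, nv$pos, nv$ref, nv$alt, sep = ":")
}

#' Match calls against a truth table
#'
#' A call matches a truth record iff, after VCF-style left-normalization of
#' both sides against the reference, the type and alleles agree and the
#' positions differ by at most `tolerance` (default 0). Each truth record is
#' matched at most once.
#'
#' @param calls Data.frame with columns `pos`, `type`, `ref`, `alt` (either
#'   normalized minimal or anchored representations).
#' @param truth Data.frame with columns `pos`, `type`, `ref`, `alt`.
#' @param refseq Reference sequence both coordinate sets refer to.
#' @param tolerance Maximum position difference after normalization.
#' @return A list with `tp`, `fp`, `fn` and logical vectors
#'   `call_matched`, `truth_matched`.
#' @export
match_calls <- function(calls, truth, refseq, tolerance = 0L) {
  norm <- function(df) {
    if (nrow(df) == 0L) {
      return(data.frame(pos = integer(0), type = character(0),
                        ref = character(0), alt = character(0)))
    }
    out <- lapply(seq_len(nrow(df)), function(i) {
      nv <- normalize_variant(df$pos[i], df$ref[i], df$alt[i], refseq)
      data.frame(pos = nv$pos, type = nv$type, ref = nv$ref, alt = nv$alt,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  nc <- norm(calls)
  nt <- norm(truth)
  call_matched <- rep(FALSE, nrow(nc))
  truth_matched <- rep(FALSE, nrow(nt))
  for (i in seq_len(nrow(nc))) {
    for (j in seq_len(nrow(nt))) {
      if (truth_matched[j]) next
      if (nc$type[i] == nt$type[j] && nc$ref[i] == nt$ref[j] &&
          nc$alt[i] == nt$alt[j] &&
          abs(nc$pos[i] - nt$pos[j]) <= tolerance) {
        call_matched[i] <- TRUE
        truth_matched[j] <- TRUE
        break
      }
    }
  }
  list(tp = sum(call_matched), fp = sum(!call_matched),
       fn = sum(!truth_matched),
       call_matched = call_matched, truth_matched = truth_matched)
}

#' Classify a per-sample calling outcome
#'
#' Maps the presence/absence pattern of true positives, false positives and
#' false negatives to one of 7 outcome classes. A sample where every truth
#' record was recovered and nothing else was called — including a clean
#' negative control — is `"Perfect"`; the remaining patterns are labelled
#' `TP+/-, FP+/-, FN+/-`.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return A single class label string.
#' @export
classify_sample <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (fp == 0 && fn == 0) return("Perfect")
  sprintf("TP%s/FP%s/FN%s",
          if (tp > 0) "+" else "-",
          if (fp > 0) "+" else "-",
          if (fn > 0) "+" else "-")
}

#' Aggregate cohort-level alteration hotspots
#'
#' Groups identical variants (position, alleles, type) across samples,
#' counts the number of distinct samples carrying each, and reports the
#' nucleotide context before and after the altered location. Recurrent
#' artifacts surface at the top of this table; a caller that removes
#' cohort-recurrent alterations should contribute only counts of 0 or 1.
#'
#' @param calls Data.frame with columns `sample`, `pos`, `type`, `ref`,
#'   `alt` (normalized or anchored; normalized internally).
#' @param refseq The shared reference sequence.
#' @param top Number of rows to keep (default 25).
#' @param flank Context width on each side (default 8).
#' @return Data.frame with `pos`, `before`, `ref`, `alt`, `type`, `after`,
#'   `count`, sorted by decreasing count.
#' @export
hotspot_table <- function(calls, refseq, top = 25L, flank = 8L) {
  empty <- data.frame(pos = integer(0), before = character(0),
                      ref = character(0), alt = character(0),
                      type = character(0), after = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) return(empty)
  norm <- lapply(seq_len(nrow(calls)), function(i) {
    nv <- normalize_variant(calls$pos[i], calls$ref[i], calls$alt[i], refseq)
    data.frame(sample = calls$sample[i], pos = nv$pos, type = nv$type,
               ref = nv$ref, alt = nv$alt, stringsAsFactors = FALSE)
  })
  norm <- do.call(rbind, norm)
  key <- paste(norm$pos, norm$ref, norm$alt, norm$type, sep = ":")
  counts <- vapply(split(norm$sample, key),
                   function(s) length(unique(s)), integer(1))
  first <- norm[!duplicated(key), , drop = FALSE]
  first$count <- counts[paste(first$pos, first$ref, first$alt, first$type,
                              sep = ":")]
  L <- nchar(refseq)
  first$before <- substr(refseq, pmax(1L, first$pos - flank), first$pos - 1L)
  last_affected <- first$pos + pmax(nchar(first$ref) - 1L, 0L)
  first$after <- substr(refseq, last_affected + 1L,
                        pmin(L, last_affected + flank))
  out <- first[order(-first$count, first$pos),
               c("pos", "before", "ref", "alt", "type", "after", "count")]
  rownames(out) <- NULL
  utils::head(out, top)
}

#' Score a whole cohort run against its truth table
#'
#' Convenience wrapper: per sample, matches that sample's calls against its
#' truth records and classifies the outcome.
#'
#' @param calls Data.frame with a `sample_id` (or `sample`) column plus
#'   `pos`, `type`, `ref`, `alt`.
#' @param truth Data.frame with `sample`, `pos`, `type`, `ref`, `alt`.
#' @param refseq Shared reference sequence.
#' @param sample_ids Samples to score (default: union of both tables).
#' @param tolerance Passed to [match_calls()].
#' @return Data.frame with one row per sample: `sample`, `tp`, `fp`, `fn`,
#'   `truth_n`, `class`.
#' @export
score_cohort <- function(calls, truth, refseq, sample_ids = NULL,
                         tolerance = 0L) {
  sc <- if ("sample_id" %in% names(calls)) calls$sample_id else calls$sample
  if (is.null(sample_ids)) sample_ids <- union(unique(sc), unique(truth$sample))
  rows <- lapply(sample_ids, function(id) {
    m <- match_calls(calls[!is.na(sc) & sc == id, , drop = FALSE],
                     truth[truth$sample == id, , drop = FALSE],
                     refseq, tolerance)
    data.frame(sample = id, tp = m$tp, fp = m$fp, fn = m$fn,
               truth_n = sum(truth$sample == id),
               class = classify_sample(m$tp, m$fp, m$fn),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stacked-proportion plot of outcome classes
#'
#' Visualizes the share of samples per outcome class, optionally split by a
#' grouping column (e.g. altered-read fraction). Requires ggplot2.
#'
#' @param outcomes Data.frame from [score_cohort()], optionally with a
#'   `group` column.
#' @return A ggplot object.
#' @export
plot_outcome_classes <- function(outcomes) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  if (!"group" %in% names(outcomes)) outcomes$group <- "all"
  ggplot2::ggplot(outcomes,
                  ggplot2::aes(x = factor(group), fill = class)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::labs(x = NULL, y = "proportion of samples", fill = "outcome") +
    ggplot2::theme_minimal()
}
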