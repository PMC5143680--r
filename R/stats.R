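# Cohort resampling: null distribution of count ratios, empirical p-values,
# z-scores, and the final specificity decision.
#
# The null hypothesis is "no association between reads and samples": an
# alteration produced by a recurrent sequencing artifact appears at a similar
# rate in read sets resampled from the pooled cohort, while a private
# mutation concentrates in one sample and its observed count ratio lands far
# in the tail of the resampled ratios.

#' Pool the cohort's reads
#'
#' @param samples Named list of character vectors, one read set per sample.
#' @return An object of class `cohort_pool`: a list with `reads` (the pooled
#'   reads, duplicates retained) and `origin` (per-read sample tag).
#' @export
build_cohort_pool <- function(samples) {
  stopifnot(is.list(samples))
  if (length(samples) < 2L) {
    stop("a cohort pool needs at least 2 samples to form a null", call. = FALSE)
  }
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- paste0("sample", seq_along(samples))
  }
  pool <- list(
    reads = toupper(unlist(samples, use.names = FALSE)),
    origin = rep(names(samples), lengths(samples))
  )
  class(pool) <- "cohort_pool"
  pool
}

#' @export
print.cohort_pool <- function(x, ...) {
  cat(sprintf("cohort pool: %d reads from %d samples\n",
              length(x$reads), length(unique(x$origin))))
  invisible(x)
}

# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# N sets of m read indices drawn without replacement from pool_n reads.
resample_indices <- function(pool_n, m, N, seed) {
  if (m > pool_n) stop("resample size m exceeds the pool size", call. = FALSE)
  with_local_seed(seed,
    vapply(seq_len(N), function(i) sample.int(pool_n, m), integer(m)))
}

#' Null distribution of a path's count ratio under cohort resampling
#'
#' Draws `N` read sets of size `m` without replacement from the pooled
#' cohort; in each resample the count ratio
#' `c_i = r_i(p_a) / (r_i(p_a) + r_i(p_r))` is computed (0/0 defined as 0).
#' By the explicit-edge construction a read supports a path exactly when it
#' contains the path's spelled sequence, so supports can be counted by
#' substring matching (`method = "substring"`, the default) without building
#' each resample's graph; `method = "graph"` builds every resampled sample
#' graph (same `k` and `min_support` as real samples) and queries
#' [path_read_support()] — the two are equivalent and the graph route exists
#' as a cross-check.
#'
#' @param pool A `cohort_pool`.
#' @param alt_seq Spelled sequence of the (parent) alternative path.
#' @param ref_seq Spelled sequence of its reference path.
#' @param m Resample size (reads per resample).
#' @param N Number of resamplings.
#' @param seed Integer seed; identical seeds give identical draws.
#' @param k,min_support Graph parameters, used by `method = "graph"`.
#' @param method `"substring"` or `"graph"`.
#' @return An object of class `null_distribution`: list with `c_i` (length
#'   `N`), `N`, `m`, `seed`.
#' @export
null_distribution <- function(pool, alt_seq, ref_seq, m, N = 1000L,
                              seed = 1L, k = NULL, min_support = 2L,
                              method = c("substring", "graph")) {
  method <- match.arg(method)
  stopifnot(inherits(pool, "cohort_pool"), N >= 1L)
  idx <- resample_indices(length(pool$reads), m, N, seed)
  if (method == "substring") {
    alt_mask <- grepl(alt_seq, pool$reads, fixed = TRUE)
    ref_mask <- grepl(ref_seq, pool$reads, fixed = TRUE)
    a <- colSums(matrix(alt_mask[idx], nrow = m))
    r <- colSums(matrix(ref_mask[idx], nrow = m))
  } else {
    if (is.null(k)) k <- nchar(alt_seq) # any k <= path length works
    a <- numeric(N); r <- numeric(N)
    for (i in seq_len(N)) {
      g <- suppressWarnings(
        build_sample_graph(pool$reads[idx[, i]], k = k,
                           min_support = min_support))
      a[i] <- seq_read_support(g$reads, alt_seq)
      r[i] <- seq_read_support(g$reads, ref_seq)
    }
  }
  c_i <- ifelse(a + r == 0, 0, a / (a + r))
  out <- list(c_i = c_i, N = as.integer(N), m = as.integer(m),
              seed = as.integer(seed))
  class(out) <- "null_distribution"
  out
}

#' Empirical p-value of an observed count ratio
#'
#' `p = |{c_i > c_obs}| / N` — the fraction of resampled count ratios
#' strictly greater than the observed one (ties do not count against the
#' observation).
#'
#' @param c_obs Observed count ratio.
#' @param null A `null_distribution` (or a numeric vector of `c_i`).
#' @return The empirical p-value in `[0, 1]`.
#' @export
empirical_pvalue <- function(c_obs, null) {
  c_i <- if (inherits(null, "null_distribution")) null$c_i else null
  if (length(c_i) == 0L) stop("empty null distribution", call. = FALSE)
  mean(c_i > c_obs)
}

#' Z-score of an observed count ratio against its null
#'
#' `(c_obs - mean(c_i)) / sd(c_i)` with the sample standard deviation
#' (denominator `N - 1`). Degenerate nulls (all `c_i` equal, sd 0) occur when
#' a path never appears in resamples; there the z-score is `+Inf` when
#' `c_obs` exceeds the common value (passes any threshold), 0 when equal,
#' `-Inf` below.
#'
#' @inheritParams empirical_pvalue
#' @return The z-score (possibly infinite).
#' @export
zscore <- function(c_obs, null) {
  c_i <- if (inherits(null, "null_distribution")) null$c_i else null
  if (length(c_i) < 2L) stop("need at least 2 resamples for a z-score", call. = FALSE)
  s <- stats::sd(c_i)
  mu <- mean(c_i)
  if (s == 0) {
    return(if (c_obs > mu) Inf else if (c_obs < mu) -Inf else 0)
  }
  (c_obs - mu) / s
}

#' Test alteration records for sample specificity and call variants
#'
#' For each parent alternative path among `records`, computes the resampling
#' null of its count ratio against the pooled cohort and derives the
#' empirical p-value and z-score; atomic records inherit their parent's
#' statistics (their read support is the parent's by construction). A record
#' is called when `p < alpha`, `z >= z_min`, and its count ratio is at least
#' `min_vaf`. The `N` resampled read sets are drawn once and shared across
#' paths. Known-SNP alterations never reach this stage: haplotype sequences
#' are part of the reference graph, so their paths are not alternative.
#'
#' @param records Alteration records from [sample_alterations()] for one
#'   sample.
#' @param pool A `cohort_pool` built from the whole cohort.
#' @param alpha Significance level for the empirical p-value (default 0.01).
#' @param z_min Minimum z-score (default 10).
#' @param m Resample size; defaults to the analyzed sample's retained read
#'   count (`sample_size`), capped at the pool size.
#' @param N Number of resamplings (default 1000).
#' @param seed Integer seed for the resampling draws.
#' @param min_vaf Minimum count ratio for a record to be reported as a call
#'   (default 0.03).
#' @param sample_size Read count of the analyzed sample (sets the default
#'   `m`).
#' @param sample_id Optional sample tag; when `exclude_self = TRUE`, reads
#'   originating from this sample are removed from the pool before
#'   resampling.
#' @param exclude_self Drop the tested sample's own reads from the pool
#'   (default `FALSE`: the null uses the whole cohort read set).
#' @param adjust Optional multiple-testing correction of the p-values
#'   (`"none"`, default, or `"BH"` for Benjamini-Hochberg); the corrected
#'   value is compared with `alpha`.
#' @return `records` with columns `p`, `z`, `called` appended (and
#'   `sample_id` when given).
#' @export
call_variants <- function(records, pool, alpha = 0.01, z_min = 10,
                          m = NULL, N = 1000L, seed = 1L, min_vaf = 0.03,
                          sample_size = NULL, sample_id = NULL,
                          exclude_self = FALSE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(pool, "cohort_pool"))
  if (nrow(records) == 0L) {
    records$p <- numeric(0); records$z <- numeric(0)
    records$called <- logical(0)
    if (!is.null(sample_id)) records$sample_id <- character(0)
    return(records)
  }
  reads <- pool$reads
  if (exclude_self) {
    if (is.null(sample_id)) {
      stop("exclude_self requires sample_id", call. = FALSE)
    }
    reads <- reads[pool$origin != sample_id]
  }
  if (is.null(m)) {
    m <- if (!is.null(sample_size)) sample_size else length(reads)
  }
  m <- min(m, length(reads))
  idx <- resample_indices(length(reads), m, N, seed)
  parents <- unique(records[, c("parent_seq", "ref_seq")])
  p <- numeric(nrow(records)); z <- numeric(nrow(records))
  for (g in seq_len(nrow(parents))) {
    alt_mask <- grepl(parents$parent_seq[g], reads, fixed = TRUE)
    ref_mask <- grepl(parents$ref_seq[g], reads, fixed = TRUE)
    a <- colSums(matrix(alt_mask[idx], nrow = m))
    r <- colSums(matrix(ref_mask[idx], nrow = m))
    c_i <- ifelse(a + r == 0, 0, a / (a + r))
    sel <- records$parent_seq == parents$parent_seq[g] &
      records$ref_seq == parents$ref_seq[g]
    c_obs <- records$c[sel][1L]
    p[sel] <- empirical_pvalue(c_obs, c_i)
    z[sel] <- zscore(c_obs, c_i)
  }
  records$p <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  records$z <- z
  records$called <- records$p < alpha & records$z >= z_min &
    records$c >= min_vaf
  if (!is.null(sample_id)) records$sample_id <- sample_id
  records
}
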