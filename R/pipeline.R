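# Run configuration and the end-to-end pipeline: graph construction,
# alternative-path search and the cohort permutation test for one sample or
# a whole cohort.

utils::globalVariables(c("group", "class"))

#' Run configuration
#'
#' Bundles and validates every tunable of the pipeline. `k = 30` suits
#' long alterations such as internal tandem duplications; smaller k (10-15)
#' tolerates higher per-base error on short amplicons. `max_path_len`
#' defaults to `10 * k` edges.
#'
#' @param k K-mer length.
#' @param min_support Minimum vertex read support in sample graphs.
#' @param max_path_len Maximum alternative/reference path length in edges
#'   (`NULL` = `10 * k`).
#' @param alpha Significance level of the permutation p-value.
#' @param z_min Minimum z-score.
#' @param n_resamples Number of cohort resamplings `N`.
#' @param resample_size Reads per resample (`NULL` = the analyzed sample's
#'   retained read count).
#' @param min_vaf Minimum count ratio for a reported call.
#' @param exclude_self Drop the analyzed sample's reads from the pool.
#' @param seed Integer seed.
#' @return An object of class `run_config` (a validated named list).
#' @export
run_config <- function(k = 30L, min_support = 2L, max_path_len = NULL,
                       alpha = 0.01, z_min = 10, n_resamples = 1000L,
                       resample_size = NULL, min_vaf = 0.03,
                       exclude_self = FALSE, seed = 1L) {
  check_k(k)
  stopifnot(min_support >= 1, alpha > 0, alpha < 1, z_min >= 0,
            n_resamples >= 1, min_vaf >= 0, min_vaf < 1,
            is.logical(exclude_self))
  if (!is.null(max_path_len)) stopifnot(max_path_len >= 2)
  if (!is.null(resample_size)) stopifnot(resample_size >= 1)
  cfg <- list(k = as.integer(k), min_support = as.integer(min_support),
              max_path_len = max_path_len, alpha = alpha, z_min = z_min,
              n_resamples = as.integer(n_resamples),
              resample_size = resample_size, min_vaf = min_vaf,
              exclude_self = exclude_self, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with any subset of [run_config()]'s fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write a run configuration to a YAML file
#'
#' @param config A `run_config`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))],
                   path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run configuration:\n")
  for (n in names(x)) {
    cat(sprintf("  %-14s %s\n", n,
                if (is.null(x[[n]])) "(default)" else format(x[[n]])))
  }
  invisible(x)
}

as_reads_list <- function(x) {
  # accept a directory of FASTQ/FASTA files, a vector of file paths, or a
  # named list of read vectors
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    fq <- list.files(x, pattern = "\\.(fastq|fq)$", full.names = TRUE)
    # fall back to FASTA samples only when the directory has no FASTQ, so a
    # reference.fasta sitting next to the sample FASTQs is not read in
    x <- if (length(fq) > 0L) fq else {
      list.files(x, pattern = "\\.(fasta|fa)$", full.names = TRUE)
    }
    if (length(x) == 0L) stop("no read files found in directory", call. = FALSE)
  }
  if (is.character(x)) {
    out <- lapply(x, read_reads)
    names(out) <- sub("\\.[^.]*$", "", basename(x))
    return(out)
  }
  stopifnot(is.list(x))
  x
}

as_references <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      !dir.exists(x)) {
    return(read_reference_fasta(x))
  }
  toupper(unlist(x))
}

#' Call variants for one sample against its cohort
#'
#' Executes the three stages for a single sample: build the reference and
#' sample graphs, enumerate and decompose alternative paths, then test each
#' alteration's count ratio against the cohort resampling null. Returns every
#' tested record with its statistics; the `called` column marks the final
#' calls.
#'
#' @param sample_reads Character vector of reads, or a FASTQ/FASTA path.
#' @param cohort Named list of read vectors (the whole cohort, normally
#'   including this sample), a vector of file paths, or a directory.
#' @param reference Named character vector of reference sequences or a FASTA
#'   path; the first (or `primary`) record is the coordinate backbone.
#' @param config A [run_config()].
#' @param sample_id Sample label (used for tagging and `exclude_self`).
#' @param out_dir When given, writes `<sample_id>.vcf` (called records) and
#'   `<sample_id>.tsv` (all tested records) there.
#' @return Data.frame of alteration records with statistics (see
#'   [sample_alterations()] and [call_variants()]).
#' @export
run_call <- function(sample_reads, cohort, reference, config = run_config(),
                     sample_id = "sample", out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(sample_reads) && length(sample_reads) == 1L &&
      file.exists(sample_reads)) {
    sample_reads <- read_reads(sample_reads)
  }
  cohort <- as_reads_list(cohort)
  reference <- as_references(reference)
  ref <- build_reference_graph(reference, k = config$k)
  sg <- build_sample_graph(sample_reads, k = config$k,
                           min_support = config$min_support,
                           sample_id = sample_id)
  records <- sample_alterations(sg, ref, max_len = config$max_path_len)
  pool <- build_cohort_pool(cohort)
  calls <- call_variants(records, pool,
                         alpha = config$alpha, z_min = config$z_min,
                         m = config$resample_size,
                         N = config$n_resamples, seed = config$seed,
                         min_vaf = config$min_vaf,
                         sample_size = length(sg$reads),
                         sample_id = sample_id,
                         exclude_self = config$exclude_self)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(calls, file.path(out_dir, paste0(sample_id, ".vcf")),
              chrom = ref$primary, n_resamples = config$n_resamples)
    write_calls_tsv(calls, file.path(out_dir, paste0(sample_id, ".tsv")))
  }
  calls
}

#' Call variants for every sample of a cohort
#'
#' Runs [run_call()]'s stages for each sample, reusing the reference graph
#' and cohort pool. Per-sample resampling seeds are derived from
#' `config$seed` so the whole run is deterministic.
#'
#' @param cohort Named list of read vectors, file paths, or a directory.
#' @param reference Reference sequences or FASTA path.
#' @param config A [run_config()].
#' @param out_dir Optional output directory for per-sample VCF/TSV and a
#'   cohort `summary.tsv`.
#' @return A list with `calls` (combined data.frame over samples) and
#'   `per_sample` (named list of per-sample data.frames).
#' @export
run_all <- function(cohort, reference, config = run_config(),
                    out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- as_reads_list(cohort)
  if (length(cohort) < 2L) stop("cohort must contain >= 2 samples", call. = FALSE)
  reference <- as_references(reference)
  ref <- build_reference_graph(reference, k = config$k)
  pool <- build_cohort_pool(cohort)
  seeds <- with_local_seed(config$seed,
    sample.int(.Machine$integer.max %/% 2L, length(cohort)))
  per_sample <- vector("list", length(cohort))
  names(per_sample) <- names(cohort)
  for (s in seq_along(cohort)) {
    id <- names(cohort)[s]
    sg <- build_sample_graph(cohort[[s]], k = config$k,
                             min_support = config$min_support,
                             sample_id = id)
    records <- sample_alterations(sg, ref, max_len = config$max_path_len)
    per_sample[[s]] <- call_variants(
      records, pool, alpha = config$alpha, z_min = config$z_min,
      m = config$resample_size, N = config$n_resamples, seed = seeds[s],
      min_vaf = config$min_vaf, sample_size = length(sg$reads),
      sample_id = id, exclude_self = config$exclude_self)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_vcf(per_sample[[s]], file.path(out_dir, paste0(id, ".vcf")),
                chrom = ref$primary, n_resamples = config$n_resamples)
      write_calls_tsv(per_sample[[s]], file.path(out_dir, paste0(id, ".tsv")))
    }
  }
  calls <- do.call(rbind, per_sample[vapply(per_sample, nrow,
                                            integer(1)) > 0L])
  if (is.null(calls)) {
    calls <- per_sample[[1L]]
  }
  rownames(calls) <- NULL
  if (!is.null(out_dir)) {
    summary <- data.frame(
      sample = names(per_sample),
      n_records = vapply(per_sample, nrow, integer(1)),
      n_called = vapply(per_sample, function(x) sum(x$called), integer(1)))
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(calls = calls, per_sample = per_sample)
}
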