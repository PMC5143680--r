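# File I/O: FASTA/FASTQ via Biostrings, VCF 4.2 and TSV output for calls.

#' Read reference sequences from a FASTA file
#'
#' Record IDs become the reference labels (colors).
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read sample reads from FASTQ or FASTA
#'
#' Format is chosen from the file extension (`.fastq`/`.fq` vs everything
#' else). Qualities are not used by the graphs and are discarded.
#'
#' @param path Reads file.
#' @return Character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)) {
    "fastq"
  } else {
    "fasta"
  }
  unname(as.character(Biostrings::readDNAStringSet(path, format = fmt)))
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads Character vector of read sequences.
#' @param quals Character vector of quality strings (same lengths as
#'   `reads`); when `NULL`, constant Q40.
#' @param path Output file.
#' @param ids Optional read names.
#' @return Invisibly, `path`.
#' @export
write_reads_fastq <- function(reads, quals = NULL, path, ids = NULL) {
  if (is.null(quals)) {
    quals <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  }
  stopifnot(all(nchar(quals) == nchar(reads)))
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Write reference sequences as FASTA
#'
#' @param references Named character vector.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_reference_fasta <- function(references, path) {
  x <- Biostrings::DNAStringSet(unlist(references))
  names(x) <- names(references)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Write variant calls as VCF 4.2
#'
#' One row per called (or, with `called_only = FALSE`, per tested) record,
#' on the primary reference with 1-based positions and anchored-base indel
#' alleles. INFO carries the count ratio `C`, supports `RALT`/`RREF`, the
#' permutation p-value `PV`, z-score `Z` and resampling count `NR`.
#'
#' @param calls Data.frame from [call_variants()].
#' @param path Output file.
#' @param chrom Primary reference ID used in the CHROM column.
#' @param n_resamples Value reported in INFO `NR`.
#' @param called_only Keep only records with `called == TRUE` (default).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(calls, path, chrom = "amplicon", n_resamples = NA,
                      called_only = TRUE) {
  if (called_only && "called" %in% names(calls)) {
    calls <- calls[calls$called, , drop = FALSE]
  }
  calls <- calls[!is.na(calls$vcf_pos), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cohortvar",
    sprintf("##contig=<ID=%s>", chrom),
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Alteration type: X substitution, I insertion, D deletion\">",
    "##INFO=<ID=C,Number=1,Type=Float,Description=\"Count ratio r_alt/(r_alt+r_ref)\">",
    "##INFO=<ID=RALT,Number=1,Type=Integer,Description=\"Read support of the alternative path\">",
    "##INFO=<ID=RREF,Number=1,Type=Integer,Description=\"Read support of the reference path in the sample\">",
    "##INFO=<ID=PV,Number=1,Type=Float,Description=\"Empirical p-value from cohort resampling\">",
    "##INFO=<ID=Z,Number=1,Type=Float,Description=\"Z-score of the count ratio against the resampling null\">",
    sprintf("##INFO=<ID=NR,Number=1,Type=Integer,Description=\"Number of resamplings (%s)\">",
            n_resamples),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character(0)
  if (nrow(calls) > 0L) {
    info <- sprintf("TYPE=%s;C=%.6g;RALT=%d;RREF=%d;PV=%.6g;Z=%.6g",
                    calls$type, calls$c, calls$r_alt, calls$r_ref,
                    if ("p" %in% names(calls)) calls$p else NA,
                    if ("z" %in% names(calls)) calls$z else NA)
    body <- paste(chrom, calls$vcf_pos, ".", calls$vcf_ref, calls$vcf_alt,
                  ".", "PASS", info, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read calls back from a cohortvar VCF
#'
#' Minimal reader for the files produced by [write_vcf()]: returns positions,
#' anchored alleles, and the INFO statistics.
#'
#' @param path VCF file.
#' @return Data.frame with `vcf_pos`, `vcf_ref`, `vcf_alt`, `type`, `c`,
#'   `r_alt`, `r_ref`, `p`, `z`.
#' @export
read_vcf_calls <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(vcf_pos = integer(0), vcf_ref = character(0),
                      vcf_alt = character(0), type = character(0),
                      c = numeric(0), r_alt = integer(0), r_ref = integer(0),
                      p = numeric(0), z = numeric(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(?<=", key, "=)[^;]+"), info,
                                  perl = TRUE))
    if (length(m) == 0L) NA_character_ else m
  }
  infos <- vapply(f, `[[`, character(1), 8L)
  data.frame(
    vcf_pos = as.integer(vapply(f, `[[`, character(1), 2L)),
    vcf_ref = vapply(f, `[[`, character(1), 4L),
    vcf_alt = vapply(f, `[[`, character(1), 5L),
    type = vapply(infos, info_get, character(1), "TYPE", USE.NAMES = FALSE),
    c = as.numeric(vapply(infos, info_get, character(1), "C",
                          USE.NAMES = FALSE)),
    r_alt = as.integer(vapply(infos, info_get, character(1), "RALT",
                              USE.NAMES = FALSE)),
    r_ref = as.integer(vapply(infos, info_get, character(1), "RREF",
                              USE.NAMES = FALSE)),
    p = as.numeric(vapply(infos, info_get, character(1), "PV",
                          USE.NAMES = FALSE)),
    z = as.numeric(vapply(infos, info_get, character(1), "Z",
                          USE.NAMES = FALSE)),
    stringsAsFactors = FALSE
  )
}

#' Write calls (all tested records) as TSV
#'
#' @param calls Data.frame from [call_variants()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
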