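# Shared toy fixtures, built in code.

# Bubble toy: reference CGATTTGAA; 8 reads with the T>G substitution, 2
# clean reads, 1 truncated read continuing with a non-A base.
bubble_reads <- function(truncated = "CGATTTGAC") {
  c(rep("CGATGTGAA", 8L), rep("CGATTTGAA", 2L), truncated)
}
bubble_ref <- function() c(ref = "CGATTTGAA")

# Tip toy: a sample sequence overlapping the reference only in its middle,
# so both path endpoints are tips needing anchors.
tip_ref <- function() c(ref = "CTCGTTAACTTTGCGG")
tip_sample_read <- function() "TTCAACTGGCC"

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Tiny cohort for permutation-test unit tests: `n_samples` read sets over a
# short reference; sample `mut_sample` carries `mut_frac` reads with a
# substitution, and every sample shares a recurrent deletion at rate
# `rec_frac`.
toy_cohort <- function(reference, n_samples = 5L, n_reads = 60L,
                       mut_sample = NULL, mut_frac = 0, rec_frac = 0,
                       seed = 1L) {
  set.seed(seed)
  L <- nchar(reference)
  mid <- L %/% 2L
  mut_seq <- paste0(substr(reference, 1L, mid - 1L),
                    chartr("ACGT", "GTAC", substr(reference, mid, mid)),
                    substr(reference, mid + 1L, L))
  rec_pos <- L %/% 3L
  rec_seq <- paste0(substr(reference, 1L, rec_pos - 1L),
                    substr(reference, rec_pos + 1L, L))
  samples <- lapply(seq_len(n_samples), function(s) {
    reads <- rep(reference, n_reads)
    n_rec <- round(rec_frac * n_reads)
    if (n_rec > 0L) reads[seq_len(n_rec)] <- rec_seq
    if (!is.null(mut_sample) && s == mut_sample) {
      n_mut <- round(mut_frac * n_reads)
      reads[n_reads - seq_len(n_mut) + 1L] <- mut_seq
    }
    sample(reads)
  })
  names(samples) <- paste0("S", seq_len(n_samples))
  list(samples = samples, mut_seq = mut_seq, rec_seq = rec_seq,
       mut_pos = mid, rec_pos = rec_pos)
}
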