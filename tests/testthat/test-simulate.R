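# Synthetic cohorts: reference generation, spiked alterations, the error
# model, and cohort-level structure.

count_runs <- function(seq, min_run = 4) nrow(homopolymer_runs_test(seq, min_run))
homopolymer_runs_test <- function(seq, min_run) {
  r <- rle(strsplit(seq, "")[[1]])
  start <- cumsum(c(1, r$lengths[-length(r$lengths)]))
  data.frame(start = start[r$lengths >= min_run],
             length = r$lengths[r$lengths >= min_run])
}

test_that("generated references have the requested homopolymer structure", {
  ref <- generate_reference(500, 0.05, seed = 1)
  expect_equal(nchar(ref), 500)
  expect_false(grepl("[^ACGT]", ref))
  expect_gte(count_runs(ref), 3)
  # determinism and seed sensitivity
  expect_identical(ref, generate_reference(500, 0.05, seed = 1))
  expect_false(identical(ref, generate_reference(500, 0.05, seed = 2)))
  # zero density plants nothing on purpose (incidental runs possible)
  ref0 <- generate_reference(200, 0, seed = 2)
  expect_equal(nchar(ref0), 200)
  expect_error(generate_reference(500, 0.6), "<= 0.5")
  expect_error(generate_reference(100, 0.05), ">= 200")
})

test_that("spiked alterations are consistent with their truth records", {
  ref <- generate_reference(500, 0.05, seed = 3)
  # forced substitution: exactly one differing position, equal length
  spX <- spike_alterations(ref, n_alt = 1, seed = 4, types = "X")
  expect_equal(nchar(spX$haplotype), nchar(ref))
  diffs <- which(strsplit(ref, "")[[1]] != strsplit(spX$haplotype, "")[[1]])
  expect_length(diffs, 1)
  expect_equal(spX$truth$pos, diffs)
  # three alterations: replaying the truth table rebuilds the haplotype
  sp3 <- spike_alterations(ref, n_alt = 3, seed = 5, min_spacing = 40)
  expect_equal(nrow(sp3$truth), 3)
  expect_lte(abs(nchar(sp3$haplotype) - nchar(ref)), 15)
  ops <- data.frame(type = sp3$truth$type, pos = sp3$truth$pos,
                    ref = sp3$truth$ref, alt = sp3$truth$alt)
  expect_equal(apply_edits(ref, ops), sp3$haplotype)
  expect_true(all(diff(sort(sp3$truth$pos)) >= 40 - 6))
  # forced 5-nt deletions shorten the haplotype accordingly
  for (s in 1:10) {
    spD <- spike_alterations(ref, n_alt = 1, seed = 100 + s, types = "D",
                             max_len = 5)
    expect_equal(nchar(ref) - nchar(spD$haplotype), nchar(spD$truth$ref))
    expect_lte(nchar(spD$truth$ref), 5)
  }
})

test_that("read simulation follows the error model", {
  ref <- generate_reference(500, 0.05, seed = 6)
  sp <- spike_alterations(ref, n_alt = 1, seed = 7, types = "X")
  # no errors, hard assignment: exactly phi*n mutant reads, rest identical
  clean <- error_model(0, 0, 0, 1)
  sim <- simulate_reads(c(ref, sp$haplotype), c(0.6, 0.4), 1000, clean,
                        seed = 8, truths = list(NULL, sp$truth))
  expect_length(sim$reads, 1000)
  expect_equal(sum(sim$reads == sp$haplotype), 400)
  expect_equal(sum(sim$reads == ref), 600)
  expect_true(all(nchar(sim$quals) == nchar(sim$reads)))
  # spiked alteration bases carry the maximum quality
  mut_qual <- substr(sim$quals[sim$origin == 2][1], sp$truth$pos,
                     sp$truth$pos)
  expect_equal(mut_qual, "~")
  # mismatch-only model: per-read mismatch counts match the binomial oracle
  mm <- error_model(0.025, 0, 0, 1)
  sim2 <- simulate_reads(ref, 1, 1000, mm, seed = 9)
  n_mm <- vapply(sim2$reads, function(r) {
    sum(strsplit(r, "")[[1]] != strsplit(ref, "")[[1]])
  }, integer(1), USE.NAMES = FALSE)
  expect_true(all(nchar(sim2$reads) == 500))
  mu <- 500 * 0.025
  sdn <- sqrt(500 * 0.025 * 0.975)
  expect_lt(abs(mean(n_mm) - mu), 3 * sdn / sqrt(1000))
  # single error-free read equals its haplotype
  sim3 <- simulate_reads(ref, 1, 1, clean, seed = 10)
  expect_equal(sim3$reads, ref)
  expect_identical(simulate_reads(ref, 1, 5, mm, seed = 11)$reads,
                   simulate_reads(ref, 1, 5, mm, seed = 11)$reads)
})

test_that("recurrent sites fire identically-distributed across samples", {
  ref <- generate_reference(600, 0.08, seed = 12)
  sites <- recurrent_error_sites(ref, n_sites = 1, prob = 0.2, seed = 13)
  expect_equal(nrow(sites), 1)
  model <- error_model(0, 0, 0, 1, recurrent_sites = sites)
  # with all other rates at zero a read either matches the reference or
  # carries exactly the recurrent deletion
  del_seq <- paste0(substr(ref, 1, sites$pos - 1),
                    substr(ref, sites$pos + 1, nchar(ref)))
  counts <- vapply(1:4, function(s) {
    sim <- simulate_reads(ref, 1, 300, model, seed = 20 + s)
    expect_true(all(sim$reads %in% c(ref, del_seq)))
    sum(sim$reads == del_seq)
  }, integer(1))
  # frequencies are statistically indistinguishable across samples
  expect_gt(stats::chisq.test(cbind(counts, 300 - counts))$p.value, 0.01)
  expect_true(all(counts > 30) && all(counts < 100))
})

test_that("cohorts have controls, private truths, and determinism", {
  co <- generate_cohort(n_samples = 5, n_controls = 2, n_reads = 150,
                        phi = 0.4, n_alt = 1, ref_length = 400,
                        min_spacing = 30, seed = 14)
  expect_length(co$samples, 5)
  expect_equal(co$controls, c("S01", "S02"))
  expect_false(any(co$truth$sample %in% co$controls))
  expect_equal(nrow(co$truth), 3)
  # private: each truth record belongs to exactly one sample
  expect_equal(anyDuplicated(paste(co$truth$pos, co$truth$ref,
                                   co$truth$alt)), 0)
  expect_true(all(vapply(co$samples, function(s) length(s$reads) == 150,
                         logical(1))))
  co2 <- generate_cohort(n_samples = 5, n_controls = 2, n_reads = 150,
                         phi = 0.4, n_alt = 1, ref_length = 400,
                         min_spacing = 30, seed = 14)
  expect_identical(co$samples, co2$samples)
  expect_identical(co$truth, co2$truth)
  # carrier counts: ~phi*n reads of a mutated sample carry the alteration
  co3 <- generate_cohort(n_samples = 3, n_controls = 2, n_reads = 1000,
                         phi = 0.03, n_alt = 1, ref_length = 400,
                         min_spacing = 30, seed = 15)
  tr <- co3$truth
  hap <- apply_edits(co3$reference[[1]],
                     data.frame(type = tr$type, pos = tr$pos,
                                ref = tr$ref, alt = tr$alt))
  win <- substr(hap, max(1, tr$pos[1] - 15), tr$pos[1] + 15)
  n_carrier <- sum(grepl(win, co3$samples[["S03"]]$reads, fixed = TRUE))
  expect_gt(n_carrier, 10)
  expect_lt(n_carrier, 50)
})

test_that("cohort files round-trip through FASTQ/FASTA/TSV", {
  co <- generate_cohort(n_samples = 3, n_controls = 1, n_reads = 30,
                        phi = 0.4, ref_length = 300, min_spacing = 30,
                        seed = 16)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "reference.fasta")))
  ref_back <- read_reference_fasta(file.path(dir, "reference.fasta"))
  expect_equal(unname(ref_back[1]), unname(co$reference[[1]]))
  reads_back <- read_reads(file.path(dir, "S02.fastq"))
  expect_equal(reads_back, co$samples[["S02"]]$reads)
  truth_back <- utils::read.delim(file.path(dir, "truth.tsv"),
                                  stringsAsFactors = FALSE)
  expect_equal(nrow(truth_back), nrow(co$truth))
})
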