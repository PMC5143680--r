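# Synthetic targeted long-read cohorts: a circular-consensus-like error
# model (uniform mismatch/indel rates, elevated deletions inside homopolymer
# runs, cohort-shared recurrent deletion sites) plus sample-private spiked
# alterations with a truth table.

#' Error model for synthetic long reads
#'
#' Rates are per base and uniform along the read, except that the deletion
#' rate is multiplied by `hp_multiplier` for bases inside homopolymer runs of
#' length 4 or more, and that `recurrent_sites` (typically homopolymer
#' deletions shared by the whole cohort) fire independently per read with
#' their own probability. Defaults emulate consensus long reads with an
#' overall error rate around 2-2.5% per base, indel-dominated and
#' concentrated in homopolymers.
#'
#' @param mismatch,insertion,deletion Per-base rates.
#' @param hp_multiplier Deletion-rate multiplier inside homopolymer runs
#'   `>= 4`.
#' @param recurrent_sites `NULL` or a data.frame with columns `pos` (1-based
#'   reference position of the deleted base), `type` (currently `"D"`) and
#'   `prob` (per-read probability); see [recurrent_error_sites()].
#' @return An object of class `error_model`.
#' @export
error_model <- function(mismatch = 0.006, insertion = 0.003,
                        deletion = 0.006, hp_multiplier = 4,
                        recurrent_sites = NULL) {
  rates <- c(mismatch, insertion, deletion)
  stopifnot(all(rates >= 0), all(rates <= 1), hp_multiplier >= 1)
  if (mismatch + insertion + deletion * hp_multiplier > 0.10) {
    stop("total per-base error rate exceeds 0.10", call. = FALSE)
  }
  if (!is.null(recurrent_sites)) {
    stopifnot(is.data.frame(recurrent_sites),
              all(c("pos", "type", "prob") %in% names(recurrent_sites)),
              all(recurrent_sites$prob >= 0 & recurrent_sites$prob <= 1))
  }
  m <- list(mismatch = mismatch, insertion = insertion, deletion = deletion,
            hp_multiplier = hp_multiplier, recurrent_sites = recurrent_sites)
  class(m) <- "error_model"
  m
}

#' Generate a random amplicon reference with planted homopolymers
#'
#' @param length Reference length in nt (`>= 200`).
#' @param homopolymer_density Target fraction of positions inside planted
#'   homopolymer runs (length 4-6); must be `<= 0.5`.
#' @param seed Integer seed (same arguments and seed give the same
#'   sequence).
#' @return A single DNA string.
#' @export
generate_reference <- function(length, homopolymer_density = 0.05, seed = 1L) {
  stopifnot(length >= 200)
  if (homopolymer_density > 0.5) {
    stop("homopolymer_density must be <= 0.5", call. = FALSE)
  }
  with_local_seed(seed, {
    base <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    n_runs <- round(homopolymer_density * length / 5)
    if (n_runs > 0) {
      taken <- rep(FALSE, length)
      planted <- 0L
      tries <- 0L
      while (planted < n_runs && tries < 50L * n_runs) {
        tries <- tries + 1L
        l <- sample(4:6, 1L)
        p <- sample.int(length - l - 1L, 1L) + 1L
        span <- max(1L, p - 1L):min(length, p + l)
        if (any(taken[span])) next
        b <- sample(c("A", "C", "G", "T"), 1L)
        base[p:(p + l - 1L)] <- b
        # keep flanks distinct so the planted run has exact length
        if (p > 1L && base[p - 1L] == b) {
          base[p - 1L] <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }
        if (p + l <= length && base[p + l] == b) {
          base[p + l] <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }
        taken[span] <- TRUE
        planted <- planted + 1L
      }
    }
    paste(base, collapse = "")
  })
}

# Homopolymer runs of at least `min_run` identical bases:
# data.frame(start, length, base).
homopolymer_runs <- function(seq, min_run = 4L) {
  r <- rle(strsplit(seq, "")[[1]])
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  keep <- r$lengths >= min_run
  data.frame(start = start[keep], length = r$lengths[keep],
             base = r$values[keep], stringsAsFactors = FALSE)
}

#' Plant cohort-shared recurrent error sites in homopolymers
#'
#' Picks homopolymer runs of the reference and defines one single-base
#' deletion site per chosen run (left-aligned at the run start, the natural
#' normalized placement for a deletion inside a homopolymer). All samples of
#' a cohort share these sites, emulating recurrent context-specific
#' artifacts.
#'
#' @param reference Reference sequence.
#' @param n_sites Number of sites (truncated to the available runs).
#' @param prob Per-read probability that the deletion occurs.
#' @param seed Integer seed.
#' @param margin Keep sites at least this many bases from either end.
#' @return Data.frame with columns `pos`, `type` (`"D"`), `base`, `prob`.
#' @export
recurrent_error_sites <- function(reference, n_sites = 3L, prob = 0.05,
                                  seed = 1L, margin = 40L) {
  runs <- homopolymer_runs(reference)
  runs <- runs[runs$start > margin &
                 runs$start + runs$length < nchar(reference) - margin, ,
               drop = FALSE]
  if (nrow(runs) == 0L) {
    return(data.frame(pos = integer(0), type = character(0),
                      base = character(0), prob = numeric(0)))
  }
  with_local_seed(seed, {
    take <- sample.int(nrow(runs), min(n_sites, nrow(runs)))
    take <- take[order(runs$start[take])]
    data.frame(pos = runs$start[take], type = "D", base = runs$base[take],
               prob = prob, stringsAsFactors = FALSE)
  })
}

#' Spike private alterations into a reference
#'
#' Chooses `n_alt` alterations with uniform probability among mismatch,
#' insertion and deletion; lengths are 1 for mismatches and uniform on
#' 1..`max_len` for indels; insertion content is a random l-mer. Positions
#' are drawn uniformly inside the mappable bounds and redrawn when closer
#' than `min_spacing` to a previous alteration (keeps alternative paths
#' separable) or within `min_spacing` of an `avoid` position (so private
#' mutations stay identifiable next to planted recurrent artifacts).
#'
#' @param reference Reference sequence.
#' @param n_alt Number of alterations (1-3 in a typical study).
#' @param seed Integer seed.
#' @param max_len Maximum indel length (default 5).
#' @param min_spacing Minimum distance between alterations (use about `2k`
#'   for the `k` the cohort will be analyzed with).
#' @param margin Exclusion zone at the reference ends.
#' @param avoid Optional integer vector of positions to stay clear of.
#' @param types Candidate types to draw from (default `c("X","I","D")`).
#' @return A list with `haplotype` (the altered sequence) and `truth`, a
#'   data.frame with columns `pos`, `type`, `ref`, `alt` (minimal
#'   left-normalized representation on the reference).
#' @export
spike_alterations <- function(reference, n_alt = 1L, seed = 1L, max_len = 5L,
                              min_spacing = 60L, margin = 30L,
                              avoid = integer(0), types = c("X", "I", "D")) {
  stopifnot(n_alt >= 1L)
  L <- nchar(reference)
  with_local_seed(seed, {
    chosen <- integer(0)
    recs <- vector("list", n_alt)
    for (i in seq_len(n_alt)) {
      for (try in 1:1000) {
        p <- sample((margin + 1L):(L - margin - max_len), 1L)
        if (all(abs(p - c(chosen, avoid)) >= min_spacing)) break
        if (try == 1000) stop("could not place alterations with the ",
                              "requested spacing", call. = FALSE)
      }
      chosen <- c(chosen, p)
      type <- sample(types, 1L)
      l <- if (type == "X") 1L else sample.int(max_len, 1L)
      if (type == "X") {
        rb <- substr(reference, p, p)
        ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
        rec <- list(pos = p, type = "X", ref = rb, alt = ab)
      } else if (type == "D") {
        rec <- list(pos = p, type = "D",
                    ref = substr(reference, p, p + l - 1L), alt = "")
      } else {
        rec <- list(pos = p, type = "I", ref = "",
                    alt = paste(sample(c("A", "C", "G", "T"), l,
                                       replace = TRUE), collapse = ""))
      }
      nv <- normalize_variant(rec$pos, rec$ref, rec$alt, reference)
      recs[[i]] <- data.frame(pos = nv$pos, type = nv$type, ref = nv$ref,
                              alt = nv$alt, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, recs)
    truth <- truth[order(truth$pos), , drop = FALSE]
    rownames(truth) <- NULL
    ops <- data.frame(type = truth$type,
                      pos = truth$pos, ref = truth$ref, alt = truth$alt,
                      stringsAsFactors = FALSE)
    list(haplotype = apply_edits(reference, ops), truth = truth)
  })
}

# Translate reference positions onto a haplotype carrying `truth`
# alterations (net indel offsets of alterations strictly upstream).
shift_positions <- function(pos, truth) {
  if (is.null(truth) || nrow(truth) == 0L) return(pos)
  vapply(pos, function(p) {
    up <- truth[truth$pos < p, , drop = FALSE]
    p + sum(nchar(up$alt) - nchar(up$ref))
  }, numeric(1))
}

#' Simulate reads from weighted haplotypes
#'
#' Draws full-length amplicon reads from the given haplotypes and applies
#' the error model: recurrent sites fire per read with their probability,
#' then uniform per-base mismatches, insertions (one random base appended
#' after the position) and deletions, with the deletion rate multiplied
#' inside homopolymer runs. Base qualities are constant high (Q40, `I`)
#' except error positions (Q7, `(`); bases introduced by spiked alterations
#' carry the maximum quality (`~`), as alteration bases are planted, not
#' called. With `hard_assign = TRUE` (default) exactly
#' `floor(weight * n)` reads come from each non-first haplotype and the
#' remainder from the first, making carrier counts exact; otherwise
#' assignment is multinomial.
#'
#' @param haplotypes Character vector of haplotype sequences (first one is
#'   the reference/wild type).
#' @param weights Numeric weights summing to 1.
#' @param n Number of reads.
#' @param model An [error_model()].
#' @param seed Integer seed.
#' @param truths Optional list (parallel to `haplotypes`) of truth tables
#'   used to shift recurrent-site coordinates onto each haplotype and to
#'   flag max-quality alteration bases; `NULL` entries mean "no spiked
#'   alterations".
#' @param hard_assign Deterministic haplotype counts (default) or
#'   multinomial.
#' @return A list with `reads`, `quals` (Phred+33 strings, same lengths) and
#'   `origin` (haplotype index per read).
#' @export
simulate_reads <- function(haplotypes, weights = 1, n, model = error_model(),
                           seed = 1L, truths = NULL, hard_assign = TRUE) {
  stopifnot(length(haplotypes) >= 1L, n >= 1L,
            abs(sum(weights) - 1) < 1e-8,
            length(weights) == length(haplotypes))
  with_local_seed(seed, {
    H <- length(haplotypes)
    if (hard_assign) {
      counts <- floor(weights * n)
      counts[1L] <- counts[1L] + (n - sum(counts))
    } else {
      counts <- as.vector(stats::rmultinom(1L, n, weights))
    }
    origin <- rep(seq_len(H), counts)
    # per-haplotype precomputations
    hap_chars <- lapply(haplotypes, function(h) strsplit(h, "")[[1]])
    del_rate <- lapply(seq_len(H), function(h) {
      ch <- hap_chars[[h]]
      rate <- rep(model$deletion, length(ch))
      runs <- homopolymer_runs(haplotypes[[h]])
      for (r in seq_len(nrow(runs))) {
        span <- runs$start[r]:(runs$start[r] + runs$length[r] - 1L)
        rate[span] <- model$deletion * model$hp_multiplier
      }
      rate
    })
    rec_pos <- lapply(seq_len(H), function(h) {
      rs <- model$recurrent_sites
      if (is.null(rs) || nrow(rs) == 0L) return(NULL)
      tr <- if (!is.null(truths)) truths[[h]] else NULL
      data.frame(pos = shift_positions(rs$pos, tr), prob = rs$prob)
    })
    max_q <- lapply(seq_len(H), function(h) {
      ch <- hap_chars[[h]]
      flag <- rep(FALSE, length(ch))
      tr <- if (!is.null(truths)) truths[[h]] else NULL
      if (!is.null(tr) && nrow(tr) > 0L) {
        for (r in seq_len(nrow(tr))) {
          hp <- shift_positions(tr$pos[r], tr)
          l <- nchar(tr$alt[r])
          if (tr$type[r] == "X") flag[hp] <- TRUE
          if (tr$type[r] == "I") {
            span <- (hp + 1L):(hp + l)
            flag[span[span <= length(ch)]] <- TRUE
          }
        }
      }
      flag
    })
    bases <- c("A", "C", "G", "T")
    reads <- character(n); quals <- character(n)
    for (i in seq_len(n)) {
      h <- origin[i]
      ch <- hap_chars[[h]]
      L <- length(ch)
      q <- ifelse(max_q[[h]], "~", "I")
      mis <- stats::runif(L) < model$mismatch
      if (any(mis)) {
        ch[mis] <- vapply(ch[mis],
                          function(b) sample(setdiff(bases, b), 1L),
                          character(1), USE.NAMES = FALSE)
        q[mis] <- "("
      }
      del <- stats::runif(L) < del_rate[[h]]
      rp <- rec_pos[[h]]
      if (!is.null(rp)) {
        fire <- stats::runif(nrow(rp)) < rp$prob
        del[rp$pos[fire]] <- TRUE
      }
      ins <- stats::runif(L) < model$insertion
      ins_base <- rep("", L); ins_qual <- rep("", L)
      if (any(ins)) {
        ins_base[ins] <- sample(bases, sum(ins), replace = TRUE)
        ins_qual[ins] <- "("
      }
      keep_ch <- ifelse(del, "", ch)
      keep_q <- ifelse(del, "", q)
      reads[i] <- paste(paste0(keep_ch, ins_base), collapse = "")
      quals[i] <- paste(paste0(keep_q, ins_qual), collapse = "")
    }
    list(reads = reads, quals = quals, origin = origin)
  })
}

#' Generate a synthetic targeted cohort with truth table
#'
#' Builds (or takes) a reference amplicon, plants cohort-shared recurrent
#' homopolymer deletion sites, assigns the first `n_controls` samples as
#' negative controls (no spiked alterations) and gives every other sample
#' its own private alterations carried by a fraction `phi` of its reads.
#' All samples share the same error model and recurrent sites.
#'
#' @param n_samples Number of samples (`>= 3`).
#' @param n_controls Number of leading negative-control samples.
#' @param n_reads Reads per sample (single value or vector per sample).
#' @param phi Fraction of altered reads per mutated sample (single value or
#'   vector of length `n_samples - n_controls`), each in `[0.03, 0.80]`.
#' @param n_alt Alterations per mutated sample (1-3; single value or
#'   vector).
#' @param reference Optional reference sequence; generated with
#'   [generate_reference()] when `NULL`.
#' @param ref_length,homopolymer_density Passed to [generate_reference()].
#' @param model Optional [error_model()]; when `NULL`, the default model
#'   plus `n_recurrent` recurrent sites at `recurrent_prob` is used.
#' @param n_recurrent,recurrent_prob Recurrent-site defaults (see
#'   [recurrent_error_sites()]).
#' @param min_spacing Minimum spacing between alterations and to recurrent
#'   sites (about `2k`).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return An object of class `synthetic_cohort`: list with `reference`
#'   (named character), `samples` (named list of `list(reads, quals)`),
#'   `truth` (data.frame `sample`, `pos`, `type`, `ref`, `alt`, `vaf`),
#'   `model`, `sample_ids`, `controls`.
#' @export
generate_cohort <- function(n_samples = 6L, n_controls = 2L, n_reads = 500L,
                            phi = 0.1, n_alt = 1L, reference = NULL,
                            ref_length = 500L, homopolymer_density = 0.05,
                            model = NULL, n_recurrent = 3L,
                            recurrent_prob = 0.05, min_spacing = 60L,
                            seed = 1L) {
  stopifnot(n_samples >= 3L, n_controls >= 0L, n_controls <= n_samples)
  n_mut <- n_samples - n_controls
  phi <- rep(phi, length.out = n_mut)
  stopifnot(all(phi >= 0.03 & phi <= 0.80))
  n_alt <- rep(as.integer(n_alt), length.out = n_mut)
  n_reads <- rep(as.integer(n_reads), length.out = n_samples)
  seeds <- with_local_seed(seed,
    sample.int(.Machine$integer.max %/% 2L, 2L + 2L * n_samples))
  if (is.null(reference)) {
    reference <- generate_reference(ref_length, homopolymer_density,
                                    seed = seeds[1L])
  } else {
    reference <- toupper(reference)
  }
  if (is.null(model)) {
    sites <- recurrent_error_sites(reference, n_sites = n_recurrent,
                                   prob = recurrent_prob, seed = seeds[2L])
    model <- error_model(recurrent_sites = sites)
  }
  avoid <- if (!is.null(model$recurrent_sites)) model$recurrent_sites$pos
           else integer(0)
  ids <- sprintf("S%02d", seq_len(n_samples))
  samples <- vector("list", n_samples)
  names(samples) <- ids
  truth_list <- list()
  for (s in seq_len(n_samples)) {
    if (s <= n_controls) {
      sim <- simulate_reads(reference, 1, n_reads[s], model,
                            seed = seeds[2L + 2L * s])
    } else {
      j <- s - n_controls
      sp <- spike_alterations(reference, n_alt = n_alt[j],
                              seed = seeds[1L + 2L * s],
                              min_spacing = min_spacing, avoid = avoid)
      sim <- simulate_reads(c(reference, sp$haplotype), c(1 - phi[j], phi[j]),
                            n_reads[s], model, seed = seeds[2L + 2L * s],
                            truths = list(NULL, sp$truth))
      truth_list[[ids[s]]] <- cbind(sample = ids[s], sp$truth,
                                    vaf = phi[j], stringsAsFactors = FALSE)
    }
    samples[[s]] <- list(reads = sim$reads, quals = sim$quals)
  }
  truth <- if (length(truth_list) > 0L) {
    tr <- do.call(rbind, truth_list); rownames(tr) <- NULL; tr
  } else {
    data.frame(sample = character(0), pos = integer(0), type = character(0),
               ref = character(0), alt = character(0), vaf = numeric(0))
  }
  out <- list(reference = c(amplicon = reference), samples = samples,
              truth = truth, model = model, sample_ids = ids,
              controls = ids[seq_len(n_controls)])
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic cohort: %d samples (%d controls), ",
                     "%d-nt reference, %d spiked alteration(s)\n"),
              length(x$samples), length(x$controls),
              nchar(x$reference[[1L]]), nrow(x$truth)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `reference.fasta`, one `<sample>.fastq` per sample (Phred+33) and
#' `truth.tsv`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reference_fasta(cohort$reference, file.path(dir, "reference.fasta"))
  for (id in names(cohort$samples)) {
    write_reads_fastq(cohort$samples[[id]]$reads,
                      cohort$samples[[id]]$quals,
                      file.path(dir, paste0(id, ".fastq")))
  }
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
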