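# Difference graph, alternative-path enumeration, tip anchoring, reference
# path choice, atomic decomposition, and coordinate mapping.

test_that("difference graph keeps sample-only edges over union vertices", {
  ref <- build_reference_graph(tip_ref(), k = 3)
  smp <- build_sample_graph(tip_sample_read(), k = 3, min_support = 1)
  d <- difference_graph(smp, ref)
  keys <- paste(d$edges$from, d$edges$to, sep = ">")
  expect_true(all(c("TTC>TCA", "ACT>CTG") %in% keys))
  expect_false("AAC>ACT" %in% keys)  # explained by the reference
  expect_setequal(d$vertices, union(smp$vertices, ref$vertices))
  # identical sample -> no alternative edges, shared k-mers are singletons
  ref2 <- build_reference_graph(bubble_ref(), k = 3)
  same <- build_sample_graph(rep("CGATTTGAA", 5), k = 3, min_support = 1)
  d2 <- difference_graph(same, ref2)
  expect_equal(nrow(d2$edges), 0)
  expect_true(all(kmerize("CGATTTGAA", 3) %in% d2$vertices))
  # bubble toy: shared k-mers outside the bubble stay as singleton vertices
  smp3 <- build_sample_graph(bubble_reads(), k = 3, min_support = 1)
  d3 <- difference_graph(smp3, ref2)
  expect_true("CGA" %in% d3$vertices)
  expect_false("CGA" %in% c(d3$edges$from, d3$edges$to))
  expect_error(difference_graph(build_sample_graph("ACGT", 4, 1), ref2),
               "different k")
})

test_that("alternative paths of the figure toys are found exactly", {
  # tip toy: two alternative paths, both with one tip endpoint
  ref <- build_reference_graph(tip_ref(), k = 3)
  smp <- build_sample_graph(tip_sample_read(), k = 3, min_support = 1)
  p <- find_alternative_paths(difference_graph(smp, ref), ref, smp)
  expect_setequal(p$seq, c("TTCAAC", "ACTGGCC"))
  expect_equal(sort(attr(detect_tips(p, ref), "tips")), c("GCC", "TTC"))
  expect_equal(p$tip_start[p$seq == "TTCAAC"], TRUE)
  expect_equal(p$tip_end[p$seq == "ACTGGCC"], TRUE)
  # bubble toy drawn as in the figure (truncated read ends at the bubble):
  # exactly one alternative path through the substituted k-mers
  ref2 <- build_reference_graph(bubble_ref(), k = 3)
  smp2 <- build_sample_graph(bubble_reads(truncated = "CGATTTGA"),
                             k = 3, min_support = 1)
  p2 <- find_alternative_paths(difference_graph(smp2, ref2), ref2, smp2)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$seq, "GATGTGA")
  expect_equal(p2$start, "GAT")
  expect_equal(p2$end, "TGA")
  expect_equal(p2$support, 8)
  expect_false(any(p2$tip_start | p2$tip_end))
  expect_equal(attr(p2, "vertices")[[1]][2:4], c("ATG", "TGT", "GTG"))
  # identical sample: nothing to report
  same <- build_sample_graph(rep("CGATTTGAA", 3), k = 3, min_support = 1)
  p3 <- find_alternative_paths(difference_graph(same, ref2), ref2, same)
  expect_equal(nrow(p3), 0)
})

test_that("path enumeration agrees with exhaustive igraph enumeration", {
  skip_if_not_installed("igraph")
  set.seed(31)
  for (rep in 1:10) {
    k <- 3
    refseq <- random_dna(sample(15:25, 1))
    ref <- build_reference_graph(c(r = refseq), k = k)
    reads <- vapply(1:6, function(i) {
      s <- strsplit(refseq, "")[[1]]
      p <- sample(seq(2, length(s) - 1), 1)
      s[p] <- sample(c("A", "C", "G", "T"), 1)
      paste(s, collapse = "")
    }, character(1))
    smp <- build_sample_graph(reads, k = k, min_support = 1)
    if (length(smp$vertices) > 30) next
    d <- difference_graph(smp, ref)
    got <- find_alternative_paths(d, ref, smp)
    expect_setequal(got$seq, igraph_alt_paths(d, ref))
  }
})

test_that("tips are anchored by edit distance then path-length proximity", {
  ref <- build_reference_graph(tip_ref(), k = 3)
  a1 <- anchor_tip("TTC", "start", companion = "AAC", ref = ref,
                   alt_edges = 3)
  expect_equal(a1$anchor, "TTA")  # CTC and TTA tie at lev 1; TTA is closer
  expect_equal(a1$dist, 2)
  a2 <- anchor_tip("GCC", "end", companion = "ACT", ref = ref,
                   alt_edges = 4)
  expect_equal(a2$anchor, "GCG")
  # a tip at distance 0 from a unique reference vertex anchors there
  a3 <- anchor_tip("TCG", "start", companion = "AAC", ref = ref,
                   alt_edges = 4)
  expect_equal(a3$anchor, "TCG")
  expect_equal(a3$lev, 0)
  expect_error(anchor_tip("TTC", "start", companion = "XXX", ref = ref,
                          alt_edges = 2), "reference vertex")
})

test_that("best reference path maximizes sample read support", {
  ref <- build_reference_graph(bubble_ref(), k = 3)
  smp <- build_sample_graph(bubble_reads(), k = 3, min_support = 1)
  rp <- best_reference_path("GAT", "TGA", ref, smp, alt_edges = 4)
  expect_equal(rp$seq, "GATTTGA")
  expect_equal(rp$support, 3)
  # adjacent anchors -> the single-edge path
  rp2 <- best_reference_path("CGA", "GAT", ref, smp, alt_edges = 1)
  expect_equal(rp2$seq, "CGAT")
  expect_equal(rp2$n_edges, 1)
  # two known-SNP haplotypes: the one the sample reads carry wins
  set.seed(19)
  k <- 5
  repeat { # draw a haplotype pair whose k-mers are all distinct
    hapA <- random_dna(30)
    hapB <- paste0(substr(hapA, 1, 14),
                   chartr("ACGT", "GTAC", substr(hapA, 15, 15)),
                   substr(hapA, 16, 30))
    if (!anyDuplicated(kmerize(hapA, k)) &&
        !anyDuplicated(kmerize(hapB, k))) break
  }
  ref2 <- build_reference_graph(c(a = hapA, b = hapB), k = k)
  smpB <- build_sample_graph(rep(hapB, 10), k = k, min_support = 1)
  first <- kmerize(hapB, k)[1]
  last <- kmerize(hapB, k)[26]
  rp3 <- best_reference_path(first, last, ref2, smpB,
                             alt_edges = nchar(hapB) - k)
  expect_equal(rp3$seq, hapB)
  expect_equal(rp3$support, 10)
})

test_that("atomic decomposition splits multi-alteration paths into blocks", {
  ops <- atomic_decomposition("CGAGTAGAA", "CGATTCATGGAA")
  expect_equal(nrow(ops), 3)
  expect_equal(ops$type, c("X", "D", "D"))
  expect_equal(ops$ref[ops$type == "X"], "T")
  expect_equal(ops$alt[ops$type == "X"], "G")
  expect_setequal(ops$ref[ops$type == "D"], c("C", "TG"))
  # identity and the single-substitution bubble
  expect_equal(nrow(atomic_decomposition("ACGT", "ACGT")), 0)
  one <- atomic_decomposition("GATGTGA", "GATTTGA")
  expect_equal(nrow(one), 1)
  expect_equal(one$type, "X")
  expect_equal(one$ref, "T")
  expect_equal(one$alt, "G")
  # a multi-nt insertion is one block even when it echoes its context
  ref <- "ACCTGAGTCCATTGCA"
  alt <- paste0(substr(ref, 1, 8), "GTGTC", substr(ref, 9, 16))
  ins <- atomic_decomposition(alt, ref)
  expect_equal(nrow(ins), 1)
  expect_equal(ins$type, "I")
  expect_equal(nchar(ins$alt), 5)
})

test_that("decomposition is minimal and reconstructs the alternative", {
  set.seed(17)
  for (i in 1:60) {
    a <- random_dna(sample(5:35, 1))
    b <- random_dna(sample(5:35, 1))
    ops <- atomic_decomposition(a, b)
    expect_equal(apply_edits(b, ops), a)
    # unit edit count before block merging equals the DP oracle distance
    expect_equal(attr(ops, "n_unit_ops"),
                 as.integer(utils::adist(b, a)))
  }
})

test_that("count ratio follows its definition and bounds", {
  expect_equal(count_ratio(8, 3), 8 / 11)
  expect_equal(count_ratio(5, 0), 1)
  expect_equal(count_ratio(1, 99), 0.01)
  expect_error(count_ratio(0, 5), "unsupported")
  set.seed(3)
  r_alt <- sample(1:50, 20, replace = TRUE)
  r_ref <- sample(0:50, 20, replace = TRUE)
  cc <- count_ratio(r_alt, r_ref)
  expect_true(all(cc > 0 & cc <= 1))
  expect_equal(cc == 1, r_ref == 0)
})

test_that("alterations map onto primary reference coordinates", {
  ref <- build_reference_graph(bubble_ref(), k = 3)
  # the bubble substitution sits at position 5 of CGATTTGAA
  recs <- sample_alterations(
    build_sample_graph(bubble_reads(), k = 3, min_support = 1), ref)
  main <- recs[recs$r_alt == 8, ]
  expect_equal(main$pos, 5)
  expect_equal(main$ref, "T")
  expect_equal(main$alt, "G")
  expect_equal(main$vcf_pos, 5)
  expect_equal(main$c, 8 / 11)
  # deletion at the reference start anchors on the following base
  op <- list(type = "D", pos = 1L, ref = "C", alt = "")
  m <- map_to_reference_coordinates(op, "CGATTTGA", ref)
  expect_equal(m$vcf_pos, 1)
  expect_equal(m$vcf_ref, "CG")
  expect_equal(m$vcf_alt, "G")
  # insertion after position 7 of a toy reference
  refseq <- "GATCCTAGGA"
  ref2 <- build_reference_graph(c(r = refseq), k = 3)
  op2 <- list(type = "I", pos = 7L, ref = "", alt = "AC")
  m2 <- map_to_reference_coordinates(op2, refseq, ref2)
  expect_equal(m2$vcf_pos, 7)
  expect_equal(m2$vcf_ref, "A")
  expect_equal(m2$vcf_alt, "AAC")
  # unlocatable path sequence degrades to NA with a warning
  expect_warning(
    bad <- map_to_reference_coordinates(op2, "TTTTTTT", ref2),
    "not found")
  expect_true(is.na(bad$pos))
})

test_that("indel normalization left-aligns within repeats", {
  seq <- "ACGGGGTA"
  # deleting any G of the run normalizes to the leftmost G
  for (p in 3:6) {
    nv <- normalize_variant(p, "G", "", seq)
    expect_equal(nv$pos, 3)
    expect_equal(nv$type, "D")
  }
  # anchored representation normalizes identically to the minimal one
  nv2 <- normalize_variant(4, "GG", "G", seq)
  expect_equal(nv2[c("pos", "ref", "alt", "type")],
               list(pos = 3L, ref = "G", alt = "", type = "D"))
  # insertion of G anywhere inside the run left-rolls to after position 2
  nv3 <- normalize_variant(5, "", "G", seq)
  expect_equal(nv3$pos, 2)
  expect_equal(nv3$type, "I")
})

test_that("every parent path's edits rebuild its spelled sequence", {
  set.seed(23)
  refseq <- random_dna(120)
  ref <- build_reference_graph(c(r = refseq), k = 7)
  # reads carrying one deletion and one substitution
  mut <- paste0(substr(refseq, 1, 39), substr(refseq, 43, 59),
                "T", substr(refseq, 61, 120))
  smp <- build_sample_graph(c(rep(refseq, 6), rep(mut, 4)), k = 7,
                            min_support = 2)
  recs <- sample_alterations(smp, ref)
  expect_gt(nrow(recs), 0)
  for (parent in unique(recs$parent_seq)) {
    sub <- recs[recs$parent_seq == parent, ]
    ops <- atomic_decomposition(parent, sub$ref_seq[1])
    expect_equal(apply_edits(sub$ref_seq[1], ops), parent)
  }
})
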