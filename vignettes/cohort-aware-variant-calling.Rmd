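---
title: "Cohort-aware alignment-free variant calling: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort-aware alignment-free variant calling: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortvar)
```

## The problem

Targeted amplicon sequencing of a patient cohort — for example long-read
circular-consensus sequencing of a cancer gene across tens of samples —
produces deep read sets in which true somatic mutations coexist with
sequencing and PCR artifacts at similar allele fractions. The artifacts are
not uniform noise: deletions inside homopolymer runs, in particular, recur
at the *same* positions across samples and can carry maximal base
qualities, so neither frequency filters nor quality filters separate them
from mutations. Aligners add their own biases, especially around indels.

`cohortvar` attacks both issues at once. It never aligns a read; instead
it represents sequences as de Bruijn graphs and detects alterations as
graph differences. And it never judges an alteration in isolation;
instead it asks whether the alteration is *specific to one sample*
relative to the whole cohort, using a resampling (permutation) null built
from the pooled reads. A recurrent artifact looks the same in any random
subset of the cohort, so it fails the specificity test; a private mutation
concentrates in its sample and passes.

## Graphs

For k-mer length $k$, the **reference graph** is a colored de Bruijn graph
over the gene's reference sequences — splicing variants and known-SNP
haplotypes — with one color (label) per sequence. Vertices are the k-mers;
a directed edge $(v, w)$ exists only when the $(k{+}1)$-mer $v \cdot w_k$
actually occurs in a source sequence (*explicit* edges). Consequently every
walk spells a sequence present in at least one source, and known SNPs are
reference walks — they can never surface as variants.

The **sample graph** is the single-color graph of one sample's reads. Each
vertex carries its *read support* $r(v)$: the number of reads containing
the k-mer, counting each read once. Vertices with
$r(v) < \texttt{min\_support}$ are removed with their incident edges,
discarding most singleton sequencing errors. Reads are used as given
(forward-oriented); `orient_reads()` offers a shared-k-mer voting pass that
reverse-complements a read when it matches the primary reference better
that way.

## Alternative paths

The **difference graph** keeps the union of vertices but only the edges of
the sample that the reference does not explain:
$V^* = V_s \cup V_{\mathrm{ref}}$, $E^* = E_s \setminus E_{\mathrm{ref}}$.
An **alternative path** is a simple path along $E^*$ whose interior avoids
reference vertices; it starts at a vertex with an outgoing alternative
edge and ends at one with an incoming alternative edge. Endpoints are
ideally reference k-mers (the anchors of a "bubble"); endpoints absent
from the reference are **tips**, arising from truncated reads, terminal
alterations, or support filtering. Paths meeting an interior reference
vertex are split there rather than discarded, so composite events
decompose into anchored pieces. Enumeration is depth-first over simple
paths with a cap of $10k$ edges; alterations longer than that are outside
the tool's use case, and the cap bounds the search in cyclic tangles,
which the underlying model (short local variants on an amplicon) does not
otherwise constrain.

A tip is **anchored** by scanning the reference walks between the relevant
reference terminus and the path's other endpoint for the vertex with the
smallest Levenshtein distance to the tip k-mer; ties prefer the candidate
whose walk length (in edges) to the companion endpoint is closest to the
alternative path's length, then the shorter walk, then lexicographic
order.

Among all reference paths connecting the two anchors (several can exist
when SNP haplotypes diverge), the one with the largest read support in the
*sample* is retained. Every read supporting a candidate reference path
necessarily contains both anchor k-mers, so this choice maximizes the
overlap with the reads covering the alternative path's anchor context — a
concrete reading of "maximize the supporting-read intersection" that the
two-haplotype unit test pins down. Ties again prefer the length closest to
the alternative path's, then lexicographic spelled sequence.

Support of a path is the number of reads containing its spelled sequence
as a contiguous substring — by the explicit-edge construction this is the
same as supporting every consecutive k-mer, and it is how the permutation
stage can avoid rebuilding graphs (below).

## Atomic decomposition

An alternative path may carry several alterations. Its spelled sequence is
aligned to the chosen reference path's sequence by a unit-cost edit
distance; among the minimal alignments we prefer the one with the fewest
gap openings (a three-state dynamic program with a secondary objective),
so a multi-nucleotide indel stays one block even when its content echoes
the flanking sequence. Adjacent same-type single-character edits are
merged into block operations; blocks are then left-normalized (VCF
convention) and re-merged until stable, which makes the output independent
of residual alignment tie-breaks. Each resulting operation — substitution
`X`, insertion `I`, deletion `D` — defines one **atomic alternative
path**; atomics inherit the read support of their parent path, since no
physical read carries one of a parent's alterations in isolation.

Each atomic gets a **count ratio**

$$c \;=\; \frac{r(p_a)}{r(p_a) + r(p_r)} \in (0, 1],$$

where both supports are counted in the sample's reads. Positions are
mapped onto the primary reference by locating the reference path's spelled
sequence (first occurrence, with a warning if ambiguous), then reported
both minimally and in anchored VCF form.

## The permutation test

Let $R$ be the pooled cohort reads. For each parent path we draw $N$ read
sets of size $m$ without replacement from $R$ and compute the count ratio
$c_i$ in each (0/0 counts as 0). The empirical p-value is the strict
exceedance fraction $p = |\{c_i > c\}|/N$, and the z-score standardizes
$c$ by the null's mean and standard deviation (denominator $N-1$). A
record is called when $p < \alpha$, $z \ge z_{\min}$ and
$c \ge \texttt{min\_vaf}$.

Design choices worth stating explicitly:

* **Resamples are shared.** The $N$ index sets are drawn once per sample
  and reused for every tested path, which matches the "draw random
  samples, then evaluate each path in them" formulation and keeps the cost
  at $O(\text{paths} \times N)$ simple sums.
* **$N = 1000$ by default** (500 in the bundled simulation studies):
  resolves p-values at the $\alpha = 0.01$ grain with ten expected
  boundary exceedances.
* **$m$ defaults to the analyzed sample's retained read count**, so null
  ratios are computed at matched depth.
* **The tested sample's own reads stay in the pool** by default (the null
  is the *whole* cohort); `exclude_self` removes them, which turns truly
  private paths into degenerate all-zero nulls.
* **Degenerate nulls** (sd 0) give $z = +\infty$ when $c$ exceeds the
  common value, 0 at equality — a path never seen in resamples is maximally
  specific.
* **Strict inequality** in $p$: ties between $c_i$ and $c$ do not count
  against the observation.
* **No multiple-testing correction by default**; the z-score gate is the
  de-facto stringency control. Benjamini–Hochberg is available behind a
  flag.
* **Substring shortcut.** Null supports are counted by fixed-string
  matching of the two spelled sequences in the resampled reads; a unit
  test enforces equality with full graph reconstruction of every
  resample.

## Choosing k and min_support

A read supports a path only through an error-free window of roughly
$2k{+}1$ bases around the alteration, so at per-base error rate $e$ the
usable fraction of carrier reads is about $(1-e)^{2k+1}$. Large $k$ buys
anchor uniqueness and the ability to span long insertions (the default
$k = 30$ detects internal-tandem-duplication-scale events); small $k$
tolerates error. For the bundled 500-nt synthetic amplicon studies at
$\sim$2% per-base error we use $k = 11$: k-mer collisions in a 500-nt
random sequence are negligible, while window survival stays near 70%.
`min_support = 2` removes singleton error k-mers yet keeps a 3% allele
fraction visible at a few hundred reads of depth.

## The synthetic cohort generator

`generate_cohort()` emulates a targeted consensus-long-read cohort rather
than any particular instrument: a random amplicon (default 500 nt) with
planted homopolymer runs (4–6 nt, ~5% of positions); uniform per-base
errors (defaults: mismatch 0.6%, insertion 0.3%, deletion 0.6%); a
homopolymer deletion multiplier of 4 inside runs $\ge 4$; and a handful of
cohort-shared recurrent homopolymer deletion sites firing in 5% of reads
of *every* sample — together an indel-dominated ~2–2.5% per-base error
profile concentrated in homopolymers, which is the regime the specificity
test exists for. Recurrent sites are modeled at 5% per read because
artifacts at that level defeat common allele-fraction filters, which is
what makes them dangerous.

Mutated samples carry 1–3 private alterations (type uniform over
mismatch/insertion/deletion, indel lengths 1–5, insertion content random)
in a hard-assigned fraction $\varphi \in [0.03, 0.80]$ of reads, so
carrier counts are exact and tests can assert them. Alterations are
re-drawn if they fall within $2k$ of each other (paths must stay
separable) or of a recurrent site — a private mutation at an artifact
position would be unidentifiable *by design*, not by failure. Spiked bases
get the maximal quality character, mirroring the observation that
artifact bases can be maximally confident; qualities are otherwise
constant-high with low-quality error positions, kept only for FASTQ
validity since the graphs ignore them.

What the generator does **not** model: chimeras and PCR duplicates,
read-length variation and truncation (reads are full-length amplicons by
default), quality-score structure learned from real data, and reverse
strands. Passing the bundled tests therefore demonstrates the method's
statistical behaviour under its own assumptions — recurrent vs private
alterations at realistic error rates — not robustness to every artifact
of real instruments.

## Simulation studies bundled with the tests

The test suite runs two cohort-scale studies, sized to finish in minutes
on one core:

* **Null uniformity / specificity.** Five samples, 400 reads each, *only*
  shared recurrent deletion errors (8 sites at 5%). Every tested path then
  follows the null: across samples the empirical p-values are checked for
  uniformity (Kolmogorov–Smirnov at $N = 500$ resamples), and no record
  may survive $\alpha = 0.01 \wedge z \ge 10$.
* **Recovery.** Six samples, 500 reads each, three negative controls and
  three samples with one private alteration at
  $\varphi \in \{0.05, 0.10, 0.40\}$, full error model. Alterations at
  $\varphi \ge 0.10$ must be recovered (recall $\ge 0.9$) and the planted
  recurrent artifact positions must never be called in any sample. The
  5% sample sits at the detection edge at this depth and is reported but
  not required.

## Limitations

* Cohort size drives the null's resolution: with very few samples a
  private mutation still dominates the pooled reads and the z-score gate
  loses power (the worked 55-read toy cohort cannot reach $z \ge 10$ at
  all). The test is meaningful from a handful of samples upward.
* Two samples sharing a true recurrent mutation will suppress each other —
  cohort specificity is the explicit working assumption, appropriate for
  loss-of-function mutation surveys, not for hotspot oncogenes.
* Alterations within $2k$ of each other travel on one parent path and are
  tested jointly, not phased beyond that.
* The DFS enumeration caps path length at $10k$ edges; larger structural
  events are out of scope.
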