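---
title: "Model and methods of the bayestx assembler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods of the bayestx assembler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Reference-based transcriptome assembly asks: given spliced alignments of
paired-end RNA-seq reads to a genome, which transcript isoforms are present
in the sample, and at what abundance? The hard part is not finding exons and
junctions — the aligner gives those — but deciding which *combinations* of
junctions correspond to real, expressed molecules. `bayestx` treats this as
Bayesian model selection: the set of expressed isoforms is a latent binary
vector with a sparsity-inducing prior, and the evidence for each isoform is
the posterior probability of its inclusion.

## Pipeline overview

1. **Fragment loading.** A *fragment* is one read pair (both mates from a
   single cDNA molecule). Only proper pairs are used; multimapping pairs and
   putative PCR duplicates (identical chromosome, block structure of both
   mates and strand evidence — the strictest safe operational definition,
   since coordinate identity is the only observable) are removed. The strand
   of transcription comes from mate orientation for stranded protocols, and
   from the `XS:A` tag of spliced aligners for unstranded data.
2. **Splice graphs.** Fragments are clustered into loci: coverage runs
   separated by at least one uncovered base are distinct unless a spliced
   fragment bridges them. Per locus (per strand), exon segments are coverage
   runs split at every junction donor/acceptor, so vertices are minimal
   disjoint segments; edges are observed junctions, plus adjacency edges
   between abutting segments supported by a read running across the
   boundary. Loci with fewer than two fragments, and unstranded loci whose
   strand cannot be inferred, are dropped.
3. **Candidates.** All source-to-sink paths are enumerated depth first. If
   more than 100 paths exist, an edge-coverage threshold (starting at 1) is
   raised and all edges below it removed, iterating until the search
   completes within the cap or no edges remain (isolated exons then each
   yield a single-exon candidate). A *pre-mRNA candidate* — one exon
   spanning the whole locus — is added to absorb unspliced precursor signal.
   Multi-exon candidates with any junction lacking fragment support are
   removed, and candidates of overlapping same-strand graphs are pooled.
4. **Likelihoods.** Each fragment gets a likelihood under each candidate:
   zero if structurally incompatible, otherwise the truncated-Gaussian
   probability of the implied transcript-coordinate length divided by the
   candidate's effective length.
5. **Inference.** A Gibbs sampler explores which candidates are expressed
   (`z`), their relative abundances (`e`), and the fragment assignments
   (`t`).
6. **Output.** Candidates with confidence above 0.5 and expected fragment
   count of at least 12 are written as GTF.

## The generative model

For a locus with $m$ candidates and $n$ fragments:

* $z_j \sim \mathrm{Bernoulli}(\pi)$ independently, *truncated* to exclude
  the all-zero vector; the normalizer is
  $K_{z_0} = 1/(1-(1-\pi)^m)$. This is a spike-and-slab prior: unexpressed
  candidates have exactly zero abundance.
* Given $b_z = \sum_j z_j$, the expressed abundances
  $e^+ \sim \mathrm{Dirichlet}(\gamma, \ldots, \gamma)$, with $\gamma = 1$
  (uniform) by default.
* Each fragment picks its source transcript $t_i \sim
  \mathrm{Categorical}(e)$ and is then emitted with probability
  $P(f_i \mid t_i)$ from the fragment-length model.

The sampler iterates three conditionals, in this order:

1. $b_z \mid c$: on support $|J^+| \le b \le m$ (where $J^+$ are candidates
   with assigned fragments),
   $P(b) \propto \binom{|J^0|}{\,b-|J^+|\,}
   \frac{\Gamma(b\gamma)}{\Gamma(n+b\gamma)} \pi^b (1-\pi)^{m-b}$,
   computed in log space with log-sum-exp (the Gamma ratios overflow
   catastrophically otherwise). Then $z$ sets $J^+$ to one and fills the
   remaining $b_z - |J^+|$ slots uniformly without replacement from $J^0$.
2. $e \mid z, c$: $e^+ \sim \mathrm{Dirichlet}(c^+ + \gamma)$, scattered so
   $e_j = 0$ exactly where $z_j = 0$.
3. $t \mid e$: each fragment independently,
   $P(t_i = j) \propto P(f_i \mid j)\, e_j$.

Burn-in is $60m + 1000$ iterations; $10\times$ that many samples are then
retained. *Confidence* is the fraction of retained iterations with
$z_j = 1$; the abundance estimate is the mean of $e_j$ over expressed
iterations, normalized by effective length and library size on the FPKM
convention ($e_j\, n_{\text{locus}} / \ell^{\text{eff}}_j \times 10^9 /
N_{\text{library}}$); the expected count is the mean of $c_j$ over all
retained iterations (the posterior expectation of the assigned count —
averaging over expressed iterations only would bias it upward for
rarely-expressed candidates).

The sparsity parameter is calibrated from the data as $\pi = m_{\min}/m$,
where $m_{\min}$ is a greedy minimum set cover: repeatedly pick the
candidate with positive likelihood for the most still-unexplained fragments
(ties to the lowest index) until all fragments are covered. It is estimated
per locus, from that locus's likelihood matrix.

## Fragment-length model and likelihood

Lengths are modeled as Gaussian with parameters estimated robustly — median
for $\mu$, median absolute deviation for $\sigma$ — from fragments on
single-path loci whose transcript is at least 2500 nt (where the mapping
from genomic to transcript coordinates is unambiguous). The MAD is scaled
by 1.4826 so it is consistent for a Gaussian $\sigma$; an unscaled MAD
would shrink $\sigma$ by a third and over-sharpen every likelihood. If no
locus qualifies, configurable defaults (250, 25 nt — typical of Illumina
paired-end libraries) are used with a warning.

The per-candidate length distribution is the Gaussian discretized on
$\{1, \ldots, L\}$ and renormalized (finite transcripts require a
truncation convention; this one keeps the effective-length sum exact). A
fragment is compatible with a candidate when each mate's blocks sit inside
single candidate exons and successive blocks are contiguous in transcript
coordinates — equivalently, each mate's intron chain is a contiguous
sub-chain of the candidate's. Candidate introns that fall entirely within
the unsequenced inter-mate insert are allowed: they are spliced out of the
molecule and leave no trace in either mate. Base qualities are carried but
ignored by the default likelihood: the error model of the cited likelihood
framework is not specified precisely, and binary compatibility is the
reproducible core. Fragments incompatible with every candidate of their
locus are dropped from that locus's inference (the model has no noise
component, so they carry no information), with a logged count.

## Numerical and design choices

* **Path endpoints under pruning.** When coverage pruning removes an edge,
  an interior exon can lose all incoming or outgoing edges. Transcript
  start/end points are taken from the *unpruned* topology: a dead end
  created by pruning does not spawn a truncated candidate. This keeps the
  path count monotone non-increasing in the threshold, which is also what
  makes the pruning loop well behaved.
* **Reverse-strand graphs** are stored in genomic coordinates and handled
  by one code path; enumeration order is genomic, with the candidate list
  reversed for reverse-strand loci so ordering is deterministic per strand.
* **Expected-count threshold at exactly 12.** "At least 12" retained is
  used (`expected_count >= 12`); the confidence threshold is strict
  (`> 0.5`).
* **Seeding.** Each locus draws from a stream derived deterministically
  from the root seed and the locus index, so results do not depend on the
  order in which loci are processed. The compiled sampler uses R's RNG, so
  a single `set.seed()` reproduces runs bit for bit.
* **Two engines.** The Gibbs loop exists in compiled form (default) and as
  a pure-R reference built from the exported single-step samplers; both are
  exercised against an exact-enumeration oracle in the test suite. The
  compiled engine exists because the schedule ($60m+1000$ burn-in,
  $10\times$ samples) over thousands of fragments is not practical in
  interpreted R.
* **Degenerate inputs.** Empty alignment files produce a valid empty GTF;
  edgeless graphs yield single-exon candidates; a locus whose candidates
  are all filtered is skipped with a count.

## What the simulator does and does not emulate

`simulate_dataset()` draws from exactly the generative model above:
truncated-Bernoulli expression, symmetric-Dirichlet abundances, categorical
assignment, Gaussian lengths truncated to the transcript (and bounded below
by the read length, since two 100 nt mates cannot come from a shorter
fragment). Gene structures are two-event genes — a three-way mutually
exclusive exon choice and one skippable exon joined by a short linker exon
(human-typical internal exon lengths, 80–200 nt) — giving six isoform
chains and small, identifiable candidate sets; an optional single-isoform
"calibration locus" longer than 2500 nt exercises the fragment-length
estimator. Reads are emitted as proper FR pairs with spliced CIGARs,
`NH:i:1`, and `XS:A` tags on junction reads; by default fragments that
would be byte-identical duplicates are resampled so the loader's duplicate
filter is a no-op on simulated data.

Not emulated: sequencing errors and base-quality variation, positional or
sequence bias, multimapping, intergenic noise, incomplete junction
coverage, and genes with many weakly distinguishable isoforms. A green
recovery test therefore establishes correctness of the inference machinery
on identifiable instances — not performance on real tissue libraries,
where candidate sets are larger and posteriors legitimately more diffuse.

## Known limitations

* Graph construction is a documented simplified equivalent of the external
  builder the original pipeline delegates to; only the stated behaviours
  (1-base gene gap, 2-fragment minimum, per-strand graphs, strand-
  unresolvable discard) are reproduced, and exon boundary detail beyond
  junction splitting is this package's own fixed choice.
* Mate orientation is not checked beyond proper-pair flags; an FF pair that
  an aligner marked proper would be accepted.
* The likelihood ignores base qualities and has no noise component.
* Overlapping same-strand graphs are merged, but per-strand clustering
  makes such overlaps rare by construction; antisense (opposite-strand)
  merging is deliberately not performed.
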