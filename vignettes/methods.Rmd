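---
title: "Methods: comparative analysis of phage genome collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of phage genome collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phagecompare implements a complete comparative and evolutionary analysis of
a collection of bacteriophage genomes: minimal ORF calling, protein-family
("pham") assignment, whole-genome dot plots, nucleotide-identity genome
clustering, CRISPR-spacer (protospacer) searching for host-range inference,
and a Nei–Gojobori $\pi_N/\pi_S$ analysis of selection on gene families.
This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic-data validation does and does not
establish.

## ORF calling

The built-in gene caller deliberately implements only two rules, mirroring
the behaviour of self-training phage annotation tools: candidate ORFs
shorter than **300 bp** (start through stop codon) are discarded, and each
stop-to-stop open stretch yields at most one ORF anchored at its
**5'-most ATG** (alternative start codons can be supplied). All six frames
are scanned; codons containing `N` never act as start or stop; genomes are
treated as linear, so ORFs spanning a circular origin are not called — a
documented limitation, acceptable for comparative statistics. These rules
slightly undercount genes relative to curated annotation, uniformly across
genomes, which is the property that matters for comparisons such as ORFs
per kb or the ORF-count/genome-size regression.

## Pham assignment

Proteins are compared pairwise and linked when **either** criterion holds:

* global percent identity $\ge$ 35 (affine-gap global alignment, BLOSUM62,
  gap open 10 / extend 1), or
* best local (Smith–Waterman) alignment e-value $\le 10^{-50}$
  (BLOSUM62, gap open 11 / extend 1).

The OR semantics follows the established pham-building convention the
thresholds come from. Both thresholds are inclusive at the boundary.
E-values use ungapped Karlin–Altschul statistics
($E = KmN e^{-\lambda S}$, $\lambda = 0.3176$, $K = 0.134$) with the search
space $N$ set to the total residue count of the run; they are documented
approximations — family membership is threshold-based, and nothing
downstream depends on exact tail calibration. Phams are the connected
components of the link graph (single linkage); isolated proteins become
singleton phams ("ORFans"). Pham ids are assigned by each component's
smallest member id so runs diff cleanly.

The identity denominator is a genuine free choice; we use identical columns
divided by alignment columns after stripping terminal-gap columns, with
internal gap columns counted as mismatches. This is the conservative
reading and is applied consistently to nucleotide identity as well.

For large runs `protein_pairwise(prefilter_k = 5)` restricts evaluation to
pairs sharing an exact amino-acid 5-mer. Both link criteria demand
substantial exact conservation (35% identity over a full-length global
alignment, or a local score near 400), so pairs without any shared 5-mer
cannot pass them in practice; the prefilter is off by default and the test
suite checks it leaves the link set unchanged on representative data.

The evolutionary analysis uses **strict families**: the same construction
at 50% identity, keeping families with **15 or more members** so that
within-family diversity is estimated from a well-populated alignment.

## Genome clustering

Two genomes are linked when they share **more than 45%** nucleotide
identity **and more than 20** distinct protein families (both strict
inequalities: 45.0 and 20 do not qualify). Clusters are connected
components of at least **3** members under single linkage; everything else
is a singleton. Single linkage matches the dot-plot-driven practice this
rule descends from; a complete-linkage mode (`linkage = "complete"`) is
available where every within-cluster pair must qualify. Clusters are
lettered by decreasing size. Sub-cluster assignment is not computed — no
defensible criterion is available.

Requiring both identity and shared gene content makes the rule robust: the
global-alignment identity of entirely unrelated DNA is pushed toward ~40%
by the aligner's freedom to place gaps, but unrelated genomes share
essentially no families, so the conjunction keeps them apart.

### Nucleotide identity

Pairs up to 10 kb are aligned by full affine-gap dynamic programming
(match +1, mismatch −1, gap open −5, extend −1; end gaps penalized; a gap
of length $k$ costs $5 + k$), implemented in C++ with identity counted on
an optimal path. Longer pairs use exact k-mer **anchor chaining**: maximal
runs of shared unique 16-mers (11-mers as fallback) are chained by a
collinear weighted longest-increasing-subsequence, inter-anchor blocks are
aligned by DP, and identity is pooled across columns. Chains that are
incoherent in diagonal or cover less than max(200 bp, 2%) of the shorter
sequence are treated as spurious and discarded. Anchor-free blocks beyond
6 kb are length-weighted estimates from three evenly spaced 1-kb
sub-blocks — an explicit approximation that only affects pairs with little
or no homology, far below the 45% clustering threshold. The test suite
requires anchored and full-DP identity to agree within 2 percentage points
on 10-kb pairs across 45–90% true identity.

## Dot plots

`window_matches()` marks every position pair whose exact
**10-nucleotide** windows agree (window length configurable; `N` never
matches), using a hash index of one sequence's windows, with an optional
reverse-complement channel. `plot_dotplot()` concatenates the collection,
plots it against itself and draws genome boundaries with cluster letters
along the top axis. Exact-word matching reproduces the word-mode dot plots
used for visual cluster confirmation; scored or fuzzy windows are out of
scope.

## CRISPR spacer search

Spacers (25–75 bp) are too short for default nucleotide-search heuristics,
so the search uses the relaxed parameter set quoted for this task: e-value
ceiling **0.3**, word size **7**, gap open **10** / extend **2**, mismatch
penalty **1**, no dust filtering, with match reward +1 (the classic default
paired with these penalties). A strand is scored only if it shares an
exact 7-mer with the spacer (the seed requirement of a word-based search);
scoring is Smith–Waterman; e-values use ungapped $\lambda = 1.33$,
$K = 0.621$ for ±1 scoring with search space spacer length × total genome
length. One best hit per (spacer, genome, strand) is reported by default;
`count_all = TRUE` iteratively masks and re-searches. Hits are classified
by comparing the spacer's species of origin to the phage's recorded host
at the "Genus species" level, strain suffixes ignored.

## Selection analysis ($\pi_N/\pi_S$)

For each strict family, coding sequences are translated, the proteins
aligned (MAFFT), and the alignment back-translated so gaps occupy whole
codons; codon columns containing any gap are dropped (complete deletion,
the common default; pairwise deletion is exposed as an option). For each
sequence pair the Nei–Gojobori (1986) method counts:

* sites: each codon position contributes $f/3$ synonymous sites, $f$ the
  number of its three single-nucleotide alternatives preserving the amino
  acid (genetic code 11); changes producing stop codons count as
  non-synonymous, so $s + n = 3$ per codon exactly;
* differences: codons differing at $k > 1$ positions average synonymous and
  non-synonymous step counts over all $k!$ substitution orderings,
  excluding pathways through stop codons (if every pathway is blocked, all
  orderings are used with stop steps counted non-synonymous).

$\pi_N$ and $\pi_S$ are the averages of the pairwise proportions $p_N =
N_d/N$ and $p_S = S_d/S$ over all unordered pairs, duplicates included.
Proportions are uncorrected by default because the object of interest is
the ratio; a Jukes–Cantor variant is available since reference
implementations offer both. Families with $\pi_S = 0$ report an undefined
ratio and are excluded from ratio histograms but retained in the paired
test, which uses $\pi_N$ and $\pi_S$ directly. Across families,
`selection_test()` runs a paired Wilcoxon signed-rank test (zero
differences dropped; exact distribution up to 25 untied pairs, otherwise
normal approximation with continuity correction), one-sided for
$\pi_N < \pi_S$ — the signature of purifying selection — and also reports
the count of ratios below 1 and the fraction in $[0, 0.5]$. The spec-level
minimum is five families with defined values, the smallest design for
which the exact one-sided test can reach $p = 1/32$.

## The synthetic-data generator

`simulate_genome_set()` emulates the structure of a real phage collection
at desk scale. Per cluster an ancestor genome of ORF-shaped gene modules
(ATG + random sense codons + stop, 300–750 bp) separated by intergenic
spacers is built; each member then receives point substitutions and module
gain/loss. Defaults: 5 clusters × 3 members + 5 singletons, 36–54 modules
per genome (≈20–30 kb; counts vary so the collection shows the genome-size
spread — and hence the ORF-count/size correlation — real surveys report),
pairwise member identity target 0.75, module swap rate 0.06, 40% of
clusters split across two host species. These defaults mirror
the proportions of the motivating collection — about three quarters of
genomes clustered, multi-host clusters in a minority, within-cluster
identity comfortably above the 45% rule — at roughly one-sixth scale so a
twenty-replicate recovery experiment runs in minutes.

Choices worth knowing about:

* Intergenic spacers embed a fixed cassette with stop codons in all six
  frames (and terminal in-frame stops before each gene), so the minimal ORF
  caller recovers exactly the planted genes; gene start/stop codons and the
  cassettes are protected from mutation, and substitutions that would
  create an in-frame stop inside a gene are redrawn.
* The per-member substitution rate solves $(1-r)^2 + r^2/3 = t$ so that
  *pairwise member* identity, not member-to-ancestor identity, lands on the
  target $t$.
* Spacer loci are drawn so the excised sequence occurs exactly once in its
  source genome; a repeated locus would make the planted origin ambiguous
  under best-hit reporting.
* `simulate_codon_family()` evolves a star phylogeny from a stop-free
  ancestor: proposals are uniform single-nucleotide changes at rate
  `divergence` per site per branch (default 0.04, a realistic within-family
  diversity giving $\pi_S \approx 0.08$ while keeping multiple-hit bias
  small); synonymous proposals are always accepted, non-synonymous accepted
  with probability $\omega$, stop-creating proposals rejected. A uniform
  (Jukes–Cantor-like) proposal kernel without transition bias keeps the
  relationship between $\omega$ and $\pi_N/\pi_S$ clean.

What the generator does **not** emulate: real promoter/terminator grammar,
codon-usage and GC heterogeneity, recombination and mosaicism within
genes, tree-shaped (non-star) family phylogenies, transition/transversion
bias, and GenBank-grade annotation noise. Passing the recovery tests
therefore demonstrates that the pipeline's logic is correct under its own
assumptions, not that the thresholds are optimal for any particular real
collection.

### A known, deliberate bias at neutrality

Because the family simulator rejects stop-creating proposals while the
NG86 site definition counts changes-to-stop as non-synonymous sites, the
realized non-synonymous substitution rate at $\omega = 1$ is a few percent
below the rate the site counts imply: from the code-11 codon table, the
non-stop fraction of non-synonymous changes is 0.72/0.76 ≈ 0.945, so
neutral families measure $\pi_N/\pi_S \approx 0.95$ rather than 1. The
mean-ratio recovery band (0.85–1.15) absorbs this, but a paired test
across 50 families is sensitive enough to detect the deficit as a
"significant" $\pi_N < \pi_S$ signal. This is a property of the
simulator/estimator pair, not of the estimator on real data; the
corresponding non-significance expectation in the acceptance suite fails
for this reason and is retained as an honest record rather than papered
over by weakening the simulator or the site definition.

## Problem sizes and determinism

The test suite validates every fast path against independent brute-force
implementations (quadratic dot-plot scan, R dynamic-programming global and
local aligners, pathway-enumeration NG86, union-find components) on inputs
where the oracles are exact, and runs recovery experiments at the scale
described above: 20 seeded replicates for cluster recovery, 20
meta-replicates × 50 families for the selection regimes, 100 planted
spacers for search sensitivity. All randomness flows through explicit
integer seeds; generators save and restore the session RNG state, and
repeated runs are byte-identical, which the suite also checks.
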