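---
title: "Methods: topology, divergence and contribution in the odor network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topology, divergence and contribution in the odor network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odornet)
```

# The analysis

`odornet` asks how the wiring of a small signaling network relates to the
molecular evolution of its genes and to their behavioral contribution. The
working system is the composite volatile-odor signaling network of
*Caenorhabditis elegans* (16 genes spanning the AWA, AWB and AWC neuron
pairs), with interspecies divergence measured against *Pristionchus
pacificus* orthologs. The pipeline has five stages: per-gene codon-level
divergence (dN/dS), per-node topology metrics on the undirected interaction
graph, chemotaxis-derived contribution indices, a rank-correlation battery
relating the three layers, and a randomization null asking whether the
network's mean dN/dS is lower than that of random gene sets drawn from a
genome-wide ortholog pool.

Because the original sequence sets are not redistributable, every stage is
validated against simulated inputs with known truth; the built-in fixture
carries the network itself and its published behavioral data.

# Divergence estimation

Two estimators are implemented and kept deliberately independent so each can
check the other.

**NG86 (counting).** Each codon position contributes one site, split between
synonymous and nonsynonymous in proportion to the fraction of its non-stop
single-nucleotide changes that are synonymous. This normalization (over
non-stop alternatives) keeps `S + N = 3n` exactly for `n` codons.
Differences between unequal codons are averaged over all minimal
substitution paths with equal weights; paths through stop codons are
excluded (and, in the rare case every path is blocked, the constraint is
relaxed rather than dropping the codon). Proportions are converted to
distances with the Jukes–Cantor correction; a proportion at or beyond 3/4
is flagged `saturated` and the distance reported as `NA`.

One consequence worth knowing: for purely synonymous two- or three-position
codon changes whose intermediate steps are nonsynonymous (the serine
TCN/AGY classes), equal-weight path averaging assigns a small fractional
nonsynonymous count. Simulations with a true omega of 0 therefore give NG86
dN values near, but not exactly, zero; the protein sequences themselves are
identical.

**YN00 (approximate model-based).** Codon frequencies come from the F3x4
model estimated from the pair (equal frequencies are available via
`equal_freqs = TRUE`). The transition/transversion ratio kappa is estimated
from positions that are fourfold degenerate in both codons and positions
nondegenerate in both: K80 transition and transversion distances are
computed within each class, pooled with weights proportional to the class
site counts, and kappa taken as twice the ratio of pooled transition to
transversion distance (one transition versus two transversion alternatives
per site). When those logs are undefined — very short or saturated inputs —
kappa falls back to 1 with a flag rather than failing. Site counts then
weight each possible change by `pi_target * kappa^[transition]`; difference
counting weights each minimal path by the product of its step rates,
including `omega` for nonsynonymous steps, and the whole estimate is
iterated from `omega = 1` to convergence (tolerance 1e-6, cap 100
iterations, `nonconverged` flagged). Synonymous and nonsynonymous distances
each get a K80-style two-parameter correction, so dS can legitimately take
very large values on saturated comparisons before the correction's domain
runs out.

**Policies.** `dS = 0` with positive dN makes omega undefined: it is
reported `NA`, flagged, and excluded from network means with a message —
averaging infinities would otherwise dominate a 16-gene mean. Both
estimators are symmetric in their two sequences and return exactly 0/0 on
identical inputs.

**Validation scale.** The estimator-recovery checks simulate 100 replicate
pairs of 500 codons at 0.3 expected substitutions per codon for true omega
values 0.1, 0.2 and 1.0, and require the mean estimate within 15% of truth.
At those conditions NG86 shows its known mild downward bias under
transition bias (about 10–13% here, from unweighted site counting) and
YN00 is nearly unbiased (2–5%). Cross-method Spearman concordance exceeds
0.9 on shared simulations.

# The codon-pair simulator

The generator evolves a descendant from an equilibrium-drawn ancestor under
a Goldman–Yang-style codon model: universal code, 61 sense codons (stop
codons excluded from the state space, so simulated sequences never contain
them), rates proportional to `kappa` for transitions and `omega` for
nonsynonymous changes, equal codon frequencies by default and configurable
otherwise. The rate matrix is scaled so branch length is in expected
substitutions per codon, and transition probabilities come from the exact
matrix exponential (symmetric eigendecomposition of the reversible
generator) rather than stepwise simulation, so a branch length of zero
reproduces the ancestor exactly and omega = 0 can never create an amino
acid difference. Defaults (`kappa = 2`, `omega = 0.2`,
`branch_length = 0.5`) reflect a typical nematode interspecies comparison:
moderate transition bias and clear purifying selection. Every generator
takes an explicit seed and restores the caller's RNG state.

What the simulator does *not* emulate: indels and alignment error, codon
usage bias beyond the frequency vector, rate variation among sites and
lineages, and selection heterogeneity along the gene. Passing recovery
tests therefore demonstrates estimator correctness under the model's
assumptions, not robustness to real-data artifacts.

# Nucleotide diversity

`pairwise_pi()` is the average over unordered sequence pairs of the
proportion of differing sites; with two sequences (the interspecies case
the pipeline defaults to) this is simply the mismatch proportion. Sites
carrying ambiguity codes are excluded from both numerator and denominator
of the affected pair. The sliding scan uses 100-bp windows advanced in
20-bp steps, emitting only full windows (a trailing partial window is
dropped so window statistics stay comparable); no multiple-hit correction
is applied, matching the descriptive use of these profiles.

# Network metrics

The graph container is a simple undirected network: no self-loops, no
multi-edges, exact-string node identity. All shortest-path quantities come
from one breadth-first pass per source that counts shortest paths
alongside distances. Conventions, since the upstream tooling (Cytoscape
NetworkAnalyzer) is named but not specified formula-by-formula:

* **Betweenness** sums over unordered pairs `{s, t}` distinct from the
  node; disconnected pairs contribute zero. Both the raw value and the
  variant normalized by `(N-1)(N-2)/2` are reported; correlations use raw
  values by default (`betweenness_normalized = TRUE` switches).
* **Stress** is the count, not fraction, of shortest paths through the node.
* **Closeness** is the reciprocal of the mean distance to *reachable*
  nodes; **radiality** is `(diameter + 1 - mean distance) / diameter` with
  the diameter taken within the node's component; the **topological
  coefficient** averages shared-neighbor counts (plus the adjacency
  indicator) over nodes sharing at least one neighbor, divided by the
  degree, and is 0 for degree < 2.
* Disconnected graphs (which the randomization stage can produce) are
  handled within components: the characteristic path length averages over
  connected pairs only and the summary carries a `connected = FALSE` flag.
  Isolated nodes get `NA` closeness/radiality rather than a conventional 0.

Correctness is established two ways: exhaustive brute-force path
enumeration over every connected graph on up to six nodes (143 isomorphism
classes, generated by edge-set enumeration and canonically deduplicated —
legitimate because label-invariance of every metric is itself a tested
property), and cross-checks against igraph where it implements the same
quantity.

# The fixture and its curation

The published interaction map exists only as a schematic figure, so the
shipped edge list is an explicit curated reconstruction (see
`inst/extdata/README.md`): edges were chosen from the pathway logic under
the constraint of reproducing the published summary statistics, which it
does exactly — 16 nodes, 16 edges, diameter 5, characteristic path length
2.825, mean neighbors 2, with odr-3 and egl-4 the two most connected nodes.
Per-node values derived from it are faithful to those constraints, not to
the unpublished original edge multiset; analyses of the real network should
treat them accordingly.

The chemotaxis table reproduces every published value verbatim: wildtype
odortaxis references (AWA 0.9, AWB −0.95, AWC 0.85), wildtype long-term
adaptation responses (AWA 0.5, AWC 0.65), and the mutant `ci_diff` values
for the 11 genes with published assays. Mutant indices are back-computed
as `ci_wt - ci_diff` where that lands in [−1, 1] and left `NA` otherwise
(the daf-11 AWB deficit of 0.6 against a −0.95 reference cannot be
inverted). Genes without published assays have no rows — absent records,
not zeros — and the phenotype index treats absent neurons as contributing
zero while reporting how many neurons were measured.

# Contribution indices

The phenotype index is implemented exactly as the printed sum of squared
neuron-normalized deficits, `PI = sum over neurons of (ci_diff/ci_wt)^2`;
a Euclidean-norm (square-root) variant exists behind `root = TRUE` but is
not the default, because the single published worked example cannot
discriminate the two forms. Squaring makes PI invariant to the sign
convention of the repulsive AWB neuron. The LTA index is the fraction of
the wildtype adaptation response lost in the mutant.

The printed group-level formula is typographically garbled; it is read as
the weight-normalized mean `WPI = sum(PI*w)/sum(w)`, the only reading
consistent with "weighted" and with `w` defined as an odor count. Per-gene
odor counts were never published, so the fixture's `n_odors` column
defaults to the number of neuron classes with a recorded assay and can be
replaced by real counts. Grouping is by pathway position (the 6/6/4
classes) or by tertiles of betweenness or degree, ties broken
deterministically by gene id.

# Correlations and the randomization null

Spearman, Kendall (tau-b) and Pearson statistics delegate to R's `cor.test`
machinery — these are standard computations, and the test suite checks them
against independent rank- and pair-counting oracles. Large-sample
approximations are used (t for Spearman, normal for Kendall), switching to
exact small-sample distributions for tie-free samples of up to 8
observations; the network's n = 16 sits in the approximation regime.

The randomization null resamples gene sets of 16 from an ortholog pool,
with replacement read literally as with-replacement draws *within* each set
(a without-replacement-within-set option is exposed). The composition
constraint fixes exactly six draws from the Galpha-tagged subset,
mirroring the network's six Galpha-subunit genes. The hypothesis is
directional — the network is under *stronger* purifying selection, i.e. a
*lower* mean omega than random sets — so the empirical p counts null means
at or below the observed mean, with the add-one rule so p is never zero.
The pool generator draws omega from a gamma law (default mean 0.14, the
genome-wide ortholog average; shape 0.6, giving the right-skewed,
heavy-tailed profile typical of ortholog-wide dN/dS distributions — a
choice made once on that reasoning). Consistency checks run at 5,000
replicates against 3-Monte-Carlo-standard-error bands and verify the
constrained null shifts from the pool mean toward the tagged-subset mean,
the direction the published 0.106 < 0.14 comparison shows; production runs
use the conventional 50,000.

# Problem sizes in the test suite

Estimator recovery: 3 omega values x 100 replicates x 500 codons.
Concordance and kappa checks: 60 and 30 replicates at 200 codons. Topology:
all 143 connected-graph classes on <= 6 nodes plus randomized property
checks. Diversity: 50 random alignments up to 500 bp. Randomization: pools
up to 5,666 entries, 5,000 replicates. These sizes were chosen so the whole
suite exercises every claim at meaningful statistical resolution in well
under a minute of estimator time.

# Known limitations

* The curated edge list is constraint-faithful, not figure-faithful; node
  ranks beyond the two hubs may differ from the original network.
* YN00 here is the approximate pairwise method; no maximum-likelihood
  (codeml-style) estimation, no >2-sequence or sliding-window dN/dS.
* Diversity is uncorrected pi only — no theta-W, no Tajima's D.
* The kappa-pooling variant differs in detail from the original yn00
  weighting; its accuracy is established empirically by the recovery and
  monotonicity tests rather than by formula identity.
* Correlation p-values are unadjusted for multiple testing, matching the
  original analysis battery.
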