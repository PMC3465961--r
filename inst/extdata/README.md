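# Built-in odor-network fixtures

`odor_network.tsv` — curated, synthetic reconstruction of the 16-gene
composite volatile-odor interaction network of *C. elegans*. The published
network figure is a schematic without a machine-readable edge list, so the
edge set here was assembled from the pathway logic (Galpha regulators and
RGS/arrestin upstream; cyclases, CNG channels, PKG and calcineurin in the
middle; Go/Gq/DGK and glutamatergic actuators downstream) under the
constraint that it reproduce the published summary statistics. It does so
exactly: 16 nodes, 16 edges (mean number of neighbors 2), network diameter
5, characteristic path length 2.825, with odr-3 and egl-4 as the two most
highly connected nodes. It is a reconstruction, not the authors' edge list:
per-node metric values are faithful to these constraints, not to the
original figure.

`odor_chemotaxis.tsv` — every published chemotaxis value for the network's
mutants: wildtype odortaxis references per neuron class (AWA 0.9, AWB -0.95,
AWC 0.85), wildtype long-term-adaptation (LTA) responses, and mutant
chemotaxis-index differences (`ci_diff`). `ci_mut` is back-computed as
`ci_wt - ci_diff` where that lands inside [-1, 1] and is `NA` otherwise
(daf-11 AWB). Genes without published assays (gpa-3, gpa-5, gpa-13, arr-1,
tax-6) have no rows: absent assays are absent records, not zeros. `n_odors`
is a configurable weight column defaulting to the number of neuron classes
with a recorded assay for the gene; per-mutant odor counts were not
published, so supply your own to override.

`odor_categories.tsv` — the three pathway-position classes: regulators
class 1 (6 genes), regulators class 2 (6 genes), actuators (4 genes).
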