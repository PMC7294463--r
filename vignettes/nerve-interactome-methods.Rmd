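---
title: "Methods: ligand–receptor interactome analysis of peripheral nerve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-receptor interactome analysis of peripheral nerve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nerveLR)
```

# The analysis in outline

The injured peripheral nerve supports axon regeneration through paracrine
signals produced by its resident cell types. `nerveLR` models that signaling
environment as a chain of binary membership decisions:

1. which ligand mRNAs the nerve expresses (bulk anchor thresholding, then a
   single-cell 2% detection rule);
2. which cell type contributes each ligand (highest detection fraction);
3. which receptors each target neuron population carries
   (proteomics-anchored thresholding of its transcriptome);
4. which ligand→receptor routes are therefore open (database lookup), and
5. how transcriptional states relate across conditions (mock-bulk
   differential correlation of single cells).

Every decision is binary by design — the underlying measurements (droplet
UMI counts near the detection limit, microarray intensities across
platforms) do not support a quantitative interaction strength, and the
published analysis this package re-implements deliberately stayed binary.
That assumption is the main thing to keep in mind when interpreting any
output: an edge means "plausible route", not "strong interaction".

# Detection fractions and the 2% rule

A cell *detectably expresses* a gene iff its raw UMI count is ≥ 1. No
normalized value enters this decision: droplet UMI data near the detection
limit make "at least one deduplicated molecule observed" the only robust
per-cell statement, and using raw counts keeps the statistic invariant to
library-size normalization choices. `detection_fractions()` then reports

$$F(g,t) = 100 \cdot \frac{\#\{\text{cells of type } t : \mathrm{UMI}_g \ge 1\}}{n_t}.$$

A ligand is *expressed* in a cell type when $F \ge 2\%$ (inclusive: the
bundled tables print 2.0 as expressed, and their below-threshold code is
defined as $F < 2\%$). The 2% default balances dropout (a gene expressed in
every cell of a rare state still clears it) against ambient-RNA
contamination; it is exposed as `threshold` in `expressed_sets()` and in the
pipeline configuration.

Pooled ("combined mesenchymal"-style) columns are computed over the pooled
cells, i.e. the cell-count-weighted mean of member fractions
(`combined_fraction()`), never the unweighted mean — merging the cells and
recomputing gives the identical number, which is tested as an invariant.

**Highest-type assignment** (`assign_highest()`) uses the strict maximum
over the compared cell types, with aggregate columns excluded from the
comparison. Exact ties are *surfaced*, not silently broken: the result
flags them and leaves the assignment `NA` unless a `tie_break` map resolves
them. In the bundled injured-nerve table two ligands (Pomc, Cxcl2) tie at
the table's printed one-decimal precision; the table's own per-ligand
annotation — computed by the original analysis from unrounded fractions —
disambiguates both, and the acceptance script uses exactly that annotation
as its tie-break. **Fold changes** divide raw (unrounded where available)
fractions, emit a lower bound `">x"` when the denominator is zero and the
numerator positive, and `"-"` when both are zero. Regression tests against
the printed fold-change column therefore check that each printed ratio lies
inside the interval permitted by one-decimal rounding of its inputs, rather
than asserting equality.

**Enrichment flags** ("made by ≥ 4-fold more of this cell type than any
other") are computed on detection fractions, not mean expression, because
every other quantity in the chain is a detection fraction; the factor is an
argument, and at factor 1 the flag degenerates to at-least-highest
(strict-highest plus ties), which is tested as a limit case.

# Anchor thresholding of bulk profiles

For ligand calling in whole-nerve microarrays the cutoff is the expression
of *Ntf3*, a neurotrophin known to be expressed in nerve: a panel ligand is
expressed iff its value is ≥ the anchor's (inclusive, so the anchor calls
itself expressed). The anchor's percentile is reported as the fraction of
all probed genes at or below it; because "top X%" phrasing is ambiguous
about ties, both the at-or-below (default) and strictly-below conventions
are exposed in `anchor_threshold()`. Raising the anchor can only shrink the
expressed set — a monotonicity property the suite checks across a sweep of
anchor values.

Receptor repertoires use the same idea with three modes
(`anchor_receptor_call()`, `percentile_receptor_call()`,
`fpkm_receptor_call()`):

* **anchor** — the cutoff gene is the mass-spectrometry-detected surface
  receptor with the *lowest* mRNA expression; this grounds the transcriptome
  threshold in protein-level evidence and sidesteps percentile-convention
  ambiguity entirely. Ties at the cutoff are included; the cutoff gene is a
  member of its own call.
* **percentile** — for populations without proteomics (motor neurons), the
  panel genes within the top *q*% of all mRNAs by expression, cutoff order
  statistic included. We adopt at-or-above on the order statistic
  (`k = round(n·q/100)` genes from the top) since the source convention is
  not recoverable from a printed list alone.
* **fpkm** — for RNA-seq (retinal ganglion cells), strictly FPKM > 1, and
  the profile must be declared in FPKM units to prevent accidental use on
  log-intensity data.

Probe-level microarray tables are summarized replicate-mean-first, then
max-over-probes per gene (`summarize_probe_level()`), matching standard
practice when one probeset saturates or cross-hybridizes low.

# The ligand–receptor database and interaction prediction

The database is a directed set of (ligand, receptor) pairs. Receptor
complexes are annotation only: each component receptor is its own pair and
an interaction is predicted when *any* cognate receptor is expressed (OR
semantics). We chose OR because the bundled interaction tables list each
complex component as a separate row (e.g. CLCF1 → CNTFR, IL6ST and LIFR
separately); whether the original curation distinguished obligate
coreceptors (which would imply AND semantics for some complexes) is not
recoverable, so the more permissive reading is used and flagged here.

The bundled default database (`default_lr_db()`) is reconstructed as the
union of all pairs across the four printed target-population interaction
models (332 pairs, 128 ligands). This reconstruction is exact for the
printed results: re-predicting the sympathetic, sensory and RGC models from
(ligand panel × printed receptor list × reconstructed database) reproduces
each printed edge set with zero differences — a regression test, not an
assumption. A user-supplied database (any ligand/receptor TSV via
`load_db()`) will generally contain pairs outside this union and therefore
yield larger models; the reconstruction embeds whatever manual curation
shaped the printed tables, which cannot be reversed from the publication.

`predict_interactions()` is a membership-filtered cross join with fully
deterministic (ligand, receptor) lexicographic output ordering, verified
against a brute-force double loop on random instances. The headline size of
a model is its **ligand-node count** (a ligand with ≥ 1 cognate expressed
receptor), not its edge count; both are available, and the distinction
matters because multi-receptor families (BMPs, ephrins, Wnts) multiply
edges but not nodes.

# Mock bulks and differential correlation

`mock_bulk()` averages (by default library-size-normalized,
log1p-transformed) expression per gene over all cells of a dataset;
`correlate_cells()` computes Pearson r of each cell against each bulk on
the shared genes, and `differential_coordinates()` maps each cell to
`x = r(cell, A) − r(cell, B)` per axis pair. The *difference* of
correlations was chosen over a ratio because it is antisymmetric under pair
swap and bounded in [−2, 2], matching a plane symmetric about 0; the
alternative was considered and rejected as unbounded when the subtrahend
correlation approaches 0. Normalization (library-size vs none) must match
between bulks and cells and is therefore a shared argument. The gene set
for the correlation is all shared genes by default, with a
highly-variable-gene subset available via `gene_subset` since the upstream
clustering pipeline this mirrors uses variable genes elsewhere; which of
the two the original figure used is not stated, so the more reproducible
default (all genes) was adopted. Zero-variance cells have no defined r and
are excluded with a flag; constant bulk profiles are an error.

# The synthetic-data generator

`simulate_dge()` emulates exactly the statistical structure the downstream
stages consume: per-gene, per-cell-type Bernoulli detection (so the truth
table is the probability matrix itself), with counts given detection drawn
from a zero-truncated negative binomial (mean `mean_expr`, variance
`mu + dispersion·mu²`; dispersion 0 gives truncated Poisson). The
zero-truncation is deliberate: the detection rule downstream is binary, so
only the zero/nonzero structure must be faithful, and the NB tail gives
realistic magnitudes for IO and normalization code. Batches act only as
depth multipliers on the count means — they change counts, never the
detection event — because batch *correction* is out of scope here, and this
keeps recovery exact by construction. Seeds are mandatory and all
randomness is local (`set.seed` inside the generator); identical
configurations are bit-identical, which the pipeline's checksum manifest
also verifies end to end.

What the generator does **not** emulate: ambient RNA, doublets,
myelin-debris contamination, gene–gene correlation, or batch effects on
detection probability. Passing tests on simulated data therefore
demonstrate correctness of the estimators and the pipeline plumbing, not
robustness to those artifacts in real droplet data.

`simulate_bulk()` draws a log-normal expression universe and places the
anchor gene *between* the two order statistics of the other genes that
bracket the requested quantile, so the at-or-below fraction is exact to 1/n
by construction rather than approximately calibrated. `simulate_proteome()`
is a two-rate Bernoulli detector (sensitivity on true receptors, a small
false-positive rate on decoys), mirroring how partial sensitivity of
cell-surface capture propagates into anchor-mode receptor calls.

# Problem sizes, tolerances and test design

Fixture-driven regressions run on the bundled tables (143 ligands × 7 cell
types and smaller) in well under a second each. Stochastic checks use
5,000-cell simulations for binomial-interval recovery of detection
fractions (exact 99% intervals via `qbinom`), a 10,000-cell run for the
convergence check (max absolute error below 1.5 percentage points at
detection probabilities 0.02–0.9), and a 2,000-gene, 120-cell two-population
simulation for the differential-correlation side-of-axis check (≥ 95% of
cells on their population's side). These sizes were chosen as the smallest
that make the interval checks sharp; the full suite runs in about a minute
on one CPU.

# Known limitations

* **Printed-precision ties.** One-decimal fractions produce two exact ties
  in the injured-nerve table that the unrounded data did not have; the
  package surfaces them and the bundled annotation resolves them (above).
* **Motor-neuron receptor column.** The bundled receptor tables are
  internally inconsistent for motor neurons: the printed MN column omits 17
  receptors (Eph receptors, plexins, NEO1, UNC5B, LINGO1, netrin-G
  receptors, MST1R, RTN4RL1) that the same table's three-population
  intersect column and the printed MN interaction model both contain, and
  conversely includes 19 receptors the intersect excludes. Recomputing the
  three-way intersection from the printed columns gives 274 (printed: 272)
  and the four-way 256 (printed: 258). Tests therefore pin the set
  identities that do hold (the printed intersect columns are consistent
  with each other and with the sympathetic/sensory repertoires), and the
  motor-neuron network comparisons use the printed MN model directly.
* **Database completeness.** The default database is a reconstruction from
  printed models (exact for them, see above); it is necessarily a subset of
  the full curated database, so novel ligand/receptor inputs should be
  analyzed with a user-supplied database.
* **No interaction scoring.** Membership is binary end to end; expression
  level, affinity and spatial accessibility are out of scope.

# Command-line use

All orchestration is library-first: `run_pipeline()` takes one
configuration object and writes per-stage TSVs plus a manifest with seed,
parameters and md5 checksums, so identical configurations produce
byte-identical outputs. A thin wrapper (`inst/scripts/run-pipeline.R`)
exposes the same entry point to shell users with a JSON/YAML config; all
subcommand-style operations (simulation, ligand calling, abundance,
receptor calling, prediction, comparison, differential correlation) are the
exported functions themselves, which keeps every tested code path identical
to the interactive one.
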