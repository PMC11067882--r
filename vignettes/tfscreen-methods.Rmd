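---
title: "Methods: demultiplexing and scoring pooled TF-overexpression screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demultiplexing and scoring pooled TF-overexpression screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfscreen)
```

# The screen and its two inference problems

A pooled induced-TF (iTF) screen expresses one transcription factor per cell
line from a common doxycycline-inducible vector, pools the lines, and reads
the outcome by droplet scRNA-seq. The package implements the two
computational halves of that design: deciding which TF each cell expresses,
and quantifying how far each TF pushes the transcriptome away from the
control state.

# Junction tags

The ectopic transcript differs from the endogenous mRNA only at its ends,
where vector sequence abuts the ORF. A *forward tag* is therefore defined as
the last 7 nt of vector sequence upstream of the insert followed by the
first 21 nt of the coding sequence; a *reverse tag* is the reverse
complement of the last 21 nt of the ORF (including the stop codon) followed
by the first 7 nt of downstream vector. Both default to 28 nt.

Two failure modes are handled by `build_tag_table()`:

* a tag that occurs verbatim in the reference genome (either strand) cannot
  distinguish ectopic from genomic reads;
* two ORFs sharing an end would produce identical tags.

In either case the tag is grown on the **ORF side**, one nucleotide at a
time, re-checking after each step, until unique or 50 nt is reached
(`UniquenessUnreachable` beyond that). Growing the ORF side rather than the
vector side is a design choice: the vector context is shared by all
constructs, so vector-side extension can never separate two colliding tags,
whereas ORF-side extension eventually must. Genome collision means an exact
full-length substring match; near-matches are deliberately ignored because
tag scanning itself is exact by default. Ambiguity codes are rejected at
parse time — tags must be exact-matchable. A non-ATG start or missing stop
codon produces a warning rather than an error, so tagged fusion constructs
remain usable.

# Tag scanning and UMI aggregation

`scan_reads()` reports every occurrence of every tag (and of its reverse
complement, since reads come from both strands) as a substring of each read,
allowing up to `max_mismatches` substitutions and no indels. Exact substring
matching is the default: at 28 nt a tag is specific enough that allowing
indels or scoring alignments would add failure modes without adding
sensitivity. Internally, reads are concatenated into a single subject
separated by runs of `N` (which can never match an ACGT tag base) so each
pattern needs one C-level scan; matches spanning a separator are discarded
when positions are mapped back to reads. Reads missing a cell barcode or UMI
are dropped before scanning and counted in the scan log — dropping before or
after scanning yields identical assignments, which the test suite asserts.

Hits are aggregated per (cell barcode, UMI): each transcript is assigned the
TF with the most supporting reads; a tie excludes the transcript
(`tf_tie`). Majority vote, rather than discarding multi-TF reads outright,
was chosen because resolution naturally belongs at the transcript level. A
second exclusion uses an external aligner's per-read gene annotation when
available (`resolve_gene_conflicts()`): if **strictly more than half** of a
transcript's reads are annotated to a different gene, the transcript is
excluded (`aligner_conflict`); reads annotated `"NA"` or lacking annotation
never count against a transcript.

# Cell assignment: the minimum-UMI threshold sweep

Each cell line carries one construct, so a cell should show one iTF; ambient
molecules from lysed cells, PCR artefacts, and index hopping add spurious
low-UMI assignments. `sweep_umi_thresholds()` counts, for each threshold
t in 1..5, the cells with exactly one TF at ≥ t UMIs; `select_threshold()`
takes the argmax (smallest threshold on ties). Contamination is typically
worth 1–2 UMIs while genuine expression is worth many, so the single-iTF
count rises while the threshold climbs past contamination and falls once it
begins to exclude genuine cells — under the package's default simulation
conditions the optimum is 3.

`classify_cells()` makes the partition total: `single` (exactly one TF at
threshold), `multi` (two or more), `control` (zero iTF UMIs at any level,
the strictest possible control definition), and `unassigned` (sub-threshold
iTF evidence only — such cells are neither confidently perturbed nor clean
controls; making this label explicit keeps the partition exhaustive).

Cell quality control (`qc_filter_cells()`) applies three strict
inequalities: more than 1000 detected genes, less than 10% mitochondrial
counts, more than 10,000 molecules. Boundary cells (exactly 1000 genes, 10%
mito, 10,000 molecules) fail. Mitochondrial genes default to the mouse
`mt-` name prefix and can be overridden with an explicit list.

# The differentiation index

Expression is normalized per cell to 10,000 counts and log(1+x)
transformed (`log1p_cp10k`). This is a deliberate simplification of
variance-stabilizing regression approaches: it is deterministic,
dependency-free and order-preserving, which is what the downstream distance
statistic needs. The interface is pluggable — `normalize_counts()` accepts
any function honouring the same shape contract, and `method = "none"` lets a
pre-normalized (e.g. externally variance-stabilized) matrix flow through.

PCA (`fit_pca()`) is fitted on **all cells jointly** — controls and
perturbed cells share one space so distances are comparable — after
excluding the iTF genes themselves, so the ectopic transcript cannot drive
the embedding. Fifty components are kept by default (explained variance is
typically negligible beyond that in screens of this size); the count is
capped at the feasible rank with a warning. Numerically the decomposition
uses the symmetric eigendecomposition of whichever of the gene-gene
covariance or cell-cell Gram matrix is smaller, which is exact and fast
single-threaded at cohort scale; the test suite verifies both branches
against `prcomp`'s SVD.

The index itself (`differentiation_index()`) is the z-normalized Euclidean
distance from the control-cell centroid:
d_i = (‖s_i − c‖ − μ)/σ, with μ and σ the sample mean and standard deviation
(n−1 convention) of control distances. Euclidean distance is the natural
metric for PCA coordinates. At least 3 control cells and σ > 0 are required
(`DegenerateControls` otherwise — note that perfectly symmetric control
configurations, where every control is equidistant from the centroid, are
degenerate by construction).

# Potency testing

`potency_test()` compares each TF population's indexes to the controls'
with a Mann–Whitney U test, one-sided (`greater`): the index is constructed
so that departure from the control state is positive, and a population
*below* controls has no fate-conversion interpretation. A two-sided option
is available. P-values are Benjamini–Hochberg adjusted across tested TFs
(Bonferroni available); `potent` means adjusted p < 0.01. TFs with fewer
than 3 single-iTF cells are reported untested rather than silently dropped.

# Gene-set variants, ranks and similarity

`geneset_indexes()` repeats the whole pipeline per gene set: normalize,
restrict genes to the set, refit PCA, recompute the index. Refitting per set
(rather than subsetting one global score matrix) is the choice consistent
with computing an index *of* the gene set's transcriptional program. The iTF
genes are excluded from every set; ribosomal genes (default `Rps`/`Rpl`
prefixes, or an explicit list) can additionally be excluded; sets with fewer
than 15 genes after exclusions are dropped (`SetTooSmall`) because a
PC-space distance over a handful of genes is dominated by noise.

Because index ranges differ across gene sets, per-TF medians are compared
via `percentile_ranks()`: rank = 100·(#smaller + 0.5·#ties)/(n−1), so the
largest median maps to 100 and full ties to 50. `tf_similarity()`
correlates TFs' median-index profiles across sets (Pearson by default) and
orders them by average-linkage hierarchical clustering on 1 − correlation;
zero-variance rows are dropped with a warning.

# Pseudobulk and smoothing

`pseudobulk_means()` averages log-normalized expression per gene over each
single-iTF group and the controls; groups with fewer than 3 cells are
flagged `low_n` rather than removed. `marker_report()` expresses a marker
panel relative to controls, by default as the ratio of de-logged means (so
the control column is exactly 1), with a log-difference option.
`moving_window_average()` (window 100, stride 1 by default) smooths, e.g.,
binding peak scores over genes ordered by relative expression;
`permute_scores()` provides the seeded randomized comparison series (scores
permuted across genes — permutation preserves the score distribution while
destroying the association with the expression ordering).

# The synthetic-data generators

`simulate_tag_reads()` emulates the read-level evidence: every cell carries
one true TF with Poisson(mean 8) molecules truncated to ≥ 1; with
probability 0.5 the cell gains 1–2 molecules (uniform) of one random other
TF — ambient contamination, the mechanism that creates spurious multi-iTF
cells; each molecule emits 3 reads embedding the TF's forward or reverse tag
at a random offset on a random strand, with optional substitution noise
(default 0). Doublets (two whole cells) are not simulated; contamination is
strictly the low-UMI ambient kind.

`simulate_expression_cohort()` draws counts from a negative binomial with
dispersion 0.3 (typical scRNA-seq overdispersion) around log-normal baseline
gene means (meanlog 0, sdlog 1 — a few counts per gene per cell, a realistic
depth for droplet data). Potent populations multiply the means of 50
randomly chosen non-iTF genes by exp(2); null populations are drawn from the
unmodified baseline. Defaults are 2000 genes, 2000 control cells, 10 potent
and 10 null populations of 100 cells — the package's reference cohort.

Both generators are pure functions of their parameters and seed, and return
ground truth sufficient to recompute every downstream expectation.

**What the simulations do not capture:** real transcript structure
(splicing, positional bias), barcode sequencing errors, doublets, batch and
cell-cycle effects, mean–variance relationships beyond a single dispersion,
and correlated gene programs. Passing tests on these fixtures demonstrate
the *algorithms* are correct under their stated assumptions, not that any
particular biological dataset will behave as cleanly.

# Problem sizes and numerical choices

The test suite exercises the reference cohort (4000 cells × 2000 genes, 50
replicates) for potency recovery, 20 replicate read simulations of 1000
cells for threshold selection, 200 small pure-null cohorts for type-I
control, and 10,000-read oracle comparisons for tag scanning — sizes chosen
so the whole suite runs in minutes on one core while keeping Monte-Carlo
error well below the margins being asserted. Tag-panel size does not affect
threshold selection, so simulations use 20-TF panels.

Other numerical details: eigenvalues are clipped at zero and components
beyond the numerical rank (relative tolerance 1e-12) are discarded;
`wilcox.test` switches between exact and normal-approximation p-values by
its own sample-size rule, so toy cases are exact; ties in `select_threshold`
break toward the smaller threshold (fewer discarded cells); the all-zero
cell is left as zeros by normalization with a warning rather than dropped.

# Known limitations

* Tag scanning tolerates substitutions but not indels; an indel inside the
  28-mer loses the read (at these lengths the loss is small).
* No barcode/UMI error correction or whitelist rescue is attempted.
* The threshold sweep optimizes single-iTF count globally; per-TF thresholds
  are not supported.
* `geneset_indexes()` refits PCA per set, which is quadratic-ish in the
  number of sets; very large collections (hundreds of sets on large
  cohorts) take correspondingly long.
* Real-data scale claims (cell counts, potent-TF counts per time point)
  require the original sequencing data and are out of scope here; the
  package's evidence is simulation-based.
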