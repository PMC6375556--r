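---
title: "Models and methods behind neoexome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neoexome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoexome)
```

# Scope and design

`neoexome` implements the desk analysis of a neoadjuvant breast-cancer
cohort in which diagnostic (pre-treatment) and residual-disease
(post-treatment) tumour exomes were sequenced with matched germline
controls. The pipeline starts at the *variant level*: read alignment,
primary variant calling and effect annotation are upstream tools' jobs, and
their outputs (depths, allele counts, caller quality, consequence classes,
six predictor verdicts, INDEL read geometry) are this package's inputs.
Every stage is a plain function over data.frames so that each step can be
audited, re-run and tested in isolation.

# Somatic filtering

The SNV filter keeps a call when caller q-value ≥ 12, tumour depth ≥ 50×,
germline depth ≥ 20×, germline mismatch fraction < 0.10 and VAF ≥ 0.10. The
INDEL filter requires ≥ 20 supporting reads, ≥ 5 interior supporting reads
(INDEL ≥ 25 bp from both read ends), ≥ 20 germline reads covering the site
with zero germline INDELs within 20 bp, local 10-bp mismatch rate < 0.10,
VAF ≥ 0.10, and ≤ 5 adjacent repetitive regions.

Boundary semantics are read literally from how each threshold is stated:
"at least"/"minimum" thresholds are inclusive, "less/lower than" thresholds
strict. In particular a VAF of exactly 0.10 is *kept* (the exclusion rule is
"less than 10%"). The audit records **every** failing reason per record, not
just the first, so that synthetic audits reproduce exactly and real audits
answer "why was this call lost?" without re-running.

Two inputs are deliberately ingested precomputed rather than derived:
the germline mismatch fraction (its per-base vs per-read definition is an
upstream caller detail) and the adjacent-repeat count (the unit of a
"repetitive region" is operationalized as the count of annotated
homopolymer/short-tandem-repeat units overlapping ±20 bp of the INDEL,
supplied by the annotator or the generator).

# HFI consensus

An SNV is high functional impact when at least 3 of the 6 predictor
verdicts are "deleterious". "Unknown" verdicts are non-votes: the
denominator stays six, which is the conservative reading (a variant with
three predictions returned, all deleterious, is HFI; one with two cannot
be). All INDELs are HFI by rule. The classifier is validated against
exhaustive enumeration of all 3^6 verdict combinations.

# Mutation burden

Callable bases are positions at depth ≥ 20 (inclusive), one megabase is
10^6 bases, and two counting modes are reported: *all* (every kept SNV,
including synonymous, intronic and intergenic, plus INDELs) and *nonsyn*
(missense, stop-gained, splice-site SNVs plus INDELs). Burden is displayed
to two significant figures; the raw rate is retained. Invariants:
nonsyn ≤ all, and scaling the callable territory by c scales burden by 1/c.

# Mutational-signature refitting

Qualifying SNVs (VAF > 0.10 and quality > 20, both strict; all consequence
classes) are binned into the 96 canonical classes: six pyrimidine-centred
substitutions × 16 flanking-base pairs, with purine-reference calls
reverse-complemented. The refit models the catalog's class proportions
$p \in \Delta^{95}$ as a convex combination $p \approx S^\top w$ of
reference signature rows with $w \ge 0$, $\sum w \le 1$.

Estimation is by deterministic forward selection: each candidate
signature's weight is optimized alone by golden-section line search on its
feasible interval, the signature yielding the largest decrease in squared
error is updated, and iteration stops when the best relative improvement
falls below `tol` (10^-3 of the current SSE; the relative form is used
because the absolute scale of the SSE varies by orders of magnitude with
catalog sparsity, and an absolute cutoff demonstrably under-fits clean
mixtures). Weights below the 0.06 minimum contribution are then pruned and
the survivors re-optimized, re-pruning if needed; mass not assigned to any
signature is reported as "unexplained". Normalisation is the raw catalog
proportions — no exome-to-genome trinucleotide-opportunity rescaling is
applied by default, since no opportunity table is part of the procedure; a
rescaling hook can be added upstream by reweighting the catalog before
fitting.

Against a full-matrix nonnegative least-squares oracle the fit's SSE agrees
to well under 5% of the catalog's total variance on both clean and
multinomially sampled mixtures. Note that an *unconstrained* 30-signature
NNLS also absorbs sampling noise that a pruned convex fit intentionally
refuses to fit, so raw SSE ratios are not a meaningful agreement metric on
noisy catalogs.

## The reference matrix is synthetic

The packaged `synthetic_signatures()` matrix is a deterministic synthetic
stand-in with the *structure* of a COSMIC v2-style catalog (30 rows, 96
probability columns, sparse and mutually well-separated) but not its
content. All signature results in tests and examples are therefore
statements about the algorithm, not about biological signatures. Any real
reference matrix in the documented CSV schema drops in via
`read_signature_matrix()`.

# EASE enrichment

The EASE score is Fisher's one-sided exact test with one overlapping gene
removed: for overlap $k$ of an $n$-gene query with a $K$-gene pathway in an
$N$-gene background, $p = P[X \ge k-1]$, $X \sim \mathrm{Hyper}(N, K, n)$;
$k \le 1$ gives $p = 1$ by convention. This is always at least the
classical Fisher p, which is the intended conservatism. Significance is
α = 0.05 per pathway with no multiple-testing correction — matching the
original per-sample review procedure — with an optional Benjamini–Hochberg
mode. The background defaults to the distinct genes of the loaded
collection, the natural choice when the true annotation universe is
unstated; it is overridable. Group comparisons report per-pathway counts of
significant samples per group and deliberately compute no pooled statistic.

# Clone tracking

Clonal structure is inferred from VAFs only: alt counts are modelled as
binomial mixtures over depth, fitted by EM for k = 1..5 with means
initialized on a fixed VAF quantile grid (determinism without restarts;
seeded jitter only revives empty components), and k chosen by BIC with
2k − 1 free parameters. Clusters need ≥ 2 members; singleton assignments
merge into the nearest component. Diagnostic and residual clusters are then
matched greedily by descending Jaccard overlap of variant ids, each cluster
used once; Jaccard ≥ 0.5 makes a clone *persistent*, unmatched residual
clusters are *emergent*, unmatched diagnostic clusters *extinct*.

This is an intentional simplification of copy-number-aware cancer-exome
clonality inference: it assumes diploid, copy-neutral sites, so VAF ≈ half
the cancer-cell fraction, and it does not reconstruct phylogenies or use
cohort germline controls. On simulated patients (2–4 clones at VAFs from
the grid 0.50/0.35/0.22/0.12, depth 200, 30 variants per clone — separations
of ≥ 3 binomial standard deviations, which is what real subclone calling at
exome depth also requires) fate classification is ≥ 95% accurate over 50
seeded replicates.

# Clinical statistics

Breast pCR is ypT0/is ypN0–3 (no invasive cells in the breast; in-situ
disease and nodal involvement permitted for the breast-only endpoint); nCR
is scattered tumour cells only, assigned only to non-pCR patients. The
package reports percentages with numerators and raw fractions, at one
decimal, because the cohort sizes (40/15/15/10) make integer percentages
lossy in both directions.

The single-stage design declares the regimen worth further study at ≥ 17
responses among 40 patients; operating characteristics are exact binomial
tails, `P[X ≥ 17 | 40, 0.30]` ≈ 6% type I error and `P[X ≥ 17 | 40, 0.50]`
≈ 87% power (integer-rounded), cross-checked against Monte-Carlo simulation.
DFS runs from registration with progression-during-treatment not an event;
the estimator is the product-limit (Kaplan–Meier) curve via the survival
package, with the median defined as the first time S(t) ≤ 0.5 and undefined
while events are too few. Adverse events count a patient once per term;
terms are reported at ≥ 10% any-grade incidence or any grade ≥ 3 event.

# The synthetic-data generator

The generator exists so that every stage has inputs with known truth:

* **Variant pairs** (`generate_pair()`): tumour depths Poisson around 150×,
  germline around 50× (the study's nominal coverages), alt counts binomial
  at the record's clone VAF, trinucleotide contexts drawn from a chosen
  signature mixture. Records intended to pass clear every threshold with a
  margin of one unit (1 read/point for integers, 0.01 for fractions);
  planted failures fail exactly one named condition. Depths are clamped
  after sampling to preserve intended fates — realistic overdispersion is
  out of scope.
* **Depth tracks** (`generate_depth_track()`): exact callable fractions by
  construction.
* **Cohorts** (`generate_cohort()`): per-subtype response counts expand
  into a 40-row outcomes table whose marginals equal the requests exactly;
  defaults are the study's published marginals (22/40 breast pCR split
  12/7/3 across HER2-amplified/TNBC/HR-positive, 18/40 breast+LN pCR,
  13 ypT0 ypN0, 4 nCR, 19 breast-conserving, 7 DFS events, 35/40 at ≥ 85%
  relative dose intensity, and the published per-term toxicity counts).
  Which individual patient carries which flag is plumbing, assigned
  deterministically (responders-first orderings and seeded draws).
* **Two-timepoint patients** (`simulate_clone_patient()`): persistent
  clones keep their variant ids across timepoints; extinct ones appear only
  at diagnosis, emergent ones only in residual disease at freed VAF slots.

One master seed drives everything; each generator derives its own RNG
stream by a fixed offset, so adding one generator never perturbs another's
draws, and all outputs are byte-reproducible.

What the generator does *not* emulate — FFPE artefacts, strand bias,
mapping error, copy-number change, overdispersed coverage, germline
contamination — bounds what passing tests prove: they validate the
*algorithms* (filters fire on exactly the planted conditions; refitting
recovers planted mixtures; tracking recovers planted fates; endpoint code
reproduces planted marginals), not robustness of upstream calling on
degraded material.

# Problem sizes and numerical choices

Default test and acceptance runs use: 300–400 variant records with planted
failures, 1000 randomized records for filter invariants, 2000-mutation
catalogs × 25–100 replicates for signature recovery, 10-Mb depth tracks,
exhaustive hypergeometric enumeration to N = 60, and 50 simulated
two-timepoint patients. These sizes make each property estimate stable at
a few percent while keeping a full run in minutes on one core.

Ties and degenerate inputs: VAF ties at thresholds follow the literal
boundary rules above; catalogs with zero qualifying mutations are an error
(refitting needs data); clustering fewer than two variants is an error; an
empty overlap in enrichment returns an empty result rather than p = 1 rows;
k = 1 EASE overlaps return p = 1 flagged by convention.

# Known limitations

Variant-level start (no realignment or recalling); VAF-only clonality
(no CNA, no phylogeny); synthetic reference signatures; no multiple-testing
correction by default in enrichment (by design, matching the original
analysis — interpret single-sample significances descriptively); the
outcomes generator reproduces marginal tables, not joint patient-level
correlations beyond the constraints listed.
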