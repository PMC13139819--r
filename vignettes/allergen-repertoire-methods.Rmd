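---
title: "Methods: comparative allergen-repertoire analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative allergen-repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allerprofile)
```

`allerprofile` compares the protein and allergen repertoires of related
crustacean species from four kinds of evidence: scored electrophoresis
band profiles, homolog sequence conservation, serological assays, and
transcript abundance. This vignette documents the statistical models and
procedures, the tunable parameters and why their defaults are what they
are, what the synthetic-data generators do and do not emulate, and the
numerical edge-case rules.

## Band-profile similarity and clustering

Each species' gel or immunoblot lane is scored into a binary band
vector; bands shared between species carry the same label, assigned at
annotation time (there is no automatic molecular-weight-window matching
— cross-species band identity is a curation decision, not an inference
this package makes). For two profiles with $X$ and $Y$ bands of which
$Z$ are shared, the similarity index is the Dice coefficient on the
percent scale,

$$ SI = \frac{2Z}{X+Y} \times 100 , $$

which is 100 exactly for identical non-empty band sets and undefined
when both profiles are empty (the package raises an explicit
degenerate-input error rather than returning 0). For IgE immunoblot
profiles the Pearson product-moment correlation of the binary vectors
(equivalently the phi coefficient) is available as an alternative
metric; rows with zero variance (all bands present or all absent) have
no defined correlation and are rejected by name.

Dendrograms are built agglomeratively on the distance $100 - SI$
(percent scale) or $1 - r$ (correlation scale). The linkage is a
genuinely open design choice — band-profile studies typically report
the dendrogram without naming the algorithm — and we default to UPGMA
(average linkage), the standard choice for band-sharing data, which
yields ultrametric trees; single and complete linkage are available by
flag. Two numerical conventions matter:

* **Heights.** A node's height is the cluster distance at which its
  children merged (the `hclust` convention), so the height at which two
  leaves first share a cluster reproduces their input distance exactly
  when the input is ultrametric. Newick branch lengths are
  parent-minus-child height differences; a two-leaf cherry merged at
  height $h$ is written `(A:h,B:h);`.
* **Tie-breaking.** Among all minimal-distance cluster pairs, the pair
  whose (lexicographically sorted) representative labels are smallest
  merges first. This makes the agglomeration fully deterministic, which
  matters for byte-identical reproduction of pipeline runs.

The agglomeration is implemented in the package (rather than calling
`hclust`) precisely to pin down the tie rule; the test suite verifies
that on tie-free inputs its cophenetic heights agree with
`stats::hclust` + `stats::cophenetic` to machine precision.

## Consensus calling and conservation scoring

A consensus over an $n$-row alignment emits, per column, the most
frequent symbol (gaps count as a symbol) when its count reaches the
threshold *and* it is the unique most frequent symbol; otherwise the
ambiguity character `X`. The default threshold is a strict majority,
$\lfloor n/2 \rfloor + 1$ — 4 of 6 for the six-species alignments this
package targets. With a strict majority a two-way tie at threshold is
impossible; sub-threshold ties also emit `X`.

Each sequence is scored against the consensus column by column with
BLOSUM62 (bundled as a plain-text NCBI-format asset and parsed at run
time):

* columns where the consensus is `X`, or where both symbols are gaps,
  are **excluded** from the denominator;
* equal symbols are **identical**;
* differing residues whose substitution score reaches the
  `similar_cutoff` are **similar**;
* everything else — including a residue facing a gap — is
  **dissimilar**.

$$ \mathrm{percent} = \frac{\mathrm{identical} + \mathrm{similar}}
   {\mathrm{length} - \mathrm{excluded}} \times 100 $$

Two boundary decisions here were genuinely open. First, "scored above
one" is ambiguous between $>1$ and $\ge 1$; we implement score
$\ge$ `similar_cutoff` with default 1 and expose the cutoff (0 accepts
any positive score). Since BLOSUM62 is integer-valued, $\ge 1$ and
$>0$ coincide, and raising the cutoff can only lower a score — a
monotonicity the tests assert. Second, gap handling: counting
gap-vs-residue columns as dissimilar (not excluded) keeps a sequence's
self-similarity at 100 without rewarding shared deletions; gap-vs-gap
columns are excluded for the same reason. The consensus is built on all
rows, including the row being scored — the alternative (leave-one-out)
is not what interactive consensus tools display, and with six rows and
a 4-of-6 threshold the difference is small.

Epitopes are defined as 1-based inclusive intervals on an *ungapped*
reference sequence, with the expected peptide stored alongside and
validated on use — a mismatch between stated peptide and reference
substring is a hard error, catching off-by-one coordinate mistakes
early. Mapping walks the gapped reference, skipping gap columns, and
returns the full spanned sub-alignment (including columns where the
reference itself is gapped). Per epitope, the consensus is rebuilt on
the epitope sub-alignment and every species scored against it; an
epitope whose consensus excludes every column (e.g. a single column
with a 3/3 split) is reported as `NA` and flagged rather than silently
dropped.

## Serology

The ELISA positivity cutoff is $3 \times$ the arithmetic mean OD450 of
the nonallergic control sera (multiplier exposed). Positivity is
*strictly above* the cutoff — an OD equal to the cutoff is negative —
a conservative boundary rule; replicates are averaged before
thresholding and their standard deviation carried into the output.
Sensitization rates are reported as percents rounded to one decimal
place, always together with their counts, since a rate like 41.4% of
29 sera is only interpretable with its denominator.

Percent inhibition uses the difference-ratio form
$100\,(S_0 - S)/S_0$ for both inhibition ELISA (OD450) and inhibition
immunoblot (pre-quantified band intensity). Negative values (signal
enhancement) are reported and flagged, not clamped. A dilution series
is summarized by its maximum percent inhibition, the concentration at
the maximum, and a dose-dependence flag: the inhibition vector must be
non-decreasing in concentration within a 2-percentage-point tolerance,
so small replicate jitter on a flat or rising curve does not break
monotonicity, while a genuine dip does. Half-maximal-concentration
(4PL/IC50) curve fitting is deliberately out of scope: the quantities
of interest are the maximal inhibition and the presence of a
dose-dependent pattern.

## Expression

Per-sample Salmon `quant.sf` tables are merged by transcript id;
transcripts absent from a sample are imputed as TPM 0 with a warning.
Allergen-level abundance is the **sum** of member-transcript TPM
(isoform aggregation by sum is the natural choice when isoforms of one
gene family are quantified separately); with a species-aware transcript
mapping, an allergen with no mapped transcript in a species is `NA`
("missing"), never silently 0. Heatmap values are $\log_2(TPM + 1)$:
the pseudocount keeps zero abundance at 0 and puts a transcript
dominating its sample (TPM near $10^6$) at $\approx 20$, matching the
0–20 display scale; an optional per-column z-score standardization is
off by default because the raw log scale is the reported one.
Mixed-tissue samples are carried with a tissue label and excluded from
cross-species group comparisons by default, since tissue composition
confounds species differences.

Group comparisons are a thin standard-statistics stage: one-way ANOVA
(`stats::aov`) followed by Tukey HSD (`stats::TukeyHSD`), with p-values
encoded as significance codes 0–4 by the strict-inequality bins
(0: $p > 0.05$; 1: $p < 0.05$; 2: $p < 0.01$; 3: $p < 0.001$;
4: $p < 0.0001$). The code is the largest bin whose strict inequality
holds, so $p = 0.05$ exactly codes 0.

## What the synthetic data emulates — and what it does not

The generators produce inputs with the statistical *structure* the
analysis assumes, under a fixed seed (identical seeds give
byte-identical output, and every generator attaches its ground truth):

* `gen_band_profiles` — a Bernoulli(0.7) root band profile evolving by
  independent state flips with probability (0.05 per unit branch
  length by default) along a six-species tree
  `((((CF,PP),SP),(CO,ES)),PC)` whose branch lengths (cherries at
  height 1–2, root at height 5, the outgroup PC on the longest branch)
  were chosen so the expected similarity levels match the observed
  band-profile regime — cherry pairs in the low 90s, the outgroup in
  the 70s. Default 50 bands.
* `gen_protein_family` — Poisson substitution counts per branch and
  site (0.05 per site per unit branch length), uniform replacement
  among the other 19 residues, epitope blocks substituted at 0.2× the
  background rate. No indels by default (columns stay in register); a
  gap-injection option exists solely to exercise the gap-handling
  rules. This is deliberately *not* an empirical amino-acid model —
  only relative conservation structure matters for testing the
  scoring, not phylogenetic realism.
* `gen_od_plate` — 50 allergic plus 3 nonallergic sera; lognormal ODs
  with mean 0.02 (CV 0.2) for negatives and non-sensitized allergic
  sera, 20× that for the truly sensitized fraction (14% by default),
  comfortably above the 3× cutoff.
* `gen_inhibition_series` — Hill dose-response
  $I(c) = I_{max} c^h / (IC_{50}^h + c^h)$ over seven 10-fold
  dilutions spanning $10^{-4}$–$10^2$ µg/mL, signals under
  multiplicative lognormal noise (CV 5%). The no-inhibitor reference
  is itself a measured, noisy quantity — treating it as exact would
  understate the variance every real inhibition assay has.
* `gen_tpm` — lognormal TPM around allergen-specific means with the
  tropomyosin-like allergen at $2^{19}$ relative units (two isoforms,
  split 2:1, to exercise aggregation) and hemocyanin near zero in
  muscle; unmapped background transcripts added; every sample
  renormalized to $10^6$ TPM.

They do **not** emulate: gel image formation and band calling,
molecular-weight calibration, mass-spectrometry identification,
basophil activation, read-level RNA-seq, or real phylogenetic
substitution processes. A green test on synthetic data therefore shows
the *computations* are right under the assumed structure, not that the
upstream annotation and assays are.

## Recovery experiments and their limits

The suite runs three 100-replicate recovery experiments (sizes chosen
to keep the whole suite fast on one CPU: 50 bands, 300-residue
families, 7-point dose series):

* **Outgroup conservation.** The species with the largest generating
  divergence (PC) attains the minimum consensus similarity in
  effectively every replicate — this recovery is easy and robust.
* **Seroprevalence.** The 3×-cutoff pipeline recovers the configured
  14% prevalence exactly on noise-free plates and within binomial
  error on noisy ones.
* **Tree topology.** At the default study conditions — 50 bands,
  per-branch flip probability capped at 0.05 — SI + UPGMA recovers the
  generating topology in only about half of the replicates. This is a
  genuine statistical limit, not an implementation defect: the
  SP-placement split rests on an expected SI gap of roughly 8 points
  against Dice sampling noise of roughly 5 points at 50 bands, and the
  same pipeline recovers the topology in ≥99/100 replicates at 500
  bands. Band counts of real gels simply carry limited topological
  signal; dendrograms from ~30–50 bands should be read as descriptive
  groupings, not phylogenies.
* **Hill $I_{max}$.** The dose-response summary reports the *maximum*
  of the observed percent-inhibition vector, which on a noisy series
  is an upward-biased estimator (a maximum over noisy points). At 5%
  signal CV the per-point percent-inhibition noise is
  $\approx 5(1 - I_{max}/100)\sqrt{2}$ points, so recovery within ±3
  points is reliable near the top of the scale ($I_{max} = 93$) but
  not for weak inhibitors ($I_{max} = 10$, noise ≈ 6 points/point).
  The estimator is kept as the plain observed maximum because that is
  what inhibition assays report; users needing unbiased plateau
  estimates at low inhibition should average replicate series.

## Known limitations

Band identity across species is trusted as annotated; no
molecular-weight-window matching or bootstrap support is computed.
Conservation scoring assumes a reasonable input alignment — it does not
realign. The ANOVA/Tukey stage is a convenience for significance
coding, not a differential-expression model (no dispersion shrinkage,
no multi-factor designs). Myosin-superfamily isoform disentangling is
out of scope; isoforms are summed.
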