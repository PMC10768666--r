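---
title: "Methods: comparative host-endophyte metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative host-endophyte metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holometab)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are: the processing model and its assumptions, the
parameters that matter, what the synthetic generator does and does not
emulate, the numerical choices, and the known limitations.

## The comparison being made

Two metabolomes are compared over one aligned feature space: the *host*
dataset (chromatographic fractions plus a crude extract of a single leaf)
and the *fungal* dataset (organic and aqueous extracts of endophyte strains
cultured from the same host). A feature — an aligned ion with consensus
m/z, retention time and a representative MS/MS spectrum — is the atomic
unit. The headline statistic is the set of *shared* features: those called
present in at least one sample on each side. Everything else (per-strain
overlap, enrichment, shared molecular families, class distributions) is a
re-aggregation of the same presence calls, which is why the presence rule
is the single most consequential parameter block in the package.

## Feature-table processing

The chain is fixed as: per-replicate deduplication → isotope grouping →
MS2-presence filter → join alignment → blank subtraction → replicate
filtering → replicate averaging with per-feature normalization → dataset
splitting. Tolerances default to values typical of high-resolution
orbitrap data: duplicates at 8 ppm / 0.03 min, isotope grouping at
8 ppm / 0.02 min with charge up to 2 (spacings n·1.003355/z, n ≤ 2),
alignment at 10 ppm / 0.04 min with m/z and RT score weights of 10. All
ppm tolerances are computed on the mean of the two masses; RT tolerances
are absolute minutes.

Choices worth calling out:

* **Duplicate and isotope groups are connected components** of the
  pairwise rule, resolved to the most intense member. A chain a–b–c where
  only adjacent pairs are within tolerance still collapses to one
  survivor; the suite checks this against brute-force oracles.
* **Join alignment is greedy best-score-first**, one feature per row per
  sample list, with ties broken by (higher score, lower row index, lower
  feature id) so runs are reproducible. Row consensus is the running mean
  of members. The upstream aligner this mirrors also exposes an optional
  spectral-similarity gate on merging; that gate's role is ambiguous in
  the original tool, so it is not applied here.
* **Blank subtraction removes rather than subtracts**: a row is discarded
  when its mean intensity across solvent and media blanks exceeds
  `blank_ratio` (default 0.1) times its best biological per-sample mean.
  The threshold is a package choice — the removal criterion is usually
  left unstated in methods sections — and is exposed as a parameter.
* **The replicate rule** retains a row only if detected in *all*
  `n_replicates_required` (default 3) replicates of at least one
  biological sample, then calls the row present in any sample with
  ≥ `cooccurrence_min` (default 2) detections. Detections below the
  co-occurrence threshold are zeroed, so downstream intensity shares never
  include sub-threshold evidence; whether to zero or keep them is a
  genuinely open choice, and zeroing is flagged in the output rather than
  silent.
* **Averaging precedes normalization**: replicate means per sample are
  computed first, then each row is scaled to sum to 1 across samples. With
  equal replicate counts the two orders differ only by a per-row constant,
  and only this order makes the unit-row-sum contract exact, which the
  suite asserts to 1e-12.

## Molecular networking

Spectral similarity is the modified cosine: fragment pairs may align
directly or shifted by the precursor mass difference, intensities are
square-root transformed and L2-normalized (the convention of the dominant
networking platform; the transform is rarely stated in papers), and the
score is an exact maximum-weight one-to-one matching over candidate pairs,
solved by branch-and-bound with suffix-sum pruning. Candidate graphs from
real spectra are small and sparse, so exactness is cheap; the suite checks
500 random pairs against an exhaustive matching enumeration, and the
implementation was cross-checked against the field's reference
implementation on random spectra.

Edges require score **strictly above** `min_cosine = 0.7` and
`min_matched_peaks = 7` matched peaks — "more than six" read literally;
set 6 for compatibility with tools whose convention is "at least six".
Mutual top-`k` pruning (k = 10) keeps an edge only if each endpoint ranks
in the other's top k; ties at rank k are all kept, a deliberate reading
since rank-tie handling is typically unspecified. Families larger than
`max_family_size = 100` lose their lowest-scoring edges one at a time
(ties by lexicographic node ids) until compliant — a deterministic greedy
sequence, matched step-by-step by an independent oracle in the tests. The
fragment tolerance for networking defaults to 0.02 Da (the common platform
default); the annotation searches use their own 0.01 Da.

## Annotation

The cascade is: identity match against authentic standards (20 ppm
precursor, score ≥ 0.8 — the "confirmed" tier), MS2 search against a
structure–organism library (parent gate 0.01 Da, fragment 0.01 Da,
σ ≥ 0.2, ≥ 6 peaks, 50 candidates), taxonomically informed re-ranking,
then network-consensus classes; features with no MS2 candidates fall back
to taxonomy-restricted MS1 adduct matches over five common positive-mode
adducts ([M+H]+, [M+Na]+, [M+NH4]+, [M+K]+, [M+H−H2O]+ — extendable).

The re-ranking bonus is linear: `final = σ + τ·(R − d)/R` with τ = 1 by
default, d the 0-based rank index (species = 0) of the lowest common
ancestor between the sample's taxon and the candidate's nearest source
organism, and R = 7 for taxa sharing no ancestor below the root. The
published description of this step constrains the weight only to be
inversely related to taxonomic distance; the linear form is this package's
stand-in, chosen for monotonicity (strictly increasing in σ, non-increasing
in d — both property-tested) and a bounded, interpretable bonus. A
candidate whose source organism is the analyzed species gains the full
+1.0; one from another kingdom gains nothing.

Consensus classes pool the rank-1 candidate of a node and its direct
neighbors (radius 1, configurable — the scope of "network topology" is
another under-specified point), weighted by final score, with lexicographic
tie-breaks; candidates then gain `class_bonus = 0.1` per ontology level on
which they match the consensus (magnitude invented, configurable) before
the top 3 are retained. Re-ranking happens before consensus, matching the
order in which the steps are usually described; the package does not claim
this is the only defensible order.

## The synthetic generator

The generator emulates the study *design*, not the instrument: 15 strains
× 2 extraction phases (organic factor 1.0, aqueous 0.5), 47 fractions plus
a crude extract, triplicates, 2 solvent and 2 media blanks. Metabolites
carry a neutral mass (130–1950 Da, the scan range), an RT in 0.3–7.7 min
(mirroring a 7-min gradient plus 1-min hold), a class triple from a
3-level ontology, a 6–12-peak fragmentation template with max relative
intensity 1, and a lognormal base abundance (meanlog log(1e6),
sdlog 0.8). Producer sets implement the membership categories: host-only,
strain-specific, multi-strain (2–5 strains), shared host∩strain, plus
solvent contaminants (present everywhere including blanks) and media
metabolites (fungal samples and media blanks) that exercise blank
subtraction.

Host elution over fractions is a discretized Gaussian (center uniform over
fractions, width 1.0–2.5), normalized to sum 1 so fraction abundances
conserve the base abundance; no published elution model exists for this
design, so a unimodal profile is the minimal realistic choice. The crude
extract sees every host metabolite at `crude_dilution = 0.02` of its total
abundance — fractionation concentrates, crude profiling dilutes — which
reproduces the qualitative enrichment effect (far more features in the
fractions than the crude extract at a finite detection limit). Noise is
four-parameter: multiplicative lognormal intensity noise (σ, default 0.3),
m/z jitter (2 ppm), RT jitter (0.005 min), detection dropout (0.1), plus
decoy fragment peaks (3 per spectrum, uniform in (50, precursor − 10) Da,
≤ 5 % of the base peak). Each detected feature also emits an M+1 isotope
companion (ratio 0.05–0.4, no MS/MS scan) that the isotope grouper must
remove. Only the protonated adduct is simulated by default, keeping MS1
annotation testable without combinatorial explosion.

Two identifiability choices are deliberate: distinct metabolites are
rejection-sampled so that no pair is simultaneously close in RT (< 0.1
min) and close in mass at any isotope spacing (within 0.05 Da of
{0, 0.502, 1.003, 2.007}), so recovery oracles are exact rather than
probabilistic; and the per-dataset MGF carries the generating metabolite
id per entry as provenance, which the pipeline itself never reads —
recovery scoring re-identifies features only by consensus m/z and RT.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: chromatographic peak shapes and co-elution,
adduct/in-source-fragment redundancy, isotope fine structure beyond M+1,
retention drift between batches, shared substructures producing partial
spectral similarity between different compounds (synthetic templates are
independent, so molecular families rarely exceed one metabolite), and any
biology of fungal colonization — a shared metabolite is simply one whose
producer set contains the host and a strain.

## Study conditions used by the acceptance checks

The recovery checks run the full design (15 strains, 47 fractions,
triplicates) over 90 biological metabolites (40 host-only, 30
strain-specific, 10 multi-strain, 10 shared) plus 3 contaminants and 3
media metabolites, with a 140-entry library (90 true + 50 decoy entries).
The zero-noise run uses no detection limit — the perfect-information limit
in which the shared-category precision and recall and the rank-1
annotation accuracy must all be exactly 1. The moderate-noise run (σ =
0.3, dropout 0.1, defaults elsewhere, detection limit 1e4) must keep
shared recall at or above 0.8. These sizes keep a full end-to-end run in
the tens of seconds while leaving every stage non-trivially exercised.

## Numerical conventions and degenerate inputs

* All printed percentages use one rule: half *away from zero* at a fixed
  number of decimals (0 for headline shared percentages, 1 for enrichment
  percentages) — base R's round-half-even would print 0.25 as 0.2.
* ppm differences are symmetric (denominator = mean of the two masses).
* Ties are always broken deterministically: lexicographic ids for edge
  removal and consensus labels, (score, row, feature id) in alignment.
* Degenerate inputs have defined behavior: empty spectra score 0; an empty
  sample set aligns to an empty table; `top_k = 0` empties the edge set;
  an all-zero feature row is a normalization error, not a NaN; a missing
  crude extract yields a partial enrichment report with a flag; absence of
  blanks leaves the table unchanged with a warning.
* Every source of randomness flows from the design seed through R's RNG;
  identical (design, seed) gives byte-identical serialized outputs.

## Known limitations

The pipeline starts at per-sample feature lists: chromatogram building and
deconvolution from raw scans, gap-filling, and QC-based drift correction
are out of scope (QC samples are carried in metadata only). Class labels
come from the library/ground truth, not from a trained class-prediction
model, so consensus quality is bounded by library coverage. The
shared-cluster rule (one node present on both sides suffices) is the
weakest consistent reading of "a family containing both origins" and is
configurable rather than asserted as canonical. Negative ionization is
supported as a configuration tag only; defaults are tuned for
positive-mode data.
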