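---
title: "Mapping energy-metabolism pathway expression on the cortex: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping energy-metabolism pathway expression on the cortex: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(energymaps)
```

## The problem

Brain energy metabolism runs through a handful of interlocking biochemical
pathways — glycolysis, the pentose phosphate pathway (PPP), the TCA cycle,
oxidative phosphorylation (OXPHOS), and lactate metabolism and transport.
PET imaging measures glucose and oxygen uptake but cannot separate these
downstream pathways.  Bulk transcriptomics can: each pathway has a curated
set of nuclear-encoded genes, and the regional expression of those genes,
averaged over the set, yields a parcel-level cortical map of the pathway's
transcriptional capacity.  `energymaps` implements this analysis end to
end — gene-set curation, donor microarray processing, pathway map
construction, spatially aware inference, and developmental (lifespan)
trajectories — together with a synthetic-data module that generates every
input the pipeline consumes, so the whole analysis runs and is testable
without any external download.

## Gene-set curation

A pathway gene set is the intersection of two annotation exports (emulating
a GO biological-process export and a Reactome pathway export): a gene is
retained only when both knowledge bases annotate it to the pathway
(`consensus_gene_set()`).  Documented exclusions are then applied
(`apply_exclusions()`); the shipped exclusion list holds the hexokinase
isoenzymes, which catalyze the committed first step of both glycolysis and
the PPP and therefore cannot be attributed to either pathway alone.  Gene
symbols are upper-cased and whitespace-stripped; no alias resolution is
attempted (probe reannotation happens upstream of this package's inputs),
keeping curation deterministic and auditable.  Where one source uses
propagated child-term annotations and the other direct annotation, the
consensus rule operates on whatever rows the exports contain; the packaged
reference sets sidestep the question.

The five packaged reference sets (`load_energy_genesets()`) are a
*synthetic curation*: their file is named `energy_pathways_synthetic.tsv`
and membership was assembled from standard pathway biochemistry so that the
documented structure holds exactly — the TCA and OXPHOS sets share
precisely the three succinate dehydrogenase complex genes (SDHA, SDHB,
SDHC) active in both pathways, glycolysis and lactate share only the
regulatory enzyme gene *PFKFB2*, all other pairs are disjoint, the OXPHOS
set is dominated by nuclear-encoded complex I subunits, and the PPP set is
dominated by its non-oxidative branch (*RPIA*, *RPEL1*, *PRPS2*, *RBKS*)
plus *PGD* from the oxidative branch.  Mitochondrially encoded genes are
absent, as they are from microarray platforms.

## Donor microarray processing

`assemble_expression()` turns a list of donor sample tables (coordinates in
mm plus probe-by-sample intensities with above-background calls) into one
donor-averaged parcel-by-gene matrix:

1. **Probe intensity filter.**  Above-background calls are pooled across
   donors; a probe is kept only if it falls below background in *less than*
   50% of all samples (the exact-half case is discarded).
2. **Bilateral mirroring.**  Every sample acquires a duplicate with the
   x-coordinate negated, increasing spatial coverage under the assumption
   that regional expression is approximately hemispherically symmetric.
3. **Parcel assignment.**  A sample joins the parcel with the nearest
   same-hemisphere centroid if that distance is at most 2 mm (configurable);
   ties go to the lower parcel index; unassigned samples are discarded.
   The package is atlas-file-free: the 2 mm rule is evaluated against
   parcel centroids rather than voxel masks, a deliberate simplification
   that keeps the procedure's logic while removing all imaging I/O.
4. **Probe selection by differential stability.**  For genes indexed by
   several probes, each probe's regional profile (raw within-parcel
   averages) is correlated (Spearman) between every donor pair on the
   parcels sampled in both; the mean over pairs is the probe's differential
   stability (DS), and the probe with maximal DS wins (ties:
   lexicographically smaller probe id).  With a single donor DS is
   undefined; selection then falls back to the lexicographic rule and the
   DS filter below is skipped.
5. **Robust sigmoid normalization.**  Each sample's expression is passed
   through `1 / (1 + exp(-(x - median) / (IQR / 1.35)))` across genes, then
   min–max rescaled to [0, 1]; the identical transform is then applied per
   gene across samples.  The 1.35 constant is the IQR-to-sigma conversion
   for a normal distribution.  A zero-IQR vector maps to a flagged constant
   0.5.  The rescale is applied per normalization pass.
6. **Within-parcel averaging and interpolation.**  Samples assigned to the
   same parcel are averaged per donor; parcels left empty receive the
   inverse-distance-weighted mean of the 10 nearest samples (weights 1/d,
   distances floored at 0.1 mm), the parcel-level counterpart of mapping
   every voxel of a missing region to its nearest sample.
7. **Donor averaging and DS filter.**  Donor matrices are averaged and
   genes with DS strictly greater than 0.1 are retained.

One property worth knowing: the *cross-gene* normalization pass (step 5,
first pass) uses each sample's own median and IQR, which vary across the
cortex whenever many genes share a spatial factor.  The composed pipeline
is therefore not exactly rank-preserving per gene: with 60 independently
patterned genes, noiseless synthetic donors are recovered at a median
per-gene Spearman of about 0.98 rather than 1.0, and shared spatial signal
is partially absorbed by the normalization.  This is inherent to the
normalization design (it is what removes sample-level array effects), not
an implementation artifact; recovery tests use independently patterned
genes and require median rho >= 0.95.

## Pathway maps

`pathway_mean_map()` averages the expression matrix over a pathway's
available genes per parcel; `zscore_map()` standardizes a map to mean 0 and
population SD 1; `pathway_pc1_map()` computes the first principal component
of the parcel-by-pathway-gene submatrix.  PC1 uses correlation PCA (gene
columns centered and scaled): genes already share the [0, 1] scale but with
heterogeneous variances, and standardization stops high-variance genes from
dominating.  The PC1 sign is fixed by non-negative correlation with the
mean map, so the two summaries are directly comparable; on synthetic
cohorts with a dominant shared pathway factor they agree at Spearman
rho > 0.99.  Z-scoring is applied to the final donor-averaged map.
`group_mean()` aggregates any map over arbitrary parcel classes.

## Spatial inference

Parcel values on the cortex are spatially autocorrelated, so i.i.d.
permutation nulls overstate significance.  The package's null model
("spin" test) rotates parcel centroids on a sphere: per hemisphere,
centroids are projected onto the unit sphere about the hemisphere mean,
rotated by a Haar-uniform rotation (the right hemisphere by the sagittally
mirrored rotation M R M), and each original parcel is matched to a distinct
rotated parcel by scanning all pairs in ascending distance and accepting a
pair when both members are unassigned.  Every permutation is therefore a
hemisphere-closed bijection with no duplicate reassignments.

Two inference patterns are built on the ensemble:

* `spin_correlation_test()` — observed Spearman correlation of two maps
  against correlations of one map's spun versions with the other;
  two-sided p via `p = (1 + #{|null| >= |rho|}) / (n_rot + 1)`, so p is
  never below `1/(n_rot + 1)`.
* `class_enrichment_test()` — per-class mean of a z-scored map against the
  spun-map means over the same fixed mask; two-sided p measures deviation
  from the null median, with the direction reported.

Two-sided tests are the conservative default throughout; multiplicity is
handled with Benjamini–Hochberg FDR (`bh_fdr()`).  `degree_strength()`
provides the network covariates (count of nonzero connections; sum of
incident weights) for comparing maps against connectivity attributes.

### Calibration, and what the tests show

With 200 parcels per hemisphere and exponential spatial covariance of
correlation length 0.3 rad, the spin test rejects independent map pairs at
the nominal 5% rate (measured 0.052–0.054 over 1000 pairs spread across 10
independently seeded ensembles), while a naive i.i.d. permutation test on
the same pairs rejects at 20–35%.  Two design points matter here.  First,
the rejection rate *conditional on a single rotation ensemble* fluctuates
beyond binomial noise (we observed 0.050 and 0.072 on two single-ensemble
runs), so calibration is assessed unconditionally across several
ensembles; within one analysis run the package still fixes a single
serialized ensemble so that every test shares identical nulls.  Second,
the calibration study draws hemispherically independent fields
(`gp_maps(..., bilateral = "independent")`); with exactly mirrored
hemispheres the effective number of independent parcels halves and the
greedy matching's small distortion compounds, nudging the rate to ~0.066.
Real cortical maps sit between these extremes.

Detection power depends steeply on background smoothness.  A 1-SD mean
shift planted in a contiguous class of ~30 of 400 parcels is detected in
97% of runs when the background correlation length (0.1 rad) is well below
the class's angular radius (~0.31 rad), but on very smooth backgrounds
(0.3 rad) the same effect is frequently absorbed by the spin null and power
drops below 50%.  This is the test behaving as designed — a class-sized
bump on a class-sized-bumpy background is not distinguishable — but it
means class enrichment results on strongly autocorrelated maps should be
read as conservative.

## Lifespan trajectories

The developmental pipeline mirrors standard RNA-seq practice: (1)
`lifespan_cleanup()` keeps regions with at least one sample in every one of
the eight developmental stages, collapses duplicate gene symbols to their
first occurrence, and retains a gene only if at least 80% (inclusive) of
the samples in *every* retained region to stage cell express it at
RPKM >= 1 (strictest reading of the per-cell rule; a log2-signal >= 6
variant covers microarray inputs); (2) `log2_transform()` applies
log2(x + 1) — the +1 offset keeps the transform total at zero RPKM, which
the filter does not quite exclude; (3) `upper_quartile_normalize()` scales
each donor by its 75th percentile (type-7 quantile) times the mean 75th
percentile across donors, after which every donor's upper quartile is
identical; (4) `stage_trajectory()` takes the per-sample mean over pathway
genes and the per-stage median over samples; (5) `loess_trajectory()` fits
a locally weighted linear regression (tricube kernel, degree 1, span 0.75,
exact "direct" surface) against log10(age in post-conception days) on a
100-point grid.

The stage table (`default_stage_table()`) is the package's own
operationalization of the standard eight-stage binning, in post-conception
days with birth at 280: early fetal 56–91, mid fetal 91–182, late fetal
182–280, infancy 280–828 (~1.5 y), early childhood to ~6 y (2470), late
childhood to ~12 y (4660), adolescence to ~20 y (7580), adulthood to 40 y.
Lower bounds are inclusive.

## The synthetic cohort

`synthetic_spec()` fixes the generator's conditions; every generator is a
pure function of (spec, seed).  Defaults: 100 parcels per hemisphere, 6
donors of which 2 carry right-hemisphere samples (matching the typical
donor-atlas asymmetry), 60 genes in five pathway-named sets of 8–12 plus
background genes, exponential spatial kernel with correlation length
0.3 rad, within-donor intensity noise SD 0.5, 15% of parcels unsampled per
donor, 30% of genes carrying a decoy probe, 5% of probe-sample pairs
flagged below background, and lifespan noise SD 0.5 on the log2 scale with
3–6 cortical regions and 4 donors per stage.

Geometry: each hemisphere is its own full Fibonacci sphere (radius 35 mm,
centre offset 45 mm from the midline), the right an exact sagittal mirror
of the left.  Full spherical coverage per hemisphere is what makes
rotation-based nulls behave; volumetric centroids of a real hemisphere
likewise surround the hemisphere's own centre.  Class and network
annotations are contiguous k-means clusters of the left lattice, mirrored.

Planted structure: each gene's pattern is `w x (shared pathway factor) +
sqrt(1 - w^2) x (gene-specific field)` with `w = 0.7` by default, made
exactly bilaterally symmetric (the assumption under which sample mirroring
is valid), plus optional per-class mean shifts in field-SD units.  Decoy
probes shuffle the regional profile independently per donor, so their
cross-donor stability is low; faithful probes carry the suffix `_2` and
decoys `_1`, so a naive lexicographic choice would pick the decoy and
selection accuracy genuinely measures the DS criterion.  The lifespan
generator plants per-stage log2 shifts per pathway (defaults emulate the
canonical trajectories: ATP-producing pathways rising to a childhood peak;
the PPP-like set declining monotonically from fetal stages), one always-low
gene to exercise the expression filter, and one duplicated symbol to
exercise deduplication.

What the synthetic data does *not* emulate: cortical geometry beyond a
sphere, realistic probe counts (tens of probes rather than tens of
thousands), donor-specific batch effects beyond i.i.d. noise, non-stationary
or anisotropic spatial covariance, and any coupling between the microarray
and lifespan cohorts.  Passing tests therefore demonstrate that the
*procedures* are implemented correctly and behave as designed under
controlled conditions — not that any particular biological conclusion
transfers to real atlas data.

## Numerical choices and degenerate inputs

* Quantiles are type 7 (R's default) everywhere; IQR likewise.
* Spearman correlations use average ranks; zero rank variance is an
  explicit `NA` with a warning (and an error where a test statistic needs
  it).
* Tie-breaks are deterministic: lexicographic probe ids, lowest parcel
  index, first-encountered pair in the greedy spin matching.
* GP covariance matrices get 1e-8 diagonal jitter before Cholesky; with
  mirrored hemispheres the matrix is near-singular by construction and the
  jitter carries the factorization.
* The DS retention rule is strict (`DS > 0.1`); raising the threshold can
  only shrink the gene set.
* p-values use +1 smoothing and can never be exactly zero.
* Interpolation distances are floored at 0.1 mm so a sample coincident
  with a centroid cannot produce an infinite weight.

## Interfaces and problem sizes

The exported functions are the package's interface; `run_pipeline()` chains
curation inputs, assembly, maps, inference and trajectories into one
reproducible run that writes TSV artifacts plus a checksummed
`manifest.json` (rerunning with the same configuration and seed is
byte-identical; changing only the seed changes only the null ensembles).
All formats are plain text: parcel tables, donor TSV trios, gene-set TSVs,
permutation matrices with JSON sidecars.  The test-suite and acceptance
studies run at deliberately modest sizes — 400 parcels, 1000 rotations,
1000 calibration pairs, 100 power seeds, 50 lifespan seeds, 60 genes —
chosen so the full battery completes in a few minutes while leaving every
statistical conclusion comfortably resolved.

## Known limitations

* Parcel assignment and interpolation operate on centroids, not voxel
  masks; parcels with strongly non-convex shapes would be served better by
  point clouds (supported in principle by supplying denser "centroids").
* The greedy spin matching is the standard duplicate-free variant; it
  mildly degrades autocorrelation at coarse parcel resolutions, which is
  visible as the ~0.066 rejection rate under exactly mirrored map pairs.
* Differential stability uses pairwise-complete parcels; donors sampling
  disjoint parcel subsets would silently lower the effective pair count.
* The lifespan module assumes the upstream consortium normalization
  (conditional quantile, batch correction) has already happened; it applies
  only the documented cleanup, log2, and upper-quartile steps.
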