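---
title: "Predicting likely drug-resistance mutations in small-molecule targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting likely drug-resistance mutations in small-molecule targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resmutscan)
```

## The problem

Targeted cancer therapies fail when point mutations in the drug-binding site
of the target protein weaken inhibitor binding while sparing catalysis — the
classic example being the EGFR T790M gatekeeper mutation arising under
gefitinib treatment. Two questions decide whether a candidate mutation is a
clinical threat: *how likely is it to arise* in a given cancer type, and
*what does it do* to drug binding. `resmutscan` answers both with a single
pipeline:

1. **Mutation likelihood.** Cancer genomes accumulate substitutions through
   a small number of mutational processes, each with a characteristic
   probability profile over the 96 trinucleotide-context substitutions
   (written `A[C>T]G`: 5' flank, substitution, 3' flank). Given a signature
   catalog and the per-cancer-type contribution (exposure) of each
   signature, the likelihood of an amino-acid change is
   $$L_{m,c} = \sum_{s \in M(m)} \sum_{k \in S(c)} W_{k,c}\, P_{s,k},$$
   where $M(m)$ are all single-nucleotide substitutions producing the
   amino-acid change $m$ (several codon changes can yield the same residue),
   $W_{k,c}$ is the exposure of signature $k$ in cancer type $c$, and
   $P_{s,k}$ is that signature's probability for the substitution in its
   context.
2. **Resistance impact.** For every binding-site mutation a mutant
   structural model is built, a schema-fixed feature vector describing the
   wild-type/mutant pair is extracted, and a four-class random forest
   predicts the phenotype: strong resistance (SRES, ≥ 5-fold affinity drop),
   resistance (RES, 1.2–5-fold drop), neutral (NEU, inside the 1.2-fold
   band) or increased sensitivity (ISEN, ≥ 1.2-fold gain). Class
   confidences are combined into the Resistance Score
   $$RS = S_{SRES} P_{SRES} + S_{RES} P_{RES} - S_{NEU} P_{NEU} - S_{ISEN} P_{ISEN},$$
   where $S_x$ are the tree-vote confidences and $P_x$ the per-class
   cross-validation precisions; within one scored experiment RS values are
   min–max rescaled to the normalized score NRS ∈ [0, 1].
3. **Alternative inhibitors.** A ligand-schema classifier scores every
   (mutation, candidate compound) pair into a sensitivity map, and mutations
   are grouped as hardly/easily/targetable depending on how many compounds
   retain predicted activity.

## Strand handling in the likelihood model

Signature catalogs are published over the 96 pyrimidine-context
substitutions. Because the coding sequence is read on a fixed strand, the
catalog is extended to all 192 contexts: a purine-context substitution takes
the probability of its reverse-complement pyrimidine context. Signatures
with a strong transcriptional strand bias are the exception — their purine
contexts are set to zero, with no renormalisation (the flagged set defaults
to signatures 4, 7, 11, 22, 24 and 29, and the rule is configurable per
signature since only the ultraviolet signature's rule is documented
explicitly; `bias_rules` of `extend_to_full_context()` accepts a
replacement). Context flanks are always read on the coding strand; codons at
the extreme ends of the CDS lack a flank, get an `N` placeholder, and
contribute zero likelihood with a warning.

Enrichment of a substitution class among the top of a ranked landscape is
measured by the classical 2×2 odds ratio at a cut rank (default 50). The
Haldane–Anscombe +0.5 correction is applied to all four cells whenever one
is empty, so scans across top ranks stay finite; a class absent from the
whole landscape yields a flagged `NA` rather than an error. Ranking ties are
broken deterministically by (position, then replacement residue).

## Structural modelling choices

The binding site is the residue set with any heavy atom within 9.5 Å of the
co-crystallized ligand; hydrogens are excluded by default because most
crystal structures do not resolve them (configurable). Mutant models are
produced by a pluggable backend. The default `graft` backend removes the
side chain of the mutated residue and grows an idealized replacement from
the unchanged backbone (tetrahedral CB placement, extended side chains,
planar aromatic rings); no other atom moves, so backbone RMSD between wild
type and mutant is exactly zero and the features downstream are fully
deterministic. An `external` backend hook accepts a user command for
comparative-modelling engines; truncating (stop-gained) mutations are never
modelled.

## Feature schemas

The feature registry is the source of truth for what the classifiers see.
Two schemas are defined: `aa-v1` (237 values) for the amino-acid-level
classifier and `lig-v1` (241 values) for the ligand-level one. Both share a
core: binding-site and residue surface areas with relative solvent
accessibility (in-house Shrake–Rupley integrator, 960 lattice points per
atom, 1.4 Å probe, Tien 2013 theoretical maxima as RSA denominators), the
20-position mutation vector (−1 wild type, +1 mutant), hydrogen bonding to
the ligand (N/O/F heavy-atom pairs at ≤ 3.2 Å), six annular 0–6 Å
structural-environment shells encoded as 20-length presence vectors, the ±5
sequence window, a three-state secondary-structure label, a documented
stability surrogate, BLOSUM62 column conservation (when an alignment is
supplied), raw and outlier-refined superposition RMSD, CA-to-ligand
distance statistics, the charge-annotated mutation vector, the
Kyte–Doolittle hydrophobicity delta, and the measured wild-type affinity as
log10(nM) plus measure type. `aa-v1` adds half-sphere exposure (13 Å
radius, glycine pseudo-CB from backbone geometry), protein–protein
salt-bridge counts (≤ 4.0 Å) and disulfide checks (SG–SG within
1.8–2.2 Å). `lig-v1` drops those and adds the protein–ligand interaction
fingerprint: halogen bonds (≤ 4.0 Å, C–X⋯A angle ≥ 140°), π-stacking
(centroids ≤ 5.5 Å, parallel within 30° or T-shaped at 60–90°), π-cation
(≤ 6.0 Å), water bridges (both polar distances ≤ 3.6 Å) and hydrophobic
contacts (apolar C–C ≤ 4.0 Å) — the published defaults of the standard
interaction-profiler family, pinned in `FINGERPRINT_DEFAULTS`.

Design notes on points the feature definitions leave open:

* The historical feature counts (58 and 89) enumerate feature *items*
  before one-hot expansion; the expanded lengths are defined by the
  registry (`feature_schema()`), which documents the exact ordering.
* The structural-environment shells are *annular* (0,1], …, (5,6] rather
  than cumulative, avoiding six nearly collinear encodings of the same
  neighbourhood.
* Missing values never enter the vectors: a missing family is encoded as
  sentinel 0 with a parallel `*_known` indicator set to 0 (and provenance
  `"unknown"`), so tree models can split on missingness.
* The secondary-structure assigner is a backbone-dihedral classifier
  (helix for φ ∈ [−100°, −30°], ψ ∈ [−80°, −5°]; strand for
  φ ∈ [−180°, −45°] with ψ ≥ 90° or ≤ −150°; coil otherwise). A
  hydrogen-bond-pattern assigner needs amide protons and full DSSP
  energetics that neither crystal inputs nor the graft backend provide; the
  dihedral windows reproduce the canonical assignments on ideal geometries
  and are deterministic. Residues without a complete ±1 backbone window
  fall back to coil with `known = FALSE`.
* The stability backend is an interface. The bundled default is an explicit
  surrogate, not a reimplementation of any external predictor:
  ΔΔG = 0.4 (h_mt − h_wt)(1 − RSA_wt) − 0.02 |V_mt − V_wt| kcal/mol
  (Kyte–Doolittle hydropathy h, residue volume V). Its sign gives the
  STABLE/UNSTABLE category; a failing backend yields UNKNOWN, mirroring the
  unscored fraction seen with external predictors.
* Ligand aromatic rings are perceived as planar 5/6-cycles of C/N atoms
  from distance-inferred connectivity; an annotation list can override
  perception for exotic chemistry.

## Classifier protocol

Training tables follow a measured-affinity layout (id, mutation,
n_mutations, structure paths, wild-type/mutant affinities, measure type,
ligand id). Rows with more than one mutation are removed — the classifier
assesses single substitutions — and the drop-oriented fold change
(mutant / wild-type value, > 1 is worse binding) assigns labels. The exact
1.2 boundary goes outward (RES or ISEN; the NEU band is open), because the
resistant band is defined as a 1.2-fold-or-greater drop and the sensitive
band as a 1.2-fold-or-greater gain. The over-represented SRES and RES
classes are down-sampled (seeded) to a cap of 180; NEU stays at its natural
size — no oversampling. Forests use 1000 trees, 20 candidate features per
split and unlimited depth. Evaluation is stratified 10-fold
cross-validation with per-class one-vs-rest AUC, precision, recall, the
unweighted mean AUC (macro averaging), and Cohen's kappa from the pooled
out-of-fold confusion matrix; a class smaller than k reduces k with a
warning rather than failing. Argmax ties resolve by the fixed order
SRES > RES > NEU > ISEN and are flagged. The precision weights of the
Resistance Score are per-class CV *precision* (the per-class quantity
reported alongside the score's definition), configurable to recall by
passing a different vector. An affinity-only baseline
(`affinity_only_baseline()`) trains the same protocol on just two
externally predicted affinities, as a floor for what structure-blind
scoring achieves; docking itself is consumed, never performed.

## What the synthetic fixtures emulate

`make_fixture_bundle()` generates every input format offline: valid
96-context catalogs (random simplex draws — format and normalisation
validity, *not* realistic signature shapes), exposure profiles, an
extended-chain toy complex with idealized side chains, a small aromatic
ligand and a bridging water, a CDS that translates exactly to the
structure, boundary-geometry structures that sit exactly at each detector
cutoff (9.4/9.6 Å site membership, 3.19/3.21 Å hydrogen bonds, 2.0/2.3 Å
disulfides, 3.9/4.1 Å salt bridges), and training tables whose class
signal is *planted in physically meaningful features*: the mutant ligand is
displaced along the residue–ligand axis by a class-dependent amount
(+2.5 Å SRES, +1.0 Å RES, 0 NEU, −1.0 Å ISEN at unit signal strength,
0.15 Å isotropic noise, 0.05 Å coordinate jitter), so the signal must
survive mutant building and feature extraction — not just classifier
fitting — to be recovered. Fold changes are drawn inside each class's band,
so relabelling from affinities reproduces the intended classes exactly.
Multi-mutant decoy rows exercise the single-mutant filter. Regeneration
under a fixed seed is byte-identical.

What passing these tests shows — and does not. They demonstrate that the
likelihood algebra, the geometric detectors, the feature plumbing and the
training/scoring protocol are correct and that a genuine structural signal
of the planted kind is recovered essentially perfectly (cross-validated
mean AUC ≥ 0.95 at high signal, chance-level AUC under label shuffling).
They do not certify accuracy on real crystal structures, where signal is
weaker, features are correlated and label noise is substantial; reported
real-data performance of this class of classifier is far from perfect, and
nothing in the synthetic design emulates that difficulty.

## Problem sizes and numerics

The packaged experiments use an 8-residue toy complex (≈ 65 heavy atoms),
the balanced 180/180/70/180 training design (610 instances) and 10-fold
cross-validation; the surface integrator runs at 960 points per atom by
default (test fixtures drop to 240 where only deltas matter — the lattice
is deterministic, so identical pairs still cancel exactly). Probability
sums are validated to 1e-3 on parsing; likelihood equality to the
brute-force oracle holds to 1e-12. Degenerate cases are defined, not
special-cased ad hoc: an all-equal RS batch normalises to zeros with a
warning flag, an absent substitution class yields a flagged undefined odds
ratio, unmappable structure residues are skipped with a report.

## Known limitations

* Likelihoods are population-level: exposures are per cancer *type*, not
  per tumour, and germ-line or pre-malignant variation is out of scope.
* The graft backend never moves the backbone, so mutations whose effect is
  mediated by backbone rearrangement (e.g. proline insertions into a helix)
  are only captured through side-chain geometry.
* The model applies to non-covalent, reversible inhibitors only.
* Real-data headline numbers depend on external versioned resources
  (structure and affinity databases, signature catalogs); the package
  validates against oracles and constructed fixtures instead.

## A worked run

```{r example, eval = FALSE}
bundle <- make_fixture_bundle(seed = 1)
catalog <- extend_catalog(parse_signature_catalog(
  bundle$signatures$catalog, biased_ids = bundle$signatures$biased_id))
exposure <- read_exposure_profile(bundle$signatures$exposures[1])
cds <- read_cds_fasta(bundle$complex$cds_fasta)
wt <- load_complex(bundle$complex$pdb, "LIG")
site <- define_binding_site(wt)                   # 9.5 A default
land <- likelihood_landscape(cds, site$residues$resno, exposure, catalog)
head(land)

ts <- build_training_set(bundle$training$csv, seed = 1)
cv <- cross_validate(ts, k = 10, seed = 1)
model <- set_class_precisions(train_classifier(ts, seed = 1), cv)
mut <- enumerate_binding_site_mutants(site, cds)[[3]]
mt <- build_mutant_model(wt, mut)
fv <- extract_features(wt, mt$structure, site, mut, feature_schema("aa-v1"),
                       wt_affinity_nM = 25, measure = "IC50")
sc <- predict_scores(model, fv)
resistance_score(sc, model$precisions)
```
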