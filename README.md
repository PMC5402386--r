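# resmutscan

Prospective prediction of drug-resistance point mutations in
small-molecule cancer-therapy targets.

Resistance to targeted therapies frequently arises from single amino-acid
substitutions in the drug-binding site — EGFR T790M under gefitinib being
the canonical case. `resmutscan` ranks *which* binding-site mutations are
likely to arise in a given cancer type and *what* each would do to drug
binding, then screens candidate compounds for alternatives that remain
active. It is written for computational structural biologists and drug
hunters working on kinase-inhibitor-class (non-covalent, reversible)
therapies.

## The model

**Likelihood.** Cancer mutational processes are summarised as signatures:
probability profiles over the 96 trinucleotide-context substitutions
(`A[C>T]G` notation). With per-cancer-type exposures W and the catalog
extended to all 192 strand-resolved contexts (purine contexts mirror their
reverse complement; strand-biased signatures have them zeroed), the
likelihood of an amino-acid mutation m in cancer type c is

    L(m, c) = sum over causal SNVs s of m, sum over signatures k:
              W[k, c] * P[s, k]

grouping every nucleotide change that yields the same residue. Class
enrichment among the top of a ranked landscape is a 2x2 odds ratio with
Haldane-Anscombe correction.

**Resistance.** For each SNV-reachable binding-site mutation (residues with
any heavy atom within 9.5 Å of the co-crystallized ligand) a mutant model
is built on the fixed backbone, a schema-versioned feature vector is
extracted (surface areas and RSA, half-sphere exposure, hydrogen bonds,
structural-environment shells, secondary structure, stability surrogate,
conservation, superposition RMSD, ligand distances, charge and
hydrophobicity, salt bridges, disulfides, and — for the ligand-level
schema — a full protein-ligand interaction fingerprint), and a 1000-tree
random forest assigns confidences over four phenotypes: SRES (≥ 5-fold
affinity drop), RES (1.2–5-fold), NEU (within the 1.2-fold band), ISEN
(≥ 1.2-fold gain). Confidences combine into the precision-weighted
Resistance Score

    RS = S_SRES * P_SRES + S_RES * P_RES - S_NEU * P_NEU - S_ISEN * P_ISEN

min-max normalised to NRS within an experiment. A mutations × compounds
NRS matrix (sensitivity map) nominates alternative inhibitors and groups
mutations as hardly / easily / targetable.

## Worked example

Everything below runs offline on the bundled synthetic-fixture generator
(seeded, byte-reproducible):

```r
library(resmutscan)
bundle  <- make_fixture_bundle(seed = 1)
catalog <- extend_catalog(parse_signature_catalog(
  bundle$signatures$catalog, biased_ids = bundle$signatures$biased_id))
exposure <- read_exposure_profile(bundle$signatures$exposures[1])
cds  <- read_cds_fasta(bundle$complex$cds_fasta)
wt   <- load_complex(bundle$complex$pdb, "LIG")
site <- define_binding_site(wt)          # <binding_site: 6 residues within 9.5 A>
land <- likelihood_landscape(cds, site$residues$resno, exposure, catalog)
head(land, 5)
#>   position ref_aa alt_aa likelihood dominant_substitution rank
#> 1        6      Q      K 0.02015123                   C>A    1
#> 2        5      F      I 0.01595856                   T>A    2
#> 3        5      F      Y 0.01595856                   T>A    3
#> 4        3      K      I 0.01579555                   T>A    4
#> 5        4      C      R 0.01503437                   T>C    5
```

Likelihoods are dimensionless sums of exposure-weighted context
probabilities: Q6K ranks first because its causal `C>A` context draws high
probability under this exposure profile. Training and scoring:

```r
ts <- build_training_set(bundle$training$csv, seed = 1)
cv <- cross_validate(ts, k = 5, seed = 1,
                     params = list(ntree = 300, mtry = 20, maxnodes = NULL))
cv
#> <cv_report: 5-fold, mean AUC 0.982, kappa 0.796>
#>   SRES AUC 1.000 precision 1.000 recall 0.917
#>   RES  AUC 0.958 precision 0.769 recall 0.833
#>   NEU  AUC 1.000 precision 1.000 recall 0.900
#>   ISEN AUC 0.968 precision 0.692 recall 0.750
model <- set_class_precisions(train_classifier(ts, seed = 1,
           params = list(ntree = 300, mtry = 20, maxnodes = NULL)), cv)

mut <- enumerate_binding_site_mutants(site, cds)[[3]]   # S1F
mt  <- build_mutant_model(wt, mut)                       # graft backend
fv  <- extract_features(wt, mt$structure, site, mut, feature_schema("aa-v1"),
                        wt_affinity_nM = 25, measure = "IC50")
sc  <- predict_scores(model, fv)
round(sc$scores, 3)
#>  SRES   RES   NEU  ISEN
#> 0.107 0.147 0.690 0.057        # class: NEU
resistance_score(sc, model$precisions)
#> [1] -0.5097
```

A negative RS means the neutral/sensitive confidences outweigh the
resistant ones — this substitution is not predicted to threaten the
treatment. `screen_compounds()` repeats this per candidate compound and
`classify_targetability()` summarises each mutation's escape options.

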