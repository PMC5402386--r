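# Shared fixtures, built once per test run.

.toy_cache <- new.env()

toy_fixture <- function() {
  if (is.null(.toy_cache$toy)) {
    .toy_cache$toy <- suppressWarnings(make_toy_complex(8, seed = 42))
    .toy_cache$wt <- load_complex(.toy_cache$toy$pdb, "LIG")
    .toy_cache$cds <- read_cds_fasta(.toy_cache$toy$cds_fasta)
    .toy_cache$site <- define_binding_site(.toy_cache$wt)
    .toy_cache$mutants <- suppressWarnings(
      enumerate_binding_site_mutants(.toy_cache$site, .toy_cache$cds))
  }
  .toy_cache
}

small_training_fixture <- function() {
  if (is.null(.toy_cache$ts)) {
    tt <- suppressWarnings(make_toy_training_table(
      c(SRES = 12, RES = 12, NEU = 10, ISEN = 12),
      signal_strength = 1, seed = 7))
    ts <- suppressWarnings(build_training_set(tt$csv, seed = 7))
    .toy_cache$tt <- tt
    .toy_cache$ts <- ts
    .toy_cache$cv <- suppressWarnings(cross_validate(
      ts, k = 5, params = list(ntree = 300, mtry = 20, maxnodes = NULL),
      seed = 7))
    model <- train_classifier(ts, params = list(ntree = 300, mtry = 20,
                                                maxnodes = NULL), seed = 7)
    .toy_cache$model <- set_class_precisions(model, .toy_cache$cv)
  }
  .toy_cache
}

# Random extended in-memory catalog + exposure for likelihood property tests.
random_catalog <- function(n_sig, biased = character(0)) {
  ids <- as.character(seq_len(n_sig))
  sigs <- lapply(ids, function(id) {
    p <- stats::rexp(96)
    p <- stats::setNames(p / sum(p), resmutscan:::PYRIMIDINE_CONTEXTS)
    resmutscan:::new_mut_signature(id, p, strand_biased = id %in% biased)
  })
  names(sigs) <- ids
  extend_catalog(sigs)
}

random_exposure <- function(ids) {
  exposure_profile(stats::setNames(stats::runif(length(ids), 0.01, 0.3), ids))
}

random_aa_mutation <- function(n_snv = 2) {
  bases <- c("A", "C", "G", "T")
  snvs <- lapply(seq_len(n_snv), function(i) {
    ref <- sample(bases, 1)
    list(codon_position = sample(1:3, 1), ref_base = ref,
         alt_base = sample(setdiff(bases, ref), 1),
         fiveprime = sample(bases, 1), threeprime = sample(bases, 1))
  })
  resmutscan:::new_aa_mutation(10L, "T", "M", snvs)
}

# Independent brute-force likelihood: an explicit double loop over SNVs and
# signatures reading the probability maps directly.
brute_force_likelihood <- function(m, exposure, catalog) {
  total <- 0
  for (snv in m$causal_snvs) {
    key <- paste0(snv$fiveprime, "[", snv$ref_base, ">", snv$alt_base, "]",
                  snv$threeprime)
    for (id in names(exposure$weights)) {
      w <- exposure$weights[[id]]
      if (w > 0) total <- total + w * catalog[[id]]$probs[[key]]
    }
  }
  total
}

# Random atom-cloud complex for binding-site oracle tests.
random_complex <- function(n_res = 8, atoms_per_res = 3, n_lig = 4) {
  rows <- list()
  for (r in seq_len(n_res)) {
    centre <- stats::runif(3, -12, 12)
    for (a in seq_len(atoms_per_res)) {
      rows[[length(rows) + 1]] <- data.frame(
        type = "ATOM", eleno = 0L, elety = if (a == 1) "CA" else paste0("C", a),
        resid = "ALA", chain = "A", resno = r,
        x = centre[1] + stats::rnorm(1), y = centre[2] + stats::rnorm(1),
        z = centre[3] + stats::rnorm(1), o = 1, b = 0, element = "C",
        stringsAsFactors = FALSE)
    }
  }
  for (a in seq_len(n_lig)) {
    rows[[length(rows) + 1]] <- data.frame(
      type = "HETATM", eleno = 0L, elety = paste0("C", a), resid = "LIG",
      chain = "A", resno = 500L, x = stats::rnorm(1, sd = 2),
      y = stats::rnorm(1, sd = 2), z = stats::rnorm(1, sd = 2),
      o = 1, b = 0, element = "C", stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  at$eleno <- seq_len(nrow(at))
  complex_model(at, "LIG", "random toy")
}

# Rigid-body transform of a complex model.
transform_complex <- function(model, rot, shift) {
  move <- function(at) {
    if (!nrow(at)) return(at)
    at[, c("x", "y", "z")] <- sweep(as.matrix(at[, c("x", "y", "z")]) %*% t(rot),
                                    2, shift, "+")
    at
  }
  model$protein <- move(model$protein)
  model$ligand <- move(model$ligand)
  model$water <- move(model$water)
  model
}
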