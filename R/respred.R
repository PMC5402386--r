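## Four-class resistance-phenotype prediction: training-set construction
## from an affinity fold-change table, random-forest training,
## cross-validation, and the precision-weighted Resistance Score.

#' The four resistance phenotype classes, in fixed order
#'
#' SRES (strong resistance, >=5-fold affinity drop), RES (1.2- to 5-fold
#' drop), NEU (within the 1.2-fold band) and ISEN (>=1.2-fold affinity
#' gain).  The order is also the argmax tie-break order.
#' @export
PHENOTYPE_CLASSES <- c("SRES", "RES", "NEU", "ISEN")

#' Phenotype label from a drop-oriented affinity fold change
#'
#' The fold change is mutant affinity value over wild-type value for
#' Kd/Ki/IC50 measures, so values > 1 mean weaker binding.  SRES for a
#' >=5-fold drop; RES for a drop in [1.2, 5); NEU inside the open
#' (1/1.2, 1.2) band; ISEN for a >=1.2-fold increase (fold <= 1/1.2).  The
#' 1.2 boundaries are assigned outward (RES / ISEN); the NEU band is open.
#'
#' @param fold positive fold change (vectorised).
#' @return factor with levels \code{PHENOTYPE_CLASSES}.
#' @export
label_from_fold_change <- function(fold) {
  if (any(!is.finite(fold) | fold <= 0)) stop("fold changes must be finite and > 0")
  lab <- ifelse(fold >= 5, "SRES",
         ifelse(fold >= 1.2, "RES",
         ifelse(fold <= 1 / 1.2, "ISEN", "NEU")))
  factor(lab, levels = PHENOTYPE_CLASSES)
}

#' Parse a protein mutation label such as "T790M"
#' @param label character like \code{"T790M"}.
#' @return An \code{aa_mutation} (with no causal SNVs attached).
#' @export
parse_mutation <- function(label) {
  m <- regmatches(label, regexec("^([A-Z])([0-9]+)([A-Z])$", label))[[1]]
  if (length(m) != 4 || !(m[2] %in% AA1) || !(m[4] %in% AA1))
    stop("cannot parse mutation label '", label, "'")
  new_aa_mutation(as.integer(m[3]), m[2], m[4], list())
}

#' Build a training set from an affinity fold-change table
#'
#' The table (CSV) follows the layout: id, protein, mutation (e.g. T790M),
#' n_mutations, wt_structure, mt_structure, affinity_wt, affinity_mt,
#' measure (Ki|Kd|IC50), ligand_id.  Rows with more than one mutation are
#' removed (the classifier assesses single mutations), labels are assigned
#' from the fold change (affinity_mt / affinity_wt), the over-represented
#' SRES and RES classes are down-sampled uniformly at random (seeded) to
#' \code{cap}, and features are extracted for every surviving instance.
#' Instances whose structures cannot be loaded are dropped and logged.
#'
#' @param table path to the CSV, or a data.frame.
#' @param schema a \code{feature_schema} (default aa-v1).
#' @param seed integer seed for the down-sampling.
#' @param cap per-class cap applied to SRES and RES (default 180).
#' @param offset residue-number offset between structures and mutation
#'   labels.
#' @param n_points surface-integrator density passed through to
#'   \code{\link{extract_features}}.
#' @return A \code{training_set}: list(features = numeric matrix, labels =
#'   factor, table = kept rows, report = list of removal logs).
#' @export
build_training_set <- function(table, schema = feature_schema("aa-v1"),
                               seed = 1, cap = 180, offset = 0,
                               n_points = 960) {
  tab <- if (is.data.frame(table)) table
  else utils::read.csv(table, stringsAsFactors = FALSE)
  req <- c("id", "mutation", "n_mutations", "wt_structure", "mt_structure",
           "affinity_wt", "affinity_mt", "measure", "ligand_id")
  stopifnot(all(req %in% names(tab)))
  report <- list()

  multi <- tab$n_mutations > 1
  report$multi_mutant_removed <- tab$id[multi]
  tab <- tab[!multi, , drop = FALSE]

  fold <- tab$affinity_mt / tab$affinity_wt
  tab$fold_change <- fold
  tab$label <- as.character(label_from_fold_change(fold))

  set.seed(seed %% .Machine$integer.max)
  keep <- logical(nrow(tab))
  for (cls in PHENOTYPE_CLASSES) {
    idx <- which(tab$label == cls)
    if (cls %in% c("SRES", "RES") && length(idx) > cap)
      idx <- sort(sample(idx, cap))
    keep[idx] <- TRUE
  }
  report$downsampled_out <- tab$id[!keep]
  tab <- tab[keep, , drop = FALSE]

  feats <- vector("list", nrow(tab))
  failed <- character(0)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    fv <- try({
      wt <- load_complex(row$wt_structure, row$ligand_id)
      mt <- load_complex(row$mt_structure, row$ligand_id)
      site <- define_binding_site(wt)
      spec <- parse_mutation(row$mutation)
      extract_features(wt, mt, site, spec, schema,
                       wt_affinity_nM = row$affinity_wt,
                       measure = row$measure, offset = offset,
                       n_points = n_points)
    }, silent = TRUE)
    if (inherits(fv, "try-error")) failed <- c(failed, row$id)
    else feats[[i]] <- fv
  }
  report$structure_failed <- failed
  ok <- !vapply(feats, is.null, logical(1))
  tab <- tab[ok, , drop = FALSE]
  feats <- feats[ok]
  features <- if (length(feats))
    do.call(rbind, lapply(feats, function(f) f$values))
  else matrix(numeric(0), nrow = 0, ncol = length(schema$features),
              dimnames = list(NULL, schema$features))
  rownames(features) <- tab$id
  structure(list(features = features,
                 labels = factor(tab$label, levels = PHENOTYPE_CLASSES),
                 table = tab, schema = schema, report = report),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set %s: %d instances x %d features; %s>\n",
              x$schema$name, nrow(x$features), ncol(x$features),
              paste(names(table(x$labels)), table(x$labels),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Default random-forest parameters
#'
#' 1000 trees, 20 candidate features per split, unlimited depth.
#' @export
default_rf_params <- function() list(ntree = 1000, mtry = 20, maxnodes = NULL)

#' Train a four-class resistance random forest
#'
#' @param ts a \code{training_set}.
#' @param params list(ntree, mtry, maxnodes); see
#'   \code{\link{default_rf_params}}.
#' @param seed integer seed.
#' @return A \code{resistance_classifier} embedding the schema id, seed and
#'   parameters; class precisions are attached by
#'   \code{\link{cross_validate}} via \code{\link{set_class_precisions}}.
#' @export
train_classifier <- function(ts, params = default_rf_params(), seed = 1) {
  stopifnot(inherits(ts, "training_set"))
  if (nlevels(droplevels(ts$labels)) < 2)
    stop("training set must contain at least two classes")
  set.seed(seed %% .Machine$integer.max)
  rf <- randomForest::randomForest(
    x = ts$features, y = droplevels(ts$labels),
    ntree = params$ntree,
    mtry = min(params$mtry, ncol(ts$features)),
    maxnodes = params$maxnodes)
  structure(list(rf = rf, schema_name = ts$schema$name, seed = seed,
                 params = params, classes = levels(droplevels(ts$labels)),
                 precisions = NULL),
            class = "resistance_classifier")
}

#' @export
print.resistance_classifier <- function(x, ...) {
  cat(sprintf("<resistance_classifier (%s): %d trees, classes %s>\n",
              x$schema_name, x$params$ntree, paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Attach per-class cross-validation precisions to a classifier
#' @param model a \code{resistance_classifier}.
#' @param cv a \code{cv_report} (or a named precision vector).
#' @export
set_class_precisions <- function(model, cv) {
  prec <- if (inherits(cv, "cv_report")) cv$precision else cv
  model$precisions <- prec
  model
}

stratified_folds <- function(labels, k, seed) {
  set.seed(seed %% .Machine$integer.max)
  fold <- integer(length(labels))
  for (cls in levels(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the resistance classifier
#'
#' Reports per-class one-vs-rest AUC, precision and recall from pooled
#' out-of-fold predictions, the unweighted mean AUC, Cohen's kappa and the
#' 4x4 confusion matrix.  If the smallest class has fewer than k members, k
#' is reduced with a warning.
#'
#' @param ts a \code{training_set}.
#' @param k number of folds (default 10).
#' @param params random-forest parameters.
#' @param seed integer seed (folds and forests).
#' @return A \code{cv_report}.
#' @export
cross_validate <- function(ts, k = 10, params = default_rf_params(), seed = 1) {
  stopifnot(inherits(ts, "training_set"))
  labels <- droplevels(ts$labels)
  classes <- levels(labels)
  nmin <- min(table(labels))
  if (nmin < k) {
    warning("smallest class has ", nmin, " members; reducing k to ", nmin)
    k <- nmin
  }
  fold <- stratified_folds(labels, k, seed)
  n <- length(labels)
  probs <- matrix(NA_real_, n, length(classes), dimnames = list(NULL, classes))
  pred <- character(n)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    set.seed((seed + f) %% .Machine$integer.max)
    rf <- randomForest::randomForest(
      x = ts$features[tr, , drop = FALSE], y = droplevels(labels[tr]),
      ntree = params$ntree, mtry = min(params$mtry, ncol(ts$features)),
      maxnodes = params$maxnodes)
    p <- stats::predict(rf, ts$features[te, , drop = FALSE], type = "prob")
    probs[te, colnames(p)] <- p
    pred[te] <- apply(p, 1, function(r) argmax_class(r, colnames(p)))
  }
  probs[is.na(probs)] <- 0
  pred <- factor(pred, levels = classes)
  conf <- table(truth = labels, predicted = pred)
  auc <- vapply(classes, function(cls) {
    resp <- as.integer(labels == cls)
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(resp, probs[, cls], quiet = TRUE,
                         direction = "<", levels = c(0, 1)))
  }, numeric(1))
  precision <- vapply(classes, function(cls) {
    tp <- conf[cls, cls]; pp <- sum(conf[, cls])
    if (pp == 0) NA_real_ else tp / pp
  }, numeric(1))
  recall <- vapply(classes, function(cls) {
    tp <- conf[cls, cls]; ap <- sum(conf[cls, ])
    if (ap == 0) NA_real_ else tp / ap
  }, numeric(1))
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- (po - pe) / (1 - pe)
  structure(list(auc = auc, mean_auc = mean(auc, na.rm = TRUE),
                 precision = precision, recall = recall, kappa = kappa,
                 confusion = conf, k = k, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d-fold, mean AUC %.3f, kappa %.3f>\n",
              x$k, x$mean_auc, x$kappa))
  for (cls in names(x$auc))
    cat(sprintf("  %-4s AUC %.3f precision %.3f recall %.3f\n", cls,
                x$auc[cls], x$precision[cls], x$recall[cls]))
  invisible(x)
}

## Argmax with the fixed SRES > RES > NEU > ISEN tie order.
argmax_class <- function(scores, classes) {
  ord <- intersect(PHENOTYPE_CLASSES, classes)
  scores <- scores[ord]
  ord[which.max(scores)]
}

#' Class-confidence scores for a feature vector
#'
#' Tree-vote fractions for the four phenotypes; they sum to 1.  The
#' predicted class is the argmax, ties broken by the fixed class order
#' (SRES > RES > NEU > ISEN) and flagged.
#'
#' @param model a \code{resistance_classifier}.
#' @param fv a \code{feature_vector}, a named numeric vector, or a matrix of
#'   rows in schema order.
#' @return A \code{class_scores}: list(scores, class, tie) for a single
#'   input; a data.frame for matrix input.
#' @export
predict_scores <- function(model, fv) {
  stopifnot(inherits(model, "resistance_classifier"))
  x <- if (inherits(fv, "feature_vector")) {
    if (!identical(fv$schema$name, model$schema_name))
      stop("feature vector schema (", fv$schema$name,
           ") does not match the model (", model$schema_name, ")")
    matrix(fv$values, nrow = 1, dimnames = list(NULL, names(fv$values)))
  } else if (is.matrix(fv)) fv
  else matrix(fv, nrow = 1, dimnames = list(NULL, names(fv)))
  p <- stats::predict(model$rf, x, type = "prob")
  out <- lapply(seq_len(nrow(p)), function(i) {
    sc <- p[i, ]
    full <- stats::setNames(rep(0, 4), PHENOTYPE_CLASSES)
    full[colnames(p)] <- sc
    cls <- argmax_class(full, PHENOTYPE_CLASSES)
    tie <- sum(abs(full - max(full)) < 1e-12) > 1
    structure(list(scores = full, class = cls, tie = tie),
              class = "class_scores")
  })
  if (length(out) == 1) out[[1]] else out
}

#' Precision-weighted Resistance Score
#'
#' \deqn{RS = S_{SRES} P_{SRES} + S_{RES} P_{RES} - S_{NEU} P_{NEU} -
#'       S_{ISEN} P_{ISEN}}
#' where S are the class-confidence scores and P the per-class
#' cross-validation precisions.
#'
#' @param scores a \code{class_scores} or named numeric vector of the four
#'   confidences.
#' @param precisions named numeric vector of per-class precisions in [0,1].
#' @return The resistance score (dimensionless).
#' @export
resistance_score <- function(scores, precisions) {
  s <- if (inherits(scores, "class_scores")) scores$scores else scores
  stopifnot(all(PHENOTYPE_CLASSES %in% names(s)),
            all(PHENOTYPE_CLASSES %in% names(precisions)))
  p <- precisions[PHENOTYPE_CLASSES]
  s <- s[PHENOTYPE_CLASSES]
  unname(s["SRES"] * p["SRES"] + s["RES"] * p["RES"] -
           s["NEU"] * p["NEU"] - s["ISEN"] * p["ISEN"])
}

#' Min-max normalisation of resistance scores within an experiment
#'
#' NRS = (RS - min) / (max - min): the highest RS of the batch maps to 1.0,
#' the lowest to 0.0.  A degenerate batch (all equal) returns all zeros with
#' attribute \code{degenerate = TRUE} and a warning.
#'
#' @param batch numeric vector of RS values from one scored experiment.
#' @return NRS values in [0, 1], order-preserving.
#' @export
normalize_scores <- function(batch) {
  stopifnot(length(batch) >= 1, all(is.finite(batch)))
  rng <- range(batch)
  if (diff(rng) < 1e-12) {
    warning("degenerate RS batch (all values equal); returning zeros")
    out <- rep(0, length(batch))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (batch - rng[1]) / diff(rng)
}

#' Affinity-only baseline classifier
#'
#' Trains the same random-forest protocol on just two features: externally
#' predicted wild-type and mutant binding affinities (e.g. from a docking
#' engine; docking itself is not performed here).  Also reports the
#' per-instance fold change, computed as the wild-type over mutant predicted
#' affinity ratio, and how many instances exceed the 1.2-fold band in either
#' direction.
#'
#' @param pairs data.frame with columns \code{wt_affinity},
#'   \code{mt_affinity}, \code{label}; rows with missing affinities are
#'   skipped and logged.
#' @param params random-forest parameters.
#' @param k folds.
#' @param seed integer seed.
#' @return list(model, cv, fold_changes, n_beyond_1.2, skipped).
#' @export
affinity_only_baseline <- function(pairs, params = default_rf_params(),
                                   k = 10, seed = 1) {
  stopifnot(all(c("wt_affinity", "mt_affinity", "label") %in% names(pairs)))
  ok <- is.finite(pairs$wt_affinity) & is.finite(pairs$mt_affinity)
  skipped <- which(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  feats <- as.matrix(pairs[, c("wt_affinity", "mt_affinity")])
  labels <- factor(pairs$label, levels = PHENOTYPE_CLASSES)
  ts <- structure(list(features = feats, labels = labels,
                       table = pairs, schema = list(name = "affinity-only"),
                       report = list()), class = "training_set")
  model <- train_classifier(ts, params = params, seed = seed)
  cv <- cross_validate(ts, k = k, params = params, seed = seed)
  fold <- pairs$wt_affinity / pairs$mt_affinity
  n_beyond <- sum(fold > 1.2 | fold < 1 / 1.2)
  list(model = model, cv = cv, fold_changes = fold,
       n_beyond_1.2 = n_beyond, skipped = skipped)
}
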