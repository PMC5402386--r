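test_that("fold-change labelling partitions the positive axis into the four bands", {
  expect_equal(as.character(label_from_fold_change(6)), "SRES")
  expect_equal(as.character(label_from_fold_change(5.0)), "SRES")
  expect_equal(as.character(label_from_fold_change(4.99)), "RES")
  expect_equal(as.character(label_from_fold_change(1.2)), "RES")     # boundary outward
  expect_equal(as.character(label_from_fold_change(1.19)), "NEU")
  expect_equal(as.character(label_from_fold_change(1.0)), "NEU")
  expect_equal(as.character(label_from_fold_change(1 / 1.19)), "NEU")
  expect_equal(as.character(label_from_fold_change(1 / 1.2)), "ISEN") # boundary outward
  expect_equal(as.character(label_from_fold_change(1 / 1.5)), "ISEN")
  # totality: every positive fold maps to exactly one class
  set.seed(4)
  folds <- exp(stats::runif(500, log(1e-4), log(1e4)))
  labs <- label_from_fold_change(folds)
  expect_false(anyNA(labs))
  expect_error(label_from_fold_change(0), "positive|> 0")
  expect_error(label_from_fold_change(-2), "positive|> 0")
})

test_that("training-set construction filters multi-mutants and caps classes", {
  fx <- small_training_fixture()
  ts <- fx$ts
  expect_equal(length(fx$ts$report$multi_mutant_removed), fx$tt$n_decoys)
  expect_equal(nrow(ts$features), fx$tt$n_instances)
  expect_true(all(grepl("^decoy", fx$ts$report$multi_mutant_removed)))
  # labels agree with the fold-change rule applied to the kept table
  expect_equal(as.character(ts$labels),
               as.character(label_from_fold_change(ts$table$fold_change)))
  # down-sampling cap is honoured and seeded
  big <- data.frame(id = sprintf("r%03d", 1:60), protein = "p",
                    mutation = "A1G", n_mutations = 1L,
                    wt_structure = "missing.pdb", mt_structure = "missing.pdb",
                    affinity_wt = 1, affinity_mt = 10, measure = "Ki",
                    ligand_id = "LIG", stringsAsFactors = FALSE)
  # all SRES (fold 10); cap at 20: kept rows are reproducible under the seed
  t1 <- suppressWarnings(build_training_set(big, seed = 5, cap = 20))
  t2 <- suppressWarnings(build_training_set(big, seed = 5, cap = 20))
  expect_equal(length(t1$report$downsampled_out), 40)
  expect_identical(t1$report$downsampled_out, t2$report$downsampled_out)
  # unresolvable structures are dropped with a report, not an error
  expect_equal(length(t1$report$structure_failed), 20)
  expect_equal(nrow(t1$features), 0)
})

test_that("classifier training is seeded and learns the planted signal", {
  fx <- small_training_fixture()
  model <- fx$model
  expect_equal(model$params$ntree, 300)
  # default parameters follow the published triple
  expect_equal(default_rf_params(), list(ntree = 1000, mtry = 20,
                                         maxnodes = NULL))
  # training-set argmax accuracy on a separable planted set is high
  preds <- predict_scores(model, fx$ts$features)
  acc <- mean(vapply(preds, function(p) p$class, character(1)) ==
                as.character(fx$ts$labels))
  expect_gt(acc, 0.9)
  # determinism under seed
  m2 <- train_classifier(fx$ts, params = model$params, seed = 7)
  p1 <- predict_scores(model, fx$ts$features[1, ])
  p2 <- predict_scores(m2, fx$ts$features[1, ])
  expect_identical(p1$scores, p2$scores)
  # single-class sets are rejected
  one <- fx$ts
  keep <- one$labels == "SRES"
  one$features <- one$features[keep, , drop = FALSE]
  one$labels <- droplevels(one$labels[keep])
  expect_error(train_classifier(one), "two classes")
})

test_that("cross-validation reports coherent metrics and a sane null", {
  fx <- small_training_fixture()
  cv <- fx$cv
  expect_s3_class(cv, "cv_report")
  # confusion-matrix rows sum to the class counts
  expect_equal(as.numeric(rowSums(cv$confusion)),
               as.numeric(table(fx$ts$labels)[rownames(cv$confusion)]))
  expect_true(all(cv$auc >= 0 & cv$auc <= 1, na.rm = TRUE))
  expect_gt(cv$mean_auc, 0.8)   # separable planted data
  expect_gt(cv$kappa, 0.5)
  # shuffled labels: no signal left
  set.seed(42)
  null <- fx$ts
  null$labels <- sample(null$labels)
  cvn <- suppressWarnings(cross_validate(
    null, k = 5, params = list(ntree = 200, mtry = 20, maxnodes = NULL),
    seed = 3))
  expect_lt(abs(cvn$mean_auc - 0.5), 0.15)
  expect_lt(abs(cvn$kappa), 0.2)
  # k is reduced with a warning when the smallest class is too small
  expect_warning(cross_validate(fx$ts, k = 50,
                                params = list(ntree = 50, mtry = 10,
                                              maxnodes = NULL), seed = 1),
                 "reducing k")
})

test_that("class scores are a distribution with the documented tie rule", {
  fx <- small_training_fixture()
  sc <- predict_scores(fx$model, fx$ts$features[3, ])
  expect_equal(sum(sc$scores), 1, tolerance = 1e-9)
  expect_true(all(sc$scores >= 0 & sc$scores <= 1))
  expect_equal(names(sc$scores), PHENOTYPE_CLASSES)
  expect_equal(sc$class, names(which.max(sc$scores)))
  # schema mismatch is an error
  wrong <- structure(list(schema = feature_schema("lig-v1"),
                          values = rep(0, length(feature_schema("lig-v1")$features)),
                          provenance = NULL), class = "feature_vector")
  expect_error(predict_scores(fx$model, wrong), "schema")
  # exact tie resolves by the fixed class order and is flagged
  tied <- stats::setNames(c(0.3, 0.3, 0.2, 0.2), PHENOTYPE_CLASSES)
  expect_equal(resmutscan:::argmax_class(tied, PHENOTYPE_CLASSES), "SRES")
})

test_that("resistance score matches the weighted-sum arithmetic and its bounds", {
  # degenerate: all confidence in SRES, all precisions 1
  expect_equal(resistance_score(
    stats::setNames(c(1, 0, 0, 0), PHENOTYPE_CLASSES),
    stats::setNames(rep(1, 4), PHENOTYPE_CLASSES)), 1)
  # uniform scores with equal precisions cancel
  expect_equal(resistance_score(
    stats::setNames(rep(0.25, 4), PHENOTYPE_CLASSES),
    stats::setNames(rep(0.7, 4), PHENOTYPE_CLASSES)), 0)
  # linearity in each class score
  prec <- stats::setNames(c(0.63, 0.50, 0.48, 0.59), PHENOTYPE_CLASSES)
  s0 <- stats::setNames(c(0.4, 0.3, 0.1, 0.2), PHENOTYPE_CLASSES)
  base <- resistance_score(s0, prec)
  s1 <- s0; s1["SRES"] <- s0["SRES"] + 0.1
  expect_equal(resistance_score(s1, prec) - base, 0.1 * prec["SRES"],
               ignore_attr = TRUE)
  # bounded by the largest precision
  set.seed(6)
  for (i in 1:50) {
    s <- stats::runif(4); s <- stats::setNames(s / sum(s), PHENOTYPE_CLASSES)
    p <- stats::setNames(stats::runif(4), PHENOTYPE_CLASSES)
    expect_lte(abs(resistance_score(s, p)), max(p))
  }
})

test_that("score normalisation is a min-max rescaling with degenerate handling", {
  expect_equal(normalize_scores(c(1, 2, 3)), c(0, 0.5, 1))
  batch <- stats::rnorm(20)
  nrs <- normalize_scores(batch)
  expect_equal(nrs[which.max(batch)], 1)
  expect_equal(nrs[which.min(batch)], 0)
  expect_equal(order(nrs), order(batch))
  # affine invariance
  expect_equal(normalize_scores(3 * batch - 7), nrs)
  expect_warning(out <- normalize_scores(rep(2, 5)), "degenerate")
  expect_equal(as.numeric(out), rep(0, 5))
  expect_true(attr(out, "degenerate"))
})

test_that("affinity-only baseline trains on two features and reports fold changes", {
  set.seed(12)
  n <- 40
  lab <- rep(PHENOTYPE_CLASSES, each = n / 4)
  wt <- stats::runif(n, 5, 6)
  shift <- c(SRES = 3, RES = 1, NEU = 0, ISEN = -1)[lab]
  mt <- wt + shift + stats::rnorm(n, sd = 0.1)
  pairs <- data.frame(wt_affinity = wt, mt_affinity = mt, label = lab)
  pairs$mt_affinity[3] <- NA
  out <- suppressWarnings(affinity_only_baseline(
    pairs, params = list(ntree = 200, mtry = 2, maxnodes = NULL),
    k = 5, seed = 2))
  expect_equal(out$skipped, 3)
  expect_gt(out$cv$mean_auc, 0.8)
  expect_length(out$fold_changes, n - 1)
  # identical affinities give unit fold changes and an empty beyond-band count
  same <- data.frame(wt_affinity = wt, mt_affinity = wt, label = lab)
  out2 <- suppressWarnings(affinity_only_baseline(
    same, params = list(ntree = 100, mtry = 2, maxnodes = NULL),
    k = 5, seed = 2))
  expect_true(all(out2$fold_changes == 1))
  expect_equal(out2$n_beyond_1.2, 0)
  # the beyond-band counter uses the 1.2 threshold in both directions
  expect_equal(out$n_beyond_1.2,
               sum(out$fold_changes > 1.2 | out$fold_changes < 1 / 1.2))
})

test_that("prediction frequencies on fresh planted data recover the planted mix", {
  fx <- small_training_fixture()
  # fresh instances from the same generator, different seed
  tt2 <- suppressWarnings(make_toy_training_table(
    c(SRES = 10, RES = 10, NEU = 10, ISEN = 10),
    signal_strength = 1, seed = 99))
  ts2 <- suppressWarnings(build_training_set(tt2$csv, seed = 99))
  preds <- predict_scores(fx$model, ts2$features)
  got <- table(factor(vapply(preds, function(p) p$class, character(1)),
                      levels = PHENOTYPE_CLASSES))
  # each planted class recovered within binomial error of its share
  for (cls in PHENOTYPE_CLASSES) {
    expect_gt(got[[cls]], 2)
    expect_lt(got[[cls]], 20)
  }
})
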