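test_that("model input embeds the three maps with sentinel zeros and a 52-cell mask", {
  nm <- fx_norm()
  lay <- fx_layout()
  set.seed(81)
  rec <- sample_normal_field(50, fx_truth(), id = "x")
  x <- vf_model_input(list(rec), nm, lay)
  expect_identical(dim(x), c(1L, 8L, 9L, 4L))
  expect_identical(sum(x[1, , , 4]), 52)
  off <- x[1, , , 4] == 0
  for (ch in 1:3) expect_true(all(x[1, , , ch][off] == 0))
  # PDP channel is the ordinal code scaled to [0, 1]
  maps <- deviation_maps(rec, nm)
  expect_equal(vf_extract(lay, x[1, , , 3]), maps$pd_cat / 4)
})

test_that("untrained models are deterministic in their initialization and scores normalize", {
  m1 <- build_vf_model("PDP", seed = 9)
  m2 <- build_vf_model("PDP", seed = 9)
  expect_identical(m1$layers, m2$layers)
  m3 <- build_vf_model("PDP", seed = 10)
  expect_false(identical(m1$layers, m3$layers))
  expect_error(build_vf_model("OCT"), "unknown map kind")
  # forward softmax sums to 1, even on an all-sentinel (blank) input
  ns <- asNamespace("vfscreen")
  x0 <- array(0, c(1, 8, 9, 2))
  p <- ns$nn_predict(list(layers = m1$layers), x0)
  expect_equal(sum(p), 1)
  expect_true(all(is.finite(p)))
})

test_that("training separates a defect cohort and fixes a validation Youden threshold", {
  m <- fx_small_model()
  expect_true(m$trained)
  expect_gte(m$val_auc, 0.95)
  expect_true(m$operating_threshold > 0 && m$operating_threshold < 1)
  scores <- predict_vf_model(m, fx_small_cohort()$records[1:50], fx_norm())
  expect_true(all(scores >= 0 & scores <= 1))
})

test_that("patient-level split integrity is enforced", {
  coh <- fx_small_cohort()$records[1:40]
  ids <- rep(sprintf("pat%02d", 1:20), each = 2)  # two records per patient
  bad_mask <- rep(c(TRUE, FALSE), 20)             # splits every patient
  expect_error(
    train_vf_model(build_vf_model("PDP", seed = 1), coh,
                   patient_ids = ids, val_mask = bad_mask, norm = fx_norm(),
                   epochs = 1, seed = 1),
    "patient overlap"
  )
  expect_error(
    train_vf_model(build_vf_model("PDP", seed = 1), coh,
                   patient_ids = ids, val_mask = rep(FALSE, 40),
                   norm = fx_norm(), epochs = 1, seed = 1),
    "non-empty"
  )
})

test_that("training on permuted labels yields chance-level validation AUC", {
  coh <- fx_small_cohort()
  nm <- fx_norm()
  set.seed(82)
  labels <- vapply(coh$records, function(r) r$label == "glaucoma",
                   logical(1))
  perm <- sample(labels)  # break the label-input association
  val <- rep(c(FALSE, TRUE), c(350, 150))
  m <- train_vf_model(build_vf_model("PDP", seed = 6), coh$records,
                      labels = perm, val_mask = val, norm = nm,
                      epochs = 6, patience = 6, seed = 6)
  # scored on a fresh cohort with labels independent of the inputs, the
  # permutation-trained model performs at chance
  coh2 <- simulate_cohort(sim_config(300, c(normal = 0.5,
                                            arcuate_sup = 0.25,
                                            advanced = 0.25),
                                     c(10, 18), seed = 32),
                          fx_truth(), fx_layout())
  lab2 <- sample(c(TRUE, FALSE), 300, replace = TRUE)
  auc <- pair_auc(predict_vf_model(m, coh2$records, nm), lab2)
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("training is deterministic given data and seed", {
  coh <- fx_small_cohort()$records[1:150]
  nm <- fx_norm()
  m1 <- train_vf_model(build_vf_model("PDP", seed = 4), coh, norm = nm,
                       epochs = 3, patience = 3, seed = 4)
  m2 <- train_vf_model(build_vf_model("PDP", seed = 4), coh, norm = nm,
                       epochs = 3, patience = 3, seed = 4)
  expect_identical(m1$operating_threshold, m2$operating_threshold)
  expect_identical(m1$layers, m2$layers)
})

test_that("ensemble fusion is the mean of available scores", {
  expect_equal(ensemble_score(c(0.9, 0.9, 0.9)), 0.9)
  expect_equal(ensemble_score(c(1, 0, 0.5)), 0.5)
  expect_equal(ensemble_score(0.73), 0.73)
  expect_equal(ensemble_score(c(0.4, NA, 0.6)), 0.5)
  expect_error(ensemble_score(numeric(0)), "no scores")
})

test_that("Grad-CAM heatmaps are non-negative, max-normalized and model-gated", {
  m <- fx_small_model()
  set.seed(83)
  rec <- apply_archetype(sample_normal_field(55, fx_truth()),
                         "arcuate_sup", 14)
  h <- gradcam_heatmap(m, rec, fx_norm())
  expect_identical(dim(h), c(8L, 9L))
  expect_true(all(h >= 0))
  expect_equal(max(h), 1)
  raw <- gradcam_heatmap(m, rec, fx_norm(), normalize = FALSE)
  expect_true(max(raw) > 0)
  expect_error(gradcam_heatmap(build_vf_model("PDP"), rec, fx_norm()),
               "untrained")
})
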