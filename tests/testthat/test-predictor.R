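# two-element protein: an acceptor-like O cluster and a donor-like N cluster,
# far apart, so class labels are linearly separable from the voxel densities
separable_fixture <- function(seed = 1, n_per = 60, n_neg = 80) {
  set.seed(seed)
  atoms <- tibble::tibble(
    x = c(0, 20), y = c(0, 0), z = c(0, 0),
    element = c("O", "N"), residue_name = "GLY",
    atom_name = c("O", "N"), resno = 1:2, chain = "A", is_hydrogen = FALSE)
  prot <- protein_structure(atoms, annotate_groups(atoms))
  acc <- c(1, 0, 0, 0, 0, 0); don <- c(0, 1, 0, 0, 0, 0)
  samples <- list()
  for (i in seq_len(n_per)) {
    samples[[length(samples) + 1]] <- training_sample(
      prot, c(0, 0, 0) + stats::rnorm(3, sd = 0.8), acc)
    samples[[length(samples) + 1]] <- training_sample(
      prot, c(20, 0, 0) + stats::rnorm(3, sd = 0.8), don)
  }
  for (i in seq_len(n_neg)) {
    samples[[length(samples) + 1]] <- training_sample(
      prot, c(10, 0, 0) + stats::rnorm(3, sd = 2.0), rep(0, 6))
  }
  list(protein = prot, samples = sample(samples))
}

auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

test_that("predict_point returns six confidences and a 32-d embedding", {
  prot <- protein_structure(tibble::tibble(
    x = 0, y = 0, z = 0, element = "C", residue_name = "GLY",
    atom_name = "CA", resno = 1L, chain = "A", is_hydrogen = FALSE))
  model <- site_predictor(seed = 4)
  p <- predict_point(model, prot, c(0, 0, 0))
  expect_named(p$confidences, pharm_classes())
  expect_true(all(p$confidences >= 0 & p$confidences <= 1))
  expect_length(p$embedding, 32)
  # deterministic for fixed weights
  p2 <- predict_point(model, prot, c(0, 0, 0))
  expect_identical(p$confidences, p2$confidences)
  # constant-zero logits give sigma(0) = 0.5 everywhere
  z <- predict_point(constant_predictor(0), prot, c(1, 2, 3))
  expect_equal(unname(z$confidences), rep(0.5, 6))
  # shape mismatch between config and model is an error
  expect_error(predict_point(model, prot, c(0, 0, 0),
                             config = predictor_config(box_edge = 12)),
               "shape")
})

test_that("training separates a linearly separable fixture (held-out AUC)", {
  fx <- separable_fixture(seed = 5)
  n <- length(fx$samples)
  test_idx <- seq(1, n, by = 4)
  model <- train_predictor(fx$samples[-test_idx], seed = 2, epochs = 120)
  pts <- do.call(rbind, lapply(fx$samples[test_idx], `[[`, "point"))
  labs <- do.call(rbind, lapply(fx$samples[test_idx], `[[`, "labels"))
  pred <- predict_confidences(model, fx$protein, pts)
  for (ci in 1:2) {  # acceptor, donor: the two classes with positives
    expect_gt(auc(pred$confidences[, ci], labs[, ci]), 0.95)
  }
  # reproducible: same seed, same final loss
  model2 <- train_predictor(fx$samples[-test_idx], seed = 2, epochs = 120)
  expect_identical(tail(model$trace, 1), tail(model2$trace, 1))
  expect_identical(model$net$W[[1]], model2$net$W[[1]])
})

test_that("degenerate one-polarity training sets warn but train", {
  fx <- separable_fixture(seed = 6, n_per = 5, n_neg = 0)
  pos_only <- Filter(function(s) sum(s$labels) > 0, fx$samples)
  expect_warning(train_predictor(pos_only, seed = 1, epochs = 3),
                 "degenerate")
})

test_that("adversarial mining follows the clash and complementarity rules", {
  p0 <- c(0, 0, 0)
  mk_prot <- function(donor_at, extra = NULL) {
    atoms <- tibble::tibble(
      x = donor_at[1], y = donor_at[2], z = donor_at[3], element = "N",
      residue_name = "GLY", atom_name = "N", resno = 1L, chain = "A",
      is_hydrogen = FALSE)
    if (!is.null(extra)) atoms <- dplyr::bind_rows(atoms, extra)
    protein_structure(atoms, annotate_groups(atoms))
  }
  model <- oracle_predictor(tibble::tibble(class = "HydrogenAcceptor",
                                           x = 0, y = 0, z = 0),
                            blob_sigma = 0.8, seed = 3)
  box <- box3(p0 - 1, p0 + 1)
  key <- function(s) sprintf("%.2f,%.2f,%.2f", s$point[1], s$point[2],
                             s$point[3])

  # donor group 5 A away: every fired acceptor point is unsupported
  adv_far <- generate_adversarial_negatives(model, mk_prot(c(5, 0, 0)), box)
  expect_true(length(adv_far) > 0)
  expect_true("0.00,0.00,0.00" %in% vapply(adv_far, key, character(1)))
  expect_true(all(vapply(adv_far, function(s) s$is_adversarial, logical(1))))
  expect_true(all(vapply(adv_far, function(s) all(s$labels == 0), logical(1))))

  # donor group 3 A away (also the nearest heavy atom at 3 A): supported
  adv_ok <- generate_adversarial_negatives(model, mk_prot(c(3, 0, 0)), box)
  expect_false("0.00,0.00,0.00" %in% vapply(adv_ok, key, character(1)))

  # inert heavy atom 1 A from the prediction: clash, flagged despite support
  inert <- tibble::tibble(x = 1, y = 0, z = 0, element = "C",
                          residue_name = "GLY", atom_name = "CA", resno = 2L,
                          chain = "A", is_hydrogen = FALSE)
  adv_clash <- generate_adversarial_negatives(model, mk_prot(c(3, 0, 0),
                                                             inert), box)
  expect_true("0.00,0.00,0.00" %in% vapply(adv_clash, key, character(1)))

  # the rule is a pure function: re-running adds nothing new
  adv_rep <- generate_adversarial_negatives(model, mk_prot(c(5, 0, 0)), box)
  expect_equal(vapply(adv_rep, key, character(1)),
               vapply(adv_far, key, character(1)))
})

test_that("adversarial retraining suppresses flagged points, keeps recall", {
  fx <- separable_fixture(seed = 9)
  n <- length(fx$samples)
  test_idx <- seq(1, n, by = 4)
  train_set <- fx$samples[-test_idx]
  model <- train_predictor(train_set, seed = 3, epochs = 120)
  # mine negatives in an unsupported region (no donor/acceptor group nearby)
  adv <- generate_adversarial_negatives(model, fx$protein,
                                        box3(c(6, -2, -2), c(14, 2, 2)))
  recall_of <- function(m) {
    pts <- do.call(rbind, lapply(fx$samples[test_idx], `[[`, "point"))
    labs <- do.call(rbind, lapply(fx$samples[test_idx], `[[`, "labels"))
    pred <- predict_confidences(m, fx$protein, pts)$confidences
    pos <- labs == 1
    sum(pred[pos] > 0.5) / sum(pos)
  }
  r_before <- recall_of(model)
  if (length(adv) > 0) {
    model2 <- train_predictor(c(train_set, adv), seed = 3, epochs = 120)
    r_after <- recall_of(model2)
    expect_gt(r_after, r_before - 0.05)
    pts <- do.call(rbind, lapply(adv, `[[`, "point"))
    pred2 <- predict_confidences(model2, fx$protein, pts)$confidences
    expect_lt(mean(pred2 > 0.5), 0.05)
  } else {
    succeed("model fired nowhere in the unsupported region")
  }
})
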