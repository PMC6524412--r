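test_that("activity labelling follows the 10/50 micromolar rule", {
  expect_equal(assign_label(10000), "positive")      # 10 uM exactly
  expect_equal(assign_label(50100), "negative")      # 50.1 uM
  expect_equal(assign_label(25000), "excluded")      # in the gap
  expect_equal(assign_label(c(500, 50000, 12000)),
               c("positive", "excluded", "excluded"))
  expect_error(assign_label(0), "positive")
  expect_error(assign_label(-5), "positive")
})

test_that("p_activity is 9 minus log10 of the nanomolar value", {
  expect_equal(p_activity(1), 9)
  expect_equal(p_activity(1000), 6)
  expect_equal(p_activity(10000), 5)                 # 10 uM
  expect_error(p_activity(0), "positive")
})

test_that("pose filtering applies score and pocket rules, best pose wins", {
  poses <- data.frame(
    molecule_id = c("m1", "m1", "m2", "m3"),
    docking_score = c(-9.0, -9.5, -7.0, -9.0),
    x = c(3, 2, 0, 12), y = 0, z = 0,
    ref_x = 0, ref_y = 0, ref_z = 0)
  kept <- filter_poses(poses, score_max = -8.2, pocket_radius = 8)
  # m1 keeps only its better pose; m2 fails the score; m3 is off-pocket
  expect_equal(kept$molecule_id, "m1")
  expect_equal(kept$docking_score, -9.5)
  expect_true(all(kept$molecule_id %in% poses$molecule_id))
  expect_false(any(duplicated(kept$molecule_id)))
  expect_equal(nrow(filter_poses(poses[0, ])), 0)
})

test_that("the split protocol yields the expected part sizes at n = 1740", {
  sp <- split_dataset(sprintf("id%04d", 1:1740), seed = 7)
  expect_length(sp, 10)
  expect_length(sp[[1]]$test, 158)      # round(1740 / 11)
  expect_length(sp[[1]]$valid, 176)     # round(1582 / 9)
  expect_length(sp[[1]]$train, 1406)
  # test set fixed across the ten repeats
  for (r in 2:10) expect_identical(sp[[r]]$test, sp[[1]]$test)
  # the 10% reading is available behind the flag
  spf <- split_dataset(sprintf("id%04d", 1:1740), seed = 7,
                       test_rule = "fraction")
  expect_length(spf[[1]]$test, 174)
})

test_that("splits partition the ids and are reproducible", {
  for (n in c(22, 47, 200, 1111, 5000)) {
    ids <- sprintf("x%05d", seq_len(n))
    sp <- split_dataset(ids, seed = n)
    for (s in sp) {
      expect_length(intersect(s$test, s$valid), 0)
      expect_length(intersect(s$test, s$train), 0)
      expect_length(intersect(s$valid, s$train), 0)
      expect_setequal(c(s$test, s$valid, s$train), ids)
    }
  }
  sp1 <- split_dataset(1:100, seed = 5)
  sp2 <- split_dataset(1:100, seed = 5)
  expect_identical(sp1, sp2)
  expect_false(identical(split_dataset(1:100, seed = 6), sp1))
  expect_error(split_dataset(1:10, seed = 1), "22")
})

test_that("grid search enumerates the Cartesian product and picks argmax", {
  g1 <- grid_spec(dropout = 0.1, learning_rate = 0.01, hidden = list(c(4, 4)))
  ds <- make_fingerprint_dataset(
    fingerprint_dataset_spec(n_samples = 60, n_features = 6,
                             n_signal_bits = 3, seed = 2))
  cfg <- tifp_net_config(input_dim = 6, batch_size = 16, max_epochs = 3,
                         patience = 3)
  gr <- grid_search(g1, ds$x[1:40, ], ds$y[1:40], ds$x[41:60, ], ds$y[41:60],
                    cfg)
  expect_equal(nrow(gr$results), 1)
  expect_equal(gr$best, 1)
  expect_error(grid_spec(dropout = numeric(0)), "empty")
  # rigged trainer: one combination dominates
  rig <- function(x, y, xv, yv, config) {
    win <- config$dropout == 0.2 && config$learning_rate == 0.01
    hist <- data.frame(epoch = 1, loss = 1,
                       train_recall = 1, train_precision = 1,
                       train_roc_auc = 1, train_prc_auc = 1,
                       valid_recall = 1, valid_precision = 1,
                       valid_roc_auc = 1,
                       valid_prc_auc = if (win) 0.99 else 0.5,
                       valid_metric = if (win) 0.99 else 0.5)
    structure(list(config = config, params = NULL, best_epoch = 1L,
                   stopped_epoch = 1L, history = hist), class = "tifp_net")
  }
  g <- grid_spec(dropout = c(0.1, 0.2), learning_rate = c(0.01, 0.001),
                 hidden = list(c(4, 4), c(8, 8)))
  gr2 <- grid_search(g, ds$x, ds$y, ds$x, ds$y, cfg, trainer = rig)
  expect_equal(nrow(gr2$results), 2 * 2 * 2)
  best <- gr2$results[gr2$best, ]
  expect_equal(best$dropout, 0.2)
  expect_equal(best$learning_rate, 0.01)
  # tie-break: equal PRC-AUC rows resolve to lower dropout then lower lr
  flat <- function(x, y, xv, yv, config) {
    h <- rig(x, y, xv, yv, config)
    h$history$valid_prc_auc <- 0.7
    h
  }
  gr3 <- grid_search(g, ds$x, ds$y, ds$x, ds$y, cfg, trainer = flat)
  expect_equal(gr3$results[gr3$best, ]$dropout, 0.1)
  expect_equal(gr3$results[gr3$best, ]$learning_rate, 0.001)
})

test_that("repeat summaries reproduce hand-computed mean and sd", {
  inj <- data.frame(recall = c(0.6, 0.8, 0.7), prc_auc = c(0.70, 0.74, 0.78))
  s <- summarize_repeats(inj)
  expect_equal(s["mean", "recall"], 0.7, tolerance = 1e-12)
  expect_equal(s["sd", "recall"], 0.1, tolerance = 1e-12)
  expect_equal(s["mean", "prc_auc"], 0.74, tolerance = 1e-12)
  expect_equal(s["sd", "prc_auc"], 0.04, tolerance = 1e-12)
  same <- data.frame(prc_auc = rep(0.8, 10))
  expect_true(all(summarize_repeats(same)["sd", ] == 0))
  expect_error(summarize_repeats(data.frame(prc_auc = 0.8)), "2 repeats")
})

test_that("repeated training returns one model per split and a best index", {
  ds <- make_fingerprint_dataset(
    fingerprint_dataset_spec(n_samples = 120, n_features = 10,
                             n_signal_bits = 4, prevalence = 0.3, seed = 8))
  sp <- split_dataset(rownames(ds$x), seed = 99, repeats = 3)
  cfg <- tifp_net_config(input_dim = 10, hidden = c(8, 8), batch_size = 16,
                         max_epochs = 4, patience = 4, seed = 1)
  rt <- repeated_training(ds$x, ds$y, sp, cfg)
  expect_equal(nrow(rt$metrics), 3)
  expect_equal(rownames(rt$summary), c("mean", "sd"))
  expect_equal(rt$best, which.max(rt$metrics$prc_auc))
  expect_length(rt$models, 3)
})

test_that("pairwise Tanimoto coefficients and their histogram are exact", {
  expect_equal(pairwise_similarity(list(c(1, 2, 3), c(1, 2, 3)))$coefficients,
               1.0)
  expect_equal(pairwise_similarity(list(c(1, 2), c(3, 4)))$coefficients, 0.0)
  sets <- lapply(1:10, function(i) seq_len(i + 1))
  ps <- pairwise_similarity(sets)
  expect_length(ps$coefficients, 45)
  expect_equal(sum(ps$histogram), 45)
  # nested sets: |A n B| / |A u B| = |A| / |B| for A within B
  expect_equal(ps$coefficients[1], 2 / 3)
  expect_error(pairwise_similarity(list(integer(0), 1:3)), "empty")
  m <- rbind(c(1, 1, 0), c(1, 0, 1))
  expect_equal(pairwise_similarity(m)$coefficients, 1 / 3)
})
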