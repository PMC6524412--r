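# The dataset-assembly and evaluation protocol: activity labelling, pose
# filtering, the 1:10 / 1:8 x 10 split scheme, multi-grid hyperparameter
# search, repeated training with a mean +/- sd summary, and chemical
# diversity analysis via pairwise Tanimoto coefficients.

#' Activity label from a measured potency
#'
#' Compounds at or below `pos_max_uM` (default 10 micromolar) are
#' positive, above `neg_min_uM` (default 50 micromolar) negative, and the
#' gap in between is excluded from training.
#'
#' @param value_nM potency (IC50/EC50/Ki) in nanomolar, positive.
#' @param pos_max_uM,neg_min_uM thresholds in micromolar.
#' @return Character vector `"positive"`/`"negative"`/`"excluded"`.
#' @export
assign_label <- function(value_nM, pos_max_uM = 10, neg_min_uM = 50) {
  if (any(!is.finite(value_nM)) || any(value_nM <= 0))
    stop("activity values must be positive")
  pos_max <- pos_max_uM * 1000; neg_min <- neg_min_uM * 1000
  ifelse(value_nM <= pos_max, "positive",
         ifelse(value_nM > neg_min, "negative", "excluded"))
}

#' Negative log-molar activity
#'
#' `p_activity = 9 - log10(value in nM)`, i.e. pIC50/pEC50/pKi of the
#' molar concentration.
#'
#' @param value_nM potency in nanomolar, positive.
#' @return Numeric vector.
#' @export
p_activity <- function(value_nM) {
  if (any(!is.finite(value_nM)) || any(value_nM <= 0))
    stop("activity values must be positive")
  9 - log10(value_nM)
}

#' Filter docked poses by score and pocket membership
#'
#' Retains poses scoring at or below `score_max` (more negative = better;
#' default -8.2) whose centroid lies within `pocket_radius` of the
#' reference pocket centroid, then keeps only the best-scoring retained
#' pose per molecule.
#'
#' @param poses data frame with columns `molecule_id`, `docking_score`,
#'   and centroid coordinates `x`, `y`, `z` plus reference coordinates
#'   `ref_x`, `ref_y`, `ref_z`.
#' @param score_max docking-score threshold.
#' @param pocket_radius pocket membership radius in Angstrom.
#' @return The retained subset of `poses` (at most one row per molecule).
#' @export
filter_poses <- function(poses, score_max = -8.2, pocket_radius = 8) {
  need <- c("molecule_id", "docking_score", "x", "y", "z",
            "ref_x", "ref_y", "ref_z")
  stopifnot(all(need %in% names(poses)))
  if (nrow(poses) == 0) return(poses)
  d <- sqrt((poses$x - poses$ref_x)^2 + (poses$y - poses$ref_y)^2 +
            (poses$z - poses$ref_z)^2)
  keep <- poses$docking_score <= score_max & d <= pocket_radius
  out <- poses[keep, , drop = FALSE]
  if (nrow(out) == 0) return(out)
  ord <- order(out$molecule_id, out$docking_score)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(out$molecule_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test/validation/train splits of the screening dataset
#'
#' A test set of `round(n / 11)` ids (the 1:10 reading of the protocol;
#' `test_rule = "fraction"` instead takes `round(0.1 * n)`) is drawn
#' once.  The remainder is reshuffled `repeats` times; each repeat sets
#' aside `round(remainder / 9)` validation ids and trains on the rest.
#' The test set is identical across repeats and everything is
#' reproducible from `seed`.
#'
#' @param ids vector of sample ids (>= 22 so all parts are non-empty).
#' @param seed integer seed.
#' @param repeats number of validation/train reshuffles (default 10).
#' @param test_rule `"ratio"` (test:rest = 1:10) or `"fraction"` (10%).
#' @return List of class `dataset_splits`: one element per repeat, each
#'   with `test`, `valid`, `train`, `repeat_index`, `seed`.
#' @export
split_dataset <- function(ids, seed = 1L, repeats = 10L,
                          test_rule = c("ratio", "fraction")) {
  test_rule <- match.arg(test_rule)
  ids <- unique(ids)
  n <- length(ids)
  if (n < 22) stop("need at least 22 ids for non-empty parts")
  n_test <- if (test_rule == "ratio") round(n / 11) else round(0.1 * n)
  set.seed(seed)
  test <- sort(sample(ids, n_test))
  rest <- setdiff(ids, test)
  n_valid <- round(length(rest) / 9)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, repeats)
  splits <- lapply(seq_len(repeats), function(r) {
    set.seed(rep_seeds[r])
    shuffled <- sample(rest)
    list(test = test, valid = sort(shuffled[seq_len(n_valid)]),
         train = sort(shuffled[-seq_len(n_valid)]),
         repeat_index = r - 1L, seed = rep_seeds[r])
  })
  structure(splits, class = "dataset_splits", seed = seed)
}

#' Write splits as JSON id lists
#'
#' @param splits a [split_dataset()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_splits <- function(splits, path) {
  jsonlite::write_json(lapply(unclass(splits), function(s)
    list(repeat_index = s$repeat_index, test = s$test, valid = s$valid,
         train = s$train)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Hyperparameter grid specification
#'
#' Defaults reproduce the searched grid: dropout 0.1/0.2, four learning
#' rates, four hidden-layer-size pairs (32 combinations).
#'
#' @param dropout,learning_rate numeric axes.
#' @param hidden list of integer pairs.
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(dropout = c(0.1, 0.2),
                      learning_rate = c(0.001, 0.0005, 0.0001, 0.00005),
                      hidden = list(c(500, 100), c(100, 500),
                                    c(320, 640), c(500, 1000))) {
  if (length(dropout) == 0 || length(learning_rate) == 0 ||
      length(hidden) == 0) stop("empty grid axis")
  structure(list(dropout = dropout, learning_rate = learning_rate,
                 hidden = hidden), class = "grid_spec")
}

# metrics row of one trained model at its selected epoch
.fit_metrics_row <- function(fit) {
  h <- fit$history
  row <- h[h$epoch == fit$best_epoch, , drop = FALSE]
  data.frame(stop_epoch = fit$stopped_epoch,
             train_recall = row$train_recall,
             train_precision = row$train_precision,
             train_roc_auc = row$train_roc_auc,
             train_prc_auc = row$train_prc_auc,
             valid_recall = row$valid_recall,
             valid_precision = row$valid_precision,
             valid_roc_auc = row$valid_roc_auc,
             valid_prc_auc = row$valid_prc_auc)
}

#' Multi-grid hyperparameter search
#'
#' Trains one classifier per combination of the grid axes (Cartesian
#' product) and records the stop epoch plus train/validation recall,
#' precision, ROC-AUC and PRC-AUC at each model's selected epoch.  The
#' best combination maximizes validation PRC-AUC; exact ties go to the
#' lower dropout, then the lower learning rate.
#'
#' @param grid a [grid_spec()].
#' @param x,y training fingerprints and labels.
#' @param xval,yval validation fingerprints and labels.
#' @param base_config a [tifp_net_config()] supplying every
#'   non-searched field (batch size, epochs, patience, seed, input_dim).
#' @param trainer the function fitting one combination; defaults to
#'   [tifp_net()].  Replaceable for protocol tests.
#' @return List of class `grid_result`: `results` (one row per
#'   combination), `best` (row index), `best_config`.
#' @export
grid_search <- function(grid, x, y, xval, yval,
                        base_config = tifp_net_config(),
                        trainer = tifp_net) {
  stopifnot(inherits(grid, "grid_spec"))
  combos <- expand.grid(h = seq_along(grid$hidden),
                        lr = seq_along(grid$learning_rate),
                        dp = seq_along(grid$dropout))
  rows <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    cmb <- combos[k, ]
    cfg <- base_config
    cfg$dropout <- grid$dropout[cmb$dp]
    cfg$learning_rate <- grid$learning_rate[cmb$lr]
    cfg$hidden <- as.integer(grid$hidden[[cmb$h]])
    fit <- trainer(x, y, xval, yval, cfg)
    rows[[k]] <- cbind(
      data.frame(dropout = cfg$dropout, learning_rate = cfg$learning_rate,
                 hidden = paste(cfg$hidden, collapse = "x")),
      .fit_metrics_row(fit))
  }
  results <- do.call(rbind, rows)
  ord <- order(-results$valid_prc_auc, results$dropout,
               results$learning_rate)
  best <- ord[1]
  best_config <- base_config
  best_config$dropout <- results$dropout[best]
  best_config$learning_rate <- results$learning_rate[best]
  best_config$hidden <- as.integer(
    strsplit(results$hidden[best], "x")[[1]])
  structure(list(results = results, best = best,
                 best_config = best_config), class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("grid_result:", nrow(x$results), "combinations; best row", x$best,
      sprintf("(valid PRC-AUC %.3f)\n", x$results$valid_prc_auc[x$best]))
  print(x$results[x$best, , drop = FALSE], row.names = FALSE)
  invisible(x)
}

#' Mean and standard deviation summary of repeated-training metrics
#'
#' @param metrics data frame of per-model metric columns.
#' @return data frame with rows `mean` and `sd`.
#' @export
summarize_repeats <- function(metrics) {
  if (nrow(metrics) < 2) stop("need at least 2 repeats for a sd")
  num <- vapply(metrics, is.numeric, TRUE)
  m <- metrics[, num, drop = FALSE]
  out <- rbind(vapply(m, mean, 0), vapply(m, stats::sd, 0))
  rownames(out) <- c("mean", "sd")
  as.data.frame(out)
}

#' Train one model per split and summarize
#'
#' Fits the configuration on each of the splits (seed offset by the
#' repeat index), evaluates recall, precision, accuracy, ROC-AUC and
#' PRC-AUC on each validation set at the selected epoch, and reports the
#' per-model table, a mean +/- sd summary and the index of the best model
#' by validation PRC-AUC.
#'
#' @param x fingerprint matrix for the full dataset (rownames = ids).
#' @param y labels aligned with `x` rows.
#' @param splits a [split_dataset()] result.
#' @param config a [tifp_net_config()].
#' @return List of class `repeated_training`: `metrics` (one row per
#'   split), `summary`, `best` (index), `models` (the fitted objects).
#' @export
repeated_training <- function(x, y, splits, config = tifp_net_config()) {
  stopifnot(inherits(splits, "dataset_splits"))
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  names(y) <- rownames(x)
  fits <- vector("list", length(splits))
  rows <- vector("list", length(splits))
  for (r in seq_along(splits)) {
    s <- splits[[r]]
    cfg <- config; cfg$seed <- config$seed + s$repeat_index
    fit <- tifp_net(x[as.character(s$train), , drop = FALSE],
                    y[as.character(s$train)],
                    x[as.character(s$valid), , drop = FALSE],
                    y[as.character(s$valid)], cfg)
    pv <- predict(fit, x[as.character(s$valid), , drop = FALSE])
    yv <- .as01(y[as.character(s$valid)])
    bm <- suppressWarnings(
      basic_metrics(confusion_counts(yv, as.integer(pv >= 0.5))))
    rows[[r]] <- data.frame(model = r, recall = bm[["recall"]],
                            precision = bm[["precision"]],
                            accuracy = bm[["accuracy"]],
                            roc_auc = roc_auc(pv, yv),
                            prc_auc = prc_auc(pv, yv))
    fits[[r]] <- fit
  }
  metrics <- do.call(rbind, rows)
  structure(list(metrics = metrics,
                 summary = summarize_repeats(metrics[, -1]),
                 best = which.max(metrics$prc_auc), models = fits),
            class = "repeated_training")
}

#' @export
print.repeated_training <- function(x, ...) {
  cat("repeated_training over", nrow(x$metrics), "splits; best model",
      x$best, "\n")
  print(round(x$metrics, 3), row.names = FALSE)
  cat("\nsummary:\n"); print(round(x$summary, 3))
  invisible(x)
}

#' Pairwise Tanimoto similarity of molecular fingerprints
#'
#' Computes `|A intersect B| / |A union B|` for every molecule pair and a
#' fixed-width histogram of the coefficients, the standard diversity
#' check of a screening dataset.  Fingerprint generation itself (e.g.
#' circular/Morgan bitsets) is left to standard cheminformatics tooling;
#' this function consumes the bitsets.
#'
#' @param bitsets list of integer vectors of set-bit indices, or a
#'   logical/0-1 matrix (rows = molecules).
#' @param breaks histogram breaks over `[0, 1]`.
#' @return List with `coefficients` (length `n (n - 1) / 2`) and
#'   `histogram` (named bin counts).
#' @export
pairwise_similarity <- function(bitsets, breaks = seq(0, 1, 0.1)) {
  if (is.matrix(bitsets))
    bitsets <- apply(bitsets != 0, 1, which, simplify = FALSE)
  n <- length(bitsets)
  if (n < 2) stop("need at least 2 molecules")
  if (any(vapply(bitsets, length, 0L) == 0)) stop("empty bitset")
  cf <- numeric(n * (n - 1) / 2); k <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + 1L
    a <- bitsets[[i]]; b <- bitsets[[j]]
    inter <- length(intersect(a, b))
    cf[k] <- inter / (length(a) + length(b) - inter)
  }
  h <- graphics::hist(cf, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  list(coefficients = cf,
       histogram = stats::setNames(h$counts,
                                   paste0("[", utils::head(breaks, -1), ",",
                                          breaks[-1], ")")))
}
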