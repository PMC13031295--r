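# Metrics over masked multitarget predictions, scaffold cross-validation,
# and the conformer-fidelity x solvent-regime benchmark grid.

#' Masked multitarget regression metrics
#'
#' MAE, RMSE (nm for the wavelength targets, unitless for log10 PLQY) and R2
#' computed only over observed (mask = 1) slots; R2 uses the evaluation
#' subset's own observed-label mean.  Targets with zero observations are
#' reported as absent (with a warning), never as zero or NaN.
#'
#' @param predictions n x 3 matrix (or list of length-3 vectors).
#' @param labels n x 3 matrix of targets (NA allowed at masked slots).
#' @param masks n x 3 binary matrix.
#' @return an `sc_metrics` object: per-target list of `mae`, `rmse`, `r2`,
#'   `n`.
#' @export
masked_metrics <- function(predictions, labels, masks) {
  to_mat <- function(x) if (is.list(x)) do.call(rbind, x) else as.matrix(x)
  P <- to_mat(predictions); Y <- to_mat(labels); M <- to_mat(masks)
  if (!all(dim(P) == dim(Y)) || !all(dim(P) == dim(M)))
    stop_sc("predictions, labels and masks must have identical shape")
  out <- list()
  for (k in seq_len(ncol(P))) {
    obs <- which(M[, k] == 1)
    nm <- target_names()[k]
    if (!length(obs)) {
      warning(sprintf("target %s has no observed slots; reported as absent", nm),
              call. = FALSE)
      next
    }
    e <- P[obs, k] - Y[obs, k]
    sst <- sum((Y[obs, k] - mean(Y[obs, k]))^2)
    r2 <- if (sst > 0) 1 - sum(e^2) / sst else NA_real_
    out[[nm]] <- list(mae = mean(abs(e)), rmse = sqrt(mean(e^2)), r2 = r2,
                      n = length(obs))
  }
  structure(out, class = "sc_metrics")
}

#' @export
print.sc_metrics <- function(x, ...) {
  cat("<sc_metrics>\n")
  for (nm in names(x))
    cat(sprintf("  %-10s MAE %.2f  RMSE %.2f  R2 %s  (n = %d)\n", nm,
                x[[nm]]$mae, x[[nm]]$rmse,
                ifelse(is.na(x[[nm]]$r2), "NA", sprintf("%.3f", x[[nm]]$r2)),
                x[[nm]]$n))
  invisible(x)
}

#' @export
as.data.frame.sc_metrics <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(nm)
    data.frame(target = nm, mae = x[[nm]]$mae, rmse = x[[nm]]$rmse,
               r2 = x[[nm]]$r2, n = x[[nm]]$n)))
}

#' Evaluate a trained model on a subset of records
#'
#' @param model a trained `sc_model`.
#' @param dataset an [sc_dataset()].
#' @param indices record indices to evaluate (e.g.
#'   `split_indices(split, "TEST")`).
#' @param fidelity conformer fidelity to run on (defaults to the model's
#'   coarse input fidelity; reference coordinates are never read).
#' @return list with `metrics` ([masked_metrics()]), `predictions`,
#'   `labels`, `masks`.
#' @export
evaluate_model <- function(model, dataset, indices, fidelity = NULL) {
  log_label_read(model, dataset, indices, "eval")
  P <- matrix(NA_real_, length(indices), 3)
  for (q in seq_along(indices)) {
    rec <- dataset$records[[indices[q]]]
    P[q, ] <- forward_record(model, rec, fidelity)$predictions
  }
  Y <- dataset_targets(dataset)[indices, , drop = FALSE]
  M <- dataset_masks(dataset)[indices, , drop = FALSE]
  list(metrics = masked_metrics(P, Y, M), predictions = P, labels = Y,
       masks = M)
}

#' Scaffold cross-validation
#'
#' Trains a fresh model per fold with [scaffold_kfold()] splits and evaluates
#' on each held-out fold.  Records whose keys appear in `exclusions` are
#' dropped from TEST metrics only (they still train).  The summary reports
#' the unweighted mean and sample standard deviation across folds.
#'
#' @param model_factory function(fold_seed) returning a fresh initialized
#'   `sc_model`.
#' @param dataset an [sc_dataset()].
#' @param k number of folds.
#' @param seed integer seed; per-fold seeds are derived as seed + fold index.
#' @param schedule a [train_schedule()].
#' @param exclusions character vector of record keys (see format in the
#'   manifest: `"<chromophore key> | <solvent key>"`).
#' @param targets property-loss targets, as in [two_phase_train()].
#' @return an `sc_cv_result`: `folds` (per-fold `sc_metrics`), `summary`
#'   (data.frame of mean and sd per target/metric), `excluded_per_fold`.
#' @export
crossvalidate <- function(model_factory, dataset, k = 5L, seed = 1L,
                          schedule = train_schedule(), exclusions = character(),
                          targets = "lambda_abs") {
  splits <- scaffold_kfold(dataset, k, seed = seed)
  keys <- vapply(dataset$records, record_key, "")
  folds <- vector("list", k)
  excluded_per_fold <- integer(k)
  for (f in seq_len(k)) {
    fold_seed <- seed + f
    sch <- schedule
    sch$seed <- fold_seed
    model <- model_factory(fold_seed)
    state <- if (length(targets) > 1)
      train_multitarget(model, dataset, splits[[f]], sch)
    else two_phase_train(model, dataset, splits[[f]], sch, targets = targets)
    test_idx <- split_indices(splits[[f]], "TEST")
    drop <- keys[test_idx] %in% exclusions
    excluded_per_fold[f] <- sum(drop)
    folds[[f]] <- evaluate_model(state$model, dataset, test_idx[!drop])$metrics
  }
  rows <- list()
  for (nm in target_names()) {
    vals <- lapply(folds, function(m) m[[nm]])
    vals <- vals[!vapply(vals, is.null, TRUE)]
    if (!length(vals)) next
    for (met in c("mae", "rmse", "r2")) {
      v <- vapply(vals, `[[`, 0, met)
      rows[[length(rows) + 1L]] <- data.frame(
        target = nm, metric = met, mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else NA_real_, n_folds = length(v))
    }
  }
  structure(list(folds = folds, summary = do.call(rbind, rows),
                 excluded_per_fold = excluded_per_fold, k = k, seed = seed),
            class = "sc_cv_result")
}

#' @export
print.sc_cv_result <- function(x, ...) {
  cat(sprintf("<sc_cv_result> %d-fold scaffold CV (seed %d)\n", x$k, x$seed))
  s <- x$summary[x$summary$metric == "mae", ]
  for (r in seq_len(nrow(s)))
    cat(sprintf("  %-10s MAE %.2f +/- %s\n", s$target[r], s$mean[r],
                ifelse(is.na(s$sd[r]), "NA", sprintf("%.2f", s$sd[r]))))
  invisible(x)
}

#' Conformer-source x solvent-regime benchmark grid
#'
#' Trains one independently seeded model per grid cell, holding every
#' non-varied hyperparameter fixed, and evaluates all cells on the identical
#' TEST assignment.  Regime `NONE` uses the solvent-blind ablation; regime
#' `EMBEDDING` uses the given fusion strategy.  Grid cells train and infer on
#' the cell's conformer source (no conformation-pair refinement:
#' `w_coord = 0`).
#'
#' @param dataset an [sc_dataset()].
#' @param split a shared `sc_split`.
#' @param sources character vector of fidelity tags.
#' @param regimes subset of `c("NONE", "EMBEDDING")`.
#' @param strategies fusion strategy used in the EMBEDDING regime.
#' @param schedule a [train_schedule()].
#' @param base_config a [model_config()] providing non-varied hyperparameters.
#' @param solvent_params optional pretrained solvent encoder parameters.
#' @param seed integer; per-cell seeds derive from it and the cell key.
#' @return an `sc_grid_result` with a `table` data.frame keyed by
#'   (source, regime, strategy) and per-cell `sc_metrics`.
#' @export
run_benchmark_grid <- function(dataset, split, sources = c("RDKIT", "XTB", "DFT_IMP"),
                               regimes = c("NONE", "EMBEDDING"),
                               strategies = "VIRTUAL_NODE",
                               schedule = train_schedule(),
                               base_config = model_config(),
                               solvent_params = NULL, seed = 1L) {
  test_idx <- split_indices(split, "TEST")
  for (src in sources) {
    missing_cf <- which(vapply(dataset$records, function(r)
      is.null(r$conformers[[src]]), TRUE))
    if (length(missing_cf))
      stop_sc("fidelity '%s' missing for records: %s", src,
              paste(utils::head(missing_cf, 10), collapse = ", "))
  }
  cells <- list()
  rows <- list()
  for (src in sources) for (reg in regimes) {
    strats <- if (reg == "NONE") "NONE" else strategies
    for (strat in strats) {
      cell_key <- paste(src, reg, strat, sep = "/")
      cfg <- base_config
      cfg$fusion <- strat
      cfg$pair <- pair_training_config(src, src, w_prop = 1, w_coord = 0)
      sch <- schedule
      sch$seed <- derive_seed(seed, cell_key)
      model <- model_init(cfg, seed = sch$seed,
                          solvent_params = if (strat != "NONE") solvent_params)
      state <- two_phase_train(model, dataset, split, sch,
                               targets = "lambda_abs")
      ev <- evaluate_model(state$model, dataset, test_idx)
      cells[[cell_key]] <- ev$metrics
      m <- ev$metrics$lambda_abs
      rows[[length(rows) + 1L]] <- data.frame(
        source = src, regime = reg, strategy = strat, target = "lambda_abs",
        mae = m$mae, rmse = m$rmse, r2 = m$r2, n = m$n)
    }
  }
  structure(list(table = do.call(rbind, rows), cells = cells,
                 test_indices = test_idx, seed = seed),
            class = "sc_grid_result")
}

#' @export
print.sc_grid_result <- function(x, ...) {
  cat("<sc_grid_result>\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a grid result to CSV
#' @param grid an `sc_grid_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.csv(grid$table, path, row.names = FALSE)
  invisible(path)
}
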