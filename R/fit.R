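# Front-end fitting interface: one call from curated dataset to a trained,
# evaluated model, returning a classed object with the usual methods.

#' Fit a solvent-aware chromophore property model
#'
#' End-to-end convenience wrapper: scaffold-splits the data (unless a split
#' is supplied), optionally pretrains the solvent encoder on the 2D
#' dual-encoder baseline using TRAIN records only, assembles the 3D model
#' with the requested fusion strategy, runs the two-phase training schedule,
#' and evaluates on the held-out TEST scaffolds.
#'
#' @param dataset an [sc_dataset()] with conformers attached.
#' @param split an `sc_split` from [scaffold_split()], or `NULL` to draw an
#'   80/10/10 scaffold split from `seed`.
#' @param config a [model_config()].
#' @param schedule a [train_schedule()].
#' @param targets property-loss targets (default absorption only; pass
#'   `target_names()` for the multitarget objective).
#' @param pretrain pretrain the solvent encoder (ignored for fusion `NONE`).
#' @param pretrain_epochs epochs for the pretraining stage.
#' @param seed master seed.
#' @return an object of class `solvachrom` with components `model`,
#'   `train_state`, `split`, `test` (held-out evaluation), `pretrain`
#'   (pretraining history or `NULL`) and `call`.  Methods: `print`,
#'   `summary`, `predict`, `coef`, `plot`, `residuals`.
#' @examples
#' \donttest{
#' fix <- make_fixture_dataset(fixture_spec(n_chromophores = 12, seed = 1))
#' fit <- solvachrom(fix$dataset,
#'                   config = model_config(backbone = backbone_config(
#'                     width = 32, layers = 1, heads = 4, K = 16)),
#'                   schedule = train_schedule(phase1_epochs = 3,
#'                                             phase2_epochs = 2),
#'                   seed = 1)
#' print(fit)
#' }
#' @export
solvachrom <- function(dataset, split = NULL, config = model_config(),
                       schedule = train_schedule(), targets = "lambda_abs",
                       pretrain = TRUE, pretrain_epochs = 15L, seed = 1L) {
  stopifnot(inherits(dataset, "sc_dataset"))
  cl <- match.call()
  split <- split %||% scaffold_split(dataset, c(0.8, 0.1, 0.1), seed = seed)
  schedule$seed <- schedule$seed %||% seed
  pre <- NULL
  solvent_params <- NULL
  if (pretrain && config$fusion != "NONE") {
    pre <- pretrain_solvent_encoder(dataset, split,
                                    width = config$solvent_width,
                                    depth = config$solvent_depth,
                                    epochs = pretrain_epochs,
                                    seed = derive_seed(seed, "pretrain"),
                                    targets = targets[1])
    solvent_params <- pre$params
  }
  model <- model_init(config, seed = seed, solvent_params = solvent_params)
  state <- if (length(targets) > 1)
    train_multitarget(model, dataset, split, schedule)
  else two_phase_train(model, dataset, split, schedule, targets = targets)
  test_idx <- split_indices(split, "TEST")
  test <- evaluate_model(state$model, dataset, test_idx)
  structure(list(model = state$model, train_state = state, split = split,
                 test = test, test_indices = test_idx, pretrain = pre,
                 targets = targets, call = cl),
            class = "solvachrom")
}

#' @export
print.solvachrom <- function(x, ...) {
  cat("Solvent-aware chromophore property model\n")
  cat(sprintf("  fusion: %s; input fidelity: %s; targets: %s\n",
              x$model$config$fusion, x$model$config$pair$input_fidelity,
              paste(x$targets, collapse = ", ")))
  tab <- table(x$split$assignment$subset)
  cat(sprintf("  records: %s\n",
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  cat("  held-out test metrics:\n")
  for (nm in names(x$test$metrics)) {
    m <- x$test$metrics[[nm]]
    cat(sprintf("    %-10s MAE %.2f  RMSE %.2f  R2 %s  (n = %d)\n", nm,
                m$mae, m$rmse,
                ifelse(is.na(m$r2), "NA", sprintf("%.3f", m$r2)), m$n))
  }
  invisible(x)
}

#' @export
summary.solvachrom <- function(object, ...) {
  h <- object$train_state$history
  out <- list(test = as.data.frame(object$test$metrics),
              epochs = nrow(h),
              best_val = object$train_state$best_val,
              update_counts = object$train_state$update_counts,
              norm = object$model$norm)
  class(out) <- "summary.solvachrom"
  out
}

#' @export
print.summary.solvachrom <- function(x, ...) {
  cat("solvachrom fit summary\n")
  cat(sprintf("  %d training epochs, best validation metric %.4g\n",
              x$epochs, x$best_val))
  cat(sprintf("  Adam steps per group: %s\n",
              paste(sprintf("%s %d", names(x$update_counts), x$update_counts),
                    collapse = ", ")))
  cat("  held-out test metrics:\n")
  print(x$test, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predict on new records
#'
#' @param object a fitted `solvachrom` model.
#' @param newdata an [sc_dataset()] or list of [labeled_pair()] records.
#' @param fidelity conformer fidelity to run on (default: the model's coarse
#'   input fidelity).
#' @param ... unused.
#' @return matrix of predictions (rows = records, columns = targets, physical
#'   units).
#' @export
predict.solvachrom <- function(object, newdata = NULL, fidelity = NULL, ...) {
  if (is.null(newdata))
    stop_sc("newdata is required (an sc_dataset or list of records)")
  records <- if (inherits(newdata, "sc_dataset")) newdata$records
  else if (inherits(newdata, "sc_record")) list(newdata)
  else newdata
  P <- t(vapply(records, function(rec)
    forward_record(object$model, rec, fidelity)$predictions, numeric(3)))
  colnames(P) <- target_names()
  P
}

#' @export
coef.solvachrom <- function(object, ...) object$model$params

#' @export
residuals.solvachrom <- function(object, ...) {
  R <- object$test$predictions - object$test$labels
  R[object$test$masks == 0] <- NA_real_
  colnames(R) <- target_names()
  R
}

#' Plot training history and test predictions
#'
#' Left: per-epoch training loss and validation metric (phases separated by
#' a vertical line).  Right: observed vs predicted absorption on the held-out
#' test records.
#'
#' @param x a fitted `solvachrom` model.
#' @param ... unused.
#' @export
plot.solvachrom <- function(x, ...) {
  h <- x$train_state$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(seq_len(nrow(h)), h$val_metric, type = "b", pch = 16,
                 cex = 0.6, xlab = "epoch", ylab = "validation metric",
                 main = "training history")
  if (any(h$phase == 2))
    graphics::abline(v = sum(h$phase == 1) + 0.5, lty = 2, col = "grey40")
  obs <- x$test$labels[, 1]
  pred <- x$test$predictions[, 1]
  ok <- x$test$masks[, 1] == 1
  graphics::plot(obs[ok], pred[ok], pch = 16, cex = 0.6,
                 xlab = "observed lambda_abs (nm)",
                 ylab = "predicted lambda_abs (nm)",
                 main = "held-out test")
  graphics::abline(0, 1, col = "grey40")
  invisible(x)
}
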