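# Optimization: Adam, solvent-encoder pretraining, two-phase training with
# parameter-group freezing, masked multitarget objectives.

adam_new <- function() list(m = list(), v = list(), t = 0L)

# One Adam step.  Walks the gradient structure and updates only parameters
# that received a gradient; frozen groups pass NULL gradients and are
# untouched (bit-exact).
adam_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  walk <- function(p, g, m, v) {
    if (is.null(g)) return(list(p = p, m = m, v = v))
    if (is.list(g)) {
      if (is.null(m)) m <- list()
      if (is.null(v)) v <- list()
      for (k in names(g)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps) - lr * weight_decay * p
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, opt$m, opt$v)
  opt$m <- r$m; opt$v <- r$v
  list(params = r$p, opt = opt)
}

#' Training schedule
#'
#' Phase 1 trains the regression head to convergence with both encoders (the
#' 3D backbone and the solvent D-MPNN, plus the solvent projection) frozen;
#' phase 2 unfreezes the entire network for a joint finetune.  Convergence is
#' operationalized as early stopping on the validation metric with the given
#' patience.
#'
#' @param phase1_epochs,phase2_epochs maximum epochs per phase.
#' @param patience early-stopping patience (validation evaluations).
#' @param lr_phase1,lr_phase2 Adam learning rates per phase.
#' @param batch_size minibatch size.
#' @param seed integer seed governing shuffling (weights are seeded at
#'   [model_init()]).
#' @param val_metric `"lambda_abs"` (validation MAE on absorption, default),
#'   another target name, or `"loss"` (masked multitarget validation loss).
#' @param lr_decay multiplicative per-epoch decay of the phase-2 learning
#'   rate (1 = constant).
#' @param weight_decay decoupled weight decay applied in phase 2 (0 = off).
#' @return a `TrainSchedule` list.
#' @export
train_schedule <- function(phase1_epochs = 40L, phase2_epochs = 15L,
                           patience = 10L, lr_phase1 = 1e-3,
                           lr_phase2 = 3e-4, batch_size = 32L, seed = 1L,
                           val_metric = "lambda_abs", lr_decay = 1,
                           weight_decay = 0) {
  list(phase1_epochs = as.integer(phase1_epochs),
       phase2_epochs = as.integer(phase2_epochs),
       patience = as.integer(patience), lr_phase1 = lr_phase1,
       lr_phase2 = lr_phase2, batch_size = as.integer(batch_size),
       seed = as.integer(seed), val_metric = val_metric, lr_decay = lr_decay,
       weight_decay = weight_decay)
}

# normalization constants from TRAIN observed targets only
norm_from_train <- function(dataset, train_idx) {
  tg <- dataset_targets(dataset)[train_idx, , drop = FALSE]
  mu <- numeric(3); sd <- rep(1, 3)
  for (k in 1:3) {
    obs <- tg[!is.na(tg[, k]), k]
    if (length(obs)) mu[k] <- mean(obs)
    if (length(obs) > 1 && stats::sd(obs) > 1e-12) sd[k] <- stats::sd(obs)
  }
  list(mu = mu, sd = sd)
}

log_label_read <- function(model, dataset, idx, purpose) {
  seen <- model$log$seen %||% new.env(parent = emptyenv())
  model$log$seen <- seen
  for (i in idx) {
    key <- record_key(dataset$records[[i]])
    tag <- paste(purpose, key)
    if (is.null(seen[[tag]])) {
      seen[[tag]] <- TRUE
      log_event(model, paste0("labels-", purpose), key)
    }
  }
  invisible(NULL)
}

# static per-record features reused across epochs
build_static <- function(model, dataset, idx, fidelity) {
  out <- vector("list", length(dataset$records))
  for (i in idx) {
    rec <- dataset$records[[i]]
    cf <- rec$conformers[[fidelity]]
    if (is.null(cf))
      stop_sc("record %d has no conformer at fidelity '%s'", i, fidelity)
    out[[i]] <- list(sfeat = featurize_graph(rec$solvent),
                     bf = backbone_featurize(rec$chromophore, cf,
                                             model$config$backbone))
  }
  out
}

val_metric_value <- function(model, dataset, val_idx, statics, targets,
                             metric, refs = NULL) {
  if (metric == "loss") {
    # full objective on the validation subset, including the coordinate term
    # when conformation-pair supervision is active
    tot <- 0
    for (i in val_idx) {
      rec <- dataset$records[[i]]
      fwd <- forward_record(model, rec, keep_cache = FALSE,
                            static = statics[[i]], log = FALSE)
      jl <- joint_loss_grad(fwd$predictions, fwd$refined, rec,
                            if (is.null(refs)) NULL else refs[[i]],
                            model$config$pair, model$norm, targets = targets)
      tot <- tot + jl$value
    }
    return(tot / max(length(val_idx), 1))
  }
  k <- match(metric, target_names())
  err <- n <- 0
  for (i in val_idx) {
    rec <- dataset$records[[i]]
    if (rec$mask[k] != 1L) next
    fwd <- forward_record(model, rec, keep_cache = FALSE,
                          static = statics[[i]], log = FALSE)
    err <- err + abs(fwd$predictions[k] - rec$targets[k])
    n <- n + 1
  }
  if (n == 0) stop_sc("validation subset has no observed %s", metric)
  err / n
}

#' Two-phase training of a solvent-aware model
#'
#' Phase 1 optimizes only the property head (encoders frozen, bit-exact);
#' phase 2 unfreezes everything for a joint finetune with the conformation-
#' pair objective.  The best checkpoint is selected by the validation metric.
#' Deterministic given (model seed, dataset, split, schedule).
#'
#' @param model an initialized [model_init()] model.
#' @param dataset an [sc_dataset()].
#' @param split an `sc_split` with non-empty TRAIN and VAL subsets.
#' @param schedule a [train_schedule()].
#' @param targets target names the property loss reads (masked slots never
#'   contribute); default absorption only.
#' @return an `sc_train_state`: `model` (best checkpoint), `history`
#'   (per-epoch losses and validation metric), `update_counts` (Adam steps
#'   per parameter group), `norm`, `schedule`.
#' @export
two_phase_train <- function(model, dataset, split, schedule = train_schedule(),
                            targets = "lambda_abs") {
  train_idx <- split_indices(split, "TRAIN")
  val_idx <- split_indices(split, "VAL")
  if (!length(train_idx)) stop_sc("TRAIN subset is empty")
  if (!length(val_idx)) stop_sc("validation subset is empty")
  cfg <- model$config
  fid <- cfg$pair$input_fidelity
  ref_fid <- cfg$pair$reference_fidelity

  model$norm <- norm_from_train(dataset, train_idx)
  log_label_read(model, dataset, train_idx, "train")
  log_label_read(model, dataset, val_idx, "val")
  statics <- build_static(model, dataset, c(train_idx, val_idx), fid)
  refs <- vector("list", length(dataset$records))
  if (cfg$pair$w_coord > 0)
    for (i in c(train_idx, val_idx))
      refs[[i]] <- dataset$records[[i]]$conformers[[ref_fid]]

  history <- data.frame()
  update_counts <- c(backbone = 0L, solvent = 0L, proj = 0L, head = 0L)
  sel <- match(targets, target_names())

  ## ---- phase 1: frozen encoders, head only (cached head inputs) ----
  xs <- vector("list", length(dataset$records))
  for (i in c(train_idx, val_idx)) {
    fwd <- forward_record(model, dataset$records[[i]], keep_cache = TRUE,
                          static = statics[[i]], log = FALSE)
    xs[[i]] <- fwd$cache$head$x
  }
  head_metric <- function(head) {
    m2 <- model; m2$params$head <- head
    if (schedule$val_metric == "loss") {
      tot <- 0
      for (i in val_idx) {
        rec <- dataset$records[[i]]
        y <- model$norm$mu + model$norm$sd * head_forward(xs[[i]], head)$y
        jl <- joint_loss_grad(stats::setNames(y, target_names()), NULL, rec,
                              NULL, cfg$pair, model$norm, targets = targets)
        tot <- tot + jl$value
      }
      tot / length(val_idx)
    } else {
      k <- match(schedule$val_metric, target_names())
      errs <- vapply(val_idx, function(i) {
        rec <- dataset$records[[i]]
        if (rec$mask[k] != 1L) return(NA_real_)
        y <- model$norm$mu[k] + model$norm$sd[k] * head_forward(xs[[i]], head)$y[k]
        abs(y - rec$targets[k])
      }, 0)
      mean(errs, na.rm = TRUE)
    }
  }
  opt <- adam_new()
  head <- model$params$head
  best_head <- head; best_val <- Inf; wait <- 0L
  for (ep in seq_len(schedule$phase1_epochs)) {
    ord <- with_seed(derive_seed(schedule$seed, paste0("p1e", ep)),
                     sample(train_idx))
    ep_loss <- 0
    for (start in seq(1, length(ord), by = schedule$batch_size)) {
      batch <- ord[start:min(start + schedule$batch_size - 1L, length(ord))]
      acc <- NULL
      for (i in batch) {
        rec <- dataset$records[[i]]
        hf <- head_forward(xs[[i]], head, keep_cache = TRUE)
        pred <- model$norm$mu + model$norm$sd * hf$y
        names(pred) <- target_names()
        jl <- joint_loss_grad(pred, NULL, rec, NULL, cfg$pair, model$norm,
                              targets = targets)
        hb <- head_backward(jl$dpred * model$norm$sd, hf$cache, head)
        acc <- if (is.null(acc)) hb$grads else plist_add(acc, hb$grads)
        ep_loss <- ep_loss + jl$value
      }
      st <- adam_step(opt, head, plist_scale(acc, 1 / length(batch)),
                      schedule$lr_phase1)
      head <- st$params; opt <- st$opt
      update_counts["head"] <- update_counts["head"] + 1L
    }
    vm <- head_metric(head)
    history <- rbind(history, data.frame(phase = 1L, epoch = ep,
                                         train_loss = ep_loss / length(ord),
                                         val_metric = vm))
    if (vm < best_val - 1e-9) { best_val <- vm; best_head <- head; wait <- 0L }
    else { wait <- wait + 1L; if (wait >= schedule$patience) break }
  }
  model$params$head <- best_head

  ## ---- phase 2: joint finetune of the entire network ----
  opt2 <- adam_new()
  best_params <- model$params
  best_val2 <- val_metric_value(model, dataset, val_idx, statics, targets,
                                schedule$val_metric, refs = refs)
  wait <- 0L
  for (ep in seq_len(schedule$phase2_epochs)) {
    ord <- with_seed(derive_seed(schedule$seed, paste0("p2e", ep)),
                     sample(train_idx))
    ep_loss <- 0
    for (start in seq(1, length(ord), by = schedule$batch_size)) {
      batch <- ord[start:min(start + schedule$batch_size - 1L, length(ord))]
      acc <- NULL
      for (i in batch) {
        rg <- record_grad(model, dataset$records[[i]], refs[[i]],
                          static = statics[[i]], targets = targets)
        acc <- if (is.null(acc)) rg$grads else plist_add(acc, rg$grads)
        ep_loss <- ep_loss + rg$loss
      }
      st <- adam_step(opt2, model$params, plist_scale(acc, 1 / length(batch)),
                      schedule$lr_phase2 * (schedule$lr_decay %||% 1)^(ep - 1),
                      weight_decay = schedule$weight_decay %||% 0)
      model$params <- st$params; opt2 <- st$opt
      for (gname in names(update_counts))
        if (!is.null(acc[[gname]]))
          update_counts[gname] <- update_counts[gname] + 1L
    }
    vm <- val_metric_value(model, dataset, val_idx, statics, targets,
                           schedule$val_metric, refs = refs)
    history <- rbind(history, data.frame(phase = 2L, epoch = ep,
                                         train_loss = ep_loss / length(ord),
                                         val_metric = vm))
    if (vm < best_val2 - 1e-9) {
      best_val2 <- vm; best_params <- model$params; wait <- 0L
    } else { wait <- wait + 1L; if (wait >= schedule$patience) break }
  }
  final_params <- model$params   # last optimizer state, pre checkpoint revert
  model$params <- best_params

  structure(list(model = model, final_params = final_params,
                 history = history,
                 update_counts = update_counts, norm = model$norm,
                 schedule = schedule, targets = targets,
                 best_val = min(best_val2, best_val)),
            class = "sc_train_state")
}

#' @export
print.sc_train_state <- function(x, ...) {
  cat(sprintf("<sc_train_state> %d epochs (%d phase-1, %d phase-2), best val %.4g\n",
              nrow(x$history), sum(x$history$phase == 1),
              sum(x$history$phase == 2), x$best_val))
  invisible(x)
}

#' Masked multitarget training
#'
#' [two_phase_train()] with the masked multitarget loss over absorption,
#' emission and log10 PLQY: gradients are computed only for observed
#' annotations, and checkpoint selection uses the masked multitarget
#' validation loss.
#'
#' @inheritParams two_phase_train
#' @return an `sc_train_state`.
#' @export
train_multitarget <- function(model, dataset, split,
                              schedule = train_schedule(val_metric = "loss")) {
  tg <- dataset_targets(dataset)
  if (any(colSums(!is.na(tg)) == 0))
    stop_sc("each target needs at least one observation for multitarget training")
  schedule$val_metric <- "loss"
  two_phase_train(model, dataset, split, schedule, targets = target_names())
}

#' Pretrain the solvent encoder on the 2D dual-encoder baseline
#'
#' Trains [dual_predict()] (two independent D-MPNNs + regression head) on the
#' TRAIN subset only, then returns the solvent-branch parameters marked
#' frozen for reuse as a fixed source of solvent embeddings.  Training never
#' touches VAL or TEST records (auditable from the returned access keys).
#'
#' @param dataset an [sc_dataset()].
#' @param split an `sc_split`; TRAIN must contain observed absorption values.
#' @param width,depth encoder size.
#' @param head_hidden regression head hidden width.
#' @param epochs,lr,batch_size,patience optimization settings.
#' @param seed integer seed.
#' @param targets targets to pretrain on (default absorption only; pass all
#'   three names for multitarget pretraining).
#' @return list with `params` (solvent `EncoderParams`), `frozen = TRUE`,
#'   `history`, `accessed_keys` (record keys read during training), `dual`
#'   (the full dual-model parameters).
#' @export
pretrain_solvent_encoder <- function(dataset, split, width = 64L, depth = 2L,
                                     head_hidden = 64L, epochs = 25L,
                                     lr = 1e-3, batch_size = 32L,
                                     patience = 6L, seed = 1L,
                                     targets = "lambda_abs") {
  train_idx <- split_indices(split, "TRAIN")
  val_idx <- split_indices(split, "VAL")
  if (!length(train_idx)) stop_sc("TRAIN subset is empty")
  tg <- dataset_targets(dataset)
  sel <- match(targets, target_names())
  if (!any(!is.na(tg[train_idx, sel])))
    stop_sc("TRAIN subset has no observed values for %s",
            paste(targets, collapse = ","))
  norm <- norm_from_train(dataset, train_idx)
  params <- dual_init(width, depth, head_hidden, n_targets = 3L, seed = seed)
  feats <- vector("list", length(dataset$records))
  for (i in c(train_idx, val_idx))
    feats[[i]] <- list(chrom = featurize_graph(dataset$records[[i]]$chromophore),
                       solv = featurize_graph(dataset$records[[i]]$solvent))
  pcfg <- list(w_prop = 1, w_coord = 0)
  fwd_rec <- function(i, keep = FALSE) {
    fc <- mpnn_forward(feats[[i]]$chrom, params$chrom, keep_cache = keep)
    fs <- mpnn_forward(feats[[i]]$solv, params$solv, keep_cache = keep)
    hf <- head_forward(c(fc$z, fs$z), params$head, keep_cache = keep)
    list(fc = fc, fs = fs, hf = hf,
         pred = stats::setNames(norm$mu + norm$sd * hf$y, target_names()))
  }
  vmetric <- function() {
    idx <- if (length(val_idx)) val_idx else train_idx
    e <- vapply(idx, function(i) {
      rec <- dataset$records[[i]]
      if (rec$mask[sel[1]] != 1L) return(NA_real_)
      abs(fwd_rec(i)$pred[sel[1]] - rec$targets[sel[1]])
    }, 0)
    mean(e, na.rm = TRUE)
  }
  opt <- adam_new()
  best <- params; best_val <- Inf; wait <- 0L
  history <- data.frame()
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, paste0("pre", ep)), sample(train_idx))
    ep_loss <- 0
    for (start in seq(1, length(ord), by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1L, length(ord))]
      acc <- NULL
      for (i in batch) {
        rec <- dataset$records[[i]]
        f <- fwd_rec(i, keep = TRUE)
        jl <- joint_loss_grad(f$pred, NULL, rec, NULL, pcfg, norm,
                              targets = targets)
        hb <- head_backward(jl$dpred * norm$sd, f$hf$cache, params$head)
        g <- list(chrom = mpnn_backward(hb$dx[seq_len(width)], f$fc$cache,
                                        params$chrom),
                  solv = mpnn_backward(hb$dx[width + seq_len(width)],
                                       f$fs$cache, params$solv),
                  head = hb$grads)
        acc <- if (is.null(acc)) g else plist_add(acc, g)
        ep_loss <- ep_loss + jl$value
      }
      st <- adam_step(opt, params, plist_scale(acc, 1 / length(batch)), lr)
      params <- st$params; opt <- st$opt
    }
    vm <- vmetric()
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = ep_loss / length(ord),
                                         val_mae = vm))
    if (vm < best_val - 1e-9) { best_val <- vm; best <- params; wait <- 0L }
    else { wait <- wait + 1L; if (wait >= patience) break }
  }
  solvent <- best$solv
  attr(solvent, "frozen") <- TRUE
  list(params = solvent, frozen = TRUE, history = history,
       accessed_keys = unique(vapply(train_idx, function(i)
         record_key(dataset$records[[i]]), "")),
       norm = norm, dual = best)
}
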