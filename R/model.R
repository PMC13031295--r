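# Assembly of the solvent-aware 3D property models: fusion strategies,
# joint property + coordinate-refinement objective, coarse-conformer
# inference.

#' Conformation-pair training configuration
#'
#' @param input_fidelity fidelity tag of the coarse input conformer.
#' @param reference_fidelity fidelity tag of the reference (target) geometry.
#' @param w_prop,w_coord non-negative loss weights for the masked property
#'   term and the Kabsch-aligned coordinate term (not both zero).
#' @param coord_heavy_only restrict the coordinate loss to heavy atoms.
#' @param levels registered fidelity tags.
#' @return a `PairTrainingConfig` list.
#' @export
pair_training_config <- function(input_fidelity = "XTB",
                                 reference_fidelity = "DFT_IMP",
                                 w_prop = 1, w_coord = 1,
                                 coord_heavy_only = FALSE,
                                 levels = fidelity_levels()) {
  if (!input_fidelity %in% levels || !reference_fidelity %in% levels)
    stop_sc("fidelity tags must be registered levels (%s)",
            paste(levels, collapse = ", "))
  if (w_prop < 0 || w_coord < 0 || (w_prop == 0 && w_coord == 0))
    stop_sc("loss weights must be >= 0 and not both zero")
  list(input_fidelity = input_fidelity, reference_fidelity = reference_fidelity,
       w_prop = w_prop, w_coord = w_coord, coord_heavy_only = coord_heavy_only)
}

#' Full model configuration
#'
#' @param fusion `"VIRTUAL_NODE"` (solvent embedding projected and summed
#'   into the virtual node before the first attention block),
#'   `"HEAD_CONCAT"` (solvent embedding concatenated with the final
#'   molecule embedding at the regression head) or `"NONE"` (solvent-blind
#'   ablation).
#' @param backbone a [backbone_config()].
#' @param solvent_width,solvent_depth D-MPNN solvent encoder size.
#' @param head_hidden hidden width of the property head.
#' @param pair a [pair_training_config()].
#' @param refine_iterations refinement steps used by coordinate utilities.
#' @return a model configuration list.
#' @export
model_config <- function(fusion = c("VIRTUAL_NODE", "HEAD_CONCAT", "NONE"),
                         backbone = backbone_config(),
                         solvent_width = 64L, solvent_depth = 2L,
                         head_hidden = 64L,
                         pair = pair_training_config(),
                         refine_iterations = 1L) {
  fusion <- match.arg(fusion)
  list(fusion = fusion, backbone = backbone,
       solvent_width = as.integer(solvent_width),
       solvent_depth = as.integer(solvent_depth),
       head_hidden = as.integer(head_hidden), pair = pair,
       refine_iterations = as.integer(refine_iterations))
}

#' Initialize a solvent-aware model
#'
#' @param config a [model_config()].
#' @param seed integer seed; all weight initialization derives from it.
#' @param solvent_params optional pretrained solvent-encoder parameters (from
#'   [pretrain_solvent_encoder()]); freshly initialized when omitted.
#' @return an object of class `sc_model` holding parameter groups
#'   (`backbone`, `solvent`, `proj`, `head`), normalization constants and an
#'   access log.
#' @export
model_init <- function(config = model_config(), seed = 1L,
                       solvent_params = NULL) {
  W <- config$backbone$width
  head_in <- if (config$fusion == "HEAD_CONCAT") W + config$solvent_width else W
  solvent <- solvent_params %||%
    mpnn_init(config$solvent_width, config$solvent_depth,
              seed = derive_seed(seed, "solvent"))
  if (solvent$width != config$solvent_width)
    stop_sc("solvent encoder width %d does not match config width %d",
            solvent$width, config$solvent_width)
  params <- list(
    backbone = backbone_init(config$backbone, seed = derive_seed(seed, "backbone")),
    solvent = solvent,
    proj = list(Wp = with_seed(derive_seed(seed, "proj"),
                               init_weight(config$solvent_width, W))),
    head = with_seed(derive_seed(seed, "head"), list(
      W1 = init_weight(head_in, config$head_hidden),
      b1 = stats::rnorm(config$head_hidden, sd = 0.02),
      W2 = init_weight(config$head_hidden, 3L), b2 = numeric(3L)))
  )
  structure(list(config = config, params = params,
                 norm = list(mu = c(0, 0, 0), sd = c(1, 1, 1)),
                 seed = as.integer(seed),
                 log = new.env(parent = emptyenv())),
            class = "sc_model")
}

#' @export
print.sc_model <- function(x, ...) {
  cat(sprintf("<sc_model> fusion %s, backbone %dx%d (width %d), solvent D-MPNN %d/%d\n",
              x$config$fusion, x$config$backbone$layers, x$config$backbone$heads,
              x$config$backbone$width, x$config$solvent_width, x$config$solvent_depth))
  invisible(x)
}

log_event <- function(model, type, key, detail = NA_character_) {
  ev <- model$log$events %||% list()
  ev[[length(ev) + 1L]] <- list(type = type, key = key, detail = detail)
  model$log$events <- ev
  invisible(NULL)
}

#' Access log of a model
#' @param model an `sc_model`.
#' @return data.frame of logged data accesses (type, key, detail).
#' @export
access_log <- function(model) {
  ev <- model$log$events %||% list()
  do.call(rbind, c(list(data.frame(type = character(), key = character(),
                                   detail = character())),
                   lapply(ev, function(e)
                     data.frame(type = e$type, key = e$key, detail = e$detail))))
}

record_key <- function(record)
  paste(record$chromophore$canonical_key, record$solvent$canonical_key, sep = " | ")

#' Inject a solvent embedding into the virtual-node embedding
#'
#' Returns `virtual_embedding + W_p %*% solvent_embedding`; applied once,
#' before the first attention block (fusion strategy of the virtual-node
#' kind).
#'
#' @param virtual_embedding numeric vector (backbone atom-feature width).
#' @param solvent_embedding numeric vector (solvent encoder width).
#' @param projection matrix `W_p` of shape solvent width x backbone width.
#' @return numeric vector of the backbone width.
#' @export
inject_solvent <- function(virtual_embedding, solvent_embedding, projection) {
  if (length(solvent_embedding) != nrow(projection) ||
      length(virtual_embedding) != ncol(projection))
    stop_sc("projection shape %dx%d incompatible with embeddings (%d, %d)",
            nrow(projection), ncol(projection),
            length(solvent_embedding), length(virtual_embedding))
  as.numeric(virtual_embedding) + as.numeric(solvent_embedding %*% projection)
}

# Forward pass over one record.  Returns predictions in physical units,
# refined coordinates, and caches for backprop when requested.
forward_record <- function(model, record, fidelity = NULL, keep_cache = FALSE,
                           static = NULL, log = TRUE) {
  cfg <- model$config
  fidelity <- fidelity %||% cfg$pair$input_fidelity
  conformer <- record$conformers[[fidelity]]
  if (is.null(conformer))
    stop_sc("record has no conformer at fidelity '%s' (available: %s)",
            fidelity, paste(names(record$conformers), collapse = ", "))
  if (log) log_event(model, "conformer", record_key(record), fidelity)

  sfeat <- static$sfeat %||% featurize_graph(record$solvent)
  bffeat <- static$bf %||% backbone_featurize(record$chromophore, conformer,
                                              cfg$backbone)
  zs <- NULL; scache <- NULL
  if (cfg$fusion != "NONE") {
    sfwd <- mpnn_forward(sfeat, model$params$solvent, keep_cache = keep_cache)
    zs <- sfwd$z
    scache <- sfwd$cache
  }
  ve <- if (cfg$fusion == "VIRTUAL_NODE")
    as.numeric(zs %*% model$params$proj$Wp) else NULL
  bb <- backbone_pass(bffeat, conformer$coords, model$params$backbone,
                      cfg$backbone, virtual_extra = ve, keep_cache = keep_cache)
  x <- if (cfg$fusion == "HEAD_CONCAT") c(bb$virtual, zs) else bb$virtual
  hf <- head_forward(x, model$params$head, keep_cache = keep_cache)
  pred <- model$norm$mu + model$norm$sd * hf$y
  names(pred) <- target_names()
  refined <- conformer$coords + bb$displacement
  out <- list(predictions = pred, refined = refined, conformer = conformer)
  if (keep_cache)
    out$cache <- list(bb = bb$cache, head = hf$cache, solvent = scache,
                      zs = zs, fidelity = fidelity, n = nrow(conformer$coords))
  out
}

#' Predict properties and refined coordinates for one record
#'
#' Fusion strategy `VIRTUAL_NODE`: the solvent embedding is injected into the
#' virtual node and the property head reads the final virtual-node embedding.
#' `HEAD_CONCAT`: the backbone runs solvent-blind and the head reads the
#' concatenation of the virtual-node and solvent embeddings.  `NONE`: the
#' head reads the virtual node only.  Predictions are returned in physical
#' units (de-normalized).
#'
#' @param record an [labeled_pair()] record.
#' @param fidelity conformer fidelity tag to run on.
#' @param model an `sc_model`.
#' @return list with `predictions` (named numeric: lambda_abs nm, lambda_ems
#'   nm, log10 PLQY) and `refined` (N x 3 refined coordinates).
#' @export
solvachrom_forward <- function(record, fidelity, model) {
  out <- forward_record(model, record, fidelity)
  out[c("predictions", "refined")]
}

#' Joint masked property + coordinate-refinement loss
#'
#' `w_prop` weights a masked L1 loss on normalized predictions (averaged over
#' observed target slots only; a record with no observed targets contributes
#' nothing to this term).  `w_coord` weights the mean per-atom distance
#' between refined and reference coordinates after Kabsch alignment (the
#' alignment removes all rigid-body ambiguity, so the term is invariant to
#' rigid motions of either argument).
#'
#' @param predictions named numeric predictions in physical units.
#' @param refined_coords N x 3 refined coordinates.
#' @param record the [labeled_pair()] supplying targets and mask.
#' @param reference reference [sc_conformer()] (or `NULL` to skip the
#'   coordinate term).
#' @param config a [pair_training_config()].
#' @param norm normalization constants (`mu`, `sd`) used for the property
#'   term; defaults to the identity scaling.
#' @return scalar loss with attribute `components` (property, coordinate).
#' @export
joint_loss <- function(predictions, refined_coords, record, reference, config,
                       norm = list(mu = c(0, 0, 0), sd = c(1, 1, 1))) {
  jl <- joint_loss_grad(predictions, refined_coords, record, reference, config,
                        norm)
  structure(jl$value, components = jl$components)
}

# Loss with gradients w.r.t. predictions (physical units) and refined coords.
joint_loss_grad <- function(predictions, refined_coords, record, reference,
                            config, norm, targets = target_names()) {
  sel <- match(targets, target_names())
  mask <- record$mask
  use <- which(mask == 1L & seq_along(mask) %in% sel)
  dpred <- numeric(3)
  lp <- 0
  if (config$w_prop > 0 && length(use)) {
    pn <- (predictions[use] - record$targets[use]) / norm$sd[use]
    lp <- mean(abs(pn))
    dpred[use] <- config$w_prop * sign(pn) / (length(use) * norm$sd[use])
  }
  lc <- 0
  drefined <- NULL
  if (config$w_coord > 0 && !is.null(reference)) {
    refc <- reference$coords
    if (nrow(refc) != nrow(refined_coords))
      stop_sc("reference atom count %d does not match refined coordinates %d",
              nrow(refc), nrow(refined_coords))
    idx <- seq_len(nrow(refc))
    if (isTRUE(config$coord_heavy_only)) idx <- which(reference$elements != "H")
    al <- kabsch_rmsd(refined_coords[idx, , drop = FALSE],
                      refc[idx, , drop = FALSE])
    diff <- refined_coords[idx, , drop = FALSE] - al$aligned
    d <- sqrt(rowSums(diff^2))
    lc <- mean(d)
    dref_sub <- diff / pmax(d, 1e-12) / length(idx)
    drefined <- matrix(0, nrow(refined_coords), 3)
    drefined[idx, ] <- config$w_coord * dref_sub
  }
  value <- config$w_prop * lp + config$w_coord * lc
  list(value = value, components = c(property = lp, coordinate = lc),
       dpred = dpred, drefined = drefined)
}

#' Coarse-conformer inference
#'
#' Runs the model on the requested coarse fidelity only; reference-fidelity
#' coordinates are never read (auditable from the access log).
#'
#' @param record an [labeled_pair()] record.
#' @param model a trained `sc_model`.
#' @param inference_fidelity fidelity tag to run on (defaults to the model's
#'   configured coarse input fidelity).
#' @return named numeric target predictions in physical units.
#' @export
infer_coarse <- function(record, model, inference_fidelity = NULL) {
  fid <- inference_fidelity %||% model$config$pair$input_fidelity
  forward_record(model, record, fid)$predictions
}

# Per-record gradient of the joint objective w.r.t. all parameter groups.
# Returns list(loss, grads) with grads matching model$params structure
# (NULL entries for groups that received no gradient).
record_grad <- function(model, record, reference, static = NULL,
                        targets = target_names()) {
  cfg <- model$config
  fwd <- forward_record(model, record, keep_cache = TRUE, static = static,
                        log = FALSE)
  jl <- joint_loss_grad(fwd$predictions, fwd$refined, record, reference,
                        cfg$pair, model$norm, targets = targets)
  dy <- jl$dpred * model$norm$sd            # head output is normalized scale
  hb <- head_backward(dy, fwd$cache$head, model$params$head)
  W <- cfg$backbone$width
  dvirtual <- hb$dx[seq_len(W)]
  dzs_head <- if (cfg$fusion == "HEAD_CONCAT") hb$dx[-seq_len(W)] else NULL
  ddisp <- jl$drefined
  bbwd <- backbone_bwd(dvirtual, NULL, ddisp, fwd$cache$bb,
                       model$params$backbone, cfg$backbone)
  grads <- list(backbone = bbwd$grads, solvent = NULL, proj = NULL,
                head = hb$grads)
  if (cfg$fusion == "VIRTUAL_NODE") {
    dve <- bbwd$dvirtual_extra
    grads$proj <- list(Wp = outer(fwd$cache$zs, dve))
    dzs <- as.numeric(model$params$proj$Wp %*% dve)
    grads$solvent <- mpnn_backward(dzs, fwd$cache$solvent, model$params$solvent)
  } else if (cfg$fusion == "HEAD_CONCAT") {
    grads$solvent <- mpnn_backward(dzs_head, fwd$cache$solvent,
                                   model$params$solvent)
  }
  grads <- grads[!vapply(grads, is.null, TRUE)]
  list(loss = jl$value, components = jl$components, grads = grads)
}
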