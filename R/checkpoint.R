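# Model bundle serialization: JSON manifest + binary weight payloads.

# canonical flat order of a parameter structure with shape metadata
param_shapes <- function(p, prefix = "") {
  if (is.list(p)) {
    keys <- names(p) %||% as.character(seq_along(p))
    out <- list()
    for (q in seq_along(p))
      out <- c(out, param_shapes(p[[q]], paste0(prefix, "/", keys[q])))
    return(out)
  }
  stats::setNames(list(as.integer(dim(p) %||% length(p))), prefix)
}

#' Save a model bundle
#'
#' Writes a directory with `manifest.json` (fusion strategy, architecture
#' configuration, pair-training configuration, normalization constants, seed,
#' parameter shapes) and one little-endian double binary payload per
#' parameter group.
#'
#' @param model an `sc_model`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "solvachrom", format = 1L,
                   config = model$config[setdiff(names(model$config), "")],
                   norm = model$norm, seed = model$seed,
                   groups = lapply(model$params, param_shapes))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (g in names(model$params)) {
    con <- file(file.path(dir, paste0(g, ".bin")), "wb")
    writeBin(plist_unlist(model$params[[g]]), con, size = 8, endian = "little")
    close(con)
  }
  invisible(dir)
}

#' Load a model bundle
#'
#' Validates the manifest header (format, parameter shapes) against the
#' reconstructed configuration before reading the binary payloads.
#'
#' @param dir bundle directory written by [save_model()].
#' @return an `sc_model`.
#' @export
load_model <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  if (!identical(mf$package, "solvachrom") || mf$format != 1L)
    stop_sc("not a solvachrom model bundle: %s", dir)
  cfg <- mf$config
  config <- model_config(
    fusion = cfg$fusion,
    backbone = backbone_config(width = cfg$backbone$width,
                               layers = cfg$backbone$layers,
                               heads = cfg$backbone$heads,
                               K = cfg$backbone$pair$K,
                               r_max = max(cfg$backbone$pair$centers),
                               coord_hidden = cfg$backbone$coord_hidden,
                               ffn_mult = cfg$backbone$ffn_mult,
                               max_displacement = cfg$backbone$max_displacement),
    solvent_width = cfg$solvent_width, solvent_depth = cfg$solvent_depth,
    head_hidden = cfg$head_hidden,
    pair = pair_training_config(cfg$pair$input_fidelity,
                                cfg$pair$reference_fidelity,
                                cfg$pair$w_prop, cfg$pair$w_coord,
                                isTRUE(cfg$pair$coord_heavy_only)),
    refine_iterations = cfg$refine_iterations)
  model <- model_init(config, seed = mf$seed %||% 1L)
  for (g in names(model$params)) {
    want <- param_shapes(model$params[[g]])
    got <- mf$groups[[g]]
    if (!identical(lapply(unname(want), as.integer),
                   lapply(unname(got), as.integer)) ||
        !identical(names(want), names(got)))
      stop_sc("checkpoint header mismatch for group '%s'", g)
    path <- file.path(dir, paste0(g, ".bin"))
    n_total <- sum(vapply(want, prod, 0))
    con <- file(path, "rb")
    vals <- readBin(con, "double", n = n_total, size = 8, endian = "little")
    close(con)
    if (length(vals) != n_total)
      stop_sc("checkpoint payload %s has %d values, expected %d",
              path, length(vals), n_total)
    model$params[[g]] <- plist_relist(vals, model$params[[g]])
  }
  model$norm <- list(mu = as.numeric(mf$norm$mu), sd = as.numeric(mf$norm$sd))
  model
}
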