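# Structured run configuration: one YAML/JSON document with sections
# {data, model, fusion, pair_training, schedule, split, outputs}; every run
# can write back a fully resolved copy.

#' Read a run configuration file
#'
#' Accepts YAML (if the yaml package is installed) or JSON.  Unknown keys are
#' kept; missing keys fall back to package defaults when the configuration is
#' resolved with [resolve_config()].
#'
#' @param path configuration file.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_sc("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Resolve a run configuration against package defaults
#'
#' @param raw list from [read_run_config()] (or an empty list).
#' @return list with fully populated `model` ([model_config()]), `schedule`
#'   ([train_schedule()]), `split` (fractions + seed) and `fixture`
#'   ([fixture_spec()]) sections plus the raw document.
#' @export
resolve_config <- function(raw = list()) {
  bk <- raw$model$backbone %||% list()
  backbone <- backbone_config(
    width = bk$width %||% 128L, layers = bk$layers %||% 4L,
    heads = bk$heads %||% 8L, K = bk$K %||% 64L, r_max = bk$r_max %||% 12,
    coord_hidden = bk$coord_hidden %||% 16L)
  pt <- raw$pair_training %||% list()
  pair <- pair_training_config(
    input_fidelity = pt$input_fidelity %||% "XTB",
    reference_fidelity = pt$reference_fidelity %||% "DFT_IMP",
    w_prop = pt$w_prop %||% 1, w_coord = pt$w_coord %||% 1,
    coord_heavy_only = isTRUE(pt$coord_heavy_only))
  model <- model_config(
    fusion = raw$fusion$strategy %||% "VIRTUAL_NODE", backbone = backbone,
    solvent_width = raw$model$solvent_width %||% 64L,
    solvent_depth = raw$model$solvent_depth %||% 2L,
    head_hidden = raw$model$head_hidden %||% 64L, pair = pair)
  sc <- raw$schedule %||% list()
  schedule <- train_schedule(
    phase1_epochs = sc$phase1_epochs %||% 40L,
    phase2_epochs = sc$phase2_epochs %||% 15L,
    patience = sc$patience %||% 10L,
    lr_phase1 = sc$lr_phase1 %||% 1e-3, lr_phase2 = sc$lr_phase2 %||% 3e-4,
    batch_size = sc$batch_size %||% 32L, seed = sc$seed %||% 1L,
    val_metric = sc$val_metric %||% "lambda_abs")
  sp <- raw$split %||% list()
  split <- list(fractions = sp$fractions %||% c(0.8, 0.1, 0.1),
                seed = sp$seed %||% 1L, k = sp$k %||% 5L)
  fx <- raw$fixture %||% list()
  fixture <- do.call(fixture_spec,
                     fx[intersect(names(fx), names(formals(fixture_spec)))])
  list(model = model, schedule = schedule, split = split, fixture = fixture,
       data = raw$data %||% list(), outputs = raw$outputs %||% list(),
       raw = raw)
}

#' Write the resolved configuration next to a run's outputs
#' @param resolved output of [resolve_config()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_resolved_config <- function(resolved, path) {
  jsonlite::write_json(resolved[setdiff(names(resolved), "raw")], path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(path)
}
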