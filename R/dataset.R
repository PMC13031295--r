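# Dataset of chromophore-solvent records with masked multitarget labels.

#' Target slot names
#' @return character vector: absorption maximum (nm), emission maximum (nm),
#'   log10 photoluminescence quantum yield.
#' @export
target_names <- function() c("lambda_abs", "lambda_ems", "log_plqy")

#' Construct a labeled chromophore-solvent record
#'
#' @param chromophore,solvent [sc_molecule()] objects.
#' @param targets numeric length-3 vector `(lambda_abs nm, lambda_ems nm,
#'   log10 PLQY)`; unobserved slots carry `NA` (the sentinel) and are never
#'   read by losses or metrics.
#' @param mask binary length-3 vector, 1 = observed.
#' @param conformers named list mapping fidelity tag to [sc_conformer()] (for
#'   the chromophore).  At most one conformer per fidelity level.
#' @param provenance free-text origin note.
#' @return an object of class `sc_record`.
#' @export
labeled_pair <- function(chromophore, solvent, targets, mask = NULL,
                         conformers = list(), provenance = NA_character_) {
  stopifnot(inherits(chromophore, "sc_molecule"), inherits(solvent, "sc_molecule"))
  targets <- as.numeric(targets)
  if (length(targets) != 3) stop_sc("targets must have length 3: %s",
                                    paste(target_names(), collapse = ", "))
  if (is.null(mask)) mask <- as.integer(!is.na(targets))
  mask <- as.integer(mask)
  if (length(mask) != 3 || any(!mask %in% c(0L, 1L)))
    stop_sc("mask must be a binary vector of length 3")
  if (any(mask == 1L & is.na(targets)))
    stop_sc("observed target slots cannot be NA")
  targets[mask == 0L] <- NA_real_
  if (mask[1] == 1L && targets[1] <= 0) stop_sc("observed lambda_abs must be > 0")
  if (mask[2] == 1L && targets[2] <= 0) stop_sc("observed lambda_ems must be > 0")
  if (length(conformers)) {
    tags <- names(conformers)
    if (is.null(tags) || anyDuplicated(tags))
      stop_sc("conformers must be uniquely named by fidelity tag (one conformer per level)")
  }
  names(targets) <- names(mask) <- target_names()
  structure(list(chromophore = chromophore, solvent = solvent,
                 targets = targets, mask = mask, conformers = conformers,
                 provenance = provenance),
            class = "sc_record")
}

#' Construct a dataset of labeled records
#'
#' @param records list of [labeled_pair()] records.
#' @param levels fidelity registry for the conformers present.
#' @return an object of class `sc_dataset`.
#' @export
sc_dataset <- function(records, levels = fidelity_levels()) {
  stopifnot(all(vapply(records, inherits, TRUE, "sc_record")))
  structure(list(records = records, levels = levels), class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  nobs <- colSums(dataset_masks(x))
  cat(sprintf("<sc_dataset> %d records, %d chromophores, %d solvents\n",
              length(x$records), length(unique(chromophore_keys(x))),
              length(unique(solvent_keys(x)))))
  cat(sprintf("  observed: lambda_abs %d, lambda_ems %d, log_plqy %d\n",
              nobs[1], nobs[2], nobs[3]))
  invisible(x)
}

#' @export
length.sc_dataset <- function(x) length(x$records)

#' Canonical keys of a dataset's chromophores / solvents
#' @param dataset an [sc_dataset()].
#' @return character vector, one key per record.
#' @export
chromophore_keys <- function(dataset)
  vapply(dataset$records, function(r) r$chromophore$canonical_key, "")

#' @rdname chromophore_keys
#' @export
solvent_keys <- function(dataset)
  vapply(dataset$records, function(r) r$solvent$canonical_key, "")

dataset_targets <- function(dataset)
  do.call(rbind, lapply(dataset$records, `[[`, "targets"))

dataset_masks <- function(dataset)
  do.call(rbind, lapply(dataset$records, `[[`, "mask"))

#' Read a labels table (CSV) into a dataset
#'
#' Expects header columns `chromophore_smiles, solvent_smiles, lambda_abs_nm,
#' lambda_ems_nm, plqy`; empty cells mean missing (mask 0).  PLQY is stored as
#' log10(PLQY); rows with PLQY outside (0, 1], non-positive wavelengths, or
#' unparseable SMILES are rejected with an entry in the load report
#' (`attr(ds, "load_report")`), never silently dropped.
#'
#' @param path CSV file path.
#' @return an [sc_dataset()]; rejected rows are described in the
#'   `load_report` attribute (data.frame: row, reason).
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(chromophore_smiles = "character",
                                       solvent_smiles = "character"))
  need <- c("chromophore_smiles", "solvent_smiles", "lambda_abs_nm",
            "lambda_ems_nm", "plqy")
  if (!all(need %in% names(df)))
    stop_sc("labels CSV must have columns: %s", paste(need, collapse = ", "))
  records <- list()
  rejected <- data.frame(row = integer(), reason = character())
  reject <- function(row, reason)
    rejected <<- rbind(rejected, data.frame(row = row, reason = reason))
  for (r in seq_len(nrow(df))) {
    chrom <- tryCatch(parse_structure(df$chromophore_smiles[r]), error = identity)
    if (inherits(chrom, "error")) { reject(r, conditionMessage(chrom)); next }
    solv <- tryCatch(parse_structure(df$solvent_smiles[r]), error = identity)
    if (inherits(solv, "error")) { reject(r, conditionMessage(solv)); next }
    la <- suppressWarnings(as.numeric(df$lambda_abs_nm[r]))
    le <- suppressWarnings(as.numeric(df$lambda_ems_nm[r]))
    q <- suppressWarnings(as.numeric(df$plqy[r]))
    if (!is.na(la) && la <= 0) { reject(r, "non-positive lambda_abs"); next }
    if (!is.na(le) && le <= 0) { reject(r, "non-positive lambda_ems"); next }
    if (!is.na(q) && (q <= 0 || q > 1)) {
      reject(r, "PLQY outside (0, 1]"); next
    }
    records[[length(records) + 1L]] <-
      labeled_pair(chrom, solv, c(la, le, if (is.na(q)) NA_real_ else log10(q)),
                   provenance = sprintf("%s:%d", basename(path), r))
  }
  ds <- sc_dataset(records)
  attr(ds, "load_report") <- rejected
  ds
}

#' Attach conformers to dataset records
#'
#' Matches conformers to records by chromophore canonical key.  A second
#' conformer at an already-occupied fidelity level for the same record is an
#' error (one conformer per (molecule, fidelity level)).
#'
#' @param dataset an [sc_dataset()].
#' @param conformers list of [sc_conformer()] objects with `source_key` set.
#' @return the dataset with conformer maps filled in.
#' @export
attach_conformers <- function(dataset, conformers) {
  keys <- chromophore_keys(dataset)
  for (cf in conformers) {
    hit <- which(keys == cf$source_key)
    if (!length(hit))
      stop_sc("conformer key '%s' matches no chromophore in the dataset", cf$source_key)
    for (idx in hit) {
      if (!is.null(dataset$records[[idx]]$conformers[[cf$fidelity]]))
        stop_sc("record %d already has a conformer at level %s (one per level)",
                idx, cf$fidelity)
      dataset$records[[idx]]$conformers[[cf$fidelity]] <- cf
    }
  }
  dataset
}

#' Curation rule configuration
#'
#' @param check_topology verify conformer/graph topology consistency.
#' @param collapse_duplicates collapse exact duplicates of
#'   (chromophore key, solvent key, identical targets).
#' @param flag_conflicts flag same-pair records with conflicting targets.
#' @param flag_protonation flag protonation variants sharing a neutral parent
#'   skeleton.
#' @param tolerance bond-perception tolerance (Angstrom) for topology checks.
#' @param topology_levels `"highest"` (default) checks only the highest-
#'   fidelity conformer of each record -- distance-based bond perception is
#'   only meaningful for optimized geometries, not force-field-level ones --
#'   while `"all"` checks every conformer; a character vector of tags checks
#'   exactly those levels.
#' @return a curation rules list.
#' @export
curation_rules <- function(check_topology = TRUE, collapse_duplicates = TRUE,
                           flag_conflicts = TRUE, flag_protonation = TRUE,
                           tolerance = 0.4, topology_levels = "highest") {
  list(check_topology = check_topology, collapse_duplicates = collapse_duplicates,
       flag_conflicts = flag_conflicts, flag_protonation = flag_protonation,
       tolerance = tolerance, topology_levels = topology_levels)
}

# Charge-stripped skeleton key, used to group protonation variants.
skeleton_key <- function(mol) {
  m2 <- mol
  m2$charges <- integer(n_atoms(mol))
  m2 <- tryCatch(sc_molecule(m2$elements, m2$charges, m2$bonds), error = function(e) NULL)
  if (is.null(m2)) return(NA_character_)
  molecule_canonical_key(m2)
}

#' Curate a dataset
#'
#' Applies the enabled checks: removes records whose conformer topology is
#' inconsistent with their 2D graph, collapses exact duplicate records,
#' flags (never drops) same-pair records with conflicting targets, and flags
#' protonation variants that share a neutral parent skeleton.  Problems are
#' reported, not raised.  Curation is idempotent.
#'
#' @param dataset an [sc_dataset()].
#' @param rules a [curation_rules()] list.
#' @return list with elements `dataset` (curated) and `report` (class
#'   `sc_curation_report`: counts inspected/removed/retained, per-rule
#'   breakdown, flagged record identifiers with reasons).
#' @export
curate <- function(dataset, rules = curation_rules()) {
  n <- length(dataset$records)
  drop <- logical(n)
  per_rule <- c(topology_inconsistent = 0L, duplicate = 0L,
                conflicting_labels = 0L, protonation_variant = 0L)
  flagged <- data.frame(record = integer(), pair_key = character(),
                        reason = character())
  keys <- paste(chromophore_keys(dataset), solvent_keys(dataset), sep = " | ")

  if (rules$check_topology) {
    lvl_order <- c("RDKIT", "XTB", "DFT_VAC", "DFT_IMP", "REFINED")
    for (r in seq_len(n)) {
      rec <- dataset$records[[r]]
      tags <- names(rec$conformers)
      check_tags <- if (identical(rules$topology_levels, "all")) tags
        else if (identical(rules$topology_levels, "highest")) {
          rk <- match(tags, lvl_order)
          if (length(tags)) tags[which.max(ifelse(is.na(rk), 0L, rk))] else character(0)
        } else intersect(tags, rules$topology_levels)
      for (cf in rec$conformers[check_tags]) {
        ok <- tryCatch(check_topology_consistency(rec$chromophore, cf, rules$tolerance),
                       error = function(e) FALSE)
        if (!isTRUE(as.logical(ok))) {
          drop[r] <- TRUE
          per_rule["topology_inconsistent"] <- per_rule["topology_inconsistent"] + 1L
          break
        }
      }
    }
  }

  if (rules$collapse_duplicates) {
    tg <- dataset_targets(dataset)
    full <- paste(keys, apply(tg, 1, function(z) paste(signif(z, 12), collapse = ",")))
    dup <- duplicated(full) & !drop
    per_rule["duplicate"] <- sum(dup)
    drop <- drop | dup
  }

  if (rules$flag_conflicts) {
    keep_idx <- which(!drop)
    tg <- dataset_targets(dataset)
    for (k in unique(keys[keep_idx])) {
      grp <- keep_idx[keys[keep_idx] == k]
      if (length(grp) < 2) next
      vals <- tg[grp, , drop = FALSE]
      conflict <- any(apply(vals, 2, function(col) {
        col <- col[!is.na(col)]
        length(col) > 1 && diff(range(col)) > 1e-9
      }))
      if (conflict) {
        per_rule["conflicting_labels"] <- per_rule["conflicting_labels"] + length(grp)
        flagged <- rbind(flagged, data.frame(record = grp, pair_key = k,
                                             reason = "conflicting labels"))
      }
    }
  }

  if (rules$flag_protonation) {
    keep_idx <- which(!drop)
    ck <- chromophore_keys(dataset)
    charged <- vapply(dataset$records, function(r) any(r$chromophore$charges != 0L), TRUE)
    sk <- rep(NA_character_, n)
    cand <- keep_idx[charged[keep_idx] | TRUE]
    # only compute skeletons for chromophores that appear with >1 distinct key
    for (idx in keep_idx) sk[idx] <- if (charged[idx]) skeleton_key(dataset$records[[idx]]$chromophore) else ck[idx]
    for (s in unique(stats::na.omit(sk[keep_idx]))) {
      grp <- keep_idx[!is.na(sk[keep_idx]) & sk[keep_idx] == s]
      if (length(unique(ck[grp])) > 1 && any(charged[grp])) {
        per_rule["protonation_variant"] <- per_rule["protonation_variant"] + length(grp)
        flagged <- rbind(flagged, data.frame(record = grp, pair_key = keys[grp],
                                             reason = "protonation variant of shared skeleton"))
      }
    }
  }

  curated <- dataset
  curated$records <- dataset$records[!drop]
  report <- structure(list(inspected = n, removed = sum(drop),
                           retained = n - sum(drop), per_rule = per_rule,
                           flagged = flagged),
                      class = "sc_curation_report")
  list(dataset = curated, report = report)
}

#' @export
print.sc_curation_report <- function(x, ...) {
  cat(sprintf("<curation report> inspected %d, removed %d, retained %d\n",
              x$inspected, x$removed, x$retained))
  for (r in names(x$per_rule))
    if (x$per_rule[[r]] > 0) cat(sprintf("  %s: %d\n", r, x$per_rule[[r]]))
  if (nrow(x$flagged)) cat(sprintf("  flagged for review: %d records\n", nrow(x$flagged)))
  invisible(x)
}
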