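# Bemis-Murcko scaffolds and scaffold-grouped dataset partitioning.
#
# The grouping unit is the chromophore: all records of one chromophore share a
# subset, and no scaffold ever spans two subsets.  Solvents are not
# scaffold-constrained.

#' Scaffold key of acyclic molecules
#' @return the designated key for ring-free molecules.
#' @export
EMPTY_SCAFFOLD <- "EMPTY"

#' Bemis-Murcko scaffold of a molecule
#'
#' Iteratively deletes terminal non-ring atoms until only ring systems and the
#' linker atoms connecting them remain; exocyclic atoms attached by a multiple
#' bond to a retained atom are kept (the common toolkit convention).  Acyclic
#' molecules map to the designated [EMPTY_SCAFFOLD].  The returned key is the
#' canonical structure key of the framework, so it is independent of input
#' atom ordering, and idempotent: the scaffold of a scaffold is itself.
#'
#' @param molecule an [sc_molecule()].
#' @return scaffold canonical key (character scalar) with the retained atom
#'   indices attached as attribute `atoms`.
#' @export
murcko_scaffold <- function(molecule) {
  stopifnot(inherits(molecule, "sc_molecule"))
  n <- n_atoms(molecule)
  bonds <- molecule$bonds
  keep <- rep(TRUE, n)
  repeat {
    deg <- integer(n)
    act <- keep[bonds$i] & keep[bonds$j]
    for (k in which(act)) {
      deg[bonds$i[k]] <- deg[bonds$i[k]] + 1L
      deg[bonds$j[k]] <- deg[bonds$j[k]] + 1L
    }
    prune <- keep & (deg <= 1L)
    if (!any(prune)) break
    keep[prune] <- FALSE
  }
  if (!any(keep)) return(structure(EMPTY_SCAFFOLD, atoms = integer(0)))
  # re-attach exocyclic double/triple-bonded terminal atoms (e.g. ring C=O)
  repeat {
    add <- which(!keep & vapply(seq_len(n), function(a) {
      kk <- which((bonds$i == a & keep[bonds$j]) | (bonds$j == a & keep[bonds$i]))
      any(!is.na(bonds$order[kk]) & bonds$order[kk] >= 2)
    }, TRUE))
    if (!length(add)) break
    keep[add] <- TRUE
  }
  idx <- which(keep)
  remap <- match(seq_len(n), idx)
  sub <- bonds[keep[bonds$i] & keep[bonds$j], , drop = FALSE]
  sub$i <- remap[sub$i]; sub$j <- remap[sub$j]
  scaf <- sc_molecule(molecule$elements[idx], molecule$charges[idx], sub)
  key <- molecule_canonical_key(scaf)
  if (is.na(key)) key <- paste0("SCAFFOLD_RAW:", paste(molecule$elements[idx], collapse = ""))
  structure(key, atoms = idx)
}

# scaffold key per record (chromophore level), memoized per unique chromophore
record_scaffolds <- function(dataset) {
  ck <- chromophore_keys(dataset)
  uk <- unique(ck)
  sk <- vapply(uk, function(k) {
    rec <- dataset$records[[match(k, ck)]]
    as.character(murcko_scaffold(rec$chromophore))
  }, "")
  unname(sk[match(ck, uk)])
}

new_split_assignment <- function(subset, ck, sk, fractions = NULL, seed = NULL,
                                 fold = NULL) {
  df <- data.frame(record_index = seq_along(subset), chromophore_key = ck,
                   scaffold_key = sk, subset = subset,
                   stringsAsFactors = FALSE)
  if (!is.null(fold)) df$fold <- fold
  structure(list(assignment = df, fractions = fractions, seed = seed),
            class = "sc_split")
}

#' @export
print.sc_split <- function(x, ...) {
  tab <- table(x$assignment$subset)
  cat("<sc_split>", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      sprintf("(%d scaffolds, seed %s)\n",
              length(unique(x$assignment$scaffold_key)),
              x$seed %||% "NA"))
  invisible(x)
}

#' Indices of records in a split subset
#' @param split an `sc_split` from [scaffold_split()] or [scaffold_kfold()].
#' @param subset `"TRAIN"`, `"VAL"` or `"TEST"`.
#' @return integer record indices.
#' @export
split_indices <- function(split, subset) {
  split$assignment$record_index[split$assignment$subset == subset]
}

assert_split_integrity <- function(split) {
  df <- split$assignment
  for (what in c("scaffold_key", "chromophore_key")) {
    tab <- unique(df[, c(what, "subset")])
    if (anyDuplicated(tab[[what]]))
      stop_sc("split integrity violation: a %s appears in more than one subset", what)
  }
  invisible(TRUE)
}

#' Scaffold-grouped train/validation/test split
#'
#' Scaffolds (whole groups of chromophores, with all their solvent records)
#' are assigned by seeded random order, filling TRAIN to its record quota
#' first, then VAL, then TEST.  Quotas use largest-remainder rounding on
#' record counts; a scaffold overflowing a quota goes to the next unfilled
#' subset.  Deterministic given (dataset, fractions, seed).
#'
#' @param dataset an [sc_dataset()].
#' @param fractions length-3 positive vector `(train, val, test)` summing to 1.
#' @param seed integer seed for the scaffold shuffle.
#' @return an `sc_split`; see [split_indices()].
#' @export
scaffold_split <- function(dataset, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop_sc("fractions must be 3 positive numbers summing to 1")
  ck <- chromophore_keys(dataset)
  sk <- record_scaffolds(dataset)
  groups <- split(seq_along(sk), sk)
  if (length(groups) < 3)
    stop_sc("need at least 3 scaffolds for a 3-way split (found %d)", length(groups))
  n <- length(sk)
  quota <- floor(fractions * n)
  rem <- fractions * n - quota
  for (k in order(rem, decreasing = TRUE)[seq_len(n - sum(quota))])
    quota[k] <- quota[k] + 1
  ord <- with_seed(seed, sample(names(groups)))
  filled <- c(TRAIN = 0L, VAL = 0L, TEST = 0L)
  names(quota) <- names(filled)
  subset <- character(n)
  for (g in ord) {
    open <- names(filled)[filled < quota]
    tgt <- if (length(open)) open[1] else "TEST"
    subset[groups[[g]]] <- tgt
    filled[tgt] <- filled[tgt] + length(groups[[g]])
  }
  # guarantee non-empty VAL and TEST by stealing a whole scaffold from TRAIN
  for (need in c("VAL", "TEST")) {
    if (any(subset == need)) next
    donors <- names(groups)[vapply(groups, function(ix) all(subset[ix] == "TRAIN"), TRUE)]
    sizes <- vapply(groups[donors], length, 0L)
    g <- donors[which.min(sizes)]
    subset[groups[[g]]] <- need
  }
  out <- new_split_assignment(subset, ck, sk, fractions = fractions, seed = seed)
  assert_split_integrity(out)
  out
}

#' Scaffold-grouped k-fold partition
#'
#' Scaffolds are partitioned into `k` disjoint folds of near-equal record
#' counts (seeded shuffle, then greedy assignment of each scaffold to the
#' currently smallest fold).  Fold `i`'s assignment marks fold `i` TEST and
#' the rest TRAIN, optionally carving validation scaffolds out of TRAIN
#' (re-drawn per fold with the fold index mixed into the seed).  Every record
#' is TEST exactly once across folds.
#'
#' @param dataset an [sc_dataset()].
#' @param k number of folds (>= 2, <= number of scaffolds).
#' @param seed integer seed.
#' @param val_fraction fraction of TRAIN records carved out as VAL within each
#'   fold (0 disables).
#' @return list of `k` `sc_split` objects.
#' @export
scaffold_kfold <- function(dataset, k, seed = 1L, val_fraction = 0.1) {
  if (k < 2) stop_sc("k must be >= 2")
  ck <- chromophore_keys(dataset)
  sk <- record_scaffolds(dataset)
  groups <- split(seq_along(sk), sk)
  if (k > length(groups))
    stop_sc("k = %d exceeds scaffold count %d", k, length(groups))
  ord <- with_seed(seed, sample(names(groups)))
  fold_of <- integer(length(sk))
  fold_sizes <- integer(k)
  for (g in ord) {
    f <- which.min(fold_sizes)
    fold_of[groups[[g]]] <- f
    fold_sizes[f] <- fold_sizes[f] + length(groups[[g]])
  }
  lapply(seq_len(k), function(f) {
    subset <- ifelse(fold_of == f, "TEST", "TRAIN")
    if (val_fraction > 0) {
      tr_groups <- names(groups)[vapply(groups, function(ix) all(fold_of[ix] != f), TRUE)]
      ordv <- with_seed(derive_seed(seed, paste0("fold", f)), sample(tr_groups))
      target <- val_fraction * sum(subset == "TRAIN")
      got <- 0L
      for (g in ordv) {
        if (got >= target) break
        if (got + length(groups[[g]]) > sum(subset == "TRAIN") - 1) next
        subset[groups[[g]]] <- "VAL"
        got <- got + length(groups[[g]])
      }
    }
    out <- new_split_assignment(subset, ck, sk, seed = seed, fold = fold_of)
    out$fold_id <- f
    assert_split_integrity(out)
    out
  })
}

#' Write / read a split manifest
#'
#' The manifest is a CSV (`record_index, chromophore_key, scaffold_key,
#' subset`) plus a JSON sidecar (`<path>.json`) recording seed and fractions.
#'
#' @param split an `sc_split`.
#' @param path CSV output path.
#' @return `path`, invisibly (writer); an `sc_split` (reader).
#' @export
write_split_manifest <- function(split, path) {
  utils::write.csv(split$assignment, path, row.names = FALSE)
  meta <- list(seed = split$seed, fractions = split$fractions,
               fold_id = split$fold_id %||% NULL)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE) else list()
  out <- structure(list(assignment = df,
                        fractions = meta$fractions %||% NULL,
                        seed = meta$seed %||% NULL),
                   class = "sc_split")
  if (!is.null(meta$fold_id)) out$fold_id <- meta$fold_id
  assert_split_integrity(out)
  out
}
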