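# Conformers: Cartesian coordinates at a named fidelity level, plus SDF/XYZ I/O.

#' Default conformer fidelity registry
#'
#' The ladder of geometry-optimization levels, ordered coarse to fine:
#' force-field (`RDKIT`), semi-empirical (`XTB`), DFT in vacuum (`DFT_VAC`),
#' DFT in implicit solvent (`DFT_IMP`).  `REFINED` tags model-refined output.
#' The registry is extensible: functions taking a `levels` argument accept any
#' superset.
#' @return character vector of registered fidelity tags.
#' @export
fidelity_levels <- function() c("RDKIT", "XTB", "DFT_VAC", "DFT_IMP", "REFINED")

#' Construct a conformer
#'
#' @param elements character element symbols, one per atom row.
#' @param coords N x 3 numeric matrix of Cartesian coordinates in Angstrom.
#' @param fidelity fidelity tag (see [fidelity_levels()]).
#' @param source_key canonical key of the molecule this geometry belongs to.
#' @param levels registered fidelity tags.
#' @return an object of class `sc_conformer`.
#' @export
sc_conformer <- function(elements, coords, fidelity, source_key = NA_character_,
                         levels = fidelity_levels()) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3)
    stop_sc("coords must be an N x 3 numeric matrix")
  if (nrow(coords) != length(elements))
    stop_sc("coordinate rows (%d) must equal element count (%d)",
            nrow(coords), length(elements))
  if (!all(is.finite(coords))) stop_sc("coordinates must all be finite")
  if (!fidelity %in% levels)
    stop_sc("unknown fidelity tag '%s'; registered levels: %s",
            fidelity, paste(levels, collapse = ", "))
  structure(list(elements = elements, coords = unname(coords),
                 fidelity = fidelity, source_key = source_key),
            class = "sc_conformer")
}

#' @export
print.sc_conformer <- function(x, ...) {
  cat(sprintf("<sc_conformer> %d atoms, fidelity %s, key %s\n",
              nrow(x$coords), x$fidelity,
              ifelse(is.na(x$source_key), "<unset>", x$source_key)))
  invisible(x)
}

#' Read conformers from an SDF or XYZ file
#'
#' SDF records carry the fidelity level in a `> <FIDELITY>` property field and
#' the molecule linkage in `> <CANONICAL_KEY>` (falling back to the record
#' title).  XYZ blocks carry `key=<canonical_key> fidelity=<tag>` on the
#' comment line.
#'
#' @param path file path.
#' @param format `"sdf"` or `"xyz"`; inferred from the extension when `NULL`.
#' @param levels registered fidelity tags.
#' @return list of [sc_conformer()] objects, in file order.
#' @export
read_conformers <- function(path, format = NULL, levels = fidelity_levels()) {
  if (!file.exists(path)) stop_sc("file not found: %s", path)
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
         sdf = read_conformers_sdf(path, levels),
         xyz = read_conformers_xyz(path, levels),
         stop_sc("unknown conformer format '%s' (use 'sdf' or 'xyz')", format))
}

read_conformers_sdf <- function(path, levels) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  out <- vector("list", length(sdfset))
  for (b in seq_along(sdfset)) {
    sdf <- sdfset[[b]]
    ab <- ChemmineR::atomblock(sdf)
    if (nrow(ab) == 0) stop_sc("malformed SDF block %d in %s", b, path)
    elements <- sub("_.*$", "", rownames(ab))
    coords <- unname(ab[, 1:3, drop = FALSE])
    db <- ChemmineR::datablock(sdf)
    fid <- if ("FIDELITY" %in% names(db)) db[["FIDELITY"]] else NA_character_
    key <- if ("CANONICAL_KEY" %in% names(db)) db[["CANONICAL_KEY"]]
           else ChemmineR::header(sdf)[1]
    if (is.na(fid) || !nzchar(fid))
      stop_sc("SDF block %d has no FIDELITY property field", b)
    if (!fid %in% levels)
      stop_sc("SDF block %d: unknown fidelity token '%s'; registered levels: %s",
              b, fid, paste(levels, collapse = ", "))
    out[[b]] <- sc_conformer(elements, coords, fid,
                             source_key = unname(key), levels = levels)
  }
  out
}

read_conformers_xyz <- function(path, levels) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  out <- list()
  pos <- 1L
  block <- 0L
  while (pos <= length(lines)) {
    block <- block + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1)
      stop_sc("malformed XYZ block %d in %s: bad atom-count line", block, path)
    if (pos + 1L + nat > length(lines))
      stop_sc("malformed XYZ block %d in %s: expected %d coordinate lines",
              block, path, nat)
    comment <- lines[pos + 1L]
    rows <- lines[pos + 1L + seq_len(nat)]
    toks <- strsplit(trimws(rows), "\\s+")
    if (any(vapply(toks, length, 0L) < 4))
      stop_sc("malformed XYZ block %d in %s: bad coordinate line", block, path)
    elements <- vapply(toks, `[[`, "", 1)
    coords <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (any(!is.finite(coords)))
      stop_sc("malformed XYZ block %d in %s: non-numeric coordinates", block, path)
    key <- sub(".*key=(\\S+).*", "\\1", comment)
    if (identical(key, comment)) key <- NA_character_
    fid <- sub(".*fidelity=(\\S+).*", "\\1", comment)
    if (identical(fid, comment))
      stop_sc("XYZ block %d has no fidelity=<tag> token on its comment line", block)
    if (!fid %in% levels)
      stop_sc("XYZ block %d: unknown fidelity token '%s'; registered levels: %s",
              block, fid, paste(levels, collapse = ", "))
    out[[block]] <- sc_conformer(elements, coords, fid, source_key = key,
                                 levels = levels)
    pos <- pos + 2L + nat
  }
  out
}

#' Write conformers to an SDF or XYZ file
#'
#' Inverse of [read_conformers()]; coordinates round-trip to the printed
#' precision of the format (4 decimals for SDF, 6 for XYZ).
#'
#' @param conformers list of [sc_conformer()] objects.
#' @param path output file path.
#' @param format `"sdf"` or `"xyz"`; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_conformers <- function(conformers, path, format = NULL) {
  if (inherits(conformers, "sc_conformer")) conformers <- list(conformers)
  format <- tolower(format %||% tools::file_ext(path))
  txt <- switch(format,
    sdf = vapply(conformers, function(cf) {
      mol <- sc_molecule(cf$elements, validate = FALSE)
      paste0(write_molblock(mol, cf$coords, title = cf$source_key %||% ""),
             sprintf("\n> <FIDELITY>\n%s\n\n> <CANONICAL_KEY>\n%s\n\n$$$$",
                     cf$fidelity, cf$source_key))
    }, ""),
    xyz = vapply(conformers, function(cf) {
      rows <- sprintf("%-3s %14.6f %14.6f %14.6f", cf$elements,
                      cf$coords[, 1], cf$coords[, 2], cf$coords[, 3])
      paste(c(nrow(cf$coords),
              sprintf("key=%s fidelity=%s", cf$source_key, cf$fidelity), rows),
            collapse = "\n")
    }, ""),
    stop_sc("unknown conformer format '%s' (use 'sdf' or 'xyz')", format))
  writeLines(txt, path)
  invisible(path)
}
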