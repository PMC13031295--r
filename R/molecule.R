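# Chemical data model: molecules as 2D labelled graphs.
#
# SMILES parsing and canonicalization are delegated to OpenBabel through
# ChemmineOB; a light valence screen on top enforces chemical sanity that
# OpenBabel does not (it happily accepts, e.g., pentavalent carbon).

# Smallest allowed valences per element; larger alternatives listed where
# hypervalence is common.  Used both for the valence screen and for implicit
# hydrogen counts.
.allowed_valences <- list(
  H = 1, B = 3, C = 4, N = c(3, 5), O = 2, F = 1, Si = 4, P = c(3, 5),
  S = c(2, 4, 6), Cl = c(1, 3, 5, 7), Se = c(2, 4, 6), Br = c(1, 3, 5), I = c(1, 3, 5, 7)
)

.canon_cache <- new.env(parent = emptyenv())

ob_convert <- function(from, to, source) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = source)),
    error = function(e) ""
  )
  if (length(out) == 0) out <- ""
  out
}

# Canonical SMILES of a SMILES string via OpenBabel; "" on failure.
ob_canonical_smiles <- function(smiles) {
  key <- paste0("smi:", smiles)
  hit <- .canon_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- ob_convert("SMI", "CAN", smiles)
  out <- sub("\\s.*$", "", trimws(out))
  assign(key, out, envir = .canon_cache)
  out
}

ob_canonical_from_molblock <- function(molblock) {
  out <- ob_convert("SDF", "CAN", molblock)
  sub("\\s.*$", "", trimws(out))
}

# Locate cheap syntactic problems in a SMILES string so parse errors can name
# the offending token.  Returns NULL if nothing obvious is wrong.
smiles_syntax_issue <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(sprintf("unmatched ')' at position %d", i))
    }
  }
  if (depth > 0L) return("unmatched '(' (unclosed branch)")
  ring <- table(unlist(regmatches(smiles, gregexpr("(?<![%@+-])[0-9]", smiles, perl = TRUE))))
  odd <- names(ring)[ring %% 2 == 1]
  if (length(odd)) return(sprintf("unclosed ring-bond digit '%s'", odd[1]))
  bad <- regexpr("[^A-Za-z0-9()\\[\\]=#$:@+\\-/\\\\%.*]", smiles)
  if (bad > 0) return(sprintf("illegal character '%s' at position %d",
                              substr(smiles, bad, bad), bad))
  NULL
}

#' Construct a molecule object
#'
#' Low-level constructor; most users should call [parse_structure()].
#'
#' @param elements character vector of element symbols (heavy atoms).
#' @param charges integer formal charges, same length.
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices),
#'   `order` (1, 2, 3; may be `NA` for perceived connectivity) and `aromatic`
#'   (logical).
#' @param canonical_key canonical structure key, or `NA` if unknown.
#' @param validate check invariants (indices valid, no duplicate bonds).
#' @return an object of class `sc_molecule` with fields `elements`, `charges`,
#'   `aromatic`, `n_h` (implicit hydrogen counts), `bonds`, `canonical_key`.
#' @export
sc_molecule <- function(elements, charges = integer(length(elements)),
                        bonds = data.frame(i = integer(), j = integer(),
                                           order = integer(), aromatic = logical()),
                        canonical_key = NA_character_, validate = TRUE) {
  n <- length(elements)
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
  swap <- bonds$i > bonds$j
  if (any(swap)) { tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp }
  if (validate) {
    if (nrow(bonds)) {
      if (any(bonds$i < 1 | bonds$j > n)) stop_sc("bond atom index out of range (n = %d)", n)
      if (any(bonds$i == bonds$j)) stop_sc("self-bond i == j is not allowed")
      if (anyDuplicated(paste(bonds$i, bonds$j))) stop_sc("duplicate bond in bond list")
    }
  }
  mol <- structure(list(elements = elements, charges = as.integer(charges),
                        bonds = bonds, canonical_key = canonical_key),
                   class = "sc_molecule")
  mol$n_h <- implicit_h_counts(mol)
  mol$aromatic <- aromatic_flags(mol)
  if (nrow(mol$bonds)) {
    br <- bond_is_bridge(n, mol$bonds)
    mol$bonds$aromatic <- (mol$bonds$aromatic %in% TRUE) |
      (!br & mol$aromatic[mol$bonds$i] & mol$aromatic[mol$bonds$j])
  }
  mol
}

#' @export
print.sc_molecule <- function(x, ...) {
  cat(sprintf("<sc_molecule> %d heavy atoms, %d bonds, key: %s\n",
              length(x$elements), nrow(x$bonds),
              ifelse(is.na(x$canonical_key), "<unset>", x$canonical_key)))
  invisible(x)
}

n_atoms <- function(mol) length(mol$elements)

# Bond-order sum per atom (aromatic order-4 bonds count 1.5, total rounded up).
bond_order_sums <- function(mol) {
  n <- n_atoms(mol)
  s <- numeric(n)
  if (nrow(mol$bonds)) {
    ord <- mol$bonds$order
    ord[is.na(ord)] <- 1
    ord[ord == 4] <- 1.5
    for (k in seq_len(nrow(mol$bonds))) {
      s[mol$bonds$i[k]] <- s[mol$bonds$i[k]] + ord[k]
      s[mol$bonds$j[k]] <- s[mol$bonds$j[k]] + ord[k]
    }
  }
  ceiling(s - 1e-9)
}

# Allowed valences adjusted for formal charge (amine N+ -> 4, alkoxide O- -> 1, ...).
adjusted_valences <- function(element, charge) {
  v <- .allowed_valences[[element]]
  if (is.null(v)) return(NULL)
  if (element %in% c("N", "P", "O", "S", "B")) v <- v + charge
  if (element == "C" && charge != 0) v <- v - abs(charge)
  v[v >= 0]
}

# Implicit hydrogens: smallest allowed valence that accommodates the explicit
# bond order sum; errors on atoms that exceed every allowed valence.
implicit_h_counts <- function(mol) {
  bos <- bond_order_sums(mol)
  n_h <- integer(n_atoms(mol))
  for (a in seq_len(n_atoms(mol))) {
    el <- mol$elements[a]
    v <- adjusted_valences(el, mol$charges[a])
    if (is.null(v)) { n_h[a] <- 0L; next }   # uncommon element: no implicit H
    ok <- v[v >= bos[a]]
    if (!length(ok))
      stop_sc("valence error at atom %d (%s): bond order sum %d exceeds maximum %d",
              a, el, bos[a], max(v))
    n_h[a] <- as.integer(min(ok) - bos[a])
  }
  n_h
}

# Bridge detection (iterative DFS).  Returns logical vector over bond rows:
# TRUE if the bond is a bridge (not part of any cycle).
bond_is_bridge <- function(n, bonds) {
  m <- nrow(bonds)
  if (m == 0) return(logical(0))
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], k)
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], k)
  }
  other <- function(k, v) if (bonds$i[k] == v) bonds$j[k] else bonds$i[k]
  disc <- integer(n); low <- integer(n); timer <- 0L
  bridge <- logical(m)
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    stack <- list(list(v = root, pe = 0L, ei = 1L))
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$ei <= length(adj[[v]])) {
        k <- adj[[v]][fr$ei]
        stack[[length(stack)]]$ei <- fr$ei + 1L
        if (k == fr$pe) next
        w <- other(k, v)
        if (disc[w] == 0L) {
          timer <- timer + 1L; disc[w] <- low[w] <- timer
          stack[[length(stack) + 1L]] <- list(v = w, pe = k, ei = 1L)
        } else low[v] <- min(low[v], disc[w])
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          pv <- stack[[length(stack)]]$v
          low[pv] <- min(low[pv], low[v])
          if (low[v] > disc[pv]) bridge[fr$pe] <- TRUE
        }
      }
    }
  }
  bridge
}

# Atoms that belong to at least one ring (= incident to a non-bridge bond).
ring_atom_flags <- function(mol) {
  n <- n_atoms(mol)
  fl <- logical(n)
  if (!nrow(mol$bonds)) return(fl)
  br <- bond_is_bridge(n, mol$bonds)
  cyc <- which(!br)
  fl[mol$bonds$i[cyc]] <- TRUE
  fl[mol$bonds$j[cyc]] <- TRUE
  fl
}

# Approximate aromatic perception on the kekulized graph: a ring atom is
# flagged aromatic when it carries an in-ring multiple bond (or an explicit
# order-4 bond).  This is a conjugated-ring flag used for featurization only;
# structure identity always goes through the canonical key.
aromatic_flags <- function(mol) {
  n <- n_atoms(mol)
  fl <- logical(n)
  if (!nrow(mol$bonds)) return(fl)
  br <- bond_is_bridge(n, mol$bonds)
  ord <- mol$bonds$order
  hit <- !br & (is.na(ord) | ord >= 2 | ord == 4 |
                  (!is.na(mol$bonds$aromatic) & mol$bonds$aromatic))
  hit[is.na(hit)] <- FALSE
  ringy <- ring_atom_flags(mol)
  fl[mol$bonds$i[hit]] <- TRUE
  fl[mol$bonds$j[hit]] <- TRUE
  # heteroatoms sandwiched between two aromatic ring atoms (furan O, thiophene S)
  for (a in which(ringy & !fl)) {
    nb <- c(mol$bonds$j[mol$bonds$i == a], mol$bonds$i[mol$bonds$j == a])
    if (sum(fl[nb]) >= 2) fl[a] <- TRUE
  }
  fl & ringy
}

# MDL charge codes for the atom block.
.mdl_charge_code <- c(`3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L, `-1` = 5L, `-2` = 6L, `-3` = 7L)

#' Write a V2000 molblock for a molecule
#'
#' @param mol an `sc_molecule`.
#' @param coords optional N x 3 coordinate matrix (zeros if omitted).
#' @param title record title.
#' @return a single molblock string (no `$$$$` terminator).
#' @keywords internal
write_molblock <- function(mol, coords = NULL, title = "") {
  n <- n_atoms(mol)
  if (is.null(coords)) coords <- matrix(0, n, 3)
  lines <- c(title, "  solvachrom", "")
  lines <- c(lines, sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(mol$bonds)))
  code <- .mdl_charge_code[as.character(pmax(pmin(mol$charges, 3L), -3L))]
  code[is.na(code)] <- 0L
  for (a in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                              coords[a, 1], coords[a, 2], coords[a, 3],
                              mol$elements[a], code[a]))
  }
  if (nrow(mol$bonds)) {
    ord <- mol$bonds$order
    ord[is.na(ord)] <- 1L
    for (k in seq_len(nrow(mol$bonds)))
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$i[k], mol$bonds$j[k], ord[k]))
  }
  chg <- which(mol$charges != 0L)
  if (length(chg)) {
    for (start in seq(1, length(chg), by = 8)) {
      idx <- chg[start:min(start + 7, length(chg))]
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(idx)),
                               paste0(sprintf("%4d%4d", idx, mol$charges[idx]), collapse = "")))
    }
  }
  lines <- c(lines, "M  END")
  paste(lines, collapse = "\n")
}

# Canonical key for a graph-built molecule (via OpenBabel on its molblock).
molecule_canonical_key <- function(mol) {
  mb <- write_molblock(mol)
  key <- ob_canonical_from_molblock(mb)
  if (!nzchar(key)) NA_character_ else key
}

#' Parse a SMILES string into a molecule
#'
#' Parsing and canonicalization are performed by OpenBabel; the result is
#' additionally screened for valence consistency (OpenBabel accepts
#' hypervalent input silently).  The canonical key is atom-order independent:
#' any two SMILES spellings of the same structure receive the same key.
#'
#' @param smiles a non-empty SMILES string.
#' @return an [sc_molecule()] with `canonical_key` populated.
#' @examples
#' mol <- parse_structure("CCO")
#' length(mol$elements)  # 3 heavy atoms
#' @export
parse_structure <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(trimws(smiles)))
    stop_sc("smiles must be a single non-empty string")
  smiles <- trimws(smiles)
  key <- ob_canonical_smiles(smiles)
  if (!nzchar(key)) {
    issue <- smiles_syntax_issue(smiles)
    stop_sc("cannot parse SMILES '%s': %s", smiles,
            issue %||% "not a valid SMILES string")
  }
  sdf <- ob_convert("SMI", "SDF", smiles)
  if (!nzchar(sdf)) stop_sc("cannot parse SMILES '%s'", smiles)
  parsed <- parse_molblock_text(sdf)
  mol <- sc_molecule(parsed$elements, parsed$charges, parsed$bonds,
                     canonical_key = key)   # valence screen runs here
  mol
}

# Minimal V2000 reader used for OpenBabel round-trips and SDF ingestion
# (ChemmineR handles multi-record SDF files; this handles a single block).
parse_molblock_text <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na)) stop_sc("malformed molblock: bad counts line")
  atoms <- lines[4 + seq_len(na)]
  elements <- trimws(substr(atoms, 32, 34))
  coords <- cbind(as.numeric(substr(atoms, 1, 10)),
                  as.numeric(substr(atoms, 11, 20)),
                  as.numeric(substr(atoms, 21, 30)))
  charges <- integer(na)
  bonds <- data.frame(i = integer(), j = integer(), order = integer(), aromatic = logical())
  if (nb > 0) {
    bl <- lines[4 + na + seq_len(nb)]
    ord <- as.integer(substr(bl, 7, 9))
    bonds <- data.frame(i = as.integer(substr(bl, 1, 3)),
                        j = as.integer(substr(bl, 4, 6)),
                        order = ifelse(ord == 4L, 4L, ord),
                        aromatic = ord == 4L)
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    cnt <- toks[1]
    for (q in seq_len(cnt)) charges[toks[2 * q]] <- toks[2 * q + 1]
  }
  list(elements = elements, charges = charges, bonds = bonds, coords = coords)
}
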