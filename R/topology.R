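# Geometry -> connectivity perception and topology-consistency checks.

# Covalent radii in Angstrom (Cordero et al. consensus values).
.covalent_radii <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71,
  O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, K = 2.03, Ca = 1.76, Fe = 1.32, Co = 1.26,
  Ni = 1.24, Cu = 1.32, Zn = 1.22, Se = 1.20, Br = 1.20, I = 1.39
)

#' Perceive heavy-atom connectivity from 3D coordinates
#'
#' Two atoms are bonded when their distance does not exceed the sum of their
#' covalent radii plus `tolerance`.  Hydrogen rows are not returned as atoms;
#' each is folded into the attached-hydrogen count of its nearest bonded heavy
#' atom.  Bond orders are left unset (`NA`): orders are never perceived from
#' geometry.
#'
#' @param conformer an [sc_conformer()].
#' @param tolerance slack added to the covalent-radius sum, in Angstrom.
#' @return an [sc_molecule()] with heavy-atom connectivity and `NA` bond
#'   orders; `canonical_key` is left unset.  The heavy-atom row mapping is
#'   attached as attribute `heavy_index`.
#' @export
perceive_connectivity <- function(conformer, tolerance = 0.4) {
  stopifnot(inherits(conformer, "sc_conformer"))
  if (!is.numeric(tolerance) || tolerance <= 0) stop_sc("tolerance must be > 0")
  el <- conformer$elements
  unknown <- setdiff(unique(el), names(.covalent_radii))
  if (length(unknown))
    stop_sc("no tabulated covalent radius for element '%s'", unknown[1])
  xyz <- conformer$coords
  n <- nrow(xyz)
  r <- .covalent_radii[el]
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(r, r, `+`) + tolerance
  adj <- d <= cut & upper.tri(d)
  heavy <- which(el != "H")
  hmap <- match(seq_len(n), heavy)
  pairs <- which(adj, arr.ind = TRUE)
  n_h <- integer(length(heavy))
  keep <- matrix(0L, 0, 2)
  if (nrow(pairs)) {
    isH_i <- el[pairs[, 1]] == "H"
    isH_j <- el[pairs[, 2]] == "H"
    hh <- isH_i & isH_j
    hx <- xor(isH_i, isH_j)
    heavy_pair <- !isH_i & !isH_j
    # attach each hydrogen to its single nearest heavy neighbour
    for (h in which(el == "H")) {
      cand <- heavy[d[h, heavy] <= cut[h, heavy]]
      if (length(cand)) {
        a <- cand[which.min(d[h, cand])]
        n_h[hmap[a]] <- n_h[hmap[a]] + 1L
      }
    }
    keep <- pairs[heavy_pair, , drop = FALSE]
  }
  bonds <- data.frame(i = hmap[keep[, 1]], j = hmap[keep[, 2]],
                      order = rep(NA_integer_, nrow(keep)),
                      aromatic = rep(FALSE, nrow(keep)))
  mol <- sc_molecule(el[heavy], charges = integer(length(heavy)), bonds = bonds,
                     validate = TRUE)
  mol$n_h <- n_h   # observed hydrogens override valence-filled counts
  attr(mol, "heavy_index") <- heavy
  mol
}

# Canonical edge-set strings for an element-labelled graph under a given
# vertex order (used for direct comparison when atom orders align).
edge_keys <- function(bonds) {
  if (!nrow(bonds)) return(character(0))
  paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j), sep = "-")
}

#' Check that a conformer's topology matches a molecule's 2D graph
#'
#' Perceives heavy-atom connectivity from the conformer coordinates and tests
#' element-labelled graph isomorphism against the molecule's heavy-atom graph
#' (bond orders ignored).  When the conformer rows align with the molecule's
#' atom order (identical element sequence), the mismatch report lists the
#' extra and missing edges explicitly; otherwise isomorphism is decided by
#' canonical refinement.
#'
#' @param molecule an [sc_molecule()].
#' @param conformer an [sc_conformer()]; its heavy-atom element multiset must
#'   equal the molecule's (error otherwise, never a `FALSE` return).
#' @param tolerance passed to [perceive_connectivity()].
#' @return logical scalar with attribute `report`: a list with `consistent`,
#'   `extra_edges`, `missing_edges`.
#' @export
check_topology_consistency <- function(molecule, conformer, tolerance = 0.4) {
  stopifnot(inherits(molecule, "sc_molecule"), inherits(conformer, "sc_conformer"))
  perceived <- perceive_connectivity(conformer, tolerance)
  me <- sort(molecule$elements)
  pe <- sort(perceived$elements)
  if (length(me) != length(pe) || !all(me == pe))
    stop_sc("element multiset mismatch: molecule has [%s], conformer heavy atoms [%s]",
            paste(me, collapse = ","), paste(pe, collapse = ","))
  extra <- missing_ <- character(0)
  if (identical(molecule$elements, perceived$elements)) {
    ek_mol <- edge_keys(molecule$bonds)
    ek_per <- edge_keys(perceived$bonds)
    extra <- setdiff(ek_per, ek_mol)
    missing_ <- setdiff(ek_mol, ek_per)
    ok <- !length(extra) && !length(missing_)
  } else {
    ok <- labelled_graph_isomorphic(molecule, perceived)
  }
  structure(ok, report = list(consistent = ok, extra_edges = extra,
                              missing_edges = missing_))
}

# Element-labelled isomorphism via canonical form (exact for the small
# molecules this package handles; falls back to WL-refined invariants).
labelled_graph_isomorphic <- function(a, b) {
  if (n_atoms(a) != n_atoms(b) || nrow(a$bonds) != nrow(b$bonds)) return(FALSE)
  sig <- function(m) {
    # Weisfeiler-Lehman colour refinement; colours are re-compressed to
    # canonical integer ids each round (rank of the sorted signature
    # strings), so ids are comparable across graphs and stay short
    n <- n_atoms(m)
    col <- match(m$elements, sort(unique(m$elements)))
    adj <- vector("list", n)
    for (k in seq_len(nrow(m$bonds))) {
      adj[[m$bonds$i[k]]] <- c(adj[[m$bonds$i[k]]], m$bonds$j[k])
      adj[[m$bonds$j[k]]] <- c(adj[[m$bonds$j[k]]], m$bonds$i[k])
    }
    for (it in seq_len(max(1L, n))) {
      str <- vapply(seq_len(n), function(v)
        paste(col[v], paste(sort(col[adj[[v]]]), collapse = "|"), sep = ":"),
        "")
      nxt <- match(str, sort(unique(str)))
      if (length(unique(nxt)) == length(unique(col))) { col <- nxt; break }
      col <- nxt
    }
    paste(sort(col), collapse = ";")
  }
  identical(sig(a), sig(b))
}
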