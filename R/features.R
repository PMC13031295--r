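# 2D graph featurization for the directed message-passing encoder.

.atom_vocab <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Se", "Br", "I")

#' Atom and directed-bond features of a molecular graph
#'
#' Per-atom features: element one-hot over a fixed vocabulary plus an OTHER
#' bucket (unseen elements are absorbed, never an error), scaled formal
#' charge, aromatic flag and scaled attached-hydrogen count.  Per-directed-
#' bond features: bond order one-hot (1/2/3) and aromatic flag; both
#' directions of every bond are emitted.
#'
#' @param molecule an [sc_molecule()].
#' @return list with `atom` (N x Fa feature matrix), `bond` (2E x Fb feature
#'   matrix), `src`/`dst` (source/target atom of each directed bond), `rev`
#'   (index of the reverse directed bond).
#' @export
featurize_graph <- function(molecule) {
  stopifnot(inherits(molecule, "sc_molecule"))
  n <- n_atoms(molecule)
  vocab <- .atom_vocab
  onehot <- matrix(0, n, length(vocab) + 1L,
                   dimnames = list(NULL, c(vocab, "OTHER")))
  hit <- match(molecule$elements, vocab)
  hit[is.na(hit)] <- length(vocab) + 1L
  onehot[cbind(seq_len(n), hit)] <- 1
  atom <- cbind(onehot,
                charge = pmax(pmin(molecule$charges, 2L), -2L) / 2,
                aromatic = as.numeric(molecule$aromatic),
                n_h = pmin(molecule$n_h, 4L) / 4)
  nb <- nrow(molecule$bonds)
  if (nb) {
    ord <- molecule$bonds$order
    ord[is.na(ord)] <- 1L
    arom <- molecule$bonds$aromatic | ord == 4L
    ord[ord == 4L] <- 1L
    bf1 <- cbind(ord == 1, ord == 2, ord == 3, arom) * 1
    bond <- rbind(bf1, bf1)
    src <- c(molecule$bonds$i, molecule$bonds$j)
    dst <- c(molecule$bonds$j, molecule$bonds$i)
    rev <- c(nb + seq_len(nb), seq_len(nb))
  } else {
    bond <- matrix(0, 0, 4)
    src <- dst <- rev <- integer(0)
  }
  colnames(bond) <- c("single", "double", "triple", "aromatic")
  list(atom = atom, bond = bond, src = src, dst = dst, rev = rev, n = n)
}

#' @rdname featurize_graph
#' @format NULL
#' @export
atom_feature_dim <- function() length(.atom_vocab) + 1L + 3L

#' @rdname featurize_graph
#' @export
bond_feature_dim <- function() 4L
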