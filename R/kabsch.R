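# Optimal rigid superposition (Kabsch algorithm).

#' Minimal RMSD over rigid superpositions
#'
#' Finds the proper rotation `R` and translation `t` minimizing the root mean
#' squared deviation between `A` and the transformed `B` (rows are points,
#' Angstrom).  Reflections are excluded: the returned rotation always has
#' determinant +1.
#'
#' @param A,B N x 3 coordinate matrices of equal shape (N >= 1).
#' @return list with `rmsd` (Angstrom), `rotation` (3 x 3, applied to row
#'   vectors of `B` as `B %*% t(rotation)`), `translation` (length 3, added
#'   after rotation), and `aligned` (the transformed copy of `B`).
#' @examples
#' A <- matrix(rnorm(15), 5, 3)
#' kabsch_rmsd(A, A)$rmsd  # 0
#' @export
kabsch_rmsd <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3)
    stop_sc("A and B must be N x 3 matrices of equal shape")
  n <- nrow(A)
  if (n == 1) {
    t <- as.numeric(A - B)
    return(list(rmsd = 0, rotation = diag(3), translation = t, aligned = A))
  }
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(B0, A0)                 # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)            # column-vector rotation
  aligned <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((A0 - aligned)^2)))
  translation <- ca - as.numeric(R %*% cb)
  list(rmsd = rmsd, rotation = R, translation = translation,
       aligned = sweep(aligned, 2, ca, `+`))
}
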