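# Directed edge-message-passing encoder (D-MPNN) over 2D molecular graphs,
# with hand-derived backpropagation, plus the dual-encoder 2D baseline used to
# pretrain the solvent encoder.

# scatter-add rows of `mat` into `n` bins given by `idx`
scatter_sum <- function(mat, idx, n) {
  out <- matrix(0, n, ncol(mat))
  if (length(idx)) {
    rs <- rowsum(mat, idx)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

#' Initialize D-MPNN encoder parameters
#'
#' @param width hidden width (>= 1).
#' @param depth number of message-passing rounds T (>= 0).
#' @param seed integer seed for weight initialization.
#' @return an `EncoderParams` list: input projection `Wi`/`bi`, message update
#'   `Wm`/`bm`, atom update `Wa`/`ba`, plus `width` and `depth`.
#' @export
mpnn_init <- function(width = 128L, depth = 3L, seed = 1L) {
  if (width < 1 || depth < 0) stop_sc("width must be >= 1 and depth >= 0")
  fa <- atom_feature_dim(); fb <- bond_feature_dim()
  with_seed(seed, list(
    Wi = init_weight(fa + fb, width), bi = numeric(width),
    Wm = init_weight(width, width), bm = numeric(width),
    Wa = init_weight(fa + width, width), ba = numeric(width),
    width = as.integer(width), depth = as.integer(depth)
  ))
}

# Forward pass.  Returns embedding, atom states and a cache for backprop.
mpnn_forward <- function(feat, params, keep_cache = FALSE) {
  X <- feat$atom
  n <- feat$n
  t_rounds <- params$depth
  E <- length(feat$src)
  if (E > 0) {
    Xe <- cbind(X[feat$src, , drop = FALSE], feat$bond)
    H0pre <- sweep(Xe %*% params$Wi, 2, params$bi, `+`)
    H0 <- relu(H0pre)
    H <- H0
    Ms <- Pres <- if (keep_cache) vector("list", t_rounds) else NULL
    if (t_rounds > 0) {
      for (t in seq_len(t_rounds)) {
        Asum <- scatter_sum(H, feat$dst, n)
        M <- Asum[feat$src, , drop = FALSE] - H[feat$rev, , drop = FALSE]
        pre <- H0 + sweep(M %*% params$Wm, 2, params$bm, `+`)
        if (keep_cache) { Ms[[t]] <- M; Pres[[t]] <- pre }
        H <- relu(pre)
      }
    }
    S <- scatter_sum(H, feat$dst, n)
  } else {
    Xe <- matrix(0, 0, ncol(X) + bond_feature_dim())
    H0pre <- H0 <- H <- matrix(0, 0, params$width)
    Ms <- Pres <- NULL
    S <- matrix(0, n, params$width)
  }
  Xa <- cbind(X, S)
  Apre <- sweep(Xa %*% params$Wa, 2, params$ba, `+`)
  Hatom <- relu(Apre)
  if (!all(is.finite(Hatom)))
    stop_sc("non-finite activation in D-MPNN atom update")
  z <- colMeans(Hatom)
  out <- list(z = z, atom_states = Hatom)
  if (keep_cache)
    out$cache <- list(feat = feat, Xe = Xe, H0pre = H0pre, H0 = H0, H = H,
                      Ms = Ms, Pres = Pres, S = S, Xa = Xa, Apre = Apre, n = n)
  out
}

# Backward pass: gradients of a scalar loss w.r.t. encoder parameters, given
# the gradient w.r.t. the molecule embedding (dz) and/or atom states.
mpnn_backward <- function(dz, cache, params, datom_states = NULL) {
  feat <- cache$feat
  n <- cache$n
  dHatom <- matrix(dz / n, n, params$width, byrow = TRUE)
  if (!is.null(datom_states)) dHatom <- dHatom + datom_states
  dApre <- dHatom * (cache$Apre > 0)
  g <- list(Wi = array(0, dim(params$Wi)), bi = numeric(params$width),
            Wm = array(0, dim(params$Wm)), bm = numeric(params$width),
            Wa = crossprod(cache$Xa, dApre), ba = colSums(dApre))
  E <- length(feat$src)
  if (E == 0) return(g)
  fa <- ncol(feat$atom)
  dS <- dApre %*% t(params$Wa[(fa + 1):(fa + params$width), , drop = FALSE])
  dH <- dS[feat$dst, , drop = FALSE]     # d loss / d final edge states
  dH0 <- matrix(0, E, params$width)
  if (params$depth > 0) {
    for (t in rev(seq_len(params$depth))) {
      dpre <- dH * (cache$Pres[[t]] > 0)
      dH0 <- dH0 + dpre
      g$Wm <- g$Wm + crossprod(cache$Ms[[t]], dpre)
      g$bm <- g$bm + colSums(dpre)
      dM <- dpre %*% t(params$Wm)
      B <- scatter_sum(dM, feat$src, n)
      dH <- B[feat$dst, , drop = FALSE] - dM[feat$rev, , drop = FALSE]
    }
    dH0 <- dH0 + dH                       # H at t=0 is H0 itself
  } else {
    dH0 <- dH
  }
  dH0pre <- dH0 * (cache$H0pre > 0)
  g$Wi <- crossprod(cache$Xe, dH0pre)
  g$bi <- colSums(dH0pre)
  g
}

#' Encode a molecule with a D-MPNN
#'
#' Directed edge states are initialized from concatenated source-atom and bond
#' features; `depth` rounds of edge-message updates follow, where the message
#' into edge (v -> w) sums incoming edge states at v excluding the reverse
#' edge; atom states are formed from incoming edge states and the molecule
#' embedding is the mean over atom states.  The output is invariant to input
#' atom ordering.
#'
#' @param molecule an [sc_molecule()].
#' @param params encoder parameters from [mpnn_init()].
#' @return numeric embedding vector of length `params$width`.
#' @export
encode_2d <- function(molecule, params) {
  mpnn_forward(featurize_graph(molecule), params)$z
}

#' Initialize the dual-encoder 2D baseline
#'
#' Two D-MPNNs with identical architecture but independent weights (one for
#' the chromophore, one for the solvent) feeding a feed-forward regression
#' head on the concatenated embeddings.
#'
#' @param width,depth encoder size.
#' @param head_hidden hidden width of the regression head.
#' @param n_targets number of regression outputs.
#' @param seed integer seed.
#' @return a parameter list with `chrom`, `solv`, `head` components.
#' @export
dual_init <- function(width = 128L, depth = 3L, head_hidden = 128L,
                      n_targets = 3L, seed = 1L) {
  list(chrom = mpnn_init(width, depth, seed = derive_seed(seed, "chrom")),
       solv = mpnn_init(width, depth, seed = derive_seed(seed, "solv")),
       head = with_seed(derive_seed(seed, "head"), list(
         W1 = init_weight(2L * width, head_hidden), b1 = numeric(head_hidden),
         W2 = init_weight(head_hidden, n_targets), b2 = numeric(n_targets))))
}

head_forward <- function(x, head, keep_cache = FALSE) {
  pre <- as.numeric(x %*% head$W1) + head$b1
  h <- relu(pre)
  y <- as.numeric(h %*% head$W2) + head$b2
  out <- list(y = y)
  if (keep_cache) out$cache <- list(x = x, pre = pre, h = h)
  out
}

head_backward <- function(dy, cache, head) {
  dh <- as.numeric(head$W2 %*% dy)
  dpre <- dh * (cache$pre > 0)
  list(grads = list(W1 = outer(as.numeric(cache$x), dpre), b1 = dpre,
                    W2 = outer(cache$h, dy), b2 = dy),
       dx = as.numeric(head$W1 %*% dpre))
}

#' Predict targets with the dual 2D encoder baseline
#'
#' Computes `head(concat(encode_2d(chromophore), encode_2d(solvent)))`.
#' Predictions are on the (normalized) head output scale; training utilities
#' handle target normalization.
#'
#' @param chromophore,solvent [sc_molecule()] objects.
#' @param params parameters from [dual_init()].
#' @return numeric vector, one value per target.
#' @export
dual_predict <- function(chromophore, solvent, params) {
  if (params$chrom$width != params$solv$width)
    stop_sc("chromophore and solvent encoders must share the same width")
  zc <- encode_2d(chromophore, params$chrom)
  zs <- encode_2d(solvent, params$solv)
  head_forward(c(zc, zs), params$head)$y
}
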