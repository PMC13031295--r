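# SE(3)-invariant global-attention backbone over (molecule, conformer).
#
# Scalar channels see interatomic distances only (Gaussian radial basis
# expansion + graph-derived attention biases), so all scalar outputs are
# invariant to rigid motions by construction.  The coordinate head emits a
# sum of scalar pair weights times unit difference vectors, which makes the
# predicted displacement rotation-equivariant and translation-invariant.
# Row 1 of the internal state is the virtual node: a coordinate-free global
# token whose final embedding is the molecule-level representation.

#' Gaussian radial basis specification for pair distances
#'
#' @param K number of Gaussian basis functions (>= 1).
#' @param r_max span of the centers in Angstrom; centers are equally spaced on
#'   `[0, r_max]` and the shared width defaults to the center spacing.
#' @param sigma shared width in Angstrom (> 0).
#' @return a `PairFeatureSpec` list with `K`, `centers`, `sigma`.
#' @export
pair_feature_spec <- function(K = 64L, r_max = 12, sigma = NULL) {
  if (K < 1) stop_sc("K must be >= 1")
  centers <- if (K == 1) 0 else seq(0, r_max, length.out = K)
  sigma <- sigma %||% if (K == 1) r_max else centers[2] - centers[1]
  if (sigma <= 0) stop_sc("sigma must be > 0")
  if (is.unsorted(centers, strictly = K > 1)) stop_sc("centers must be strictly increasing")
  list(K = as.integer(K), centers = centers, sigma = sigma)
}

#' Gaussian pair-distance features
#'
#' Entry `(i, j, k)` is `exp(-(d_ij - mu_k)^2 / (2 sigma^2))` for `i != j`,
#' with zeros on the diagonal; symmetric in `(i, j)`.
#'
#' @param coordinates N x 3 matrix (Angstrom), all finite.
#' @param spec a [pair_feature_spec()].
#' @return N x N x K numeric array.
#' @export
gaussian_pair_features <- function(coordinates, spec = pair_feature_spec()) {
  coordinates <- as.matrix(coordinates)
  if (!all(is.finite(coordinates))) stop_sc("coordinates must be finite")
  n <- nrow(coordinates)
  D <- as.matrix(stats::dist(coordinates))
  G <- gaussian_expand(D, spec)
  array(G, dim = c(n, n, spec$K))
}

# (N^2) x K matrix form used internally; diagonal rows are zero.
gaussian_expand <- function(D, spec) {
  n <- nrow(D)
  dv <- as.vector(D)
  G <- exp(-(outer(dv, spec$centers, `-`))^2 / (2 * spec$sigma^2))
  G[seq(1, n * n, by = n + 1), ] <- 0
  G
}

#' Backbone configuration
#'
#' @param width embedding width (divisible by `heads`).
#' @param layers number of attention + feed-forward blocks.
#' @param heads attention heads.
#' @param K,r_max Gaussian basis size and span (see [pair_feature_spec()]).
#' @param coord_hidden hidden width of the pair-scalar coordinate head.
#' @param ffn_mult feed-forward expansion factor.
#' @param max_displacement per-atom displacement norm (Angstrom) above which
#'   refinement aborts (training-instability guard).
#' @param perception_tolerance bond-perception tolerance used when the
#'   conformer's atom list does not match the molecule's heavy atoms.
#' @return a backbone configuration list.
#' @export
backbone_config <- function(width = 128L, layers = 4L, heads = 8L, K = 64L,
                            r_max = 12, coord_hidden = 16L, ffn_mult = 2L,
                            max_displacement = 10,
                            perception_tolerance = 0.45) {
  if (width %% heads != 0) stop_sc("width must be divisible by heads")
  list(width = as.integer(width), layers = as.integer(layers),
       heads = as.integer(heads), pair = pair_feature_spec(K, r_max),
       coord_hidden = as.integer(coord_hidden), ffn_mult = as.integer(ffn_mult),
       max_displacement = max_displacement,
       perception_tolerance = perception_tolerance,
       sp_buckets = 8L, vocab = c(.atom_vocab, "OTHER"))
}

#' Initialize backbone parameters
#'
#' Coordinate-head output weights start at zero, so an untrained backbone
#' predicts zero displacement for any geometry.
#'
#' @param config a [backbone_config()].
#' @param seed integer seed.
#' @return a `BackboneState` parameter list.
#' @export
backbone_init <- function(config = backbone_config(), seed = 1L) {
  W <- config$width; nh <- config$heads; K <- config$pair$K
  Fm <- config$ffn_mult * W
  V <- length(config$vocab)
  fv <- 3L + V
  with_seed(seed, {
    layers <- lapply(seq_len(config$layers), function(l) list(
      g1 = rep(1, W), g2 = rep(1, W),
      Wq = init_weight(W, W), bq = numeric(W),
      Wk = init_weight(W, W), bk = numeric(W),
      Wv = init_weight(W, W), bv = numeric(W),
      Wo = init_weight(W, W, rng_scale = 1 / sqrt(2 * config$layers)), bo = numeric(W),
      Wg = init_weight(K, nh, rng_scale = 0.3),
      sp_emb = matrix(stats::rnorm(config$sp_buckets * nh, sd = 0.1), config$sp_buckets, nh),
      vb_from = numeric(nh), vb_to = numeric(nh),
      Wf1 = init_weight(W, Fm), bf1 = numeric(Fm),
      Wf2 = init_weight(Fm, W, rng_scale = 1 / sqrt(2 * config$layers)), bf2 = numeric(W)
    ))
    list(emb_el = matrix(stats::rnorm(V * W, sd = 0.5), V, W),
         emb_deg = matrix(stats::rnorm(7 * W, sd = 0.2), 7, W),
         emb_ring = matrix(stats::rnorm(2 * W, sd = 0.2), 2, W),
         W_rdf = init_weight(K, W, rng_scale = 0.5),
         virt_W = matrix(stats::rnorm(fv * W, sd = 0.3), fv, W),
         virt_b = stats::rnorm(W, sd = 0.5),
         layers = layers,
         gf = rep(1, W),
         Wc_a = init_weight(W, config$coord_hidden),
         Wc_b = init_weight(W, config$coord_hidden),
         Wc_g = init_weight(K, config$coord_hidden),
         bc = numeric(config$coord_hidden),
         wc2 = numeric(config$coord_hidden))
  })
}

# --- static (geometry-independent) featurization -------------------------

# BFS all-pairs shortest path lengths on a small graph, capped.
bfs_sp <- function(n, adj_list, cap = 6L) {
  SP <- matrix(cap + 1L, n, n)       # cap+1 = far / disconnected bucket
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    dist[s] <- 0L
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj_list[[v]]) if (dist[w] < 0L) { dist[w] <- dist[v] + 1L; q <- c(q, w) }
    }
    hit <- dist >= 0L
    SP[s, hit] <- pmin(dist[hit], cap + 1L)
  }
  SP
}

# Graph-side features for the backbone; independent of coordinates up to the
# fallback bond perception.  Result is cacheable per (molecule, conformer).
backbone_featurize <- function(molecule, conformer, config) {
  n <- nrow(conformer$coords)
  if (identical(conformer$elements, molecule$elements)) {
    bonds <- molecule$bonds
    ring <- ring_atom_flags(molecule)
  } else {
    if (!setequal(unique(conformer$elements),
                  union(unique(molecule$elements), "H")) &&
        !identical(sort(conformer$elements[conformer$elements != "H"]),
                   sort(molecule$elements)))
      stop_sc("conformer element list does not match the molecule")
    # conformer carries explicit hydrogens (or reordered atoms): perceive
    r <- .covalent_radii[conformer$elements]
    if (anyNA(r)) stop_sc("no tabulated covalent radius for element '%s'",
                          conformer$elements[which(is.na(r))[1]])
    D <- as.matrix(stats::dist(conformer$coords))
    adj <- D <= outer(r, r, `+`) + config$perception_tolerance & upper.tri(D)
    pr <- which(adj, arr.ind = TRUE)
    bonds <- data.frame(i = pr[, 1], j = pr[, 2], order = NA_integer_,
                        aromatic = FALSE)
    ring <- ring_atom_flags(list(elements = conformer$elements, bonds = bonds))
  }
  adj_list <- vector("list", n)
  deg <- integer(n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    adj_list[[i]] <- c(adj_list[[i]], j); adj_list[[j]] <- c(adj_list[[j]], i)
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
  }
  SP <- bfs_sp(n, adj_list)
  el_idx <- match(conformer$elements, config$vocab)
  el_idx[is.na(el_idx)] <- length(config$vocab)
  counts <- tabulate(el_idx, nbins = length(config$vocab))
  fvec <- c(n, sum(ring), sum(deg == 1L), counts) / 10
  sp_idx <- pmin(SP, config$sp_buckets - 1L) + 1L
  diag(sp_idx) <- 1L                     # self bucket
  list(n = n, el_idx = el_idx, deg = pmin(deg, 6L), ring = ring,
       sp = SP, sp_idx = sp_idx, fvec = fvec)
}

rmsnorm_fwd <- function(X, g, eps = 1e-6) {
  r <- sqrt(rowMeans(X^2) + eps)
  list(Y = (X / r) * rep(g, each = nrow(X)), r = r)
}

rmsnorm_bwd <- function(dY, X, g, r) {
  W <- ncol(X)
  gd <- dY * rep(g, each = nrow(X))
  s <- rowSums(gd * X)
  dX <- gd / r - X * (s / (W * r^3))
  dg <- colSums(dY * (X / r))
  list(dX = dX, dg = dg)
}

softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# --- forward --------------------------------------------------------------

# Full backbone pass.  `virtual_extra` is an optional vector added to the
# virtual-node input embedding (solvent injection, fusion strategy B).
# Dispatches to the compiled core unless options(solvachrom.compiled = FALSE);
# the R implementation below is the reference the compiled port is tested
# against.
backbone_pass <- function(bf, coords, params, config, virtual_extra = NULL,
                          keep_cache = FALSE) {
  if (isTRUE(getOption("solvachrom.compiled", TRUE))) {
    out <- .cpp_backbone_pass(bf$el_idx, bf$deg, as.integer(bf$ring), bf$fvec,
                              bf$sp_idx, coords, params, config,
                              virtual_extra, keep_cache)
    out$virtual <- as.numeric(out$virtual)
    if (keep_cache) {
      out$cache <- list(engine = "cpp", cpp = out$cache, bf = bf,
                        virtual_extra = virtual_extra)
    }
    return(out)
  }
  backbone_pass_ref(bf, coords, params, config, virtual_extra, keep_cache)
}

backbone_pass_ref <- function(bf, coords, params, config, virtual_extra = NULL,
                              keep_cache = FALSE) {
  n <- bf$n
  W <- config$width; nh <- config$heads; dh <- W / nh
  M <- n + 1L
  spec <- config$pair

  D <- as.matrix(stats::dist(coords))
  Gmat <- gaussian_expand(D, spec)
  # unit difference vectors (r_i - r_j) / d_ij as three N x N matrices
  Dsafe <- D; diag(Dsafe) <- 1
  Ux <- outer(coords[, 1], coords[, 1], `-`) / Dsafe
  Uy <- outer(coords[, 2], coords[, 2], `-`) / Dsafe
  Uz <- outer(coords[, 3], coords[, 3], `-`) / Dsafe
  diag(Ux) <- diag(Uy) <- diag(Uz) <- 0

  # per-atom radial distribution over the Gaussian basis: a direct,
  # invariant geometry channel into the atom embeddings
  rdf <- matrix(0, n, spec$K)
  for (k in seq_len(spec$K)) rdf[, k] <- rowSums(matrix(Gmat[, k], n, n))

  H <- matrix(0, M, W)
  H[1, ] <- params$virt_b + as.numeric(bf$fvec %*% params$virt_W)
  if (!is.null(virtual_extra)) H[1, ] <- H[1, ] + virtual_extra
  H[-1, ] <- params$emb_el[bf$el_idx, , drop = FALSE] +
    params$emb_deg[bf$deg + 1L, , drop = FALSE] +
    params$emb_ring[as.integer(bf$ring) + 1L, , drop = FALSE] +
    rdf %*% params$W_rdf

  sp_idx <- bf$sp_idx
  lc <- if (keep_cache) vector("list", config$layers) else NULL

  for (l in seq_len(config$layers)) {
    p <- params$layers[[l]]
    nrm1 <- rmsnorm_fwd(H, p$g1)
    Hn <- nrm1$Y
    Q <- sweep(Hn %*% p$Wq, 2, p$bq, `+`)
    Km <- sweep(Hn %*% p$Wk, 2, p$bk, `+`)
    Vm <- sweep(Hn %*% p$Wv, 2, p$bv, `+`)
    GB <- Gmat %*% p$Wg                                 # (N^2) x nh
    O <- matrix(0, M, W)
    Ph <- if (keep_cache) vector("list", nh) else NULL
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      B <- matrix(0, M, M)
      B[-1, -1] <- matrix(GB[, h], n, n) +
        matrix(p$sp_emb[sp_idx, h], n, n)
      B[1, -1] <- p$vb_from[h]
      B[, 1] <- p$vb_to[h]
      S <- tcrossprod(Q[, cols, drop = FALSE], Km[, cols, drop = FALSE]) / sqrt(dh) + B
      P <- softmax_rows(S)
      O[, cols] <- P %*% Vm[, cols, drop = FALSE]
      if (keep_cache) Ph[[h]] <- P
    }
    attn <- sweep(O %*% p$Wo, 2, p$bo, `+`)
    H1 <- H + attn
    nrm2 <- rmsnorm_fwd(H1, p$g2)
    Fpre <- sweep(nrm2$Y %*% p$Wf1, 2, p$bf1, `+`)
    Fh <- relu(Fpre)
    H2 <- H1 + sweep(Fh %*% p$Wf2, 2, p$bf2, `+`)
    if (!all(is.finite(H2))) stop_sc("non-finite activation in backbone layer %d", l)
    if (keep_cache)
      lc[[l]] <- list(Hin = H, Hn = Hn, r1 = nrm1$r, Q = Q, K = Km, V = Vm,
                      Ph = Ph, O = O, H1 = H1, Hn2 = nrm2$Y, r2 = nrm2$r,
                      Fpre = Fpre, Fh = Fh)
    H <- H2
  }

  nrmf <- rmsnorm_fwd(H, params$gf)
  HF <- nrmf$Y
  virtual <- HF[1, ]
  atom_emb <- HF[-1, , drop = FALSE]

  # equivariant displacement head
  if (n > 1) {
    Ap <- atom_emb %*% params$Wc_a
    Bp <- atom_emb %*% params$Wc_b
    Gp <- Gmat %*% params$Wc_g
    ii <- rep(seq_len(n), times = n)   # row index of pair p = i + (j-1) n
    jj <- rep(seq_len(n), each = n)
    Cpre <- Ap[ii, , drop = FALSE] + Bp[jj, , drop = FALSE] + Gp
    Cpre <- sweep(Cpre, 2, params$bc, `+`)
    Crelu <- relu(Cpre)
    cvec <- as.numeric(Crelu %*% params$wc2)
    Cm <- matrix(cvec, n, n)
    diag(Cm) <- 0
    disp <- cbind(rowSums(Cm * Ux), rowSums(Cm * Uy), rowSums(Cm * Uz))
  } else {
    disp <- matrix(0, n, 3)
    Cpre <- Crelu <- NULL
    ii <- jj <- integer(0)
  }

  out <- list(virtual = virtual, atom_emb = atom_emb, displacement = disp)
  if (keep_cache)
    out$cache <- list(bf = bf, coords = coords, Gmat = Gmat, rdf = rdf,
                      Ux = Ux, Uy = Uy, Uz = Uz, sp_idx = sp_idx,
                      layers = lc, Hlast = H, rF = nrmf$r, HF = HF,
                      Cpre = Cpre, Crelu = Crelu, ii = ii, jj = jj,
                      virtual_extra = virtual_extra)
  out
}

# Backward pass.  Gradients flow to parameters and (for fusion strategy B) to
# the injected virtual-node vector; coordinates are treated as inputs.
backbone_bwd <- function(dvirtual, datom_emb, ddisp, cache, params, config) {
  if (identical(cache$engine, "cpp")) {
    bf <- cache$bf
    out <- .cpp_backbone_bwd(dvirtual, datom_emb, ddisp, cache$cpp,
                             bf$el_idx, bf$deg, as.integer(bf$ring), bf$fvec,
                             params, config)
    out$grads <- plist_conform(out$grads, params)
    out$dvirtual_extra <- as.numeric(out$dvirtual_extra)
    return(out)
  }
  backbone_bwd_ref(dvirtual, datom_emb, ddisp, cache, params, config)
}

backbone_bwd_ref <- function(dvirtual, datom_emb, ddisp, cache, params, config) {
  bf <- cache$bf
  n <- bf$n
  W <- config$width; nh <- config$heads; dh <- W / nh
  M <- n + 1L
  g <- plist_zeros_like(params)

  dAtom <- if (is.null(datom_emb)) matrix(0, n, W) else datom_emb
  # coordinate head
  if (!is.null(ddisp) && n > 1 && any(ddisp != 0)) {
    dC <- cache$Ux * matrix(ddisp[, 1], n, n) +
      cache$Uy * matrix(ddisp[, 2], n, n) +
      cache$Uz * matrix(ddisp[, 3], n, n)
    diag(dC) <- 0
    dcvec <- as.numeric(dC)
    g$wc2 <- as.numeric(crossprod(cache$Crelu, dcvec))
    dCpre <- outer(dcvec, params$wc2) * (cache$Cpre > 0)
    g$bc <- colSums(dCpre)
    g$Wc_g <- crossprod(cache$Gmat, dCpre)
    dAp <- rowsum(dCpre, cache$ii)
    dBp <- rowsum(dCpre, cache$jj)
    atom_emb <- cache$HF[-1, , drop = FALSE]
    g$Wc_a <- crossprod(atom_emb, dAp)
    g$Wc_b <- crossprod(atom_emb, dBp)
    dAtom <- dAtom + dAp %*% t(params$Wc_a) + dBp %*% t(params$Wc_b)
  }

  dHF <- rbind(if (is.null(dvirtual)) numeric(W) else dvirtual, dAtom)
  nb <- rmsnorm_bwd(dHF, cache$Hlast, params$gf, cache$rF)
  dH <- nb$dX
  g$gf <- nb$dg

  for (l in rev(seq_len(config$layers))) {
    p <- params$layers[[l]]
    lc <- cache$layers[[l]]
    gl <- g$layers[[l]]
    # FFN block
    dFh <- dH %*% t(p$Wf2)
    gl$Wf2 <- crossprod(lc$Fh, dH)
    gl$bf2 <- colSums(dH)
    dFpre <- dFh * (lc$Fpre > 0)
    gl$Wf1 <- crossprod(lc$Hn2, dFpre)
    gl$bf1 <- colSums(dFpre)
    dHn2 <- dFpre %*% t(p$Wf1)
    nb2 <- rmsnorm_bwd(dHn2, lc$H1, p$g2, lc$r2)
    gl$g2 <- nb2$dg
    dH1 <- dH + nb2$dX
    # attention block
    dattn <- dH1
    dO <- dattn %*% t(p$Wo)
    gl$Wo <- crossprod(lc$O, dattn)
    gl$bo <- colSums(dattn)
    dQ <- matrix(0, M, W); dK <- matrix(0, M, W); dV <- matrix(0, M, W)
    dGB <- matrix(0, n * n, nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      P <- lc$Ph[[h]]
      dOh <- dO[, cols, drop = FALSE]
      dP <- tcrossprod(dOh, lc$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(P, dOh)
      dS <- P * (dP - rowSums(dP * P))
      dQ[, cols] <- dS %*% lc$K[, cols, drop = FALSE] / sqrt(dh)
      dK[, cols] <- crossprod(dS, lc$Q[, cols, drop = FALSE]) / sqrt(dh)
      dBr <- dS[-1, -1, drop = FALSE]
      dGB[, h] <- as.numeric(dBr)
      sp_sums <- rowsum(as.numeric(dBr), as.integer(cache$sp_idx))
      gl$sp_emb[as.integer(rownames(sp_sums)), h] <-
        gl$sp_emb[as.integer(rownames(sp_sums)), h] + sp_sums
      gl$vb_from[h] <- sum(dS[1, -1])
      gl$vb_to[h] <- sum(dS[, 1])
    }
    gl$Wg <- crossprod(cache$Gmat, dGB)
    dHn <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    gl$bq <- colSums(dQ); gl$bk <- colSums(dK); gl$bv <- colSums(dV)
    gl$Wq <- crossprod(lc$Hn, dQ)
    gl$Wk <- crossprod(lc$Hn, dK)
    gl$Wv <- crossprod(lc$Hn, dV)
    nb1 <- rmsnorm_bwd(dHn, lc$Hin, p$g1, lc$r1)
    gl$g1 <- nb1$dg
    dH <- dH1 + nb1$dX
    g$layers[[l]] <- gl
  }

  # input embeddings
  g$virt_b <- dH[1, ]
  g$virt_W <- outer(bf$fvec, dH[1, ])
  dAt <- dH[-1, , drop = FALSE]
  g$emb_el <- scatter_sum(dAt, bf$el_idx, nrow(params$emb_el))
  g$emb_deg <- scatter_sum(dAt, bf$deg + 1L, 7L)
  g$emb_ring <- scatter_sum(dAt, as.integer(bf$ring) + 1L, 2L)
  g$W_rdf <- crossprod(cache$rdf, dAt)
  list(grads = g, dvirtual_extra = dH[1, ])
}

#' Run the invariant backbone on a molecule and conformer
#'
#' @param molecule an [sc_molecule()] (graph features / attention biases).
#' @param conformer an [sc_conformer()] whose atoms match the molecule (heavy
#'   atoms in order, or with explicit hydrogens, in which case connectivity is
#'   perceived from the geometry).
#' @param state parameter list from [backbone_init()].
#' @param config the matching [backbone_config()].
#' @param virtual_extra optional vector added to the virtual-node input
#'   embedding before the first attention block (solvent injection).
#' @return list with `virtual` (virtual-node embedding, invariant to rigid
#'   motions), `atom_emb` (per-atom embeddings) and `displacement` (N x 3
#'   rotation-equivariant, translation-invariant coordinate update).
#' @export
backbone_forward <- function(molecule, conformer, state,
                             config = backbone_config(),
                             virtual_extra = NULL) {
  bf <- backbone_featurize(molecule, conformer, config)
  out <- backbone_pass(bf, conformer$coords, state, config, virtual_extra)
  out[c("virtual", "atom_emb", "displacement")]
}

#' Iteratively refine a conformer with the backbone
#'
#' Applies the backbone `iterations` times, adding each predicted displacement
#' to the coordinates (re-featurizing distances in between).  Errors if any
#' per-atom displacement norm exceeds `config$max_displacement`.
#'
#' @inheritParams backbone_forward
#' @param iterations number of refinement steps (>= 1).
#' @return an [sc_conformer()] with fidelity tag `REFINED`.
#' @export
refine_coordinates <- function(molecule, conformer, state,
                               config = backbone_config(), iterations = 1L,
                               virtual_extra = NULL) {
  if (iterations < 1) stop_sc("iterations must be >= 1")
  bf <- backbone_featurize(molecule, conformer, config)
  coords <- conformer$coords
  for (r in seq_len(iterations)) {
    out <- backbone_pass(bf, coords, state, config, virtual_extra)
    nrm <- sqrt(rowSums(out$displacement^2))
    if (any(nrm > config$max_displacement))
      stop_sc("displacement norm %.2f exceeds guard %.2f at iteration %d",
              max(nrm), config$max_displacement, r)
    coords <- coords + out$displacement
  }
  sc_conformer(conformer$elements, coords, "REFINED",
               source_key = conformer$source_key)
}
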