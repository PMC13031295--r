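# Shared fixtures, built in code and memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small generated dataset used by many structural tests (108 records).
tiny_fixture <- function() {
  cached("tiny", make_fixture_dataset(
    fixture_spec(n_chromophores = 12, seed = 401)))
}

# Midsize dataset for short training runs.
small_train_fixture <- function() {
  cached("small_train", make_fixture_dataset(
    fixture_spec(n_chromophores = 40, seed = 402)))
}

# A small backbone configuration that keeps tests fast.
tiny_backbone <- function(width = 32L, layers = 2L, heads = 4L, K = 16L)
  backbone_config(width = width, layers = layers, heads = heads, K = K,
                  coord_hidden = 8L)

tiny_model_config <- function(fusion = "VIRTUAL_NODE",
                              pair = pair_training_config("XTB", "DFT_IMP")) {
  model_config(fusion = fusion, backbone = tiny_backbone(),
               solvent_width = 16L, solvent_depth = 2L, head_hidden = 32L,
               pair = pair)
}

# A backbone parameter set with an active (non-zero) coordinate head.
active_backbone <- function(config, seed = 5L) {
  st <- backbone_init(config, seed = seed)
  st$wc2 <- with_seed_test(seed + 1L, stats::rnorm(config$coord_hidden, sd = 0.3))
  st
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# random proper rotation + translation
random_rigid_motion <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 5))
}

apply_rigid <- function(coords, motion)
  sweep(coords %*% t(motion$R), 2, motion$t, `+`)

# a molecule + random-geometry conformer pair for backbone tests
random_mol_conformer <- function(smiles = "C=CC=Cc1ccc(N)cc1", sd = 2,
                                 seed = 1L) {
  mol <- parse_structure(smiles)
  n <- length(mol$elements)
  coords <- with_seed_test(seed, matrix(stats::rnorm(n * 3, sd = sd), n, 3))
  list(mol = mol, cf = sc_conformer(mol$elements, coords, "XTB",
                                    mol$canonical_key))
}

# Independent single-pass oracle for depth 0: no message passing, atom states
# from input projections only, written as plain loops.
encode_t0_oracle <- function(mol, params) {
  feat <- featurize_graph(mol)
  n <- feat$n
  H0 <- matrix(0, length(feat$src), params$width)
  for (e in seq_along(feat$src)) {
    x <- c(feat$atom[feat$src[e], ], feat$bond[e, ])
    H0[e, ] <- pmax(as.numeric(x %*% params$Wi) + params$bi, 0)
  }
  states <- matrix(0, n, params$width)
  for (v in seq_len(n)) {
    s <- numeric(params$width)
    for (e in seq_along(feat$dst)) if (feat$dst[e] == v) s <- s + H0[e, ]
    states[v, ] <- pmax(as.numeric(c(feat$atom[v, ], s) %*% params$Wa) +
                          params$ba, 0)
  }
  colMeans(states)
}
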