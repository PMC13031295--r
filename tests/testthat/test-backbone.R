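# SE(3)-invariant backbone: pair features, attention, coordinate head,
# Kabsch superposition.

test_that("gaussian_pair_features matches its definition (loop oracle)", {
  spec <- pair_feature_spec(K = 7, r_max = 8)
  coords <- with_seed_test(2, matrix(stats::rnorm(15, sd = 3), 5, 3))
  G <- gaussian_pair_features(coords, spec)
  expect_equal(dim(G), c(5, 5, 7))
  # plain-loop oracle
  for (i in 1:5) for (j in 1:5) for (k in 1:7) {
    want <- if (i == j) 0 else {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      exp(-(d - spec$centers[k])^2 / (2 * spec$sigma^2))
    }
    expect_equal(G[i, j, k], want, tolerance = 1e-12)
  }
  # exact center hit -> 1.0
  two <- matrix(c(0, 0, 0, spec$centers[3], 0, 0), 2, 3, byrow = TRUE)
  expect_equal(gaussian_pair_features(two, spec)[1, 2, 3], 1.0)
  # symmetry, zero diagonal, range
  expect_equal(G, aperm(G, c(2, 1, 3)))
  expect_true(all(G[cbind(1:5, 1:5, rep(1:7, each = 5))] == 0))
  off <- G[rep(1:5, 5) != rep(1:5, each = 5)]
  expect_true(all(off > 0 & off <= 1))
})

test_that("scalar outputs are SE(3)-invariant and displacements equivariant", {
  cfg <- tiny_backbone()
  st <- active_backbone(cfg)
  rc <- random_mol_conformer(seed = 3)
  base <- backbone_forward(rc$mol, rc$cf, st, cfg)
  for (q in 1:20) {
    mo <- with_seed_test(100 + q, random_rigid_motion())
    moved <- sc_conformer(rc$cf$elements, apply_rigid(rc$cf$coords, mo), "XTB")
    out <- backbone_forward(rc$mol, moved, st, cfg)
    expect_lt(max(abs(out$virtual - base$virtual)) /
                max(abs(base$virtual)), 1e-5)
    expect_lt(max(abs(out$atom_emb - base$atom_emb)), 1e-8)
    expect_lt(max(abs(out$displacement - base$displacement %*% t(mo$R))),
              1e-8)
  }
})

test_that("atom permutation permutes per-atom outputs, virtual node unchanged", {
  cfg <- tiny_backbone()
  st <- active_backbone(cfg, seed = 9)
  mk <- make_chromophore(2, list(ring1 = "furan"), seed = 12)
  mol <- mk$molecule; cf <- mk$conformer
  base <- backbone_forward(mol, cf, st, cfg)
  for (q in 1:5) {
    perm <- with_seed_test(q, sample(length(mol$elements)))
    inv <- match(seq_along(perm), perm)
    pmol <- sc_molecule(mol$elements[perm], mol$charges[perm],
                        data.frame(i = inv[mol$bonds$i], j = inv[mol$bonds$j],
                                   order = mol$bonds$order,
                                   aromatic = mol$bonds$aromatic))
    pcf <- sc_conformer(cf$elements[perm], cf$coords[perm, ], cf$fidelity)
    out <- backbone_forward(pmol, pcf, st, cfg)
    expect_lt(max(abs(out$virtual - base$virtual)), 1e-8)
    expect_lt(max(abs(out$atom_emb - base$atom_emb[perm, ])), 1e-8)
    expect_lt(max(abs(out$displacement - base$displacement[perm, ])), 1e-8)
  }
})

test_that("zero coordinate-head weights give exactly zero displacement", {
  cfg <- tiny_backbone()
  st <- backbone_init(cfg, seed = 2)       # wc2 is zero-initialized
  rc <- random_mol_conformer(seed = 5)
  out <- backbone_forward(rc$mol, rc$cf, st, cfg)
  expect_true(all(out$displacement == 0))
  # single-atom input: displacement defined as zero
  one <- sc_conformer("O", matrix(0, 1, 3), "XTB")
  omol <- parse_structure("O")
  st2 <- active_backbone(cfg)
  expect_true(all(backbone_forward(omol, one, st2, cfg)$displacement == 0))
})

test_that("refine_coordinates composes, preserves equivariance, and guards", {
  cfg <- tiny_backbone()
  rc <- random_mol_conformer(seed = 6)

  # zero displacement -> identity for any iteration count
  st0 <- backbone_init(cfg, seed = 3)
  ref <- refine_coordinates(rc$mol, rc$cf, st0, cfg, iterations = 3)
  expect_equal(ref$coords, rc$cf$coords)
  expect_identical(ref$fidelity, "REFINED")

  # R = 2 equals two applications of R = 1 with re-featurization
  st <- active_backbone(cfg, seed = 7)
  st$wc2 <- st$wc2 * 0.1                   # keep displacements tame
  r2 <- refine_coordinates(rc$mol, rc$cf, st, cfg, iterations = 2)
  r1 <- refine_coordinates(rc$mol, rc$cf, st, cfg, iterations = 1)
  r11 <- refine_coordinates(rc$mol, r1, st, cfg, iterations = 1)
  expect_equal(r2$coords, r11$coords, tolerance = 1e-12)

  # equivariance across iterations
  mo <- with_seed_test(1, random_rigid_motion())
  moved <- sc_conformer(rc$cf$elements, apply_rigid(rc$cf$coords, mo), "XTB")
  rmoved <- refine_coordinates(rc$mol, moved, st, cfg, iterations = 2)
  expect_lt(max(abs(rmoved$coords - apply_rigid(r2$coords, mo))), 1e-8)

  # explosion guard
  stbig <- active_backbone(cfg, seed = 8)
  stbig$wc2 <- stbig$wc2 * 1e6
  expect_error(refine_coordinates(rc$mol, rc$cf, stbig, cfg),
               "exceeds guard")
  expect_error(refine_coordinates(rc$mol, rc$cf, st, cfg, iterations = 0),
               ">= 1")
})

test_that("compiled backbone equals the reference R implementation", {
  cfg <- tiny_backbone(width = 24, layers = 2, heads = 4, K = 9)
  st <- active_backbone(cfg, seed = 11)
  rc <- random_mol_conformer("C=Cc1ccoc1", seed = 13)
  bf <- solvachrom:::backbone_featurize(rc$mol, rc$cf, cfg)
  ve <- with_seed_test(5, stats::rnorm(24, sd = 0.3))
  run <- function(compiled) {
    withr::local_options(solvachrom.compiled = compiled)
    fwd <- solvachrom:::backbone_pass(bf, rc$cf$coords, st, cfg,
                                      virtual_extra = ve, keep_cache = TRUE)
    n <- nrow(rc$cf$coords)
    dv <- with_seed_test(6, stats::rnorm(24))
    da <- with_seed_test(7, matrix(stats::rnorm(n * 24), n, 24))
    dd <- with_seed_test(8, matrix(stats::rnorm(n * 3), n, 3))
    bwd <- solvachrom:::backbone_bwd(dv, da, dd, fwd$cache, st, cfg)
    list(fwd = fwd[c("virtual", "atom_emb", "displacement")], bwd = bwd)
  }
  a <- run(TRUE); b <- run(FALSE)
  expect_equal(a$fwd$virtual, b$fwd$virtual, tolerance = 1e-12)
  expect_equal(a$fwd$displacement, b$fwd$displacement, tolerance = 1e-12,
               ignore_attr = TRUE)
  diffs <- solvachrom:::plist_unlist(
    solvachrom:::plist_map2(a$bwd$grads, b$bwd$grads,
                            function(x, y) max(abs(x - y), 0)))
  expect_lt(max(diffs), 1e-10)
  expect_equal(a$bwd$dvirtual_extra, b$bwd$dvirtual_extra, tolerance = 1e-12)
})

test_that("kabsch_rmsd finds the optimal proper superposition", {
  A <- with_seed_test(1, matrix(stats::rnorm(24, sd = 2), 8, 3))
  expect_equal(kabsch_rmsd(A, A)$rmsd, 0, tolerance = 1e-12)

  for (q in 1:5) {
    mo <- with_seed_test(q, random_rigid_motion())
    B <- apply_rigid(A, mo)
    res <- kabsch_rmsd(A, B)
    expect_lt(res$rmsd, 1e-8)
    expect_equal(det(res$rotation), 1, tolerance = 1e-9)
    expect_lt(max(abs(res$aligned - A)), 1e-8)
  }

  # hand-derived case: centers coincide after centering, optimal rotation is
  # the identity, per-point deviation 0.5
  A2 <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  B2 <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(kabsch_rmsd(A2, B2)$rmsd, 0.5, tolerance = 1e-12)

  # symmetry and upper bound by the unaligned RMSD
  for (q in 1:10) {
    A3 <- with_seed_test(20 + q, matrix(stats::rnorm(18), 6, 3))
    B3 <- with_seed_test(40 + q, matrix(stats::rnorm(18), 6, 3))
    r_ab <- kabsch_rmsd(A3, B3)$rmsd
    expect_equal(r_ab, kabsch_rmsd(B3, A3)$rmsd, tolerance = 1e-9)
    expect_lte(r_ab, sqrt(mean(rowSums((A3 - B3)^2))) + 1e-12)
  }
  expect_error(kabsch_rmsd(A, A[1:3, ]), "equal shape")
})

test_that("kabsch_rmsd agrees with a numeric optimizer over rotations", {
  euler <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz * cy, cz * sy * sx - sz * cx, cz * sy * cx + sz * sx,
             sz * cy, sz * sy * sx + cz * cx, sz * sy * cx - cz * sx,
             -sy, cy * sx, cy * cx), 3, 3, byrow = TRUE)
  }
  for (q in 1:5) {
    A <- with_seed_test(50 + q, matrix(stats::rnorm(15, sd = 1.5), 5, 3))
    B <- with_seed_test(70 + q, matrix(stats::rnorm(15, sd = 1.5), 5, 3))
    A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
    obj <- function(ang) sqrt(mean(rowSums((A0 - B0 %*% t(euler(ang)))^2)))
    best <- Inf
    for (s in 1:8) {
      start <- with_seed_test(90 + 10 * q + s, stats::runif(3, -pi, pi))
      best <- min(best, stats::optim(start, obj,
                                     method = "Nelder-Mead")$value)
    }
    expect_equal(kabsch_rmsd(A, B)$rmsd, best, tolerance = 1e-4)
  }
})
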