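# Model assembly: fusion strategies, joint objective, coarse inference.

make_tiny_model <- function(fusion = "VIRTUAL_NODE", seed = 3L,
                            pair = pair_training_config("XTB", "DFT_IMP")) {
  m <- model_init(tiny_model_config(fusion, pair), seed = seed)
  m$norm <- list(mu = c(380, 420, -0.5), sd = c(40, 45, 0.3))
  m
}

test_that("inject_solvent is the projected sum it claims to be", {
  W_p <- with_seed_test(1, matrix(stats::rnorm(5 * 8), 5, 8))
  v <- with_seed_test(2, stats::rnorm(8))
  s <- with_seed_test(3, stats::rnorm(5))

  # zero solvent embedding leaves the virtual node unchanged
  expect_equal(inject_solvent(v, numeric(5), W_p), v)
  # zero virtual node with identity projection returns the solvent embedding
  expect_equal(inject_solvent(numeric(5), s, diag(5)), s)
  # random inputs match a plain loop oracle
  oracle <- v
  for (j in seq_len(8)) oracle[j] <- v[j] + sum(s * W_p[, j])
  expect_equal(inject_solvent(v, s, W_p), oracle, tolerance = 1e-10)
  expect_error(inject_solvent(v, s, diag(8)), "incompatible")
})

test_that("fusion strategies degenerate consistently with zero solvent input", {
  fix <- tiny_fixture()
  rec <- fix$dataset$records[[3]]
  mN <- make_tiny_model("NONE")
  mB <- make_tiny_model("VIRTUAL_NODE")
  mA <- make_tiny_model("HEAD_CONCAT")
  # share backbone weights; force the solvent embedding to zero
  zero_solvent <- function(m) {
    m$params$backbone <- mN$params$backbone
    m$params$solvent$Wa[] <- 0
    m$params$solvent$ba[] <- 0
    m
  }
  mB <- zero_solvent(mB); mA <- zero_solvent(mA)
  mB$params$head <- mN$params$head
  # strategy A: head input is longer; make the extra rows irrelevant and the
  # shared rows equal to the NONE head
  W <- mN$config$backbone$width
  mA$params$head$W1[seq_len(W), ] <- mN$params$head$W1
  mA$params$head$W1[-seq_len(W), ] <- 0
  mA$params$head$b1 <- mN$params$head$b1
  mA$params$head$W2 <- mN$params$head$W2
  mA$params$head$b2 <- mN$params$head$b2

  pN <- solvachrom_forward(rec, "XTB", mN)$predictions
  pB <- solvachrom_forward(rec, "XTB", mB)$predictions
  pA <- solvachrom_forward(rec, "XTB", mA)$predictions
  expect_lt(max(abs(pB - pN)), 1e-6)
  expect_lt(max(abs(pA - pN)), 1e-6)
})

test_that("predictions are invariant to rigid motions of the conformer", {
  fix <- tiny_fixture()
  rec <- fix$dataset$records[[5]]
  m <- make_tiny_model("VIRTUAL_NODE")
  m$params$backbone$wc2 <- with_seed_test(4, stats::rnorm(8, sd = 0.2))
  base <- solvachrom_forward(rec, "XTB", m)
  for (q in 1:5) {
    mo <- with_seed_test(q, random_rigid_motion())
    rec2 <- rec
    cf <- rec$conformers[["XTB"]]
    rec2$conformers[["XTB"]] <- sc_conformer(cf$elements,
                                             apply_rigid(cf$coords, mo),
                                             "XTB", cf$source_key)
    out <- solvachrom_forward(rec2, "XTB", m)
    expect_lt(max(abs(out$predictions - base$predictions)) /
                max(abs(base$predictions)), 1e-5)
  }
})

test_that("the solvent-blind ablation ignores the solvent; fusion B does not", {
  fix <- tiny_fixture()
  recs <- fix$dataset$records
  ck <- vapply(recs, function(r) r$chromophore$canonical_key, "")
  sk <- vapply(recs, function(r) r$solvent$canonical_key, "")
  grp <- which(ck == ck[1] & !duplicated(sk))[1:2]   # same chromophore, two solvents
  # same per-chromophore XTB conformer: records differ only in solvent
  expect_identical(recs[[grp[1]]]$conformers[["XTB"]]$coords,
                   recs[[grp[2]]]$conformers[["XTB"]]$coords)

  mN <- make_tiny_model("NONE")
  pN1 <- solvachrom_forward(recs[[grp[1]]], "XTB", mN)$predictions
  pN2 <- solvachrom_forward(recs[[grp[2]]], "XTB", mN)$predictions
  expect_equal(pN1, pN2, tolerance = 1e-12)

  mB <- make_tiny_model("VIRTUAL_NODE")
  pB1 <- solvachrom_forward(recs[[grp[1]]], "XTB", mB)$predictions
  pB2 <- solvachrom_forward(recs[[grp[2]]], "XTB", mB)$predictions
  expect_gt(max(abs(pB1 - pB2)), 1e-8)
  # ... but only through the projection: zero W_p removes the sensitivity
  mB0 <- mB
  mB0$params$proj$Wp[] <- 0
  expect_equal(solvachrom_forward(recs[[grp[1]]], "XTB", mB0)$predictions,
               solvachrom_forward(recs[[grp[2]]], "XTB", mB0)$predictions,
               tolerance = 1e-12)
})

test_that("missing conformer fidelity errors and lists available tags", {
  fix <- tiny_fixture()
  m <- make_tiny_model()
  expect_error(solvachrom_forward(fix$dataset$records[[1]], "REFINED", m),
               "available.*RDKIT")
})

test_that("joint_loss matches a brute-force two-term oracle", {
  fix <- tiny_fixture()
  rec <- fix$dataset$records[[2]]
  ref <- rec$conformers[["DFT_IMP"]]
  n <- nrow(ref$coords)
  cfg <- pair_training_config("XTB", "DFT_IMP", w_prop = 0.7, w_coord = 1.3)
  norm <- list(mu = c(380, 420, -0.5), sd = c(40, 45, 0.3))

  for (q in 1:20) {
    pred <- with_seed_test(q, rec$targets + stats::rnorm(3, sd = 30))
    pred[is.na(pred)] <- 400
    names(pred) <- target_names()
    refined <- with_seed_test(100 + q, ref$coords +
                                matrix(stats::rnorm(n * 3, sd = 0.3), n, 3))
    got <- joint_loss(pred, refined, rec, ref, cfg, norm)

    # oracle: explicit mask loop + kabsch-based alignment
    terms <- c()
    for (k in 1:3) if (rec$mask[k] == 1)
      terms <- c(terms, abs((pred[k] - rec$targets[k]) / norm$sd[k]))
    lp <- if (length(terms)) mean(terms) else 0
    al <- kabsch_rmsd(refined, ref$coords)
    lc <- mean(sqrt(rowSums((refined - al$aligned)^2)))
    expect_equal(as.numeric(got), 0.7 * lp + 1.3 * lc, tolerance = 1e-9)
  }

  # refined = reference and exact predictions -> zero loss
  exact <- rec$targets
  exact[is.na(exact)] <- 0
  names(exact) <- target_names()
  expect_equal(as.numeric(joint_loss(exact, ref$coords, rec, ref, cfg, norm)),
               0, tolerance = 1e-9)

  # all targets masked: only the coordinate term remains
  rec0 <- rec
  rec0$mask[] <- 0L
  rec0$targets[] <- NA_real_
  refined <- ref$coords + 0.2
  l0 <- joint_loss(exact, refined, rec0, ref,
                   pair_training_config("XTB", "DFT_IMP", 1, 1), norm)
  expect_equal(as.numeric(l0), 0, tolerance = 1e-9)  # pure translation aligns away
  expect_error(joint_loss(exact, refined[-1, ], rec, ref, cfg, norm),
               "atom count")
})

test_that("coordinate loss is invariant to rigid motions of either argument", {
  fix <- tiny_fixture()
  rec <- fix$dataset$records[[4]]
  rec$mask[] <- 0L; rec$targets[] <- NA_real_
  ref <- rec$conformers[["DFT_IMP"]]
  n <- nrow(ref$coords)
  cfg <- pair_training_config("XTB", "DFT_IMP", w_prop = 0, w_coord = 1)
  refined <- with_seed_test(8, ref$coords + matrix(stats::rnorm(n * 3, sd = .4), n, 3))
  pred <- stats::setNames(c(400, 450, -1), target_names())
  base <- as.numeric(joint_loss(pred, refined, rec, ref, cfg))
  for (q in 1:5) {
    mo <- with_seed_test(q, random_rigid_motion())
    moved_refined <- apply_rigid(refined, mo)
    expect_equal(as.numeric(joint_loss(pred, moved_refined, rec, ref, cfg)),
                 base, tolerance = 1e-9)
    ref2 <- sc_conformer(ref$elements, apply_rigid(ref$coords, mo), "DFT_IMP")
    expect_equal(as.numeric(joint_loss(pred, refined, rec, ref2, cfg)),
                 base, tolerance = 1e-9)
  }
})

test_that("masked target slots receive exactly zero gradient", {
  fix <- tiny_fixture()
  rec <- fix$dataset$records[[6]]
  rec$mask <- c(1L, 0L, 0L)
  rec$targets[2:3] <- NA_real_
  ref <- rec$conformers[["DFT_IMP"]]
  cfg <- pair_training_config("XTB", "DFT_IMP", 1, 1)
  norm <- list(mu = c(380, 420, -0.5), sd = c(40, 45, 0.3))
  pred <- stats::setNames(c(400, 430, -0.3), target_names())
  refined <- ref$coords + 0.1
  jl <- solvachrom:::joint_loss_grad(pred, refined, rec, ref, cfg, norm)
  expect_identical(jl$dpred[2:3], c(0, 0))          # analytic: exactly zero
  # finite differences confirm flatness in the masked directions
  for (k in 2:3) {
    for (eps in c(1e-3, 1)) {
      p2 <- pred; p2[k] <- pred[k] + eps
      expect_equal(as.numeric(joint_loss(p2, refined, rec, ref, cfg, norm)),
                   as.numeric(joint_loss(pred, refined, rec, ref, cfg, norm)),
                   tolerance = 1e-12)
    }
  }
})

test_that("w_coord = 0 silences the coordinate head gradient entirely", {
  fix <- tiny_fixture()
  rec <- fix$dataset$records[[7]]
  ref <- rec$conformers[["DFT_IMP"]]
  m <- make_tiny_model("VIRTUAL_NODE",
                       pair = pair_training_config("XTB", "DFT_IMP",
                                                   w_prop = 1, w_coord = 0))
  m$params$backbone$wc2 <- with_seed_test(2, stats::rnorm(8, sd = 0.2))
  rg <- solvachrom:::record_grad(m, rec, ref)
  expect_true(all(rg$grads$backbone$wc2 == 0))
  expect_true(all(rg$grads$backbone$Wc_a == 0))
  # with w_coord > 0 the same head receives gradient
  m2 <- make_tiny_model("VIRTUAL_NODE",
                        pair = pair_training_config("XTB", "DFT_IMP", 1, 1))
  m2$params$backbone <- m$params$backbone
  rg2 <- solvachrom:::record_grad(m2, rec, ref)
  expect_gt(max(abs(rg2$grads$backbone$wc2)), 0)
})

test_that("infer_coarse never reads reference-fidelity coordinates", {
  fix <- tiny_fixture()
  m <- make_tiny_model("VIRTUAL_NODE")
  rec <- fix$dataset$records[[1]]
  p <- infer_coarse(rec, m, "XTB")
  expect_true(all(is.finite(p)))
  lg <- access_log(m)
  conf_reads <- lg[lg$type == "conformer", ]
  expect_true(all(conf_reads$detail == "XTB"))
  expect_false("DFT_IMP" %in% conf_reads$detail)
  # inference on the reference level itself is permitted
  p2 <- infer_coarse(rec, m, "DFT_IMP")
  expect_true(all(is.finite(p2)))
})

test_that("record gradients agree with finite differences end to end", {
  # The coordinate term differentiates through the refined coordinates with
  # the Kabsch transform held fixed at its optimum (stop-gradient through the
  # alignment), so the finite-difference oracle evaluates the loss against
  # the frozen aligned reference.
  fix <- tiny_fixture()
  rec <- fix$dataset$records[[9]]
  ref <- rec$conformers[["DFT_IMP"]]
  m <- make_tiny_model("VIRTUAL_NODE")
  m$params$backbone$wc2 <- with_seed_test(3, stats::rnorm(8, sd = 0.2))
  # nudge biases off zero so no ReLU pre-activation sits exactly at its kink
  m$params$solvent$bm <- with_seed_test(4, stats::rnorm(16, sd = 0.05))
  m$params$backbone$bc <- with_seed_test(5, stats::rnorm(8, sd = 0.05))
  rg <- solvachrom:::record_grad(m, rec, ref)
  fwd0 <- solvachrom:::forward_record(m, rec, log = FALSE)
  aligned_ref <- kabsch_rmsd(fwd0$refined, ref$coords)$aligned
  loss_of <- function(mm) {
    fwd <- solvachrom:::forward_record(mm, rec, log = FALSE)
    use <- which(rec$mask == 1L)
    lp <- mean(abs((fwd$predictions[use] - rec$targets[use]) / m$norm$sd[use]))
    lc <- mean(sqrt(rowSums((fwd$refined - aligned_ref)^2)))
    lp + lc
  }
  eps <- 1e-5
  probes <- list(c("backbone", "wc2"), c("backbone", "Wc_g"),
                 c("backbone", "virt_W"), c("proj", "Wp"),
                 c("solvent", "Wm"), c("head", "W1"))
  for (pr in probes) {
    x <- m$params[[pr[1]]][[pr[2]]]
    idx <- with_seed_test(sum(utf8ToInt(pr[2])), sample(length(x), 3))
    for (i in idx) {
      mp <- m; mp$params[[pr[1]]][[pr[2]]][i] <- x[i] + eps
      mm <- m; mm$params[[pr[1]]][[pr[2]]][i] <- x[i] - eps
      fd <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(rg$grads[[pr[1]]][[pr[2]]][i], fd, tolerance = 1e-4)
    }
  }
})
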