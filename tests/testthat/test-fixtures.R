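# Synthetic chromophore-solvent generator.

test_that("make_chromophore builds valid, deterministic, size-consistent molecules", {
  mk1 <- make_chromophore(1, seed = 3)
  expect_s3_class(mk1$molecule, "sc_molecule")
  expect_false(is.na(mk1$molecule$canonical_key))
  expect_true(check_topology_consistency(mk1$molecule, mk1$conformer))

  # bit-identical under the same seed
  mk1b <- make_chromophore(1, seed = 3)
  expect_identical(mk1$conformer$coords, mk1b$conformer$coords)

  # L = 3 vs L = 4: exactly one vinylene unit (2 carbons) difference
  m3 <- make_chromophore(3, seed = 5)
  m4 <- make_chromophore(4, seed = 5)
  expect_equal(length(m4$molecule$elements) - length(m3$molecule$elements), 2)
  expect_error(make_chromophore(0), "L must be >= 1")
})

test_that("ground_truth_targets evaluates the declared closed form", {
  spec <- fixture_spec()
  tg <- ground_truth_targets(4, 0.5, 0, spec)
  expect_equal(unname(tg["lambda_abs"]), 250 + 25 * 4 + 60 * 0.5 - 0)  # 380 nm
  expect_equal(unname(tg["lambda_ems"]), 380 + 20 + 30 * 0.5)
  expect_equal(unname(tg["plqy"]), 1 / (1 + exp(-2)))   # maximal at theta = 0

  # twisting reduces PLQY; polarity red-shifts absorption monotonically
  expect_lt(ground_truth_targets(4, 0.5, 60, spec)["plqy"], tg["plqy"])
  ps <- seq(0, 1, by = 0.1)
  las <- vapply(ps, function(p)
    ground_truth_targets(3, p, 30, spec)[["lambda_abs"]], 0)
  expect_true(all(diff(las) > 0))
})

test_that("perturb_conformer is seeded noise of the declared scale", {
  mk <- make_chromophore(3, seed = 4)
  expect_identical(perturb_conformer(mk$conformer, 0, "XTB", 1)$coords,
                   mk$conformer$coords)
  a <- perturb_conformer(mk$conformer, 0.2, "XTB", 9)
  b <- perturb_conformer(mk$conformer, 0.2, "XTB", 9)
  expect_identical(a$coords, b$coords)
  expect_identical(a$fidelity, "XTB")

  # Monte-Carlo: aligned RMSD approaches sigma*sqrt(3) from below
  sigma <- 0.1
  rmsds <- vapply(1:500, function(s)
    kabsch_rmsd(mk$conformer$coords,
                perturb_conformer(mk$conformer, sigma, "XTB", s)$coords)$rmsd,
    0)
  expect_lt(mean(rmsds), sigma * sqrt(3))         # alignment only reduces it
  expect_gt(mean(rmsds), 0.8 * sigma * sqrt(3))   # but not by much
})

test_that("make_fixture_dataset honors masks, noise and determinism", {
  spec0 <- fixture_spec(n_chromophores = 6, sigma_y = 0, sigma_logplqy = 0,
                        missing = c(lambda_abs = 0, lambda_ems = 0,
                                    log_plqy = 0), seed = 31)
  fix <- make_fixture_dataset(spec0)
  M <- do.call(rbind, lapply(fix$dataset$records, `[[`, "mask"))
  expect_true(all(M == 1L))
  # zero label noise: labels equal ground truth exactly
  tg <- do.call(rbind, lapply(fix$dataset$records, `[[`, "targets"))
  expect_equal(tg[, 1], fix$truth$lambda_abs, tolerance = 1e-12)
  expect_equal(tg[, 2], fix$truth$lambda_ems, tolerance = 1e-12)
  expect_equal(tg[, 3], log10(fix$truth$plqy), tolerance = 1e-12)

  # full determinism: same spec -> byte-identical export
  fix2 <- make_fixture_dataset(spec0)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  fixture_export(fix, d1); fixture_export(fix2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  # missing-label probabilities produce masked sentinels
  fixm <- tiny_fixture()
  Mm <- do.call(rbind, lapply(fixm$dataset$records, `[[`, "mask"))
  expect_gt(sum(Mm[, 3] == 0), 0)
  Tm <- do.call(rbind, lapply(fixm$dataset$records, `[[`, "targets"))
  expect_true(all(is.na(Tm[Mm == 0])))
})

test_that("generated datasets are curation-clean with diverse scaffolds", {
  fix <- tiny_fixture()
  cu <- curate(fix$dataset)
  expect_equal(cu$report$removed, 0)
  sk <- unique(solvachrom:::record_scaffolds(fix$dataset))
  expect_gte(length(sk), max(3, 5))
})

test_that("the noise ladder must be strictly decreasing", {
  expect_error(fixture_spec(sigma_geo = c(RDKIT = 0.1, XTB = 0.15,
                                          DFT_VAC = 0.05, DFT_IMP = 0.02)),
               "strictly decreasing")
  expect_error(fixture_spec(missing = c(lambda_abs = 1.2, lambda_ems = 0,
                                        log_plqy = 0)), "missing")
  expect_error(fixture_spec(L_range = c(0, 3)), "L_min")
})

test_that("regressing labels on descriptors recovers the generator coefficients", {
  fix <- cached("crit5_like", make_fixture_dataset(
    fixture_spec(n_chromophores = 250, solvents_per_chromophore = 8,
                 seed = 77)))
  tr <- fix$truth
  lab <- vapply(seq_len(nrow(tr)), function(i)
    fix$dataset$records[[i]]$targets[["lambda_abs"]], 0)
  keep <- !is.na(lab)
  fit <- stats::lm(lab[keep] ~ tr$L[keep] + tr$P[keep] +
                     I(1 - cos(tr$theta[keep] * pi / 180)))
  co <- summary(fit)$coefficients
  want <- c(250, 25, 60, -40)
  for (k in 1:4) {
    expect_lt(abs(co[k, "Estimate"] - want[k]), 3 * co[k, "Std. Error"] + 1e-9)
  }
})

test_that("solvent-equilibrated reference geometries carry solvent information", {
  # the DFT_IMP twist shrinks with polarity (20% of the gap to the preferred
  # twist), so high-polarity records of the same chromophore are more planar
  fix <- tiny_fixture()
  tr <- fix$truth
  one <- tr[tr$chromophore_key == tr$chromophore_key[1], ]
  expect_true(all(diff(one$theta[order(one$P)]) <= 1e-12))
})
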