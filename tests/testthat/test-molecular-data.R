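# Chemical data model, file I/O and curation checks.

test_that("parse_structure builds valence-consistent molecules with canonical keys", {
  m <- parse_structure("CCO")
  expect_s3_class(m, "sc_molecule")
  expect_length(m$elements, 3)
  expect_equal(nrow(m$bonds), 2)
  expect_equal(m$n_h, c(3L, 2L, 1L))

  # same structure, different spelling -> identical key
  expect_identical(parse_structure("c1ccccc1")$canonical_key,
                   parse_structure("C1=CC=CC=C1")$canonical_key)

  # pentavalent carbon is chemically invalid
  expect_error(parse_structure("C(C)(C)(C)(C)C"), "valence error at atom")
  # syntactically broken input names the offending token
  expect_error(parse_structure("C1CC"), "ring-bond digit")
  expect_error(parse_structure(""), "non-empty")
})

test_that("canonical keys are invariant to atom-order permutation", {
  spellings <- list(
    c("OC(=O)c1ccccc1", "c1ccccc1C(O)=O", "C(c1ccccc1)(=O)O"),
    c("CC(N)C(=O)O", "OC(=O)C(C)N", "NC(C)C(O)=O"),
    c("Clc1ccc(cc1)C#N", "N#Cc1ccc(Cl)cc1"))
  for (group in spellings) {
    keys <- vapply(group, function(s) parse_structure(s)$canonical_key, "")
    expect_length(unique(keys), 1)
  }
  # graph-built molecule: permute atom order, key unchanged
  mk <- make_chromophore(2, list(ring1 = "furan"), seed = 9)
  mol <- mk$molecule
  perm <- with_seed_test(3, sample(length(mol$elements)))
  inv <- match(seq_along(perm), perm)
  pm <- sc_molecule(mol$elements[perm], mol$charges[perm],
                    data.frame(i = inv[mol$bonds$i], j = inv[mol$bonds$j],
                               order = mol$bonds$order,
                               aromatic = mol$bonds$aromatic))
  expect_identical(solvachrom:::molecule_canonical_key(pm), mol$canonical_key)
})

test_that("conformer readers and writers round-trip both formats", {
  mk <- make_chromophore(2, seed = 3)
  cf <- mk$conformer
  for (fmt in c("sdf", "xyz")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_conformers(list(cf, cf), path)
    back <- read_conformers(path)
    expect_length(back, 2)
    digits <- if (fmt == "sdf") 4 else 6
    expect_equal(back[[1]]$coords, round(cf$coords, digits),
                 tolerance = 10^(-digits))
    expect_identical(back[[1]]$fidelity, cf$fidelity)
    expect_identical(back[[1]]$source_key, cf$source_key)
  }
})

test_that("malformed conformer files raise informative errors", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "key=k fidelity=XTB", "C 0 0 0", "C 1 0 0"), p)
  expect_error(read_conformers(p), "block 1")

  writeLines(c("1", "key=k fidelity=NOT_A_LEVEL", "C 0 0 0"), p)
  expect_error(read_conformers(p), "registered levels")

  writeLines(c("1", "key=k", "C 0 0 0"), p)
  expect_error(read_conformers(p), "fidelity")

  # single-block XYZ file parses to one conformer with 3 rows
  writeLines(c("3", "key=k fidelity=XTB", "C 0 0 0", "C 1.4 0 0", "O 2.1 1 0"), p)
  out <- read_conformers(p)
  expect_length(out, 1)
  expect_equal(nrow(out[[1]]$coords), 3)
})

test_that("perceive_connectivity follows the covalent-radius rule", {
  two_c <- function(d) sc_conformer(c("C", "C"),
                                    matrix(c(0, 0, 0, d, 0, 0), 2, 3,
                                           byrow = TRUE), "XTB")
  expect_equal(nrow(perceive_connectivity(two_c(1.54), 0.4)$bonds), 1)
  expect_equal(nrow(perceive_connectivity(two_c(3.0), 0.4)$bonds), 0)
  expect_error(perceive_connectivity(two_c(1.5), -1), "tolerance")
  unknown <- sc_conformer(c("C", "Xx"), matrix(0, 2, 3), "XTB")
  expect_error(perceive_connectivity(unknown, 0.4), "Xx")
})

test_that("perceived ethanol topology matches its 2D graph (distance oracle)", {
  # idealized ethanol heavy atoms from standard bond lengths/angles
  cc <- 1.54; co <- 1.43; ang <- 109.5 * pi / 180
  coords <- rbind(c(0, 0, 0),
                  c(cc, 0, 0),
                  c(cc + co * cos(pi - ang), co * sin(pi - ang), 0))
  cf <- sc_conformer(c("C", "C", "O"), coords, "DFT_VAC")
  # brute-force pairwise-distance oracle, independent of the implementation
  radii <- c(C = 0.76, C = 0.76, O = 0.66)
  oracle_bonds <- list()
  for (i in 1:2) for (j in (i + 1):3)
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <=
        radii[i] + radii[j] + 0.4)
      oracle_bonds[[length(oracle_bonds) + 1L]] <- c(i, j)
  perceived <- perceive_connectivity(cf, 0.4)
  expect_equal(nrow(perceived$bonds), length(oracle_bonds))
  expect_true(check_topology_consistency(parse_structure("CCO"), cf))
})

test_that("perceive_connectivity is invariant under rigid motions", {
  mk <- make_chromophore(3, list(ring2 = "pyridine"), seed = 5)
  base <- perceive_connectivity(mk$conformer, 0.4)
  for (q in 1:5) {
    mo <- with_seed_test(q, random_rigid_motion())
    moved <- sc_conformer(mk$conformer$elements,
                          apply_rigid(mk$conformer$coords, mo), "DFT_VAC")
    expect_identical(perceive_connectivity(moved, 0.4)$bonds, base$bonds)
  }
})

test_that("topology consistency detects broken bonds and reports edges", {
  mk <- make_chromophore(2, list(ring1 = "furan"), seed = 7)
  expect_true(check_topology_consistency(mk$molecule, mk$conformer))

  broken <- mk$conformer
  broken$coords[1, ] <- broken$coords[1, ] + c(10, 0, 0)
  res <- check_topology_consistency(mk$molecule, broken)
  expect_false(as.logical(res))
  expect_gt(length(attr(res, "report")$missing_edges), 0)

  wrong <- sc_conformer(rep("C", length(mk$molecule$elements)),
                        mk$conformer$coords, "XTB")
  expect_error(check_topology_consistency(mk$molecule, wrong),
               "element multiset mismatch")
})

test_that("cyclohexane chair geometry is consistent with C1CCCCC1", {
  # idealized chair coordinates (standard C-C 1.54 A)
  theta <- seq(0, 5) * pi / 3
  z0 <- 0.25                                  # chair puckering amplitude
  r_xy <- sqrt(1.536^2 - (2 * z0)^2) / (2 * sin(pi / 6))
  coords <- cbind(r_xy * cos(theta), r_xy * sin(theta), z0 * rep(c(1, -1), 3))
  # verify edge lengths with the brute-force distance oracle before asserting
  d_ring <- sqrt(rowSums((coords - coords[c(2:6, 1), ])^2))
  expect_true(all(d_ring > 1.2 & d_ring < 1.92))       # all bonded
  d_13 <- sqrt(sum((coords[1, ] - coords[3, ])^2))
  expect_gt(d_13, 1.92)                                 # no 1-3 bond
  cf <- sc_conformer(rep("C", 6), coords, "DFT_VAC")
  expect_true(check_topology_consistency(parse_structure("C1CCCCC1"), cf))
})

test_that("labels CSV loading masks empty cells and rejects bad rows", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("chromophore_smiles,solvent_smiles,lambda_abs_nm,lambda_ems_nm,plqy",
               "c1ccccc1C=O,O,320,,0.5",
               "CCO,O,,400,",
               "c1ccccc1,O,450,500,1.5",     # PLQY > 1
               "c1ccccc1,O,-10,,0.2",        # negative wavelength
               "C1CC,O,300,,0.1"), p)        # invalid SMILES
  ds <- read_labels_csv(p)
  expect_length(ds$records, 2)
  expect_equal(ds$records[[1]]$mask, c(lambda_abs = 1L, lambda_ems = 0L,
                                       log_plqy = 1L))
  expect_equal(ds$records[[1]]$targets[["log_plqy"]], log10(0.5))
  expect_true(is.na(ds$records[[2]]$targets[["lambda_abs"]]))
  rej <- attr(ds, "load_report")
  expect_equal(nrow(rej), 3)
  expect_true(any(grepl("PLQY", rej$reason)))
})

test_that("curation collapses duplicates, flags conflicts, and is idempotent", {
  fix <- tiny_fixture()
  ds <- fix$dataset

  # clean dataset: unchanged, all-zero report
  cu <- curate(ds)
  expect_equal(cu$report$removed, 0)
  expect_equal(cu$report$inspected, length(ds$records))
  expect_equal(sum(cu$report$per_rule), 0)
  expect_length(cu$dataset$records, length(ds$records))

  # exact duplicate -> one removed; conflicting labels -> flagged, kept
  r1 <- ds$records[[1]]
  conflict <- r1
  conflict$targets[1] <- r1$targets[1] + 70
  ds2 <- sc_dataset(c(ds$records, list(r1, conflict)))
  cu2 <- curate(ds2)
  expect_equal(unname(cu2$report$per_rule["duplicate"]), 1)
  expect_equal(cu2$report$removed, 1)
  expect_true(all(c("conflicting labels") %in% cu2$report$flagged$reason))
  expect_equal(cu2$report$removed + cu2$report$retained, cu2$report$inspected)

  # idempotence: curate(curate(D)) changes nothing more
  cu3 <- curate(cu2$dataset)
  expect_equal(cu3$report$removed, 0)
  expect_equal(unname(cu3$report$per_rule["duplicate"]), 0)
})

test_that("protonation variants sharing a neutral skeleton are flagged", {
  neutral <- parse_structure("CC(=O)O")
  anion <- parse_structure("CC(=O)[O-]")
  solv <- parse_structure("O")
  ds <- sc_dataset(list(
    labeled_pair(neutral, solv, c(400, NA, NA)),
    labeled_pair(anion, solv, c(410, NA, NA))))
  cu <- curate(ds, curation_rules(check_topology = FALSE))
  expect_gt(unname(cu$report$per_rule["protonation_variant"]), 0)
  expect_equal(cu$report$removed, 0)   # flagged, never dropped
})
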