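# Seeded generator of toy chromophore-solvent datasets with known ground
# truth: donor/acceptor-substituted diaryl polyenes (two terminal rings
# joined by a conjugated chain), a closed-form solvatochromic target model,
# a multi-fidelity conformer noise ladder and configurable missing-label
# patterns.  This is a statistical surrogate for verification, NOT a
# physical model of photophysics.

.ring_templates <- list(
  benzene = list(elements = rep("C", 6),
                 orders = c(2L, 1L, 2L, 1L, 2L, 1L), attach = 1L, sub = 4L),
  pyridine = list(elements = c("C", "C", "C", "N", "C", "C"),
                  orders = c(2L, 1L, 2L, 1L, 2L, 1L), attach = 1L, sub = 3L),
  thiophene = list(elements = c("S", "C", "C", "C", "C"),
                   orders = c(1L, 2L, 1L, 2L, 1L), attach = 3L, sub = 5L),
  furan = list(elements = c("O", "C", "C", "C", "C"),
               orders = c(1L, 2L, 1L, 2L, 1L), attach = 3L, sub = 5L)
)

#' Default solvent panel
#'
#' Nine common spectroscopy solvents with normalized empirical polarity
#' values (Reichardt-style scale, 0 = n-hexane, 1 = water).
#' @return data.frame with `name`, `smiles`, `polarity`.
#' @export
default_solvents <- function() {
  data.frame(
    name = c("hexane", "toluene", "thf", "dcm", "acetone", "dmso",
             "acetonitrile", "methanol", "water"),
    smiles = c("CCCCCC", "Cc1ccccc1", "C1CCOC1", "ClCCl", "CC(C)=O",
               "CS(C)=O", "CC#N", "CO", "O"),
    polarity = c(0.009, 0.099, 0.207, 0.309, 0.355, 0.444, 0.460, 0.762, 1.0),
    stringsAsFactors = FALSE)
}

#' Synthetic fixture specification
#'
#' Defines the study conditions of the generated benchmark: chromophore
#' family, solvent panel, target-model coefficients, label noise, the
#' geometry-fidelity noise ladder and missing-label probabilities.
#'
#' The noiseless target model is
#' `lambda_abs = lambda0 + a*L + b*P - c*(1 - cos theta)` (nm),
#' `lambda_ems = lambda_abs + s0 + s1*P` (nm),
#' `PLQY = 1 / (1 + exp(-(k0 - k1*(1 - cos theta))))`,
#' where `L` is the conjugation length (number of vinylene units), `P` the
#' solvent polarity and `theta` the inter-ring twist of the reference
#' geometry.
#'
#' The implicit-solvent geometry (`DFT_IMP`, the reference level) is solvent-
#' equilibrated: the twist relaxes toward the solvent-preferred value
#' `theta*(1 - P)` by `imp_shift` of the gap, and the chain bond-length
#' alternation shrinks with polarity (`delta = delta0*(1 - bla_beta*P)`),
#' so high-fidelity geometries genuinely carry solvent information.  Vacuum
#' levels use the vacuum twist and BLA; the force-field level (`RDKIT`) has
#' no BLA at all.
#'
#' @param n_chromophores number of distinct chromophores.
#' @param L_range integer range of conjugation lengths `c(L_min, L_max)`.
#' @param donor_prob,acceptor_prob,methyl_prob per-ring probability of a
#'   terminal donor (amine) / acceptor (fluoro) / methyl substituent (the
#'   remainder is unsubstituted).
#' @param solvents solvent panel (see [default_solvents()]).
#' @param solvents_per_chromophore how many panel solvents each chromophore
#'   is paired with (`NULL` = all).
#' @param lambda0,a,b,cc,s0,s1,k0,k1 target-model coefficients (nm where
#'   dimensioned).
#' @param sigma_y wavelength label noise sd (nm).
#' @param sigma_logplqy log10-PLQY label noise sd.
#' @param sigma_geo named geometry noise ladder (Angstrom per coordinate),
#'   strictly decreasing along RDKIT, XTB, DFT_VAC, DFT_IMP.
#' @param missing named per-target missing-label probabilities.
#' @param theta_range inter-ring twist range in degrees.
#' @param delta0 vacuum bond-length alternation (Angstrom).
#' @param bla_beta fractional BLA reduction at P = 1.
#' @param imp_shift fraction of the twist gap relaxed in implicit solvent.
#' @param seed integer master seed; (spec, seed) fully determine the dataset.
#' @return a `FixtureSpec` list (validated).
#' @export
fixture_spec <- function(n_chromophores = 250L, L_range = c(2L, 5L),
                         donor_prob = 0.2, acceptor_prob = 0.2,
                         methyl_prob = 0.15,
                         solvents = default_solvents(),
                         solvents_per_chromophore = NULL,
                         lambda0 = 250, a = 25, b = 60, cc = 40,
                         s0 = 20, s1 = 30, k0 = 2, k1 = 6,
                         sigma_y = 5, sigma_logplqy = 0.05,
                         sigma_geo = c(RDKIT = 0.30, XTB = 0.15,
                                       DFT_VAC = 0.05, DFT_IMP = 0.02),
                         missing = c(lambda_abs = 0.05, lambda_ems = 0.35,
                                     log_plqy = 0.50),
                         theta_range = c(0, 90), delta0 = 0.10,
                         bla_beta = 0.6, imp_shift = 0.2, seed = 1L) {
  if (L_range[1] < 1) stop_sc("L_min must be >= 1")
  if (sigma_y < 0 || sigma_logplqy < 0 || any(sigma_geo < 0))
    stop_sc("noise levels must be >= 0")
  if (any(missing < 0 | missing > 1)) stop_sc("missing probabilities must be in [0,1]")
  ladder <- sigma_geo[c("RDKIT", "XTB", "DFT_VAC", "DFT_IMP")]
  if (anyNA(ladder) || any(diff(ladder) >= 0))
    stop_sc("sigma_geo must be strictly decreasing along RDKIT, XTB, DFT_VAC, DFT_IMP")
  if (donor_prob + acceptor_prob + methyl_prob > 1)
    stop_sc("substituent probabilities must sum to at most 1")
  spec <- list(n_chromophores = as.integer(n_chromophores),
               L_range = as.integer(L_range), donor_prob = donor_prob,
               acceptor_prob = acceptor_prob, methyl_prob = methyl_prob,
               solvents = solvents,
               solvents_per_chromophore = solvents_per_chromophore,
               lambda0 = lambda0, a = a, b = b, cc = cc, s0 = s0, s1 = s1,
               k0 = k0, k1 = k1, sigma_y = sigma_y,
               sigma_logplqy = sigma_logplqy, sigma_geo = sigma_geo,
               missing = missing, theta_range = theta_range, delta0 = delta0,
               bla_beta = bla_beta, imp_shift = imp_shift,
               seed = as.integer(seed))
  class(spec) <- "FixtureSpec"
  spec
}

#' Noiseless targets of the surrogate solvatochromic model
#'
#' @param L conjugation length (vinylene units, >= 1).
#' @param P solvent polarity in `[0, 1]`.
#' @param theta inter-ring twist in degrees.
#' @param spec a [fixture_spec()] supplying the coefficients.
#' @return named numeric: `lambda_abs` (nm), `lambda_ems` (nm), `plqy`
#'   (fraction in (0, 1]).
#' @export
ground_truth_targets <- function(L, P, theta, spec = fixture_spec()) {
  tw <- 1 - cos(theta * pi / 180)
  lambda_abs <- spec$lambda0 + spec$a * L + spec$b * P - spec$cc * tw
  lambda_ems <- lambda_abs + spec$s0 + spec$s1 * P
  plqy <- 1 / (1 + exp(-(spec$k0 - spec$k1 * tw)))
  c(lambda_abs = lambda_abs, lambda_ems = lambda_ems, plqy = plqy)
}

# Rodrigues rotation of points about an axis through `origin` with unit
# direction `u` by `theta` degrees.
rotate_about_axis <- function(pts, origin, u, theta_deg) {
  th <- theta_deg * pi / 180
  u <- u / sqrt(sum(u^2))
  Kx <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  R <- diag(3) + sin(th) * Kx + (1 - cos(th)) * (Kx %*% Kx)
  sweep(sweep(pts, 2, origin) %*% t(R), 2, origin, `+`)
}

.substituent_atoms <- c(donor = "N", acceptor = "F", methyl = "C")

# Deterministic idealized geometry + graph of a diaryl polyene.
# Returns list(elements, charges, bonds, coords, meta).
chromophore_build <- function(L, ring1 = "benzene", ring2 = "benzene",
                              sub1 = "none", sub2 = "none",
                              theta = 0, delta = 0.10) {
  t1 <- .ring_templates[[ring1]]; t2 <- .ring_templates[[ring2]]
  if (is.null(t1) || is.null(t2))
    stop_sc("unknown ring template (choose from %s)",
            paste(names(.ring_templates), collapse = ", "))
  attach_len <- 1.46
  s_len <- 1.40 + delta / 2; d_len <- 1.40 - delta / 2
  m <- 2L * L
  ang <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180))

  # polyene chain in the xy-plane, standard 120-degree zig-zag
  chain <- matrix(0, m, 2)
  for (k in seq_len(m - 1)) {
    len <- if (k %% 2 == 1) d_len else s_len
    chain[k + 1, ] <- chain[k, ] + len * ang(ifelse(k %% 2 == 1, 30, -30))
  }
  place_ring <- function(tmpl, attach_pos, away_dir) {
    mr <- length(tmpl$elements)
    # 5-rings get a longer side: heteroatom bonds (S-C 1.71 A) stretch the
    # ring, and a regular 1.39 A pentagon puts 1-3 contacts at the bond-
    # perception cutoff
    side <- if (mr == 5) 1.50 else 1.39
    r <- side / (2 * sin(pi / mr))
    center <- attach_pos + r * away_dir
    psi <- atan2(attach_pos[2] - center[2], attach_pos[1] - center[1])
    beta <- 2 * pi * (seq_len(mr) - tmpl$attach) / mr
    cbind(center[1] + r * cos(psi + beta), center[2] + r * sin(psi + beta))
  }
  a1 <- chain[1, ] - attach_len * ang(-30)
  ring1_xy <- place_ring(t1, a1, (a1 - chain[1, ]) / attach_len)
  phi2 <- ifelse(m %% 2 == 1, 30, -30)
  a2 <- chain[m, ] + attach_len * ang(phi2)
  ring2_xy <- place_ring(t2, a2, ang(phi2))

  ring_center <- function(xy) colMeans(xy)
  sub_pos <- function(xy, tmpl, len = 1.40) {
    ctr <- ring_center(xy)
    v <- xy[tmpl$sub, ] - ctr
    xy[tmpl$sub, ] + len * v / sqrt(sum(v^2))
  }

  n1 <- length(t1$elements); n2 <- length(t2$elements)
  elements <- c(t1$elements, rep("C", m), t2$elements)
  xy <- rbind(ring1_xy, chain, ring2_xy)
  cyc_bonds <- function(tmpl, off) {
    mr <- length(tmpl$elements)
    data.frame(i = off + seq_len(mr), j = off + c(seq_len(mr - 1) + 1L, 1L),
               order = tmpl$orders, aromatic = FALSE)
  }
  bonds <- rbind(
    cyc_bonds(t1, 0L),
    data.frame(i = t1$attach, j = n1 + 1L, order = 1L, aromatic = FALSE),
    if (m > 1) data.frame(i = n1 + seq_len(m - 1), j = n1 + seq_len(m - 1) + 1L,
                          order = rep(c(2L, 1L), length.out = m - 1),
                          aromatic = FALSE),
    data.frame(i = n1 + m, j = n1 + m + t2$attach, order = 1L, aromatic = FALSE),
    cyc_bonds(t2, n1 + m))
  sub2_idx <- integer(0)
  if (sub1 != "none") {
    elements <- c(elements, .substituent_atoms[[sub1]])
    xy <- rbind(xy, sub_pos(ring1_xy, t1, len = if (sub1 == "acceptor") 1.35 else 1.42))
    bonds <- rbind(bonds, data.frame(i = t1$sub, j = length(elements),
                                     order = 1L, aromatic = FALSE))
  }
  if (sub2 != "none") {
    elements <- c(elements, .substituent_atoms[[sub2]])
    xy <- rbind(xy, sub_pos(ring2_xy, t2, len = if (sub2 == "acceptor") 1.35 else 1.42))
    sub2_idx <- length(elements)
    bonds <- rbind(bonds, data.frame(i = n1 + m + t2$sub, j = length(elements),
                                     order = 1L, aromatic = FALSE))
  }
  coords <- cbind(xy, 0)
  # twist ring 2 (and its substituent) about the terminal single bond
  ring2_idx <- c(n1 + m + seq_len(n2), sub2_idx)
  axis_from <- coords[n1 + m, ]
  axis_to <- coords[n1 + m + t2$attach, ]
  coords[ring2_idx, ] <- rotate_about_axis(coords[ring2_idx, , drop = FALSE],
                                           axis_from, axis_to - axis_from,
                                           theta)
  list(elements = elements, charges = integer(length(elements)),
       bonds = bonds, coords = coords,
       meta = list(L = L, ring1 = ring1, ring2 = ring2, sub1 = sub1,
                   sub2 = sub2, theta = theta, delta = delta))
}

#' Build a toy conjugated chromophore with idealized geometry
#'
#' Constructs a diaryl polyene of conjugation length `L` (two terminal rings
#' joined by `L` vinylene units), with deterministic idealized coordinates
#' (standard bond lengths, planar backbone, seeded inter-ring twist).  The
#' geometry always passes [check_topology_consistency()] against its own
#' graph.
#'
#' @param L conjugation length (>= 1).
#' @param substituents list with optional `ring1`, `ring2` (one of
#'   "benzene", "pyridine", "thiophene", "furan") and terminal substituents
#'   `sub1`, `sub2` (one of "none", "donor" = amine, "acceptor" = fluoro,
#'   "methyl"); the logical shorthands `donor`, `acceptor` set `sub1`/`sub2`.
#' @param seed integer seed (draws the twist angle).
#' @param theta_range twist range in degrees.
#' @return list with `molecule` ([sc_molecule()] with canonical key) and
#'   `conformer` (the reference geometry, fidelity `DFT_VAC`).
#' @export
make_chromophore <- function(L, substituents = list(), seed = 1L,
                             theta_range = c(0, 90)) {
  if (L < 1) stop_sc("L must be >= 1")
  sub <- utils::modifyList(list(ring1 = "benzene", ring2 = "benzene",
                                donor = FALSE, acceptor = FALSE,
                                sub1 = NULL, sub2 = NULL), substituents)
  sub1 <- sub$sub1 %||% if (isTRUE(sub$donor)) "donor" else "none"
  sub2 <- sub$sub2 %||% if (isTRUE(sub$acceptor)) "acceptor" else "none"
  theta <- with_seed(seed, stats::runif(1, theta_range[1], theta_range[2]))
  built <- chromophore_build(L, sub$ring1, sub$ring2, sub1, sub2,
                             theta = theta, delta = 0.10)
  mol <- sc_molecule(built$elements, built$charges, built$bonds)
  mol$canonical_key <- molecule_canonical_key(mol)
  cf <- sc_conformer(built$elements, built$coords, "DFT_VAC",
                     source_key = mol$canonical_key)
  attr(cf, "meta") <- built$meta
  list(molecule = mol, conformer = cf)
}

#' Add seeded Gaussian geometry noise to a conformer
#'
#' Independent zero-mean Gaussian noise (sd `sigma_geo` per coordinate) is
#' added to every atom; the fidelity tag is replaced.
#'
#' @param conformer an [sc_conformer()].
#' @param sigma_geo noise sd in Angstrom (>= 0).
#' @param fidelity new fidelity tag.
#' @param seed integer seed (same seed, same output).
#' @return a perturbed [sc_conformer()].
#' @export
perturb_conformer <- function(conformer, sigma_geo, fidelity, seed = 1L) {
  if (sigma_geo < 0) stop_sc("sigma_geo must be >= 0")
  n <- nrow(conformer$coords)
  noise <- with_seed(seed, matrix(stats::rnorm(n * 3, sd = sigma_geo), n, 3))
  sc_conformer(conformer$elements, conformer$coords + noise, fidelity,
               source_key = conformer$source_key)
}

#' Generate a synthetic chromophore-solvent dataset with ground truth
#'
#' Samples chromophores (ring variants, conjugation length, substituents,
#' twist) and solvent pairings, computes noiseless targets from the surrogate
#' model, adds label noise, applies per-target Bernoulli missing-label masks,
#' and attaches the full conformer fidelity ladder.  The reference level is
#' the lowest-noise tag (`DFT_IMP`), whose geometry is solvent-equilibrated
#' and stored per record.  The output is fully determined by `(spec,
#' spec$seed)` and passes [curate()] with zero removals.
#'
#' @param spec a [fixture_spec()].
#' @return list with `dataset` (an [sc_dataset()]) and `truth` (data.frame of
#'   per-record descriptors `L`, `P`, `theta` and noiseless targets).
#' @export
make_fixture_dataset <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "FixtureSpec"))
  rings <- names(.ring_templates)
  solv_tab <- spec$solvents
  solv_mols <- lapply(solv_tab$smiles, parse_structure)
  records <- list()
  truth <- list()
  seen_keys <- character(0)
  for (ci in seq_len(spec$n_chromophores)) {
    cs <- derive_seed(spec$seed, paste0("chrom", ci))
    # redraw on structural collision so chromophores are distinct (duplicate
    # keys would create same-pair records with conflicting labels)
    subs <- c("none", "donor", "acceptor", "methyl")
    sub_prob <- c(1 - spec$donor_prob - spec$acceptor_prob - spec$methyl_prob,
                  spec$donor_prob, spec$acceptor_prob, spec$methyl_prob)
    for (attempt in 1:120) {
      # after 40 distribution-faithful draws, fall back to flat substituent
      # sampling so the tail of the structural family remains reachable
      pr <- if (attempt <= 40) sub_prob else rep(0.25, 4)
      draw <- with_seed(derive_seed(cs, paste0("draw", attempt)), list(
        ring1 = sample(rings, 1), ring2 = sample(rings, 1),
        L = sample(seq(spec$L_range[1], spec$L_range[2]), 1),
        sub1 = sample(subs, 1, prob = pr),
        sub2 = sample(subs, 1, prob = pr),
        theta = stats::runif(1, spec$theta_range[1], spec$theta_range[2])))
      built_vac <- chromophore_build(draw$L, draw$ring1, draw$ring2, draw$sub1,
                                     draw$sub2, theta = draw$theta,
                                     delta = spec$delta0)
      mol <- sc_molecule(built_vac$elements, built_vac$charges, built_vac$bonds)
      mol$canonical_key <- molecule_canonical_key(mol)
      if (!mol$canonical_key %in% seen_keys) break
    }
    if (mol$canonical_key %in% seen_keys) next   # family exhausted: skip
    seen_keys <- c(seen_keys, mol$canonical_key)
    built_ff <- chromophore_build(draw$L, draw$ring1, draw$ring2, draw$sub1,
                                  draw$sub2, theta = draw$theta, delta = 0)
    base <- list(
      RDKIT = sc_conformer(built_ff$elements, built_ff$coords, "RDKIT",
                           mol$canonical_key),
      XTB = sc_conformer(built_vac$elements, built_vac$coords, "XTB",
                         mol$canonical_key),
      DFT_VAC = sc_conformer(built_vac$elements, built_vac$coords, "DFT_VAC",
                             mol$canonical_key))
    shared <- lapply(names(base), function(tag)
      perturb_conformer(base[[tag]], spec$sigma_geo[[tag]], tag,
                        seed = derive_seed(cs, tag)))
    names(shared) <- names(base)
    solv_idx <- if (is.null(spec$solvents_per_chromophore)) seq_len(nrow(solv_tab))
      else with_seed(derive_seed(cs, "solv"),
                     sample(seq_len(nrow(solv_tab)),
                            spec$solvents_per_chromophore))
    for (si in solv_idx) {
      P <- solv_tab$polarity[si]
      theta_pref <- draw$theta * (1 - P)
      theta_imp <- draw$theta + spec$imp_shift * (theta_pref - draw$theta)
      delta_imp <- spec$delta0 * (1 - spec$bla_beta * P)
      built_imp <- chromophore_build(draw$L, draw$ring1, draw$ring2,
                                     draw$sub1, draw$sub2,
                                     theta = theta_imp, delta = delta_imp)
      cf_imp <- perturb_conformer(
        sc_conformer(built_imp$elements, built_imp$coords, "DFT_IMP",
                     mol$canonical_key),
        spec$sigma_geo[["DFT_IMP"]], "DFT_IMP",
        seed = derive_seed(cs, paste0("imp", si)))
      tg <- ground_truth_targets(draw$L, P, theta_imp, spec)
      noise <- with_seed(derive_seed(cs, paste0("lab", si)),
                         c(stats::rnorm(2, sd = spec$sigma_y),
                           stats::rnorm(1, sd = spec$sigma_logplqy)))
      labels <- c(tg[["lambda_abs"]] + noise[1],
                  tg[["lambda_ems"]] + noise[2],
                  min(log10(tg[["plqy"]]) + noise[3], 0))  # PLQY stays <= 1
      mask <- with_seed(derive_seed(cs, paste0("mask", si)),
                        as.integer(stats::runif(3) >= spec$missing))
      labels[mask == 0L] <- NA_real_
      records[[length(records) + 1L]] <- labeled_pair(
        mol, solv_mols[[si]], labels, mask,
        conformers = c(shared, list(DFT_IMP = cf_imp)),
        provenance = sprintf("synthetic chrom %d / %s", ci, solv_tab$name[si]))
      truth[[length(truth) + 1L]] <- data.frame(
        record = length(records), chromophore_key = mol$canonical_key,
        solvent = solv_tab$name[si], L = draw$L, P = P, theta = theta_imp,
        ring1 = draw$ring1, ring2 = draw$ring2, sub1 = draw$sub1,
        sub2 = draw$sub2,
        lambda_abs = tg[["lambda_abs"]], lambda_ems = tg[["lambda_ems"]],
        plqy = tg[["plqy"]])
    }
  }
  list(dataset = sc_dataset(records), truth = do.call(rbind, truth))
}

#' Export a fixture dataset as standard input files
#'
#' Writes the labels CSV, per-fidelity conformer SDF files and a ground-truth
#' sidecar JSON, so generated fixtures are indistinguishable from real inputs
#' to the rest of the pipeline.  Implicit-solvent conformers are per record
#' and carry a `RECORD_INDEX` property.
#'
#' @param fixture output of [make_fixture_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
fixture_export <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- fixture$dataset
  tg <- dataset_targets(ds)
  df <- data.frame(chromophore_smiles = chromophore_keys(ds),
                   solvent_smiles = solvent_keys(ds),
                   lambda_abs_nm = tg[, 1], lambda_ems_nm = tg[, 2],
                   plqy = 10^tg[, 3])
  utils::write.csv(df, file.path(dir, "labels.csv"), row.names = FALSE,
                   na = "")
  for (tag in c("RDKIT", "XTB", "DFT_VAC")) {
    seen <- character(0)
    cfs <- list()
    for (rec in ds$records) {
      cf <- rec$conformers[[tag]]
      if (is.null(cf) || cf$source_key %in% seen) next
      seen <- c(seen, cf$source_key)
      cfs[[length(cfs) + 1L]] <- cf
    }
    if (length(cfs))
      write_conformers(cfs, file.path(dir, sprintf("conformers_%s.sdf", tag)))
  }
  imp <- lapply(ds$records, function(r) r$conformers[["DFT_IMP"]])
  imp <- imp[!vapply(imp, is.null, TRUE)]
  if (length(imp)) {
    txt <- vapply(seq_along(imp), function(q) {
      cf <- imp[[q]]
      mol <- sc_molecule(cf$elements, validate = FALSE)
      paste0(write_molblock(mol, cf$coords, title = cf$source_key),
             sprintf("\n> <FIDELITY>\n%s\n\n> <CANONICAL_KEY>\n%s\n\n> <RECORD_INDEX>\n%d\n\n$$$$",
                     cf$fidelity, cf$source_key, q))
    }, "")
    writeLines(txt, file.path(dir, "conformers_DFT_IMP.sdf"))
  }
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
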