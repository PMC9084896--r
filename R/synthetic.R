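# Synthetic multiconformer apo/holo pair generator with fully known planted
# heterogeneity. Chains are idealized poly-Ser segments (with a few Val/Leu
# decorations) laid out along x with 3.8 A Calpha spacing; side chains are
# built with ideal bond lengths and tetrahedral angles so that the realized
# chi1 equals the requested value exactly. Binding-site rigidification and
# distal flexibilization are planted through occupancy shifts of
# two-conformer residues, which leaves coordinates (and therefore distances
# and solvent accessibility) identical between the apo and holo structures.

TETRA_DEG <- acos(-1 / 3) * 180 / pi  # ideal tetrahedral angle, 109.4712 deg
CA_SPACING <- 3.8
BOND_CA_CB <- 1.53
BOND_CB_CG <- 1.53
BOND_CB_OG <- 1.42
BOND_CH <- 1.09

# sin^2 of the angle between two chi1 bond vectors 120 deg apart in chi
# (cos Theta = 1/9 + 8/9 cos dchi); for dchi = 120 or 240, sin^2 = 8/9
chi1_sin2 <- function(dchi) {
  ct <- 1 / 9 + 8 / 9 * cos(dchi * pi / 180)
  1 - ct^2
}

# analytic two-site angular order parameter for a chi1 jump
true_s2_ang_two_site <- function(q1, q2, dchi) {
  1 - 3 * q1 * q2 * chi1_sin2(dchi)
}

# Calpha trace: 3.8 A spacing along x with a small alternating y offset
# (a strictly collinear trace would make rigid superposition ill-posed)
chain_ca <- function(index) {
  c((index - 1) * CA_SPACING, 0.25 * (-1)^index, 0)
}

backbone_coords <- function(index) {
  ca <- chain_ca(index)
  list(N = ca + c(-0.72, -1.25, 0), CA = ca, C = ca + c(0.76, -1.26, 0),
       O = ca + c(0.76, -2.49, 0), H = ca + c(-1.308, -2.034, 0),
       CB = ca + c(0, 0.604, 1.406))
}

# side-chain atom coordinates for one conformer (named list)
sidechain_coords <- function(aa, bb, chi1, chi2 = 60) {
  g <- function(len, tor) place_atom(bb$N, bb$CA, bb$CB, len, TETRA_DEG, tor)
  switch(aa,
    SER = {
      og <- g(BOND_CB_OG, chi1)
      list(OG = og, HB2 = g(BOND_CH, chi1 + 120), HB3 = g(BOND_CH, chi1 + 240),
           HG = place_atom(bb$CA, bb$CB, og, 0.96, TETRA_DEG, 180))
    },
    VAL = list(CG1 = g(BOND_CB_CG, chi1), CG2 = g(BOND_CB_CG, chi1 + 240),
               HB = g(BOND_CH, chi1 + 120)),
    LEU = {
      cg <- g(BOND_CB_CG, chi1)
      list(CG = cg,
           HB2 = g(BOND_CH, chi1 + 120), HB3 = g(BOND_CH, chi1 + 240),
           CD1 = place_atom(bb$CA, bb$CB, cg, BOND_CB_CG, TETRA_DEG, chi2),
           CD2 = place_atom(bb$CA, bb$CB, cg, BOND_CB_CG, TETRA_DEG,
                            chi2 + 240),
           HG = place_atom(bb$CA, bb$CB, cg, BOND_CH, TETRA_DEG, chi2 + 120))
    },
    stop("unsupported synthetic residue type: ", aa))
}

#' Residue specification for the synthetic builder
#'
#' @param aa "SER", "VAL" or "LEU".
#' @param chi1 chi1 angle (degrees, [0, 360)) per conformer.
#' @param occupancies Conformer occupancies (sum <= 1).
#' @param b_sidechain Side-chain B-factor per conformer, Angstrom^2.
#' @param b_calpha Backbone/Calpha B-factor, Angstrom^2.
#' @param chi2 chi2 per conformer (Leu only).
#' @return List of class `residue_spec`.
#' @export
residue_spec <- function(aa, chi1, occupancies = 1, b_sidechain = 14,
                         b_calpha = 12, chi2 = 60) {
  n <- length(chi1)
  occupancies <- rep_len(occupancies, n)
  if (sum(occupancies) > 1 + 1e-9) stop("occupancies sum above 1")
  if (any(chi1 < 0 | chi1 >= 360)) stop("chi1 must lie in [0, 360)")
  structure(list(aa = toupper(aa), chi1 = chi1, occupancies = occupancies,
                 b_sidechain = rep_len(b_sidechain, n), b_calpha = b_calpha,
                 chi2 = rep_len(chi2, n)),
            class = "residue_spec")
}

#' Build one multiconformer residue with ideal geometry
#'
#' Constructs backbone and side-chain coordinates at chain position `index`
#' (Calpha at x = 3.8 (index - 1)) so that the realized chi1 dihedral of
#' each conformer equals the specified angle to numerical precision.
#' Backbone atoms are shared (blank altloc); side-chain atoms carry altloc
#' labels A, B, ... when there is more than one conformer. Hydrogens are
#' placed explicitly on Cbeta (and the Ser hydroxyl and backbone amide).
#'
#' @param spec A [residue_spec()].
#' @param index Integer chain position (1-based).
#' @param chain Chain identifier.
#' @return A [multiconf_residue()].
#' @export
build_residue <- function(spec, index, chain = "A") {
  bb <- backbone_coords(index)
  n <- length(spec$chi1)
  labels <- if (n == 1) "" else LETTERS[seq_len(n)]
  bb_names <- c("N", "CA", "C", "O", "H")
  cfs <- lapply(seq_len(n), function(i) {
    sc <- sidechain_coords(spec$aa, bb, spec$chi1[i], spec$chi2[i])
    sc_names <- c("CB", names(sc))
    sc_xyz <- rbind(bb$CB, do.call(rbind, sc))
    at_bb <- atom_table(name = bb_names,
                        element = substr(bb_names, 1, 1),
                        x = vapply(bb[bb_names], `[[`, 0, 1),
                        y = vapply(bb[bb_names], `[[`, 0, 2),
                        z = vapply(bb[bb_names], `[[`, 0, 3),
                        occupancy = 1, b = spec$b_calpha, altloc = "")
    at_sc <- atom_table(name = sc_names,
                        element = substr(sc_names, 1, 1),
                        x = sc_xyz[, 1], y = sc_xyz[, 2], z = sc_xyz[, 3],
                        occupancy = spec$occupancies[i],
                        b = spec$b_sidechain[i], altloc = labels[i])
    conformer(labels[i], spec$occupancies[i], rbind(at_bb, at_sc))
  })
  multiconf_residue(chain = chain, seqnum = index, aa = spec$aa,
                    conformers = cfs)
}

# rigid 10-carbon ring ligand (HETATM group "LIG"), ring in the y-z plane
build_ligand_ring <- function(center, occupancy = 1, b = 18,
                              seqnum = 501, chain = "A") {
  rad <- 1.52 / (2 * sin(pi / 10))
  th <- 2 * pi * (seq_len(10) - 1) / 10
  at <- atom_table(name = paste0("C", seq_len(10)), element = "C",
                   x = center[1], y = center[2] + rad * cos(th),
                   z = center[3] + rad * sin(th),
                   occupancy = occupancy, b = b, is_hetero = TRUE)
  multiconf_residue(chain = chain, seqnum = seqnum, aa = "LIG",
                    conformers = list(conformer("", occupancy, at)),
                    hetero = TRUE)
}

# occluding neighbour shells (HETATM "SHL" groups of 8 carbons) burying the
# side chains of the given chain positions
build_burial_shells <- function(indices, chain = "A", radius = 3.35,
                                n_points = 32, seq_base = 600) {
  out <- list()
  for (i in indices) {
    center <- chain_ca(i) + c(0, 0.794, 1.850)  # mid side chain
    pts <- sweep(sphere_points(n_points) * radius, 2, center, "+")
    chunks <- split(seq_len(n_points), ceiling(seq_len(n_points) / 8))
    for (k in seq_along(chunks)) {
      rows <- chunks[[k]]
      at <- atom_table(name = paste0("C", seq_along(rows)), element = "C",
                       x = pts[rows, 1], y = pts[rows, 2], z = pts[rows, 3],
                       occupancy = 1, b = 20, is_hetero = TRUE)
      out[[length(out) + 1L]] <- multiconf_residue(
        chain = chain, seqnum = seq_base + length(out),
        aa = "SHL", conformers = list(conformer("", 1, at)), hetero = TRUE)
    }
  }
  out
}

# occupancy of the major conformer realizing a target two-site s2_ang for a
# 120-degree chi1 jump; errors when the target is out of reach
solve_major_occupancy <- function(s2_target) {
  rhs <- (1 - s2_target) * 3 / 8
  if (any(rhs < 5e-4 | rhs > 0.25 + 1e-12))
    stop(sprintf("infeasible planted effect: target s2_ang %.4f outside the
two-conformer range", s2_target))
  (1 + sqrt(pmax(1 - 4 * rhs, 0))) / 2
}

#' Cohort specification for the synthetic generator
#'
#' Defines the study conditions of a synthetic apo/holo cohort: the chain
#' layout, the planted binding-site rigidification (median and spread of the
#' per-pair mean holo-minus-apo order-parameter change), the generative
#' residual slope linking distal buried residues to the binding-site change,
#' and the B-factor/resolution regime.
#'
#' @param n_pairs Number of apo/holo pairs.
#' @param n_residues Residues per chain (>= 26).
#' @param binding_site Chain positions designated as the binding site.
#' @param flip_residue Binding-site position whose single conformer changes
#'   rotamer in non-preorganized pairs.
#' @param category_residue Position (outside binding site and distant
#'   regions) carrying the planted rotamer-change category example.
#' @param buried_residues Positions wrapped in occluding shells (buried,
#'   distant).
#' @param delta_bs_median,delta_bs_sd Median and SD of the per-pair mean
#'   binding-site delta s2 (holo - apo).
#' @param residual_slope Generative slope of the residual (distant-buried
#'   minus binding-site delta) on the binding-site delta.
#' @param residual_sd SD of the residual noise.
#' @param resolution_range Uniform range of pair resolutions, Angstrom.
#' @param b_sidechain Side-chain B-factor, Angstrom^2.
#' @param norm_factor Target Calpha-B normalization factor
#'   (b_calpha = 10 * norm_factor * resolution).
#' @param q_flex Apo major-conformer occupancy of flexible residues.
#' @param preorganized_fraction Fraction of pairs whose binding-site
#'   residues all keep their rotamer sets.
#' @param seed Integer seed for cohort generation.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pairs = 200, n_residues = 30, binding_site = 4:6,
                        flip_residue = 6, category_residue = 3,
                        buried_residues = 12:19,
                        delta_bs_median = 0.03, delta_bs_sd = 0.012,
                        residual_slope = -0.44, residual_sd = 0.0055,
                        resolution_range = c(1.2, 1.9), b_sidechain = 14,
                        norm_factor = 0.8, q_flex = 0.75,
                        preorganized_fraction = 0.11, seed = 1L) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (n_residues < 26) stop("n_residues must be >= 26")
  if (delta_bs_sd < 0 || residual_sd < 0) stop("noise SDs must be >= 0")
  structure(as.list(environment()), class = "cohort_spec")
}

# chain layout: residue type and baseline conformer plan per position
cohort_layout <- function(spec) {
  n <- spec$n_residues
  val_pos <- c(n - 6, n - 4)
  leu_pos <- n
  aa <- rep("SER", n)
  aa[val_pos] <- "VAL"
  aa[leu_pos] <- "LEU"
  flexible <- rep(TRUE, n)
  flexible[c(spec$flip_residue, spec$category_residue, val_pos, leu_pos)] <- FALSE
  list(aa = aa, flexible = flexible, val_pos = val_pos, leu_pos = leu_pos)
}

#' Build one synthetic apo/holo pair with planted effects
#'
#' Constructs matched apo and holo structures sharing sequence, space group,
#' cell and resolution. The holo structure carries a 10-carbon ring ligand
#' placed so that exactly the designated binding-site residues have heavy
#' atoms within 5 A; distant buried residues are wrapped in occluding
#' shells. Binding-site rigidification (`x_p`: the planted mean
#' holo-minus-apo s2_calc over binding-site residues) and distal
#' flexibilization (`d_p`: the planted mean over realized distant buried
#' residues) are planted exactly through occupancy shifts of two-conformer
#' chi1 = 60/180 side chains.
#'
#' @param spec A [cohort_spec()].
#' @param pair_id Pair identifier string.
#' @param x_p Planted mean binding-site delta s2.
#' @param d_p Planted mean distant-buried delta s2.
#' @param resolution Pair resolution, Angstrom.
#' @param preorganized Logical: keep all binding-site rotamer sets equal.
#' @param category Planted rotamer-change category at the category residue:
#'   "no_change", "distinct", "remodeled_holo_loss" or
#'   "remodeled_holo_gain".
#' @return List with `apo`, `holo` ([structure_model()]s), `ligand`,
#'   `truth_pair` (one-row data.frame) and `truth_residues`.
#' @export
build_pair <- function(spec, pair_id = "pair_001", x_p = 0.03, d_p = 0.0,
                       resolution = 1.6, preorganized = FALSE,
                       category = "no_change") {
  lay <- cohort_layout(spec)
  n <- spec$n_residues
  q0 <- spec$q_flex
  b_ca <- 10 * spec$norm_factor * resolution
  bs_idx <- spec$binding_site

  # chi plans: flexible residues are two-conformer 60/180 jumps
  chi_apo <- chi_holo <- vector("list", n)
  occ_apo <- vector("list", n)
  for (i in seq_len(n)) {
    if (lay$flexible[i]) {
      chi_apo[[i]] <- chi_holo[[i]] <- c(60, 180)
      occ_apo[[i]] <- c(q0, 1 - q0)
    } else {
      chi_apo[[i]] <- chi_holo[[i]] <- if (lay$aa[i] == "SER") 60 else 180
      occ_apo[[i]] <- 1
    }
  }
  # planted rotamer-change category at the category residue (class "other")
  ci <- spec$category_residue
  cat_occ_apo <- 1; cat_occ_holo <- 1
  switch(category,
    no_change = NULL,
    distinct = { chi_holo[[ci]] <- 300 },
    remodeled_holo_loss = {
      chi_apo[[ci]] <- c(60, 300); cat_occ_apo <- c(0.65, 0.35)
    },
    remodeled_holo_gain = {
      chi_holo[[ci]] <- c(60, 300); cat_occ_holo <- c(0.65, 0.35)
    },
    stop("unknown category: ", category))
  # binding-site rotamer flip in non-preorganized pairs
  if (!preorganized) chi_holo[[spec$flip_residue]] <- 300

  mk_residue <- function(i, chis, occs) {
    build_residue(residue_spec(lay$aa[i], chi1 = chis, occupancies = occs,
                               b_sidechain = spec$b_sidechain,
                               b_calpha = b_ca,
                               chi2 = rep(180, length(chis))), index = i)
  }
  occ_holo <- occ_apo
  occ_apo[[ci]] <- cat_occ_apo
  occ_holo[[ci]] <- cat_occ_holo

  shells <- build_burial_shells(spec$buried_residues)
  # ring bottom sits ~3.1 A above the chain axis: the Cbeta atoms of the
  # designated site are then within 5 A for any chi1, the +/-2 neighbours
  # never are
  lig_center <- c((bs_idx[2] - 1) * CA_SPACING, 5.6, 0)
  ligand <- build_ligand_ring(lig_center)
  cell <- c(CA_SPACING * (n + 4), 40, 40, 90, 90, 90)

  holo0 <- structure_model(
    id = paste0(pair_id, "_holo"),
    residues = lapply(seq_len(n), function(i)
      mk_residue(i, chi_holo[[i]], occ_holo[[i]])),
    ligands = c(list(ligand), shells),
    space_group = "P 1", cell = cell, resolution = resolution)

  # realized spatial classes (coordinates are final; occupancy shifts
  # planted below do not move atoms or change the major conformer)
  env <- environment_table(holo0, ligand, sasa_scope = "distant",
                           n_points = 320)
  realized_bs <- env$seqnum[env$environment == "binding_site"]
  if (!setequal(realized_bs, bs_idx))
    stop("designated binding site not realized: got ",
         paste(realized_bs, collapse = ","))
  buried <- env$seqnum[env$environment == "distant_buried"]
  if (!all(lay$flexible[buried]))
    stop("infeasible layout: a rigid residue was buried")

  # plant deltas through occupancy shifts; s2_calc = s2on * s2_ang with
  # s2on fixed, so delta s2_ang = delta s2_calc / s2on
  s2o <- s2_ortho(spec$b_sidechain, spec$b_sidechain)
  s2on <- normalize_s2_ortho(s2o, b_ca, resolution)
  s2a0 <- true_s2_ang_two_site(q0, 1 - q0, 120)
  shiftable_bs <- intersect(bs_idx, which(lay$flexible))
  target <- function(delta) solve_major_occupancy(s2a0 + delta / s2on)
  for (i in shiftable_bs) {
    qh <- target(x_p * length(bs_idx) / length(shiftable_bs))
    occ_holo[[i]] <- c(qh, 1 - qh)
  }
  for (i in buried) occ_holo[[i]] <- {
    qh <- target(d_p); c(qh, 1 - qh)
  }

  # the provisional holo already has the final coordinates everywhere and
  # the final occupancies outside the planted regions: update occupancies
  # in place for holo, and rebuild only the chi-changed residues for apo
  set_occ <- function(res, occs) {
    for (k in seq_along(res$conformers)) {
      res$conformers[[k]]$occupancy <- occs[k]
      lab <- res$conformers[[k]]$atoms$altloc != ""
      res$conformers[[k]]$atoms$occupancy[lab] <- occs[k]
    }
    res
  }
  holo <- holo0
  holo$id <- paste0(pair_id, "_holo")
  for (i in c(shiftable_bs, buried))
    holo$residues[[i]] <- set_occ(holo$residues[[i]], occ_holo[[i]])
  apo <- holo0
  apo$id <- paste0(pair_id, "_apo")
  apo$ligands <- shells
  for (i in seq_len(n))
    if (!identical(chi_apo[[i]], chi_holo[[i]]) || i == ci)
      apo$residues[[i]] <- mk_residue(i, chi_apo[[i]], occ_apo[[i]])

  # analytic ground truth
  truth_res <- do.call(rbind, lapply(seq_len(n), function(i) {
    s2a_apo <- if (length(chi_apo[[i]]) == 2)
      true_s2_ang_two_site(occ_apo[[i]][1], occ_apo[[i]][2],
                           diff(chi_apo[[i]])) else 1
    s2a_holo <- if (length(chi_holo[[i]]) == 2)
      true_s2_ang_two_site(occ_holo[[i]][1], occ_holo[[i]][2],
                           diff(chi_holo[[i]])) else 1
    # well labels as the pipeline reports them (Leu carries a chi2 letter;
    # the generator fixes chi2 = 180, the t well)
    wells <- function(chis) {
      lab <- vapply(chis, bin_chi, "")
      if (lay$aa[i] == "LEU") lab <- paste0(lab, "t")
      paste(sort(unique(lab)), collapse = ",")
    }
    data.frame(pair_id = pair_id, seqnum = i, aa = lay$aa[i],
               environment = env$environment[i],
               s2_ang_apo = s2a_apo, s2_ang_holo = s2a_holo,
               s2_ortho = s2o, s2_ortho_norm = s2on,
               s2_calc_apo = s2on * s2a_apo, s2_calc_holo = s2on * s2a_holo,
               delta_s2 = s2on * (s2a_holo - s2a_apo),
               n_conf_apo = length(chi_apo[[i]]),
               n_conf_holo = length(chi_holo[[i]]),
               rot_apo = wells(chi_apo[[i]]), rot_holo = wells(chi_holo[[i]]),
               stringsAsFactors = FALSE)
  }))
  truth_pair <- data.frame(
    pair_id = pair_id, resolution = resolution, x_true = x_p, d_true = d_p,
    residual_true = d_p - x_p, preorganized = preorganized,
    category = category, s2_ortho_norm = s2on,
    n_binding_site = length(bs_idx), n_distant_buried = length(buried),
    stringsAsFactors = FALSE)
  list(apo = apo, holo = holo, ligand = ligand, truth_pair = truth_pair,
       truth_residues = truth_res)
}

#' Generate a synthetic apo/holo cohort
#'
#' Draws per-pair effects from the cohort specification (binding-site delta
#' `x_p ~ N(median, sd)`, distant-buried delta
#' `d_p = (1 + slope) x_p + N(0, residual_sd)`, resolution uniform in the
#' configured range, preorganization Bernoulli) and builds every pair.
#' Deterministic under the spec seed. When `dir` is given, writes the PDB
#' files plus metadata, ligand-descriptor and ground-truth CSV tables.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory (created if needed).
#' @param keep_models Keep the structure models in the returned list
#'   (default TRUE; set FALSE with `dir` to save memory).
#' @return List with `pairs` (per-pair lists from [build_pair()]),
#'   `truth_pairs`, `truth_residues`, `metadata`, `ligands`.
#' @export
build_cohort <- function(spec, dir = NULL, keep_models = TRUE) {
  set.seed(spec$seed)
  cats <- c("no_change", "distinct", "remodeled_holo_loss",
            "remodeled_holo_gain")
  pairs <- vector("list", spec$n_pairs)
  tp <- tr <- meta <- ligs <- list()
  for (p in seq_len(spec$n_pairs)) {
    pid <- sprintf("pair_%03d", p)
    x_p <- stats::rnorm(1, spec$delta_bs_median, spec$delta_bs_sd)
    d_p <- (1 + spec$residual_slope) * x_p +
      stats::rnorm(1, 0, spec$residual_sd)
    res_ang <- stats::runif(1, spec$resolution_range[1],
                            spec$resolution_range[2])
    preorg <- stats::runif(1) < spec$preorganized_fraction
    pr <- build_pair(spec, pid, x_p = x_p, d_p = d_p,
                     resolution = res_ang, preorganized = preorg,
                     category = cats[1 + (p - 1) %% length(cats)])
    tp[[p]] <- pr$truth_pair
    tr[[p]] <- pr$truth_residues
    seq1 <- paste(substr(cohort_layout(spec)$aa, 1, 1), collapse = "")
    meta_row <- function(id, role) data.frame(
      id = id, role = role, space_group = "P 1",
      a = pr$apo$cell[1], b = pr$apo$cell[2], c = pr$apo$cell[3],
      alpha = 90, beta = 90, gamma = 90, resolution = res_ang,
      sequence = seq1,
      r_free_initial = round(stats::runif(1, 0.17, 0.20), 4),
      r_free_final = NA, clashscore = round(stats::runif(1, 1, 6), 2),
      ligand_id = if (role == "holo") "LIG" else NA,
      ligand_occupancy = if (role == "holo") 1.0 else NA,
      stringsAsFactors = FALSE)
    ma <- meta_row(pr$apo$id, "apo"); mh <- meta_row(pr$holo$id, "holo")
    ma$r_free_final <- ma$r_free_initial + round(stats::runif(1, 0, 0.02), 4)
    mh$r_free_final <- mh$r_free_initial + round(stats::runif(1, 0, 0.02), 4)
    meta[[p]] <- rbind(mh, ma)
    ligs[[p]] <- data.frame(
      pair_id = pid, ligand_id = "LIG", mw = round(stats::runif(1, 150, 450), 1),
      n_heavy = sample(10:34, 1), logp = round(stats::rnorm(1, 1.5, 1.2), 2),
      n_rotatable = stats::rpois(1, 4), hbd = stats::rpois(1, 2),
      hba = stats::rpois(1, 4), stringsAsFactors = FALSE)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_pdb(pr$apo, file.path(dir, paste0(pid, "_apo.pdb")))
      write_pdb(pr$holo, file.path(dir, paste0(pid, "_holo.pdb")))
    }
    pairs[[p]] <- if (keep_models) pr else pr[c("truth_pair")]
  }
  out <- list(pairs = pairs,
              truth_pairs = do.call(rbind, tp),
              truth_residues = do.call(rbind, tr),
              metadata = do.call(rbind, meta),
              ligands = do.call(rbind, ligs))
  if (!is.null(dir)) {
    utils::write.csv(out$truth_pairs, file.path(dir, "truth_pairs.csv"),
                     row.names = FALSE)
    utils::write.csv(out$truth_residues,
                     file.path(dir, "truth_residues.csv"), row.names = FALSE)
    utils::write.csv(out$metadata, file.path(dir, "metadata.csv"),
                     row.names = FALSE)
    utils::write.csv(out$ligands, file.path(dir, "ligand_descriptors.csv"),
                     row.names = FALSE)
  }
  invisible(out)
}
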