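# Spatial partitioning of residues: binding-site and distant classes by
# heavy-atom distance to the ligand, and solvent exposure via an in-package
# Shrake-Rupley accessible-surface-area implementation with the theoretical
# maximum ASA normalization.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# Tien et al. theoretical maximum accessible surface areas (Angstrom^2)
MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
             GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
             LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
             SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

# minimal heavy-atom distance from every protein residue to the ligand
min_ligand_distance <- function(model, ligand) {
  lat <- residue_atoms_unique(ligand)
  lat <- lat[is_heavy(lat), , drop = FALSE]
  if (!nrow(lat)) stop("ligand has no heavy atoms")
  lig <- cbind(lat$x, lat$y, lat$z)
  vapply(model$residues, function(res) {
    at <- residue_atoms_unique(res)
    at <- at[is_heavy(at), , drop = FALSE]
    if (!nrow(at)) return(NA_real_)
    p <- cbind(at$x, at$y, at$z)
    d2 <- outer(rowSums(p^2), rowSums(lig^2), "+") - 2 * p %*% t(lig)
    sqrt(max(min(d2), 0))
  }, 0)
}

#' Binding-site residues of a ligand
#'
#' Residues with any heavy atom within `cutoff` Angstrom (inclusive) of any
#' ligand heavy atom.
#'
#' @param model A [structure_model()].
#' @param ligand A HETATM [multiconf_residue()] group (e.g. from
#'   `model$ligands`).
#' @param cutoff Distance cutoff in Angstrom (default 5).
#' @return Character vector of residue ids ("chain:seqnum").
#' @export
binding_site_residues <- function(model, ligand, cutoff = 5.0) {
  d <- min_ligand_distance(model, ligand)
  ids <- vapply(model$residues, residue_key, "")
  ids[!is.na(d) & d <= cutoff + 1e-9]
}

#' Residues distant from a ligand
#'
#' Residues whose minimal heavy-atom distance to the ligand exceeds `cutoff`
#' Angstrom.
#'
#' @inheritParams binding_site_residues
#' @param cutoff Distance cutoff in Angstrom (default 10).
#' @return Character vector of residue ids.
#' @export
distant_residues <- function(model, ligand, cutoff = 10.0) {
  d <- min_ligand_distance(model, ligand)
  ids <- vapply(model$residues, residue_key, "")
  ids[!is.na(d) & d > cutoff + 1e-9]
}

# deterministic, nearly uniform unit sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom accessible area by deterministic sphere-point sampling: each
#' atom's solvent-expanded sphere (van der Waals radius + probe) is covered
#' with a golden-spiral point lattice and a point counts as accessible when
#' it lies outside every neighbour's expanded sphere. Residues with
#' alternative conformations contribute their highest-occupancy conformer.
#' Hydrogens are excluded by default (DSSP-like); HETATM groups occlude but
#' their areas are also reported.
#'
#' @param model A [structure_model()].
#' @param probe Probe radius, Angstrom (default 1.4).
#' @param n_points Sphere sample points per atom (default 960).
#' @param include_hydrogens Include hydrogens as atoms (default FALSE).
#' @param subset Optional character vector of residue ids: areas are
#'   computed only for atoms of these residues (all atoms still occlude).
#' @return data.frame with residue id, hetero flag, atom name and `area`
#'   (Angstrom^2).
#' @export
shrake_rupley_sasa <- function(model, probe = 1.4, n_points = 960,
                               include_hydrogens = FALSE, subset = NULL) {
  grp <- c(model$residues, model$ligands)
  tabs <- lapply(grp, function(res) {
    occ <- vapply(res$conformers, `[[`, 0, "occupancy")
    alts <- vapply(res$conformers, `[[`, "", "altloc")
    i <- which(occ == max(occ))
    i <- i[order(alts[i])][1]
    at <- res$conformers[[i]]$atoms
    if (!include_hydrogens) at <- at[is_heavy(at), , drop = FALSE]
    if (!nrow(at)) return(NULL)
    data.frame(residue = residue_key(res), hetero = res$hetero,
               name = at$name, element = at$element,
               x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  })
  at <- do.call(rbind, tabs)
  unknown <- setdiff(unique(at$element), names(VDW_RADII))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  xyz <- cbind(at$x, at$y, at$z)
  rad <- VDW_RADII[at$element] + probe
  pts <- sphere_points(n_points)

  targets <- seq_len(nrow(at))
  if (!is.null(subset)) targets <- which(at$residue %in% subset)
  area <- rep(NA_real_, nrow(at))
  for (i in targets) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad[i] + rad)^2 & d2 > 1e-12)
    if (!length(nb)) {
      area[i] <- 4 * pi * rad[i]^2
      next
    }
    p <- pts * rad[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    ctr <- xyz[nb, , drop = FALSE]
    # squared point-to-neighbour distances, one BLAS call
    d2m <- rowSums(p^2) - 2 * tcrossprod(p, ctr) +
      rep(rowSums(ctr^2), each = n_points)
    blocked <- d2m < rep(rad[nb]^2, each = n_points)
    acc <- .rowSums(blocked, n_points, length(nb)) == 0
    area[i] <- 4 * pi * rad[i]^2 * mean(acc)
  }
  data.frame(residue = at$residue, hetero = at$hetero, name = at$name,
             area = area, stringsAsFactors = FALSE)[targets, , drop = FALSE]
}

#' Classify solvent exposure of a residue
#'
#' Relative accessible surface area (RASA) is the residue SASA divided by
#' the residue type's theoretical maximum ASA; residues at or above the
#' threshold are solvent exposed. RASA may exceed 1 for extended synthetic
#' geometries and is reported as is.
#'
#' @param residue_sasa Residue SASA, Angstrom^2.
#' @param aa Three-letter residue type.
#' @param threshold Exposure threshold on RASA (default 0.20).
#' @return List with `rasa` and `is_exposed`.
#' @export
classify_exposure <- function(residue_sasa, aa, threshold = 0.20) {
  aa <- toupper(aa)
  if (!aa %in% names(MAX_ASA)) stop("unknown residue type: ", aa)
  rasa <- residue_sasa / MAX_ASA[[aa]]
  list(rasa = rasa, is_exposed = rasa >= threshold - 1e-9)
}

#' Spatial environment table for a holo structure
#'
#' Combines ligand distances and solvent exposure into one row per protein
#' residue: binding-site membership (min heavy-atom distance <= 5 A by
#' default), distant membership (> 10 A), SASA, RASA and the exposure flag.
#' SASA can be restricted to distant residues (`sasa_scope = "distant"`),
#' which is what downstream buried/exposed splits need.
#'
#' @param model A [structure_model()] containing the ligand.
#' @param ligand A HETATM group of `model` (default: first ligand).
#' @param binding_cutoff,distant_cutoff Distance cutoffs, Angstrom.
#' @param exposure_threshold RASA exposure threshold.
#' @param sasa_scope `"all"` or `"distant"`.
#' @param n_points Sphere points for SASA.
#' @return data.frame with structure_id, chain, seqnum, icode, aa,
#'   min_ligand_distance, is_binding_site, is_distant, sasa, rasa,
#'   is_exposed, environment.
#' @export
environment_table <- function(model, ligand = NULL, binding_cutoff = 5.0,
                              distant_cutoff = 10.0,
                              exposure_threshold = 0.20,
                              sasa_scope = c("all", "distant"),
                              n_points = 960) {
  sasa_scope <- match.arg(sasa_scope)
  if (is.null(ligand)) {
    if (!length(model$ligands)) stop("model has no ligand")
    ligand <- model$ligands[[1]]
  }
  d <- min_ligand_distance(model, ligand)
  ids <- vapply(model$residues, residue_key, "")
  out <- data.frame(structure_id = model$id,
                    chain = vapply(model$residues, `[[`, "", "chain"),
                    seqnum = vapply(model$residues, `[[`, 0L, "seqnum"),
                    icode = vapply(model$residues, `[[`, "", "icode"),
                    aa = vapply(model$residues, `[[`, "", "aa"),
                    min_ligand_distance = d,
                    is_binding_site = !is.na(d) & d <= binding_cutoff + 1e-9,
                    is_distant = !is.na(d) & d > distant_cutoff + 1e-9,
                    sasa = NA_real_, rasa = NA_real_, is_exposed = NA,
                    stringsAsFactors = FALSE)
  subset <- if (sasa_scope == "distant") ids[out$is_distant] else NULL
  sasa <- shrake_rupley_sasa(model, n_points = n_points, subset = subset)
  sasa <- sasa[!sasa$hetero, , drop = FALSE]
  per_res <- tapply(sasa$area, sasa$residue, sum)
  hit <- match(ids, names(per_res))
  out$sasa <- as.numeric(per_res[hit])
  known <- !is.na(out$sasa) & out$aa %in% names(MAX_ASA)
  out$rasa[known] <- out$sasa[known] / MAX_ASA[out$aa[known]]
  out$is_exposed[known] <- out$rasa[known] >= exposure_threshold - 1e-9
  out$environment <- ifelse(out$is_binding_site, "binding_site",
                     ifelse(out$is_distant & !is.na(out$is_exposed) &
                              !out$is_exposed, "distant_buried",
                     ifelse(out$is_distant, "distant_exposed", "other")))
  out
}
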