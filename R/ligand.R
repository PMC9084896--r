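# Ligand descriptor normalization and occupancy / normalized-B analyses.
# Descriptors (molecular weight, logP, rotatable bonds, H-bond donors and
# acceptors) are consumed from a table; the pipeline never requires
# cheminformatics software.

#' Normalize ligand descriptors
#'
#' Derives the size-normalized descriptor ratios used for quartile
#' comparisons: rotatable bonds per unit molecular weight and hydrogen
#' bonds (donors + acceptors) per heavy atom.
#'
#' @param raw data.frame with columns ligand_id, mw, n_heavy, logp,
#'   n_rotatable, hbd, hba (one row per ligand).
#' @return The input with `rot_per_mw` and `hb_per_heavy` columns added.
#' @export
normalize_descriptors <- function(raw) {
  need <- c("ligand_id", "mw", "n_heavy", "logp", "n_rotatable", "hbd", "hba")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("descriptor table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(raw$mw <= 0)) stop("molecular weight must be > 0")
  if (any(raw$n_heavy <= 0)) stop("heavy-atom count must be > 0")
  raw$rot_per_mw <- raw$n_rotatable / raw$mw
  raw$hb_per_heavy <- (raw$hbd + raw$hba) / raw$n_heavy
  raw
}

#' Ligand occupancy class
#'
#' Classifies a ligand as `"full"` (single conformer whose occupancy sums
#' to at least the full-occupancy tolerance), `"multiconf_full"` (several
#' alternative conformations that together amount to full occupancy) or
#' `"partial"` (total occupancy below full).
#'
#' @param ligand A HETATM [multiconf_residue()].
#' @param full_tol Full-occupancy tolerance (default 0.99).
#' @return One of "full", "multiconf_full", "partial".
#' @export
ligand_occupancy_class <- function(ligand, full_tol = 0.99) {
  occ <- vapply(ligand$conformers, `[[`, 0, "occupancy")
  total <- sum(occ)
  if (total <= 1e-9) stop("ligand has zero occupancy")
  if (total >= full_tol) {
    if (length(occ) == 1) "full" else "multiconf_full"
  } else "partial"
}

#' Normalized ligand B-factor
#'
#' Occupancy-weighted mean heavy-atom B-factor of the ligand divided by the
#' mean Calpha B-factor of all residues in the structure. Scale-invariant
#' under uniform rescaling of all B-factors.
#'
#' @param ligand A HETATM [multiconf_residue()].
#' @param model The containing [structure_model()] (for the Calpha mean).
#' @return Unitless ratio.
#' @export
ligand_b_norm <- function(ligand, model) {
  lig_b <- residue_bfactor(ligand, scope = "all")
  ca_b <- vapply(model$residues, atom_b_weighted, 0, name = "CA")
  ca_b <- ca_b[!is.na(ca_b)]
  if (!length(ca_b)) stop("model has no Calpha atoms")
  lig_b / mean(ca_b)
}
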