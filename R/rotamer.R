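# Chi dihedral computation, rotamer-well assignment per conformer, and the
# four-way apo/holo rotamer-change classification for multiconformer pairs.
#
# Wells use 120-degree chi binning: p = [0,120), t = [120,240), m = [240,360);
# chemically symmetric terminal torsions (Phe/Tyr chi2, Asp chi2, Glu chi3)
# are folded modulo 180 first. This replaces a full rotamer library: only the
# well identity matters for the change classification.

# chi atom quadruples per residue type; attr "sym" marks the terminal
# symmetric torsion index (0 = none)
CHI_ATOMS <- list(
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "CE", "CZ"))
)
SYMMETRIC_CHI <- c(PHE = 2L, TYR = 2L, ASP = 2L, GLU = 3L)

# one chi angle into its well letter
bin_chi <- function(chi, symmetric = FALSE) {
  chi <- chi %% 360
  if (symmetric) {
    a <- chi %% 180
    return(if (a < 120) "p" else "t")
  }
  if (chi < 120) "p" else if (chi < 240) "t" else "m"
}

#' Assign a rotamer-well label to one conformer
#'
#' Computes the residue's chi dihedrals from the conformer coordinates and
#' concatenates one well letter per angle (e.g. "mt" for Leu). Residues with
#' no chi angles (Gly, Ala) return "". Conformers missing required atoms
#' return "INCOMPLETE".
#'
#' @param conf A [conformer()].
#' @param aa Three-letter residue type.
#' @return Character label (letters from p/t/m), "", or "INCOMPLETE".
#' @export
assign_rotamer <- function(conf, aa) {
  aa <- toupper(aa)
  defs <- CHI_ATOMS[[aa]]
  if (is.null(defs)) return("")
  sym_i <- if (aa %in% names(SYMMETRIC_CHI)) SYMMETRIC_CHI[[aa]] else 0L
  letters_out <- character(length(defs))
  for (k in seq_along(defs)) {
    pts <- lapply(defs[[k]], atom_xyz, cf = conf)
    if (any(vapply(pts, is.null, TRUE))) return("INCOMPLETE")
    chi <- dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    letters_out[k] <- bin_chi(chi, symmetric = (k == sym_i))
  }
  paste(letters_out, collapse = "")
}

#' Rotamer table for a structure
#'
#' One row per protein residue per conformer with its rotamer-well label.
#'
#' @param model A [structure_model()].
#' @return data.frame with structure_id, chain, seqnum, icode, aa, altloc,
#'   occupancy, label.
#' @export
rotamer_table <- function(model) {
  rows <- lapply(model$residues, function(res) {
    data.frame(structure_id = model$id, chain = res$chain,
               seqnum = res$seqnum, icode = res$icode, aa = res$aa,
               altloc = vapply(res$conformers, `[[`, "", "altloc"),
               occupancy = vapply(res$conformers, `[[`, 0, "occupancy"),
               label = vapply(res$conformers, assign_rotamer, "",
                              aa = res$aa),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify the rotamer change of one apo/holo residue pair
#'
#' Compares the sets of rotamer wells populated by the alternative
#' conformations of the matched residues:
#' equal sets are "no_change"; disjoint sets are "distinct"; a holo set that
#' is a strict subset of the apo set is "remodeled_holo_loss" (extra wells
#' populated in the apo residue only); an apo set strictly inside the holo
#' set is "remodeled_holo_gain"; overlapping sets with extras on both sides
#' are "remodeled_both". The five categories partition all pairs of
#' non-empty sets.
#'
#' @param set_apo,set_holo Character vectors of rotamer labels (non-empty).
#' @return One of "no_change", "distinct", "remodeled_holo_loss",
#'   "remodeled_holo_gain", "remodeled_both".
#' @export
classify_pair_rotamers <- function(set_apo, set_holo) {
  a <- unique(set_apo)
  h <- unique(set_holo)
  if (!length(a) || !length(h)) stop("rotamer sets must be non-empty")
  if (setequal(a, h)) return("no_change")
  if (!length(intersect(a, h))) return("distinct")
  if (all(h %in% a)) return("remodeled_holo_loss")
  if (all(a %in% h)) return("remodeled_holo_gain")
  "remodeled_both"
}

# per-residue rotamer sets (unique well labels, INCOMPLETE dropped) keyed by
# chain:seqnum+icode
residue_rotamer_sets <- function(model) {
  tab <- rotamer_table(model)
  tab <- tab[tab$label != "INCOMPLETE", , drop = FALSE]
  key <- paste0(tab$chain, ":", tab$seqnum, tab$icode)
  lapply(split(tab$label, factor(key, levels = unique(key))), unique)
}
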