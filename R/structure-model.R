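#' @keywords internal
"_PACKAGE"

# Atom tables are plain data.frames with one row per atom and columns:
# name, element, altloc ('' = blank), occupancy, b, x, y, z, is_hetero.

#' Build an atom table
#'
#' Constructs the per-atom data.frame used inside conformers. Atoms are
#' Cartesian, in Angstrom; `b` is the isotropic B-factor (Angstrom^2).
#'
#' @param name Atom name(s), e.g. "CA", "CB", "OG".
#' @param element Element symbol(s); must be non-empty.
#' @param x,y,z Coordinates in Angstrom.
#' @param occupancy Fractional occupancy in [0, 1].
#' @param b Isotropic B-factor (>= 0), Angstrom^2.
#' @param altloc Alternate-location indicator; "" means blank (shared).
#' @param is_hetero Logical flag for HETATM records.
#' @return data.frame with one row per atom.
#' @export
atom_table <- function(name, element, x, y, z, occupancy = 1, b = 0,
                       altloc = "", is_hetero = FALSE) {
  n <- max(length(name), length(x))
  df <- structure(list(name = rep_len(as.character(name), n),
                       element = rep_len(as.character(element), n),
                       altloc = rep_len(as.character(altloc), n),
                       occupancy = rep_len(as.numeric(occupancy), n),
                       b = rep_len(as.numeric(b), n),
                       x = rep_len(as.numeric(x), n),
                       y = rep_len(as.numeric(y), n),
                       z = rep_len(as.numeric(z), n),
                       is_hetero = rep_len(as.logical(is_hetero), n)),
                  class = "data.frame", row.names = seq_len(n))
  if (any(!nzchar(df$element))) stop("atom element must be non-empty")
  if (any(df$occupancy < -1e-9 | df$occupancy > 1 + 1e-9))
    stop("atom occupancy must lie in [0, 1]")
  if (any(df$b < 0)) stop("atom b_iso must be >= 0")
  df
}

#' Create a conformer
#'
#' A conformer is one alternate-location state of a residue: an altloc label,
#' the fractional occupancy shared by its labelled atoms, and an atom table.
#' Blank-altloc atoms (shared backbone etc.) may appear inside any conformer.
#'
#' @param altloc Single-character altloc label ("" for the unique conformer of
#'   an unsplit residue).
#' @param occupancy Occupancy in (0, 1].
#' @param atoms Atom table (see [atom_table()]); every atom must carry either
#'   a blank altloc or this conformer's label.
#' @return Object of class `conformer`.
#' @export
conformer <- function(altloc, occupancy, atoms) {
  if (occupancy <= 0 || occupancy > 1 + 1e-9)
    stop("conformer occupancy must lie in (0, 1]")
  bad <- atoms$altloc != "" & atoms$altloc != altloc
  if (any(bad)) stop("conformer atoms must share the conformer altloc or be blank")
  structure(list(altloc = altloc, occupancy = min(occupancy, 1), atoms = atoms),
            class = "conformer")
}

#' Create a multiconformer residue
#'
#' The unit of all per-residue metrics: a residue with one or more altloc
#' conformers, each with atoms, an occupancy and B-factors.
#'
#' @param chain Chain identifier.
#' @param seqnum Integer residue sequence number.
#' @param aa Three-letter residue code (upper case).
#' @param conformers List of [conformer()] objects (>= 1, unique altlocs,
#'   occupancies summing to <= 1 within tolerance).
#' @param icode Insertion code ("" by default).
#' @param hetero Logical; TRUE for HETATM groups (ligands).
#' @return Object of class `multiconf_residue`.
#' @export
multiconf_residue <- function(chain, seqnum, aa, conformers, icode = "",
                              hetero = FALSE) {
  if (length(conformers) < 1) stop("residue needs at least one conformer")
  alts <- vapply(conformers, function(cf) cf$altloc, "")
  if (anyDuplicated(alts)) stop("conformer altlocs must be unique within a residue")
  occ <- vapply(conformers, function(cf) cf$occupancy, 0)
  if (sum(occ) > 1 + 1e-6)
    stop(sprintf("conformer occupancies sum to %.4f > 1 for %s %s%d",
                 sum(occ), aa, chain, seqnum))
  structure(list(chain = as.character(chain), seqnum = as.integer(seqnum),
                 icode = as.character(icode), aa = toupper(aa),
                 conformers = conformers[order(alts)], hetero = isTRUE(hetero)),
            class = "multiconf_residue")
}

#' Create a structure model
#'
#' Chains of multiconformer residues plus HETATM ligand groups and crystal
#' metadata (space group, unit cell, resolution).
#'
#' @param id Structure identifier string.
#' @param residues List of protein [multiconf_residue()] objects.
#' @param ligands List of HETATM [multiconf_residue()] groups.
#' @param space_group Hermann-Mauguin symbol, or NA if the CRYST1 record was
#'   absent.
#' @param cell Numeric length-6 vector (a, b, c in Angstrom; alpha, beta,
#'   gamma in degrees), or NULL if absent.
#' @param resolution Resolution in Angstrom (> 0), or NA.
#' @param r_free Optional final R-free fraction.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(id, residues, ligands = list(), space_group = NA,
                            cell = NULL, resolution = NA, r_free = NA) {
  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    if (length(cell) != 6) stop("cell must have 6 components (a,b,c,alpha,beta,gamma)")
    if (any(cell[1:3] <= 0)) stop("cell lengths must be > 0")
    if (any(cell[4:6] <= 0 | cell[4:6] >= 180)) stop("cell angles must lie in (0, 180)")
  }
  if (!is.na(resolution) && resolution <= 0) stop("resolution must be > 0")
  structure(list(id = as.character(id), residues = residues, ligands = ligands,
                 space_group = space_group, cell = cell,
                 resolution = resolution, r_free = r_free),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d residues, %d hetero groups\n",
              x$id, length(x$residues), length(x$ligands)))
  cat(sprintf("  space group: %s  resolution: %s A\n",
              ifelse(is.na(x$space_group), "?", x$space_group),
              ifelse(is.na(x$resolution), "?", format(x$resolution))))
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT",
                    "H", "H1", "H2", "H3", "HA", "HA2", "HA3")

is_heavy <- function(atoms) !(atoms$element %in% c("H", "D"))

is_sidechain_name <- function(name) !(name %in% BACKBONE_NAMES)

residue_key <- function(res) paste0(res$chain, ":", res$seqnum, res$icode)

# all atoms of a residue across conformers, blank-altloc atoms deduplicated
residue_atoms_unique <- function(res) {
  tabs <- lapply(res$conformers, `[[`, "atoms")
  at <- do.call(rbind, tabs)
  dup <- duplicated(paste(at$name, at$altloc))
  at[!dup, , drop = FALSE]
}

# occupancy-weighted mean B of a named atom across conformers (NA if absent)
atom_b_weighted <- function(res, name) {
  bs <- occ <- numeric(0)
  for (cf in res$conformers) {
    i <- which(cf$atoms$name == name)
    if (length(i)) {
      bs <- c(bs, cf$atoms$b[i[1]])
      occ <- c(occ, cf$occupancy)
    }
  }
  if (!length(bs)) return(NA_real_)
  sum(bs * occ) / sum(occ)
}

# coordinates of a named atom in one conformer (NULL if absent)
atom_xyz <- function(cf, name) {
  i <- which(cf$atoms$name == name)
  if (!length(i)) return(NULL)
  as.numeric(cf$atoms[i[1], c("x", "y", "z")])
}

# flat heavy-atom coordinate matrix for a model (protein + ligands),
# one row per atom of every conformer (blank atoms deduplicated per residue)
model_heavy_coords <- function(model, include_ligands = TRUE) {
  grp <- c(model$residues, if (include_ligands) model$ligands)
  out <- lapply(grp, function(res) {
    at <- residue_atoms_unique(res)
    at <- at[is_heavy(at), , drop = FALSE]
    if (!nrow(at)) return(NULL)
    cbind(at$x, at$y, at$z)
  })
  keys <- rep(vapply(grp, residue_key, ""),
              vapply(out, function(m) if (is.null(m)) 0L else nrow(m), 0L))
  list(xyz = do.call(rbind, out), residue = keys)
}
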