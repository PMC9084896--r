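# Apo/holo pair construction: ligand-based role classification, the
# pair-matching criteria (space group, sequence up to terminal trimming,
# resolution and unit-cell agreement), Calpha superposition RMSD, and the
# quality-control filter.

#' Common crystallographic additives excluded from ligand classification
#' @export
COMMON_ADDITIVES <- c("HOH", "DOD", "GOL", "EDO", "PEG", "PG4", "PGE", "1PE",
                      "MPD", "DMS", "ACT", "ACE", "FMT", "CIT", "TRS", "EPE",
                      "MES", "IMD", "BME", "SO4", "PO4", "NO3", "NH4", "CL",
                      "BR", "IOD", "F", "NA", "K", "MG", "CA", "ZN", "MN",
                      "FE", "NI", "CU", "CO", "CD", "SHL")

# heavy-atom count of a HETATM group (distinct atom names, so alternative
# conformations are not double counted)
ligand_heavy_count <- function(lig) {
  at <- residue_atoms_unique(lig)
  at <- at[is_heavy(at), , drop = FALSE]
  length(unique(at$name))
}

#' Classify a structure as apo or holo
#'
#' A structure is holo when it contains at least one HETATM group with
#' `min_heavy` or more heavy atoms whose residue code is not a common
#' crystallographic additive; otherwise apo.
#'
#' @param model A [structure_model()].
#' @param additive_list Residue codes never counted as ligands.
#' @param min_heavy Minimum ligand heavy atoms (default 10).
#' @return "apo" or "holo".
#' @export
classify_role <- function(model, additive_list = COMMON_ADDITIVES,
                          min_heavy = 10) {
  for (lig in model$ligands) {
    if (lig$aa %in% additive_list) next
    if (ligand_heavy_count(lig) >= min_heavy) return("holo")
  }
  "apo"
}

# qualifying ligand groups of a holo model
qualifying_ligands <- function(model, additive_list = COMMON_ADDITIVES,
                               min_heavy = 10) {
  keep <- vapply(model$ligands, function(lig) {
    !(lig$aa %in% additive_list) && ligand_heavy_count(lig) >= min_heavy
  }, TRUE)
  model$ligands[keep]
}

# sequences equal, or equal after trimming up to `max_trim` residues from
# either terminus of either sequence (minimal total trim accepted)
sequences_compatible <- function(s1, s2, max_trim = 5) {
  if (s1 == s2) return(TRUE)
  n1 <- nchar(s1); n2 <- nchar(s2)
  for (total in 1:(4 * max_trim)) {
    for (f1 in 0:min(max_trim, total)) for (b1 in 0:min(max_trim, total - f1))
      for (f2 in 0:min(max_trim, total - f1 - b1)) {
        b2 <- total - f1 - b1 - f2
        if (b2 > max_trim) next
        if (n1 - f1 - b1 < 1 || n2 - f2 - b2 < 1) next
        if (substr(s1, f1 + 1, n1 - b1) == substr(s2, f2 + 1, n2 - b2))
          return(TRUE)
      }
  }
  FALSE
}

#' Match apo and holo structures into pairs
#'
#' Applies the pair-definition criteria to a metadata table: identical space
#' group; identical sequence (or identical after trimming up to five
#' residues from either terminus of either structure); resolution difference
#' of 0.1 Angstrom or less; unit-cell lengths differing by at most 1
#' Angstrom and angles by at most 1 degree. All (holo, apo) combinations
#' passing the rules are then reduced to one apo per holo by the smallest
#' resolution difference (ties broken by the lexicographically smallest apo
#' id).
#'
#' @param metas data.frame with columns id, role ("apo"/"holo"),
#'   space_group, a, b, c, alpha, beta, gamma, resolution, sequence.
#' @param max_dres Resolution-difference bound, Angstrom (default 0.1).
#' @param max_dcell Cell-length bound, Angstrom (default 1).
#' @param max_dangle Cell-angle bound, degrees (default 1).
#' @return data.frame with holo_id, apo_id, delta_resolution (one row per
#'   holo with a surviving match; empty for empty input).
#' @export
match_pairs <- function(metas, max_dres = 0.1, max_dcell = 1.0,
                        max_dangle = 1.0) {
  empty <- data.frame(holo_id = character(0), apo_id = character(0),
                      delta_resolution = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(metas)) return(empty)
  need <- c("id", "role", "space_group", "a", "b", "c", "alpha", "beta",
            "gamma", "resolution", "sequence")
  miss <- setdiff(need, names(metas))
  if (length(miss)) stop("metadata table missing column(s): ",
                         paste(miss, collapse = ", "))
  ok <- stats::complete.cases(metas[, need])
  if (any(!ok)) {
    warning(sum(!ok), " structure(s) with missing metadata refused")
    metas <- metas[ok, , drop = FALSE]
  }
  holos <- metas[metas$role == "holo", , drop = FALSE]
  apos <- metas[metas$role == "apo", , drop = FALSE]
  tol <- 1e-9
  rows <- list()
  for (i in seq_len(nrow(holos))) for (j in seq_len(nrow(apos))) {
    h <- holos[i, ]; a <- apos[j, ]
    if (h$space_group != a$space_group) next
    dres <- abs(h$resolution - a$resolution)
    if (dres > max_dres + tol) next
    if (any(abs(unlist(h[c("a", "b", "c")]) -
                unlist(a[c("a", "b", "c")])) > max_dcell + tol)) next
    if (any(abs(unlist(h[c("alpha", "beta", "gamma")]) -
                unlist(a[c("alpha", "beta", "gamma")])) > max_dangle + tol)) next
    if (!sequences_compatible(h$sequence, a$sequence)) next
    rows[[length(rows) + 1L]] <-
      data.frame(holo_id = h$id, apo_id = a$id, delta_resolution = dres,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  all_pairs <- do.call(rbind, rows)
  # one apo per holo: minimum resolution difference, tie -> smallest apo id
  picked <- lapply(split(all_pairs, all_pairs$holo_id), function(g) {
    g[order(g$delta_resolution, g$apo_id), ][1, ]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out[order(out$holo_id), , drop = FALSE]
}

# matched Calpha coordinate matrices of two models (highest-occupancy
# conformer per residue, paired by chain + seqnum + icode)
matched_calpha <- function(m1, m2) {
  get_ca <- function(model) {
    keys <- vapply(model$residues, residue_key, "")
    xyz <- lapply(model$residues, function(res) {
      occ <- vapply(res$conformers, `[[`, 0, "occupancy")
      atom_xyz(res$conformers[[which.max(occ)]], "CA")
    })
    keep <- !vapply(xyz, is.null, TRUE)
    list(keys = keys[keep], xyz = do.call(rbind, xyz[keep]))
  }
  a <- get_ca(m1); b <- get_ca(m2)
  common <- intersect(a$keys, b$keys)
  list(keys = common,
       ref = a$xyz[match(common, a$keys), , drop = FALSE],
       mov = b$xyz[match(common, b$keys), , drop = FALSE])
}

#' Quality-control configuration
#'
#' Thresholds for [qc_filter()]: global Calpha RMSD (1 A), binding-site
#' Calpha RMSD (0.5 A), clashscore (15), apo/holo R-free gap (0.05,
#' absolute), per-structure R-free increase across refinement (0.025), and
#' the minimum ligand occupancy (0.15).
#'
#' @param global_rmsd,binding_site_rmsd,clashscore,rfree_gap,rfree_increase,min_ligand_occ
#'   Numeric thresholds.
#' @return List of class `qc_config`.
#' @export
qc_config <- function(global_rmsd = 1.0, binding_site_rmsd = 0.5,
                      clashscore = 15, rfree_gap = 0.05,
                      rfree_increase = 0.025, min_ligand_occ = 0.15) {
  structure(as.list(environment()), class = "qc_config")
}

#' Quality-control filter for one matched pair
#'
#' Accumulates failure reasons: global Calpha RMSD above threshold after
#' Kabsch superposition; binding-site Calpha RMSD above threshold (under the
#' global superposition); clashscore above threshold in either structure;
#' absolute apo/holo R-free difference above threshold; R-free increase
#' across refinement above threshold in either structure; ligand occupancy
#' below the minimum. Clashscore and R-free values are consumed from the
#' metadata table, never computed.
#'
#' @param pair One-row data.frame with holo_id, apo_id (as from
#'   [match_pairs()]).
#' @param apo,holo Parsed [structure_model()]s.
#' @param meta data.frame indexed by `id` with columns r_free_initial,
#'   r_free_final, clashscore, ligand_occupancy (NA entries skip the
#'   corresponding check).
#' @param thresholds A [qc_config()].
#' @param binding_cutoff Binding-site cutoff, Angstrom.
#' @return The pair row extended with qc_status ("pass"/"fail"),
#'   qc_reasons (semicolon-joined), global_rmsd and binding_site_rmsd.
#' @export
qc_filter <- function(pair, apo, holo, meta, thresholds = qc_config(),
                      binding_cutoff = 5.0) {
  need <- c("id", "r_free_initial", "r_free_final", "clashscore",
            "ligand_occupancy")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("QC table missing column(s): ",
                         paste(miss, collapse = ", "))
  mrow <- function(id) meta[match(id, meta$id), , drop = FALSE]
  h <- mrow(pair$holo_id); a <- mrow(pair$apo_id)
  reasons <- character(0)

  ca <- matched_calpha(apo, holo)
  fit <- kabsch_superpose(ca$ref, ca$mov)
  if (fit$rmsd > thresholds$global_rmsd) reasons <- c(reasons, "global_rmsd")

  bs_rmsd <- NA_real_
  ligs <- qualifying_ligands(holo)
  if (length(ligs)) {
    bs <- binding_site_residues(holo, ligs[[1]], cutoff = binding_cutoff)
    sel <- ca$keys %in% bs
    if (sum(sel) >= 1) {
      fitted <- sweep(ca$mov %*% fit$rotation, 2, fit$translation, "+")
      bs_rmsd <- sqrt(mean(rowSums((fitted[sel, , drop = FALSE] -
                                      ca$ref[sel, , drop = FALSE])^2)))
      if (bs_rmsd > thresholds$binding_site_rmsd)
        reasons <- c(reasons, "binding_site_rmsd")
    }
  }
  for (m in list(h, a))
    if (!is.na(m$clashscore) && m$clashscore > thresholds$clashscore) {
      reasons <- c(reasons, "clashscore"); break
    }
  if (!is.na(h$r_free_final) && !is.na(a$r_free_final) &&
      abs(h$r_free_final - a$r_free_final) > thresholds$rfree_gap)
    reasons <- c(reasons, "rfree_gap")
  for (m in list(h, a))
    if (!is.na(m$r_free_final) && !is.na(m$r_free_initial) &&
        m$r_free_final - m$r_free_initial > thresholds$rfree_increase) {
      reasons <- c(reasons, "rfree_increase"); break
    }
  if (!is.na(h$ligand_occupancy) &&
      h$ligand_occupancy < thresholds$min_ligand_occ)
    reasons <- c(reasons, "ligand_occupancy")

  pair$qc_status <- if (length(reasons)) "fail" else "pass"
  pair$qc_reasons <- paste(reasons, collapse = ";")
  pair$global_rmsd <- fit$rmsd
  pair$binding_site_rmsd <- bs_rmsd
  pair
}
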