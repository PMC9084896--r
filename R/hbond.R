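# Geometric hydrogen-bond detection on altloc-split single-conformer models
# (HBplus-style criteria: H...acceptor distance < 3.2 A, D-H...A angle >=
# 90 degrees), with occupancy weighting and binding-site normalization for
# multiconformer structures.

# flat protein atom table of a single-conformer model
flat_protein_atoms <- function(model) {
  tabs <- lapply(model$residues, function(res) {
    at <- res$conformers[[1]]$atoms
    data.frame(residue = residue_key(res), aa = res$aa, name = at$name,
               element = at$element, altloc = at$altloc,
               occupancy = ifelse(at$altloc == "", at$occupancy,
                                  res$conformers[[1]]$occupancy),
               x = at$x, y = at$y, z = at$z,
               sidechain = is_sidechain_name(at$name),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, tabs)
}

#' Detect hydrogen bonds in a single-conformer model
#'
#' Explicit-hydrogen geometric criteria: a hydrogen covalently attached to a
#' nitrogen, oxygen or sulfur donor forms a bond with an acceptor (any
#' oxygen, or a nitrogen/sulfur carrying no hydrogen) when the
#' hydrogen-acceptor distance is below `h_a_cutoff` and the
#' donor-hydrogen-acceptor angle is at least `min_dha`. Intra-residue pairs
#' and covalently bonded pairs are excluded; bonds between two main-chain
#' atoms are discarded, keeping side-chain/side-chain and
#' side-chain/main-chain bonds only. Each bond is weighted by the lower of
#' the donor and acceptor occupancies.
#'
#' @param model A single-conformer [structure_model()] (e.g. one element of
#'   [split_by_altloc()]).
#' @param h_a_cutoff Hydrogen-acceptor distance cutoff, Angstrom (default
#'   3.2, exclusive).
#' @param min_dha Minimum donor-hydrogen-acceptor angle, degrees (default
#'   90).
#' @return data.frame with donor/hydrogen/acceptor identifiers, distance,
#'   angle, weight and class ("sidechain-sidechain" or
#'   "sidechain-mainchain").
#' @export
detect_hbonds <- function(model, h_a_cutoff = 3.2, min_dha = 90) {
  at <- flat_protein_atoms(model)
  hyd <- which(at$element %in% c("H", "D"))
  if (!length(hyd))
    stop("model has no hydrogens: generate explicit hydrogens first")
  xyz <- cbind(at$x, at$y, at$z)

  # attach each hydrogen to the nearest heavy atom of its residue (< 1.3 A)
  parent <- rep(NA_integer_, length(hyd))
  for (k in seq_along(hyd)) {
    i <- hyd[k]
    same <- which(at$residue == at$residue[i] & !(at$element %in% c("H", "D")))
    if (!length(same)) next
    d2 <- rowSums(sweep(xyz[same, , drop = FALSE], 2, xyz[i, ])^2)
    j <- same[which.min(d2)]
    if (min(d2) < 1.3^2) parent[k] <- j
  }
  keep <- !is.na(parent) & at$element[parent] %in% c("N", "O", "S")
  hyd <- hyd[keep]; parent <- parent[keep]

  has_h <- unique(stats::na.omit(parent))
  acc <- which((at$element == "O") |
                 (at$element %in% c("N", "S") &
                    !(seq_len(nrow(at)) %in% has_h)))

  out <- list()
  for (k in seq_along(hyd)) {
    i <- hyd[k]; d <- parent[k]
    cand <- acc[at$residue[acc] != at$residue[i]]
    if (!length(cand)) next
    dist <- sqrt(rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[i, ])^2))
    sel <- which(dist < h_a_cutoff & dist > 1.2)  # > 1.2 A: not covalent
    for (s in sel) {
      a <- cand[s]
      v1 <- xyz[d, ] - xyz[i, ]
      v2 <- xyz[a, ] - xyz[i, ]
      ang <- acos(pmin(pmax(sum(v1 * v2) / (vnorm(v1) * vnorm(v2)), -1), 1)) *
        180 / pi
      if (ang < min_dha) next
      if (sqrt(sum((xyz[d, ] - xyz[a, ])^2)) < 1.8) next  # bonded pair
      n_side <- at$sidechain[d] + at$sidechain[a]
      if (n_side == 0) next  # mainchain-mainchain discarded
      out[[length(out) + 1L]] <- data.frame(
        donor_res = at$residue[d], donor_atom = at$name[d],
        donor_altloc = at$altloc[d], hydrogen = at$name[i],
        acceptor_res = at$residue[a], acceptor_atom = at$name[a],
        acceptor_altloc = at$altloc[a],
        h_a_distance = dist[s], dha_angle = ang,
        weight = min(at$occupancy[d], at$occupancy[a]),
        class = if (n_side == 2) "sidechain-sidechain"
                else "sidechain-mainchain",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(donor_res = character(0), donor_atom = character(0),
                      donor_altloc = character(0), hydrogen = character(0),
                      acceptor_res = character(0),
                      acceptor_atom = character(0),
                      acceptor_altloc = character(0),
                      h_a_distance = numeric(0), dha_angle = numeric(0),
                      weight = numeric(0), class = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Occupancy-weighted hydrogen bonds per residue in a region
#'
#' Runs [detect_hbonds()] on every altloc split of a multiconformer model,
#' deduplicates bonds across splits by their donor/acceptor atom identity
#' (ignoring altloc), assigns each unique bond either the maximum
#' (default) or the sum of its per-split weights, and normalizes the total
#' weight of bonds touching the region by the number of region residues.
#'
#' @param model A multiconformer [structure_model()] with explicit
#'   hydrogens.
#' @param region Character vector of residue ids ("chain:seqnum");
#'   non-empty.
#' @param h_a_cutoff,min_dha Detection criteria (see [detect_hbonds()]).
#' @param dedup `"max"` (default) or `"sum"` across altloc splits.
#' @return Weighted hydrogen bonds per region residue (numeric scalar).
#' @export
weighted_hbond_count <- function(model, region, h_a_cutoff = 3.2,
                                 min_dha = 90, dedup = c("max", "sum")) {
  dedup <- match.arg(dedup)
  if (!length(region)) stop("region must be non-empty")
  splits <- split_by_altloc(model)
  bonds <- do.call(rbind, lapply(splits, detect_hbonds,
                                 h_a_cutoff = h_a_cutoff, min_dha = min_dha))
  if (is.null(bonds) || !nrow(bonds)) return(0)
  key <- paste(bonds$donor_res, bonds$donor_atom,
               bonds$acceptor_res, bonds$acceptor_atom)
  agg <- if (dedup == "max") tapply(bonds$weight, key, max)
         else tapply(bonds$weight, key, sum)
  first <- bonds[!duplicated(key), , drop = FALSE]
  first$weight <- as.numeric(agg[paste(first$donor_res, first$donor_atom,
                                       first$acceptor_res,
                                       first$acceptor_atom)])
  touch <- first$donor_res %in% region | first$acceptor_res %in% region
  sum(first$weight[touch]) / length(region)
}
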