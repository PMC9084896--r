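# Shared fixtures: all built in code, no files.

# two-conformer residue whose side-chain centroids sit `d` Angstrom apart
# (one side-chain heavy atom per conformer)
two_centroid_residue <- function(d = 1, q = c(0.5, 0.5), b = c(10, 20),
                                 aa = "SER") {
  mk <- function(lab, x, occ, bval) conformer(lab, occ, atom_table(
    name = c("CA", "CB"), element = "C", x = c(0, x), y = 0, z = 0,
    occupancy = c(1, occ), b = c(12, bval), altloc = c("", lab)))
  multiconf_residue("A", 1, aa, list(mk("A", 0, q[1], b[1]),
                                     mk("B", d, q[2], b[2])))
}

# minimal HETATM group with n carbon heavy atoms in a row
hetero_group <- function(n, aa = "LIG", occupancy = 1, b = 15, seqnum = 200,
                         origin = c(0, 0, 0)) {
  at <- atom_table(name = paste0("C", seq_len(n)), element = "C",
                   x = origin[1] + 1.5 * (seq_len(n) - 1), y = origin[2],
                   z = origin[3], occupancy = occupancy, b = b,
                   is_hetero = TRUE)
  multiconf_residue("A", seqnum, aa, hetero = TRUE,
                    conformers = list(conformer("", occupancy, at)))
}

# one-row structure metadata for match_pairs tests
meta_row <- function(id, role, resolution, space_group = "P 1",
                     cell = c(50, 60, 70, 90, 90, 90),
                     sequence = "SSSSSSSSSS") {
  data.frame(id = id, role = role, space_group = space_group,
             a = cell[1], b = cell[2], c = cell[3], alpha = cell[4],
             beta = cell[5], gamma = cell[6], resolution = resolution,
             sequence = sequence, stringsAsFactors = FALSE)
}

# small planted synthetic pair (5-s build), cached across tests
small_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(n_pairs = 1)
      cache <<- build_pair(spec, "fix1", x_p = 0.03, d_p = 0.015,
                           resolution = 1.6, preorganized = FALSE,
                           category = "remodeled_holo_loss")
    }
    cache
  }
})

fast_config <- function(...) {
  pipeline_config(sasa_points = 240, sasa_scope = "distant",
                  hbonds = FALSE, ...)
}
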