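# Role classification, pair matching and QC filtering.

test_that("ligand size and additive rules classify apo/holo", {
  prot <- list(multiconf_residue("A", 1, "SER", list(
    conformer("", 1, atom_table("CA", "C", 0, 0, 0)))))
  m19 <- structure_model("a", prot, ligands = list(hetero_group(19)))
  expect_equal(classify_role(m19), "holo")
  m9 <- structure_model("b", prot, ligands = list(hetero_group(9)))
  expect_equal(classify_role(m9), "apo")
  m10 <- structure_model("c", prot, ligands = list(hetero_group(10)))
  expect_equal(classify_role(m10), "holo")  # threshold boundary inclusive
  madd <- structure_model("d", prot, ligands = list(hetero_group(12, aa = "GOL")))
  expect_equal(classify_role(madd), "apo")  # additive exclusion
})

test_that("match_pairs applies the resolution boundary as <= 0.1", {
  metas <- rbind(meta_row("h1", "holo", 1.50), meta_row("a1", "apo", 1.58))
  expect_equal(nrow(match_pairs(metas)), 1)
  metas2 <- rbind(meta_row("h1", "holo", 1.50), meta_row("a1", "apo", 1.65))
  expect_equal(nrow(match_pairs(metas2)), 0)
  metas3 <- rbind(meta_row("h1", "holo", 1.50), meta_row("a1", "apo", 1.60))
  expect_equal(nrow(match_pairs(metas3)), 1)  # exactly 0.1 accepted
  expect_equal(nrow(match_pairs(metas[0, ])), 0)
})

test_that("one apo per holo by minimal resolution difference", {
  metas <- rbind(meta_row("h1", "holo", 1.50),
                 meta_row("a_far", "apo", 1.58),
                 meta_row("a_near", "apo", 1.52))
  p <- match_pairs(metas)
  expect_equal(p$apo_id, "a_near")
  expect_equal(p$delta_resolution, 0.02)
  # tie -> lexicographically smallest apo id
  metas2 <- rbind(meta_row("h1", "holo", 1.50),
                  meta_row("zz", "apo", 1.52), meta_row("aa", "apo", 1.48))
  expect_equal(match_pairs(metas2)$apo_id, "aa")
})

test_that("sequence matching allows up to five trimmed terminal residues", {
  s <- "ABCDEFGHIJKLMNOP"
  m1 <- rbind(meta_row("h", "holo", 1.5, sequence = s),
              meta_row("a", "apo", 1.5, sequence = substr(s, 6, 16)))
  expect_equal(nrow(match_pairs(m1)), 1)  # first five trimmed
  m2 <- rbind(meta_row("h", "holo", 1.5, sequence = s),
              meta_row("a", "apo", 1.5, sequence = substr(s, 7, 16)))
  expect_equal(nrow(match_pairs(m2)), 0)  # six needed -> reject
})

test_that("kabsch superposition is exact on congruent point sets", {
  set.seed(7)
  x <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch_superpose(x, x)$rmsd, 0, tolerance = 1e-9)
  shifted <- sweep(x, 2, c(5, 0, 0), "+")
  expect_lt(kabsch_superpose(x, shifted)$rmsd, 1e-9)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  fit <- kabsch_superpose(x, x %*% rot + 2)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear|degenerate")
})

test_that("kabsch rmsd for a single displaced atom matches the oracle", {
  set.seed(11)
  x <- matrix(rnorm(30, sd = 4), ncol = 3)
  y <- x
  y[1, ] <- y[1, ] + c(1, 0, 0)
  fit <- kabsch_superpose(x, y)
  expect_lte(fit$rmsd, sqrt(1 / 10) + 1e-9)
  # independent oracle: bio3d's fitted rmsd on the same points
  oracle <- bio3d::rmsd(as.vector(t(x)), as.vector(t(y)), fit = TRUE)
  expect_equal(fit$rmsd, oracle, tolerance = 1e-3)
})

test_that("qc_filter accumulates the documented failure reasons", {
  pr <- small_pair()
  meta <- data.frame(id = c("fix1_holo", "fix1_apo"),
                     r_free_initial = c(0.18, 0.18),
                     r_free_final = c(0.19, 0.19),
                     clashscore = c(3, 3), ligand_occupancy = c(1, NA),
                     stringsAsFactors = FALSE)
  pair <- data.frame(holo_id = "fix1_holo", apo_id = "fix1_apo",
                     stringsAsFactors = FALSE)
  ok <- qc_filter(pair, pr$apo, pr$holo, meta)
  expect_equal(ok$qc_status, "pass")
  expect_equal(ok$qc_reasons, "")
  expect_lt(ok$global_rmsd, 1e-6)  # identical backbones

  # non-rigid distortion of the apo -> global RMSD failure
  apo_big <- pr$apo
  for (i in seq_along(apo_big$residues))
    for (k in seq_along(apo_big$residues[[i]]$conformers)) {
      at <- apo_big$residues[[i]]$conformers[[k]]$atoms
      at[, c("x", "y", "z")] <- at[, c("x", "y", "z")] * 1.2
      apo_big$residues[[i]]$conformers[[k]]$atoms <- at
    }
  bad <- qc_filter(pair, apo_big, pr$holo, meta)
  expect_match(bad$qc_reasons, "global_rmsd")

  # metadata-driven failures
  meta2 <- meta
  meta2$clashscore[2] <- 20
  meta2$ligand_occupancy[1] <- 0.10
  meta2$r_free_final[1] <- 0.26  # gap 0.07 and increase 0.08
  bad2 <- qc_filter(pair, pr$apo, pr$holo, meta2)
  for (r in c("clashscore", "ligand_occupancy", "rfree_gap",
              "rfree_increase"))
    expect_match(bad2$qc_reasons, r)
  expect_error(qc_filter(pair, pr$apo, pr$holo, meta[, 1:3]), "column")
})
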