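# Order parameters, RMSF, B-factor aggregation and conformer counting.

test_that("angular order parameter matches its closed form", {
  expect_equal(s2_angular(rbind(c(1, 0, 0)), 1), 1.0)
  expect_equal(s2_angular(rbind(c(1, 0, 0), c(0, 1, 0)), c(0.5, 0.5)), 0.25)
  expect_equal(s2_angular(rbind(c(1, 0, 0), c(0, 1, 0)), c(0.7, 0.3)), 0.37)
  # ideal-geometry 120-degree chi1 jump: cos Theta = 1/9 - 4/9 = -1/3
  th <- acos(-1 / 3)
  v2 <- c(cos(th), sin(th), 0)
  expect_equal(s2_angular(rbind(c(1, 0, 0), v2), c(0.5, 0.5)), 1 / 3,
               tolerance = 1e-12)
  expect_error(s2_angular(rbind(c(0, 0, 0)), 1), "zero-length")
})

test_that("angular order parameter is invariant under rotation and
           occupancy-preserving permutation", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:4, 1)
    u <- matrix(rnorm(3 * n), ncol = 3)
    q <- runif(n); q <- q / sum(q)
    s <- s2_angular(u, q)
    qr_rot <- qr.Q(qr(matrix(rnorm(9), 3)))
    expect_equal(s2_angular(u %*% qr_rot, q), s, tolerance = 1e-10)
    p <- sample(n)
    expect_equal(s2_angular(u[p, ], q[p]), s, tolerance = 1e-12)
  }
})

test_that("harmonic order parameter follows the stated formula and clips", {
  expect_equal(s2_ortho(0, 0), 1.0)
  expect_equal(s2_ortho(10, 10, r = 1.09),
               1 - (3 / (16 * pi^2)) * 20 / 1.09^2)
  expect_equal(round(s2_ortho(10, 10, r = 1.09), 3), 0.680)
  expect_equal(s2_ortho(60, 60, r = 1.09), 0)  # clip floor
  expect_error(s2_ortho(10, 10, r = 0), "r must be > 0")
  # strictly decreasing until the clip floor
  b <- seq(0, 30, by = 1)
  v <- s2_ortho(b, b)
  expect_true(all(diff(v[v > 0]) < 0))
})

test_that("resolution normalization scales by b_calpha / (c * resolution)", {
  expect_equal(normalize_s2_ortho(0.8, 16, 1.6), 0.8)
  expect_equal(normalize_s2_ortho(0.8, 8, 1.6), 0.4)
  expect_equal(normalize_s2_ortho(0.8, 40, 2.0), 1.0)  # clip ceiling
  expect_error(normalize_s2_ortho(0.8, 16, 0), "resolution")
  cfg <- norm_config(clip = FALSE)
  expect_equal(normalize_s2_ortho(0.8, 40, 2.0, cfg), 1.6)
})

test_that("RMSF hand cases and invariants hold", {
  expect_equal(side_chain_rmsf(two_centroid_residue(1, c(0.5, 0.5))), 0.5)
  expect_equal(side_chain_rmsf(two_centroid_residue(1, c(0.8, 0.2))), 0.4)
  single <- multiconf_residue("A", 1, "SER", list(conformer("", 1,
    atom_table(c("CA", "CB"), "C", x = c(0, 1), y = 0, z = 0))))
  expect_equal(side_chain_rmsf(single), 0)
  gly <- multiconf_residue("A", 1, "GLY", list(conformer("", 1,
    atom_table("CA", "C", 0, 0, 0))))
  expect_true(is.na(side_chain_rmsf(gly)))
})

test_that("residue B-factors are occupancy-weighted over the scope", {
  res <- two_centroid_residue(1, c(0.6, 0.4), b = c(10, 20))
  expect_equal(residue_bfactor(res, "sidechain"), 14)
  # scope 'all' mixes in the backbone CA at B = 12 (per conformer mean)
  expect_equal(residue_bfactor(res, "all"), 0.6 * 11 + 0.4 * 16)
  flat <- multiconf_residue("A", 1, "SER", list(conformer("", 1,
    atom_table(c("CA", "CB"), "C", x = c(0, 1), y = 0, z = 0, b = 12))))
  expect_equal(residue_bfactor(flat, "all"), 12)
})

test_that("conformer_count follows the side-chain altloc rule", {
  expect_equal(conformer_count(two_centroid_residue()), 2L)
  single <- multiconf_residue("A", 1, "SER", list(conformer("", 1,
    atom_table(c("CA", "CB"), "C", x = c(0, 1), y = 0, z = 0))))
  expect_equal(conformer_count(single), 1L)
  # backbone-only altlocs do not count as side-chain conformers
  bb_alt <- multiconf_residue("A", 1, "SER", list(
    conformer("A", 0.5, atom_table(c("CA", "CB"), "C", x = c(0, 1), y = 0,
                                   z = 0, altloc = c("A", ""))),
    conformer("B", 0.5, atom_table(c("CA", "CB"), "C", x = c(0.1, 1), y = 0,
                                   z = 0, altloc = c("B", "")))))
  expect_equal(conformer_count(bb_alt), 1L)
})

test_that("residue metrics compose s2_calc and respect exclusions", {
  pr <- small_pair()
  res <- pr$apo$residues[[10]]  # flexible two-conformer Ser
  m <- residue_metrics(res, resolution = 1.6)
  expect_true(m$computable)
  expect_equal(m$s2_calc, m$s2_ortho_norm * m$s2_ang, tolerance = 1e-12)
  expect_gte(m$s2_calc, 0); expect_lte(m$s2_calc, 1)

  gly <- multiconf_residue("A", 1, "GLY", list(conformer("", 1,
    atom_table(c("N", "CA", "C"), c("N", "C", "C"), x = 0:2, y = 0, z = 0))))
  expect_false(residue_metrics(gly, 1.6)$computable)
  pro <- multiconf_residue("A", 1, "PRO", list(conformer("", 1,
    atom_table(c("N", "CA", "CB", "CG"), c("N", "C", "C", "C"),
               x = 0:3, y = 0, z = 0))))
  expect_false(residue_metrics(pro, 1.6)$computable)
  # Ala has no chi1: angular component pinned to 1
  ala <- multiconf_residue("A", 1, "ALA", list(conformer("", 1,
    atom_table(c("N", "CA", "CB"), c("N", "C", "C"), x = 0:2, y = 0, z = 0,
               b = 8))))
  ma <- residue_metrics(ala, 1.6)
  expect_true(ma$computable)
  expect_equal(ma$s2_ang, 1.0)
  # missing gamma atom -> not computable, no error
  stub <- multiconf_residue("A", 1, "SER", list(conformer("", 1,
    atom_table(c("N", "CA", "CB"), c("N", "C", "C"), x = 0:2, y = 0, z = 0))))
  expect_false(residue_metrics(stub, 1.6)$computable)
})

test_that("calibration recovers the true normalization constant", {
  set.seed(3)
  n <- 40
  c_true <- 10
  b_ca <- runif(n, 15, 30)
  s2_true <- runif(n, 0.2, 0.7)
  # lower-resolution arm: raw values carry the resolution/B distortion the
  # normalization is meant to undo; reference arm: face-value s2
  low <- data.frame(s2_raw = pmin(s2_true * (c_true * 1.8) / b_ca +
                                    rnorm(n, 0, 0.01), 1),
                    b_calpha = b_ca, resolution = 1.8)
  ref <- data.frame(s2_raw = s2_true + rnorm(n, 0, 0.01),
                    b_calpha = b_ca, resolution = 1.2)
  fit <- calibrate_normalization(low, ref, c_grid = seq(2, 30, 1))
  expect_lte(abs(fit$c - c_true), 1)
  # identical pre-normalized series: slope 1, rmse ~0, smallest c wins
  same <- data.frame(s2_raw = s2_true, b_calpha = 10, resolution = 1.0)
  fit2 <- calibrate_normalization(same, same,
                                  c_grid = c(12, 11, 15),
                                  cfg = norm_config(clip = FALSE),
                                  normalize_reference = TRUE)
  expect_equal(fit2$c, 11)
  expect_equal(max(abs(fit2$grid$slope - 1)), 0, tolerance = 1e-9)
  degenerate <- data.frame(s2_raw = rep(0.5, 5), b_calpha = 10,
                           resolution = 1)
  expect_error(calibrate_normalization(degenerate, degenerate), "degenerate")
})
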