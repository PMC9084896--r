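# Pair deltas, matched controls, residual regression, bootstrap slopes,
# rank tests, quartile comparison, category summaries and clustering.

toy_deltas <- function(pair_id = "p1") {
  data.frame(pair_id = pair_id,
             residue = paste0("A:", 1:8),
             aa = c("SER", "SER", "SER", "VAL", "SER", "SER", "VAL", "SER"),
             delta_s2 = c(0.05, 0.01, -0.02, 0.00, 0.03, -0.01, 0.02, 0.04),
             delta_b = 0, delta_rmsf = 0,
             delta_nconf = c(-1, 0, 0, 0, 1, 0, 0, 0),
             rotamer_category = c("no_change", "no_change", "distinct",
                                  "no_change", "no_change", "no_change",
                                  "remodeled_holo_loss", "no_change"),
             environment = c("binding_site", "binding_site",
                             "distant_buried", "distant_buried",
                             "distant_exposed", "other", "other", "other"),
             is_exposed = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE,
                            TRUE),
             stringsAsFactors = FALSE)
}

test_that("pair deltas carry the holo-minus-apo sign and drop unmatched
           residues", {
  pr <- small_pair()
  cfg <- fast_config()
  out <- run_pair(pr$apo, pr$holo, "LIG", cfg, "fix1")
  tr <- pr$truth_residues
  hit <- match(paste0("A:", tr$seqnum), out$deltas$residue)
  expect_equal(out$deltas$delta_s2[hit], tr$delta_s2, tolerance = 1e-9)
  # identical metrics give all-zero deltas
  same <- pair_residue_deltas(out$metrics_apo, out$metrics_apo,
                              out$environment, pair_id = "same")
  expect_true(all(same$delta_s2 == 0))
  # apo-only residue absent from the table
  apo_metrics <- out$metrics_apo
  holo_metrics <- out$metrics_holo[-1, ]
  d <- pair_residue_deltas(apo_metrics, holo_metrics, out$environment)
  expect_false("A:1" %in% d$residue)
})

test_that("pair summary residual is recomputable from its components", {
  s <- pair_summary(toy_deltas())
  expect_equal(s$mean_delta_s2_bs, 0.03)
  expect_equal(s$mean_delta_s2_distant_buried, -0.01)
  expect_equal(s$residual_buried,
               s$mean_delta_s2_distant_buried - s$mean_delta_s2_bs,
               tolerance = 1e-12)
})

test_that("matched controls draw same-type same-exposure residues outside
           the binding site", {
  set.seed(1)
  d <- toy_deltas()
  v <- matched_control_delta(d, n_draws = 50)
  draws <- attr(v, "draws")
  expect_length(draws, 50)
  # both binding-site residues are exposed Ser: the only matches are the
  # exposed Ser residues outside the site (A:5, A:6, A:8)
  pool_vals <- d$delta_s2[d$residue %in% c("A:5", "A:6", "A:8")]
  expect_true(all(draws >= min(pool_vals) - 1e-12 &
                    draws <= max(pool_vals) + 1e-12))
  expect_error(matched_control_delta(d[d$environment != "binding_site", ]),
               "binding site")
  # deterministic under a fixed seed
  set.seed(99); v1 <- matched_control_delta(d, n_draws = 20)
  set.seed(99); v2 <- matched_control_delta(d, n_draws = 20)
  expect_identical(as.numeric(v1), as.numeric(v2))
})

test_that("residual regression recovers exact linear relations", {
  x <- seq(-0.02, 0.08, length.out = 20)
  sm <- data.frame(mean_delta_s2_bs = x, residual_buried = -0.5 * x,
                   residual_all = -0.5 * x)
  fit <- residual_regression(sm)
  expect_equal(fit$slope, -0.5, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  sm$mean_delta_s2_bs <- 0.03
  expect_error(residual_regression(sm), "variance")
  expect_error(residual_regression(sm[1:2, ]), "3 pairs")
})

test_that("rank tests behave on shifted and identical samples", {
  set.seed(2)
  shifted <- paired_test(rnorm(15) + 1)
  expect_lt(shifted$p, 0.01)
  zero <- paired_test(rep(0, 10))
  expect_true(zero$undefined)
  expect_true(is.na(zero$p))
  x <- 1:10
  gt <- group_test(x, x)
  expect_equal(as.numeric(gt$U), 10 * 10 / 2)  # midranks on identical groups
  expect_gt(gt$p, 0.9)
})

test_that("quartile comparison uses floor(n/4) groups and Bonferroni", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8)
  key <- c(10, 20, 30, 40, 50, 60, 70, 80)
  qc <- quartile_compare(vals, key)
  expect_equal(qc$n_per_quartile, 2)  # n = 8 -> groups of 2
  expect_equal(qc$median_low, 1.5)
  expect_equal(qc$median_high, 7.5)
  expect_equal(qc$threshold, 0.005)
  expect_error(quartile_compare(vals, rep(1, 8)), "variation")
  expect_error(quartile_compare(vals[1:4], key[1:4]), "at least 8")
})

test_that("category summaries count fractions exactly on a toy table", {
  d <- rbind(toy_deltas("p1"), toy_deltas("p2"))
  d$rotamer_category[d$pair_id == "p2" &
                       d$environment == "binding_site"] <- "no_change"
  d$delta_nconf[d$pair_id == "p2"] <- 0
  s <- summarize_categories(d)
  expect_equal(s$n_pairs, 2)
  expect_equal(unname(s$conformer_change_fractions[c("loss", "same")]),
               c(0.5, 0.5))
  expect_equal(s$preorganized_fraction, 1.0)  # bs rows all no_change
  expect_equal(sum(s$rotamer_fractions), 1, tolerance = 1e-12)
  all_same <- toy_deltas()
  all_same$rotamer_category <- "no_change"
  expect_equal(summarize_categories(all_same)$rotamer_fractions[["no_change"]],
               1.0)
})

test_that("clustering keeps constant blocks contiguous and follows
           permutations", {
  set.seed(8)
  mat <- rbind(matrix(0.2 + rnorm(40, sd = 0.005), nrow = 4),
               matrix(-0.2 + rnorm(40, sd = 0.005), nrow = 4))
  cl <- cluster_delta_matrix(mat)
  ord <- cl$row_order
  block <- ord <= 4
  expect_true(all(diff(which(block)) == 1) || all(diff(which(!block)) == 1))
  one <- cluster_delta_matrix(mat[1, , drop = FALSE])
  expect_equal(one$row_order, 1)
  # permuted input clusters into the same groups
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  cl2 <- cluster_delta_matrix(mat[perm, ])
  groups <- perm[cl2$row_order] <= 4
  expect_true(all(diff(which(groups)) == 1) || all(diff(which(!groups)) == 1))
  bad <- mat; bad[1, 1] <- NA
  expect_error(cluster_delta_matrix(bad), "impute")
})
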