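# Pair-level and cohort-level comparative statistics: holo-minus-apo
# residue deltas, matched controls, the residual regression of distant
# versus binding-site changes, bootstrap slope comparison, rank tests,
# ligand quartile comparisons, category summaries and hierarchical
# clustering of delta matrices.

#' Per-residue holo-minus-apo deltas for one pair
#'
#' Joins the apo and holo metric tables on residue identity and returns one
#' row per residue computable in both structures, with the holo-minus-apo
#' sign convention throughout, the residue's spatial environment and its
#' rotamer-change category. Residues present in only one structure (e.g.
#' trimmed termini) are dropped.
#'
#' @param apo_metrics,holo_metrics Tables from [structure_metrics()].
#' @param environment Table from [environment_table()] (holo structure).
#' @param rotamer_categories Optional named character vector of categories
#'   keyed by residue id ("chain:seqnum").
#' @param pair_id Identifier stored in the output.
#' @return data.frame with pair_id, residue id, aa, delta_s2, delta_b,
#'   delta_rmsf, delta_nconf, rotamer_category, environment, is_exposed.
#' @export
pair_residue_deltas <- function(apo_metrics, holo_metrics, environment,
                                rotamer_categories = NULL, pair_id = NA) {
  key <- function(tab) paste0(tab$chain, ":", tab$seqnum, tab$icode)
  ka <- key(apo_metrics); kh <- key(holo_metrics)
  common <- intersect(ka, kh)
  a <- apo_metrics[match(common, ka), , drop = FALSE]
  h <- holo_metrics[match(common, kh), , drop = FALSE]
  ok <- a$computable & h$computable
  a <- a[ok, , drop = FALSE]; h <- h[ok, , drop = FALSE]
  common <- common[ok]
  ke <- key(environment)
  env <- environment[match(common, ke), , drop = FALSE]
  out <- data.frame(pair_id = pair_id, residue = common, aa = h$aa,
                    delta_s2 = h$s2_calc - a$s2_calc,
                    delta_b = h$mean_b_sidechain - a$mean_b_sidechain,
                    delta_rmsf = h$rmsf - a$rmsf,
                    delta_nconf = h$n_conformers - a$n_conformers,
                    rotamer_category = NA_character_,
                    environment = env$environment,
                    is_exposed = env$is_exposed,
                    stringsAsFactors = FALSE)
  if (!is.null(rotamer_categories)) {
    hit <- match(common, names(rotamer_categories))
    out$rotamer_category <- as.character(rotamer_categories[hit])
  }
  out
}

#' Summarize one pair's deltas
#'
#' @param deltas Table from [pair_residue_deltas()].
#' @param hbond_delta Optional holo-minus-apo weighted hydrogen bonds per
#'   binding-site residue.
#' @return One-row data.frame with pair_id, mean binding-site delta,
#'   mean distant-buried delta, mean distant (all) delta, the residuals
#'   (distant minus binding site), residue counts and hbond_delta.
#' @export
pair_summary <- function(deltas, hbond_delta = NA_real_) {
  m <- function(sel) if (any(sel, na.rm = TRUE))
    mean(deltas$delta_s2[which(sel)], na.rm = TRUE) else NA_real_
  bs <- deltas$environment == "binding_site"
  db <- deltas$environment == "distant_buried"
  da <- deltas$environment %in% c("distant_buried", "distant_exposed")
  mean_bs <- m(bs); mean_db <- m(db); mean_dall <- m(da)
  data.frame(pair_id = deltas$pair_id[1],
             mean_delta_s2_bs = mean_bs,
             mean_delta_s2_distant_buried = mean_db,
             mean_delta_s2_distant_all = mean_dall,
             residual_buried = mean_db - mean_bs,
             residual_all = mean_dall - mean_bs,
             n_binding_site = sum(bs, na.rm = TRUE),
             n_distant_buried = sum(db, na.rm = TRUE),
             hbond_delta = hbond_delta,
             stringsAsFactors = FALSE)
}

#' Matched-control mean delta for one pair
#'
#' Builds control sets matching the binding site in number, residue type
#' and solvent-exposure class: for each binding-site residue, one
#' non-binding-site residue of the same amino acid and exposure class is
#' sampled without replacement; the mean delta of the control set is
#' averaged over `n_draws` repetitions. Binding-site residues with no
#' available match are skipped (recorded in the `n_skipped` attribute).
#'
#' @param deltas Table from [pair_residue_deltas()].
#' @param n_draws Number of control draws (default 100).
#' @return Mean control delta (numeric) with attributes `draws` and
#'   `n_skipped`. Randomness uses the session RNG; seed it for
#'   reproducibility.
#' @export
matched_control_delta <- function(deltas, n_draws = 100) {
  bs <- deltas[deltas$environment == "binding_site", , drop = FALSE]
  pool <- deltas[deltas$environment != "binding_site", , drop = FALSE]
  if (!nrow(bs)) stop("empty binding site")
  draws <- vapply(seq_len(n_draws), function(d) {
    used <- logical(nrow(pool))
    vals <- numeric(0)
    for (i in seq_len(nrow(bs))) {
      cand <- which(!used & pool$aa == bs$aa[i] &
                      (pool$is_exposed %in% bs$is_exposed[i]))
      if (!length(cand)) next
      j <- if (length(cand) == 1) cand else sample(cand, 1)
      used[j] <- TRUE
      vals <- c(vals, pool$delta_s2[j])
    }
    if (!length(vals)) NA_real_ else mean(vals)
  }, 0)
  n_skip <- sum(vapply(seq_len(nrow(bs)), function(i)
    !any(pool$aa == bs$aa[i] & (pool$is_exposed %in% bs$is_exposed[i])),
    TRUE))
  out <- mean(draws, na.rm = TRUE)
  attr(out, "draws") <- draws
  attr(out, "n_skipped") <- n_skip
  out
}

#' Residual regression of distant versus binding-site changes
#'
#' Ordinary least squares of the per-pair residual (mean distant delta
#' minus mean binding-site delta) on the mean binding-site delta, with a
#' two-sided t-test on the slope.
#'
#' @param summaries Table of [pair_summary()] rows.
#' @param subset `"distant_buried"` (default; residual restricted to
#'   distant residues with RASA below the exposure threshold) or
#'   `"distant_all"`.
#' @return List with slope, intercept, r2, p (two-sided), se, n.
#' @export
residual_regression <- function(summaries,
                                subset = c("distant_buried", "distant_all")) {
  subset <- match.arg(subset)
  y <- if (subset == "distant_buried") summaries$residual_buried
       else summaries$residual_all
  x <- summaries$mean_delta_s2_bs
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 pairs with finite values")
  if (stats::var(x) < 1e-14) stop("zero variance in binding-site deltas")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits trip a perfect-fit note
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       p = sm$coefficients[2, 4],
       se = sm$coefficients[2, 2],
       n = length(x))
}

#' Bootstrap comparison of residual-regression slopes
#'
#' Resamples each cohort's pairs with replacement, refits the residual
#' regression per replicate, and compares the two bootstrap slope
#' distributions with a z statistic
#' \eqn{z = (\bar b_A - \bar b_B) / \sqrt{s_A^2 + s_B^2}} and a two-sided
#' normal p-value.
#'
#' @param cohort_a,cohort_b Summary tables (as for
#'   [residual_regression()]).
#' @param n_boot Bootstrap replicates per cohort (default 1000, >= 2).
#' @param subset Passed to [residual_regression()].
#' @return List with slope_means, slope_sds, z, p. Seed the session RNG
#'   for reproducibility.
#' @export
bootstrap_slope_compare <- function(cohort_a, cohort_b, n_boot = 1000,
                                    subset = "distant_buried") {
  if (n_boot < 2) stop("n_boot must be >= 2")
  boot_slopes <- function(sm) {
    n <- nrow(sm)
    if (n < 3) stop("both cohorts need at least 3 pairs")
    vapply(seq_len(n_boot), function(b) {
      res <- tryCatch(
        residual_regression(sm[sample.int(n, n, replace = TRUE), ,
                               drop = FALSE], subset = subset)$slope,
        error = function(e) NA_real_)
      res
    }, 0)
  }
  sa <- boot_slopes(cohort_a)
  sb <- boot_slopes(cohort_b)
  ma <- mean(sa, na.rm = TRUE); mb <- mean(sb, na.rm = TRUE)
  va <- stats::var(sa, na.rm = TRUE); vb <- stats::var(sb, na.rm = TRUE)
  z <- (ma - mb) / sqrt(va + vb)
  list(slope_means = c(ma, mb), slope_sds = sqrt(c(va, vb)), z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided Wilcoxon signed-rank test of paired holo-minus-apo deltas
#' against zero (normal approximation with continuity correction, so tied
#' and zero deltas are handled).
#'
#' @param deltas Numeric vector of paired differences.
#' @return List with statistic (V), p, n, and `undefined` (TRUE when all
#'   deltas are zero, in which case p is NA).
#' @export
paired_test <- function(deltas) {
  deltas <- deltas[is.finite(deltas)]
  if (all(deltas == 0))
    return(list(statistic = NA_real_, p = NA_real_, n = length(deltas),
                undefined = TRUE))
  wt <- stats::wilcox.test(deltas, mu = 0, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  list(statistic = unname(wt$statistic), p = wt$p.value, n = length(deltas),
       undefined = FALSE)
}

#' Mann-Whitney U test for independent groups
#'
#' Two-sided rank-sum test with midranks for ties, normal approximation and
#' continuity correction. The returned statistic is the U statistic for the
#' first group.
#'
#' @param x,y Numeric vectors.
#' @return List with U, p, n (c(length(x), length(y))).
#' @export
group_test <- function(x, y) {
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                           correct = TRUE)
  list(U = unname(wt$statistic), p = wt$p.value, n = c(length(x), length(y)))
}

#' Quartile comparison of a per-pair statistic against a ligand descriptor
#'
#' Splits pairs into the lowest and highest quartiles of the descriptor
#' (the floor(n/4) smallest and largest values) and compares the statistic
#' between the two groups with a Mann-Whitney U test, flagging significance
#' at the Bonferroni-corrected level alpha / m_tests.
#'
#' @param values Per-pair statistic (e.g. binding-site order parameter).
#' @param key Ligand descriptor values, same length.
#' @param alpha Family-wise error rate (default 0.05).
#' @param m_tests Number of hypotheses for Bonferroni (default 10).
#' @return One-row data.frame with group medians, U, p, the corrected
#'   threshold and a significance flag.
#' @export
quartile_compare <- function(values, key, alpha = 0.05, m_tests = 10) {
  keep <- is.finite(values) & is.finite(key)
  values <- values[keep]; key <- key[keep]
  n <- length(values)
  if (n < 8) stop("need at least 8 observations for quartile comparison")
  if (stats::var(key) < 1e-14) stop("descriptor key has no variation")
  k <- max(1L, floor(n / 4))
  ord <- order(key)
  low <- values[ord[seq_len(k)]]
  high <- values[ord[seq(n - k + 1, n)]]
  gt <- group_test(low, high)
  thr <- alpha / m_tests
  data.frame(n_per_quartile = k, median_low = stats::median(low),
             median_high = stats::median(high), U = gt$U, p = gt$p,
             threshold = thr, significant = gt$p < thr)
}

#' Cohort category summary
#'
#' Fractions of residues (overall and in binding sites) per rotamer-change
#' category, fractions of pairs gaining/losing/keeping side-chain conformer
#' counts in the binding site, and the fraction of pairs whose binding-site
#' residues all kept their rotamer sets ("preorganized" binding sites).
#'
#' @param deltas Combined delta table (rows from [pair_residue_deltas()]
#'   for all pairs).
#' @return List with rotamer_fractions, rotamer_fractions_binding_site,
#'   conformer_change_fractions (gain/loss/same of binding-site conformer
#'   counts per pair) and preorganized_fraction.
#' @export
summarize_categories <- function(deltas) {
  if (!nrow(deltas)) stop("empty delta table")
  frac <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(numeric(0))
    tab <- table(x)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  }
  bs <- deltas[deltas$environment == "binding_site", , drop = FALSE]
  per_pair <- split(bs, bs$pair_id)
  conf_change <- vapply(per_pair, function(g) {
    s <- sum(g$delta_nconf, na.rm = TRUE)
    if (s > 0) "gain" else if (s < 0) "loss" else "same"
  }, "")
  preorg <- vapply(per_pair, function(g) {
    all(g$rotamer_category == "no_change", na.rm = TRUE)
  }, TRUE)
  list(rotamer_fractions = frac(deltas$rotamer_category),
       rotamer_fractions_binding_site = frac(bs$rotamer_category),
       conformer_change_fractions = frac(conf_change),
       preorganized_fraction = mean(preorg),
       n_pairs = length(per_pair))
}

#' Hierarchically cluster a residue-by-pair delta matrix
#'
#' Agglomerative clustering (average linkage on Euclidean distances) of
#' rows and columns, returning the dendrogram leaf orders and merge heights
#' for clustermap rendering.
#'
#' @param mat Numeric matrix (residues x pairs), finite entries.
#' @return List with row_order, col_order, row_heights, col_heights.
#' @export
cluster_delta_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat)))
    stop("matrix contains non-finite entries: impute or drop them first")
  one <- function(m) {
    if (nrow(m) < 2) return(list(order = seq_len(nrow(m)),
                                 heights = numeric(0)))
    hc <- stats::hclust(stats::dist(m), method = "average")
    list(order = hc$order, heights = hc$height)
  }
  r <- one(mat)
  cl <- one(t(mat))
  list(row_order = r$order, col_order = cl$order,
       row_heights = r$heights, col_heights = cl$heights)
}
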