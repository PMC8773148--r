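test_that("thresholding keeps boundary genes and validates input", {
  recs <- make_records(rep("NEM", 3), c(0.5, 0.500001, 1e-6),
                       c(0.05, 0.05, 0.05))
  expect_equal(include_genes(recs, 0.5)$gene_id, recs$gene_id[c(1, 3)])
  expect_error(include_genes(recs, 0), "threshold")
  expect_error(include_genes(recs, 1.5), "threshold")
})

test_that("gene and group adaptation are branch means", {
  recs <- make_records(c("NEM", "NEM"), c(0.1, 0.1), c(0.05, 0.05),
                       branch = list(c(0, 0.5, 1), c(0.2, 0.2)))
  expect_equal(gene_adaptation(recs), c(0.5, 0.2))
  expect_equal(group_adaptation(recs), 0.35)
  bad <- make_records("NEM", 0.1, 0.05, branch = list(numeric(0)))
  expect_error(gene_adaptation(bad), "empty")
  expect_error(group_adaptation(recs[0, ]), "empty")
})

test_that("matching scheme and interval follow the band definition", {
  sch <- matching_scheme(alpha = 0.95, x_period = 3L)
  iv <- matching_interval(sch, 0.08)
  expect_equal(unname(iv), c(0.95 * 0.95 * 0.08, 1.05 * 0.95 * 0.08))
  expect_lt(iv[1], iv[2])
  expect_error(matching_scheme(alpha = 0), "alpha")
  expect_error(matching_scheme(alpha = 1.1), "alpha")
  expect_error(matching_scheme(x_period = 0L), "x_period")
  expect_error(matching_scheme(band_low = 1.1, band_high = 1.0), "band")
})

test_that("matched sampling is reproducible and rejects infeasible pools", {
  set.seed(99)
  pool <- rgamma(500, 2, scale = 0.025)
  sch <- matching_scheme()
  set.seed(1); s1 <- matched_sample(pool, sch, mean(pool), 50)
  set.seed(1); s2 <- matched_sample(pool, sch, mean(pool), 50)
  expect_identical(s1, s2)
  expect_equal(length(s1), 50L)
  expect_false(any(duplicated(s1)))
  expect_equal(length(attr(s1, "free")), 50L)
  # infeasible target far above anything the pool can average to
  expect_error(matched_sample(pool, sch, 10, 50), "infeasible")
  expect_error(matched_sample(pool, sch, mean(pool), 501), "exceeds")
})

test_that("excess quantification is deterministic and order invariant", {
  recs <- generate_gene_stats(scenario_preset("headline", n_nem = 80L,
                                              n_nonnem = 800L, seed = 21L))
  sch <- matching_scheme()
  e1 <- quantify_excess(recs, 0.5, sch, n_perm = 150L, seed = 5L)
  e2 <- quantify_excess(recs, 0.5, sch, n_perm = 150L, seed = 5L)
  expect_identical(e1, e2)
  shuffled <- recs[sample.int(nrow(recs)), , drop = FALSE]
  rownames(shuffled) <- NULL
  e3 <- quantify_excess(shuffled, 0.5, sch, n_perm = 150L, seed = 5L)
  expect_equal(e3$excess_pct, e1$excess_pct, tolerance = 0)
  expect_equal(e3$p_perm, e1$p_perm, tolerance = 0)
  # p-value bounds from the add-one estimator
  expect_gte(e1$p_perm, 1 / 151)
  expect_lte(e1$p_perm, 1)
  expect_lte(e1$ci_low_pct, e1$ci_high_pct)
})

test_that("excess quantification validates its inputs", {
  recs <- generate_gene_stats(scenario_preset("headline", n_nem = 30L,
                                              n_nonnem = 300L, seed = 2L))
  expect_error(quantify_excess(recs, 0.5, n_perm = 50L), "n_perm")
  only_nem <- recs[recs$nem_status == "NEM", ]
  expect_error(quantify_excess(only_nem, 0.5, n_perm = 100L), "nonempty")
  flipped <- recs
  flipped$nem_status <- ifelse(recs$nem_status == "NEM", "NONNEM", "NEM")
  expect_error(quantify_excess(flipped, 0.5, n_perm = 100L), "smaller")
})

test_that("excess curve enforces descending thresholds and flags gaps", {
  recs <- generate_gene_stats(scenario_preset("headline", n_nem = 60L,
                                              n_nonnem = 600L, seed = 13L))
  expect_error(excess_curve(recs, thresholds = c(0.1, 0.5)), "descending")
  cv <- excess_curve(recs, thresholds = c(0.9, 0.5, 0.01),
                     scheme = matching_scheme(), n_perm = 120L, seed = 3L)
  expect_equal(nrow(cv), 3L)
  # included gene counts shrink as evidence tightens
  expect_true(all(diff(cv$n_nem) <= 0))
  expect_true(all(diff(cv$n_pool) <= 0))
  # a threshold excluding every NEM gene yields a flagged NA row, not a drop
  no_strong <- recs[recs$busted_p > 1e-8 | recs$nem_status == "NONNEM", ]
  cv2 <- excess_curve(no_strong, thresholds = c(0.5, 1e-9), n_perm = 120L,
                      seed = 3L)
  expect_equal(cv2$flag[2], "insufficient")
  expect_true(is.na(cv2$excess_pct[2]))
  expect_equal(cv2$flag[1], "")
})

test_that("small NEM sets are flagged on the curve", {
  recs <- generate_gene_stats(scenario_preset("headline", n_nem = 40L,
                                              n_nonnem = 1000L, seed = 17L))
  # around 4 NEM genes survive the strictest threshold here
  cv <- excess_curve(recs, thresholds = c(0.5, 1e-5), n_perm = 120L,
                     seed = 9L)
  expect_equal(cv$flag[2], "lt10_nem")
  expect_false(is.na(cv$excess_pct[2]))
})

test_that("Fisher 2x2 handles degenerate odds ratios and extreme tables", {
  expect_equal(fisher_exact_2x2(c(3, 1, 1, 3))$p_two_sided, 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(c(3, 1, 1, 3))$odds_ratio, 9)
  expect_equal(fisher_exact_2x2(c(2, 0, 1, 3))$odds_ratio, Inf)
  expect_equal(fisher_exact_2x2(c(0, 2, 3, 1))$odds_ratio, 0)
  expect_true(is.nan(fisher_exact_2x2(c(0, 2, 0, 3))$odds_ratio))
  expect_error(fisher_exact_2x2(c(-1, 2, 3, 4)), "nonnegative")
  expect_error(fisher_exact_2x2(c(0, 0, 0, 0)), "positive")
  expect_error(fisher_exact_2x2(matrix(1, 3, 3)), "2x2")
  # fully separated table attains the minimal p for its margins
  sep <- fisher_exact_2x2(c(5, 0, 0, 5))
  expect_equal(sep$p_two_sided, 2 / choose(10, 5), tolerance = 1e-12)
})

test_that("enrichment over levels flags levels with no selected genes", {
  recs <- make_records(rep(c("NEM", "NONNEM"), 5), rep(0.6, 10),
                       rep(0.05, 10))
  en <- enrichment_test(recs, levels = c(0.05, 0.01))
  expect_equal(en$p_two_sided, c(1, 1))
  expect_equal(en$flag, rep("no_selected_genes", 2))
  expect_error(enrichment_test(recs, levels = c(0, 0.5)), "levels")
})

test_that("NEM-enriched selection classes give Fisher power at all levels", {
  hits <- 0L
  n_rep <- 100L
  for (s in seq_len(n_rep)) {
    recs <- generate_gene_stats(synthetic_config(
      n_nem = 300L, n_nonnem = 3000L,
      class_probs_nem = c(0.3, 0.5, 0.2), seed = 6000L + s))
    en <- enrichment_test(recs)
    if (all(en$p_two_sided < 0.05)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("calibration screens candidates by variance compatibility", {
  recs <- generate_gene_stats(scenario_preset("null", n_nem = 60L,
                                              n_nonnem = 600L, seed = 8L))
  cal <- calibrate_matching(recs, alpha_grid = c(0.9, 1.0), x_grid = 3L,
                            n_cal = 100L, seed = 4L)
  expect_s3_class(cal, "calibration_result")
  expect_equal(nrow(cal$grid), 2L)
  expect_true(all(c("alpha", "x_period", "var_nem", "var_nonnem",
                    "var_diff", "var_p", "mean_nem", "mean_nonnem",
                    "mean_p") %in% names(cal$grid)))
  expect_true(all(cal$grid$var_diff >= 0))
  # chosen row satisfies the variance screen whenever any candidate does
  if (!cal$fallback) {
    expect_gt(cal$chosen$var_p, 0.05)
    passing <- cal$grid[cal$grid$var_p > 0.05, ]
    expect_equal(cal$chosen$var_diff, min(passing$var_diff))
  }
  expect_error(calibrate_matching(recs, numeric(0), 3L), "nonempty")
  expect_error(calibrate_matching(recs, 0.95, 3L, n_cal = 10L), "n_cal")
})

test_that("GO-stratified excess surfaces an artificially boosted category", {
  recs <- generate_gene_stats(scenario_preset("headline", n_nem = 300L,
                                              n_nonnem = 3000L, seed = 14L))
  boosted <- "GO:SYN0003"
  hit <- recs$nem_status == "NEM" &
    vapply(recs$go_terms, function(g) boosted %in% g, logical(1))
  recs$branch_sel_prop[hit] <- lapply(recs$branch_sel_prop[hit],
                                      function(b) pmin(1, b * 3))
  ge <- go_excess(recs, threshold = 0.5, scheme = matching_scheme(1),
                  n_perm = 150L, min_genes = 10L, top_k = 15L, seed = 2L)
  expect_true(boosted %in% ge$go_term)
  expect_equal(ge$go_term[which.max(ge$excess_pct)], boosted)
  expect_lte(ge$p_perm[ge$go_term == boosted], 0.05)
  expect_true(all(ge$q_value >= ge$p_perm - 1e-12))
  # nothing qualifies at an absurd minimum size
  expect_message(empty <- go_excess(recs, min_genes = 10000L, n_perm = 150L),
                 "min_genes")
  expect_equal(nrow(empty), 0L)
})

test_that("naive unmatched quantification is available for contrast", {
  recs <- generate_gene_stats(scenario_preset("confounded_null",
                                              n_nem = 60L, n_nonnem = 600L,
                                              seed = 23L))
  naive <- quantify_excess(recs, 0.5, n_perm = 150L, seed = 7L,
                           matched = FALSE)
  expect_false(naive$matched)
  expect_true(is.finite(naive$excess_pct))
})

test_that("sub-seeds stay within the 32-bit range", {
  s <- vapply(c(1, 1000, 1e6), function(i) sub_seed(2147483628, i),
              numeric(1))
  expect_true(all(s >= 0 & s < 2^31))
  expect_true(all(s == as.integer(s)))
  expect_false(sub_seed(1, 1) == sub_seed(1, 2))
})
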