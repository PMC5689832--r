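test_that("unique pair counts follow the closed form", {
  expect_equal(n_unique_pairs(1300), 844350)
  expect_equal(n_unique_pairs(2), 1)
  expect_equal(n_unique_pairs(10), 45)
  expect_error(n_unique_pairs(1), class = "cooccurj_error_usage")
})

test_that("the Bonferroni per-test level recovers the familywise rate exactly", {
  pa <- random_pa(12, 40, seed = 4)
  res <- analyze_all_pairs(pa, family_alpha = 0.05)
  expect_equal(res$alpha_per_test * res$n_pairs, 0.05)
  expect_equal(res$n_pairs, n_unique_pairs(12))
  expect_equal(nrow(res$pairs), res$n_pairs)
})

test_that("an engineered associated pair is recovered among independent decoys", {
  withr::with_seed(31, {
    decoys <- matrix(rbinom(10 * 100, 1, 0.4), nrow = 10,
                     dimnames = list(paste0("decoy_", 1:10), NULL))
    # a pair sharing 40 of 44 occupied sites over 100
    v1 <- c(rep(1, 40), rep(1, 2), rep(0, 2), rep(0, 56))
    v2 <- c(rep(1, 40), rep(0, 2), rep(1, 2), rep(0, 56))
    pa <- pa_matrix(rbind(decoys, e1 = v1, e2 = v2))
  })
  res <- analyze_all_pairs(pa)
  hit <- dplyr::filter(res$pairs, taxon_i == "e1", taxon_j == "e2")
  expect_true(hit$sig_j)
  expect_equal(hit$dir_j, "positive")
  # its upper tail agrees with the null-model module computed directly
  direct <- tail_probabilities(hypergeometric_null(42, 58, 42), 40)
  expect_equal(hit$p_ge_hyper, direct$p_ge, tolerance = 1e-12)
  expect_lt(hit$p_ge_hyper, res$alpha_per_test)
})

test_that("independent communities rarely produce familywise-significant pairs", {
  hits <- vapply(1:20, function(s) {
    pa <- withr::with_seed(1000 + s,
      pa_matrix(matrix(rbinom(50 * 80, 1, runif(50, 0.1, 0.9)), nrow = 50)))
    res <- analyze_all_pairs(pa)
    sum(res$pairs$sig_j)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("identical taxa are positive under both metrics and degenerates are never significant", {
  half <- c(rep(1, 20), rep(0, 20))
  pa <- pa_matrix(rbind(x = half, y = half))
  res <- analyze_all_pairs(pa)
  expect_equal(res$pairs$dir_j, "positive")
  expect_equal(res$pairs$dir_r, "positive")
  # add an all-absent and an all-present taxon: their pairs are degenerate
  pa2 <- pa_matrix(rbind(x = half, y = half, none = rep(0, 40),
                         all = rep(1, 40)))
  res2 <- analyze_all_pairs(pa2)
  deg <- dplyr::filter(res2$pairs, taxon_i %in% c("none", "all") |
                         taxon_j %in% c("none", "all"))
  expect_true(all(deg$degenerate))
  expect_false(any(deg$sig_j | deg$sig_r))
  expect_true(all(deg$dir_j == "none" & deg$dir_r == "none"))
  # cells conserve sites for every pair
  with(res2$pairs, expect_true(all(a + b + c + d == 40)))
})

test_that("the analysis is deterministic for identical inputs", {
  pa <- random_pa(15, 60, seed = 9)
  r1 <- analyze_all_pairs(pa)
  r2 <- analyze_all_pairs(pa)
  expect_identical(r1$pairs, r2$pairs)
  expect_error(analyze_all_pairs(pa_matrix(matrix(1L, 1, 5))),
               class = "cooccurj_error_usage")
  expect_error(analyze_all_pairs(pa, family_alpha = 0),
               class = "cooccurj_error_config")
  expect_error(analyze_all_pairs(pa, rare_cutoff = 0.5, common_cutoff = 0.2),
               class = "cooccurj_error_config")
})

test_that("concordance counts satisfy the Venn identities and stated denominators", {
  mk <- function(sig_j, sig_r, dir_j = "positive", dir_r = "positive") {
    tibble::tibble(sig_j = sig_j, sig_r = sig_r,
                   dir_j = ifelse(sig_j, dir_j, "none"),
                   dir_r = ifelse(sig_r, dir_r, "none"),
                   degenerate = FALSE)
  }
  # sig_r = {p1, p2}; sig_j = {p2, p3}; p4 in neither
  p <- mk(sig_j = c(FALSE, TRUE, TRUE, FALSE),
          sig_r = c(TRUE, TRUE, FALSE, FALSE))
  s <- concordance_summary(p)
  expect_equal(s$frac_r_only_of_sig_r, 0.5)
  expect_equal(s$frac_j_only_of_sig_j, 0.5)
  expect_equal(s$frac_both_of_union, 1 / 3)
  expect_equal(s$n_sig_both + s$n_sig_j_only, s$n_sig_j)
  expect_equal(s$n_sig_both + s$n_sig_r_only, s$n_sig_r)
  expect_equal(s$direction_match_count, 1)
  # all significant in both with matching direction
  all_sig <- mk(sig_j = rep(TRUE, 5), sig_r = rep(TRUE, 5))
  s2 <- concordance_summary(all_sig)
  expect_equal(s2$frac_both_of_union, 1)
  expect_equal(s2$direction_match_count, 5)
  # no significant pairs: fractions undefined, counts zero
  s3 <- concordance_summary(mk(sig_j = rep(FALSE, 3), sig_r = rep(FALSE, 3)))
  expect_equal(s3$n_sig_j + s3$n_sig_r, 0)
  expect_true(is.na(s3$frac_both_of_union))
  expect_true(is.na(s3$frac_r_only_of_sig_r))
  expect_error(concordance_summary(p[0, ]), class = "cooccurj_error_usage")
})

test_that("direction agreement is reported from the data, not assumed", {
  p <- tibble::tibble(sig_j = c(TRUE, TRUE), sig_r = c(TRUE, TRUE),
                      dir_j = c("positive", "positive"),
                      dir_r = c("positive", "negative"),
                      degenerate = FALSE)
  expect_equal(concordance_summary(p)$direction_match_count, 1)
})

test_that("prevalence binning places pairs by sorted prevalence with half-open bins", {
  p <- tibble::tibble(prevalence_i = 0.07, prevalence_j = 0.03,
                      sig_j = TRUE, sig_r = FALSE, degenerate = FALSE)
  g <- prevalence_grid(p, bin_width = 0.05)
  cell <- dplyr::filter(g, n_total > 0)
  expect_equal(nrow(cell), 1)
  expect_equal(c(cell$bin_lo_min, cell$bin_hi_min), c(0, 0.05))
  expect_equal(c(cell$bin_lo_max, cell$bin_hi_max), c(0.05, 0.10))
  expect_equal(cell$n_sig_j, 1)
  expect_equal(cell$diff_sig, 1)
  # prevalence 1.0 falls in the final closed bin
  p2 <- tibble::tibble(prevalence_i = 1, prevalence_j = 0.999,
                       sig_j = FALSE, sig_r = FALSE, degenerate = FALSE)
  g2 <- prevalence_grid(p2, bin_width = 0.05)
  top <- dplyr::filter(g2, n_total > 0)
  expect_equal(c(top$bin_lo_min, top$bin_hi_max), c(0.95, 1))
})

test_that("grid totals conserve the number of pairs", {
  pa <- random_pa(20, 50, seed = 12)
  res <- analyze_all_pairs(pa)
  g <- prevalence_grid(res)
  expect_equal(sum(g$n_total), res$n_pairs)
  expect_true(all(g$empty == (g$n_total == 0)))
  # only upper-triangle cells exist
  expect_true(all(g$bin_lo_min <= g$bin_lo_max))
})

test_that("rare-pair fractions use strict cutoffs and exact enumeration", {
  all_half <- pa_matrix(matrix(rep(c(1, 0), 30), nrow = 3, byrow = TRUE))
  rf <- rare_pair_fractions(all_half)
  expect_equal(unlist(rf), c(frac_at_least_one_rare = 0, frac_both_rare = 0))
  # prevalences (0.05, 0.05, 0.5) over 20 sites
  m <- rbind(r1 = c(1, rep(0, 19)), r2 = c(0, 1, rep(0, 18)),
             c1 = rep(c(1, 0), 10))
  rf2 <- rare_pair_fractions(pa_matrix(m))
  expect_equal(rf2$frac_at_least_one_rare, 1)
  expect_equal(rf2$frac_both_rare, 1 / 3)
  # cutoff is strict: prevalence exactly 0.10 is not rare
  m3 <- rbind(a = c(1, rep(0, 9)), b = c(1, rep(0, 9)))
  expect_equal(rare_pair_fractions(pa_matrix(m3), 0.10)$frac_both_rare, 0)
})

test_that("tidy, glance, edges and plots expose the result object", {
  pa <- random_pa(10, 40, seed = 6)
  res <- analyze_all_pairs(pa)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 45)
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_pairs, 45)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_prevalence_grid(prevalence_grid(res)), "ggplot")
  expect_s3_class(plot_null_distribution(hypergeometric_null(5, 5, 4), 3),
                  "ggplot")
  ed <- significant_edges(res)
  expect_true(all(c("taxon_i", "taxon_j", "direction", "j", "p") %in% names(ed)))
})
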