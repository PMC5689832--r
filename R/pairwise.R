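#' Number of unordered taxon pairs
#'
#' @param n_taxa Number of taxa (at least 2).
#' @return `n_taxa * (n_taxa - 1) / 2`.
#' @export
#' @examples
#' n_unique_pairs(1300)  # 844350
n_unique_pairs <- function(n_taxa) {
  if (!is_count_scalar(n_taxa) || n_taxa < 2) {
    stop_cooccurj("n_taxa must be an integer >= 2",
                  class = "cooccurj_error_usage")
  }
  n_taxa * (n_taxa - 1) / 2
}

#' All-pairs co-occurrence screen with familywise correction
#'
#' Runs the full pairwise analysis of a presence/absence matrix: for every
#' unordered taxon pair it computes the 2x2 contingency cells, the phi
#' coefficient and Jaccard's index, exact tail probabilities of the
#' co-occurrence count under the prevalence-specific hypergeometric null
#' and under the standard binomial null, and a significance test for phi.
#' Significance is assessed at `family_alpha / n_pairs` (Bonferroni), so
#' the familywise error rate over all pairs is controlled at
#' `family_alpha`.
#'
#' Pairs for which either metric is undefined (a taxon present nowhere or
#' everywhere) are flagged `degenerate` and never reported significant,
#' but remain in the table so pair counts stay auditable.
#'
#' @param pa A [pa_matrix()] with at least two taxa.
#' @param family_alpha Familywise error rate (default 0.05).
#' @param correction Multiplicity correction; only `"bonferroni"` is
#'   implemented (the per-test level is then `family_alpha / n_pairs`).
#' @param rare_cutoff Prevalence below which a taxon counts as rare
#'   (strict `<`, default 0.10).
#' @param common_cutoff Prevalence above which a taxon counts as
#'   moderately common (default 0.20).
#' @param bin_width Prevalence bin width for [prevalence_grid()]
#'   (default 0.05).
#' @param r_test Null model for phi: `"chisq"` (default) or `"exact"`; see
#'   [r_significance()].
#' @param eq3_p_mode Success probability of the standard binomial null:
#'   `"third"` (exact 1/3) or `"literal"` (0.33).
#' @return An object of class `pa_cooccurrence`: a list with `pairs` (one
#'   tibble row per unordered pair; see Details), `config`, `n_taxa`,
#'   `n_sites` and `alpha_per_test`. Use [generics::tidy()] for the pair
#'   table, [generics::glance()] for a one-row summary,
#'   [concordance_summary()], [prevalence_grid()] and [autoplot.pa_cooccurrence()]
#'   for the comparison artifacts.
#' @details The `pairs` tibble has columns `taxon_i`, `taxon_j`, the cells
#'   `a`,`b`,`c`,`d`, `prevalence_i`, `prevalence_j`, `r`, `j`, the
#'   hypergeometric tails `p_le_hyper`/`p_eq_hyper`/`p_ge_hyper`, the
#'   standard-null tails `p_le_standard`/`p_ge_standard`, the phi p-value
#'   `r_p`, flags `sig_j`, `sig_r`, `sig_r_onesided`, directions `dir_j`,
#'   `dir_r`, `dir_j_standard`, and `degenerate`.
#' @export
analyze_all_pairs <- function(pa,
                              family_alpha = 0.05,
                              correction = "bonferroni",
                              rare_cutoff = 0.10,
                              common_cutoff = 0.20,
                              bin_width = 0.05,
                              r_test = c("chisq", "exact"),
                              eq3_p_mode = c("third", "literal")) {
  r_test <- match.arg(r_test)
  eq3_p_mode <- match.arg(eq3_p_mode)
  correction <- match.arg(correction, "bonferroni")
  if (!is.numeric(family_alpha) || family_alpha <= 0 || family_alpha >= 1) {
    stop_cooccurj("family_alpha must lie in (0, 1)",
                  class = "cooccurj_error_config")
  }
  if (!is.numeric(bin_width) || bin_width <= 0 || bin_width > 1) {
    stop_cooccurj("bin_width must lie in (0, 1]",
                  class = "cooccurj_error_config")
  }
  if (rare_cutoff >= common_cutoff) {
    stop_cooccurj("rare_cutoff must be below common_cutoff",
                  class = "cooccurj_error_config")
  }
  if (nrow(pa) < 2) {
    stop_cooccurj("at least two taxa are required",
                  class = "cooccurj_error_usage")
  }
  x <- unclass(pa)
  n_taxa <- nrow(x)
  n_sites <- ncol(x)
  n_pairs <- n_unique_pairs(n_taxa)
  alpha <- family_alpha / n_pairs

  occ <- rowSums(x)
  co <- tcrossprod(x)
  ut <- which(upper.tri(co), arr.ind = TRUE)
  i <- ut[, "row"]; j <- ut[, "col"]
  a <- co[ut]
  b <- occ[i] - a
  c_ <- occ[j] - a
  d <- n_sites - a - b - c_

  phi <- phi_vec(a, b, c_, d)
  jac <- jaccard_vec(a, b, c_)

  # hypergeometric tails: species 1 margin m = occ[i], draw k = occ[j]
  p_ge_h <- phyper(a - 1, occ[i], n_sites - occ[i], occ[j], lower.tail = FALSE)
  p_le_h <- phyper(a, occ[i], n_sites - occ[i], occ[j])
  p_eq_h <- dhyper(a, occ[i], n_sites - occ[i], occ[j])

  # standard binomial null on n = a+b+c occupied sites
  p_std <- resolve_p_cooccur(eq3_p_mode)
  n_occ <- a + b + c_
  p_ge_s <- pbinom(a - 1, n_occ, p_std, lower.tail = FALSE)
  p_le_s <- pbinom(a, n_occ, p_std)

  rsig <- r_significance(tibble(a = a, b = b, c = c_, d = d),
                         alpha = alpha, method = r_test)

  degenerate <- !phi$defined | !jac$defined
  dir_j <- classify_direction_vec(p_le_h, p_ge_h, alpha)
  dir_j[degenerate] <- "none"
  dir_j_std <- classify_direction_vec(p_le_s, p_ge_s, alpha)
  dir_j_std[degenerate] <- "none"
  sig_j <- dir_j != "none"
  sig_r <- rsig$significant & !degenerate
  sig_r_onesided <- !degenerate & rsig$testable &
    !is.na(rsig$p_value) & (rsig$p_value / 2 <= alpha)
  dir_r <- rsig$direction
  dir_r[degenerate | !sig_r] <- "none"

  pairs <- tibble(
    taxon_i = rownames(x)[i], taxon_j = rownames(x)[j],
    a = as.integer(a), b = as.integer(b), c = as.integer(c_),
    d = as.integer(d),
    prevalence_i = occ[i] / n_sites, prevalence_j = occ[j] / n_sites,
    r = phi$value, j = jac$value,
    p_le_hyper = p_le_h, p_eq_hyper = p_eq_h, p_ge_hyper = p_ge_h,
    p_le_standard = p_le_s, p_ge_standard = p_ge_s,
    r_p = rsig$p_value,
    sig_j = sig_j, sig_r = sig_r, sig_r_onesided = sig_r_onesided,
    dir_j = dir_j, dir_r = dir_r, dir_j_standard = dir_j_std,
    degenerate = degenerate
  )

  structure(
    list(pairs = pairs,
         config = list(family_alpha = family_alpha, correction = correction,
                       rare_cutoff = rare_cutoff, common_cutoff = common_cutoff,
                       bin_width = bin_width, r_test = r_test,
                       eq3_p_mode = eq3_p_mode),
         n_taxa = n_taxa, n_sites = n_sites, n_pairs = n_pairs,
         alpha_per_test = alpha),
    class = "pa_cooccurrence")
}

pairs_table <- function(x) {
  if (inherits(x, "pa_cooccurrence")) return(x$pairs)
  if (is.data.frame(x)) return(x)
  stop_cooccurj("expected a pa_cooccurrence object or its pair table",
                class = "cooccurj_error_usage")
}

#' Significance concordance between Jaccard's index and phi
#'
#' Summarizes how often the two metrics agree on which pairs are
#' significant: counts of pairs significant under each metric, both, or
#' exactly one, the three mismatch fractions (each with its own
#' denominator: significant-for-r pairs, significant-for-J pairs, and
#' their union), and how many both-significant pairs agree in direction.
#'
#' @param results A `pa_cooccurrence` object or its `pairs` tibble.
#' @return A one-row tibble with columns `n_pairs`, `n_degenerate`,
#'   `n_sig_j`, `n_sig_r`, `n_sig_both`, `n_sig_j_only`, `n_sig_r_only`,
#'   `frac_r_only_of_sig_r`, `frac_j_only_of_sig_j`, `frac_both_of_union`,
#'   `direction_match_count`. Fractions are `NA` when their denominator is
#'   zero.
#' @export
concordance_summary <- function(results) {
  p <- pairs_table(results)
  if (nrow(p) == 0) {
    stop_cooccurj("no pair results supplied", class = "cooccurj_error_usage")
  }
  n_sig_j <- sum(p$sig_j)
  n_sig_r <- sum(p$sig_r)
  both <- sum(p$sig_j & p$sig_r)
  union_ <- n_sig_j + n_sig_r - both
  tibble(
    n_pairs = nrow(p),
    n_degenerate = sum(p$degenerate),
    n_sig_j = n_sig_j, n_sig_r = n_sig_r,
    n_sig_both = both,
    n_sig_j_only = n_sig_j - both,
    n_sig_r_only = n_sig_r - both,
    frac_r_only_of_sig_r = if (n_sig_r > 0) (n_sig_r - both) / n_sig_r else NA_real_,
    frac_j_only_of_sig_j = if (n_sig_j > 0) (n_sig_j - both) / n_sig_j else NA_real_,
    frac_both_of_union = if (union_ > 0) both / union_ else NA_real_,
    direction_match_count = sum(p$sig_j & p$sig_r & p$dir_j == p$dir_r)
  )
}

#' Prevalence-binned significance grid
#'
#' Bins each pair by the prevalences of its two members (lower prevalence
#' indexes the row bin, higher the column bin, so the populated region is
#' the upper triangle including the diagonal) and counts, per cell, the
#' total pairs and those significant for Jaccard's index and for phi.
#' Bins are half-open `[lo, hi)` with the final bin closed at 1. The
#' `diff_sig` layer (`n_sig_j - n_sig_r`) exposes the characteristic
#' prevalence pattern of the disagreement between the two metrics:
#' positive where one member is rare and the other common, negative where
#' both are rare.
#'
#' @param results A `pa_cooccurrence` object or its `pairs` tibble.
#' @param bin_width Prevalence bin width; defaults to the analysis config
#'   (0.05 for a plain tibble).
#' @return A tibble with one row per grid cell: `bin_lo_min`, `bin_hi_min`
#'   (bin of the less prevalent member), `bin_lo_max`, `bin_hi_max`,
#'   `n_total`, `n_sig_j`, `n_sig_r`, `diff_sig`, `empty`. All upper-
#'   triangle cells are present; cells with no pairs have `empty = TRUE`.
#' @export
prevalence_grid <- function(results, bin_width = NULL) {
  p <- pairs_table(results)
  if (nrow(p) == 0) {
    stop_cooccurj("no pair results supplied", class = "cooccurj_error_usage")
  }
  if (is.null(bin_width)) {
    bin_width <- if (inherits(results, "pa_cooccurrence"))
      results$config$bin_width else 0.05
  }
  n_bins <- ceiling(1 / bin_width)
  bin_of <- function(prev) pmin(floor(prev / bin_width), n_bins - 1L) + 1L
  lo <- pmin(p$prevalence_i, p$prevalence_j)
  hi <- pmax(p$prevalence_i, p$prevalence_j)
  cell <- tibble(bin_min = bin_of(lo), bin_max = bin_of(hi),
                 sig_j = p$sig_j, sig_r = p$sig_r)
  counts <- cell |>
    dplyr::group_by(.data$bin_min, .data$bin_max) |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_sig_j = sum(.data$sig_j),
                     n_sig_r = sum(.data$sig_r), .groups = "drop")
  full <- tidyr::expand_grid(bin_min = seq_len(n_bins), bin_max = seq_len(n_bins)) |>
    dplyr::filter(.data$bin_min <= .data$bin_max)
  full |>
    dplyr::left_join(counts, by = c("bin_min", "bin_max")) |>
    dplyr::mutate(dplyr::across(c("n_total", "n_sig_j", "n_sig_r"),
                                ~ tidyr::replace_na(.x, 0L)),
                  diff_sig = .data$n_sig_j - .data$n_sig_r,
                  empty = .data$n_total == 0L,
                  bin_lo_min = (.data$bin_min - 1) * bin_width,
                  bin_hi_min = pmin(.data$bin_min * bin_width, 1),
                  bin_lo_max = (.data$bin_max - 1) * bin_width,
                  bin_hi_max = pmin(.data$bin_max * bin_width, 1)) |>
    dplyr::select("bin_lo_min", "bin_hi_min", "bin_lo_max", "bin_hi_max",
                  "n_total", "n_sig_j", "n_sig_r", "diff_sig", "empty")
}

#' Fraction of pairs involving rare taxa
#'
#' Over all unordered pairs, the fraction with at least one member below
#' the rare-prevalence cutoff and the fraction with both members below it
#' (strict `<`). Communities with long tails of rare taxa have most of
#' their pairs in the first class, which is where the phi/Jaccard
#' disagreement concentrates.
#'
#' @param pa A [pa_matrix()] with at least two taxa.
#' @param rare_cutoff Prevalence cutoff (default 0.10).
#' @return A one-row tibble: `frac_at_least_one_rare`, `frac_both_rare`.
#' @export
rare_pair_fractions <- function(pa, rare_cutoff = 0.10) {
  if (nrow(pa) < 2) {
    stop_cooccurj("at least two taxa are required",
                  class = "cooccurj_error_usage")
  }
  rare <- prevalence(pa) < rare_cutoff
  n <- length(rare)
  n_pairs <- n_unique_pairs(n)
  n_rare <- sum(rare)
  both <- n_rare * (n_rare - 1) / 2
  none <- (n - n_rare) * (n - n_rare - 1) / 2
  tibble(frac_at_least_one_rare = (n_pairs - none) / n_pairs,
         frac_both_rare = both / n_pairs)
}

#' Export significant pairs as an edge list
#'
#' @param results A `pa_cooccurrence` object or its `pairs` tibble.
#' @return A tibble of significant-for-Jaccard pairs with columns
#'   `taxon_i`, `taxon_j`, `direction`, `j`, `p` (the tail probability on
#'   the significant side), suitable for network tools.
#' @export
significant_edges <- function(results) {
  p <- pairs_table(results)
  p |>
    dplyr::filter(.data$sig_j) |>
    dplyr::mutate(p = ifelse(.data$dir_j == "positive",
                             .data$p_ge_hyper, .data$p_le_hyper)) |>
    dplyr::select("taxon_i", "taxon_j", direction = "dir_j", "j", "p")
}

#' @export
print.pa_cooccurrence <- function(x, ...) {
  cat(sprintf("<pa_cooccurrence> %d taxa, %d sites, %d pairs\n",
              x$n_taxa, x$n_sites, x$n_pairs))
  cat(sprintf("  familywise alpha %.3g (%s), per-test alpha %.3g\n",
              x$config$family_alpha, x$config$correction, x$alpha_per_test))
  s <- concordance_summary(x)
  cat(sprintf("  significant pairs: J %d, r %d, both %d (degenerate %d)\n",
              s$n_sig_j, s$n_sig_r, s$n_sig_both, s$n_degenerate))
  invisible(x)
}
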