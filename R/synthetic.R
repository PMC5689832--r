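#' Generate a taxon pair with controlled joint occupancy
#'
#' Draws two binary site vectors from the bivariate Bernoulli law with
#' marginals `p1`, `p2` and joint co-occurrence probability `p11`
#' (independence when `p11 = p1 * p2`). The Frechet bounds
#' `max(0, p1 + p2 - 1) <= p11 <= min(p1, p2)` delimit the attainable
#' joint probabilities and are enforced.
#'
#' @param n_sites Number of sites.
#' @param p1,p2 Marginal prevalences in `[0, 1]`.
#' @param p11 Joint co-occurrence probability; defaults to independence.
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return A 2-taxon [pa_matrix()] (rows `taxon_1`, `taxon_2`).
#' @export
generate_pair <- function(n_sites, p1, p2, p11 = p1 * p2, seed = NULL) {
  if (!is_count_scalar(n_sites) || n_sites < 1) {
    stop_cooccurj("n_sites must be a positive integer",
                  class = "cooccurj_error_usage")
  }
  check_pair_spec(p1, p2, p11)
  probs <- c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
  probs <- pmax(probs, 0)  # guard tiny negative rounding at the bounds
  draw <- function() {
    cell <- sample.int(4L, n_sites, replace = TRUE, prob = probs)
    rbind(taxon_1 = as.integer(cell %in% c(1L, 2L)),
          taxon_2 = as.integer(cell %in% c(1L, 3L)))
  }
  m <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  pa_matrix(m, sample_ids = paste0("site_", seq_len(n_sites)))
}

check_pair_spec <- function(p1, p2, p11) {
  for (v in list(p1 = p1, p2 = p2, p11 = p11)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop_cooccurj("p1, p2 and p11 must be single probabilities in [0, 1]",
                    class = "cooccurj_error_usage")
    }
  }
  tol <- 1e-09
  lo <- max(0, p1 + p2 - 1)
  hi <- min(p1, p2)
  if (p11 < lo - tol || p11 > hi + tol) {
    stop_cooccurj(sprintf(
      "p11 = %g violates the Frechet bounds [%g, %g] for p1 = %g, p2 = %g",
      p11, lo, hi, p1, p2), class = "cooccurj_error_usage")
  }
  invisible(TRUE)
}

#' Generate an independent pair with exact occupancy counts
#'
#' Fixes the number of occupied sites for each species and assigns the
#' identities of the occupied sites uniformly at random, independently for
#' the two species — the sampling experiment whose co-occurrence count is
#' distributed exactly as [hypergeometric_null()].
#'
#' @param n_sites Number of sites.
#' @param occ1,occ2 Exact occupied-site counts.
#' @param seed Optional integer seed.
#' @return A 2-taxon [pa_matrix()] with row sums exactly `occ1`, `occ2`.
#' @export
generate_fixed_margin_pair <- function(n_sites, occ1, occ2, seed = NULL) {
  for (v in list(n_sites, occ1, occ2)) {
    if (!is_count_scalar(v)) {
      stop_cooccurj("n_sites, occ1 and occ2 must be nonnegative integers",
                    class = "cooccurj_error_usage")
    }
  }
  if (occ1 > n_sites || occ2 > n_sites) {
    stop_cooccurj("occupancy cannot exceed the number of sites",
                  class = "cooccurj_error_usage")
  }
  draw <- function() {
    v1 <- integer(n_sites); v1[sample.int(n_sites, occ1)] <- 1L
    v2 <- integer(n_sites); v2[sample.int(n_sites, occ2)] <- 1L
    rbind(taxon_1 = v1, taxon_2 = v2)
  }
  m <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  pa_matrix(m, sample_ids = paste0("site_", seq_len(n_sites)))
}

#' Draw prevalences from the long-tailed community distribution
#'
#' A two-component mixture tuned to the statistical shape of a WGS skin
#' microbiome community: a rare component `Beta(0.4, 25)` (weight 0.38)
#' holding the long tail of low-occupancy taxa, and a moderate component
#' `Beta(2, 7.5)`. With 286 sites these defaults put roughly 75% of taxon
#' pairs at "at least one member below 10% prevalence", roughly 25% at
#' "both below 10%", and the median pairwise co-absence near 76%.
#'
#' @param n_taxa Number of prevalences to draw.
#' @param rare_weight Mixture weight of the rare component.
#' @param rare_shape,common_shape Length-2 Beta shape parameters.
#' @return Numeric vector of prevalences in `[0, 1]`.
#' @export
r_longtail_prevalence <- function(n_taxa, rare_weight = 0.38,
                                  rare_shape = c(0.4, 25),
                                  common_shape = c(2, 7.5)) {
  z <- runif(n_taxa) < rare_weight
  ifelse(z, rbeta(n_taxa, rare_shape[1], rare_shape[2]),
         rbeta(n_taxa, common_shape[1], common_shape[2]))
}

#' Generate a synthetic community with known association structure
#'
#' Builds a presence/absence matrix whose taxa are placed independently
#' with prevalences drawn from the long-tailed mixture of
#' [r_longtail_prevalence()] (or supplied directly), optionally replacing
#' chosen taxon slots with associated pairs generated by [generate_pair()].
#' The injected associations are returned as a ground-truth table so that
#' recovery and power can be measured.
#'
#' @param n_sites Number of sites (default 286).
#' @param n_taxa Number of taxa (default 1300).
#' @param prevalences Optional numeric vector of length `n_taxa`; drawn
#'   from the long-tail mixture when `NULL`.
#' @param associations Optional data frame with columns `p1`, `p2`, `p11`;
#'   each row is injected into the next two free taxon slots.
#' @param seed Integer seed governing every random draw.
#' @param ... Passed to [r_longtail_prevalence()].
#' @return A list of class `synthetic_community`: `pa` (the
#'   [pa_matrix()]), `truth` (tibble `taxon_i`, `taxon_j`, `p1`, `p2`,
#'   `p11`), and `prevalences` (the generating marginals).
#' @export
generate_community <- function(n_sites = 286, n_taxa = 1300,
                               prevalences = NULL, associations = NULL,
                               seed = 1L, ...) {
  if (!is_count_scalar(n_sites) || n_sites < 1 ||
      !is_count_scalar(n_taxa) || n_taxa < 2) {
    stop_cooccurj("need n_sites >= 1 and n_taxa >= 2",
                  class = "cooccurj_error_usage")
  }
  if (!is.null(associations)) {
    if (!is.data.frame(associations) ||
        !all(c("p1", "p2", "p11") %in% names(associations))) {
      stop_cooccurj("associations must be a data frame with columns p1, p2, p11",
                    class = "cooccurj_error_usage")
    }
    if (2 * nrow(associations) > n_taxa) {
      stop_cooccurj("too many injected pairs for the number of taxon slots",
                    class = "cooccurj_error_usage")
    }
    for (r in seq_len(nrow(associations))) {
      check_pair_spec(associations$p1[r], associations$p2[r],
                      associations$p11[r])
    }
  }
  n_inj <- if (is.null(associations)) 0L else nrow(associations)

  withr::with_seed(as.integer(seed), {
    if (is.null(prevalences)) {
      prevalences <- r_longtail_prevalence(n_taxa, ...)
    } else if (length(prevalences) != n_taxa ||
               any(prevalences < 0 | prevalences > 1)) {
      stop_cooccurj("prevalences must be n_taxa values in [0, 1]",
                    class = "cooccurj_error_usage")
    }
    occupancy <- matrix(0L, nrow = n_taxa, ncol = n_sites)
    if (n_inj > 0) {
      for (r in seq_len(n_inj)) {
        pair <- generate_pair(n_sites, associations$p1[r], associations$p2[r],
                              associations$p11[r])
        occupancy[2 * r - 1, ] <- unclass(pair)[1, ]
        occupancy[2 * r, ] <- unclass(pair)[2, ]
        prevalences[2 * r - 1] <- associations$p1[r]
        prevalences[2 * r] <- associations$p2[r]
      }
    }
    free <- setdiff(seq_len(n_taxa), seq_len(2 * n_inj))
    if (length(free) > 0) {
      occupancy[free, ] <- matrix(
        rbinom(length(free) * n_sites, 1L, rep(prevalences[free], n_sites)),
        nrow = length(free))
    }
    truth <- if (n_inj > 0) {
      tibble(taxon_i = paste0("taxon_", 2 * seq_len(n_inj) - 1),
             taxon_j = paste0("taxon_", 2 * seq_len(n_inj)),
             p1 = associations$p1, p2 = associations$p2,
             p11 = associations$p11)
    } else {
      tibble(taxon_i = character(), taxon_j = character(),
             p1 = numeric(), p2 = numeric(), p11 = numeric())
    }
    structure(
      list(pa = pa_matrix(occupancy,
                          taxon_ids = paste0("taxon_", seq_len(n_taxa)),
                          sample_ids = paste0("site_", seq_len(n_sites))),
           truth = truth,
           prevalences = prevalences),
      class = "synthetic_community")
  })
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf("<synthetic_community> %d taxa x %d sites, %d injected pair(s)\n",
              nrow(x$pa), ncol(x$pa), nrow(x$truth)))
  invisible(x)
}
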