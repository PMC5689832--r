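new_null_distribution <- function(x, prob, source, params, extra = NULL) {
  out <- tibble(x = as.integer(x), prob = as.numeric(prob))
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  structure(out,
            class = c("null_distribution", class(tibble())),
            source = source, params = params)
}

#' Standard binomial null distribution for the co-occurrence count
#'
#' The classical null for Jaccard's index models the co-occurrence count
#' `a` out of the `n = a + b + c` occupied sites as Binomial(n, 1/3). The
#' 1/3 arises from assuming every taxon has 50% prevalence, so that
#' uncorrelated taxa yield equal expected `a`, `b` and `c`. That assumption
#' fails for real communities, which is the motivation for the
#' prevalence-specific [hypergeometric_null()]. The published form of the
#' model prints the success probability as 0.33; `p_cooccur = "literal"`
#' reproduces that rounding, while the default uses the exact 1/3 the
#' equal-thirds argument implies.
#'
#' @param n_occupied Total occupied sites for the pair (`a + b + c`).
#' @param p_cooccur Success probability: `"third"` (exact 1/3, default),
#'   `"literal"` (0.33), or a number in (0, 1).
#' @return A `null_distribution` tibble with columns `x` (support
#'   `0..n_occupied`) and `prob`.
#' @export
standard_binomial_null <- function(n_occupied, p_cooccur = c("third", "literal")) {
  if (!is_count_scalar(n_occupied)) {
    stop_cooccurj("n_occupied must be a single nonnegative integer",
                  class = "cooccurj_error_usage")
  }
  p <- resolve_p_cooccur(p_cooccur)
  support <- 0:n_occupied
  new_null_distribution(support, dbinom(support, n_occupied, p),
                        source = "standard_binomial",
                        params = list(n_occupied = n_occupied, p_cooccur = p))
}

resolve_p_cooccur <- function(p_cooccur) {
  if (is.character(p_cooccur)) {
    mode <- match.arg(p_cooccur, c("third", "literal"))
    return(if (mode == "third") 1 / 3 else 0.33)
  }
  if (!is.numeric(p_cooccur) || length(p_cooccur) != 1 ||
      p_cooccur <= 0 || p_cooccur >= 1) {
    stop_cooccurj("p_cooccur must be 'third', 'literal' or a number in (0, 1)",
                  class = "cooccurj_error_config")
  }
  p_cooccur
}

#' Prevalence-specific hypergeometric null distribution
#'
#' The exact null of Veech's probabilistic model of species co-occurrence:
#' with species 1 occupying `m` of the `m + n_unocc` sites and species 2
#' occupying `k` sites placed uniformly at random, the co-occurrence count
#' `x` follows
#' `P(X = x) = choose(m, x) * choose(n_unocc, k - x) / choose(m + n_unocc, k)`.
#' Because `m` and `k` are the observed occupancies, each species pair gets
#' its own null — the prevalence correction the standard binomial null
#' lacks.
#'
#' @param m Sites occupied by species 1.
#' @param n_unocc Sites not occupied by species 1 (`N - m`).
#' @param k Sites occupied by species 2; must not exceed `m + n_unocc`.
#' @return A `null_distribution` tibble over the support
#'   `max(0, k - n_unocc) .. min(m, k)`.
#' @export
hypergeometric_null <- function(m, n_unocc, k) {
  for (v in list(m = m, n_unocc = n_unocc, k = k)) {
    if (!is_count_scalar(v)) {
      stop_cooccurj("m, n_unocc and k must be single nonnegative integers",
                    class = "cooccurj_error_usage")
    }
  }
  if (k > m + n_unocc) {
    stop_cooccurj("k cannot exceed the total number of sites m + n_unocc",
                  class = "cooccurj_error_usage")
  }
  support <- max(0, k - n_unocc):min(m, k)
  new_null_distribution(support, dhyper(support, m, n_unocc, k),
                        source = "hypergeometric",
                        params = list(m = m, n_unocc = n_unocc, k = k))
}

#' Monte-Carlo null distribution by random site assignment
#'
#' Fixes each species' number of occupied sites and assigns the identities
#' of the occupied sites uniformly at random, independently for the two
#' species; the co-occurrence count `x` and the resulting Jaccard value
#' `J = x / (occ1 + occ2 - x)` are recorded per trial. The empirical pmf
#' converges to [hypergeometric_null()], which is the closed form of the
#' same experiment.
#'
#' @param n_sites Number of sites.
#' @param occ1,occ2 Occupied-site counts for the two species.
#' @param trials Number of random assignments (default 100000).
#' @param seed Integer seed; the full random stream derives from it.
#' @return A `null_distribution` tibble with columns `x`, `j` and `prob`
#'   (`prob` is exactly trial frequency / `trials`).
#' @export
simulate_null <- function(n_sites, occ1, occ2, trials = 100000, seed = 1L) {
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
  if (!is_count_scalar(trials) || trials < 1) {
    stop_cooccurj("trials must be a positive integer",
                  class = "cooccurj_error_usage")
  }
  draws <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(trials), function(t) {
      s1 <- sample.int(n_sites, occ1)
      s2 <- sample.int(n_sites, occ2)
      sum(s1 %in% s2)
    }, integer(1))
  })
  support <- max(0, occ1 + occ2 - n_sites):min(occ1, occ2)
  counts <- tabulate(draws - support[1] + 1L, nbins = length(support))
  n_occ <- occ1 + occ2 - support
  j <- ifelse(n_occ > 0, support / n_occ, NA_real_)
  new_null_distribution(support, counts / trials,
                        source = "monte_carlo",
                        params = list(n_sites = n_sites, occ1 = occ1,
                                      occ2 = occ2, trials = trials, seed = seed),
                        extra = tibble(j = j))
}

#' Exact tail probabilities of a null distribution
#'
#' Decomposes the probability mass around an observed co-occurrence count
#' into `P(X < x)`, `P(X = x)` and `P(X > x)`, plus the one-sided tails
#' `p_le` and `p_ge` that include the observed point (standard exact-test
#' convention). `p_ge` tests positive association, `p_le` negative. An
#' observation outside the support is clamped to tail probabilities 0/1.
#'
#' @param dist A `null_distribution` (from [standard_binomial_null()],
#'   [hypergeometric_null()] or [simulate_null()]).
#' @param x_obs Observed co-occurrence count(s); vectorized.
#' @return A tibble with columns `x_obs`, `p_lt`, `p_eq`, `p_gt`, `p_le`,
#'   `p_ge`.
#' @export
tail_probabilities <- function(dist, x_obs) {
  if (!inherits(dist, "null_distribution")) {
    stop_cooccurj("dist must be a null_distribution",
                  class = "cooccurj_error_usage")
  }
  x <- dist$x
  pr <- dist$prob
  cum <- cumsum(pr)
  total <- cum[length(cum)]
  res <- lapply(x_obs, function(xo) {
    p_lt <- if (xo <= x[1]) 0 else cum[max(which(x < xo))]
    p_eq <- if (xo %in% x) pr[match(xo, x)] else 0
    c(p_lt = p_lt, p_eq = p_eq, p_gt = max(0, total - p_lt - p_eq))
  })
  m <- unname(do.call(rbind, res))
  clamp01 <- function(v) pmin(1, pmax(0, v))
  tibble(x_obs = as.integer(x_obs),
         p_lt = m[, 1], p_eq = m[, 2], p_gt = m[, 3],
         p_le = clamp01(m[, 1] + m[, 2]),
         p_ge = clamp01(m[, 3] + m[, 2]))
}

#' Classify association direction from tail probabilities
#'
#' A pair is called positive when the upper tail `p_ge` is at most `alpha`,
#' negative when the lower tail `p_le` is, and unassociated otherwise. Each
#' tail is tested separately at the per-test level (direction comes from
#' which side of the null the observation falls on); in the rare case of a
#' support so small that both tails pass, the smaller tail wins.
#'
#' @param tails A tibble from [tail_probabilities()] (vectorized over rows),
#'   or any data frame with columns `p_le` and `p_ge`.
#' @param alpha Per-test significance level in (0, 1).
#' @return Character vector: `"positive"`, `"negative"` or `"none"`.
#' @export
classify_direction <- function(tails, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop_cooccurj("alpha must be a single number in (0, 1)",
                  class = "cooccurj_error_usage")
  }
  classify_direction_vec(tails$p_le, tails$p_ge, alpha)
}

classify_direction_vec <- function(p_le, p_ge, alpha) {
  dplyr::case_when(
    is.na(p_le) | is.na(p_ge) ~ "none",
    p_ge <= alpha & p_le <= alpha ~ ifelse(p_ge <= p_le, "positive", "negative"),
    p_ge <= alpha ~ "positive",
    p_le <= alpha ~ "negative",
    TRUE ~ "none"
  )
}

#' Significance test for the phi coefficient
#'
#' Default method: the chi-square statistic `N * r^2` on 1 degree of
#' freedom, the classical large-sample test of association in a 2x2 table.
#' `method = "exact"` instead uses the conditional exact test built on the
#' same hypergeometric machinery as the Jaccard null (two-sided by summing
#' all outcomes no more probable than the observed one). The choice of null
#' model for phi is a configuration, reported in the result, because no
#' single convention is universal.
#'
#' @param tab Data frame with columns `a`, `b`, `c`, `d` (vectorized rows).
#' @param alpha Per-test significance level.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return A tibble with columns `r`, `statistic` (chi-square; `NA` for
#'   exact), `p_value` (two-sided), `significant`, `direction`
#'   (sign of `r` when significant, otherwise `"none"`), `testable`
#'   (`FALSE` where phi is undefined), `method`.
#' @export
r_significance <- function(tab, alpha = 0.05, method = c("chisq", "exact")) {
  method <- match.arg(method)
  tab <- check_cells(tab)
  phi <- phi_vec(tab$a, tab$b, tab$c, tab$d)
  n <- tab$a + tab$b + tab$c + tab$d
  if (method == "chisq") {
    stat <- ifelse(phi$defined, n * phi$value^2, NA_real_)
    p <- ifelse(phi$defined, pchisq(stat, df = 1, lower.tail = FALSE), NA_real_)
  } else {
    stat <- rep(NA_real_, nrow(tab))
    p <- vapply(seq_len(nrow(tab)), function(r) {
      if (!phi$defined[r]) return(NA_real_)
      exact_conditional_p(tab$a[r], tab$b[r], tab$c[r], tab$d[r])
    }, numeric(1))
  }
  sig <- !is.na(p) & p <= alpha
  tibble(r = phi$value, statistic = stat, p_value = p,
         significant = sig,
         direction = dplyr::case_when(
           !sig | is.na(phi$value) | phi$value == 0 ~ "none",
           phi$value > 0 ~ "positive",
           TRUE ~ "negative"),
         testable = phi$defined, method = method)
}

## Two-sided conditional exact p: condition on both margins, sum the
## probability of every co-occurrence count at most as likely as observed.
exact_conditional_p <- function(a, b, c, d) {
  m <- a + b
  n_unocc <- c + d
  k <- a + c
  dist <- dhyper(max(0, k - n_unocc):min(m, k), m, n_unocc, k)
  p_obs <- dhyper(a, m, n_unocc, k)
  sum(dist[dist <= p_obs * (1 + 1e-07)])
}

#' @export
print.null_distribution <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<null_distribution: %s> support %d..%d\n",
              attr(x, "source"), min(x$x), max(x$x)))
  NextMethod()
}
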