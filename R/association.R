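## Vectorized internals shared with the all-pairs engine. Both metrics are
## pure functions of the 2x2 cells; degenerate denominators yield NA with a
## FALSE 'defined' flag rather than a sentinel value.

phi_vec <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; m3 <- a + c; m4 <- b + d
  defined <- m1 > 0 & m2 > 0 & m3 > 0 & m4 > 0
  # pairwise sqrt keeps the radicand well inside double range for large N
  denom <- sqrt(m1 * m2) * sqrt(m3 * m4)
  value <- ifelse(defined, (a * d - b * c) / denom, NA_real_)
  list(value = value, defined = defined)
}

jaccard_vec <- function(a, b, c) {
  n_occ <- a + b + c
  defined <- n_occ > 0
  list(value = ifelse(defined, a / n_occ, NA_real_), defined = defined)
}

check_cells <- function(tab) {
  if (!is.data.frame(tab) || !all(c("a", "b", "c", "d") %in% names(tab))) {
    stop_cooccurj("expected a data frame with columns a, b, c, d",
                  class = "cooccurj_error_usage")
  }
  cells <- as.matrix(tab[, c("a", "b", "c", "d")])
  if (length(cells) > 0 &&
      (any(!is.finite(cells)) || any(cells < 0) || any(cells != trunc(cells)))) {
    stop_cooccurj("contingency cells must be nonnegative integers",
                  class = "cooccurj_error_validation")
  }
  tab
}

#' Phi coefficient of a 2x2 contingency table
#'
#' Pearson's product-moment correlation applied to two binary variables:
#' `r = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`, in `[-1, 1]`. The result is
#' flagged undefined when any marginal is zero (a taxon absent from, or
#' present at, every site). Unlike Jaccard's index, phi uses the co-absent
#' cell `d`, which makes it sensitive to the number of sites where neither
#' taxon occurs; see [coabsence_sweep()].
#'
#' @param tab Data frame with integer columns `a`, `b`, `c`, `d` (one row
#'   per table; vectorized).
#' @return A tibble with columns `metric` (`"phi"`), `value` and `defined`,
#'   one row per input row. `value` is `NA` where `defined` is `FALSE`.
#' @export
#' @examples
#' phi_coefficient(data.frame(a = 100, b = 45, c = 65, d = c(10, 200)))
phi_coefficient <- function(tab) {
  tab <- check_cells(tab)
  res <- phi_vec(tab$a, tab$b, tab$c, tab$d)
  tibble(metric = "phi", value = res$value, defined = res$defined)
}

#' Jaccard's index of a 2x2 contingency table
#'
#' `J = a / (a + b + c)`, in `[0, 1]`; the co-absent cell `d` never enters.
#' Undefined when no site contains either taxon.
#'
#' @inheritParams phi_coefficient
#' @return A tibble with columns `metric` (`"jaccard"`), `value`, `defined`.
#' @export
jaccard_index <- function(tab) {
  tab <- check_cells(tab)
  res <- jaccard_vec(tab$a, tab$b, tab$c)
  tibble(metric = "jaccard", value = res$value, defined = res$defined)
}

#' Co-absence sensitivity sweep of the phi coefficient
#'
#' Holds the cells `a`, `b`, `c` fixed and sweeps the co-absence count `d`,
#' recording phi at every point. Jaccard's index is constant along the sweep
#' (it does not involve `d`), while phi increases monotonically with `d` and
#' can cross zero — the mechanism by which large co-absence counts, typical
#' of rare-taxon-rich microbiome data, inflate apparent positive
#' association.
#'
#' @param a,b,c Fixed cell counts, not all zero.
#' @param d_values Nonnegative integer co-absence counts to sweep.
#' @return A tibble with columns `d`, `r` (phi at that `d`) and `j` (the
#'   constant Jaccard value).
#' @export
#' @examples
#' coabsence_sweep(100, 45, 65, c(10, 200))
coabsence_sweep <- function(a, b, c, d_values) {
  if (length(d_values) == 0) {
    stop_cooccurj("d_values must be a nonempty sequence",
                  class = "cooccurj_error_usage")
  }
  check_cells(tibble(a = a, b = b, c = c, d = d_values))
  if (a + b + c == 0) {
    stop_cooccurj("a, b and c must not all be zero",
                  class = "cooccurj_error_usage")
  }
  r <- phi_vec(a, b, c, d_values)$value
  j <- jaccard_vec(a, b, c)$value
  tibble(d = as.integer(d_values), r = r, j = j)
}

#' Expected Jaccard index for two independently placed taxa
#'
#' Under independence the expected cell frequencies are `a = p1 p2`,
#' `b = p1 (1 - p2)`, `c = (1 - p1) p2`, giving
#' `J = p1 p2 / (p1 + p2 - p1 p2)`. At `p1 = p2 = 0.5` this recovers 1/3,
#' the expectation the standard binomial null hard-wires for every pair;
#' at any other prevalence the two disagree, which is why that null
#' misclassifies independent pairs.
#'
#' @param p1,p2 Prevalences in `[0, 1]` (vectorized).
#' @return Numeric vector of expected Jaccard values; `NA` where
#'   `p1 = p2 = 0` (undefined).
#' @export
predicted_jaccard_independence <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE)) {
    stop_cooccurj("prevalences must lie in [0, 1]",
                  class = "cooccurj_error_usage")
  }
  denom <- p1 + p2 - p1 * p2
  ifelse(denom > 0, p1 * p2 / denom, NA_real_)
}
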