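# Fixtures are built in code; no data files.

toy_counts <- function() {
  count_table(rbind(A = c(150L, 0L, 99L), B = c(101L, 101L, 0L)),
              sample_ids = c("s1", "s2", "s3"))
}

random_pa <- function(n_taxa, n_sites, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    pa_matrix(matrix(rbinom(n_taxa * n_sites, 1L, p), nrow = n_taxa))
  })
}

# Independent oracle: pmf of the co-occurrence count by exhaustive
# enumeration of every placement of species 2 over N sites, species 1 fixed
# on the first m sites. Returns probabilities over support 0..min(m, k).
enum_cooccurrence_pmf <- function(m, n_unocc, k) {
  N <- m + n_unocc
  support <- 0:min(m, k)
  if (k == 0) {
    return(stats::setNames(as.numeric(support == 0), support))
  }
  placements <- utils::combn(N, k)
  overlap <- apply(placements, 2, function(s2) sum(s2 <= m))
  counts <- vapply(support, function(x) sum(overlap == x), numeric(1))
  stats::setNames(counts / ncol(placements), support)
}

# Independent oracle: textbook Pearson chi-square on a 2x2 table from
# observed vs margin-expected counts, without touching the phi shortcut.
chisq_2x2_oracle <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  n <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))
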