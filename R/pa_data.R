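#' Construct a taxon-by-sample count table
#'
#' A count table holds nonnegative integer read counts with one row per
#' taxon and one column per sample. It is the raw input of the analysis;
#' downstream work happens on the presence/absence matrix produced by
#' [threshold_counts()].
#'
#' @param counts Numeric matrix of nonnegative integers, taxa as rows.
#' @param taxon_ids Character vector of unique row labels. Defaults to the
#'   matrix rownames.
#' @param sample_ids Character vector of unique column labels. Defaults to
#'   the matrix colnames.
#' @return An integer matrix of class `count_table` with taxa as rownames
#'   and samples as colnames.
#' @export
count_table <- function(counts, taxon_ids = rownames(counts),
                        sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon_", seq_len(nrow(counts)), recycle0 = TRUE)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(counts)), recycle0 = TRUE)
  validate_labels(taxon_ids, nrow(counts), "taxon")
  validate_labels(sample_ids, ncol(counts), "sample")
  if (length(counts) > 0) {
    bad <- which(!is.finite(counts) | counts < 0 | counts != trunc(counts))
    if (length(bad) > 0) {
      i <- ((bad[1] - 1) %% nrow(counts)) + 1
      j <- ((bad[1] - 1) %/% nrow(counts)) + 1
      stop_cooccurj(
        sprintf("count for taxon '%s', sample '%s' is not a nonnegative integer (value: %s)",
                taxon_ids[i], sample_ids[j], format(counts[bad[1]])),
        class = "cooccurj_error_parse")
    }
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(as.character(taxon_ids), as.character(sample_ids))
  structure(counts, class = c("count_table", class(matrix())))
}

#' Construct a presence/absence matrix
#'
#' @param occupancy Matrix of 0/1 values, taxa as rows, samples as columns.
#' @inheritParams count_table
#' @return An integer 0/1 matrix of class `pa_matrix`.
#' @export
pa_matrix <- function(occupancy, taxon_ids = rownames(occupancy),
                      sample_ids = colnames(occupancy)) {
  occupancy <- as.matrix(occupancy)
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon_", seq_len(nrow(occupancy)), recycle0 = TRUE)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(occupancy)), recycle0 = TRUE)
  validate_labels(taxon_ids, nrow(occupancy), "taxon")
  validate_labels(sample_ids, ncol(occupancy), "sample")
  if (length(occupancy) > 0 && !all(occupancy %in% c(0, 1))) {
    stop_cooccurj("occupancy entries must all be 0 or 1",
                  class = "cooccurj_error_validation")
  }
  storage.mode(occupancy) <- "integer"
  dimnames(occupancy) <- list(as.character(taxon_ids), as.character(sample_ids))
  structure(occupancy, class = c("pa_matrix", class(matrix())))
}

validate_labels <- function(labels, n, axis) {
  if (length(labels) != n) {
    stop_cooccurj(sprintf("%d %s labels supplied for %d rows/columns",
                          length(labels), axis, n),
                  class = "cooccurj_error_validation")
  }
  if (anyDuplicated(labels)) {
    dup <- labels[duplicated(labels)][1]
    stop_cooccurj(sprintf("duplicate %s label: '%s'", axis, dup),
                  class = "cooccurj_error_validation")
  }
  invisible(labels)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d taxa x %d samples\n", nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(8, ncol(x))), drop = FALSE])
  invisible(x)
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf("<pa_matrix> %d taxa x %d samples (sites)\n", nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(8, ncol(x))), drop = FALSE])
  invisible(x)
}

detect_delimiter <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_body <- function(path, delimiter) {
  if (!file.exists(path)) {
    stop_cooccurj(sprintf("input file does not exist: '%s'", path),
                  class = "cooccurj_error_io")
  }
  df <- readr::read_delim(path, delim = delimiter,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE, show_col_types = FALSE,
                          name_repair = "minimal")
  if (ncol(df) < 1) {
    stop_cooccurj(sprintf("no columns found in '%s'", path),
                  class = "cooccurj_error_parse")
  }
  df
}

#' Read a taxon-by-sample count table from delimited text
#'
#' The first row holds sample labels and the first column taxon labels.
#' The delimiter is auto-detected from the file extension (`.csv` = comma,
#' anything else = tab) unless given explicitly.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field delimiter; `NULL` (default) auto-detects.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, delimiter = NULL) {
  delimiter <- detect_delimiter(path, delimiter)
  df <- read_table_body(path, delimiter)
  taxa <- df[[1]]
  samples <- names(df)[-1]
  body <- as.matrix(df[, -1, drop = FALSE])
  mat <- matrix(0L, nrow = length(taxa), ncol = length(samples))
  if (length(body) > 0) {
    ok <- grepl("^[0-9]+$", body)
    if (!all(ok)) {
      bad <- which(!ok)[1]
      i <- ((bad - 1) %% nrow(body)) + 1
      j <- ((bad - 1) %/% nrow(body)) + 1
      stop_cooccurj(
        sprintf("cell for taxon '%s', sample '%s' is not a nonnegative integer: '%s'",
                taxa[i], samples[j], body[bad]),
        class = "cooccurj_error_parse")
    }
    mat <- matrix(as.integer(body), nrow = nrow(body), ncol = ncol(body))
  }
  count_table(mat, taxon_ids = taxa, sample_ids = samples)
}

#' Read a presence/absence matrix from delimited text
#'
#' Same layout as [read_count_table()], with all body cells 0 or 1.
#'
#' @inheritParams read_count_table
#' @return A [pa_matrix()].
#' @export
read_pa_matrix <- function(path, delimiter = NULL) {
  tab <- read_count_table(path, delimiter)
  if (length(tab) > 0 && !all(tab %in% c(0L, 1L))) {
    stop_cooccurj(sprintf("'%s' contains values other than 0/1; binarize with threshold_counts() first",
                          path),
                  class = "cooccurj_error_parse")
  }
  pa_matrix(unclass(tab))
}

#' Write a count table or presence/absence matrix to delimited text
#'
#' Writes the same layout the readers expect (row 1 sample labels, column 1
#' taxon labels), so a write/read cycle round-trips losslessly.
#'
#' @param x A `count_table` or `pa_matrix`.
#' @param path Output path.
#' @param delimiter Field delimiter; `NULL` auto-detects from extension.
#' @return `path`, invisibly.
#' @export
write_pa_table <- function(x, path, delimiter = NULL) {
  delimiter <- detect_delimiter(path, delimiter)
  df <- as_tibble(as.data.frame(unclass(x)), rownames = "taxon_id")
  readr::write_delim(df, path, delim = delimiter, progress = FALSE)
  invisible(path)
}

#' Binarize read counts to presence/absence
#'
#' A taxon is scored present in a sample only when its read count strictly
#' exceeds `min_reads`. The default of 100 reads suppresses spurious
#' low-count classifier assignments while keeping genuinely detected taxa.
#'
#' @param table A [count_table()] (a plain matrix is accepted too).
#' @param min_reads Nonnegative integer threshold; counts strictly greater
#'   map to presence. With `min_reads = 0` any positive count is a presence.
#' @return A [pa_matrix()] with the same labels.
#' @export
#' @examples
#' tab <- count_table(rbind(A = c(150, 0, 99), B = c(101, 101, 0)))
#' threshold_counts(tab)
threshold_counts <- function(table, min_reads = 100) {
  if (!is_count_scalar(min_reads)) {
    stop_cooccurj("min_reads must be a single nonnegative integer",
                  class = "cooccurj_error_config")
  }
  m <- unclass(as.matrix(table))
  pa_matrix((m > min_reads) * 1L,
            taxon_ids = rownames(m), sample_ids = colnames(m))
}

#' Per-pair 2x2 contingency table
#'
#' Cross-tabulates two taxa over all sites: `a` co-presence, `b` sites with
#' taxon `i` only, `c` sites with taxon `j` only, `d` co-absence.
#' `a + b + c + d` always equals the number of sites.
#'
#' @param pa A [pa_matrix()].
#' @param i,j Distinct taxon indices (integer position or taxon label).
#' @return A one-row tibble with integer columns `a`, `b`, `c`, `d`.
#' @export
contingency_for_pair <- function(pa, i, j) {
  ri <- resolve_taxon(pa, i)
  rj <- resolve_taxon(pa, j)
  if (ri == rj) {
    stop_cooccurj("i and j must name two different taxa",
                  class = "cooccurj_error_usage")
  }
  x <- unclass(pa)[ri, ]
  y <- unclass(pa)[rj, ]
  a <- sum(x == 1L & y == 1L)
  b <- sum(x == 1L & y == 0L)
  c_ <- sum(x == 0L & y == 1L)
  tibble(a = a, b = b, c = c_, d = length(x) - a - b - c_)
}

resolve_taxon <- function(pa, i) {
  if (is.character(i)) {
    idx <- match(i, rownames(pa))
    if (is.na(idx)) {
      stop_cooccurj(sprintf("unknown taxon label '%s'", i),
                    class = "cooccurj_error_usage")
    }
    return(idx)
  }
  if (!is_count_scalar(i) || i < 1 || i > nrow(pa)) {
    stop_cooccurj(sprintf("taxon index %s out of range 1..%d", format(i), nrow(pa)),
                  class = "cooccurj_error_usage")
  }
  as.integer(i)
}

#' Taxon prevalence (occupancy)
#'
#' Fraction of sites at which each taxon is present.
#'
#' @param pa A [pa_matrix()].
#' @param i Optional taxon index/label (vectorized); all taxa if `NULL`.
#' @return Named numeric vector of prevalences in `[0, 1]`.
#' @export
prevalence <- function(pa, i = NULL) {
  if (ncol(pa) == 0) {
    stop_cooccurj("prevalence is undefined for a matrix with zero sites",
                  class = "cooccurj_error_usage")
  }
  p <- rowSums(unclass(pa)) / ncol(pa)
  names(p) <- rownames(pa)
  if (is.null(i)) return(p)
  p[vapply(i, function(ii) resolve_taxon(pa, ii), integer(1))]
}

#' Median co-absent percentage over all taxon pairs
#'
#' For every unordered pair of taxa, the percentage of sites at which both
#' are absent (`100 * d / N`); returns the median across pairs. Microbiome
#' tables sit far above the 50-70% typical of macroecological surveys,
#' which is what makes the co-absence sensitivity of the phi coefficient so
#' consequential for them.
#'
#' @param pa A [pa_matrix()] with at least two taxa and one site.
#' @return Median co-absent percentage (scalar in `[0, 100]`).
#' @export
coabsent_percent_summary <- function(pa) {
  if (nrow(pa) < 2) {
    stop_cooccurj("at least two taxa are required", class = "cooccurj_error_usage")
  }
  if (ncol(pa) < 1) {
    stop_cooccurj("at least one site is required", class = "cooccurj_error_usage")
  }
  x <- unclass(pa)
  n <- ncol(x)
  occ <- rowSums(x)
  co <- tcrossprod(x)          # a for every pair
  ut <- upper.tri(co)
  d <- n - outer(occ, occ, "+")[ut] + co[ut]
  median(100 * d / n)
}
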