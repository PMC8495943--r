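#' Remove guides poorly represented in the 0-hour baseline
#'
#' A guide is retained only when every baseline replicate carries at least
#' `min_reads` reads for it: guides with fewer than the threshold in either
#' 0-hour replicate are removed before normalization. The boundary is
#' inclusive — exactly `min_reads` reads survive. Lung counts are never
#' touched. With more than two baseline replicates the rule generalizes
#' conservatively: all replicates must meet the threshold.
#'
#' @param matrix a [count_matrix()] with at least one baseline sample.
#' @param min_reads integer threshold, default 30; `min_reads = 0` is the
#'   identity.
#' @return the filtered [count_matrix()], with attribute `removed_guides`
#'   recording what was dropped.
#' @export
filter_low_baseline <- function(matrix, min_reads = 30) {
  b <- baseline_idx(matrix)
  if (length(b) == 0) stop("no baseline samples in the count matrix")
  keep <- rowSums(matrix$counts[, b, drop = FALSE] >= min_reads) == length(b)
  out <- count_matrix(matrix$counts[keep, , drop = FALSE], matrix$samples,
                      unname(matrix$gene[keep]))
  attr(out, "removed_guides") <- rownames(matrix$counts)[!keep]
  attr(out, "min_reads") <- min_reads
  out
}

#' Total normalization against the grand mean sample depth
#'
#' Every sample's counts are divided by its size factor, defined as the
#' sample total over the grand mean of all sample totals, so that every
#' normalized column sums to the grand mean total. This is the "total"
#' normalization of the MAGeCK family, re-implemented from its formula.
#' Within-sample guide ranks and cross-sample relative abundances are
#' preserved exactly up to the scalar factor.
#'
#' @param matrix a [count_matrix()]; every sample must have a positive
#'   total.
#' @return object of class `normalized_matrix`: list with `values`
#'   (nonnegative real matrix), `size_factors` (named, positive), `gene`,
#'   `samples`, and `provenance`.
#' @export
total_normalize <- function(matrix) {
  totals <- colSums(matrix$counts)
  zero <- totals == 0
  if (any(zero)) {
    stop("zero-total sample(s): ",
         paste(matrix$samples$sample_id[zero], collapse = ", "))
  }
  sf <- totals / mean(totals)
  values <- sweep(matrix$counts, 2L, sf, "/")
  structure(
    list(values = values,
         size_factors = stats::setNames(sf, matrix$samples$sample_id),
         gene = matrix$gene,
         samples = matrix$samples,
         provenance = list(normalization = "total",
                           grand_mean_total = mean(totals),
                           removed_low_baseline = attr(matrix, "removed_guides"),
                           min_baseline_reads = attr(matrix, "min_reads"))),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d guides x %d samples, size factors %.3g..%.3g\n",
              nrow(x$values), ncol(x$values),
              min(x$size_factors), max(x$size_factors)))
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

#' Drop guides with no reads assigned after normalization
#'
#' Removes guides whose normalized value is zero in every sample (baseline
#' and lung alike). A guide detected only in the baseline is retained; its
#' absence from individual lungs is what the presence count `n` measures.
#'
#' @param matrix a `normalized_matrix`.
#' @return the `normalized_matrix` without all-zero guides; provenance
#'   records what was dropped.
#' @export
drop_zero_guides <- function(matrix) {
  keep <- rowSums(matrix$values != 0) > 0
  matrix$provenance$removed_all_zero <- rownames(matrix$values)[!keep]
  matrix$values <- matrix$values[keep, , drop = FALSE]
  matrix$gene <- matrix$gene[keep]
  matrix
}

#' Run the fixed preprocessing sequence
#'
#' Baseline filter, then total normalization, then all-zero guide removal —
#' the order in which the statistics are defined downstream.
#'
#' @param matrix a [count_matrix()].
#' @param min_baseline_reads threshold for [filter_low_baseline()].
#' @return a `normalized_matrix` ready for [percentile_membership()].
#' @export
preprocess_counts <- function(matrix, min_baseline_reads = 30) {
  drop_zero_guides(total_normalize(filter_low_baseline(matrix, min_baseline_reads)))
}
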