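#' Parameters of the percentile-ranking statistic
#'
#' @param percentile_q quantile defining per-animal membership, in (0,1);
#'   default 0.98 (the "98th percentile").
#' @param hit_fraction fraction of animals a guide must exceed (strictly)
#'   to be called a hit; default 0.30.
#' @param quantile_rule interpolation convention for the quantile over the
#'   sorted abundances; `"linear"` (linear interpolation between order
#'   statistics, R type 7) is the default and currently the only rule.
#' @param include_zeros if `TRUE`, the per-animal quantile is computed over
#'   all guides including zero-count ones (sensitivity analysis); the
#'   default `FALSE` uses only guides with reads in that animal, since
#'   zero-read guides contribute no reads to the lung's relative
#'   abundances and the bottleneck makes zeros overwhelming.
#' @return list of class `rank_params`.
#' @export
rank_params <- function(percentile_q = 0.98, hit_fraction = 0.30,
                        quantile_rule = "linear", include_zeros = FALSE) {
  if (!(percentile_q > 0 && percentile_q < 1)) stop("percentile_q must be in (0,1)")
  if (!(hit_fraction > 0 && hit_fraction < 1)) stop("hit_fraction must be in (0,1)")
  quantile_rule <- match.arg(quantile_rule, "linear")
  structure(list(percentile_q = percentile_q, hit_fraction = hit_fraction,
                 quantile_rule = quantile_rule,
                 include_zeros = isTRUE(include_zeros)),
            class = "rank_params")
}

#' Per-animal top-percentile membership
#'
#' For each lung sample independently, the `percentile_q` quantile T of the
#' normalized abundances of the guides detected (nonzero) in that animal is
#' computed by linear interpolation over the sorted values; a guide is a
#' member iff its nonzero abundance is `>= T` (ties at the threshold are
#' members). Zero-count guides are never members. Membership is invariant
#' to rescaling a sample by any positive constant.
#'
#' @param matrix a `normalized_matrix` with at least one lung sample.
#' @param params a [rank_params()].
#' @return logical guide-by-lung matrix; all-`FALSE` column (with a
#'   warning) for a lung without any detected guide.
#' @export
percentile_membership <- function(matrix, params = rank_params()) {
  lungs <- lung_idx(matrix)
  if (length(lungs) == 0) stop("no lung samples in the matrix")
  vals <- matrix$values[, lungs, drop = FALSE]
  member <- matrix(FALSE, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    nz <- x > 0
    if (!any(nz)) {
      warning("lung sample '", matrix$samples$sample_id[lungs[j]],
              "' has no detected guides")
      next
    }
    pool <- if (params$include_zeros) x else x[nz]
    thr <- stats::quantile(pool, probs = params$percentile_q, type = 7,
                           names = FALSE)
    member[, j] <- nz & x >= thr
  }
  member
}

#' Per-guide summary statistics over the lung samples
#'
#' For each guide: `n_present` — the number of lung samples (animals) with
#' nonzero normalized count (the statistic's n); `count_mean` — the mean
#' normalized count over those animals (m); `sd` — the sample standard
#' deviation over the same animals (n-1 denominator; 0 when n = 1);
#' `sem = sd / sqrt(n_present)`; `z_score` — the mean normalized lung count
#' minus the mean of the guide's normalized 0-hour baseline values, divided
#' by the SEM; `n_nep` — in how many animals the guide sits within the top
#' percentile of that animal's abundances (the membership row sum). z is
#' reported as `NA` when undefined (`n_present <= 1` or `sd == 0`).
#'
#' @param matrix a `normalized_matrix` containing baseline and lung
#'   samples.
#' @param membership logical matrix from [percentile_membership()], same
#'   guides and lung samples.
#' @return data frame of class `guide_stats` with one row per guide:
#'   `guide_id`, `gene`, `n_present`, `count_mean`, `sd`, `sem`, `z_score`,
#'   `n_nep`; attributes record the number of lung samples analyzed.
#' @export
compute_guide_stats <- function(matrix, membership) {
  b <- baseline_idx(matrix)
  lungs <- lung_idx(matrix)
  if (length(b) == 0) stop("no baseline samples: z-scores need the 0-hour reference")
  if (!identical(dim(membership), c(nrow(matrix$values), length(lungs)))) {
    stop("membership dimensions do not match the matrix's guides x lungs")
  }
  lung_vals <- matrix$values[, lungs, drop = FALSE]
  present <- lung_vals > 0
  n_present <- rowSums(present)
  sum_present <- rowSums(lung_vals * present)
  m <- ifelse(n_present > 0, sum_present / n_present, NA_real_)
  # sample SD over the present animals only; 0 by convention when n = 1
  ss <- rowSums((lung_vals - ifelse(is.na(m), 0, m))^2 * present)
  sdv <- ifelse(n_present > 1, sqrt(ss / (n_present - 1)),
                ifelse(n_present == 1, 0, NA_real_))
  sem <- ifelse(n_present >= 1, sdv / sqrt(n_present), NA_real_)
  baseline_mean <- rowMeans(matrix$values[, b, drop = FALSE])
  z <- ifelse(n_present > 1 & sdv > 0, (m - baseline_mean) / sem, NA_real_)
  out <- data.frame(
    guide_id = rownames(matrix$values),
    gene = unname(matrix$gene),
    n_present = as.integer(n_present),
    count_mean = m,
    sd = sdv,
    sem = sem,
    z_score = z,
    n_nep = as.integer(rowSums(membership)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_lung_samples") <- length(lungs)
  class(out) <- c("guide_stats", "data.frame")
  out
}

#' Rank guides by percentile membership, then z-score
#'
#' Guides are ordered by descending `n_nep` (in how many animals they reach
#' the top percentile), ties broken by descending z-score — an undefined z
#' ranks below any finite z — and remaining ties by `guide_id`, so the
#' ranking is deterministic. Ranks are 1..nrow.
#'
#' @param table a `guide_stats` data frame.
#' @return the table reordered, with a `rank` column appended.
#' @export
rank_guides <- function(table) {
  z_key <- ifelse(is.na(table$z_score), -Inf, table$z_score)
  ord <- order(-table$n_nep, -z_key, table$guide_id)
  out <- table[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_lung_samples") <- attr(table, "n_lung_samples")
  class(out) <- class(table)
  out
}

#' Apply the robust-regulator hit filter
#'
#' A guide is a hit iff it reaches the top percentile in strictly more than
#' `hit_fraction` of the animals: `n_nep / n_mice > hit_fraction`. At 40
#' animals and the default 30%, 12/40 (exactly 30%) fails and 13/40
#' (32.5%) passes.
#'
#' @param table a (ranked) `guide_stats` data frame.
#' @param n_mice number of animals in the cohort, `>= 1`.
#' @param params a [rank_params()].
#' @return the table with a logical `is_hit` column.
#' @export
call_hits <- function(table, n_mice, params = rank_params()) {
  if (n_mice < 1) stop("n_mice must be >= 1")
  table$is_hit <- table$n_nep / n_mice > params$hit_fraction
  table
}

#' Aggregate the per-guide table to genes
#'
#' The statistic deliberately analyses each guide individually — guides of
#' one gene target different TSSs and are not interchangeable — so gene
#' aggregation is reporting, not testing: each gene inherits its best
#' (lowest-rank) guide's `n_nep`, `z_score` and `rank`, and is a hit iff
#' any of its guides is. Nontargeting controls are aggregated under the
#' control label and flagged so reports list them separately from gene
#' hits.
#'
#' @param table a ranked, hit-flagged `guide_stats` data frame.
#' @param library the [guide_library()]; every guide in the table must be
#'   present.
#' @return data frame of class `gene_stats`: `gene`, `best_guide`,
#'   `n_guides`, `n_nep`, `z_score`, `rank`, `gene_is_hit`, `is_control`,
#'   ordered by best rank.
#' @export
aggregate_to_genes <- function(table, library) {
  missing_g <- setdiff(table$guide_id, library$guide_id)
  if (length(missing_g) > 0) {
    stop("guide(s) in table absent from library: ",
         paste(missing_g, collapse = ", "))
  }
  if (is.null(table$rank) || is.null(table$is_hit)) {
    stop("table must be ranked (rank_guides) and hit-flagged (call_hits)")
  }
  gene_of <- library$gene[match(table$guide_id, library$guide_id)]
  ctrl_of <- library$is_control[match(table$guide_id, library$guide_id)]
  pieces <- lapply(split(seq_len(nrow(table)), gene_of), function(idx) {
    sub <- table[idx, , drop = FALSE]
    best <- which.min(sub$rank)
    data.frame(gene = gene_of[idx[1L]],
               best_guide = sub$guide_id[best],
               n_guides = nrow(sub),
               n_nep = sub$n_nep[best],
               z_score = sub$z_score[best],
               rank = sub$rank[best],
               gene_is_hit = any(sub$is_hit),
               is_control = ctrl_of[idx[1L]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_stats", "data.frame")
  out
}

#' Full percentile-ranking analysis of a normalized matrix
#'
#' Convenience wrapper: membership, per-guide statistics, ranking and hit
#' calling in one step.
#'
#' @param matrix a `normalized_matrix`.
#' @param params a [rank_params()].
#' @return a ranked, hit-flagged `guide_stats` data frame.
#' @export
percentile_rank <- function(matrix, params = rank_params()) {
  membership <- percentile_membership(matrix, params)
  stats <- compute_guide_stats(matrix, membership)
  ranked <- rank_guides(stats)
  call_hits(ranked, n_mice = length(lung_idx(matrix)), params = params)
}
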