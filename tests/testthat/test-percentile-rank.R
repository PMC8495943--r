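# A normalized_matrix built directly from values, bypassing count I/O.
as_normalized <- function(values, roles, gene = NULL) {
  n <- ncol(values)
  sheet <- sample_sheet(sprintf("s%d", seq_len(n)), roles,
                        cohort = "A",
                        animal_id = ifelse(roles == "lung",
                                           sprintf("m%d", seq_len(n)), ""))
  if (is.null(gene)) gene <- rep("G", nrow(values))
  structure(list(values = values,
                 size_factors = setNames(rep(1, n), sheet$sample_id),
                 gene = setNames(gene, rownames(values)),
                 samples = sheet, provenance = list()),
            class = "normalized_matrix")
}

test_that("membership thresholds follow the linear-interpolation percentile", {
  vals <- cbind(b = rep(1, 100), m = sample(1:100))
  rownames(vals) <- sprintf("g%03d", 1:100)
  nm <- as_normalized(vals, c("baseline", "lung"))
  mem <- percentile_membership(nm, rank_params(percentile_q = 0.98))
  # 100 distinct values 1..100: threshold 98.02, members are 99 and 100
  expect_equal(sum(mem), 2L)
  expect_equal(sort(vals[mem[, 1], "m"]), c(99L, 100L), ignore_attr = TRUE)

  # all detected guides tie: the threshold equals the common value and
  # every detected guide is a member (>= comparison)
  tied <- as_normalized(cbind(b = rep(1, 5), m = c(7, 7, 7, 0, 7),
                              deparse.level = 0) |>
                          `rownames<-`(sprintf("g%d", 1:5)),
                        c("baseline", "lung"))
  memt <- percentile_membership(tied)
  expect_equal(unname(memt[, 1]), c(TRUE, TRUE, TRUE, FALSE, TRUE))

  # zero-count guides are never members, whatever the threshold
  expect_false(any(memt[4, ]))

  # a lung without detected guides warns and yields an all-false column
  dead <- as_normalized(cbind(b = c(1, 1), m1 = c(0, 0), m2 = c(2, 1),
                              deparse.level = 0) |>
                          `rownames<-`(c("g1", "g2")),
                        c("baseline", "lung", "lung"))
  expect_warning(memd <- percentile_membership(dead), "no detected guides")
  expect_false(any(memd[, 1]))
})

test_that("membership is invariant to rescaling a lung sample", {
  for (seed in 1:10) {
    set.seed(seed)
    vals <- cbind(rpois(40, 50), matrix(rpois(40 * 4, 3), ncol = 4))
    rownames(vals) <- sprintf("g%02d", 1:40)
    nm <- as_normalized(vals, c("baseline", rep("lung", 4)))
    mem <- percentile_membership(nm)
    scaled <- nm
    scaled$values[, 3] <- scaled$values[, 3] * 17.3
    expect_identical(percentile_membership(scaled), mem)
  }
})

test_that("membership count per lung is bounded by the percentile tail plus ties", {
  for (seed in 1:20) {
    set.seed(seed)
    vals <- cbind(rpois(30, 20), matrix(rpois(30 * 3, 2), ncol = 3))
    rownames(vals) <- sprintf("g%02d", 1:30)
    nm <- as_normalized(vals, c("baseline", rep("lung", 3)))
    mem <- percentile_membership(nm)
    for (j in 1:3) {
      x <- nm$values[, j + 1]
      nz <- sum(x > 0)
      if (nz == 0) next
      thr <- quantile(x[x > 0], 0.98, type = 7, names = FALSE)
      bound <- ceiling(0.02 * nz) + sum(x == thr)
      expect_lte(sum(mem[, j]), bound)
    }
  }
})

test_that("per-guide statistics reproduce the defining formulas", {
  vals <- rbind(g1 = c(5, 5, 10, 20, 30, 0),
                g2 = c(2, 2, 0, 0, 0, 0),
                g3 = c(7, 7, 7, 7, 7, 0),
                g4 = c(1, 3, 0, 12, 0, 0))
  nm <- as_normalized(vals, c("baseline", "baseline", rep("lung", 4)))
  # the fourth lung is deliberately empty (no detected guides)
  mem <- suppressWarnings(percentile_membership(nm))
  st <- compute_guide_stats(nm, mem)
  i <- match(c("g1", "g2", "g3", "g4"), st$guide_id)
  # lung values {10,20,30} present in 3 mice, baseline mean 5
  expect_equal(st$n_present[i], c(3L, 0L, 3L, 1L))
  expect_equal(st$count_mean[i[1]], 20)
  expect_equal(st$sd[i[1]], 10)
  expect_equal(st$sem[i[1]], 10 / sqrt(3), tolerance = 1e-12)
  expect_equal(st$z_score[i[1]], (20 - 5) / (10 / sqrt(3)), tolerance = 1e-12)
  expect_equal(round(st$z_score[i[1]], 3), 2.598)
  # absent guide: n = 0, n_nep = 0, z missing
  expect_true(is.na(st$z_score[i[2]]))
  expect_equal(st$n_nep[i[2]], 0L)
  # constant lung values: SD = 0, z missing (0/0 guarded)
  expect_equal(st$sd[i[3]], 0)
  expect_true(is.na(st$z_score[i[3]]))
  # single present mouse: sd 0 by convention, z missing
  expect_equal(st$sd[i[4]], 0)
  expect_true(is.na(st$z_score[i[4]]))
  # structural invariants
  expect_true(all(st$n_nep <= st$n_present))
  expect_true(all(st$n_present <= 4))
  ok <- st$n_present >= 1
  expect_equal(st$sem[ok], st$sd[ok] / sqrt(st$n_present[ok]))
})

test_that("guides rank by n_NEP, then z, then id, with missing z last", {
  tab <- data.frame(
    guide_id = c("A", "B", "C", "D", "E"),
    gene = c("Olfr441", "Pcdh7", "Fut7", "Mgat5", "Tmem116"),
    n_present = 20L, count_mean = 1, sd = 1, sem = 1,
    z_score = c(9.04, 8.73, 10.76, NA, 8.47),
    n_nep = c(13L, 13L, 16L, 13L, 13L),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("guide_stats", "data.frame")
  ranked <- rank_guides(tab)
  # the 16-mouse guide leads; 13-mouse guides follow by z; missing z is last
  expect_equal(ranked$guide_id, c("C", "A", "B", "E", "D"))
  expect_equal(ranked$rank, 1:5)

  same <- tab
  same$z_score <- 1; same$n_nep <- 2L
  expect_equal(rank_guides(same)$guide_id, c("A", "B", "C", "D", "E"))
  single <- rank_guides(tab[3, , drop = FALSE])
  expect_equal(single$rank, 1L)
})

test_that("the hit filter is strict at the 30% boundary", {
  tab <- data.frame(guide_id = sprintf("g%02d", 0:40), gene = "G",
                    n_nep = 0:40, stringsAsFactors = FALSE)
  hits <- call_hits(tab, n_mice = 40, rank_params(hit_fraction = 0.30))
  expect_false(hits$is_hit[hits$n_nep == 12])   # exactly 30%: excluded
  expect_true(hits$is_hit[hits$n_nep == 13])    # 32.5% of mice
  expect_true(hits$is_hit[hits$n_nep == 16])
  expect_equal(min(hits$n_nep[hits$is_hit]), 13L)
  # n_nep = 0 is never a hit for any cohort size
  for (n in c(1, 5, 40, 1000)) {
    expect_false(call_hits(tab[1, ], n, rank_params())$is_hit)
  }
})

test_that("gene aggregation takes each gene's best guide and separates controls", {
  lib <- guide_library(
    guide_id = c(sprintf("GX_g%d", 1:5), "GY_g1", "NTC_1"),
    gene = c(rep("GX", 5), "GY", CONTROL_GENE_LABEL),
    tss_id = c(sprintf("GX_t%d", 1:5), "GY_t1", ""),
    protospacer = c("AAAA", "CCCC", "GGGG", "TTTT", "ACGT", "TGCA", "CAGT"),
    is_control = c(rep(FALSE, 6), TRUE)
  )
  tab <- data.frame(
    guide_id = lib$guide_id,
    gene = lib$gene,
    n_present = 10L, count_mean = 1, sd = 1, sem = 1,
    z_score = c(5, 1, NA, NA, 2, 3, 9),
    n_nep = c(16L, 2L, 0L, 0L, 1L, 3L, 14L),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("guide_stats", "data.frame")
  agg <- aggregate_to_genes(call_hits(rank_guides(tab), 40), lib)
  gx <- agg[agg$gene == "GX", ]
  expect_equal(gx$best_guide, "GX_g1")
  expect_equal(gx$n_nep, 16L)
  expect_true(gx$gene_is_hit)        # hit via its best guide (16/40)
  expect_false(agg$gene_is_hit[agg$gene == "GY"])  # 3/40 is no hit
  ctrl <- agg[agg$is_control, ]
  expect_equal(ctrl$gene, CONTROL_GENE_LABEL)      # control flagged separately
  expect_true(ctrl$gene_is_hit)                    # 14/40 control flagged, not a gene hit
  expect_error(aggregate_to_genes(call_hits(rank_guides(
    transform(tab, guide_id = sub("NTC_1", "ghost", guide_id))), 40), lib),
    "absent from library")
})

test_that("the full ranking wrapper matches its composed stages", {
  sim <- simulate_screen(sim_config(n_genes = 12, guides_per_gene = 5,
                                    n_controls = 6, baseline_depth = 2e4,
                                    n_mice = 8, injection_cells = 1e4,
                                    met_bottleneck = 15, lung_depth = 1e4,
                                    seed = 31))
  nm <- preprocess_counts(sim$counts)
  whole <- percentile_rank(nm)
  mem <- percentile_membership(nm)
  manual <- call_hits(rank_guides(compute_guide_stats(nm, mem)), n_mice = 8)
  expect_equal(whole, manual)
})
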