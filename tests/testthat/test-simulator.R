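test_that("generated libraries have the configured composition and are seeded", {
  lib <- generate_library(3, 2, 4, seed = 11, protospacer_length = 10)
  expect_equal(nrow(lib), 3 * 2 + 4)
  expect_equal(sum(!lib$is_control), 6L)
  expect_equal(sum(lib$is_control), 4L)
  expect_equal(unname(table(lib$gene[!lib$is_control])), rep(2L, 3),
               ignore_attr = TRUE)
  expect_identical(generate_library(3, 2, 4, seed = 11, protospacer_length = 10),
                   lib)
  expect_false(identical(generate_library(3, 2, 4, seed = 12,
                                          protospacer_length = 10)$protospacer,
                         lib$protospacer))
  one <- generate_library(1, 1, 0, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(sum(one$is_control), 0L)
  # alphabet too small for the requested uniqueness
  expect_error(generate_library(4, 1, 0, seed = 1, protospacer_length = 1),
               "too short")
})

test_that("plasmid proportions are positive, normalized, and dispersion-calibrated", {
  lib <- random_library(3, n_genes = 40, guides_per_gene = 5, n_controls = 0)
  p0 <- simulate_plasmid_proportions(lib, sigma = 0, seed = 5)
  expect_equal(unname(p0), rep(1 / nrow(lib), nrow(lib)))
  p1 <- simulate_plasmid_proportions(lib, sigma = 1, seed = 5)
  expect_identical(p1, simulate_plasmid_proportions(lib, sigma = 1, seed = 5))
  expect_true(all(p1 > 0))
  expect_equal(sum(p1), 1, tolerance = 1e-12)
  expect_error(simulate_plasmid_proportions(lib, sigma = -1), ">= 0")
  # the SD of log proportions estimates sigma (normalization only shifts logs)
  big <- generate_library(2245, 5, 0, seed = 2, protospacer_length = 20)
  sds <- vapply(1:5, function(s) {
    sd(log(simulate_plasmid_proportions(big, sigma = 1, seed = s)))
  }, numeric(1))
  expect_equal(mean(sds), 1, tolerance = 0.05)
})

test_that("baseline replicates are exact-depth multinomial draws", {
  lib <- random_library(4, n_genes = 5, guides_per_gene = 2, n_controls = 0)
  p <- simulate_plasmid_proportions(lib, 0.3, seed = 9)
  base <- simulate_baseline(p, depth = 1000, n_reps = 2, seed = 9)
  expect_equal(ncol(base$counts), 2L)
  expect_true(all(base$samples$role == "baseline"))
  expect_equal(unname(colSums(base$counts)), c(1000, 1000))
  expect_error(simulate_baseline(p, depth = 0, n_reps = 2), ">= 1")
  d1 <- simulate_baseline(p, depth = 1, n_reps = 3, seed = 1)
  expect_equal(unname(colSums(d1$counts > 0)), rep(1L, 3))
})

test_that("uniform-proportion baselines pass a chi-square goodness-of-fit sweep", {
  # depth 1e6 over 100 equally likely guides: expected 1e4 per guide; the
  # GOF test should reject at alpha = 0.01 in at most ~1% of seeds
  lib <- random_library(7, n_genes = 50, guides_per_gene = 2, n_controls = 0)
  p <- simulate_plasmid_proportions(lib, sigma = 0, seed = 1)
  ok <- vapply(1:50, function(s) {
    cnt <- simulate_baseline(p, depth = 1e6, n_reps = 1, seed = s)$counts[, 1]
    suppressWarnings(stats::chisq.test(cnt, p = rep(1 / 100, 100))$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(ok), 45)
})

test_that("lung sampling honors the clonal bottleneck", {
  lib <- random_library(5, n_genes = 100, guides_per_gene = 5, n_controls = 25)
  p <- simulate_plasmid_proportions(lib, 0.5, seed = 3)
  cfg <- sim_config(n_genes = 100, guides_per_gene = 5, n_controls = 25,
                    injection_cells = 1e4, met_bottleneck = 1,
                    lung_depth = 5000, seed = 3)
  one <- simulate_mouse_lung(p, NULL, cfg, mouse_seed = 42)
  expect_equal(sum(one), 5000)
  expect_equal(sum(one > 0), 1L)  # a single clone seeds the whole lung
  cfg50 <- sim_config(n_genes = 100, guides_per_gene = 5, n_controls = 25,
                      injection_cells = 1e4, met_bottleneck = 50,
                      lung_depth = 5000, seed = 3)
  for (ms in 1:20) {
    lung <- simulate_mouse_lung(p, NULL, cfg50, mouse_seed = ms)
    expect_lte(sum(lung > 0), 50)
  }
})

test_that("a selected guide's expected read share matches the weighted-sampling formula", {
  # one driver at 10x weight among 100 equally represented guides, no
  # outgrowth noise: its expected lung read share is f(1+s)/(1 + f*s)
  lib <- random_library(6, n_genes = 50, guides_per_gene = 2, n_controls = 0)
  p <- simulate_plasmid_proportions(lib, sigma = 0, seed = 1)
  cfg <- sim_config(n_genes = 50, guides_per_gene = 2, n_controls = 0,
                    injection_cells = 1e5, met_bottleneck = 100,
                    clone_expansion_sigma = 0, lung_depth = 1e4,
                    selection_s = 9, seed = 1)
  s <- setNames(9, lib$guide_id[1])
  f <- 1 / nrow(lib)
  expected_share <- f * 10 / (1 + f * 9)
  shares <- vapply(1:200, function(ms) {
    lung <- simulate_mouse_lung(p, s, cfg, mouse_seed = ms)
    lung[1] / sum(lung)
  }, numeric(1))
  se <- sqrt(expected_share * (1 - expected_share) / cfg$met_bottleneck / 200)
  expect_equal(mean(shares), expected_share, tolerance = 5 * se / expected_share)
})

test_that("whole-screen simulation has the configured shape and is reproducible", {
  cfg <- sim_config(n_genes = 20, guides_per_gene = 5, n_controls = 10,
                    baseline_depth = 1e4, n_mice = 10, injection_cells = 5000,
                    met_bottleneck = 20, lung_depth = 5000, seed = 21)
  sim <- simulate_screen(cfg)
  expect_equal(dim(sim$counts$counts), c(110L, 12L))
  expect_equal(sum(sim$counts$samples$role == "baseline"), 2L)
  expect_equal(sum(sim$counts$samples$role == "lung"), 10L)
  sim2 <- simulate_screen(cfg)
  expect_identical(sim$counts$counts, sim2$counts$counts)
  expect_identical(sim$truth, sim2$truth)
  # truth marks exactly the configured driver guides
  cfgd <- sim_config(n_genes = 20, guides_per_gene = 5, n_controls = 10,
                     baseline_depth = 1e4, n_mice = 4, injection_cells = 5000,
                     met_bottleneck = 20, lung_depth = 5000,
                     driver_genes = 3, driver_guides_per_gene = 2, seed = 21)
  simd <- simulate_screen(cfgd)
  expect_equal(sum(simd$truth$is_driver_guide), 6L)
  expect_equal(length(unique(simd$truth$gene[simd$truth$is_driver_gene])), 3L)
  expect_true(all(simd$truth$s[simd$truth$is_driver_guide] == cfgd$selection_s))
  expect_true(all(simd$truth$s[!simd$truth$is_driver_guide] == 0))
})

test_that("cohort assignment splits 40 mice 13/14/13", {
  cfg <- sim_config(n_genes = 5, guides_per_gene = 2, n_controls = 2,
                    baseline_depth = 1000, n_mice = 40, injection_cells = 1000,
                    met_bottleneck = 10, lung_depth = 1000, seed = 2)
  sim <- simulate_screen(cfg)
  lungs <- sim$counts$samples[sim$counts$samples$role == "lung", ]
  expect_equal(sort(unname(table(lungs$cohort))), c(13L, 13L, 14L),
               ignore_attr = TRUE)
})

test_that("emitted FASTQ realizes the column and respects the layout bounds", {
  lib <- tiny_library()
  lay <- read_layout(prefix = "ACGTT", protospacer_length = 20)
  fq <- withr::local_tempfile(fileext = ".fastq")
  counts <- setNames(c(3L, 0L, 0L, 0L), lib$guide_id)
  emit_fastq(counts, lib, lay, fq)
  lines <- readLines(fq)
  expect_equal(length(lines), 12L)  # 3 reads x 4 lines
  seqs <- lines[seq(2, 12, by = 4)]
  expect_true(all(grepl(lib$protospacer[1], seqs, fixed = TRUE)))
  expect_true(all(nchar(seqs) == 50))
  # empty column -> valid empty FASTQ
  emit_fastq(setNames(integer(4), lib$guide_id), lib, lay, fq)
  expect_equal(length(readLines(fq)), 0L)
  # protospacer no longer fits after the prefix
  long <- read_layout(prefix = strrep("A", 40), protospacer_length = 20)
  expect_error(emit_fastq(counts, lib, long, fq), "exceeds the read length")
})
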