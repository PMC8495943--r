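# Fixtures are built in code; no data files.

tiny_library <- function() {
  guide_library(
    guide_id = c("GeneA_g1", "GeneA_g2", "GeneB_g1", "NTC_1"),
    gene = c("GeneA", "GeneA", "GeneB", CONTROL_GENE_LABEL),
    tss_id = c("GeneA_tss1", "GeneA_tss2", "GeneB_tss1", ""),
    protospacer = c("AAAACCCCGGGGTTTTAAAA", "CCCCGGGGTTTTAAAACCCC",
                    "GGGGTTTTAAAACCCCGGGG", "TTTTAAAACCCCGGGGTTTT"),
    is_control = c(FALSE, FALSE, FALSE, TRUE)
  )
}

# counts with 2 baseline + n_lung lung columns, rownames g1..g<n>
make_counts <- function(mat, n_baseline = 2, guide_ids = NULL, gene = NULL) {
  mat <- as.matrix(mat)
  if (is.null(guide_ids)) guide_ids <- sprintf("g%d", seq_len(nrow(mat)))
  rownames(mat) <- guide_ids
  n_lung <- ncol(mat) - n_baseline
  sheet <- sample_sheet(
    sample_id = c(sprintf("baseline_%d", seq_len(n_baseline)),
                  sprintf("mouse_%02d", seq_len(n_lung))),
    role = rep(c("baseline", "lung"), c(n_baseline, n_lung)),
    cohort = "A",
    animal_id = c(rep("", n_baseline), sprintf("m%02d", seq_len(n_lung)))
  )
  if (is.null(gene)) gene <- sprintf("Gene%d", seq_len(nrow(mat)))
  count_matrix(mat, sheet, gene)
}

random_library <- function(seed, n_genes = 4, guides_per_gene = 2,
                           n_controls = 2, len = 8) {
  generate_library(n_genes, guides_per_gene, n_controls, seed = seed,
                   protospacer_length = len)
}

random_count_matrix <- function(seed, n_guides = 8, n_baseline = 2, n_lung = 3,
                                max_count = 500) {
  set.seed(seed)
  mat <- matrix(sample.int(max_count + 1L, n_guides * (n_baseline + n_lung),
                           replace = TRUE) - 1L,
                nrow = n_guides)
  make_counts(mat, n_baseline = n_baseline)
}

# The study-scale simulation used by the calibration and recovery suites:
# the 11,225-guide library scaled tenfold down (215 genes x 5 + 50 controls
# = 1,125 guides), 40 mice, injection and bottleneck as configured by
# default, sequencing depths scaled to keep baseline coverage near 180x.
scaled_sim_config <- function(seed, drivers = 0) {
  sim_config(n_genes = 215, guides_per_gene = 5, n_controls = 50,
             plasmid_lognormal_sigma = 0.5,
             baseline_depth = 2e5, n_mice = 40, injection_cells = 5.5e5,
             met_bottleneck = 100, clone_expansion_sigma = 1,
             lung_depth = 1e5,
             driver_genes = drivers, driver_guides_per_gene = 1,
             seed = seed)
}

# Brute-force membership oracle: per lung, sort the pooled values, apply
# the linear-interpolation quantile definition directly, compare with >=.
# Independent of percentile_membership's implementation.
oracle_membership <- function(values, roles, q = 0.98) {
  lungs <- which(roles == "lung")
  out <- matrix(FALSE, nrow(values), length(lungs))
  for (jj in seq_along(lungs)) {
    x <- values[, lungs[jj]]
    pool <- sort(x[x > 0])
    n <- length(pool)
    if (n == 0) next
    h <- 1 + (n - 1) * q
    lo <- floor(h); hi <- ceiling(h)
    thr <- pool[lo] + (h - lo) * (pool[hi] - pool[lo])
    out[, jj] <- x > 0 & x >= thr
  }
  out
}
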