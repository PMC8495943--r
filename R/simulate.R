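#' Simulation configuration for a synthetic bottlenecked screen
#'
#' The defaults describe the study design the package targets: a pooled
#' CRISPRa library of 2195 genes x 5 guides plus 250 nontargeting controls
#' (11,225 guides), two deep "0-hour" baseline replicates, and 40 animals
#' each injected subcutaneously with 5.5e5 library-carrying cells (50x
#' coverage). Each lung is seeded through a severe clonal bottleneck;
#' designated driver guides carry a multiplicative seeding advantage and
#' seeded clones grow out with lognormal dispersion before sequencing.
#'
#' @param n_genes number of targeted genes.
#' @param guides_per_gene guides per gene.
#' @param n_controls nontargeting control guides.
#' @param protospacer_length protospacer length (a library property).
#' @param plasmid_lognormal_sigma SD of log plasmid abundance across guides;
#'   0 gives a perfectly uniform library. Transduction and puromycin
#'   selection are absorbed into this dispersion, as they precede the 0-hour
#'   reference.
#' @param n_baseline_reps number of 0-hour replicates (two in the assay).
#' @param baseline_depth reads per baseline replicate.
#' @param n_mice number of lung samples (animals).
#' @param injection_cells cells injected per animal.
#' @param met_bottleneck clones seeding each lung; must not exceed
#'   `injection_cells`.
#' @param clone_expansion_sigma SD of log clone outgrowth in the lung.
#' @param lung_depth reads per lung sample.
#' @param driver_genes number of genes given a seeding advantage.
#' @param driver_guides_per_gene how many of a driver gene's guides carry it.
#' @param selection_s multiplicative seeding advantage: a driver guide's
#'   clones enter the lung with weight `1 + selection_s` per injected cell.
#'   The default models a strong metastasis driver (roughly a hundredfold
#'   advantage), the regime in which single guides dominate lungs in a
#'   third or more of the cohort.
#' @param seed master RNG seed; every stage and animal draws from a
#'   substream derived from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2195,
                       guides_per_gene = 5,
                       n_controls = 250,
                       protospacer_length = 20,
                       plasmid_lognormal_sigma = 0.5,
                       n_baseline_reps = 2,
                       baseline_depth = 5e6,
                       n_mice = 40,
                       injection_cells = 5.5e5,
                       met_bottleneck = 100,
                       clone_expansion_sigma = 1,
                       lung_depth = 1e6,
                       driver_genes = 0,
                       driver_guides_per_gene = 1,
                       selection_s = 99,
                       seed = 1L) {
  cfg <- list(n_genes = n_genes, guides_per_gene = guides_per_gene,
              n_controls = n_controls, protospacer_length = protospacer_length,
              plasmid_lognormal_sigma = plasmid_lognormal_sigma,
              n_baseline_reps = n_baseline_reps, baseline_depth = baseline_depth,
              n_mice = n_mice, injection_cells = injection_cells,
              met_bottleneck = met_bottleneck,
              clone_expansion_sigma = clone_expansion_sigma,
              lung_depth = lung_depth, driver_genes = driver_genes,
              driver_guides_per_gene = driver_guides_per_gene,
              selection_s = selection_s, seed = as.integer(seed))
  positive <- c("n_genes", "guides_per_gene", "protospacer_length",
                "n_baseline_reps", "baseline_depth", "n_mice",
                "injection_cells", "met_bottleneck", "lung_depth")
  for (f in positive) {
    if (cfg[[f]] < 1) stop("sim_config field '", f, "' must be positive")
  }
  if (cfg$n_controls < 0 || cfg$driver_genes < 0) stop("counts must be nonnegative")
  if (cfg$selection_s < 0) stop("selection_s must be >= 0")
  if (cfg$plasmid_lognormal_sigma < 0 || cfg$clone_expansion_sigma < 0) {
    stop("dispersion sigmas must be >= 0")
  }
  if (cfg$met_bottleneck > cfg$injection_cells) {
    stop("met_bottleneck cannot exceed injection_cells")
  }
  if (cfg$driver_genes > cfg$n_genes) stop("driver_genes cannot exceed n_genes")
  if (cfg$driver_guides_per_gene > cfg$guides_per_gene) {
    stop("driver_guides_per_gene cannot exceed guides_per_gene")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Substream seeds: seed the RNG once with the master seed and draw one
# 31-bit seed per consumer (library, plasmid, baseline, each mouse, truth).
# Keeps animals independent yet fully reproducible, without the stream
# collisions that additive master+offset schemes create.
derive_seeds <- function(master_seed, n) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(master_seed)
  sample.int(2147483646L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Generate a synthetic guide library
#'
#' Targeting guides are named `<gene>_g<k>`; protospacers are drawn
#' uniformly over fixed-length DNA and rejection-sampled to uniqueness.
#'
#' @param n_genes,guides_per_gene,n_controls library composition.
#' @param seed RNG seed.
#' @param protospacer_length protospacer length in nt.
#' @return a [guide_library()] with `n_genes * guides_per_gene` targeting
#'   records followed by `n_controls` controls; deterministic for a fixed
#'   seed.
#' @export
generate_library <- function(n_genes, guides_per_gene, n_controls, seed = 1L,
                             protospacer_length = 20) {
  n_target <- n_genes * guides_per_gene
  n_total <- n_target + n_controls
  if (4^protospacer_length < n_total * 2) {
    stop("protospacer length ", protospacer_length,
         " too short to draw ", n_total, " unique sequences")
  }
  protos <- with_seed(seed, draw_unique_protospacers(n_total, protospacer_length))
  genes <- sprintf("Gene%04d", seq_len(n_genes))
  guide_library(
    guide_id = c(paste0(rep(genes, each = guides_per_gene), "_g",
                        rep(seq_len(guides_per_gene), times = n_genes)),
                 sprintf("NTC_%04d", seq_len(n_controls))),
    gene = c(rep(genes, each = guides_per_gene),
             rep(CONTROL_GENE_LABEL, n_controls)),
    tss_id = c(paste0(rep(genes, each = guides_per_gene), "_tss",
                      rep(seq_len(guides_per_gene), times = n_genes)),
               rep("", n_controls)),
    protospacer = protos,
    is_control = rep(c(FALSE, TRUE), c(n_target, n_controls))
  )
}

draw_unique_protospacers <- function(n, len) {
  bases <- c("A", "C", "G", "T")
  draw <- function(k) {
    apply(matrix(sample(bases, k * len, replace = TRUE), nrow = k), 1, paste0,
          collapse = "")
  }
  protos <- unique(draw(n))
  guard <- 0L
  while (length(protos) < n) {
    protos <- unique(c(protos, draw(n - length(protos))))
    guard <- guard + 1L
    if (guard > 1000L) stop("failed to draw unique protospacers")
  }
  protos[seq_len(n)]
}

#' Simulate plasmid-library guide proportions
#'
#' Log abundances are iid normal with the given dispersion; `sigma = 0`
#' returns the uniform vector. This is the standard minimal model of uneven
#' library representation after cloning and amplification.
#'
#' @param library a [guide_library()].
#' @param sigma SD of log abundance, `>= 0`.
#' @param seed RNG seed.
#' @return named numeric vector of proportions summing to 1.
#' @export
simulate_plasmid_proportions <- function(library, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  n <- nrow(library)
  w <- if (sigma == 0) rep(1, n) else with_seed(seed, exp(rnorm(n, 0, sigma)))
  stats::setNames(w / sum(w), library$guide_id)
}

#' Simulate the 0-hour baseline replicates
#'
#' Each replicate is an independent multinomial draw of `depth` reads over
#' the plasmid proportions, so column sums equal the depth exactly.
#'
#' @param proportions named proportion vector (see
#'   [simulate_plasmid_proportions()]).
#' @param depth reads per replicate, `>= 1`.
#' @param n_reps number of replicates, `>= 1`.
#' @param seed RNG seed.
#' @param gene gene symbols parallel to `proportions` (for the count matrix).
#' @param cohort cohort label recorded on the baseline samples.
#' @return a [count_matrix()] with `n_reps` baseline columns.
#' @export
simulate_baseline <- function(proportions, depth, n_reps, seed = 1L,
                              gene = NULL, cohort = "pooled") {
  if (depth < 1) stop("depth must be >= 1")
  if (n_reps < 1) stop("n_reps must be >= 1")
  counts <- with_seed(seed, rmultinom(n_reps, depth, proportions))
  rownames(counts) <- names(proportions)
  sheet <- sample_sheet(sprintf("baseline_%d", seq_len(n_reps)),
                        role = "baseline", cohort = cohort, animal_id = "")
  if (is.null(gene)) gene <- rep(NA_character_, length(proportions))
  count_matrix(counts, sheet, gene)
}

#' Simulate one animal's lung sample
#'
#' Three conditionally multinomial stages model the spontaneous-metastasis
#' readout: (1) injection — `injection_cells` cells drawn multinomially over
#' the library proportions; (2) metastatic seeding — `met_bottleneck` clones
#' drawn with weight `injected_count * (1 + s_g)` per guide, the bottleneck
#' that makes lungs sparse; (3) outgrowth and sequencing — every seeded
#' clone's mass is scaled by an independent lognormal factor and
#' `lung_depth` reads are drawn over the resulting clone-mass proportions.
#' At most `met_bottleneck` guides can have nonzero reads.
#'
#' @param proportions named plasmid proportion vector.
#' @param s named per-guide selection coefficients (0 = neutral); missing
#'   names are treated as 0.
#' @param config a [sim_config()].
#' @param mouse_seed RNG seed for this animal.
#' @return integer vector of reads per guide (named as `proportions`).
#' @export
simulate_mouse_lung <- function(proportions, s, config, mouse_seed) {
  n <- length(proportions)
  s_vec <- rep(0, n)
  names(s_vec) <- names(proportions)
  if (!is.null(s) && length(s) > 0) s_vec[names(s)] <- s
  with_seed(mouse_seed, {
    injected <- rmultinom(1, config$injection_cells, proportions)[, 1L]
    weights <- injected * (1 + s_vec)
    seeded <- rmultinom(1, config$met_bottleneck, weights)[, 1L]
    idx <- which(seeded > 0)
    # one lognormal outgrowth factor per seeded clone, summed within guide
    mass <- vapply(idx, function(i) {
      sum(rlnorm(seeded[i], meanlog = 0, sdlog = config$clone_expansion_sigma))
    }, numeric(1))
    reads <- integer(n)
    reads[idx] <- rmultinom(1, config$lung_depth, mass)[, 1L]
    stats::setNames(reads, names(proportions))
  })
}

#' Simulate a complete synthetic screen
#'
#' Generates the library, plasmid proportions, baseline replicates and one
#' lung column per animal, together with the ground truth needed for
#' recovery testing. Animals are split into three near-equal cohorts
#' (A/B/C), mirroring independently transduced experimental groups; the
#' analysis pools them.
#'
#' @param config a [sim_config()].
#' @return list with elements `library` (a [guide_library()]), `counts`
#'   (a [count_matrix()] with `n_baseline_reps + n_mice` columns),
#'   `proportions`, and `truth` (data frame: `guide_id`, `gene`, `s`,
#'   `is_driver_guide`, `is_driver_gene`). Fully reproducible from
#'   `config$seed`.
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 4L + config$n_mice)
  lib <- generate_library(config$n_genes, config$guides_per_gene,
                          config$n_controls, seed = seeds[1L],
                          protospacer_length = config$protospacer_length)
  props <- simulate_plasmid_proportions(lib, config$plasmid_lognormal_sigma,
                                        seed = seeds[2L])
  truth <- draw_truth(lib, config, seed = seeds[3L])
  s <- stats::setNames(truth$s[truth$s > 0], truth$guide_id[truth$s > 0])

  baseline <- simulate_baseline(props, config$baseline_depth,
                                config$n_baseline_reps, seed = seeds[4L],
                                gene = lib$gene)
  lungs <- vapply(seq_len(config$n_mice), function(i) {
    simulate_mouse_lung(props, s, config, mouse_seed = seeds[4L + i])
  }, numeric(nrow(lib)))
  rownames(lungs) <- lib$guide_id

  cohort_sizes <- diff(round(seq(0, config$n_mice, length.out = 4)))
  cohorts <- rep(c("A", "B", "C"), times = cohort_sizes)
  lung_sheet <- sample_sheet(sprintf("mouse_%02d", seq_len(config$n_mice)),
                             role = "lung", cohort = cohorts,
                             animal_id = sprintf("m%02d", seq_len(config$n_mice)))
  sheet <- sample_sheet(c(baseline$samples$sample_id, lung_sheet$sample_id),
                        c(baseline$samples$role, lung_sheet$role),
                        c(baseline$samples$cohort, lung_sheet$cohort),
                        c(baseline$samples$animal_id, lung_sheet$animal_id))
  counts <- count_matrix(cbind(baseline$counts, lungs), sheet, lib$gene)
  list(library = lib, counts = counts, proportions = props, truth = truth)
}

draw_truth <- function(lib, config, seed = 1L) {
  s <- rep(0, nrow(lib))
  driver_gene <- rep(FALSE, nrow(lib))
  if (config$driver_genes > 0) {
    genes <- unique(lib$gene[!lib$is_control])
    chosen <- with_seed(seed, sample(genes, config$driver_genes))
    driver_gene <- lib$gene %in% chosen
    for (g in chosen) {
      idx <- which(lib$gene == g)[seq_len(config$driver_guides_per_gene)]
      s[idx] <- config$selection_s
    }
  }
  data.frame(guide_id = lib$guide_id, gene = lib$gene, s = s,
             is_driver_guide = s > 0, is_driver_gene = driver_gene,
             stringsAsFactors = FALSE)
}

#' Emit a FASTQ file realizing a count column
#'
#' Writes exactly `count[g]` reads per guide `g`. Each read is
#' `prefix + protospacer + suffix`, right-padded with `A` or truncated to
#' the layout's read length, with a constant high quality string — the
#' layout the bespoke sequencing primer produces. Quantifying the file with
#' the same layout recovers the column exactly.
#'
#' @param counts named integer vector (guide_id -> reads).
#' @param library a [guide_library()].
#' @param layout a [read_layout()].
#' @param path destination FASTQ (`.gz` supported).
#' @return `path`, invisibly.
#' @export
emit_fastq <- function(counts, library, layout, path) {
  stopifnot(inherits(layout, "read_layout"))
  if (protospacer_length(library) != layout$protospacer_length) {
    stop("layout protospacer_length does not match the library")
  }
  if (nchar(layout$prefix) + layout$protospacer_length > layout$read_length) {
    stop("prefix plus protospacer exceeds the read length")
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    x <- Biostrings::DNAStringSet(character(0))
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(character(0)),
                                compress = grepl("\\.gz$", path))
    return(invisible(path))
  }
  ids <- names(counts)
  protos <- library$protospacer[match(ids, library$guide_id)]
  if (any(is.na(protos))) {
    stop("counts name guides absent from the library: ",
         paste(ids[is.na(protos)], collapse = ", "))
  }
  seq1 <- paste0(layout$prefix, protos, layout$suffix)
  pad <- strrep("A", pmax(0L, layout$read_length - nchar(seq1)))
  seq1 <- substr(paste0(seq1, pad), 1L, layout$read_length)
  times <- as.integer(unname(counts))
  reads <- rep(seq1, times = times)
  read_names <- paste0(rep(ids, times = times), ":read", sequence(times))
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- read_names
  qual <- Biostrings::BStringSet(rep(strrep("I", layout$read_length),
                                     length(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
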