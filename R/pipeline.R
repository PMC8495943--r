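#' Run configuration for the end-to-end pipeline
#'
#' Exactly one count source must be given: a set of per-sample FASTQ files
#' (with a library and layout), a counts TSV (with a sample sheet), or a
#' simulator configuration.
#'
#' @param out_dir directory for all outputs.
#' @param counts,samples paths to a counts TSV and sample-sheet TSV.
#' @param fastq named character vector of FASTQ paths keyed by sample_id
#'   (requires `library_path`, `layout` and `samples`).
#' @param library_path guide-library TSV/FASTA for quantification.
#' @param layout a [read_layout()] for quantification.
#' @param sim a [sim_config()] to simulate the screen instead of reading
#'   data.
#' @param min_baseline_reads baseline filter threshold.
#' @param params a [rank_params()].
#' @param seed seed recorded in provenance; the simulator uses its own
#'   config seed.
#' @param simulate_only if `TRUE`, stop after writing simulated counts and
#'   truth.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       counts = NULL, samples = NULL,
                       fastq = NULL, library_path = NULL, layout = NULL,
                       sim = NULL,
                       min_baseline_reads = 30,
                       params = rank_params(),
                       seed = 1L,
                       simulate_only = FALSE) {
  sources <- c(fastq = !is.null(fastq), counts = !is.null(counts),
               sim = !is.null(sim))
  if (sum(sources) != 1L) {
    stop("exactly one count source required (fastq, counts or sim); got: ",
         if (sum(sources) == 0) "none" else paste(names(sources)[sources], collapse = " + "))
  }
  if (!is.null(fastq) && (is.null(library_path) || is.null(layout) || is.null(samples))) {
    stop("the fastq source needs library_path, layout and samples")
  }
  if (!is.null(counts) && is.null(samples)) {
    stop("the counts source needs a sample sheet")
  }
  for (p in c(counts, samples, library_path, unname(fastq))) {
    if (!file.exists(p)) stop("configured path does not exist: ", p)
  }
  structure(list(out_dir = out_dir, counts = counts, samples = samples,
                 fastq = fastq, library_path = library_path, layout = layout,
                 sim = sim, min_baseline_reads = min_baseline_reads,
                 params = params, seed = as.integer(seed),
                 simulate_only = isTRUE(simulate_only)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' The YAML mirrors the [run_config()] / [sim_config()] / [rank_params()] /
#' [read_layout()] field names, nested under keys `sim`, `params` and
#' `layout`.
#'
#' @param path YAML file.
#' @param out_dir output directory (overrides any `out_dir` in the file).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    out <- ifelse(grepl("^/", p), p, file.path(base, p))
    stats::setNames(out, names(p))
  }
  run_config(
    out_dir = if (!is.null(out_dir)) out_dir else y$out_dir,
    counts = resolve(y$counts), samples = resolve(y$samples),
    fastq = resolve(unlist(y$fastq)), library_path = resolve(y$library),
    layout = if (!is.null(y$layout)) do.call(read_layout, y$layout) else NULL,
    sim = if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL,
    min_baseline_reads = if (!is.null(y$min_baseline_reads)) y$min_baseline_reads else 30,
    params = if (!is.null(y$params)) do.call(rank_params, y$params) else rank_params(),
    seed = if (!is.null(y$seed)) y$seed else 1L,
    simulate_only = isTRUE(y$simulate_only)
  )
}

log_stage <- function(stage, ...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the simulate/quantify -> preprocess -> rank-and-call pipeline
#'
#' Executes the enabled stages in fixed order and writes every output with
#' a provenance JSON (parameters, seed, input hashes). Identical
#' configuration and seed produce byte-identical outputs.
#'
#' @param config a [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @return invisibly, a list with the in-memory results (`counts`,
#'   `normalized`, `ranked`, `genes`, `truth` when simulated) and `paths`
#'   to the files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  truth <- NULL
  library <- NULL

  if (!is.null(config$sim)) {
    log_stage("simulate", "synthetic screen, seed ", config$sim$seed)
    sim <- simulate_screen(config$sim)
    counts <- sim$counts
    truth <- sim$truth
    library <- sim$library
    paths$counts <- file.path(config$out_dir, "counts.tsv")
    paths$samples <- file.path(config$out_dir, "samples.tsv")
    paths$truth <- file.path(config$out_dir, "truth.tsv")
    paths$library <- file.path(config$out_dir, "library.tsv")
    write_counts(counts, paths$counts, paths$samples)
    write_table(truth, paths$truth)
    write_library(library, paths$library)
  } else if (!is.null(config$fastq)) {
    log_stage("quantify", length(config$fastq), " FASTQ file(s)")
    library <- read_library(config$library_path)
    sheet <- read_sample_sheet(config$samples)
    reports <- lapply(config$fastq, quantify_fastq, library = library,
                      layout = config$layout)
    counts <- assemble_matrix(reports, sheet, library)
    paths$counts <- file.path(config$out_dir, "counts.tsv")
    write_counts(counts, paths$counts)
  } else {
    log_stage("load", "counts from ", config$counts)
    counts <- read_counts(config$counts, config$samples)
  }

  result <- list(counts = counts, truth = truth, paths = paths)
  if (config$simulate_only) {
    write_provenance(config, paths, file.path(config$out_dir, "provenance.json"))
    log_stage("done", "simulate-only run")
    return(invisible(result))
  }

  log_stage("preprocess", "baseline filter at ", config$min_baseline_reads,
            " reads, total normalization")
  normalized <- preprocess_counts(counts, config$min_baseline_reads)

  log_stage("callhits", "percentile q=", config$params$percentile_q,
            ", hit fraction ", config$params$hit_fraction)
  ranked <- percentile_rank(normalized, config$params)
  genes <- if (!is.null(library)) aggregate_to_genes(ranked, library) else NULL

  paths$ranked <- file.path(config$out_dir, "ranked.tsv")
  write_table(ranked, paths$ranked)
  if (!is.null(genes)) {
    paths$genes <- file.path(config$out_dir, "genes.tsv")
    write_table(genes, paths$genes)
  }
  paths$report <- file.path(config$out_dir, "report.md")
  writeLines(render_report(ranked, genes, truth = truth), paths$report)
  write_provenance(config, paths, file.path(config$out_dir, "provenance.json"))
  log_stage("done", sum(ranked$is_hit), " hit guide(s)")
  invisible(c(result, list(normalized = normalized, ranked = ranked,
                           genes = genes, paths = paths)))
}

write_provenance <- function(config, paths, path) {
  cfg <- config
  cfg$layout <- unclass(cfg$layout)
  cfg$sim <- unclass(cfg$sim)
  cfg$params <- unclass(cfg$params)
  hashes <- lapply(paths, function(p) unname(tools::md5sum(p)))
  jsonlite::write_json(
    list(package = "prscreen",
         version = as.character(utils::packageVersion("prscreen")),
         config = unclass(cfg),
         outputs = hashes),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Render a human-readable screen report
#'
#' Markdown summary: the top guides, the hit list, a summary of the
#' nontargeting controls, and — when simulation ground truth is supplied —
#' precision and recall of the gene-level hit calls against the designated
#' driver genes.
#'
#' @param ranked a ranked, hit-flagged `guide_stats` data frame.
#' @param genes optional `gene_stats` data frame.
#' @param truth optional simulation truth (data frame with `gene`,
#'   `is_driver_gene`).
#' @param top_n how many top guides to tabulate (default 20).
#' @return character vector of Markdown lines.
#' @export
render_report <- function(ranked, genes = NULL, truth = NULL, top_n = 20) {
  lines <- c("# Screen report", "")
  n_mice <- attr(ranked, "n_lung_samples")
  lines <- c(lines,
             sprintf("%d guides analysed across %s lung samples; %d hit guide(s).",
                     nrow(ranked),
                     if (is.null(n_mice)) "the" else as.character(n_mice),
                     sum(ranked$is_hit)),
             "")
  top <- utils::head(ranked, top_n)
  lines <- c(lines, sprintf("## Top %d guides", nrow(top)), "",
             "| rank | guide | gene | n_NEP | z |",
             "|---:|---|---|---:|---:|",
             sprintf("| %d | %s | %s | %d | %s |",
                     top$rank, top$guide_id, top$gene, top$n_nep,
                     ifelse(is.na(top$z_score), "NA",
                            sprintf("%.2f", top$z_score))),
             "")
  hits <- ranked[ranked$is_hit, , drop = FALSE]
  lines <- c(lines, "## Hits", "")
  if (nrow(hits) == 0) {
    lines <- c(lines, "No guide passed the hit filter.", "")
  } else {
    lines <- c(lines, sprintf("- %s (%s): n_NEP = %d, z = %s",
                              hits$guide_id, hits$gene, hits$n_nep,
                              ifelse(is.na(hits$z_score), "NA",
                                     sprintf("%.2f", hits$z_score))),
               "")
  }
  if (!is.null(genes)) {
    ctrl <- genes[genes$is_control, , drop = FALSE]
    ghits <- genes[genes$gene_is_hit & !genes$is_control, , drop = FALSE]
    lines <- c(lines, "## Gene-level summary", "",
               sprintf("%d gene hit(s): %s", nrow(ghits),
                       if (nrow(ghits) == 0) "none"
                       else paste(ghits$gene, collapse = ", ")),
               "")
    lines <- c(lines, "## Nontargeting controls", "")
    if (nrow(ctrl) == 0) {
      lines <- c(lines, "No control guides in the analysed table.", "")
    } else {
      lines <- c(lines,
                 sprintf("Best control guide: %s (n_NEP = %d, rank %d)%s",
                         ctrl$best_guide[1L], ctrl$n_nep[1L], ctrl$rank[1L],
                         if (any(ctrl$gene_is_hit))
                           " — WARNING: a control passes the hit filter" else ""),
                 "")
    }
    if (!is.null(truth)) {
      drivers <- unique(truth$gene[truth$is_driver_gene])
      called <- ghits$gene
      tp <- length(intersect(called, drivers))
      precision <- if (length(called) > 0) tp / length(called) else NA_real_
      recall <- if (length(drivers) > 0) tp / length(drivers) else NA_real_
      lines <- c(lines, "## Recovery against simulation truth", "",
                 sprintf("%d driver gene(s); precision = %s, recall = %s.",
                         length(drivers),
                         ifelse(is.na(precision), "NA", sprintf("%.3f", precision)),
                         ifelse(is.na(recall), "NA", sprintf("%.3f", recall))),
                 "")
    }
  }
  lines
}
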