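#' Sample metadata sheet
#'
#' Validates the per-sample metadata used throughout the pipeline. Each
#' sequenced sample is either a `baseline` ("0-hour" timepoint replicate of
#' the injected cell population) or a `lung` (one animal's lung), belongs to
#' an experimental cohort, and — for lungs — names its animal.
#'
#' @param sample_id unique sample tokens, matching count-matrix column names.
#' @param role `"baseline"` or `"lung"` per sample.
#' @param cohort cohort token (e.g. `"A"`, `"B"`, `"C"`).
#' @param animal_id animal token; empty string for baseline samples.
#' @return data frame of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, role, cohort = "", animal_id = "") {
  sheet <- data.frame(
    sample_id = as.character(sample_id),
    role = as.character(role),
    cohort = as.character(cohort),
    animal_id = as.character(animal_id),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "))
  }
  bad <- !sheet$role %in% c("baseline", "lung")
  if (any(bad)) {
    stop("sample role must be 'baseline' or 'lung'; got: ",
         paste(unique(sheet$role[bad]), collapse = ", "))
  }
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Read a sample sheet from TSV
#'
#' Expects header columns `sample_id`, `role`, `cohort`, `animal_id`.
#'
#' @param path TSV file.
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "role", "cohort", "animal_id")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("sample sheet missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  sample_sheet(tab$sample_id, tab$role, tab$cohort, tab$animal_id)
}

#' Write a sample sheet to TSV
#' @param sheet a [sample_sheet()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a guide-by-sample count matrix
#'
#' The carrier for all downstream computation: nonnegative integer counts,
#' one row per guide and one column per sample, with per-sample metadata
#' and the guide-to-gene map retained from the library.
#'
#' @param counts integer matrix, guides x samples, finite and `>= 0`;
#'   rownames are guide ids.
#' @param samples a [sample_sheet()] with one row per matrix column, in
#'   column order.
#' @param gene character vector of gene symbols parallel to the rows.
#' @return object of class `count_matrix`: a list with elements `counts`,
#'   `gene` (named by guide), and `samples`.
#' @export
count_matrix <- function(counts, samples, gene) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 && is.null(rownames(counts))) {
    stop("counts must have guide ids as rownames")
  }
  if (nrow(counts) == 0 && is.null(rownames(counts))) {
    dimnames(counts) <- list(character(0), colnames(counts))
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate guide ids in count matrix")
  if (nrow(samples) != ncol(counts)) {
    stop("sample sheet rows (", nrow(samples), ") must match count columns (",
         ncol(counts), ")")
  }
  colnames(counts) <- samples$sample_id
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (length(gene) != nrow(counts)) stop("gene vector must parallel the guide rows")
  structure(
    list(counts = counts,
         gene = stats::setNames(as.character(gene), rownames(counts)),
         samples = samples),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d guides x %d samples (%d baseline, %d lung)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$role == "baseline"), sum(x$samples$role == "lung")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix plus its sample sheet
#'
#' The counts TSV uses the dialect common to pooled-screen tools: leading
#' columns `sgRNA` and `gene`, then one integer column per sample. Sample
#' roles, cohorts and animal ids come from a separate sample sheet so that
#' real screen data drop in without renaming columns.
#'
#' @param path counts TSV.
#' @param sample_sheet path to the sample-sheet TSV, or a [sample_sheet()].
#' @return a [count_matrix()] with columns ordered as in the counts file.
#' @export
read_counts <- function(path, sample_sheet) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  sheet <- if (is.character(sample_sheet)) read_sample_sheet(sample_sheet) else sample_sheet
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (!all(c("sgRNA", "gene") %in% names(tab)[1:2])) {
    stop("counts TSV must start with columns 'sgRNA' and 'gene'")
  }
  sample_cols <- setdiff(names(tab), c("sgRNA", "gene"))
  unknown <- setdiff(sample_cols, sheet$sample_id)
  if (length(unknown) > 0) {
    stop("sample column(s) without a sample-sheet entry: ",
         paste(unknown, collapse = ", "))
  }
  if (length(sample_cols) == 0) stop("counts TSV has no sample columns")
  raw <- as.matrix(tab[, sample_cols, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw), ncol = ncol(raw)))
  if (any(is.na(num) & !is.na(raw))) {
    stop("non-numeric count cell(s), e.g. '", raw[which(is.na(num))[1L]], "'")
  }
  if (any(is.na(num))) stop("missing count cell(s)")
  if (any(num < 0)) stop("negative count cell(s), e.g. ", min(num))
  if (any(num != round(num))) {
    stop("non-integer count cell(s), e.g. ", num[which(num != round(num))[1L]])
  }
  dimnames(num) <- list(tab$sgRNA, sample_cols)
  sheet_ordered <- sheet[match(sample_cols, sheet$sample_id), , drop = FALSE]
  rownames(sheet_ordered) <- NULL
  count_matrix(num, sample_sheet(sheet_ordered$sample_id, sheet_ordered$role,
                                 sheet_ordered$cohort, sheet_ordered$animal_id),
               gene = tab$gene)
}

#' Write a count matrix (and optionally its sample sheet) to TSV
#'
#' `read_counts(write_counts(m), sheet)` is the identity.
#'
#' @param matrix a [count_matrix()].
#' @param path destination counts TSV.
#' @param sample_sheet_path optional path for the companion sample sheet.
#' @return `path`, invisibly.
#' @export
write_counts <- function(matrix, path, sample_sheet_path = NULL) {
  rn <- rownames(matrix$counts)
  if (is.null(rn)) rn <- character(0)  # a 0-guide matrix has no dimnames
  out <- data.frame(sgRNA = rn,
                    gene = unname(matrix$gene),
                    matrix$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet_path)) write_sample_sheet(matrix$samples, sample_sheet_path)
  invisible(path)
}

#' Write a per-guide statistics table to TSV
#'
#' @param stats a data frame of per-guide statistics (see
#'   [compute_guide_stats()]).
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_table <- function(stats, path) {
  utils::write.table(as.data.frame(stats), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

baseline_idx <- function(x) which(x$samples$role == "baseline")
lung_idx <- function(x) which(x$samples$role == "lung")
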