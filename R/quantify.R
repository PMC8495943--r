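#' Read layout for guide quantification
#'
#' Single-end reads carry the protospacer at a fixed offset behind a known
#' 5' adapter/primer sequence. Trimming removes that prefix and takes the
#' next `protospacer_length` bases as the match candidate; everything 3' of
#' the protospacer (vector backbone) is ignored. Only the forward
#' orientation is supported — the bespoke sequencing primer fixes it.
#'
#' @param prefix DNA string expected at the read start (may be empty).
#' @param protospacer_length protospacer length in nt; must match the
#'   library's.
#' @param suffix DNA string 3' of the protospacer, used only when emitting
#'   synthetic reads.
#' @param read_length read length in nt for synthetic reads (default 50).
#' @param anchored if `TRUE` (default) the prefix must sit at position 1;
#'   if `FALSE` the first occurrence anywhere in the read is used.
#' @return a list of class `read_layout`.
#' @export
read_layout <- function(prefix = "", protospacer_length = 20, suffix = "",
                        read_length = 50, anchored = TRUE) {
  if (grepl("[^ACGT]", prefix) || grepl("[^ACGT]", suffix)) {
    stop("layout prefix/suffix must be DNA over A/C/G/T (possibly empty)")
  }
  if (protospacer_length < 1) stop("protospacer_length must be >= 1")
  structure(list(prefix = prefix,
                 protospacer_length = as.integer(protospacer_length),
                 suffix = suffix,
                 read_length = as.integer(read_length),
                 orientation = "forward",
                 anchored = isTRUE(anchored)),
            class = "read_layout")
}

#' Trim reads to protospacer candidates
#'
#' For each read: if the layout prefix occurs at the read start (or, for an
#' unanchored layout, anywhere), return the following
#' `protospacer_length` bases; otherwise `NA`. Reads too short to contain a
#' full protospacer after the prefix yield `NA`. Vectorized.
#'
#' @param reads character vector of read sequences.
#' @param layout a [read_layout()].
#' @return character vector of candidates, `NA` where no candidate exists.
#' @export
trim_read <- function(reads, layout) {
  stopifnot(inherits(layout, "read_layout"))
  L <- layout$protospacer_length
  if (nzchar(layout$prefix)) {
    if (layout$anchored) {
      start <- ifelse(startsWith(reads, layout$prefix),
                      nchar(layout$prefix) + 1L, NA_integer_)
    } else {
      pos <- regexpr(layout$prefix, reads, fixed = TRUE)
      start <- ifelse(pos > 0L, pos + nchar(layout$prefix), NA_integer_)
    }
  } else {
    start <- rep(1L, length(reads))
  }
  cand <- substr(reads, start, start + L - 1L)
  cand[is.na(start) | nchar(cand) < L] <- NA_character_
  cand
}

#' Quantify a FASTQ file against a guide library
#'
#' Each read is trimmed and its candidate compared for an exact match —
#' no mismatches, no indels — against the library protospacers. A read
#' increments exactly one guide (protospacers are unique by library
#' invariant) or is counted as unmatched.
#'
#' @param fastq_path FASTQ file, plain or gzipped.
#' @param library a [guide_library()].
#' @param layout a [read_layout()].
#' @return a list of class `quant_report`: `total_reads`, `matched_reads`,
#'   `unmatched_reads`, and `counts` (named integer vector over all library
#'   guides, zeros included). Always `matched + unmatched = total`.
#' @export
quantify_fastq <- function(fastq_path, library, layout) {
  if (!file.exists(fastq_path)) stop("FASTQ not found: ", fastq_path)
  validate_fastq_structure(fastq_path)
  reads <- tryCatch(
    as.character(Biostrings::readDNAStringSet(fastq_path, format = "fastq")),
    error = function(e) {
      stop("malformed FASTQ '", fastq_path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  cand <- trim_read(unname(reads), layout)
  hit <- match(cand, library$protospacer)
  counts <- tabulate(hit, nbins = nrow(library))
  names(counts) <- library$guide_id
  matched <- sum(!is.na(hit))
  structure(list(total_reads = length(reads),
                 matched_reads = matched,
                 unmatched_reads = length(reads) - matched,
                 counts = counts),
            class = "quant_report")
}

# Four-line record structure check with line-numbered diagnostics; the
# sequence parsing itself is delegated to Biostrings.
validate_fastq_structure <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ '", path, "': ", length(lines),
         " lines is not a multiple of 4 (truncated record at line ",
         4 * (length(lines) %/% 4) + 1, ")", call. = FALSE)
  }
  if (length(lines) == 0) return(invisible(TRUE))
  head_lines <- seq(1L, length(lines), by = 4L)
  bad_at <- head_lines[!startsWith(lines[head_lines], "@")]
  if (length(bad_at) > 0) {
    stop("malformed FASTQ '", path, "': record header without '@' at line ",
         bad_at[1L], call. = FALSE)
  }
  bad_plus <- head_lines[!startsWith(lines[head_lines + 2L], "+")]
  if (length(bad_plus) > 0) {
    stop("malformed FASTQ '", path, "': separator without '+' at line ",
         bad_plus[1L] + 2L, call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.quant_report <- function(x, ...) {
  cat(sprintf("quant_report: %d reads, %d matched (%.1f%%), %d unmatched\n",
              x$total_reads, x$matched_reads,
              if (x$total_reads > 0) 100 * x$matched_reads / x$total_reads else 0,
              x$unmatched_reads))
  invisible(x)
}

#' Assemble per-sample quantification reports into a count matrix
#'
#' @param reports named list of [quantify_fastq()] reports, names being
#'   sample ids; every sample id must appear in the sheet. Columns are
#'   ordered as in the sample sheet; sheet samples without a report are an
#'   error, as is a report for an unknown sample.
#' @param sheet a [sample_sheet()].
#' @param library the [guide_library()] shared by all reports.
#' @return a [count_matrix()]; a guide unseen in a sample gets 0 there.
#' @export
assemble_matrix <- function(reports, sheet, library) {
  if (is.null(names(reports)) || any(!nzchar(names(reports)))) {
    stop("reports must be a named list keyed by sample_id")
  }
  if (anyDuplicated(names(reports))) {
    stop("duplicate sample_id among reports: ",
         paste(unique(names(reports)[duplicated(names(reports))]), collapse = ", "))
  }
  extra <- setdiff(names(reports), sheet$sample_id)
  if (length(extra) > 0) {
    stop("report(s) for sample(s) not in the sample sheet: ",
         paste(extra, collapse = ", "))
  }
  missing_rep <- setdiff(sheet$sample_id, names(reports))
  if (length(missing_rep) > 0) {
    stop("no report for sample(s): ", paste(missing_rep, collapse = ", "))
  }
  cols <- vapply(sheet$sample_id, function(s) {
    cnt <- reports[[s]]$counts
    full <- stats::setNames(integer(nrow(library)), library$guide_id)
    full[names(cnt)] <- cnt
    full
  }, integer(nrow(library)))
  rownames(cols) <- library$guide_id
  count_matrix(cols, sheet, library$gene)
}
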