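#' Reserved gene label for nontargeting control guides
#'
#' Nontargeting control gRNAs match no genomic site and carry no gene symbol;
#' they are grouped under this reserved label throughout the package.
#'
#' @export
CONTROL_GENE_LABEL <- "non-targeting"

#' Construct a guide library
#'
#' A guide library is the shared reference for the simulator, the quantifier
#' and the reporter: one row per gRNA with its identifier, target gene symbol
#' (or [CONTROL_GENE_LABEL] for nontargeting controls), the transcription
#' start site it targets, and the protospacer sequence used for exact-match
#' quantification.
#'
#' @param guide_id character vector of unique guide identifiers.
#' @param gene character vector of gene symbols; controls must carry
#'   [CONTROL_GENE_LABEL].
#' @param tss_id character vector naming the targeted TSS (empty string for
#'   controls).
#' @param protospacer uppercase DNA strings over A/C/G/T, all of one length,
#'   unique within the library.
#' @param is_control logical; must agree with `gene == CONTROL_GENE_LABEL`.
#'
#' @return A data frame of class `guide_library` with the five columns above,
#'   in input order.
#' @export
guide_library <- function(guide_id, gene, tss_id, protospacer, is_control) {
  lib <- data.frame(
    guide_id = as.character(guide_id),
    gene = as.character(gene),
    tss_id = as.character(tss_id),
    protospacer = as.character(protospacer),
    is_control = as.logical(is_control),
    stringsAsFactors = FALSE
  )
  validate_guide_library(lib)
  class(lib) <- c("guide_library", "data.frame")
  lib
}

validate_guide_library <- function(lib) {
  dup_id <- lib$guide_id[duplicated(lib$guide_id)]
  if (length(dup_id) > 0) {
    stop("duplicate guide_id in library: ", paste(unique(dup_id), collapse = ", "))
  }
  dup_ps <- lib$protospacer[duplicated(lib$protospacer)]
  if (length(dup_ps) > 0) {
    offenders <- lib$guide_id[lib$protospacer %in% dup_ps]
    stop("duplicate protospacer shared by guides: ",
         paste(offenders, collapse = ", "))
  }
  if (any(is.na(lib$protospacer)) || any(nchar(lib$protospacer) == 0)) {
    stop("protospacers must be nonempty")
  }
  bad <- grepl("[^ACGT]", lib$protospacer)
  if (any(bad)) {
    stop("protospacer with characters outside A/C/G/T for guide(s): ",
         paste(lib$guide_id[bad], collapse = ", "))
  }
  if (length(unique(nchar(lib$protospacer))) > 1) {
    stop("protospacers must share a single length within a library")
  }
  mismatch <- lib$is_control != (lib$gene == CONTROL_GENE_LABEL)
  if (any(mismatch)) {
    stop("is_control must be TRUE exactly when gene is '", CONTROL_GENE_LABEL,
         "'; offending guide(s): ", paste(lib$guide_id[mismatch], collapse = ", "))
  }
  invisible(lib)
}

#' Exact-match protospacer index of a library
#'
#' @param library a [guide_library()].
#' @return named character vector mapping protospacer to guide_id.
#' @export
protospacer_index <- function(library) {
  stats::setNames(library$guide_id, library$protospacer)
}

#' Protospacer length of a library
#'
#' Protospacer length is a property of the library, not a package constant.
#'
#' @param library a [guide_library()].
#' @return integer length shared by all protospacers.
#' @export
protospacer_length <- function(library) {
  nchar(library$protospacer[1L])
}

#' Read a guide library from TSV or FASTA
#'
#' The TSV dialect has a header with columns `guide_id`, `gene`, `tss_id`,
#' `protospacer`, `is_control`. The FASTA dialect encodes
#' `guide_id|gene|tss_id|is_control` in each header line, with the
#' protospacer as the sequence.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"fasta"`; default guessed from the extension.
#' @return a validated [guide_library()], in file order.
#' @export
read_library <- function(path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("library file not found: ", path)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("fa", "fasta", "fna")) "fasta" else "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character", check.names = FALSE)
    need <- c("guide_id", "gene", "tss_id", "protospacer", "is_control")
    missing_cols <- setdiff(need, names(tab))
    if (length(missing_cols) > 0) {
      stop("library TSV missing column(s): ", paste(missing_cols, collapse = ", "))
    }
    guide_library(tab$guide_id, tab$gene, tab$tss_id, toupper(tab$protospacer),
                  tolower(tab$is_control) %in% c("true", "t", "1"))
  } else {
    seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
    fields <- strsplit(names(seqs), "|", fixed = TRUE)
    bad <- lengths(fields) != 4L
    if (any(bad)) {
      stop("FASTA header not of the form guide_id|gene|tss_id|is_control: ",
           names(seqs)[bad][1L])
    }
    fields <- do.call(rbind, fields)
    guide_library(fields[, 1L], fields[, 2L], fields[, 3L],
                  as.character(seqs),
                  tolower(fields[, 4L]) %in% c("true", "t", "1"))
  }
}

#' Write a guide library to TSV or FASTA
#'
#' @param library a [guide_library()].
#' @param path destination file.
#' @param format `"tsv"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- as.data.frame(library)
    out$is_control <- ifelse(out$is_control, "TRUE", "FALSE")
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    seqs <- Biostrings::DNAStringSet(library$protospacer)
    names(seqs) <- paste(library$guide_id, library$gene, library$tss_id,
                         ifelse(library$is_control, "TRUE", "FALSE"), sep = "|")
    Biostrings::writeXStringSet(seqs, path, format = "fasta")
  }
  invisible(path)
}

#' @export
print.guide_library <- function(x, ...) {
  cat(sprintf("guide_library: %d guides (%d targeting %d genes, %d nontargeting controls), protospacer length %d\n",
              nrow(x), sum(!x$is_control),
              length(unique(x$gene[!x$is_control])),
              sum(x$is_control), protospacer_length(x)))
  invisible(x)
}
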