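#' Read transcript annotations from GFF3 or BED
#'
#' Parses an annotation file into a `GRanges` with a `transcript_id`
#' metadata column. Coordinates follow the usual R/Bioconductor convention
#' (1-based, closed); GFF3 is already 1-based, BED intervals (0-based,
#' half-open) are converted at import. Records are returned sorted by
#' `transcript_id`, so the result does not depend on record order in the
#' file.
#'
#' For GFF3 the transcript identifier is taken from the `ID` attribute,
#' falling back to `Name`, then `locus_tag`; for BED it is the name field.
#' Every transcript must be on an explicit strand (`+` or `-`): the 5' end
#' of a minus-strand transcript is its highest genomic coordinate, and all
#' downstream coverage profiles are oriented accordingly.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"`, `"bed"`, or `"auto"` (default) to guess from the
#'   file extension.
#' @param feature_type Optional GFF3 `type` filter (e.g. `"gene"`); `NULL`
#'   keeps all records.
#' @return A `GRanges` with one range per transcript and a `transcript_id`
#'   metadata column.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed"),
                            feature_type = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "gff3") {
    check_field_counts(path, n_fields = 9L, what = "GFF3")
    gr <- rtracklayer::import(path, format = "gff3")
    if (!is.null(feature_type)) {
      gr <- gr[!is.na(gr$type) & as.character(gr$type) %in% feature_type]
    }
    id <- as.character(gr$ID)
    if (!is.null(gr$Name)) {
      id[is.na(id)] <- as.character(gr$Name)[is.na(id)]
    }
    if (!is.null(gr$locus_tag)) {
      id[is.na(id)] <- as.character(gr$locus_tag)[is.na(id)]
    }
    if (length(gr) && anyNA(id)) {
      stop("GFF3 records without an ID/Name/locus_tag attribute at rows: ",
           paste(utils::head(which(is.na(id)), 5), collapse = ", "))
    }
  } else {
    check_field_counts(path, n_fields = 6L, what = "BED")
    gr <- rtracklayer::import(path, format = "bed")
    id <- as.character(gr$name)
  }
  if (any(width(gr) < 1L)) {
    stop("annotation contains empty intervals (end <= start in 0-based terms)")
  }
  if (any(as.character(strand(gr)) == "*")) {
    stop("every transcript must carry an explicit strand (+ or -)")
  }
  if (anyDuplicated(id)) {
    stop("duplicate transcript_id in annotation: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  mcols(gr) <- NULL
  gr$transcript_id <- id
  gr[order(gr$transcript_id)]
}

#' Read aligned-read intervals from BED
#'
#' Reads single, unspliced alignment intervals (one line per read) and tags
#' them with a sample identifier. Intervals are converted from BED's
#' 0-based half-open convention at import and returned coordinate-sorted,
#' so the result has set semantics with respect to line order.
#'
#' @param path Path to a BED file (3 or more columns; column 6, when
#'   present, supplies the strand).
#' @param sample_id Sample label attached to every interval.
#' @return A `GRanges` with a `sample_id` metadata column.
#' @export
read_reads <- function(path, sample_id) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  check_field_counts(path, n_fields = 3L, what = "BED")
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    gr <- GRanges()
    gr$sample_id <- character(0)
    return(gr)
  }
  gr <- rtracklayer::import(path, format = "bed")
  if (any(width(gr) < 1L)) {
    bad <- which(width(gr) < 1L)[1]
    stop("read interval with end <= start at record ", bad)
  }
  mcols(gr) <- NULL
  gr$sample_id <- sample_id
  sort(gr, ignore.strand = TRUE)
}

# Cheap pre-parse so malformed lines are reported with their line number;
# real parsing is rtracklayer's job.
check_field_counts <- function(path, n_fields, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  data <- nzchar(lines) & !grepl("^(#|track|browser)", lines)
  nf <- lengths(strsplit(lines[data], "\t", fixed = TRUE))
  if (any(nf < n_fields)) {
    bad <- which(data)[which(nf < n_fields)[1]]
    stop(what, " parse error at line ", bad, ": expected at least ",
         n_fields, " tab-separated fields, found ", nf[which(nf < n_fields)[1]])
  }
  invisible(TRUE)
}

#' Construct a validated counts table
#'
#' Bundles a transcript-by-sample matrix of non-negative integer read
#' counts with its sample metadata. Column order of `counts` must match the
#' row order of `samples`.
#'
#' @param counts Integer matrix, rows = transcripts (rownames =
#'   transcript_id), columns = samples.
#' @param samples Data frame with columns `sample_id`, `condition`
#'   (`"WT"`/`"mutant"`), `phase` (`"log"`/`"stationary"`) and `replicate`.
#' @return An object of class `counts_table`: a list with elements `counts`
#'   and `samples`.
#' @export
counts_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have transcript_id rownames")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"
  req <- c("sample_id", "condition", "phase", "replicate")
  if (!all(req %in% names(samples))) {
    stop("samples metadata needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(samples) != ncol(counts)) {
    stop("samples rows must match counts columns")
  }
  if (!all(samples$condition %in% c("WT", "mutant"))) {
    stop("condition must be 'WT' or 'mutant'")
  }
  if (!all(samples$phase %in% c("log", "stationary"))) {
    stop("phase must be 'log' or 'stationary'")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- samples$sample_id
  } else if (!identical(colnames(counts), as.character(samples$sample_id))) {
    stop("counts column names must equal samples$sample_id (same order)")
  }
  structure(list(counts = counts,
                 samples = as.data.frame(samples, stringsAsFactors = FALSE)),
            class = "counts_table")
}

#' @export
print.counts_table <- function(x, ...) {
  cat("counts_table:", nrow(x$counts), "transcripts x",
      ncol(x$counts), "samples\n")
  cat("  conditions:", paste(sort(unique(x$samples$condition)), collapse = ", "),
      "| phases:", paste(sort(unique(x$samples$phase)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a counts table and its sample sheet from TSV
#'
#' @param counts_path TSV whose first column is `transcript_id`, remaining
#'   columns one per sample.
#' @param samples_path TSV with columns `sample_id`, `condition`, `phase`,
#'   `replicate` (and optionally `path` pointing at per-sample read BEDs).
#' @return A [counts_table].
#' @export
read_counts <- function(counts_path, samples_path) {
  tab <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  samples <- read.delim(samples_path, stringsAsFactors = FALSE)
  counts_table(mat[, as.character(samples$sample_id), drop = FALSE], samples)
}

#' Count reads overlapping each transcript
#'
#' A read is counted for a transcript when it overlaps it by at least one
#' nucleotide; in stranded mode only reads on the transcript's strand are
#' counted.
#'
#' @param reads_by_sample Named list of read `GRanges`, one per sample, in
#'   the order of `samples`.
#' @param annotations Annotation `GRanges` from [read_annotation()].
#' @param samples Sample metadata data frame (see [counts_table()]).
#' @param stranded Count strand-specifically (default `TRUE`).
#' @return A [counts_table].
#' @export
count_reads <- function(reads_by_sample, annotations, samples,
                        stranded = TRUE) {
  stopifnot(length(reads_by_sample) == nrow(samples))
  mat <- vapply(reads_by_sample, function(rd) {
    countOverlaps(annotations, rd, minoverlap = 1L,
                  ignore.strand = !stranded)
  }, numeric(length(annotations)))
  rownames(mat) <- annotations$transcript_id
  colnames(mat) <- samples$sample_id
  counts_table(mat, samples)
}
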