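#' Write and read result tables
#'
#' Fixed-column TSV serialization for the three result tables:
#' slopes (`transcript_id, phase, slope, intercept, n_bins`), differential
#' abundance (`transcript_id, phase, log2fc, pvalue, padj`) and candidates
#' (`transcript_id, phase, log2fc, slope`). Extra in-memory columns (e.g.
#' `r2`, `base_mean`, pass flags) are not serialized.
#'
#' @param slopes,de,candidates Result data frames as produced by
#'   [slope_table()], [nb_test()] and [select_candidates()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @name results_io
NULL

write_tsv_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  ok <- tryCatch({
    write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' @rdname results_io
#' @export
write_slopes <- function(slopes, path) {
  if (!"n_bins" %in% names(slopes)) slopes$n_bins <- rep(100L, nrow(slopes))
  write_tsv_cols(slopes, c("transcript_id", "phase", "slope", "intercept",
                           "n_bins"), path)
}

#' @rdname results_io
#' @export
read_slopes <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(transcript_id = "character", phase = "character"))
}

#' @rdname results_io
#' @export
write_de <- function(de, path) {
  write_tsv_cols(de, c("transcript_id", "phase", "log2fc", "pvalue", "padj"),
                 path)
}

#' @rdname results_io
#' @export
read_de <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(transcript_id = "character", phase = "character"))
}

#' @rdname results_io
#' @export
write_candidates <- function(candidates, path) {
  if ("candidate" %in% names(candidates)) {
    candidates <- candidates[candidates$candidate, , drop = FALSE]
  }
  write_tsv_cols(candidates, c("transcript_id", "phase", "log2fc", "slope"),
                 path)
}

#' @rdname results_io
#' @export
read_candidates <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(transcript_id = "character", phase = "character"))
}

#' Write the two-section candidate summary table
#'
#' Lays the candidate lists of the two growth phases side by side, one
#' column set per phase (the conventional presentation for a per-phase
#' candidate table). Rows are padded with empty cells when the phases have
#' different numbers of candidates.
#'
#' @param candidates Candidate data frame (all rows or flagged rows; only
#'   `candidate == TRUE` rows are used when the flag is present).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  if ("candidate" %in% names(candidates)) {
    candidates <- candidates[candidates$candidate, , drop = FALSE]
  }
  section <- function(ph) {
    sec <- candidates[candidates$phase == ph,
                      c("transcript_id", "log2fc", "slope"), drop = FALSE]
    sec <- sec[order(sec$transcript_id), , drop = FALSE]
    names(sec) <- paste(ph, names(sec), sep = ".")
    sec
  }
  secs <- lapply(c("log", "stationary"), section)
  n <- max(vapply(secs, nrow, 0L), 1L)
  pad <- function(sec) {
    out <- as.data.frame(lapply(sec, function(col) {
      c(as.character(col), rep("", n - length(col)))
    }), stringsAsFactors = FALSE, check.names = FALSE)
    if (!nrow(out)) out[seq_len(n), ] <- ""
    out
  }
  wide <- do.call(cbind, lapply(secs, pad))
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write all result tables for a run
#'
#' Writes `slopes.tsv`, `differential_abundance.tsv`, `candidates.tsv` and
#' the side-by-side `candidate_table.tsv` into `dir`.
#'
#' @param slopes,de,candidates Result data frames.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_results <- function(slopes, de, candidates, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    slopes = file.path(dir, "slopes.tsv"),
    de = file.path(dir, "differential_abundance.tsv"),
    candidates = file.path(dir, "candidates.tsv"),
    candidate_table = file.path(dir, "candidate_table.tsv")
  )
  write_slopes(slopes, paths[["slopes"]])
  write_de(de, paths[["de"]])
  write_candidates(candidates, paths[["candidates"]])
  write_candidate_table(candidates, paths[["candidate_table"]])
  invisible(paths)
}
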