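#' Per-base 5'->3' coverage profiles for a set of transcripts
#'
#' Computes, for every transcript, the number of reads covering each of its
#' bases (a read contributes to every base it overlaps; it is counted as
#' overlapping the transcript when it shares at least one nucleotide with
#' it). Profiles are oriented 5' to 3': for minus-strand transcripts the
#' per-base vector is reversed so that index 1 is always the biological 5'
#' end. In stranded mode (the default — decay direction is the object of
#' study) only reads on the transcript's strand contribute.
#'
#' @param reads Read `GRanges` (pool replicate samples by concatenating
#'   their `GRanges` before calling, e.g. with `c()`).
#' @param annotations Annotation `GRanges` with `transcript_id` (see
#'   [read_annotation()]).
#' @param stranded Match read strand to transcript strand (default `TRUE`).
#' @return A list of class `positional_profiles` with elements `depth`
#'   (named list of numeric vectors, one per transcript, length = transcript
#'   length) and `n_reads` (named integer vector of overlapping-read
#'   counts).
#' @export
positional_profiles <- function(reads, annotations, stranded = TRUE) {
  stopifnot(is(reads, "GRanges"), is(annotations, "GRanges"),
            !is.null(annotations$transcript_id))
  ids <- annotations$transcript_id
  n_reads <- countOverlaps(annotations, reads, minoverlap = 1L,
                           ignore.strand = !stranded)
  names(n_reads) <- ids
  depth <- stats::setNames(vector("list", length(annotations)), ids)

  ann_strand <- as.character(strand(annotations))
  groups <- if (stranded) c("+", "-") else "*"
  for (s in groups) {
    idx <- if (stranded) which(ann_strand == s) else seq_along(annotations)
    if (!length(idx)) next
    rd <- if (stranded) reads[as.character(strand(reads)) == s] else reads
    cov <- coverage(rd)
    for (i in idx) {
      chr <- as.character(seqnames(annotations))[i]
      a <- start(annotations)[i]
      b <- end(annotations)[i]
      v <- numeric(b - a + 1L)
      if (chr %in% names(cov)) {
        r <- cov[[chr]]
        hi <- min(b, length(r))
        if (hi >= a) v[seq_len(hi - a + 1L)] <- as.numeric(r[a:hi])
      }
      if (ann_strand[i] == "-") v <- rev(v)
      depth[[ids[i]]] <- v
    }
  }
  structure(list(depth = depth, n_reads = n_reads),
            class = "positional_profiles")
}

#' Per-base coverage of a single transcript
#'
#' Single-transcript convenience form of [positional_profiles()].
#'
#' @param reads Read `GRanges`.
#' @param tx A length-1 annotation `GRanges` (with `transcript_id`).
#' @param stranded Match read strand to transcript strand.
#' @return A list with `transcript_id`, `depth` (numeric, index 1 = 5' end)
#'   and `n_overlapping_reads`.
#' @export
compute_depth <- function(reads, tx, stranded = TRUE) {
  if (!is(tx, "GRanges") || length(tx) != 1L) {
    stop("tx must be a single-transcript GRanges")
  }
  if (is.null(tx$transcript_id)) stop("tx lacks a transcript_id")
  pp <- positional_profiles(reads, tx, stranded = stranded)
  list(transcript_id = tx$transcript_id,
       depth = pp$depth[[1]],
       n_overlapping_reads = unname(pp$n_reads[1]))
}

#' Rescale a per-base profile to 100 positional bins
#'
#' Converts per-base depth to relative coverage `r(p) = depth[p] / total`
#' and sums it into 100 bins by the floor rule: base `p` (0-based within
#' the transcript) belongs to bin `floor(100 * p / L) + 1`. Mass-summing
#' conserves the total exactly, so the bins sum to 1 for any transcript
#' length; multiplying the depth by any positive constant leaves the result
#' unchanged.
#'
#' @param depth Numeric vector of per-base depth (index 1 = 5' end), or the
#'   list returned by [compute_depth()].
#' @return Numeric vector of 100 non-negative bin masses summing to 1.
#' @section Degenerate inputs:
#' Transcripts shorter than 100 nt raise an error of class
#' `exoshift_too_short` (a 100-bin rescaling is ill-defined below 100
#' bases); all-zero profiles raise `exoshift_unquantifiable`. The batch
#' wrapper [binned_profiles()] converts these into per-transcript exclusion
#' flags instead of errors.
#' @export
bin_profile <- function(depth) {
  if (is.list(depth)) depth <- depth$depth
  L <- length(depth)
  if (L < 100L) {
    stop(structure(class = c("exoshift_too_short", "error", "condition"),
                   list(message = sprintf(
                     "transcript too short for 100-bin profile (%d nt)", L),
                     call = sys.call(-1))))
  }
  total <- sum(depth)
  if (!is.finite(total) || total <= 0) {
    stop(structure(class = c("exoshift_unquantifiable", "error", "condition"),
                   list(message = "no coverage: profile unquantifiable",
                        call = sys.call(-1))))
  }
  idx <- floor(100 * (seq_len(L) - 1) / L) + 1
  as.numeric(rowsum(depth / total, idx))
}

#' Bin all positional profiles of a sample or condition
#'
#' Applies [bin_profile()] to every transcript, recording exclusions
#' instead of failing: transcripts shorter than 100 nt are flagged
#' `"too_short"` and zero-coverage transcripts `"unquantifiable"`; both get
#' `NA` bins and are dropped from the downstream slope analysis.
#'
#' @param profiles A `positional_profiles` object.
#' @return A list of class `binned_profiles` with elements `bins`
#'   (transcripts x 100 matrix, `NA` rows for excluded transcripts),
#'   `n_reads` (named integer) and `status` (named character:
#'   `"ok"`, `"too_short"` or `"unquantifiable"`).
#' @export
binned_profiles <- function(profiles) {
  stopifnot(inherits(profiles, "positional_profiles"))
  ids <- names(profiles$depth)
  bins <- matrix(NA_real_, nrow = length(ids), ncol = 100L,
                 dimnames = list(ids, NULL))
  status <- stats::setNames(rep("ok", length(ids)), ids)
  for (id in ids) {
    v <- profiles$depth[[id]]
    if (length(v) < 100L) {
      status[id] <- "too_short"
    } else if (sum(v) <= 0) {
      status[id] <- "unquantifiable"
    } else {
      bins[id, ] <- bin_profile(v)
    }
  }
  structure(list(bins = bins, n_reads = profiles$n_reads, status = status),
            class = "binned_profiles")
}

#' @export
print.binned_profiles <- function(x, ...) {
  cat("binned_profiles:", nrow(x$bins), "transcripts (",
      sum(x$status == "ok"), "ok,",
      sum(x$status == "too_short"), "too_short,",
      sum(x$status == "unquantifiable"), "unquantifiable )\n")
  invisible(x)
}

#' Export per-base coverage as bedGraph
#'
#' Writes the genomic (unreversed) per-base depth of every transcript as a
#' bedGraph track for genome-browser inspection.
#'
#' @param profiles A `positional_profiles` object.
#' @param annotations The annotation `GRanges` the profiles were built
#'   from.
#' @param path Output bedGraph path.
#' @return The path, invisibly.
#' @export
export_bedgraph <- function(profiles, annotations, path) {
  stopifnot(inherits(profiles, "positional_profiles"))
  grl <- lapply(seq_along(annotations), function(i) {
    id <- annotations$transcript_id[i]
    v <- profiles$depth[[id]]
    if (as.character(strand(annotations))[i] == "-") v <- rev(v)
    r <- Rle(v)
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    GRanges(as.character(seqnames(annotations))[i],
            IRanges(start(annotations)[i] + starts - 1L,
                    start(annotations)[i] + ends - 1L),
            score = runValue(r))
  })
  gr <- do.call(c, grl)
  gr <- gr[gr$score > 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
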