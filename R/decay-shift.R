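#' Wild-type minus mutant difference curve
#'
#' Subtracts the mutant 100-bin relative coverage profile from the
#' wild-type one, bin by bin. Because both profiles sum to 1 the curve sums
#' to 0 exactly (up to floating point); 5' depletion in the wild type shows
#' up as negative values near the 5' end compensated by positive values
#' toward the 3' end, i.e. an increasing curve.
#'
#' @param wt,mut Numeric vectors of 100 bin masses (from [bin_profile()]),
#'   or lists/one-row objects carrying `transcript_id` and `bins`.
#' @param transcript_id Optional identifier; when both inputs carry one,
#'   they must agree.
#' @return A list of class `difference_curve` with `transcript_id`,
#'   `values` (length 100) and `x`, the bin-midpoint abscissa
#'   `x_i = (i - 0.5) / 100` on `(0, 1)`.
#' @export
difference_curve <- function(wt, mut, transcript_id = NULL) {
  unpack <- function(p) {
    if (is.list(p)) list(id = p$transcript_id, bins = p$bins)
    else list(id = NULL, bins = p)
  }
  w <- unpack(wt); m <- unpack(mut)
  if (!is.null(w$id) && !is.null(m$id) && !identical(w$id, m$id)) {
    stop("difference_curve: transcript_id mismatch (", w$id, " vs ", m$id, ")")
  }
  id <- transcript_id
  if (is.null(id)) id <- w$id
  if (is.null(id)) id <- m$id
  if (length(w$bins) != 100L || length(m$bins) != 100L) {
    stop("profiles must have exactly 100 bins")
  }
  structure(list(transcript_id = id,
                 values = as.numeric(w$bins) - as.numeric(m$bins),
                 x = (seq_len(100) - 0.5) / 100),
            class = "difference_curve")
}

#' OLS slope of a difference curve
#'
#' Fits `D_i = intercept + slope * x_i` by ordinary least squares, with the
#' abscissa the normalized position `x_i = (i - 0.5)/100` on `(0, 1)` (so a
#' slope per 100-bin index equals `slope / 100`). A positive slope means
#' the wild type is 5'-depleted relative to the mutant — the signature of
#' 5' to 3' exonucleolytic decay. Because the difference curve sums to
#' zero, the fitted intercept always equals `-slope / 2`.
#'
#' @param curve A [difference_curve()], or a numeric vector of 100 values.
#' @return A one-row data frame: `transcript_id`, `slope`, `intercept`,
#'   `r2`. `r2` is `NA` for an all-zero (degenerate) curve.
#' @export
ols_slope <- function(curve) {
  if (inherits(curve, "difference_curve")) {
    d <- curve$values; x <- curve$x; id <- curve$transcript_id
  } else {
    d <- as.numeric(curve); x <- (seq_along(d) - 0.5) / length(d); id <- NA_character_
  }
  if (length(d) != 100L) stop("difference curve must have 100 values")
  if (any(!is.finite(d))) stop("non-finite values in difference curve")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- sum(xc * d) / sxx
  intercept <- mean(d) - slope * mean(x)
  sst <- sum((d - mean(d))^2)
  r2 <- if (sst > 0) slope^2 * sxx / sst else NA_real_
  data.frame(transcript_id = if (is.null(id)) NA_character_ else id,
             slope = slope, intercept = intercept, r2 = r2,
             stringsAsFactors = FALSE)
}

#' Decay-shift slopes for all eligible transcripts
#'
#' Pairs the wild-type and mutant binned profiles of one growth phase and
#' computes the difference-curve slope for every eligible transcript. A
#' transcript is eligible when both conditions have an `"ok"` binned
#' profile (length >= 100 nt, nonzero coverage) and at least `min_reads`
#' pooled overlapping reads; ineligible transcripts are recorded with their
#' exclusion reason in the `"exclusions"` attribute.
#'
#' @param wt,mut `binned_profiles` for the wild-type and mutant condition
#'   (replicates pooled), over the same transcript set.
#' @param phase `"log"` or `"stationary"`.
#' @param min_reads Minimum pooled overlapping reads per condition
#'   (default 50).
#' @return A data frame with columns `transcript_id`, `phase`, `slope`,
#'   `intercept`, `r2`, `n_bins`, ordered by `transcript_id`; attribute
#'   `"exclusions"` is a data frame `transcript_id, reason`.
#' @export
slope_table <- function(wt, mut, phase = c("log", "stationary"),
                        min_reads = 50) {
  phase <- match.arg(phase)
  stopifnot(inherits(wt, "binned_profiles"), inherits(mut, "binned_profiles"))
  ids <- rownames(wt$bins)
  if (!identical(ids, rownames(mut$bins))) {
    stop("wt and mut profiles cover different transcript sets")
  }
  reason <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (id in ids) {
    st <- c(wt$status[id], mut$status[id])
    if (any(st == "too_short")) {
      reason[id] <- "too_short"
    } else if (any(st == "unquantifiable")) {
      reason[id] <- "unquantifiable"
    } else if (wt$n_reads[id] < min_reads || mut$n_reads[id] < min_reads) {
      reason[id] <- "low_coverage"
    }
  }
  eligible <- ids[is.na(reason)]
  if (!length(eligible)) {
    warning("slope_table: no eligible transcripts (",
            paste(sprintf("%s=%d", names(table(reason)), table(reason)),
                  collapse = ", "), ")")
  }
  rows <- lapply(eligible, function(id) {
    rec <- ols_slope(difference_curve(wt$bins[id, ], mut$bins[id, ],
                                      transcript_id = id))
    rec
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(0), slope = numeric(0),
               intercept = numeric(0), r2 = numeric(0),
               stringsAsFactors = FALSE)
  out$phase <- rep(phase, nrow(out))
  out$n_bins <- rep(100L, nrow(out))
  out <- out[, c("transcript_id", "phase", "slope", "intercept", "r2",
                 "n_bins")]
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  excl <- data.frame(transcript_id = ids[!is.na(reason)],
                     reason = reason[!is.na(reason)],
                     stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "exclusions") <- excl
  out
}
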