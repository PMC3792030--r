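#' Mean + SD selection thresholds for one growth phase
#'
#' The candidate filter is relative, not absolute: a transcript must exceed
#' the background mean plus one standard deviation of both statistics. The
#' background is every transcript possessing both a differential-abundance
#' result (finite `log2fc`) and a slope in the phase; means use the
#' arithmetic mean and SDs the sample standard deviation (n - 1
#' denominator).
#'
#' @param de Differential-abundance data frame from [nb_test()].
#' @param slopes Slope data frame from [slope_table()].
#' @param phase `"log"` or `"stationary"`.
#' @return A list of class `selection_thresholds`: `phase`, `fc_mean`,
#'   `fc_sd`, `fc_cutoff`, `slope_mean`, `slope_sd`, `slope_cutoff`,
#'   `n_background`, and `background` (the transcript ids used).
#' @export
compute_thresholds <- function(de, slopes, phase = c("log", "stationary")) {
  phase <- match.arg(phase)
  bg <- selection_background(de, slopes, phase)
  if (nrow(bg) < 2L) {
    stop("selection background has fewer than 2 transcripts; ",
         "mean + SD cutoffs are undefined")
  }
  fc_mean <- mean(bg$log2fc); fc_sd <- stats::sd(bg$log2fc)
  slope_mean <- mean(bg$slope); slope_sd <- stats::sd(bg$slope)
  structure(list(phase = phase,
                 fc_mean = fc_mean, fc_sd = fc_sd,
                 fc_cutoff = fc_mean + fc_sd,
                 slope_mean = slope_mean, slope_sd = slope_sd,
                 slope_cutoff = slope_mean + slope_sd,
                 n_background = nrow(bg),
                 background = bg$transcript_id),
            class = "selection_thresholds")
}

#' @export
print.selection_thresholds <- function(x, ...) {
  cat(sprintf(paste0("selection_thresholds [%s]: n=%d\n",
                     "  log2fc cutoff %.4f (mean %.4f + sd %.4f)\n",
                     "  slope  cutoff %.6f (mean %.6f + sd %.6f)\n"),
              x$phase, x$n_background, x$fc_cutoff, x$fc_mean, x$fc_sd,
              x$slope_cutoff, x$slope_mean, x$slope_sd))
  invisible(x)
}

selection_background <- function(de, slopes, phase) {
  de_ph <- de[de$phase == phase & is.finite(de$log2fc), , drop = FALSE]
  sl_ph <- slopes[slopes$phase == phase & is.finite(slopes$slope), ,
                  drop = FALSE]
  bg <- merge(de_ph[, c("transcript_id", "log2fc")],
              sl_ph[, c("transcript_id", "slope")],
              by = "transcript_id")
  bg[order(bg$transcript_id), , drop = FALSE]
}

#' Select candidate 5' to 3' decay targets
#'
#' Applies the dual rule: a transcript is a candidate when its log2 fold
#' change (mutant over wild type) is at least the fold-change cutoff AND
#' its difference-curve slope is at least the slope cutoff AND the slope is
#' strictly positive. Comparisons at the cutoffs are inclusive (`>=`).
#'
#' @param de Differential-abundance data frame from [nb_test()].
#' @param slopes Slope data frame from [slope_table()].
#' @param thresholds A [compute_thresholds()] result for the same phase
#'   (computed if omitted).
#' @param phase `"log"` or `"stationary"`.
#' @return Data frame over the background transcripts with columns
#'   `transcript_id`, `phase`, `log2fc`, `slope`, `passes_fc`,
#'   `passes_slope`, `candidate`, ordered by `transcript_id`; the
#'   `thresholds` object is attached as an attribute.
#' @export
select_candidates <- function(de, slopes, thresholds = NULL,
                              phase = c("log", "stationary")) {
  phase <- match.arg(phase)
  if (is.null(thresholds)) thresholds <- compute_thresholds(de, slopes, phase)
  stopifnot(inherits(thresholds, "selection_thresholds"))
  if (!identical(thresholds$phase, phase)) {
    stop("thresholds were computed for phase ", thresholds$phase,
         ", not ", phase)
  }
  bg <- selection_background(de, slopes, phase)
  out <- data.frame(transcript_id = bg$transcript_id,
                    phase = phase,
                    log2fc = bg$log2fc,
                    slope = bg$slope,
                    stringsAsFactors = FALSE)
  out$passes_fc <- out$log2fc >= thresholds$fc_cutoff
  out$passes_slope <- out$slope >= thresholds$slope_cutoff
  out$candidate <- out$passes_fc & out$passes_slope & out$slope > 0
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  out
}
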