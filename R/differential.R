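#' Median-of-ratios size factors
#'
#' Computes one normalization factor per sample as the median, over
#' transcripts, of the ratio of the sample's count to the transcript's
#' geometric mean across samples. Only transcripts with nonzero counts in
#' every sample enter the median; if no such transcript exists the median
#' is taken per sample over transcripts with a nonzero count in that
#' sample (with a warning).
#'
#' @param counts A [counts_table] or a numeric count matrix (transcripts x
#'   samples).
#' @return Named numeric vector of positive per-sample size factors.
#' @export
size_factors <- function(counts) {
  mat <- if (inherits(counts, "counts_table")) counts$counts else as.matrix(counts)
  if (ncol(mat) < 1L || nrow(mat) < 1L) stop("empty counts matrix")
  if (any(colSums(mat) == 0)) {
    stop("every sample needs at least one transcript with nonzero counts")
  }
  logmat <- log(mat)
  loggeo <- rowMeans(logmat)
  allpos <- is.finite(loggeo)
  if (any(allpos)) {
    ratios <- sweep(mat[allpos, , drop = FALSE], 1, exp(loggeo[allpos]), "/")
    sf <- apply(ratios, 2, median)
  } else {
    warning("no transcript with nonzero counts in all samples; ",
            "falling back to per-sample positive transcripts")
    # geometric mean over positive entries only, per transcript
    loggeo2 <- apply(logmat, 1, function(v) mean(v[is.finite(v)]))
    sf <- vapply(seq_len(ncol(mat)), function(j) {
      ok <- is.finite(logmat[, j]) & is.finite(loggeo2)
      median(mat[ok, j] / exp(loggeo2[ok]))
    }, numeric(1))
  }
  stats::setNames(as.numeric(sf), colnames(mat))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment across the supplied tests.
#' Input values must lie in `[0, 1]`; `NA`s are propagated.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Negative-binomial differential-abundance test (mutant vs wild type)
#'
#' Two-condition exact-style NB test in the classic style: counts are
#' normalized with median-of-ratios [size_factors()]; a per-transcript
#' overdispersion `alpha` (`Var = mu + alpha mu^2`) is estimated by pooled
#' method of moments across conditions and moderated by a parametric trend
#' `alpha(mu) = a0 + a1/mu` fitted by least squares, taking the larger of
#' the gene estimate and the trend (floor `1e-8`); the conservative
#' maximum keeps the test calibrated at two replicates, where the noisy
#' per-gene estimate alone is anticonservative; the p-value conditions on
#' the per-transcript total by enumerating all splits of the summed counts
#' between the two conditions and summing the probabilities of splits at
#' most as likely as the observed one. The log2 fold change (mutant over
#' wild type) uses a pseudocount of 0.5 normalized counts in both the
#' numerator and denominator, for reporting only — the test itself sees no
#' pseudocount. Adjusted p-values are Benjamini-Hochberg across tested
#' transcripts.
#'
#' Transcripts with zero counts in every sample of the phase are excluded
#' from testing and reported with `NA` p-values.
#'
#' @param counts A [counts_table] covering at least the requested phase
#'   with >= 2 replicates per condition.
#' @param phase `"log"` or `"stationary"`.
#' @param dispersion_floor Lower bound for the dispersion estimate.
#' @return Data frame with columns `transcript_id`, `phase`, `log2fc`,
#'   `base_mean`, `pvalue`, `padj`, ordered by `transcript_id`.
#' @export
nb_test <- function(counts, phase = c("log", "stationary"),
                    dispersion_floor = 1e-8) {
  phase <- match.arg(phase)
  stopifnot(inherits(counts, "counts_table"))
  sel <- counts$samples$phase == phase
  if (!any(sel)) stop("no samples for phase ", phase)
  mat <- counts$counts[, sel, drop = FALSE]
  cond <- counts$samples$condition[sel]
  n_wt <- sum(cond == "WT"); n_mut <- sum(cond == "mutant")
  if (n_wt < 2L || n_mut < 2L) {
    stop("need >= 2 replicates per condition in phase ", phase,
         " (found WT=", n_wt, ", mutant=", n_mut, ")")
  }
  # order-invariant: compute on a canonical sample ordering
  ord <- order(cond, counts$samples$sample_id[sel])
  mat <- mat[, ord, drop = FALSE]
  cond <- cond[ord]

  sf <- size_factors(mat)
  q <- sweep(mat, 2, sf, "/")
  iw <- cond == "WT"; im <- cond == "mutant"
  q_wt <- rowMeans(q[, iw, drop = FALSE])
  q_mut <- rowMeans(q[, im, drop = FALSE])
  base_mean <- rowMeans(q)
  tested <- rowSums(mat) > 0

  disp <- estimate_dispersion(q, iw, im, sf, base_mean, tested,
                              dispersion_floor)

  k_wt <- rowSums(mat[, iw, drop = FALSE])
  k_mut <- rowSums(mat[, im, drop = FALSE])
  pval <- rep(NA_real_, nrow(mat))
  idx <- which(tested)
  s_wt <- sf[iw]; s_mut <- sf[im]
  for (g in idx) {
    pval[g] <- nb_exact_pvalue(k_wt[g], k_mut[g], s_wt, s_mut, disp[g])
  }
  padj <- rep(NA_real_, nrow(mat))
  padj[tested] <- bh_adjust(pval[tested])

  out <- data.frame(transcript_id = rownames(mat),
                    phase = phase,
                    log2fc = log2((q_mut + 0.5) / (q_wt + 0.5)),
                    base_mean = base_mean,
                    pvalue = pval,
                    padj = padj,
                    stringsAsFactors = FALSE)
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dispersion") <- disp
  attr(out, "size_factors") <- sf
  out
}

# Pooled method-of-moments dispersion, moderated by a parametric trend
# a0 + a1/mu. With two replicates the per-gene estimate has ~2 residual df;
# taking the maximum of the gene estimate and the trend (the conservative
# sharing rule classically used at low replication) keeps the test's
# type-I error at or below nominal, where an equal-weight average of the
# two is measurably anticonservative.
estimate_dispersion <- function(q, iw, im, sf, base_mean, tested, floor_) {
  rv <- function(m) {
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (ncol(m) - 1)
  }
  w <- (rv(q[, iw, drop = FALSE]) + rv(q[, im, drop = FALSE])) / 2
  z <- base_mean * mean(1 / sf)   # expected shot-noise part of Var(q)
  raw <- rep(floor_, length(base_mean))
  pos <- tested & base_mean > 0
  raw[pos] <- pmax((w[pos] - z[pos]) / base_mean[pos]^2, floor_)
  fit_rows <- pos & is.finite(raw)
  if (sum(fit_rows) >= 3) {
    X <- cbind(1, 1 / base_mean[fit_rows])
    cf <- lm.fit(X, raw[fit_rows])$coefficients
    trend <- pmax(cf[1] + cf[2] / base_mean, floor_)
  } else {
    trend <- raw
  }
  out <- pmax(raw, trend, floor_)
  out[!pos] <- floor_
  out
}

# Exact-style conditional NB test: given totals kA, kB with per-sample
# means q0 * s_j and NB variance, P(observing a split at most as likely).
nb_exact_pvalue <- function(kA, kB, sA_vec, sB_vec, alpha) {
  ks <- kA + kB
  if (ks == 0) return(NA_real_)
  q0 <- ks / (sum(sA_vec) + sum(sB_vec))
  musum <- function(s) q0 * sum(s)
  varsum <- function(s) q0 * sum(s) + alpha * q0^2 * sum(s^2)
  muA <- musum(sA_vec); muB <- musum(sB_vec)
  sizeA <- muA^2 / max(varsum(sA_vec) - muA, 1e-12)
  sizeB <- muB^2 / max(varsum(sB_vec) - muB, 1e-12)
  a <- 0:ks
  pa <- dnbinom(a, mu = muA, size = sizeA) *
    dnbinom(ks - a, mu = muB, size = sizeB)
  tot <- sum(pa)
  if (tot <= 0) return(1)
  pobs <- pa[kA + 1]
  min(1, sum(pa[pa <= pobs * (1 + 1e-7)]) / tot)
}
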