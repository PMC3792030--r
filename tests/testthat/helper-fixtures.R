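# Small constructors shared by the tests.

mk_annotation <- function(ids, start, width, strand = "+", chrom = "chrSim") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = width),
                               strand = strand)
  gr$transcript_id <- ids
  gr
}

mk_reads <- function(start, end, strand = "+", chrom = "chrSim",
                     sample_id = "s1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  gr$sample_id <- rep(sample_id, length(gr))
  gr
}

# a normalized 100-bin profile from arbitrary non-negative weights
mk_bins <- function(w) w / sum(w)

# linear-depletion analytic bins: proportional to 1 - d * (1 - x_i)
analytic_bins <- function(d) {
  x <- (1:100 - 0.5) / 100
  mk_bins(1 - d * (1 - x))
}

small_counts <- function(mat, conditions, phase = "log") {
  n <- ncol(mat)
  samples <- data.frame(
    sample_id = paste0("s", seq_len(n)),
    condition = conditions,
    phase = phase,
    replicate = as.integer(stats::ave(seq_len(n), conditions, FUN = seq_along)),
    stringsAsFactors = FALSE)
  colnames(mat) <- samples$sample_id
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("TX_%04d", seq_len(nrow(mat)))
  }
  exoshift::counts_table(mat, samples)
}
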