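# Independent brute-force reference implementations used as oracles.
# Deliberately written as explicit loops, sharing no code with the package.

oracle_size_factors <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  geo <- numeric(n)
  allpos <- logical(n)
  for (i in seq_len(n)) {
    allpos[i] <- all(mat[i, ] > 0)
    geo[i] <- prod(mat[i, ])^(1 / m)
  }
  sf <- numeric(m)
  for (j in seq_len(m)) {
    ratios <- c()
    for (i in seq_len(n)) {
      if (allpos[i]) ratios <- c(ratios, mat[i, j] / geo[i])
    }
    sf[j] <- median(ratios)
  }
  sf
}

oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running_min <- Inf
  for (k in n:1) {
    i <- ord[k]
    val <- p[i] * n / k
    running_min <- min(running_min, val)
    adj[i] <- min(running_min, 1)
  }
  adj
}

oracle_bin_profile <- function(depth) {
  L <- length(depth)
  total <- sum(depth)
  bins <- numeric(100)
  for (p in 0:(L - 1)) {
    b <- floor(100 * p / L) + 1
    bins[b] <- bins[b] + depth[p + 1] / total
  }
  bins
}

oracle_depth <- function(read_starts, read_ends, tx_start, tx_end, minus) {
  # interval stabbing, genomic coordinates, 1-based closed
  L <- tx_end - tx_start + 1
  depth <- numeric(L)
  for (k in seq_along(read_starts)) {
    for (pos in seq(tx_start, tx_end)) {
      if (read_starts[k] <= pos && pos <= read_ends[k]) {
        depth[pos - tx_start + 1] <- depth[pos - tx_start + 1] + 1
      }
    }
  }
  if (minus) depth <- rev(depth)
  depth
}

oracle_select <- function(tab, fc_cutoff, slope_cutoff) {
  keep <- character(0)
  for (i in seq_len(nrow(tab))) {
    if (tab$log2fc[i] >= fc_cutoff && tab$slope[i] >= slope_cutoff &&
        tab$slope[i] > 0) {
      keep <- c(keep, tab$transcript_id[i])
    }
  }
  sort(keep)
}
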