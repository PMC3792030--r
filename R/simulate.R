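#' Configuration for the synthetic RNA-seq generator
#'
#' Defines the two-strain (wild type vs nuclease deletion mutant), two
#' growth-phase, replicated design the generator emulates, together with
#' the decay model for true targets. For a true target the wild-type
#' read-start weight at relative position `x` in `[0,1]` (0 = 5' end) is
#' `1 - decay_depth * (1 - x)` — a linear 5' depletion — while the mutant
#' is uniform and `2^target_log2fc`-fold more abundant. Non-targets are
#' uniform with equal expected abundance in both strains.
#'
#' @param n_transcripts Number of simulated transcripts.
#' @param length_range Two integers, min/max transcript length in nt
#'   (lengths drawn uniformly).
#' @param n_replicates Biological replicates per condition and phase.
#' @param read_length Read footprint in nt; reads running past the 3' end
#'   of their transcript are truncated there.
#' @param mean_depth Expected reads per transcript per sample for a
#'   transcript of average abundance.
#' @param abundance_sigma Log-normal scale of between-transcript abundance
#'   (meanlog is set so the expected relative abundance is 1).
#' @param nb_dispersion Negative-binomial overdispersion `alpha` of
#'   replicate counts, `Var = mu + alpha * mu^2`. Must be > 0.
#' @param target_fraction Fraction of transcripts that are true 5'->3'
#'   decay targets (0 < f < 1).
#' @param decay_depth Linear 5'-depletion strength `d` in `[0, 1)` applied
#'   to wild-type targets.
#' @param target_log2fc Mutant-over-wild-type log2 abundance shift of
#'   targets.
#' @param seed Master seed; the transcript-structure stream uses
#'   `set.seed(seed)` and sample `j` (in the fixed phase x condition x
#'   replicate order) uses `set.seed((seed + j) %% .Machine$integer.max)`,
#'   so adding samples never perturbs existing ones.
#' @param gap Intergenic gap between consecutive simulated transcripts, nt.
#' @param chrom Name of the single synthetic replicon.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_transcripts = 500L,
                              length_range = c(300L, 3000L),
                              n_replicates = 2L,
                              read_length = 76L,
                              mean_depth = 1000,
                              abundance_sigma = 0.8,
                              nb_dispersion = 0.05,
                              target_fraction = 0.1,
                              decay_depth = 0.6,
                              target_log2fc = 2,
                              seed = 1L,
                              gap = 200L,
                              chrom = "chrSim") {
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              length_range = as.integer(length_range),
              n_replicates = as.integer(n_replicates),
              read_length = as.integer(read_length),
              mean_depth = as.numeric(mean_depth),
              abundance_sigma = as.numeric(abundance_sigma),
              nb_dispersion = as.numeric(nb_dispersion),
              target_fraction = as.numeric(target_fraction),
              decay_depth = as.numeric(decay_depth),
              target_log2fc = as.numeric(target_log2fc),
              seed = as.integer(seed),
              gap = as.integer(gap),
              chrom = as.character(chrom))
  with(cfg, {
    if (n_transcripts < 1L) stop("n_transcripts must be >= 1")
    if (length(length_range) != 2L || length_range[1] > length_range[2] ||
        length_range[1] < 1L) stop("invalid length_range")
    if (n_replicates < 1L) stop("n_replicates must be >= 1")
    if (read_length < 1L) stop("read_length must be >= 1")
    if (mean_depth <= 0) stop("mean_depth must be > 0")
    if (abundance_sigma < 0) stop("abundance_sigma must be >= 0")
    if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
    if (target_fraction <= 0 || target_fraction >= 1)
      stop("target_fraction must be in (0, 1)")
    if (decay_depth < 0 || decay_depth >= 1)
      stop("decay_depth must be in [0, 1): d >= 1 implies negative 5' weights")
  })
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:", x$n_transcripts, "transcripts,",
      x$n_replicates, "replicates x 2 conditions x 2 phases\n")
  cat(sprintf("  decay_depth=%.2f target_log2fc=%.2f target_fraction=%.2f",
              x$decay_depth, x$target_log2fc, x$target_fraction),
      sprintf("mean_depth=%g nb_dispersion=%g seed=%d\n",
              x$mean_depth, x$nb_dispersion, x$seed))
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file with any subset of [simulation_config()] fields;
#'   unspecified fields take their defaults.
#' @return `read_sim_config()` returns a `simulation_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  if (!is.null(vals$length_range)) vals$length_range <- unlist(vals$length_range)
  do.call(simulation_config, vals)
}

#' @rdname read_sim_config
#' @param config A `simulation_config`.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Expected difference-curve slope under linear 5' depletion
#'
#' Analytic oracle for the decay-shift statistic. With wild-type read-start
#' density proportional to `1 - d(1 - x)` and a uniform mutant, the
#' probability-normalized 100-bin difference curve is exactly linear in the
#' bin midpoint `x`, with slope `d / (100 * (1 - d/2))` per unit of
#' normalized position. This is the noiseless expectation of [ols_slope()]
#' on such a pair in the limit where coverage equals read-start density
#' (read footprint small relative to transcript length).
#'
#' @param d Decay depth(s) in `[0, 1)`.
#' @return Numeric vector of expected slopes.
#' @examples
#' expected_slope(0)    # 0
#' expected_slope(0.5)  # 1/150 = 0.00667
#' @export
expected_slope <- function(d) {
  if (any(!is.finite(d)) || any(d < 0) || any(d >= 1)) {
    stop("decay depth must lie in [0, 1)")
  }
  d / (100 * (1 - d / 2))
}

#' Simulate a wild-type vs deletion-mutant RNA-seq dataset
#'
#' Generates annotations, per-sample read intervals, a counts table and a
#' ground-truth table for the two-condition, two-phase, replicated design
#' described in [simulation_config()]. Per-sample read counts are drawn
#' `NB(mu, alpha)`; read 5'-start positions are drawn from the linear
#' decay model for wild-type targets and uniformly otherwise, and each read
#' extends `read_length` nt in the 3' direction, truncated at the
#' transcript's 3' boundary. The counts table equals the realized number of
#' simulated reads per transcript and sample. Identical configurations
#' (including seed) give bit-identical output.
#'
#' @param config A [simulation_config()].
#' @param reads If `FALSE`, skip read placement and return counts only
#'   (useful for count-level studies at large replicate numbers).
#' @return A list of class `decay_sim` with elements `annotations`
#'   (`GRanges`), `reads` (named list of `GRanges`, one per sample, empty
#'   when `reads = FALSE`), `counts` ([counts_table]), `truth` (data frame
#'   `transcript_id, is_target, d, true_log2fc`) and `config`.
#' @export
simulate_dataset <- function(config, reads = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_transcripts

  ## transcript structure stream
  set.seed(config$seed)
  lens <- sample(seq.int(config$length_range[1], config$length_range[2]),
                 n, replace = TRUE)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  n_targets <- round(n * config$target_fraction)
  target_idx <- sort(sample.int(n, n_targets))
  is_target <- seq_len(n) %in% target_idx
  abundance <- rlnorm(n, meanlog = -config$abundance_sigma^2 / 2,
                      sdlog = config$abundance_sigma)

  starts <- cumsum(c(1L, lens[-n] + config$gap))
  ids <- sprintf("TX_%04d", seq_len(n))
  annotations <- GRanges(config$chrom,
                         IRanges(starts, width = lens),
                         strand = strands)
  annotations$transcript_id <- ids

  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         condition = c("WT", "mutant"),
                         phase = c("log", "stationary"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("phase", "condition", "replicate")]
  samples$sample_id <- with(samples, paste(condition, phase, replicate,
                                           sep = "_"))
  samples <- samples[, c("sample_id", "condition", "phase", "replicate")]

  mu_wt <- config$mean_depth * abundance
  fc <- ifelse(is_target, 2^config$target_log2fc, 1)

  counts <- matrix(0, nrow = n, ncol = nrow(samples),
                   dimnames = list(ids, samples$sample_id))
  read_sets <- stats::setNames(vector("list", nrow(samples)),
                               samples$sample_id)

  for (j in seq_len(nrow(samples))) {
    set.seed((config$seed + j) %% .Machine$integer.max)
    mutant <- samples$condition[j] == "mutant"
    mu <- if (mutant) mu_wt * fc else mu_wt
    nij <- rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
    counts[, j] <- nij
    if (reads) {
      read_sets[[j]] <- place_reads(nij, lens, starts, strands,
                                    is_target & !mutant,
                                    config$decay_depth, config$read_length,
                                    config$chrom)
    }
  }

  truth <- data.frame(transcript_id = ids,
                      is_target = is_target,
                      d = ifelse(is_target, config$decay_depth, 0),
                      true_log2fc = ifelse(is_target, config$target_log2fc, 0),
                      stringsAsFactors = FALSE)

  structure(list(annotations = annotations,
                 reads = if (reads) read_sets else list(),
                 counts = counts_table(counts, samples),
                 truth = truth,
                 config = config),
            class = "decay_sim")
}

# Draw read 5'-start positions per transcript and lay genomic intervals.
# depleted: logical per transcript — apply the linear 5' weight 1 - d(1-x).
place_reads <- function(nij, lens, starts, strands, depleted, d, read_length,
                        chrom) {
  pos <- vector("list", length(nij))
  for (i in seq_along(nij)) {
    if (nij[i] == 0L) { pos[[i]] <- integer(0); next }
    L <- lens[i]
    if (depleted[i] && d > 0) {
      x <- (seq_len(L) - 0.5) / L
      w <- 1 - d * (1 - x)
      pos[[i]] <- sample.int(L, nij[i], replace = TRUE, prob = w)
    } else {
      pos[[i]] <- sample.int(L, nij[i], replace = TRUE)
    }
  }
  p5 <- unlist(pos, use.names = FALSE)          # 1-based offset from 5' end
  if (is.null(p5)) p5 <- integer(0)
  tx <- rep.int(seq_along(nij), nij)
  tx_start <- starts[tx]
  tx_end <- starts[tx] + lens[tx] - 1L
  minus <- strands[tx] == "-"
  gstart <- ifelse(minus,
                   pmax(tx_start, tx_end - p5 + 1L - (read_length - 1L)),
                   tx_start + p5 - 1L)
  gend <- ifelse(minus,
                 tx_end - p5 + 1L,
                 pmin(tx_end, tx_start + p5 - 1L + (read_length - 1L)))
  GRanges(chrom, IRanges(as.integer(gstart), as.integer(gend)),
          strand = strands[tx])
}

#' @export
print.decay_sim <- function(x, ...) {
  cat("decay_sim:", length(x$annotations), "transcripts,",
      ncol(x$counts$counts), "samples,",
      sum(x$truth$is_target), "true targets\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes `annotation.gff3`, one `reads_<sample_id>.bed` per sample (when
#' reads were simulated), `counts.tsv`, `samples.tsv` (with a `path` column
#' pointing at the BED files), `truth.tsv` and `config.yaml`.
#'
#' @param sim A `decay_sim` from [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Named list of written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "decay_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- sim$annotations
  gff <- ann
  mcols(gff) <- NULL
  gff$source <- "exoshift_sim"
  gff$type <- "gene"
  gff$ID <- ann$transcript_id
  gff$Name <- ann$transcript_id
  ann_path <- file.path(dir, "annotation.gff3")
  rtracklayer::export(gff, ann_path, format = "gff3")

  samples <- sim$counts$samples
  bed_paths <- character(0)
  if (length(sim$reads)) {
    bed_paths <- file.path(dir, paste0("reads_", samples$sample_id, ".bed"))
    for (j in seq_along(bed_paths)) {
      rtracklayer::export(sim$reads[[samples$sample_id[j]]], bed_paths[j],
                          format = "bed")
    }
    samples$path <- basename(bed_paths)
  }

  counts_path <- file.path(dir, "counts.tsv")
  ctab <- data.frame(transcript_id = rownames(sim$counts$counts),
                     sim$counts$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write.table(ctab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)

  samples_path <- file.path(dir, "samples.tsv")
  write.table(samples, samples_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  truth_path <- file.path(dir, "truth.tsv")
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  config_path <- file.path(dir, "config.yaml")
  write_sim_config(sim$config, config_path)

  invisible(list(annotation = ann_path, reads = bed_paths,
                 counts = counts_path, samples = samples_path,
                 truth = truth_path, config = config_path))
}
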