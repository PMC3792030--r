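#' Run the full decay-detection workflow
#'
#' Executes, per growth phase: replicate pooling per condition, per-base
#' coverage, 100-bin profiles, difference-curve slopes, the NB
#' differential-abundance test, mean + SD thresholds and candidate
#' selection; then writes the combined result TSVs, a descriptive table of
#' significantly changed transcripts (`padj < padj_threshold`), and a run
#' log recording the configuration, seed, thresholds and exclusion counts.
#'
#' @param config Either a [simulation_config()] (the dataset is simulated
#'   in memory) or a list with elements `annotation` (GFF3/BED path),
#'   `samples` (sample-sheet TSV path whose `path` column names per-sample
#'   read BEDs, relative to the sheet's directory) and optionally `counts`
#'   (counts TSV path; when absent, counts are taken by overlap counting
#'   from the read intervals).
#' @param output_dir Directory for result files (created if absent).
#' @param phases Phases to analyze (default both).
#' @param min_reads Pooled-read floor per condition for the slope analysis.
#' @param stranded Strand-specific coverage and counting (default `TRUE`).
#' @param padj_threshold Significance level of the descriptive DE table
#'   (default 0.1).
#' @return Invisibly, a list with `slopes`, `de`, `candidates` (combined
#'   across phases), `thresholds` (per phase), `truth` (when simulated) and
#'   `paths` of the written files.
#' @export
run_pipeline <- function(config, output_dir, phases = c("log", "stationary"),
                         min_reads = 50, stranded = TRUE,
                         padj_threshold = 0.1) {
  phases <- match.arg(phases, several.ok = TRUE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (inherits(config, "simulation_config")) {
    say("input: simulated dataset (seed %d)", config$seed)
    sim <- with_stage("synthetic_data", simulate_dataset(config))
    annotations <- sim$annotations
    reads <- sim$reads
    counts <- sim$counts
    truth <- sim$truth
    say("config: %s", paste(vapply(unclass(config), function(v)
      paste(v, collapse = ","), ""), collapse = " | "))
  } else {
    stopifnot(is.list(config), !is.null(config$annotation),
              !is.null(config$samples))
    say("input: annotation=%s samples=%s", config$annotation, config$samples)
    annotations <- with_stage("io_formats",
                              read_annotation(config$annotation))
    samples <- read.delim(config$samples, stringsAsFactors = FALSE)
    base <- dirname(config$samples)
    reads <- NULL
    if (!is.null(samples$path)) {
      reads <- with_stage("io_formats", stats::setNames(
        lapply(seq_len(nrow(samples)), function(j) {
          read_reads(file.path(base, samples$path[j]), samples$sample_id[j])
        }), samples$sample_id))
    }
    counts <- if (!is.null(config$counts)) {
      with_stage("io_formats", read_counts(config$counts, config$samples))
    } else if (!is.null(reads)) {
      with_stage("io_formats",
                 count_reads(reads, annotations, samples, stranded = stranded))
    } else {
      stop("run_pipeline: need either a counts table or per-sample read BEDs")
    }
    truth <- NULL
  }

  sample_info <- counts$samples
  slopes_all <- list(); de_all <- list(); cand_all <- list()
  thresholds <- list()

  for (ph in phases) {
    if (!is.null(reads) && length(reads)) {
      pooled <- lapply(c("WT", "mutant"), function(cn) {
        sel <- sample_info$phase == ph & sample_info$condition == cn
        do.call(c, unname(reads[sample_info$sample_id[sel]]))
      })
      profs <- with_stage("coverage_profiles", lapply(pooled, function(rd) {
        binned_profiles(positional_profiles(rd, annotations,
                                            stranded = stranded))
      }))
      sl <- with_stage("decay_shift",
                       slope_table(profs[[1]], profs[[2]], phase = ph,
                                   min_reads = min_reads))
      excl <- attr(sl, "exclusions")
      say("[%s] slope analysis: %d transcripts, excluded: %s", ph, nrow(sl),
          if (nrow(excl)) paste(sprintf("%s=%d", names(table(excl$reason)),
                                        table(excl$reason)), collapse = ", ")
          else "none")
    } else {
      sl <- data.frame(transcript_id = character(0), phase = character(0),
                       slope = numeric(0), intercept = numeric(0),
                       r2 = numeric(0), n_bins = integer(0),
                       stringsAsFactors = FALSE)
      say("[%s] slope analysis skipped: no read intervals supplied", ph)
    }
    de <- with_stage("differential_abundance", nb_test(counts, phase = ph))
    say("[%s] DE: %d tested, %d significant at padj < %g", ph,
        sum(!is.na(de$padj)), sum(!is.na(de$padj) & de$padj < padj_threshold),
        padj_threshold)
    if (nrow(sl)) {
      th <- with_stage("selection_pipeline", compute_thresholds(de, sl, ph))
      cand <- with_stage("selection_pipeline",
                         select_candidates(de, sl, th, ph))
      thresholds[[ph]] <- th
      say(paste0("[%s] thresholds: fc_cutoff=%.4f slope_cutoff=%.6f ",
                 "(background n=%d); candidates=%d"),
          ph, th$fc_cutoff, th$slope_cutoff, th$n_background,
          sum(cand$candidate))
      cand_all[[ph]] <- cand
    }
    slopes_all[[ph]] <- sl
    de_all[[ph]] <- de
  }

  slopes <- do.call(rbind, slopes_all); rownames(slopes) <- NULL
  de <- do.call(rbind, de_all); rownames(de) <- NULL
  candidates <- if (length(cand_all)) {
    x <- do.call(rbind, cand_all); rownames(x) <- NULL; x
  } else {
    data.frame(transcript_id = character(0), phase = character(0),
               log2fc = numeric(0), slope = numeric(0),
               passes_fc = logical(0), passes_slope = logical(0),
               candidate = logical(0), stringsAsFactors = FALSE)
  }

  paths <- write_results(slopes, de, candidates, output_dir)
  sig <- de[!is.na(de$padj) & de$padj < padj_threshold, , drop = FALSE]
  sig_path <- file.path(output_dir, "de_significant.tsv")
  write_de(sig, sig_path)
  paths <- c(paths, de_significant = sig_path)
  if (!is.null(truth)) {
    truth_path <- file.path(output_dir, "truth.tsv")
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, truth = truth_path)
  }
  log_path <- file.path(output_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  paths <- c(paths, log = log_path)

  invisible(list(slopes = slopes, de = de, candidates = candidates,
                 thresholds = thresholds, truth = truth, paths = paths))
}

# Propagate any stage failure with the stage name, per the pipeline
# error contract.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}
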