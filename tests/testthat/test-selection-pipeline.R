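mk_tables <- function(ids, log2fc, slope, phase = "log") {
  list(
    de = data.frame(transcript_id = ids, phase = phase, log2fc = log2fc,
                    base_mean = 100, pvalue = 0.5, padj = 0.5,
                    stringsAsFactors = FALSE),
    slopes = data.frame(transcript_id = ids, phase = phase, slope = slope,
                        intercept = -slope / 2, r2 = 0.5, n_bins = 100L,
                        stringsAsFactors = FALSE))
}

test_that("thresholds are background mean + one sample SD", {
  tabs <- mk_tables(letters[1:4], log2fc = c(0, 0, 0, 4),
                    slope = rep(0.005, 4))
  th <- compute_thresholds(tabs$de, tabs$slopes, "log")
  expect_equal(th$fc_mean, 1)
  expect_equal(th$fc_sd, 2)       # sample SD, n - 1 denominator
  expect_equal(th$fc_cutoff, 3)
  expect_equal(th$slope_cutoff, 0.005)  # SD = 0 when all slopes equal
  expect_equal(th$n_background, 4)
  expect_setequal(th$background, letters[1:4])

  one <- mk_tables("a", 1, 0.01)
  expect_error(compute_thresholds(one$de, one$slopes, "log"), "fewer than 2")
})

test_that("a fully degenerate background yields no candidates", {
  tabs <- mk_tables(letters[1:5], log2fc = rep(1.3, 5), slope = rep(0, 5))
  cand <- select_candidates(tabs$de, tabs$slopes, phase = "log")
  # everything ties at both cutoffs (SD = 0) but slope > 0 fails
  expect_true(all(cand$passes_fc & cand$passes_slope))
  expect_false(any(cand$candidate))
})

test_that("selection matches exhaustive enumeration on toy and random tables", {
  ids <- sprintf("g%02d", 1:10)
  tabs <- mk_tables(ids,
                    log2fc = c(3, 2.5, 0.1, -1, 0.4, 2.9, 0.2, 0.1, 5, 0.3),
                    slope = c(0.009, -0.002, 0.001, 0.008, 0, 0.007,
                              0.002, 0.001, 0.012, -0.004))
  th <- compute_thresholds(tabs$de, tabs$slopes, "log")
  cand <- select_candidates(tabs$de, tabs$slopes, th, "log")
  expect_equal(sort(cand$transcript_id[cand$candidate]),
               oracle_select(tabs$de |>
                               merge(tabs$slopes, by = c("transcript_id", "phase")),
                             th$fc_cutoff, th$slope_cutoff))

  set.seed(90)
  for (i in 1:40) {
    n <- sample(5:40, 1)
    tabs <- mk_tables(sprintf("g%02d", 1:n),
                      log2fc = rnorm(n, 0, 1.5),
                      slope = rnorm(n, 0, 0.004))
    th <- compute_thresholds(tabs$de, tabs$slopes, "log")
    cand <- select_candidates(tabs$de, tabs$slopes, th, "log")
    merged <- merge(tabs$de, tabs$slopes, by = c("transcript_id", "phase"))
    expect_equal(sort(cand$transcript_id[cand$candidate]),
                 oracle_select(merged, th$fc_cutoff, th$slope_cutoff))
  }
})

test_that("ties at the cutoffs are included (inclusive >=)", {
  tabs <- mk_tables(letters[1:4], log2fc = c(0, 0, 0, 4),
                    slope = c(0.001, 0.002, 0.003, 0.010))
  th <- compute_thresholds(tabs$de, tabs$slopes, "log")
  # transcript d sits exactly at neither cutoff; craft one that does
  tabs$de$log2fc[4] <- th$fc_cutoff
  cand <- select_candidates(tabs$de, tabs$slopes, th, "log")
  expect_true(cand$passes_fc[cand$transcript_id == "d"])
})

test_that("selection is monotone and order-invariant", {
  set.seed(33)
  n <- 25
  tabs <- mk_tables(sprintf("g%02d", 1:n), rnorm(n, 0, 1.5),
                    rnorm(n, 0.001, 0.004))
  th <- compute_thresholds(tabs$de, tabs$slopes, "log")
  cand <- select_candidates(tabs$de, tabs$slopes, th, "log")
  hit <- cand$transcript_id[cand$candidate]
  # raising a candidate's statistics (thresholds held fixed) keeps it in
  for (id in hit) {
    de2 <- tabs$de; sl2 <- tabs$slopes
    de2$log2fc[de2$transcript_id == id] <- de2$log2fc[de2$transcript_id == id] + 1
    sl2$slope[sl2$transcript_id == id] <- sl2$slope[sl2$transcript_id == id] + 0.01
    cand2 <- select_candidates(de2, sl2, th, "log")
    expect_true(cand2$candidate[cand2$transcript_id == id])
  }
  # permuting table rows changes nothing
  perm <- sample(n)
  cand3 <- select_candidates(tabs$de[perm, ], tabs$slopes[rev(perm), ], th, "log")
  expect_equal(cand3, cand, ignore_attr = TRUE)
})

test_that("phase mismatch between thresholds and selection is an error", {
  tabs <- mk_tables(letters[1:4], c(0, 0, 0, 4), rep(0.005, 4))
  th <- compute_thresholds(tabs$de, tabs$slopes, "log")
  expect_error(select_candidates(tabs$de, tabs$slopes, th, "stationary"),
               "phase")
})

test_that("run_pipeline writes the full output set and honors phase choice", {
  cfg <- simulation_config(n_transcripts = 60, mean_depth = 250, seed = 12)
  out <- tempfile()
  res <- run_pipeline(cfg, out)
  expect_true(all(file.exists(unlist(res$paths))))
  expect_setequal(unique(res$slopes$phase), c("log", "stationary"))
  expect_setequal(unique(res$de$phase), c("log", "stationary"))
  log_txt <- readLines(res$paths[["log"]])
  expect_true(any(grepl("thresholds", log_txt)))
  expect_true(any(grepl("seed", log_txt)))

  out_log <- tempfile()
  res_log <- run_pipeline(cfg, out_log, phases = "log")
  expect_equal(unique(res_log$de$phase), "log")
  expect_false(any(res_log$candidates$phase == "stationary"))
})

test_that("candidates on a simulated dataset score against the ground truth", {
  cfg <- simulation_config(n_transcripts = 150, mean_depth = 600,
                           decay_depth = 0.6, target_log2fc = 2, seed = 4)
  res <- run_pipeline(cfg, tempfile(), phases = "log")
  truth <- res$truth
  cand <- res$candidates[res$candidates$candidate, ]
  hits <- truth$is_target[match(cand$transcript_id, truth$transcript_id)]
  expect_gt(length(hits), 0)
  expect_gt(mean(hits), 0.5)  # most selected transcripts are true targets
})
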