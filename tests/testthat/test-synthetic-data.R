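test_that("identical config and seed give bit-identical datasets", {
  cfg <- simulation_config(n_transcripts = 40, mean_depth = 150, seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$reads, GenomicRanges::start),
                   lapply(b$reads, GenomicRanges::start))
  expect_identical(lapply(a$reads, GenomicRanges::end),
                   lapply(b$reads, GenomicRanges::end))

  da <- tempfile(); db <- tempfile()
  write_dataset(a, da); write_dataset(b, db)
  for (f in list.files(da)) {
    expect_identical(readLines(file.path(da, f)), readLines(file.path(db, f)),
                     label = paste("file", f))
  }
})

test_that("adding replicates never perturbs existing samples", {
  base <- simulate_dataset(simulation_config(n_transcripts = 30,
                                             n_replicates = 2, seed = 7))
  more <- simulate_dataset(simulation_config(n_transcripts = 30,
                                             n_replicates = 3, seed = 7))
  # sample j in the fixed enumeration is driven by stream seed + j; the
  # first sample of each phase x condition block is unchanged
  shared <- intersect(colnames(base$counts$counts), colnames(more$counts$counts))
  expect_gt(length(shared), 0)
  first_of_block <- shared[grepl("_1$", shared)]
  expect_identical(base$counts$counts[, "WT_log_1"],
                   more$counts$counts[, "WT_log_1"])
})

test_that("truth table covers the transcript set at the configured target fraction", {
  cfg <- simulation_config(n_transcripts = 137, target_fraction = 0.1,
                           seed = 2)
  sim <- simulate_dataset(cfg, reads = FALSE)
  expect_setequal(sim$truth$transcript_id, sim$annotations$transcript_id)
  expect_equal(sum(sim$truth$is_target), round(137 * 0.1))
  expect_true(all(sim$truth$d[!sim$truth$is_target] == 0))
  expect_true(all(sim$truth$d[sim$truth$is_target] == cfg$decay_depth))
  expect_true(all(sim$truth$true_log2fc[sim$truth$is_target] ==
                    cfg$target_log2fc))
})

test_that("simulated reads stay inside their transcript and match read_length", {
  cfg <- simulation_config(n_transcripts = 25, length_range = c(150, 600),
                           read_length = 60, mean_depth = 80, seed = 13)
  sim <- simulate_dataset(cfg)
  ann <- sim$annotations
  for (rd in sim$reads) {
    hits <- GenomicRanges::findOverlaps(rd, ann, type = "within")
    expect_equal(S4Vectors::queryLength(hits), length(rd))
    expect_true(all(GenomicRanges::width(rd) <= 60))
    # reads shorter than read_length must end exactly at a 3' boundary
    short <- GenomicRanges::width(rd) < 60
    if (any(short)) {
      sh <- rd[short]
      tx <- ann[S4Vectors::subjectHits(GenomicRanges::findOverlaps(sh, ann))]
      at_3prime <- ifelse(as.character(GenomicRanges::strand(tx)) == "+",
                          GenomicRanges::end(sh) == GenomicRanges::end(tx),
                          GenomicRanges::start(sh) == GenomicRanges::start(tx))
      expect_true(all(at_3prime))
    }
  }
})

test_that("replicate counts follow NB(mu, alpha) moments", {
  # count-level check at many replicates: 10 transcripts x 200 replicates
  cfg <- simulation_config(n_transcripts = 10, n_replicates = 200,
                           mean_depth = 500, abundance_sigma = 0.5,
                           nb_dispersion = 0.08, target_fraction = 0.2,
                           decay_depth = 0, target_log2fc = 0, seed = 31)
  sim <- simulate_dataset(cfg, reads = FALSE)
  mat <- sim$counts$counts
  wt_log <- mat[, sim$counts$samples$condition == "WT" &
                  sim$counts$samples$phase == "log"]
  m <- rowMeans(wt_log)
  v <- apply(wt_log, 1, var)
  alpha_hat <- (v - m) / m^2
  # 200 replicates: dispersion recoverable within a generous band
  expect_true(all(alpha_hat > 0.03 & alpha_hat < 0.16))
  # and clearly overdispersed relative to Poisson
  expect_true(all(v > 1.5 * m))
})

test_that("null configuration gives equal expected abundance in both strains", {
  cfg <- simulation_config(n_transcripts = 400, decay_depth = 0,
                           target_log2fc = 0, mean_depth = 200, seed = 17)
  sim <- simulate_dataset(cfg, reads = FALSE)
  cs <- colSums(sim$counts$counts)
  grand <- mean(cs)
  expect_true(all(abs(cs - grand) / grand < 0.15))
})

test_that("expected_slope matches its closed form and rejects bad depths", {
  expect_equal(expected_slope(0), 0)
  expect_equal(expected_slope(0.5), 1 / 150)
  expect_equal(expected_slope(0.5), 0.00667, tolerance = 5e-4)
  expect_equal(expected_slope(0.8), 0.8 / 60)
  expect_error(expected_slope(1), "\\[0, 1\\)")
  expect_error(expected_slope(-0.1), "\\[0, 1\\)")
  expect_error(simulation_config(decay_depth = 1), "decay_depth")
})

test_that("counting simulated reads reproduces the simulated counts table", {
  cfg <- simulation_config(n_transcripts = 30, mean_depth = 120, seed = 23)
  sim <- simulate_dataset(cfg)
  recount <- count_reads(sim$reads, sim$annotations, sim$counts$samples,
                         stranded = TRUE)
  expect_equal(recount$counts, sim$counts$counts)
})

test_that("config YAML round-trips", {
  cfg <- simulation_config(n_transcripts = 42, decay_depth = 0.35, seed = 9)
  f <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  expect_equal(read_sim_config(f), cfg)
  writeLines("bogus_field: 3", f)
  expect_error(read_sim_config(f), "unknown config fields")
})
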