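# run a simulated corpus through file IO, scoring and MSS profiling,
# exactly as a user would from the written tables
profile_from_sim <- function(cfg, window_bp = 5e6) {
  dir <- tempfile("corpus")
  sim <- simulate_corpus(cfg)
  write_corpus(sim, cfg, dir)
  genome <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  sigs <- read_signatures(file.path(dir, "signatures.tsv"), genome)
  m <- read_overlap_matrix(file.path(dir, "samples.tsv"),
                           file.path(dir, "overlaps.tsv"),
                           scope_id = cfg$populations$population_id[1])
  w <- weight_signatures(sigs, compute_study_weights(m), scope = "breed")
  list(sim = sim, genome = genome,
       profile = compute_mss_profile(w, genome, window_bp = window_bp))
}

tier3_studies <- function(k) {
  data.frame(study_id = sprintf("S%02d", seq_len(k)), n_samples = 100)
}

one_hotspot <- function(detect_prob = 1, p3 = 1) {
  data.frame(population_id = "SIMPOP", chrom = "1", center = 25e6,
             width = 1e6, detect_prob = detect_prob,
             p_tier1 = (1 - p3) / 2, p_tier2 = (1 - p3) / 2, p_tier3 = p3,
             stringsAsFactors = FALSE)
}

test_that("simulation is deterministic given the seed, down to the bytes", {
  cfg <- sim_config(seed = 9)
  d1 <- tempfile(); d2 <- tempfile()
  write_corpus(simulate_corpus(cfg), cfg, d1)
  write_corpus(simulate_corpus(cfg), cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed gives a different corpus
  d3 <- tempfile()
  cfg3 <- sim_config(seed = 10)
  write_corpus(simulate_corpus(cfg3), cfg3, d3)
  expect_false(identical(readLines(file.path(d1, "signatures.tsv")),
                         readLines(file.path(d3, "signatures.tsv"))))
})

test_that("zero detection and zero background give an empty corpus", {
  cfg <- sim_config(seed = 1, hotspots = one_hotspot(detect_prob = 0),
                    background_rate = 0)
  sim <- simulate_corpus(cfg)
  expect_equal(nrow(sim$signatures), 0)
  expect_equal(nrow(sim$truth$provenance), 0)
})

test_that("k independent tier-3 studies at full detection give MSS = 3k", {
  cfg <- sim_config(seed = 5, studies = tier3_studies(10),
                    hotspots = one_hotspot(), background_rate = 0)
  res <- profile_from_sim(cfg)
  expect_equal(nrow(res$sim$signatures), 10)
  at <- mss_at_locus("1", 25e6, weight_signatures(
    res$sim$signatures,
    compute_study_weights(independent_matrix(10, scope = "SIMPOP")),
    scope = "breed"), res$genome)
  expect_equal(at$mss, 30)
  expect_equal(max(res$profile$mss), 30)
})

test_that("sample-sharing blocks realise the pairwise design exactly", {
  cfg <- sim_config(seed = 2, studies = tier3_studies(4),
                    sharing = list(list(studies = c("S01", "S02", "S03"),
                                        n_shared = 40),
                                   list(studies = c("S01", "S02"),
                                        n_shared = 20)))
  sim <- simulate_corpus(cfg)
  ov <- sim$overlaps[sim$overlaps$scope_id == "SIMPOP", ]
  get <- function(i, j) {
    r <- ov[(ov$study_i == i & ov$study_j == j) |
              (ov$study_i == j & ov$study_j == i), ]
    if (nrow(r)) r$n_shared else 0
  }
  expect_equal(get("S01", "S02"), 60)  # both blocks
  expect_equal(get("S01", "S03"), 40)
  expect_equal(get("S02", "S03"), 40)
  expect_equal(get("S01", "S04"), 0)
  # infeasible designs are configuration errors
  expect_error(
    sim_config(studies = tier3_studies(2),
               sharing = list(list(studies = c("S01", "S02"), n_shared = 150))),
    class = "sweepmeta_config_error")
})

test_that("MSS at a planted hotspot is Binomial(k, p) x 3 in expectation", {
  k <- 5; p <- 0.5
  vals <- vapply(1:200, function(seed) {
    cfg <- sim_config(seed = seed, genome = genome_map("1", 1e7),
                      studies = tier3_studies(k),
                      hotspots = data.frame(population_id = "SIMPOP",
                                            chrom = "1", center = 5e6,
                                            width = 1e6, detect_prob = p,
                                            p_tier1 = 0, p_tier2 = 0,
                                            p_tier3 = 1),
                      background_rate = 0)
    sim <- simulate_corpus(cfg)
    if (!nrow(sim$signatures)) return(0)
    w <- weight_signatures(sim$signatures, compute_study_weights(
      independent_matrix(k, scope = "SIMPOP")), scope = "breed")
    mss_at_locus("1", 5e6, w, cfg$genome)$mss
  }, numeric(1))
  se <- 3 * sqrt(k * p * (1 - p)) / sqrt(200)
  expect_lt(abs(mean(vals) - 3 * k * p), 3 * se)
})

test_that("recovery metrics report sensitivity, false fraction and NA cases", {
  cfg <- sim_config(seed = 12, studies = tier3_studies(10),
                    background_rate = 0)
  res <- profile_from_sim(cfg)
  regions <- call_peaks(res$profile)
  met <- recovery_metrics(regions, res$sim$truth, res$profile)
  expect_equal(met$pooled$sensitivity, 1)
  expect_equal(met$pooled$false_fraction, 0)
  expect_true(met$pooled$mean_boundary_error_bp >= 0)

  # background-only corpus: sensitivity undefined, false fraction 1
  cfg0 <- sim_config(seed = 3, studies = tier3_studies(6),
                     hotspots = one_hotspot(detect_prob = 0),
                     background_rate = 0.1)
  res0 <- profile_from_sim(cfg0)
  reg0 <- call_peaks(res0$profile)
  met0 <- recovery_metrics(reg0, list(
    hotspots = res0$sim$truth$hotspots[0, ],
    provenance = res0$sim$truth$provenance), res0$profile)
  expect_true(is.na(met0$pooled$sensitivity))
  if (nrow(reg0)) expect_equal(met0$pooled$false_fraction, 1)
})
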