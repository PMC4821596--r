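weighted_fixture <- function(study, start, end, rep_pos, ss, chrom = "1") {
  data.frame(study_id = study, population_id = "P",
             population_level = "breed", archetype = "european",
             assembly = "UMD3.1", chrom = chrom, start = start, end = end,
             rep_pos = rep_pos, tier = 3L, test_name = NA, scope_id = "P",
             d = 1, ss = ss, stringsAsFactors = FALSE)
}

test_that("MSS at a locus follows the windowed per-study-max sum", {
  gm <- toy_genome()
  # one fully independent top-tier record -> MSS = 3
  w1 <- weighted_fixture("S01", 9e6, 11e6, 10e6, 3)
  expect_equal(mss_at_locus("1", 10e6, w1, gm)$mss, 3)
  # empty window -> 0
  expect_equal(mss_at_locus("1", 40e6, w1, gm)$mss, 0)
  # per-study max: one study with ss {1, 2} plus an independent study 3
  w <- rbind(weighted_fixture("S01", 9e6, 9.5e6, 9.2e6, 1),
             weighted_fixture("S01", 10e6, 10.5e6, 10.2e6, 2),
             weighted_fixture("S02", 11e6, 11.5e6, 11.2e6, 3))
  at <- mss_at_locus("1", 10e6, w, gm)
  expect_equal(at$mss, 5)
  expect_equal(at$contrib$study_id, c("S01", "S02"))
  expect_equal(at$contrib$ss, c(2, 3))
  # spans qualify by any 1 bp overlap with the window edge
  wedge <- weighted_fixture("S01", 12.5e6, 14e6, 13e6, 3)
  expect_equal(mss_at_locus("1", 10e6, wedge, gm)$mss, 3)
  expect_equal(mss_at_locus("1", 9.99e6, wedge, gm)$mss, 0)
})

test_that("profiles evaluate at unique reported positions only", {
  gm <- toy_genome()
  w1 <- weighted_fixture("S01", 9e6, 11e6, 10e6, 2.5)
  prof <- compute_mss_profile(w1, gm)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$pos, 10e6)
  expect_equal(prof$mss, 2.5)
  # two independent studies 6 Mb apart with a 5 Mb window: no cross-talk
  w2 <- rbind(weighted_fixture("S01", 9.5e6, 10.5e6, 10e6, 3),
              weighted_fixture("S02", 15.5e6, 16.5e6, 16e6, 3))
  prof2 <- compute_mss_profile(w2, gm)
  expect_equal(prof2$mss, c(3, 3))
  expect_equal(prof2$n_studies, c(1L, 1L))
})

test_that("profile computation matches the brute-force oracle on random corpora", {
  for (seed in c(3, 17, 49)) {
    w <- rand_weighted(seed)
    prof <- compute_mss_profile(w, toy_genome())
    expect_equal(prof$mss, oracle_mss_profile(w, toy_genome(), 5e6),
                 tolerance = 1e-12)
  }
})

test_that("MSS is additive over disjoint study sets and monotone in studies", {
  gm <- toy_genome()
  w <- rand_weighted(23, max_rec = 120, max_k = 8)
  studies <- unique(w$study_id)
  s1 <- studies[seq_len(floor(length(studies) / 2))]
  wa <- w[w$study_id %in% s1, ]
  wb <- w[!w$study_id %in% s1, ]
  full <- compute_mss_profile(w, gm)
  at <- function(recs, chrom, pos) mss_at_locus(chrom, pos, recs, gm)$mss
  for (i in sample.int(nrow(full), 25)) {
    a <- at(wa, full$chrom[i], full$pos[i])
    b <- at(wb, full$chrom[i], full$pos[i])
    expect_equal(a + b, full$mss[i], tolerance = 1e-12)  # additivity
    expect_gte(full$mss[i], a)                           # monotonicity
    expect_gte(full$mss[i], b)
  }
})

test_that("peaks are maximal runs strictly above the threshold", {
  mk_prof <- function(mss) {
    prof <- data.frame(chrom = "1", pos = seq_along(mss) * 1e6, mss = mss,
                       n_studies = 2L, stringsAsFactors = FALSE)
    prof$contrib <- rep(list(NULL), length(mss))
    attr(prof, "population_id") <- "P"
    class(prof) <- c("mss_profile", "data.frame")
    prof
  }
  prof <- mk_prof(c(1, 4, 5, 4, 2))
  reg <- call_peaks(prof, threshold = 3, split = FALSE)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, prof$pos[2])
  expect_equal(reg$end, prof$pos[4])
  expect_equal(reg$max_mss, 5)
  expect_equal(reg$pos_of_max, prof$pos[3])
  # nothing above threshold -> no regions
  expect_equal(nrow(call_peaks(mk_prof(rep(3, 5)), 3)), 0)
  # single locus above -> degenerate region
  one <- call_peaks(mk_prof(c(3, 3, 3, 3, 3.5)), 3)
  expect_equal(nrow(one), 1)
  expect_equal(one$start, one$end)
})

test_that("merged peaks split at strict local-minimum valleys and plateaus", {
  mk_run <- function(mss) {
    data.frame(chrom = "1", pos = seq_along(mss) * 1e6, mss = mss,
               n_studies = 2L, stringsAsFactors = FALSE)
  }
  # single maximum: unchanged
  mono <- split_at_valleys(mk_run(c(4, 6, 8, 6, 4)), "P")
  expect_equal(nrow(mono), 1)
  expect_equal(c(mono$start, mono$end), c(1e6, 5e6))
  # 4 8 4 9 4: two regions sharing the middle valley locus
  two <- split_at_valleys(mk_run(c(4, 8, 4, 9, 4)), "P")
  expect_equal(nrow(two), 2)
  expect_equal(two$start, c(1e6, 3e6))
  expect_equal(two$end, c(3e6, 5e6))
  expect_equal(two$max_mss, c(8, 9))
  # plateau valley 4 8 5 5 9 4: left ends at first 5, right starts at second 5
  pl <- split_at_valleys(mk_run(c(4, 8, 5, 5, 9, 4)), "P")
  expect_equal(pl$start, c(1e6, 4e6))
  expect_equal(pl$end, c(3e6, 6e6))
})

test_that("peak calling + valley splitting matches the exhaustive oracle", {
  for (seed in 1:60) {
    prof <- rand_profile(seed)
    reg <- call_peaks(prof, threshold = 3, split = TRUE)
    for (cm in unique(prof$chrom)) {
      sl <- prof[prof$chrom == cm, ]
      want <- oracle_segment(sl$pos, sl$mss, 3)
      got <- reg[reg$chrom == cm, ]
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("every region locus exceeds the threshold and flanks do not", {
  prof <- rand_profile(99)
  reg <- call_peaks(prof, threshold = 3, split = FALSE)
  for (i in seq_len(nrow(reg))) {
    sl <- prof[prof$chrom == reg$chrom[i], ]
    inside <- sl$pos >= reg$start[i] & sl$pos <= reg$end[i]
    expect_true(all(sl$mss[inside] > 3))
    before <- which(sl$pos < reg$start[i])
    after <- which(sl$pos > reg$end[i])
    if (length(before)) expect_lte(sl$mss[max(before)], 3)
    if (length(after)) expect_lte(sl$mss[min(after)], 3)
  }
})

test_that("split regions concatenate back to the original run's loci", {
  for (seed in c(5, 21)) {
    prof <- rand_profile(seed)
    raw <- call_peaks(prof, threshold = 3, split = FALSE)
    fine <- call_peaks(prof, threshold = 3, split = TRUE)
    for (i in seq_len(nrow(raw))) {
      parts <- fine[fine$chrom == raw$chrom[i] & fine$start >= raw$start[i] &
                      fine$end <= raw$end[i], ]
      expect_equal(min(parts$start), raw$start[i])
      expect_equal(max(parts$end), raw$end[i])
      # pieces tile the run: each next start is the previous end or later
      if (nrow(parts) > 1) {
        parts <- parts[order(parts$start), ]
        expect_true(all(parts$start[-1] >= parts$end[-nrow(parts)] - 0))
      }
    }
  }
})

test_that("regions group transitively into unique and shared hotspots", {
  mk_reg <- function(pop, start, end, chrom = "1") {
    data.frame(population_id = pop, chrom = chrom, start = start, end = end,
               max_mss = 5, pos_of_max = start, n_studies = 2L,
               n_loci = 2L, assembly = "UMD3.1", stringsAsFactors = FALSE)
  }
  # disjoint regions from two populations: two unique hotspots
  ht <- classify_regions(rbind(mk_reg("p1", 1e6, 2e6), mk_reg("p2", 5e6, 6e6)))
  expect_equal(ht$summary$n_hotspots, 2)
  expect_equal(ht$summary$n_unique, 2)
  expect_equal(unique(ht$regions$classification), "unique")
  # chained overlap A[10,20] B[15,25] C[24,30]: one 3-way hotspot
  ht2 <- classify_regions(rbind(mk_reg("p1", 10e6, 20e6),
                                mk_reg("p2", 15e6, 25e6),
                                mk_reg("p3", 24e6, 30e6)))
  expect_equal(ht2$summary$n_hotspots, 1)
  expect_equal(ht2$hotspots$start, 10e6)
  expect_equal(ht2$hotspots$end, 30e6)
  expect_equal(ht2$hotspots$n_populations, 3)
  expect_equal(ht2$regions$classification, rep("shared", 3))
  expect_setequal(strsplit(ht2$regions$shared_with[1], ",")[[1]],
                  c("p2", "p3"))
  # identical lists in two populations: everything 2-way shared
  ht3 <- classify_regions(rbind(mk_reg("p1", 1e6, 2e6), mk_reg("p2", 1e6, 2e6),
                                mk_reg("p1", 8e6, 9e6), mk_reg("p2", 8e6, 9e6)))
  expect_equal(ht3$summary$n_unique, 0)
  expect_equal(ht3$summary$n_shared, 2)
  expect_equal(unname(ht3$summary$multiplicity["2"]), 2L)
  # abutting (zero-overlap) intervals do not share
  ht4 <- classify_regions(rbind(mk_reg("p1", 1e6, 2e6), mk_reg("p2", 2e6 + 1, 3e6)))
  expect_equal(ht4$summary$n_hotspots, 2)
  # mixed assemblies are rejected
  bad <- rbind(mk_reg("p1", 1e6, 2e6), mk_reg("p2", 1e6, 2e6))
  bad$assembly <- c("UMD3.1", "Btau4.0")
  expect_error(classify_regions(bad), class = "sweepmeta_validation_error")
})
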