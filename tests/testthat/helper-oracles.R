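# Independent reference implementations used to cross-check the
# package's vectorised code paths, plus small fixture builders.
# The oracles are deliberately written as explicit scans/loops.

# Brute-force MSS: for one locus, walk every record, keep per-study
# maxima among spans intersecting the window, and sum them.
oracle_mss_at <- function(chrom, pos, records, genome, window_bp) {
  half <- floor(window_bp / 2)
  len <- genome$length[match(chrom, genome$chrom)]
  ws <- max(pos - half, 1)
  we <- min(pos + half, len)
  best <- list()
  for (i in seq_len(nrow(records))) {
    if (records$chrom[i] != chrom) next
    if (records$end[i] < ws || records$start[i] > we) next
    sid <- records$study_id[i]
    if (is.null(best[[sid]]) || records$ss[i] > best[[sid]])
      best[[sid]] <- records$ss[i]
  }
  if (!length(best)) 0 else sum(unlist(best))
}

oracle_mss_profile <- function(records, genome, window_bp) {
  loci <- unique(records[, c("chrom", "rep_pos")])
  loci <- loci[order(loci$chrom, loci$rep_pos), ]
  vapply(seq_len(nrow(loci)), function(i)
    oracle_mss_at(loci$chrom[i], loci$rep_pos[i], records, genome,
                  window_bp), numeric(1))
}

# Exhaustive segmentation: find runs of loci above the threshold by
# explicit scanning, then cut each run at every internal
# strict-local-minimum plateau (left piece ends at plateau first locus,
# right piece starts at plateau last locus).  Returns a data.frame of
# (start, end) locus positions per region for one chromosome.
oracle_segment <- function(pos, mss, threshold) {
  n <- length(pos)
  regions <- list()
  i <- 1
  while (i <= n) {
    if (mss[i] <= threshold) { i <- i + 1; next }
    j <- i
    while (j < n && mss[j + 1] > threshold) j <- j + 1
    vals <- mss[i:j]
    m <- length(vals)
    cuts <- list()
    a <- 2
    while (a <= m - 1) {
      b <- a
      while (b < m && vals[b + 1] == vals[a]) b <- b + 1
      if (b < m && vals[a - 1] > vals[a] && vals[b + 1] > vals[a])
        cuts[[length(cuts) + 1]] <- c(a, b)
      a <- b + 1
    }
    seg_start <- 1
    for (cc in cuts) {
      regions[[length(regions) + 1]] <- c(pos[i:j][seg_start], pos[i:j][cc[1]])
      seg_start <- cc[2]
    }
    regions[[length(regions) + 1]] <- c(pos[i:j][seg_start], pos[i:j][m])
    i <- j + 1
  }
  if (!length(regions))
    return(data.frame(start = numeric(), end = numeric()))
  out <- do.call(rbind, regions)
  data.frame(start = out[, 1], end = out[, 2])
}

# ---- fixture builders ------------------------------------------------------

toy_genome <- function() genome_map(c("1", "2"), c(5e7, 4e7))

# Random already-weighted records: spans from 1 bp to tens of Mb,
# up to `max_k` studies, arbitrary d in (0, 1] and tiers 1..3.
rand_weighted <- function(seed, genome = toy_genome(), max_rec = 500,
                          max_k = 10) {
  set.seed(seed)
  n <- sample(20:max_rec, 1)
  k <- sample(2:max_k, 1)
  studies <- sprintf("S%02d", seq_len(k))
  d <- setNames(runif(k, 0.2, 1), studies)
  ci <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$length)
  chrom <- genome$chrom[ci]
  len <- genome$length[ci]
  rep_pos <- floor(runif(n, 1, len))
  span <- pmin(round(rlnorm(n, log(5e5), 1.5)), 3e7)
  start <- pmax(rep_pos - floor(span / 2), 1)
  end <- pmin(start + pmax(span, 1) - 1, len)
  rep_pos <- pmin(pmax(rep_pos, start), end)
  sid <- sample(studies, n, replace = TRUE)
  tier <- sample(1:3, n, replace = TRUE)
  data.frame(study_id = sid, population_id = "P", population_level = "breed",
             archetype = "european", assembly = "UMD3.1", chrom = chrom,
             start = start, end = end, rep_pos = rep_pos, tier = tier,
             test_name = NA_character_, scope_id = "P", d = d[sid],
             ss = d[sid] * tier, stringsAsFactors = FALSE)
}

# Random MSS profile (single population, possibly several chromosomes)
# for segmentation tests; mss values drawn to produce plateaus and
# sub-threshold stretches.
rand_profile <- function(seed, max_loci = 200) {
  set.seed(seed)
  n <- sample(5:max_loci, 1)
  chrom <- sort(sample(c("1", "2"), n, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(i)
    sort(sample.int(5e7, length(i)))), use.names = FALSE)
  mss <- sample(c(0, 1, 2, 3, 3.5, 4, 4, 5, 6, 8, 10), n, replace = TRUE)
  prof <- data.frame(chrom = chrom, pos = pos, mss = mss,
                     n_studies = pmax(1L, as.integer(ceiling(mss / 3))),
                     stringsAsFactors = FALSE)
  prof$contrib <- rep(list(data.frame(study_id = "S01", ss = 1,
                                      record_id = "r1")), n)
  attr(prof, "population_id") <- "P"
  attr(prof, "window_bp") <- 5e6
  attr(prof, "assembly") <- "UMD3.1"
  class(prof) <- c("mss_profile", "data.frame")
  prof
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal well-formed signatures table
toy_signatures <- function() {
  data.frame(
    study_id = c("S01", "S02", "S03"),
    population_id = "Holstein", population_level = "breed",
    archetype = "european", assembly = "UMD3.1", chrom = "1",
    start = c(1e6, 2e6, 30e6), end = c(2e6, 3e6, 32e6),
    rep_pos = c(1500000, NA, 31e6), tier = c(1L, 2L, 3L),
    test_name = c("Fst", "iHS", "XP-EHH"), stringsAsFactors = FALSE)
}

independent_matrix <- function(k, n = rep(100, k), scope = "P") {
  ids <- sprintf("S%02d", seq_len(k))
  overlap_matrix(setNames(n, ids), scope = scope)
}

# Faster brute-force MSS oracle: outer loop over loci, per-study maxima
# via tapply over the qualifying records.  Same definition as
# oracle_mss_at, different mechanics; used for the large equivalence
# sweeps.
oracle_mss_profile_fast <- function(records, genome, window_bp) {
  half <- floor(window_bp / 2)
  loci <- unique(records[, c("chrom", "rep_pos")])
  loci <- loci[order(loci$chrom, loci$rep_pos), ]
  lens <- genome$length[match(records$chrom, genome$chrom)]
  vapply(seq_len(nrow(loci)), function(i) {
    len <- genome$length[match(loci$chrom[i], genome$chrom)]
    ws <- max(loci$rep_pos[i] - half, 1)
    we <- min(loci$rep_pos[i] + half, len)
    sel <- records$chrom == loci$chrom[i] &
      records$start <= we & records$end >= ws
    if (!any(sel)) return(0)
    sum(tapply(records$ss[sel], records$study_id[sel], max))
  }, numeric(1))
}
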