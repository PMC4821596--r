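# Core windowed-sum engine shared by mss_at_locus() and
# compute_mss_profile().  For each evaluation locus the window is
# [pos - w/2, pos + w/2] (inclusive, clipped at chromosome ends); a
# record qualifies when its [start, end] span intersects the window;
# within a window each study contributes only its highest-SS qualifying
# record, and the MSS is the sum of those per-study maxima.
mss_core <- function(loci, records, genome, window_bp) {
  half <- floor(window_bp / 2)
  if (is.null(records$record_id))
    records$record_id <- sprintf("r%d", seq_len(nrow(records)))
  empty_contrib <- data.frame(study_id = character(), ss = numeric(),
                              record_id = character(),
                              stringsAsFactors = FALSE)
  n_loci <- nrow(loci)
  mss <- numeric(n_loci)
  n_studies <- integer(n_loci)
  contrib <- rep(list(empty_contrib), n_loci)
  for (cm in unique(loci$chrom)) {
    li <- which(loci$chrom == cm)
    ri <- which(records$chrom == cm)
    if (!length(ri)) next
    len <- chrom_length(genome, cm)
    wstart <- pmax(loci$pos[li] - half, 1)
    wend <- pmin(loci$pos[li] + half, len)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(wstart, wend),
      IRanges::IRanges(records$start[ri], records$end[ri]))
    if (!length(hits)) next
    q <- S4Vectors::queryHits(hits)
    s <- ri[S4Vectors::subjectHits(hits)]
    # per (locus, study) keep the max SS; ties to the earlier record
    ord <- order(q, records$study_id[s], -records$ss[s], s)
    q <- q[ord]; s <- s[ord]
    keep <- !duplicated(paste(q, records$study_id[s], sep = "\r"))
    q <- q[keep]; s <- s[keep]
    sums <- rowsum(records$ss[s], q)
    at <- match(as.character(seq_along(li)), rownames(sums))
    mss[li] <- ifelse(is.na(at), 0, sums[at, 1])
    n_studies[li] <- tabulate(q, nbins = length(li))
    parts <- split(data.frame(study_id = records$study_id[s],
                              ss = records$ss[s],
                              record_id = records$record_id[s],
                              stringsAsFactors = FALSE),
                   factor(q, levels = seq_along(li)))
    contrib[li] <- lapply(parts, function(d) {
      d <- d[order(d$study_id), , drop = FALSE]
      rownames(d) <- NULL
      d
    })
  }
  list(mss = mss, n_studies = n_studies, contrib = contrib)
}

#' Meta-selection-score at one locus
#'
#' The MSS at locus \eqn{l} is \eqn{MSS_l = \sum_{i=1}^{k} SS_{il}}: the
#' sum, over studies, of the weighted selection-signature scores of
#' records whose span overlaps the sliding window centred on \eqn{l}.
#' When a study has several qualifying records only its highest SS is
#' counted, so no study contributes more than 3 at any locus.
#'
#' @param chrom,pos locus coordinates (bp, 1-based).
#' @param weighted weighted records from [weight_signatures()].
#' @param genome a [genome_map()] (the window is clipped at chromosome
#'   ends).
#' @param window_bp sliding-window span in bp (default 5 Mb, i.e.
#'   ~2.5 Mb each side of the locus).
#' @return A list with `mss` and `contrib` (a `data.frame` of
#'   `study_id`, `ss`, `record_id`, one row per contributing study).
#'   An empty window gives `mss = 0`.
#' @export
mss_at_locus <- function(chrom, pos, weighted, genome, window_bp = 5e6) {
  res <- mss_core(data.frame(chrom = as.character(chrom), pos = pos,
                             stringsAsFactors = FALSE),
                  weighted, genome, window_bp)
  list(mss = res$mss[1], contrib = res$contrib[[1]])
}

#' Compute the MSS profile of one population
#'
#' Evaluates [mss_at_locus()] at every unique reported position
#' (`rep_pos`) of the supplied records, per chromosome in coordinate
#' order.  Spans contribute to any window they overlap, but only
#' reported positions define evaluation loci.
#'
#' @param weighted weighted records of one analysis scope, from
#'   [weight_signatures()].
#' @param genome a [genome_map()].
#' @param window_bp sliding-window span in bp.
#' @param population population/scope label to attach; defaults to the
#'   scope id of the records.
#' @return A `data.frame` of class `mss_profile` with columns `chrom`,
#'   `pos`, `mss`, `n_studies` and a `contrib` list-column, sorted by
#'   (chrom, pos); attributes `population_id`, `window_bp`, `assembly`.
#' @export
compute_mss_profile <- function(weighted, genome, window_bp = 5e6,
                                population = NULL) {
  if (is.null(population))
    population <- if (nrow(weighted) && !is.null(weighted$scope_id))
      weighted$scope_id[1] else NA_character_
  loci <- unique(data.frame(chrom = as.character(weighted$chrom),
                            pos = weighted$rep_pos,
                            stringsAsFactors = FALSE))
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  rownames(loci) <- NULL
  res <- mss_core(loci, weighted, genome, window_bp)
  prof <- data.frame(chrom = loci$chrom, pos = loci$pos, mss = res$mss,
                     n_studies = res$n_studies, stringsAsFactors = FALSE)
  prof$contrib <- res$contrib
  attr(prof, "population_id") <- population
  attr(prof, "window_bp") <- window_bp
  attr(prof, "assembly") <- if (nrow(weighted))
    unique(weighted$assembly)[1] else NA_character_
  class(prof) <- c("mss_profile", "data.frame")
  prof
}

#' @export
print.mss_profile <- function(x, ...) {
  cat(sprintf("<mss_profile> %s: %d locus/loci, window %.1f Mb, max MSS %.3g\n",
              attr(x, "population_id"), nrow(x),
              (attr(x, "window_bp") %||% NA) / 1e6,
              if (nrow(x)) max(x$mss) else NA))
  print.data.frame(utils::head(as.data.frame(x)[, c("chrom", "pos", "mss",
                                                    "n_studies")], 10))
  invisible(x)
}
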