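region_from_slice <- function(slice, population, assembly) {
  imax <- which.max(slice$mss)  # ties resolve to the lowest coordinate
  data.frame(population_id = population,
             chrom = slice$chrom[1],
             start = slice$pos[1],
             end = slice$pos[nrow(slice)],
             max_mss = slice$mss[imax],
             pos_of_max = slice$pos[imax],
             n_studies = slice$n_studies[imax],
             n_loci = nrow(slice),
             assembly = assembly,
             stringsAsFactors = FALSE)
}

empty_regions <- function() {
  data.frame(population_id = character(), chrom = character(),
             start = numeric(), end = numeric(), max_mss = numeric(),
             pos_of_max = numeric(), n_studies = integer(),
             n_loci = integer(), assembly = character(),
             stringsAsFactors = FALSE)
}

#' Call validated peak regions from an MSS profile
#'
#' A peak is a maximal run of consecutive profile loci on one chromosome
#' whose MSS is strictly above the validation threshold (default 3, i.e.
#' supported by more than one independent study-equivalent).  The first
#' and last locus of the run define the region boundaries; the maximum
#' MSS, its position (ties to the lowest coordinate) and the number of
#' distinct studies contributing there are recorded.  With
#' `split = TRUE` (the default for final outputs), runs that merge
#' several peaks are subdivided at intervening valleys via
#' [split_at_valleys()].
#'
#' @param profile an [compute_mss_profile()] result.
#' @param threshold validation threshold; loci must exceed it strictly.
#' @param split subdivide merged peaks at valley plateaus.
#' @return A region `data.frame` (possibly empty): `population_id`,
#'   `chrom`, `start`, `end`, `max_mss`, `pos_of_max`, `n_studies`,
#'   `n_loci`, `assembly`.
#' @export
call_peaks <- function(profile, threshold = 3, split = TRUE) {
  population <- attr(profile, "population_id") %||% NA_character_
  assembly <- attr(profile, "assembly") %||% NA_character_
  out <- list()
  for (cm in unique(profile$chrom)) {
    sl <- profile[profile$chrom == cm, , drop = FALSE]
    sl <- sl[order(sl$pos), , drop = FALSE]
    above <- sl$mss > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      run <- sl[starts[i]:ends[i], , drop = FALSE]
      out[[length(out) + 1L]] <-
        if (split) split_at_valleys(run, population, assembly)
        else region_from_slice(run, population, assembly)
    }
  }
  if (!length(out)) return(empty_regions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split a merged peak run at its valleys
#'
#' Densely studied populations can produce consecutive peaks that never
#' drop to the threshold between them; their boundary is then drawn at
#' the span of lowest MSS value(s) between the two peaks.  Concretely,
#' every internal strict local-minimum plateau of the locus-ordered MSS
#' sequence becomes a cut: the left region ends at the first locus of
#' the plateau and the right region begins at its last locus (so
#' single-locus valleys are shared boundary points).  A run with a
#' single maximum is returned as one region.
#'
#' @param run `data.frame` of the consecutive loci of one peak run
#'   (columns `chrom`, `pos`, `mss`, `n_studies`), sorted by position.
#' @param population,assembly labels for the emitted regions.
#' @return A region `data.frame` with one row per sub-peak.
#' @export
split_at_valleys <- function(run, population = NA_character_,
                             assembly = NA_character_) {
  n <- nrow(run)
  r <- rle(run$mss)
  m <- length(r$values)
  pl_end <- cumsum(r$lengths)
  pl_start <- pl_end - r$lengths + 1L
  cut_left <- integer(0)   # last index of left region
  cut_right <- integer(0)  # first index of right region
  if (m >= 3) {
    for (i in 2:(m - 1)) {
      if (r$values[i] < r$values[i - 1] && r$values[i] < r$values[i + 1]) {
        cut_left <- c(cut_left, pl_start[i])
        cut_right <- c(cut_right, pl_end[i])
      }
    }
  }
  seg_start <- c(1L, cut_right)
  seg_end <- c(cut_left, n)
  out <- lapply(seq_along(seg_start), function(i) {
    region_from_slice(run[seg_start[i]:seg_end[i], , drop = FALSE],
                      population, assembly)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
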