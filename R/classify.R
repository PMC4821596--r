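#' Classify validated regions into unique and shared hotspots
#'
#' Regions from different populations that overlap by at least
#' `min_overlap_bp` are grouped transitively into one hotspot (interval
#' union).  A region is *unique* when its hotspot contains regions from
#' exactly one population, *shared* otherwise; the sharing multiplicity
#' (2-way, 3-way, ...) is the number of distinct populations in the
#' hotspot.
#'
#' @param regions a region `data.frame` (typically the row-bind of
#'   [call_peaks()] results across populations).  All regions must be on
#'   one assembly.
#' @param min_overlap_bp minimum overlap to count as sharing (default
#'   1 bp).
#' @return An object of class `hotspot_table`: a list with
#'   `regions` (input plus `hotspot_id`, `classification`,
#'   `shared_with`), `hotspots` (one row per hotspot: interval union,
#'   member populations, multiplicity) and `summary` (total, unique and
#'   shared counts plus a multiplicity breakdown).
#' @export
classify_regions <- function(regions, min_overlap_bp = 1) {
  if (!is.null(regions$assembly)) {
    asm <- unique(regions$assembly[!is.na(regions$assembly)])
    if (length(asm) > 1)
      stop_validation("regions mix assemblies: %s", paste(asm, collapse = ", "))
  }
  n <- nrow(regions)
  if (!n) {
    regions$hotspot_id <- integer(0)
    regions$classification <- character(0)
    regions$shared_with <- character(0)
    hotspots <- data.frame(hotspot_id = integer(), chrom = character(),
                           start = numeric(), end = numeric(),
                           n_regions = integer(), n_populations = integer(),
                           populations = character(),
                           stringsAsFactors = FALSE)
    return(structure(list(regions = regions, hotspots = hotspots,
                          summary = list(n_hotspots = 0L, n_unique = 0L,
                                         n_shared = 0L,
                                         multiplicity = integer())),
                     class = "hotspot_table"))
  }
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  hits <- GenomicRanges::findOverlaps(gr, gr, minoverlap = min_overlap_bp)
  # transitive closure over the overlap graph (union-find)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (e in seq_along(qh)) {
    a <- find(qh[e]); b <- find(sh[e])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  # stable hotspot ids ordered by (chrom, start) of the union interval
  comp_ids <- unique(comp)
  uni <- data.frame(
    comp = comp_ids,
    chrom = vapply(comp_ids, function(cid) regions$chrom[comp == cid][1], ""),
    start = vapply(comp_ids, function(cid) min(regions$start[comp == cid]), 0),
    end = vapply(comp_ids, function(cid) max(regions$end[comp == cid]), 0))
  uni <- uni[order(uni$chrom, uni$start, uni$end), , drop = FALSE]
  uni$hotspot_id <- seq_len(nrow(uni))
  regions$hotspot_id <- uni$hotspot_id[match(comp, uni$comp)]

  pops_of <- lapply(uni$hotspot_id, function(h)
    sort(unique(regions$population_id[regions$hotspot_id == h])))
  hotspots <- data.frame(
    hotspot_id = uni$hotspot_id, chrom = uni$chrom,
    start = uni$start, end = uni$end,
    n_regions = as.integer(tabulate(regions$hotspot_id, nrow(uni))),
    n_populations = vapply(pops_of, length, integer(1)),
    populations = vapply(pops_of, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  rownames(hotspots) <- NULL

  mult <- hotspots$n_populations[regions$hotspot_id]
  regions$classification <- ifelse(mult > 1, "shared", "unique")
  regions$shared_with <- vapply(seq_len(n), function(i) {
    others <- setdiff(pops_of[[regions$hotspot_id[i]]],
                      regions$population_id[i])
    paste(others, collapse = ",")
  }, character(1))

  multiplicity <- table(hotspots$n_populations)
  structure(list(
    regions = regions,
    hotspots = hotspots,
    summary = list(
      n_hotspots = nrow(hotspots),
      n_unique = sum(hotspots$n_populations == 1L),
      n_shared = sum(hotspots$n_populations > 1L),
      multiplicity = setNames(as.integer(multiplicity),
                              names(multiplicity)))),
    class = "hotspot_table")
}

#' @export
print.hotspot_table <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<hotspot_table> %d hotspot(s) from %d region(s): ",
                     "%d unique, %d shared\n"),
              s$n_hotspots, nrow(x$regions), s$n_unique, s$n_shared))
  if (length(s$multiplicity)) {
    cat("  populations per hotspot:",
        paste(sprintf("%s-way: %d", names(s$multiplicity), s$multiplicity),
              collapse = ", "), "\n")
  }
  invisible(x)
}
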