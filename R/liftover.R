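#' Read a marker map for assembly harmonisation
#'
#' TSV with columns `marker_id`, `assembly`, `chrom`, `pos`.  A marker
#' can be used as a lift anchor between two assemblies when it is
#' present on both.
#'
#' @param path file path.
#' @return A `data.frame` with the four columns above.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stop_config("marker file not found: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "assembly", "chrom", "pos")
  if (length(setdiff(need, names(tab))))
    stop_format("marker table needs columns: %s", paste(need, collapse = ", "))
  tab$chrom <- as.character(tab$chrom)
  if (anyDuplicated(tab[, c("marker_id", "assembly")]))
    stop_validation("duplicated (marker_id, assembly) entries in marker map")
  tab
}

#' Lift one position between assemblies via the nearest shared marker
#'
#' If a shared marker sits exactly at `pos` on the source assembly its
#' target position is returned; otherwise the nearest source marker (by
#' absolute bp distance) that also exists on the target is used and the
#' position becomes that marker's target position.  Equidistant markers
#' are resolved toward the lower source coordinate.  No interpolation is
#' done by default: the marker position itself is the lifted position
#' (`interpolate = TRUE` adds the source offset instead, clipped to the
#' target chromosome when `genome` is supplied).
#'
#' @param pos position (bp, 1-based) on the source assembly.
#' @param chrom source chromosome.
#' @param source_assembly,target_assembly assembly names in `markers`.
#' @param markers marker map from [read_markers()].
#' @param interpolate preserve the bp offset from the anchoring marker.
#' @param genome optional target [genome_map()] used to clip
#'   interpolated positions.
#' @return A list with `chrom`, `pos`, `marker_id`, `mapped` (logical).
#'   Unmappable positions (no shared marker on the chromosome) return
#'   `mapped = FALSE` with `NA` coordinates.
#' @export
lift_position <- function(pos, chrom, source_assembly, markers,
                          target_assembly, interpolate = FALSE,
                          genome = NULL) {
  src <- markers[markers$assembly == source_assembly &
                   markers$chrom == chrom, , drop = FALSE]
  tgt <- markers[markers$assembly == target_assembly, , drop = FALSE]
  src <- src[src$marker_id %in% tgt$marker_id, , drop = FALSE]
  if (!nrow(src))
    return(list(chrom = NA_character_, pos = NA_real_,
                marker_id = NA_character_, mapped = FALSE))
  d <- abs(src$pos - pos)
  # nearest; ties toward the lower source coordinate, then marker id
  ord <- order(d, src$pos, src$marker_id)
  anchor <- src[ord[1L], ]
  trow <- tgt[match(anchor$marker_id, tgt$marker_id), ]
  new_pos <- trow$pos
  if (interpolate) {
    new_pos <- new_pos + (pos - anchor$pos)
    if (!is.null(genome)) {
      lim <- chrom_length(genome, trow$chrom)
      new_pos <- min(max(new_pos, 1), lim)
    }
  }
  list(chrom = trow$chrom, pos = new_pos, marker_id = anchor$marker_id,
       mapped = TRUE)
}

#' Lift a signature record onto the target assembly
#'
#' `start`, `end` and `rep_pos` are lifted independently with
#' [lift_position()].  If the lifted endpoints invert (marker order
#' differs between assemblies) they are swapped and the record flagged
#' `inverted`; an anchor on a different target chromosome flags
#' `cross_chrom`; endpoints anchoring to different target chromosomes,
#' or any unmappable position, flag the whole record `unmappable`.
#'
#' @param rec one-row signature `data.frame`.
#' @param markers marker map.
#' @param target target assembly name.
#' @param interpolate,genome passed to [lift_position()].
#' @return The record with updated coordinates, `assembly = target`, and
#'   a `lift_flags` column (`""`, `"inverted"`, `"cross_chrom"`,
#'   `"unmappable"`; multiple flags joined with `,`).
#' @export
lift_record <- function(rec, markers, target, interpolate = FALSE,
                        genome = NULL) {
  if (rec$assembly == target) {
    rec$lift_flags <- ""
    return(rec)
  }
  ls <- lift_position(rec$start, rec$chrom, rec$assembly, markers, target,
                      interpolate, genome)
  le <- lift_position(rec$end, rec$chrom, rec$assembly, markers, target,
                      interpolate, genome)
  lm <- lift_position(rec$rep_pos, rec$chrom, rec$assembly, markers, target,
                      interpolate, genome)
  flags <- character(0)
  if (!ls$mapped || !le$mapped || !lm$mapped ||
      ls$chrom != le$chrom || ls$chrom != lm$chrom) {
    rec$lift_flags <- "unmappable"
    return(rec)
  }
  if (ls$chrom != rec$chrom) flags <- c(flags, "cross_chrom")
  s <- ls$pos; e <- le$pos
  if (s > e) {
    tmp <- s; s <- e; e <- tmp
    flags <- c(flags, "inverted")
  }
  rec$chrom <- ls$chrom
  rec$start <- s
  rec$end <- e
  rec$rep_pos <- min(max(lm$pos, s), e)
  rec$assembly <- target
  rec$lift_flags <- paste(flags, collapse = ",")
  rec
}

#' Lift a whole signature table onto the target assembly
#'
#' Records already on the target pass through unchanged; unmappable
#' records are dropped from the result and reported separately.
#'
#' @param records signature `data.frame`.
#' @param markers marker map.
#' @param target target assembly name.
#' @param interpolate,genome passed to [lift_position()].
#' @return The lifted records, with an `unmappable` attribute holding
#'   the dropped rows.
#' @export
lift_signatures <- function(records, markers, target, interpolate = FALSE,
                            genome = NULL) {
  if (!nrow(records)) {
    records$lift_flags <- character(0)
    attr(records, "unmappable") <- records
    return(records)
  }
  lifted <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    lift_record(records[i, , drop = FALSE], markers, target,
                interpolate, genome)
  }))
  bad <- lifted$lift_flags == "unmappable"
  if (any(bad))
    message(sprintf("lift_signatures: %d record(s) unmappable to %s, dropped",
                    sum(bad), target))
  out <- lifted[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmappable") <- lifted[bad, , drop = FALSE]
  out
}
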