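#' Read a table of published selection-signature calls
#'
#' Expects a tab-separated file with header columns `study_id`,
#' `population_id`, `population_level` (`breed`/`group`), `archetype`
#' (`european`/`african`/`zebu`/`composite`), `assembly`, `chrom`,
#' `start`, `end`, and either `tier` (1, 2 or 3) or `threshold_pct`
#' (declared significance threshold as a percentage, converted with
#' [assign_tier()]).  Optional columns: `rep_pos` (top-score position)
#' and `test_name`.  Coordinates are 1-based inclusive bp.
#'
#' Rows violating record invariants (`end < start`, tier outside 1..3,
#' `rep_pos` outside the span, span beyond the chromosome end on the
#' reference assembly) are rejected individually with row-numbered
#' diagnostics; `strict = TRUE` turns any rejection into an error.
#' A row giving only a single position (`start`/`end` empty, `rep_pos`
#' present) is kept with `start = end = rep_pos`.  A missing `rep_pos`
#' defaults to the span midpoint (rounded down).
#'
#' @param path TSV file path.
#' @param genome a [genome_map()]; chromosome names are validated against
#'   it, and spans are bounds-checked for records already on its assembly.
#' @param strict if `TRUE`, any invalid row fails the whole file.
#' @return A `data.frame` of validated records, one per signature, with a
#'   `rejected` attribute (`data.frame` of `row`, `reason`) describing
#'   dropped rows.
#' @export
read_signatures <- function(path, genome, strict = FALSE) {
  if (!file.exists(path)) stop_config("signatures file not found: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("study_id", "population_id", "population_level", "archetype",
                "assembly", "chrom", "start", "end")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop_format("signatures table is missing required column(s): %s",
                paste(miss, collapse = ", "))
  if (!("tier" %in% names(tab)) && !("threshold_pct" %in% names(tab)))
    stop_format("signatures table needs a 'tier' or 'threshold_pct' column")
  if (!("rep_pos" %in% names(tab))) tab$rep_pos <- NA_real_
  if (!("test_name" %in% names(tab))) tab$test_name <- NA_character_
  tab$chrom <- as.character(tab$chrom)

  bad_chrom <- setdiff(unique(tab$chrom), genome$chrom)
  if (length(bad_chrom))
    stop_validation("chromosome(s) not in genome: %s (rows %s)",
                    paste(bad_chrom, collapse = ", "),
                    paste(which(tab$chrom %in% bad_chrom), collapse = ", "))

  # single-position rows: only rep_pos given
  single <- is.na(tab$start) & is.na(tab$end) & !is.na(tab$rep_pos)
  tab$start[single] <- tab$rep_pos[single]
  tab$end[single] <- tab$rep_pos[single]

  reasons <- character(nrow(tab))
  flag <- function(idx, why) {
    idx <- which(idx & !nzchar(reasons))
    reasons[idx] <<- why
  }
  flag(is.na(tab$start) | is.na(tab$end), "missing start/end")
  flag(!is.na(tab$end) & !is.na(tab$start) & tab$end < tab$start,
       "end < start")

  if ("tier" %in% names(tab)) {
    tier <- suppressWarnings(as.integer(tab$tier))
    flag(is.na(tier) | !(tier %in% 1:3), "tier not in {1,2,3}")
  } else {
    pct <- suppressWarnings(as.numeric(tab$threshold_pct))
    ok <- !is.na(pct) & pct > 0 & pct <= 5
    flag(!ok, "threshold_pct outside (0, 5]")
    tier <- rep(NA_integer_, nrow(tab))
    tier[ok] <- assign_tier(pct[ok])
  }
  tab$tier <- tier

  flag(!is.na(tab$rep_pos) &
         (tab$rep_pos < tab$start | tab$rep_pos > tab$end),
       "rep_pos outside [start, end]")
  # bounds check only meaningful once on the reference assembly
  on_ref <- !is.na(tab$assembly) & tab$assembly == attr(genome, "assembly")
  len <- genome$length[match(tab$chrom, genome$chrom)]
  flag(on_ref & (!is.na(tab$start)) & (tab$start < 1 | tab$end > len),
       "span outside chromosome bounds")

  bad <- nzchar(reasons)
  rejected <- data.frame(row = which(bad), reason = reasons[bad],
                         stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    diag <- paste(sprintf("row %d: %s", rejected$row, rejected$reason),
                  collapse = "; ")
    if (strict)
      stop_validation("invalid signature row(s): %s", diag)
    message(sprintf("read_signatures: rejected %d of %d row(s) [%s]",
                    nrow(rejected), nrow(tab), diag))
  }
  keep_cols <- c(required, "rep_pos", "tier", "test_name",
                 intersect("record_id", names(tab)))
  out <- tab[!bad, keep_cols, drop = FALSE]
  midpoint <- is.na(out$rep_pos)
  out$rep_pos[midpoint] <- floor((out$start[midpoint] + out$end[midpoint]) / 2)
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Construct a study sample-overlap matrix
#'
#' Holds, for one analysis scope (a breed or an archetype group), the
#' per-study DNA sample counts \eqn{n_i} and the symmetric pairwise
#' shared-sample counts \eqn{n_{ij}} used by [dna_score()].
#'
#' @param n named numeric vector of per-study sample counts (names are
#'   study ids); all `>= 1`.
#' @param shared symmetric numeric matrix of pairwise shared counts with
#'   matching dimnames, or `NULL` for fully independent studies.  The
#'   diagonal is always forced to `n`.
#' @param scope scope identifier (population or archetype id).
#' @return An object of class `overlap_matrix`.
#' @examples
#' overlap_matrix(c(A = 100, B = 100),
#'                matrix(c(100, 50, 50, 100), 2, 2,
#'                       dimnames = list(c("A", "B"), c("A", "B"))))
#' @export
overlap_matrix <- function(n, shared = NULL, scope = "scope") {
  if (is.null(names(n)) || anyDuplicated(names(n)))
    stop_validation("sample counts must be uniquely named by study id")
  if (any(is.na(n)) || any(n < 1))
    stop_validation("per-study sample counts must be >= 1")
  k <- length(n)
  studies <- names(n)
  if (is.null(shared)) {
    shared <- matrix(0, k, k, dimnames = list(studies, studies))
  } else {
    shared <- as.matrix(shared)
    if (!identical(dim(shared), c(k, k)) ||
        !identical(rownames(shared), studies) ||
        !identical(colnames(shared), studies))
      stop_validation("shared matrix dimnames must match the study ids")
    if (!isTRUE(all.equal(shared, t(shared))))
      stop_validation("shared-sample matrix must be symmetric")
  }
  diag(shared) <- n
  if (any(shared < 0))
    stop_validation("shared-sample counts must be >= 0")
  lim <- outer(n, n, pmin)
  if (any(shared > lim)) {
    off <- which(shared > lim, arr.ind = TRUE)[1, ]
    stop_validation("n_ij (%g) exceeds min(n_i, n_j) for pair %s/%s",
                    shared[off[1], off[2]], studies[off[1]], studies[off[2]])
  }
  structure(list(scope = scope, studies = studies, n = n, shared = shared),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("<overlap_matrix> scope %s: %d studies\n", x$scope,
              length(x$studies)))
  print(x$shared)
  invisible(x)
}

#' Read per-study sample sizes and pairwise sample overlaps
#'
#' `samples.tsv` has columns `study_id`, `scope_id`, `n_samples`;
#' `overlaps.tsv` has `study_i`, `study_j`, `scope_id`, `n_shared`.
#' Pairs absent from the overlaps table are taken as sharing zero
#' samples; a pair listed in both orientations with conflicting values
#' is an error.
#'
#' @param samples_path path to the sample-size table.
#' @param overlaps_path path to the pairwise-overlap table, or `NULL`
#'   when all studies are independent.
#' @param scope_id return the matrix for this scope only; default returns
#'   a named list with one [overlap_matrix()] per scope in the file.
#' @return An `overlap_matrix`, or a named list of them.
#' @export
read_overlap_matrix <- function(samples_path, overlaps_path = NULL,
                                scope_id = NULL) {
  if (!file.exists(samples_path))
    stop_config("samples file not found: %s", samples_path)
  smp <- read.delim(samples_path, stringsAsFactors = FALSE)
  need <- c("study_id", "scope_id", "n_samples")
  if (length(setdiff(need, names(smp))))
    stop_format("samples table needs columns: %s", paste(need, collapse = ", "))
  ovl <- NULL
  if (!is.null(overlaps_path) && file.exists(overlaps_path) &&
      file.size(overlaps_path) > 0) {
    ovl <- read.delim(overlaps_path, stringsAsFactors = FALSE)
    need2 <- c("study_i", "study_j", "scope_id", "n_shared")
    if (length(setdiff(need2, names(ovl))))
      stop_format("overlaps table needs columns: %s",
                  paste(need2, collapse = ", "))
  }
  build_one <- function(sc) {
    rows <- smp[smp$scope_id == sc, , drop = FALSE]
    if (anyDuplicated(rows$study_id))
      stop_validation("duplicate study_id in scope %s of samples table", sc)
    n <- setNames(as.numeric(rows$n_samples), rows$study_id)
    shared <- matrix(0, length(n), length(n),
                     dimnames = list(names(n), names(n)))
    if (!is.null(ovl)) {
      orows <- ovl[ovl$scope_id == sc, , drop = FALSE]
      if (nrow(orows)) {
        unknown <- setdiff(c(orows$study_i, orows$study_j), names(n))
        if (length(unknown))
          stop_validation("overlaps table names study(ies) absent from scope %s: %s",
                          sc, paste(unknown, collapse = ", "))
        for (r in seq_len(nrow(orows))) {
          i <- orows$study_i[r]; j <- orows$study_j[r]
          v <- as.numeric(orows$n_shared[r])
          prev <- shared[i, j]
          if (prev != 0 && prev != v)
            stop_validation(
              "conflicting n_shared for pair %s/%s in scope %s (%g vs %g)",
              i, j, sc, prev, v)
          shared[i, j] <- v
          shared[j, i] <- v
        }
      }
    }
    diag(shared) <- n
    overlap_matrix(n, shared, scope = sc)
  }
  scopes <- unique(smp$scope_id)
  if (!is.null(scope_id)) {
    if (!(scope_id %in% scopes))
      stop_validation("scope %s not present in samples table", scope_id)
    return(build_one(scope_id))
  }
  out <- lapply(scopes, build_one)
  names(out) <- scopes
  if (length(out) == 1L) out[[1L]] else out
}

# -- writers / readers for result tables ------------------------------------

region_columns <- c("population_id", "chrom", "start", "end", "max_mss",
                    "pos_of_max", "n_studies", "classification", "shared_with")

#' Write validated regions to a TSV file
#'
#' Rows are sorted by (population, chrom, start) so output is
#' deterministic under any input permutation.
#'
#' @param regions region `data.frame` from [call_peaks()] or
#'   [classify_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_regions()], [write_track()]
#' @export
write_regions <- function(regions, path) {
  cols <- intersect(region_columns, names(regions))
  if (!nrow(regions)) {
    out <- regions[, cols, drop = FALSE]
  } else {
    ord <- order(regions$population_id, regions$chrom, regions$start)
    out <- regions[ord, cols, drop = FALSE]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a regions TSV written by [write_regions()]
#' @param path file path.
#' @return A region `data.frame`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop_config("regions file not found: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  tab$chrom <- as.character(tab$chrom)
  tab
}

#' Write an MSS profile to a TSV file
#'
#' The per-locus contributing studies are serialised as
#' `study:ss` pairs joined with `;` in a `contributing` column.
#'
#' @param profile an [compute_mss_profile()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  contributing <- vapply(profile$contrib, function(d) {
    if (is.null(d) || !nrow(d)) return("")
    paste(sprintf("%s:%s", d$study_id, formatC(d$ss, digits = 17, format = "g")),
          collapse = ";")
  }, character(1))
  out <- data.frame(population_id = attr(profile, "population_id") %||% NA,
                    chrom = profile$chrom, pos = profile$pos,
                    mss = profile$mss, n_studies = profile$n_studies,
                    contributing = contributing, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an MSS profile written by [write_profile()]
#' @param path file path.
#' @param window_bp sliding-window span to attach (bp).
#' @return An MSS profile `data.frame`.
#' @export
read_profile <- function(path, window_bp = 5e6) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  contrib <- lapply(tab$contributing, function(s) {
    if (is.na(s) || !nzchar(s))
      return(data.frame(study_id = character(), ss = numeric(),
                        stringsAsFactors = FALSE))
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(study_id = vapply(parts, `[`, "", 1),
               ss = as.numeric(vapply(parts, `[`, "", 2)),
               stringsAsFactors = FALSE)
  })
  prof <- data.frame(chrom = as.character(tab$chrom), pos = tab$pos,
                     mss = tab$mss, n_studies = tab$n_studies,
                     stringsAsFactors = FALSE)
  prof$contrib <- contrib
  attr(prof, "population_id") <- tab$population_id[1]
  attr(prof, "window_bp") <- window_bp
  class(prof) <- c("mss_profile", "data.frame")
  prof
}

#' Write a browser track (bedGraph-style)
#'
#' Emits 4 columns (`chrom`, `start`, `end`, `score`) in 0-based
#' half-open coordinates.  For an MSS profile each locus becomes a 1-bp
#' interval scored with its MSS; for a region table each region is
#' scored with its maximum MSS.
#'
#' @param x an MSS profile or a region `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(x, path) {
  if ("pos" %in% names(x)) {
    out <- data.frame(chrom = x$chrom, start = x$pos - 1, end = x$pos,
                      score = x$mss)
  } else {
    out <- data.frame(chrom = x$chrom, start = x$start - 1, end = x$end,
                      score = x$max_mss)
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
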