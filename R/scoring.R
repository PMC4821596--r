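#' DNA score: down-weight for repeated DNA samples across studies
#'
#' Studies that re-analyse the same animals (e.g. repeated use of
#' consortium panels) must not each count as independent evidence.  For
#' study \eqn{i} among the \eqn{k} studies of an analysis scope, with
#' sample counts \eqn{n_i} and pairwise shared counts \eqn{n_{ij}}, the
#' DNA score is
#' \deqn{d_i = 1 / \sum_{j=1}^{k} \frac{n_{ij}}{n_i + n_j - n_{ij}}}
#' i.e. the reciprocal of the summed Jaccard sample overlaps.  The sum
#' includes the self term \eqn{j = i} (always 1), so a study sharing no
#' samples with any other has \eqn{d_i = 1}, and \eqn{d_i} strictly
#' decreases as overlaps grow: two studies on exactly the same animals
#' each get \eqn{d = 1/2}.
#'
#' @param study_id study to score.
#' @param matrix an [overlap_matrix()].
#' @return The DNA score, a value in (0, 1].
#' @examples
#' m <- overlap_matrix(c(A = 100, B = 100),
#'                     matrix(c(100, 50, 50, 100), 2, 2,
#'                            dimnames = list(c("A", "B"), c("A", "B"))))
#' dna_score("A", m)  # 1 / (1 + 50/150) = 0.75
#' @export
dna_score <- function(study_id, matrix) {
  i <- match(study_id, matrix$studies)
  if (is.na(i))
    stop_validation("study %s absent from overlap matrix (scope %s)",
                    study_id, matrix$scope)
  n <- matrix$n
  nij <- matrix$shared[i, ]
  1 / sum(nij / (n[i] + n - nij))
}

#' DNA scores for every study of an analysis scope
#'
#' @param matrix an [overlap_matrix()], or a named list of them (one per
#'   scope, as returned by [read_overlap_matrix()]).
#' @return A `data.frame` with columns `study_id`, `scope_id`, `d`.
#' @export
compute_study_weights <- function(matrix) {
  if (inherits(matrix, "overlap_matrix")) matrix <- list(matrix)
  out <- lapply(matrix, function(m) {
    data.frame(study_id = m$studies, scope_id = m$scope,
               d = vapply(m$studies, dna_score, numeric(1), matrix = m),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' SNP score: tier for a declared significance threshold
#'
#' Result sets declared at the top 5\%, 1\% and 0.1\% of their test
#' statistic are weighted \eqn{s = 1}, \eqn{s = 2} and \eqn{s = 3}
#' respectively, so that more stringent reporting contributes more.
#' Buckets are half-open on the stringent side: `pct <= 0.1` maps to 3,
#' `0.1 < pct <= 1` to 2, `1 < pct <= 5` to 1.  Thresholds outside
#' (0, 5] are outside the admissible range and rejected.
#'
#' @param threshold_pct numeric vector of thresholds as percentages
#'   (e.g. `1` for the top 1\%).
#' @return Integer vector of tiers (1, 2 or 3).
#' @examples
#' assign_tier(c(5, 1, 0.1, 0.5))  # 1 2 3 2
#' @export
assign_tier <- function(threshold_pct) {
  pct <- as.numeric(threshold_pct)
  if (any(is.na(pct)) || any(pct <= 0) || any(pct > 5))
    stop_validation(
      "significance threshold(s) outside the admissible (0, 5]%% range: %s",
      paste(threshold_pct[is.na(pct) | pct <= 0 | pct > 5], collapse = ", "))
  ifelse(pct <= 0.1, 3L, ifelse(pct <= 1, 2L, 1L))
}

#' Weight signature records: SS = d x s
#'
#' Attaches to each record its weighted selection-signature score
#' \eqn{SS_{il} = d_i \times s_i}: the study's DNA score for the
#' analysis scope times the record's SNP-score tier.  A single study can
#' therefore contribute at most 3 (fully independent samples, top-0.1\%
#' tier).
#'
#' @param records signature `data.frame` from [read_signatures()].
#' @param weights `data.frame` from [compute_study_weights()].
#' @param scope `"breed"` (scope id is the record's `population_id`) or
#'   `"group"` (scope id is the record's `archetype`).
#' @return `records` with columns `scope_id`, `d` and `ss` appended;
#'   row order preserved.
#' @export
weight_signatures <- function(records, weights, scope = c("breed", "group")) {
  scope <- match.arg(scope)
  if (!nrow(records)) {
    records$scope_id <- character(0)
    records$d <- numeric(0)
    records$ss <- numeric(0)
    return(records)
  }
  scope_id <- if (scope == "breed") records$population_id else records$archetype
  key <- paste(records$study_id, scope_id, sep = "\r")
  wkey <- paste(weights$study_id, weights$scope_id, sep = "\r")
  hit <- match(key, wkey)
  if (anyNA(hit)) {
    missing <- unique(paste0(records$study_id, " (scope ",
                             scope_id, ")")[is.na(hit)])
    stop_validation("no DNA score for study/scope: %s",
                    paste(missing, collapse = ", "))
  }
  records$scope_id <- scope_id
  records$d <- weights$d[hit]
  records$ss <- records$d * records$tier
  stopifnot(all(records$ss > 0), all(records$ss <= 3 + 1e-12))
  records
}
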