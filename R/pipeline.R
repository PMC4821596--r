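#' Assemble a pipeline run configuration
#'
#' Accepts either a YAML file path or a named list; unknown keys are an
#' error, so typos in config files fail fast.  `window_mb` may be given
#' instead of `window_bp`.
#'
#' @param config YAML path or named list.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_config("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(signatures = NULL, samples = NULL, overlaps = NULL,
                   chrom_sizes = NULL, assembly = "UMD3.1", markers = NULL,
                   genes = NULL, out_dir = ".", window_bp = 5e6,
                   window_mb = NULL, threshold = 3, scope = "breed",
                   strict = FALSE, min_studies = 2, min_overlap_bp = 1,
                   interpolate = FALSE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_config("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(cfg$window_mb)) cfg$window_bp <- cfg$window_mb * 1e6
  if (cfg$window_bp <= 0 || cfg$threshold <= 0)
    stop_config("window_bp and threshold must be positive")
  if (!cfg$scope %in% c("breed", "group"))
    stop_config("scope must be 'breed' or 'group'")
  for (key in c("signatures", "samples", "chrom_sizes")) {
    if (is.null(cfg[[key]]))
      stop_config("config key '%s' is required", key)
    if (!file.exists(cfg[[key]]))
      stop_config("%s file not found: %s", key, cfg[[key]])
  }
  structure(cfg, class = "run_config")
}

#' Run the full meta-assembly pipeline
#'
#' Executes, in order: read inputs, marker-anchored lifting onto the
#' reference assembly (when a marker map is given), DNA-score weighting
#' per analysis scope, MSS profiles per population (breed scope) or per
#' archetype group (group scope; group analyses pool group-level records
#' with breed-level records of member breeds), validated peak calling
#' with valley splitting, unique/shared classification and, when a gene
#' annotation is given, per-region gene content.  Populations with
#' fewer than `min_studies` distinct contributing studies are skipped
#' (single-study populations cannot be independently validated).
#'
#' Writes to `out_dir`: `mss_<population>.tsv` and
#' `mss_<population>.bedgraph`, `regions.tsv`, `regions.bedgraph`,
#' `hotspots.tsv`, a gene-density `gene_density.bedgraph` (if genes
#' given) and a machine-readable `manifest.json` with per-stage record
#' counts.
#'
#' @param config a `run_config`, YAML path or named list (see
#'   [read_run_config()]).
#' @return Invisibly, a list with `genome`, `records`, `weights`,
#'   `profiles`, `regions`, `hotspots` and `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_chrom_sizes(cfg$chrom_sizes, assembly = cfg$assembly)

  sigs <- read_signatures(cfg$signatures, genome, strict = cfg$strict)
  n_rejected <- nrow(attr(sigs, "rejected"))
  n_in <- nrow(sigs) + n_rejected

  n_unmappable <- 0L
  off_ref <- sigs$assembly != cfg$assembly
  if (any(off_ref)) {
    if (is.null(cfg$markers))
      stop_validation(
        "%d record(s) are not on %s and no marker map was supplied",
        sum(off_ref), cfg$assembly)
    markers <- read_markers(cfg$markers)
    sigs <- lift_signatures(sigs, markers, cfg$assembly,
                            interpolate = cfg$interpolate, genome = genome)
    n_unmappable <- nrow(attr(sigs, "unmappable"))
  }

  matrices <- read_overlap_matrix(cfg$samples, cfg$overlaps)
  weights <- compute_study_weights(matrices)

  units <- if (cfg$scope == "breed") {
    sort(unique(sigs$population_id[sigs$population_level == "breed"]))
  } else {
    sort(unique(sigs$archetype))
  }
  profiles <- list()
  regions <- empty_regions()
  unit_counts <- list()
  for (u in units) {
    sub <- if (cfg$scope == "breed") {
      sigs[sigs$population_level == "breed" & sigs$population_id == u, ,
           drop = FALSE]
    } else {
      sigs[sigs$archetype == u, , drop = FALSE]
    }
    if (length(unique(sub$study_id)) < cfg$min_studies) {
      message(sprintf("run_pipeline: skipping %s (fewer than %d studies)",
                      u, cfg$min_studies))
      next
    }
    w <- weight_signatures(sub, weights, scope = cfg$scope)
    prof <- compute_mss_profile(w, genome, window_bp = cfg$window_bp,
                                population = u)
    profiles[[u]] <- prof
    write_profile(prof, file.path(cfg$out_dir, sprintf("mss_%s.tsv", u)))
    write_track(prof, file.path(cfg$out_dir, sprintf("mss_%s.bedgraph", u)))
    reg <- call_peaks(prof, threshold = cfg$threshold, split = TRUE)
    unit_counts[[u]] <- list(n_records = nrow(sub), n_loci = nrow(prof),
                             n_regions = nrow(reg))
    regions <- rbind(regions, reg)
  }
  rownames(regions) <- NULL

  ht <- classify_regions(regions, min_overlap_bp = cfg$min_overlap_bp)
  out_regions <- ht$regions
  if (!is.null(cfg$genes)) {
    genes <- read_genes(cfg$genes)
    out_regions <- annotate_regions(out_regions, genes)
    dens <- gene_density(genes, genome)
    write.table(data.frame(dens$chrom, dens$bin_start - 1, dens$bin_end,
                           dens$gene_count),
                file.path(cfg$out_dir, "gene_density.bedgraph"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  write_regions(out_regions, file.path(cfg$out_dir, "regions.tsv"))
  if (nrow(out_regions))
    write_track(out_regions, file.path(cfg$out_dir, "regions.bedgraph"))
  write.table(ht$hotspots, file.path(cfg$out_dir, "hotspots.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    tool = "sweepmeta",
    version = as.character(packageVersion("sweepmeta")),
    config = cfg[!vapply(cfg, is.null, logical(1))],
    counts = list(
      signatures_in = n_in,
      rejected = n_rejected,
      unmappable = n_unmappable,
      kept = n_in - n_rejected - n_unmappable,
      populations_analysed = length(profiles),
      per_population = unit_counts,
      regions = nrow(out_regions),
      hotspots = ht$summary$n_hotspots,
      hotspots_unique = ht$summary$n_unique,
      hotspots_shared = ht$summary$n_shared))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(genome = genome, records = sigs, weights = weights,
                 profiles = profiles, regions = out_regions,
                 hotspots = ht, manifest = manifest))
}
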