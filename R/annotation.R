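#' Read gene annotations from BED or GFF3
#'
#' The format is auto-detected from the file extension (`.bed` is
#' 0-based half-open, `.gff`/`.gff3` 1-based inclusive); both are
#' converted to the internal 1-based inclusive convention.  For GFF3,
#' only `gene` features are kept when a `type` column is present.
#'
#' @param path annotation file.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`,
#'   `end`.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop_config("gene annotation file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_config("reading gene annotations requires the rtracklayer package")
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- gr$name
  } else if (ext %in% c("gff", "gff3", "gtf")) {
    gr <- rtracklayer::import(path, format = if (ext == "gtf") "GTF" else "GFF3")
    if (!is.null(gr$type) && any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    ids <- gr$gene_id %||% NULL
    if (is.null(ids) || all(is.na(ids))) ids <- gr$ID
    if (is.null(ids) || all(is.na(ids))) ids <- gr$Name
  } else {
    stop_format("unrecognised gene annotation extension: .%s", ext)
  }
  if (is.null(ids) || all(is.na(ids)))
    ids <- sprintf("gene_%04d", seq_along(gr))
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Gene-density track in fixed genomic bins
#'
#' Tiles each chromosome with consecutive `bin_bp` bins (the last bin is
#' truncated at the chromosome end) and counts, in each bin, the genes
#' whose span overlaps it; a gene crossing a bin boundary is counted in
#' every bin it touches (`count = "midpoint"` assigns each gene to the
#' single bin holding its midpoint instead).  Genes extending past the
#' chromosome end are clipped with a warning.
#'
#' @param genes gene `data.frame` from [read_genes()].
#' @param genome a [genome_map()].
#' @param bin_bp bin width in bp (default 1 Mb).
#' @param count `"overlap"` (default) or `"midpoint"`.
#' @return A `data.frame` of class `density_track` with columns `chrom`,
#'   `bin_start`, `bin_end`, `gene_count` and attributes
#'   `mean_per_mb` (mean genes per Mb of binned genome) and
#'   `frac_empty` (fraction of bins with no gene).
#' @export
gene_density <- function(genes, genome, bin_bp = 1e6,
                         count = c("overlap", "midpoint")) {
  count <- match.arg(count)
  if (nrow(genes)) {
    len <- chrom_length(genome, genes$chrom)
    if (any(genes$end > len) || any(genes$start < 1)) {
      warning(sprintf("%d gene(s) extend beyond chromosome bounds; clipped",
                      sum(genes$end > len | genes$start < 1)))
      genes$start <- pmax(genes$start, 1)
      genes$end <- pmin(genes$end, len)
    }
  }
  bins <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    starts <- seq(1, genome$length[i], by = bin_bp)
    data.frame(chrom = genome$chrom[i], bin_start = starts,
               bin_end = pmin(starts + bin_bp - 1, genome$length[i]),
               stringsAsFactors = FALSE)
  }))
  if (count == "midpoint" && nrow(genes)) {
    mid <- floor((genes$start + genes$end) / 2)
    genes$start <- mid
    genes$end <- mid
  }
  bins$gene_count <- if (nrow(genes)) {
    GenomicRanges::countOverlaps(
      GenomicRanges::GRanges(bins$chrom,
                             IRanges::IRanges(bins$bin_start, bins$bin_end)),
      GenomicRanges::GRanges(genes$chrom,
                             IRanges::IRanges(genes$start, genes$end)))
  } else rep(0L, nrow(bins))
  attr(bins, "bin_bp") <- bin_bp
  attr(bins, "mean_per_mb") <-
    sum(bins$gene_count) / (sum(bins$bin_end - bins$bin_start + 1) / 1e6)
  attr(bins, "frac_empty") <- mean(bins$gene_count == 0)
  class(bins) <- c("density_track", "data.frame")
  bins
}

#' Genes overlapping a validated region
#'
#' @param region a one-row region `data.frame` (or list) with `chrom`,
#'   `start`, `end`.
#' @param genes gene `data.frame`.
#' @return Genes overlapping the region by at least 1 bp, sorted by
#'   start.
#' @export
genes_in_region <- function(region, genes) {
  hit <- genes$chrom == region$chrom &
    genes$start <= region$end & genes$end >= region$start
  out <- genes[hit, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate regions with their gene content
#'
#' @param regions region `data.frame`.
#' @param genes gene `data.frame`.
#' @return `regions` with `gene_count` and `gene_ids` (comma-separated)
#'   columns appended.
#' @export
annotate_regions <- function(regions, genes) {
  lists <- lapply(seq_len(nrow(regions)), function(i)
    genes_in_region(regions[i, , drop = FALSE], genes))
  regions$gene_count <- vapply(lists, nrow, integer(1))
  regions$gene_ids <- vapply(lists, function(g)
    paste(g$gene_id, collapse = ","), character(1))
  regions
}
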