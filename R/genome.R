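#' Construct a genome map
#'
#' A genome map names the reference assembly and lists its chromosomes
#' with their lengths.  All internal coordinates are 1-based inclusive;
#' every record and region is validated against these bounds.
#'
#' @param chrom character vector of chromosome names (unique).
#' @param length integer vector of chromosome lengths in bp (> 0).
#' @param assembly assembly name, e.g. `"UMD3.1"`.
#' @return A `data.frame` of class `genome_map` with columns `chrom` and
#'   `length` and an `assembly` attribute.
#' @examples
#' genome_map(c("1", "2"), c(50e6, 40e6), assembly = "UMD3.1")
#' @export
genome_map <- function(chrom, length, assembly = "UMD3.1") {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom))
    stop_validation("duplicated chromosome names in genome map: %s",
                    paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  if (any(is.na(length)) || any(length <= 0))
    stop_validation("chromosome lengths must be positive")
  gm <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  attr(gm, "assembly") <- assembly
  class(gm) <- c("genome_map", "data.frame")
  gm
}

#' Read a chromosome-sizes file
#'
#' Two-column, tab-separated `chrom<TAB>length`, no header (the common
#' `.chrom.sizes` convention).
#'
#' @param path file path.
#' @param assembly assembly name to attach.
#' @return A [genome_map()].
#' @export
read_chrom_sizes <- function(path, assembly = "UMD3.1") {
  if (!file.exists(path)) stop_config("chrom.sizes file not found: %s", path)
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "length"))
  genome_map(tab$chrom, tab$length, assembly = assembly)
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("<genome_map> assembly %s: %d chromosome(s), %.1f Mb total\n",
              attr(x, "assembly"), nrow(x), sum(x$length) / 1e6))
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i))
    stop_validation("chromosome(s) not in genome: %s",
                    paste(unique(chrom[is.na(i)]), collapse = ", "))
  genome$length[i]
}
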