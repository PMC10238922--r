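#' Genome specification for a two-parent cross
#'
#' Defines the chromosomes (physical length in bp, genetic length in cM) and
#' the biallelic marker map used by the cross simulator and the BSA scan.
#' Genetic positions are obtained by linear interpolation along each
#' chromosome, so physical distance maps to genetic distance at a constant
#' rate within a chromosome.
#'
#' @param chromosomes A data frame with columns `name` (character),
#'   `length_bp` (integer, > 0) and `length_cM` (numeric, >= 0).
#' @param markers Optional data frame with columns `chrom` and `pos`
#'   (1-based bp, strictly increasing within a chromosome). When `NULL`, a
#'   regular grid with one marker every `marker_spacing_bp` bp is laid down
#'   on every chromosome.
#' @param marker_spacing_bp Spacing of the default marker grid, in bp.
#'
#' @return An object of class `genome_spec`: a list with elements
#'   `chromosomes` (tibble), `markers` (tibble with `chrom`, `pos`, `gpos`
#'   where `gpos` is the genetic position in cM) and `marker_spacing_bp`
#'   (`NA` when explicit markers were supplied).
#' @seealso [default_genome()]
#' @export
#' @examples
#' g <- genome_spec(data.frame(name = "chrI", length_bp = 1e6, length_cM = 50),
#'                  marker_spacing_bp = 1e5)
#' g$markers
genome_spec <- function(chromosomes, markers = NULL, marker_spacing_bp = 10000) {
  chromosomes <- tibble::as_tibble(chromosomes)
  required <- c("name", "length_bp", "length_cM")
  if (!all(required %in% names(chromosomes))) {
    stop("`chromosomes` needs columns name, length_bp, length_cM", call. = FALSE)
  }
  if (anyDuplicated(chromosomes$name)) {
    stop("chromosome names must be unique", call. = FALSE)
  }
  if (any(chromosomes$length_bp < 1)) {
    stop("chromosome physical lengths must be positive", call. = FALSE)
  }
  if (any(chromosomes$length_cM < 0)) {
    stop("chromosome genetic lengths must be non-negative", call. = FALSE)
  }

  if (is.null(markers)) {
    stop_if_not_scalar_count(marker_spacing_bp, "marker_spacing_bp")
    markers <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
      pos <- seq(marker_spacing_bp, chromosomes$length_bp[i], by = marker_spacing_bp)
      if (length(pos) == 0L) {
        stop(sprintf("marker spacing larger than chromosome '%s'",
                     chromosomes$name[i]), call. = FALSE)
      }
      data.frame(chrom = chromosomes$name[i], pos = as.integer(pos))
    }))
    spacing <- as.integer(marker_spacing_bp)
  } else {
    markers <- as.data.frame(markers)[, c("chrom", "pos")]
    spacing <- NA_integer_
  }

  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  if (!all(markers$chrom %in% chromosomes$name)) {
    stop("marker chromosome not present in `chromosomes`", call. = FALSE)
  }
  # keep chromosome order, markers sorted within chromosome
  markers <- markers[order(match(markers$chrom, chromosomes$name), markers$pos), ]
  rownames(markers) <- NULL

  by_chrom <- split(seq_len(nrow(markers)),
                    factor(markers$chrom, levels = chromosomes$name))
  gpos <- numeric(nrow(markers))
  for (i in seq_len(nrow(chromosomes))) {
    rows <- by_chrom[[i]]
    if (length(rows) == 0L) {
      stop(sprintf("chromosome '%s' has no markers", chromosomes$name[i]),
           call. = FALSE)
    }
    p <- markers$pos[rows]
    if (any(p < 1) || any(p > chromosomes$length_bp[i])) {
      stop(sprintf("marker positions outside chromosome '%s'",
                   chromosomes$name[i]), call. = FALSE)
    }
    if (any(diff(p) <= 0)) {
      stop(sprintf("marker positions must be strictly increasing on '%s'",
                   chromosomes$name[i]), call. = FALSE)
    }
    gpos[rows] <- p / chromosomes$length_bp[i] * chromosomes$length_cM[i]
  }
  markers$gpos <- gpos

  structure(
    list(chromosomes = chromosomes,
         markers = tibble::as_tibble(markers),
         index = by_chrom,
         marker_spacing_bp = spacing),
    class = "genome_spec"
  )
}

#' Default C. elegans-like genome
#'
#' Six chromosomes with physical lengths close to the C. elegans reference
#' assembly and a genetic length of 50 cM each (the canonical map length of
#' C. elegans chromosomes). Chromosome IV, the mapped unit in the worked
#' examples, is 17.49 Mb.
#'
#' @param marker_spacing_bp Marker grid spacing in bp (default one marker per
#'   10 kb, ~10,100 markers genome-wide).
#' @param length_cM Genetic length applied to every chromosome, in cM.
#' @return A [genome_spec()] object.
#' @export
default_genome <- function(marker_spacing_bp = 10000, length_cM = 50) {
  chroms <- data.frame(
    name = c("chrI", "chrII", "chrIII", "chrIV", "chrV", "chrX"),
    length_bp = c(15070000L, 15280000L, 13780000L, 17490000L, 20920000L, 17720000L),
    length_cM = length_cM
  )
  genome_spec(chroms, marker_spacing_bp = marker_spacing_bp)
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %d chromosomes, %d markers\n",
              nrow(x$chromosomes), nrow(x$markers)))
  print(x$chromosomes)
  invisible(x)
}

n_markers <- function(genome) nrow(genome$markers)

chrom_rows <- function(genome, chrom) {
  rows <- genome$index[[chrom]]
  if (is.null(rows)) {
    stop(sprintf("chromosome '%s' not in genome", chrom), call. = FALSE)
  }
  rows
}
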