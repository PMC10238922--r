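#' Write / read a RIL genotype table
#'
#' Long TSV with columns `line_id`, `chrom`, `pos`, `genotype` (`AA`, `AB`,
#' `BB`; A = CB4932, B = JU1242).
#'
#' @param pop A [ril_population()].
#' @param path Output file.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_genotypes <- function(pop, path) {
  gm <- pop$genome$markers
  n_lines <- nrow(pop$geno)
  d <- data.table::data.table(
    line_id = rep(pop$line_ids, each = nrow(gm)),
    chrom = rep(gm$chrom, n_lines),
    pos = rep(gm$pos, n_lines),
    genotype = c("AA", "AB", "BB")[as.integer(t(pop$geno)) + 1L]
  )
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  d <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("line_id", "chrom", "genotype"), integer = "pos"))
  if (!all(d$genotype %in% c("AA", "AB", "BB"))) {
    stop("genotypes must be AA, AB or BB", call. = FALSE)
  }
  tibble::as_tibble(d)
}

#' Write / read per-animal phenotypes
#'
#' CSV with columns `line_id`, `animal_index`, `phenotype`, mirroring the
#' layout of supplementary phenotype sheets so that real tables exported to
#' CSV load through the same reader.
#'
#' @param pop A phenotyped [ril_population()].
#' @param path Output file.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_phenotypes <- function(pop, path) {
  if (is.null(pop$phenotypes)) stop("population has no phenotypes", call. = FALSE)
  n_animals <- ncol(pop$phenotypes)
  d <- data.table::data.table(
    line_id = rep(pop$line_ids, each = n_animals),
    animal_index = rep(seq_len(n_animals), nrow(pop$phenotypes)),
    phenotype = as.numeric(t(pop$phenotypes))
  )
  data.table::fwrite(d, path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  tibble::as_tibble(data.table::fread(path))
}

#' Read a group/value phenotype table
#'
#' Generic two-column reader for the nonparametric tests: the first (or
#' named) column gives the group label, the second the phenotype value.
#' Supplementary data sheets exported to CSV load directly.
#'
#' @param path CSV/TSV file.
#' @param group_col,value_col Column names or indices.
#' @return Tibble with columns `group` and `value`.
#' @export
read_phenotype_groups <- function(path, group_col = 1, value_col = 2) {
  d <- data.table::fread(path)
  out <- tibble::tibble(group = as.character(d[[group_col]]),
                        value = as.numeric(d[[value_col]]))
  if (anyNA(out$value)) stop("non-numeric phenotype values", call. = FALSE)
  out
}

#' Write / read a pool count table as TSV
#'
#' Columns `CHROM`, `POS`, `ORIGIN`, `VAR1`, `TOT1`, `VAR2`, `TOT2`;
#' round-trips losslessly with [read_pool_counts()].
#'
#' @param counts A [pool_counts()] table.
#' @param path Output file.
#' @return `path`, invisibly (writer); a `pool_counts` tibble (reader).
#' @export
write_pool_counts <- function(counts, path) {
  d <- data.table::data.table(CHROM = counts$chrom, POS = counts$pos,
                              ORIGIN = counts$origin,
                              VAR1 = counts$var1, TOT1 = counts$tot1,
                              VAR2 = counts$var2, TOT2 = counts$tot2)
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname write_pool_counts
#' @export
read_pool_counts <- function(path) {
  d <- data.table::fread(path, sep = "\t")
  need <- c("CHROM", "POS", "ORIGIN", "VAR1", "TOT1", "VAR2", "TOT2")
  if (!all(need %in% names(d))) {
    stop("pool count TSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  pool_counts(tibble::tibble(chrom = as.character(d$CHROM),
                             pos = as.integer(d$POS),
                             origin = as.character(d$ORIGIN),
                             var1 = as.integer(d$VAR1), tot1 = as.integer(d$TOT1),
                             var2 = as.integer(d$VAR2), tot2 = as.integer(d$TOT2)))
}

#' Write / read pool counts as a minimal VCF
#'
#' One record per site with the variant origin in the `PO` INFO key and the
#' per-pool allelic depths in the `AD` FORMAT field (`ref,alt`; the
#' ascertained variant is the ALT allele, so `alt = var` and `ref = tot -
#' var`). Two samples named by the pool labels. The reader (built on
#' [vcfR::read.vcfR()]) rejects records without an `AD` value, naming the
#' site.
#'
#' @param counts A [pool_counts()] table.
#' @param path Output `.vcf` file.
#' @param pool_names Two sample names; defaults to the table's pool labels.
#' @return `path`, invisibly (writer); a `pool_counts` tibble (reader).
#' @export
write_pool_vcf <- function(counts, path, pool_names = NULL) {
  pool_names <- pool_names %||% attr(counts, "pool_labels") %||%
    c("pool1", "pool2")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsamap",
    '##INFO=<ID=PO,Number=1,Type=String,Description="Parental origin of the ALT allele">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pool_names), collapse = "\t")
  )
  body <- sprintf("%s\t%d\t.\tA\tT\t.\tPASS\tPO=%s\tAD\t%d,%d\t%d,%d",
                  counts$chrom, counts$pos, counts$origin,
                  counts$tot1 - counts$var1, counts$var1,
                  counts$tot2 - counts$var2, counts$var2)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_pool_vcf
#' @export
read_pool_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (nrow(fix) == 0L) stop("no records in VCF", call. = FALSE)
  origin <- sub("^.*PO=([^;]+).*$", "\\1", fix[, "INFO"])
  if (!all(origin %in% c("JU1242", "CB4932"))) {
    stop("VCF records must carry a PO INFO key (JU1242/CB4932)", call. = FALSE)
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (ncol(ad) != 2L) stop("expected exactly two pool samples", call. = FALSE)
  bad <- which(is.na(ad), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("missing AD at %s:%s", fix[bad[1L, 1L], "CHROM"],
                 fix[bad[1L, 1L], "POS"]), call. = FALSE)
  }
  parse_ad <- function(s) {
    m <- matrix(as.integer(unlist(strsplit(s, ",", fixed = TRUE))),
                ncol = 2L, byrow = TRUE)
    if (anyNA(m)) stop("malformed AD field", call. = FALSE)
    m
  }
  ad1 <- parse_ad(ad[, 1L])
  ad2 <- parse_ad(ad[, 2L])
  pool_counts(tibble::tibble(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]), origin = origin,
    var1 = ad1[, 2L], tot1 = ad1[, 1L] + ad1[, 2L],
    var2 = ad2[, 2L], tot2 = ad2[, 1L] + ad2[, 2L]
  ), labels = colnames(ad))
}

#' Write / read a smoothed frequency track
#'
#' TSV with `CHROM`, `POS`, `FREQ_POOL1`, `FREQ_POOL2`, `N_SNPS` and, when
#' present, `LOR`.
#'
#' @param track Track tibble (from [smooth_frequencies()] or [bsa_scan()]).
#' @param path Output file.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_track <- function(track, path) {
  d <- data.table::as.data.table(track)
  data.table::setnames(d, toupper(names(d)))
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  d <- tibble::as_tibble(data.table::fread(path, sep = "\t"))
  names(d) <- tolower(names(d))
  d
}

#' Write / read QTL intervals as BED
#'
#' Internally intervals are 1-based inclusive; BED is 0-based half-open, so
#' a 1-based interval `[start, end]` is written as `start - 1`, `end`. The
#' `name` column carries the direction.
#'
#' @param intervals Interval tibble from [call_qtl_intervals()].
#' @param path Output `.bed` file.
#' @return `path`, invisibly (writer); a tibble with 1-based `start`
#'   (reader).
#' @export
write_bed <- function(intervals, path) {
  d <- data.table::data.table(chrom = intervals$chrom,
                              start = intervals$start - 1L,
                              end = intervals$end,
                              name = intervals$direction)
  data.table::fwrite(d, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "name")[1:4])
  tibble::tibble(chrom = as.character(d$chrom), start = as.integer(d$start) + 1L,
                 end = as.integer(d$end), direction = as.character(d$name))
}

#' Write a threshold report as JSON
#'
#' @param thresholds A `bsa_threshold`.
#' @param path Output `.json` file.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
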