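#' Define a genomic region
#'
#' A lightweight container for a named region on one chromosome.
#' Coordinates are 0-based half-open internally; see
#' [breakpoint_coordinates].
#'
#' @param name region label, unique within a catalog.
#' @param chrom chromosome label (e.g. `"chr22"`).
#' @param start 0-based start (inclusive).
#' @param end 0-based end (exclusive); must be `> start`.
#' @param assembly free-text assembly tag, e.g. `"GRCh38"` or `"toy"`.
#' @return an object of class `genomic_region`.
#' @export
#' @examples
#' genomic_region("Major_BCR", "chr22", 23289490, 23292664, "GRCh38")
genomic_region <- function(name, chrom, start, end, assembly = "unspecified") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(chrom), length(chrom) == 1L)
  if (!.is_count(start) || !.is_count(end) || start >= end) {
    .stop_format("region '%s': need integer coordinates with start < end", name)
  }
  structure(
    list(name = name, chrom = chrom, start = as.numeric(start),
         end = as.numeric(end), assembly = assembly),
    class = "genomic_region"
  )
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("<genomic_region> %s  %s:%s-%s (0-based half-open, %s; %s bp)\n",
              x$name, x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              x$assembly, format(x$end - x$start, big.mark = ",")))
  invisible(x)
}

region_width <- function(region) region$end - region$start

region_contains <- function(region, pos) {
  pos >= region$start & pos < region$end
}

#' Build a region catalog
#'
#' A catalog is a named collection of [genomic_region()] objects, keyed by
#' region name. It owns locus assignment for cohort tables.
#'
#' @param ... `genomic_region` objects.
#' @return an object of class `region_catalog`.
#' @seealso [bcr_abl1_catalog()] for the shipped GRCh38 default,
#'   [toy_catalog()] for the simulator's toy layout.
#' @export
region_catalog <- function(...) {
  regions <- list(...)
  if (length(regions) == 1L && is.list(regions[[1L]]) &&
      !inherits(regions[[1L]], "genomic_region")) {
    regions <- regions[[1L]]
  }
  ok <- vapply(regions, inherits, logical(1L), "genomic_region")
  if (!all(ok)) .stop_format("all catalog entries must be genomic_region objects")
  nms <- vapply(regions, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) {
    .stop_format("duplicate region name in catalog: %s",
                 nms[duplicated(nms)][1L])
  }
  names(regions) <- nms
  structure(list(regions = regions), class = "region_catalog")
}

#' @export
print.region_catalog <- function(x, ...) {
  cat(sprintf("<region_catalog> %d regions\n", length(x$regions)))
  for (r in x$regions) print(r)
  invisible(x)
}

#' The BCR/ABL1 breakpoint region catalog (GRCh38)
#'
#' The breakpoint cluster regions targeted in genomic BCR::ABL1 fusion
#' mapping, in GRCh38/hg38 coordinates: the minor BCR region (intron 1,
#' ~71.5 kbp, yielding p190), the Major BCR region (introns 13-14,
#' ~2.9 kbp, yielding p210), the micro BCR region (p230), and the ABL1
#' breakpoint area (intron 1 plus the upstream EXOSC2/intergenic stretch).
#'
#' The 1-based inclusive spans are chr22:23,180,958-23,254,000 (minor),
#' chr22:23,289,491-23,292,664 (Major), chr22:23,311,732-23,313,035
#' (micro) and chr9:130,699,582-130,855,101 (ABL1); they are stored
#' 0-based half-open internally.
#'
#' @return a [region_catalog()] with regions `minor_BCR`, `Major_BCR`,
#'   `micro_BCR`, `ABL1`.
#' @export
#' @examples
#' bcr_abl1_catalog()
bcr_abl1_catalog <- function() {
  region_catalog(
    genomic_region("minor_BCR", "chr22", 23180958 - 1, 23254000, "GRCh38"),
    genomic_region("Major_BCR", "chr22", 23289491 - 1, 23292664, "GRCh38"),
    genomic_region("micro_BCR", "chr22", 23311732 - 1, 23313035, "GRCh38"),
    genomic_region("ABL1",      "chr9",  130699582 - 1, 130855101, "GRCh38")
  )
}

#' Toy region catalog matching [make_toy_reference()]
#'
#' Lays the three BCR-analog breakpoint cluster regions onto the toy
#' chr22 sequence and one ABL1-analog region onto the toy chr9 sequence.
#' Regions keep a margin away from the sequence ends so junction-spanning
#' reads and classification flanks never run off the reference.
#'
#' @param len22,len9 toy chromosome lengths in bases.
#' @return a [region_catalog()] with regions `minor_BCR`, `Major_BCR`,
#'   `micro_BCR` (on `chr22_toy`) and `ABL1` (on `chr9_toy`).
#' @export
toy_catalog <- function(len22 = 80000, len9 = 120000) {
  if (len22 < 20000 || len9 < 20000) {
    .stop_format("toy chromosomes must be at least 20 kbp")
  }
  # proportional layout: minor takes most of chr22, Major and micro are
  # small downstream regions, mirroring the real BCR architecture
  minor_end <- round(len22 * 0.66)
  major_start <- round(len22 * 0.72)
  major_end <- round(len22 * 0.80)
  micro_start <- round(len22 * 0.84)
  micro_end <- round(len22 * 0.90)
  region_catalog(
    genomic_region("minor_BCR", "chr22_toy", 2000, minor_end, "toy"),
    genomic_region("Major_BCR", "chr22_toy", major_start, major_end, "toy"),
    genomic_region("micro_BCR", "chr22_toy", micro_start, micro_end, "toy"),
    genomic_region("ABL1", "chr9_toy", 2000, len9 - 2000, "toy")
  )
}

# short locus labels <-> catalog region names
.locus_region_name <- function(locus) {
  switch(locus,
         minor = "minor_BCR", Major = "Major_BCR", micro = "micro_BCR",
         .stop_format("unknown locus '%s'", locus))
}

#' Assign the BCR-side locus of a breakpoint pair
#'
#' Determines which BCR breakpoint cluster region (`minor`, `Major`,
#' `micro`) contains the chr22 coordinate, and flags chr9 coordinates
#' lying upstream of (before the start of) the ABL1 region as locus
#' `"upstream"`.
#'
#' @param pos22,pos9 internal 0-based coordinates (vectors recycle).
#' @param catalog a [region_catalog()] with the four standard regions.
#' @param warn warn on coordinates outside every region.
#' @return character vector of loci: `minor`, `Major`, `micro`,
#'   `upstream`, or `NA` when the chr22 coordinate is outside all BCR
#'   regions.
#' @export
assign_locus <- function(pos22, pos9 = NA, catalog = bcr_abl1_catalog(),
                         warn = TRUE) {
  n <- max(length(pos22), length(pos9))
  pos22 <- rep_len(as.numeric(pos22), n)
  pos9 <- rep_len(as.numeric(pos9), n)
  locus <- rep(NA_character_, n)
  for (short in c("minor", "Major", "micro")) {
    reg <- catalog$regions[[.locus_region_name(short)]]
    if (is.null(reg)) next
    hit <- !is.na(pos22) & region_contains(reg, pos22)
    locus[hit] <- short
  }
  abl <- catalog$regions[["ABL1"]]
  if (!is.null(abl)) {
    up <- !is.na(pos9) & pos9 < abl$start
    locus[up] <- "upstream"
    beyond <- !is.na(pos9) & pos9 >= abl$end
    if (warn && any(beyond)) {
      warning(sprintf("%d chr9 coordinate(s) beyond the 3' end of the %s region",
                      sum(beyond), abl$name), call. = FALSE)
    }
  }
  if (warn && anyNA(locus[!is.na(pos22)])) {
    warning(sprintf("%d chr22 coordinate(s) outside every BCR region; locus set to NA",
                    sum(is.na(locus) & !is.na(pos22))), call. = FALSE)
  }
  locus
}
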