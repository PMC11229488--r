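# Readers and writers for the cohort table, sequences, reads and
# intervals. All conversions between the 1-based file convention and the
# 0-based internal convention happen here and nowhere else.

# default column mapping of the cohort TSV; users of differently-shaped
# tables (e.g. published supplementary tables) can remap any column name
.default_cohort_columns <- function() {
  list(
    patient_id = "patient_id",
    diagnosis = "diagnosis",
    age_years = "age_years",
    sex = "sex",
    pos22 = "chr22_pos",
    pos9 = "chr9_pos",
    pos22_rec = "chr22_pos_reciprocal",
    pos9_rec = "chr9_pos_reciprocal",
    junction_seq = "junction_seq"
  )
}

#' Read a cohort breakpoint table
#'
#' Reads a tab-separated cohort table (one row per patient, `#` comment
#' lines allowed, UTF-8) holding diagnosis, demographics, the forward
#' (BCR::ABL1-analog) breakpoint pair, optionally the reciprocal
#' (ABL1::BCR-analog) pair, and optionally a junction sequence. File
#' coordinates are 1-based and converted to internal 0-based on read;
#' the BCR-side locus is assigned from `catalog` (see [assign_locus()]).
#'
#' Mandatory columns (default names, remappable through `columns`):
#' `patient_id`, `diagnosis`, `chr22_pos`, `chr9_pos`. Optional:
#' `age_years`, `sex`, `chr22_pos_reciprocal`, `chr9_pos_reciprocal`,
#' `junction_seq`.
#'
#' @param path TSV file path.
#' @param catalog a [region_catalog()] used for locus assignment.
#' @param columns named list remapping internal field names to file
#'   column names; defaults cover the package's own writer.
#' @return a `data.frame` of class `fusion_cohort` with columns
#'   `patient_id`, `diagnosis`, `age_years`, `sex`, `locus`, `pos22`,
#'   `pos9`, `pos22_rec`, `pos9_rec`, `junction_seq` (positions 0-based).
#'   Rows whose coordinates could not be parsed are reported in a warning
#'   and returned in the `"bad_rows"` attribute, never silently dropped.
#' @export
read_cohort_table <- function(path, catalog = bcr_abl1_catalog(),
                              columns = list()) {
  if (!file.exists(path)) .stop_format("cohort table not found: %s", path)
  cols <- utils::modifyList(.default_cohort_columns(), columns)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8")
  for (mand in c("patient_id", "diagnosis", "pos22", "pos9")) {
    if (!cols[[mand]] %in% names(raw)) {
      .stop_format("cohort table %s: missing mandatory column '%s'",
                   path, cols[[mand]])
    }
  }
  get_col <- function(field, default = NA_character_) {
    nm <- cols[[field]]
    if (nm %in% names(raw)) raw[[nm]] else rep(default, nrow(raw))
  }
  parse_pos <- function(x) {
    x <- gsub(",", "", trimws(x))      # tolerate 23,180,958-style grouping
    suppressWarnings(as.numeric(x))
  }
  pos22 <- parse_pos(get_col("pos22"))
  pos9 <- parse_pos(get_col("pos9"))
  bad <- which((is.na(pos22) & nzchar(trimws(get_col("pos22"))) &
                  !is.na(get_col("pos22"))) |
                 (is.na(pos9) & nzchar(trimws(get_col("pos9"))) &
                    !is.na(get_col("pos9"))))
  if (length(bad)) {
    warning(sprintf("cohort table %s: %d row(s) with unparseable coordinates (rows %s)",
                    path, length(bad),
                    paste(utils::head(bad, 10L), collapse = ", ")),
            call. = FALSE)
  }
  diagnosis <- trimws(get_col("diagnosis"))
  unknown_dx <- setdiff(unique(diagnosis), c("CML", "ALL", NA, ""))
  if (length(unknown_dx)) {
    warning(sprintf("diagnosis values outside {CML, ALL}: %s",
                    paste(unknown_dx, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(
    patient_id = get_col("patient_id"),
    diagnosis = diagnosis,
    age_years = suppressWarnings(as.numeric(get_col("age_years"))),
    sex = get_col("sex"),
    locus = NA_character_,
    pos22 = pos22 - 1,                 # 1-based file -> 0-based internal
    pos9 = pos9 - 1,
    pos22_rec = parse_pos(get_col("pos22_rec")) - 1,
    pos9_rec = parse_pos(get_col("pos9_rec")) - 1,
    junction_seq = toupper(get_col("junction_seq")),
    stringsAsFactors = FALSE
  )
  out$junction_seq[!is.na(out$junction_seq) & out$junction_seq == ""] <-
    NA_character_
  out$sex[!out$sex %in% c("M", "F")] <- NA_character_
  out$locus <- assign_locus(out$pos22, out$pos9, catalog)
  attr(out, "bad_rows") <- bad
  attr(out, "catalog") <- catalog
  class(out) <- c("fusion_cohort", class(out))
  out
}

#' Write a cohort breakpoint table
#'
#' Inverse of [read_cohort_table()]: internal 0-based coordinates are
#' written 1-based. `read_cohort_table(write_cohort_table(x))` is the
#' identity on valid tables.
#'
#' @param cohort a cohort `data.frame` with internal 0-based coordinates.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  cols <- .default_cohort_columns()
  out <- data.frame(
    cohort$patient_id, cohort$diagnosis, cohort$age_years, cohort$sex,
    cohort$pos22 + 1, cohort$pos9 + 1,
    cohort$pos22_rec + 1, cohort$pos9_rec + 1,
    cohort$junction_seq,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(out) <- unlist(cols[c("patient_id", "diagnosis", "age_years", "sex",
                              "pos22", "pos9", "pos22_rec", "pos9_rec",
                              "junction_seq")])
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# cohort breakpoint table; coordinates 1-based inclusive", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read named nucleotide sequences from FASTA
#'
#' Sequences are uppercased and validated against the IUPAC alphabet;
#' the write/read round trip is the identity.
#'
#' @param path FASTA file.
#' @return a named character vector of uppercase sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) .stop_format("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)    # BString: keep any chars, check ourselves
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  for (i in seq_along(seqs)) {
    bad <- regexpr(sprintf("[^%s]", paste(names(IUPAC_MAP), collapse = "")),
                   seqs[[i]])
    if (bad > 0) {
      .stop_format("FASTA %s, record '%s': non-IUPAC character '%s' at position %d",
                   path, names(seqs)[i], substr(seqs[[i]], bad, bad), bad)
    }
  }
  seqs
}

#' Write named nucleotide sequences to FASTA
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  if (is.character(seqs)) {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
      .stop_format("sequences must be named for FASTA output")
    }
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read junction-spanning reads from FASTQ
#'
#' @param path FASTQ file.
#' @return a named character vector of read sequences (qualities are not
#'   used by the caller and are dropped).
#' @export
read_junction_reads <- function(path) {
  if (!file.exists(path)) .stop_format("FASTQ file not found: %s", path)
  info <- file.info(path)
  if (info$size == 0) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  reads <- toupper(as.character(set))
  names(reads) <- sub("\\s.*$", "", names(set))
  reads
}

# FASTQ writer used by the read simulator; constant qualities.
.write_fastq <- function(reads, path, qual_char = "I") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(reads)) {
    lines <- as.vector(rbind(paste0("@", names(reads)),
                             unname(reads),
                             "+",
                             vapply(nchar(reads),
                                    function(n) strrep(qual_char, n),
                                    character(1L))))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write intervals to BED
#'
#' @param intervals `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `name`, `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  out <- data.frame(
    intervals$chrom, intervals$start, intervals$end,
    if ("name" %in% names(intervals)) intervals$name else ".",
    if ("score" %in% names(intervals)) intervals$score else 0,
    if ("strand" %in% names(intervals)) intervals$strand else ".",
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED file (3-6 columns).
#' @return `data.frame` with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) .stop_format("BED file not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(raw) <- nm[seq_len(min(ncol(raw), 6L))]
  raw
}
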