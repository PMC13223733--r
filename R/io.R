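#' Read and write localization tables
#'
#' Localization tables are CSV files with the header
#' `x_nm, y_nm, frame, photons, ellipticity, psf_width_px` — coordinates
#' in nm, PSF width in camera pixels.
#'
#' @param table data frame with the columns above.
#' @param path file path.
#' @return `read_localizations` returns the data frame;
#'   `write_localizations` returns `path` invisibly.
#' @export
write_localizations <- function(table, path) {
  cols <- c("x_nm", "y_nm", "frame", "photons", "ellipticity", "psf_width_px")
  stopifnot(all(cols %in% names(table)))
  write.csv(table[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  tab <- read.csv(path)
  cols <- c("x_nm", "y_nm", "frame", "photons", "ellipticity", "psf_width_px")
  missing <- setdiff(cols, names(tab))
  if (length(missing))
    stop("localization table lacks columns: ", paste(missing, collapse = ", "))
  tab
}

#' Write and read SAM-style alignment records
#'
#' `write_sam` writes a minimal valid SAM file (with `@HD` and `@SQ`
#' headers) from a data frame of core fields; `read_sam` reads one back
#' through Rsamtools (SAM is converted to BAM in a temporary directory and
#' scanned), returning the same core fields.
#'
#' @param records data frame with columns
#'   `qname, flag, rname, pos, mapq, cigar, seq` (as produced by
#'   [simulate_reads()]).
#' @param path SAM file path.
#' @param seq_lengths named integer vector of reference lengths for the
#'   `@SQ` header; defaults to a length covering all alignments.
#' @return `read_sam` returns a data frame of the core fields.
#' @export
write_sam <- function(records, path, seq_lengths = NULL) {
  cols <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  stopifnot(all(cols %in% names(records)))
  if (is.null(seq_lengths)) {
    refs <- unique(as.character(records$rname))
    if (!length(refs)) refs <- "chr1"
    seq_lengths <- setNames(rep.int(1L, length(refs)), refs)
    for (r in refs) {
      sub <- records[records$rname == r, ]
      ends <- sub$pos + vapply(as.character(sub$cigar), .cigar_ref_width, 0)
      seq_lengths[r] <- max(1000L, as.integer(max(ends)) + 1000L)
    }
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
                   as.integer(seq_lengths)))
  body <- if (nrow(records)) sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
    records$qname, as.integer(records$flag), as.character(records$rname),
    as.integer(records$pos), as.integer(records$mapq),
    as.character(records$cigar), as.character(records$seq)) else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")))[[1]]
  data.frame(qname = res$qname, flag = res$flag,
             rname = as.character(res$rname), pos = res$pos,
             mapq = res$mapq, cigar = res$cigar,
             seq = as.character(res$seq))
}

.cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

#' Construct a local splicing variation record
#'
#' A local splicing variation (LSV) groups the splice junctions that share
#' one reference exon: a *source* LSV shares the donor exon, a *target*
#' LSV the acceptor exon. Per junction the record carries the change in
#' percent-selected-index between conditions (deltaPSI, percent) and
#' 1-based closed genomic coordinates of the junction (first/last intronic
#' base); `ir` marks an intron-retention "junction" spanning an unspliced
#' intron.
#'
#' @param lsv_id identifier.
#' @param orientation `"source"` or `"target"`.
#' @param dpsi numeric vector, percent change in junction usage.
#' @param probability LSV change probability in `[0, 1]`.
#' @param junctions optional data frame `start, end` (1-based closed) and
#'   optional logical `ir`; one row per junction.
#' @param gene_id optional gene identifier.
#' @return list of class `lsv_record`.
#' @export
lsv_record <- function(lsv_id, orientation = c("source", "target"),
                       dpsi, probability, junctions = NULL,
                       gene_id = NA_character_) {
  orientation <- match.arg(orientation)
  if (probability < 0 || probability > 1)
    stop("probability must be in [0, 1]")
  if (!is.null(junctions)) {
    stopifnot(all(c("start", "end") %in% names(junctions)),
              nrow(junctions) == length(dpsi))
    if (is.null(junctions$ir)) junctions$ir <- FALSE
    if (any(junctions$end < junctions$start))
      stop("junction end < start")
  }
  structure(list(gene_id = gene_id, lsv_id = lsv_id,
                 orientation = orientation, dpsi = as.numeric(dpsi),
                 probability = probability, junctions = junctions),
            class = "lsv_record")
}

#' Write and read LSV tables as TSV
#'
#' Junction deltaPSIs are stored semicolon-separated in one column, as in
#' flat exports of splicing quantifiers.
#'
#' @param table LSV data frame (list column `dpsi`), as from
#'   [simulate_lsv_table()].
#' @param path TSV path.
#' @export
write_lsv_table <- function(table, path) {
  flat <- table
  flat$dpsi <- vapply(table$dpsi, function(v)
    paste(format(v, trim = TRUE, digits = 10), collapse = ";"), "")
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lsv_table
#' @export
read_lsv_table <- function(path) {
  flat <- read.delim(path, stringsAsFactors = FALSE)
  flat$dpsi <- I(lapply(strsplit(as.character(flat$dpsi), ";"), as.numeric))
  flat
}
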