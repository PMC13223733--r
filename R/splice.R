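#' Classify a local splicing variation as regulated or not
#'
#' Applies the standard stratification rule to an LSV's junction deltaPSI
#' values (percent) and change probability:
#' *regulated* when the maximum absolute junction deltaPSI exceeds 5% and
#' the change probability exceeds 0.5; *non-regulated* when the maximum
#' absolute deltaPSI is below 2% and the change probability is exactly 0;
#' everything in between is *ambiguous* (kept as a third class rather
#' than silently dropped).
#'
#' @param lsv an [lsv_record()] or any list with elements `dpsi`
#'   (numeric, percent) and `probability` (fraction in `[0, 1]`).
#' @return `"regulated"`, `"non_regulated"` or `"ambiguous"`.
#' @export
classify_regulated <- function(lsv) {
  m <- max(abs(lsv$dpsi))
  p <- lsv$probability
  if (m > 5 && p > 0.5) "regulated"
  else if (m < 2 && p == 0) "non_regulated"
  else "ambiguous"
}

#' Classify every row of an LSV table
#'
#' @param table data frame with a `dpsi` list column and `probability`,
#'   as from [simulate_lsv_table()] or [read_lsv_table()].
#' @return character vector of classes, one per row.
#' @export
classify_lsv_table <- function(table) {
  vapply(seq_len(nrow(table)), function(i)
    classify_regulated(list(dpsi = table$dpsi[[i]],
                            probability = table$probability[i])),
    "")
}

#' Reduce an LSV to its two main junctions
#'
#' Ranks junctions by absolute deltaPSI and retains the LSV only if the
#' second-strongest junction explains at least 50% of the change of the
#' strongest one (|deltaPSI2| >= 0.5 * |deltaPSI1|) *and* the two changes
#' have opposing signs, i.e. usage genuinely shifts from one junction to
#' the other. LSVs passing this rule behave as binary events.
#'
#' @param lsv an [lsv_record()] or list with a `dpsi` vector (>= 2
#'   junctions; `junctions` rows are carried along when present).
#' @return list: `retained` (logical); when retained also `main` and
#'   `second` (junction indices into the original order), `dpsi_main`,
#'   `dpsi_second`.
#' @export
binarize_lsv <- function(lsv) {
  d <- lsv$dpsi
  if (length(d) < 2) stop("an LSV needs at least 2 junctions")
  ord <- order(abs(d), decreasing = TRUE)
  i1 <- ord[1]; i2 <- ord[2]
  ok <- abs(d[i2]) >= 0.5 * abs(d[i1]) && sign(d[i1]) * sign(d[i2]) < 0
  if (!ok) return(list(retained = FALSE))
  list(retained = TRUE, main = i1, second = i2,
       dpsi_main = d[i1], dpsi_second = d[i2])
}

#' Classify a binary splicing event from its source and target LSVs
#'
#' Combines the two main junctions of a *source* LSV (junctions sharing a
#' donor exon) and a *target* LSV (sharing an acceptor exon) into one
#' event call, requiring both LSVs to be regulated
#' ([classify_regulated()]) and binary ([binarize_lsv()]). The geometric
#' rules on 1-based closed junction coordinates are:
#'
#' * a main junction flagged as intron retention => `intron_retention`;
#' * two distinct junctions sharing their donor (start) with different
#'   acceptors (ends) => `alt_3ss`;
#' * two distinct junctions sharing their acceptor with different
#'   donors => `alt_5ss`;
#' * a skip junction common to both LSVs plus an inclusion junction on
#'   each side enclosing a middle exon => `cassette`.
#'
#' @param source_lsv,target_lsv [lsv_record()]s with junction
#'   coordinates.
#' @return list of class `event_call`: `type`, `junctions` (the distinct
#'   main junctions involved), `source_id`, `target_id`, and
#'   `cassette_exon` (`c(start, end)` of the variable exon for cassette
#'   events).
#' @export
classify_event <- function(source_lsv, target_lsv) {
  for (l in list(source_lsv, target_lsv)) {
    if (is.null(l$junctions)) stop("LSVs must carry junction coordinates")
    if (classify_regulated(l) != "regulated")
      stop("both LSVs must be regulated")
  }
  if (source_lsv$orientation != "source" ||
      target_lsv$orientation != "target")
    stop("expected one source and one target LSV")
  bs <- binarize_lsv(source_lsv); bt <- binarize_lsv(target_lsv)
  if (!bs$retained || !bt$retained)
    stop("both LSVs must pass binarization")
  js <- source_lsv$junctions[c(bs$main, bs$second), , drop = FALSE]
  jt <- target_lsv$junctions[c(bt$main, bt$second), , drop = FALSE]
  all_j <- rbind(js, jt)
  if (any(all_j$end < all_j$start)) stop("inconsistent junction coordinates")
  key <- paste(all_j$start, all_j$end)
  uniq <- all_j[!duplicated(key), , drop = FALSE]
  mk <- function(type, cassette_exon = NULL)
    structure(list(type = type, junctions = uniq,
                   source_id = source_lsv$lsv_id,
                   target_id = target_lsv$lsv_id,
                   cassette_exon = cassette_exon),
              class = "event_call")
  if (any(uniq$ir)) return(mk("intron_retention"))
  if (nrow(uniq) == 2) {
    if (uniq$start[1] == uniq$start[2] && uniq$end[1] != uniq$end[2])
      return(mk("alt_3ss"))
    if (uniq$end[1] == uniq$end[2] && uniq$start[1] != uniq$start[2])
      return(mk("alt_5ss"))
    stop("two-junction event with inconsistent geometry")
  }
  if (nrow(uniq) == 3) {
    ## cassette: skip junction D -> A shared by both LSVs, inclusion
    ## junctions D -> e_start and e_end -> A around the variable exon
    skip_key <- intersect(paste(js$start, js$end), paste(jt$start, jt$end))
    if (length(skip_key) == 1) {
      skip <- uniq[paste(uniq$start, uniq$end) == skip_key, ]
      inc_s <- js[paste(js$start, js$end) != skip_key, ]   # D -> A1
      inc_t <- jt[paste(jt$start, jt$end) != skip_key, ]   # D2 -> A
      if (inc_s$start == skip$start && inc_t$end == skip$end &&
          inc_s$end < inc_t$start)
        return(mk("cassette",
                  cassette_exon = c(inc_s$end + 1, inc_t$start - 1)))
    }
  }
  stop("event geometry not classifiable from the main junctions")
}

#' @export
print.event_call <- function(x, ...) {
  cat(sprintf("event_call: %s (%s / %s)\n", x$type, x$source_id,
              x$target_id))
  invisible(x)
}

#' Sub-classify a cassette event
#'
#' Distinguishes simple cassette exons from alternative first/last exons
#' and complex events. An event whose LSVs carry more than the binary
#' junction pattern (any LSV with more than two junctions showing
#' appreciable change) is `complex`. Otherwise the variable exon is
#' located in the transcript model: terminal at the 5' end gives
#' `alt_first_exon`, terminal at the 3' end `alt_last_exon`, internal
#' `simple`. Without a transcript model, `complex` is still callable but
#' the first/last distinction is not: the call is `"unknown"`.
#'
#' @param event an `event_call` of type `"cassette"` from
#'   [classify_event()].
#' @param transcript_model optional data frame of transcript exons
#'   (`start, end`, 1-based closed, in transcript order).
#' @param source_lsv,target_lsv optionally the LSVs the event came from,
#'   used to detect complex junction patterns (> 2 junctions with
#'   |deltaPSI| above `complex_min_dpsi`).
#' @param complex_min_dpsi percent threshold above which extra junctions
#'   flag a complex event (default 1).
#' @return `"simple"`, `"alt_first_exon"`, `"alt_last_exon"`,
#'   `"complex"`, or `"unknown"` (cassette with no transcript model).
#' @export
subclassify_cassette <- function(event, transcript_model = NULL,
                                 source_lsv = NULL, target_lsv = NULL,
                                 complex_min_dpsi = 1) {
  stopifnot(inherits(event, "event_call"))
  if (event$type != "cassette") stop("event is not a cassette")
  n_active <- function(l) sum(abs(l$dpsi) > complex_min_dpsi)
  if ((!is.null(source_lsv) && n_active(source_lsv) > 2) ||
      (!is.null(target_lsv) && n_active(target_lsv) > 2))
    return("complex")
  if (is.null(transcript_model)) return("unknown")
  ex <- event$cassette_exon
  hit <- which(transcript_model$start <= ex[1] &
                 transcript_model$end >= ex[2])
  if (!length(hit)) return("unknown")
  if (min(hit) == 1) "alt_first_exon"
  else if (max(hit) == nrow(transcript_model)) "alt_last_exon"
  else "simple"
}

#' Count polyA-evidence reads over a genomic region
#'
#' A read counts as polyA evidence if its alignment carries a
#' non-templated adenosine tail: a 3' soft-clipped segment of at least
#' `min_tail` nt whose adenosine fraction is at least `min_a_frac`.
#' Strand-aware: on reverse-strand alignments the tail appears as a 5'
#' soft clip of thymidines. Adenosine runs encoded in the template (i.e.
#' aligned, not clipped) never count. A read is attributed to the region
#' when its aligned 3' end (the polyadenylation-site-proximal end) falls
#' within the region.
#'
#' @param records alignment data frame (`flag, rname, pos, cigar, seq`),
#'   e.g. from [simulate_reads()] or [read_sam()].
#' @param region list `(chrom, start, end)`, 1-based closed, non-empty.
#' @param min_tail minimum soft-clip length in nt (default 6).
#' @param min_a_frac minimum A (or T) fraction of the clip (default 0.8).
#' @param reference_count optional count from a reference sample
#'   (e.g. the t = 0 library); when given, a log2 fold change with a +1
#'   pseudocount is reported.
#' @return list of class `pa_count`: `region`, `n_pa`, `n_total`,
#'   `log2fc` (`NA` without a reference).
#' @export
count_pa_reads <- function(records, region, min_tail = 6, min_a_frac = 0.8,
                           reference_count = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(region)))
  if (region$end < region$start) stop("empty region")
  n <- nrow(records)
  if (n == 0)
    return(structure(list(region = region, n_pa = 0L, n_total = 0L,
                          log2fc = if (is.null(reference_count)) NA_real_
                          else log2(1 / (reference_count + 1))),
                     class = "pa_count"))
  cigars <- as.character(records$cigar)
  ref_w <- vapply(cigars, .cigar_ref_width, 0, USE.NAMES = FALSE)
  aln_end <- records$pos + ref_w - 1
  reverse <- bitwAnd(as.integer(records$flag), 16L) > 0
  ## genomic position of the read's 3' end
  end3 <- ifelse(reverse, records$pos, aln_end)
  in_region <- as.character(records$rname) == region$chrom &
    end3 >= region$start & end3 <= region$end
  ops <- GenomicAlignments::explodeCigarOps(cigars)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigars)
  is_pa <- vapply(seq_len(n), function(i) {
    op <- ops[[i]]; ln <- lens[[i]]
    sq <- as.character(records$seq[i])
    if (reverse[i]) {
      if (op[1] != "S") return(FALSE)
      clip_len <- ln[1]
      clip <- substr(sq, 1, clip_len)
      base <- "T"
    } else {
      k <- length(op)
      if (op[k] != "S") return(FALSE)
      clip_len <- ln[k]
      clip <- substr(sq, nchar(sq) - clip_len + 1, nchar(sq))
      base <- "A"
    }
    if (clip_len < min_tail) return(FALSE)
    frac <- sum(strsplit(clip, "")[[1]] == base) / clip_len
    frac >= min_a_frac
  }, TRUE)
  n_pa <- sum(is_pa & in_region)
  n_total <- sum(in_region)
  log2fc <- if (is.null(reference_count)) NA_real_
  else log2((n_pa + 1) / (reference_count + 1))
  structure(list(region = region, n_pa = as.integer(n_pa),
                 n_total = as.integer(n_total), log2fc = log2fc),
            class = "pa_count")
}

#' @export
print.pa_count <- function(x, ...) {
  cat(sprintf("pa_count: %d polyA-evidence of %d reads in %s:%d-%d%s\n",
              x$n_pa, x$n_total, x$region$chrom, x$region$start,
              x$region$end,
              if (is.finite(x$log2fc))
                sprintf(" (log2FC %.2f)", x$log2fc) else ""))
  invisible(x)
}
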