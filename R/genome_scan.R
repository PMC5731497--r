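# Sliding-window scanner: score every window of a sequence with a trained
# network and nominate candidate splice sites at the anchor coordinate
# (1-based first base of the dinucleotide), with neighborhood suppression.

#' Scan a sequence for candidate splice sites
#'
#' Every window start at stride \code{step} is encoded under \code{scheme}
#' and scored by the network; windows scoring at or above \code{threshold}
#' emit a call at the anchor coordinate. Windows containing non-ACGT
#' characters are skipped and counted (attribute \code{"skipped"}).
#'
#' @param network A trained \code{stacked_network}.
#' @param scheme The \code{encoding_scheme} the network was trained with.
#' @param record A single DNA sequence: \code{DNAString}, one-record
#'   \code{DNAStringSet}, or character string.
#' @param site_type \code{"acceptor"} or \code{"donor"} (reported in calls).
#' @param step Stride in nt (default 1).
#' @param threshold Minimum probability to emit a call.
#' @param strand \code{"+"} scans the sequence as given; \code{"-"} scans its
#'   reverse complement and reports calls at the mirrored plus-strand
#'   coordinate of the anchor (position of the anchor interval's first base).
#' @param chrom Sequence id for the calls (default taken from the record).
#' @return \code{data.frame} of class \code{splice_site_calls} with columns
#'   \code{chrom}, \code{position} (1-based anchor first base),
#'   \code{strand}, \code{site_type}, \code{score}; sorted by position.
#' @export
scan <- function(network, scheme, record, site_type, step = 1L,
                 threshold = 0.5, strand = c("+", "-"), chrom = NULL) {
  anchor_consensus(site_type)
  strand <- match.arg(strand)
  if (methods::is(record, "DNAStringSet")) {
    if (length(record) != 1L) stop("scan takes a single sequence record")
    chrom <- chrom %||% names(record) %||% "seq"
    s <- as.character(record[[1L]])
  } else if (methods::is(record, "DNAString")) {
    s <- as.character(record)
    chrom <- chrom %||% "seq"
  } else {
    s <- as.character(record)
    chrom <- chrom %||% (names(record) %||% "seq")
  }
  s <- normalize_dna(s)
  n_seq <- nchar(s)
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  L <- if (scheme$unit == "mono") network$d_input else network$d_input + 1L
  empty <- calls_frame(character(0), integer(0), character(0), character(0),
                       numeric(0))
  if (nchar(s) < L) {
    warning("sequence shorter than the ", L, "-nt window; no calls")
    return(empty)
  }
  starts <- seq(1L, nchar(s) - L + 1L, by = as.integer(step))
  wins <- substring(s, starts, starts + L - 1L)
  ok <- !grepl("[^ACGT]", wins)
  n_skipped <- sum(!ok)
  starts <- starts[ok]; wins <- wins[ok]
  out <- empty
  if (length(wins)) {
    X <- encode_batch(wins, scheme)$x
    p <- predict_proba(network, X)
    hit <- p >= threshold
    anchor_pos <- starts[hit] + floor(L / 2) - 1L
    if (strand == "-") anchor_pos <- n_seq - anchor_pos  # mirror to plus coords
    out <- calls_frame(rep(chrom, sum(hit)), anchor_pos,
                       rep(strand, sum(hit)), rep(site_type, sum(hit)), p[hit])
    out <- out[order(out$position), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- n_skipped
  out
}

calls_frame <- function(chrom, position, strand, site_type, score) {
  df <- data.frame(chrom = chrom, position = as.integer(position),
                   strand = strand, site_type = site_type,
                   score = as.numeric(score), stringsAsFactors = FALSE)
  class(df) <- c("splice_site_calls", "data.frame")
  df
}

#' Suppress clustered calls
#'
#' Keeps a call only if no other call within \code{radius} nt (on the same
#' chromosome) has a higher score, or an equal score at a smaller position
#' (ties go to the leftmost call).
#'
#' @param calls A \code{splice_site_calls} data frame.
#' @param radius Neighborhood half-width in nt.
#' @return The filtered calls, original order preserved.
#' @export
suppress <- function(calls, radius) {
  if (!nrow(calls)) return(calls)
  keep <- vapply(seq_len(nrow(calls)), function(i) {
    near <- calls$chrom == calls$chrom[i] &
      abs(calls$position - calls$position[i]) <= radius
    better <- calls$score[near] > calls$score[i] |
      (calls$score[near] == calls$score[i] &
         calls$position[near] < calls$position[i])
    !any(better)
  }, logical(1L))
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write calls as BED6
#'
#' The interval covers the 2-nt anchor (0-based half-open); the BED score
#' column is \code{round(1000 * score)}.
#'
#' @param calls A \code{splice_site_calls} data frame.
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  if (!nrow(calls)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    calls$chrom,
    IRanges::IRanges(start = calls$position, end = calls$position + 1L),
    strand = calls$strand)
  gr$name <- calls$site_type
  gr$score <- round(1000 * calls$score)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read calls back from a BED6 file written by \code{\link{write_calls}}
#'
#' @param path BED file path.
#' @return A \code{splice_site_calls} data frame (scores on the 0-1 scale).
#' @export
read_calls <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first))
    return(calls_frame(character(0), integer(0), character(0), character(0),
                       numeric(0)))
  gr <- read_bed(path)
  calls_frame(as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr),
              as.character(GenomicRanges::strand(gr)),
              gr$name %||% NA_character_,
              (gr$score %||% NA_real_) / 1000)
}
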