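# FASTA/BED I/O and window construction.
#
# Splice-site windows are fixed-length sequences anchored on the 2-nt splice
# dinucleotide (intron-terminal AG for acceptors, intron-initial GT for
# donors). Coordinates are carried 1-based closed (the GRanges convention);
# BED files are converted at the boundary. A window of length L places the
# anchor on central positions floor(L/2)-1 and floor(L/2) (0-based within
# the window), so the default acceptor windows span 90 nt and donor windows
# 15 nt around their dinucleotide.

default_window_len <- function(site_type) {
  switch(site_type, acceptor = 90L, donor = 15L,
         stop("unknown site_type: ", site_type))
}

anchor_consensus <- function(site_type) {
  switch(site_type, acceptor = "AG", donor = "GT",
         stop("unknown site_type: ", site_type))
}

#' Read / write multi-FASTA
#'
#' Thin wrappers over Biostrings with id preservation; line wrapping is
#' normalized on write, so read-write-read round-trips are stable.
#'
#' @param path FASTA file path.
#' @param records A named character vector or \code{DNAStringSet}.
#' @return \code{read_fasta}: a \code{Biostrings::DNAStringSet}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- Biostrings::readDNAStringSet(path)
  if (!length(recs)) stop("empty FASTA file: ", path)
  # keep the id token only, as scanners report "chrom" ids
  names(recs) <- sub("\\s.*$", "", names(recs))
  recs
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  if (!methods::is(records, "XStringSet"))
    records <- Biostrings::DNAStringSet(records)
  Biostrings::writeXStringSet(records, path, width = 70L)
  invisible(path)
}

#' Read site annotations from BED
#'
#' Accepts BED3+ with optional name/score/strand columns; BED coordinates
#' (0-based half-open) are converted to 1-based closed \code{GRanges}.
#'
#' @param path BED file path.
#' @return A \code{GenomicRanges::GRanges} of validated annotations.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("malformed BED file '", path,
                                          "': ", conditionMessage(e)))
  if (any(GenomicRanges::width(gr) < 1L))
    stop("BED intervals require start < end")
  if (any(GenomicRanges::start(gr) < 1L))
    stop("negative BED coordinates")
  gr
}

# Assemble the window_set data frame used throughout the package.
window_set <- function(chrom, start, end, strand, site_type, sequence, label) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   site_type = as.character(site_type),
                   sequence = as.character(sequence),
                   label = as.integer(label), stringsAsFactors = FALSE)
  class(df) <- c("window_set", "data.frame")
  df
}

#' Extract anchored positive windows around annotated splice sites
#'
#' Each annotation marks the 2-nt splice dinucleotide on the plus strand of
#' its source sequence. The extracted window places the anchor on the two
#' central window positions; minus-strand sites are reverse-complemented so
#' the returned sequence reads the site in its transcriptional orientation.
#' Sites whose window would run off the sequence are skipped; the skip count
#' is attached as attribute \code{"skipped"} and reported via a message.
#'
#' @param genome A \code{DNAStringSet} (e.g. from \code{\link{read_fasta}}).
#' @param sites A \code{GRanges} of width-2 anchors (e.g. from
#'   \code{\link{read_bed}}); unstranded entries are treated as plus.
#' @param site_type \code{"acceptor"} or \code{"donor"}.
#' @param window_len Window length in nt (default 90 acceptor / 15 donor).
#' @return A \code{window_set} data frame with \code{label = 1}; coordinates
#'   are 1-based closed window extents on the source sequence.
#' @export
extract_windows <- function(genome, sites, site_type,
                            window_len = default_window_len(site_type)) {
  if (window_len < 2L) stop("window_len must be >= 2")
  anchor_consensus(site_type)  # validates site_type
  if (!all(GenomicRanges::width(sites) == 2L))
    stop("site anchors must have width 2 (the splice dinucleotide)")
  chrom <- as.character(GenomicRanges::seqnames(sites))
  if (!all(chrom %in% names(genome)))
    stop("annotation sequence ids missing from genome: ",
         paste(setdiff(chrom, names(genome)), collapse = ", "))
  strand <- as.character(GenomicRanges::strand(sites))
  strand[strand == "*"] <- "+"
  left <- floor(window_len / 2) - 1L   # nt before the anchor's first base
  a_start <- GenomicRanges::start(sites)
  win_start <- ifelse(strand == "+", a_start - left,
                      a_start + 1L + left - (window_len - 1L))
  win_end <- win_start + window_len - 1L
  seq_len_of <- Biostrings::width(genome)[match(chrom, names(genome))]
  keep <- win_start >= 1L & win_end <= seq_len_of
  n_skipped <- sum(!keep)
  if (n_skipped) message(n_skipped, " site(s) skipped: window out of range")
  chrom <- chrom[keep]; strand <- strand[keep]
  win_start <- win_start[keep]; win_end <- win_end[keep]
  seqs <- character(length(chrom))
  if (length(chrom)) {
    views <- Biostrings::DNAStringSet(
      mapply(function(ch, s, e) Biostrings::subseq(genome[[ch]], s, e),
             chrom, win_start, win_end, SIMPLIFY = FALSE))
    minus <- strand == "-"
    if (any(minus))
      views[minus] <- Biostrings::reverseComplement(views[minus])
    seqs <- as.character(views)
  }
  out <- window_set(chrom, win_start, win_end, strand, site_type, seqs, 1L)
  attr(out, "skipped") <- n_skipped
  out
}

#' Construct negative (non-site) windows
#'
#' Two policies: \code{"decoy"} centers windows on occurrences of the
#' anchor dinucleotide (AG/GT) that are not annotated sites — the hard
#' negatives a scanner must reject; \code{"random"} samples uniform
#' positions whose anchor does not overlap any annotated site. Seeded and
#' deterministic.
#'
#' @inheritParams extract_windows
#' @param policy \code{"decoy"} or \code{"random"}.
#' @param ratio Negatives per positive (of \code{length(sites)}).
#' @param seed Integer seed.
#' @return A \code{window_set} with \code{label = 0}.
#' @export
make_negatives <- function(genome, sites, site_type,
                           window_len = default_window_len(site_type),
                           policy = c("decoy", "random"), ratio = 1,
                           seed = 1L) {
  policy <- match.arg(policy)
  if (ratio <= 0) stop("ratio must be positive")
  n_needed <- ceiling(ratio * length(sites))
  left <- floor(window_len / 2) - 1L
  cand <- list()
  for (ch in names(genome)) {
    L <- Biostrings::width(genome)[match(ch, names(genome))]
    if (policy == "decoy") {
      hits <- Biostrings::matchPattern(anchor_consensus(site_type),
                                       genome[[ch]])
      pos <- Biostrings::start(hits)
    } else {
      pos <- seq_len(max(L - 1L, 0L))
    }
    pos <- pos[pos - left >= 1L & pos - left + window_len - 1L <= L]
    if (length(pos))
      cand[[ch]] <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos, pos + 1L))
  }
  if (!length(cand)) stop("no candidate negative positions available")
  cand <- suppressWarnings(do.call(c, unname(cand)))
  if (length(sites)) {
    ov <- GenomicRanges::findOverlaps(cand, sites, ignore.strand = TRUE)
    if (length(ov)) cand <- cand[-unique(S4Vectors::queryHits(ov))]
  }
  if (length(cand) < n_needed)
    stop("insufficient candidate positions: need ", n_needed,
         ", have ", length(cand))
  picked <- with_seed(seed, sort(sample.int(length(cand), n_needed)))
  neg <- extract_windows(genome, cand[picked], site_type, window_len)
  neg$label <- 0L
  neg
}

#' Stratified train/validation split
#'
#' Draws the validation subset uniformly without replacement, stratified by
#' label so both parts preserve the class balance (within one sample).
#'
#' @param windows A \code{window_set}.
#' @param n_validation Validation size (default 5000).
#' @param seed Integer seed.
#' @return List of class \code{dataset_split} with \code{train},
#'   \code{validation} (disjoint, exhaustive) and \code{seed}.
#' @export
split_train_validation <- function(windows, n_validation = 5000L, seed = 1L) {
  n <- nrow(windows)
  if (n_validation >= n)
    stop("n_validation must be smaller than the number of windows")
  if (n_validation < 1L) stop("n_validation must be >= 1")
  with_seed(seed, {
    labs <- windows$label
    val_idx <- integer(0)
    remaining <- n_validation
    lab_levels <- sort(unique(labs))
    for (i in seq_along(lab_levels)) {
      idx <- which(labs == lab_levels[i])
      take <- if (i == length(lab_levels)) remaining
              else round(n_validation * length(idx) / n)
      take <- min(take, length(idx), remaining)
      val_idx <- c(val_idx, sample(idx, take))
      remaining <- remaining - take
    }
    val_idx <- sort(val_idx)
    structure(list(train = windows[-val_idx, , drop = FALSE],
                   validation = windows[val_idx, , drop = FALSE],
                   seed = as.integer(seed)),
              class = "dataset_split")
  })
}

#' Write a window set as TSV (id, coordinates, strand, label, sequence)
#'
#' @param windows A \code{window_set}.
#' @param path Output path.
#' @export
write_windows_tsv <- function(windows, path) {
  utils::write.table(as.data.frame(windows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows_tsv
#' @export
read_windows_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(sequence = "character"))
  window_set(df$chrom, df$start, df$end, df$strand, df$site_type,
             df$sequence, df$label)
}
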