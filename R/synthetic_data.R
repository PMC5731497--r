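# Synthetic splice-site window generator.
#
# Positives carry the splice dinucleotide (AG or GT) at the window's
# anchoring positions, flanked by a position-weight-matrix (PWM) motif
# context; everything else is drawn from a background base composition.
# Negatives are background throughout; "decoy" negatives additionally carry
# the anchor dinucleotide at the center, isolating the motif context as the
# only discriminating signal.

BASES <- c("A", "C", "G", "T")

#' Build a splice-site motif model
#'
#' The flank PWM spans \code{flank_width} positions on each side of the
#' 2-nt anchor; each flank column puts \code{flank_prob} mass on one
#' consensus base (chosen deterministically from \code{seed}) and the rest
#' evenly on the other three. With the default \code{flank_prob = 0.7} the
#' motif is strong but not deterministic; \code{flank_prob = 0.25} gives an
#' uninformative PWM under uniform background (positives and decoy
#' negatives become indistinguishable).
#'
#' @param site_type \code{"acceptor"} (AG anchor, 90-nt window) or
#'   \code{"donor"} (GT anchor, 15-nt window).
#' @param window_len Window length; defaults to the site type's standard.
#' @param flank_width PWM positions on each side of the anchor (clipped to
#'   the available window).
#' @param flank_prob Probability mass on the consensus base per flank
#'   column.
#' @param background Base probabilities (A, C, G, T); default uniform.
#' @param seed Seed fixing the flank consensus bases.
#' @return Object of class \code{motif_model} with the full per-position
#'   \code{pwm} (4 x window positions for mono positions; anchor columns are
#'   deterministic).
#' @export
motif_model <- function(site_type = c("acceptor", "donor"),
                        window_len = NULL, flank_width = 10L,
                        flank_prob = 0.7, background = rep(0.25, 4),
                        seed = 1L) {
  site_type <- match.arg(site_type)
  window_len <- as.integer(window_len %||% default_window_len(site_type))
  if (window_len < 4L) stop("window_len must be >= 4")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("background must be 4 probabilities summing to 1")
  if (flank_prob < 0 || flank_prob > 1) stop("flank_prob must be in [0, 1]")
  consensus <- anchor_consensus(site_type)
  anchor_at <- floor(window_len / 2)   # 1-based index of anchor's first base
  pwm <- matrix(rep(background, window_len), nrow = 4L,
                dimnames = list(BASES, NULL))
  # anchor columns are deterministic
  pwm[, anchor_at] <- as.numeric(BASES == substr(consensus, 1L, 1L))
  pwm[, anchor_at + 1L] <- as.numeric(BASES == substr(consensus, 2L, 2L))
  flank_cols <- c(seq(anchor_at - 1L, by = -1L, length.out = flank_width),
                  seq(anchor_at + 2L, by = 1L, length.out = flank_width))
  flank_cols <- flank_cols[flank_cols >= 1L & flank_cols <= window_len]
  flank_consensus <- with_seed(seed,
                               sample(BASES, length(flank_cols), replace = TRUE))
  for (j in seq_along(flank_cols)) {
    col <- rep((1 - flank_prob) / 3, 4L)
    col[match(flank_consensus[j], BASES)] <- flank_prob
    pwm[, flank_cols[j]] <- col
  }
  stopifnot(all(abs(colSums(pwm) - 1) < 1e-9))
  structure(list(site_type = site_type, consensus = consensus,
                 window_len = window_len, anchor_at = anchor_at,
                 pwm = pwm, background = background,
                 flank_cols = sort(flank_cols), seed = as.integer(seed)),
            class = "motif_model")
}

sample_bases <- function(n, prob) sample(BASES, n, replace = TRUE, prob = prob)

# One window drawn column-wise from a 4 x L probability matrix.
sample_from_pwm <- function(pwm) {
  paste(vapply(seq_len(ncol(pwm)), function(j)
    sample(BASES, 1L, prob = pwm[, j]), character(1L)), collapse = "")
}

#' Sample one positive / negative window
#'
#' \code{sample_positive} draws anchor-consensus plus PWM flanks plus
#' background remainder; \code{sample_negative} draws background throughout
#' (\code{decoy = TRUE} forces the anchor dinucleotide at the center).
#' Both draw from the current RNG stream; seed at the caller
#' (\code{\link{generate_dataset}} does this).
#'
#' @param model A \code{\link{motif_model}}.
#' @param decoy Force the anchor dinucleotide into a negative.
#' @return A one-row \code{window_set} data frame.
#' @export
sample_positive <- function(model) {
  seq <- sample_from_pwm(model$pwm)
  window_set("synthetic", 1L, model$window_len, "+", model$site_type, seq, 1L)
}

#' @rdname sample_positive
#' @export
sample_negative <- function(model, decoy = FALSE) {
  chars <- sample_bases(model$window_len, model$background)
  if (decoy) {
    chars[model$anchor_at] <- substr(model$consensus, 1L, 1L)
    chars[model$anchor_at + 1L] <- substr(model$consensus, 2L, 2L)
  }
  window_set("synthetic", 1L, model$window_len, "+", model$site_type,
             paste(chars, collapse = ""), 0L)
}

#' Generate a labelled synthetic window dataset
#'
#' @param n_pos,n_neg Window counts per class (>= 0).
#' @param model A \code{\link{motif_model}}.
#' @param decoy_fraction Fraction of negatives carrying the anchor
#'   dinucleotide at center.
#' @param seed Integer seed; the dataset is a deterministic function of
#'   (model, counts, seed), rows deterministically shuffled.
#' @return A \code{window_set} of \code{n_pos + n_neg} rows.
#' @export
generate_dataset <- function(n_pos, n_neg, model, decoy_fraction = 0,
                             seed = 1L) {
  if (n_pos < 0 || n_neg < 0) stop("window counts must be >= 0")
  with_seed(seed, {
    pos <- if (n_pos > 0)
      do.call(rbind, replicate(n_pos, sample_positive(model),
                               simplify = FALSE))
    n_decoy <- round(decoy_fraction * n_neg)
    neg <- if (n_neg > 0)
      do.call(rbind, lapply(seq_len(n_neg), function(i)
        sample_negative(model, decoy = i <= n_decoy)))
    out <- rbind(pos, neg)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("window_set", "data.frame")
    out
  })
}

#' Plant positive windows into a background genome
#'
#' Draws a background sequence of the requested length and overwrites a
#' sampled positive window at each given anchor position, so that
#' \code{\link{extract_windows}} on the returned annotations recovers the
#' planted windows exactly.
#'
#' @param length Genome length in nt.
#' @param site_positions 1-based positions of each anchor's first base.
#' @param model A \code{\link{motif_model}}.
#' @param seed Integer seed.
#' @param name Sequence id of the synthetic genome record.
#' @return List with \code{genome} (a one-record \code{DNAStringSet}) and
#'   \code{sites} (a width-2 \code{GRanges} of the planted anchors).
#' @export
plant_genome <- function(length, site_positions, model, seed = 1L,
                         name = "synth_chr") {
  length <- as.integer(length)
  site_positions <- sort(as.integer(site_positions))
  L <- model$window_len
  left <- floor(L / 2) - 1L
  win_start <- site_positions - left
  win_end <- win_start + L - 1L
  if (any(win_start < 1L) || any(win_end > length))
    stop("planted windows out of genome range")
  if (length(site_positions) > 1L &&
      any(win_start[-1L] <= win_end[-length(win_end)]))
    stop("planted windows overlap")
  with_seed(seed, {
    chars <- sample_bases(length, model$background)
    for (i in seq_along(site_positions)) {
      w <- strsplit(sample_positive(model)$sequence, "")[[1L]]
      chars[win_start[i]:win_end[i]] <- w
    }
    genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(genome) <- name
    sites <- GenomicRanges::GRanges(
      name, IRanges::IRanges(site_positions, site_positions + 1L),
      strand = "+")
    list(genome = genome, sites = sites)
  })
}
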