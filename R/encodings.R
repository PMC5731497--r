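# Numeric DNA encoding schemes.
#
# Five schemes are shipped: DAX and GF(4) integer codes, the EIIP
# electron-ion interaction potential, a complementary code in which
# Watson-Crick partners map to negations, and the unified nearest-neighbour
# dinucleotide enthalpy (delta-H, kcal/mol). Mono schemes map single bases,
# di schemes map adjacent base pairs, so a length-L sequence encodes to L or
# L-1 values respectively.

default_scheme_tables <- function() {
  list(
    DAX = list(unit = "mono",
               table = c(T = 0, C = 1, A = 2, G = 3)),
    EIIP = list(unit = "mono",
                table = c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)),
    COMPLEMENTARY = list(unit = "mono",
                         table = c(A = -2, T = 2, C = -1, G = 1)),
    GALOIS4 = list(unit = "mono",
                   table = c(A = 0, C = 1, G = 2, T = 3)),
    # Unified nearest-neighbour delta-H, kcal/mol, 5'->3' dinucleotides.
    ENTHALPY = list(unit = "di",
                    table = c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
                              CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
                              GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
                              TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9))
  )
}

scheme_keys <- function(unit) {
  bases <- c("A", "C", "G", "T")
  if (unit == "mono") bases
  else as.vector(outer(bases, bases, paste0))
}

#' Build a DNA encoding scheme
#'
#' Returns one of the five packaged schemes (\code{"DAX"}, \code{"EIIP"},
#' \code{"COMPLEMENTARY"}, \code{"ENTHALPY"}, \code{"GALOIS4"}), optionally
#' with entries overridden, or a fully user-specified \code{"CUSTOM"} scheme.
#'
#' @param name Scheme name (case-insensitive; \code{"comp"} and
#'   \code{"galois"} abbreviations accepted) or \code{"CUSTOM"}.
#' @param overrides Named numeric vector of table entries to merge over the
#'   packaged defaults. For \code{CUSTOM} this must be the complete table
#'   (4 mono or 16 di entries).
#' @param unit For \code{CUSTOM} only: \code{"mono"} or \code{"di"}.
#' @param scale \code{NULL} for raw table values, or a length-2 numeric
#'   \code{c(lo, hi)}; outputs are affinely rescaled so the table minimum and
#'   maximum map to \code{lo} and \code{hi}. Network input uses
#'   \code{c(0, 1)} to match the sigmoid reconstruction range.
#' @return An object of class \code{encoding_scheme} with fields
#'   \code{name}, \code{unit}, \code{table}, \code{scale}.
#' @examples
#' sch <- build_scheme("EIIP", scale = c(0, 1))
#' encode_sequence("ACGT", sch)
#' @export
build_scheme <- function(name, overrides = NULL, unit = NULL, scale = NULL) {
  nm <- toupper(as.character(name)[1L])
  nm <- switch(nm, COMP = "COMPLEMENTARY", GALOIS = "GALOIS4", "GF4" = "GALOIS4",
               DI_ENTHALPY = "ENTHALPY", nm)
  defaults <- default_scheme_tables()
  if (nm == "CUSTOM") {
    if (is.null(unit) || !unit %in% c("mono", "di"))
      stop("CUSTOM scheme requires unit = 'mono' or 'di'")
    tab <- overrides
  } else {
    if (!nm %in% names(defaults)) stop("unknown encoding scheme: ", name)
    unit <- defaults[[nm]]$unit
    tab <- defaults[[nm]]$table
    if (!is.null(overrides)) {
      if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
        stop("overrides must be a named numeric vector")
      tab[toupper(names(overrides))] <- overrides
    }
  }
  keys <- scheme_keys(unit)
  if (is.null(tab) || is.null(names(tab)))
    stop("scheme table must be a named numeric vector")
  names(tab) <- toupper(names(tab))
  missing <- setdiff(keys, names(tab))
  if (length(missing))
    stop("incomplete scheme table; missing: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(tab), keys)
  if (length(extra))
    stop("scheme table has entries outside the DNA alphabet: ",
         paste(extra, collapse = ", "))
  tab <- as.numeric(tab[keys])
  names(tab) <- keys
  if (any(!is.finite(tab))) stop("scheme table values must be finite")
  if (!is.null(scale)) {
    if (length(scale) != 2L || !all(is.finite(scale)) || scale[2] <= scale[1])
      stop("scale must be c(lo, hi) with lo < hi")
    scale <- as.numeric(scale)
  }
  structure(list(name = nm, unit = unit, table = tab, scale = scale),
            class = "encoding_scheme")
}

#' @export
print.encoding_scheme <- function(x, ...) {
  cat("<encoding_scheme>", x$name, paste0("(", x$unit, ")"),
      if (!is.null(x$scale)) sprintf("rescaled to [%g, %g]", x$scale[1], x$scale[2])
      else "raw values", "\n")
  print(x$table)
  invisible(x)
}

# Affine map sending the table's min/max onto scale[1]/scale[2].
rescale_values <- function(values, scheme) {
  if (is.null(scheme$scale)) return(values)
  lo <- min(scheme$table); hi <- max(scheme$table)
  if (hi == lo) stop("cannot rescale a constant table")
  scheme$scale[1] + (values - lo) * (scheme$scale[2] - scheme$scale[1]) / (hi - lo)
}

#' Encode a DNA sequence as a numeric vector
#'
#' Looks up each base (mono schemes) or each adjacent base pair (di schemes)
#' in the scheme table; a length-L sequence yields L values (mono) or L-1
#' (di). Lower-case input is accepted and U is read as T.
#'
#' @param seq DNA string over A/C/G/T.
#' @param scheme An \code{encoding_scheme} from \code{\link{build_scheme}}.
#' @param ambiguity Policy for characters outside A/C/G/T: \code{"reject"}
#'   (default, error) or \code{"mean"} (impute the table mean; for di schemes
#'   any pair touching the ambiguous base is imputed).
#' @return Numeric vector, rescaled if the scheme carries a scale.
#' @export
encode_sequence <- function(seq, scheme, ambiguity = c("reject", "mean")) {
  ambiguity <- match.arg(ambiguity)
  stopifnot(inherits(scheme, "encoding_scheme"))
  s <- normalize_dna(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- !chars %in% c("A", "C", "G", "T")
  if (any(bad) && ambiguity == "reject")
    stop("sequence contains non-ACGT character(s): ",
         paste(unique(chars[bad]), collapse = ", "))
  if (scheme$unit == "mono") {
    vals <- unname(scheme$table[chars])
    if (any(bad)) vals[bad] <- mean(scheme$table)
  } else {
    if (length(chars) < 2L) stop("di scheme requires sequence length >= 2")
    keys <- paste0(chars[-length(chars)], chars[-1L])
    vals <- unname(scheme$table[keys])
    if (any(bad)) {
      touched <- bad[-length(bad)] | bad[-1L]
      vals[touched] <- mean(scheme$table)
    }
  }
  rescale_values(vals, scheme)
}

#' Encode a set of equal-length windows into a matrix
#'
#' @param windows A \code{window_set} data frame (see
#'   \code{\link{generate_dataset}} / \code{\link{extract_windows}}), or a
#'   character vector of equal-length sequences.
#' @param scheme An \code{encoding_scheme}.
#' @param ambiguity Passed to \code{\link{encode_sequence}}.
#' @return List with \code{x}: numeric matrix, one encoded window per row;
#'   \code{y}: integer label vector aligned with rows (all \code{NA} when
#'   \code{windows} carries no labels).
#' @export
encode_batch <- function(windows, scheme, ambiguity = "reject") {
  if (is.data.frame(windows)) {
    seqs <- windows$sequence
    labels <- if ("label" %in% names(windows)) as.integer(windows$label)
              else rep(NA_integer_, nrow(windows))
  } else {
    seqs <- as.character(windows)
    labels <- rep(NA_integer_, length(seqs))
  }
  lens <- nchar(seqs)
  if (length(seqs) && length(unique(lens)) > 1L)
    stop("all windows must have identical length")
  L <- if (length(seqs)) lens[1L] else 0L
  width <- if (scheme$unit == "mono") L else max(L - 1L, 0L)
  if (!length(seqs))
    return(list(x = matrix(numeric(0), nrow = 0L, ncol = width), y = integer(0)))
  x <- t(vapply(seqs, encode_sequence, numeric(width),
                scheme = scheme, ambiguity = ambiguity, USE.NAMES = FALSE))
  list(x = x, y = labels)
}

#' Read or write an encoding table as a flat key-value file
#'
#' The file holds one \code{KEY: value} pair per line (YAML-compatible), with
#' mono- or dinucleotide keys.
#'
#' @param path File path.
#' @param scheme For writing, an \code{encoding_scheme}.
#' @return \code{read_scheme_table}: a named numeric vector usable as
#'   \code{overrides}/\code{CUSTOM} table in \code{\link{build_scheme}}.
#' @export
read_scheme_table <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("empty scheme table file: ", path)
  vapply(raw, as.numeric, numeric(1L))
}

#' @rdname read_scheme_table
#' @export
write_scheme_table <- function(scheme, path) {
  stopifnot(inherits(scheme, "encoding_scheme"))
  yaml::write_yaml(as.list(scheme$table), path)
  invisible(path)
}
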