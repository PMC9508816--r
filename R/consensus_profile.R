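# Target windows and per-position consensus profiles with decile-weighted
# matching scores.
#
# A window is a stretch of transcript sequence centred on an edited (or
# candidate) cytidine: offset 0 is the C, negative offsets run upstream.
# The standard extraction is -30..+5; the delivered construct targets use
# -40..+5. Windows are plain data frames (one row per window) so sets of
# windows compose by rbind().

#' Construct a target window
#'
#' @param sequence nucleotide string covering offsets `lo` .. `lo +
#'   nchar(sequence) - 1`; '-' pads transcript ends, U is normalised to T.
#' @param gene,transcript_id identifiers (may be empty).
#' @param position transcript coordinate (0-based) of the edited C, or `NA`.
#' @param lo offset of the first character; the default `-30` together with a
#'   36-nt sequence gives the standard -30..+5 window.
#' @param rate observed editing rate in `[0,1]`, or `NA`.
#' @param check_c require the reference base at offset 0 to be C (default).
#' @return one-row data frame with columns `gene`, `transcript_id`,
#'   `position`, `lo`, `hi`, `sequence`, `rate`.
#' @examples
#' w <- target_window(paste(c(rep("A", 30), "C", rep("G", 5)), collapse = ""))
#' window_base(w, 0)   # "C"
#' window_base(w, -14) # "A"
#' @export
target_window <- function(sequence, gene = "", transcript_id = "",
                          position = NA_integer_, lo = -30L,
                          rate = NA_real_, check_c = TRUE) {
  sequence <- normalize_nt(sequence)
  lo <- as.integer(lo)
  hi <- lo + nchar(sequence) - 1L
  if (check_c) {
    if (lo > 0L || hi < 0L) {
      stop("window [", lo, "..", hi, "] does not contain offset 0")
    }
    at0 <- substr(sequence, 1L - lo, 1L - lo)
    if (at0 != "C") {
      stop("reference base at offset 0 must be C, got ", at0)
    }
  }
  data.frame(gene = gene, transcript_id = transcript_id,
             position = as.integer(position), lo = lo, hi = hi,
             sequence = sequence, rate = as.numeric(rate),
             stringsAsFactors = FALSE)
}

#' Extract bases at given offsets from a window
#'
#' @param window one-row window data frame.
#' @param offsets integer vector of offsets; offsets outside the window
#'   return `"-"`.
#' @return character vector of single bases.
#' @export
window_base <- function(window, offsets) {
  lo <- window$lo[1L]
  hi <- window$hi[1L]
  idx <- offsets - lo + 1L
  out <- rep("-", length(offsets))
  inside <- offsets >= lo & offsets <= hi
  if (any(inside)) {
    out[inside] <- substring(window$sequence[1L], idx[inside], idx[inside])
  }
  out
}

decile_of <- function(f) {
  # frequency -> decile weight: floored to the nearest lower 10% step,
  # counted from 40%, capped at 90 (the step ladder has no 100 step)
  d <- 10L * as.integer(floor(10 * f + 1e-9))
  d[d > 90L] <- 90L
  d[d < 40L] <- NA_integer_
  d
}

#' Construct a consensus profile from per-offset nucleotide frequencies
#'
#' A profile stores, for each offset in `bounds`, the relative frequencies of
#' A/C/G/T and, where a unique nucleotide dominates with frequency >= 40%,
#' that nucleotide with its decile weight (frequency floored to the nearest
#' 10% step, 40..90). Matching scores sum decile weights over these
#' thresholded offsets.
#'
#' @param freq numeric matrix with rownames A,C,G,T and one column per
#'   offset; columns must sum to 1 (or be all-`NA` for offsets with no data).
#' @param bounds integer pair `(lo, hi)` of offsets covered by the columns.
#' @return object of class `consensus_profile` with elements `bounds`,
#'   `offsets`, `freq`, `decile` (data frame `offset`, `nt`, `decile`) and
#'   `n_windows`.
#' @export
consensus_profile <- function(freq, bounds) {
  bounds <- as.integer(bounds)
  offsets <- seq.int(bounds[1L], bounds[2L])
  if (!is.matrix(freq) || nrow(freq) != 4L ||
      !identical(rownames(freq), c("A", "C", "G", "T"))) {
    stop("freq must be a 4-row matrix with rownames A,C,G,T")
  }
  if (ncol(freq) != length(offsets)) {
    stop("freq has ", ncol(freq), " columns but bounds span ",
         length(offsets), " offsets")
  }
  colnames(freq) <- offsets
  sums <- colSums(freq)
  bad <- which(!is.na(sums) & abs(sums - 1) > 1e-9)
  if (length(bad)) {
    stop("frequencies at offset ", offsets[bad[1L]], " sum to ",
         sums[bad[1L]], ", not 1")
  }
  dec <- lapply(seq_along(offsets), function(j) {
    f <- freq[, j]
    if (anyNA(f)) return(NULL)
    top <- max(f)
    # unique dominant required: a tie at the top is not thresholded
    if (sum(f >= top - 1e-9) != 1L) return(NULL)
    d <- decile_of(top)
    if (is.na(d)) return(NULL)
    data.frame(offset = offsets[j], nt = names(f)[which.max(f)], decile = d,
               stringsAsFactors = FALSE)
  })
  dec <- do.call(rbind, dec)
  if (is.null(dec)) {
    dec <- data.frame(offset = integer(0), nt = character(0),
                      decile = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(bounds = bounds, offsets = offsets, freq = freq,
                 decile = dec, n_windows = NA_integer_),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("<consensus profile %d..%+d, %d thresholded offsets, max score %d%s>\n",
              x$bounds[1L], x$bounds[2L], nrow(x$decile), max_score(x),
              if (is.na(x$n_windows)) "" else
                sprintf(", built from %d windows", x$n_windows)))
  cat(" consensus:", consensus_string(x), "\n")
  invisible(x)
}

#' Build a consensus profile from observed target windows
#'
#' Per offset, counts A/C/G/T over all windows (pads '-' and N are excluded
#' from numerator and denominator) and normalises to frequencies. With
#' `dedupe = TRUE`, windows with identical sequence in transcript variants of
#' the same gene are counted once.
#'
#' @param windows window set (data frame, one row per window).
#' @param bounds integer pair of offsets; the default `-17..+5` covers the
#'   repeat array of a 13-repeat PLS factor plus the downstream context.
#' @param dedupe collapse identical (gene, sequence) windows first.
#' @return a [consensus_profile()].
#' @export
build_profile <- function(windows, bounds = c(-17L, 5L), dedupe = TRUE) {
  if (is.null(windows) || nrow(windows) == 0L) {
    stop("build_profile needs at least one window")
  }
  bounds <- as.integer(bounds)
  if (bounds[1L] > bounds[2L] || bounds[1L] < -40L || bounds[2L] > 5L) {
    stop("bounds must be an increasing pair within -40..+5")
  }
  if (dedupe) {
    windows <- windows[!duplicated(paste(windows$gene, windows$sequence,
                                         sep = "\r")), , drop = FALSE]
  }
  offsets <- seq.int(bounds[1L], bounds[2L])
  counts <- matrix(0L, 4L, length(offsets),
                   dimnames = list(c("A", "C", "G", "T"), offsets))
  for (i in seq_len(nrow(windows))) {
    obs <- window_base(windows[i, , drop = FALSE], offsets)
    keep <- obs %in% rownames(counts)
    idx <- cbind(match(obs[keep], rownames(counts)), which(keep))
    counts[idx] <- counts[idx] + 1L
  }
  tot <- colSums(counts)
  freq <- sweep(counts, 2L, tot, "/")
  freq[, tot == 0L] <- NA_real_
  prof <- consensus_profile(freq, bounds)
  prof$n_windows <- nrow(windows)
  prof
}

#' Matching score of a window against a consensus profile
#'
#' The score sums, over the profile's thresholded offsets, the decile weight
#' (40..90) wherever the window carries the consensus nucleotide; other
#' offsets (including pads) contribute 0. It is an integer between 0 and
#' [max_score()].
#'
#' @param window one-row window data frame covering the profile bounds.
#' @param profile a [consensus_profile()].
#' @return non-negative integer score.
#' @export
matching_score <- function(window, profile) {
  stopifnot(inherits(profile, "consensus_profile"))
  if (window$lo[1L] > profile$bounds[1L] || window$hi[1L] < profile$bounds[2L]) {
    stop("window [", window$lo[1L], "..", window$hi[1L],
         "] does not cover profile bounds [", profile$bounds[1L], "..",
         profile$bounds[2L], "]")
  }
  if (!nrow(profile$decile)) return(0L)
  obs <- window_base(window, profile$decile$offset)
  sum(profile$decile$decile[obs == profile$decile$nt])
}

#' Maximum possible matching score of a profile
#'
#' Sum of the decile weights over all thresholded offsets; the window that
#' carries the consensus nucleotide at every thresholded offset scores
#' exactly this value.
#'
#' @param profile a [consensus_profile()].
#' @return non-negative integer.
#' @export
max_score <- function(profile) {
  stopifnot(inherits(profile, "consensus_profile"))
  sum(profile$decile$decile)
}

#' One-character-per-offset consensus rendering
#'
#' Thresholded offsets are shown as the uppercase consensus nucleotide;
#' offsets with a unique most-frequent nucleotide below threshold (or a tie
#' at threshold) as that nucleotide in lower case (ties broken
#' alphabetically); offsets whose four frequencies are uniform within 1e-9,
#' or without data, as '.'.
#'
#' @param profile a [consensus_profile()].
#' @return a character string, one character per offset.
#' @export
consensus_string <- function(profile) {
  stopifnot(inherits(profile, "consensus_profile"))
  chars <- vapply(seq_along(profile$offsets), function(j) {
    off <- profile$offsets[j]
    hit <- profile$decile$nt[profile$decile$offset == off]
    if (length(hit)) return(hit)
    f <- profile$freq[, j]
    if (anyNA(f)) return(".")
    if (max(f) - min(f) < 1e-9) return(".")
    tolower(names(f)[which.max(f)])
  }, character(1))
  paste(chars, collapse = "")
}

#' Report consensus shifts between two profiles
#'
#' Lists every offset at which the thresholded (nucleotide, decile) pair
#' differs between the two profiles — the readout used to demonstrate that
#' mutating a single repeat redirects the dominant nucleotide at its
#' juxtaposed position. Symmetric: offsets thresholded in either profile
#' only are reported too.
#'
#' @param profile_a,profile_b profiles with identical bounds.
#' @return data frame with columns `offset`, `nt_a`, `decile_a`, `nt_b`,
#'   `decile_b` (NA where an offset is not thresholded in one profile);
#'   zero rows when the thresholded consensus is identical.
#' @export
profile_shift_report <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "consensus_profile"),
            inherits(profile_b, "consensus_profile"))
  if (!identical(profile_a$bounds, profile_b$bounds)) {
    stop("profiles have different bounds")
  }
  a <- profile_a$decile
  b <- profile_b$decile
  m <- merge(a, b, by = "offset", all = TRUE, suffixes = c("_a", "_b"))
  differs <- is.na(m$nt_a) | is.na(m$nt_b) |
    m$nt_a != m$nt_b | m$decile_a != m$decile_b
  out <- m[differs, c("offset", "nt_a", "decile_a", "nt_b", "decile_b")]
  rownames(out) <- NULL
  out[order(out$offset), , drop = FALSE]
}

#' Read / write consensus profiles and window sets as TSV
#'
#' Profiles serialise with columns offset, fA, fC, fG, fT, consensus_char,
#' decile; windows with columns gene, transcript, position, sequence, rate
#' (the window span is recovered from the sequence length, with the last
#' five characters downstream of the edited C).
#'
#' @param profile a [consensus_profile()].
#' @param path file path.
#' @return readers return the reconstructed object; writers the path,
#'   invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "consensus_profile"))
  cons <- strsplit(consensus_string(profile), "")[[1]]
  dec <- rep(NA_integer_, length(profile$offsets))
  dec[match(profile$decile$offset, profile$offsets)] <- profile$decile$decile
  df <- data.frame(offset = profile$offsets,
                   fA = profile$freq["A", ], fC = profile$freq["C", ],
                   fG = profile$freq["G", ], fT = profile$freq["T", ],
                   consensus_char = cons, decile = dec)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- read_tsv_checked(path, c("offset", "fA", "fC", "fG", "fT",
                                 "consensus_char", "decile"))
  freq <- t(as.matrix(df[, c("fA", "fC", "fG", "fT")]))
  rownames(freq) <- c("A", "C", "G", "T")
  consensus_profile(freq, c(min(df$offset), max(df$offset)))
}

#' @rdname write_profile
#' @param windows window set to serialise.
#' @export
write_windows <- function(windows, path) {
  df <- data.frame(gene = windows$gene, transcript = windows$transcript_id,
                   position = windows$position, sequence = windows$sequence,
                   rate = windows$rate)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param check_c passed to [target_window()].
#' @export
read_windows <- function(path, check_c = TRUE) {
  df <- read_tsv_checked(path, c("gene", "transcript", "position",
                                 "sequence", "rate"))
  rows <- lapply(seq_len(nrow(df)), function(i) {
    target_window(df$sequence[i], gene = df$gene[i],
                  transcript_id = df$transcript[i],
                  position = df$position[i],
                  lo = -(nchar(df$sequence[i]) - 6L),
                  rate = df$rate[i], check_c = check_c)
  })
  do.call(rbind, rows)
}

#' Export a profile as a minimal MEME-style frequency matrix block
#'
#' Writes a letter-probability matrix (alphabet ACGT, one row per offset)
#' in a minimal MEME-like text block, for use with external motif tools.
#'
#' @param profile a [consensus_profile()].
#' @param path file path.
#' @param name motif name recorded in the block.
#' @export
write_pfm_meme <- function(profile, path, name = "consensus") {
  stopifnot(inherits(profile, "consensus_profile"))
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             paste("MOTIF", name),
             sprintf("letter-probability matrix: alength= 4 w= %d",
                     length(profile$offsets)))
  rows <- apply(profile$freq, 2L, function(f) {
    paste(sprintf("%.6f", ifelse(is.na(f), 0.25, f)), collapse = " ")
  })
  writeLines(c(lines, rows), path)
  invisible(path)
}
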