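# Transcriptome-wide candidate-target scanning with the consensus matching
# score.

#' Scan a transcriptome for candidate editing sites
#'
#' Slides the consensus profile over every transcript position whose
#' reference base is C and computes the matching score of the surrounding
#' window. Windows overhanging transcript ends are scored with '-' pads
#' contributing 0 and flagged `truncated`. Candidates scoring at least
#' `min_score` are returned sorted by score (descending), then transcript id
#' and position (ascending) for deterministic ranking.
#'
#' @param annotations annotation data frame with reference `sequence`.
#' @param profile a [consensus_profile()] (the weight matrix).
#' @param min_score minimum matching score to report.
#' @param top_n optional; truncate the ranked table to the first `top_n`
#'   rows.
#' @return data frame with columns `transcript_id`, `position`, `score`,
#'   `max_score`, `truncated`, `window`. When `min_score` exceeds the
#'   profile's maximum the result is empty and carries attribute
#'   `"warning"`.
#' @export
scan_transcriptome <- function(annotations, profile, min_score,
                               top_n = NULL) {
  stopifnot(inherits(profile, "consensus_profile"))
  if (is.null(annotations) || nrow(annotations) == 0L ||
      any(!nzchar(annotations$sequence))) {
    stop("annotations must supply non-empty transcript sequences")
  }
  empty <- data.frame(transcript_id = character(0), position = integer(0),
                      score = integer(0), max_score = integer(0),
                      truncated = logical(0), window = character(0),
                      stringsAsFactors = FALSE)
  ms <- max_score(profile)
  if (min_score > ms) {
    warning("min_score (", min_score, ") exceeds the profile maximum (", ms,
            "); no candidate can qualify")
    attr(empty, "warning") <- "min_score exceeds max_score"
    return(empty)
  }
  lo <- profile$bounds[1L]
  hi <- profile$bounds[2L]
  width <- hi - lo + 1L
  pieces <- lapply(seq_len(nrow(annotations)), function(i) {
    seq <- annotations$sequence[i]
    pos <- as.integer(gregexpr("C", seq, fixed = TRUE)[[1L]])
    if (length(pos) == 1L && pos == -1L) return(NULL)
    pos <- pos - 1L  # 0-based site coordinates
    pad <- strrep("-", width)
    padded <- paste0(pad, seq, pad)
    starts <- pos + lo + width + 1L  # 1-based into padded string
    windows <- substring(padded, starts, starts + width - 1L)
    # score = sum of decile weights where the window carries the consensus
    # nucleotide, evaluated only at the thresholded offsets
    score <- integer(length(windows))
    for (k in seq_len(nrow(profile$decile))) {
      at <- profile$decile$offset[k] - lo + 1L
      hitnt <- substring(windows, at, at) == profile$decile$nt[k]
      score <- score + ifelse(hitnt, profile$decile$decile[k], 0L)
    }
    data.frame(transcript_id = annotations$transcript_id[i], position = pos,
               score = score, max_score = ms,
               truncated = grepl("-", windows, fixed = TRUE),
               window = windows, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(empty)
  out <- out[out$score >= min_score, , drop = FALSE]
  out <- out[order(-out$score, out$transcript_id, out$position), ,
             drop = FALSE]
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}

#' Compare predicted candidate sites with observed editing calls
#'
#' Joins scanner candidates and caller output on (transcript_id, position)
#' and reports the confusion counts, in particular the high-scoring
#' candidates at which no editing was observed — the cases that reveal
#' determinants beyond the primary sequence preference (structure,
#' competing RNA-binding proteins).
#'
#' @param candidates data frame from [scan_transcriptome()].
#' @param calls data frame of observed calls with `transcript_id` and
#'   `position` (e.g. from [call_offtargets()]).
#' @return list with `counts` (n_candidates, n_calls, n_edited_candidates,
#'   n_unedited_candidates, n_calls_missed) and `unedited_candidates` (the
#'   candidate rows without an observed call, ranked by score).
#' @export
predicted_vs_observed <- function(candidates, calls) {
  ckey <- paste(candidates$transcript_id, candidates$position, sep = "\r")
  okey <- paste(calls$transcript_id, calls$position, sep = "\r")
  edited <- ckey %in% okey
  list(
    counts = c(n_candidates = nrow(candidates),
               n_calls = nrow(calls),
               n_edited_candidates = sum(edited),
               n_unedited_candidates = sum(!edited),
               n_calls_missed = sum(!okey %in% ckey)),
    unedited_candidates = candidates[!edited, , drop = FALSE]
  )
}
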