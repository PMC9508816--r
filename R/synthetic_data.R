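# Synthetic fixtures with the statistical structure the caller assumes:
# transcriptomes with planted C-to-U targets, replicate pileups with binomial
# editing over Poisson coverage and a low sequencing-error background, and
# Sanger-like peak pairs.
#
# All generators are pure functions of (arguments, seed): the same call
# yields byte-identical output. simulate_pileups() fans the global seed out
# into per-replicate substreams (seed + 7919 * k mod 2^31 - 1, with k the
# replicate counter: factor replicates count 1, 2, ...; control replicates
# 101, 102, ...), so adding a replicate never perturbs the ones already
# drawn.

PPR56_LIKE_LAYOUT <- paste(
  # N- to C-terminal; P/S-type 5/L pairs and L-11/L-5/L2-2 follow the
  # published PPR56 annotations; S-13, P-12 and L-8 residues are synthetic
  # placeholders (chosen to mirror the weak A/U context preferences) since
  # their key residues are not printed - hence "PPR56-like", not PPR56.
  "S-13\tS\tT\tN",
  "P-12\tP\tN\tD",
  "L-11\tL\tM\tD",
  "S-10\tS\tT\tD",
  "P-9\tP\tT\tN",
  "L-8\tL\tV\tT",
  "S-7\tS\tT\tD",
  "P-6\tP\tN\tD",
  "L-5\tL\tL\tD",
  "S-4\tS\tT\tN",
  "P2-3\tP2\tN\tD",
  "L2-2\tL2\tV\tD",
  "S2-1\tS2\tN\tD",
  sep = "\n")

#' Build an editing factor from a layout or preset
#'
#' Either parses a factor-definition layout (see [read_factor()]) or returns
#' the built-in `"PPR56-like"` preset: a 13-repeat PLS array ending in
#' P2-L2-S2 whose terminal repeat S2-1 carries N/D (predicting U at offset
#' -4). The layout must use only P/L/S classes before a terminal P2-L2-S2
#' triplet.
#'
#' @param spec `"PPR56-like"` or layout text / path accepted by
#'   [read_factor()].
#' @param name factor name.
#' @param has_dyw stored on the factor (editing-dead controls use `FALSE`).
#' @return an [editing_factor()].
#' @export
make_factor <- function(spec = "PPR56-like", name = NULL, has_dyw = TRUE) {
  if (!length(spec) || !nzchar(spec[1L])) stop("empty factor layout")
  if (identical(spec, "PPR56-like")) {
    fac <- read_factor(PPR56_LIKE_LAYOUT,
                       name = if (is.null(name)) "PPR56-like" else name,
                       has_dyw = has_dyw)
  } else {
    fac <- read_factor(spec, name = name, has_dyw = has_dyw)
  }
  classes <- unname(vapply(fac$motifs, `[[`, character(1), "motif_class"))
  n <- length(classes)
  if (n < 3L || !identical(classes[(n - 2L):n], c("P2", "L2", "S2"))) {
    stop("layout must end in a P2-L2-S2 triplet")
  }
  if (!all(classes[seq_len(n - 3L)] %in% c("P", "L", "S"))) {
    stop("layout must alternate P/L/S classes before the terminal triplet")
  }
  fac
}

#' The consensus-matching window of a profile
#'
#' Returns the window that carries the thresholded consensus nucleotide at
#' every thresholded offset (and therefore scores exactly
#' [max_score()]); non-thresholded offsets carry the most frequent
#' nucleotide, offset 0 the reference C.
#'
#' @param profile a [consensus_profile()].
#' @param lo,hi window span; defaults to the profile bounds extended to
#'   cover offset 0.
#' @return one-row window data frame.
#' @export
consensus_window <- function(profile, lo = min(profile$bounds[1L], -30L),
                             hi = max(profile$bounds[2L], 5L)) {
  offsets <- seq.int(lo, hi)
  chars <- vapply(offsets, function(off) {
    hit <- profile$decile$nt[profile$decile$offset == off]
    if (length(hit)) return(hit)
    if (off == 0L) return("C")
    j <- match(off, profile$offsets)
    if (is.na(j) || anyNA(profile$freq[, j])) return("A")
    names(which.max(profile$freq[, j]))
  }, character(1))
  target_window(paste(chars, collapse = ""), lo = lo,
                check_c = chars[match(0L, offsets)] == "C")
}

#' Generate a synthetic transcriptome with planted editing targets
#'
#' Draws `n_transcripts` random transcripts (uniform A/C/G/T background by
#' default), assigns each a CDS occupying the central 60% of its length, and
#' plants target windows at controlled positions. Each planted entry is a
#' list with `efficiency` (true editing fraction) and optionally `window`
#' (an explicit window sequence; default: the consensus-matching window of
#' `profile`), `transcript` (index; default round-robin) and `position`
#' (0-based site coordinate; default drawn so the window fits without
#' padding and plantings do not overlap).
#'
#' @param n_transcripts,length transcriptome dimensions.
#' @param planted list of planted-site specifications (possibly empty).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param profile optional [consensus_profile()]; required when a planted
#'   entry has no explicit `window`, and used to record construction-time
#'   matching scores in the truth table.
#' @param composition named numeric background composition over A/C/G/T.
#' @param num_reads abundance estimate recorded per transcript (default 100,
#'   comfortably above the expressed-transcript cut of 10).
#' @return list with `annotations` (data frame incl. `sequence`) and `truth`
#'   (one row per planted site: transcript, position, region, efficiency,
#'   score).
#' @export
make_transcriptome <- function(n_transcripts = 10, length = 1000,
                               planted = list(), seed = 1, profile = NULL,
                               composition = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25),
                               num_reads = 100) {
  stopifnot(n_transcripts >= 1, length >= 50)
  set.seed(seed)
  composition <- composition / sum(composition)
  seqs <- vapply(seq_len(n_transcripts), function(i) {
    paste(sample(names(composition), length, replace = TRUE,
                 prob = composition), collapse = "")
  }, character(1))
  cds_start <- as.integer(floor(length * 0.2))
  cds_len <- as.integer(floor(length * 0.6 / 3) * 3)
  ann <- data.frame(
    transcript_id = sprintf("TX%02d", seq_len(n_transcripts)),
    gene = sprintf("GENE%02d", seq_len(n_transcripts)),
    protein_name = sprintf("synthetic protein %d", seq_len(n_transcripts)),
    cds_start = cds_start, cds_end = cds_start + cds_len,
    num_reads = num_reads, sequence = seqs, stringsAsFactors = FALSE
  )

  truth <- data.frame(transcript_id = character(0), gene = character(0),
                      position = integer(0), region = character(0),
                      efficiency = numeric(0), score = integer(0),
                      stringsAsFactors = FALSE)
  occupied <- vector("list", n_transcripts)
  for (k in seq_along(planted)) {
    p <- planted[[k]]
    win_seq <- p$window
    if (is.null(win_seq)) {
      if (is.null(profile)) {
        stop("planted entry ", k, " has no window and no profile was given")
      }
      win_seq <- consensus_window(profile)$sequence
    }
    win_seq <- normalize_nt(win_seq)
    w <- nchar(win_seq)
    lo <- -(w - 6L)  # window convention: 5 nt downstream of the site
    ti <- if (is.null(p$transcript)) ((k - 1L) %% n_transcripts) + 1L else
      p$transcript
    pos <- p$position
    if (is.null(pos)) {
      for (try in 1:200) {
        cand <- sample(seq.int(-lo, length - 6L), 1L)
        span <- seq.int(cand + lo, cand + 5L)
        if (!any(span %in% occupied[[ti]])) { pos <- cand; break }
      }
      if (is.null(pos)) stop("could not place planted window ", k)
    }
    span <- seq.int(pos + lo, pos + 5L)
    if (span[1L] < 0L || span[length(span)] >= length) {
      stop("planted window ", k, " does not fit transcript ", ti)
    }
    occupied[[ti]] <- c(occupied[[ti]], span)
    s <- ann$sequence[ti]
    substr(s, pos + lo + 1L, pos + 6L) <- win_seq
    ann$sequence[ti] <- s
    region <- if (pos < ann$cds_start[ti]) "5'UTR" else
      if (pos >= ann$cds_end[ti]) "3'UTR" else "CDS"
    score <- if (is.null(profile)) NA_integer_ else
      matching_score(extract_context(ann[ti, ], pos,
                                     upstream = max(30L, -profile$bounds[1L])),
                     profile)
    truth <- rbind(truth, data.frame(
      transcript_id = ann$transcript_id[ti], gene = ann$gene[ti],
      position = as.integer(pos), region = region,
      efficiency = p$efficiency, score = score, stringsAsFactors = FALSE))
  }
  list(annotations = ann, truth = truth, seed = seed)
}

substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * k) %% 2147483647)
}

# exact multinomial error split via sequential conditional binomials,
# vectorised over sites: three draws at per-base rate e3 each
draw_errors <- function(remaining, e3) {
  b1 <- stats::rbinom(length(remaining), remaining, e3)
  rem <- remaining - b1
  b2 <- stats::rbinom(length(rem), rem, e3 / (1 - e3))
  rem <- rem - b2
  b3 <- stats::rbinom(length(rem), rem, e3 / (1 - 2 * e3))
  cbind(b1, b2, b3)
}

#' Simulate per-site, per-replicate pileup counts
#'
#' For every transcript position and replicate, total coverage is drawn as
#' Poisson(`coverage`). At planted sites in factor replicates the T count is
#' Binomial(total, efficiency + error * (1 - efficiency)); everywhere else,
#' and in all control replicates, each non-reference base receives
#' sequencing-error reads at per-base rate `error / 3`. Reproducible under
#' `seed` via per-replicate substreams.
#'
#' @param transcriptome list from [make_transcriptome()] (or any list with
#'   `annotations` and `truth` of that shape).
#' @param n_factor_reps,n_control_reps replicate counts (defaults 3 + 3,
#'   the design of the expression experiment).
#' @param coverage Poisson mean coverage per site (lambda), > 0.
#' @param error per-read sequencing error rate, in [0, 0.01).
#' @param seed integer seed.
#' @return pileup data frame with columns `transcript_id`, `position`,
#'   `replicate_id`, `group`, `nA`, `nC`, `nG`, `nT`.
#' @export
simulate_pileups <- function(transcriptome, n_factor_reps = 3,
                             n_control_reps = 3, coverage = 100,
                             error = 0.001, seed = 1) {
  stopifnot(coverage > 0, error >= 0, error < 0.01, n_factor_reps >= 1,
            n_control_reps >= 1)
  ann <- transcriptome$annotations
  truth <- transcriptome$truth
  bases <- c("A", "C", "G", "T")

  site_tx <- rep(ann$transcript_id, nchar(ann$sequence))
  site_pos <- unlist(lapply(nchar(ann$sequence),
                            function(l) seq.int(0L, l - 1L)))
  refs <- unlist(strsplit(ann$sequence, ""))
  n_sites <- length(refs)
  ref_idx <- match(refs, bases)

  eff <- numeric(n_sites)
  if (nrow(truth)) {
    ti <- match(paste(truth$transcript_id, truth$position),
                paste(site_tx, site_pos))
    eff[ti] <- truth$efficiency
  }
  e3 <- error / 3
  # non-reference bases per site, in alphabetical order
  nonref <- t(vapply(ref_idx, function(r) which(seq_len(4L) != r),
                     integer(3)))

  one_rep <- function(rep_seed, group, rep_id) {
    set.seed(rep_seed)
    tot <- stats::rpois(n_sites, coverage)
    counts <- matrix(0L, n_sites, 4L, dimnames = list(NULL, bases))
    planted <- group == "factor" & eff > 0
    idx_bg <- which(!planted)
    idx_pl <- which(planted)
    if (length(idx_bg)) {
      if (e3 > 0) {
        errs <- draw_errors(tot[idx_bg], e3)
      } else {
        errs <- matrix(0L, length(idx_bg), 3L)
      }
      for (j in 1:3) {
        counts[cbind(idx_bg, nonref[idx_bg, j])] <- errs[, j]
      }
      counts[cbind(idx_bg, ref_idx[idx_bg])] <- tot[idx_bg] - rowSums(errs)
    }
    if (length(idx_pl)) {
      # planted sites have reference C; edited reads appear as T
      p_edit <- eff[idx_pl] + error * (1 - eff[idx_pl])
      nT <- stats::rbinom(length(idx_pl), tot[idx_pl], p_edit)
      rem <- tot[idx_pl] - nT
      if (e3 > 0) {
        a <- stats::rbinom(length(rem), rem, e3)
        g <- stats::rbinom(length(rem), rem - a, e3 / (1 - e3))
      } else {
        a <- g <- integer(length(rem))
      }
      counts[idx_pl, "T"] <- nT
      counts[idx_pl, "A"] <- a
      counts[idx_pl, "G"] <- g
      counts[idx_pl, "C"] <- rem - a - g
    }
    data.frame(transcript_id = site_tx, position = site_pos,
               replicate_id = rep_id, group = group,
               nA = counts[, "A"], nC = counts[, "C"],
               nG = counts[, "G"], nT = counts[, "T"],
               stringsAsFactors = FALSE)
  }

  reps <- c(
    lapply(seq_len(n_factor_reps), function(k) {
      one_rep(substream_seed(seed, k), "factor", sprintf("F%d", k))
    }),
    lapply(seq_len(n_control_reps), function(k) {
      one_rep(substream_seed(seed, 100L + k), "control", sprintf("C%d", k))
    })
  )
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  out
}

#' Simulate a Sanger chromatogram peak pair at an edited site
#'
#' Draws an observed editing fraction from Normal(`efficiency`, `sd`),
#' truncated to [0, 1], and returns thymidine/cytidine peak heights whose
#' [sanger_rate()] equals that fraction.
#'
#' @param efficiency true editing fraction in [0, 1].
#' @param sd measurement noise of the peak-ratio readout (default 0.02).
#' @param seed optional integer seed.
#' @param scale total peak height (arbitrary units).
#' @return named numeric vector `c(peak_T, peak_C)`.
#' @export
simulate_sanger <- function(efficiency, sd = 0.02, seed = NULL,
                            scale = 1000) {
  stopifnot(efficiency >= 0, efficiency <= 1, sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  rate <- if (sd == 0) efficiency else
    min(1, max(0, stats::rnorm(1L, efficiency, sd)))
  c(peak_T = rate * scale, peak_C = (1 - rate) * scale)
}
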