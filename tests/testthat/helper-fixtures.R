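ACGT <- c("A", "C", "G", "T")

# random -30..+5 style window with C at offset 0
random_window <- function(lo = -30L, hi = 5L, gene = "", tx = "",
                          rate = NA_real_) {
  chars <- sample(ACGT, hi - lo + 1L, replace = TRUE)
  chars[1L - lo] <- "C"
  target_window(paste(chars, collapse = ""), gene = gene,
                transcript_id = tx, lo = lo, rate = rate)
}

# window with prescribed bases at named offsets, constant filler elsewhere
window_with <- function(at = list(), lo = -30L, hi = 5L, fill = "A") {
  chars <- rep(fill, hi - lo + 1L)
  chars[1L - lo] <- "C"
  for (nm in names(at)) chars[as.integer(nm) - lo + 1L] <- at[[nm]]
  target_window(paste(chars, collapse = ""), lo = lo,
                check_c = chars[1L - lo] == "C")
}

# profile with uniform background and prescribed per-offset frequencies;
# spec is a named list: spec[["-14"]] = c(A = 0.43, C = 0.19, ...)
profile_with <- function(spec = list(), bounds = c(-17L, 5L)) {
  offsets <- seq.int(bounds[1L], bounds[2L])
  freq <- matrix(0.25, 4L, length(offsets),
                 dimnames = list(ACGT, offsets))
  for (nm in names(spec)) {
    col <- match(as.integer(nm), offsets)
    f <- rep(0, 4L)
    names(f) <- ACGT
    f[names(spec[[nm]])] <- spec[[nm]]
    f[setdiff(ACGT, names(spec[[nm]]))] <-
      (1 - sum(spec[[nm]])) / (4L - length(spec[[nm]]))
    freq[, col] <- f
  }
  consensus_profile(freq, bounds)
}

# a small window set whose sequences share prescribed bases at some offsets
# with probability p, random elsewhere
windows_biased <- function(n, at, p, lo = -30L, hi = 5L) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    chars <- sample(ACGT, hi - lo + 1L, replace = TRUE)
    chars[1L - lo] <- "C"
    for (nm in names(at)) {
      if (stats::runif(1) < p) chars[as.integer(nm) - lo + 1L] <- at[[nm]]
    }
    target_window(paste(chars, collapse = ""), gene = paste0("g", i),
                  transcript_id = paste0("t", i), lo = lo)
  }))
}

# candidate rows in the shape apply_filters() expects
candidate_row <- function(id, factor_T, factor_total, control_A = 0,
                          control_C, control_G = 0, control_T,
                          n_reps = 3L) {
  data.frame(transcript_id = id, position = 100L,
             n_replicates_detected = n_reps,
             factor_A = 0, factor_C = factor_total - factor_T, factor_G = 0,
             factor_T = factor_T,
             control_A = control_A, control_C = control_C,
             control_G = control_G, control_T = control_T,
             factor_total = factor_total,
             control_total = control_A + control_C + control_G + control_T,
             stringsAsFactors = FALSE)
}

# pileup rows for one site across replicates
site_pileup <- function(tx, pos, reps, groups, nC, nT, nA = 0, nG = 0) {
  data.frame(transcript_id = tx, position = pos, replicate_id = reps,
             group = groups, nA = nA, nC = nC, nG = nG, nT = nT,
             stringsAsFactors = FALSE)
}
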