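# Replicate-filtered C-to-U editing-site calling from per-site base counts.
#
# Inputs are pileup summaries (per transcript position, per replicate, A/C/G/T
# counts) for factor-expressing samples and editing-dead / mock controls, plus
# a transcriptome annotation carrying the reference sequence, CDS bounds and
# an abundance estimate. Coordinates are 0-based half-open internally; all
# human-facing labels are 1-based.

#' Restrict a transcriptome annotation to sufficiently expressed transcripts
#'
#' Keeps transcripts whose abundance estimate reaches `min_reads` mapped read
#' pairs (default 10), the rule used to assemble a customised mapping
#' reference from expressed transcripts only. Order is preserved.
#'
#' @param annotations annotation data frame (see [read_annotation()]).
#' @param min_reads minimum `num_reads` to retain (default 10).
#' @return the filtered annotation data frame.
#' @export
reference_filter <- function(annotations, min_reads = 10) {
  annotations[annotations$num_reads >= min_reads, , drop = FALSE]
}

#' Per-replicate editing call at one site
#'
#' A replicate supports editing at a C position when it holds at least
#' `min_edited` T reads and the per-replicate T fraction reaches `min_rate`.
#' Zero-coverage replicates return `FALSE`, not an error. This is a
#' deliberately simple, documented detector; the discriminating power of the
#' pipeline comes from the replicate-consensus and background filters
#' downstream.
#'
#' @param nT,total numeric vectors: T reads and total reads per replicate.
#' @param min_edited minimum edited reads (default 2).
#' @param min_rate minimum per-replicate edited fraction (default 0.01).
#' @return logical vector.
#' @export
per_replicate_call <- function(nT, total, min_edited = 2, min_rate = 0.01) {
  total > 0 & nT >= min_edited & nT / pmax(total, 1) >= min_rate
}

pileup_columns <- c("transcript_id", "position", "replicate_id", "group",
                    "nA", "nC", "nG", "nT")

pool_by_site <- function(pileup) {
  key <- paste(pileup$transcript_id, pileup$position, sep = "\r")
  pooled <- rowsum(pileup[, c("nA", "nC", "nG", "nT")], key)
  ids <- strsplit(rownames(pooled), "\r", fixed = TRUE)
  data.frame(transcript_id = vapply(ids, `[[`, character(1), 1L),
             position = as.integer(vapply(ids, `[[`, character(1), 2L)),
             pooled, row.names = NULL, stringsAsFactors = FALSE)
}

#' Candidate editing sites by replicate consensus against controls
#'
#' A transcript position is a candidate C-to-U site when its reference base
#' is C, [per_replicate_call()] is true in at least `min_replicates` factor
#' replicates and in no control replicate. Controls (samples expressing an
#' editing-dead DYW mutant, a different factor, or tags only) are mandatory.
#'
#' @param pileup pileup data frame with columns `transcript_id`, `position`,
#'   `replicate_id`, `group` (`"factor"` / `"control"`), `nA`, `nC`, `nG`,
#'   `nT`.
#' @param annotations annotation data frame carrying reference `sequence`.
#' @param min_replicates minimum supporting factor replicates (default 2).
#' @param min_edited,min_rate per-replicate thresholds, see
#'   [per_replicate_call()].
#' @return data frame of candidates, one row per site, with pooled factor and
#'   control counts (`factor_A` .. `factor_T`, `control_A` .. `control_T`,
#'   totals) and the number of calling replicates per group.
#' @export
call_sites <- function(pileup, annotations, min_replicates = 2,
                       min_edited = 2, min_rate = 0.01) {
  missing_cols <- setdiff(pileup_columns, names(pileup))
  if (length(missing_cols)) {
    stop("pileup lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!any(pileup$group == "control")) {
    stop("control replicates are mandatory: no rows with group == 'control'")
  }
  fac <- pileup[pileup$group == "factor", , drop = FALSE]
  ctl <- pileup[pileup$group == "control", , drop = FALSE]
  if (length(unique(fac$replicate_id)) < min_replicates) {
    stop("need at least ", min_replicates, " factor replicates")
  }

  total <- function(p) p$nA + p$nC + p$nG + p$nT
  fac$called <- per_replicate_call(fac$nT, total(fac), min_edited, min_rate)
  ctl$called <- per_replicate_call(ctl$nT, total(ctl), min_edited, min_rate)

  key <- function(p) paste(p$transcript_id, p$position, sep = "\r")
  n_fac <- rowsum(as.integer(fac$called), key(fac))
  n_ctl <- rowsum(as.integer(ctl$called), key(ctl))

  cand_keys <- rownames(n_fac)[n_fac[, 1L] >= min_replicates]
  in_ctl <- cand_keys %in% rownames(n_ctl)
  ctl_called <- integer(length(cand_keys))
  ctl_called[in_ctl] <- n_ctl[cand_keys[in_ctl], 1L]
  cand_keys <- cand_keys[ctl_called == 0L]
  if (!length(cand_keys)) return(empty_candidates())

  fac_pool <- pool_by_site(fac)
  ctl_pool <- pool_by_site(ctl)
  fp_key <- paste(fac_pool$transcript_id, fac_pool$position, sep = "\r")
  cp_key <- paste(ctl_pool$transcript_id, ctl_pool$position, sep = "\r")

  fi <- match(cand_keys, fp_key)
  ci <- match(cand_keys, cp_key)
  out <- data.frame(
    transcript_id = fac_pool$transcript_id[fi],
    position = fac_pool$position[fi],
    n_replicates_detected = n_fac[cand_keys, 1L],
    factor_A = fac_pool$nA[fi], factor_C = fac_pool$nC[fi],
    factor_G = fac_pool$nG[fi], factor_T = fac_pool$nT[fi],
    control_A = zero_na(ctl_pool$nA[ci]), control_C = zero_na(ctl_pool$nC[ci]),
    control_G = zero_na(ctl_pool$nG[ci]), control_T = zero_na(ctl_pool$nT[ci]),
    stringsAsFactors = FALSE
  )
  out$factor_total <- out$factor_A + out$factor_C + out$factor_G + out$factor_T
  out$control_total <- out$control_A + out$control_C + out$control_G +
    out$control_T

  # only positions whose reference base is C are C-to-U candidates
  ref <- ref_base(annotations, out$transcript_id, out$position)
  out <- out[!is.na(ref) & ref == "C", , drop = FALSE]
  out <- out[order(out$transcript_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

zero_na <- function(x) ifelse(is.na(x), 0, x)

empty_candidates <- function() {
  data.frame(transcript_id = character(0), position = integer(0),
             n_replicates_detected = integer(0),
             factor_A = numeric(0), factor_C = numeric(0),
             factor_G = numeric(0), factor_T = numeric(0),
             control_A = numeric(0), control_C = numeric(0),
             control_G = numeric(0), control_T = numeric(0),
             factor_total = numeric(0), control_total = numeric(0),
             stringsAsFactors = FALSE)
}

ref_base <- function(annotations, transcript_id, position) {
  i <- match(transcript_id, annotations$transcript_id)
  out <- rep(NA_character_, length(position))
  ok <- !is.na(i)
  out[ok] <- substring(annotations$sequence[i[ok]], position[ok] + 1L,
                       position[ok] + 1L)
  out[out == ""] <- NA_character_
  out
}

#' Background, coverage and efficiency filters on candidate sites
#'
#' Applies the four site-level criteria to candidates from [call_sites()]:
#' (i) a clean cytidine background above `ref_c_min` in the pooled
#' control/reference counts, (ii) a thymidine background below `ref_t_max`
#' there, (iii) pooled coverage of at least `min_coverage` reads in the
#' factor group and in the control group, and (iv) a pooled editing
#' efficiency of at least `min_rate`. Sites with no control coverage fail
#' with the coverage reason (iii); the background fractions are then not
#' evaluable. The four predicates are independent, so the passing set does
#' not depend on `filter_order` (which only orders the reason codes).
#'
#' @param candidates data frame from [call_sites()].
#' @param ref_c_min minimum control C fraction (default 0.99, i.e. >99%).
#' @param ref_t_max maximum control T fraction (default 0.005, i.e. <0.5%).
#' @param min_coverage minimum pooled reads per group (default 20).
#' @param min_rate minimum pooled edited fraction (default 0.015).
#' @param filter_order permutation of `c("i","ii","iii","iv")`.
#' @return `candidates` with added columns `edit_rate`, `pass` (logical) and
#'   `reasons` (comma-separated violated criteria, "" when passing).
#' @export
apply_filters <- function(candidates, ref_c_min = 0.99, ref_t_max = 0.005,
                          min_coverage = 20, min_rate = 0.015,
                          filter_order = c("i", "ii", "iii", "iv")) {
  stopifnot(setequal(filter_order, c("i", "ii", "iii", "iv")))
  n <- nrow(candidates)
  if (!n) {
    candidates$edit_rate <- numeric(0)
    candidates$pass <- logical(0)
    candidates$reasons <- character(0)
    return(candidates)
  }
  ctot <- candidates$control_total
  ftot <- candidates$factor_total
  has_ctl <- ctot > 0
  checks <- list(
    # background criteria are only evaluable with control coverage; absent
    # controls are caught by (iii)
    i   = ifelse(has_ctl, candidates$control_C / pmax(ctot, 1) > ref_c_min,
                 TRUE),
    ii  = ifelse(has_ctl, candidates$control_T / pmax(ctot, 1) < ref_t_max,
                 TRUE),
    iii = ftot >= min_coverage & ctot >= min_coverage,
    iv  = ftot > 0 & candidates$factor_T / pmax(ftot, 1) >= min_rate
  )
  checks <- checks[filter_order]
  failed <- vapply(seq_len(n), function(r) {
    paste(names(checks)[!vapply(checks, `[[`, logical(1), r)], collapse = ",")
  }, character(1))
  candidates$edit_rate <- ifelse(ftot > 0, candidates$factor_T / pmax(ftot, 1),
                                 NA_real_)
  candidates$pass <- failed == ""
  candidates$reasons <- failed
  candidates
}

#' Pooled editing rate across replicates
#'
#' The editing rate at a site is the ratio of edited (T) to total reads,
#' summed over replicates before dividing — pooled, not averaged per
#' replicate.
#'
#' @param edited numeric vector of T read counts, one entry per replicate.
#' @param total numeric vector of total read counts per replicate.
#' @return a single fraction in `[0, 1]`.
#' @examples
#' edit_rate(c(5, 10), c(50, 50))  # 0.15
#' @export
edit_rate <- function(edited, total) {
  if (length(edited) != length(total) || !length(edited)) {
    stop("edited and total must be equal-length, non-empty vectors")
  }
  if (sum(total) == 0) stop("editing rate undefined: zero total coverage")
  sum(edited) / sum(total)
}

#' Editing rate from Sanger chromatogram peaks
#'
#' The ratio of the thymidine peak to the sum of thymidine and cytidine
#' peaks at the editing position.
#'
#' @param peak_T,peak_C non-negative peak heights.
#' @return fraction in `[0, 1]`.
#' @examples
#' sanger_rate(560, 440)  # 0.56
#' @export
sanger_rate <- function(peak_T, peak_C) {
  if (any(peak_T < 0) || any(peak_C < 0)) stop("peak heights must be >= 0")
  tot <- peak_T + peak_C
  if (any(tot == 0)) stop("editing rate undefined: both peaks are zero")
  peak_T / tot
}

#' Extract the sequence context window around a site
#'
#' Returns the `upstream + 1 + downstream` window centred on `position`
#' (default 30 nt upstream and 5 nt downstream, the standard off-target
#' context; the delivered construct targets use 40/5). Positions where the
#' window overhangs the transcript are padded with '-'.
#'
#' @param annotation one-row annotation data frame (with `sequence`).
#' @param position 0-based transcript coordinate of the site.
#' @param upstream,downstream window extents in nucleotides.
#' @param check_c require the base at `position` to be C (default).
#' @return a one-row window data frame, see [target_window()].
#' @export
extract_context <- function(annotation, position, upstream = 30,
                            downstream = 5, check_c = TRUE) {
  seq <- annotation$sequence[1L]
  len <- nchar(seq)
  if (position < 0L || position >= len) {
    stop("position ", position, " outside transcript ",
         annotation$transcript_id[1L], " (length ", len, ")")
  }
  lo <- position - upstream
  hi <- position + downstream
  left_pad <- max(0L, -lo)
  right_pad <- max(0L, hi - (len - 1L))
  body <- substring(seq, max(lo, 0L) + 1L, min(hi, len - 1L) + 1L)
  window_seq <- paste0(strrep("-", left_pad), body, strrep("-", right_pad))
  target_window(window_seq, gene = annotation$gene[1L],
                transcript_id = annotation$transcript_id[1L],
                position = position, lo = -as.integer(upstream),
                check_c = check_c)
}

#' Editing-site nomenclature label
#'
#' Labels a site as gene + "eU" + position. For CDS sites the position is
#' 1-based within the coding sequence, followed by the amino acids before and
#' after applying the C-to-T change in the containing codon (standard genetic
#' code; a gained stop codon is written '*'), e.g. `nad4eU272SL`. Sites in
#' UTRs use a signed distance instead: `eU-55` for 55 nt upstream of the
#' start codon (nearest upstream base = 1), `eU+743` for 743 nt downstream of
#' the stop (first base after the stop = 1).
#'
#' @param annotation one-row annotation data frame with `gene`, `sequence`,
#'   `cds_start`, `cds_end` (0-based half-open CDS).
#' @param position 0-based transcript coordinate; reference base must be C.
#' @return list with elements `label`, `region` (`"CDS"`, `"5'UTR"` or
#'   `"3'UTR"`), and for CDS sites `cds_position`, `aa_before`, `aa_after`.
#' @export
label_site <- function(annotation, position) {
  seq <- annotation$sequence[1L]
  len <- nchar(seq)
  if (position < 0L || position >= len) {
    stop("position ", position, " outside transcript ",
         annotation$transcript_id[1L], " (length ", len, ")")
  }
  base <- substring(seq, position + 1L, position + 1L)
  if (base != "C") {
    stop("reference base at position ", position, " is ", base, ", not C")
  }
  gene <- annotation$gene[1L]
  cds_start <- annotation$cds_start[1L]
  cds_end <- annotation$cds_end[1L]
  if (position < cds_start) {
    return(list(label = paste0(gene, "eU-", cds_start - position),
                region = "5'UTR"))
  }
  if (position >= cds_end) {
    return(list(label = paste0(gene, "eU+", position - cds_end + 1L),
                region = "3'UTR"))
  }
  in_cds <- position - cds_start
  codon_start <- cds_start + 3L * (in_cds %/% 3L)
  codon <- substring(seq, codon_start + 1L, codon_start + 3L)
  edited <- codon
  substr(edited, in_cds %% 3L + 1L, in_cds %% 3L + 1L) <- "T"
  aa_before <- unname(Biostrings::GENETIC_CODE[codon])
  aa_after <- unname(Biostrings::GENETIC_CODE[edited])
  list(label = paste0(gene, "eU", in_cds + 1L, aa_before, aa_after),
       region = "CDS", cds_position = in_cds + 1L,
       aa_before = aa_before, aa_after = aa_after)
}

#' Parse an eU nomenclature label
#'
#' Inverse of [label_site()]: recovers the gene, region, position within the
#' region and (for CDS labels) the amino-acid change.
#'
#' @param label a label such as `"nad4eU272SL"`, `"MKNK1eU-55"` or
#'   `"QSOX1eU+743"`.
#' @return list with `gene`, `region`, `position` (1-based within region)
#'   and, for CDS labels, `aa_before` / `aa_after`.
#' @export
parse_site_label <- function(label) {
  m <- regmatches(label,
                  regexec("^(.+)eU([+-]?)([0-9]+)([A-Z*])?([A-Z*])?$", label))[[1]]
  if (!length(m)) stop("not a valid eU label: ", label)
  gene <- m[2L]; sign <- m[3L]; pos <- as.integer(m[4L])
  if (sign == "-") return(list(gene = gene, region = "5'UTR", position = pos))
  if (sign == "+") return(list(gene = gene, region = "3'UTR", position = pos))
  if (m[5L] == "" || m[6L] == "") stop("CDS label lacks amino acids: ", label)
  list(gene = gene, region = "CDS", position = pos,
       aa_before = m[5L], aa_after = m[6L])
}

#' Site membership across several off-target call sets
#'
#' Joins call sets on (transcript_id, position) and reports which sets
#' contain each site — used e.g. to count the sites shared between a native
#' factor and its retargeted mutants.
#'
#' @param call_sets named list (>= 2) of call data frames, each with
#'   `transcript_id` and `position` columns.
#' @return data frame with one row per distinct site, one logical column per
#'   set, and `n_sets`; the number of sites present in all sets is attached
#'   as attribute `"intersection"` and pairwise overlap counts as
#'   `"pairwise"`.
#' @export
shared_offtargets <- function(call_sets) {
  if (is.null(names(call_sets)) || length(call_sets) < 2L) {
    stop("call_sets must be a named list of at least two call sets")
  }
  keys <- lapply(call_sets, function(d) {
    unique(paste(d$transcript_id, d$position, sep = "\r"))
  })
  all_keys <- sort(unique(unlist(keys)))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  member <- matrix(member, nrow = length(all_keys),
                   dimnames = list(NULL, names(call_sets)))
  ids <- strsplit(all_keys, "\r", fixed = TRUE)
  out <- data.frame(transcript_id = vapply(ids, `[[`, character(1), 1L),
                    position = as.integer(vapply(ids, `[[`, character(1), 2L)),
                    member, n_sets = rowSums(member),
                    stringsAsFactors = FALSE)
  nm <- names(call_sets)
  pairs <- utils::combn(nm, 2L)
  pw <- apply(pairs, 2L, function(p) sum(member[, p[1L]] & member[, p[2L]]))
  attr(out, "intersection") <- sum(out$n_sets == length(call_sets))
  attr(out, "pairwise") <- stats::setNames(pw, apply(pairs, 2L, paste,
                                                     collapse = "&"))
  out
}

#' Call, filter, quantify and label off-target editing sites
#'
#' Runs the full site-level chain on one sample: [call_sites()] against the
#' controls, [apply_filters()], pooled [edit_rate()], context extraction and
#' nomenclature labelling, and (optionally) matching-score annotation against
#' a consensus profile.
#'
#' @param pileup pileup data frame (factor and control replicates).
#' @param annotations annotation data frame with reference sequences.
#' @param profile optional [consensus_profile()] used to annotate each call
#'   with its matching score.
#' @param min_replicates,min_edited,min_rate_rep replicate-consensus
#'   thresholds, see [call_sites()] and [per_replicate_call()].
#' @param ref_c_min,ref_t_max,min_coverage,min_rate site filters, see
#'   [apply_filters()].
#' @param upstream,downstream context extents, see [extract_context()].
#' @return data frame of passing calls (label, region, edit rate, supporting
#'   replicates, context window sequence, optional matching score); the
#'   pre-filter candidate table is attached as attribute `"candidates"`.
#' @export
call_offtargets <- function(pileup, annotations, profile = NULL,
                            min_replicates = 2, min_edited = 2,
                            min_rate_rep = 0.01, ref_c_min = 0.99,
                            ref_t_max = 0.005, min_coverage = 20,
                            min_rate = 0.015, upstream = 30, downstream = 5) {
  cand <- call_sites(pileup, annotations, min_replicates = min_replicates,
                     min_edited = min_edited, min_rate = min_rate_rep)
  cand <- apply_filters(cand, ref_c_min = ref_c_min, ref_t_max = ref_t_max,
                        min_coverage = min_coverage, min_rate = min_rate)
  calls <- cand[cand$pass, , drop = FALSE]
  n <- nrow(calls)
  label <- character(n); region <- character(n); context <- character(n)
  gene <- character(n); score <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ann <- annotations[annotations$transcript_id == calls$transcript_id[i], ,
                       drop = FALSE]
    lab <- label_site(ann, calls$position[i])
    win <- extract_context(ann, calls$position[i], upstream, downstream)
    label[i] <- lab$label
    region[i] <- lab$region
    context[i] <- win$sequence
    gene[i] <- ann$gene[1L]
    if (!is.null(profile)) score[i] <- matching_score(win, profile)
  }
  out <- data.frame(
    transcript_id = calls$transcript_id, gene = gene,
    position = calls$position, label = label, region = region,
    edit_rate = calls$edit_rate,
    n_replicates_detected = calls$n_replicates_detected,
    context = context, matching_score = score, stringsAsFactors = FALSE
  )
  attr(out, "candidates") <- cand
  out
}

#' Off-target calls as a window set
#'
#' Converts the `context` column of [call_offtargets()] output into a window
#' data frame suitable for [build_profile()].
#'
#' @param calls data frame from [call_offtargets()].
#' @param upstream upstream extent used when the contexts were extracted.
#' @return window data frame.
#' @export
calls_to_windows <- function(calls, upstream = 30) {
  if (!nrow(calls)) {
    stop("no calls to convert")
  }
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    target_window(calls$context[i], gene = calls$gene[i],
                  transcript_id = calls$transcript_id[i],
                  position = calls$position[i], lo = -as.integer(upstream),
                  rate = calls$edit_rate[i])
  })
  do.call(rbind, rows)
}
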