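# Shared readers/writers and the end-to-end pipeline driver. All tabular
# interchange is tab-separated (protein names may contain commas); artifacts
# written by pipeline_run() carry the configuration hash as a '#' comment
# line, which the readers skip.

#' Read and write FASTA sequence sets
#'
#' Thin wrappers over Biostrings. Identifiers are preserved verbatim;
#' mixed-case input is normalised to upper case with a note.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  raw <- readLines(path)
  if (any(grepl("[a-z]", raw[!startsWith(raw, ">")]))) {
    message("read_fasta: mixed-case input normalised to upper case")
  }
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- names(set)
  seqs
}

#' @rdname read_fasta
#' @param sequences named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences),
                              filepath = path)
  invisible(path)
}

# schema-checked TSV reader; '#' comment lines (config-hash stamps) skipped
read_tsv_checked <- function(path, required_cols) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#", quote = "")
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols)) {
    stop("file ", path, " lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

write_tsv_stamped <- function(df, path, required_cols, hash = NULL) {
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols)) {
    stop("refusing to write ", path, ": missing columns ",
         paste(missing_cols, collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config_hash=", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-site, per-replicate pileup table
#'
#' Expects a TSV with header `transcript_id`, `position`, `replicate_id`,
#' `group`, `nA`, `nC`, `nG`, `nT`; counts must be non-negative and `group`
#' either `"factor"` or `"control"`. Malformed rows fail fast with their row
#' number.
#'
#' @param path TSV file path.
#' @return pileup data frame.
#' @export
read_pileup <- function(path) {
  df <- read_tsv_checked(path, pileup_columns)
  for (col in c("nA", "nC", "nG", "nT")) {
    bad <- which(is.na(df[[col]]) | df[[col]] < 0)
    if (length(bad)) {
      stop("pileup ", path, ": invalid ", col, " at data row ", bad[1L])
    }
  }
  bad <- which(!df$group %in% c("factor", "control"))
  if (length(bad)) {
    stop("pileup ", path, ": group must be factor/control at data row ",
         bad[1L])
  }
  df
}

#' @rdname read_pileup
#' @param pileup pileup data frame to serialise.
#' @export
write_pileup <- function(pileup, path) {
  write_tsv_stamped(pileup, path, pileup_columns)
}

#' Read a transcript annotation table
#'
#' Expects a TSV with columns `transcript_id`, `gene`, `protein_name`,
#' `cds_start`, `cds_end` (0-based half-open CDS) and `num_reads`; when
#' `fasta` is given (path or named character vector of sequences) the
#' sequences are attached and validated: every transcript must have a
#' sequence, the CDS must lie within it, and its length must be a multiple
#' of three.
#'
#' @param path annotation TSV path.
#' @param fasta optional FASTA path or named character vector.
#' @return annotation data frame (with a `sequence` column when `fasta` is
#'   given).
#' @export
read_annotation <- function(path, fasta = NULL) {
  df <- read_tsv_checked(path, c("transcript_id", "gene", "protein_name",
                                 "cds_start", "cds_end", "num_reads"))
  if (!is.null(fasta)) {
    seqs <- if (is.character(fasta) && length(fasta) == 1L &&
                file.exists(fasta)) read_fasta(fasta) else fasta
    df$sequence <- unname(seqs[df$transcript_id])
    if (anyNA(df$sequence)) {
      stop("annotation row ", which(is.na(df$sequence))[1L],
           ": transcript has no sequence in the FASTA")
    }
    bad <- which(df$cds_end > nchar(df$sequence) | df$cds_start < 0 |
                   df$cds_start >= df$cds_end |
                   (df$cds_end - df$cds_start) %% 3 != 0)
    if (length(bad)) {
      stop("annotation row ", bad[1L], ": invalid CDS interval for ",
           df$transcript_id[bad[1L]])
    }
  }
  df
}

annotation_columns <- c("transcript_id", "gene", "protein_name",
                        "cds_start", "cds_end", "num_reads")

#' @rdname read_annotation
#' @param annotations annotation data frame to serialise (the `sequence`
#'   column, if present, is dropped; sequences travel in FASTA).
#' @export
write_annotation <- function(annotations, path) {
  write_tsv_stamped(annotations[, annotation_columns, drop = FALSE], path,
                    annotation_columns)
}

config_hash <- function(config) {
  keep <- config[!vapply(config, is.data.frame, logical(1))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(keep[order(names(keep))]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full off-target pipeline
#'
#' Sequences the analysis stages on one configuration: expressed-transcript
#' filtering, replicate-consensus candidate calling against mandatory
#' controls, the background/coverage/efficiency filters, context extraction
#' and labelling, consensus-profile construction from the passing calls, and
#' matching-score annotation. Per-stage record counts and the thresholds
#' actually applied are logged with `message()`; artifacts in `out_dir`
#' (calls.tsv, windows.tsv, profile.tsv, run_info.txt) carry the
#' configuration hash.
#'
#' @param config a list with inputs — either paths (`fasta`, `annotation`,
#'   `pileup`) or in-memory objects (`annotations` incl. sequences,
#'   `pileup_data`) — and optional parameters `min_reads`, `min_replicates`,
#'   `min_edited`, `min_rate_rep`, `ref_c_min`, `ref_t_max`, `min_coverage`,
#'   `min_rate`, `upstream`, `downstream`, `profile_bounds`, `dedupe`,
#'   `out_dir`.
#' @return invisibly, a list with `calls`, `candidates`, `profile`,
#'   `windows`, `counts` (per-stage record counts) and `config_hash`.
#' @export
pipeline_run <- function(config) {
  defaults <- list(min_reads = 10, min_replicates = 2, min_edited = 2,
                   min_rate_rep = 0.01, ref_c_min = 0.99, ref_t_max = 0.005,
                   min_coverage = 20, min_rate = 0.015, upstream = 30,
                   downstream = 5, profile_bounds = c(-17L, 5L),
                   dedupe = TRUE, out_dir = NULL)
  unknown <- setdiff(names(config),
                     c(names(defaults), "fasta", "annotation", "pileup",
                       "annotations", "pileup_data"))
  if (length(unknown)) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  hash <- config_hash(cfg)

  ann <- if (!is.null(cfg$annotations)) cfg$annotations else
    read_annotation(cfg$annotation, cfg$fasta)
  if (is.null(ann$sequence)) {
    stop("annotations must carry transcript sequences (supply 'fasta')")
  }
  pileup <- if (!is.null(cfg$pileup_data)) cfg$pileup_data else
    read_pileup(cfg$pileup)

  message(sprintf("[reference_filter] %d transcripts in, min_reads=%g",
                  nrow(ann), cfg$min_reads))
  ann <- reference_filter(ann, min_reads = cfg$min_reads)
  message(sprintf("[reference_filter] %d transcripts retained", nrow(ann)))

  if (!any(pileup$group == "control")) {
    stop("aborting before calling: configuration supplies no control ",
         "replicates (controls are mandatory)")
  }
  pileup <- pileup[pileup$transcript_id %in% ann$transcript_id, ,
                   drop = FALSE]

  message(sprintf(
    "[call] min_replicates=%d min_edited=%d min_rate_rep=%g",
    cfg$min_replicates, cfg$min_edited, cfg$min_rate_rep))
  message(sprintf(
    "[filter] ref_c_min=%g ref_t_max=%g min_coverage=%g min_rate=%g",
    cfg$ref_c_min, cfg$ref_t_max, cfg$min_coverage, cfg$min_rate))
  calls <- call_offtargets(
    pileup, ann, profile = NULL,
    min_replicates = cfg$min_replicates, min_edited = cfg$min_edited,
    min_rate_rep = cfg$min_rate_rep, ref_c_min = cfg$ref_c_min,
    ref_t_max = cfg$ref_t_max, min_coverage = cfg$min_coverage,
    min_rate = cfg$min_rate, upstream = cfg$upstream,
    downstream = cfg$downstream)
  candidates <- attr(calls, "candidates")
  message(sprintf("[call] %d candidates, %d pass filters",
                  nrow(candidates), nrow(calls)))

  profile <- NULL
  windows <- NULL
  if (nrow(calls)) {
    windows <- calls_to_windows(calls, upstream = cfg$upstream)
    profile <- build_profile(windows, bounds = cfg$profile_bounds,
                             dedupe = cfg$dedupe)
    message(sprintf("[profile] %d windows (dedupe=%s), max score %d",
                    profile$n_windows, cfg$dedupe, max_score(profile)))
    calls$matching_score <- vapply(seq_len(nrow(windows)), function(i) {
      matching_score(windows[i, , drop = FALSE], profile)
    }, integer(1))
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_stamped(calls, file.path(cfg$out_dir, "calls.tsv"),
                      c("transcript_id", "gene", "position", "label",
                        "region", "edit_rate", "n_replicates_detected",
                        "context"), hash = hash)
    if (!is.null(windows)) {
      write_tsv_stamped(
        data.frame(gene = windows$gene, transcript = windows$transcript_id,
                   position = windows$position, sequence = windows$sequence,
                   rate = windows$rate),
        file.path(cfg$out_dir, "windows.tsv"),
        c("gene", "transcript", "position", "sequence", "rate"), hash = hash)
      write_profile(profile, file.path(cfg$out_dir, "profile.tsv"))
    }
    writeLines(c(
      paste0("config_hash: ", hash),
      paste0("transcripts_retained: ", nrow(ann)),
      paste0("candidates: ", nrow(candidates)),
      paste0("calls: ", nrow(calls))
    ), file.path(cfg$out_dir, "run_info.txt"))
  }

  invisible(list(calls = calls, candidates = candidates, profile = profile,
                 windows = windows,
                 counts = c(transcripts = nrow(ann),
                            candidates = nrow(candidates),
                            calls = nrow(calls)),
                 config_hash = hash))
}
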