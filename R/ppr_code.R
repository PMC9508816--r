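# PLS-type PPR arrays and the PPR-RNA recognition code.
#
# Internal nucleotide alphabet is DNA (A,C,G,T); 'U' is accepted on input and
# normalised to 'T'. Motif numbering is backwards: the C-terminal repeat is
# S2-1 and pairs with target offset -4 (offset 0 = the edited cytidine), so
# repeat number n pairs with offset -(n + 3).

PPR_CLASSES <- c("P", "L", "S", "P2", "L2", "S2")

# purine<->purine / pyrimidine<->pyrimidine partners
TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

AA_ALPHABET1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Normalise a nucleotide string to the internal DNA alphabet
#'
#' Uppercases and maps U to T. Characters outside A/C/G/T/N/- are rejected.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over A, C, G, T, N and '-'.
#' @export
normalize_nt <- function(x) {
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN-]", x)
  if (any(bad)) {
    stop("invalid nucleotide characters in: ", paste(x[bad], collapse = ", "))
  }
  x
}

check_aa <- function(aa, what) {
  if (!is.character(aa) || length(aa) != 1L || !aa %in% AA_ALPHABET1) {
    stop(what, " must be a single uppercase one-letter amino-acid code, got: ",
         deparse(aa))
  }
  invisible(aa)
}

#' Construct a single PPR motif
#'
#' A PPR motif is described by its class (P, L, S, or the C-terminal variants
#' P2, L2, S2), its backward repeat number (the terminal repeat is 1), and the
#' amino acids at the two RNA-facing key positions 5 and L.
#'
#' @param motif_class one of `"P"`, `"L"`, `"S"`, `"P2"`, `"L2"`, `"S2"`.
#' @param repeat_number positive integer; backward numbering, terminal = 1.
#' @param aa5,aaL one-letter amino-acid codes at positions 5 and L.
#' @return an object of class `ppr_motif` with a `label` of the form
#'   `"S-7"` or `"P2-3"`.
#' @examples
#' ppr_motif("S2", 1, "N", "D")
#' @export
ppr_motif <- function(motif_class, repeat_number, aa5, aaL) {
  motif_class <- match.arg(motif_class, PPR_CLASSES)
  repeat_number <- as.integer(repeat_number)
  if (is.na(repeat_number) || repeat_number < 1L) {
    stop("repeat_number must be a positive integer")
  }
  check_aa(aa5, "aa5")
  check_aa(aaL, "aaL")
  structure(
    list(
      label = paste0(motif_class, "-", repeat_number),
      motif_class = motif_class,
      repeat_number = repeat_number,
      aa5 = aa5,
      aaL = aaL
    ),
    class = "ppr_motif"
  )
}

#' @export
print.ppr_motif <- function(x, ...) {
  cat(sprintf("<PPR motif %s%s%s, target offset %d>\n",
              x$label, x$aa5, x$aaL, motif_position(x)))
  invisible(x)
}

#' Construct an editing factor from an ordered PPR array
#'
#' Motifs are given from N- to C-terminus. The array must end in an S2-1
#' repeat, repeat numbers must strictly decrease towards the C-terminus, and
#' labels must be unique.
#'
#' @param name factor name, e.g. `"PPR56"`.
#' @param motifs list of [ppr_motif()] objects, N- to C-terminal order.
#' @param has_dyw logical; whether the factor carries a (functional) DYW
#'   cytidine deaminase domain. Editing-dead DYW mutants used as controls
#'   carry `FALSE`. Bookkeeping only.
#' @return an object of class `editing_factor`.
#' @export
editing_factor <- function(name, motifs, has_dyw = TRUE) {
  if (!length(motifs)) stop("an editing factor needs at least one motif")
  if (!all(vapply(motifs, inherits, logical(1), "ppr_motif"))) {
    stop("motifs must be a list of ppr_motif objects")
  }
  nums <- vapply(motifs, `[[`, integer(1), "repeat_number")
  labels <- vapply(motifs, `[[`, character(1), "label")
  last <- motifs[[length(motifs)]]
  if (last$motif_class != "S2" || last$repeat_number != 1L) {
    stop("the C-terminal motif must be S2-1, got ", last$label)
  }
  if (any(diff(nums) >= 0)) {
    stop("repeat numbers must strictly decrease towards the C-terminus")
  }
  if (anyDuplicated(labels)) stop("motif labels must be unique")
  structure(
    list(name = name, motifs = stats::setNames(motifs, labels),
         has_dyw = isTRUE(has_dyw)),
    class = "editing_factor"
  )
}

#' @export
print.editing_factor <- function(x, ...) {
  cat(sprintf("<editing factor %s: %d PPRs, %s>\n", x$name, length(x$motifs),
              if (x$has_dyw) "DYW+" else "DYW- (editing-dead control)"))
  tab <- vapply(x$motifs, function(m) paste0(m$label, m$aa5, m$aaL),
                character(1))
  cat(" ", paste(tab, collapse = " "), "\n")
  invisible(x)
}

#' Nucleotide prediction of the PPR-RNA code
#'
#' The core code maps the amino acids at PPR positions 5 and L to a target
#' nucleotide: T/S + N -> A, T/S + D -> G, N + S -> C, N + D -> U and
#' N + N -> C or U. All other combinations carry no prediction and return an
#' empty set. Predictions are returned in the DNA alphabet (U as T).
#'
#' @param aa5,aaL single uppercase amino-acid letters.
#' @return character vector of predicted nucleotides (possibly empty).
#' @examples
#' code_prediction("T", "N")  # "A"
#' code_prediction("N", "D")  # "T" (i.e. U)
#' code_prediction("N", "N")  # c("C", "T")
#' code_prediction("M", "D")  # character(0): no prediction
#' @export
code_prediction <- function(aa5, aaL) {
  check_aa(aa5, "aa5")
  check_aa(aaL, "aaL")
  if (aa5 %in% c("T", "S")) {
    if (aaL == "N") return("A")
    if (aaL == "D") return("G")
  } else if (aa5 == "N") {
    if (aaL == "S") return("C")
    if (aaL == "D") return("T")
    if (aaL == "N") return(c("C", "T"))
  }
  character(0)
}

#' Target offset bound by a PPR motif
#'
#' The terminal repeat S2-1 pairs with offset -4 upstream of the edited
#' cytidine (offset 0), one nucleotide per repeat, so repeat number n pairs
#' with offset -(n + 3).
#'
#' @param motif a [ppr_motif()] object or a positive integer repeat number.
#' @return integer target offset (negative, upstream of the edited site).
#' @examples
#' motif_position(ppr_motif("S2", 1, "N", "D"))  # -4
#' motif_position(7)                             # -10
#' @export
motif_position <- function(motif) {
  n <- if (inherits(motif, "ppr_motif")) motif$repeat_number else
    as.integer(motif)
  if (any(is.na(n)) || any(n < 1L)) stop("repeat number must be >= 1")
  -(n + 3L)
}

# classification of one observed nucleotide against a predicted set;
# pads/N are reported "none" (no prediction can be evaluated against them)
classify_nt <- function(predicted, observed) {
  if (!length(predicted)) return("none")
  if (!observed %in% c("A", "C", "G", "T")) return("none")
  if (observed %in% predicted) return("match")
  if (observed %in% TRANSITION_PARTNER[predicted]) return("transition")
  "transversion"
}

#' Juxtapose a PPR array with a target window
#'
#' Aligns each repeat of the factor with its target offset and classifies the
#' observed nucleotide against the code prediction: "match" when observed is
#' in the predicted set; "transition" when it is the purine-purine or
#' pyrimidine-pyrimidine partner of a predicted nucleotide (and not a match);
#' "transversion" otherwise; "none" when the code makes no prediction (a
#' match always wins over a transition). Repeats of the L/L2 classes are not
#' covered by the core code; their rows are flagged `canonical = FALSE`.
#'
#' @param factor an [editing_factor()].
#' @param window a target window (one-row data frame from [target_window()]).
#' @return data frame with one row per motif: `motif`, `position`,
#'   `predicted` ("/"-separated set, "" when empty), `observed`, `class`,
#'   `canonical`.
#' @export
juxtapose <- function(factor, window) {
  stopifnot(inherits(factor, "editing_factor"))
  positions <- vapply(factor$motifs, motif_position, integer(1))
  lo <- window$lo[1L]
  hi <- window$hi[1L]
  uncovered <- positions[positions < lo | positions > hi]
  if (length(uncovered)) {
    stop("window [", lo, "..", hi, "] does not cover motif position ",
         min(uncovered))
  }
  observed <- window_base(window, positions)
  rows <- lapply(seq_along(factor$motifs), function(i) {
    m <- factor$motifs[[i]]
    pred <- code_prediction(m$aa5, m$aaL)
    data.frame(
      motif = m$label,
      position = positions[[i]],
      predicted = paste(pred, collapse = "/"),
      observed = observed[[i]],
      class = classify_nt(pred, observed[[i]]),
      canonical = !m$motif_class %in% c("L", "L2"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Point-mutate the key residues of one PPR motif
#'
#' Returns a new factor identical to `factor` except that the named motif's
#' positions 5 and L carry the new amino acids; the input factor is not
#' modified. This models the single-repeat retargeting experiments in which
#' e.g. an S-type TD repeat (predicting G) is changed to TN (predicting A).
#'
#' @param factor an [editing_factor()].
#' @param label motif label to change, e.g. `"S-7"`.
#' @param new_aa5,new_aaL replacement amino acids for positions 5 and L.
#' @return a new `editing_factor`.
#' @export
mutate_motif <- function(factor, label, new_aa5, new_aaL) {
  stopifnot(inherits(factor, "editing_factor"))
  if (!label %in% names(factor$motifs)) {
    stop("no motif labelled ", label, " in factor ", factor$name)
  }
  m <- factor$motifs[[label]]
  factor$motifs[[label]] <- ppr_motif(m$motif_class, m$repeat_number,
                                      new_aa5, new_aaL)
  factor
}

#' Tally juxtaposition classes over a set of windows
#'
#' Runs [juxtapose()] on every window and sums, per motif, the number of
#' windows classified match / transition / transversion / none. For each
#' motif, match + transition + transversion + none equals the number of
#' windows.
#'
#' @param factor an [editing_factor()].
#' @param windows a window set (data frame, one row per window).
#' @return data frame with columns `motif`, `position`, `canonical`,
#'   `match`, `transition`, `transversion`, `none`.
#' @export
match_tally <- function(factor, windows) {
  stopifnot(inherits(factor, "editing_factor"))
  positions <- vapply(factor$motifs, motif_position, integer(1))
  base <- data.frame(
    motif = names(factor$motifs),
    position = positions,
    canonical = !vapply(factor$motifs, `[[`, character(1), "motif_class") %in%
      c("L", "L2"),
    match = 0L, transition = 0L, transversion = 0L, none = 0L,
    stringsAsFactors = FALSE
  )
  if (is.null(windows) || nrow(windows) == 0L) return(base)
  for (i in seq_len(nrow(windows))) {
    jx <- juxtapose(factor, windows[i, , drop = FALSE])
    idx <- cbind(seq_len(nrow(base)),
                 match(jx$class, c("match", "transition", "transversion",
                                   "none")) + 3L)
    base[idx] <- as.integer(unlist(base[idx])) + 1L
  }
  base
}

#' Read / write editing-factor definitions
#'
#' The factor definition format is a tab-separated text file with one motif
#' per line in N- to C-terminal order and columns label, class, aa5, aaL;
#' lines starting with '#' are comments. `read_factor()` also accepts the
#' text itself (a character vector with more than one element or containing
#' newlines).
#'
#' @param path file path (or definition text for `read_factor`).
#' @param name factor name; defaults to the file name stem.
#' @param has_dyw logical, stored on the factor.
#' @return `read_factor()` an [editing_factor()]; `write_factor()` the path,
#'   invisibly.
#' @export
read_factor <- function(path, name = NULL, has_dyw = TRUE) {
  if (!length(path) || !nzchar(path[1L])) stop("empty factor definition")
  if (length(path) > 1L || grepl("\n", path[1L], fixed = TRUE)) {
    lines <- unlist(strsplit(path, "\n", fixed = TRUE))
    if (is.null(name)) name <- "factor"
  } else {
    lines <- readLines(path)
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty factor definition")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad)) {
    stop("malformed factor definition line ", bad[1L], ": expected 4 fields")
  }
  motifs <- lapply(fields, function(f) {
    cls <- f[2L]
    num <- as.integer(sub("^.*-", "", f[1L]))
    m <- ppr_motif(cls, num, f[3L], f[4L])
    if (m$label != f[1L]) {
      stop("label ", f[1L], " does not reconstruct from class ", cls,
           " and repeat number ", num)
    }
    m
  })
  editing_factor(name, motifs, has_dyw = has_dyw)
}

#' @rdname read_factor
#' @param factor an [editing_factor()] to serialise.
#' @export
write_factor <- function(factor, path) {
  stopifnot(inherits(factor, "editing_factor"))
  lines <- c(
    paste0("# editing factor ", factor$name),
    vapply(factor$motifs, function(m) {
      paste(m$label, m$motif_class, m$aa5, m$aaL, sep = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
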