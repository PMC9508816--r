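ann_with <- function(seq, gene = "g", tx = "t1", cds_start = 0L,
                     cds_end = nchar(seq), num_reads = 100) {
  data.frame(transcript_id = tx, gene = gene, protein_name = "p",
             cds_start = cds_start, cds_end = cds_end,
             num_reads = num_reads, sequence = seq,
             stringsAsFactors = FALSE)
}

test_that("the expressed-transcript filter keeps NumReads >= threshold", {
  ann <- do.call(rbind, lapply(1:3, function(i) {
    ann_with(strrep("ACG", 10), tx = paste0("t", i))
  }))
  ann$num_reads <- c(12, 9, 10)
  expect_identical(reference_filter(ann)$transcript_id, c("t1", "t3"))
  expect_identical(nrow(reference_filter(ann, min_reads = 13)), 0L)
  expect_identical(reference_filter(ann, min_reads = 0), ann)
})

test_that("per-replicate detection needs 2 edited reads and 1% rate", {
  expect_true(per_replicate_call(2, 50))     # {C:48, T:2}
  expect_false(per_replicate_call(1, 100))   # only one edited read
  expect_false(per_replicate_call(0, 0))     # zero coverage, not an error
  expect_false(per_replicate_call(2, 250))   # 0.8% < 1%
  expect_identical(per_replicate_call(c(2, 1, 0), c(50, 100, 0)),
                   c(TRUE, FALSE, FALSE))
})

test_that("candidates need >= 2 factor replicates and silent controls", {
  seq <- paste0(strrep("A", 50), "C", strrep("A", 49))
  ann <- ann_with(seq)
  base <- function(nT_fac, nT_ctl) rbind(
    site_pileup("t1", 50L, c("F1", "F2", "F3"), "factor", nC = 100 - nT_fac,
                nT = nT_fac),
    site_pileup("t1", 50L, c("C1", "C2", "C3"), "control",
                nC = 100 - nT_ctl, nT = nT_ctl)
  )
  # edited in 3/3 factor replicates, no control: candidate
  cand <- call_sites(base(c(5, 5, 5), 0), ann)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$n_replicates_detected, 3L)
  expect_identical(cand$factor_T, 15)
  # 1/3 factor replicates: rejected
  expect_identical(nrow(call_sites(base(c(5, 0, 0), 0), ann)), 0L)
  # 2/3 factor but one control replicate also calls it: rejected
  expect_identical(nrow(call_sites(base(c(5, 5, 0), c(5, 0, 0)), ann)), 0L)
  # non-C reference positions are never candidates
  pu <- base(c(5, 5, 5), 0)
  pu$position <- 10L  # an A position
  expect_identical(nrow(call_sites(pu, ann)), 0L)
  # controls are mandatory
  fac_only <- base(c(5, 5, 5), 0)
  fac_only <- fac_only[fac_only$group == "factor", ]
  expect_error(call_sites(fac_only, ann), "control")
})

test_that("site filters pass exactly the constructed survivors", {
  cand <- rbind(
    candidate_row("pass1", factor_T = 2, factor_total = 60,
                  control_C = 995, control_T = 2, control_A = 3),
    candidate_row("fail_iv_rate", factor_T = 1, factor_total = 100,
                  control_C = 995, control_T = 2, control_A = 3),
    candidate_row("fail_iii_sample_cov", factor_T = 2, factor_total = 19,
                  control_C = 995, control_T = 2, control_A = 3),
    candidate_row("fail_iii_ref_cov", factor_T = 3, factor_total = 60,
                  control_C = 19, control_T = 0),
    candidate_row("fail_i_c_background", factor_T = 3, factor_total = 60,
                  control_C = 980, control_T = 2, control_A = 18),
    candidate_row("fail_ii_t_background", factor_T = 3, factor_total = 60,
                  control_C = 991, control_T = 8, control_A = 1),
    candidate_row("pass2", factor_T = 9, factor_total = 600,
                  control_C = 1000, control_T = 0),
    candidate_row("fail_i_and_iv", factor_T = 1, factor_total = 100,
                  control_C = 980, control_T = 2, control_A = 18),
    candidate_row("pass3", factor_T = 40, factor_total = 50,
                  control_C = 199, control_T = 0, control_A = 1),
    candidate_row("pass4", factor_T = 2, factor_total = 20,
                  control_C = 20, control_T = 0)
  )
  out <- apply_filters(cand)
  expect_identical(out$transcript_id[out$pass],
                   c("pass1", "pass2", "pass3", "pass4"))
  expect_identical(out$reasons[out$transcript_id == "fail_iv_rate"], "iv")
  expect_match(out$reasons[out$transcript_id == "fail_iii_sample_cov"], "iii")
  expect_identical(out$reasons[out$transcript_id == "fail_i_c_background"],
                   "i")
  expect_identical(out$reasons[out$transcript_id == "fail_ii_t_background"],
                   "ii")
  expect_setequal(
    strsplit(out$reasons[out$transcript_id == "fail_i_and_iv"], ",")[[1]],
    c("i", "iv"))

  # the passing set is identical under every filter-order permutation
  perms <- list(c("iv", "iii", "ii", "i"), c("ii", "i", "iv", "iii"),
                c("iii", "i", "iv", "ii"))
  for (ord in perms) {
    alt <- apply_filters(cand, filter_order = ord)
    expect_identical(alt$pass, out$pass)
    expect_setequal(strsplit(alt$reasons[8], ",")[[1]],
                    strsplit(out$reasons[8], ",")[[1]])
  }
})

test_that("sites without control coverage fail with the coverage reason", {
  cand <- candidate_row("no_ctl", factor_T = 5, factor_total = 60,
                        control_C = 0, control_T = 0)
  out <- apply_filters(cand)
  expect_false(out$pass)
  expect_identical(out$reasons, "iii")
})

test_that("editing rates pool replicate counts before dividing", {
  expect_equal(edit_rate(c(5, 10), c(50, 50)), 0.15)
  expect_equal(edit_rate(0, 40), 0)
  expect_error(edit_rate(c(0, 0), c(0, 0)), "undefined")
  set.seed(31)
  for (i in 1:20) {
    edited <- rpois(5, 4)
    total <- edited + rpois(5, 60)
    num <- 0; den <- 0
    for (r in 1:5) { num <- num + edited[r]; den <- den + total[r] }
    expect_equal(edit_rate(edited, total), num / den)
  }
})

test_that("Sanger rates are the T peak over the T+C peak sum", {
  expect_equal(sanger_rate(560, 440), 0.56)
  expect_equal(sanger_rate(0, 900), 0)
  expect_equal(sanger_rate(900, 0), 1)
  expect_error(sanger_rate(0, 0), "undefined")
})

test_that("context windows extract -30..+5 with pads at transcript ends", {
  seq <- paste(sample(c("A", "G", "T"), 200, TRUE), collapse = "")
  substr(seq, 101, 101) <- "C"
  ann <- ann_with(seq)
  w <- extract_context(ann, 100L)
  expect_identical(nchar(w$sequence), 36L)
  expect_identical(w$lo, -30L)
  expect_identical(window_base(w, 0), "C")
  expect_identical(window_base(w, -1), substr(seq, 100, 100))

  substr(seq, 11, 11) <- "C"
  ann <- ann_with(seq)
  wb <- extract_context(ann, 10L)
  expect_identical(substr(wb$sequence, 1, 20), strrep("-", 20))
  expect_identical(window_base(wb, 0), "C")

  # construct-style extraction: 40 upstream + site + 5 downstream = 46 nt
  wc <- extract_context(ann, 100L, upstream = 40)
  expect_identical(nchar(wc$sequence), 46L)
  expect_error(extract_context(ann, 500L), "outside")
})

test_that("eU labels encode CDS codon changes and UTR distances", {
  # CDS: serine codon TCA edited in place 2 becomes leucine TTA;
  # CDS position 272 = codon 91, middle base
  utr5 <- 10L
  cds <- strrep("GCT", 120)  # alanines
  substr(cds, 271, 273) <- "TCA"
  seq <- paste0(strrep("A", utr5), cds, strrep("A", 50))
  ann <- ann_with(seq, gene = "nad4", cds_start = utr5,
                  cds_end = utr5 + nchar(cds))
  lab <- label_site(ann, utr5 + 271L)  # 0-based: CDS offset 271 = pos 272
  expect_identical(lab$label, "nad4eU272SL")
  expect_identical(lab$region, "CDS")

  # stop gain: CAA (Gln) -> TAA, written '*'
  substr(seq, utr5 + 301, utr5 + 303) <- "CAA"
  ann2 <- ann_with(seq, gene = "AGFG", cds_start = utr5,
                   cds_end = utr5 + nchar(cds))
  lab2 <- label_site(ann2, utr5 + 300L)
  expect_identical(lab2$label, "AGFGeU301Q*")

  # 3'-UTR: distance downstream of the stop, first base after stop = 1
  utr3 <- ann_with(paste0(strrep("A", 100), strrep("G", 800), "C",
                          strrep("A", 99)),
                   gene = "QSOX1", cds_start = 10L, cds_end = 158L)
  expect_identical(label_site(utr3, 158L + 742L)$label, "QSOX1eU+743")
  expect_identical(label_site(utr3, 158L + 742L)$region, "3'UTR")

  # 5'-UTR: distance upstream of the start, nearest base = 1
  utr5ann <- ann_with(paste0(strrep("A", 20), "C", strrep("A", 100),
                             strrep("GCT", 30)),
                      gene = "MKNK1", cds_start = 75L, cds_end = 165L)
  expect_identical(label_site(utr5ann, 20L)$label, "MKNK1eU-55")
  expect_identical(label_site(utr5ann, 20L)$region, "5'UTR")

  expect_error(label_site(utr5ann, 5000L), "outside")
  expect_error(label_site(utr5ann, 0L), "not C")
})

test_that("labels round-trip through the nomenclature parser", {
  cases <- list(
    list(label = "nad4eU272SL", region = "CDS", position = 272L,
         aa_before = "S", aa_after = "L"),
    list(label = "AGFGeU301Q*", region = "CDS", position = 301L,
         aa_before = "Q", aa_after = "*"),
    list(label = "QSOX1eU+743", region = "3'UTR", position = 743L),
    list(label = "MKNK1eU-55", region = "5'UTR", position = 55L)
  )
  for (cs in cases) {
    p <- parse_site_label(cs$label)
    expect_identical(p$region, cs$region)
    expect_identical(p$position, cs$position)
    if (cs$region == "CDS") {
      expect_identical(p$aa_before, cs$aa_before)
      expect_identical(p$aa_after, cs$aa_after)
    }
  }
  expect_error(parse_site_label("notalabel"), "eU")
})

test_that("shared off-target membership obeys set algebra", {
  mk <- function(tx, pos) data.frame(transcript_id = tx, position = pos,
                                     stringsAsFactors = FALSE)
  # disjoint sets: empty intersection
  d <- shared_offtargets(list(a = mk("t1", 1:3), b = mk("t2", 1:3)))
  expect_identical(attr(d, "intersection"), 0L)
  # identical sets: intersection equals either set
  s <- mk("t1", 1:5)
  i <- shared_offtargets(list(a = s, b = s))
  expect_identical(attr(i, "intersection"), 5L)

  # three sets with a planted 7-site shared core
  core <- mk("t1", 1:7)
  three <- list(native = rbind(core, mk("t2", 1:20)),
                mut1 = rbind(core, mk("t3", 1:5)),
                mut2 = rbind(core, mk("t4", 1:11)))
  tab <- shared_offtargets(three)
  expect_identical(attr(tab, "intersection"), 7L)
  pw <- attr(tab, "pairwise")
  expect_true(all(attr(tab, "intersection") <= pw))
  expect_identical(sum(tab$n_sets == 1L), 20L + 5L + 11L)
  expect_error(shared_offtargets(list(mk("t1", 1))), "named list")
})
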