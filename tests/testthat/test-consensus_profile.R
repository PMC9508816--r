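test_that("target windows validate and normalise their sequence", {
  w <- target_window(paste(c(rep("a", 30), "c", rep("u", 5)), collapse = ""))
  expect_identical(w$lo, -30L)
  expect_identical(w$hi, 5L)
  expect_identical(window_base(w, 0), "C")
  expect_identical(window_base(w, 5), "T")    # U normalised to T
  expect_identical(window_base(w, -31), "-")  # outside the window
  expect_error(target_window(strrep("A", 36)), "must be C")
  expect_error(target_window("ACGX"), "invalid nucleotide")
})

test_that("profile frequencies and deciles follow the 40%-step rule", {
  set.seed(3)
  wins <- windows_biased(10, at = list(`-14` = "A"), p = 1)
  prof <- build_profile(wins)
  expect_equal(prof$freq["A", "-14"], 1.0)
  dec <- prof$decile
  expect_identical(dec$decile[dec$offset == -14], 90L)  # capped, no 100 step
  expect_identical(dec$nt[dec$offset == 0], "C")        # invariant C at 0
  expect_true(all(dec$decile %in% seq(40L, 90L, 10L)))
  # flooring is idempotent on the decile scale
  expect_identical(ppredit:::decile_of(dec$decile / 100), dec$decile)
  # column sums are 1 where data exist
  sums <- colSums(prof$freq)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9))
  expect_error(build_profile(wins[0, ]), "at least one window")
})

test_that("a 0.43 dominant frequency thresholds at decile 40", {
  prof <- profile_with(list(`-14` = c(A = 0.43)))
  dec <- prof$decile
  expect_identical(dec$nt[dec$offset == -14], "A")
  expect_identical(dec$decile[dec$offset == -14], 40L)
  # uniform offsets are not thresholded
  expect_false(-13 %in% dec$offset)
})

test_that("an exact tie at threshold is not thresholded", {
  prof <- profile_with(list(`-5` = c(A = 0.45, G = 0.45, C = 0.05, T = 0.05)))
  expect_false(-5 %in% prof$decile$offset)
})

test_that("deduplication counts identical windows once per gene", {
  seq36 <- paste(c(rep("A", 30), "C", rep("G", 5)), collapse = "")
  w <- rbind(
    target_window(seq36, gene = "g1", transcript_id = "t1"),
    target_window(seq36, gene = "g1", transcript_id = "t2"),  # variant, dup
    target_window(seq36, gene = "g2", transcript_id = "t3")   # other gene
  )
  prof <- build_profile(w, dedupe = TRUE)
  expect_identical(prof$n_windows, 2L)
  prof_all <- build_profile(w, dedupe = FALSE)
  expect_identical(prof_all$n_windows, 3L)
})

test_that("build_profile is permutation-invariant in its windows", {
  set.seed(5)
  wins <- windows_biased(40, at = list(`-13` = "G"), p = 0.8)
  p1 <- build_profile(wins)
  p2 <- build_profile(wins[sample(nrow(wins)), ])
  expect_equal(p1$freq, p2$freq)
  expect_identical(p1$decile, p2$decile)
})

test_that("matching scores reproduce the worked per-position weights", {
  # an A at -14 over a 0.43 consensus contributes 40
  p40 <- profile_with(list(`-14` = c(A = 0.43)))
  expect_identical(matching_score(window_with(list(`-14` = "A")), p40), 40L)
  expect_identical(matching_score(window_with(list(`-14` = "G")), p40), 0L)
  # a G at -13 over a 0.74 consensus contributes 70
  p70 <- profile_with(list(`-13` = c(G = 0.74)))
  expect_identical(matching_score(window_with(list(`-13` = "G")), p70), 70L)
  # both positions together sum, and equal the profile maximum
  p <- profile_with(list(`-14` = c(A = 0.43), `-13` = c(G = 0.74)))
  expect_identical(max_score(p), 110L)
  expect_identical(
    matching_score(window_with(list(`-14` = "A", `-13` = "G")), p), 110L)
  expect_error(matching_score(window_with(list(), lo = -10L), p40),
               "does not cover")
})

test_that("matching_score equals a position-by-position loop oracle", {
  set.seed(17)
  for (rep in 1:20) {
    wins <- windows_biased(30, at = list(`-10` = "G", `-6` = "T"),
                           p = stats::runif(1, 0.3, 0.9))
    prof <- build_profile(wins)
    w <- random_window()
    expected <- 0L
    for (k in seq_len(nrow(prof$decile))) {
      off <- prof$decile$offset[k]
      if (window_base(w, off) == prof$decile$nt[k]) {
        expected <- expected + prof$decile$decile[k]
      }
    }
    expect_identical(matching_score(w, prof), expected)
    expect_lte(matching_score(w, prof), max_score(prof))
  }
})

test_that("converting one thresholded offset to matching adds its decile", {
  prof <- profile_with(list(`-14` = c(A = 0.43), `-13` = c(G = 0.74),
                            `-9` = c(T = 0.58)))
  w <- window_with(list(`-14` = "A", `-13` = "C", `-9` = "C"))
  s0 <- matching_score(w, prof)
  w2 <- window_with(list(`-14` = "A", `-13` = "G", `-9` = "C"))
  expect_identical(matching_score(w2, prof), s0 + 70L)
})

test_that("the consensus-matching window achieves the maximum score", {
  set.seed(23)
  wins <- windows_biased(50, at = list(`-13` = "G", `-10` = "G", `-4` = "T"),
                         p = 0.7)
  prof <- build_profile(wins)
  cw <- consensus_window(prof)
  expect_identical(matching_score(cw, prof), max_score(prof))
  empty <- profile_with(list())
  expect_identical(max_score(empty), 0L)
})

test_that("consensus strings mix case by threshold and dot uniform offsets", {
  prof <- profile_with(list(`-14` = c(A = 0.43),
                            `-3` = c(T = 0.38, A = 0.22, C = 0.2, G = 0.2)))
  s <- consensus_string(prof)
  chars <- strsplit(s, "")[[1]]
  offsets <- seq.int(prof$bounds[1], prof$bounds[2])
  expect_identical(chars[match(-14, offsets)], "A")  # thresholded: upper
  expect_identical(chars[match(-3, offsets)], "t")   # dominant below: lower
  expect_identical(chars[match(-5, offsets)], ".")   # uniform
})

test_that("profile shifts report exactly the planted consensus changes", {
  a <- profile_with(list(`-10` = c(G = 0.62), `-7` = c(A = 0.55),
                         `-4` = c(T = 0.81)))
  expect_identical(nrow(profile_shift_report(a, a)), 0L)

  # single shift at -10: G -> A, as in a retargeted S-type repeat
  b1 <- profile_with(list(`-10` = c(A = 0.62), `-7` = c(A = 0.55),
                          `-4` = c(T = 0.81)))
  r1 <- profile_shift_report(a, b1)
  expect_identical(r1$offset, -10L)
  expect_identical(r1$nt_a, "G")
  expect_identical(r1$nt_b, "A")

  # three planted differences: changed nt, changed decile, lost threshold
  b3 <- profile_with(list(`-10` = c(A = 0.62), `-7` = c(A = 0.71),
                          `-4` = c(T = 0.3)))
  expect_identical(profile_shift_report(a, b3)$offset, c(-10L, -7L, -4L))

  short <- profile_with(list(), bounds = c(-10L, 5L))
  expect_error(profile_shift_report(a, short), "bounds")
})

test_that("profiles and window sets round-trip through TSV", {
  set.seed(29)
  wins <- windows_biased(20, at = list(`-13` = "G"), p = 0.9)
  wins$rate <- round(stats::runif(20), 3)
  prof <- build_profile(wins)

  wpath <- withr::local_tempfile(fileext = ".tsv")
  write_windows(wins, wpath)
  back <- read_windows(wpath)
  expect_identical(back$sequence, wins$sequence)
  expect_identical(back$lo, wins$lo)
  expect_equal(back$rate, wins$rate)

  ppath <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, ppath)
  pback <- read_profile(ppath)
  expect_equal(pback$freq, prof$freq)
  expect_identical(pback$decile, prof$decile)

  mpath <- withr::local_tempfile(fileext = ".txt")
  write_pfm_meme(prof, mpath)
  expect_true(any(grepl("letter-probability matrix", readLines(mpath))))
})
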