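test_that("PSPM from aligned sites gives per-position residue fractions", {
  m <- slim57_pspm()
  expect_equal(m$width, 9L)
  expect_equal(unname(m$matrix[5, "C"]), 0.5)
  expect_equal(unname(m$matrix[5, "I"]), 0.5)
  expect_equal(unname(m$matrix[1, "L"]), 1)
  expect_equal(sum(m$matrix[1, setdiff(aa_alphabet(), "L")]), 0)
  expect_equal(unname(m$matrix[9, "C"]), 1)

  single <- build_pspm("AAAA", "mono")
  expect_equal(unname(single$matrix[, "A"]), rep(1, 4))

  expect_error(build_pspm(c("AAA", "AAAA"), "bad"), "unequal")
  expect_error(build_pspm(character(0), "bad"), "no sites")
  expect_error(build_pspm("AXB", "bad"), "non-standard")
})

test_that("PSPM rows always sum to exactly 1 for rational counts", {
  set.seed(11)
  for (rep in 1:10) {
    w <- sample(3:9, 1)
    n <- sample(2:12, 1)
    sites <- vapply(seq_len(n), function(i) random_seq(w), character(1))
    m <- build_pspm(sites, "r")
    expect_identical(unname(rowSums(m$matrix)), rep(1, w))
  }
})

test_that("pattern compilation produces reciprocal-class-size scores", {
  m <- compile_pattern("[IL]QxW")
  expect_equal(m$width, 4L)
  expect_equal(m$position_scores, c(0.5, 1, 1, 1))

  m2 <- compile_pattern("LTEY[IC]QGPC")
  expect_equal(m2$width, 9L)
  expect_equal(m2$position_scores,
               c(1, 1, 1, 1, 0.5, 1, 1, 1, 1))

  m3 <- compile_pattern("xxxx")
  expect_equal(m3$width, 4L)
  expect_equal(m3$position_scores, rep(1, 4))
  expect_equal(score_window_re("WYCA", m3), 4)

  expect_error(compile_pattern("[ILQ"), "unbalanced")
  expect_error(compile_pattern("A]Q"), "unbalanced")
  expect_error(compile_pattern("[]Q"), "empty class")
  expect_error(compile_pattern("A1Q"), "illegal character")
})

test_that("word count of a pattern equals the product of class sizes", {
  set.seed(3)
  for (rep in 1:8) {
    # keep the enumeration small: classes only, few positions
    w <- sample(2:4, 1)
    pat <- paste(vapply(seq_len(w), function(i) {
      paste0("[", paste(sample(AA, sample(2:4, 1)), collapse = ""), "]")
    }, character(1)), collapse = "")
    m <- compile_pattern(pat)
    words <- do.call(expand.grid, m$positions)
    n_words <- nrow(unique(words))
    expect_equal(n_words, prod(lengths(m$positions)))
    matches <- apply(words, 1, function(rw)
      score_window_re(paste(rw, collapse = ""), m) > 0)
    expect_true(all(matches))
  }
})

test_that("the canonical CaM-binding registry holds the 14 known motifs", {
  reg <- canonical_motifs()
  expect_equal(length(reg), 14L)
  expect_setequal(reg$ids,
    c("1-10", "1-5-10", "Basic 1-5-10", "1-12", "1-14", "1-8-14",
      "1-5-8-14", "Basic 1-8-14", "1-16", "IQ", "IQ-like", "IQ-2A",
      "IQ-2B", "IQ unconventional"))
  iq <- reg$motifs[[which(reg$ids == "IQ")]]
  expect_equal(iq$pattern, "[FILV]Qxxx[RK]Gxxx[RK]xx[FILVWY]")
  expect_equal(iq$width, 14L)
  m110 <- reg$motifs[[which(reg$ids == "1-10")]]
  expect_equal(m110$width, 10L)
  expect_equal(m110$position_scores[c(1, 10)], c(0.2, 0.2))
  expect_equal(m110$position_scores[2:9], rep(1, 8))
})

test_that("occupancy counting uses a strict threshold", {
  m <- slim57_pspm()
  occ <- occupancy_profile(m, 0.5, classes = list(cys = "C"))
  # position 9 is all-C; position 5 sits exactly at 0.5 and is excluded
  expect_identical(occ$positions$cys, 9L)
  expect_identical(unname(occ$counts), 1L)

  all20 <- occupancy_profile(m, 0.5, classes = list(all = aa_alphabet()))
  expect_identical(unname(all20$counts), m$width)

  unif <- pspm_motif(matrix(1 / 20, 4, 20,
                            dimnames = list(NULL, aa_alphabet())), "u")
  half <- occupancy_profile(unif, 0.5,
                            classes = list(ten = aa_alphabet()[1:10]))
  expect_identical(unname(half$counts), 0L)

  expect_error(occupancy_profile(m, classes = list(bad = "1")), "unknown")
})

test_that("MEME text round-trips PSPMs and rejects malformed blocks", {
  set.seed(5)
  motifs <- list(slim57_pspm(), random_pspm(6, "rand6"))
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme_motifs(motifs, f)
  back <- parse_meme_motifs(f)
  expect_equal(length(back), 2L)
  for (i in 1:2) {
    expect_equal(back$motifs[[i]]$id, motifs[[i]]$id)
    expect_lt(max(abs(back$motifs[[i]]$matrix - motifs[[i]]$matrix)),
              1e-6)
  }

  # declared width 9 but only 8 rows
  lines <- readLines(f)
  hdr <- grep("w= 9", lines)[1]
  bad <- withr::local_tempfile(fileext = ".meme")
  writeLines(lines[-(hdr + 9)], bad)
  expect_error(parse_meme_motifs(bad), "expected 9 matrix rows")

  # no alphabet declaration
  noalpha <- withr::local_tempfile(fileext = ".meme")
  writeLines(lines[!grepl("^ALPHABET", lines)], noalpha)
  expect_error(parse_meme_motifs(noalpha), "ALPHABET")

  # zero blocks -> empty set with warning
  none <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "",
               paste0("ALPHABET= ", paste(aa_alphabet(), collapse = ""))),
             none)
  expect_warning(ms <- parse_meme_motifs(none), "no letter-probability")
  expect_equal(length(ms), 0L)

  # a row sum far from 1 is an error naming motif and row
  broken <- readLines(f)
  data_rows <- grep("^[0-9]", broken)
  broken[data_rows[1]] <- paste(rep("0.100000", 20), collapse = " ")
  badsum <- withr::local_tempfile(fileext = ".meme")
  writeLines(broken, badsum)
  expect_error(parse_meme_motifs(badsum), "SLiM#57.*row")
})

test_that("column order is remapped from the declared alphabet", {
  m <- slim57_pspm()
  # write with a scrambled alphabet by permuting columns and the header
  perm <- rev(seq_len(20))
  f <- withr::local_tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "",
    paste0("ALPHABET= ", paste(rev(aa_alphabet()), collapse = "")), "",
    "MOTIF scrambled",
    "letter-probability matrix: alength= 20 w= 9 nsites= 6 E= 0",
    apply(m$matrix[, perm], 1, function(r)
      paste(sprintf("%.6f", r), collapse = " "))), f)
  back <- parse_meme_motifs(f)
  expect_lt(max(abs(back$motifs[[1]]$matrix - m$matrix)), 1e-6)
})
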