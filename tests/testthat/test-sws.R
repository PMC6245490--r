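test_that("PPM window scores reproduce the worked example", {
  m <- slim57_pspm()
  expect_equal(score_window_ppm("LTEYIQGPC", m), 8.5)
  expect_equal(score_window_ppm("LTEYCQGPC", m), 8.5)
  expect_equal(score_window_ppm("AAAAAAAAA", m), 0)
  unif <- pspm_motif(matrix(1 / 20, 9, 20,
                            dimnames = list(NULL, aa_alphabet())), "u")
  expect_equal(score_window_ppm("LTEYIQGPC", unif), 0.45)
  expect_error(score_window_ppm("SHORT", m), "width")
})

test_that("true-site threshold is a fraction of the maximal score, inclusive", {
  expect_true(is_true_site(8.5, 9, 0.6))   # 8.5 >= 5.4
  expect_true(is_true_site(5.4, 9, 0.6))   # boundary is inclusive
  expect_false(is_true_site(5.3999, 9, 0.6))
  expect_false(is_true_site(0, 9, 0.6))
})

test_that("protein-level PPM scoring sums true sites into S, N, T", {
  m <- slim57_pspm()
  one <- score_protein_ppm("LTEYIQGPC", m)
  expect_equal(one[c("S", "N", "T")], list(S = 8.5, N = 1L, T = 8.5))

  two <- score_protein_ppm("LTEYIQGPCLTEYCQGPC", m)
  expect_equal(two[c("S", "N", "T")], list(S = 17, N = 2L, T = 8.5))

  none <- score_protein_ppm(strrep("A", 50), m)
  expect_equal(none[c("S", "N", "T")], list(S = 0, N = 0L, T = 0))

  short <- score_protein_ppm("LTEY", m)  # W > L: zero windows
  expect_equal(short$N, 0L)
})

test_that("RE window scoring is all-or-nothing with reciprocal scores", {
  m <- compile_pattern("[IL]QxW")
  expect_equal(score_window_re("IQAW", m), 3.5)
  expect_equal(score_window_re("LQCW", m), 3.5)
  expect_equal(score_window_re("AQAW", m), 0)
  expect_error(score_window_re("IQA", m), "width")

  p <- score_protein_re("IQAWIQAW", m)
  expect_equal(p[c("S", "N", "T")], list(S = 7, N = 2L, T = 3.5))
  expect_equal(score_protein_re("GGGG", m)$S, 0)
  wild <- score_protein_re("IQAW", compile_pattern("xxxx"))
  expect_equal(wild[c("S", "N")], list(S = 4, N = 1L))
})

test_that("non-standard residues score zero and never match", {
  m <- slim57_pspm()
  expect_equal(score_window_ppm("XTEYIQGPC", m), 7.5)
  r <- compile_pattern("xQ")
  expect_equal(score_window_re("XQ", r), 0)  # even wildcards reject X
})

test_that("PPM scoring matches a literal brute-force oracle", {
  set.seed(101)
  for (rep in 1:60) {
    W <- sample(2:6, 1)
    L <- sample(W:50, 1)
    motif <- random_pspm(W, concentrated = sample(c(TRUE, FALSE), 1))
    s <- random_seq(L, alphabet = c(AA, "X", "B"))
    tau <- sample(c(0.3, 0.6, 0.9), 1)
    got <- score_protein_ppm(s, motif, tau)
    want <- oracle_ppm(s, motif, tau)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$N, want$N)
    expect_equal(got$T, want$T, tolerance = 1e-12)
  }
})

test_that("RE match offsets equal those of the PCRE engine", {
  set.seed(202)
  for (rep in 1:60) {
    W <- sample(2:6, 1)
    pat <- random_pattern(W)
    motif <- compile_pattern(pat)
    # bias the sequence toward matches by splicing in sampled sites
    s <- random_seq(sample(W:60, 1))
    got <- score_protein_re(s, motif)
    offs <- oracle_re_offsets(s, pat)
    expect_equal(got$N, length(offs))
    expect_equal(got$S, length(offs) * sum(motif$position_scores))
  }
})

test_that("window score bounds and S = N * T consistency hold", {
  set.seed(303)
  for (rep in 1:30) {
    W <- sample(2:8, 1)
    motif <- random_pspm(W, concentrated = TRUE)
    s <- random_seq(sample(W:80, 1))
    r <- score_protein_ppm(s, motif, tau = 0.3)
    if (r$N >= 1) {
      expect_equal(r$S, r$N * r$T, tolerance = 1e-12)
      expect_gte(r$S, r$T - 1e-12)
    } else {
      expect_identical(r$T, 0)
    }
    ws <- vapply(enumerate_windows(s, W)$window, score_window_ppm,
                 numeric(1), motif = motif)
    expect_true(all(ws >= 0 & ws <= W + 1e-12))
  }
})

test_that("lowering tau never decreases S or N", {
  set.seed(404)
  for (rep in 1:10) {
    motif <- random_pspm(4, concentrated = TRUE)
    s <- random_seq(60)
    taus <- c(0.9, 0.6, 0.3, 0.1)
    res <- lapply(taus, function(t) score_protein_ppm(s, motif, t))
    S <- vapply(res, `[[`, numeric(1), "S")
    N <- vapply(res, `[[`, numeric(1), "N")
    expect_true(all(diff(S) >= -1e-12))
    expect_true(all(diff(N) >= 0))
  }
})

test_that("score matrices respect row/column order and method kinds", {
  m <- slim57_pspm()
  ps <- protein_set("P1", "LTEYIQGPC")
  sm <- build_score_matrix(ps, motif_set(list(m)), scoring_config("ppm"))
  expect_equal(unname(sm$scores[1, 1]), 8.5)
  smT <- build_score_matrix(ps, motif_set(list(m)),
                            scoring_config("ppm", "T"))
  expect_equal(unname(smT$scores[1, 1]), 8.5)  # N = 1 so S = T

  # mismatched motif kind names the motif
  expect_error(
    build_score_matrix(ps, motif_set(list(compile_pattern("[IL]Q"))),
                       scoring_config("ppm")),
    "\\[IL\\]Q")

  # permutation equivariance over proteins and motifs
  set.seed(9)
  ps4 <- protein_set(paste0("P", 1:4),
                     vapply(rep(40, 4), random_seq, character(1)))
  motifs <- motif_set(lapply(1:3, function(i)
    random_pspm(3, paste0("m", i), concentrated = TRUE)))
  base <- build_score_matrix(ps4, motifs, scoring_config("ppm", tau = 0.3))
  perm <- c(3, 1, 4, 2)
  permuted <- build_score_matrix(
    protein_set(ps4$id[perm], ps4$sequence[perm]), motifs,
    scoring_config("ppm", tau = 0.3))
  expect_equal(permuted$scores, base$scores[perm, ])
  mperm <- c(2, 3, 1)
  permuted_m <- build_score_matrix(
    ps4, motif_set(motifs$motifs[mperm]),
    scoring_config("ppm", tau = 0.3))
  expect_equal(permuted_m$scores, base$scores[, mperm])
})

test_that("score-matrix TSV round-trips values, labels and metadata", {
  set.seed(12)
  ps <- protein_set(paste0("P", 1:3),
                    vapply(rep(30, 3), random_seq, character(1)))
  ds <- labeled_dataset(ps, stats::setNames(c(1L, 0L, 1L), ps$id))
  sm <- build_score_matrix(ds, canonical_motifs(), scoring_config("re"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_score_matrix(sm, f)
  back <- read_score_matrix(f)
  expect_equal(back$scores, sm$scores, tolerance = 1e-5)
  expect_identical(back$labels, sm$labels)
  expect_identical(back$method, sm$method)
  expect_identical(back$variant, sm$variant)
})
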