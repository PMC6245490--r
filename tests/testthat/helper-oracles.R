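# Independent brute-force oracles and random-input generators used by the
# property tests. The oracles deliberately share no code with the package
# internals: windows are cut with substring, scores summed per character,
# and regex matching is delegated to R's PCRE engine.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(len, alphabet = AA) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# random PSPM via Dirichlet-like normalized uniforms
random_pspm <- function(w, id = "rand", concentrated = FALSE) {
  mat <- matrix(stats::runif(w * 20)^(if (concentrated) 8 else 1),
                nrow = w, ncol = 20)
  mat <- mat / rowSums(mat)
  colnames(mat) <- AA
  pspm_motif(mat, id)
}

# random SLiM-syntax pattern of width w
random_pattern <- function(w) {
  paste(vapply(seq_len(w), function(i) {
    kind <- sample(c("fixed", "class", "wild"), 1L,
                   prob = c(0.4, 0.3, 0.3))
    switch(kind,
      fixed = sample(AA, 1L),
      class = paste0("[", paste(sample(AA, sample(2:5, 1L)),
                                collapse = ""), "]"),
      wild = "x")
  }, character(1L)), collapse = "")
}

# literal implementation of the window score and S/N/T aggregation
oracle_ppm <- function(sequence, motif, tau = 0.6) {
  W <- motif$width
  L <- nchar(sequence)
  scores <- c()
  if (L >= W) {
    for (off in 0:(L - W)) {
      lmer <- substring(sequence, off + 1, off + W)
      s <- 0
      for (i in seq_len(W)) {
        aa <- substring(lmer, i, i)
        if (aa %in% AA) s <- s + motif$matrix[i, aa]
      }
      scores <- c(scores, s)
    }
  }
  sites <- scores[scores >= tau * W]
  N <- length(sites)
  list(S = sum(sites), N = N, T = if (N > 0) sum(sites) / N else 0)
}

# translate a SLiM pattern to PCRE and find all (overlapping) match
# offsets with a lookahead
oracle_re_offsets <- function(sequence, pattern) {
  pcre <- gsub("x", ".", pattern)
  hits <- gregexpr(paste0("(?=", pcre, ")"), sequence, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
}

# the SLiM #57 worked-example motif: two site variants, equal multiplicity
slim57_pspm <- function() {
  build_pspm(rep(c("LTEYIQGPC", "LTEYCQGPC"), 3L), "SLiM#57")
}
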