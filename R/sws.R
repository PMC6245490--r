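# Sliding-window scoring (SWS). A protein sequence of length L is cut into
# all L-W+1 overlapping windows of motif width W. SWS_PPM scores a window
# against a probability matrix as the sum over positions of the probability
# of the observed residue; windows reaching the fraction tau of the maximal
# attainable score W are true sites. SWS_RE scores a window against a
# regular-expression motif: a non-matching window scores 0, a matching one
# scores the sum of reciprocal-class-size position scores. Per protein and
# motif, S is the total over true sites and T = S / N their average.

#' Scoring configuration
#'
#' @param method `"ppm"` (probability-matrix scoring) or `"re"`
#'   (regular-expression scoring).
#' @param variant `"S"` (total score over true sites) or `"T"` (average).
#' @param tau True-site threshold as a fraction of the maximal window score
#'   `W`; a window is a true site when its score is `>= tau * W`. Only used
#'   by the PPM method — for RE scoring, pattern match alone defines a site.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(method = c("ppm", "re"), variant = c("S", "T"),
                           tau = 0.6) {
  method <- match.arg(method)
  variant <- match.arg(variant)
  stopifnot(tau > 0, tau <= 1)
  structure(list(method = method, variant = variant, tau = tau),
            class = "scoring_config")
}

#' Score one window against a PSPM
#'
#' The information content of an l-mer `a` given matrix `X` is the sum over
#' positions of the probability of the observed residue,
#' `sum_i X[i, a_i]`, in `[0, W]`. Non-standard residues contribute 0.
#'
#' @param window An l-mer of exactly the motif width.
#' @param motif A [pspm_motif()].
#' @return Numeric window score.
#' @export
#' @examples
#' m <- build_pspm(c("LTEYIQGPC", "LTEYCQGPC"), "SLiM#57")
#' score_window_ppm("LTEYIQGPC", m)  # 8.5
score_window_ppm <- function(window, motif) {
  stopifnot(inherits(motif, "pspm_motif"))
  chars <- .seq_chars(toupper(window))
  if (length(chars) != motif$width) {
    stop("window length ", length(chars), " != motif width ", motif$width,
         call. = FALSE)
  }
  col <- match(chars, aa_alphabet())
  keep <- !is.na(col)
  sum(motif$matrix[cbind(which(keep), col[keep])])
}

#' True-site decision for a PPM window score
#'
#' A window is a true site when its score reaches the fraction `tau` of the
#' maximal attainable score `W` (the sum of W probabilities is at most W),
#' i.e. `score >= tau * W`, inclusive.
#'
#' @param score Window score in `[0, W]`.
#' @param w Motif width.
#' @param tau Threshold fraction (default 0.6).
#' @return Logical.
#' @export
is_true_site <- function(score, w, tau = 0.6) {
  score >= tau * w
}

#' Score one protein against a PSPM
#'
#' Applies [score_window_ppm()] to every window, keeps the true sites
#' ([is_true_site()]), and returns their total `S`, count `N` and average
#' `T = S / N` (`T = 0` when no window passes — the average is undefined at
#' `N = 0` and the zero convention keeps feature vectors total).
#'
#' @param sequence Protein sequence string (`W > L` allowed: zero windows).
#' @param motif A [pspm_motif()].
#' @param tau True-site threshold fraction.
#' @return List with `S`, `N`, `T`.
#' @export
score_protein_ppm <- function(sequence, motif, tau = 0.6) {
  stopifnot(inherits(motif, "pspm_motif"))
  scores <- .window_scores_ppm(toupper(sequence), motif)
  sites <- scores[is_true_site(scores, motif$width, tau)]
  .aggregate_sites(sites)
}

# vectorized window scores for one sequence: O(L * W)
.window_scores_ppm <- function(sequence, motif) {
  L <- nchar(sequence)
  W <- motif$width
  n <- L - W + 1L
  if (n < 1L) return(numeric(0))
  col <- match(.seq_chars(sequence), aa_alphabet())  # NA for non-standard
  out <- numeric(n)
  for (i in seq_len(W)) {
    ci <- col[i:(i + n - 1L)]
    p <- ifelse(is.na(ci), 0, motif$matrix[i, ][ci])
    p[is.na(p)] <- 0
    out <- out + p
  }
  out
}

.aggregate_sites <- function(site_scores) {
  N <- length(site_scores)
  S <- sum(site_scores)
  list(S = S, N = N, T = if (N > 0L) S / N else 0)
}

#' Score one window against a regular-expression motif
#'
#' A window whose residue at any position falls outside that position's
#' admissible set is not a site and scores 0. A matching window scores the
#' sum of the motif's position scores (reciprocal class sizes, wildcard 1).
#' Non-standard residues never match any position.
#'
#' @param window An l-mer of exactly the motif width.
#' @param motif A [regex_motif][compile_pattern()].
#' @return Numeric window score (0 or the fixed match score).
#' @export
#' @examples
#' m <- compile_pattern("[IL]QxW")
#' score_window_re("IQAW", m)  # 3.5
#' score_window_re("AQAW", m)  # 0
score_window_re <- function(window, motif) {
  stopifnot(inherits(motif, "regex_motif"))
  chars <- .seq_chars(toupper(window))
  if (length(chars) != motif$width) {
    stop("window length ", length(chars), " != motif width ", motif$width,
         call. = FALSE)
  }
  for (i in seq_along(chars)) {
    if (!chars[i] %in% motif$positions[[i]]) return(0)
  }
  sum(motif$position_scores)
}

#' Score one protein against a regular-expression motif
#'
#' Every window offset is tested (overlapping matches allowed); `S` is the
#' sum of scores of matching windows, `N` their count, `T = S / N` (0 when
#' no window matches). Since every match carries the same fixed score,
#' `T` equals that score whenever `N >= 1`.
#'
#' @param sequence Protein sequence string.
#' @param motif A [regex_motif][compile_pattern()].
#' @return List with `S`, `N`, `T`.
#' @export
score_protein_re <- function(sequence, motif) {
  stopifnot(inherits(motif, "regex_motif"))
  hits <- .match_offsets_re(toupper(sequence), motif)
  .aggregate_sites(rep(sum(motif$position_scores), length(hits)))
}

# 0-based offsets of all matching windows (set-membership test per position)
.match_offsets_re <- function(sequence, motif) {
  L <- nchar(sequence)
  W <- motif$width
  n <- L - W + 1L
  if (n < 1L) return(integer(0))
  chars <- .seq_chars(sequence)
  ok <- rep(TRUE, n)
  for (i in seq_len(W)) {
    ok <- ok & chars[i:(i + n - 1L)] %in% motif$positions[[i]]
  }
  which(ok) - 1L
}

#' Build a proteins x motifs score matrix
#'
#' Transforms every protein into its feature vector over the motif set:
#' entry (i, j) is the S (total) or T (averaged) score of protein i against
#' motif j under the configured method. Row order follows the dataset,
#' column order the motif set.
#'
#' @param dataset A [labeled_dataset()] or a `protein_set`.
#' @param motifs A [motif_set()]; all motifs must match the method (PSPM
#'   motifs for `"ppm"`, regex motifs for `"re"`).
#' @param config A [scoring_config()].
#' @return An object of class `sws_score_matrix`: list with `scores`
#'   (numeric matrix, dimnames = protein ids x motif ids), `labels`
#'   (integer vector or NULL), `method`, `variant`, `tau`.
#' @export
build_score_matrix <- function(dataset, motifs, config = scoring_config()) {
  stopifnot(inherits(motifs, "motif_set"), length(motifs) > 0L,
            inherits(config, "scoring_config"))
  if (inherits(dataset, "labeled_dataset")) {
    proteins <- dataset$proteins
    labels <- dataset$labels
  } else {
    proteins <- dataset
    labels <- NULL
  }
  want <- if (config$method == "ppm") "pspm_motif" else "regex_motif"
  for (m in motifs$motifs) {
    if (!inherits(m, want)) {
      stop("motif '", m$id, "' is not a ",
           if (config$method == "ppm") "PSPM" else "regex pattern",
           " as required by method SWS_",
           toupper(config$method), call. = FALSE)
    }
  }
  vals <- vapply(motifs$motifs, function(m) {
    vapply(proteins$sequence, function(s) {
      r <- if (config$method == "ppm") {
        score_protein_ppm(s, m, config$tau)
      } else {
        score_protein_re(s, m)
      }
      r[[config$variant]]
    }, numeric(1L), USE.NAMES = FALSE)
  }, numeric(nrow(proteins)))
  vals <- matrix(vals, nrow = nrow(proteins), ncol = length(motifs),
                 dimnames = list(proteins$id, motifs$ids))
  structure(
    list(scores = vals, labels = labels, method = config$method,
         variant = config$variant, tau = config$tau),
    class = "sws_score_matrix"
  )
}

#' @export
print.sws_score_matrix <- function(x, ...) {
  cat(sprintf("sws_score_matrix: %d protein(s) x %d motif(s), SWS_%s, %s scores, tau=%g\n",
              nrow(x$scores), ncol(x$scores), toupper(x$method), x$variant,
              x$tau))
  invisible(x)
}

#' Write a score matrix as TSV
#'
#' One row per protein, columns `protein_id`, optional `label`, then one
#' column per motif (6 significant digits). A metadata comment line records
#' method, variant and tau.
#'
#' @param sm An `sws_score_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method=SWS_%s variant=%s tau=%g",
                     toupper(sm$method), sm$variant, sm$tau), con)
  df <- data.frame(protein_id = rownames(sm$scores),
                   stringsAsFactors = FALSE)
  if (!is.null(sm$labels)) df$label <- sm$labels
  df <- cbind(df, as.data.frame(signif(sm$scores, 6)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score matrix TSV written by [write_score_matrix()]
#'
#' @param path Input path.
#' @return An `sws_score_matrix`.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  method <- "ppm"; variant <- "S"; tau <- 0.6
  if (length(meta) > 0L) {
    get <- function(key) {
      m <- regmatches(meta[1L],
                      regexpr(paste0(key, "=[^ ]+"), meta[1L]))
      if (length(m) == 0L) NA_character_ else sub(".*=", "", m)
    }
    mv <- get("method"); if (!is.na(mv)) method <- tolower(sub("SWS_", "", mv))
    vv <- get("variant"); if (!is.na(vv)) variant <- vv
    tv <- get("tau"); if (!is.na(tv)) tau <- as.numeric(tv)
  }
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.integer(df$label)
    df$label <- NULL
  }
  mat <- as.matrix(df[, setdiff(names(df), "protein_id"), drop = FALSE])
  rownames(mat) <- df$protein_id
  structure(list(scores = mat, labels = labels, method = method,
                 variant = variant, tau = tau),
            class = "sws_score_matrix")
}
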