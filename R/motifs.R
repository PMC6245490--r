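#' Construct a position-specific probability motif (PSPM)
#'
#' A width-W motif represented as a W x 20 matrix of residue probabilities,
#' columns in canonical alphabet order ([aa_alphabet()]). Every row must sum
#' to 1 (within `1e-9` after optional renormalization by the callers that
#' read external files).
#'
#' @param matrix Numeric W x 20 matrix; columns named by residue letters
#'   (any order; reordered to canonical) or unnamed (assumed canonical).
#' @param id Motif identifier.
#' @param consensus Optional consensus/pattern string.
#' @return An object of class `pspm_motif` with fields `id`, `width`,
#'   `matrix`, `consensus`.
#' @export
pspm_motif <- function(matrix, id, consensus = NULL) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 20L) {
    stop("PSPM must have 20 columns, got ", ncol(matrix), call. = FALSE)
  }
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- aa_alphabet()
  } else {
    if (!setequal(colnames(matrix), aa_alphabet())) {
      stop("PSPM columns must be the 20 standard residues", call. = FALSE)
    }
    matrix <- matrix[, aa_alphabet(), drop = FALSE]
  }
  if (nrow(matrix) < 1L) stop("PSPM must have >= 1 row", call. = FALSE)
  if (any(matrix < 0 | matrix > 1)) {
    stop("PSPM entries must lie in [0, 1]", call. = FALSE)
  }
  sums <- rowSums(matrix)
  bad <- which(abs(sums - 1) > 1e-9)
  if (length(bad) > 0L) {
    stop("PSPM '", id, "' row(s) ", paste(bad, collapse = ", "),
         " do not sum to 1", call. = FALSE)
  }
  rownames(matrix) <- NULL
  structure(
    list(id = as.character(id), width = nrow(matrix), matrix = matrix,
         consensus = consensus),
    class = "pspm_motif"
  )
}

#' Estimate a PSPM from aligned motif sites
#'
#' Each matrix entry is the fraction of sites carrying that residue at that
#' position, so rows sum to exactly 1 (rational counts).
#'
#' @param sites Character vector of equal-length site strings (standard
#'   residues only). Repeats count with their multiplicity.
#' @param id Motif identifier.
#' @return A [pspm_motif()].
#' @export
#' @examples
#' # a 9-residue SLiM observed as two variants with equal multiplicity:
#' m <- build_pspm(rep(c("LTEYIQGPC", "LTEYCQGPC"), 3), "SLiM#57")
#' m$matrix[5, c("C", "I")]  # 0.5 and 0.5
#' m$matrix[1, "L"]          # 1
build_pspm <- function(sites, id) {
  if (length(sites) == 0L) stop("no sites supplied", call. = FALSE)
  sites <- toupper(sites)
  w <- nchar(sites[1L])
  if (any(nchar(sites) != w)) {
    stop("sites have unequal lengths", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  if (any(!.is_standard(chars))) {
    stop("non-standard residue(s) in sites: ",
         paste(unique(chars[!.is_standard(chars)]), collapse = ", "),
         call. = FALSE)
  }
  counts <- vapply(
    seq_len(w),
    function(i) tabulate(factor(chars[, i], levels = aa_alphabet()),
                         nbins = 20L),
    numeric(20L)
  )
  mat <- t(counts) / length(sites)
  colnames(mat) <- aa_alphabet()
  pspm_motif(mat, id)
}

#' Compile a regular-expression motif pattern
#'
#' Patterns use the SLiM syntax: a single residue letter fixes a position, a
#' bracket class `[...]` admits any listed residue, and `x` (or `X`) is a
#' wildcard admitting all 20 residues. Each position carries the score
#' `1 / (number of admissible residues)`, except wildcards which score 1.
#'
#' @param pattern Pattern string, e.g. `"[IL]QxW"`.
#' @param id Motif identifier (defaults to the pattern itself).
#' @return An object of class `regex_motif` with fields `id`, `width`,
#'   `pattern`, `positions` (list of admissible residue sets) and
#'   `position_scores`.
#' @export
#' @examples
#' m <- compile_pattern("[IL]QxW")
#' m$position_scores  # 0.5 1 1 1
compile_pattern <- function(pattern, id = pattern) {
  chars <- .seq_chars(pattern)
  if (length(chars) == 0L) stop("empty pattern", call. = FALSE)
  positions <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- NULL
      j <- i + 1L
      while (j <= length(chars)) {
        if (chars[j] == "]") { close <- j; break }
        j <- j + 1L
      }
      if (is.null(close)) {
        stop("unbalanced '[' in pattern '", pattern, "'", call. = FALSE)
      }
      if (close == i + 1L) {
        stop("empty class '[]' in pattern '", pattern, "'", call. = FALSE)
      }
      members <- unique(toupper(chars[(i + 1L):(close - 1L)]))
      if (any(!members %in% aa_alphabet())) {
        stop("illegal residue(s) in class: ",
             paste(members[!members %in% aa_alphabet()], collapse = ", "),
             call. = FALSE)
      }
      positions[[length(positions) + 1L]] <- members
      i <- close + 1L
    } else if (ch == "]") {
      stop("unbalanced ']' in pattern '", pattern, "'", call. = FALSE)
    } else if (toupper(ch) == "X") {
      positions[[length(positions) + 1L]] <- aa_alphabet()
      i <- i + 1L
    } else if (toupper(ch) %in% aa_alphabet()) {
      positions[[length(positions) + 1L]] <- toupper(ch)
      i <- i + 1L
    } else {
      stop("illegal character '", ch, "' in pattern '", pattern, "'",
           call. = FALSE)
    }
  }
  sizes <- lengths(positions)
  scores <- ifelse(sizes == 20L, 1, 1 / sizes)
  structure(
    list(id = as.character(id), width = length(positions),
         pattern = pattern, positions = positions,
         position_scores = scores),
    class = "regex_motif"
  )
}

#' Bundle motifs into an ordered motif set
#'
#' The order of motifs in a set is fixed and defines score-matrix column
#' order.
#'
#' @param motifs List of [pspm_motif()] and/or [regex_motif][compile_pattern()]
#'   objects.
#' @param provenance One of `"SM"`, `"CM"`, `"canonical"`, `"user"`.
#' @return An object of class `motif_set`.
#' @export
motif_set <- function(motifs, provenance = "user") {
  provenance <- match.arg(provenance, c("SM", "CM", "canonical", "user"))
  ok <- vapply(motifs, function(m)
    inherits(m, "pspm_motif") || inherits(m, "regex_motif"), logical(1L))
  if (!all(ok)) stop("motifs must be pspm_motif or regex_motif objects",
                     call. = FALSE)
  ids <- vapply(motifs, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate motif id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(motifs = motifs, ids = ids, provenance = provenance),
            class = "motif_set")
}

#' @export
length.motif_set <- function(x) length(x$motifs)

#' @export
print.motif_set <- function(x, ...) {
  cat("motif_set of", length(x), "motif(s), provenance", x$provenance, "\n")
  for (m in x$motifs) {
    kind <- if (inherits(m, "pspm_motif")) "PSPM" else "regex"
    cat(sprintf("  %-20s %-5s W=%d\n", m$id, kind, m$width))
  }
  invisible(x)
}

#' The 14 canonical calmodulin-binding motifs
#'
#' Returns the registry of previously known canonical CaM-binding motif
#' patterns (1-10, 1-5-10, Basic 1-5-10, 1-12, 1-14, 1-8-14, 1-5-8-14,
#' Basic 1-8-14, 1-16, IQ, IQ-like, IQ-2A, IQ-2B, IQ unconventional), each
#' compiled as a [regex_motif][compile_pattern()]. Patterns are stored
#' verbatim in `inst/extdata/canonical_cam_motifs.tsv` and compiled at call
#' time.
#'
#' @return A [motif_set()] of 14 regex motifs, provenance `"canonical"`.
#' @export
#' @examples
#' reg <- canonical_motifs()
#' length(reg)  # 14
canonical_motifs <- function() {
  path <- system.file("extdata", "canonical_cam_motifs.tsv",
                      package = "swscan", mustWork = TRUE)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
  motifs <- Map(compile_pattern, tab$pattern, tab$name)
  motif_set(unname(motifs), provenance = "canonical")
}

#' Per-class positional occupancy of a PSPM
#'
#' For each residue class, counts the motif positions where the summed
#' probability over class members strictly exceeds `threshold` (the "more
#' than 50% occupancy" rule at the default). Also reports the dominant
#' residue at every position. Default classes are `basic = {R, K}` and
#' `hydrophobic = {F, A, I, L, V, W, M, C, Y}`; both are overridable since
#' class membership is a convention, not part of the matrix.
#'
#' @param motif A [pspm_motif()].
#' @param threshold Occupancy fraction in (0, 1]; comparison is strict (>).
#' @param classes Named list of residue-character vectors.
#' @return List with `counts` (named integer vector per class), `positions`
#'   (named list of 1-based position indices per class) and `dominant`
#'   (character vector, most probable residue at each position).
#' @export
occupancy_profile <- function(motif, threshold = 0.5,
                              classes = list(
                                basic = c("R", "K"),
                                hydrophobic = c("F", "A", "I", "L", "V",
                                                "W", "M", "C", "Y"))) {
  stopifnot(inherits(motif, "pspm_motif"),
            threshold > 0, threshold <= 1, length(classes) > 0L)
  for (nm in names(classes)) {
    bad <- setdiff(toupper(classes[[nm]]), aa_alphabet())
    if (length(bad) > 0L) {
      stop("unknown residue(s) in class '", nm, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  X <- motif$matrix
  positions <- lapply(classes, function(cl) {
    occ <- rowSums(X[, toupper(cl), drop = FALSE])
    which(occ > threshold)
  })
  list(
    counts = vapply(positions, length, integer(1L)),
    positions = positions,
    dominant = aa_alphabet()[max.col(X, ties.method = "first")]
  )
}
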