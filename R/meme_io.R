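# Reader/writer for MEME minimal (text) motif format, the format in which
# motif-discovery runs report their letter-probability matrices. Only the
# parts needed for probability-matrix scoring are handled: the ALPHABET
# declaration and the `letter-probability matrix` block of each MOTIF.

#' Parse motifs from MEME text output
#'
#' Reads MEME minimal/text format and returns one PSPM per
#' `letter-probability matrix` block. Columns are remapped from the file's
#' declared alphabet to the canonical order. Rows whose sum deviates from 1
#' by at most `1e-3` are renormalized; larger deviations are an error.
#'
#' @param path Path to a MEME text or minimal-format file.
#' @return A [motif_set()] of [pspm_motif()] objects (provenance `"user"`).
#'   A file with no motif blocks yields an empty set with a warning.
#' @export
parse_meme_motifs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  alpha_line <- grep("^\\s*ALPHABET\\s*=", lines, value = TRUE)
  if (length(alpha_line) == 0L) {
    stop("MEME file has no ALPHABET= declaration: ", path, call. = FALSE)
  }
  alphabet <- .seq_chars(gsub("\\s", "", sub("^.*=", "", alpha_line[1L])))
  if (!setequal(alphabet, aa_alphabet())) {
    stop("MEME alphabet is not the 20-residue protein alphabet",
         call. = FALSE)
  }

  motif_starts <- grep("^MOTIF\\b", lines)
  motifs <- list()
  for (s in motif_starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1L]][2L]
    if (is.na(name)) name <- paste0("motif_", length(motifs) + 1L)
    block_end <- c(motif_starts[motif_starts > s], length(lines) + 1L)[1L] - 1L
    hdr_rel <- grep("letter-probability matrix", lines[s:block_end])
    if (length(hdr_rel) == 0L) next
    hdr_i <- s + hdr_rel[1L] - 1L
    hdr <- lines[hdr_i]
    w <- .meme_attr(hdr, "w")
    alength <- .meme_attr(hdr, "alength")
    if (!is.na(alength) && alength != length(alphabet)) {
      stop("motif '", name, "': alength= disagrees with ALPHABET",
           call. = FALSE)
    }
    if (is.na(w)) {
      stop("motif '", name, "': missing w= in matrix header", call. = FALSE)
    }
    rows <- list()
    i <- hdr_i + 1L
    while (i <= block_end && length(rows) < w) {
      ln <- trimws(lines[i])
      if (nzchar(ln)) {
        vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]]))
        if (anyNA(vals) || length(vals) != length(alphabet)) break
        rows[[length(rows) + 1L]] <- vals
      }
      i <- i + 1L
    }
    if (length(rows) != w) {
      stop("motif '", name, "': expected ", w, " matrix rows, found ",
           length(rows), call. = FALSE)
    }
    mat <- do.call(rbind, rows)
    colnames(mat) <- alphabet
    sums <- rowSums(mat)
    bad <- which(abs(sums - 1) > 1e-3)
    if (length(bad) > 0L) {
      stop("motif '", name, "': row(s) ", paste(bad, collapse = ", "),
           " sum to ", paste(signif(sums[bad], 6), collapse = ", "),
           ", outside 1 +/- 1e-3", call. = FALSE)
    }
    mat <- mat / sums
    motifs[[length(motifs) + 1L]] <- pspm_motif(mat[, aa_alphabet(),
                                                    drop = FALSE], name)
  }
  if (length(motifs) == 0L) {
    warning("no letter-probability matrix blocks in ", path, call. = FALSE)
  }
  motif_set(motifs, provenance = "user")
}

.meme_attr <- function(header, key) {
  m <- regmatches(header,
                  regexpr(paste0("\\b", key, "\\s*=\\s*[0-9]+"), header))
  if (length(m) == 0L) return(NA_integer_)
  as.integer(sub(".*=\\s*", "", m))
}

#' Write PSPMs in MEME minimal format
#'
#' @param motifs A [motif_set()] or list of [pspm_motif()] objects.
#' @param path Output file path.
#' @param nsites Site count recorded in each block header (cosmetic).
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path, nsites = 20L) {
  if (inherits(motifs, "motif_set")) motifs <- motifs$motifs
  ok <- vapply(motifs, inherits, logical(1L), "pspm_motif")
  if (!all(ok)) stop("only PSPM motifs can be written in MEME format",
                     call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste0("ALPHABET= ", paste(aa_alphabet(), collapse = "")),
               ""), con)
  for (m in motifs) {
    writeLines(paste("MOTIF", m$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 20 w= %d nsites= %d E= 0",
      m$width, nsites), con)
    writeLines(apply(m$matrix, 1L, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}
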