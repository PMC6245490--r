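#' Read protein sequences from a FASTA file
#'
#' Reads a protein FASTA file into a protein-set data frame with one row per
#' record. Sequences are uppercased and line wrapping is removed; record
#' order is preserved. Residues outside the 20-letter standard alphabet
#' (B, J, O, U, X, Z, `*`) are retained but flagged per record; they score
#' zero in every scoring method.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` of class `protein_set` with columns `id`
#'   (first whitespace-delimited token of the header), `sequence`, `length`
#'   and `nonstandard` (logical; record contains non-standard residues).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1", "LTEYI", "QGPC"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  .validate_fasta_lines(path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("no records in FASTA file: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) {
    stop("FASTA record with empty id in ", path, call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  protein_set(ids, seqs)
}

# light pre-check so malformed input fails with a line number rather than a
# parser-internal message
.validate_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    stop("no records in FASTA file: ", path, call. = FALSE)
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("not FASTA: expected '>' header at line ", first, " of ", path,
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a protein set
#'
#' @param id Character vector of unique, nonempty identifiers.
#' @param sequence Character vector of protein sequences (uppercased).
#' @return A `data.frame` of class `protein_set`.
#' @export
protein_set <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(id))) stop("protein ids must be nonempty", call. = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate protein id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(sequence))) {
    stop("zero-length sequence for id(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "), call. = FALSE)
  }
  nonstd <- vapply(
    sequence,
    function(s) any(!.is_standard(.seq_chars(s))),
    logical(1L), USE.NAMES = FALSE
  )
  out <- data.frame(
    id = id, sequence = sequence, length = nchar(sequence),
    nonstandard = nonstd, stringsAsFactors = FALSE
  )
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Write a protein set to FASTA
#'
#' @param proteins A `protein_set` (or data frame with `id` and `sequence`).
#' @param path Output file path.
#' @param width Line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  set <- Biostrings::BStringSet(proteins$sequence)
  names(set) <- proteins$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a two-column label file
#'
#' Expects a TSV with columns `id` and label in `{1, 0}` (or
#' `positive`/`negative`); a header line is detected and skipped.
#'
#' @param path Path to the TSV file.
#' @return Named integer vector (1 = positive, 0 = negative), names = ids.
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           col.names = c("id", "label"))
  if (nrow(tab) > 0L && tolower(tab$label[1L]) %in% c("label", "class")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  lab <- tolower(tab$label)
  val <- ifelse(lab %in% c("1", "positive", "pos"), 1L,
         ifelse(lab %in% c("0", "negative", "neg"), 0L, NA_integer_))
  if (anyNA(val)) {
    stop("unrecognized label value(s): ",
         paste(unique(tab$label[is.na(val)]), collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(val, tab$id)
}

#' Write labels as a two-column TSV
#'
#' @param labels Named vector (names = ids, values coerced to 0/1).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(id = names(labels), label = as.integer(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Attach labels to a protein set
#'
#' Validates that every label key matches exactly one record id and that
#' every record is labeled.
#'
#' @param proteins A `protein_set`.
#' @param labels Named vector as returned by [read_labels()].
#' @return A `labeled_dataset`: list with `proteins` and `labels` (integer
#'   vector aligned to record order).
#' @export
labeled_dataset <- function(proteins, labels) {
  missing_rec <- setdiff(names(labels), proteins$id)
  if (length(missing_rec) > 0L) {
    stop("label id(s) with no matching record: ",
         paste(missing_rec, collapse = ", "), call. = FALSE)
  }
  missing_lab <- setdiff(proteins$id, names(labels))
  if (length(missing_lab) > 0L) {
    stop("record(s) without a label: ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  out <- list(proteins = proteins,
              labels = as.integer(labels[proteins$id]))
  class(out) <- "labeled_dataset"
  out
}

#' Enumerate sliding windows of a sequence
#'
#' All overlapping substrings (l-mers) of length `w`, with 0-based offsets
#' `0..L-w`. A window width exceeding the sequence length yields zero
#' windows.
#'
#' @param sequence A single protein sequence string.
#' @param w Window width in residues (>= 1).
#' @return `data.frame` with columns `offset` (0-based) and `window`;
#'   `max(L - w + 1, 0)` rows.
#' @export
#' @examples
#' enumerate_windows("LTEYIQGPC", 9)  # one window
#' nrow(enumerate_windows(strrep("A", 100), 9))  # 92
enumerate_windows <- function(sequence, w) {
  stopifnot(length(sequence) == 1L, w >= 1L)
  L <- nchar(sequence)
  n <- max(L - w + 1L, 0L)
  if (n == 0L) {
    return(data.frame(offset = integer(0), window = character(0),
                      stringsAsFactors = FALSE))
  }
  offs <- 0:(n - 1L)
  data.frame(
    offset = offs,
    window = substring(sequence, offs + 1L, offs + w),
    stringsAsFactors = FALSE
  )
}
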