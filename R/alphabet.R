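# Canonical 20-letter amino-acid alphabet in the display order used by
# MEME's protein alphabet. All probability matrices are keyed to this order.

#' Canonical amino-acid alphabet
#'
#' The 20 standard amino-acid one-letter codes in the canonical column order
#' used throughout the package (A, C, D, E, ..., Y). Every position-specific
#' probability matrix has its columns in this order.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# ambiguity / non-standard codes that may appear in real FASTA records;
# they are flagged on read and score zero in every scoring method
.nonstandard_codes <- c("B", "J", "O", "U", "X", "Z", "*")

.is_standard <- function(chars) chars %in% aa_alphabet()

# split a sequence string into its residue characters
.seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1L]]

# run code with a temporary RNG state seeded from `seed`
.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
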