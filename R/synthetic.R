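# Planted-motif simulator. Emulates the two-class study design the scoring
# pipeline assumes: positives are background sequences carrying planted
# motif sites, negatives are pure background (except for an optional leak
# rate). Returns sequences, labels and the ground-truth site annotations,
# fully determined by a single integer seed.

#' Synthetic dataset configuration
#'
#' @param n_pos,n_neg Class sizes (>= 1).
#' @param len_range Integer range (min, max) of sequence lengths in
#'   residues, sampled uniformly.
#' @param background Named numeric vector of residue frequencies over the
#'   20-letter alphabet, summing to 1 (default uniform 1/20, which keeps
#'   chance-match probabilities closed-form).
#' @param motifs A [motif_set()] (or single motif) of motifs to plant.
#' @param sites_per_positive Number of sites planted in each positive, per
#'   motif.
#' @param mutation_rate Per-residue probability that a planted site residue
#'   is replaced by a uniform random residue.
#' @param leak_rate Probability that a negative receives one planted site.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pos = 100L, n_neg = 100L,
                             len_range = c(150L, 400L),
                             background = NULL,
                             motifs,
                             sites_per_positive = 1L,
                             mutation_rate = 0,
                             leak_rate = 0) {
  stopifnot(n_pos >= 1L, n_neg >= 1L,
            length(len_range) == 2L, len_range[1] <= len_range[2],
            sites_per_positive >= 0L,
            mutation_rate >= 0, mutation_rate <= 1,
            leak_rate >= 0, leak_rate <= 1)
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20L), aa_alphabet())
  }
  stopifnot(setequal(names(background), aa_alphabet()),
            abs(sum(background) - 1) < 1e-9, all(background >= 0))
  if (inherits(motifs, "pspm_motif") || inherits(motifs, "regex_motif")) {
    motifs <- motif_set(list(motifs))
  }
  stopifnot(inherits(motifs, "motif_set"))
  widths <- vapply(motifs$motifs, `[[`, integer(1L), "width")
  if (max(widths) > len_range[1]) {
    stop("planted motif width ", max(widths),
         " exceeds minimum sequence length ", len_range[1], call. = FALSE)
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 len_range = as.integer(len_range),
                 background = background[aa_alphabet()],
                 motifs = motifs,
                 sites_per_positive = as.integer(sites_per_positive),
                 mutation_rate = mutation_rate, leak_rate = leak_rate),
            class = "synthetic_config")
}

# draw one site string from a motif: PSPM rows as categorical
# distributions, regex positions uniform over the admissible set
.sample_site <- function(motif) {
  if (inherits(motif, "pspm_motif")) {
    paste(vapply(seq_len(motif$width), function(i) {
      sample(aa_alphabet(), 1L, prob = motif$matrix[i, ])
    }, character(1L)), collapse = "")
  } else {
    paste(vapply(motif$positions, function(set) {
      if (length(set) == 1L) set else sample(set, 1L)
    }, character(1L)), collapse = "")
  }
}

.mutate_site <- function(site, rate) {
  if (rate <= 0) return(site)
  chars <- .seq_chars(site)
  hit <- stats::runif(length(chars)) < rate
  chars[hit] <- sample(aa_alphabet(), sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

#' Generate a labeled synthetic dataset with planted motif sites
#'
#' Background residues are i.i.d. from the configured frequencies. Each
#' positive receives the configured number of sites per planted motif,
#' sampled from the motif, mutated at the per-residue rate, and embedded at
#' non-overlapping uniform-random offsets (offsets are re-drawn up to 100
#' times before erroring). Negatives receive one site with probability
#' `leak_rate`. The output is fully determined by `seed`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return List of class `synthetic_dataset`: `dataset` (a
#'   [labeled_dataset()]), and `sites` (`data.frame` with `protein_id`,
#'   `start` (1-based), `end`, `motif_id`, `site`).
#' @export
generate_dataset <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(seed, .generate_dataset_impl(config))
}

.generate_dataset_impl <- function(config) {
  n <- config$n_pos + config$n_neg
  ids <- sprintf("SYN%04d", seq_len(n))
  labels <- c(rep(1L, config$n_pos), rep(0L, config$n_neg))
  lens <- sample(seq(config$len_range[1], config$len_range[2]), n,
                 replace = TRUE)
  sites <- list()
  seqs <- character(n)
  for (p in seq_len(n)) {
    chars <- sample(aa_alphabet(), lens[p], replace = TRUE,
                    prob = config$background)
    planted <- list()  # list of c(start, end) 1-based, occupied intervals
    plant <- function(motif) {
      site <- .mutate_site(.sample_site(motif), config$mutation_rate)
      w <- nchar(site)
      for (try in seq_len(100L)) {
        start <- sample.int(lens[p] - w + 1L, 1L)
        end <- start + w - 1L
        clash <- any(vapply(planted, function(iv)
          start <= iv[2L] && end >= iv[1L], logical(1L)))
        if (!clash) {
          planted[[length(planted) + 1L]] <<- c(start, end)
          chars[start:end] <<- .seq_chars(site)
          sites[[length(sites) + 1L]] <<- data.frame(
            protein_id = ids[p], start = start, end = end,
            motif_id = motif$id, site = site, stringsAsFactors = FALSE)
          return(invisible(TRUE))
        }
      }
      stop("cannot place non-overlapping site in protein ", ids[p],
           call. = FALSE)
    }
    if (labels[p] == 1L) {
      for (m in config$motifs$motifs) {
        for (s in seq_len(config$sites_per_positive)) plant(m)
      }
    } else if (config$leak_rate > 0 &&
               stats::runif(1L) < config$leak_rate) {
      plant(config$motifs$motifs[[sample.int(length(config$motifs), 1L)]])
    }
    seqs[p] <- paste(chars, collapse = "")
  }
  ds <- labeled_dataset(protein_set(ids, seqs),
                        stats::setNames(labels, ids))
  site_df <- if (length(sites)) do.call(rbind, sites) else
    data.frame(protein_id = character(0), start = integer(0),
               end = integer(0), motif_id = character(0),
               site = character(0), stringsAsFactors = FALSE)
  structure(list(dataset = ds, sites = site_df),
            class = "synthetic_dataset")
}

#' End-to-end label recovery on synthetic data
#'
#' Generates a dataset, scores it against the planted motif set, and
#' cross-validates a classifier on the resulting score matrix — the
#' pipeline's self-test: with exact planted sites the classes should
#' separate, with fully randomized sites accuracy should fall to chance.
#'
#' @param config A [synthetic_config()].
#' @param scoring A [scoring_config()] compatible with the planted motifs.
#' @param spec A [classifier_spec()].
#' @param folds CV folds.
#' @param seed Integer seed (generation, folds and training).
#' @return An `eval_result` (see [cross_validate()]).
#' @export
recover_labels <- function(config, scoring = scoring_config("re"),
                           spec = classifier_spec("rf", seed = seed),
                           folds = 3L, seed = 1L) {
  syn <- generate_dataset(config, seed = seed)
  sm <- build_score_matrix(syn$dataset, config$motifs, scoring)
  cross_validate(sm, spec = spec, folds = folds, seed = seed)
}

#' Write a synthetic dataset to disk
#'
#' Writes FASTA sequences, a label TSV and a ground-truth site TSV
#' (`protein_id`, 1-based `start`, `end`, `motif_id`).
#'
#' @param syn A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(syn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(syn$dataset$proteins, file.path(dir, "sequences.fasta"))
  write_labels(stats::setNames(syn$dataset$labels,
                               syn$dataset$proteins$id),
               file.path(dir, "labels.tsv"))
  utils::write.table(syn$sites[, c("protein_id", "start", "end",
                                   "motif_id")],
                     file.path(dir, "sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
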