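#' Specification of a planted-motif protein sequence fixture
#'
#' Random amino-acid sequences with a controlled number of non-overlapping
#' planted IWN 4-mers (first residue I/L/V, then W, then two hydrophilic
#' residues). Used to validate the motif scanner by construction.
#'
#' @param n_sequences number of sequences.
#' @param length residues per sequence.
#' @param planted_motifs_per_sequence planted IWN occurrences per sequence.
#' @param alphabet_frequencies named numeric vector of residue sampling
#'   weights (names from the 20-letter alphabet); default uniform over the
#'   20 standard residues. Residues absent from the names are never drawn.
#' @param seed integer seed.
#' @return An object of class `sequence_fixture_spec`.
#' @export
sequence_fixture_spec <- function(n_sequences = 5L, length = 500L,
                                  planted_motifs_per_sequence = 3L,
                                  alphabet_frequencies = NULL, seed = 1L) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(alphabet_frequencies))
    alphabet_frequencies <- stats::setNames(rep(1, 20), aa20)
  if (is.null(names(alphabet_frequencies)) ||
      !all(names(alphabet_frequencies) %in% aa20))
    stop("alphabet_frequencies must be named with standard amino acids")
  if (length < 4L * max(1L, planted_motifs_per_sequence) &&
      planted_motifs_per_sequence > 0L)
    stop("sequence length too short for the requested motif count")
  structure(list(n_sequences = as.integer(n_sequences),
                 length = as.integer(length),
                 planted_motifs_per_sequence =
                   as.integer(planted_motifs_per_sequence),
                 alphabet_frequencies = alphabet_frequencies,
                 seed = as.integer(seed)),
            class = "sequence_fixture_spec")
}

# sample `k` non-overlapping 4-mer start positions in 1..(len-3)
.sample_motif_positions <- function(len, k, max_tries = 1000L) {
  if (k == 0L) return(integer(0))
  for (try in seq_len(max_tries)) {
    pos <- sort(sample.int(len - 3L, k))
    if (k == 1L || all(diff(pos) >= 4L)) return(pos)
  }
  stop("could not place non-overlapping motifs; sequence too short")
}

#' Generate protein sequences with planted IWN motifs
#'
#' @param spec a [sequence_fixture_spec()].
#' @return list with `sequences` (a [Biostrings::AAStringSet]) and
#'   `planted` (data frame: `seq_id`, `position` (1-based), `window`).
#' @export
generate_sequence_fixtures <- function(spec) {
  stopifnot(inherits(spec, "sequence_fixture_spec"))
  old <- .switch_seed(spec$seed)
  on.exit(.restore_seed(old), add = TRUE)
  alphabet <- names(spec$alphabet_frequencies)
  w <- spec$alphabet_frequencies / sum(spec$alphabet_frequencies)
  hydset <- strsplit(iwn_hydrophilic_set(), "")[[1]]
  seqs <- character(spec$n_sequences)
  planted <- list()
  for (i in seq_len(spec$n_sequences)) {
    res <- sample(alphabet, spec$length, replace = TRUE, prob = w)
    pos <- .sample_motif_positions(spec$length,
                                   spec$planted_motifs_per_sequence)
    for (p in pos) {
      motif <- c(sample(c("I", "L", "V"), 1L), "W",
                 sample(hydset, 1L), sample(hydset, 1L))
      res[p:(p + 3L)] <- motif
      planted[[length(planted) + 1L]] <-
        data.frame(seq_id = sprintf("synthetic_seq_%03d", i),
                   position = p, window = paste(motif, collapse = ""))
    }
    seqs[i] <- paste(res, collapse = "")
  }
  aaset <- Biostrings::AAStringSet(seqs)
  names(aaset) <- sprintf("synthetic_seq_%03d", seq_len(spec$n_sequences))
  planted_df <- if (length(planted)) do.call(rbind, planted) else
    data.frame(seq_id = character(0), position = integer(0),
               window = character(0))
  list(sequences = aaset, planted = planted_df)
}

#' Generate a BLAST-style hit table with a planted pass fraction
#'
#' Constructs `n_rows` tabular hits of which exactly
#' `round(n_rows * fraction_passing)` strictly satisfy both homolog-screen
#' filters (query coverage > 40 percent and e-value < 1e-3). Failing rows
#' include exact boundary values (coverage 40.0, e-value 1e-3) so the
#' strictness of the filter is exercised.
#'
#' @param n_rows number of hits.
#' @param fraction_passing fraction in `[0, 1]` that must pass the filter.
#' @param seed integer seed.
#' @param min_coverage,max_evalue the filter bounds the table is built
#'   against (defaults are the homolog-screen values).
#' @return list with `table` (data frame: `query_id`, `subject_id`,
#'   `query_coverage_percent`, `evalue`, `taxon`) and `n_expected_pass`.
#' @export
generate_blast_table <- function(n_rows, fraction_passing, seed = 1L,
                                 min_coverage = 40, max_evalue = 1e-3) {
  if (fraction_passing < 0 || fraction_passing > 1)
    stop("fraction_passing must lie in [0, 1]")
  old <- .switch_seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  n_pass <- round(n_rows * fraction_passing)
  n_fail <- n_rows - n_pass
  taxa <- c("Caenorhabditis elegans", "Homo sapiens", "Dictyostelium discoideum",
            "Entamoeba histolytica", "Arabidopsis thaliana",
            "Monosiga brevicollis")
  cov_pass <- stats::runif(n_pass, min_coverage + 1, 100)
  ev_pass <- 10^stats::runif(n_pass, -60, log10(max_evalue) - 1)
  # failures: below-coverage, above-evalue, both, or exactly on a boundary
  mode <- if (n_fail > 0) sample(1:4, n_fail, replace = TRUE) else integer(0)
  cov_fail <- ev_fail <- numeric(n_fail)
  for (j in seq_len(n_fail)) {
    cov_fail[j] <- switch(mode[j],
      stats::runif(1, 0, min_coverage),            # low coverage only
      stats::runif(1, min_coverage + 1, 100),      # bad evalue only
      stats::runif(1, 0, min_coverage),            # both bad
      min_coverage)                                # exact boundary
    ev_fail[j] <- switch(mode[j],
      10^stats::runif(1, -60, log10(max_evalue) - 1),
      10^stats::runif(1, log10(max_evalue), 2),
      10^stats::runif(1, log10(max_evalue), 2),
      max_evalue)                                  # exact boundary
  }
  tab <- data.frame(
    query_id = "RME8_QUERY",
    subject_id = sprintf("synthetic_hit_%04d", seq_len(n_rows)),
    query_coverage_percent = c(cov_pass, cov_fail),
    evalue = c(ev_pass, ev_fail),
    taxon = sample(taxa, n_rows, replace = TRUE))
  tab <- tab[sample.int(n_rows), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, n_expected_pass = n_pass)
}
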