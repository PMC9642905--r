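#' @title IWN-repeat scanning and homolog curation
#' @description The homolog-screening computation: scan protein sequences
#'   for the four-residue IWN repeat (I/L/V, then W, then two hydrophilic
#'   residues), filter BLAST hit tables on query coverage and e-value
#'   (strict `> 40`\% and `< 1e-3`), and call a hit a homolog candidate
#'   when it passes the filter and carries at least three IWN repeats.
#' @name iwn-motif
NULL

# default hydrophilic residue set (position 3-4 of the motif): polar +
# charged. Histidine included; widen via the `hydrophilic` argument if a
# looser curation is wanted (e.g., add Y, C).
.iwn_hydrophilic <- "STNQDEKRH"

#' The default hydrophilic residue set of the IWN motif
#'
#' @return A string of one-letter residue codes accepted at motif
#'   positions 3 and 4.
#' @export
iwn_hydrophilic_set <- function() .iwn_hydrophilic

#' Validate and normalize a protein sequence record
#'
#' @param identifier sequence id.
#' @param residues amino-acid string; upper-cased; must use the 20-letter
#'   alphabet plus X.
#' @return An object of class `sequence_record`.
#' @export
sequence_record <- function(identifier, residues) {
  residues <- toupper(as.character(residues))
  if (nchar(residues) > 0 && grepl("[^ACDEFGHIKLMNPQRSTVWYX]", residues))
    stop(sprintf("sequence '%s' contains non-amino-acid characters",
                 identifier))
  structure(list(identifier = as.character(identifier), residues = residues),
            class = "sequence_record")
}

#' Scan a protein sequence for IWN repeats
#'
#' Reports every 4-residue window whose first residue is I, L, or V,
#' second residue W, and third and fourth residues hydrophilic.
#' Overlapping windows are all reported, in order of position. The
#' unknown residue X never matches any position.
#'
#' @param seq a [sequence_record()], a `Biostrings::AAString`, or a plain
#'   character string.
#' @param hydrophilic residues accepted at motif positions 3-4, as a
#'   single string (default [iwn_hydrophilic_set()]).
#' @return data frame with columns `position` (1-based first residue of
#'   the window) and `window` (the matched 4-mer); zero rows when no
#'   motif is present.
#' @examples
#' scan_iwn("AAIWDNAA")   # one hit at position 3
#' @export
scan_iwn <- function(seq, hydrophilic = iwn_hydrophilic_set()) {
  s <- if (inherits(seq, "sequence_record")) seq$residues
       else toupper(as.character(seq))
  if (length(s) != 1L) stop("expected a single sequence")
  if (nchar(s) < 4L)
    return(data.frame(position = integer(0), window = character(0)))
  pat <- sprintf("(?=([ILV]W[%s]{2}))", hydrophilic)
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(position = integer(0), window = character(0)))
  pos <- as.integer(m)
  data.frame(position = pos,
             window = substring(s, pos, pos + 3L))
}

#' Filter a BLAST hit table on coverage and e-value
#'
#' Keeps rows with query coverage strictly greater than `min_coverage`
#' percent AND e-value strictly less than `max_evalue` (both comparisons
#' strict, matching the published "> 40\%" and "< 1E-3" screen). Row
#' order is preserved; filtering is idempotent.
#'
#' @param rows data frame with at least columns `query_coverage_percent`
#'   and `evalue`.
#' @param min_coverage coverage cut (percent), default 40.
#' @param max_evalue e-value cut, default 1e-3.
#' @return the surviving rows, original order.
#' @export
filter_blast <- function(rows, min_coverage = 40, max_evalue = 1e-3) {
  need <- c("query_coverage_percent", "evalue")
  miss <- setdiff(need, names(rows))
  if (length(miss))
    stop("hit table lacks required column(s): ", paste(miss, collapse = ", "))
  cov <- rows$query_coverage_percent
  ev <- rows$evalue
  bad <- which(!is.finite(cov) | !is.finite(ev) | cov < 0 | cov > 100 | ev < 0)
  if (length(bad))
    stop(sprintf("malformed hit table row %d: coverage=%s evalue=%s",
                 bad[1], format(cov[bad[1]]), format(ev[bad[1]])))
  rows[cov > min_coverage & ev < max_evalue, , drop = FALSE]
}

#' Call a BLAST hit as an RME-8 homolog candidate
#'
#' A subject is a candidate iff its hit row passes the coverage/e-value
#' filter AND its sequence contains at least `min_motifs` IWN repeats
#' (default 3, the curation rule).
#'
#' @param row single-row data frame (one BLAST hit) with `subject_id`,
#'   `query_coverage_percent`, `evalue`, and optionally `taxon`.
#' @param seq a [sequence_record()] whose identifier matches
#'   `row$subject_id`.
#' @param min_motifs minimum IWN repeats required (default 3).
#' @param min_coverage,max_evalue filter bounds passed to [filter_blast()].
#' @param hydrophilic residue set passed to [scan_iwn()].
#' @return list of class `homolog_call`: `subject_id`, `taxon`,
#'   `n_motifs`, `passes_blast_filter`, `is_candidate`.
#' @export
call_homolog <- function(row, seq, min_motifs = 3L, min_coverage = 40,
                         max_evalue = 1e-3,
                         hydrophilic = iwn_hydrophilic_set()) {
  stopifnot(inherits(seq, "sequence_record"))
  if (nrow(row) != 1L) stop("expected exactly one hit row")
  if (!identical(as.character(row$subject_id), seq$identifier))
    stop(sprintf("hit subject_id '%s' does not match sequence '%s'",
                 row$subject_id, seq$identifier))
  passes <- nrow(filter_blast(row, min_coverage, max_evalue)) == 1L
  n_motifs <- nrow(scan_iwn(seq, hydrophilic))
  structure(list(subject_id = seq$identifier,
                 taxon = if ("taxon" %in% names(row))
                   as.character(row$taxon) else NA_character_,
                 n_motifs = n_motifs,
                 passes_blast_filter = passes,
                 is_candidate = passes && n_motifs >= min_motifs),
            class = "homolog_call")
}

#' @export
print.homolog_call <- function(x, ...) {
  cat(sprintf("<homolog_call> %s: %d IWN repeats, blast filter %s -> %s\n",
              x$subject_id, x$n_motifs,
              if (x$passes_blast_filter) "pass" else "fail",
              if (x$is_candidate) "CANDIDATE" else "not a candidate"))
  invisible(x)
}

#' Per-taxon homolog presence table with tree-annotation lines
#'
#' Aggregates homolog calls by taxon: candidate count and a presence
#' flag per taxon, sorted by taxon name for determinism, plus iTOL-style
#' TREE_COLORS annotation lines coloring presence/absence branches.
#'
#' @param calls list of `homolog_call` objects.
#' @param taxa optional named character vector mapping `subject_id` to a
#'   taxon label, overriding any taxon stored in the calls. Subjects
#'   missing from the mapping raise a warning and are kept with a blank
#'   taxon.
#' @param present_color,absent_color branch colors for the annotation.
#' @return list with `table` (data frame: `taxon`, `n_candidates`,
#'   `present`) and `annotation` (character vector of iTOL lines).
#' @export
presence_table <- function(calls, taxa = NULL,
                           present_color = "#ff0000",
                           absent_color = "#999999") {
  if (length(calls) == 0L)
    return(list(table = data.frame(taxon = character(0),
                                   n_candidates = integer(0),
                                   present = logical(0)),
                annotation = character(0)))
  rows <- lapply(calls, function(cl) {
    tx <- cl$taxon
    if (!is.null(taxa)) {
      if (cl$subject_id %in% names(taxa)) {
        tx <- unname(taxa[[cl$subject_id]])
      } else {
        warning(sprintf("subject '%s' has no taxon mapping; keeping blank",
                        cl$subject_id))
        tx <- ""
      }
    }
    if (is.na(tx)) tx <- ""
    data.frame(taxon = tx, candidate = cl$is_candidate)
  })
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(candidate ~ taxon, data = df, FUN = sum)
  tab <- data.frame(taxon = agg$taxon,
                    n_candidates = as.integer(agg$candidate),
                    present = agg$candidate > 0)
  tab <- tab[order(tab$taxon), , drop = FALSE]
  rownames(tab) <- NULL
  ann <- c("TREE_COLORS", "SEPARATOR TAB", "DATA",
           sprintf("%s\trange\t%s\t%s", tab$taxon,
                   ifelse(tab$present, present_color, absent_color),
                   ifelse(tab$present, "RME-8 present", "RME-8 absent")))
  list(table = tab, annotation = ann)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return list of [sequence_record()].
#' @export
read_fasta_records <- function(path) {
  aaset <- Biostrings::readAAStringSet(path)
  mapply(function(nm, s) sequence_record(nm, s),
         names(aaset), as.character(aaset),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param sequences a `Biostrings::AAStringSet` or list of
#'   [sequence_record()].
#' @param path output file.
#' @export
write_fasta_records <- function(sequences, path) {
  if (!inherits(sequences, "AAStringSet")) {
    s <- Biostrings::AAStringSet(vapply(sequences, `[[`, "", "residues"))
    names(s) <- vapply(sequences, `[[`, "", "identifier")
    sequences <- s
  }
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Read a BLAST-style tabular hit file
#'
#' Accepts a tab-separated file whose header names at least
#' `query_coverage_percent` and `evalue`, or standard 12-column tabular
#' output with a `qcovs` column appended when a column map is given.
#'
#' @param path TSV file.
#' @param column_map optional named character vector renaming file
#'   columns to the canonical names (e.g.,
#'   `c(qcovs = "query_coverage_percent")`).
#' @return data frame of hits.
#' @export
read_blast_table <- function(path, column_map = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (old in names(column_map)) {
      if (old %in% names(tab))
        names(tab)[names(tab) == old] <- column_map[[old]]
    }
  }
  need <- c("query_coverage_percent", "evalue")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("hit table lacks required column(s): ", paste(miss, collapse = ", "))
  tab
}
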