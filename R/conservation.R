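#' Construct an alignment block
#'
#' Equal-length gapped amino-acid sequences (gap `-`), one per species or
#' homolog, as produced by a multiple aligner.
#'
#' @param rows named character vector of equal-length gapped sequences.
#' @return object of class `alignment_block`.
#' @export
alignment_block <- function(rows) {
  if (length(rows) < 2) stop("alignment needs >= 2 rows")
  if (is.null(names(rows)) || anyDuplicated(names(rows))) {
    stop("rows must have unique sequence ids")
  }
  rows <- toupper(rows)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1) {
    bad <- names(rows)[lens != lens[1]][1]
    stop("ragged alignment: row '", bad, "' has a different length")
  }
  allowed <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "-")
  chars <- unique(strsplit(paste(rows, collapse = ""), "")[[1]])
  unknown <- setdiff(chars, allowed)
  if (length(unknown)) {
    stop("unknown alignment characters: ", paste(unknown, collapse = ", "))
  }
  structure(rows, class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("Alignment block: %d rows x %d columns (%s)\n", length(x),
              nchar(x[1]), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return an [alignment_block()], input row order preserved.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  rows <- if (format == "fasta") {
    ss <- Biostrings::readAAStringSet(path)
    stats::setNames(as.character(ss), names(ss))
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    ss <- as(aln, "AAStringSet")
    stats::setNames(as.character(ss), names(ss))
  }
  # strip FASTA description after first whitespace
  names(rows) <- sub("\\s.*$", "", names(rows))
  alignment_block(rows)
}

.aln_matrix <- function(a) {
  do.call(rbind, strsplit(unclass(a), ""))
}

#' Majority-threshold consensus of an alignment
#'
#' Per column, the most frequent symbol (gaps count as a symbol) is emitted
#' when its count reaches `threshold_count` and it is the unique most
#' frequent symbol; otherwise the ambiguity character is emitted. The
#' default threshold is a strict majority, `floor(n/2) + 1` — 4 for a
#' six-sequence alignment.
#'
#' @param a an [alignment_block()].
#' @param threshold_count minimum per-column count for the winning symbol.
#' @param ambiguity ambiguity character, default `"X"`.
#' @return object of class `consensus_sequence`: the gapped consensus
#'   string with attributes `threshold_count` and `ambiguity`.
#' @export
build_consensus <- function(a, threshold_count = NULL, ambiguity = "X") {
  M <- .aln_matrix(a)
  n <- nrow(M)
  if (is.null(threshold_count)) threshold_count <- n %/% 2 + 1
  if (threshold_count < 1 || threshold_count > n) {
    stop("threshold_count must be between 1 and the number of rows (", n, ")")
  }
  cons <- apply(M, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    if (tab[1] >= threshold_count &&
        (length(tab) == 1 || tab[1] > tab[2])) names(tab)[1] else ambiguity
  })
  structure(paste(cons, collapse = ""), threshold_count = threshold_count,
            ambiguity = ambiguity, class = "consensus_sequence")
}

#' Score a gapped sequence against a consensus
#'
#' Columns where the consensus is the ambiguity character, or where both
#' the sequence and the consensus hold a gap, are excluded from the
#' denominator. Identical symbols count as identical; differing residues
#' whose substitution score reaches `similar_cutoff` count as similar;
#' everything else — including a residue facing a gap — is dissimilar.
#' The percent score is `(identical + similar) / (length - excluded) x 100`.
#'
#' @param row gapped sequence (character scalar), same length as consensus.
#' @param cons a [build_consensus()] result.
#' @param matrix a `substitution_matrix`; default [blosum62()].
#' @param similar_cutoff minimum substitution score for a differing residue
#'   pair to count as similar (default 1).
#' @return object of class `similarity_score`: list with `percent` and the
#'   column counts `identical`, `similar`, `dissimilar`, `excluded`. When
#'   every column is excluded, `percent` is `NA` and `all_excluded = TRUE`.
#' @export
similarity_to_consensus <- function(row, cons, matrix = blosum62(),
                                    similar_cutoff = 1) {
  row <- toupper(row)
  cs <- strsplit(unclass(cons), "")[[1]]
  rs <- strsplit(row, "")[[1]]
  if (length(rs) != length(cs)) {
    stop("sequence length (", length(rs), ") != consensus length (",
         length(cs), ")")
  }
  amb <- attr(cons, "ambiguity")
  n_id <- n_sim <- n_dis <- n_exc <- 0L
  for (k in seq_along(cs)) {
    c <- cs[k]; r <- rs[k]
    if (c == amb || (c == "-" && r == "-")) {
      n_exc <- n_exc + 1L
    } else if (r == c) {
      n_id <- n_id + 1L
    } else if (r != "-" && c != "-" &&
               .sub_score(matrix, r, c) >= similar_cutoff) {
      n_sim <- n_sim + 1L
    } else {
      n_dis <- n_dis + 1L
    }
  }
  denom <- length(cs) - n_exc
  structure(list(
    percent = if (denom > 0) 100 * (n_id + n_sim) / denom else NA_real_,
    identical = n_id, similar = n_sim, dissimilar = n_dis, excluded = n_exc,
    all_excluded = denom == 0
  ), class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf(
    "similarity %.1f%% (identical %d, similar %d, dissimilar %d, excluded %d)\n",
    x$percent, x$identical, x$similar, x$dissimilar, x$excluded))
  invisible(x)
}

#' Define an epitope region on an ungapped reference sequence
#'
#' @param allergen allergen id (e.g. `"TM"`).
#' @param epitope_id epitope id (e.g. `"TM_E1"`).
#' @param reference_id sequence id of the reference row.
#' @param start,end 1-based inclusive coordinates on the ungapped reference.
#' @param peptide expected reference peptide; validated by [map_epitope()].
#' @return object of class `epitope_region`.
#' @export
epitope_region <- function(allergen, epitope_id, reference_id, start, end,
                           peptide) {
  if (start < 1 || end < start) stop("need 1 <= start <= end")
  peptide <- toupper(peptide)
  if (nchar(peptide) != end - start + 1) {
    stop("peptide length does not match the coordinate span")
  }
  structure(list(allergen = allergen, epitope_id = epitope_id,
                 reference_id = reference_id, start = start, end = end,
                 peptide = peptide), class = "epitope_region")
}

#' Read an epitope definition table
#'
#' TSV with columns `allergen`, `epitope_id`, `reference_id`, `start`,
#' `end`, `peptide`; coordinates 1-based inclusive on the ungapped
#' reference.
#'
#' @param path file path.
#' @return list of [epitope_region()] objects.
#' @export
read_epitopes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("allergen", "epitope_id", "reference_id", "start", "end", "peptide")
  if (!all(need %in% names(df))) {
    stop("epitope table must have columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    with(df[i, ], epitope_region(allergen, epitope_id, reference_id,
                                 start, end, peptide))
  })
}

#' Map an epitope through a gapped alignment
#'
#' Converts the epitope's ungapped reference coordinates to alignment
#' columns (gaps in the reference do not advance the coordinate) and
#' returns the spanned sub-alignment for every row, including any interior
#' columns where the reference is gapped.
#'
#' @param a an [alignment_block()].
#' @param e an [epitope_region()].
#' @return an [alignment_block()] of the epitope columns, with attribute
#'   `columns` giving the alignment column range.
#' @export
map_epitope <- function(a, e) {
  if (!(e$reference_id %in% names(a))) {
    stop("reference sequence '", e$reference_id, "' not in alignment")
  }
  ref <- strsplit(a[[e$reference_id]], "")[[1]]
  ungapped_cols <- which(ref != "-")
  if (e$end > length(ungapped_cols)) {
    stop(sprintf("epitope %s: end %d beyond ungapped reference length %d",
                 e$epitope_id, e$end, length(ungapped_cols)))
  }
  found <- paste(ref[ungapped_cols[e$start:e$end]], collapse = "")
  if (found != e$peptide) {
    stop(sprintf("epitope %s: peptide mismatch, expected '%s' but found '%s'",
                 e$epitope_id, e$peptide, found))
  }
  cols <- ungapped_cols[e$start]:ungapped_cols[e$end]
  sub <- vapply(unclass(a), function(s) {
    paste(strsplit(s, "")[[1]][cols], collapse = "")
  }, "")
  structure(alignment_block(sub), columns = range(cols))
}

#' Epitope-by-species conservation table
#'
#' For each epitope, extracts the epitope sub-alignment, builds its
#' majority consensus and scores every row against it with the
#' substitution matrix.
#'
#' @param a an [alignment_block()].
#' @param epitopes list of [epitope_region()] objects.
#' @param matrix a `substitution_matrix`; default [blosum62()].
#' @param threshold_count consensus threshold; default strict majority.
#' @param similar_cutoff see [similarity_to_consensus()].
#' @return numeric matrix (epitope x sequence id) of percents; epitopes
#'   whose consensus excludes every column are `NA` and listed in the
#'   `all_excluded` attribute.
#' @export
epitope_similarity_table <- function(a, epitopes, matrix = blosum62(),
                                     threshold_count = NULL,
                                     similar_cutoff = 1) {
  ids <- names(a)
  out <- matrix(NA_real_, length(epitopes), length(ids),
                dimnames = list(vapply(epitopes, `[[`, "", "epitope_id"), ids))
  flagged <- character(0)
  for (i in seq_along(epitopes)) {
    sub <- map_epitope(a, epitopes[[i]])
    cons <- build_consensus(sub, threshold_count = threshold_count)
    scores <- lapply(unclass(sub), similarity_to_consensus, cons = cons,
                     matrix = matrix, similar_cutoff = similar_cutoff)
    if (any(vapply(scores, `[[`, TRUE, "all_excluded"))) {
      flagged <- c(flagged, epitopes[[i]]$epitope_id)
    }
    out[i, ] <- vapply(scores, `[[`, 0, "percent")
  }
  structure(out, all_excluded = flagged)
}

#' Whole-protein conservation scores against the consensus
#'
#' Builds the alignment-wide consensus and scores each sequence against it.
#'
#' @inheritParams epitope_similarity_table
#' @return named list: `percent` (per sequence id), `scores` (full
#'   [similarity_to_consensus()] objects), `consensus`.
#' @export
protein_similarity_scores <- function(a, matrix = blosum62(),
                                      threshold_count = NULL,
                                      similar_cutoff = 1) {
  cons <- build_consensus(a, threshold_count = threshold_count)
  scores <- lapply(unclass(a), similarity_to_consensus, cons = cons,
                   matrix = matrix, similar_cutoff = similar_cutoff)
  list(percent = vapply(scores, `[[`, 0, "percent"), scores = scores,
       consensus = cons)
}
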