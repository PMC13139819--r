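#' Read an NCBI-format amino-acid substitution matrix
#'
#' Parses the plain-text matrix layout used by NCBI BLAST (`#` comments,
#' a header row of symbols, one labelled score row per symbol).
#'
#' @param path path to the matrix file.
#' @return integer score matrix of class `substitution_matrix` with a
#'   `name` attribute.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  syms <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  lab <- vapply(rows, `[`, "", 1)
  vals <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(syms))))
  dimnames(vals) <- list(lab, syms)
  vals <- vals[syms, syms]
  if (!isSymmetric(unname(vals))) stop("substitution matrix is not symmetric")
  structure(vals, name = tools::file_path_sans_ext(basename(path)),
            class = c("substitution_matrix", "matrix"))
}

#' The bundled BLOSUM62 matrix
#'
#' BLOSUM62 amino-acid substitution scores (half-bit units) as distributed
#' by NCBI, loaded from the package's plain-text asset.
#'
#' @return a `substitution_matrix`.
#' @export
blosum62 <- function() {
  read_substitution_matrix(
    system.file("extdata", "BLOSUM62.txt", package = "allerprofile",
                mustWork = TRUE))
}

.sub_score <- function(m, a, b) {
  if (!(a %in% rownames(m)) || !(b %in% colnames(m))) {
    stop(sprintf("symbols '%s'/'%s' not covered by substitution matrix", a, b))
  }
  m[a, b]
}
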