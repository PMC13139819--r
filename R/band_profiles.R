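#' Construct a band presence/absence profile matrix
#'
#' A `band_profile_matrix` holds the scored polypeptide bands of several
#' species as a binary species x band matrix, with the apparent molecular
#' weight (kDa) of each band attached. Cross-species band identity is
#' established at annotation time by giving shared bands the same label;
#' no molecular-weight window matching is performed here.
#'
#' @param calls integer/logical matrix (species x band) of 0/1 calls, with
#'   species as rownames and band labels as colnames.
#' @param mw_kda numeric vector of molecular weights (kDa), one per band,
#'   named by band label (or unnamed in column order).
#' @return an object of class `band_profile_matrix`: the binary integer
#'   matrix with attribute `mw_kda`.
#' @export
band_profile_matrix <- function(calls, mw_kda) {
  calls <- as.matrix(calls)
  if (is.logical(calls)) storage.mode(calls) <- "integer"
  if (!all(calls %in% c(0L, 1L))) {
    stop("band calls must be strictly binary (0/1)")
  }
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("calls must have species rownames and band-label colnames")
  }
  if (anyDuplicated(colnames(calls))) {
    stop("band labels must be unique")
  }
  if (anyDuplicated(rownames(calls))) {
    stop("species labels must be unique")
  }
  if (is.null(names(mw_kda))) names(mw_kda) <- colnames(calls)
  mw_kda <- mw_kda[colnames(calls)]
  if (any(is.na(mw_kda)) || any(mw_kda <= 0)) {
    stop("every band needs a positive molecular weight (kDa)")
  }
  if (any(rowSums(calls) == 0)) {
    warning("species with no scored bands: ",
            paste(rownames(calls)[rowSums(calls) == 0], collapse = ", "))
  }
  structure(calls, mw_kda = mw_kda, class = c("band_profile_matrix", "matrix"))
}

#' Read a band-call table
#'
#' Reads a delimited text table with columns `species`, `band_label`,
#' `mw_kda` and `present`, as produced when scoring gel or immunoblot
#' lanes for band presence (+) or absence (-). Species keep their input
#' order; bands are ordered by descending molecular weight.
#'
#' @param path path to a TSV (default) or CSV file.
#' @param sep field separator; `"\t"` by default, `","` accepted.
#' @return a [band_profile_matrix()].
#' @export
read_band_calls <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE)
  need <- c("species", "band_label", "mw_kda", "present")
  if (!all(need %in% names(df))) {
    stop("band-call table must have columns: ", paste(need, collapse = ", "))
  }
  dup <- duplicated(df[, c("species", "band_label")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate (species, band_label) pair at row %d: (%s, %s)",
                 i, df$species[i], df$band_label[i]))
  }
  pres <- .parse_presence(df$present)
  if (anyNA(pres)) {
    i <- which(is.na(pres))[1]
    stop(sprintf("non-binary presence call at row %d: '%s'", i, df$present[i]))
  }
  species <- unique(df$species)
  # bands by descending molecular weight, label as tiebreak
  bw <- tapply(df$mw_kda, df$band_label, function(x) x[1])
  bands <- names(bw)[order(-bw, names(bw))]
  calls <- matrix(0L, length(species), length(bands),
                  dimnames = list(species, bands))
  calls[cbind(match(df$species, species), match(df$band_label, bands))] <- pres
  band_profile_matrix(calls, mw_kda = bw[bands])
}

.parse_presence <- function(x) {
  x <- trimws(tolower(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("1", "+", "true", "t", "yes")] <- 1L
  # both ASCII hyphen and the typographic minus used in band scoring
  out[x %in% c("0", "-", "−", "false", "f", "no")] <- 0L
  out
}

#' Band-sharing similarity index (Dice coefficient x 100)
#'
#' SI = 2Z / (X + Y) x 100, where Z is the number of bands shared by the
#' two profiles and X and Y are their individual band counts. Equals 100
#' exactly when the two (non-empty) band sets are identical.
#'
#' @param row_a,row_b binary band vectors of equal length.
#' @return similarity percent in \[0, 100\].
#' @export
similarity_index <- function(row_a, row_b) {
  row_a <- as.integer(row_a); row_b <- as.integer(row_b)
  if (length(row_a) != length(row_b)) stop("band vectors differ in length")
  if (!all(c(row_a, row_b) %in% c(0L, 1L))) stop("band vectors must be binary")
  x <- sum(row_a); y <- sum(row_b)
  if (x + y == 0) {
    stop("similarity index undefined: both profiles have zero bands (X+Y = 0)")
  }
  z <- sum(row_a == 1L & row_b == 1L)
  200 * z / (x + y)
}

.similarity_matrix <- function(values, labels, scale) {
  dimnames(values) <- list(labels, labels)
  structure(values, scale = scale, class = c("similarity_matrix", "matrix"))
}

#' Pairwise similarity-index matrix
#'
#' Computes the band-sharing similarity index ([similarity_index()]) for
#' every species pair of a band profile matrix.
#'
#' @param m a [band_profile_matrix()].
#' @return a `similarity_matrix` on the percent scale (diagonal 100).
#' @export
pairwise_si_matrix <- function(m) {
  if (nrow(m) < 2) stop("need at least two species")
  n <- nrow(m)
  v <- matrix(100, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sij <- tryCatch(similarity_index(m[i, ], m[j, ]),
                      error = function(e) {
                        stop(sprintf("pair (%s, %s): %s", rownames(m)[i],
                                     rownames(m)[j], conditionMessage(e)),
                             call. = FALSE)
                      })
      v[i, j] <- v[j, i] <- sij
    }
  }
  .similarity_matrix(v, rownames(m), "percent_0_100")
}

#' Pairwise Pearson (phi) similarity matrix
#'
#' Pearson product-moment correlation of the binary band vectors of every
#' species pair (the phi coefficient). Rows with zero variance (all bands
#' present or all absent) have no defined correlation and are rejected.
#'
#' @param m a [band_profile_matrix()].
#' @return a `similarity_matrix` on the correlation scale (diagonal 1).
#' @export
pearson_similarity_matrix <- function(m) {
  if (nrow(m) < 2) stop("need at least two species")
  vzero <- apply(m, 1, stats::var) == 0
  if (any(vzero)) {
    stop("zero-variance band profile (all present or all absent) for: ",
         paste(rownames(m)[vzero], collapse = ", "))
  }
  v <- stats::cor(t(m))
  .similarity_matrix(v, rownames(m), "correlation_minus1_1")
}

#' Convert a similarity matrix to distances
#'
#' Percent-scale similarities map to `100 - value`; correlation-scale to
#' `1 - value`.
#' @param s a `similarity_matrix`.
#' @return a numeric distance matrix.
#' @export
similarity_to_distance <- function(s) {
  scale <- attr(s, "scale")
  if (is.null(scale)) stop("not a similarity_matrix")
  d <- if (scale == "percent_0_100") 100 - s else 1 - s
  d <- unclass(d)
  attr(d, "scale") <- NULL
  d
}

#' @export
print.similarity_matrix <- function(x, digits = 1, ...) {
  cat(sprintf("Similarity matrix (%s), %d labels\n", attr(x, "scale"), nrow(x)))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Write a similarity matrix as labelled TSV
#'
#' Percent values are written to 1 decimal place; correlations to 3.
#'
#' @param s a `similarity_matrix`.
#' @param path output file path.
#' @export
write_similarity_tsv <- function(s, path) {
  digits <- if (identical(attr(s, "scale"), "percent_0_100")) 1 else 3
  df <- data.frame(label = rownames(s), round(unclass(s), digits),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
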