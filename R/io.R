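#' Write a band profile matrix as a band-call table
#'
#' Inverse of [read_band_calls()]: long TSV with columns `species`,
#' `band_label`, `mw_kda`, `present`.
#'
#' @param m a [band_profile_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_band_calls <- function(m, path) {
  mw <- attr(m, "mw_kda")
  df <- data.frame(
    species = rep(rownames(m), each = ncol(m)),
    band_label = rep(colnames(m), nrow(m)),
    mw_kda = rep(unname(mw), nrow(m)),
    present = as.vector(t(unclass(m)))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an alignment block as FASTA
#'
#' @param a an [alignment_block()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(a, path) {
  writeLines(as.vector(rbind(paste0(">", names(a)), unclass(a))), path)
  invisible(path)
}

#' Write an OD plate as TSV
#'
#' @param plate an [od_plate()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_od_plate_tsv <- function(plate, path) {
  utils::write.table(as.data.frame(plate), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write inhibition series as TSV
#'
#' One table for one or more series, with the 0-concentration row holding
#' the no-inhibitor reference (inverse of [read_inhibition_series()]).
#'
#' @param series an [inhibition_series()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_inhibition_tsv <- function(series, path) {
  if (inherits(series, "inhibition_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(inhibitor = s$inhibitor,
               concentration_ug_ml = c(0, s$concentrations),
               signal = c(s$signal_no_inhibitor, s$signals))
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
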