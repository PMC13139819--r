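#' Read Salmon-style transcript quantification tables
#'
#' Each file follows the `quant.sf` layout (tab-separated columns `Name`,
#' `Length`, `EffectiveLength`, `TPM`, `NumReads`). Tables are merged by
#' transcript id; a transcript absent from a sample is imputed as TPM 0
#' with a warning.
#'
#' @param paths character vector of quant table paths; names (or the
#'   parent directory name, Salmon-style) become sample ids.
#' @return numeric TPM matrix, transcripts x samples.
#' @export
read_quant <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- basename(dirname(normalizePath(paths, mustWork = FALSE)))
    if (anyDuplicated(names(paths))) names(paths) <- basename(paths)
  }
  tabs <- lapply(seq_along(paths), function(i) {
    df <- utils::read.table(paths[i], header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!all(c("Name", "TPM") %in% names(df))) {
      stop("malformed quant header (need Name and TPM columns) in file: ",
           paths[i])
    }
    if (!is.numeric(df$TPM)) stop("TPM column not numeric in file: ", paths[i])
    df[, c("Name", "TPM")]
  })
  ids <- unique(unlist(lapply(tabs, `[[`, "Name")))
  tpm <- matrix(0, length(ids), length(paths),
                dimnames = list(ids, names(paths)))
  for (i in seq_along(tabs)) {
    missing <- setdiff(ids, tabs[[i]]$Name)
    if (length(missing)) {
      warning(sprintf("sample %s: %d transcripts missing, TPM set to 0",
                      names(paths)[i], length(missing)))
    }
    tpm[tabs[[i]]$Name, i] <- tabs[[i]]$TPM
  }
  tpm
}

#' Assemble an annotated expression table
#'
#' @param tpm transcript x sample TPM matrix (e.g. from [read_quant()]).
#' @param mapping data.frame with columns `transcript_id`, `allergen` and
#'   optionally `species` (transcripts are then only counted for samples
#'   of that species).
#' @param samples data.frame with columns `sample_id`, `species` and
#'   optionally `tissue`.
#' @return object of class `expression_table`.
#' @export
expression_table <- function(tpm, mapping, samples) {
  if (!all(c("transcript_id", "allergen") %in% names(mapping))) {
    stop("mapping needs columns transcript_id, allergen")
  }
  if (!all(c("sample_id", "species") %in% names(samples))) {
    stop("samples sheet needs columns sample_id, species")
  }
  if (anyDuplicated(samples$sample_id)) stop("sample ids must be unique")
  if (!all(colnames(tpm) %in% samples$sample_id)) {
    stop("samples sheet does not cover all TPM columns")
  }
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  samples <- samples[match(colnames(tpm), samples$sample_id), ]
  if (is.null(samples$tissue)) samples$tissue <- "muscle"
  structure(list(tpm = tpm, mapping = mapping, samples = samples),
            class = "expression_table")
}

#' Aggregate transcript TPM to allergen level
#'
#' Allergen abundance in a sample is the sum of its member transcripts'
#' TPM (isoforms are summed). When the mapping is species-aware, only
#' transcripts mapped to the sample's species contribute; an allergen with
#' no mapped transcript for a species is reported as missing (`NA`), not
#' zero.
#'
#' @param t an [expression_table()].
#' @return numeric allergen x sample matrix (possibly with `NA`s).
#' @export
aggregate_to_allergen <- function(t) {
  allergens <- unique(t$mapping$allergen)
  out <- matrix(NA_real_, length(allergens), ncol(t$tpm),
                dimnames = list(allergens, colnames(t$tpm)))
  by_species <- "species" %in% names(t$mapping)
  for (j in seq_len(ncol(t$tpm))) {
    map_j <- if (by_species) {
      t$mapping[t$mapping$species == t$samples$species[j], ]
    } else t$mapping
    map_j <- map_j[map_j$transcript_id %in% rownames(t$tpm), ]
    if (nrow(map_j) == 0) next
    sums <- tapply(t$tpm[map_j$transcript_id, j], map_j$allergen, sum)
    out[names(sums), j] <- sums
  }
  out
}

#' Heatmap normalization of allergen TPM
#'
#' `log2(TPM + 1)` — the pseudocount keeps zero abundance at 0 and leaves
#' a TPM-dominant transcript (TPM near 10^6) at ~20, the top of the
#' printed heatmap scale. Optionally each column is additionally
#' standardized (z-score); off by default since the raw 0-20 range is the
#' reported display scale.
#'
#' @param m allergen x sample TPM matrix.
#' @param scale_columns standardize each column after the log transform.
#' @return matrix of normalized values with attribute `normalization`.
#' @export
heatmap_normalize <- function(m, scale_columns = FALSE) {
  if (any(m < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  v <- log2(m + 1)
  if (scale_columns) v <- scale(v)[, , drop = FALSE]
  structure(v, normalization = if (scale_columns) {
    "log2(TPM+1), column z-score"
  } else "log2(TPM+1)")
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Standard one-way analysis of variance across groups (e.g. allergen
#' groups of similarity or expression values), followed by Tukey's honest
#' significant difference test for all pairwise contrasts.
#'
#' @param values numeric response vector.
#' @param groups group label per value (>= 2 groups, >= 2 values each).
#' @return list with `f_statistic`, `p_value` (ANOVA), and `pairwise` — a
#'   data.frame of Tukey contrasts (`group_a`, `group_b`, `diff`, `p_adj`).
#' @export
group_compare <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) {
    bad <- names(which(table(groups) < 2))
    stop("groups with fewer than 2 observations: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  list(
    f_statistic = an[["F value"]][1],
    p_value = an[["Pr(>F)"]][1],
    pairwise = data.frame(group_a = pairs[, 1], group_b = pairs[, 2],
                          diff = tk[, "diff"], p_adj = tk[, "p adj"],
                          row.names = NULL)
  )
}

#' Encode p-values as heatmap significance codes
#'
#' Bins: 0 for p > 0.05; 1 for p < 0.05; 2 for p < 0.01; 3 for p < 0.001;
#' 4 for p < 0.0001. The code is the largest bin whose strict inequality
#' holds, so a boundary value (p = 0.05 exactly) codes 0.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return integer vector of codes in 0..4.
#' @export
significance_codes <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  vapply(p_values, function(p) {
    sum(p < c(0.05, 0.01, 0.001, 0.0001))
  }, integer(1))
}
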