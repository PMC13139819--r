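#' Default six-species tree
#'
#' The generating topology used by the synthetic-data module:
#' `((((CF,PP),SP),(CO,ES)),PC)` with the king crab PC as the outgroup on
#' the longest branch. Branch lengths are ultrametric (leaf heights 0,
#' root height 5).
#'
#' @return an `ape` `phylo` tree.
#' @export
species_tree <- function() {
  ape::read.tree(text = "((((CF:1,PP:1):1,SP:2):1,(CO:2,ES:2):1):2,PC:5);")
}

# lognormal draws parameterized by arithmetic mean and CV; cv = 0 gives
# the noise-free limit
.lnorm <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# preorder edge list (each parent appears before its children)
.preorder_edges <- function(tree) {
  tr <- stats::reorder(tree, "cladewise")
  cbind(tr$edge, tr$edge.length)
}

#' Simulate band profiles on a species tree
#'
#' The root profile draws each band present with probability `root_prob`;
#' along every branch each band's state flips independently with
#' probability `flip_prob x branch length`. Expected band sharing between
#' two leaves therefore decays with their path length, emulating scored
#' gel/blot profiles of related species.
#'
#' @param tree a `phylo` tree (default [species_tree()]).
#' @param n_bands number of scored bands (>= 10).
#' @param flip_prob per-unit-branch-length state-flip probability.
#' @param root_prob root presence probability per band.
#' @param seed integer seed.
#' @return a [band_profile_matrix()] (rows in tree tip order) with
#'   attribute `truth` holding the generating tree (Newick) and parameters.
#' @export
gen_band_profiles <- function(tree = species_tree(), n_bands = 50,
                              flip_prob = 0.05, root_prob = 0.7, seed = 1) {
  if (n_bands < 10) stop("need n_bands >= 10")
  if (flip_prob < 0 || flip_prob > 1 || root_prob < 0 || root_prob > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  edges <- .preorder_edges(tree)
  if (any(flip_prob * edges[, 3] > 1)) {
    stop("flip_prob x branch length exceeds 1 on some branch")
  }
  set.seed(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- stats::rbinom(n_bands, 1, root_prob)
  for (k in seq_len(nrow(edges))) {
    p <- flip_prob * edges[k, 3]
    flips <- stats::rbinom(n_bands, 1, p)
    states[[edges[k, 2]]] <- abs(states[[edges[k, 1]]] - flips)
  }
  calls <- do.call(rbind, states[seq_len(ntip)])
  rownames(calls) <- tree$tip.label
  mw <- sort(stats::runif(n_bands, 10, 250), decreasing = TRUE)
  colnames(calls) <- sprintf("B%02d", seq_len(n_bands))
  out <- suppressWarnings(
    band_profile_matrix(calls, stats::setNames(mw, colnames(calls))))
  attr(out, "truth") <- list(tree = ape::write.tree(tree),
                             flip_prob = flip_prob, root_prob = root_prob,
                             seed = seed)
  out
}

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulate a protein family on a species tree
#'
#' A random root sequence evolves along the tree: per branch and site the
#' substitution count is Poisson with rate `base_rate x branch length`
#' (times `epitope_rate_multiplier` inside epitope regions), each
#' substitution replacing the residue uniformly among the other 19 amino
#' acids. No indels are introduced by default, so the rows stay in
#' register; `gap_prob` can punch random gaps to exercise gap handling.
#'
#' @param tree a `phylo` tree (default [species_tree()]).
#' @param length sequence length (columns).
#' @param base_rate substitutions per site per unit branch length.
#' @param epitope_regions list of `c(start, end)` integer pairs
#'   (non-overlapping) marking conserved epitope blocks.
#' @param epitope_rate_multiplier relative substitution rate inside
#'   epitopes, in (0, 1].
#' @param gap_prob per-cell gap probability (default 0 = gapless).
#' @param seed integer seed.
#' @return an [alignment_block()] (rows in tree tip order) with attribute
#'   `truth` (generating tree, rates, regions).
#' @export
gen_protein_family <- function(tree = species_tree(), length = 300,
                               base_rate = 0.05, epitope_regions = NULL,
                               epitope_rate_multiplier = 0.2, gap_prob = 0,
                               seed = 1) {
  if (epitope_rate_multiplier <= 0 || epitope_rate_multiplier > 1) {
    stop("epitope_rate_multiplier must lie in (0, 1]")
  }
  is_epi <- rep(FALSE, length)
  if (!is.null(epitope_regions)) {
    for (r in epitope_regions) {
      if (r[1] < 1 || r[2] > length || r[2] < r[1]) {
        stop("epitope region out of bounds")
      }
      if (any(is_epi[r[1]:r[2]])) stop("overlapping epitope regions")
      is_epi[r[1]:r[2]] <- TRUE
    }
  }
  set.seed(seed)
  site_mult <- ifelse(is_epi, epitope_rate_multiplier, 1)
  edges <- .preorder_edges(tree)
  ntip <- base::length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample(.AA, length, replace = TRUE)
  for (k in seq_len(nrow(edges))) {
    s <- seqs[[edges[k, 1]]]
    nsub <- stats::rpois(length, base_rate * site_mult * edges[k, 3])
    for (i in which(nsub > 0)) {
      for (j in seq_len(nsub[i])) s[i] <- sample(setdiff(.AA, s[i]), 1)
    }
    seqs[[edges[k, 2]]] <- s
  }
  rows <- vapply(seqs[seq_len(ntip)], paste, "", collapse = "")
  names(rows) <- tree$tip.label
  if (gap_prob > 0) {
    M <- do.call(rbind, strsplit(rows, ""))
    M[matrix(stats::runif(base::length(M)) < gap_prob, nrow(M))] <- "-"
    rows <- stats::setNames(apply(M, 1, paste, collapse = ""), names(rows))
  }
  out <- alignment_block(rows)
  attr(out, "truth") <- list(tree = ape::write.tree(tree),
                             base_rate = base_rate,
                             epitope_regions = epitope_regions,
                             epitope_rate_multiplier = epitope_rate_multiplier,
                             seed = seed)
  out
}

#' Simulate an ELISA OD plate with known sensitization status
#'
#' Nonallergic sera and non-sensitized allergic sera draw their OD450 from
#' a lognormal with mean `neg_mean`; truly sensitized sera (the first
#' `ceiling(true_positive_fraction x n_allergic)` allergic sera) draw from
#' a lognormal with mean `pos_fold x neg_mean`. With `pos_fold` above the
#' cutoff multiplier (3), expected positives clear the 3x-negative-mean
#' cutoff.
#'
#' @param n_allergic,n_negative numbers of allergic and nonallergic sera.
#' @param true_positive_fraction fraction of allergic sera truly
#'   sensitized.
#' @param neg_mean mean negative OD450.
#' @param pos_fold fold-increase of sensitized sera over `neg_mean` (> 3).
#' @param cv lognormal coefficient of variation (0 = noise-free).
#' @param antigen antigen id.
#' @param seed integer seed.
#' @return an [od_plate()] data.frame with attribute `truth` (logical
#'   `sensitized` per allergic serum and the parameters).
#' @export
gen_od_plate <- function(n_allergic = 50, n_negative = 3,
                         true_positive_fraction = 0.14, neg_mean = 0.02,
                         pos_fold = 20, cv = 0.2, antigen = "rMDH",
                         seed = 1) {
  if (n_allergic < 1 || n_negative < 1) stop("invalid plate sizes")
  if (true_positive_fraction < 0 || true_positive_fraction > 1) {
    stop("true_positive_fraction must lie in [0, 1]")
  }
  if (pos_fold <= 3) stop("pos_fold must exceed the 3x cutoff multiplier")
  set.seed(seed)
  # epsilon guards against binary float artifacts (0.14 * 50 > 7)
  n_pos <- ceiling(true_positive_fraction * n_allergic - 1e-9)
  sens <- c(rep(TRUE, n_pos), rep(FALSE, n_allergic - n_pos))
  od_all <- ifelse(sens, .lnorm(n_allergic, pos_fold * neg_mean, cv),
                   .lnorm(n_allergic, neg_mean, cv))
  od_neg <- .lnorm(n_negative, neg_mean, cv)
  df <- data.frame(
    serum_id = c(sprintf("A%02d", seq_len(n_allergic)),
                 sprintf("N%02d", seq_len(n_negative))),
    status = c(rep("allergic", n_allergic), rep("nonallergic", n_negative)),
    antigen = antigen,
    od = c(od_all, od_neg),
    stringsAsFactors = FALSE
  )
  out <- od_plate(df)
  attr(out, "truth") <- list(sensitized = sens, neg_mean = neg_mean,
                             pos_fold = pos_fold, cv = cv, seed = seed)
  out
}

#' Simulate a Hill-shaped inhibition dilution series
#'
#' True inhibition at concentration c is
#' `Imax x c^h / (IC50^h + c^h)`; the measured signal is
#' `od0 x (1 - inhibition/100)` under multiplicative lognormal noise.
#'
#' @param Imax maximal inhibition percent, in \[0, 100\].
#' @param IC50 half-maximal concentration (ug/mL), > 0.
#' @param hill Hill slope.
#' @param concentrations inhibitor concentrations (ug/mL), increasing;
#'   default seven 10-fold dilutions spanning 1e-4 to 100.
#' @param od0 no-inhibitor signal.
#' @param cv multiplicative noise CV (0 = noise-free).
#' @param inhibitor inhibitor id.
#' @param seed integer seed.
#' @return an [inhibition_series()] with attribute `truth`.
#' @export
gen_inhibition_series <- function(Imax = 93, IC50 = 0.1, hill = 1,
                                  concentrations = 10^seq(-4, 2), od0 = 1,
                                  cv = 0.05, inhibitor = "PC-MDH", seed = 1) {
  if (Imax < 0 || Imax > 100) stop("Imax must lie in [0, 100]")
  if (IC50 <= 0) stop("IC50 must be positive")
  set.seed(seed)
  inh <- Imax * concentrations^hill / (IC50^hill + concentrations^hill)
  signals <- od0 * (1 - inh / 100) * .lnorm(length(concentrations), 1, cv)
  ref <- od0 * .lnorm(1, 1, cv)
  out <- inhibition_series(inhibitor, concentrations, signals, ref)
  attr(out, "truth") <- list(Imax = Imax, IC50 = IC50, hill = hill,
                             cv = cv, seed = seed)
  out
}

.default_allergen_means <- c(
  TM = 524288, AK = 16384, PM = 8192, MHC = 4096, FLNC = 2048, ALD = 2048,
  GP = 1024, HSP = 1024, PGM = 512, MDH = 512, HC = 8
)

#' Simulate a cross-species allergen expression table
#'
#' Per species and sample, each allergen's TPM draws from a lognormal
#' around its configured mean (relative units); tropomyosin's default mean
#' of 2^19 makes it the dominant transcript, and hemocyanin is near zero
#' in muscle, emulating the observed expression structure. TM carries two
#' isoform transcripts (mean split 2:1) to exercise isoform aggregation;
#' unmapped background transcripts are added, and every sample is
#' renormalized so its TPM sums to 10^6.
#'
#' @param allergen_means named vector of mean TPM (relative units) per
#'   allergen, all >= 0.
#' @param n_samples_per_species samples per species.
#' @param dispersion lognormal CV of TPM around the mean (0 = noise-free).
#' @param species species labels; `mixed_tissue_species` get tissue
#'   "mixed" in the sample sheet, the rest "muscle".
#' @param mixed_tissue_species species whose samples are mixed-tissue.
#' @param n_background number of unmapped background transcripts.
#' @param seed integer seed.
#' @return an [expression_table()] with attribute `truth`.
#' @export
gen_tpm <- function(allergen_means = .default_allergen_means,
                    n_samples_per_species = 3, dispersion = 0.5,
                    species = c("CF", "CO", "ES", "PP", "SP", "PC"),
                    mixed_tissue_species = c("PP", "CO"),
                    n_background = 50, seed = 1) {
  if (any(allergen_means < 0) || is.null(names(allergen_means))) {
    stop("allergen_means must be a named non-negative vector")
  }
  set.seed(seed)
  allergens <- names(allergen_means)
  tx <- character(0); map <- NULL
  for (sp in species) {
    for (al in allergens) {
      niso <- if (al == "TM") 2L else 1L
      ids <- sprintf("%s_%s_t%d", sp, al, seq_len(niso))
      tx <- c(tx, ids)
      map <- rbind(map, data.frame(transcript_id = ids, allergen = al,
                                   species = sp))
    }
    bg <- sprintf("%s_BG_t%03d", sp, seq_len(n_background))
    tx <- c(tx, bg)
  }
  sample_ids <- as.vector(t(outer(species, seq_len(n_samples_per_species),
                                  function(s, i) sprintf("%s_%d", s, i))))
  tpm <- matrix(0, length(tx), length(sample_ids),
                dimnames = list(tx, sample_ids))
  for (j in seq_along(sample_ids)) {
    sp <- sub("_[0-9]+$", "", sample_ids[j])
    for (al in allergens) {
      m <- allergen_means[[al]]
      niso <- if (al == "TM") 2L else 1L
      iso_means <- if (niso == 2) m * c(2, 1) / 3 else m
      for (k in seq_len(niso)) {
        id <- sprintf("%s_%s_t%d", sp, al, k)
        tpm[id, j] <- if (iso_means[k] == 0) 0 else {
          .lnorm(1, iso_means[k], dispersion)
        }
      }
    }
    bg <- sprintf("%s_BG_t%03d", sp, seq_len(n_background))
    tpm[bg, j] <- .lnorm(n_background, 500, max(dispersion, 0))
    tpm[, j] <- tpm[, j] / sum(tpm[, j]) * 1e6
  }
  samples <- data.frame(
    sample_id = sample_ids,
    species = sub("_[0-9]+$", "", sample_ids),
    tissue = ifelse(sub("_[0-9]+$", "", sample_ids) %in%
                      mixed_tissue_species, "mixed", "muscle")
  )
  out <- expression_table(tpm, map, samples)
  attr(out, "truth") <- list(allergen_means = allergen_means,
                             dispersion = dispersion, seed = seed)
  out
}

#' Write an expression table as per-sample quant.sf files
#'
#' One `DIR/<sample_id>/quant.sf` per sample in the Salmon layout
#' (`Name`, `Length`, `EffectiveLength`, `TPM`, `NumReads`); round-trips
#' through [read_quant()].
#'
#' @param t an [expression_table()].
#' @param dir output directory (created if needed).
#' @return character vector of the written file paths, invisibly.
#' @export
write_quant_sf <- function(t, dir) {
  paths <- character(ncol(t$tpm))
  len <- 500 + (seq_len(nrow(t$tpm)) %% 37) * 50
  for (j in seq_len(ncol(t$tpm))) {
    d <- file.path(dir, colnames(t$tpm)[j])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    df <- data.frame(Name = rownames(t$tpm), Length = len,
                     EffectiveLength = len - 100,
                     TPM = t$tpm[, j],
                     NumReads = round(t$tpm[, j] * (len - 100) / 1000))
    paths[j] <- file.path(d, "quant.sf")
    utils::write.table(df, paths[j], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
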