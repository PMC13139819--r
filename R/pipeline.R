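#' Run the allergen-repertoire analysis pipeline
#'
#' Orchestrates the four analysis stages — band profiles, conservation,
#' serology, expression — from a single declarative configuration,
#' validating every referenced input path before any stage runs. Outputs
#' (similarity matrices, Newick trees, conservation tables, calls and
#' rates, heatmap matrices, significance codes) are written under
#' `out_dir` together with a machine-readable JSON report and a plain-text
#' log. Two runs with the same configuration and seed produce identical
#' reports.
#'
#' Configuration fields (YAML file or nested list): `out_dir`, `seed`,
#' `stages` (subset of `bands`, `conservation`, `serology`, `expression`),
#' and one block per stage:
#' \describe{
#'   \item{bands}{`calls` (band-call TSV), `metric` (`si`/`pearson`/both),
#'     `linkage` (default `upgma`)}
#'   \item{conservation}{`alignments` (named FASTA/Clustal paths),
#'     `format`, `epitopes` (epitope TSV, optional), `threshold_count`,
#'     `similar_cutoff`}
#'   \item{serology}{`plate` (OD TSV), `cutoff_multiplier` (default 3),
#'     `inhibition` (series TSV, optional)}
#'   \item{expression}{`quant` (named quant.sf paths) or `quant_dir`,
#'     `mapping` TSV, `samples` TSV, `scale_columns`,
#'     `exclude_mixed_tissue` (default TRUE)}
#' }
#'
#' @param config list or path to a YAML configuration file.
#' @return the run report (nested list), invisibly; also written as
#'   `report.json` under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  stages <- config$stages %||% c("bands", "conservation", "serology",
                                 "expression")
  unknown <- setdiff(stages, c("bands", "conservation", "serology",
                               "expression"))
  if (length(unknown)) stop("unknown stages: ", paste(unknown, collapse = ", "))
  .validate_paths(config, stages)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$out_dir, "run.log")
  cat(sprintf("allerprofile run: stages = %s\n", paste(stages, collapse = ", ")),
      file = logfile)
  log <- function(...) cat(sprintf(...), "\n", file = logfile, append = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)

  report <- list(stages = stages, parameters = list(seed = config$seed))
  for (st in stages) {
    log("stage %s: start", st)
    res <- tryCatch(switch(st,
      bands        = .stage_bands(config, log),
      conservation = .stage_conservation(config, log),
      serology     = .stage_serology(config, log),
      expression   = .stage_expression(config, log)
    ), error = function(e) {
      log("stage %s: FAILED: %s", st, conditionMessage(e))
      stop(sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
           call. = FALSE)
    })
    report[[st]] <- res
    log("stage %s: done", st)
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validate_paths <- function(config, stages) {
  paths <- character(0)
  if ("bands" %in% stages) paths <- c(paths, config$bands$calls)
  if ("conservation" %in% stages) {
    paths <- c(paths, unlist(config$conservation$alignments),
               config$conservation$epitopes)
  }
  if ("serology" %in% stages) {
    paths <- c(paths, config$serology$plate, config$serology$inhibition)
  }
  if ("expression" %in% stages) {
    paths <- c(paths, unlist(config$expression[["quant"]]),
               config$expression$quant_dir, config$expression$mapping,
               config$expression$samples)
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input paths: ", paste(missing, collapse = ", "))
  }
}

.stage_bands <- function(config, log) {
  cfg <- config$bands
  if (is.null(cfg$calls)) stop("bands stage needs a 'calls' path")
  m <- read_band_calls(cfg$calls)
  metrics <- cfg$metric %||% c("si", "pearson")
  linkage <- cfg$linkage %||% "upgma"
  out <- list()
  for (metric in metrics) {
    s <- if (metric == "si") pairwise_si_matrix(m) else {
      pearson_similarity_matrix(m)
    }
    t <- build_dendrogram(s, linkage = linkage)
    base <- file.path(config$out_dir, paste0("bands_", metric))
    write_similarity_tsv(s, paste0(base, "_similarity.tsv"))
    write_newick(t, paste0(base, "_dendrogram.nwk"))
    log("bands: %s matrix + %s dendrogram written", metric, linkage)
    out[[metric]] <- list(similarity = unclass(round(s, 1)),
                          newick = newick_string(t))
  }
  out$n_species <- nrow(m); out$n_bands <- ncol(m)
  out
}

.stage_conservation <- function(config, log) {
  cfg <- config$conservation
  if (is.null(cfg$alignments)) stop("conservation stage needs 'alignments'")
  mat <- blosum62()
  epis <- if (!is.null(cfg$epitopes)) read_epitopes(cfg$epitopes)
  out <- list()
  for (al in names(cfg$alignments)) {
    a <- read_alignment(cfg$alignments[[al]],
                        format = cfg$format %||% "fasta")
    prot <- protein_similarity_scores(
      a, matrix = mat, threshold_count = cfg$threshold_count,
      similar_cutoff = cfg$similar_cutoff %||% 1)
    out[[al]] <- list(protein_percent = round(prot$percent, 1))
    if (!is.null(epis)) {
      mine <- Filter(function(e) e$allergen == al, epis)
      if (length(mine)) {
        tab <- epitope_similarity_table(
          a, mine, matrix = mat, threshold_count = cfg$threshold_count,
          similar_cutoff = cfg$similar_cutoff %||% 1)
        utils::write.table(
          data.frame(epitope = rownames(tab), round(tab, 1),
                     check.names = FALSE),
          file.path(config$out_dir,
                    paste0("conservation_", al, "_epitopes.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
        out[[al]]$epitope_percent <- round(tab, 1)
      }
    }
    log("conservation: %s scored (%d sequences)", al, length(a))
  }
  prot_tab <- do.call(rbind, lapply(out, `[[`, "protein_percent"))
  utils::write.table(
    data.frame(allergen = rownames(prot_tab), prot_tab, check.names = FALSE),
    file.path(config$out_dir, "conservation_proteins.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

.stage_serology <- function(config, log) {
  cfg <- config$serology
  if (is.null(cfg$plate)) stop("serology stage needs a 'plate' path")
  plate <- read_od_plate(cfg$plate)
  neg <- plate$od[plate$status == "nonallergic"]
  cutoff <- elisa_cutoff(neg, multiplier = cfg$cutoff_multiplier %||% 3)
  calls <- call_positives(plate[plate$status == "allergic", ], cutoff)
  utils::write.table(calls, file.path(config$out_dir, "serology_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rates <- lapply(split(calls, calls$antigen), function(d) {
    unclass(sensitization_rate(d$positive, antigen = d$antigen[1]))
  })
  log("serology: cutoff %.4f, %d antigens", cutoff, length(rates))
  out <- list(cutoff = cutoff, rates = rates)
  if (!is.null(cfg$inhibition)) {
    series <- read_inhibition_series(cfg$inhibition)
    out$inhibition <- lapply(series, function(s) {
      d <- data.frame(concentration_ug_ml = s$concentrations,
                      signal = s$signals,
                      percent_inhibition = round(s$percent_inhibition, 1))
      utils::write.table(
        d, file.path(config$out_dir,
                     paste0("inhibition_", s$inhibitor, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      inhibition_summary(s)
    })
    log("serology: %d inhibition series summarized", length(series))
  }
  out
}

.stage_expression <- function(config, log) {
  cfg <- config$expression
  quant <- cfg[["quant"]]   # exact: $quant would partial-match quant_dir
  if (is.null(quant) && !is.null(cfg$quant_dir)) {
    quant <- list.files(cfg$quant_dir, pattern = "^quant\\.sf$",
                        recursive = TRUE, full.names = TRUE)
  }
  if (is.null(quant) || !length(quant)) stop("expression stage needs quant files")
  tpm <- read_quant(unlist(quant))
  mapping <- utils::read.table(cfg$mapping, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  samples <- utils::read.table(cfg$samples, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  t <- expression_table(tpm, mapping, samples)
  agg <- aggregate_to_allergen(t)
  hm <- heatmap_normalize(agg, scale_columns = isTRUE(cfg$scale_columns))
  utils::write.table(
    data.frame(allergen = rownames(hm), round(unclass(hm), 2),
               check.names = FALSE),
    file.path(config$out_dir, "expression_heatmap.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # cross-species comparisons on per-sample allergen values; mixed-tissue
  # samples excluded by default
  keep <- if (isTRUE(cfg$exclude_mixed_tissue %||% TRUE)) {
    t$samples$tissue != "mixed"
  } else rep(TRUE, ncol(agg))
  vals <- agg[, keep, drop = FALSE]
  long <- data.frame(value = as.vector(log2(vals + 1)),
                     allergen = rep(rownames(vals), ncol(vals)))
  long <- long[!is.na(long$value), ]
  cmp <- group_compare(long$value, long$allergen)
  cmp$pairwise$code <- significance_codes(cmp$pairwise$p_adj)
  utils::write.table(cmp$pairwise,
                     file.path(config$out_dir, "expression_codes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log("expression: %d allergens x %d samples, ANOVA p = %.3g",
      nrow(agg), ncol(agg), cmp$p_value)
  list(heatmap = unclass(round(hm, 2)), anova_p = cmp$p_value,
       f_statistic = cmp$f_statistic,
       n_samples_tested = sum(keep))
}
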