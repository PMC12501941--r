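#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with the defaults
#' used throughout: strict and relaxed p-value cutoffs (0.01 / 0.05),
#' absolute log2 fold-change minimum (1), heatmap variability fraction
#' (top 30% by sd), zero-replacement floor (0.1) and the peptide mean
#' signal-to-noise minimum (3). All are overridable.
#'
#' @param p_strict strict p threshold (volcano / concordance).
#' @param p_relaxed relaxed p threshold (membrane analysis).
#' @param lfc_min absolute log2 fold-change threshold.
#' @param sd_top_frac heatmap sd fraction.
#' @param zero_floor zero replacement value.
#' @param peptide_sn_min peptide mean-S/N minimum.
#' @param seed root seed for every stochastic stage.
#' @param synthetic NULL, or a [synthetic_params()] object to generate
#'   inputs instead of reading them.
#' @param paths named list of input paths (`quant`, `design`,
#'   `contaminants`, `annotations`, `gene_sets`, `plates`); unused
#'   entries may be NULL.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(p_strict = 0.01, p_relaxed = 0.05,
                            lfc_min = 1, sd_top_frac = 0.3,
                            zero_floor = 0.1, peptide_sn_min = 3,
                            seed = 1L, synthetic = NULL,
                            paths = list()) {
  stopifnot(p_strict > 0, p_relaxed > 0, lfc_min > 0,
            sd_top_frac > 0, sd_top_frac < 1, zero_floor > 0,
            peptide_sn_min >= 0)
  structure(list(p_strict = p_strict, p_relaxed = p_relaxed,
                 lfc_min = lfc_min, sd_top_frac = sd_top_frac,
                 zero_floor = zero_floor,
                 peptide_sn_min = peptide_sn_min,
                 seed = as.integer(seed), synthetic = synthetic,
                 paths = paths),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes ingest -> normalization -> differential -> concordance and
#' membrane analysis (-> enrichment and dose-response when inputs are
#' given), writing each stage's table under `outdir` and recording a
#' manifest of stages, row counts and output-file hashes. With a
#' synthetic configuration the inputs are generated first and the
#' ground truth is written alongside.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed); NULL skips all
#'   file output.
#' @return a `run_manifest`: list with `config`, `stages` (data.frame
#'   of stage, n_proteins, output, md5), and `results` (the in-memory
#'   stage outputs: `quant`, `filtered`, `normalized`, `diff_table`,
#'   `sig_strict`, `sig_relaxed`, `concordance`, `membrane`, `truth`
#'   where applicable).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  stages <- list()
  results <- list()
  emit <- function(stage, n, obj = NULL, writer = NULL, filename = NULL) {
    path <- NA_character_; md5 <- NA_character_
    if (!is.null(outdir) && !is.null(writer)) {
      path <- file.path(outdir, filename)
      writer(obj, path)
      md5 <- unname(tools::md5sum(path))
    }
    stages[[length(stages) + 1]] <<- data.frame(
      stage = stage, n_proteins = n, output = path, md5 = md5,
      stringsAsFactors = FALSE)
  }

  # --- inputs
  contaminants <- character(0)
  if (!is.null(config$synthetic)) {
    params <- config$synthetic
    ds <- simulate_dataset(params, seed = config$seed)
    q <- ds$quant
    results$truth <- ds$truth
    contaminants <- ds$truth$proteins$accession[
      ds$truth$proteins$is_contaminant]
    if (!is.null(outdir)) {
      write_quant_tsv(q, file.path(outdir, "quant.tsv"))
      write_truth_tsv(ds$truth, file.path(outdir, "truth.tsv"))
    }
  } else {
    q <- read_quant_tsv(config$paths$quant, config$paths$design)
    if (!is.null(config$paths$contaminants))
      contaminants <- read_contaminants(config$paths$contaminants)
  }
  results$quant <- q
  emit("ingest", nrow(q$values))

  # --- filtering
  q <- filter_master_proteins(q)
  emit("master_filter", nrow(q$values))
  q <- remove_contaminants(q, contaminants)
  results$filtered <- q
  emit("contaminant_filter", nrow(q$values), q, write_quant_tsv,
       "filtered.tsv")

  # --- normalization
  norm <- normalize_quant(q, floor = config$zero_floor)
  results$normalized <- norm
  emit("normalize", nrow(norm$values), norm, write_quant_tsv,
       "normalized.tsv")

  # --- differential
  tab <- compute_lfc(norm)
  results$diff_table <- tab
  emit("differential", nrow(tab), tab,
       function(o, p) utils::write.table(o, p, sep = "\t",
                                         quote = FALSE,
                                         row.names = FALSE),
       "differential.tsv")
  results$sig_strict <- volcano_filter(tab, config$p_strict,
                                       config$lfc_min)
  results$sig_relaxed <- volcano_filter(tab, config$p_relaxed,
                                        config$lfc_min)

  # --- concordance & membrane
  results$concordance <- classify_concordance(results$sig_strict)
  emit("concordance", nrow(results$concordance$records),
       results$concordance$records,
       function(o, p) utils::write.table(o, p, sep = "\t",
                                         quote = FALSE,
                                         row.names = FALSE),
       "concordance.tsv")
  if (!is.null(config$paths$annotations)) {
    annot <- read_annotation_tsv(config$paths$annotations)
    results$membrane <- membrane_ratio(results$sig_relaxed, annot,
                                       accessions(q))
    emit("membrane", nrow(results$membrane), results$membrane,
         function(o, p) utils::write.table(o, p, sep = "\t",
                                           quote = FALSE,
                                           row.names = FALSE),
         "membrane.tsv")
  }

  # --- enrichment (optional)
  if (!is.null(config$paths$gene_sets)) {
    sets <- read_gmt(config$paths$gene_sets)
    conc <- results$concordance
    common <- conc$records$accession[
      conc$records$class %in% c("common_up", "common_down")]
    if (length(common) > 0) {
      results$ora <- ora_analysis(common, sets, accessions(q))
      emit("ora", nrow(results$ora))
    }
  }

  # --- dose-response (optional)
  if (!is.null(config$paths$plates)) {
    plate <- read_plate_csv(config$paths$plates)
    pct <- percent_of_control(plate)
    fits <- lapply(split(pct, pct$condition), function(pp)
      fit_4pl(pp$concentration_uM, pp$mean_pct))
    results$dose_response <- fits
    emit("dose_response", length(fits))
  }

  manifest <- structure(
    list(config = config, stages = do.call(rbind, stages),
         results = results),
    class = "run_manifest")
  manifest
}

#' Summary counts in the style of the study's reporting
#'
#' From a completed manifest, tabulates the quantified-protein total,
#' per-cell-line differential counts at the strict thresholds, the
#' all-lines concordance class counts (and their conservation sum),
#' and, when a membrane analysis ran, the annotated counts and ratios.
#'
#' @param manifest a [run_pipeline()] manifest.
#' @return list with `n_quantified`, `per_line` (named counts),
#'   `concordance` (named class counts), `n_common_all` (their sum over
#'   the all-lines classes), and optionally `membrane`.
#' @export
report_counts <- function(manifest) {
  res <- manifest$results
  per_line <- vapply(res$sig_strict,
                     function(s) length(s$up) + length(s$down),
                     integer(1))
  cc <- res$concordance$counts
  out <- list(n_quantified = nrow(res$filtered$values),
              per_line = per_line,
              concordance = cc,
              n_common_all = unname(cc["common_up"] + cc["common_down"] +
                                    cc["discordant"]))
  if (!is.null(res$membrane)) out$membrane <- res$membrane
  out
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("spheroprot run manifest (seed ", x$config$seed, ")\n", sep = "")
  print(x$stages[, c("stage", "n_proteins")], row.names = FALSE)
  invisible(x)
}
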