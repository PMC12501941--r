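#' Study design: multiplexed batch/channel layout
#'
#' Builds a randomized but seed-reproducible assignment of biological
#' samples to (batch, channel) slots across a set of isobaric-labeling
#' (TMTpro) batches, with a fixed number of pooled-reference channels in
#' every batch. Reference pools are formed by randomly partitioning the
#' biological samples into `references_per_batch` sets; one aliquot of
#' each pool is run in every batch so that cross-batch normalization is
#' possible.
#'
#' @param cell_lines character vector of cell-line labels.
#' @param replicates biological replicates per (cell line, dimension).
#' @param n_batches number of TMT batches.
#' @param references_per_batch number of pooled-reference channels per
#'   batch (also the number of distinct reference pools).
#' @param plex_capacity maximum channels per batch (18 for TMTpro).
#' @param dimensions culture-dimension labels, default `c("2D","3D")`.
#' @param seed integer RNG seed; same seed gives an identical layout.
#' @return a `study_design`: data.frame with columns `batch`, `channel`,
#'   `channel_id`, `sample_id`, `cell_line`, `dimension`, `replicate`,
#'   `is_reference`, `ref_set`.
#' @examples
#' d <- generate_design(seed = 1)
#' table(d$batch, d$is_reference)
#' @export
generate_design <- function(cell_lines = c("PEO1", "PEO4", "UWB1.289",
                                           "UWB1.289+BRCA1"),
                            replicates = 3, n_batches = 4,
                            references_per_batch = 3, plex_capacity = 18,
                            dimensions = c("2D", "3D"), seed = 1L) {
  stopifnot(length(cell_lines) >= 1, replicates >= 1, n_batches >= 1,
            references_per_batch >= 1)
  samples <- expand.grid(replicate = seq_len(replicates),
                         dimension = dimensions,
                         cell_line = cell_lines,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("cell_line", "dimension", "replicate")]
  samples$sample_id <- sprintf("%s_%s_r%d", samples$cell_line,
                               samples$dimension, samples$replicate)
  n <- nrow(samples)

  # balanced dealing: batch sizes differ by at most one
  per_batch <- rep(n %/% n_batches, n_batches)
  extra <- n %% n_batches
  if (extra > 0) per_batch[seq_len(extra)] <- per_batch[seq_len(extra)] + 1L
  overfull <- which(per_batch + references_per_batch > plex_capacity)
  if (length(overfull))
    stop(sprintf(
      "batch %d would need %d channels, exceeding the %d-plex capacity",
      overfull[1], per_batch[overfull[1]] + references_per_batch,
      plex_capacity))

  set.seed(seed)
  ord <- sample.int(n)
  samples <- samples[ord, , drop = FALSE]
  samples$batch <- rep(seq_len(n_batches), times = per_batch)
  # random partition of samples into reference pools
  samples$ref_set <- sample(rep_len(seq_len(references_per_batch), n))

  rows <- lapply(seq_len(n_batches), function(b) {
    sb <- samples[samples$batch == b, , drop = FALSE]
    refs <- data.frame(
      batch = b, channel = seq_len(references_per_batch),
      sample_id = sprintf("ref%d_b%d", seq_len(references_per_batch), b),
      cell_line = NA_character_, dimension = NA_character_,
      replicate = NA_integer_, is_reference = TRUE,
      ref_set = seq_len(references_per_batch),
      stringsAsFactors = FALSE)
    bio <- data.frame(
      batch = b, channel = references_per_batch + seq_len(nrow(sb)),
      sample_id = sb$sample_id, cell_line = sb$cell_line,
      dimension = sb$dimension, replicate = sb$replicate,
      is_reference = FALSE, ref_set = sb$ref_set,
      stringsAsFactors = FALSE)
    rbind(refs, bio)
  })
  design <- do.call(rbind, rows)
  design$channel_id <- sprintf("%d:%d", design$batch, design$channel)
  design <- design[, c("channel_id", "batch", "channel", "sample_id",
                       "cell_line", "dimension", "replicate",
                       "is_reference", "ref_set")]
  rownames(design) <- NULL
  class(design) <- c("study_design", "data.frame")
  design
}

#' Synthetic-data generation parameters
#'
#' Collects the generative-model parameters with validation. Defaults
#' describe a deep-coverage experiment: ~6000 quantified proteins, 10%
#' carrying a true culture-dimension effect of 2 log2 units, 90% of
#' those shared with one sign across all cell lines, moderate cell-line
#' baseline variation, batch effects comparable to biological noise,
#' and observed zeros at under 0.5% of measurements.
#'
#' @param n_proteins number of (human) protein rows.
#' @param frac_de fraction of proteins with a true 3D-vs-2D effect.
#' @param effect_log2 magnitude of the true dimension shift (log2).
#' @param frac_common fraction of differential proteins whose effect has
#'   one shared sign across all cell lines.
#' @param cellline_effect_sd log2 sd of per-(protein, cell line)
#'   baseline offsets.
#' @param batch_effect_sd log2 sd of per-(protein, batch) multiplicative
#'   offsets.
#' @param noise_sd log2 sd of replicate-level biological/technical noise.
#' @param zero_rate probability a sample-channel measurement is reported
#'   as zero; must lie in [0, 0.05].
#' @param n_contaminants contaminant (mouse matrix protein) rows, spiked
#'   only into 3D sample channels.
#' @param baseline_mean,baseline_sd log2 location and spread of protein
#'   baseline abundances (signal-to-noise-like scale).
#' @param seed integer RNG seed for the whole generation.
#' @return a validated `synthetic_params` list.
#' @export
synthetic_params <- function(n_proteins = 6000, frac_de = 0.1,
                             effect_log2 = 2, frac_common = 0.9,
                             cellline_effect_sd = 0.5,
                             batch_effect_sd = 0.25, noise_sd = 0.25,
                             zero_rate = 0.004, n_contaminants = 40,
                             baseline_mean = 7, baseline_sd = 2,
                             seed = 1L) {
  stopifnot(n_proteins >= 1, frac_de >= 0, frac_de <= 1,
            frac_common >= 0, frac_common <= 1,
            cellline_effect_sd >= 0, batch_effect_sd >= 0, noise_sd >= 0,
            zero_rate >= 0, zero_rate <= 0.05, n_contaminants >= 0,
            effect_log2 >= 0)
  structure(list(n_proteins = as.integer(n_proteins), frac_de = frac_de,
                 effect_log2 = effect_log2, frac_common = frac_common,
                 cellline_effect_sd = cellline_effect_sd,
                 batch_effect_sd = batch_effect_sd, noise_sd = noise_sd,
                 zero_rate = zero_rate,
                 n_contaminants = as.integer(n_contaminants),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

#' Ground truth for a synthetic dataset
#'
#' Draws per-protein baselines, cell-line offsets and true differential
#' effects. Exactly `round(n_proteins * frac_de)` proteins are
#' differential; of those, `round(frac_common * n_de)` share one sign
#' across all cell lines and the remainder get independent per-line
#' signs. The full dimension effect is placed on the 3D condition, so
#' the true log2 fold change (3D minus 2D) of a differential protein in
#' a given line is `sign * effect_log2`.
#'
#' @param params a [synthetic_params()] object.
#' @param design a [generate_design()] layout.
#' @return a `ground_truth` list: `proteins` (data.frame with
#'   `accession`, `is_de`, `is_common`, `is_contaminant` and per-line
#'   `sign_<line>` columns) and `mu`, a 3-d array
#'   (protein x cell line x dimension) of true log2 means. Contaminant
#'   rows appear in `proteins` but not in `mu`; their log2 abundance in
#'   3D samples is in `contaminant_mu`.
#' @export
generate_truth <- function(params, design) {
  stopifnot(inherits(params, "synthetic_params"))
  lines <- unique(design$cell_line[!design$is_reference])
  dims <- unique(design$dimension[!design$is_reference])
  stopifnot(length(dims) == 2)
  set.seed(params$seed)
  p <- params$n_proteins
  acc <- sprintf("HUM%05d", seq_len(p))

  n_de <- round(p * params$frac_de)
  n_common <- round(n_de * params$frac_common)
  de_idx <- if (n_de > 0) sample.int(p, n_de) else integer(0)
  common_idx <- if (n_common > 0) de_idx[seq_len(n_common)] else integer(0)

  signs <- matrix(0L, p, length(lines), dimnames = list(acc, lines))
  if (n_common > 0) {
    s <- sample(c(-1L, 1L), n_common, replace = TRUE)
    signs[common_idx, ] <- s     # recycled column-wise: same sign per row
  }
  indep_idx <- setdiff(de_idx, common_idx)
  if (length(indep_idx) > 0)
    signs[indep_idx, ] <- sample(c(-1L, 1L),
                                 length(indep_idx) * length(lines),
                                 replace = TRUE)

  baseline <- stats::rnorm(p, params$baseline_mean, params$baseline_sd)
  line_off <- matrix(stats::rnorm(p * length(lines), 0,
                                  params$cellline_effect_sd),
                     p, length(lines))
  mu <- array(NA_real_, dim = c(p, length(lines), 2),
              dimnames = list(acc, lines, c("2D", "3D")))
  mu[, , "2D"] <- baseline + line_off
  mu[, , "3D"] <- baseline + line_off + signs * params$effect_log2

  proteins <- data.frame(accession = acc,
                         is_de = seq_len(p) %in% de_idx,
                         is_common = seq_len(p) %in% common_idx,
                         is_contaminant = FALSE,
                         stringsAsFactors = FALSE)
  for (ln in lines) proteins[[paste0("sign_", ln)]] <- signs[, ln]

  contaminant_mu <- NULL
  if (params$n_contaminants > 0) {
    cacc <- sprintf("CONT_MOUSE_%04d", seq_len(params$n_contaminants))
    contaminant_mu <- stats::setNames(
      stats::rnorm(params$n_contaminants, params$baseline_mean,
                   params$baseline_sd), cacc)
    crows <- data.frame(accession = cacc, is_de = FALSE,
                        is_common = FALSE, is_contaminant = TRUE,
                        stringsAsFactors = FALSE)
    for (ln in lines) crows[[paste0("sign_", ln)]] <- 0L
    proteins <- rbind(proteins, crows)
  }
  structure(list(proteins = proteins, mu = mu,
                 contaminant_mu = contaminant_mu,
                 cell_lines = lines, params = params),
            class = "ground_truth")
}

#' Generate a synthetic reporter-intensity matrix
#'
#' Implements the generative model the normalization cascade is designed
#' to invert: on the log2 scale a biological sample's abundance is
#' baseline + cell-line offset + dimension effect + replicate noise; the
#' measured channel additionally carries a per-(protein, batch)
#' multiplicative offset. A reference pool is the linear-scale mean of
#' the sample abundances pooled into its set (pooling happens before
#' labeling, so the pool sees no batch effect of its own; the batch
#' offset applies to its measured aliquot in each batch). Zeros are
#' injected only into sample channels. Contaminant rows are nonzero only
#' in 3D sample channels.
#'
#' @param params a [synthetic_params()] object.
#' @param design a [generate_design()] layout.
#' @param truth a [generate_truth()] object consistent with both.
#' @return a [quant_matrix()] on the linear scale.
#' @export
generate_quant <- function(params, design, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(params$seed + 1L)
  p <- params$n_proteins
  lines <- truth$cell_lines
  bio <- design[!design$is_reference, , drop = FALSE]
  n_bio <- nrow(bio)
  batches <- sort(unique(design$batch))

  # per-sample true abundance (linear), before any batch effect
  noise <- matrix(stats::rnorm(p * n_bio, 0, params$noise_sd), p, n_bio)
  mu_s <- truth$mu[cbind(rep(seq_len(p), n_bio),
                         rep(match(bio$cell_line, lines), each = p),
                         rep(match(bio$dimension, c("2D", "3D")), each = p))]
  A <- 2 ^ (matrix(mu_s, p, n_bio) + noise)
  colnames(A) <- bio$sample_id

  # reference pools: linear mean of each set's sample abundances
  n_ref_sets <- max(design$ref_set, na.rm = TRUE)
  pools <- vapply(seq_len(n_ref_sets), function(r)
    rowMeans(A[, bio$ref_set == r, drop = FALSE]), numeric(p))
  pools <- matrix(pools, nrow = p)

  beta <- matrix(stats::rnorm(p * length(batches), 0,
                              params$batch_effect_sd),
                 p, length(batches), dimnames = list(NULL, batches))

  values <- matrix(NA_real_, p, nrow(design),
                   dimnames = list(truth$proteins$accession[seq_len(p)],
                                   design$channel_id))
  for (j in seq_len(nrow(design))) {
    b <- match(design$batch[j], batches)
    if (design$is_reference[j]) {
      values[, j] <- pools[, design$ref_set[j]] * 2 ^ beta[, b]
    } else {
      s <- match(design$sample_id[j], bio$sample_id)
      values[, j] <- A[, s] * 2 ^ beta[, b]
    }
  }

  # sparse observed zeros, sample channels only
  if (params$zero_rate > 0) {
    sc <- which(!design$is_reference)
    zmask <- matrix(stats::runif(p * length(sc)) < params$zero_rate,
                    p, length(sc))
    values[, sc][zmask] <- 0
  }

  # contaminants: nonzero only in 3D sample channels
  if (params$n_contaminants > 0) {
    cacc <- names(truth$contaminant_mu)
    cvals <- matrix(0, length(cacc), nrow(design),
                    dimnames = list(cacc, design$channel_id))
    is3d <- !design$is_reference & design$dimension == "3D"
    cnoise <- matrix(stats::rnorm(length(cacc) * sum(is3d), 0,
                                  params$noise_sd),
                     length(cacc), sum(is3d))
    cvals[, is3d] <- 2 ^ (truth$contaminant_mu + cnoise)
    values <- rbind(values, cvals)
  }
  quant_matrix(values, as.data.frame(design), stage = "linear")
}

#' One-call synthetic dataset
#'
#' Convenience wrapper producing design, truth and quantification matrix
#' from a single parameter object.
#'
#' @param params a [synthetic_params()] object.
#' @param ... passed to [generate_design()] (the design seed defaults to
#'   the params seed).
#' @return list with `design`, `truth`, `quant`.
#' @export
simulate_dataset <- function(params = synthetic_params(), ...) {
  args <- list(...)
  if (is.null(args$seed)) args$seed <- params$seed
  design <- do.call(generate_design, args)
  truth <- generate_truth(params, design)
  quant <- generate_quant(params, design, truth)
  list(design = design, truth = truth, quant = quant)
}
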