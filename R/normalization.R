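#' Replace observed zeros with a small floor
#'
#' Observed zeros (biological absence) are replaced with a small
#' positive floor so that ratios and log transforms are defined; `NA`s
#' are left untouched.
#'
#' @param q a linear-scale [quant_matrix()].
#' @param floor positive replacement value, default 0.1.
#' @return a [quant_matrix()] with no zeros.
#' @export
replace_zeros <- function(q, floor = 0.1) {
  if (!is.numeric(floor) || floor <= 0) stop("`floor` must be > 0")
  v <- q$values
  v[!is.na(v) & v == 0] <- floor
  with_values(q, v)
}

#' Sample-wise median normalization
#'
#' Each channel is divided by its own median (over finite values) and
#' rescaled by the grand median of all channel medians, so that after
#' normalization every channel shares the same median while values stay
#' on an interpretable signal-to-noise-like scale.
#'
#' @param q a linear-scale [quant_matrix()] (zeros already floored).
#' @return the normalized [quant_matrix()].
#' @export
median_normalize <- function(q) {
  med <- apply(q$values, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(med)) || any(med == 0))
    stop("channel with median 0 or no finite values; run replace_zeros first")
  grand <- stats::median(med)
  v <- sweep(q$values, 2, med, "/") * grand
  with_values(q, v)
}

#' Log2 transform
#' @param q a linear-scale [quant_matrix()] with strictly positive
#'   (or `NA`) values.
#' @return a [quant_matrix()] at stage `"raw-log2"`.
#' @export
log2_transform <- function(q) {
  if (any(q$values[!is.na(q$values)] <= 0))
    stop("nonpositive values present; run replace_zeros first")
  with_values(q, log2(q$values), stage = "raw-log2")
}

#' Scale by the pooled-reference channels of each batch
#'
#' Within each batch, the per-protein mean of that batch's reference
#' channels is subtracted from every channel of the batch (references
#' included, so that cross-batch reference replicates become directly
#' comparable). Because a per-(protein, batch) multiplicative offset
#' shifts samples and reference aliquots of a batch equally on the log2
#' scale, this subtraction removes batch effects exactly under the
#' additive model.
#'
#' @param m a log2-scale [quant_matrix()].
#' @return a [quant_matrix()] at stage `"reference-scaled"`.
#' @export
reference_scale <- function(m) {
  if (m$stage == "linear")
    stop("reference_scale expects log2-scale values")
  d <- m$design
  v <- m$values
  for (b in unique(d$batch)) {
    cols <- which(d$batch == b)
    refs <- cols[d$is_reference[cols]]
    if (length(refs) == 0)
      stop("batch ", b, " has no reference channels")
    ref_mean <- rowMeans(v[, refs, drop = FALSE], na.rm = TRUE)
    if (all(is.na(ref_mean)))
      stop("batch ", b, " reference channels contain no finite values")
    v[, cols] <- v[, cols, drop = FALSE] - ref_mean
  }
  with_values(m, v, stage = "reference-scaled")
}

#' Center each protein at zero across all samples
#'
#' Subtracts from each row its mean over the biological sample channels
#' (finite entries only; reference channels do not contribute to the
#' mean but are shifted by the same amount).
#'
#' @param m a log2-scale [quant_matrix()].
#' @return a [quant_matrix()] at stage `"centered"`.
#' @export
center_rows <- function(m) {
  sc <- sample_channels(m)
  rm_ <- rowMeans(m$values[, sc, drop = FALSE], na.rm = TRUE)
  rm_[is.nan(rm_)] <- 0
  with_values(m, m$values - rm_, stage = "centered")
}

#' Full normalization cascade
#'
#' Convenience composition of [replace_zeros()], [median_normalize()],
#' [log2_transform()], [reference_scale()] and [center_rows()], in that
#' order.
#'
#' The median step estimates per-channel loading factors from order
#' statistics; when channels truly share a common loading (as synthetic
#' data does by construction) it is a no-op only in expectation, with
#' O(1/(n * density)) realization error. Exactness checks therefore
#' disable it via `median_norm = FALSE`; real data should keep it on.
#'
#' @param q a linear-scale [quant_matrix()].
#' @param floor zero-replacement floor.
#' @param median_norm apply the sample-wise median step (default TRUE).
#' @return a centered log2 [quant_matrix()].
#' @export
normalize_quant <- function(q, floor = 0.1, median_norm = TRUE) {
  q <- replace_zeros(q, floor)
  if (median_norm) q <- median_normalize(q)
  center_rows(reference_scale(log2_transform(q)))
}

#' Principal component analysis of the channels
#'
#' Singular-value decomposition of the row-mean-subtracted protein
#' matrix; each channel (sample) gets a score per component. Proteins
#' with any missing value are excluded from the decomposition.
#'
#' @param m a log2-scale [quant_matrix()].
#' @param k number of components to keep.
#' @param channels which channels to include (`"all"` or `"samples"`).
#' @return a `pca_result`: `scores` (channels x k), `var_frac`
#'   (variance fraction per component), `design` rows of the channels
#'   used.
#' @export
run_pca <- function(m, k = 2, channels = c("all", "samples")) {
  channels <- match.arg(channels)
  cols <- if (channels == "samples") sample_channels(m)
          else seq_len(ncol(m$values))
  v <- m$values[, cols, drop = FALSE]
  v <- v[stats::complete.cases(v), , drop = FALSE]
  if (nrow(v) == 0) stop("no complete rows for PCA")
  if (k > min(dim(v))) stop("k exceeds matrix rank bound")
  centered <- v - rowMeans(v)
  s <- svd(centered)
  if (max(s$d) == 0) stop("degenerate input: no variance")
  ev <- s$d^2
  scores <- s$v %*% diag(s$d, length(s$d))
  rownames(scores) <- colnames(v)
  structure(list(scores = scores[, seq_len(k), drop = FALSE],
                 var_frac = ev[seq_len(k)] / sum(ev),
                 design = m$design[cols, , drop = FALSE]),
            class = "pca_result")
}

#' Pairwise correlation matrices
#'
#' `level = "sample"` gives the Pearson correlation of channel profiles
#' (the sample-clustering QC display); `level = "ratio"` expects a
#' matrix of per-cell-line 3D/2D log2 ratios (proteins x cell lines,
#' e.g. the `lfc_*` columns of a differential table) and correlates the
#' ratio vectors. Missing values are excluded pairwise; a constant
#' column yields `NA` with a warning.
#'
#' @param x a log2 [quant_matrix()] (sample level) or numeric matrix of
#'   ratio vectors (ratio level).
#' @param level `"sample"` or `"ratio"`.
#' @param include_references include reference channels at sample level?
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x, level = c("sample", "ratio"),
                               include_references = FALSE) {
  level <- match.arg(level)
  v <- if (level == "sample") {
    stopifnot(inherits(x, "quant_matrix"))
    cols <- if (include_references) seq_len(ncol(x$values))
            else sample_channels(x)
    x$values[, cols, drop = FALSE]
  } else {
    as.matrix(x)
  }
  sds <- apply(v, 2, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0))
    warning("constant column(s): correlations reported as NA")
  cc <- suppressWarnings(
    stats::cor(v, use = "pairwise.complete.obs", method = "pearson"))
  diag(cc) <- 1
  cc
}
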