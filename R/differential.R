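#' Classical one-way ANOVA from explicit sums of squares
#'
#' Equal-variance one-way ANOVA computed directly from the between- and
#' within-group sums of squares (not delegated to a model-fitting
#' routine). With two groups the F statistic equals the square of the
#' pooled two-sample t statistic.
#'
#' Degenerate cases: if every value is identical, `F = 0, p = 1`; if the
#' within-group variance is exactly zero but the group means differ,
#' the p-value is reported as the smallest representable positive
#' double and flagged via the `degenerate` field.
#'
#' @param values numeric vector of observations (NAs dropped).
#' @param groups group labels, same length as `values`.
#' @return list with `F`, `p`, `df1`, `df2`, `degenerate`.
#' @export
oneway_anova <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  groups <- droplevels(groups)
  n <- length(values)
  k <- nlevels(groups)
  if (k < 2) stop("need >= 2 groups with finite values")
  if (any(tabulate(groups) < 2))
    stop("every group needs >= 2 finite values")
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tabulate(groups)
  ss_between <- sum(ns * (means - gm)^2)
  ss_within <- sum((values - means[as.integer(groups)])^2)
  df1 <- k - 1
  df2 <- n - k
  if (ss_between == 0 && ss_within == 0)
    return(list(F = 0, p = 1, df1 = df1, df2 = df2, degenerate = FALSE))
  if (ss_within == 0)
    return(list(F = Inf, p = .Machine$double.xmin, df1 = df1, df2 = df2,
                degenerate = TRUE))
  Fstat <- (ss_between / df1) / (ss_within / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, degenerate = FALSE)
}

# row-wise ANOVA p over a value matrix given a channel grouping
row_anova_p <- function(values, groups) {
  apply(values, 1, function(v) {
    res <- tryCatch(oneway_anova(v, groups), error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$p
  })
}

#' Differential table: per-line fold changes and p-values
#'
#' For each protein, computes the global ANOVA p across all
#' (cell line x dimension) groups, and per cell line the 3D-vs-2D log2
#' fold change (mean over 3D replicates minus mean over 2D replicates;
#' positive = up in spheroids) together with the two-group ANOVA
#' p-value on that line's samples. Reference channels are excluded.
#'
#' @param m a normalized log2 [quant_matrix()].
#' @return a `data.frame` with columns `accession`, `anova_p`, then
#'   `lfc_<line>` and `p_<line>` per cell line; attribute `cell_lines`
#'   lists the lines.
#' @export
compute_lfc <- function(m) {
  d <- m$design
  sc <- sample_channels(m)
  v <- m$values[, sc, drop = FALSE]
  ds <- d[sc, , drop = FALSE]
  lines <- unique(ds$cell_line)
  group <- paste(ds$cell_line, ds$dimension, sep = ":")

  tab <- data.frame(accession = rownames(v),
                    anova_p = row_anova_p(v, group),
                    stringsAsFactors = FALSE)
  for (ln in lines) {
    i3 <- which(ds$cell_line == ln & ds$dimension == "3D")
    i2 <- which(ds$cell_line == ln & ds$dimension == "2D")
    if (length(i3) == 0 || length(i2) == 0) {
      warning("cell line ", ln, " lacks one dimension; lfc set to NA")
      tab[[paste0("lfc_", ln)]] <- NA_real_
      tab[[paste0("p_", ln)]] <- NA_real_
      next
    }
    m3 <- rowMeans(v[, i3, drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(v[, i2, drop = FALSE], na.rm = TRUE)
    tab[[paste0("lfc_", ln)]] <- m3 - m2
    tab[[paste0("p_", ln)]] <- row_anova_p(
      v[, c(i3, i2), drop = FALSE],
      rep(c("3D", "2D"), c(length(i3), length(i2))))
  }
  attr(tab, "cell_lines") <- lines
  tab
}

#' Threshold a differential table (volcano filter)
#'
#' A protein is significant for a cell line iff its pairwise p-value is
#' strictly below `p_thresh` and its absolute log2 fold change is
#' strictly above `lfc_thresh` (both inequalities strict, as the
#' display convention "p < x, |lfc| > y" implies).
#'
#' @param tab a [compute_lfc()] table.
#' @param p_thresh p-value threshold (default 0.01).
#' @param lfc_thresh absolute log2 fold-change threshold (default 1).
#' @return named list per cell line, each a list with `up` and `down`
#'   character vectors of accessions.
#' @export
volcano_filter <- function(tab, p_thresh = 0.01, lfc_thresh = 1) {
  stopifnot(p_thresh > 0, lfc_thresh > 0)
  lines <- attr(tab, "cell_lines")
  if (is.null(lines))
    lines <- sub("^lfc_", "", grep("^lfc_", names(tab), value = TRUE))
  out <- lapply(lines, function(ln) {
    p <- tab[[paste0("p_", ln)]]
    lfc <- tab[[paste0("lfc_", ln)]]
    sig <- !is.na(p) & !is.na(lfc) & p < p_thresh & abs(lfc) > lfc_thresh
    list(up = tab$accession[sig & lfc > 0],
         down = tab$accession[sig & lfc < 0])
  })
  names(out) <- lines
  out
}

#' Select proteins for the global heatmap
#'
#' Restricts to proteins with global ANOVA p strictly below `p_thresh`,
#' then keeps the top `top_frac` fraction (ceiling) by per-protein
#' standard deviation of the centered log2 values; ties at the cutoff
#' standard deviation are all kept.
#'
#' @param tab a [compute_lfc()] table (for `anova_p`).
#' @param m the centered log2 [quant_matrix()] used for the sd.
#' @param p_thresh ANOVA p threshold (default 0.01).
#' @param top_frac fraction of the significant set to keep (default 0.3).
#' @return list with `accessions` (selected), `sd` (named, per
#'   significant protein), `sd_cutoff`.
#' @export
heatmap_select <- function(tab, m, p_thresh = 0.01, top_frac = 0.3) {
  stopifnot(top_frac > 0, top_frac <= 1)
  sig <- tab$accession[!is.na(tab$anova_p) & tab$anova_p < p_thresh]
  if (length(sig) == 0)
    return(list(accessions = character(0), sd = numeric(0),
                sd_cutoff = NA_real_))
  sc <- sample_channels(m)
  sds <- apply(m$values[sig, sc, drop = FALSE], 1, stats::sd,
               na.rm = TRUE)
  n_keep <- ceiling(top_frac * length(sig))
  cutoff <- sort(sds, decreasing = TRUE)[n_keep]
  list(accessions = names(sds)[sds >= cutoff], sd = sds,
       sd_cutoff = cutoff)
}
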