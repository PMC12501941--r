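#' Quantification matrix container
#'
#' A `quant_matrix` bundles a proteins x channels table of reporter-ion
#' abundances (signal-to-noise on the linear scale, or log2 values after
#' transformation) with the per-channel sample metadata that every
#' downstream stage needs: which TMT batch a channel was measured in,
#' which biological sample it carries, and whether it is a pooled
#' reference channel.
#'
#' `NA` and `0` are distinct states throughout: `NA` means the protein
#' was not quantified in that channel (a missing measurement), while `0`
#' is an observed zero, treated as biological absence.
#'
#' @param values numeric matrix, rows = protein accessions (rownames
#'   required and unique), columns = channels. Column names must match
#'   `design$channel_id`.
#' @param design data.frame with one row per channel, in column order of
#'   `values`. Required columns: `channel_id`, `batch`, `channel`,
#'   `sample_id`, `cell_line`, `dimension`, `replicate`, `is_reference`.
#'   Reference channels carry `ref_set` (which pooled-reference aliquot
#'   they measure); biological samples carry the set they were pooled
#'   into.
#' @param stage character tag recording how far through the
#'   normalization cascade the values are. One of `"linear"`,
#'   `"raw-log2"`, `"reference-scaled"`, `"centered"`.
#' @return an object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, design, stage = "linear") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)) > 0)
    stop("`values` must have unique rownames (protein accessions)")
  req <- c("channel_id", "batch", "channel", "sample_id", "cell_line",
           "dimension", "replicate", "is_reference")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols))
    stop("design is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(design) != ncol(values))
    stop("design has ", nrow(design), " rows but values has ",
         ncol(values), " channels")
  if (is.null(colnames(values))) colnames(values) <- design$channel_id
  if (!identical(colnames(values), as.character(design$channel_id)))
    stop("colnames(values) must equal design$channel_id in order")
  if (any(values[is.finite(values)] < 0) && stage == "linear")
    stop("linear-scale values must be nonnegative")
  stage <- match.arg(stage,
                     c("linear", "raw-log2", "reference-scaled", "centered"))
  structure(list(values = values, design = design, stage = stage),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "quant_matrix: %d proteins x %d channels (%d sample, %d reference) | %d batch(es) | stage: %s\n",
    nrow(x$values), ncol(x$values), sum(!d$is_reference),
    sum(d$is_reference), length(unique(d$batch)), x$stage))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Accessions of a quant_matrix
#' @param q a quant_matrix
#' @return character vector of protein accessions
#' @export
accessions <- function(q) rownames(q$values)

#' Indices of biological-sample (non-reference) channels
#' @param q a quant_matrix
#' @return integer vector of column indices
#' @export
sample_channels <- function(q) which(!q$design$is_reference)

#' Indices of pooled-reference channels
#' @param q a quant_matrix
#' @return integer vector of column indices
#' @export
reference_channels <- function(q) which(q$design$is_reference)

#' Subset a quant_matrix by protein
#' @param q a quant_matrix
#' @param keep logical/integer/character index into the rows
#' @return a quant_matrix with the selected proteins
#' @export
subset_proteins <- function(q, keep) {
  quant_matrix(q$values[keep, , drop = FALSE], q$design, stage = q$stage)
}

# internal: replace the value matrix, keeping metadata
with_values <- function(q, values, stage = q$stage) {
  quant_matrix(values, q$design, stage = stage)
}
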