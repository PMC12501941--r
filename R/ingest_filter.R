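#' Aggregate peptide-level reporter values to protein level
#'
#' Applies the quantification inclusion rules used for reporter-ion
#' data: only peptides unique to a single protein group are used, and a
#' peptide contributes only if its mean reporter signal-to-noise across
#' all channels is strictly greater than `sn_min`. The protein value in
#' each channel is the sum of its retained peptides' S/N. Proteins with
#' no retained peptide are dropped.
#'
#' @param peptides data.frame with columns `peptide_id`, `accession`
#'   (the protein group; `;`-separated when shared), `unique` (logical),
#'   then one numeric column per channel.
#' @param design channel design (see [generate_design()]); its
#'   `channel_id` values name the peptide table's channel columns.
#' @param sn_min mean-S/N threshold, strict inequality (default 3).
#' @return a [quant_matrix()] of summed S/N values.
#' @export
aggregate_peptides <- function(peptides, design, sn_min = 3) {
  chan <- as.character(design$channel_id)
  missing_cols <- setdiff(chan, names(peptides))
  if (length(missing_cols))
    stop("peptide table lacks channel columns: ",
         paste(missing_cols, collapse = ", "))
  keep <- as.logical(peptides$unique)
  sn <- as.matrix(peptides[, chan, drop = FALSE])
  keep <- keep & rowMeans(sn, na.rm = TRUE) > sn_min
  if (!any(keep)) stop("no peptides survive the S/N filter")
  pep <- peptides[keep, , drop = FALSE]
  sn <- sn[keep, , drop = FALSE]
  acc <- factor(pep$accession)
  vals <- apply(sn, 2, function(col)
    tapply(col, acc, sum, na.rm = TRUE))
  vals <- matrix(vals, nrow = nlevels(acc),
                 dimnames = list(levels(acc), chan))
  quant_matrix(vals, as.data.frame(design), stage = "linear")
}

#' Retain quantifiable (master) proteins
#'
#' Drops any protein whose values are missing (`NA`) across an entire
#' batch. Proteins containing observed zeros are retained: in
#' multiplexed reporter data a zero is read as true biological absence
#' rather than a technical failure, while a batch-wide `NA` means the
#' protein was never quantified in that run.
#'
#' @param q a [quant_matrix()] with batches annotated in its design.
#' @return the filtered [quant_matrix()]; attribute `n_dropped` records
#'   the removal count.
#' @export
filter_master_proteins <- function(q) {
  batches <- unique(q$design$batch)
  all_na_somewhere <- rep(FALSE, nrow(q$values))
  for (b in batches) {
    cols <- which(q$design$batch == b)
    all_na_somewhere <- all_na_somewhere |
      rowSums(!is.na(q$values[, cols, drop = FALSE])) == 0
  }
  out <- subset_proteins(q, !all_na_somewhere)
  attr(out, "n_dropped") <- sum(all_na_somewhere)
  out
}

#' Remove contaminant protein groups
#'
#' A protein group is removed when any accession in its (possibly
#' `;`-separated) identifier appears in the contaminant list, matching
#' the practice of excluding every group containing at least one matrix
#' (mouse) accession.
#'
#' @param q a [quant_matrix()].
#' @param contaminants character vector of contaminant accessions.
#' @return the filtered [quant_matrix()]; attribute `n_removed` records
#'   how many groups were excluded.
#' @export
remove_contaminants <- function(q, contaminants) {
  if (length(contaminants) == 0) {
    attr(q, "n_removed") <- 0L
    return(q)
  }
  hit <- vapply(strsplit(rownames(q$values), ";", fixed = TRUE),
                function(a) any(a %in% contaminants), logical(1))
  out <- subset_proteins(q, !hit)
  attr(out, "n_removed") <- sum(hit)
  out
}
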