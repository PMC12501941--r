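#' Cross-cell-line concordance classification
#'
#' Intersects the per-cell-line significant sets from
#' [volcano_filter()] and classifies each protein that is significant
#' in every line by sign unanimity: `common_up` (up in all lines),
#' `common_down` (down in all lines), or `discordant` (significant in
#' all lines with mixed signs). Proteins significant in at least one
#' but not all lines are labelled `not_common`. The three
#' all-lines classes always partition the all-lines intersection, so
#' their counts sum to its size.
#'
#' @param sig per-line signed significant sets, as returned by
#'   [volcano_filter()].
#' @return list with `records` (data.frame: `accession`, per-line
#'   `sign_<line>` in {-1, 0, +1} where 0 = not significant in that
#'   line, and `class`) and `counts` (named integer vector over the
#'   four classes).
#' @export
classify_concordance <- function(sig) {
  lines <- names(sig)
  stopifnot(length(lines) >= 2)
  all_acc <- unique(unlist(lapply(sig, function(s) c(s$up, s$down))))
  if (length(all_acc) == 0) {
    counts <- stats::setNames(integer(4),
      c("common_up", "common_down", "discordant", "not_common"))
    return(list(records = data.frame(accession = character(0)),
                counts = counts))
  }
  signs <- sapply(sig, function(s) {
    out <- integer(length(all_acc))
    out[all_acc %in% s$up] <- 1L
    out[all_acc %in% s$down] <- -1L
    out
  })
  signs <- matrix(signs, nrow = length(all_acc),
                  dimnames = list(all_acc, lines))
  in_all <- rowSums(signs != 0L) == length(lines)
  cls <- ifelse(!in_all, "not_common",
         ifelse(rowSums(signs == 1L) == length(lines), "common_up",
         ifelse(rowSums(signs == -1L) == length(lines), "common_down",
                "discordant")))
  records <- data.frame(accession = all_acc, stringsAsFactors = FALSE)
  for (ln in lines) records[[paste0("sign_", ln)]] <- signs[, ln]
  records$class <- cls
  counts <- vapply(c("common_up", "common_down", "discordant",
                     "not_common"),
                   function(cl) sum(cls == cl), integer(1))
  list(records = records, counts = counts)
}

#' Membrane-annotation ratio table
#'
#' For each named differential set (typically one per cell line plus
#' intersections), counts its members carrying a plasma-membrane
#' annotation, split by direction when signed sets are given, and
#' reports the percentage of annotated members among the total. A
#' baseline row gives the annotated fraction of the whole identified
#' universe, the reference against which enrichment (or its absence) is
#' judged.
#'
#' @param sig_sets named list; each element either a character vector
#'   of accessions or a list with `up`/`down` character vectors.
#' @param annot character vector of annotated accessions.
#' @param universe character vector: all retained proteins.
#' @return data.frame with one row per set plus a `universe` baseline:
#'   `set`, `n_total`, `n_membrane`, `n_membrane_up`, `n_membrane_down`,
#'   `ratio_pct`.
#' @export
membrane_ratio <- function(sig_sets, annot, universe) {
  annot <- intersect(annot, universe)
  one_row <- function(nm, s) {
    if (is.list(s)) {
      up <- s$up; down <- s$down; all <- c(up, down)
      n_up <- sum(up %in% annot); n_down <- sum(down %in% annot)
    } else {
      all <- s; n_up <- NA_integer_; n_down <- NA_integer_
    }
    n_tot <- length(unique(all))
    n_mem <- sum(unique(all) %in% annot)
    if (n_tot == 0) {
      warning("empty differential set '", nm, "': ratio is NA")
      pct <- NA_real_
    } else pct <- 100 * n_mem / n_tot
    data.frame(set = nm, n_total = n_tot, n_membrane = n_mem,
               n_membrane_up = n_up, n_membrane_down = n_down,
               ratio_pct = pct, stringsAsFactors = FALSE)
  }
  rows <- Map(one_row, names(sig_sets), sig_sets)
  base <- data.frame(set = "universe", n_total = length(universe),
                     n_membrane = length(annot),
                     n_membrane_up = NA_integer_,
                     n_membrane_down = NA_integer_,
                     ratio_pct = 100 * length(annot) / length(universe),
                     stringsAsFactors = FALSE)
  out <- do.call(rbind, c(rows, list(base)))
  rownames(out) <- NULL
  out
}

#' Signed intersection of two cell lines' significant sets
#'
#' Proteins significant in both lines with the same direction, the
#' "commonly changing" sets reported for related cell-line pairs.
#'
#' @param a,b elements of a [volcano_filter()] result (lists with
#'   `up`/`down`).
#' @return list with `up` and `down` character vectors.
#' @export
common_signed <- function(a, b) {
  list(up = intersect(a$up, b$up), down = intersect(a$down, b$down))
}
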