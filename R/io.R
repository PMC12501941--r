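#' Write a quant_matrix to TSV
#'
#' The value table goes to `file` with first column `accession` and one
#' column per channel named `<batch>:<channel>`; `NA` is written as an
#' empty cell so that the missing-vs-zero distinction survives a round
#' trip. A `#stage=` header line records the normalization stage. The
#' design is written alongside (or to `design_file`).
#'
#' @param q a [quant_matrix()].
#' @param file path for the value table.
#' @param design_file path for the design table; default replaces the
#'   extension of `file` with `.design.tsv`.
#' @return invisibly, the two paths written.
#' @export
write_quant_tsv <- function(q, file,
                            design_file = sub("\\.tsv$", ".design.tsv",
                                              file)) {
  df <- data.frame(accession = rownames(q$values), q$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(file, "w")
  writeLines(paste0("#stage=", q$stage), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  close(con)
  write_design_tsv(q$design, design_file)
  invisible(c(file, design_file))
}

#' Read a quant_matrix from TSV
#' @param file path of a value table written by [write_quant_tsv()].
#' @param design_file path of the matching design table.
#' @return a [quant_matrix()].
#' @export
read_quant_tsv <- function(file,
                           design_file = sub("\\.tsv$", ".design.tsv",
                                             file)) {
  first <- readLines(file, n = 1)
  stage <- if (startsWith(first, "#stage=")) sub("^#stage=", "", first)
           else "linear"
  df <- utils::read.delim(file, comment.char = "#", check.names = FALSE,
                          na.strings = "", stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  mode(vals) <- "numeric"
  rownames(vals) <- df$accession
  quant_matrix(vals, read_design_tsv(design_file), stage = stage)
}

#' @rdname write_quant_tsv
#' @param design a design data.frame (see [generate_design()]).
#' @export
write_design_tsv <- function(design, file) {
  utils::write.table(as.data.frame(design), file, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname read_quant_tsv
#' @export
read_design_tsv <- function(file) {
  d <- utils::read.delim(file, check.names = FALSE, na.strings = "",
                         stringsAsFactors = FALSE)
  d$is_reference <- as.logical(d$is_reference)
  d
}

#' Read/write a ground-truth table
#' @param truth a `ground_truth` object.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_truth_tsv <- function(truth, file) {
  utils::write.table(truth$proteins, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(file)
}

#' Read a contaminant-accession list (one accession per line)
#' @param file path; blank lines and `#` comments ignored.
#' @return character vector of accessions.
#' @export
read_contaminants <- function(file) {
  x <- trimws(readLines(file))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member accessions, all
#' tab-separated (the broadly used gene-matrix-transposed dialect).
#'
#' @param file path to a `.gmt` file.
#' @return named list of character vectors; each element carries a
#'   `description` attribute.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line (need name, description, >=1 member): ",
           substr(ln, 1, 60))
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    attr(members, "description") <- parts[2]
    out[[parts[1]]] <- members
  }
  out
}

#' @rdname read_gmt
#' @param sets named list of character vectors (optionally with
#'   `description` attributes).
#' @export
write_gmt <- function(sets, file) {
  lines <- vapply(names(sets), function(nm) {
    d <- attr(sets[[nm]], "description")
    if (is.null(d)) d <- nm
    paste(c(nm, d, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Read a two-column annotation table (accession, source)
#' @param file TSV path with a header.
#' @return character vector of annotated accessions (unique).
#' @export
read_annotation_tsv <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  unique(d[[1]])
}

#' Read plate readings for dose-response analysis
#'
#' Expects CSV columns `condition, replicate, concentration_uM,
#' intensity, is_background`.
#' @param file CSV path.
#' @return data.frame of plate readings.
#' @export
read_plate_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  req <- c("condition", "replicate", "concentration_uM", "intensity",
           "is_background")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols))
    stop("plate file missing columns: ",
         paste(missing_cols, collapse = ", "))
  d$is_background <- as.logical(d$is_background)
  d
}
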