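# Delimited-text I/O for cohort tables and taxa count tables.
# Cohort: CSV, one header row, one row per child, categorical fields as
# lowercase tokens, missing values as empty cells.  Counts: TSV with the
# sample id in the first column; taxonomy as a companion TSV.

.cohort_mandatory <- c("child_id", "age", "sex", "haz", "stunting_category",
                       "comm", "ps", "pes", "fm", "gm", "overall_score")

#' Write / read a cohort table
#'
#' @param cohort cohort data frame (see [generate_cohort()]).
#' @param path file path.
#' @return \code{read_cohort} returns the cohort data frame;
#'   \code{write_cohort} returns \code{path} invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = "", check.names = FALSE)
  missing_cols <- setdiff(.cohort_mandatory, names(x))
  if (length(missing_cols))
    stop("cohort file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(x$child_id))
    stop("duplicated child ids: ",
         paste(unique(x$child_id[duplicated(x$child_id)]), collapse = ", "),
         call. = FALSE)
  x$stunting_category <- factor(x$stunting_category,
                                levels = c("normal", "moderate", "severe"))
  x
}

#' Write / read a samples x taxa count table and its taxonomy
#'
#' @param counts integer matrix, samples in rows (rownames = sample ids).
#' @param path file path (TSV; first column \code{sample_id}).
#' @return \code{read_counts} returns the integer count matrix;
#'   writers return \code{path} invisibly.
#' @export
write_counts <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id")
    stop("counts file must have 'sample_id' as its first column",
         call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicated sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "counts must be non-negative integers; first offence at sample '%s', taxon '%s'",
      ids[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' @rdname write_counts
#' @param taxonomy data frame with columns \code{taxon}, \code{family},
#'   \code{genus}.
#' @export
write_taxonomy <- function(taxonomy, path) {
  stopifnot(all(c("taxon", "family", "genus") %in% names(taxonomy)))
  utils::write.table(taxonomy[, c("taxon", "family", "genus")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_taxonomy <- function(path) {
  tx <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("taxon", "family", "genus"), names(tx))
  if (length(missing_cols))
    stop("taxonomy file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (any(is.na(tx$family) | tx$family == ""))
    stop("every taxon must have a family", call. = FALSE)
  tx
}
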