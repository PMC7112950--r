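#' Find synthetic rows that exactly replicate an original row
#'
#' A synthetic row is a replicate iff every field exactly matches some
#' original row — all variables, with missing matching missing and numeric
#' values compared exactly (donor sampling copies original doubles verbatim,
#' so exact equality is well-defined). Each synthetic row is counted once,
#' however many original rows it matches. A `FAKE_DATA` provenance column is
#' excluded from matching.
#'
#' @param original,synthetic Data frames with identical schemas.
#' @return Object of class `replicate_report`: sorted unique `indices` of
#'   replicated synthetic rows, their `count`, the `proportion` of synthetic
#'   rows, and `n_synthetic`.
#' @export
find_replicates <- function(original, synthetic) {
  original <- .strip_label(original); synthetic <- .strip_label(synthetic)
  if (!identical(unclass(schema_of(original)), unclass(schema_of(synthetic))))
    stop("original and synthetic tables have different schemas", call. = FALSE)
  idx <- which(.row_keys(synthetic) %in% .row_keys(original))
  structure(list(indices = idx, count = length(idx),
                 proportion = length(idx) / max(nrow(synthetic), 1L),
                 n_synthetic = nrow(synthetic)),
            class = "replicate_report")
}

#' @export
print.replicate_report <- function(x, ...) {
  cat(sprintf("%d of %d synthetic row(s) replicate an original row (%.1f%%)\n",
              x$count, x$n_synthetic, 100 * x$proportion))
  invisible(x)
}

#' Apply statistical disclosure control to a synthetic dataset
#'
#' Optionally removes exact replicates of original rows (reducing
#' re-identification risk) and adds a constant categorical `FAKE_DATA`
#' column as the *first* column, so that anyone encountering the file
#' without context cannot mistake it for real data. The label never alters
#' any pre-existing cell; dropping the column restores the data exactly.
#'
#' @param synthetic The synthetic data frame.
#' @param report A `replicate_report` computed against this table
#'   (required when `remove_replicates = TRUE`).
#' @param remove_replicates Drop the rows flagged in `report`?
#' @param add_label Prepend the `FAKE_DATA` column? Default `TRUE`.
#' @return The processed data frame.
#' @export
apply_sdc <- function(synthetic, report = NULL, remove_replicates = FALSE,
                      add_label = TRUE) {
  out <- synthetic
  if (remove_replicates) {
    if (is.null(report)) stop("replicate removal needs a replicate_report", call. = FALSE)
    stopifnot(inherits(report, "replicate_report"))
    if (report$n_synthetic != nrow(.strip_label(synthetic)))
      stop(sprintf("stale replicate report: computed on %d rows, table has %d",
                   report$n_synthetic, nrow(.strip_label(synthetic))), call. = FALSE)
    if (report$count > 0L) out <- out[-report$indices, , drop = FALSE]
    rownames(out) <- NULL
  }
  if (add_label && !"FAKE_DATA" %in% names(out)) {
    lab <- factor(rep("FAKE_DATA", nrow(out)), levels = "FAKE_DATA")
    out <- cbind(data.frame(FAKE_DATA = lab), out)
  }
  out
}

#' Collapse categorical levels
#'
#' Remaps chosen levels of a categorical column onto other (typically
#' broader) levels — e.g. folding a sparsely populated "70-79" age band into
#' "60-69" — updating both the values and the schema's level set. Levels not
#' named in the mapping are untouched; total row counts are conserved.
#'
#' @param data A data frame.
#' @param column Name of a categorical (factor) column.
#' @param mapping Named character vector `old_level = "new_level"`. New
#'   levels may be existing levels or fresh labels.
#' @return The data frame with the column remapped.
#' @export
collapse_levels <- function(data, column, mapping) {
  stopifnot(column %in% names(data))
  x <- data[[column]]
  if (!is.factor(x)) stop("column '", column, "' is not categorical", call. = FALSE)
  if (length(mapping) == 0L) return(data)
  if (is.null(names(mapping)) || any(!nzchar(names(mapping))))
    stop("mapping must be a named vector old_level = new_level", call. = FALSE)
  unknown <- setdiff(names(mapping), levels(x))
  if (length(unknown))
    stop("mapping names unknown level(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vals <- as.character(x)
  hit <- vals %in% names(mapping)
  vals[hit] <- unname(mapping[vals[hit]])
  new_levels <- unique(c(ifelse(levels(x) %in% names(mapping),
                                unname(mapping[levels(x)]), levels(x))))
  data[[column]] <- factor(vals, levels = new_levels)
  data
}

#' Top-code a numeric column
#'
#' Converts a numeric column to a categorical one in which every value equal
#' to or above the threshold becomes a single label (e.g. ages \eqn{\ge} 70
#' become `"70+"`), while values below keep their identity representation.
#' Missing cells stay missing.
#'
#' @param data A data frame.
#' @param column Name of a numeric column.
#' @param threshold Values `>= threshold` are collapsed.
#' @param label Label for the collapsed category.
#' @return The data frame with the column converted to a factor whose levels
#'   are the sorted below-threshold values followed by `label`.
#' @export
top_code <- function(data, column, threshold, label) {
  stopifnot(column %in% names(data))
  x <- data[[column]]
  if (!is.numeric(x)) stop("column '", column, "' is not numeric", call. = FALSE)
  vals <- ifelse(is.na(x), NA_character_,
                 ifelse(x >= threshold, label, as.character(x)))
  below <- sort(unique(x[!is.na(x) & x < threshold]))
  data[[column]] <- factor(vals, levels = c(as.character(below), label))
  data
}
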