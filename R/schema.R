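#' Declare the schema of a single column
#'
#' A column is either `numeric` (stored as double precision) or `categorical`
#' (a factor whose level set is fixed by the schema, not inferred from the
#' data, so levels with zero observed count survive synthesis and line up in
#' utility comparisons).
#'
#' @param name Column name (non-empty string).
#' @param kind Either `"numeric"` or `"categorical"`.
#' @param levels Character vector of unique, non-empty level labels; required
#'   for categorical columns and forbidden for numeric ones. Order matters:
#'   the first level is the dummy-coding reference in model fits.
#' @param na_allowed May cells of this column be missing? Default `TRUE`.
#' @return An object of class `col_schema`.
#' @seealso [table_schema()], [read_table()]
#' @export
col_schema <- function(name, kind = c("numeric", "categorical"),
                       levels = NULL, na_allowed = TRUE) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("column name must be a non-empty string", call. = FALSE)
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) == 0L)
      stop(sprintf("categorical column '%s' needs a non-empty level set", name),
           call. = FALSE)
    levels <- as.character(levels)
    if (anyDuplicated(levels))
      stop(sprintf("duplicate levels in column '%s'", name), call. = FALSE)
    if (any(!nzchar(levels)) || anyNA(levels))
      stop(sprintf("empty or NA level label in column '%s'", name), call. = FALSE)
  } else if (!is.null(levels)) {
    stop(sprintf("numeric column '%s' must not declare levels", name), call. = FALSE)
  }
  structure(list(name = name, kind = kind, levels = levels,
                 na_allowed = isTRUE(na_allowed)),
            class = "col_schema")
}

#' Assemble a table schema from column schemas
#'
#' @param ... `col_schema` objects (or a single list of them).
#' @return An object of class `table_schema`: a named list of `col_schema`.
#' @export
table_schema <- function(...) {
  cols <- list(...)
  if (length(cols) == 1L && is.list(cols[[1L]]) && !inherits(cols[[1L]], "col_schema"))
    cols <- cols[[1L]]
  if (!all(vapply(cols, inherits, logical(1L), "col_schema")))
    stop("all arguments must be col_schema objects", call. = FALSE)
  nm <- vapply(cols, `[[`, character(1L), "name")
  if (anyDuplicated(nm))
    stop("duplicate column names in schema: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  names(cols) <- nm
  structure(cols, class = "table_schema")
}

#' Derive the schema of an existing data frame
#'
#' Factor columns become categorical (their level sets are kept verbatim),
#' numeric columns become numeric. Character columns are refused: levels must
#' be declared, not inferred.
#'
#' @param data A data frame.
#' @param na_allowed Default missingness flag applied to every column.
#' @return A `table_schema`.
#' @export
schema_of <- function(data, na_allowed = TRUE) {
  stopifnot(is.data.frame(data))
  cols <- lapply(names(data), function(nm) {
    x <- data[[nm]]
    if (is.factor(x))
      col_schema(nm, "categorical", levels = levels(x), na_allowed = na_allowed)
    else if (is.numeric(x))
      col_schema(nm, "numeric", na_allowed = na_allowed)
    else
      stop(sprintf("column '%s' is neither numeric nor factor; declare a schema explicitly", nm),
           call. = FALSE)
  })
  table_schema(cols)
}

#' @export
print.table_schema <- function(x, ...) {
  cat("table schema with", length(x), "column(s):\n")
  for (cs in x) {
    if (cs$kind == "categorical")
      cat(sprintf("  %s: categorical {%s}%s\n", cs$name,
                  paste(cs$levels, collapse = ", "),
                  if (cs$na_allowed) "" else " [no NA]"))
    else
      cat(sprintf("  %s: numeric%s\n", cs$name, if (cs$na_allowed) "" else " [no NA]"))
  }
  invisible(x)
}

#' Validate a data frame against a schema
#'
#' Checks column names and order, storage kinds, level sets, equal column
#' lengths (guaranteed for a data frame) and the `na_allowed` flags.
#'
#' @param data A data frame.
#' @param schema A `table_schema`; defaults to [schema_of()] of `data`.
#' @return `data`, invisibly, with factor levels aligned to the schema.
#' @export
validate_table <- function(data, schema = schema_of(data)) {
  stopifnot(is.data.frame(data), inherits(schema, "table_schema"))
  if (!identical(names(data), names(schema)))
    stop("column names do not match schema: data has [",
         paste(names(data), collapse = ", "), "], schema has [",
         paste(names(schema), collapse = ", "), "]", call. = FALSE)
  for (cs in schema) {
    x <- data[[cs$name]]
    if (cs$kind == "numeric") {
      if (!is.numeric(x))
        stop(sprintf("column '%s' must be numeric", cs$name), call. = FALSE)
      data[[cs$name]] <- as.double(x)
    } else {
      vals <- if (is.factor(x)) as.character(x) else x
      if (!is.character(vals) && !all(is.na(vals)))
        stop(sprintf("column '%s' must be categorical", cs$name), call. = FALSE)
      bad <- which(!is.na(vals) & !(vals %in% cs$levels))
      if (length(bad))
        stop(sprintf("column '%s', row %d: value '%s' is not a declared level",
                     cs$name, bad[1L], vals[bad[1L]]), call. = FALSE)
      data[[cs$name]] <- factor(vals, levels = cs$levels)
    }
    if (!cs$na_allowed && anyNA(data[[cs$name]]))
      stop(sprintf("column '%s', row %d: missing value where na_allowed is FALSE",
                   cs$name, which(is.na(data[[cs$name]]))[1L]), call. = FALSE)
  }
  invisible(data)
}

#' Read a schema sidecar file
#'
#' The sidecar is a Debian-control-style key-value text file, one block per
#' column:
#' ```
#' name: group
#' kind: categorical
#' levels: a, b
#' na_allowed: yes
#' ```
#'
#' @param path Path to the schema file.
#' @return A `table_schema`.
#' @export
read_schema <- function(path) {
  m <- read.dcf(path, fields = c("name", "kind", "levels", "na_allowed"))
  if (nrow(m) == 0L) stop("empty schema file: ", path, call. = FALSE)
  cols <- lapply(seq_len(nrow(m)), function(i) {
    lv <- m[i, "levels"]
    lv <- if (is.na(lv)) NULL else trimws(strsplit(lv, ",", fixed = TRUE)[[1L]])
    naa <- m[i, "na_allowed"]
    naa <- is.na(naa) || tolower(trimws(naa)) %in% c("yes", "true", "1")
    col_schema(unname(m[i, "name"]), unname(m[i, "kind"]), levels = lv,
               na_allowed = naa)
  })
  table_schema(cols)
}

#' Write a schema sidecar file
#'
#' @param schema A `table_schema`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "table_schema"))
  m <- do.call(rbind, lapply(schema, function(cs)
    c(name = cs$name, kind = cs$kind,
      levels = if (is.null(cs$levels)) NA_character_ else paste(cs$levels, collapse = ", "),
      na_allowed = if (cs$na_allowed) "yes" else "no")))
  write.dcf(m, path)
  invisible(path)
}

# 17 significant digits round-trips an IEEE double exactly
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' Read a CSV data file against a schema
#'
#' The CSV must have a header row whose names match the schema exactly (same
#' order). Missing cells are recognised from `na_tokens` (empty field and
#' `"NA"` by default). Values are validated against the schema: undeclared
#' categorical levels, non-numeric cells in numeric columns and ragged rows
#' raise errors naming the offending cell.
#'
#' @param csv_path Path to the CSV file.
#' @param schema A `table_schema`, or a path to a schema sidecar file.
#' @param na_tokens Strings read as missing cells.
#' @return A validated data frame (categoricals as factors with the declared
#'   levels, numerics as doubles).
#' @export
read_table <- function(csv_path, schema, na_tokens = c("", "NA")) {
  if (is.character(schema)) schema <- read_schema(schema)
  stopifnot(inherits(schema, "table_schema"))
  raw <- utils::read.csv(csv_path, colClasses = "character", check.names = FALSE,
                         na.strings = character(0L))
  if (!identical(names(raw), names(schema)))
    stop("CSV header [", paste(names(raw), collapse = ", "),
         "] does not match schema [", paste(names(schema), collapse = ", "), "]",
         call. = FALSE)
  out <- raw
  for (cs in schema) {
    v <- raw[[cs$name]]
    v[v %in% na_tokens] <- NA_character_
    if (cs$kind == "numeric") {
      num <- suppressWarnings(as.double(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop(sprintf("column '%s', row %d: '%s' is not numeric",
                     cs$name, bad[1L], v[bad[1L]]), call. = FALSE)
      out[[cs$name]] <- num
    } else {
      out[[cs$name]] <- v
    }
  }
  validate_table(out, schema)
}

#' Write a data table to CSV
#'
#' Numeric cells are written with 17 significant digits so that
#' `read_table(write_table(t))` reproduces `t` cell for cell, including
#' missingness (emitted as the empty field). Categorical cells are quoted.
#'
#' @param data A data frame satisfying its schema.
#' @param csv_path Output path.
#' @param schema Optional `table_schema` (defaults to [schema_of()]).
#' @return `csv_path`, invisibly.
#' @export
write_table <- function(data, csv_path, schema = schema_of(data)) {
  data <- validate_table(data, schema)
  chr <- data
  for (cs in schema) {
    chr[[cs$name]] <-
      if (cs$kind == "numeric") .fmt_num(data[[cs$name]])
      else as.character(data[[cs$name]])
  }
  utils::write.csv(as.data.frame(chr, check.names = FALSE), csv_path,
                   row.names = FALSE, na = "", quote = which(vapply(schema, `[[`, character(1L), "kind") == "categorical"))
  invisible(csv_path)
}

#' Exact equality of two rows
#'
#' Two rows from schema-identical tables match iff every field is exactly
#' equal; two missing cells in the same position match. Numeric comparison is
#' exact (donor sampling copies original doubles bit for bit, so exact
#' equality is the operational definition of a replicated record).
#'
#' @param a,b Single-row data frames with identical schemas.
#' @return `TRUE` or `FALSE`.
#' @export
rows_equal <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b), nrow(a) == 1L, nrow(b) == 1L)
  sa <- schema_of(a); sb <- schema_of(b)
  if (!identical(unclass(sa), unclass(sb)))
    stop("rows come from tables with different schemas", call. = FALSE)
  .row_keys(a) == .row_keys(b)
}

# Serialize rows to collision-safe keys: numerics at full precision,
# factors as labels, NA as a sentinel outside any level alphabet.
.row_keys <- function(data) {
  cols <- lapply(data, function(x) {
    v <- if (is.numeric(x)) .fmt_num(x) else as.character(x)
    v[is.na(v)] <- "\x01NA\x01"
    v
  })
  if (length(cols) == 0L) return(character(nrow(data)))
  do.call(paste, c(cols, sep = "\x02"))
}

# Drop the FAKE_DATA provenance column if present; it is metadata, not data.
.strip_label <- function(data) {
  data[names(data) != "FAKE_DATA"]
}
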