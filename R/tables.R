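# Typed containers for the three tabular inputs the pipeline touches:
# sample-by-OTU count tables, sample-by-metabolite concentration tables, and
# the cohort sample registry. Samples are always rows internally.

ROLE_LEVELS <- c("patient", "relative", "fd_mouse", "control_mouse")

#' Construct a validated sample-by-feature count table
#'
#' The canonical abundance container: an integer matrix with samples as rows
#' and features (OTUs) as columns, plus optional taxonomy lineage strings.
#'
#' @param counts Numeric matrix of nonnegative integers. Row names are sample
#'   ids, column names are feature ids; both are required and must be unique.
#' @param taxonomy Optional named character vector mapping feature id to a
#'   lineage string. Names must be a subset of the feature ids.
#' @return An object of class `count_table` with elements `counts` and
#'   `taxonomy`.
#' @export
count_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) ||
      (ncol(counts) > 0L && is.null(colnames(counts)))) {
    stop("count_table: counts must have sample row names and feature column names")
  }
  if (anyDuplicated(rownames(counts))) stop("count_table: duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("count_table: duplicate feature ids")
  if (!is.numeric(counts)) stop("count_table: counts must be numeric")
  if (any(!is.finite(counts))) stop("count_table: non-finite counts")
  if (any(counts < 0)) stop("count_table: negative counts")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("count_table: non-integer count at sample '%s', feature '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)) || !all(names(taxonomy) %in% colnames(counts))) {
      stop("count_table: taxonomy names must be feature ids")
    }
    taxonomy <- taxonomy[intersect(colnames(counts), names(taxonomy))]
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d features (total reads %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' Sample ids of a count table
#' @param t A `count_table`.
#' @return Character vector of sample ids in table order.
#' @export
ct_samples <- function(t) rownames(t$counts)

#' Feature ids of a count table
#' @param t A `count_table`.
#' @return Character vector of feature ids in table order.
#' @export
ct_features <- function(t) colnames(t$counts)

#' Construct a validated concentration table
#'
#' @param values Nonnegative numeric matrix, samples as rows, metabolites as
#'   columns (named).
#' @param units Named character vector, one unit string per metabolite
#'   (e.g. "nanomoles/gram"). A single unnamed string is recycled.
#' @return An object of class `concentration_table`.
#' @export
concentration_table <- function(values, units) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("concentration_table: values must have sample and metabolite names")
  }
  if (anyDuplicated(rownames(values))) stop("concentration_table: duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("concentration_table: duplicate metabolite ids")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("concentration_table: values must be finite and >= 0")
  }
  if (length(units) == 1L && is.null(names(units))) {
    units <- stats::setNames(rep(units, ncol(values)), colnames(values))
  }
  if (!setequal(names(units), colnames(values))) {
    stop("concentration_table: units must name every metabolite exactly once")
  }
  units <- units[colnames(values)]
  structure(list(values = values, units = units), class = "concentration_table")
}

#' @export
print.concentration_table <- function(x, ...) {
  cat(sprintf("concentration_table: %d samples x %d metabolites (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$units), collapse = ", ")))
  invisible(x)
}

#' Construct a validated cohort metadata registry
#'
#' One row per sample. Required columns: `sample_id`, `subject_id`,
#' `family_id`, `role`, `collection_date` (ISO 8601). Any further columns are
#' carried as opaque covariates; missing values are empty strings, never
#' imputed.
#'
#' @param df A data frame with at least the required columns.
#' @return A data frame of class `cohort_metadata`.
#' @export
cohort_metadata <- function(df) {
  req <- c("sample_id", "subject_id", "family_id", "role", "collection_date")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("cohort_metadata: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cc in names(df)) df[[cc]] <- as.character(df[[cc]])
  if (anyDuplicated(df$sample_id)) stop("cohort_metadata: duplicate sample ids")
  bad_role <- setdiff(unique(df$role), ROLE_LEVELS)
  if (length(bad_role)) {
    stop("cohort_metadata: role value(s) outside vocabulary: ",
         paste(bad_role, collapse = ", "))
  }
  dates <- as.Date(df$collection_date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop("cohort_metadata: unparseable collection_date: ",
         paste(df$sample_id[is.na(dates)], collapse = ", "))
  }
  # a subject must keep one role and one family across all of its samples
  by_subj <- split(df, df$subject_id)
  for (s in by_subj) {
    if (length(unique(s$role)) > 1L || length(unique(s$family_id)) > 1L) {
      stop("cohort_metadata: subject '", s$subject_id[1],
           "' has inconsistent role or family across samples")
    }
  }
  class(df) <- c("cohort_metadata", "data.frame")
  df
}

#' Parsed collection dates of a metadata registry
#' @param meta A `cohort_metadata`.
#' @return A `Date` vector named by sample id, usable in day arithmetic.
#' @export
collection_dates <- function(meta) {
  stats::setNames(as.Date(meta$collection_date, format = "%Y-%m-%d"),
                  meta$sample_id)
}

# ---------------------------------------------------------------------------
# TSV readers/writers. All output is UTF-8, tab-separated, LF line endings,
# written field-by-field so round-trips are byte stable.

write_tsv_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines)) stop("empty file: ", path)
  strsplit(lines, "\t", fixed = TRUE)
}

parse_count_cell <- function(x, row_id, col_id) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) || abs(v - round(v)) > 1e-8) {
    stop(sprintf("non-integer count at row '%s', column '%s': '%s'",
                 row_id, col_id, x))
  }
  as.integer(round(v))
}

#' Read a count table from TSV
#'
#' Two dialects are supported. `plain_tsv` is a headered TSV whose first
#' column holds ids; `orientation` says whether rows are samples (canonical)
#' or features. `mothur_shared` is the mothur "shared" file dialect: columns
#' `label`, `Group`, `numOtus` followed by one count column per OTU, one row
#' per sample.
#'
#' @param path Path to a TSV file.
#' @param dialect `"plain_tsv"` or `"mothur_shared"`.
#' @param orientation For `plain_tsv`: `"samples"` if rows are samples,
#'   `"features"` if rows are features.
#' @return A [count_table()] (samples as rows).
#' @export
read_count_table <- function(path, dialect = c("plain_tsv", "mothur_shared"),
                             orientation = c("samples", "features")) {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  rows <- read_tsv_raw(path)
  header <- rows[[1]]
  body <- rows[-1]
  if (!length(body)) stop("count table has no data rows: ", path)
  if (dialect == "mothur_shared") {
    if (length(header) < 4L ||
        !identical(tolower(header[2:3]), c("group", "numotus"))) {
      stop("not a mothur shared file (expect label/Group/numOtus header): ", path)
    }
    otus <- header[-(1:3)]
    mats <- lapply(body, function(r) {
      if (length(r) != length(header)) {
        stop("ragged mothur shared row for sample '", r[2], "'")
      }
      n_otus <- parse_count_cell(r[3], r[2], "numOtus")
      if (n_otus != length(otus)) {
        stop("numOtus mismatch for sample '", r[2], "'")
      }
      vapply(seq_along(otus),
             function(j) parse_count_cell(r[j + 3L], r[2], otus[j]), 0L)
    })
    m <- do.call(rbind, mats)
    rownames(m) <- vapply(body, `[`, "", 2L)
    colnames(m) <- otus
    attr_label <- vapply(body, `[`, "", 1L)
    tab <- count_table(m)
    attr(tab, "mothur_label") <- unique(attr_label)
    return(tab)
  }
  ids <- vapply(body, `[`, "", 1L)
  cols <- header[-1]
  m <- do.call(rbind, lapply(body, function(r) {
    if (length(r) != length(header)) stop("ragged row for id '", r[1], "'")
    vapply(seq_along(cols), function(j) parse_count_cell(r[j + 1L], r[1], cols[j]), 0L)
  }))
  rownames(m) <- ids
  colnames(m) <- cols
  if (orientation == "features") m <- t(m)
  count_table(m)
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]; `write` then `read` is the identity on
#' valid tables (byte-stable column order, tabs, LF endings).
#'
#' @param t A `count_table`.
#' @param path Output path.
#' @param dialect `"plain_tsv"` (samples as rows) or `"mothur_shared"`.
#' @param label Shared-file distance label (mothur convention), default "0.03".
#' @return `path`, invisibly.
#' @export
write_count_table <- function(t, path, dialect = c("plain_tsv", "mothur_shared"),
                              label = "0.03") {
  dialect <- match.arg(dialect)
  m <- t$counts
  if (dialect == "mothur_shared") {
    header <- paste(c("label", "Group", "numOtus", colnames(m)), collapse = "\t")
    lines <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(label, rownames(m)[i], ncol(m), m[i, ]), collapse = "\t")
    }, "")
  } else {
    header <- paste(c("sample_id", colnames(m)), collapse = "\t")
    lines <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], m[i, ]), collapse = "\t")
    }, "")
  }
  write_tsv_lines(c(header, lines), path)
}

#' Read cohort metadata from TSV
#'
#' @param path Headered TSV with the columns required by [cohort_metadata()];
#'   unknown columns are preserved as opaque strings.
#' @return A `cohort_metadata`.
#' @export
read_metadata <- function(path) {
  rows <- read_tsv_raw(path)
  header <- rows[[1]]
  body <- rows[-1]
  if (!length(body)) stop("metadata file has no data rows: ", path)
  df <- as.data.frame(do.call(rbind, lapply(body, function(r) {
    length(r) <- length(header)  # trailing empty fields
    r[is.na(r)] <- ""
    r
  })), stringsAsFactors = FALSE)
  names(df) <- header
  cohort_metadata(df)
}

#' Write cohort metadata to TSV
#' @param meta A `cohort_metadata`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  header <- paste(names(meta), collapse = "\t")
  lines <- vapply(seq_len(nrow(meta)), function(i) {
    paste(unlist(meta[i, ], use.names = FALSE), collapse = "\t")
  }, "")
  write_tsv_lines(c(header, lines), path)
}

#' Read a concentration table from TSV
#'
#' Format: header row (`sample_id` then metabolite names), a `#units` line
#' giving one unit string per metabolite, then one row per sample.
#'
#' @param path Path to the TSV file.
#' @return A [concentration_table()].
#' @export
read_concentration_table <- function(path) {
  rows <- read_tsv_raw(path)
  header <- rows[[1]]
  if (length(rows) < 2L || rows[[2]][1] != "#units") {
    stop("concentration table must carry a '#units' line: ", path)
  }
  units_row <- rows[[2]]
  body <- rows[-(1:2)]
  if (!length(body)) stop("concentration table has no data rows: ", path)
  mets <- header[-1]
  units <- stats::setNames(units_row[-1], mets)
  m <- do.call(rbind, lapply(body, function(r) {
    if (length(r) != length(header)) stop("ragged row for sample '", r[1], "'")
    v <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(v)) stop("non-numeric concentration for sample '", r[1], "'")
    v
  }))
  rownames(m) <- vapply(body, `[`, "", 1L)
  colnames(m) <- mets
  concentration_table(m, units)
}

#' Write a concentration table to TSV
#' @param ctab A `concentration_table`.
#' @param path Output path.
#' @param digits Significant digits used for values (default 10).
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(ctab, path, digits = 10) {
  m <- ctab$values
  header <- paste(c("sample_id", colnames(m)), collapse = "\t")
  units <- paste(c("#units", ctab$units), collapse = "\t")
  lines <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], digits = digits, trim = TRUE,
                                   scientific = FALSE)), collapse = "\t")
  }, "")
  write_tsv_lines(c(header, units, lines), path)
}
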