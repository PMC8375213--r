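#' Read an activity table
#'
#' Reads a delimited table of potency measurements into a canonical activity
#' table. One row is one experimental measurement of a compound against a
#' target; `(compound_id, target_id)` pairs may repeat — replicates are
#' expected and are the input to [replicate_sd()].
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param column_map Named list mapping canonical field names to column names
#'   in the file. `compound_id`, `target_id` and `p_activity` are required;
#'   `assay_id`, `measurement_type` and `source` are optional.
#' @param delimiter Field delimiter; `NULL` (default) sniffs comma vs tab
#'   from the header line.
#' @return A data.frame of class `"activity_table"` with canonical column
#'   names, in file order. Rows with a missing or non-numeric potency are
#'   skipped; the skip count is reported via `message()` and stored in the
#'   `"n_skipped"` attribute. Potencies outside 0-15 raise a warning but are
#'   kept (pActivity is typically 2-12).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("cmpd,target,pchembl", "C1,T1,5.6", "C1,T1,6.3"), f)
#' read_activity_table(f, list(compound_id = "cmpd", target_id = "target",
#'                             p_activity = "pchembl"))
#' @export
read_activity_table <- function(path, column_map, delimiter = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  required <- c("compound_id", "target_id", "p_activity")
  if (!all(required %in% names(column_map)))
    stop("'column_map' must name columns for: ",
         paste(setdiff(required, names(column_map)), collapse = ", "),
         call. = FALSE)
  if (is.null(delimiter)) delimiter <- sniff_delimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "",
                           colClasses = "character")
  column_map <- Filter(Negate(is.null), column_map)
  for (field in names(column_map)) {
    col <- column_map[[field]]
    if (!col %in% names(raw))
      stop("configuration error: column '", col, "' (mapped to '", field,
           "') not found in ", path, call. = FALSE)
  }
  out <- data.frame(
    compound_id = raw[[column_map$compound_id]],
    target_id = raw[[column_map$target_id]],
    p_activity = suppressWarnings(as.numeric(raw[[column_map$p_activity]])),
    stringsAsFactors = FALSE
  )
  for (field in c("assay_id", "measurement_type", "source"))
    if (!is.null(column_map[[field]]))
      out[[field]] <- raw[[column_map[[field]]]]

  bad <- !is.finite(out$p_activity)
  if (any(bad)) {
    message(sum(bad), " row(s) with missing or non-numeric p_activity skipped")
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  outside <- out$p_activity < 0 | out$p_activity > 15
  if (any(outside))
    warning(sum(outside), " p_activity value(s) outside 0-15; pActivity is ",
            "expected on the -log10 molar scale", call. = FALSE)
  attr(out, "n_skipped") <- sum(bad)
  class(out) <- c("activity_table", "data.frame")
  out
}

#' Write an activity table
#'
#' @param records An activity table (or compatible data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

sniff_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_comma <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab > n_comma) "\t" else ","
}

# Validate a binary feature matrix: entries exactly 0/1; all-zero columns are
# kept but flagged (dropping them silently would desynchronise feature ids).
validate_feature_matrix <- function(x, warn_zero_cols = FALSE) {
  x <- as.matrix(x)
  if (!all(x %in% c(0, 1)))
    stop("feature matrix entries must be exactly 0 or 1", call. = FALSE)
  storage.mode(x) <- "double"
  if (warn_zero_cols) {
    zero <- colSums(x) == 0
    if (any(zero))
      warning(sum(zero), " all-zero feature column(s) kept: ",
              paste(utils::head(colnames(x)[zero], 5), collapse = ", "),
              call. = FALSE)
  }
  x
}

#' Read a binary feature matrix
#'
#' Fingerprint-like binary feature matrices are accepted in two layouts:
#' dense (one row per compound, first column the compound id, remaining
#' columns 0/1 features) and sparse triplets (columns `row_id`, `feature_id`,
#' `value`, listing only the set bits).
#'
#' @param path CSV/TSV path.
#' @param format `"dense"` or `"sparse"`.
#' @param delimiter Field delimiter; `NULL` sniffs comma vs tab.
#' @return A numeric 0/1 matrix with compound ids as row names and feature
#'   ids as column names. All-zero columns are kept with a warning.
#' @export
read_feature_matrix <- function(path, format = c("dense", "sparse"),
                                delimiter = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter)) delimiter <- sniff_delimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "dense") {
    ids <- as.character(raw[[1]])
    m <- as.matrix(raw[, -1, drop = FALSE])
    rownames(m) <- ids
  } else {
    rows <- as.character(raw[[1]])
    feats <- as.character(raw[[2]])
    vals <- as.numeric(raw[[3]])
    urows <- unique(rows)
    ufeats <- sort(unique(feats))
    m <- matrix(0, length(urows), length(ufeats),
                dimnames = list(urows, ufeats))
    m[cbind(match(rows, urows), match(feats, ufeats))] <- vals
  }
  validate_feature_matrix(m, warn_zero_cols = TRUE)
}

#' Write a binary feature matrix (dense layout)
#'
#' @param features 0/1 matrix with compound-id row names.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  df <- data.frame(compound_id = rownames(features),
                   features, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregation schemes for replicate analysis
#'
#' An aggregation scheme names the keys that define a replicate group when
#' auditing measurement variability. Compound and target are always part of
#' the grouping (replicates are per compound-target pair); further keys make
#' the grouping finer. Three named presets mirror common ways of pooling
#' public bioactivity data:
#' \describe{
#'   \item{`intra_assay`}{replicates within the same assay
#'     (compound, target, assay id) — the floor of experimental variability.}
#'   \item{`cross_assay`}{replicates pooled across assays
#'     (compound, target) — what naive database aggregation does.}
#'   \item{`intra_measurement_type`}{replicates pooled within one measurement
#'     type (compound, target, IC50/EC50/Ki/Kd).}
#' }
#'
#' @param grouping_keys Character vector of grouping keys; must contain
#'   `compound_id` and `target_id`.
#' @param name Label for reports.
#' @return An object of class `"aggregation_scheme"`.
#' @export
aggregation_scheme <- function(grouping_keys, name = "custom") {
  grouping_keys <- as.character(grouping_keys)
  if (!all(c("compound_id", "target_id") %in% grouping_keys))
    stop("grouping_keys must include compound_id and target_id",
         call. = FALSE)
  allowed <- c("compound_id", "target_id", "assay_id", "measurement_type",
               "source")
  if (!all(grouping_keys %in% allowed))
    stop("unknown grouping key(s): ",
         paste(setdiff(grouping_keys, allowed), collapse = ", "),
         call. = FALSE)
  structure(list(name = name, grouping_keys = grouping_keys),
            class = "aggregation_scheme")
}

scheme_presets <- function(name) {
  switch(name,
    intra_assay = aggregation_scheme(
      c("compound_id", "target_id", "assay_id"), "intra_assay"),
    cross_assay = aggregation_scheme(
      c("compound_id", "target_id"), "cross_assay"),
    intra_measurement_type = aggregation_scheme(
      c("compound_id", "target_id", "measurement_type"),
      "intra_measurement_type"),
    stop("unknown scheme preset: '", name, "' (use intra_assay, ",
         "cross_assay, intra_measurement_type, or an aggregation_scheme)",
         call. = FALSE)
  )
}

#' Replicate standard-deviation audit of an activity table
#'
#' Groups measurements by an aggregation scheme and computes the standard
#' deviation of the replicate potencies within each group, plus the median
#' of the per-group standard deviations. Pooling replicates across assays or
#' measurement types typically shows substantially larger spread than
#' replicates within one assay, which is the empirical basis for choosing
#' the soft-label `sigma` in [label_config()].
#'
#' @param records An activity table.
#' @param scheme An [aggregation_scheme()] or the name of a preset
#'   (`"intra_assay"`, `"cross_assay"`, `"intra_measurement_type"`).
#' @param min_replicates Minimum group size to contribute; must be >= 2.
#' @param denominator `"sample"` for the n-1 denominator (default: the
#'   standard estimator for replicate variability) or `"population"` for n.
#' @return An object of class `"replicate_sd"`: list with `table` (data.frame
#'   of group key columns, `n_replicates`, `sd`), `median_sd` (NA if no group
#'   qualifies), `scheme` and `denominator`.
#' @examples
#' tab <- data.frame(compound_id = c("C1", "C1"), target_id = "T1",
#'                   p_activity = c(5.6, 6.3))
#' replicate_sd(tab, "cross_assay")$table$sd  # 0.495 (n-1); 0.35 with n
#' @export
replicate_sd <- function(records, scheme = "cross_assay",
                         min_replicates = 2,
                         denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  if (is.character(scheme)) scheme <- scheme_presets(scheme)
  stopifnot(inherits(scheme, "aggregation_scheme"))
  if (min_replicates < 2)
    stop("'min_replicates' must be >= 2", call. = FALSE)
  keys <- scheme$grouping_keys
  missing_keys <- setdiff(keys, names(records))
  if (length(missing_keys))
    stop("activity table lacks grouping column(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)

  key_df <- as.data.frame(records)[, keys, drop = FALSE]
  grp <- interaction(key_df, drop = TRUE, sep = "\r", lex.order = TRUE)
  vals <- split(records$p_activity, grp)
  n <- lengths(vals)
  keep <- n >= min_replicates
  if (!any(keep)) {
    warning("no group has >= ", min_replicates, " replicates", call. = FALSE)
    empty <- key_df[0, , drop = FALSE]
    empty$n_replicates <- integer(0)
    empty$sd <- numeric(0)
    return(structure(list(table = empty, median_sd = NA_real_,
                          scheme = scheme, denominator = denominator),
                     class = "replicate_sd"))
  }
  vals <- vals[keep]
  n <- n[keep]
  sds <- vapply(vals, stats::sd, numeric(1))
  if (denominator == "population")
    sds <- sds * sqrt((n - 1) / n)
  key_cols <- do.call(rbind, strsplit(names(vals), "\r", fixed = TRUE))
  out <- as.data.frame(key_cols, stringsAsFactors = FALSE)
  names(out) <- keys
  out$n_replicates <- as.integer(n)
  out$sd <- unname(sds)
  rownames(out) <- NULL
  structure(list(table = out, median_sd = stats::median(sds),
                 scheme = scheme, denominator = denominator),
            class = "replicate_sd")
}

#' @export
print.replicate_sd <- function(x, ...) {
  cat(sprintf("Replicate SD audit (%s aggregation, %s sd)\n",
              x$scheme$name, x$denominator))
  cat(sprintf("  %d group(s) with replicates; median sd: %s\n",
              nrow(x$table),
              if (is.na(x$median_sd)) "undefined" else
                sprintf("%.4f", x$median_sd)))
  invisible(x)
}
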