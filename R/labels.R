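#' Convert a potency measurement into a soft activity label
#'
#' Computes the probability that a compound belongs to the active class given
#' its measured potency, an activity threshold and an assumed normal
#' measurement error. The soft label is the cumulative normal distribution
#' evaluated at `p_activity` with mean `p_threshold` and standard deviation
#' `sigma`:
#' \deqn{\Delta y = \frac{1}{2}\left[1 + \mathrm{erf}\left(
#'   \frac{p_{activity} - p_{threshold}}{\sigma\sqrt{2}}\right)\right]}
#'
#' With `sigma = 0` the conversion degenerates to the hard step function:
#' 1 when `p_activity >= p_threshold`, else 0 (equality counts as active,
#' matching the usual "pActivity at or above threshold is active"
#' convention). A compound measured at pActivity 5.1 against a threshold of
#' 5.0 with `sigma = 0.3` receives a soft label of about 0.63: a 63% chance
#' of belonging to the active class rather than the 100% a binary label
#' would assert.
#'
#' @param p_activity Numeric vector of potencies on the -log10 molar scale
#'   (pIC50/pEC50/pKi/pKd); must be finite.
#' @param p_threshold Activity threshold on the same scale (e.g. 5 for
#'   10 uM, 6 for 1 uM, 7 for 0.1 uM).
#' @param sigma Standard deviation of the assumed measurement error in log
#'   units; must be >= 0. The error model is homoscedastic: one sigma for
#'   all measurements.
#' @return Numeric vector of probabilities in \[0, 1\], one per element of
#'   `p_activity`.
#' @examples
#' delta_y(5.1, 5, 0.3)            # ~0.63
#' delta_y(c(4.9, 5.1), 5, 0.3)    # symmetric around 0.5
#' delta_y(5.1, 5, 0)              # hard label 1
#' @seealso [label_dataset()] to label a whole feature matrix.
#' @export
delta_y <- function(p_activity, p_threshold, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("'sigma' must be a single non-negative number", call. = FALSE)
  if (!all(is.finite(p_activity)))
    stop("'p_activity' must be finite", call. = FALSE)
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      !is.finite(p_threshold))
    stop("'p_threshold' must be a single finite number", call. = FALSE)
  if (sigma == 0)
    return(as.numeric(p_activity >= p_threshold))
  stats::pnorm(p_activity, mean = p_threshold, sd = sigma)
}

#' Label configuration for soft activity labels
#'
#' Bundles the activity threshold and measurement-error standard deviation
#' that define a soft-labelling of an activity table.
#'
#' @inheritParams delta_y
#' @return An object of class `"label_config"`.
#' @export
label_config <- function(p_threshold = 5, sigma = 0.3) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("'sigma' must be a single non-negative number", call. = FALSE)
  structure(list(p_threshold = p_threshold, sigma = sigma),
            class = "label_config")
}

#' @export
print.label_config <- function(x, ...) {
  cat(sprintf("Soft-label config: threshold %g (-log10 M), sigma %g\n",
              x$p_threshold, x$sigma))
  invisible(x)
}

#' Build a soft-label dataset from activity records and a feature matrix
#'
#' Aligns an activity table with a binary feature matrix by compound id and
#' attaches per-sample soft labels (via [delta_y()]) and hard binary labels.
#' Compounds listed in `putative_inactive_ids` are putative inactives:
#' compounds assumed inactive without a measurement (e.g. selected by sphere
#' exclusion at low structural similarity to all actives). They receive
#' `delta_y = 0` and `hard_label = 0` at every `sigma`.
#'
#' Compounds with replicate measurements contribute the median of their
#' observed potencies.
#'
#' @param records An activity table as returned by [read_activity_table()],
#'   or any data.frame with `compound_id` and `p_activity` columns.
#' @param features Binary feature matrix with compound ids as row names.
#' @param config A [label_config()].
#' @param putative_inactive_ids Character vector of compound ids to flag as
#'   putative inactives. Must have feature rows; a measured record for a
#'   putative id is ignored with a warning (the putative flag wins).
#' @return An object of class `"soft_label_dataset"`: a list with elements
#'   `features` (rows restricted and ordered to labelled compounds),
#'   `compound_id`, `p_activity` (NA for putative inactives), `delta_y`,
#'   `hard_label`, `is_putative_inactive` and `config`.
#' @export
label_dataset <- function(records, features, config,
                          putative_inactive_ids = character()) {
  stopifnot(inherits(config, "label_config"))
  features <- validate_feature_matrix(features)
  if (is.null(rownames(features)))
    stop("'features' must have compound ids as row names", call. = FALSE)
  ids <- rownames(features)
  putative_inactive_ids <- as.character(putative_inactive_ids)

  missing_rows <- setdiff(unique(records$compound_id), ids)
  if (length(missing_rows))
    stop("no feature row for compound(s): ",
         paste(utils::head(missing_rows, 5), collapse = ", "), call. = FALSE)
  missing_put <- setdiff(putative_inactive_ids, ids)
  if (length(missing_put))
    stop("no feature row for putative inactive(s): ",
         paste(utils::head(missing_put, 5), collapse = ", "), call. = FALSE)

  overlap <- intersect(unique(records$compound_id), putative_inactive_ids)
  if (length(overlap)) {
    warning(length(overlap), " measured compound(s) also flagged putative ",
            "inactive; the putative flag overrides the measurement",
            call. = FALSE)
    records <- records[!(records$compound_id %in% overlap), , drop = FALSE]
  }

  # median-aggregate replicates per compound
  p_obs <- vapply(split(records$p_activity, records$compound_id),
                  stats::median, numeric(1))

  labelled <- ids[ids %in% c(names(p_obs), putative_inactive_ids)]
  unlabelled <- setdiff(ids, labelled)
  if (length(unlabelled))
    warning(length(unlabelled), " feature row(s) with neither a measurement ",
            "nor a putative-inactive flag were excluded", call. = FALSE)

  p_activity <- unname(p_obs[labelled])       # NA where putative
  is_put <- labelled %in% putative_inactive_ids
  dy <- numeric(length(labelled))
  hard <- integer(length(labelled))
  measured <- !is_put
  dy[measured] <- delta_y(p_activity[measured], config$p_threshold,
                          config$sigma)
  hard[measured] <- as.integer(p_activity[measured] >= config$p_threshold)
  dy[is_put] <- 0
  hard[is_put] <- 0L

  structure(list(
    features = features[labelled, , drop = FALSE],
    compound_id = labelled,
    p_activity = p_activity,
    delta_y = dy,
    hard_label = hard,
    is_putative_inactive = is_put,
    config = config
  ), class = "soft_label_dataset")
}

#' @export
print.soft_label_dataset <- function(x, ...) {
  cat(sprintf(
    "Soft-label dataset: %d compounds x %d features (%d putative inactive)\n",
    length(x$compound_id), ncol(x$features), sum(x$is_putative_inactive)))
  print(x$config)
  cat(sprintf("  hard actives: %d | mean delta_y: %.3f\n",
              sum(x$hard_label), mean(x$delta_y)))
  invisible(x)
}
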