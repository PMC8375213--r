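#' Probability-weighted class probabilities of a node
#'
#' Given per-sample reach probabilities `pi` and per-sample class-A
#' probabilities `p_a` (the soft labels), returns the probability-weighted
#' class probability pair of the node:
#' \deqn{\bar P_A = \frac{\sum_i \pi_i \, p_{i,A}}{\sum_i \pi_i}, \qquad
#'       \bar P_B = 1 - \bar P_A.}
#' With hard labels and full reach (`pi = 1`, `p_a` in {0,1}) this is the
#' ordinary class fraction of a decision-tree node.
#'
#' @param p_a Numeric vector of per-sample class-A probabilities in \[0, 1\].
#' @param pi Numeric vector of per-sample reach probabilities in \[0, 1\];
#'   defaults to 1 for every sample.
#' @return Named numeric vector `c(p_a = , p_b = )` summing to 1.
#' @export
weighted_class_probs <- function(p_a, pi = rep(1, length(p_a))) {
  stopifnot(length(p_a) == length(pi), all(pi >= 0))
  s <- sum(pi)
  if (s <= 0)
    stop("degenerate node: total reach probability is zero", call. = FALSE)
  pa <- sum(pi * p_a) / s
  c(p_a = pa, p_b = 1 - pa)
}

#' Probability-weighted Gini impurity
#'
#' The Gini impurity computed from probability-weighted class probabilities,
#' \deqn{\bar G = 1 - (\bar P_A^2 + \bar P_B^2).}
#' Ranges over \[0, 0.5\] for two classes; 0 iff the node is pure.
#'
#' @param p_a,p_b Class probabilities in \[0, 1\] summing to 1. `p_b`
#'   defaults to `1 - p_a`.
#' @return Impurity in \[0, 0.5\].
#' @export
modified_gini <- function(p_a, p_b = 1 - p_a) {
  stopifnot(all(p_a >= 0 & p_a <= 1), all(abs(p_a + p_b - 1) < 1e-9))
  1 - (p_a^2 + p_b^2)
}

#' Probability-weighted cost of a candidate split
#'
#' The split cost is the reach-mass-weighted average of the two children's
#' probability-weighted Gini impurities,
#' \deqn{\bar G_L \frac{\sum_L \pi}{\sum \pi} +
#'       \bar G_R \frac{\sum_R \pi}{\sum \pi}.}
#' When the reach probabilities are all 0/1 this reduces to the classical
#' fraction-weighted Gini criterion. A split that sends all mass to one side
#' is rejected: its cost is the parent impurity.
#'
#' @param p_a_left,p_a_right Per-sample class-A probabilities on each side.
#' @param pi_left,pi_right Per-sample reach probabilities on each side.
#' @return The split cost (non-negative scalar).
#' @export
split_cost <- function(p_a_left, p_a_right,
                       pi_left = rep(1, length(p_a_left)),
                       pi_right = rep(1, length(p_a_right))) {
  sl <- sum(pi_left)
  sr <- sum(pi_right)
  parent <- weighted_class_probs(c(p_a_left, p_a_right),
                                 c(pi_left, pi_right))
  if (sl <= 0 || sr <= 0)
    return(modified_gini(parent[["p_a"]]))
  gl <- modified_gini(weighted_class_probs(p_a_left, pi_left)[["p_a"]])
  gr <- modified_gini(weighted_class_probs(p_a_right, pi_right)[["p_a"]])
  (sl * gl + sr * gr) / (sl + sr)
}

#' Fit a probabilistic random forest
#'
#' Trains an ensemble of probabilistic decision trees on a binary feature
#' matrix with probabilistic class labels. Each label is a probability
#' `p_a` in \[0, 1\] that the sample belongs to the active class (typically
#' produced by [delta_y()] from a potency measurement, a threshold and an
#' experimental-error sigma). Node splits minimise the probability-weighted
#' Gini cost ([split_cost()]); terminal nodes store probability-weighted
#' class probabilities ([weighted_class_probs()]). With all labels in {0, 1}
#' the criterion coincides with the classical Gini split search and the
#' learner is exactly a classical random forest (`mode = "hard"` enforces
#' this, serving as the in-package RF baseline).
#'
#' Binary features are split at 0.5: value 0 routes left, 1 routes right.
#' Feature values may optionally carry Gaussian uncertainty (`dx`), in which
#' case samples propagate to both children with split probability mass;
#' branches receiving mass below `keep_proba` are dropped. With the default
#' `dx = 0` each sample reaches exactly one child with mass 1 and
#' `keep_proba` is inert.
#'
#' @param x Either a binary (0/1) feature matrix with samples in rows, or a
#'   `soft_label_dataset` from [label_dataset()] (then `y` is taken from it).
#' @param y Per-sample class-A probabilities in \[0, 1\] (`mode = "soft"`) or
#'   binary 0/1 labels (`mode = "hard"`). Ignored when `x` is a
#'   `soft_label_dataset`.
#' @param mode `"soft"` (labels are probabilities) or `"hard"` (binary
#'   labels; the classical-RF baseline).
#' @param n_trees Number of trees (default 100).
#' @param max_depth Maximum tree depth; `Inf` (default) grows until purity or
#'   `min_samples_split`.
#' @param min_samples_split Minimum samples in a node to attempt a split
#'   (default 2).
#' @param max_features Features tried per split; default
#'   `ceiling(sqrt(ncol(x)))`, the conventional classification heuristic.
#' @param keep_proba Propagation-probability floor in \[0, 1); branches whose
#'   probability mass falls below it are pruned (default 0.05). Inert when
#'   `dx = 0`.
#' @param bootstrap Grow each tree on a bootstrap resample (default TRUE).
#' @param dx Per-feature Gaussian sd of feature uncertainty; scalar or
#'   length `ncol(x)`; default 0 (no feature uncertainty).
#' @param seed Integer seed; the same data, hyperparameters and seed give a
#'   bit-identical forest.
#' @param label_config Optional [label_config()] recorded for provenance
#'   (filled automatically from a `soft_label_dataset`).
#' @return An object of class `"prf"`.
#' @examples
#' set.seed(1)
#' x <- matrix(rbinom(200 * 16, 1, 0.5), 200, 16)
#' p <- delta_y(5 + x[, 1] + x[, 2] - 1 + rnorm(200, 0, 0.3), 5, 0.3)
#' fit <- prf(x, p, n_trees = 25, seed = 1)
#' fit
#' @seealso [predict.prf()], [prf_hard()], [write_prf()]
#' @export
prf <- function(x, y = NULL, mode = c("soft", "hard"),
                n_trees = 100, max_depth = Inf, min_samples_split = 2,
                max_features = NULL, keep_proba = 0.05, bootstrap = TRUE,
                dx = 0, seed = 1, label_config = NULL) {
  mode <- match.arg(mode)
  cl <- match.call()
  if (inherits(x, "soft_label_dataset")) {
    if (is.null(label_config)) label_config <- x$config
    y <- if (mode == "soft") x$delta_y else x$hard_label
    x <- x$features
  }
  x <- validate_feature_matrix(x)
  y <- as.numeric(y)
  if (length(y) != nrow(x))
    stop("length(y) must equal nrow(x)", call. = FALSE)
  if (any(!is.finite(y)) || any(y < 0 | y > 1))
    stop("labels must be probabilities in [0, 1]", call. = FALSE)
  if (mode == "hard" && !all(y %in% c(0, 1)))
    stop("mode = \"hard\" requires binary 0/1 labels", call. = FALSE)
  if (nrow(x) < min_samples_split)
    stop("need at least min_samples_split samples", call. = FALSE)
  if (keep_proba < 0 || keep_proba >= 1)
    stop("'keep_proba' must be in [0, 1)", call. = FALSE)
  p <- ncol(x)
  if (is.null(max_features)) max_features <- ceiling(sqrt(p))
  max_features <- min(max_features, p)
  dx <- check_dx(dx, p)
  depth <- if (is.finite(max_depth)) as.integer(max_depth) else
    .Machine$integer.max
  if (all(duplicated(x)[-1]))
    warning("all feature rows identical; forest predicts the prior",
            call. = FALSE)

  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  trees <- .grow_forest(x, y, dx, as.integer(n_trees),
                        as.integer(max_features), depth,
                        as.integer(min_samples_split), keep_proba, bootstrap)

  structure(list(
    trees = trees,
    mode = mode,
    hyperparameters = list(
      n_trees = as.integer(n_trees), max_depth = max_depth,
      min_samples_split = as.integer(min_samples_split),
      max_features = as.integer(max_features), keep_proba = keep_proba,
      bootstrap = bootstrap, seed = as.integer(seed)),
    dx = dx,
    label_config = label_config,
    feature_ids = colnames(x),
    n_samples = nrow(x),
    call = cl
  ), class = "prf")
}

#' Fit the hard-label (classical RF) baseline
#'
#' Convenience wrapper: [prf()] with `mode = "hard"`, consuming binary
#' labels. With the same data, hyperparameters and seed, a soft fit whose
#' labels are all exactly 0/1 produces an identical forest — the
#' probabilistic learner degenerates to the classical random forest when
#' label uncertainty vanishes.
#'
#' @inheritParams prf
#' @param ... Passed to [prf()].
#' @return An object of class `"prf"` with `mode = "hard"`.
#' @export
prf_hard <- function(x, y = NULL, ...) {
  prf(x, y, mode = "hard", ...)
}

check_dx <- function(dx, p) {
  if (length(dx) == 1L) dx <- rep(dx, p)
  if (length(dx) != p || any(!is.finite(dx)) || any(dx < 0))
    stop("'dx' must be a non-negative scalar or length-ncol(x) vector",
         call. = FALSE)
  dx
}

#' Predict with a probabilistic random forest
#'
#' Each sample is propagated through every tree carrying probability mass;
#' at an internal node the mass splits between children according to the
#' feature-uncertainty routing probability (deterministically, with all mass
#' to one child, when `dx = 0`). Branches whose mass falls below
#' `keep_proba` are pruned and the surviving mass renormalised, so the
#' returned class probabilities always sum to 1. The per-tree prediction is
#' the mass-weighted average of the reached terminal nodes' class
#' probabilities; the forest prediction is the mean over trees.
#'
#' @param object A fitted [prf()] model.
#' @param newdata Binary feature matrix. If both the model and `newdata`
#'   carry feature ids (column names), columns are aligned by id; a feature
#'   id required by the model but absent from `newdata` is a configuration
#'   error.
#' @param keep_proba Propagation floor; defaults to the training value.
#' @param dx Per-feature Gaussian feature uncertainty at prediction time;
#'   default 0.
#' @param ... Unused.
#' @return An object of class `"prf_prediction"`: a data.frame with columns
#'   `prob_active` (mean over trees of the per-tree class-A probability; the
#'   primary output), `prob_inactive` (`= 1 - prob_active`), `vote_fraction`
#'   (fraction of trees whose per-tree probability favours the active
#'   class) and `tree_sd` (dispersion of the per-tree probabilities). The
#'   full per-sample-per-tree probability matrix is attached as attribute
#'   `"tree_probs"`.
#' @export
predict.prf <- function(object, newdata, keep_proba = NULL, dx = 0, ...) {
  if (is.null(keep_proba)) keep_proba <- object$hyperparameters$keep_proba
  if (inherits(newdata, "soft_label_dataset")) newdata <- newdata$features
  newdata <- validate_feature_matrix(newdata)
  if (!is.null(object$feature_ids)) {
    if (!is.null(colnames(newdata))) {
      missing_f <- setdiff(object$feature_ids, colnames(newdata))
      if (length(missing_f))
        stop("configuration error: newdata lacks model feature(s): ",
             paste(utils::head(missing_f, 5), collapse = ", "),
             call. = FALSE)
      newdata <- newdata[, object$feature_ids, drop = FALSE]
    } else if (ncol(newdata) != length(object$feature_ids)) {
      stop("newdata has ", ncol(newdata), " features; model expects ",
           length(object$feature_ids), call. = FALSE)
    }
  }
  dx <- check_dx(dx, ncol(newdata))
  tree_probs <- .predict_forest(object$trees, newdata, dx, keep_proba)
  prob_a <- rowMeans(tree_probs)
  out <- data.frame(
    prob_active = prob_a,
    prob_inactive = 1 - prob_a,
    vote_fraction = rowMeans(tree_probs >= 0.5),
    tree_sd = apply(tree_probs, 1, stats::sd)
  )
  if (!is.null(rownames(newdata))) rownames(out) <- rownames(newdata)
  attr(out, "tree_probs") <- tree_probs
  class(out) <- c("prf_prediction", "data.frame")
  out
}

#' @export
print.prf <- function(x, ...) {
  h <- x$hyperparameters
  cat(sprintf("Probabilistic random forest (%s-label mode)\n", x$mode))
  cat(sprintf("  %d trees | %d training samples | %d features per split | seed %d\n",
              h$n_trees, x$n_samples, h$max_features, h$seed))
  cat(sprintf("  keep_proba %g | bootstrap %s | max depth %s\n",
              h$keep_proba, h$bootstrap,
              if (is.finite(h$max_depth)) h$max_depth else "unlimited"))
  if (!is.null(x$label_config))
    print(x$label_config)
  invisible(x)
}

#' @export
summary.prf <- function(object, ...) {
  sizes <- vapply(object$trees, function(t) length(t$feature), integer(1))
  leaves <- vapply(object$trees, function(t) sum(t$feature < 0), integer(1))
  out <- list(model = object, n_nodes = sizes, n_leaves = leaves)
  class(out) <- "summary.prf"
  out
}

#' @export
print.summary.prf <- function(x, ...) {
  print(x$model)
  cat(sprintf("  nodes/tree: median %g (range %d-%d); leaves/tree: median %g\n",
              stats::median(x$n_nodes), min(x$n_nodes), max(x$n_nodes),
              stats::median(x$n_leaves)))
  invisible(x)
}

#' Serialize a fitted model
#'
#' Writes a versioned container holding the full tree structures,
#' hyperparameters, label configuration and seed. Reloading with
#' [read_prf()] reproduces predictions bit-exactly.
#'
#' @param model A fitted [prf()] model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_prf <- function(model, path) {
  stopifnot(inherits(model, "prf"))
  container <- list(format = "prfbio-model", format_version = 1L,
                    package_version = as.character(utils::packageVersion("prfbio")),
                    model = model)
  saveRDS(container, path)
  invisible(path)
}

#' @rdname write_prf
#' @return `read_prf()` returns the restored `"prf"` model.
#' @export
read_prf <- function(path) {
  container <- readRDS(path)
  if (!identical(container$format, "prfbio-model"))
    stop("not a prfbio model file: ", path, call. = FALSE)
  if (container$format_version > 1L)
    stop("model file format version ", container$format_version,
         " is newer than this package supports", call. = FALSE)
  container$model
}
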