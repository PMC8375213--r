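#' Jaccard (Tanimoto) similarity of two binary vectors
#'
#' \eqn{|a \cap b| / |a \cup b|} over the set bits; defined as 0 when both
#' vectors are all-zero. For binary molecular fingerprints this is the
#' Tanimoto coefficient used in sphere-exclusion selection of putative
#' inactives.
#'
#' @param row_a,row_b Equal-length binary (0/1) vectors.
#' @return Similarity in \[0, 1\].
#' @examples
#' jaccard_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' @export
jaccard_similarity <- function(row_a, row_b) {
  if (length(row_a) != length(row_b))
    stop("rows must have equal length", call. = FALSE)
  inter <- sum(row_a == 1 & row_b == 1)
  union <- sum(row_a == 1 | row_b == 1)
  if (union == 0) return(0)
  inter / union
}

# Max Jaccard similarity of each candidate row against a matrix of actives,
# vectorised over candidates.
max_jaccard_to_set <- function(candidates, actives) {
  inter <- candidates %*% t(actives)
  n_cand <- rowSums(candidates)
  n_act <- rowSums(actives)
  union <- outer(n_cand, n_act, "+") - inter
  sim <- ifelse(union == 0, 0, inter / union)
  apply(sim, 1, max)
}

#' Specification for a synthetic bioactivity dataset
#'
#' Describes the statistical structure of a generated dataset: binary
#' fingerprint-like features, a latent potency per measured compound with
#' additive Gaussian experimental noise, class imbalance, and a pool of
#' putative inactives constrained by sphere exclusion (maximum Jaccard
#' similarity to every active below a cutoff).
#'
#' The defaults describe the regime the probabilistic forest targets:
#' threshold 5 (10 uM), experimental noise sigma 0.3 log units, an
#' active:inactive ratio of 0.4 (200 actives vs 300 measured + 200 putative
#' inactives), and a near-threshold mixture component so that a substantial
#' fraction of soft labels falls in the marginal 0.4-0.6 band.
#'
#' @param n_active Number of measured active compounds (latent potency at or
#'   above the threshold).
#' @param n_measured_inactive Number of measured inactives (latent potency
#'   below the threshold).
#' @param n_putative_inactive Number of putative (sphere-excluded, unmeasured)
#'   inactives.
#' @param n_features,n_informative Feature geometry; the first
#'   `n_informative` bits carry the activity signal, the rest are noise.
#' @param sigma_experimental Sd of the additive Gaussian measurement noise in
#'   log units.
#' @param p_threshold Activity threshold on the -log10 molar scale.
#' @param potency_range Length-2 numeric; latent potencies are clipped to
#'   this span.
#' @param near_threshold_weight Probability that a measured compound's latent
#'   potency is drawn from the marginal component concentrated at the
#'   threshold (sd 0.4) rather than the well-separated active/inactive mode.
#' @param se_similarity_cutoff Sphere-exclusion cutoff: every putative
#'   inactive must have Jaccard similarity below this against every active.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_active = 200, n_measured_inactive = 300,
                           n_putative_inactive = 200, n_features = 64,
                           n_informative = 16, sigma_experimental = 0.3,
                           p_threshold = 5, potency_range = c(2, 9),
                           near_threshold_weight = 0.35,
                           se_similarity_cutoff = 0.4, seed = 1) {
  stopifnot(n_informative <= n_features,
            se_similarity_cutoff > 0, se_similarity_cutoff <= 1,
            n_active >= 0, n_measured_inactive >= 0,
            n_putative_inactive >= 0, sigma_experimental >= 0,
            length(potency_range) == 2, potency_range[1] < potency_range[2],
            near_threshold_weight >= 0, near_threshold_weight <= 1)
  structure(list(
    n_active = n_active, n_measured_inactive = n_measured_inactive,
    n_putative_inactive = n_putative_inactive, n_features = n_features,
    n_informative = n_informative, sigma_experimental = sigma_experimental,
    p_threshold = p_threshold, potency_range = potency_range,
    near_threshold_weight = near_threshold_weight,
    se_similarity_cutoff = se_similarity_cutoff, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Generate a synthetic bioactivity dataset
#'
#' Latent potencies for measured compounds come from a two-component mixture
#' per class: a well-separated mode (1.5 log units above/below the threshold,
#' sd 0.8, truncated on the class side) and a marginal mode concentrated at
#' the threshold (sd 0.4, truncated on the class side) taken with probability
#' `near_threshold_weight`, so the marginal soft-label band can be populated
#' on demand. Observed potency = latent + Gaussian noise with
#' `sigma_experimental`. The informative feature bits are Bernoulli with a
#' rate that increases monotonically with latent potency (a planted, learnable
#' signal); noise bits are Bernoulli(0.2), fingerprint-like sparsity.
#' Putative inactives are drawn from a sparse Bernoulli(0.05) background and
#' rejection-filtered so that their maximum Jaccard similarity to every
#' active is below `se_similarity_cutoff`.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `"synthetic_bioactivity"`: list with
#'   `features` (0/1 matrix, compound ids as row names), `latent_p_activity`
#'   and `observed_p_activity` (NA for putative inactives),
#'   `is_putative_inactive`, `compound_id` and `spec`.
#' @export
generate_bioactivity <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  thr <- spec$p_threshold
  lo <- spec$potency_range[1]
  hi <- spec$potency_range[2]

  draw_latent <- function(n, side) {
    if (n == 0) return(numeric(0))
    marginal <- stats::runif(n) < spec$near_threshold_weight
    out <- numeric(n)
    if (side == "active") {
      out[marginal] <- rtrunc_norm(sum(marginal), thr, 0.4, thr, hi)
      out[!marginal] <- rtrunc_norm(sum(!marginal), thr + 1.5, 0.8, thr, hi)
    } else {
      out[marginal] <- rtrunc_norm(sum(marginal), thr, 0.4, lo, thr)
      out[!marginal] <- rtrunc_norm(sum(!marginal), thr - 1.5, 0.8, lo, thr)
    }
    out
  }
  latent <- c(draw_latent(spec$n_active, "active"),
              draw_latent(spec$n_measured_inactive, "inactive"))
  n_measured <- length(latent)
  observed <- latent + stats::rnorm(n_measured, 0, spec$sigma_experimental)

  # informative bits: Bernoulli rate rises with latent potency
  activity_scale <- stats::plogis(2 * (latent - thr))
  rate_inf <- 0.1 + 0.75 * activity_scale
  feat_measured <- matrix(0, n_measured, spec$n_features)
  if (spec$n_informative > 0 && n_measured > 0)
    feat_measured[, seq_len(spec$n_informative)] <-
      stats::rbinom(n_measured * spec$n_informative, 1, rep(rate_inf,
        spec$n_informative))
  n_noise <- spec$n_features - spec$n_informative
  if (n_noise > 0 && n_measured > 0)
    feat_measured[, spec$n_informative + seq_len(n_noise)] <-
      stats::rbinom(n_measured * n_noise, 1, 0.2)

  # putative inactives: sparse background + sphere-exclusion rejection
  n_put <- spec$n_putative_inactive
  feat_put <- matrix(0, 0, spec$n_features)
  if (n_put > 0) {
    actives_mask <- latent >= thr
    active_rows <- feat_measured[actives_mask, , drop = FALSE]
    accepted <- matrix(0, 0, spec$n_features)
    attempts <- 0L
    budget <- 200L * n_put
    while (nrow(accepted) < n_put && attempts < budget) {
      batch <- max(n_put - nrow(accepted), 32L)
      cand <- matrix(stats::rbinom(batch * spec$n_features, 1, 0.05),
                     batch, spec$n_features)
      ok <- if (nrow(active_rows) == 0) rep(TRUE, batch) else
        max_jaccard_to_set(cand, active_rows) < spec$se_similarity_cutoff
      accepted <- rbind(accepted, cand[ok, , drop = FALSE])
      attempts <- attempts + batch
    }
    if (nrow(accepted) < n_put)
      stop("sphere-exclusion rejection sampling exhausted its attempt ",
           "budget; loosen 'se_similarity_cutoff' or increase 'n_features'",
           call. = FALSE)
    feat_put <- accepted[seq_len(n_put), , drop = FALSE]
  }

  features <- rbind(feat_measured, feat_put)
  n_total <- nrow(features)
  ids <- sprintf("C%05d", seq_len(n_total))
  rownames(features) <- ids
  colnames(features) <- sprintf("F%03d", seq_len(spec$n_features))

  structure(list(
    features = features,
    compound_id = ids,
    latent_p_activity = c(latent, rep(NA_real_, n_put)),
    observed_p_activity = c(observed, rep(NA_real_, n_put)),
    is_putative_inactive = c(rep(FALSE, n_measured), rep(TRUE, n_put)),
    spec = spec
  ), class = "synthetic_bioactivity")
}

#' @export
print.synthetic_bioactivity <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "Synthetic bioactivity dataset: %d compounds x %d features (seed %d)\n",
    length(x$compound_id), s$n_features, s$seed))
  cat(sprintf(
    "  %d actives, %d measured inactives, %d putative inactives (Jaccard < %g)\n",
    s$n_active, s$n_measured_inactive, s$n_putative_inactive,
    s$se_similarity_cutoff))
  cat(sprintf("  threshold %g, experimental sigma %g\n",
              s$p_threshold, s$sigma_experimental))
  invisible(x)
}

#' Convert a synthetic dataset to an activity table
#'
#' Returns the measured compounds as an activity table (putative inactives
#' carry no measurement and are listed via their ids in the
#' `"putative_inactive_ids"` attribute).
#'
#' @param dataset A [generate_bioactivity()] result.
#' @param target_id Target id to stamp on the records.
#' @return An `"activity_table"` data.frame.
#' @export
as_activity_table <- function(dataset, target_id = "T1") {
  stopifnot(inherits(dataset, "synthetic_bioactivity"))
  measured <- !dataset$is_putative_inactive
  out <- data.frame(
    compound_id = dataset$compound_id[measured],
    target_id = target_id,
    p_activity = dataset$observed_p_activity[measured],
    stringsAsFactors = FALSE
  )
  attr(out, "putative_inactive_ids") <-
    dataset$compound_id[dataset$is_putative_inactive]
  class(out) <- c("activity_table", "data.frame")
  out
}

#' Fraction of soft labels in a probability band
#'
#' Computes the fraction of measured compounds whose soft label under a
#' given label configuration falls inside `[lo, hi]`. Useful to check that a
#' generator spec populates the marginal band (labels near 0.5, compounds
#' near the threshold) where the probabilistic forest differs most from a
#' classical one.
#'
#' @param dataset A [generate_bioactivity()] result.
#' @param config A [label_config()].
#' @param lo,hi Band limits, `0 <= lo < hi <= 1`; the band is closed.
#' @return Fraction in \[0, 1\].
#' @export
near_threshold_fraction <- function(dataset, config, lo, hi) {
  stopifnot(inherits(dataset, "synthetic_bioactivity"),
            inherits(config, "label_config"), lo < hi, lo >= 0, hi <= 1)
  measured <- !dataset$is_putative_inactive
  if (!any(measured)) return(NaN)
  dy <- delta_y(dataset$observed_p_activity[measured], config$p_threshold,
                config$sigma)
  mean(dy >= lo & dy <= hi)
}
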