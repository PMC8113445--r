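#' Nagelkerke pseudo-R-squared
#'
#' Likelihood-ratio fit index normalized to a maximum of one:
#' `R2 = (1 - exp((2/n) (ll_null - ll_model))) / (1 - exp((2/n) ll_null))`.
#' The null hypothesis here is that every modeled species has equal
#' relative abundance in each plot, and `n` is the sampling effort in scope
#' (all sampled individuals for the global value, one plot's effort for a
#' per-plot value). Values are negative when the model likelihood falls
#' below the equal-abundance null.
#'
#' @param loglik_model Log-likelihood of the model.
#' @param loglik_null Log-likelihood of the equal-abundance null (must be
#'   negative).
#' @param n Number of sampled individuals in scope.
#'
#' @return Scalar pseudo-R-squared (<= 1).
#' @export
nagelkerke_r2 <- function(loglik_model, loglik_null, n) {
  stopifnot(n > 0)
  if (!is.finite(loglik_null) || loglik_null >= 0) {
    stop_lv("degenerate_null",
            "null log-likelihood must be finite and negative")
  }
  (1 - exp((2 / n) * (loglik_null - loglik_model))) /
    (1 - exp((2 / n) * loglik_null))
}

#' Equal-relative-abundance null log-likelihood
#'
#' Log-likelihood of the observed counts under the hypothesis that all
#' modeled species have probability `1/S` in every plot, with `S` the full
#' modeled species pool (shared across plots for comparability).
#'
#' @param sample A [community_sample].
#' @param per_plot Return the per-plot vector instead of the total.
#'
#' @return Scalar (or per-plot vector) of null log-likelihoods.
#' @export
null_loglik <- function(sample, per_plot = FALSE) {
  stopifnot(inherits(sample, "community_sample"))
  S <- sample$n_species
  p0 <- rep(1 / S, S)
  ll <- vapply(seq_len(sample$n_plots), function(j) {
    multinomial_loglik(sample$counts[j, ], p0)
  }, numeric(1))
  if (per_plot) stats::setNames(ll, sample$plot_id) else sum(ll)
}

#' Deviance information criterion
#'
#' `DIC = D(point) + 2 pD` with `pD = mean(D) - D(point)`, the point
#' estimate being the parameter vector at the posterior median (each
#' deviance is `-2 log L`).
#'
#' @param deviance_draws Vector of posterior deviance draws.
#' @param deviance_at_point Deviance at the posterior-median parameters.
#'
#' @return List with `dic`, `p_d`, `mean_deviance` and
#'   `deviance_at_point`.
#' @export
dic <- function(deviance_draws, deviance_at_point) {
  if (length(deviance_draws) < 2L) {
    stop_lv("invalid_deviance", "need at least two deviance draws")
  }
  if (!all(is.finite(deviance_draws)) || !is.finite(deviance_at_point)) {
    stop_lv("invalid_deviance", "deviances must be finite")
  }
  p_d <- mean(deviance_draws) - deviance_at_point
  list(dic = deviance_at_point + 2 * p_d, p_d = p_d,
       mean_deviance = mean(deviance_draws),
       deviance_at_point = deviance_at_point)
}

#' Shuffle trait axes among species (null-model input)
#'
#' Applies one random permutation of the species rows jointly to all axes:
#' the multiset of values per axis and the inter-axis correlation structure
#' are preserved while the trait-abundance link is broken. The identity
#' permutation is excluded (redrawn) whenever more than one species is
#' present. Independent per-axis shuffling is available behind `per_axis`.
#'
#' @param axes A [trait_axes] object (S >= 2).
#' @param seed Integer seed for reproducibility.
#' @param per_axis Shuffle each axis independently instead of permuting
#'   whole rows.
#'
#' @return A [trait_axes] object with permuted values and the original
#'   species ids.
#' @export
null_trait_randomization <- function(axes, seed = NULL, per_axis = FALSE) {
  stopifnot(inherits(axes, "trait_axes"))
  S <- axes$n_species
  if (S < 2L) stop_lv("invalid_axes", "need at least two species")
  do_draw <- function() {
    if (per_axis) {
      apply(axes$axes, 2L, sample)
    } else {
      perm <- sample.int(S)
      while (all(perm == seq_len(S))) perm <- sample.int(S)
      axes$axes[perm, , drop = FALSE]
    }
  }
  shuffled <- if (is.null(seed)) do_draw() else withr_seed(seed, do_draw())
  rownames(shuffled) <- axes$species_id
  trait_axes(axes$species_id, shuffled,
             variance_explained = axes$variance_explained)
}

#' ROC/AUC of presence-absence predictions
#'
#' Scores every plot x species cell by its predicted equilibrium relative
#' abundance and compares against observed presence/absence (e.g. botanical
#' surveys). The AUC is the rank statistic over all cells with ties
#' averaged, so it is invariant to monotone transformations of the scores.
#'
#' @param pred Numeric plots x species matrix of predicted relative
#'   abundances.
#' @param occ Logical or 0/1 plots x species matrix of observed occurrence,
#'   same shape as `pred`.
#'
#' @return List with `auc` (scalar) and `roc` (a [pROC::roc] object).
#' @export
auc_presence <- function(pred, occ) {
  pred <- as.matrix(pred)
  occ <- as.matrix(occ)
  if (!all(dim(pred) == dim(occ))) {
    stop_lv("dimension_mismatch", "pred and occ must have the same shape")
  }
  labels <- as.integer(occ != 0)
  if (length(unique(labels)) < 2L) {
    stop_lv("single_class",
            "occurrence data contain a single class; AUC undefined")
  }
  roc <- pROC::roc(response = labels, predictor = as.numeric(pred),
                   quiet = TRUE, direction = "<", levels = c(0L, 1L))
  list(auc = as.numeric(pROC::auc(roc)), roc = roc)
}

#' Fit metrics of a calibrated model
#'
#' Evaluates the calibrated model at the posterior median (materialized as
#' the retained draw nearest the circular-aware marginal medians, see
#' [posterior_median_draw()]): global and per-plot Nagelkerke
#' pseudo-R-squared against the equal-abundance null, and the DIC computed
#' from the retained per-draw deviances. Per-plot values use the same
#' modeled species pool in the null as the global value, so plots are
#' comparable.
#'
#' @param ps A `posterior_sample` whose `log_likelihood` trace was filled
#'   (targets built by [make_log_posterior()] do this).
#' @param axes,sites,sample The calibration inputs.
#' @param g_value,b_c_value Fixed transfer constants used in calibration.
#' @param equilibrium,solver,b0_seed Equilibrium settings, as in
#'   [make_log_posterior()].
#'
#' @return List of class `fit_metrics`: `pseudo_r2_global`,
#'   `pseudo_r2_per_plot`, `dic`, `p_d`, `loglik_at_median`,
#'   `loglik_null`, `median_par`.
#' @export
fit_metrics <- function(ps, axes, sites, sample,
                        g_value = 10^-3.43, b_c_value = 10^-3.8,
                        equilibrium = c("analytic", "ode"),
                        solver = solver_control(), b0_seed = 1L) {
  stopifnot(inherits(ps, "posterior_sample"))
  equilibrium <- match.arg(equilibrium)
  med <- posterior_median_draw(ps,
                               circular = circular_par_names(axes$n_axes))
  tp <- unpack_transfer(med, axes$n_axes, g_value, b_c_value)
  pred <- predict_rel_abundance(tp, axes, sites, equilibrium = equilibrium,
                                solver = solver, b0_seed = b0_seed)
  ll_plot <- vapply(seq_len(sample$n_plots), function(j) {
    multinomial_loglik(sample$counts[j, ], pred[j, ])
  }, numeric(1))
  ll_null_plot <- null_loglik(sample, per_plot = TRUE)
  ll_model <- sum(ll_plot)
  ll_null <- sum(ll_null_plot)
  r2_global <- nagelkerke_r2(ll_model, ll_null, sum(sample$effort))
  r2_plot <- vapply(seq_len(sample$n_plots), function(j) {
    nagelkerke_r2(ll_plot[j], ll_null_plot[j], sample$effort[j])
  }, numeric(1))
  dev_draws <- -2 * retained_loglik(ps)
  dev_draws <- dev_draws[is.finite(dev_draws)]
  dic_out <- dic(dev_draws, -2 * ll_model)
  structure(
    list(pseudo_r2_global = r2_global,
         pseudo_r2_per_plot = stats::setNames(r2_plot, sample$plot_id),
         dic = dic_out$dic, p_d = dic_out$p_d,
         mean_deviance = dic_out$mean_deviance,
         loglik_at_median = ll_model, loglik_null = ll_null,
         loglik_per_plot = stats::setNames(ll_plot, sample$plot_id),
         median_par = med),
    class = "fit_metrics"
  )
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("<fit_metrics> pseudo-R2 %.3f, DIC %.1f (pD %.1f)\n",
              x$pseudo_r2_global, x$dic, x$p_d))
  invisible(x)
}

#' Posterior trait-demography correlation summaries
#'
#' For each retained posterior draw, rebuilds the per-species demographic
#' parameters and computes Pearson correlations among `theta_min`, `l` and
#' `c`, and (optionally) between each demographic parameter and each raw
#' trait. Summaries are the median and the 2.5/97.5 percentiles across
#' draws. Correlations that are undefined for a draw (zero-variance
#' parameter vector, e.g. when its scale `a_m` is zero) are recorded as
#' `NA` and counted.
#'
#' @param ps A `posterior_sample`.
#' @param axes The [trait_axes] used in calibration.
#' @param traits Optional [trait_table] of observed traits to correlate
#'   against.
#' @param g_value,b_c_value Fixed transfer constants.
#' @param max_draws Cap on the number of (evenly thinned) draws used.
#'
#' @return A data.frame with columns `pair`, `median`, `lo`, `hi`,
#'   `n_undefined`.
#' @export
posterior_demography_summary <- function(ps, axes, traits = NULL,
                                         g_value = 10^-3.43,
                                         b_c_value = 10^-3.8,
                                         max_draws = 500L) {
  stopifnot(inherits(ps, "posterior_sample"))
  draws <- as.matrix(ps)
  if (nrow(draws) < 100L) {
    stop_lv("invalid_chains", "need at least 100 retained draws")
  }
  idx <- unique(round(seq(1L, nrow(draws),
                          length.out = min(max_draws, nrow(draws)))))
  demo_names <- c("theta_min", "l", "c")
  pairs <- utils::combn(demo_names, 2L, paste, collapse = "~")
  trait_pairs <- character()
  if (!is.null(traits)) {
    stopifnot(inherits(traits, "trait_table"))
    trait_pairs <- as.character(outer(demo_names, traits$traits, paste,
                                      sep = "~"))
  }
  all_pairs <- c(pairs, trait_pairs)
  vals <- matrix(NA_real_, length(idx), length(all_pairs),
                 dimnames = list(NULL, all_pairs))
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
      stats::cor(x, y)
  }
  for (r in seq_along(idx)) {
    tp <- unpack_transfer(draws[idx[r], ], axes$n_axes, g_value, b_c_value)
    dp <- build_demography(tp, axes)
    dd <- list(theta_min = dp$theta_min, l = dp$l, c = dp$c)
    k <- 1L
    for (pp in pairs) {
      nm <- strsplit(pp, "~", fixed = TRUE)[[1L]]
      vals[r, k] <- safe_cor(dd[[nm[1L]]], dd[[nm[2L]]])
      k <- k + 1L
    }
    if (!is.null(traits)) {
      for (dn in demo_names) {
        for (tn in traits$traits) {
          vals[r, paste(dn, tn, sep = "~")] <-
            safe_cor(dd[[dn]], traits$values[, tn])
        }
      }
    }
  }
  qfun <- function(x, p) {
    if (all(is.na(x))) NA_real_ else
      unname(stats::quantile(x, probs = p, na.rm = TRUE))
  }
  data.frame(
    pair = all_pairs,
    median = apply(vals, 2L, qfun, p = 0.5),
    lo = apply(vals, 2L, qfun, p = 0.025),
    hi = apply(vals, 2L, qfun, p = 0.975),
    n_undefined = colSums(is.na(vals)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
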