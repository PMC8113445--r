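#' Generate orthogonal standard-normal trait axes
#'
#' Draws a species x N Gaussian matrix, centers its columns and
#' orthonormalizes them (QR), then rescales so every axis has exactly zero
#' mean, unit sample variance and exact mutual orthogonality -- the contract
#' trait preprocessing provides on real data.
#'
#' @param S Number of species (> N).
#' @param N Number of axes.
#' @param seed Integer seed.
#'
#' @return A [trait_axes] object.
#' @export
generate_axes <- function(S, N = 3L, seed = NULL) {
  S <- as.integer(S); N <- as.integer(N)
  if (S <= N) stop_lv("invalid_axes", "need more species than axes")
  draw <- function() matrix(stats::rnorm(S * N), S, N)
  raw <- if (is.null(seed)) draw() else withr_seed(seed, draw())
  centered <- scale(raw, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(centered))
  # columns of Q are zero-sum (combinations of centered columns),
  # orthonormal; rescale to unit sample variance
  axes <- q * sqrt(S - 1)
  # deterministic sign: make each axis correlate positively with its seed
  for (j in seq_len(N)) {
    if (sum(axes[, j] * raw[, j]) < 0) axes[, j] <- -axes[, j]
  }
  trait_axes(sprintf("sp%03d", seq_len(S)), axes)
}

#' Default ground-truth transfer parameters for synthetic scenarios
#'
#' A parameterization with clear trait signal that produces species
#' turnover along the temperature gradient: cold-tolerant species are more
#' sensitive to surrounding biomass (opposite-signed loadings of
#' `theta_min` and `l` on the first axis, giving the stress-tolerance vs.
#' competition trade-off), and competition strength varies along a partly
#' distinct direction.
#'
#' @param N Number of trait axes.
#' @param g_value,b_c_value Fixed constants.
#'
#' @return A [transfer_params] object.
#' @export
default_true_transfer <- function(N = 3L, g_value = 10^-3.43,
                                  b_c_value = 10^-3.8) {
  stopifnot(N >= 2L)
  pad <- function(phi) c(phi, rep(pi / 2, N - 1L - length(phi)))[seq_len(N - 1L)]
  transfer_params(
    phi_theta_min = pad(c(0.7, 1.2)),
    phi_l = pad(c(2.3, 4.0)),
    phi_c = pad(c(1.4, 2.2)),
    a_theta_min = 1.0, b_theta_min = 0.0,
    a_l = 0.6, b_l = -2.3, a_c = 0.4,
    g_value = g_value, b_c_value = b_c_value
  )
}

#' Synthetic community scenario
#'
#' Describes a fully synthetic study: `S` species with `N` orthogonal
#' standard-normal trait axes, `J` plots on an evenly spaced standardized
#' temperature gradient, demographic parameters generated by a known
#' transfer function, equilibrium communities from the community model, and
#' multinomial sampling of a fixed number of individuals per plot. Defaults
#' emulate the motivating study design at desk scale: 40 species, 12 plots,
#' 3 axes, 101 individuals per plot (the field design used 118 species and
#' 18 plots at the same effort).
#'
#' @param S,J,N,effort Species, plots, axes, individuals sampled per plot.
#' @param true_transfer Ground-truth [transfer_params].
#' @param seed Integer seed controlling every random element.
#'
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(S = 40L, J = 12L, N = 3L, effort = 101L,
                               true_transfer = default_true_transfer(N),
                               seed = 1L) {
  stopifnot(S >= 2L, J >= 2L, effort >= 1L,
            inherits(true_transfer, "transfer_params"),
            true_transfer$n_axes == N)
  structure(list(S = as.integer(S), J = as.integer(J), N = as.integer(N),
                 effort = as.integer(effort),
                 true_transfer = true_transfer, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Simulate a synthetic dataset from a scenario
#'
#' Runs the generative pipeline forward: trait axes, evenly spaced then
#' standardized plot temperatures, demography through the true transfer
#' function, per-plot equilibria from the community model, and multinomial
#' draws of `effort` individuals per plot with sampling probabilities equal
#' to equilibrium relative biomasses. All ground truth is retained.
#'
#' @param sc A [synthetic_scenario].
#'
#' @return List with `axes`, `sites`, `sample` ([community_sample]),
#'   `demography` (true [demographic_params]), `equilibria` (list of
#'   `equilibrium_state` per plot), `rel_abundance` (true plots x species
#'   matrix), `occurrence` (plots x species 0/1 from the true equilibria at
#'   the extinction threshold) and the scenario itself.
#' @export
simulate_dataset <- function(sc) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  axes <- generate_axes(sc$S, sc$N, seed = sc$seed)
  sites <- site_table(sprintf("plot%02d", seq_len(sc$J)), seq_len(sc$J))
  demo <- build_demography(sc$true_transfer, axes)
  eq <- lapply(sites$theta, function(th) analytic_equilibrium(demo, th))
  empty <- vapply(eq, function(e) e$degenerate, logical(1))
  if (any(empty)) {
    stop_lv("empty_community",
            paste0("no species persists at plot(s) ",
                   paste(sites$plot_id[empty], collapse = ", "),
                   "; raise b_theta_min or widen theta_min spread"),
            data = sites$plot_id[empty])
  }
  p <- do.call(rbind, lapply(eq, `[[`, "rel_abundance"))
  dimnames(p) <- list(sites$plot_id, axes$species_id)
  counts <- withr_seed(sc$seed + 1L, t(vapply(
    seq_len(sc$J),
    function(j) as.numeric(stats::rmultinom(1L, sc$effort, p[j, ])),
    numeric(sc$S)
  )))
  dimnames(counts) <- dimnames(p)
  occurrence <- (p >= eq[[1L]]$extinction_tol) * 1L
  list(axes = axes, sites = sites,
       sample = community_sample(counts, sc$effort),
       demography = demo, equilibria = eq, rel_abundance = p,
       occurrence = occurrence, scenario = sc)
}

#' Calibrate the transfer function on community data
#'
#' End-to-end inference wrapper: builds the log-posterior from the aligned
#' inputs and samples it with [run_dezs()], returning the posterior sample
#' together with fit metrics evaluated at the posterior median.
#'
#' @param axes A [trait_axes] object.
#' @param sites A [site_table].
#' @param sample A [community_sample].
#' @param prior A [prior_spec]; defaults to `prior_spec(axes$n_axes)`.
#' @param n_iter,n_internal,n_instances,burn_in,seed Sampler settings
#'   passed to [run_dezs()].
#' @param g_value,b_c_value Fixed transfer constants.
#' @param equilibrium,solver,b0_seed Equilibrium settings (see
#'   [make_log_posterior()]).
#' @param compute_metrics Evaluate [fit_metrics()] at the posterior median.
#' @param screen With several independent instances, drop instances trapped
#'   in a dominated mode before pooling (see [screen_chains()]).
#' @param ... Further arguments passed to [run_dezs()].
#'
#' @return A list of class `lv_calibration` with elements `posterior`
#'   (`posterior_sample`), `metrics` ([fit_metrics] or `NULL`),
#'   `convergence` ([gelman_rubin()] output), and the inputs' dimensions.
#' @export
calibrate <- function(axes, sites, sample, prior = NULL,
                      n_iter = 10000L, n_internal = 3L, n_instances = 1L,
                      burn_in = 0.7, seed = 1L,
                      g_value = 10^-3.43, b_c_value = 10^-3.8,
                      equilibrium = c("analytic", "ode"),
                      solver = solver_control(), b0_seed = 1L,
                      compute_metrics = TRUE, screen = TRUE, ...) {
  equilibrium <- match.arg(equilibrium)
  prior <- prior %||% prior_spec(axes$n_axes)
  target <- make_log_posterior(axes, sites, sample, prior,
                               g_value = g_value, b_c_value = b_c_value,
                               equilibrium = equilibrium, solver = solver,
                               b0_seed = b0_seed)
  ps <- run_dezs(target, prior$lower, prior$upper, prior$sample,
                 n_iter = n_iter, n_internal = n_internal,
                 n_instances = n_instances, burn_in = burn_in, seed = seed,
                 par_names = prior$par_names, ...)
  if (screen && n_instances > 1L) ps <- screen_chains(ps)
  conv <- gelman_rubin(ps)
  metrics <- if (compute_metrics) {
    fit_metrics(ps, axes, sites, sample, g_value = g_value,
                b_c_value = b_c_value, equilibrium = equilibrium,
                solver = solver, b0_seed = b0_seed)
  }
  structure(list(posterior = ps, metrics = metrics, convergence = conv,
                 prior = prior, axes = axes, sites = sites,
                 sample = sample,
                 settings = list(n_iter = n_iter, n_internal = n_internal,
                                 n_instances = n_instances,
                                 burn_in = burn_in, seed = seed,
                                 g_value = g_value, b_c_value = b_c_value,
                                 equilibrium = equilibrium)),
            class = "lv_calibration")
}

#' @export
print.lv_calibration <- function(x, ...) {
  cat(sprintf("<lv_calibration> %d species, %d plots\n",
              x$axes$n_species, x$sample$n_plots))
  print(x$posterior)
  if (!is.null(x$metrics)) print(x$metrics)
  cat(sprintf("  mpsrf: %.3f\n", x$convergence$mpsrf))
  invisible(x)
}

#' Parameter-recovery experiment on synthetic data
#'
#' Simulates a dataset from a known transfer function, calibrates the model
#' on it, and reports how well the truth is recovered: Pearson correlations
#' between true and posterior-median demographic parameter vectors,
#' coverage of the 95% credible intervals for the free transfer parameters,
#' convergence diagnostics, and the DIC of the real-axes calibration
#' against one shuffled-axes null calibration.
#'
#' @param sc A [synthetic_scenario].
#' @param n_iter,n_internal,n_instances,burn_in Sampler settings.
#' @param seed Seed for the calibrations (the data seed lives in `sc`).
#' @param run_null Also run the shuffled-axes null calibration.
#' @param ... Passed on to [calibrate()].
#'
#' @return A list of class `recovery_report`: `cor_theta_min`, `cor_l`,
#'   `cor_c` (truth vs. posterior-median demography), `ci_covered` (count
#'   of free transfer parameters whose true value falls inside its 95%
#'   credible interval) and `ci_table`, `mpsrf`, `converged`
#'   (mpsrf <= 1.1), `dic`, `dic_null`, `dic_gap` (null minus real;
#'   positive favors the real axes), plus the fitted objects.
#' @export
recovery_experiment <- function(sc, n_iter = 8000L, n_internal = 3L,
                                n_instances = 1L, burn_in = 0.7,
                                seed = 100L, run_null = TRUE, ...) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  dat <- simulate_dataset(sc)
  truth <- pack_transfer(sc$true_transfer)
  fit <- calibrate(dat$axes, dat$sites, dat$sample,
                   n_iter = n_iter, n_internal = n_internal,
                   n_instances = n_instances, burn_in = burn_in,
                   seed = seed,
                   g_value = sc$true_transfer$g_value,
                   b_c_value = sc$true_transfer$b_c_value, ...)
  med_par <- posterior_median_draw(fit$posterior,
                                   circular = circular_par_names(sc$N))
  med_tp <- unpack_transfer(med_par, sc$N,
                            sc$true_transfer$g_value,
                            sc$true_transfer$b_c_value)
  med_demo <- build_demography(med_tp, dat$axes)
  draws <- as.matrix(fit$posterior)
  ci <- t(apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975)))
  covered <- truth >= ci[, 1L] & truth <= ci[, 2L]
  null_fit <- NULL
  if (run_null) {
    null_axes <- null_trait_randomization(dat$axes, seed = sc$seed + 2L)
    null_fit <- calibrate(null_axes, dat$sites, dat$sample,
                          n_iter = n_iter, n_internal = n_internal,
                          n_instances = n_instances, burn_in = burn_in,
                          seed = seed + 1L,
                          g_value = sc$true_transfer$g_value,
                          b_c_value = sc$true_transfer$b_c_value, ...)
  }
  truth_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
      stats::cor(x, y)
  }
  structure(
    list(cor_theta_min = truth_cor(dat$demography$theta_min,
                                   med_demo$theta_min),
         cor_l = truth_cor(dat$demography$l, med_demo$l),
         cor_c = truth_cor(dat$demography$c, med_demo$c),
         ci_covered = sum(covered), n_free = length(truth),
         ci_table = data.frame(parameter = names(truth), truth = truth,
                               lo = ci[, 1L], hi = ci[, 2L],
                               covered = covered, row.names = NULL),
         mpsrf = fit$convergence$mpsrf,
         converged = is.na(fit$convergence$mpsrf) ||
           fit$convergence$mpsrf <= 1.1,
         dic = fit$metrics$dic,
         dic_null = if (run_null) null_fit$metrics$dic else NA_real_,
         dic_gap = if (run_null) null_fit$metrics$dic - fit$metrics$dic
                   else NA_real_,
         pseudo_r2 = fit$metrics$pseudo_r2_global,
         fit = fit, null_fit = null_fit, data = dat),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat(sprintf("  truth correlations: theta_min %.3f, l %.3f, c %.3f\n",
              x$cor_theta_min, x$cor_l, x$cor_c))
  cat(sprintf("  95%% CI coverage: %d / %d free parameters\n",
              x$ci_covered, x$n_free))
  cat(sprintf("  mpsrf %.3f (converged: %s)\n", x$mpsrf, x$converged))
  if (!is.na(x$dic_gap)) {
    cat(sprintf("  DIC real %.1f vs null %.1f (gap %.1f)\n",
                x$dic, x$dic_null, x$dic_gap))
  }
  if (!x$converged) {
    cat("  WARNING: convergence diagnostic above threshold;",
        "interpret with caution\n")
  }
  invisible(x)
}
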