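#' Community counts from fixed-effort sampling
#'
#' Plot x species matrix of sampled individual counts under a fixed
#' per-plot sampling effort (101 individuals per plot in the motivating
#' study design).
#'
#' @param counts Nonnegative integer plot x species matrix with plot ids as
#'   row names and species ids as column names.
#' @param effort Optional per-plot total; defaults to the row sums and must
#'   match them when supplied.
#'
#' @return An object of class `community_sample`.
#' @export
community_sample <- function(counts, effort = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_lv("invalid_counts", "counts must be nonnegative integers")
  }
  rs <- rowSums(counts)
  if (is.null(effort)) {
    effort <- rs
  } else if (length(effort) == 1L) {
    effort <- rep(effort, nrow(counts))
  }
  if (!all(rs == effort)) {
    stop_lv("invalid_counts",
            "row sums of counts must equal the stated sampling effort")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("plot%02d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sp%03d", seq_len(ncol(counts)))
  }
  structure(list(counts = counts, effort = as.numeric(effort),
                 plot_id = rownames(counts), species_id = colnames(counts),
                 n_plots = nrow(counts), n_species = ncol(counts)),
            class = "community_sample")
}

#' @export
print.community_sample <- function(x, ...) {
  cat(sprintf("<community_sample> %d plots x %d species, effort %s\n",
              x$n_plots, x$n_species,
              paste(unique(x$effort), collapse = "/")))
  invisible(x)
}

#' Exact multinomial log-likelihood
#'
#' Log probability mass of observing `counts` under sampling probabilities
#' `p`, including the multinomial coefficient so that absolute deviances,
#' DIC and pseudo-R-squared comparisons are well defined. Probabilities are
#' floored at `1e-300` inside the logarithm only, which keeps the value
#' finite when the community model drives an observed species (numerically)
#' extinct; a structurally zero probability facing a positive count yields
#' `-Inf`.
#'
#' @param counts Nonnegative integer vector.
#' @param p Probability vector of the same length, summing to one within
#'   `1e-9`.
#'
#' @return Scalar log-likelihood.
#' @export
#' @examples
#' multinomial_loglik(c(1, 1), c(0.5, 0.5))  # log(0.5)
multinomial_loglik <- function(counts, p) {
  counts <- as.numeric(counts)
  p <- as.numeric(p)
  if (length(counts) != length(p)) {
    stop_lv("dimension_mismatch", "counts and p must have equal length")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_lv("invalid_counts", "counts must be nonnegative integers")
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop_lv("invalid_probs", "p must be nonnegative and sum to one")
  }
  pos <- counts > 0
  if (!any(pos)) return(0)
  lgamma(sum(counts) + 1) - sum(lgamma(counts[pos] + 1)) +
    sum(counts[pos] * log(pmax(p[pos], 1e-300)))
}

#' Prior specification for the transfer parameters
#'
#' Uninformative (uniform) priors on all angles over their natural ranges;
#' regularizing priors on the scales and free offsets: half-normal on each
#' `a_m` and normal on each free `b_m`. The regularization controls the
#' across-species mean and spread of the demographic parameters, which keeps
#' the equilibrium solver in well-behaved territory and tempers trade-offs
#' among parameters; all hyperparameters are surfaced here rather than
#' hard-coded.
#'
#' @param N Number of trait axes.
#' @param a_scale Scale of the half-normal prior on each `a_m`.
#' @param b_theta_min_mean,b_theta_min_sd Normal prior for `b_theta_min`
#'   (standardized-temperature units).
#' @param b_l_mean,b_l_sd Normal prior for `b_l` (log-rate units).
#'
#' @return An object of class `prior_spec` with elements `log_density(par)`,
#'   `sample(n)`, `lower`, `upper` and `par_names`.
#' @export
prior_spec <- function(N = 3L, a_scale = 1,
                       b_theta_min_mean = 0, b_theta_min_sd = 1,
                       b_l_mean = -2, b_l_sd = 2) {
  N <- as.integer(N)
  stopifnot(N >= 2L, a_scale > 0, b_theta_min_sd > 0, b_l_sd > 0)
  nm <- transfer_par_names(N)
  d <- length(nm)
  is_angle <- grepl("^phi_", nm)
  is_last_angle <- grepl(sprintf("_%d$", N - 1L), nm) & is_angle
  is_a <- grepl("^a_", nm)
  lower <- ifelse(is_angle, 0, ifelse(is_a, 0, -Inf))
  upper <- ifelse(is_angle, ifelse(is_last_angle, 2 * pi, pi),
                  ifelse(is_a, Inf, Inf))
  names(lower) <- names(upper) <- nm
  b_mean <- c(b_theta_min = b_theta_min_mean, b_l = b_l_mean)
  b_sd <- c(b_theta_min = b_theta_min_sd, b_l = b_l_sd)
  angle_const <- -sum(log(upper[is_angle]))

  log_density <- function(par) {
    if (length(par) != d) {
      stop_lv("dimension_mismatch", "parameter vector has wrong length")
    }
    if (any(par < lower) || any(par > upper)) return(-Inf)
    ld <- angle_const
    ld <- ld + sum(stats::dnorm(par[is_a], 0, a_scale, log = TRUE) + log(2))
    ld + stats::dnorm(par[nm == "b_theta_min"], b_mean["b_theta_min"],
                      b_sd["b_theta_min"], log = TRUE) +
      stats::dnorm(par[nm == "b_l"], b_mean["b_l"], b_sd["b_l"],
                   log = TRUE)
  }

  sample <- function(n) {
    out <- matrix(NA_real_, n, d, dimnames = list(NULL, nm))
    for (j in seq_len(d)) {
      out[, j] <- if (is_angle[j]) {
        stats::runif(n, 0, upper[j])
      } else if (is_a[j]) {
        abs(stats::rnorm(n, 0, a_scale))
      } else if (nm[j] == "b_theta_min") {
        stats::rnorm(n, b_mean["b_theta_min"], b_sd["b_theta_min"])
      } else {
        stats::rnorm(n, b_mean["b_l"], b_sd["b_l"])
      }
    }
    out
  }

  structure(list(log_density = log_density, sample = sample,
                 lower = lower, upper = upper, par_names = nm, n_axes = N,
                 hyper = list(a_scale = a_scale,
                              b_theta_min = c(b_theta_min_mean,
                                              b_theta_min_sd),
                              b_l = c(b_l_mean, b_l_sd))),
            class = "prior_spec")
}

#' Log-posterior closure for the transfer parameters
#'
#' Builds the target density sampled by [run_dezs()]: the sum over plots of
#' the multinomial log-likelihood of the observed counts given the
#' equilibrium relative abundances at each plot's temperature, plus the log
#' prior. The returned function maps a flat parameter vector (see
#' [pack_transfer()]) to a list with `log_posterior` and `log_likelihood`.
#'
#' The equilibrium can be computed analytically (exact fixed point, the
#' default: the model's global stability makes the fixed point unique, and
#' the analytic and ODE routes are cross-validated in the test suite) or by
#' ODE integration (`equilibrium = "ode"`), in which case a fixed `b0_seed`
#' makes the random initial biomasses identical across proposals -- global
#' stability makes the equilibrium independent of them anyway.
#'
#' @param axes A [trait_axes] object.
#' @param sites A [site_table].
#' @param sample A [community_sample] aligned with `axes` and `sites`.
#' @param prior A [prior_spec].
#' @param g_value,b_c_value Fixed constants of the transfer function.
#' @param equilibrium `"analytic"` or `"ode"`.
#' @param solver [solver_control()] used when `equilibrium = "ode"`.
#' @param b0_seed Seed for the ODE initial biomasses.
#'
#' @return A function `par -> list(log_posterior, log_likelihood)`.
#' @export
make_log_posterior <- function(axes, sites, sample, prior,
                               g_value = 10^-3.43, b_c_value = 10^-3.8,
                               equilibrium = c("analytic", "ode"),
                               solver = solver_control(), b0_seed = 1L) {
  stopifnot(inherits(axes, "trait_axes"), inherits(sites, "site_table"),
            inherits(sample, "community_sample"),
            inherits(prior, "prior_spec"))
  equilibrium <- match.arg(equilibrium)
  if (sample$n_species != axes$n_species) {
    stop_lv("dimension_mismatch",
            "counts and trait axes describe different species sets")
  }
  if (sample$n_plots != nrow(sites)) {
    stop_lv("dimension_mismatch",
            "counts and site table describe different plot sets")
  }
  if (prior$n_axes != axes$n_axes) {
    stop_lv("dimension_mismatch", "prior and axes disagree on N")
  }
  N <- axes$n_axes
  S <- axes$n_species
  J <- sample$n_plots
  theta <- sites$theta
  counts <- sample$counts
  ax <- axes$axes
  # per-plot additive constants of the multinomial coefficient
  lcoef <- vapply(seq_len(J), function(j) {
    x <- counts[j, ]
    lgamma(sum(x) + 1) - sum(lgamma(x[x > 0] + 1))
  }, numeric(1))
  count_pos <- lapply(seq_len(J), function(j) which(counts[j, ] > 0))
  b0 <- withr_seed(b0_seed, stats::runif(S, 0.1, 1.0))
  m <- N - 1L

  function(par) {
    lprior <- prior$log_density(par)
    if (!is.finite(lprior)) {
      return(list(log_posterior = -Inf, log_likelihood = NA_real_))
    }
    # inline unpack + demography (hot path)
    phi_tm <- par[seq_len(m)]
    a_tm <- par[m + 1L]; b_tm <- par[m + 2L]
    phi_l <- par[m + 2L + seq_len(m)]
    a_l <- par[2L * m + 3L]; b_l <- par[2L * m + 4L]
    phi_c <- par[2L * m + 4L + seq_len(m)]
    a_c <- par[3L * m + 5L]
    theta_min <- a_tm * drop(ax %*% angles_to_unit_vector(phi_tm)) + b_tm
    xl <- a_l * drop(ax %*% angles_to_unit_vector(phi_l)) + b_l
    xc <- a_c * drop(ax %*% angles_to_unit_vector(phi_c)) + b_c_value
    l <- exp(pmin(pmax(xl, -50), 50))
    cc <- exp(pmin(pmax(xc, -50), 50))
    g <- rep(g_value, S)
    ll <- 0
    for (j in seq_len(J)) {
      p <- if (equilibrium == "analytic") {
        B <- analytic_equilibrium_fast(theta_min, g, cc, l, theta[j])
        tot <- sum(B)
        if (tot <= 0) rep(0, S) else B / tot
      } else {
        params <- demographic_params(theta_min, g, cc, l)
        st <- tryCatch(
          integrate_to_equilibrium(params, theta[j], b0 = b0,
                                   solver = solver),
          lvtraits_solver_error = function(e) NULL
        )
        if (is.null(st)) {
          return(list(log_posterior = -Inf, log_likelihood = NA_real_))
        }
        st$rel_abundance
      }
      jpos <- count_pos[[j]]
      ll <- ll + lcoef[j] +
        sum(counts[j, jpos] * log(pmax(p[jpos], 1e-300)))
    }
    list(log_posterior = ll + lprior, log_likelihood = ll)
  }
}

#' Per-plot equilibrium relative abundances for a parameter vector
#'
#' Convenience wrapper used by the evaluation layer: computes the plot x
#' species matrix of predicted equilibrium relative abundances for one
#' transfer parameterization.
#'
#' @inheritParams make_log_posterior
#' @param tp A [transfer_params] object.
#'
#' @return Numeric plots x species matrix whose rows sum to one (or to zero
#'   for degenerate plots).
#' @export
predict_rel_abundance <- function(tp, axes, sites,
                                  equilibrium = c("analytic", "ode"),
                                  solver = solver_control(), b0_seed = 1L) {
  stopifnot(inherits(tp, "transfer_params"), inherits(axes, "trait_axes"),
            inherits(sites, "site_table"))
  equilibrium <- match.arg(equilibrium)
  params <- build_demography(tp, axes)
  out <- matrix(0, nrow(sites), axes$n_species,
                dimnames = list(sites$plot_id, axes$species_id))
  for (j in seq_len(nrow(sites))) {
    st <- if (equilibrium == "analytic") {
      analytic_equilibrium(params, sites$theta[j])
    } else {
      integrate_to_equilibrium(params, sites$theta[j], solver = solver,
                               seed = b0_seed)
    }
    out[j, ] <- st$rel_abundance
  }
  out
}
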