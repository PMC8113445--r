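#' Differential-evolution MCMC with past-state archive (DEzs)
#'
#' Samples a target log-density with the DEzs algorithm: differential-
#' evolution proposals whose difference vectors are drawn from a growing
#' archive Z of past states, mixed with snooker updates that propose along
#' the line towards an archived state. Jumps use the scaling
#' `gamma = 2.38 / sqrt(2 d)` with occasional `gamma = 1` moves to hop
#' between modes; snooker jumps draw `gamma` uniformly on (1.2, 2.2) and
#' carry the `(d-1)`-power norm factor in the acceptance ratio. Proposals
#' that leave the box are reflected at the boundary for differential-
#' evolution moves (a symmetric fold, preserving detailed balance) and
#' rejected for snooker moves; `bounds = "reject"` switches both to
#' rejection.
#'
#' Several independent sampler instances (each with its own archive and
#' `n_internal` interacting walkers) can be run to mimic fully independent
#' chains for convergence diagnostics; all walkers of all instances are
#' returned as separate chains.
#'
#' @param target Function mapping a parameter vector to either a scalar
#'   log-density or a list with elements `log_posterior` and (optionally)
#'   `log_likelihood`.
#' @param lower,upper Numeric bound vectors (entries may be infinite).
#' @param init_sample Function `n -> n x d matrix` used to populate the
#'   initial archive and walker states (typically the prior's `sample`).
#' @param n_iter Iterations per walker.
#' @param n_internal Interacting walkers per sampler instance (>= 3).
#' @param n_instances Independent sampler instances.
#' @param burn_in Fraction of iterations discarded as burn-in by
#'   consumers of the returned object.
#' @param snooker_prob Probability of a snooker update.
#' @param gamma_jump_prob Probability of a `gamma = 1` full jump.
#' @param eps Standard deviation of the small Gaussian jitter added to
#'   differential-evolution proposals.
#' @param z_update_freq Append the current walkers to the archive every this
#'   many iterations.
#' @param z0_factor Initial archive size as a multiple of `d` (at least
#'   `n_internal + 3` rows are used).
#' @param seed Integer seed; identical seeds give bit-identical draws.
#' @param bounds `"reflect"` or `"reject"` for out-of-box DE proposals.
#' @param par_names Optional parameter names for the draw array.
#'
#' @return An object of class `posterior_sample`: `draws` (iterations x
#'   chains x d array), `log_posterior` and `log_likelihood` (iterations x
#'   chains), `burn_in` (first retained iteration minus one), `accept_rate`,
#'   and sampler metadata.
#' @references ter Braak & Vrugt (2008) Differential evolution Markov chain
#'   with snooker updater and fewer chains. Statistics and Computing 18.
#' @export
run_dezs <- function(target, lower, upper, init_sample,
                     n_iter = 10000L, n_internal = 3L, n_instances = 1L,
                     burn_in = 0.7, snooker_prob = 0.1,
                     gamma_jump_prob = 0.1, eps = 1e-6,
                     z_update_freq = 1L, z0_factor = 10L, seed = NULL,
                     bounds = c("reflect", "reject"), par_names = NULL) {
  bounds <- match.arg(bounds)
  d <- length(lower)
  stopifnot(length(upper) == d, n_internal >= 3L, n_iter >= 2L,
            n_instances >= 1L, burn_in >= 0, burn_in < 1)
  if (!is.null(seed)) set.seed(seed)
  par_names <- par_names %||% names(lower) %||% sprintf("par%d", seq_len(d))

  eval_target <- function(x) {
    v <- target(x)
    if (is.list(v)) {
      list(lp = as.numeric(v$log_posterior),
           ll = as.numeric(v$log_likelihood %||% NA_real_))
    } else {
      list(lp = as.numeric(v), ll = NA_real_)
    }
  }

  reflect <- function(x) {
    for (j in seq_len(d)) {
      lo <- lower[j]; up <- upper[j]
      if (x[j] >= lo && x[j] <= up) next
      if (is.finite(lo) && is.finite(up)) {
        w <- up - lo
        y <- (x[j] - lo) %% (2 * w)
        x[j] <- lo + if (y > w) 2 * w - y else y
      } else if (is.finite(lo)) {
        x[j] <- lo + abs(x[j] - lo)
      } else if (is.finite(up)) {
        x[j] <- up - abs(up - x[j])
      }
    }
    x
  }

  n_chains <- n_internal * n_instances
  draws <- array(NA_real_, c(n_iter, n_chains, d),
                 dimnames = list(NULL, NULL, par_names))
  lp_tr <- matrix(NA_real_, n_iter, n_chains)
  ll_tr <- matrix(NA_real_, n_iter, n_chains)
  accept <- numeric(n_instances)
  gamma_de <- 2.38 / sqrt(2 * d)

  for (inst in seq_len(n_instances)) {
    m0 <- max(z0_factor * d, n_internal + 3L)
    Z <- init_sample(m0)
    if (!is.matrix(Z) || ncol(Z) != d) {
      stop_lv("invalid_init", "init_sample must return an n x d matrix")
    }
    X <- matrix(NA_real_, n_internal, d)
    fx <- vector("list", n_internal)
    for (i in seq_len(n_internal)) {
      ok <- FALSE
      for (try in seq_len(500L)) {
        cand <- drop(init_sample(1L))
        v <- eval_target(cand)
        if (is.finite(v$lp)) {
          X[i, ] <- cand; fx[[i]] <- v; ok <- TRUE; break
        }
      }
      if (!ok) {
        stop_lv("bad_initialization",
                paste("could not find a starting point with finite",
                      "log-posterior; check priors and solver settings"))
      }
    }
    n_acc <- 0L
    cols <- (inst - 1L) * n_internal + seq_len(n_internal)
    for (t in seq_len(n_iter)) {
      nZ <- nrow(Z)
      for (i in seq_len(n_internal)) {
        x <- X[i, ]
        snooker <- stats::runif(1) < snooker_prob && nZ >= 3L
        log_extra <- 0
        if (snooker) {
          idx <- sample.int(nZ, 3L)
          z <- Z[idx[1L], ]
          dvec <- x - z
          nrm2 <- sum(dvec^2)
          if (nrm2 == 0) next
          e <- dvec / sqrt(nrm2)
          gs <- stats::runif(1, 1.2, 2.2)
          prop <- x + gs * sum((Z[idx[2L], ] - Z[idx[3L], ]) * e) * e
          if (any(prop < lower) || any(prop > upper)) next
          nrm2_new <- sum((prop - z)^2)
          if (nrm2_new == 0) next
          log_extra <- (d - 1) / 2 * (log(nrm2_new) - log(nrm2))
        } else {
          idx <- sample.int(nZ, 2L)
          gam <- if (stats::runif(1) < gamma_jump_prob) 1 else gamma_de
          prop <- x + gam * (Z[idx[1L], ] - Z[idx[2L], ]) +
            eps * stats::rnorm(d)
          if (bounds == "reflect") {
            prop <- reflect(prop)
          }
          if (any(prop < lower) || any(prop > upper)) next
        }
        v <- eval_target(prop)
        if (is.finite(v$lp) &&
            log(stats::runif(1)) < v$lp - fx[[i]]$lp + log_extra) {
          X[i, ] <- prop
          fx[[i]] <- v
          n_acc <- n_acc + 1L
        }
      }
      if (t %% z_update_freq == 0L) Z <- rbind(Z, X)
      draws[t, cols, ] <- X
      lp_tr[t, cols] <- vapply(fx, `[[`, numeric(1), "lp")
      ll_tr[t, cols] <- vapply(fx, `[[`, numeric(1), "ll")
    }
    accept[inst] <- n_acc / (n_iter * n_internal)
  }

  structure(
    list(draws = draws, log_posterior = lp_tr, log_likelihood = ll_tr,
         burn_in = floor(burn_in * n_iter), n_iter = n_iter,
         n_chains = n_chains, n_internal = n_internal,
         n_instances = n_instances, accept_rate = accept,
         par_names = par_names,
         meta = list(seed = seed, snooker_prob = snooker_prob,
                     gamma_jump_prob = gamma_jump_prob, eps = eps,
                     z_update_freq = z_update_freq, bounds = bounds)),
    class = "posterior_sample"
  )
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf(
    "<posterior_sample> %d iterations x %d chains x %d parameters\n",
    x$n_iter, x$n_chains, dim(x$draws)[3L]))
  cat(sprintf("  burn-in: %d, mean acceptance: %.2f\n", x$burn_in,
              mean(x$accept_rate)))
  invisible(x)
}

#' Pooled post-burn-in draws
#'
#' @param x A `posterior_sample`.
#' @param ... Unused.
#' @return Matrix (draws x parameters), chains pooled after burn-in.
#' @export
as.matrix.posterior_sample <- function(x, ...) {
  keep <- (x$burn_in + 1L):x$n_iter
  out <- do.call(rbind, lapply(seq_len(x$n_chains), function(ch) {
    m <- x$draws[keep, ch, , drop = FALSE]
    dim(m) <- dim(m)[c(1L, 3L)]
    m
  }))
  colnames(out) <- x$par_names
  out
}

#' Posterior medians of the sampled parameters
#'
#' Component-wise medians of the pooled post-burn-in draws. Parameters
#' named in `circular` (angles on the full circle `[0, 2*pi]`) use a
#' circular median — the ordinary median after re-centering the draws at
#' their circular mean — so a marginal that straddles the 0/2*pi boundary
#' does not produce a point in the middle of the gap.
#'
#' @param ps A `posterior_sample`.
#' @param circular Character vector of parameter names to treat as
#'   `2*pi`-periodic.
#' @return Named vector of per-parameter posterior medians (pooled chains,
#'   post burn-in).
#' @export
posterior_median <- function(ps, circular = character()) {
  m <- as.matrix(ps)
  out <- apply(m, 2L, stats::median)
  for (nm in intersect(circular, colnames(m))) {
    out[nm] <- circular_median(m[, nm])
  }
  out
}

#' Posterior-median point estimate as an actual retained draw
#'
#' Computes the component-wise (circular-aware) posterior medians and
#' returns the retained draw closest to them, distances standardized by
#' each marginal's spread (angular distance for circular parameters). For
#' a well-mixed unimodal posterior this coincides with the marginal
#' medians up to Monte-Carlo jitter; when walkers straddle several modes
#' it still yields a point inside the posterior's support, whereas the raw
#' component-wise median can fall between modes where the model likelihood
#' is meaningless.
#'
#' @inheritParams posterior_median
#' @return Named parameter vector (one retained draw).
#' @export
posterior_median_draw <- function(ps, circular = character()) {
  m <- as.matrix(ps)
  med <- posterior_median(ps, circular = circular)
  dist2 <- numeric(nrow(m))
  for (j in seq_len(ncol(m))) {
    nm <- colnames(m)[j]
    dev <- if (nm %in% circular) {
      d <- (m[, j] - med[j]) %% (2 * pi)
      pmin(d, 2 * pi - d)
    } else {
      m[, j] - med[j]
    }
    s <- stats::sd(m[, j])
    if (s > 0) dist2 <- dist2 + (dev / s)^2
  }
  m[which.min(dist2), ]
}

circular_median <- function(x, period = 2 * pi) {
  ang <- x * 2 * pi / period
  center <- atan2(mean(sin(ang)), mean(cos(ang))) * period / (2 * pi)
  offset <- ((x - center + period / 2) %% period) - period / 2
  (center + stats::median(offset)) %% period
}

# names of the full-circle angles among the free transfer parameters
circular_par_names <- function(N) {
  sprintf("phi_%s_%d", c("theta_min", "l", "c"), N - 1L)
}

#' Retained per-draw log-likelihoods
#'
#' @param ps A `posterior_sample`.
#' @return Numeric vector of pooled post-burn-in log-likelihood values.
#' @export
retained_loglik <- function(ps) {
  keep <- (ps$burn_in + 1L):ps$n_iter
  as.numeric(ps$log_likelihood[keep, ])
}

#' Screen sampler instances before pooling
#'
#' When several independent sampler instances are run, one can remain
#' trapped in a dominated posterior mode for the whole run. Pooling such an
#' instance with converged ones corrupts medians and credible intervals,
#' so instances whose retained median log-posterior falls more than
#' `lp_slack` below the best instance's are dropped before pooling;
#' convergence diagnostics are then assessed on the survivors. The default
#' slack, half the 99.9% chi-square quantile on `d` degrees of freedom, is
#' generous relative to within-mode log-posterior fluctuation but far
#' smaller than typical between-mode gaps.
#'
#' @param ps A `posterior_sample`.
#' @param lp_slack Log-posterior tolerance below the best instance.
#'
#' @return A `posterior_sample` containing the retained instances, with an
#'   added field `n_dropped` (instances discarded).
#' @export
screen_chains <- function(ps, lp_slack = NULL) {
  stopifnot(inherits(ps, "posterior_sample"))
  d <- dim(ps$draws)[3L]
  lp_slack <- lp_slack %||% (0.5 * stats::qchisq(0.999, d))
  keep_it <- (ps$burn_in + 1L):ps$n_iter
  inst_of <- rep(seq_len(ps$n_instances), each = ps$n_internal)
  inst_lp <- vapply(seq_len(ps$n_instances), function(i) {
    stats::median(ps$log_posterior[keep_it, inst_of == i])
  }, numeric(1))
  keep <- which(inst_lp >= max(inst_lp) - lp_slack)
  if (length(keep) == ps$n_instances) {
    ps$n_dropped <- 0L
    return(ps)
  }
  cols <- which(inst_of %in% keep)
  out <- ps
  out$draws <- ps$draws[, cols, , drop = FALSE]
  out$log_posterior <- ps$log_posterior[, cols, drop = FALSE]
  out$log_likelihood <- ps$log_likelihood[, cols, drop = FALSE]
  out$n_chains <- length(cols)
  out$n_instances <- length(keep)
  out$accept_rate <- ps$accept_rate[keep]
  out$n_dropped <- ps$n_instances - length(keep)
  out
}

#' Gelman-Rubin convergence diagnostics
#'
#' Potential scale reduction factors from multiple chains: per-parameter
#' psrf `sqrt(((n-1)/n W + B/n) / W)` and the multivariate psrf
#' `sqrt((n-1)/n + (m+1)/m * lambda_1)` with `lambda_1` the largest
#' eigenvalue of `W^{-1} B / n`.
#'
#' @param x A `posterior_sample` (post-burn-in draws are used), a 3-d array
#'   (iterations x chains x parameters), or a list of equally sized draw
#'   matrices (one per chain).
#'
#' @return List with `psrf` (named per-parameter vector) and `mpsrf`
#'   (scalar; `NA` for a single parameter, where it equals the psrf).
#' @export
gelman_rubin <- function(x) {
  chains <- if (inherits(x, "posterior_sample")) {
    keep <- (x$burn_in + 1L):x$n_iter
    lapply(seq_len(x$n_chains), function(ch) {
      m <- x$draws[keep, ch, , drop = FALSE]
      dim(m) <- dim(m)[c(1L, 3L)]
      colnames(m) <- x$par_names
      m
    })
  } else if (is.array(x) && length(dim(x)) == 3L) {
    lapply(seq_len(dim(x)[2L]), function(ch) {
      m <- x[, ch, , drop = FALSE]
      dim(m) <- dim(m)[c(1L, 3L)]
      colnames(m) <- dimnames(x)[[3L]]
      m
    })
  } else if (is.list(x)) {
    lapply(x, as.matrix)
  } else {
    stop_lv("invalid_chains", "unsupported chain container")
  }
  m <- length(chains)
  if (m < 2L) stop_lv("invalid_chains", "need at least two chains")
  n <- nrow(chains[[1L]])
  d <- ncol(chains[[1L]])
  if (n < 10L) stop_lv("invalid_chains", "need at least 10 retained draws")
  means <- t(vapply(chains, colMeans, numeric(d)))
  if (d == 1L) means <- matrix(means, ncol = 1L)
  W_list <- lapply(chains, stats::cov)
  W <- Reduce(`+`, W_list) / m
  Bn <- stats::cov(means)              # = B / n
  w_diag <- diag(as.matrix(W))
  if (any(w_diag <= 0)) {
    stop_lv("zero_variance",
            "a parameter has zero within-chain variance; psrf undefined")
  }
  psrf <- sqrt((n - 1) / n + diag(as.matrix(Bn)) / w_diag)
  names(psrf) <- colnames(chains[[1L]]) %||% sprintf("par%d", seq_len(d))
  mpsrf <- if (d > 1L) {
    lam <- max(Re(eigen(solve(W, Bn), only.values = TRUE)$values))
    sqrt((n - 1) / n + (m + 1) / m * lam)
  } else {
    NA_real_
  }
  list(psrf = psrf, mpsrf = mpsrf)
}
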