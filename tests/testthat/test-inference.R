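test_that("multinomial log-likelihood matches closed forms", {
  expect_equal(multinomial_loglik(c(1, 1), c(0.5, 0.5)), log(2 * 0.25))
  # certain outcome has probability one
  expect_equal(multinomial_loglik(c(7, 0, 0), c(1, 0, 0)), 0)
  expect_equal(multinomial_loglik(c(0, 0), c(0.3, 0.7)), 0)
  # agreement with the reference pmf
  withr_seed(2, for (k in 1:20) {
    S <- sample(2:6, 1)
    p <- runif(S); p <- p / sum(p)
    x <- as.numeric(rmultinom(1, sample(1:50, 1), p))
    expect_equal(multinomial_loglik(x, p),
                 dmultinom(x, prob = p, log = TRUE), tolerance = 1e-12)
  })
  expect_error(multinomial_loglik(c(1, 2), c(0.5, 0.6)),
               class = "lvtraits_invalid_probs")
  expect_error(multinomial_loglik(c(1.5, 1), c(0.5, 0.5)),
               class = "lvtraits_invalid_counts")
})

test_that("multinomial pmf is exactly normalized on small supports", {
  # enumeration oracle: sum over all outcomes equals one
  for (case in list(c(4, 2), c(6, 3), c(10, 4), c(5, 4))) {
    n <- case[1]; S <- case[2]
    outcomes <- enumerate_counts(n, S)
    p <- seq_len(S); p <- p / sum(p)
    total <- sum(apply(outcomes, 1, function(x)
      exp(multinomial_loglik(x, p))))
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("tiny probabilities are floored rather than fatal", {
  ll <- multinomial_loglik(c(3, 1), c(1, 0))
  expect_true(is.finite(ll))
  expect_equal(ll, lgamma(5) - lgamma(4) + log(1e-300), tolerance = 1e-9)
})

test_that("prior spec has the advertised support and density", {
  pr <- prior_spec(3)
  expect_length(pr$par_names, 11)
  par <- drop(pr$sample(1))
  expect_true(is.finite(pr$log_density(par)))
  # out-of-range angle and negative scale kill the density
  bad <- par; bad["phi_l_1"] <- pi + 0.2
  expect_identical(pr$log_density(bad), -Inf)
  bad2 <- par; bad2["a_c"] <- -0.1
  expect_identical(pr$log_density(bad2), -Inf)
  # samples respect the support
  draws <- withr_seed(3, pr$sample(500))
  expect_true(all(draws >= matrix(pr$lower, 500, 11, byrow = TRUE)))
  expect_true(all(draws <= matrix(pr$upper, 500, 11, byrow = TRUE)))
})

test_that("log-posterior composes the equilibrium and the multinomial", {
  sc <- synthetic_scenario(S = 15, J = 5, seed = 4)
  dat <- simulate_dataset(sc)
  pr <- prior_spec(3)
  lp <- make_log_posterior(dat$axes, dat$sites, dat$sample, pr)
  for (k in 1:5) {
    par <- withr_seed(50 + k, drop(pr$sample(1)))
    got <- lp(par)
    tp <- unpack_transfer(par, 3)
    dp <- build_demography(tp, dat$axes)
    # independent composition: equilibrium + floored multinomial kernel
    ll <- sum(vapply(seq_len(5), function(j) {
      p <- analytic_equilibrium(dp, dat$sites$theta[j])$rel_abundance
      x <- dat$sample$counts[j, ]
      pos <- x > 0
      lgamma(sum(x) + 1) - sum(lgamma(x[pos] + 1)) +
        sum(x[pos] * log(pmax(p[pos], 1e-300)))
    }, numeric(1)))
    expect_equal(got$log_likelihood, ll, tolerance = 1e-9)
    expect_equal(got$log_posterior, ll + pr$log_density(par),
                 tolerance = 1e-9)
  }
  # out-of-prior parameters short-circuit to -Inf
  par <- drop(pr$sample(1)); par["phi_c_1"] <- -1
  expect_identical(lp(par)$log_posterior, -Inf)
})

test_that("degenerate equilibria floor the likelihood instead of crashing", {
  sc <- synthetic_scenario(S = 8, J = 4, seed = 6)
  dat <- simulate_dataset(sc)
  pr <- prior_spec(3)
  lp <- make_log_posterior(dat$axes, dat$sites, dat$sample, pr)
  par <- pack_transfer(sc$true_transfer)
  par["b_theta_min"] <- 10  # every species above the warmest plot
  out <- lp(par)
  expect_true(is.finite(out$log_likelihood))
  expect_lt(out$log_likelihood, -1e4)
})

test_that("a single-species single-plot likelihood reduces to the prior", {
  ax <- trait_axes(c("a", "b"), rbind(c(1, 0.5, -1), c(-1, -0.5, 1)))
  sites <- site_table("p1", 0, standardize = FALSE)
  # all 101 individuals in one species; force the other extinct via counts
  counts <- matrix(c(101, 0), 1, 2,
                   dimnames = list("p1", c("a", "b")))
  pr <- prior_spec(3)
  lp <- make_log_posterior(ax, sites, community_sample(counts), pr)
  # pick parameters under which only species "a" persists
  par <- pack_transfer(default_true_transfer())
  tp <- unpack_transfer(par, 3)
  st <- analytic_equilibrium(build_demography(tp, ax), 0)
  expect_equal(lp(par)$log_likelihood,
               101 * log(max(st$rel_abundance[1], 1e-300)))
  # and when the surviving community is exactly the sampled species,
  # the log-likelihood vanishes and the posterior is the prior alone
  if (all(st$rel_abundance == c(1, 0))) {
    expect_equal(lp(par)$log_posterior, pr$log_density(par))
  }
})

test_that("likelihood is flat in the fixed growth slope", {
  sc <- synthetic_scenario(S = 12, J = 5, seed = 9)
  dat <- simulate_dataset(sc)
  pr <- prior_spec(3)
  par <- pack_transfer(sc$true_transfer)
  lls <- vapply(c(1, 0.1, 13), function(f) {
    make_log_posterior(dat$axes, dat$sites, dat$sample, pr,
                       g_value = 10^-3.43 * f)(par)$log_likelihood
  }, numeric(1))
  expect_equal(lls[2], lls[1], tolerance = 1e-9)
  expect_equal(lls[3], lls[1], tolerance = 1e-9)
})

test_that("joint rescaling of c and l leaves relative abundances alone", {
  # shifting b_c and b_l by the same amount rescales {c, l} and the total
  # biomass jointly: the multinomial likelihood cannot tell the difference,
  # which is why b_c is fixed
  sc <- synthetic_scenario(S = 12, J = 5, seed = 9)
  dat <- simulate_dataset(sc)
  pr <- prior_spec(3)
  par <- pack_transfer(sc$true_transfer)
  base <- make_log_posterior(dat$axes, dat$sites, dat$sample,
                             pr)(par)$log_likelihood
  for (delta in c(-1, 0.5, 2)) {
    par2 <- par
    par2["b_l"] <- par["b_l"] + delta
    shifted <- make_log_posterior(dat$axes, dat$sites, dat$sample, pr,
                                  b_c_value = 10^-3.8 + delta)
    expect_equal(shifted(par2)$log_likelihood, base, tolerance = 1e-9)
  }
})

test_that("duplicating every plot doubles the likelihood term only", {
  sc <- synthetic_scenario(S = 10, J = 4, seed = 12)
  dat <- simulate_dataset(sc)
  pr <- prior_spec(3)
  par <- pack_transfer(sc$true_transfer)
  single <- make_log_posterior(dat$axes, dat$sites, dat$sample, pr)(par)
  sites2 <- site_table(c(dat$sites$plot_id,
                         paste0(dat$sites$plot_id, "_dup")),
                       rep(dat$sites$theta, 2), standardize = FALSE)
  counts2 <- rbind(dat$sample$counts, dat$sample$counts)
  rownames(counts2) <- sites2$plot_id
  doubled <- make_log_posterior(dat$axes, sites2,
                                community_sample(counts2), pr)(par)
  expect_equal(doubled$log_likelihood, 2 * single$log_likelihood,
               tolerance = 1e-9)
  expect_equal(doubled$log_posterior - doubled$log_likelihood,
               single$log_posterior - single$log_likelihood,
               tolerance = 1e-9)
})

test_that("the sampler reproduces a known two-dimensional Gaussian", {
  target <- function(x) -0.5 * sum((x - c(1, -2))^2 / c(1, 0.25))
  init <- function(n) matrix(rnorm(2 * n, 0, 3), n, 2)
  ps <- run_dezs(target, rep(-Inf, 2), rep(Inf, 2), init,
                 n_iter = 6000, seed = 21, burn_in = 0.4)
  m <- as.matrix(ps)
  expect_equal(unname(colMeans(m)), c(1, -2), tolerance = 0.12)
  expect_equal(unname(apply(m, 2, var)), c(1, 0.25), tolerance = 0.15)
})

test_that("the sampler recovers a uniform target over the angle box", {
  lower <- c(0, 0); upper <- c(pi, 2 * pi)
  target <- function(x) 0
  init <- function(n) cbind(runif(n, 0, pi), runif(n, 0, 2 * pi))
  ps <- run_dezs(target, lower, upper, init, n_iter = 8000, seed = 5,
                 burn_in = 0.25)
  m <- as.matrix(ps)
  thin <- m[seq(1, nrow(m), by = 60), ]
  ks1 <- ks.test(thin[, 1], "punif", 0, pi)$p.value
  ks2 <- ks.test(thin[, 2], "punif", 0, 2 * pi)$p.value
  expect_gt(ks1, 0.01)
  expect_gt(ks2, 0.01)
  expect_true(all(m[, 1] >= 0 & m[, 1] <= pi))
  expect_true(all(m[, 2] >= 0 & m[, 2] <= 2 * pi))
})

test_that("sampling is bit-identical under a fixed seed", {
  target <- function(x) -0.5 * sum(x^2)
  init <- function(n) matrix(rnorm(3 * n), n, 3)
  ps1 <- run_dezs(target, rep(-Inf, 3), rep(Inf, 3), init, n_iter = 1500,
                  seed = 77)
  ps2 <- run_dezs(target, rep(-Inf, 3), rep(Inf, 3), init, n_iter = 1500,
                  seed = 77)
  expect_identical(ps1$draws, ps2$draws)
  expect_identical(ps1$log_posterior, ps2$log_posterior)
})

test_that("hopeless initialization raises a structured error", {
  target <- function(x) -Inf
  init <- function(n) matrix(rnorm(2 * n), n, 2)
  expect_error(run_dezs(target, rep(-Inf, 2), rep(Inf, 2), init,
                        n_iter = 10, seed = 1),
               class = "lvtraits_bad_initialization")
})

test_that("Gelman-Rubin diagnostics behave on known chain structures", {
  # i.i.d. chains from one distribution converge to psrf near one
  withr_seed(14, {
    arr <- array(rnorm(4000 * 4 * 3), c(4000, 4, 3))
    gr <- gelman_rubin(arr)
    expect_true(all(gr$psrf < 1.05))
    expect_lt(gr$mpsrf, 1.05)
    # separated chain means inflate the diagnostic
    arr2 <- arr
    arr2[, 2, ] <- arr2[, 2, ] + 3
    gr2 <- gelman_rubin(arr2)
    expect_true(all(gr2$psrf > 1.5))
    expect_gt(gr2$mpsrf, 1.5)
    # constant chains have undefined psrf
    arr3 <- array(1, c(100, 3, 2))
    expect_error(gelman_rubin(arr3), class = "lvtraits_zero_variance")
    expect_error(gelman_rubin(arr[, 1, , drop = FALSE]),
                 class = "lvtraits_invalid_chains")
  })
})

test_that("Gelman-Rubin agrees with the coda reference implementation", {
  withr_seed(9, arr <- array(rnorm(2000 * 3 * 4, sd = 2), c(2000, 3, 4)))
  arr[, 1, ] <- arr[, 1, ] + 0.2   # mild disagreement between chains
  gr <- gelman_rubin(arr)
  ml <- coda::mcmc.list(lapply(1:3, function(ch) coda::mcmc(arr[, ch, ])))
  ref <- coda::gelman.diag(ml, autoburnin = FALSE, transform = FALSE)
  expect_equal(unname(gr$psrf), unname(ref$psrf[, 1]), tolerance = 0.02)
  expect_equal(gr$mpsrf, ref$mpsrf, tolerance = 0.02)
})
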