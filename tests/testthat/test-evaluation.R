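test_that("Nagelkerke pseudo-R2 has its defining identities", {
  # model equal to the null explains nothing
  expect_equal(nagelkerke_r2(-500, -500, 101), 0)
  # a perfect model (log-likelihood zero) attains the normalized maximum
  expect_equal(nagelkerke_r2(0, -500, 101), 1)
  # model below the null goes negative
  expect_lt(nagelkerke_r2(-520, -500, 101), 0)
  # bounded above by one
  withr_seed(3, for (k in 1:20) {
    lln <- -runif(1, 10, 500)
    llm <- lln + runif(1, -100, -lln)
    expect_lte(nagelkerke_r2(llm, lln, 101), 1)
  })
  expect_error(nagelkerke_r2(-1, 0, 10),
               class = "lvtraits_degenerate_null")
})

test_that("the equal-abundance null uses the full modeled pool", {
  counts <- matrix(c(3, 2, 0, 5, 0, 0), 2, 3, byrow = TRUE,
                   dimnames = list(c("p1", "p2"), c("a", "b", "c")))
  cs <- community_sample(counts)
  per <- null_loglik(cs, per_plot = TRUE)
  expect_equal(unname(per["p1"]), multinomial_loglik(c(3, 2, 0), rep(1 / 3, 3)))
  expect_equal(unname(per["p2"]), multinomial_loglik(c(5, 0, 0), rep(1 / 3, 3)))
  expect_equal(null_loglik(cs), sum(per))
})

test_that("DIC reduces to the deviance for a constant trace", {
  out <- dic(rep(42.5, 10), 42.5)
  expect_equal(out$dic, 42.5)
  expect_equal(out$p_d, 0)
  # affine equivariance: adding k to all deviances adds k to the DIC
  base <- dic(c(10, 12, 14, 16), 11)
  shifted <- dic(c(10, 12, 14, 16) + 7, 11 + 7)
  expect_equal(shifted$dic, base$dic + 7)
  expect_error(dic(c(1, Inf), 1), class = "lvtraits_invalid_deviance")
  expect_error(dic(5, 5), class = "lvtraits_invalid_deviance")
})

test_that("DIC penalty is positive for a well-behaved posterior", {
  # conjugate normal model: y ~ N(mu, 1), mu ~ N(0, 100); deviance draws
  # from the analytic posterior of mu
  withr_seed(6, {
    y <- rnorm(25, 1.3, 1)
    post_var <- 1 / (25 + 1 / 100)
    post_mean <- sum(y) * post_var
    mus <- rnorm(4000, post_mean, sqrt(post_var))
    dev <- vapply(mus, function(m) -2 * sum(dnorm(y, m, 1, log = TRUE)),
                  numeric(1))
    dev_at_med <- -2 * sum(dnorm(y, median(mus), 1, log = TRUE))
    out <- dic(dev, dev_at_med)
    expect_gt(out$p_d, 0)
    # effective parameter count of a one-parameter model is about one
    expect_equal(out$p_d, 1, tolerance = 0.25)
  })
})

test_that("trait shuffling permutes rows jointly and never trivially", {
  ax <- generate_axes(10, 3, seed = 3)
  for (seed in 1:10) {
    sh <- null_trait_randomization(ax, seed = seed)
    # multiset per axis preserved, row bundles preserved
    expect_equal(sort(unname(sh$axes[, 1])), sort(unname(ax$axes[, 1])))
    idx <- match(data.frame(t(sh$axes)), data.frame(t(ax$axes)))
    expect_false(any(is.na(idx)))
    expect_false(all(idx == seq_len(10)))  # identity excluded
    expect_identical(sh$species_id, ax$species_id)
  }
  # per-axis variant preserves each axis multiset but may break rows
  sh2 <- null_trait_randomization(ax, seed = 1, per_axis = TRUE)
  expect_equal(sort(unname(sh2$axes[, 2])), sort(unname(ax$axes[, 2])))
  # reproducible from seed
  expect_equal(null_trait_randomization(ax, seed = 4)$axes,
               null_trait_randomization(ax, seed = 4)$axes)
})

test_that("AUC scores presence predictions as a rank statistic", {
  pred <- matrix(c(0.9, 0.8, 0.1, 0.05, 0.7, 0.02), 2, 3)
  occ <- matrix(c(1, 1, 0, 0, 1, 0), 2, 3)
  expect_equal(auc_presence(pred, occ)$auc, 1)
  # monotone transform invariance
  expect_equal(auc_presence(pred^3, occ)$auc, 1)
  expect_equal(auc_presence(log(pred + 1e-9), occ)$auc, 1)
  # labels independent of scores give about one half
  withr_seed(11, {
    pred2 <- matrix(runif(4000), 40, 100)
    occ2 <- matrix(rbinom(4000, 1, 0.4), 40, 100)
  })
  expect_equal(auc_presence(pred2, occ2)$auc, 0.5, tolerance = 0.04)
  expect_error(auc_presence(pred, matrix(1, 2, 3)),
               class = "lvtraits_single_class")
})

test_that("global pseudo-R2 composes per-plot likelihood contributions", {
  sc <- synthetic_scenario(S = 12, J = 6, seed = 21)
  dat <- simulate_dataset(sc)
  ll_plot <- vapply(seq_len(6), function(j) {
    multinomial_loglik(dat$sample$counts[j, ], dat$rel_abundance[j, ])
  }, numeric(1))
  ll_null <- null_loglik(dat$sample, per_plot = TRUE)
  r2_global <- nagelkerke_r2(sum(ll_plot), sum(ll_null),
                             sum(dat$sample$effort))
  # the global value is the Nagelkerke transform of summed plot terms
  expect_equal(
    r2_global,
    nagelkerke_r2(sum(ll_plot), sum(ll_null), 6 * 101)
  )
  expect_lte(r2_global, 1)
})

test_that("posterior demography summaries flag undefined correlations", {
  sc <- synthetic_scenario(S = 20, J = 6, seed = 2)
  dat <- simulate_dataset(sc)
  fit <- calibrate(dat$axes, dat$sites, dat$sample, n_iter = 600,
                   burn_in = 0.5, seed = 3, compute_metrics = FALSE)
  out <- posterior_demography_summary(fit$posterior, dat$axes,
                                      max_draws = 120)
  expect_true(all(c("theta_min~l", "theta_min~c", "l~c") %in% out$pair))
  ok <- is.finite(out$median)
  expect_true(all(abs(out$median[ok]) <= 1))
  expect_true(all(out$lo[ok] <= out$hi[ok]))
})

test_that("opposite-signed loadings give a strong negative correlation", {
  # theta_min and l built from the same axis with opposite-signed
  # coefficients: the posterior of their correlation must be pinned near -1
  ax <- generate_axes(40, 3, seed = 13)
  tp <- transfer_params(phi_theta_min = c(0, 1), phi_l = c(pi, 1),
                        phi_c = c(1.4, 2.2), a_theta_min = 1,
                        b_theta_min = 0, a_l = 0.6, b_l = -2.3, a_c = 0.3)
  dp <- build_demography(tp, ax)
  expect_lt(cor(dp$theta_min, dp$l), -0.9)
})
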