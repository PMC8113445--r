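# shared builders for small deterministic fixtures

toy_params <- function(S = 3, theta_min = rep(-1, S), g = rep(0.01, S),
                       cc = rep(0.005, S), l = rep(0.005, S)) {
  demographic_params(theta_min = theta_min, g = g, c = cc, l = l)
}

# draw a prior-plausible transfer function + axes + temperature, returning
# the built demography; used by equilibrium stress tests
random_instance <- function(seed, S = NULL) {
  withr_seed(seed_shift(seed), {
    S <- S %||% sample(4:30, 1)
    tp <- lvtraits::unpack_transfer(drop(lvtraits::prior_spec(3)$sample(1)), 3)
    ax <- lvtraits::generate_axes(S, 3, seed = seed)
    list(params = lvtraits::build_demography(tp, ax),
         theta = stats::runif(1, -2, 2), axes = ax, tp = tp)
  })
}

seed_shift <- function(seed) 77000L + seed

withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# enumeration oracle: all count vectors of S nonnegative integers summing
# to n, as rows of a matrix
enumerate_counts <- function(n, S) {
  if (S == 1) return(matrix(n, 1, 1))
  out <- NULL
  for (k in 0:n) {
    rest <- enumerate_counts(n - k, S - 1)
    out <- rbind(out, cbind(k, rest))
  }
  unname(out)
}

# zero-trait-signal ground truth (species-identical demography)
zero_signal_transfer <- function() {
  transfer_params(phi_theta_min = c(0.7, 1.2), phi_l = c(2.3, 4.0),
                  phi_c = c(1.4, 2.2), a_theta_min = 0, b_theta_min = -2,
                  a_l = 0, b_l = -2.3, a_c = 0)
}
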