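#' Orthogonal, scaled trait axes
#'
#' Container for the species x N matrix of trait axes that the transfer
#' function consumes. Axes produced by [pca_axes()] or [generate_axes()] are
#' mutually orthogonal with zero mean and unit variance across species, the
#' geometry under which the link scale inherits a standard normal
#' distribution.
#'
#' @param species_id Character vector of species identifiers.
#' @param axes Numeric species x N matrix (N >= 1; the transfer function
#'   itself needs N >= 2).
#' @param variance_explained Optional per-axis fraction of total trait
#'   variance.
#'
#' @return An object of class `trait_axes`.
#' @export
trait_axes <- function(species_id, axes, variance_explained = NULL) {
  axes <- as.matrix(axes)
  if (ncol(axes) < 1L) {
    stop_lv("invalid_axes", "at least one trait axis is required")
  }
  if (!all(is.finite(axes))) {
    stop_lv("invalid_axes", "trait axes must be finite")
  }
  if (length(species_id) != nrow(axes)) {
    stop_lv("dimension_mismatch", "species_id length does not match axes")
  }
  if (!is.null(variance_explained) &&
      length(variance_explained) != ncol(axes)) {
    stop_lv("dimension_mismatch",
            "variance_explained length does not match axis count")
  }
  if (is.null(colnames(axes))) {
    colnames(axes) <- sprintf("t%d", seq_len(ncol(axes)))
  }
  rownames(axes) <- as.character(species_id)
  structure(list(species_id = as.character(species_id), axes = axes,
                 n_axes = ncol(axes), n_species = nrow(axes),
                 variance_explained = variance_explained),
            class = "trait_axes")
}

#' @export
print.trait_axes <- function(x, ...) {
  cat(sprintf("<trait_axes> %d species x %d axes\n", x$n_species, x$n_axes))
  if (!is.null(x$variance_explained)) {
    cat("  variance explained:",
        paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Hyperspherical angles to unit coefficient vector
#'
#' Maps N-1 polar angles to a point on the unit hypersphere in N dimensions:
#' `(cos phi_1, sin phi_1 cos phi_2, ..., prod_k sin phi_k)`. The first N-2
#' angles live in `[0, pi]` and the last in `[0, 2*pi]`, which covers every
#' unit vector exactly once (up to the usual polar degeneracies). Used to
#' parameterize regression coefficients of fixed Euclidean norm 1, so that
#' the scale and offset of each demographic parameter are controlled
#' separately by `a` and `b`.
#'
#' @param phi Numeric vector of N-1 angles.
#'
#' @return Numeric unit vector of length N.
#' @seealso [unit_vector_to_angles()] for the inverse map.
#' @export
#' @examples
#' angles_to_unit_vector(c(pi / 2, 0))  # c(0, 1, 0)
angles_to_unit_vector <- function(phi) {
  phi <- as.numeric(phi)
  n_ang <- length(phi)
  if (n_ang < 1L) stop_lv("invalid_angles", "at least one angle is required")
  check_angle_ranges(phi)
  N <- n_ang + 1L
  s <- cumprod(sin(phi))
  coef <- numeric(N)
  coef[1L] <- cos(phi[1L])
  if (N > 2L) {
    coef[2:(N - 1L)] <- s[1:(N - 2L)] * cos(phi[2:(N - 1L)])
  }
  coef[N] <- s[n_ang]
  coef
}

check_angle_ranges <- function(phi, tol = 1e-12) {
  n_ang <- length(phi)
  if (!all(is.finite(phi))) {
    stop_lv("invalid_angles", "angles must be finite")
  }
  if (n_ang > 1L) {
    head <- phi[seq_len(n_ang - 1L)]
    if (any(head < -tol | head > pi + tol)) {
      stop_lv("invalid_angles",
              "angles 1..N-2 must lie in [0, pi]")
    }
  }
  last <- phi[n_ang]
  if (last < -tol || last > 2 * pi + tol) {
    stop_lv("invalid_angles", "last angle must lie in [0, 2*pi]")
  }
  invisible(TRUE)
}

#' Unit coefficient vector to hyperspherical angles
#'
#' Inverse of [angles_to_unit_vector()]: recovers in-range angles for any
#' coefficient vector of unit Euclidean norm, demonstrating the equivalence
#' of the hyperspherical parameterization with an ordinary linear-regression
#' coefficient vector of fixed norm.
#'
#' @param coef Numeric vector of unit Euclidean norm (length >= 2).
#'
#' @return Numeric vector of length `length(coef) - 1` of angles.
#' @export
unit_vector_to_angles <- function(coef) {
  coef <- as.numeric(coef)
  N <- length(coef)
  if (N < 2L) stop_lv("invalid_angles", "need at least two coefficients")
  nrm <- sqrt(sum(coef^2))
  if (abs(nrm - 1) > 1e-8) {
    stop_lv("invalid_angles", "coefficient vector must have unit norm")
  }
  coef <- coef / nrm
  phi <- numeric(N - 1L)
  if (N > 2L) {
    for (k in seq_len(N - 2L)) {
      tail_norm <- sqrt(sum(coef[(k + 1L):N]^2))
      phi[k] <- atan2(tail_norm, coef[k])
    }
  }
  phi[N - 1L] <- atan2(coef[N], coef[N - 1L]) %% (2 * pi)
  phi
}

#' Link scale of a demographic parameter
#'
#' Projects the trait axes onto the unit coefficient vector defined by the
#' angles: `E_i = sum_n coef_n t_{i,n}`. When the axes are orthogonal with
#' zero mean and unit variance across species, `E` is itself standard normal
#' across species for any angles, so the downstream mean and spread of each
#' demographic parameter are governed solely by its scale `a` and offset
#' `b`.
#'
#' @param axes A [trait_axes] object.
#' @param phi Angle vector of length `axes$n_axes - 1`.
#'
#' @return Numeric per-species vector `E`.
#' @export
link_scale <- function(axes, phi) {
  stopifnot(inherits(axes, "trait_axes"))
  if (length(phi) != axes$n_axes - 1L) {
    stop_lv("dimension_mismatch",
            sprintf("expected %d angles for %d axes, got %d",
                    axes$n_axes - 1L, axes$n_axes, length(phi)))
  }
  drop(axes$axes %*% angles_to_unit_vector(phi))
}

#' Log-linear map from link scale to a positive parameter
#'
#' `d_i = exp(a * E_i + b)`, used for rates that must stay positive
#' (competition `c`, biomass sensitivity `l`). The exponent is clipped at
#' `clip` (with a warning) to guard against overflow when a sampler explores
#' extreme regions; regularizing priors make that region negligible.
#'
#' @param E Link-scale vector.
#' @param a Nonnegative scale.
#' @param b Offset.
#' @param clip Bound on `|a * E + b|`.
#'
#' @return Strictly positive vector.
#' @export
to_positive_param <- function(E, a, b, clip = 50) {
  if (a < 0) stop_lv("invalid_params", "scale a must be nonnegative")
  x <- a * E + b
  if (any(abs(x) > clip)) {
    warning("exponent clipped in log-linear transfer map")
    x <- pmin(pmax(x, -clip), clip)
  }
  exp(x)
}

#' Linear map from link scale to a real-valued parameter
#'
#' `d_i = a * E_i + b`, used for parameters that can take either sign
#' (`theta_min`).
#'
#' @inheritParams to_positive_param
#' @return Numeric vector.
#' @export
to_real_param <- function(E, a, b) {
  if (a < 0) stop_lv("invalid_params", "scale a must be nonnegative")
  a * E + b
}

#' Transfer-function parameters
#'
#' The calibration target: per demographic parameter `m` in
#' `{theta_min, l, c}` a set of N-1 hyperspherical angles plus a scale `a_m`
#' and offset `b_m`, together with two constants fixed for identifiability
#' under a relative-abundance likelihood: the shared growth slope `g_value`
#' (default `10^-3.43`) and the offset of the competition rate `b_c_value`
#' (default `10^-3.8`). With N = 3 axes the free-parameter count is
#' 3 * (N - 1) + 5 = 11.
#'
#' @param phi_theta_min,phi_l,phi_c Angle vectors (length N-1 each).
#' @param a_theta_min,b_theta_min Scale (>= 0) and offset of the linear map
#'   for `theta_min`.
#' @param a_l,b_l Scale and offset of the log-linear map for `l`.
#' @param a_c Scale of the log-linear map for `c` (its offset is the fixed
#'   `b_c_value`).
#' @param g_value Fixed growth slope shared by all species.
#' @param b_c_value Fixed offset of the log-linear map for `c`.
#'
#' @return An object of class `transfer_params`.
#' @export
transfer_params <- function(phi_theta_min, phi_l, phi_c,
                            a_theta_min, b_theta_min,
                            a_l, b_l, a_c,
                            g_value = 10^-3.43, b_c_value = 10^-3.8) {
  n_ang <- length(phi_theta_min)
  if (length(phi_l) != n_ang || length(phi_c) != n_ang) {
    stop_lv("dimension_mismatch", "angle vectors must share one length")
  }
  for (phi in list(phi_theta_min, phi_l, phi_c)) check_angle_ranges(phi)
  for (a in c(a_theta_min, a_l, a_c)) {
    if (!is.finite(a) || a < 0) {
      stop_lv("invalid_params", "scales a_m must be finite and nonnegative")
    }
  }
  if (!is.finite(b_theta_min) || !is.finite(b_l)) {
    stop_lv("invalid_params", "offsets b_m must be finite")
  }
  if (!is.finite(g_value) || g_value <= 0) {
    stop_lv("invalid_params", "g_value must be positive")
  }
  structure(
    list(phi_theta_min = phi_theta_min, phi_l = phi_l, phi_c = phi_c,
         a_theta_min = a_theta_min, b_theta_min = b_theta_min,
         a_l = a_l, b_l = b_l, a_c = a_c,
         g_value = g_value, b_c_value = b_c_value,
         n_axes = n_ang + 1L),
    class = "transfer_params"
  )
}

#' @export
print.transfer_params <- function(x, ...) {
  cat(sprintf("<transfer_params> N = %d axes, %d free parameters\n",
              x$n_axes, n_free_parameters(x)))
  cat(sprintf("  theta_min: phi (%s), a = %.3g, b = %.3g\n",
              paste(signif(x$phi_theta_min, 3), collapse = ", "),
              x$a_theta_min, x$b_theta_min))
  cat(sprintf("  l        : phi (%s), a = %.3g, b = %.3g\n",
              paste(signif(x$phi_l, 3), collapse = ", "), x$a_l, x$b_l))
  cat(sprintf("  c        : phi (%s), a = %.3g, b fixed = %.3g\n",
              paste(signif(x$phi_c, 3), collapse = ", "), x$a_c,
              x$b_c_value))
  cat(sprintf("  fixed    : g = %.4g\n", x$g_value))
  invisible(x)
}

#' Number of free (calibrated) transfer parameters
#'
#' @param tp A [transfer_params] object.
#' @return Integer: `3 * (N - 1) + 5` (11 for N = 3).
#' @export
n_free_parameters <- function(tp) {
  stopifnot(inherits(tp, "transfer_params"))
  3L * (tp$n_axes - 1L) + 5L
}

#' Build per-species demography from traits via the transfer function
#'
#' Applies the transfer function to the trait axes: `theta_min` through the
#' linear map, `l` through the log-linear map, `c` through the log-linear
#' map with its offset fixed at `b_c_value`, and `g` constant at `g_value`
#' across species.
#'
#' @param tp A [transfer_params] object.
#' @param axes A [trait_axes] object with `n_axes == tp$n_axes`.
#' @param clip Exponent clipping bound for the log-linear maps.
#'
#' @return A [demographic_params] object.
#' @export
build_demography <- function(tp, axes, clip = 50) {
  stopifnot(inherits(tp, "transfer_params"), inherits(axes, "trait_axes"))
  if (axes$n_axes != tp$n_axes) {
    stop_lv("dimension_mismatch",
            sprintf("transfer expects %d axes, axes have %d",
                    tp$n_axes, axes$n_axes))
  }
  theta_min <- to_real_param(link_scale(axes, tp$phi_theta_min),
                             tp$a_theta_min, tp$b_theta_min)
  l <- to_positive_param(link_scale(axes, tp$phi_l), tp$a_l, tp$b_l, clip)
  cc <- to_positive_param(link_scale(axes, tp$phi_c), tp$a_c,
                          tp$b_c_value, clip)
  demographic_params(theta_min = theta_min,
                     g = rep(tp$g_value, axes$n_species),
                     c = cc, l = l, species_id = axes$species_id)
}

# --- flat parameter vector <-> transfer_params (sampler interface) --------

transfer_par_names <- function(N) {
  stopifnot(N >= 2)
  ang <- seq_len(N - 1L)
  c(sprintf("phi_theta_min_%d", ang), "a_theta_min", "b_theta_min",
    sprintf("phi_l_%d", ang), "a_l", "b_l",
    sprintf("phi_c_%d", ang), "a_c")
}

#' Flatten transfer parameters to the sampler's parameter vector
#'
#' @param tp A [transfer_params] object.
#' @return Named numeric vector of the free parameters (length
#'   `n_free_parameters(tp)`).
#' @export
pack_transfer <- function(tp) {
  stopifnot(inherits(tp, "transfer_params"))
  out <- c(tp$phi_theta_min, tp$a_theta_min, tp$b_theta_min,
           tp$phi_l, tp$a_l, tp$b_l, tp$phi_c, tp$a_c)
  names(out) <- transfer_par_names(tp$n_axes)
  out
}

#' Rebuild transfer parameters from the sampler's parameter vector
#'
#' @param par Numeric vector as produced by [pack_transfer()].
#' @param N Number of trait axes.
#' @param g_value,b_c_value Fixed constants.
#' @return A [transfer_params] object.
#' @export
unpack_transfer <- function(par, N, g_value = 10^-3.43,
                            b_c_value = 10^-3.8) {
  if (length(par) != 3L * (N - 1L) + 5L) {
    stop_lv("dimension_mismatch",
            sprintf("expected %d parameters for N = %d, got %d",
                    3L * (N - 1L) + 5L, N, length(par)))
  }
  m <- N - 1L
  transfer_params(
    phi_theta_min = par[seq_len(m)],
    a_theta_min = par[m + 1L], b_theta_min = par[m + 2L],
    phi_l = par[m + 2L + seq_len(m)],
    a_l = par[2L * m + 3L], b_l = par[2L * m + 4L],
    phi_c = par[2L * m + 4L + seq_len(m)],
    a_c = par[3L * m + 5L],
    g_value = g_value, b_c_value = b_c_value
  )
}
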