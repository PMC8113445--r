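#' Species x trait table
#'
#' @param species_id Character vector, one entry per species.
#' @param values Numeric species x P matrix of trait values.
#' @param log_transformed Logical per-trait flags recording which columns
#'   are on the log scale.
#'
#' @return An object of class `trait_table`.
#' @export
trait_table <- function(species_id, values, log_transformed = NULL) {
  values <- as.matrix(values)
  if (length(species_id) != nrow(values)) {
    stop_lv("dimension_mismatch", "one row per species is required")
  }
  if (anyDuplicated(species_id)) {
    stop_lv("invalid_traits", "species_id values must be unique")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("trait%d", seq_len(ncol(values)))
  }
  if (is.null(log_transformed)) {
    log_transformed <- rep(FALSE, ncol(values))
  }
  names(log_transformed) <- colnames(values)
  rownames(values) <- as.character(species_id)
  structure(list(species_id = as.character(species_id), values = values,
                 traits = colnames(values),
                 log_transformed = log_transformed),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("<trait_table> %d species x %d traits (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(x$traits, collapse = ", ")))
  invisible(x)
}

#' Average individual trait measurements by species
#'
#' Collapses a long table of individual-level measurements to one arithmetic
#' mean per species and trait. Every species must have at least one
#' measurement of every trait; gaps are reported explicitly because the
#' downstream PCA cannot handle missing values.
#'
#' @param measurements A data.frame with columns `species_id`, `trait`,
#'   `value`.
#'
#' @return A [trait_table] of species means.
#' @export
average_by_species <- function(measurements) {
  need <- c("species_id", "trait", "value")
  if (!all(need %in% names(measurements))) {
    stop_lv("invalid_traits",
            "measurements need columns species_id, trait, value")
  }
  if (!all(is.finite(measurements$value))) {
    stop_lv("invalid_traits", "measurement values must be finite")
  }
  sp <- sort(unique(as.character(measurements$species_id)))
  tr <- sort(unique(as.character(measurements$trait)))
  agg <- tapply(measurements$value,
                list(factor(measurements$species_id, levels = sp),
                     factor(measurements$trait, levels = tr)),
                mean)
  if (anyNA(agg)) {
    idx <- which(is.na(agg), arr.ind = TRUE)
    gaps <- paste(sp[idx[, 1L]], tr[idx[, 2L]], sep = ":")
    stop_lv("missing_measurements",
            paste0("missing species x trait combinations: ",
                   paste(gaps, collapse = ", ")),
            data = gaps)
  }
  trait_table(sp, agg[, tr, drop = FALSE])
}

#' Log-transform traits
#'
#' Applies the natural logarithm to every trait except those named in
#' `exempt`. Isotopic ratios (e.g. d13C, d15N) can be negative and are the
#' typical exemptions. Non-exempt traits must be strictly positive; the
#' offending species and trait are named otherwise.
#'
#' @param table A [trait_table].
#' @param exempt Character vector of trait names left untouched.
#'
#' @return A [trait_table] with updated values and `log_transformed` flags.
#' @export
log_transform_traits <- function(table, exempt = character()) {
  stopifnot(inherits(table, "trait_table"))
  unknown <- setdiff(exempt, table$traits)
  if (length(unknown)) {
    stop_lv("invalid_traits",
            paste0("exempt traits not present: ",
                   paste(unknown, collapse = ", ")))
  }
  vals <- table$values
  flags <- table$log_transformed
  for (tr in setdiff(table$traits, exempt)) {
    v <- vals[, tr]
    if (any(v <= 0)) {
      bad <- table$species_id[v <= 0][1L]
      stop_lv("nonpositive_trait",
              sprintf("trait '%s' is nonpositive for species '%s'; %s",
                      tr, bad, "exempt it or fix the data"))
    }
    vals[, tr] <- log(v)
    flags[tr] <- TRUE
  }
  trait_table(table$species_id, vals, flags)
}

#' Orthogonal scaled trait axes by correlation-matrix PCA
#'
#' Centers and unit-scales every trait (correlation PCA -- the traits mix
#' units), projects the species onto the first `k` principal axes, and
#' rescales each retained axis to unit variance across species. The
#' unit-variance rescaling, together with orthogonality, is what makes the
#' transfer function's link scale standard normal for any angles. Axis signs
#' are fixed deterministically (the largest-magnitude loading of each axis
#' is made positive) so repeated runs are identical.
#'
#' @param table A [trait_table] without missing values.
#' @param k Number of axes to retain (default 3).
#'
#' @return A [trait_axes] object with per-axis `variance_explained`
#'   (fractions of total trait variance, nonincreasing).
#' @export
pca_axes <- function(table, k = 3L) {
  stopifnot(inherits(table, "trait_table"))
  S <- nrow(table$values)
  P <- ncol(table$values)
  k <- as.integer(k)
  if (k < 1L || k > min(S - 1L, P)) {
    stop_lv("invalid_axes",
            sprintf("k must be in [1, min(S-1, P)] = [1, %d]",
                    min(S - 1L, P)))
  }
  sds <- apply(table$values, 2L, stats::sd)
  if (any(sds == 0)) {
    stop_lv("invalid_traits",
            paste0("constant traits cannot be scaled: ",
                   paste(table$traits[sds == 0], collapse = ", ")))
  }
  pc <- stats::prcomp(table$values, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  if (sum(ev > 1e-12 * ev[1L]) < k) {
    stop_lv("rank_deficient",
            sprintf("trait matrix has rank < %d after scaling", k))
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    flip <- sign(load[which.max(abs(load[, j])), j])
    if (flip < 0) scores[, j] <- -scores[, j]
  }
  scores <- scale(scores, center = TRUE, scale = TRUE)
  attr(scores, "scaled:center") <- NULL
  attr(scores, "scaled:scale") <- NULL
  colnames(scores) <- sprintf("t%d", seq_len(k))
  trait_axes(table$species_id, scores,
             variance_explained = ev[seq_len(k)] / sum(ev))
}
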