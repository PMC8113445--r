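#' Read a species x trait CSV
#'
#' Expected columns: `species_id` plus one numeric column per trait.
#'
#' @param path CSV file path.
#' @return A [trait_table].
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM", check.names = FALSE)
  if (!"species_id" %in% names(df)) {
    stop_lv("invalid_file", "trait CSV needs a species_id column")
  }
  vals <- as.matrix(df[setdiff(names(df), "species_id")])
  storage.mode(vals) <- "double"
  trait_table(df$species_id, vals)
}

#' Write a species x trait table to CSV
#' @param table A [trait_table].
#' @param path Output path.
#' @export
write_trait_table <- function(table, path) {
  stopifnot(inherits(table, "trait_table"))
  df <- data.frame(species_id = table$species_id, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read trait axes from CSV (species_id + one column per axis)
#' @param path CSV file path.
#' @return A [trait_axes].
#' @export
read_trait_axes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM", check.names = FALSE)
  if (!"species_id" %in% names(df)) {
    stop_lv("invalid_file", "axes CSV needs a species_id column")
  }
  vals <- as.matrix(df[setdiff(names(df), "species_id")])
  storage.mode(vals) <- "double"
  trait_axes(df$species_id, vals)
}

#' Write trait axes to CSV
#' @param axes A [trait_axes].
#' @param path Output path.
#' @export
write_trait_axes <- function(axes, path) {
  stopifnot(inherits(axes, "trait_axes"))
  df <- data.frame(species_id = axes$species_id, axes$axes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read the plot table (plot_id, temperature) and standardize
#' @param path CSV file path.
#' @param standardize Standardize temperatures across plots (default TRUE).
#' @return A [site_table].
#' @export
read_site_table <- function(path, standardize = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM")
  if (!all(c("plot_id", "temperature") %in% names(df))) {
    stop_lv("invalid_file", "site CSV needs plot_id and temperature columns")
  }
  site_table(df$plot_id, df$temperature, standardize = standardize)
}

#' Write the site table to CSV
#' @param sites A [site_table].
#' @param path Output path.
#' @export
write_site_table <- function(sites, path) {
  utils::write.csv(as.data.frame(sites), path, row.names = FALSE)
  invisible(path)
}

#' Read a plot x species count (or occurrence) matrix CSV
#'
#' Expected columns: `plot_id` plus one column per species.
#'
#' @param path CSV file path.
#' @param effort Optional expected per-plot total for validation.
#' @return A [community_sample].
#' @export
read_count_table <- function(path, effort = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM", check.names = FALSE)
  if (!"plot_id" %in% names(df)) {
    stop_lv("invalid_file", "count CSV needs a plot_id column")
  }
  m <- as.matrix(df[setdiff(names(df), "plot_id")])
  storage.mode(m) <- "double"
  rownames(m) <- df$plot_id
  community_sample(m, effort)
}

#' Write a community sample to CSV
#' @param sample A [community_sample].
#' @param path Output path.
#' @export
write_count_table <- function(sample, path) {
  stopifnot(inherits(sample, "community_sample"))
  df <- data.frame(plot_id = sample$plot_id, sample$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a plot x species 0/1 occurrence matrix CSV
#' @param path CSV file path.
#' @return Numeric matrix with plot ids as row names.
#' @export
read_occurrence_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM", check.names = FALSE)
  if (!"plot_id" %in% names(df)) {
    stop_lv("invalid_file", "occurrence CSV needs a plot_id column")
  }
  m <- as.matrix(df[setdiff(names(df), "plot_id")])
  storage.mode(m) <- "double"
  if (!all(m %in% c(0, 1))) {
    stop_lv("invalid_file", "occurrence values must be 0/1")
  }
  rownames(m) <- df$plot_id
  m
}

#' Write demographic parameters to CSV
#' @param params A [demographic_params].
#' @param path Output path.
#' @export
write_demography_csv <- function(params, path) {
  utils::write.csv(as.data.frame(params), path, row.names = FALSE)
  invisible(path)
}

#' Read demographic parameters from CSV
#' @param path CSV with columns species_id, theta_min, g, c, l.
#' @return A [demographic_params].
#' @export
read_demography_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM")
  need <- c("species_id", "theta_min", "g", "c", "l")
  if (!all(need %in% names(df))) {
    stop_lv("invalid_file",
            "demography CSV needs species_id, theta_min, g, c, l")
  }
  demographic_params(df$theta_min, df$g, df$c, df$l, df$species_id)
}

#' Align traits/axes, sites, counts and occurrences
#'
#' Orders the count (and occurrence) columns to the species of the trait
#' axes and the rows to the site table, failing with an explicit report of
#' offenders: the method requires traits for every modeled species.
#'
#' @param axes A [trait_axes].
#' @param sites A [site_table].
#' @param sample A [community_sample].
#' @param occurrence Optional occurrence matrix.
#'
#' @return List with the aligned `axes`, `sites`, `sample`, `occurrence`.
#' @export
align_tables <- function(axes, sites, sample, occurrence = NULL) {
  missing_traits <- setdiff(sample$species_id, axes$species_id)
  if (length(missing_traits)) {
    stop_lv("unmatched_species",
            paste0("species in counts without traits: ",
                   paste(missing_traits, collapse = ", ")),
            data = missing_traits)
  }
  dropped <- setdiff(axes$species_id, sample$species_id)
  if (length(dropped)) {
    message("species with traits never sampled (kept in the pool): ",
            paste(dropped, collapse = ", "))
    extra <- matrix(0, sample$n_plots, length(dropped),
                    dimnames = list(sample$plot_id, dropped))
    sample <- community_sample(cbind(sample$counts, extra))
  }
  missing_plots <- setdiff(sample$plot_id, sites$plot_id)
  if (length(missing_plots)) {
    stop_lv("unmatched_plots",
            paste0("plots in counts without site data: ",
                   paste(missing_plots, collapse = ", ")),
            data = missing_plots)
  }
  sites <- sites[match(sample$plot_id, sites$plot_id), ]
  class(sites) <- c("site_table", "data.frame")
  counts <- sample$counts[, axes$species_id, drop = FALSE]
  sample <- community_sample(counts)
  if (!is.null(occurrence)) {
    sp <- intersect(axes$species_id, colnames(occurrence))
    occurrence <- occurrence[sample$plot_id, sp, drop = FALSE]
  }
  list(axes = axes, sites = sites, sample = sample,
       occurrence = occurrence)
}

#' Write retained posterior draws to CSV
#'
#' One row per retained draw: chain, iteration, the free transfer
#' parameters, log-posterior and deviance.
#'
#' @param ps A `posterior_sample`.
#' @param path Output path.
#' @export
write_posterior_csv <- function(ps, path) {
  stopifnot(inherits(ps, "posterior_sample"))
  keep <- (ps$burn_in + 1L):ps$n_iter
  rows <- lapply(seq_len(ps$n_chains), function(ch) {
    m <- ps$draws[keep, ch, , drop = FALSE]
    dim(m) <- dim(m)[c(1L, 3L)]
    colnames(m) <- ps$par_names
    data.frame(chain = ch, iteration = keep, m,
               log_posterior = ps$log_posterior[keep, ch],
               deviance = -2 * ps$log_likelihood[keep, ch],
               check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Full default set of tunables: paths, preprocessing, fixed constants,
#' priors, solver and sampler settings. Values mirror the motivating study
#' design where one exists (fixed `g = 10^-3.43` and `b_c = 10^-3.8`,
#' burn-in fraction 0.7 as in 35000 of 50000 steps, 8 independent chains);
#' `n_iter` defaults to a desk-scale 10000.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    traits_csv = NULL, axes_csv = NULL, sites_csv = NULL,
    counts_csv = NULL, occurrence_csv = NULL, output_dir = "lvtraits_out",
    log_exempt_traits = character(), n_axes = 3L,
    g_value = 10^-3.43, b_c_value = 10^-3.8,
    prior = list(a_scale = 1, b_theta_min_mean = 0, b_theta_min_sd = 1,
                 b_l_mean = -2, b_l_sd = 2),
    equilibrium = "analytic",
    solver = list(rtol = 1e-8, atol = 1e-12, horizon = 1e7,
                  converged_tol = 1e-6, extinction_tol = 1e-10),
    mcmc = list(n_iter = 10000L, n_internal = 3L, n_instances = 8L,
                burn_in = 0.7, snooker_prob = 0.1),
    seed = 1L, verbose = FALSE
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      utils::modifyList(cfg[[nm]], over[[nm]])
    } else {
      over[[nm]]
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Read a YAML run configuration, merged over the defaults
#'
#' Scalar values in scientific notation without a signed exponent (e.g.
#' `1.0e6`), which YAML 1.1 parses as strings, are coerced back to
#' numbers.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  user <- coerce_numeric_strings(yaml::read_yaml(path))
  do.call(default_config, user)
}

coerce_numeric_strings <- function(x) {
  if (is.list(x)) return(lapply(x, coerce_numeric_strings))
  if (is.character(x) && length(x) == 1L &&
      grepl("^[+-]?[0-9.]+([eE][+-]?[0-9]+)?$", x)) {
    return(as.numeric(x))
  }
  x
}

#' Write a JSON run manifest
#'
#' Serializes the configuration, seeds and package version next to a run's
#' outputs so the run is reconstructible.
#'
#' @param cfg A `run_config`.
#' @param path Output JSON path.
#' @param extra Named list of additional fields (e.g. output file names).
#' @export
write_manifest <- function(cfg, path, extra = list()) {
  manifest <- c(
    list(package = "lvtraits",
         version = as.character(utils::packageVersion("lvtraits")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = unclass(cfg)),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
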