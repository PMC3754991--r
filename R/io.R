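#' Cross-sectional skeletal population data
#'
#' Container for one population's isotopic data: subadult individuals
#' (estimated age at death and bone collagen delta15N) plus the adult
#' reference statistics. Subadult ages must lie below 10 years (older
#' individuals no longer carry a weaning signal at bone turnover rates);
#' fewer than seven subadults triggers a warning because such assemblages
#' rarely constrain the weaning curve.
#'
#' @param subadults Data frame with columns `id`, `age` (years, in
#'   `[0, 10)`) and `d15n` (permil).
#' @param adult_female_mean,adult_female_sd Adult-female delta15N mean/SD,
#'   permil (`NA` if unavailable; the all-adult values substitute).
#' @param adult_all_mean,adult_all_sd All-adult delta15N mean/SD, permil.
#' @param quiet Suppress the small-sample warning.
#' @return An object of class `population_data`.
#' @export
#' @examples
#' population_data(data.frame(id = letters[1:7], age = 1:7, d15n = 12 - (1:7) / 3),
#'                 adult_female_mean = 10, adult_all_mean = 10.2)
population_data <- function(subadults, adult_female_mean = NA,
                            adult_female_sd = NA, adult_all_mean = NA,
                            adult_all_sd = NA, quiet = FALSE) {
  req <- c("id", "age", "d15n")
  if (!all(req %in% names(subadults)))
    stop("subadults must have columns: ", paste(req, collapse = ", "))
  if (!is.numeric(subadults$age) || !is.numeric(subadults$d15n))
    stop("age and d15n must be numeric")
  if (any(!is.finite(subadults$age)) || any(!is.finite(subadults$d15n)))
    stop("age and d15n must be finite")
  if (any(subadults$age < 0 | subadults$age >= 10))
    stop("subadult ages must lie in [0, 10); filter with read_population_csv()")
  if (nrow(subadults) == 0) stop("no subadult records")
  if (is.na(adult_female_mean) && is.na(adult_all_mean))
    stop("at least one adult reference mean is required")
  if (!quiet && nrow(subadults) < 7)
    warning("fewer subadults (", nrow(subadults),
            ") than the inclusion criterion of more than six")
  # Methods fallback: missing group copied from the other
  if (is.na(adult_female_mean)) {
    adult_female_mean <- adult_all_mean
    adult_female_sd <- adult_all_sd
    if (!quiet) message("adult-female mean missing; using all-adult mean")
  }
  if (is.na(adult_all_mean)) {
    adult_all_mean <- adult_female_mean
    adult_all_sd <- adult_female_sd
    if (!quiet) message("all-adult mean missing; using adult-female mean")
  }
  structure(list(subadults = subadults[req],
                 adult_female_mean = adult_female_mean,
                 adult_female_sd = adult_female_sd,
                 adult_all_mean = adult_all_mean,
                 adult_all_sd = adult_all_sd),
            class = "population_data")
}

#' @export
print.population_data <- function(x, ...) {
  cat(sprintf("Skeletal population: %d subadults (ages %.2f-%.2f y)\n",
              nrow(x$subadults), min(x$subadults$age), max(x$subadults$age)))
  cat(sprintf("  adult female mean %.2f permil, all adults %.2f permil\n",
              x$adult_female_mean, x$adult_all_mean))
  invisible(x)
}

#' Read a population from CSV
#'
#' The subadult file has one individual per row with columns `id`, `age`
#' (years) and `d15n` (permil). Adult reference statistics come either from
#' a sidecar CSV with columns `group` (`adult_female` / `adult_all`),
#' `mean` and `sd`, or directly via the arguments. Rows with age >= 10 are
#' dropped with a message (the model targets diet before adolescence); a
#' missing adult-female mean falls back to the all-adult mean.
#'
#' @param path Path to the subadult CSV.
#' @param adults_path Optional path to the adult-summary sidecar CSV.
#' @param adult_female_mean,adult_female_sd,adult_all_mean,adult_all_sd
#'   Adult statistics, overriding the sidecar when given.
#' @return A [population_data()] object.
#' @export
read_population_csv <- function(path, adults_path = NULL,
                                adult_female_mean = NA, adult_female_sd = NA,
                                adult_all_mean = NA, adult_all_sd = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty population file: ", path)
  req <- c("id", "age", "d15n")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ", paste(missing_cols, collapse = ", "))
  df$age <- suppressWarnings(as.numeric(df$age))
  df$d15n <- suppressWarnings(as.numeric(df$d15n))
  if (any(is.na(df$age)) || any(is.na(df$d15n)))
    stop("non-numeric age or d15n values in ", path)
  drop <- df$age >= 10 | df$age < 0
  if (any(drop)) {
    message("dropping ", sum(drop),
            " individual(s) with age outside [0, 10) years")
    df <- df[!drop, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no usable subadults below 10 years in ", path)

  if (!is.null(adults_path)) {
    ad <- utils::read.csv(adults_path, stringsAsFactors = FALSE)
    if (!all(c("group", "mean", "sd") %in% names(ad)))
      stop("adult sidecar needs columns group, mean, sd")
    pull <- function(g, col) {
      v <- ad[[col]][ad$group == g]
      if (length(v)) as.numeric(v[1]) else NA_real_
    }
    if (is.na(adult_female_mean)) {
      adult_female_mean <- pull("adult_female", "mean")
      adult_female_sd <- pull("adult_female", "sd")
    }
    if (is.na(adult_all_mean)) {
      adult_all_mean <- pull("adult_all", "mean")
      adult_all_sd <- pull("adult_all", "sd")
    }
  }
  population_data(df, adult_female_mean, adult_female_sd,
                  adult_all_mean, adult_all_sd)
}

#' Write a population to CSV
#'
#' Inverse of [read_population_csv()]: the subadult table and the adult
#' sidecar.
#'
#' @param pop A `population_data` object.
#' @param path Subadult CSV path.
#' @param adults_path Optional sidecar path for the adult summaries.
#' @return Invisibly, `path`.
#' @export
write_population_csv <- function(pop, path, adults_path = NULL) {
  utils::write.csv(pop$subadults, path, row.names = FALSE, quote = FALSE)
  if (!is.null(adults_path)) {
    ad <- data.frame(group = c("adult_female", "adult_all"),
                     mean = c(pop$adult_female_mean, pop$adult_all_mean),
                     sd = c(pop$adult_female_sd, pop$adult_all_sd))
    utils::write.csv(ad, adults_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write fit results to disk
#'
#' Emits the weighted particles as CSV, the posterior summary as JSON, and a
#' run manifest (seed, sampler settings, tolerance and acceptance history,
#' package version, config hash) that allows the run to be replayed
#' byte-identically.
#'
#' @param summary A `posterior_summary`.
#' @param ps The `particle_system` behind it.
#' @param dir Output directory (created if missing when `create = TRUE`).
#' @param create Create `dir` if it does not exist.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(summary, ps, dir, create = TRUE) {
  if (!dir.exists(dir)) {
    if (!create) stop("output directory does not exist: ", dir)
    dir.create(dir, recursive = TRUE)
  }
  particles <- data.frame(ps$particles, weight = ps$weights,
                          distance = ps$distances)
  utils::write.csv(particles, file.path(dir, "particles.csv"),
                   row.names = FALSE)

  sj <- list(mde = summary$mde,
             delta_wnfood = summary$delta_wnfood,
             probabilities = list(
               joint_ages = summary$mde_joint_prob_ages,
               enrichment = summary$mde_marginal_prob_e,
               wnfood = summary$mde_marginal_prob_wnfood),
             ci = list(level = summary$level,
                       t1 = unname(summary$credible_intervals[, "t1"]),
                       t2 = unname(summary$credible_intervals[, "t2"]),
                       enrichment = unname(summary$credible_intervals[, "enrichment"]),
                       wnfood = unname(summary$credible_intervals[, "wnfood"])),
             flags = summary$flags)
  jsonlite::write_json(sj, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg <- ps$config
  cfg_file <- tempfile()
  jsonlite::write_json(unclass(cfg), cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "weanabc",
    version = as.character(utils::packageVersion("weanabc")),
    seed = cfg$seed,
    n_particles = cfg$n_particles,
    n_stages = cfg$n_stages,
    tolerances = ps$tolerances,
    acceptance = ps$acceptance,
    ess = ps$ess_history,
    config_hash = unname(tools::md5sum(cfg_file)))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
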