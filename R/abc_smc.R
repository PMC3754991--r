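#' Independent-normal prior specification
#'
#' A prior made of independent normal distributions, one per parameter,
#' optionally restricted by a support constraint which is enforced by
#' rejection (i.e. the prior is truncated to the constraint region).
#'
#' @param mean,sd Numeric vectors of per-parameter prior means and standard
#'   deviations (`sd >= 0`; zero gives a degenerate point prior).
#' @param names Parameter names; defaults to the names of `mean`.
#' @param constraint Function taking an n-by-d parameter matrix and returning
#'   a logical vector marking rows inside the support, or `NULL`.
#' @return An object of class `prior_spec`.
#' @export
#' @examples
#' prior_spec(mean = c(a = 0), sd = c(a = 1))
prior_spec <- function(mean, sd, names = NULL, constraint = NULL) {
  if (length(mean) != length(sd)) stop("mean and sd lengths differ")
  if (any(sd < 0)) stop("prior SDs must be non-negative")
  nm <- names %||% base::names(mean)
  if (is.null(nm)) nm <- paste0("theta", seq_along(mean))
  structure(list(mean = unname(mean), sd = unname(sd), names = nm,
                 constraint = constraint),
            class = "prior_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default weaning-parameter prior
#'
#' Normal priors for (t1, t2, enrichment, wnfood) with the defaults used for
#' archaeological applications: means {0.5, 3.0, 1.9, adult all mean} years /
#' permil and SDs {3.0, 3.0, 0.9, 3.0}. The enrichment prior reflects the
#' spread of maternal-to-infant enrichment reported for modern and
#' archaeological mother-infant pairs; the weaning-food prior is centred on
#' the all-adult mean because the weaning-food offset is reported relative to
#' it. The support is truncated to `t1 >= 0` and `t2 >= t1`.
#'
#' @param wnfood_mean Prior mean for the weaning-food collagen value,
#'   typically the population's all-adult mean delta15N.
#' @param t1_mean,t1_sd,t2_mean,t2_sd,e_mean,e_sd,wnfood_sd Remaining
#'   per-parameter prior moments.
#' @return A [prior_spec()] for the four weaning parameters.
#' @export
#' @examples
#' weaning_prior(wnfood_mean = 10)
weaning_prior <- function(wnfood_mean,
                          t1_mean = 0.5, t1_sd = 3.0,
                          t2_mean = 3.0, t2_sd = 3.0,
                          e_mean = 1.9, e_sd = 0.9,
                          wnfood_sd = 3.0) {
  prior_spec(mean = c(t1_mean, t2_mean, e_mean, wnfood_mean),
             sd = c(t1_sd, t2_sd, e_sd, wnfood_sd),
             names = c("t1", "t2", "enrichment", "wnfood"),
             constraint = function(theta) {
               theta[, 1] >= 0 & theta[, 2] >= theta[, 1]
             })
}

#' Draw particles from a (truncated) prior
#'
#' Independent normal draws per parameter; draws violating the support
#' constraint are redrawn, so the sample follows the truncated prior.
#'
#' @param n Number of particles.
#' @param prior A [prior_spec()].
#' @param seed Optional integer seed (set once before drawing).
#' @return An n-by-d matrix with parameter names as column names.
#' @export
#' @examples
#' sample_prior(5, weaning_prior(wnfood_mean = 10), seed = 1)
sample_prior <- function(n, prior, seed = NULL) {
  if (n <= 0) stop("n must be positive")
  if (!is.null(seed)) set.seed(seed)
  d <- length(prior$mean)
  draw <- function(m) {
    matrix(stats::rnorm(m * d, rep(prior$mean, each = m),
                        rep(prior$sd, each = m)), m, d)
  }
  out <- matrix(NA_real_, n, d)
  need <- n
  while (need > 0) {
    cand <- draw(max(need, 64L))
    ok <- if (is.null(prior$constraint)) rep(TRUE, nrow(cand))
          else prior$constraint(cand)
    take <- min(sum(ok), need)
    if (take > 0) {
      out[(n - need + 1L):(n - need + take), ] <-
        cand[which(ok)[seq_len(take)], , drop = FALSE]
      need <- need - take
    }
  }
  colnames(out) <- prior$names
  out
}

# unnormalized truncated-prior density for an n x d particle matrix
.prior_density <- function(theta, prior) {
  d <- ncol(theta)
  dens <- rep(1, nrow(theta))
  for (k in seq_len(d)) {
    if (prior$sd[k] > 0) {
      dens <- dens * stats::dnorm(theta[, k], prior$mean[k], prior$sd[k])
    }
  }
  if (!is.null(prior$constraint)) dens <- dens * prior$constraint(theta)
  dens
}

#' SMC sampler configuration
#'
#' @param n_particles Number of weighted particles (default 10000).
#' @param n_stages Number of tolerance stages (default 7). Stage 1 samples
#'   the prior; each later stage halves the distance distribution via the
#'   adaptive quantile rule unless a fixed schedule is given.
#' @param tolerance_schedule Optional vector of fixed tolerances, one per
#'   stage (the first may be `Inf`). Overrides `n_stages` when supplied.
#' @param quantile Quantile of the previous stage's distances used as the
#'   next tolerance under adaptive scheduling (default 0.5).
#' @param kernel_scale Multiplier on the adaptive perturbation-kernel SD
#'   (component-wise `sqrt(2 * weighted variance)`).
#' @param ess_threshold Fraction of `n_particles` below which the effective
#'   sample size triggers a full multinomial resample.
#' @param seed Integer RNG seed threaded through every stochastic step.
#' @param max_attempt_factor Abort a stage once proposals exceed
#'   `max_attempt_factor * n_particles` with acceptance below 0.1%.
#' @return A list of class `smc_config`.
#' @export
smc_config <- function(n_particles = 10000, n_stages = 7,
                       tolerance_schedule = NULL, quantile = 0.5,
                       kernel_scale = 1, ess_threshold = 0.5,
                       seed = NULL, max_attempt_factor = 200) {
  if (n_particles <= 0 || n_stages <= 0) stop("counts must be positive")
  if (!is.null(tolerance_schedule)) {
    if (any(diff(tolerance_schedule) >= 0))
      stop("tolerance schedule must be strictly decreasing")
    n_stages <- length(tolerance_schedule)
  }
  structure(list(n_particles = as.integer(n_particles),
                 n_stages = as.integer(n_stages),
                 tolerance_schedule = tolerance_schedule,
                 quantile = quantile, kernel_scale = kernel_scale,
                 ess_threshold = ess_threshold, seed = seed,
                 max_attempt_factor = max_attempt_factor),
            class = "smc_config")
}

#' Effective sample size of a weighted particle set
#'
#' `1 / sum(w^2)` for normalized weights; ranges from 1 (one particle
#' carries all mass) to the number of particles (uniform weights).
#'
#' @param weights Normalized, non-negative weights.
#' @return Effective sample size in `[1, length(weights)]`.
#' @export
#' @examples
#' ess(rep(0.25, 4))
ess <- function(weights) {
  s <- sum(weights)
  if (s <= 0) stop("weights must sum to a positive value")
  w <- weights / s
  1 / sum(w^2)
}

#' ABC sequential Monte Carlo with partial rejection control
#'
#' Likelihood-free sequential sampler. Stage 1 draws particles from the
#' (truncated) prior. Each later stage lowers the tolerance (adaptive
#' quantile of the previous stage's distances, or a fixed schedule),
#' resamples ancestors by weight, perturbs them with a component-wise normal
#' kernel (SD = `kernel_scale * sqrt(2 * weighted variance)` of the previous
#' population), and keeps only proposals whose distance falls within the
#' tolerance (partial rejection control). Accepted particles are reweighted
#' with the kernel correction
#' \deqn{w_i \propto \pi(\theta_i) / \sum_j W_j K_\sigma(\theta_i - \theta_j),}
#' and the population is fully resampled whenever the effective sample size
#' drops below `ess_threshold * n`.
#'
#' @param prior A [prior_spec()].
#' @param distance_fun Function taking an n-by-d parameter matrix and
#'   returning a non-negative distance per row. May be stochastic; it is the
#'   only place the data enter.
#' @param config An [smc_config()].
#' @return An object of class `particle_system`: list with `particles`
#'   (n-by-d matrix), `weights` (normalized), `distances`, `tolerances`
#'   (one per stage, first `Inf`), `acceptance` (per-stage acceptance
#'   rates), `ess_history`, and the `prior` and `config` used.
#' @export
abc_smc <- function(prior, distance_fun, config = smc_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_particles
  d <- length(prior$mean)

  theta <- sample_prior(n, prior)
  dist <- distance_fun(theta)
  if (any(!is.finite(dist)) || any(dist < 0))
    stop("distance_fun must return finite non-negative values")
  w <- rep(1 / n, n)
  tolerances <- Inf
  acceptance <- 1
  ess_hist <- n

  if (config$n_stages > 1L) for (stage in 2:config$n_stages) {
    eps <- if (!is.null(config$tolerance_schedule)) {
      config$tolerance_schedule[stage]
    } else {
      e <- weighted_quantile(dist, w, config$quantile)
      prev <- tolerances[stage - 1L]
      if (is.finite(prev) && e >= prev) e <- prev * 0.9  # guard stagnation
      e
    }
    sig <- config$kernel_scale * sqrt(2 * .weighted_var_mat(theta, w))
    sig <- pmax(sig, 1e-8)

    new_theta <- matrix(NA_real_, n, d)
    new_dist <- numeric(n)
    filled <- 0L
    attempts <- 0L
    accepted <- 0L
    while (filled < n) {
      b <- max(2L * (n - filled), 256L)
      anc <- sample.int(n, b, replace = TRUE, prob = w)
      prop <- theta[anc, , drop = FALSE] +
        matrix(stats::rnorm(b * d, 0, rep(sig, each = b)), b, d)
      ok <- if (is.null(prior$constraint)) rep(TRUE, b)
            else prior$constraint(prop)
      prop <- prop[ok, , drop = FALSE]
      attempts <- attempts + b
      if (nrow(prop) > 0) {
        pd <- distance_fun(prop)
        keep <- which(pd <= eps)
        accepted <- accepted + length(keep)
        take <- seq_len(min(length(keep), n - filled))
        if (length(take) > 0) {
          rows <- keep[take]
          new_theta[(filled + 1L):(filled + length(take)), ] <-
            prop[rows, , drop = FALSE]
          new_dist[(filled + 1L):(filled + length(take))] <- pd[rows]
          filled <- filled + length(take)
        }
      }
      if (attempts > config$max_attempt_factor * n &&
          accepted / attempts < 0.001) {
        stop(sprintf(
          "ABC-SMC stage %d stalled: acceptance %.4f%% at tolerance %.4g",
          stage, 100 * accepted / attempts, eps))
      }
    }

    # Sisson-style corrected weights: prior density over kernel mixture
    pdens <- .prior_density(new_theta, prior)
    qdens <- .kernel_mixture_density(new_theta, theta, w, sig)
    w_new <- pdens / qdens
    if (all(w_new == 0)) stop("all particle weights vanished")
    w_new <- w_new / sum(w_new)

    theta <- new_theta
    dist <- new_dist
    w <- w_new
    e_now <- ess(w)
    if (e_now < config$ess_threshold * n) {
      idx <- sample.int(n, n, replace = TRUE, prob = w)
      theta <- theta[idx, , drop = FALSE]
      dist <- dist[idx]
      w <- rep(1 / n, n)
      e_now <- n
    }
    tolerances <- c(tolerances, eps)
    acceptance <- c(acceptance, accepted / attempts)
    ess_hist <- c(ess_hist, e_now)
  }

  colnames(theta) <- prior$names
  structure(list(particles = theta, weights = w, distances = dist,
                 tolerances = tolerances, acceptance = acceptance,
                 ess_history = ess_hist, prior = prior, config = config),
            class = "particle_system")
}

# column-wise weighted variance of a particle matrix
.weighted_var_mat <- function(theta, w) {
  w <- w / sum(w)
  mu <- colSums(theta * w)
  colSums((theta - rep(mu, each = nrow(theta)))^2 * w)
}

# mixture density sum_j W_j prod_d N(x_d - theta_jd; sig_d), chunked to
# bound memory at ~ chunk x n doubles
.kernel_mixture_density <- function(x, centers, w, sig, chunk = 512L) {
  n <- nrow(x)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    rows <- s:min(s + chunk - 1L, n)
    dens <- matrix(1, length(rows), nrow(centers))
    for (k in seq_len(ncol(x))) {
      dens <- dens * stats::dnorm(outer(x[rows, k], centers[, k], "-"),
                                  sd = sig[k])
    }
    out[rows] <- as.vector(dens %*% w)
  }
  out
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("ABC-SMC particle system: %d particles, %d stages\n",
              nrow(x$particles), length(x$tolerances)))
  cat("  final tolerance:", signif(utils::tail(x$tolerances, 1), 4),
      " ESS:", round(utils::tail(x$ess_history, 1)), "\n")
  mu <- colSums(x$particles * x$weights)
  cat("  weighted means:",
      paste(colnames(x$particles), signif(mu, 4), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

#' Fit the weaning model to a population by ABC-SMC
#'
#' Runs the full inference: forward-simulates bone collagen delta15N at the
#' observed subadult ages under candidate weaning parameters and drives the
#' ABC-SMC sampler with the mean squared distance to the observed values.
#' The maternal value is the adult-female mean (all-adult mean if absent),
#' and the default prior centres the weaning-food parameter on the all-adult
#' mean.
#'
#' @param data A `population_data` object (see [population_data()] or
#'   [read_population_csv()]).
#' @param prior A [prior_spec()]; defaults to [weaning_prior()] centred on
#'   the population's adult means.
#' @param config An [smc_config()].
#' @param qp Quartic turnover model (default: built-in).
#' @param dt Sub-annual quadrature step for the forward model.
#' @param shape Weaning-curve shape, see [synthesized_d15n()].
#' @return A `particle_system` with the population data, maternal value and
#'   turnover model attached (`$data`, `$d15n_mother`, `$qp`).
#' @export
#' @examples
#' \donttest{
#' qp <- default_qp()
#' pop <- generate_population(synth_spec(n = 12, seed = 1), qp)
#' fit <- run_smc(pop, config = smc_config(n_particles = 200, n_stages = 3,
#'                                         seed = 1))
#' }
run_smc <- function(data, prior = NULL, config = smc_config(),
                    qp = default_qp(), dt = 0.02, shape = 1) {
  stopifnot(inherits(data, "population_data"))
  if (nrow(data$subadults) == 0) stop("no subadult records")
  mother <- data$adult_female_mean %||% data$adult_all_mean
  if (is.null(mother) || is.na(mother)) stop("no adult reference mean available")
  wn_center <- data$adult_all_mean %||% data$adult_female_mean
  if (is.null(prior)) prior <- weaning_prior(wnfood_mean = wn_center)

  ages <- data$subadults$age
  obs <- data$subadults$d15n
  grid <- .sim_grid(max(ages, 1), qp, dt)
  distance_fun <- function(theta) {
    sim <- .simulate_bone_matrix(ages, theta, mother, qp, dt, shape, grid)
    rowMeans((sim - rep(obs, each = nrow(sim)))^2)
  }
  ps <- abc_smc(prior, distance_fun, config)
  ps$data <- data
  ps$d15n_mother <- mother
  ps$qp <- qp
  ps$dt <- dt
  ps$shape <- shape
  ps
}
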