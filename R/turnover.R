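#' Tissue-level constants for the bone turnover model
#'
#' Loads the physiological constants behind the subadult turnover model: the
#' skeletal mineral mass growth curve \eqn{M(x)}, the cancellous-bone
#' remodeling rate \eqn{R(x)}, and the collagen mineralization law. They are
#' stored in a YAML file so the physiology can be revised without touching
#' code.
#'
#' @param path Path to a YAML constants file. Defaults to the file shipped
#'   with the package.
#' @return A list with elements `ages` (integer ages 0..20), `mass` (bone
#'   mineral mass at each age, g), `rate` (fraction of existing bone
#'   remodeled per year at each age) and `mineralization` (list with
#'   `increments`, `tail_start`, `tail_ratio`).
#' @export
#' @examples
#' k <- turnover_constants()
#' k$mass[1]  # mineral mass at birth
turnover_constants <- function(path = system.file("extdata",
                                                  "turnover_constants.yaml",
                                                  package = "weanabc")) {
  raw <- yaml::read_yaml(path)
  out <- list(
    ages = as.integer(raw$skeletal_mineral_mass$ages),
    mass = as.numeric(raw$skeletal_mineral_mass$mass),
    rate = as.numeric(raw$remodeling_rate$rate),
    mineralization = list(
      increments = as.numeric(raw$mineralization$increments),
      tail_start = as.numeric(raw$mineralization$tail_start),
      tail_ratio = as.numeric(raw$mineralization$tail_ratio)
    )
  )
  stopifnot(length(out$mass) == length(out$ages),
            length(out$rate) == length(out$ages),
            !is.unsorted(out$ages))
  if (any(out$mass <= 0)) stop("skeletal mineral mass must be positive")
  if (any(out$rate < 0)) stop("remodeling rates must be non-negative")
  out
}

#' Per-year bone mineral turnover from modeling and remodeling
#'
#' Bone mineral laid down during the year from age `x` to `x + 1` has two
#' sources: net skeletal growth (modeling) and the replacement of existing
#' bone (remodeling). Expressed as a fraction of the mineral present at the
#' end of the year, the turnover over one interval is
#' \deqn{k_m(x) = \frac{M(x+1) - M(x) + \bar R(x)\,M(x)}{M(x+1)},}
#' where \eqn{\bar R(x)} is the geometric mean of the remodeling rate at the
#' interval endpoints. Values above 1 (complete replacement within the year)
#' occur in infancy.
#'
#' @param constants Constants list from [turnover_constants()].
#' @return A data frame of class `turnover_table` with columns `from`, `to`
#'   and `mineral` (fraction of bone mineral replaced per year) for the
#'   twenty one-year intervals 0--1 through 19--20.
#' @export
#' @examples
#' head(mineral_turnover_table())
mineral_turnover_table <- function(constants = turnover_constants()) {
  M <- constants$mass
  R <- constants$rate
  n <- length(M) - 1L
  Rbar <- sqrt(R[seq_len(n)] * R[seq_len(n) + 1L])
  mineral <- (M[seq_len(n) + 1L] - M[seq_len(n)] + Rbar * M[seq_len(n)]) /
    M[seq_len(n) + 1L]
  out <- data.frame(from = constants$ages[seq_len(n)],
                    to = constants$ages[seq_len(n) + 1L],
                    mineral = mineral)
  class(out) <- c("turnover_table", "data.frame")
  out
}

#' The collagen mineralization law
#'
#' Newly formed collagen matrix mineralizes quickly to most of its capacity
#' (primary mineralization) and then slowly accumulates the remainder over
#' years (secondary mineralization). `mineralization_law()` returns the law
#' as annual increments; `mineralization_fraction()` evaluates the cumulative
#' fraction of full mineralization reached by a collagen cohort `lag` whole
#' years after its formation (lag 0 = the formation year itself).
#'
#' @param constants Constants list from [turnover_constants()].
#' @return For `mineralization_law()`, an object of class
#'   `mineralization_law`. For `mineralization_fraction()`, cumulative
#'   fractions in (0, 1], non-decreasing in `lag` with limit 1.
#' @export
#' @examples
#' law <- mineralization_law()
#' mineralization_fraction(0:5, law)
mineralization_law <- function(constants = turnover_constants()) {
  law <- constants$mineralization
  stopifnot(all(law$increments >= 0),
            law$tail_start >= 0,
            law$tail_ratio >= 0, law$tail_ratio < 1)
  structure(law, class = "mineralization_law")
}

#' @rdname mineralization_law
#' @param lag Integer years since collagen matrix formation (vectorized).
#' @param law A `mineralization_law` object.
#' @export
mineralization_fraction <- function(lag, law = mineralization_law()) {
  if (any(lag < 0)) stop("lag must be non-negative")
  lag <- as.integer(lag)
  nk <- length(law$increments)
  head_mass <- sum(law$increments)
  tail_total <- if (law$tail_ratio < 1) law$tail_start / (1 - law$tail_ratio) else 0
  vapply(lag, function(l) {
    if (l < nk) {
      sum(law$increments[seq_len(l + 1L)])
    } else {
      # geometric tail: head mass plus the tail accumulated through lag l
      head_mass + tail_total * (1 - law$tail_ratio^(l - nk + 1L))
    }
  }, numeric(1))
}

# annual increments of the law out to a given maximum lag
.law_increments <- function(law, max_lag) {
  nk <- length(law$increments)
  lags <- 0:max_lag
  out <- numeric(max_lag + 1L)
  out[lags < nk] <- law$increments[seq_len(min(nk, max_lag + 1L))]
  if (max_lag >= nk) {
    tl <- nk:max_lag
    out[tl + 1L] <- law$tail_start * law$tail_ratio^(tl - nk)
  }
  out
}

#' Collagen turnover by deconvolution of the mineralization delay
#'
#' The mineral record at a given age is a mineralization-law-weighted sum over
#' collagen cohorts formed at that age and before: a cohort formed \eqn{l}
#' years ago contributes the mineral it acquires during its \eqn{l}-th year.
#' Writing \eqn{w_l} for the annual increments of the law, the per-year
#' mineral turnover satisfies
#' \deqn{k_m(x) = \sum_{l=0}^{x} w_l\,k_c(x-l),}
#' which is solved sequentially for the collagen rates \eqn{k_c}, starting
#' from the 0--1 interval (the only causally well-posed order).
#'
#' @param mineral A `turnover_table` with the mineral column filled (from
#'   [mineral_turnover_table()]).
#' @param law A [mineralization_law()] object.
#' @return The input table with a `collagen` column added (fraction of bone
#'   collagen replaced per year).
#' @export
#' @examples
#' tab <- collagen_turnover_table()
#' tab[tab$from == 0, ]
collagen_turnover_table <- function(mineral = mineral_turnover_table(),
                                    law = mineralization_law()) {
  if (!"mineral" %in% names(mineral)) stop("mineral column missing")
  m <- mineral$mineral
  n <- length(m)
  w <- .law_increments(law, n - 1L)
  if (w[1] <= 0) stop("mineralization law must have positive first-year mass")
  cc <- numeric(n)
  for (x in seq_len(n)) {
    acc <- if (x > 1L) sum(w[2:x] * cc[(x - 1L):1L]) else 0
    cc[x] <- (m[x] - acc) / w[1]
    if (!is.finite(cc[x]) || cc[x] < 0) {
      stop(sprintf(
        "deconvolution produced a non-positive collagen rate in interval %d-%d",
        mineral$from[x], mineral$to[x]))
    }
  }
  mineral$collagen <- cc
  mineral
}

#' Fit the quartic polynomial turnover model
#'
#' Condenses the twenty discrete per-year collagen turnover rates into a
#' smooth quartic polynomial in age by ordinary least squares. Each
#' interval's rate describes the bone present at the interval's end, so the
#' rate for interval \eqn{x}--\eqn{x+1} is attached to age \eqn{x+1}; ages
#' below one year are extrapolated from the fitted polynomial.
#'
#' @param table A `turnover_table` with the collagen column filled.
#' @param column Which column to fit (default `"collagen"`).
#' @return An object of class `qp_model` holding the five polynomial
#'   coefficients (constant term first).
#' @export
#' @examples
#' qp <- fit_qp(collagen_turnover_table())
#' qp_rate(qp, c(0.5, 1, 10.5))
fit_qp <- function(table, column = "collagen") {
  if (!column %in% names(table)) stop("column '", column, "' missing")
  age <- table$to
  y <- table[[column]]
  X <- stats::model.matrix(~ poly(age, 4, raw = TRUE))
  qr_x <- qr(X)
  if (qr_x$rank < 5L) stop("singular design: ages do not support a quartic fit")
  fit <- stats::lm.fit(X, y)
  structure(list(coefficients = unname(fit$coefficients)),
            class = "qp_model")
}

#' Evaluate the quartic turnover model
#'
#' Returns the instantaneous turnover rate (fraction per year) at the given
#' ages. Rates are clamped to a small positive floor (1e-6) because physical
#' turnover cannot be negative; the fitted model is positive throughout
#' 0--20 years, so the floor only guards extrapolation.
#'
#' @param qp A `qp_model` from [fit_qp()].
#' @param age Ages in years (vectorized).
#' @param floor Lower clamp for the rate.
#' @return Turnover rates, fraction per year.
#' @export
qp_rate <- function(qp, age, floor = 1e-6) {
  co <- qp$coefficients
  val <- co[1] + age * (co[2] + age * (co[3] + age * (co[4] + age * co[5])))
  pmax(val, floor)
}

#' Cumulative collagen replacement between two ages
#'
#' Definite integral of the quartic turnover rate, computed in closed form
#' from the antiderivative (no quadrature error). The value is the expected
#' cumulative fraction of collagen synthesized over the age window; it
#' exceeds 1 when the window spans high-turnover infancy.
#'
#' @param qp A `qp_model`.
#' @param from_age,to_age Integration bounds in years, `from_age <= to_age`.
#' @return The integrated turnover (dimensionless).
#' @export
#' @examples
#' qp <- fit_qp(collagen_turnover_table())
#' integrated_turnover(qp, 0, 1)
integrated_turnover <- function(qp, from_age, to_age) {
  if (any(from_age < 0)) stop("ages must be non-negative")
  if (any(to_age < from_age)) stop("to_age must be >= from_age")
  co <- qp$coefficients
  anti <- function(x) {
    x * (co[1] + x * (co[2] / 2 + x * (co[3] / 3 + x * (co[4] / 4 + x * co[5] / 5))))
  }
  anti(to_age) - anti(from_age)
}

#' Full turnover table: mineral, collagen and quartic-model rates
#'
#' Convenience wrapper running the whole turnover pipeline: mineral rates
#' from bone modeling + remodeling, collagen rates by mineralization-delay
#' deconvolution, and the quartic polynomial (QP) fit evaluated at each
#' interval's end age.
#'
#' @param constants Constants list from [turnover_constants()].
#' @return A data frame with columns `from`, `to`, `mineral`, `collagen`,
#'   `collagen_qp`, with the fitted `qp_model` attached as attribute `"qp"`.
#' @export
#' @examples
#' tab <- turnover_table()
#' attr(tab, "qp")
turnover_table <- function(constants = turnover_constants()) {
  tab <- collagen_turnover_table(mineral_turnover_table(constants),
                                 mineralization_law(constants))
  qp <- fit_qp(tab)
  tab$collagen_qp <- qp_rate(qp, tab$to)
  attr(tab, "qp") <- qp
  tab
}

# cache for the default quartic model (constants are fixed per install)
.weanabc_cache <- new.env(parent = emptyenv())

#' Default quartic collagen-turnover model
#'
#' The quartic model fitted to the package's built-in turnover table. Cached
#' after the first call.
#'
#' @return A `qp_model`.
#' @export
default_qp <- function() {
  if (is.null(.weanabc_cache$qp)) {
    .weanabc_cache$qp <- attr(turnover_table(), "qp")
  }
  .weanabc_cache$qp
}

#' @export
print.qp_model <- function(x, ...) {
  cat("Quartic turnover model (fraction/yr):\n")
  cat("  rate(age) =", paste(signif(x$coefficients, 6),
                             c("", "* a", "* a^2", "* a^3", "* a^4"),
                             collapse = " + "), "\n")
  invisible(x)
}
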