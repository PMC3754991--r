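test_that("weighted quantiles reduce to type-7 quantiles under uniform weights", {
  q <- weighted_quantile(1:100, rep(1, 100), c(0.25, 0.75))
  expect_equal(q, c(25.75, 75.25))
  set.seed(401)
  x <- rnorm(57)
  probs <- c(0.025, 0.1, 0.5, 0.9, 0.975)
  expect_equal(weighted_quantile(x, rep(2, 57), probs),
               unname(quantile(x, probs, type = 7)))
  # level-1 interval spans the particle range
  expect_equal(weighted_quantile(x, rep(1, 57), c(0, 1)), range(x))
})

test_that("credible intervals nest and validate the level", {
  fit <- shared_fit()
  ci50 <- credible_interval(fit, "t2", 0.5)
  ci90 <- credible_interval(fit, "t2", 0.9)
  expect_true(ci90["lower"] <= ci50["lower"] && ci50["upper"] <= ci90["upper"])
  expect_error(credible_interval(fit, "t2", 1.2), "level")
  expect_error(credible_interval(fit, "t2", 0), "level")
})

test_that("grid masses form a probability distribution", {
  fit <- shared_fit()
  g <- density_grids(fit)
  expect_equal(sum(g$joint$mass), 1, tolerance = 1e-9)
  expect_equal(sum(g$enrichment$mass), 1, tolerance = 1e-9)
  expect_equal(sum(g$wnfood$mass), 1, tolerance = 1e-9)
  expect_true(all(g$joint$mass >= 0))
  # doubling all weights changes nothing after normalization
  fit2 <- fit
  fit2$weights <- fit$weights * 2
  g2 <- density_grids(fit2)
  expect_equal(g2$joint$mass, g$joint$mass)
  fit3 <- fit
  fit3$weights <- rep(0, length(fit$weights))
  expect_error(density_grids(fit3), "zero")
})

test_that("a degenerate particle cloud concentrates in a single cell", {
  th <- matrix(rep(c(1, 3, 2.4, 9.5), each = 200), 200)
  g <- density_grids(fake_particle_system(th))
  m <- mde(g)
  expect_equal(m$params$t1, 1)
  expect_equal(m$params$t2, 3)
  expect_equal(m$params$enrichment, 2.4)
  expect_equal(m$params$wnfood, 9.5)
  expect_gte(m$joint_prob, 0.99)
  expect_gte(m$enrichment_prob, 0.99)
})

test_that("grid masses match the Gaussian CDF on a standard-normal cloud", {
  set.seed(402)
  n <- 100000
  th <- cbind(runif(n, 0, 2), runif(n, 2, 4), rnorm(n), rnorm(n))
  ps <- fake_particle_system(th)
  g <- density_grids(ps)
  h <- g$enrichment$bandwidth
  sd_sm <- sqrt(1 + h^2)  # KDE convolves the cloud with the kernel
  for (r in list(c(-1, 1), c(-1.96, 1.96))) {
    got <- range_probability(g, enrichment = r)
    # included cells span [lo - 0.05, hi + 0.05] after center snapping
    lo <- min(g$enrichment$centers[g$enrichment$centers >= r[1]]) - 0.05
    hi <- max(g$enrichment$centers[g$enrichment$centers <= r[2]]) + 0.05
    expect_equal(got, pnorm(hi, 0, sd_sm) - pnorm(lo, 0, sd_sm),
                 tolerance = 0.01)
  }
  # sanity value: ~95% of the mass inside +/-1.96
  expect_equal(range_probability(g, enrichment = c(-1.96, 1.96)), 0.95,
               tolerance = 0.02)
})

test_that("the MDE tracks the mode of a unimodal cloud", {
  set.seed(403)
  n <- 50000
  th <- cbind(rnorm(n, 1, 0.3), rnorm(n, 3, 0.4), rnorm(n, 2.4, 0.2),
              rnorm(n, 9.5, 0.25))
  m <- mde(density_grids(fake_particle_system(th)))
  expect_lte(abs(m$params$t1 - 1), 0.1)
  expect_lte(abs(m$params$t2 - 3), 0.1)
  expect_lte(abs(m$params$enrichment - 2.4), 0.1)
  expect_lte(abs(m$params$wnfood - 9.5), 0.1)
  expect_false(m$ties)
})

test_that("ties break toward smaller parameter values and are flagged", {
  g <- structure(list(
    joint = list(t1 = c(0, 0.1), t2 = c(1, 1.1),
                 mass = matrix(0.25, 2, 2)),
    enrichment = list(centers = c(2, 2.1), mass = c(0.5, 0.5)),
    wnfood = list(centers = c(9, 9.1), mass = c(0.4, 0.6)),
    cell = 0.1), class = "weaning_grids")
  m <- mde(g)
  expect_equal(m$params$t1, 0)
  expect_equal(m$params$t2, 1)
  expect_equal(m$params$enrichment, 2)
  expect_equal(m$params$wnfood, 9.1)
  expect_true(m$ties)
})

test_that("range probabilities are additive and normalized", {
  fit <- shared_fit()
  g <- density_grids(fit)
  t1r <- range(g$joint$t1); t2r <- range(g$joint$t2)
  expect_equal(range_probability(g, t1 = t1r, t2 = t2r), 1)
  # disjoint half-splits sum to the total
  cut <- g$joint$t1[ceiling(length(g$joint$t1) / 2)]
  left <- range_probability(g, t1 = c(t1r[1], cut), t2 = t2r)
  right <- range_probability(g, t1 = c(cut + 0.05, t1r[2]), t2 = t2r)
  expect_equal(left + right, 1, tolerance = 1e-9)
  # monotone under range inclusion
  inner <- range_probability(g, enrichment = c(1.5, 2.5))
  outer <- range_probability(g, enrichment = c(1.0, 3.0))
  expect_lte(inner, outer)
  expect_warning(p0 <- range_probability(g, enrichment = c(99, 100)), "empty")
  expect_equal(p0, 0)
  expect_error(range_probability(g, t1 = c(0, 1)), "both")
  expect_error(range_probability(g, t1 = c(0, 1), enrichment = c(0, 1)),
               "not both")
})

test_that("suspect-fit flags fire at the documented thresholds", {
  base <- list(mde = list(t1 = 1, t2 = 3, enrichment = 2.4, wnfood = 9.5),
               mde_joint_prob_ages = 0.01, mde_marginal_prob_e = 0.2,
               mde_marginal_prob_wnfood = 0.2, delta_wnfood = -0.5)
  expect_identical(flag_suspect_fit(base), character(0))
  low_joint <- base; low_joint$mde_joint_prob_ages <- 0.001
  expect_identical(flag_suspect_fit(low_joint), "low_joint_probability")
  low_marg <- base; low_marg$mde_marginal_prob_e <- 0.04
  expect_identical(flag_suspect_fit(low_marg), "low_marginal_probability")
  neg <- base; neg$delta_wnfood <- -3
  expect_identical(flag_suspect_fit(neg), "negative_wnfood_offset")
})

test_that("a clean recovery run summarizes without flags", {
  fit <- shared_fit()
  s <- posterior_summary(fit)
  expect_identical(s$flags, character(0))
  # MDE of each parameter lies inside its 95% credible interval
  ci <- s$credible_intervals
  for (p in c("t1", "t2", "enrichment", "wnfood")) {
    expect_gte(s$mde[[p]], ci["lower", p])
    expect_lte(s$mde[[p]], ci["upper", p])
  }
  expect_equal(s$delta_wnfood, s$mde$wnfood - 10)
  expect_s3_class(s$fitted, "trajectory")
})
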