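test_that("synthesized collagen follows plateau / exponential / plateau", {
  p <- weaning_params(t1 = 0.5, t2 = 2.0, enrichment = 2.4, wnfood = 9.5)
  expect_equal(synthesized_d15n(0.2, p, 10), 12.4)      # pre-weaning plateau
  expect_equal(synthesized_d15n(5.0, p, 10), 9.5)       # post-weaning plateau
  expect_equal(synthesized_d15n(0.5, p, 10), 12.4)      # continuous at t1
  expect_equal(synthesized_d15n(2.0, p, 10), 9.5)       # continuous at t2
  mid <- synthesized_d15n(1.2, p, 10)
  expect_true(mid < 12.4 && mid > 9.5)
  # monotone decline through the transition
  tr <- synthesized_d15n(seq(0.5, 2, by = 0.05), p, 10)
  expect_true(all(diff(tr) < 0))
  # shape = 0 gives the linear transition
  expect_equal(synthesized_d15n(1.25, p, 10, shape = 0), (12.4 + 9.5) / 2)
})

test_that("instantaneous weaning is a step function at t1", {
  p <- weaning_params(t1 = 1, t2 = 1, enrichment = 2, wnfood = 9)
  expect_equal(synthesized_d15n(c(0.99, 1.01), p, 10), c(12, 9))
})

test_that("parameter and input validation", {
  expect_error(weaning_params(2, 1, 2, 9), "t2")
  expect_error(weaning_params(-0.5, 1, 2, 9), "t1")
  p <- weaning_params(0.5, 2, 2, 9)
  expect_error(synthesized_d15n(-1, p, 10), "non-negative")
  expect_error(simulate_bone_d15n(c(1, 25), p, 10), "within")
  expect_error(simulate_bone_d15n(-0.1, p, 10), "within")
})

test_that("no isotopic contrast gives a flat trajectory at the mother value", {
  p <- weaning_params(0.5, 2.5, enrichment = 0, wnfood = 10)
  b <- simulate_bone_d15n(c(0, 0.7, 1, 2.2, 5, 9.9), p, d15n_mother = 10)
  expect_equal(b, rep(10, 6), tolerance = 1e-12)
})

test_that("bulk bone stays inside the plateau envelope (convex mixing)", {
  set.seed(301)
  ages <- sort(runif(15, 0, 10))
  for (i in 1:20) {
    t1 <- runif(1, 0, 3); t2 <- t1 + runif(1, 0, 4)
    e <- runif(1, 0, 4); wn <- runif(1, 7, 13)
    p <- weaning_params(t1, t2, e, wn)
    b <- simulate_bone_d15n(ages, p, 10)
    lo <- min(10, 10 + e, wn); hi <- max(10, 10 + e, wn)
    expect_true(all(b >= lo - 1e-9 & b <= hi + 1e-9))
  }
})

test_that("simulated bone responds monotonically to the enrichment factor", {
  set.seed(302)
  ages <- seq(0, 9.5, by = 0.5)
  for (i in 1:15) {
    t1 <- runif(1, 0, 2); t2 <- t1 + runif(1, 0, 4); wn <- runif(1, 8, 12)
    e1 <- runif(1, 0, 2); e2 <- e1 + runif(1, 0, 2)
    b1 <- simulate_bone_d15n(ages, weaning_params(t1, t2, e1, wn), 10)
    b2 <- simulate_bone_d15n(ages, weaning_params(t1, t2, e2, wn), 10)
    expect_true(all(b2 - b1 >= -1e-9))
  }
})

test_that("a birth diet switch converges as the integrated turnover", {
  qp <- shared_qp()
  p <- weaning_params(0, 0, 0, 12)  # diet jumps to wnfood at birth
  for (a in c(0.25, 0.45, 0.58)) {
    frac <- (simulate_bone_d15n(a, p, 10, qp) - 10) / 2
    expect_equal(frac, integrated_turnover(qp, 0, a), tolerance = 2e-3)
  }
  # 96.6% convergence is reached where the cumulative integral hits 0.966
  a966 <- uniroot(function(a) integrated_turnover(qp, 0, a) - 0.966,
                  c(0.3, 1))$root
  expect_equal(a966, 0.58, tolerance = 0.03)
  frac <- (simulate_bone_d15n(a966, p, 10, qp) - 10) / 2
  expect_equal(frac, 0.966, tolerance = 2e-3)
})

test_that("bulk bone lags the synthesized signal", {
  qp <- shared_qp()
  p <- weaning_params(0.5, 2.5, 2.4, 9.5)
  tr <- trajectory(p, 10, qp, ages = seq(0, 6, by = 0.1))
  at_t2 <- tr$bone[tr$age == 2.5]
  expect_true(at_t2 > 9.5 && at_t2 < 12.4)     # strictly between plateaus
  expect_equal(tr$synthesized[tr$age == 2.5], 9.5)
  # during the decline the bone record sits above the synthesized signal
  during <- tr$age > 0.8 & tr$age <= 2.5
  expect_true(all(tr$bone[during] > tr$synthesized[during]))
})

test_that("coarse quadrature agrees with a fine-step oracle", {
  qp <- shared_qp()
  set.seed(303)
  ages <- sort(runif(8, 0.05, 9.9))
  for (i in 1:10) {
    p <- weaning_params(runif(1, 0, 2), runif(1, 2, 5), runif(1, 1, 3),
                        runif(1, 8, 11))
    coarse <- simulate_bone_d15n(ages, p, 10, qp, dt = 0.02)
    fine <- simulate_bone_d15n(ages, p, 10, qp, dt = 0.001)
    expect_lt(max(abs(coarse - fine)), 0.01)
  }
})

test_that("mean squared distance behaves as a metric summary", {
  expect_equal(distance_msd(c(10, 12), c(10, 12)), 0)
  expect_equal(distance_msd(c(10, 12), c(11, 13)), 1)
  o <- c(9.1, 10.2, 11.3); s <- c(9.0, 10.0, 11.9)
  expect_equal(distance_msd(o, s), distance_msd(rev(o), rev(s)))
  expect_error(distance_msd(numeric(0), numeric(0)), "empty")
  expect_error(distance_msd(1:3, 1:2), "mismatch")
})
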