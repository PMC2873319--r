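gamma_surface <- function(gamma) interaction_surface(gamma)

# analytic mixed partial of the difference-form S on the interaction
# surface, derived from S = exp(-u-v-g*u*v) - exp(-u-v) with u = 1-a,
# v = 1-b (the two sign flips of the chain rule cancel)
ds_diff_oracle <- function(gamma, a, b) {
  u <- 1 - a; v <- 1 - b
  exp(-u - v - gamma * u * v) *
    ((1 + gamma * u) * (1 + gamma * v) - gamma) - exp(-u - v)
}

test_that("survival ratios follow the before/after output definition", {
  s <- gamma_surface(0.5)
  expect_equal(survival_ratio(s, 1, 1), 1)
  expect_equal(survival_ratio(s, 0.5, 1), exp(-0.5), tolerance = 1e-12)

  flat <- response_surface(function(a, b) 3.2)
  expect_equal(survival_ratio(flat, 0.1, 0.9), 1)
  expect_equal(survival_ratio(flat, 7, 0.2), 1)

  expect_error(response_surface(function(a, b) 0), "must be positive")
})

test_that("the Bliss expectation is the product of individual effects", {
  expect_equal(bliss_expected(1.0, 0.3), 0.3)
  expect_equal(bliss_expected(0.5, 0.5), 0.25)
  expect_equal(bliss_expected(0.9, 0.2), 0.18)
  expect_error(bliss_expected(0, 0.5), "positive")
  expect_error(bliss_expected(0.5, -1), "positive")
})

test_that("classification uses S = 0 as the critical point", {
  # the published original-system score for the HSP90 + proteasome pair
  expect_identical(classify_interaction(-0.2678, 1e-6), "synergism")
  expect_identical(classify_interaction(0, 0), "additive")
  expect_identical(classify_interaction(0, 10), "additive")
  expect_identical(classify_interaction(5e-7, 1e-6), "additive")
  expect_identical(classify_interaction(2e-6, 1e-6), "antagonism")
  expect_identical(classify_interaction(c(-1, 0, 1)),
                   c("synergism", "additive", "antagonism"))
})

test_that("S vanishes on the baseline edges and on separable surfaces", {
  surfaces <- list(
    gamma_surface(0.7),
    gamma_surface(-0.3),
    separable_surface(function(a) exp(-(1 - a)),
                      function(b) 0.2 + 0.8 * b, baseline = 2))
  for (surf in surfaces) {
    for (s in c(0.05, 0.3, 0.8, 1, 2)) {
      expect_equal(synergy_s(surf, 1, s)$s_value, 0)
      expect_equal(synergy_s(surf, s, 1)$s_value, 0)
      expect_lt(abs(synergy_s(surf, 1, s, form = "log")$s_value), 1e-12)
    }
  }
  sep <- surfaces[[3]]
  for (a in c(0.1, 0.5, 0.9)) {
    for (b in c(0.2, 0.7)) {
      expect_equal(synergy_s(sep, a, b)$s_value, 0, tolerance = 1e-14)
      expect_equal(synergy_s(sep, a, b, form = "log")$s_value, 0,
                   tolerance = 1e-12)
    }
  }
})

test_that("S matches the closed-form interaction surface", {
  surf <- gamma_surface(0.5)
  sc <- synergy_s(surf, 0.5, 0.5)
  expect_equal(sc$s_value, exp(-1) * (exp(-0.125) - 1), tolerance = 1e-12)
  expect_lt(sc$s_value, 0)
  expect_identical(sc$classification, "synergism")
  expect_equal(sc$r_ab, exp(-1.125), tolerance = 1e-12)
  expect_equal(sc$r_a, exp(-0.5), tolerance = 1e-12)

  # log form is exactly -gamma * u * v
  sl <- synergy_s(surf, 0.3, 0.6, form = "log")
  expect_equal(sl$s_value, -0.5 * 0.7 * 0.4, tolerance = 1e-12)

  # antagonistic gamma flips the verdict
  expect_identical(synergy_s(gamma_surface(-0.5), 0.5, 0.5)$classification,
                   "antagonism")

  td <- tidy(sc)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$form, "difference")
  expect_equal(td$s_value, sc$s_value)
})

test_that("DS recovers the analytic mixed partial", {
  surf <- gamma_surface(0.5)
  # log form: DS is the constant -gamma everywhere
  for (pt in list(c(0.7, 0.8), c(0.4, 0.4), c(1, 1))) {
    est <- ds_estimate(surf, pt, form = "log")
    expect_true(est$reliable)
    expect_equal(est$ds_value, -0.5, tolerance = 1e-4)
  }
  # difference form at the baseline point equals -gamma ...
  est0 <- ds_estimate(surf, c(1, 1), form = "difference")
  expect_equal(est0$ds_value, -0.5, tolerance = 1e-4)
  expect_equal(ds_diff_oracle(0.5, 1, 1), -0.5)
  # ... and matches the analytic mixed partial away from it
  for (pt in list(c(0.5, 0.5), c(0.8, 0.3))) {
    est <- ds_estimate(surf, pt, form = "difference")
    expect_equal(est$ds_value, ds_diff_oracle(0.5, pt[1], pt[2]),
                 tolerance = 1e-4)
  }

  # separable surfaces have DS identically zero, both stencils
  sep <- separable_surface(function(a) exp(-(1 - a)),
                           function(b) 1 / (1 + 0.7 * (1 - b)))
  for (st in c("four_point_s", "two_term_r")) {
    expect_lt(abs(ds_estimate(sep, c(0.5, 0.5), stencil = st)$ds_value),
              1e-6)
    expect_lt(abs(ds_estimate(sep, c(0.5, 0.5), stencil = st,
                              form = "log")$ds_value), 1e-6)
  }
})

test_that("the two DS stencils agree on smooth surfaces", {
  surf <- gamma_surface(0.8)
  for (form in c("difference", "log")) {
    for (pt in list(c(0.6, 0.9), c(0.3, 0.5))) {
      e1 <- ds_estimate(surf, pt, stencil = "four_point_s", form = form)
      e2 <- ds_estimate(surf, pt, stencil = "two_term_r", form = form)
      expect_equal(e1$ds_value, e2$ds_value, tolerance = 1e-4)
    }
  }
})

test_that("fixed steps are honoured and domain violations rejected", {
  surf <- gamma_surface(0.5)
  est <- ds_estimate(surf, c(0.5, 0.5), steps = c(0.01, 0.02))
  expect_equal(est$steps, c(0.01, 0.02))
  expect_equal(est$ds_value, ds_diff_oracle(0.5, 0.5, 0.5),
               tolerance = 1e-2)
  expect_error(ds_estimate(surf, c(0.5, 0.5), steps = c(0.6, 0.01)),
               "admissible")
  expect_error(ds_estimate(surf, c(0.5, 0.5), steps = c(-0.1, 0.01)),
               "admissible")
})

test_that("integrating DS over the dose rectangle recovers S", {
  surf <- gamma_surface(0.5)
  # degenerate rectangles
  expect_identical(s_from_ds(surf, c(1, 0.3)), 0)
  expect_identical(s_from_ds(surf, c(0.3, 1)), 0)
  # log form: constant DS integrates exactly to -gamma * area
  expect_equal(s_from_ds(surf, c(0.5, 0.5), mesh = 8, form = "log"),
               -0.5 * 0.25, tolerance = 1e-9)
  # difference form converges to the direct score
  direct <- synergy_s(surf, 0.4, 0.7)$s_value
  e4 <- abs(s_from_ds(surf, c(0.4, 0.7), mesh = 4) - direct)
  e8 <- abs(s_from_ds(surf, c(0.4, 0.7), mesh = 8) - direct)
  expect_lt(e8 / abs(direct), 1e-3)
  # refinement does not degrade the estimate (quadrature error already at
  # the stencil floor by mesh 8)
  expect_lte(e8, e4 + 1e-12)
})

test_that("DS < 0 on the rectangle mesh forces synergy at the corner", {
  for (gamma in c(0.3, 0.8)) {
    surf <- gamma_surface(gamma)
    target <- c(0.45, 0.6)
    nodes_a <- seq(target[1], 1, length.out = 5)
    nodes_b <- seq(target[2], 1, length.out = 5)
    ds_nodes <- vapply(nodes_a, function(a) {
      vapply(nodes_b, function(b) {
        ds_estimate(surf, c(a, b))$ds_value
      }, numeric(1))
    }, numeric(5))
    expect_true(all(ds_nodes < 0))
    expect_lte(synergy_s(surf, target[1], target[2])$s_value, 0)
  }
})

test_that("scan_surface fills the grid and tolerates failing points", {
  ta <- perturbation("a.vmax"); tb <- perturbation("b.vmax")
  surf <- gamma_surface(0.5)

  g1 <- perturbation_grid(ta, tb, 1)
  sc1 <- scan_surface(surf, g1)
  expect_equal(nrow(sc1), 1)
  expect_equal(sc1$s_value, 0)

  sep <- separable_surface(function(a) exp(-(1 - a)), function(b) b^0.3)
  g <- perturbation_grid(ta, tb, c(1, 0.7, 0.4, 0.1))
  scs <- scan_surface(sep, g)
  expect_equal(max(abs(scs$s_value)), 0, tolerance = 1e-14)
  expect_equal(attr(scs, "verdict_counts")$additive, 16L)

  # boundary rows/columns at scale 1 are additive
  scb <- scan_surface(surf, g)
  expect_equal(max(abs(scb$s_value[scb$scale_a == 1 | scb$scale_b == 1])), 0)
  m <- s_matrix(scb)
  expect_equal(dim(m), c(4, 4))
  expect_equal(unname(m[1, ]), rep(0, 4))

  flaky <- response_surface(function(a, b) {
    if (a < 0.05) stop("integration blew up")
    exp(-(1 - a)) * exp(-(1 - b))
  })
  gf <- perturbation_grid(ta, tb, c(1, 0.5, 0.01))
  scf <- scan_surface(flaky, gf)
  expect_equal(sum(is.na(scf$s_value)), 3)
  expect_equal(glance(scf)$n_failed, 3L)
  expect_equal(glance(scf)$n_additive, 6L)
})

test_that("equal-dose curves summarize the diagonal", {
  surf <- gamma_surface(0.5)
  crv <- s_curve(surf, c(1, 0.8, 0.5), form = "log")
  expect_equal(crv$s_value, -0.5 * (1 - c(1, 0.8, 0.5))^2, tolerance = 1e-12)
  expect_identical(crv$classification[1], "additive")
})
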