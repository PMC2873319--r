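test_that("transfer function Phi tracks the intermediate steady state", {
  m <- serial_motif()
  maps <- motif_mappings("serial")

  # identity mapping passes the scale through with positive slope
  ide <- phi_evaluate(m, maps$b, 0.3)
  expect_equal(ide$level, 0.3)
  expect_equal(ide$derivative_sign, 1)

  # baseline level equals the full-model steady state of the intermediate
  x0 <- phi_evaluate(m, maps$a, 1)
  expect_equal(x0$level, steady_state(m)[["B_P"]], tolerance = 1e-9)

  # a 10x Km increase lowers the activated intermediate: Phi' < 0
  ph <- phi_evaluate(m, maps$a, 10)
  expect_lt(ph$level, x0$level)
  expect_equal(ph$derivative_sign, -1)
})

test_that("clamping intermediates yields the consistent reduced cycle", {
  m <- serial_motif()
  maps <- motif_mappings("serial")
  sim <- simplify_clamp(m, maps$a, maps$b)

  expect_setequal(sim$submodel$species$name, c("C", "C_P"))
  expect_setequal(names(sim$submodel$inputs), "B_P")
  expect_setequal(sim$submodel$reactions$label,
                  c("activation_C", "deactivation_C"))
  expect_equal(unname(sim$clamp_baselines[["B_P"]]),
               steady_state(m)[["B_P"]], tolerance = 1e-9)
  expect_equal(sim$surface$baseline, sim$baseline_output,
               tolerance = 1e-6)

  mp <- parallel_motif()
  mapsp <- motif_mappings("parallel")
  simp <- simplify_clamp(mp, mapsp$a, mapsp$b)
  expect_setequal(simp$submodel$species$name, c("C", "C_P"))
  expect_setequal(names(simp$submodel$inputs), c("B1_P", "B2_P"))

  expect_error(simplify_clamp(m, target_mapping("activation_B.km", "C_P"),
                              maps$b),
               "cannot clamp the output")
  expect_error(simplify_clamp(m, target_mapping("activation_B.km", "Q"),
                              maps$b),
               "not a declared species")
  expect_error(simplify_clamp(m, maps$b, maps$b), "at least one mapping")
})

test_that("sign algebra of the simplification property", {
  expect_equal(lemma1_sign(-0.2, -1, +1), +1)  # serial: flip
  expect_equal(lemma1_sign(-0.2, -1, -1), -1)  # parallel: preserve
  expect_equal(lemma1_sign(+0.4, -1, +1), -1)
  expect_true(is.na(lemma1_sign(0, -1, +1)))
  expect_true(is.na(lemma1_sign(-0.2, 0, +1)))
})

test_that("serial and parallel sign relations hold on a dose grid", {
  for (motif in c("serial", "parallel")) {
    model <- builtin_model(motif)
    tg <- motif_targets(motif)
    grid <- perturbation_grid(tg$a, tg$b, motif_dose_scales(4))
    rep <- corollary_check(model, motif, grid = grid)
    g <- glance(rep)
    expect_equal(g$sign_agreement, 1)
    expect_gt(g$n_determinate, 0)
    # reconstructed S curve matches the original pointwise
    expect_lt(g$recon_max_abs_dev, 1e-8)
    # quantitative chain-rule prediction
    d <- tidy(rep)
    rel <- abs(d$ds_predicted - d$ds_original) /
      pmax(abs(d$ds_original), 1e-12)
    expect_lt(max(rel), 1e-3)
  }
})

test_that("negative feedback meets the preservation condition and is
           dominated by the feedback-free cascade", {
  base <- serial_motif()
  fb <- negative_feedback_motif()
  perts <- list(perturbation("activation_B.km", 3),
                perturbation("activation_C.km", 3))
  rep <- feedback_check(base, fb, perturbations = perts)
  expect_identical(rep$g_sign, "negative")
  expect_identical(rep$df_dx_sign, "positive")
  expect_true(rep$condition_met)
  expect_true(rep$domination_holds)
  expect_identical(rep$state_species, "B_P")
  expect_lte(rep$max_violation, 10 * sim_settings()$atol)
})

test_that("null feedback leaves trajectories identical", {
  base <- serial_motif()
  fb0 <- negative_feedback_motif(motif_params(fb_vmax = 0))
  rep <- feedback_check(base, fb0)
  expect_lte(rep$max_violation, 10 * sim_settings()$atol)
  expect_true(rep$domination_holds)
  expect_false(rep$condition_met)
})

test_that("positive feedback on an activating chain fails the condition
           and is not asserted to be dominated", {
  base <- serial_motif()
  fbp <- positive_feedback_motif()
  rep <- feedback_check(base, fbp)
  expect_identical(rep$g_sign, "positive")
  expect_identical(rep$df_dx_sign, "positive")
  expect_false(rep$condition_met)
  expect_false(rep$domination_holds)
  expect_gt(rep$max_violation, 10 * sim_settings()$atol)
})

test_that("feedback_check rejects models differing beyond the edge", {
  base <- serial_motif()
  fb <- negative_feedback_motif()
  tampered <- fb
  tampered$reactions$vmax[tampered$reactions$label == "activation_C"] <- 2
  expect_error(feedback_check(base, tampered),
               "beyond the declared feedback")
  expect_error(feedback_check(base, base), "no reaction labelled")
})

test_that("lemma-2 domination holds across random feedback fixtures", {
  for (seed in 1:6) {
    fb <- random_motif("negative_feedback", seed = seed)
    base <- fb
    base$reactions <- base$reactions[base$reactions$label != "feedback_B", ]
    perts <- list(perturbation("activation_B.km", 2.5),
                  perturbation("activation_C.km", 2.5))
    rep <- feedback_check(base, fb, perturbations = perts)
    expect_identical(rep$g_sign, "negative")
    expect_true(rep$condition_met)
    expect_true(rep$domination_holds)
    expect_lte(rep$max_violation, 10 * sim_settings()$atol)
  }
})
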