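test_that("built-in motifs have the documented shape and reach steady
           state", {
  m <- serial_motif()
  expect_identical(m$output, "C_P")
  expect_setequal(m$reactions$label,
                  c("activation_B", "deactivation_B", "activation_C",
                    "deactivation_C"))
  expect_identical(names(m$inputs), "A")

  p <- parallel_motif()
  expect_setequal(p$reactions$label,
                  c("activation_B1", "deactivation_B1", "activation_B2",
                    "deactivation_B2", "activation_C_via_B1",
                    "activation_C_via_B2", "deactivation_C"))

  fb <- negative_feedback_motif()
  fbr <- fb$reactions[fb$reactions$label == "feedback_B", ]
  expect_identical(fbr$kind, "mm_deactivation")
  expect_identical(fbr$substrate, "B_P")
  expect_identical(fbr$modifier, "C_P")

  for (mod in list(m, p, fb)) {
    traj <- simulate_model(mod, sim_settings(t_end = 1e4))
    expect_true(traj$steady_reached)
  }
})

test_that("inhibition lowers the motif output monotonically", {
  m <- serial_motif()
  base <- steady_state(m)[["C_P"]]
  inh <- steady_state(apply_perturbations(
    m, perturbation("activation_B.km", 10)))[["C_P"]]
  expect_lt(inh, base)

  # unperturbed survival ratio is exactly 1
  tg <- motif_targets("serial")
  surf <- model_surface(m, tg$a, tg$b)
  expect_equal(survival_ratio(surf, 1, 1), 1)
})

test_that("parallel branches combine as logic OR", {
  p <- parallel_motif()
  base <- steady_state(p)[["C_P"]]
  kill_b1 <- apply_perturbations(p, perturbation("activation_B1.km", 1e6))
  one_off <- steady_state(kill_b1)[["C_P"]]
  expect_gt(one_off, 0.3 * base)  # the other branch sustains the output
  both_off <- steady_state(apply_perturbations(
    kill_b1, perturbation("activation_B2.km", 1e6)))[["C_P"]]
  expect_lt(both_off, 0.02 * base)
})

test_that("the feedback motif reduces the output and has the serial limit", {
  serial_out <- steady_state(serial_motif())[["C_P"]]
  fb_out <- steady_state(negative_feedback_motif())[["C_P"]]
  expect_lt(fb_out, serial_out)

  # vmax -> 0: identical trajectories
  st <- sim_settings(t_end = 50, readout_mode = "endpoint")
  t_base <- simulate_model(serial_motif(), st)
  t_null <- simulate_model(negative_feedback_motif(
    motif_params(fb_vmax = 0)), st)
  expect_equal(t_null$concentrations[, colnames(t_base$concentrations)],
               t_base$concentrations, tolerance = 1e-12)

  # Km5 -> infinity: feedback flux vanishes
  t_inf <- simulate_model(negative_feedback_motif(
    motif_params(fb_km = 1e8)), st)
  expect_lt(max(abs(t_inf$concentrations[, colnames(t_base$concentrations)]
                    - t_base$concentrations)), 1e-6)
})

test_that("model JSON round-trips exactly", {
  for (build in list(serial_motif, parallel_motif,
                     negative_feedback_motif)) {
    m <- build()
    m2 <- load_model(save_model(m))
    expect_identical(as.data.frame(m2$species), as.data.frame(m$species))
    expect_identical(as.data.frame(m2$reactions),
                     as.data.frame(m$reactions))
    expect_identical(m2$inputs, m$inputs)
    expect_identical(m2$output, m$output)
  }
  # file round trip preserves the simulation output
  f <- withr::local_tempfile(fileext = ".json")
  save_model(serial_motif(), f)
  m2 <- load_model(f)
  expect_equal(steady_state(m2)[["C_P"]],
               steady_state(serial_motif())[["C_P"]])
})

test_that("schema violations name the offending JSON path", {
  doc <- jsonlite::fromJSON(save_model(serial_motif()),
                            simplifyVector = FALSE)
  reser <- function(d) jsonlite::toJSON(d, auto_unbox = TRUE, null = "null")

  d <- doc; d$output <- NULL
  expect_error(load_model(reser(d)), "\\$\\.output", fixed = FALSE)

  d <- doc; d$schema <- "other/9"
  expect_error(load_model(reser(d)), "\\$\\.schema")

  d <- doc; d$reactions[[1]]$kind <- "teleport"
  expect_error(load_model(reser(d)), "\\$\\.reactions\\[0\\]\\.kind")

  d <- doc; d$reactions[[3]]$km <- NULL
  expect_error(load_model(reser(d)), "\\$\\.reactions\\[2\\]\\.km")

  d <- doc; d$species[[2]]$initial <- NULL
  expect_error(load_model(reser(d)), "\\$\\.species\\[1\\]\\.initial")
})

test_that("shipped model documents load, validate and simulate", {
  for (nm in c("serial", "parallel", "negative_feedback",
               "nfkb_like_synthetic")) {
    f <- system.file("extdata", paste0(nm, ".json"), package = "synmotif")
    expect_true(file.exists(f))
    m <- load_model(f)
    expect_length(validate_model(m), 0)
    traj <- simulate_model(m)
    expect_true(traj$steady_reached)
  }
  # the synthetic pathway demo responds to all three inhibitor slots
  demo <- load_model(system.file("extdata", "nfkb_like_synthetic.json",
                                 package = "synmotif"))
  base <- steady_state(demo)[["ICAM1"]]
  for (tgt in c("activation_IKKK.vmax", "phosphorylation_IkB.k",
                "degradation_IkB.k")) {
    inh <- steady_state(apply_perturbations(demo,
                                            perturbation(tgt, 0.1)))
    expect_lt(inh[["ICAM1"]], base)
  }
})

test_that("random motifs are seed-deterministic and valid in batch", {
  m1 <- random_motif("serial", seed = 7)
  m2 <- random_motif("serial", seed = 7)
  expect_identical(m1, m2)
  expect_false(identical(random_motif("serial", seed = 8), m1))

  # the caller's RNG stream is untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(random_motif("parallel", seed = 1))
  after <- runif(1)
  expect_identical(before, after)

  for (seed in 1:10) {
    kind <- c("serial", "parallel", "negative_feedback")[(seed %% 3) + 1]
    m <- random_motif(kind, seed = seed)
    expect_length(validate_model(m), 0)
    traj <- simulate_model(m, sim_settings(t_end = 1e4))
    expect_true(traj$steady_reached)
  }

  # collapsed ranges reproduce the default motif exactly
  defaults <- motif_params()
  collapsed <- lapply(unclass(defaults), function(v) c(v[1], v[1]))
  m <- random_motif("serial", seed = 1, ranges = collapsed)
  expect_identical(as.data.frame(m$reactions),
                   as.data.frame(serial_motif()$reactions))
  expect_identical(as.data.frame(m$species),
                   as.data.frame(serial_motif()$species))
})
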