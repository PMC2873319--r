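#' Map an inhibitor target to its intermediate product
#'
#' The simplification rule replaces an inhibitor acting on an upstream
#' process by a virtual inhibitor acting directly on that process's product:
#' the steady-state level of the `intermediate` species, as a function of
#' the scaled parameter, is the transfer function \eqn{x = \Phi(a)} that
#' carries the inhibition downstream. When the parameter already acts inside
#' the simplified subsystem (e.g. the downstream Michaelis constant of a
#' serial cascade), set `identity = TRUE`: the transfer function is then the
#' identity on the scale and no species is clamped for that inhibitor.
#'
#' @param target parameter path as in [perturbation()].
#' @param intermediate species whose steady-state level carries the
#'   inhibition (required unless `identity`).
#' @param identity logical; the parameter acts directly inside the
#'   simplified subsystem.
#' @export
target_mapping <- function(target, intermediate = NULL, identity = FALSE) {
  if (!identity && is.null(intermediate))
    stop("target_mapping: give an intermediate species or set identity = ",
         "TRUE", call. = FALSE)
  structure(list(target = target, intermediate = intermediate,
                 identity = identity),
            class = "target_mapping")
}

#' Default simplification mappings for the built-in motifs
#'
#' For the serial family, the upstream inhibitor (on `activation_B.km`)
#' maps to its product B_P, and the downstream one (on `activation_C.km`)
#' is an identity mapping because it already acts inside the retained C
#' cycle. For the parallel motif both inhibitors map to their branch
#' products B1_P and B2_P.
#'
#' @inheritParams motif_targets
#' @return list with `target_mapping`s `a` and `b`.
#' @export
motif_mappings <- function(motif = c("serial", "parallel",
                                     "negative_feedback")) {
  motif <- match.arg(motif)
  if (motif == "parallel") {
    list(a = target_mapping("activation_B1.km", "B1_P"),
         b = target_mapping("activation_B2.km", "B2_P"))
  } else {
    list(a = target_mapping("activation_B.km", "B_P"),
         b = target_mapping("activation_C.km", identity = TRUE))
  }
}

#' Evaluate the intermediate transfer function Phi
#'
#' Computes the steady-state level of a mapping's intermediate species with
#' the mapped parameter multiplied by `scale` (everything else at baseline),
#' together with the sign of \eqn{d\Phi/d(\mathrm{scale})} by central
#' difference. Identity mappings return the scale itself with slope +1.
#'
#' @param model a valid [network_model()].
#' @param mapping a [target_mapping()].
#' @param scale perturbation scale at which to evaluate.
#' @param settings a [sim_settings()].
#' @param h relative step for the derivative sign (and for [phi_fun()]'s
#'   slope estimates).
#' @return list with `level` and `derivative_sign` (+1, -1, or 0).
#' @export
phi_evaluate <- function(model, mapping, scale = 1,
                         settings = sim_settings(), h = 1e-3) {
  if (mapping$identity)
    return(list(level = scale, derivative_sign = 1))
  phi <- phi_fun(model, mapping, settings)
  level <- phi(scale)
  d <- phi(scale * (1 + h)) - phi(scale * (1 - h))
  tol <- 1e-10 * max(abs(level), 1)
  list(level = level,
       derivative_sign = if (abs(d) <= tol) 0 else sign(d))
}

# memoized steady-state level of the intermediate as a function of the
# parameter scale; warm-started like model_surface
phi_fun <- function(model, mapping, settings = sim_settings()) {
  if (mapping$identity) return(function(scale) scale)
  if (!mapping$intermediate %in% model$species$name)
    stop("intermediate '", mapping$intermediate,
         "' is not a declared species", call. = FALSE)
  resolve_path(model, mapping$target)
  cm <- compile_model(model)
  base_params <- cm$get_params()
  loc <- compiled_loc(model, cm, mapping$target)
  idx <- match(mapping$intermediate, cm$all_names)
  memo <- new.env(parent = emptyenv())
  warm <- new.env(parent = emptyenv())
  warm$y <- NULL
  function(scale) {
    key <- sprintf("%.17g", scale)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    p <- scale_param(base_params, loc, scale)
    cm$set_params(p$vmax, p$km, p$k, p$inputs)
    on.exit(cm$set_params(base_params$vmax, base_params$km, base_params$k,
                          base_params$inputs), add = TRUE)
    ss <- NULL
    if (!is.null(warm$y)) {
      ns <- ss_newton(cm, warm$y[cm$unknown])
      if (ns$ok) ss <- ns$y
    }
    if (is.null(ss)) {
      st <- settings
      st$readout_mode <- "steady_state"
      traj <- traj_from_cm(cm, st)
      if (!traj$steady_reached && !settings$polish)
        stop("system did not settle while evaluating the transfer ",
             "function; if it oscillates, use endpoint mode readouts ",
             "instead of the steady-state simplification", call. = FALSE)
      y <- unname(traj$endpoint[cm$free])
      if (settings$polish) {
        ns <- ss_newton(cm, y[cm$unknown])
        if (ns$ok) y <- ns$y else if (!traj$steady_reached)
          stop("system did not settle while evaluating the transfer ",
               "function; if it oscillates, use endpoint mode readouts ",
               "instead of the steady-state simplification", call. = FALSE)
      }
      ss <- y
    }
    warm$y <- ss
    val <- c(ss, cm$get_params()$inputs)[idx]
    memo[[key]] <- val
    val
  }
}

#' Clamp intermediates to build the simplified system
#'
#' Implements the structural simplification: each non-identity mapping's
#' intermediate species is removed from the dynamic system and clamped as a
#' constant input at its full-model baseline steady-state level
#' \eqn{x_0 = \Phi(1)}. All reactions producing or consuming a clamped
#' species (the upstream cycle, and any feedback edge onto it) are dropped,
#' as are species the retained subsystem no longer references. The result
#' carries a [response_surface()] over virtual-inhibitor scales: axis `a`
#' at `va` clamps the first intermediate at `va * x0` (or, for an identity
#' mapping, applies the actual parameter perturbation at scale `va`), and
#' likewise for axis `b`.
#'
#' @param model a valid [network_model()].
#' @param mapping_a,mapping_b [target_mapping()]s for the two inhibitors.
#' @param settings a [sim_settings()].
#' @return object of class `simplified_system` with fields `submodel`,
#'   `clamp_baselines`, `surface`, `mappings`, `baseline_output`.
#' @export
simplify_clamp <- function(model, mapping_a, mapping_b,
                           settings = sim_settings()) {
  v <- validate_model(model)
  if (length(v))
    stop("invalid model:\n  - ", paste(v, collapse = "\n  - "), call. = FALSE)
  mappings <- list(a = mapping_a, b = mapping_b)
  clamp_sp <- purrr::compact(purrr::map(mappings, function(m) {
    if (m$identity) NULL else m$intermediate
  }))
  if (!length(clamp_sp))
    stop("simplify_clamp: at least one mapping must clamp an intermediate",
         call. = FALSE)
  for (s in clamp_sp) {
    if (identical(s, model$output))
      stop("cannot clamp the output species '", s, "' itself", call. = FALSE)
    if (!s %in% model$species$name)
      stop("intermediate '", s, "' is not a declared species", call. = FALSE)
  }

  # baseline steady state of the full model fixes the clamp levels
  ss_full <- steady_state(model, settings)
  x0 <- stats::setNames(unname(ss_full[unlist(clamp_sp)]),
                        unlist(clamp_sp))
  baseline_output <- unname(ss_full[model$output])

  rx <- model$reactions
  drop_rx <- rx$substrate %in% unlist(clamp_sp) |
    rx$product %in% unlist(clamp_sp)
  rx_keep <- rx[!drop_rx, , drop = FALSE]

  referenced <- unique(stats::na.omit(c(rx_keep$substrate, rx_keep$product,
                                        rx_keep$modifier, model$output)))
  sp <- model$species
  sp_keep <- sp[sp$name %in% referenced & !sp$name %in% unlist(clamp_sp), ,
                drop = FALSE]
  # clamped pool partners lose their conservation bookkeeping
  sp_keep$pool_partner[sp_keep$pool_partner %in% unlist(clamp_sp)] <-
    NA_character_
  sp_keep$pool_total[is.na(sp_keep$pool_partner)] <- NA_real_
  inputs_keep <- model$inputs[names(model$inputs) %in% referenced]
  missing <- setdiff(referenced,
                     c(sp_keep$name, names(inputs_keep), unlist(clamp_sp)))
  if (length(missing))
    stop("retained subsystem still references removed species: ",
         paste(missing, collapse = ", "), call. = FALSE)

  submodel <- network_model(sp_keep, rx_keep, output = model$output,
                            inputs = c(inputs_keep, x0))
  v <- validate_model(submodel)
  if (length(v))
    stop("simplified submodel invalid:\n  - ",
         paste(v, collapse = "\n  - "), call. = FALSE)

  virtual_pert <- function(m) {
    if (m$identity) perturbation(m$target)
    else perturbation(paste0("input.", m$intermediate))
  }
  surface <- model_surface(submodel, virtual_pert(mapping_a),
                           virtual_pert(mapping_b), settings)
  rel_dev <- abs(surface$baseline - baseline_output) /
    max(abs(baseline_output), .Machine$double.eps)
  if (rel_dev > 1e-6)
    stop("simplified system baseline output deviates from the full model ",
         "by ", signif(rel_dev, 3), " relative; clamped levels are not a ",
         "steady state of the retained subsystem", call. = FALSE)

  structure(list(submodel = submodel, clamp_baselines = x0,
                 surface = surface, mappings = mappings,
                 baseline_output = baseline_output),
            class = "simplified_system")
}

#' @export
print.simplified_system <- function(x, ...) {
  cat("<simplified_system> clamped: ",
      paste0(names(x$clamp_baselines), " = ",
             signif(x$clamp_baselines, 6), collapse = ", "),
      "\n  retained species: ",
      paste(x$submodel$species$name, collapse = ", "),
      "\n  baseline output: ", signif(x$baseline_output, 8), "\n", sep = "")
  invisible(x)
}

#' Predict the sign of DS from the simplified system
#'
#' The fundamental simplification property: the derivative index of the
#' full system satisfies \eqn{sign(DS) = sign(\Phi') sign(\Psi') sign(DS')}
#' where \eqn{DS'} is the derivative index of the clamped subsystem and
#' \eqn{\Phi', \Psi'} are the slopes of the two transfer functions. For the
#' serial motif \eqn{\Phi' < 0} (a Km increase lowers the intermediate) and
#' \eqn{\Psi' = +1}, so the sign flips; for the parallel motif both slopes
#' are negative and the sign is preserved.
#'
#' @param ds_simplified a [ds_estimate()] or a bare DS' value.
#' @param phi_sign,psi_sign signs of the transfer-function slopes
#'   (+1 or -1; 0 gives an indeterminate prediction).
#' @return +1, -1, or NA (indeterminate).
#' @export
lemma1_sign <- function(ds_simplified, phi_sign, psi_sign) {
  ds <- if (inherits(ds_simplified, "ds_estimate"))
    ds_simplified$ds_value else ds_simplified
  s <- sign(ds) * sign(phi_sign) * sign(psi_sign)
  if (s == 0) NA_real_ else s
}

#' Verify the serial/parallel sign relation on a dose grid
#'
#' For every grid point this computes the derivative index DS on the
#' original system, the transfer levels and slopes of both mappings, the
#' index DS' of the clamped subsystem at the corresponding virtual scales,
#' and the synergy scores of both systems. It then reports how often the
#' declared motif's sign relation (opposite signs for serial, equal signs
#' for parallel) holds at determinate points, the quantitative
#' chain-rule prediction \eqn{DS = \Phi'\Psi' DS'} (slopes of the
#' normalized virtual scales), and how closely the original S curve is
#' recovered from the simplified system.
#'
#' @param model a motif-shaped [network_model()].
#' @param motif declared structure, `"serial"` or `"parallel"`.
#' @param grid a [perturbation_grid()]; defaults to the motif's competitive
#'   dose scales on its standard inhibitor slots.
#' @param settings a [sim_settings()].
#' @param mappings optional list of `target_mapping`s `a` and `b`
#'   (defaults to [motif_mappings()]).
#' @param form synergy-score form.
#' @param ds_steps fixed relative finite-difference step for the DS
#'   stencils (`NULL` for adaptive; fixed is faster on dense grids).
#' @param det_tol magnitudes below which a DS sign is treated as
#'   indeterminate.
#' @return object of class `corollary_report`; `tidy()` gives the per-point
#'   table, `glance()` the summary (sign agreement fraction, reconstruction
#'   deviations).
#' @export
corollary_check <- function(model, motif = c("serial", "parallel"),
                            grid = NULL, settings = sim_settings(),
                            mappings = NULL,
                            form = c("difference", "log"),
                            ds_steps = 1e-3, det_tol = 1e-10) {
  motif <- match.arg(motif)
  form <- match.arg(form)
  if (is.null(mappings)) mappings <- motif_mappings(motif)
  targets <- list(a = perturbation(mappings$a$target),
                  b = perturbation(mappings$b$target))
  if (is.null(grid))
    grid <- perturbation_grid(targets$a, targets$b, motif_dose_scales())

  surf_orig <- model_surface(model, targets$a, targets$b, settings)
  simp <- simplify_clamp(model, mappings$a, mappings$b, settings)
  phi_a <- phi_fun(model, mappings$a, settings)
  phi_b <- phi_fun(model, mappings$b, settings)
  x0_a <- phi_a(1)
  x0_b <- phi_b(1)

  h <- if (is.null(ds_steps)) NULL else ds_steps
  ds_at <- function(surface, a, b) {
    if (is.null(h)) ds_estimate(surface, c(a, b), form = form)$ds_value
    else ds_raw(surface, a, b, h * a, h * b, "four_point_s", form)
  }
  slope <- function(phi, s, x0) {
    d <- 1e-3 * s
    (phi(s + d) - phi(s - d)) / (2 * d) / x0
  }

  rows <- purrr::map(seq_along(grid$scales_a), function(i) {
    purrr::map(seq_along(grid$scales_b), function(j) {
      a <- grid$scales_a[i]; b <- grid$scales_b[j]
      va <- phi_a(a) / x0_a
      vb <- phi_b(b) / x0_b
      ga <- slope(phi_a, a, x0_a)
      gb <- slope(phi_b, b, x0_b)
      ds_o <- ds_at(surf_orig, a, b)
      ds_s <- ds_at(simp$surface, va, vb)
      s_o <- s_value_at(surf_orig, a, b, form)$s
      s_r <- s_value_at(simp$surface, va, vb, form)$s
      tibble::tibble(scale_a = a, scale_b = b, va = va, vb = vb,
                     phi_slope_a = ga, phi_slope_b = gb,
                     ds_original = ds_o, ds_simplified = ds_s,
                     ds_predicted = ga * gb * ds_s,
                     s_original = s_o, s_reconstructed = s_r)
    })
  })
  res <- dplyr::bind_rows(purrr::flatten(rows))

  relation <- if (motif == "serial") -1 else +1
  res$determinate <- abs(res$ds_original) > det_tol &
    abs(res$ds_simplified) > det_tol
  res$sign_match <- ifelse(
    res$determinate,
    sign(res$ds_original) == relation * sign(res$ds_simplified), NA)

  det <- res[which(res$determinate), , drop = FALSE]
  frac <- if (nrow(det)) mean(det$sign_match) else NA_real_
  recon_dev <- max(abs(res$s_reconstructed - res$s_original))
  big <- abs(res$s_original) > 10 * 1e-6
  rel_dev <- if (any(big))
    max(abs(res$s_reconstructed[big] - res$s_original[big]) /
          abs(res$s_original[big])) else NA_real_

  structure(res, class = c("corollary_report", class(res)),
            motif = motif, relation = relation, form = form,
            sign_agreement = frac, n_determinate = nrow(det),
            recon_max_abs_dev = recon_dev, recon_max_rel_dev = rel_dev,
            simplified = simp)
}

#' @export
tidy.corollary_report <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.corollary_report <- function(x, ...) {
  tibble::tibble(motif = attr(x, "motif"),
                 relation = if (attr(x, "relation") < 0) "opposite"
                 else "same",
                 n_points = nrow(x),
                 n_determinate = attr(x, "n_determinate"),
                 sign_agreement = attr(x, "sign_agreement"),
                 recon_max_abs_dev = attr(x, "recon_max_abs_dev"),
                 recon_max_rel_dev = attr(x, "recon_max_rel_dev"),
                 form = attr(x, "form"))
}

#' @export
print.corollary_report <- function(x, ...) {
  g <- glance.corollary_report(x)
  cat("<corollary_report> ", g$motif, " motif (expected ", g$relation,
      " signs)\n  sign agreement: ",
      format(100 * g$sign_agreement, digits = 4), "% of ",
      g$n_determinate, " determinate points\n",
      "  S reconstruction: max |dev| = ",
      format(g$recon_max_abs_dev, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Check whether a feedback loop preserves the combination effect
#'
#' Compares a base system with its feedback-augmented counterpart under the
#' same inhibitor perturbations. The feedback term's sign `g_sign` is
#' classified by evaluating the feedback reaction's net contribution to the
#' state species' rate along the feedback trajectory; the downstream
#' sensitivity `df_dx_sign` by finite-differencing the output species' rate
#' in the state variable at sampled trajectory states. The preservation
#' condition holds for negative feedback with positive downstream
#' sensitivity (case 1), or positive feedback with negative sensitivity
#' (case 2). Output domination (the feedback system's output never exceeds
#' the base system's on the shared time grid) is always verified
#' numerically, never assumed from the condition.
#'
#' @param base_model,feedback_model valid models differing only by the
#'   feedback reaction(s).
#' @param feedback_labels label(s) of the feedback reaction(s) in
#'   `feedback_model`.
#' @param state_species the species through which the feedback acts
#'   (defaults to the first feedback reaction's substrate).
#' @param perturbations optional perturbation list applied to both systems
#'   before comparison.
#' @param settings a [sim_settings()]; trajectories are compared in
#'   endpoint mode on a shared time grid.
#' @param n_samples trajectory sample points for the sign classification
#'   (>= 32).
#' @param compute_s also compare synergy scores of the two systems at the
#'   perturbation scales (requires exactly two perturbations).
#' @return object of class `feedback_report`.
#' @export
feedback_check <- function(base_model, feedback_model,
                           feedback_labels = "feedback_B",
                           state_species = NULL,
                           perturbations = list(),
                           settings = sim_settings(),
                           n_samples = 64, compute_s = FALSE) {
  for (m in list(base_model, feedback_model)) {
    v <- validate_model(m)
    if (length(v))
      stop("invalid model:\n  - ", paste(v, collapse = "\n  - "),
           call. = FALSE)
  }
  n_samples <- max(n_samples, 32)
  fb_rows <- feedback_model$reactions$label %in% feedback_labels
  if (!any(fb_rows))
    stop("feedback_model has no reaction labelled ",
         paste(feedback_labels, collapse = ", "), call. = FALSE)
  stripped <- feedback_model$reactions[!fb_rows, , drop = FALSE]
  same_rx <- isTRUE(all.equal(as.data.frame(stripped),
                              as.data.frame(base_model$reactions),
                              check.attributes = FALSE))
  same_sp <- isTRUE(all.equal(as.data.frame(feedback_model$species),
                              as.data.frame(base_model$species),
                              check.attributes = FALSE)) &&
    identical(feedback_model$inputs, base_model$inputs) &&
    identical(feedback_model$output, base_model$output)
  if (!same_rx || !same_sp)
    stop("models differ beyond the declared feedback reaction(s)",
         call. = FALSE)

  fb_rx <- feedback_model$reactions[fb_rows, , drop = FALSE]
  if (is.null(state_species)) {
    # the state variable is the feedback edge's endpoint that carries the
    # signal downstream: prefer the member acting as a modifier in the base
    # dynamics, falling back to the feedback substrate
    cand <- stats::na.omit(c(fb_rx$substrate[1], fb_rx$product[1]))
    hit <- cand[cand %in% stats::na.omit(base_model$reactions$modifier)]
    state_species <- if (length(hit)) hit[1] else fb_rx$substrate[1]
  }
  if (is.na(state_species) || !state_species %in%
      feedback_model$species$name)
    stop("state_species must be a declared species", call. = FALSE)

  if (length(perturbations)) {
    base_p <- apply_perturbations(base_model, perturbations)
    fb_p <- apply_perturbations(feedback_model, perturbations)
  } else {
    base_p <- base_model
    fb_p <- feedback_model
  }

  st <- settings
  st$readout_mode <- "endpoint"
  st$n_points <- max(settings$n_points, n_samples)
  traj_base <- simulate_model(base_p, st)
  traj_fb <- simulate_model(fb_p, st)

  # g: net contribution of the feedback reaction(s) to d[state]/dt
  cm_fb <- compile_model(fb_p)
  fb_idx <- which(fb_rows)
  sgn_to_state <- ifelse(fb_rx$substrate == state_species, -1,
                         ifelse(fb_rx$product == state_species, 1, 0))
  if (all(sgn_to_state == 0))
    stop("feedback reaction(s) do not touch state species '",
         state_species, "'", call. = FALSE)
  samp <- round(seq(1, nrow(traj_fb$concentrations),
                    length.out = min(n_samples,
                                     nrow(traj_fb$concentrations))))
  free_idx <- match(cm_fb$free, colnames(traj_fb$concentrations))
  g_vals <- vapply(samp, function(i) {
    y <- traj_fb$concentrations[i, free_idx]
    conc <- c(y, cm_fb$input_vals, 1)
    sum(sgn_to_state * cm_fb$rates(conc)[fb_idx])
  }, numeric(1))
  g_floor <- 10 * settings$atol
  g_act <- g_vals[abs(g_vals) > g_floor]
  g_sign <- if (!length(g_act)) "mixed"
  else if (all(g_act < 0)) "negative"
  else if (all(g_act > 0)) "positive"
  else "mixed"

  # df/dx: sensitivity of the output species' rate to the state variable,
  # evaluated with the base (feedback-free) dynamics along the trajectory
  cm_base <- compile_model(base_p)
  out_free <- match(base_p$output, cm_base$free)
  if (is.na(out_free))
    stop("output species is clamped; downstream sensitivity undefined",
         call. = FALSE)
  x_free <- match(state_species, cm_base$free)
  if (is.na(x_free))
    stop("state species is clamped in the base model", call. = FALSE)
  free_idx_b <- match(cm_base$free, colnames(traj_fb$concentrations))
  df_vals <- vapply(samp, function(i) {
    y <- traj_fb$concentrations[i, free_idx_b]
    dx <- 1e-6 * max(abs(y[x_free]), 1)
    yp <- y; yp[x_free] <- y[x_free] + dx
    ym <- y; ym[x_free] <- max(y[x_free] - dx, 0)
    (cm_base$rhs(yp)[out_free] - cm_base$rhs(ym)[out_free]) /
      (yp[x_free] - ym[x_free])
  }, numeric(1))
  df_floor <- 1e-12
  df_act <- df_vals[abs(df_vals) > df_floor]
  df_sign <- if (!length(df_act)) "mixed"
  else if (all(df_act > 0)) "positive"
  else if (all(df_act < 0)) "negative"
  else "mixed"

  condition_met <- (g_sign == "negative" && df_sign == "positive") ||
    (g_sign == "positive" && df_sign == "negative")

  # pointwise output domination on the shared grid
  out_nm <- base_p$output
  y_base <- traj_base$concentrations[, out_nm]
  y_fb <- traj_fb$concentrations[, out_nm]
  n <- min(length(y_base), length(y_fb))
  viol <- max(c(0, y_fb[seq_len(n)] - y_base[seq_len(n)]))
  domination_holds <- viol <= 10 * settings$atol

  s_cmp <- NULL
  if (compute_s && length(perturbations) == 2) {
    mk_surface <- function(m) model_surface(
      m, with_scale(perturbations[[1]], 1), with_scale(perturbations[[2]], 1),
      settings)
    sc <- c(perturbations[[1]]$scale, perturbations[[2]]$scale)
    s_cmp <- list(
      s_base = s_value_at(mk_surface(base_model), sc[1], sc[2],
                          "difference")$s,
      s_feedback = s_value_at(mk_surface(feedback_model), sc[1], sc[2],
                              "difference")$s)
  }

  structure(list(g_sign = g_sign, df_dx_sign = df_sign,
                 condition_met = condition_met,
                 domination_holds = domination_holds,
                 max_violation = viol,
                 state_species = state_species,
                 s_comparison = s_cmp,
                 n_samples = length(samp)),
            class = "feedback_report")
}

#' @export
print.feedback_report <- function(x, ...) {
  cat("<feedback_report> g: ", x$g_sign, ", df/dx: ", x$df_dx_sign,
      "\n  preservation condition met: ", x$condition_met,
      "\n  output domination holds: ", x$domination_holds,
      " (max violation ", format(x$max_violation, digits = 3), ")\n",
      sep = "")
  if (!is.null(x$s_comparison))
    cat("  S without feedback: ",
        format(x$s_comparison$s_base, digits = 6),
        "; with feedback: ",
        format(x$s_comparison$s_feedback, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.feedback_report <- function(x, ...) {
  tibble::tibble(g_sign = x$g_sign, df_dx_sign = x$df_dx_sign,
                 condition_met = x$condition_met,
                 domination_holds = x$domination_holds,
                 max_violation = x$max_violation,
                 state_species = x$state_species)
}
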