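#' Response surfaces
#'
#' A response surface is the contract shared by ODE models and closed-form
#' test functions: a deterministic map from a pair of perturbation scales
#' `(scale_a, scale_b)` to the system's output concentration, together with
#' the cached baseline output at `(1, 1)`. All synergy operations
#' ([survival_ratio()], [synergy_s()], [ds_estimate()], [scan_surface()])
#' are defined against this contract, so they apply unchanged to simulated
#' networks and to analytically known surfaces used as oracles.
#'
#' @param evaluate function of `(scale_a, scale_b)` returning the output
#'   concentration.
#' @param label optional description used in printing.
#' @return object of class `response_surface` with fields `evaluate` and
#'   `baseline`.
#' @export
response_surface <- function(evaluate, label = NULL) {
  stopifnot(is.function(evaluate))
  baseline <- evaluate(1, 1)
  if (!is.finite(baseline) || baseline <= 0)
    stop("response surface baseline output at (1, 1) must be positive; got ",
         baseline, call. = FALSE)
  structure(list(evaluate = evaluate, baseline = baseline, label = label),
            class = "response_surface")
}

#' @export
print.response_surface <- function(x, ...) {
  cat("<response_surface>",
      if (!is.null(x$label)) paste0(" ", x$label), "\n  baseline output: ",
      signif(x$baseline, 8), "\n", sep = "")
  invisible(x)
}

#' Response surface of a kinetic model under two inhibitors
#'
#' Builds the steady-state response surface of a network model: evaluating
#' at `(scale_a, scale_b)` applies the two parameter perturbations at those
#' scales, solves for the steady state, and reads out the output species.
#'
#' Evaluations are memoized and warm-started: after the baseline steady
#' state is found by integration, subsequent points are solved by damped
#' Newton from the most recent converged state (accepted only when the
#' iteration converges to a stable, non-negative state; otherwise the ODE is
#' re-integrated). This makes dense dose grids and finite-difference
#' stencils cheap without sacrificing the integration fallback.
#'
#' @param model a valid [network_model()].
#' @param pert_a,pert_b [perturbation()] templates for the two inhibitor
#'   slots (their scales are ignored; the surface supplies them).
#' @param settings a [sim_settings()].
#' @export
model_surface <- function(model, pert_a, pert_b, settings = sim_settings()) {
  v <- validate_model(model)
  if (length(v))
    stop("invalid model:\n  - ", paste(v, collapse = "\n  - "), call. = FALSE)
  # resolve once against the unperturbed model (errors early on bad paths)
  resolve_path(model, pert_a$target)
  resolve_path(model, pert_b$target)

  cm <- compile_model(model)
  base_params <- cm$get_params()
  loc_a <- compiled_loc(model, cm, pert_a$target)
  loc_b <- compiled_loc(model, cm, pert_b$target)
  out_idx <- match(model$output, cm$all_names)

  memo <- new.env(parent = emptyenv())
  warm <- new.env(parent = emptyenv())
  warm$y <- NULL

  eval_point <- function(scale_a, scale_b) {
    stopifnot(is.finite(scale_a), scale_a > 0,
              is.finite(scale_b), scale_b > 0)
    key <- paste(sprintf("%.17g", scale_a), sprintf("%.17g", scale_b))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    p <- base_params
    p <- scale_param(p, loc_a, scale_a)
    p <- scale_param(p, loc_b, scale_b)
    cm$set_params(p$vmax, p$km, p$k, p$inputs)
    on.exit(cm$set_params(base_params$vmax, base_params$km, base_params$k,
                          base_params$inputs), add = TRUE)
    ss <- NULL
    if (!is.null(warm$y)) {
      ns <- ss_newton(cm, warm$y[cm$unknown])
      if (ns$ok) ss <- ns$y
    }
    if (is.null(ss)) {
      full <- ss_solve(cm, settings)
      ss <- unname(full[cm$free])
    }
    warm$y <- ss
    conc <- c(ss, cm$get_params()$inputs)
    val <- conc[out_idx]
    if (val < -100 * settings$atol)
      stop("negative output at scales (", scale_a, ", ", scale_b, ")",
           call. = FALSE)
    val <- max(val, 0)
    memo[[key]] <- val
    val
  }
  response_surface(eval_point,
                   label = paste0("model:", model$output, " | a=",
                                  pert_a$target, ", b=", pert_b$target))
}

# location of a parameter inside the compiled parameter vectors
compiled_loc <- function(model, cm, target) {
  loc <- resolve_path(model, target)
  if (loc$type == "input") {
    list(vec = "inputs", idx = match(loc$name, cm$clamped))
  } else {
    list(vec = loc$field, idx = loc$row)
  }
}

scale_param <- function(p, loc, scale) {
  p[[loc$vec]][loc$idx] <- p[[loc$vec]][loc$idx] * scale
  p
}

#' Closed-form test surfaces
#'
#' `interaction_surface()` is the exponential interaction family
#' \eqn{r(a,b) = e^{-u-v-\gamma u v}} with \eqn{u = 1-a}, \eqn{v = 1-b}:
#' its log-form synergy score is exactly \eqn{-\gamma u v} and its log-form
#' derivative index DS is the constant \eqn{-\gamma}, making it the standard
#' analytic oracle for the finite-difference and quadrature code.
#' `separable_surface()` builds a Bliss-independent surface
#' \eqn{r(a,b) = f_a(a) f_b(b)} (normalized so the baseline survival is 1),
#' for which S and DS vanish identically.
#'
#' @param gamma interaction strength; negative values give antagonism.
#' @param baseline baseline output concentration at scales (1, 1).
#' @param f_a,f_b positive single-scale response functions.
#' @export
interaction_surface <- function(gamma, baseline = 1) {
  response_surface(function(a, b) {
    u <- 1 - a; v <- 1 - b
    baseline * exp(-u - v - gamma * u * v)
  }, label = sprintf("exp interaction, gamma = %g", gamma))
}

#' @rdname interaction_surface
#' @export
separable_surface <- function(f_a, f_b, baseline = 1) {
  fa1 <- f_a(1); fb1 <- f_b(1)
  stopifnot(fa1 > 0, fb1 > 0)
  response_surface(function(a, b) baseline * f_a(a) * f_b(b) / (fa1 * fb1),
                   label = "separable (Bliss-null)")
}
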