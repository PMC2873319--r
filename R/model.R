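#' Build a reaction-network kinetic model
#'
#' A `network_model` represents a signaling system as a set of species and
#' elementary rate processes. Activation/deactivation cycles follow
#' Michaelis-Menten kinetics \eqn{v = V_{max} [M] [S]/(K_m + [S])}, where the
#' optional modifier \eqn{[M]} is the upstream enzyme (factor 1 when absent).
#' Species listed in `inputs` are clamped: they are held at a constant
#' concentration and contribute no ODE, which is how upstream stimuli (the
#' receptor-level input R) and simplified-system virtual inhibitors are
#' represented.
#'
#' @param species data frame with columns `name`, `initial`, and optionally
#'   `pool_partner`/`pool_total` declaring a conserved inactive/active pair
#'   (the declaring row is the inactive form; `initial + partner initial`
#'   must equal `pool_total`).
#' @param reactions data frame of reaction records, typically built with
#'   [mm_activation()] and friends via `dplyr::bind_rows()`.
#' @param output name of the readout species (may be clamped).
#' @param inputs named numeric vector of clamped species concentrations.
#' @return An object of class `network_model`.
#' @seealso [validate_model()], [simulate_model()], [serial_motif()]
#' @export
network_model <- function(species, reactions, output, inputs = numeric()) {
  species <- tibble::as_tibble(species)
  if (!"pool_partner" %in% names(species)) species$pool_partner <- NA_character_
  if (!"pool_total" %in% names(species)) species$pool_total <- NA_real_
  reactions <- tibble::as_tibble(reactions)
  for (col in c("modifier", "substrate", "product")) {
    if (!col %in% names(reactions)) reactions[[col]] <- NA_character_
  }
  for (col in c("vmax", "km", "k")) {
    if (!col %in% names(reactions)) reactions[[col]] <- NA_real_
  }
  if (is.null(names(inputs))) names(inputs) <- character(length(inputs))
  structure(
    list(species = species, reactions = reactions,
         output = output, inputs = inputs),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model> ", nrow(x$species), " species, ",
      nrow(x$reactions), " reactions\n", sep = "")
  cat("  output: ", x$output, "\n", sep = "")
  if (length(x$inputs))
    cat("  clamped: ", paste0(names(x$inputs), "=", signif(x$inputs, 4),
                              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Species record helper
#'
#' @param name species identifier.
#' @param initial initial concentration (arbitrary units, >= 0).
#' @param pool_partner optional cycle partner (the active form); declares a
#'   conserved pool.
#' @param pool_total total amount of the conserved pair.
#' @export
species_spec <- function(name, initial, pool_partner = NA_character_,
                         pool_total = NA_real_) {
  tibble::tibble(name = name, initial = initial,
                 pool_partner = pool_partner, pool_total = pool_total)
}

reaction_row <- function(label, kind, substrate = NA_character_,
                         product = NA_character_, modifier = NA_character_,
                         vmax = NA_real_, km = NA_real_, k = NA_real_) {
  tibble::tibble(label = label, kind = kind, substrate = substrate,
                 product = product, modifier = modifier,
                 vmax = vmax, km = km, k = k)
}

#' Reaction record helpers
#'
#' One-row constructors for the five supported rate laws. `mm_activation()`
#' and `mm_deactivation()` are saturating conversions
#' \eqn{v = V_{max}[M][S]/(K_m+[S])} between a substrate and its product
#' (the two kinds are distinguished only for readability of model
#' definitions). `mass_action()` is \eqn{v = k[S][M]}, `zeroth_synthesis()`
#' produces at constant rate \eqn{k[M]}, and `first_degradation()` removes at
#' rate \eqn{k[S]}.
#'
#' @param label unique reaction label, used as the stem of perturbation
#'   target paths such as `"activation_B.km"`.
#' @param substrate,product,modifier species names; the modifier is optional.
#' @param vmax,km Michaelis-Menten parameters (both must be positive).
#' @param k rate constant for the non-saturating kinds.
#' @name reaction_helpers
#' @export
mm_activation <- function(label, substrate, product, modifier = NA_character_,
                          vmax, km) {
  reaction_row(label, "mm_activation", substrate, product, modifier,
               vmax = vmax, km = km)
}

#' @rdname reaction_helpers
#' @export
mm_deactivation <- function(label, substrate, product,
                            modifier = NA_character_, vmax, km) {
  reaction_row(label, "mm_deactivation", substrate, product, modifier,
               vmax = vmax, km = km)
}

#' @rdname reaction_helpers
#' @export
mass_action <- function(label, substrate, product, modifier = NA_character_,
                        k) {
  reaction_row(label, "mass_action", substrate, product, modifier, k = k)
}

#' @rdname reaction_helpers
#' @export
zeroth_synthesis <- function(label, product, modifier = NA_character_, k) {
  reaction_row(label, "zeroth_synthesis", product = product,
               modifier = modifier, k = k)
}

#' @rdname reaction_helpers
#' @export
first_degradation <- function(label, substrate, k) {
  reaction_row(label, "first_degradation", substrate = substrate, k = k)
}

MM_KINDS <- c("mm_activation", "mm_deactivation")
ALL_KINDS <- c(MM_KINDS, "mass_action", "zeroth_synthesis",
               "first_degradation")

#' Validate a network model
#'
#' Checks every structural invariant of the model and returns a character
#' vector of violations (empty when the model is well formed). Validation
#' never raises; callers that require a valid model should test
#' `length(validate_model(m)) == 0`.
#'
#' Checks include: non-negative initial concentrations, positive
#' Michaelis-Menten parameters, declared-or-clamped species references,
#' existence of the output species, unique reaction labels, consistency of
#' conserved pools at t = 0, and that pooled species only interconvert with
#' their partner (otherwise conservation would be silently broken).
#'
#' @param model a [network_model()].
#' @return character vector of violation messages.
#' @export
validate_model <- function(model) {
  v <- character()
  sp <- model$species
  rx <- model$reactions
  declared <- sp$name
  clamped <- names(model$inputs)
  known <- c(declared, clamped)

  if (anyDuplicated(declared))
    v <- c(v, paste0("duplicated species name: ",
                     paste(unique(declared[duplicated(declared)]),
                           collapse = ", ")))
  bad_init <- which(!is.finite(sp$initial) | sp$initial < 0)
  for (i in bad_init)
    v <- c(v, paste0("species '", sp$name[i],
                     "': initial_concentration must be >= 0"))

  # conserved pools
  for (i in seq_len(nrow(sp))) {
    if (is.na(sp$pool_partner[i])) next
    p <- sp$pool_partner[i]
    j <- match(p, declared)
    if (is.na(j)) {
      v <- c(v, paste0("species '", sp$name[i], "': pool partner '", p,
                       "' is not declared"))
      next
    }
    tot <- sp$pool_total[i]
    if (is.na(tot) || tot <= 0) {
      v <- c(v, paste0("species '", sp$name[i], "': pool_total must be > 0"))
    } else if (abs(sp$initial[i] + sp$initial[j] - tot) > 1e-9 * max(1, tot)) {
      v <- c(v, paste0("pool ", sp$name[i], "/", p,
                       ": initial concentrations do not sum to pool_total"))
    }
  }

  if (nrow(rx)) {
    if (anyDuplicated(rx$label))
      v <- c(v, paste0("duplicated reaction label: ",
                       paste(unique(rx$label[duplicated(rx$label)]),
                             collapse = ", ")))
    for (i in seq_len(nrow(rx))) {
      lab <- rx$label[i]
      kind <- rx$kind[i]
      if (!kind %in% ALL_KINDS) {
        v <- c(v, paste0("reaction '", lab, "': unknown kind '", kind, "'"))
        next
      }
      refs <- c(substrate = rx$substrate[i], product = rx$product[i],
                modifier = rx$modifier[i])
      for (role in names(refs)) {
        s <- refs[[role]]
        if (!is.na(s) && !s %in% known)
          v <- c(v, paste0("reaction '", lab, "': ", role, " '", s,
                           "' is neither declared nor clamped"))
      }
      if (kind %in% MM_KINDS) {
        # vmax = 0 is allowed so that null-feedback limits are expressible
        if (is.na(rx$vmax[i]) || rx$vmax[i] < 0)
          v <- c(v, paste0("reaction '", lab, "': vmax must be >= 0"))
        if (is.na(rx$km[i]) || rx$km[i] <= 0)
          v <- c(v, paste0("reaction '", lab, "': km must be > 0"))
        if (is.na(rx$substrate[i]) || is.na(rx$product[i]))
          v <- c(v, paste0("reaction '", lab,
                           "': MM kinds need substrate and product"))
      } else {
        if (is.na(rx$k[i]) || rx$k[i] < 0)
          v <- c(v, paste0("reaction '", lab, "': rate_constant must be >= 0"))
        if (kind == "zeroth_synthesis" && is.na(rx$product[i]))
          v <- c(v, paste0("reaction '", lab, "': needs a product"))
        if (kind == "first_degradation" && is.na(rx$substrate[i]))
          v <- c(v, paste0("reaction '", lab, "': needs a substrate"))
      }
      if (!is.na(rx$substrate[i]) && !is.na(rx$product[i]) &&
          rx$substrate[i] == rx$product[i])
        v <- c(v, paste0("reaction '", lab, "': substrate equals product"))
    }

    # pooled species must only interconvert within their pair
    pooled <- stats::na.omit(unique(c(
      sp$name[!is.na(sp$pool_partner)], sp$pool_partner)))
    partner_of <- c(
      stats::setNames(sp$pool_partner[!is.na(sp$pool_partner)],
                      sp$name[!is.na(sp$pool_partner)]),
      stats::setNames(sp$name[!is.na(sp$pool_partner)],
                      sp$pool_partner[!is.na(sp$pool_partner)]))
    for (i in seq_len(nrow(rx))) {
      s <- rx$substrate[i]; p <- rx$product[i]
      for (x in c(s, p)) {
        if (is.na(x) || !x %in% pooled || x %in% clamped) next
        other <- if (identical(x, s)) p else s
        if (is.na(other) || !identical(unname(partner_of[x]), other))
          v <- c(v, paste0("reaction '", rx$label[i], "': pooled species '",
                           x, "' converts outside its conserved pair"))
      }
    }
  }

  if (!model$output %in% known)
    v <- c(v, paste0("output species '", model$output,
                     "' is neither declared nor clamped"))
  for (nm in clamped) {
    if (nm %in% declared)
      v <- c(v, paste0("species '", nm, "' is both declared and clamped"))
    if (!is.finite(model$inputs[[nm]]) || model$inputs[[nm]] < 0)
      v <- c(v, paste0("clamped species '", nm, "' must be >= 0"))
  }
  v
}

#' Simulation settings
#'
#' @param t_end integration horizon (arbitrary time units; the model carries
#'   none).
#' @param readout_mode `"steady_state"` truncates the trajectory once the
#'   max-norm of the free-species derivatives falls below `steady_tolerance`;
#'   `"endpoint"` always integrates to `t_end`.
#' @param steady_tolerance derivative threshold for steady-state detection,
#'   in concentration per time unit.
#' @param rtol,atol solver tolerances passed to [deSolve::lsoda()]. Defaults
#'   are tight because the synergy derivative DS is a second difference of
#'   outputs and amplifies solver noise.
#' @param max_steps solver step cap per call.
#' @param n_points number of output grid points.
#' @param polish apply a damped-Newton polish to the integrated endpoint when
#'   solving for steady states, reducing the residual to near machine
#'   precision (see [steady_state()]).
#' @export
sim_settings <- function(t_end = 1e4,
                         readout_mode = c("steady_state", "endpoint"),
                         steady_tolerance = 1e-9,
                         rtol = 1e-8, atol = 1e-10,
                         max_steps = 1e5, n_points = 201,
                         polish = TRUE) {
  readout_mode <- match.arg(readout_mode)
  stopifnot(t_end > 0, steady_tolerance > 0, rtol > 0, atol > 0,
            max_steps > 0, n_points >= 2)
  structure(list(t_end = t_end, readout_mode = readout_mode,
                 steady_tolerance = steady_tolerance, rtol = rtol,
                 atol = atol, max_steps = max_steps, n_points = n_points,
                 polish = polish),
            class = "sim_settings")
}

# Compile a model into index vectors + a vectorized RHS closure.
# State layout: free species first (integration order), clamped inputs
# appended, then a sentinel 1.0 so that absent substrate/modifier references
# resolve to a neutral factor.
compile_model <- function(model) {
  sp <- model$species
  free <- sp$name
  clamped <- names(model$inputs)
  all_names <- c(free, clamped)
  nfree <- length(free)
  sentinel <- length(all_names) + 1L
  rx <- model$reactions
  nr <- nrow(rx)

  idx_of <- function(x) {
    i <- match(x, all_names)
    ifelse(is.na(i), sentinel, i)
  }
  si <- idx_of(rx$substrate)
  mi <- idx_of(rx$modifier)

  M <- matrix(0, nrow = nfree, ncol = nr)
  if (nr) {
    for (i in seq_len(nr)) {
      s <- match(rx$substrate[i], free)
      p <- match(rx$product[i], free)
      if (!is.na(s)) M[s, i] <- M[s, i] - 1
      if (!is.na(p)) M[p, i] <- M[p, i] + 1
    }
  }

  is_mm <- rx$kind %in% MM_KINDS
  is_ma <- rx$kind == "mass_action"
  is_zs <- rx$kind == "zeroth_synthesis"
  is_fd <- rx$kind == "first_degradation"
  vmax <- rx$vmax; km <- rx$km; k <- rx$k

  # conserved-pool reduction for Newton: eliminate the declaring (inactive)
  # member, keep the partner as the unknown
  dep <- integer(0); rep_ <- integer(0); tot <- numeric(0)
  for (i in seq_len(nrow(sp))) {
    if (is.na(sp$pool_partner[i])) next
    j <- match(sp$pool_partner[i], free)
    if (is.na(j)) next
    dep <- c(dep, i); rep_ <- c(rep_, j); tot <- c(tot, sp$pool_total[i])
  }
  unknown <- setdiff(seq_len(nfree), dep)

  input_vals <- unname(model$inputs)
  y0 <- stats::setNames(sp$initial, free)

  rates <- function(conc) {
    r <- numeric(nr)
    s <- conc[si]; m <- conc[mi]
    if (any(is_mm)) r[is_mm] <- vmax[is_mm] * m[is_mm] * s[is_mm] /
        (km[is_mm] + s[is_mm])
    if (any(is_ma)) r[is_ma] <- k[is_ma] * s[is_ma] * m[is_ma]
    if (any(is_zs)) r[is_zs] <- k[is_zs] * m[is_zs]
    if (any(is_fd)) r[is_fd] <- k[is_fd] * s[is_fd]
    r
  }
  rhs <- function(y) {
    if (nr == 0L) return(numeric(nfree))
    conc <- c(y, input_vals, 1)
    as.vector(M %*% rates(conc))
  }

  list(model = model, free = free, clamped = clamped, nfree = nfree,
       all_names = all_names, y0 = y0, input_vals = input_vals,
       rhs = rhs, rates = rates,
       vmax = vmax, km = km, k = k,
       dep = dep, rep_ = rep_, tot = tot, unknown = unknown,
       # mutable copies used by the perturbation fast path
       set_params = function(vmax2, km2, k2, inputs2) {
         vmax <<- vmax2; km <<- km2; k <<- k2; input_vals <<- inputs2
       },
       get_params = function() list(vmax = vmax, km = km, k = k,
                                    inputs = input_vals))
}

# fresh compiled copy with independently mutable parameters
cm_clone <- function(cm) compile_model(cm$model)

#' Simulate a model's time course
#'
#' Integrates the assembled ODE system with [deSolve::lsoda()]. In
#' `"steady_state"` mode the returned trajectory is truncated at the first
#' output point where the max-norm of the free-species derivatives falls
#' below `settings$steady_tolerance`.
#'
#' @param model a valid [network_model()].
#' @param settings a [sim_settings()] object.
#' @return An object of class `sm_trajectory` with fields `times`,
#'   `concentrations` (time-by-species matrix, clamped species included as
#'   constant columns), `steady_reached`, and `endpoint` (named vector at the
#'   readout point).
#' @export
simulate_model <- function(model, settings = sim_settings()) {
  v <- validate_model(model)
  if (length(v))
    stop("invalid model:\n  - ", paste(v, collapse = "\n  - "), call. = FALSE)
  cm <- compile_model(model)
  traj_from_cm(cm, settings)
}

traj_from_cm <- function(cm, settings, y0 = NULL) {
  if (is.null(y0)) y0 <- cm$y0
  times <- seq(0, settings$t_end, length.out = settings$n_points)
  if (cm$nfree == 0L) {
    conc <- matrix(rep(cm$input_vals, each = length(times)),
                   nrow = length(times),
                   dimnames = list(NULL, cm$clamped))
    return(new_trajectory(times, conc, TRUE, cm, settings))
  }
  func <- function(t, y, p) list(cm$rhs(y))
  # in steady-state mode the integration terminates at the root of
  # (derivative max-norm - tolerance), so degenerate tails (fully
  # converted pools with underflowing rates) are never integrated
  use_root <- settings$readout_mode == "steady_state"
  rootfunc <- function(t, y, p)
    max(abs(cm$rhs(y))) - settings$steady_tolerance
  out <- deSolve::lsoda(y = y0, times = times, func = func, parms = NULL,
                        rootfunc = if (use_root) rootfunc,
                        rtol = settings$rtol, atol = settings$atol,
                        maxsteps = settings$max_steps,
                        hmax = settings$t_end / (settings$n_points - 1))
  istate <- attr(out, "istate")[1]
  if (!is.null(istate) && istate < 0)
    stop("ODE integration failed (lsoda istate = ", istate,
         "); the system may be stiff beyond the step budget -- raise ",
         "max_steps or loosen tolerances", call. = FALSE)
  root_hit <- use_root && nrow(out) <= length(times) &&
    !is.null(attr(out, "troot")) && length(attr(out, "troot")) > 0
  if (nrow(out) < length(times) && !root_hit)
    stop("ODE integration stopped early at t = ", max(out[, 1]), call. = FALSE)

  times <- out[, 1]
  ymat <- out[, -1, drop = FALSE]
  colnames(ymat) <- cm$free
  steady <- FALSE
  keep <- nrow(ymat)
  if (root_hit) {
    steady <- TRUE
  } else {
    dnorm <- apply(ymat, 1, function(y) max(abs(cm$rhs(y))))
    if (settings$readout_mode == "steady_state") {
      hit <- which(dnorm < settings$steady_tolerance)
      if (length(hit)) {
        steady <- TRUE
        keep <- hit[1]
      }
    } else {
      steady <- dnorm[keep] < settings$steady_tolerance
    }
  }
  times <- times[seq_len(keep)]
  ymat <- ymat[seq_len(keep), , drop = FALSE]
  if (length(cm$clamped)) {
    clampmat <- matrix(rep(cm$input_vals, each = keep), nrow = keep,
                       dimnames = list(NULL, cm$clamped))
    ymat <- cbind(ymat, clampmat)
  }
  new_trajectory(times, ymat, steady, cm, settings)
}

new_trajectory <- function(times, conc, steady, cm, settings) {
  lo <- if (ncol(conc)) min(conc) else 0
  if (lo < -100 * settings$atol)
    stop("concentration dropped to ", signif(lo, 4),
         ", far below the solver's absolute tolerance; the model is ",
         "inconsistent rather than subject to roundoff", call. = FALSE)
  endpoint <- conc[nrow(conc), ]
  names(endpoint) <- colnames(conc)
  structure(list(times = times, concentrations = conc,
                 steady_reached = steady, endpoint = endpoint,
                 species = colnames(conc), atol = settings$atol),
            class = "sm_trajectory")
}

#' @export
print.sm_trajectory <- function(x, ...) {
  cat("<sm_trajectory> ", length(x$times), " points, t in [0, ",
      signif(max(x$times), 4), "], steady_reached = ", x$steady_reached,
      "\n", sep = "")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.sm_trajectory <- function(x, ...) {
  tibble::as_tibble(cbind(data.frame(time = x$times),
                          as.data.frame(x$concentrations)))
}

#' Read out the model output from a trajectory
#'
#' Returns the output-species concentration at the trajectory's readout
#' point (its endpoint, which is the detected steady state in steady-state
#' mode). Small negative excursions within solver roundoff are clipped to 0.
#'
#' @param trajectory an `sm_trajectory` from [simulate_model()].
#' @param model the model it was produced from.
#' @export
readout <- function(trajectory, model) {
  nm <- model$output
  if (!nm %in% names(trajectory$endpoint))
    stop("output species '", nm, "' not present in trajectory", call. = FALSE)
  val <- unname(trajectory$endpoint[[nm]])
  if (val < -100 * trajectory$atol)
    stop("output concentration ", signif(val, 4),
         " is negative beyond roundoff", call. = FALSE)
  max(val, 0)
}

# Damped Newton on pool-reduced coordinates. Returns list(y, ok, stable).
ss_newton <- function(cm, u0, tol = 1e-12, maxit = 60L) {
  unknown <- cm$unknown
  expand <- function(u) {
    y <- numeric(cm$nfree)
    y[unknown] <- u
    if (length(cm$dep)) y[cm$dep] <- cm$tot - y[cm$rep_]
    y
  }
  resid <- function(u) cm$rhs(expand(u))[unknown]
  n <- length(unknown)
  if (n == 0L) return(list(y = expand(numeric(0)), ok = TRUE, stable = TRUE))
  u <- u0
  f <- resid(u)
  J <- NULL
  for (it in seq_len(maxit)) {
    if (max(abs(f)) < tol) break
    J <- num_jacobian(resid, u, f)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(list(y = expand(u), ok = FALSE, stable = NA))
    lambda <- 1
    repeat {
      u_new <- u + lambda * step
      f_new <- tryCatch(resid(u_new), error = function(e) NULL)
      if (!is.null(f_new) && all(is.finite(f_new)) &&
          max(abs(f_new)) < max(abs(f)) * (1 - 1e-4 * lambda) + 1e-15) {
        u <- u_new; f <- f_new
        break
      }
      lambda <- lambda / 2
      if (lambda < 1e-6) return(list(y = expand(u), ok = FALSE, stable = NA))
    }
  }
  ok <- max(abs(f)) < tol
  y <- expand(u)
  # physical plausibility: concentrations non-negative, pools in range
  if (ok) {
    if (any(y < -1e-9)) ok <- FALSE
    if (length(cm$dep) && any(y[cm$dep] < -1e-9)) ok <- FALSE
  }
  stable <- NA
  if (ok) {
    if (is.null(J)) J <- num_jacobian(resid, u, f)
    ev <- tryCatch(eigen(J, only.values = TRUE)$values,
                   error = function(e) NULL)
    stable <- !is.null(ev) && all(Re(ev) < 1e-8)
  }
  list(y = y, ok = ok && isTRUE(stable), stable = stable)
}

num_jacobian <- function(fn, u, f0 = NULL) {
  n <- length(u)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-7 * max(1, abs(u[j]))
    up <- u; up[j] <- u[j] + h
    um <- u; um[j] <- u[j] - h
    J[, j] <- (fn(up) - fn(um)) / (2 * h)
  }
  J
}

#' Solve for a model's steady state
#'
#' Integrates the ODE system until the derivative norm falls below
#' `settings$steady_tolerance`, then (by default) polishes the endpoint with
#' a damped Newton iteration on pool-reduced coordinates, driving the
#' residual to near machine precision. The polish matters when steady-state
#' outputs are differenced, as in [ds_estimate()].
#'
#' @inheritParams simulate_model
#' @param guess optional named vector of free-species concentrations used as
#'   a warm start; when Newton converges from the guess to a stable
#'   non-negative state, integration is skipped entirely.
#' @return named concentration vector (free species and clamped inputs).
#' @export
steady_state <- function(model, settings = sim_settings(), guess = NULL) {
  v <- validate_model(model)
  if (length(v))
    stop("invalid model:\n  - ", paste(v, collapse = "\n  - "), call. = FALSE)
  cm <- compile_model(model)
  ss_solve(cm, settings, guess = guess)
}

ss_solve <- function(cm, settings, guess = NULL) {
  full <- function(y) stats::setNames(c(y, cm$input_vals),
                                      c(cm$free, cm$clamped))
  if (cm$nfree == 0L) return(full(numeric(0)))
  if (!is.null(guess)) {
    u0 <- guess[cm$free][cm$unknown]
    if (all(is.finite(u0))) {
      ns <- ss_newton(cm, unname(u0))
      if (ns$ok) return(full(ns$y))
    }
  }
  st <- settings
  st$readout_mode <- "steady_state"
  traj <- traj_from_cm(cm, st)
  y <- unname(traj$endpoint[cm$free])
  if (!traj$steady_reached && !settings$polish)
    warning("steady state not reached within t_end = ", settings$t_end)
  if (settings$polish) {
    ns <- ss_newton(cm, y[cm$unknown])
    if (ns$ok) return(full(ns$y))
    if (!traj$steady_reached)
      warning("steady state not reached within t_end and Newton polish ",
              "did not converge; returning integration endpoint")
  }
  full(y)
}

#' Write a trajectory to CSV
#'
#' @param trajectory an `sm_trajectory`.
#' @param path output file; columns are `time` followed by one column per
#'   species.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(as_tibble(trajectory)), path,
                   row.names = FALSE)
  invisible(path)
}

# max over time of |inactive + active - total|, for conservation checks
pool_deviation <- function(trajectory, model) {
  sp <- model$species
  dev <- 0
  for (i in seq_len(nrow(sp))) {
    if (is.na(sp$pool_partner[i])) next
    a <- sp$name[i]; b <- sp$pool_partner[i]
    if (!all(c(a, b) %in% colnames(trajectory$concentrations))) next
    s <- trajectory$concentrations[, a] + trajectory$concentrations[, b]
    dev <- max(dev, max(abs(s - sp$pool_total[i])))
  }
  dev
}
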