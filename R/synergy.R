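#' Survival ratio of a response surface
#'
#' The survival ratio \eqn{r(a, b)} is the fraction of the baseline output
#' that remains under inhibition: the output at perturbation scales
#' `(scale_a, scale_b)` divided by the output at `(1, 1)`. It plays the role
#' of the fractional-unaffected activity in the Bliss independence
#' criterion.
#'
#' @param surface a [response_surface()].
#' @param scale_a,scale_b perturbation scales (1 = baseline).
#' @export
survival_ratio <- function(surface, scale_a = 1, scale_b = 1) {
  val <- surface$evaluate(scale_a, scale_b)
  if (val < 0)
    stop("negative output at (", scale_a, ", ", scale_b,
         "): model integrity violated", call. = FALSE)
  val / surface$baseline
}

#' Bliss-expected combined survival
#'
#' Under Bliss independence two inhibitors acting through independent
#' mechanisms combine multiplicatively: the expected combined survival
#' ratio is the product of the single-inhibitor ratios.
#'
#' @param r_a,r_b single-inhibitor survival ratios (> 0).
#' @export
bliss_expected <- function(r_a, r_b) {
  if (any(!is.finite(c(r_a, r_b))) || any(c(r_a, r_b) <= 0))
    stop("survival ratios must be positive", call. = FALSE)
  r_a * r_b
}

#' Classify an interaction from its synergy score
#'
#' The Synergism Assessment Factor uses S = 0 as the critical point:
#' S below `-tol` is synergism (the combination suppresses the output more
#' than the Bliss product predicts), above `tol` antagonism, within the
#' tolerance additive. Note the direction: a stronger combined inhibition
#' means a lower combined survival ratio, hence a negative S.
#'
#' @param s_value numeric vector of S values.
#' @param tol additivity tolerance (>= 0).
#' @return character vector in `{"synergism", "additive", "antagonism"}`.
#' @export
classify_interaction <- function(s_value, tol = 1e-6) {
  stopifnot(tol >= 0)
  out <- rep("additive", length(s_value))
  out[s_value < -tol] <- "synergism"
  out[s_value > tol] <- "antagonism"
  out[is.na(s_value)] <- NA_character_
  out
}

surv_fun <- function(surface) {
  function(a, b) surface$evaluate(a, b) / surface$baseline
}

s_value_at <- function(surface, scale_a, scale_b, form) {
  r <- surv_fun(surface)
  r_ab <- r(scale_a, scale_b)
  r_a <- r(scale_a, 1)
  r_b <- r(1, scale_b)
  s <- if (form == "difference") {
    r_ab - r_a * r_b
  } else {
    if (any(c(r_ab, r_a, r_b) <= 0))
      stop("log-form synergy score needs strictly positive survival ratios",
           call. = FALSE)
    log(r_ab) - log(r_a * r_b)
  }
  list(s = s, r_ab = r_ab, r_a = r_a, r_b = r_b)
}

#' Synergism Assessment Factor S
#'
#' Compares the actual combined effect with the Bliss-expected product of
#' individual effects. In the default difference form
#' \deqn{S = r(a, b) - r(a, b_0)\, r(a_0, b),}
#' in the log form \eqn{S = \ln r(a,b) - \ln[r(a,b_0) r(a_0,b)]}. Both share
#' the critical point S = 0 and both vanish identically on Bliss-independent
#' (multiplicatively separable) surfaces; the form used is recorded in the
#' result.
#'
#' @inheritParams survival_ratio
#' @param form `"difference"` (default) or `"log"`.
#' @param tol additivity tolerance for the classification.
#' @return object of class `synergy_score`.
#' @export
synergy_s <- function(surface, scale_a, scale_b,
                      form = c("difference", "log"), tol = 1e-6) {
  form <- match.arg(form)
  parts <- s_value_at(surface, scale_a, scale_b, form)
  structure(list(s_value = parts$s, r_ab = parts$r_ab, r_a = parts$r_a,
                 r_b = parts$r_b, scale_a = scale_a, scale_b = scale_b,
                 classification = classify_interaction(parts$s, tol),
                 form = form, tol = tol),
            class = "synergy_score")
}

#' @export
print.synergy_score <- function(x, ...) {
  cat("<synergy_score> S = ", format(x$s_value, digits = 6), " (",
      x$classification, ", ", x$form, " form)\n", sep = "")
  cat("  scales (", signif(x$scale_a, 4), ", ", signif(x$scale_b, 4),
      "); r_ab = ", signif(x$r_ab, 6), ", r_a = ", signif(x$r_a, 6),
      ", r_b = ", signif(x$r_b, 6), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.synergy_score <- function(x, ...) {
  tibble::tibble(scale_a = x$scale_a, scale_b = x$scale_b,
                 r_ab = x$r_ab, r_a = x$r_a, r_b = x$r_b,
                 s_value = x$s_value, classification = x$classification,
                 form = x$form)
}

ds_raw <- function(surface, a, b, ha, hb, stencil, form) {
  if (stencil == "four_point_s") {
    S <- function(x, y) s_value_at(surface, x, y, form)$s
    (S(a + ha, b + hb) - S(a + ha, b - hb) -
       S(a - ha, b + hb) + S(a - ha, b - hb)) / (4 * ha * hb)
  } else {
    r <- surv_fun(surface)
    if (form == "difference") {
      term1 <- (r(a + ha, b + hb) - r(a + ha, b - hb) -
                  r(a - ha, b + hb) + r(a - ha, b - hb)) / (4 * ha * hb)
      dA <- (r(a + ha, 1) - r(a - ha, 1)) / (2 * ha)
      dB <- (r(1, b + hb) - r(1, b - hb)) / (2 * hb)
      term1 - dA * dB
    } else {
      lr <- function(x, y) log(r(x, y))
      (lr(a + ha, b + hb) - lr(a + ha, b - hb) -
         lr(a - ha, b + hb) + lr(a - ha, b - hb)) / (4 * ha * hb)
    }
  }
}

#' Synergism Assessment Factor Derivative DS
#'
#' DS is the second-order mixed partial derivative of the synergy score S
#' with respect to the two perturbation scales,
#' \eqn{DS = \partial^2 S / \partial a \partial b}. Its sign over a dose
#' rectangle is a sufficient condition on S at the rectangle's far corner
#' (see [s_from_ds()]): DS < 0 throughout guarantees synergy.
#'
#' Two stencils are provided. `"four_point_s"` applies the standard
#' four-point mixed central difference to S itself; `"two_term_r"`
#' differences the survival ratio, combining the mixed partial of
#' \eqn{r(a,b)} with the product of the single-axis first derivatives
#' (the two are algebraically identical for the difference form and agree
#' to roundoff, which is exercised as a cross-check in the test-suite).
#'
#' When `steps` is `NULL` the step starts at `1e-3` of each coordinate and
#' is halved until two successive estimates agree to `rel_tol` relative
#' (Richardson extrapolation of the final pair is returned), guarding the
#' estimate against both truncation error and solver noise; failure to
#' converge is flagged in the `reliable` field.
#'
#' @inheritParams survival_ratio
#' @param point numeric length-2, the `(scale_a, scale_b)` evaluation point.
#' @param steps numeric length-2 fixed steps `(h_a, h_b)`, or `NULL` for
#'   adaptive step control.
#' @param stencil finite-difference scheme, see Details.
#' @param form synergy-score form the derivative refers to.
#' @param rel_tol convergence tolerance for adaptive step control.
#' @param max_halvings maximum number of step halvings.
#' @return object of class `ds_estimate` with fields `ds_value`, `point`,
#'   `steps`, `stencil`, `form`, `reliable`.
#' @export
ds_estimate <- function(surface, point = c(1, 1), steps = NULL,
                        stencil = c("four_point_s", "two_term_r"),
                        form = c("difference", "log"),
                        rel_tol = 1e-3, max_halvings = 6) {
  stencil <- match.arg(stencil)
  form <- match.arg(form)
  a <- point[1]; b <- point[2]
  stopifnot(a > 0, b > 0)
  if (!is.null(steps)) {
    ha <- steps[1]; hb <- steps[2]
    if (ha <= 0 || hb <= 0 || a - ha <= 0 || b - hb <= 0)
      stop("steps must be positive and keep point - step inside the ",
           "admissible scale domain", call. = FALSE)
    val <- ds_raw(surface, a, b, ha, hb, stencil, form)
    return(new_ds_estimate(val, point, c(ha, hb), stencil, form,
                           reliable = TRUE))
  }
  ha <- 1e-3 * a; hb <- 1e-3 * b
  e1 <- ds_raw(surface, a, b, ha, hb, stencil, form)
  reliable <- FALSE
  val <- e1
  # below this magnitude an estimate is indistinguishable from a true zero
  # at double precision once divided by 4*ha*hb; halving would only amplify
  # the roundoff noise
  abs_floor <- 1e-9
  for (i in seq_len(max_halvings)) {
    e2 <- ds_raw(surface, a, b, ha / 2, hb / 2, stencil, form)
    if (abs(e1) < abs_floor && abs(e2) < abs_floor) {
      val <- e2
      reliable <- TRUE
      ha <- ha / 2; hb <- hb / 2
      break
    }
    if (abs(e1 - e2) <= rel_tol * abs(e2)) {
      val <- (4 * e2 - e1) / 3   # Richardson: cancel the O(h^2) term
      reliable <- TRUE
      ha <- ha / 2; hb <- hb / 2
      break
    }
    ha <- ha / 2; hb <- hb / 2
    e1 <- e2
    val <- e2
  }
  if (!reliable)
    warning("DS estimate did not converge under step halving; the output ",
            "differences may sit at the solver noise floor", call. = FALSE)
  new_ds_estimate(val, point, c(ha, hb), stencil, form, reliable)
}

new_ds_estimate <- function(val, point, steps, stencil, form, reliable) {
  structure(list(ds_value = val, point = point, steps = steps,
                 stencil = stencil, form = form, reliable = reliable),
            class = "ds_estimate")
}

#' @export
print.ds_estimate <- function(x, ...) {
  cat("<ds_estimate> DS = ", format(x$ds_value, digits = 6), " at (",
      signif(x$point[1], 4), ", ", signif(x$point[2], 4), ") [",
      x$stencil, ", ", x$form, " form",
      if (!x$reliable) ", UNRELIABLE", "]\n", sep = "")
  invisible(x)
}

#' @export
tidy.ds_estimate <- function(x, ...) {
  tibble::tibble(scale_a = x$point[1], scale_b = x$point[2],
                 ds_value = x$ds_value, h_a = x$steps[1], h_b = x$steps[2],
                 stencil = x$stencil, form = x$form, reliable = x$reliable)
}

#' Recover S by integrating DS over the dose rectangle
#'
#' Because S vanishes on both baseline edges, the synergy score at a target
#' dose pair equals the double integral of DS over the rectangle spanned by
#' the baseline `(1, 1)` and the target:
#' \deqn{S(a, b) = \int_{1}^{a}\!\!\int_{1}^{b} DS\, \mathrm{d}a'\,
#' \mathrm{d}b'.}
#' This function evaluates that integral by composite Simpson quadrature on
#' a tensor mesh of DS estimates and is the numerical embodiment of the
#' sufficient condition: DS < 0 over the rectangle forces S < 0 at its
#' corner. It converges to [synergy_s()] as the mesh is refined and serves
#' as an independent consistency oracle for the finite-difference code.
#'
#' @inheritParams ds_estimate
#' @param target numeric length-2 `(scale_a, scale_b)` corner of the dose
#'   rectangle; either component equal to 1 gives a degenerate rectangle
#'   and S = 0.
#' @param mesh number of quadrature intervals per axis (>= 4; rounded up to
#'   even).
#' @return the integrated S value (dimensionless scalar).
#' @export
s_from_ds <- function(surface, target, mesh = 32,
                      form = c("difference", "log"),
                      stencil = c("four_point_s", "two_term_r")) {
  form <- match.arg(form)
  stencil <- match.arg(stencil)
  ta <- target[1]; tb <- target[2]
  stopifnot(ta > 0, tb > 0, mesh >= 4)
  if (ta == 1 || tb == 1) return(0)
  n <- as.integer(mesh)
  if (n %% 2L == 1L) n <- n + 1L
  lim_a <- sort(c(1, ta)); lim_b <- sort(c(1, tb))
  xa <- seq(lim_a[1], lim_a[2], length.out = n + 1)
  xb <- seq(lim_b[1], lim_b[2], length.out = n + 1)
  wa <- simpson_weights(n) * (lim_a[2] - lim_a[1]) / n
  wb <- simpson_weights(n) * (lim_b[2] - lim_b[1]) / n
  acc <- 0
  for (i in seq_along(xa)) {
    for (j in seq_along(xb)) {
      h_a <- 1e-3 * xa[i]; h_b <- 1e-3 * xb[j]
      ds <- ds_raw(surface, xa[i], xb[j], h_a, h_b, stencil, form)
      acc <- acc + wa[i] * wb[j] * ds
    }
  }
  sign(ta - 1) * sign(tb - 1) * acc
}

simpson_weights <- function(n) {
  w <- rep(c(4, 2), length.out = n - 1)
  c(1, w, 1) / 3
}

#' Scan the synergy score over a dose grid
#'
#' Evaluates S (and optionally DS) at every point of a two-inhibitor scale
#' grid. Points where the underlying evaluation fails are recorded as
#' missing rather than aborting the scan; classification counts are over
#' successful points.
#'
#' @inheritParams synergy_s
#' @param grid a [perturbation_grid()] (only its scale sequences are used;
#'   the surface already fixes the targets).
#' @param compute_ds also estimate DS at every grid point (slower).
#' @return a `scan_result`: a tibble with columns `scale_a`, `scale_b`,
#'   `r_ab`, `r_a`, `r_b`, `s_value`, `classification` (and `ds_value` when
#'   requested), carrying the grid, form and verdict counts as attributes.
#' @export
scan_surface <- function(surface, grid, form = c("difference", "log"),
                         tol = 1e-6, compute_ds = FALSE) {
  form <- match.arg(form)
  pts <- tidyr::expand_grid(scale_a = grid$scales_a,
                            scale_b = grid$scales_b)
  rows <- purrr::pmap(pts, function(scale_a, scale_b) {
    parts <- tryCatch(s_value_at(surface, scale_a, scale_b, form),
                      error = function(e) NULL)
    if (is.null(parts))
      return(tibble::tibble(scale_a = scale_a, scale_b = scale_b,
                            r_ab = NA_real_, r_a = NA_real_, r_b = NA_real_,
                            s_value = NA_real_))
    tibble::tibble(scale_a = scale_a, scale_b = scale_b,
                   r_ab = parts$r_ab, r_a = parts$r_a, r_b = parts$r_b,
                   s_value = parts$s)
  })
  res <- dplyr::bind_rows(rows)
  res$classification <- classify_interaction(res$s_value, tol)
  if (compute_ds) {
    res$ds_value <- purrr::map2_dbl(res$scale_a, res$scale_b, function(a, b) {
      tryCatch(ds_estimate(surface, c(a, b), form = form)$ds_value,
               error = function(e) NA_real_)
    })
  }
  counts <- table(factor(res$classification,
                         levels = c("synergism", "additive", "antagonism")))
  structure(res, class = c("scan_result", class(res)),
            grid = grid, form = form, tol = tol,
            verdict_counts = as.list(counts))
}

#' @export
tidy.scan_result <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.scan_result <- function(x, ...) {
  vc <- attr(x, "verdict_counts")
  tibble::tibble(n_points = nrow(x), n_failed = sum(is.na(x$s_value)),
                 n_synergism = vc$synergism, n_additive = vc$additive,
                 n_antagonism = vc$antagonism, form = attr(x, "form"),
                 tol = attr(x, "tol"))
}

#' Matrix view of a scan's S surface
#'
#' @param scan a `scan_result`.
#' @return matrix of S values, rows indexed by `scale_a`, columns by
#'   `scale_b`.
#' @export
s_matrix <- function(scan) {
  grid <- attr(scan, "grid")
  m <- matrix(scan$s_value, nrow = length(grid$scales_a),
              ncol = length(grid$scales_b), byrow = TRUE)
  dimnames(m) <- list(signif(grid$scales_a, 6), signif(grid$scales_b, 6))
  m
}

#' Equal-dose synergy curve
#'
#' Evaluates S along the equal-dose diagonal `scale_a = scale_b = s`, the
#' one-dimensional summary used to compare motif structures.
#'
#' @inheritParams synergy_s
#' @param scales vector of positive scales to evaluate.
#' @return tibble with columns `scale`, `s_value`, `classification`.
#' @export
s_curve <- function(surface, scales, form = c("difference", "log"),
                    tol = 1e-6) {
  form <- match.arg(form)
  s <- purrr::map_dbl(scales, ~ s_value_at(surface, .x, .x, form)$s)
  tibble::tibble(scale = scales, s_value = s,
                 classification = classify_interaction(s, tol))
}
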