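#' Define an inhibitor as a parameter perturbation
#'
#' Inhibitor action is modeled as multiplicative scaling of a single kinetic
#' parameter: a scale of 1 is the baseline (uninhibited) value. Reducing a
#' velocity constant (`scale < 1`) mimics non-competitive inhibition of that
#' step; increasing a Michaelis constant (`scale > 1`) mimics competitive
#' inhibition, which is the convention the built-in motifs use for their
#' inhibitor slots.
#'
#' @param target parameter path `"<reaction-label>.<field>"` with field one
#'   of `vmax`, `km`, `k`, or `"input.<species>"` for a clamped input level.
#' @param scale positive dimensionless factor.
#' @return object of class `perturbation`.
#' @export
perturbation <- function(target, scale = 1) {
  stopifnot(is.character(target), length(target) == 1)
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) ||
      scale <= 0)
    stop("perturbation scale must be a positive number", call. = FALSE)
  structure(list(target = target, scale = scale, baseline = scale == 1),
            class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  cat("<perturbation> ", x$target, " x ", signif(x$scale, 6),
      if (x$baseline) " (baseline)", "\n", sep = "")
  invisible(x)
}

with_scale <- function(pert, scale) perturbation(pert$target, scale)

# -> list(type = "reaction", row, field) | list(type = "input", name)
resolve_path <- function(model, target) {
  parts <- strsplit(target, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("cannot resolve perturbation target '", target,
         "': expected '<label>.<field>' or 'input.<species>'", call. = FALSE)
  stem <- parts[1]; field <- parts[2]
  if (stem == "input") {
    if (!field %in% names(model$inputs))
      stop("perturbation target '", target, "': no clamped input named '",
           field, "'", call. = FALSE)
    return(list(type = "input", name = field))
  }
  row <- which(model$reactions$label == stem)
  if (length(row) == 0)
    stop("perturbation target '", target, "': no reaction labelled '",
         stem, "'", call. = FALSE)
  if (length(row) > 1)
    stop("perturbation target '", target, "': reaction label '", stem,
         "' is ambiguous", call. = FALSE)
  if (!field %in% c("vmax", "km", "k"))
    stop("perturbation target '", target, "': field must be vmax, km or k",
         call. = FALSE)
  if (is.na(model$reactions[[field]][row]))
    stop("perturbation target '", target, "': reaction '", stem,
         "' has no ", field, " parameter", call. = FALSE)
  list(type = "reaction", row = row, field = field)
}

#' Apply perturbations to a model
#'
#' Returns a new model in which each targeted parameter has been multiplied
#' by its perturbation's scale; the original model is never modified.
#' Multiple perturbations on the same parameter compose multiplicatively.
#'
#' @param model a [network_model()].
#' @param perturbations a single [perturbation()] or a list of them.
#' @export
apply_perturbations <- function(model, perturbations) {
  if (inherits(perturbations, "perturbation"))
    perturbations <- list(perturbations)
  out <- model
  for (p in perturbations) {
    loc <- resolve_path(out, p$target)
    if (loc$type == "input") {
      out$inputs[[loc$name]] <- out$inputs[[loc$name]] * p$scale
    } else {
      out$reactions[[loc$field]][loc$row] <-
        out$reactions[[loc$field]][loc$row] * p$scale
    }
  }
  out
}

#' Build a two-inhibitor dose grid in scale space
#'
#' `make_grid()` produces the descending log-spaced grids used for
#' velocity-constant inhibition scans, running from `hi` (default 0.9, a
#' mild dose) down to `lo` (default 1e-4, near-complete inhibition), which
#' covers about four orders of magnitude of residual activity.
#' `perturbation_grid()` accepts arbitrary positive scale sequences, e.g.
#' ascending Michaelis-constant fold increases for competitive inhibition.
#'
#' @param template_a,template_b [perturbation()] templates naming the two
#'   targets; their scales are ignored.
#' @param n grid length per axis (>= 2).
#' @param lo,hi endpoints of the log-spaced scan, `0 < lo < hi`.
#' @return object of class `perturbation_grid` with fields `pert_a`,
#'   `pert_b`, `scales_a`, `scales_b`.
#' @export
make_grid <- function(template_a, template_b, n, lo = 1e-4, hi = 0.9) {
  stopifnot(n >= 2)
  if (!is.finite(lo) || lo <= 0)
    stop("make_grid: lo must be > 0", call. = FALSE)
  if (lo >= hi) stop("make_grid: need lo < hi", call. = FALSE)
  scales <- exp(seq(log(hi), log(lo), length.out = n))
  perturbation_grid(template_a, template_b, scales, scales)
}

#' @rdname make_grid
#' @param scales_a,scales_b positive scale sequences for the two axes.
#' @export
perturbation_grid <- function(template_a, template_b, scales_a,
                              scales_b = scales_a) {
  stopifnot(inherits(template_a, "perturbation"),
            inherits(template_b, "perturbation"))
  for (s in list(scales_a, scales_b))
    if (!length(s) || any(!is.finite(s) | s <= 0))
      stop("grid scales must be positive and finite", call. = FALSE)
  structure(list(pert_a = template_a, pert_b = template_b,
                 scales_a = as.numeric(scales_a),
                 scales_b = as.numeric(scales_b)),
            class = "perturbation_grid")
}

#' @export
print.perturbation_grid <- function(x, ...) {
  cat("<perturbation_grid> ", length(x$scales_a), " x ",
      length(x$scales_b), "\n  a: ", x$pert_a$target, " in [",
      signif(min(x$scales_a), 4), ", ", signif(max(x$scales_a), 4),
      "]\n  b: ", x$pert_b$target, " in [", signif(min(x$scales_b), 4),
      ", ", signif(max(x$scales_b), 4), "]\n", sep = "")
  invisible(x)
}
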