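#' Motif parameter sets
#'
#' Parameters for the built-in activation/deactivation cycle motifs. Each
#' stage is a covalent-modification cycle with Michaelis-Menten activation
#' (driven by the upstream species) and deactivation. All units are
#' arbitrary; the defaults (totals 1, input 1, activation Vmax 1 / Km 0.5,
#' deactivation Vmax 0.5 / Km 0.5, feedback Vmax 1 / Km 0.5) are package
#' defaults chosen to put each cycle in a partially saturated regime, not
#' values tied to any particular measured pathway.
#'
#' @param total_up,total_down conserved totals of the upstream cycle(s)
#'   (B, or B1/B2) and the downstream cycle (C).
#' @param input_level clamped concentration of the input species
#'   (A, or A1/A2).
#' @param up_vmax,up_km activation parameters of the upstream stage(s); for
#'   the parallel motif a length-2 vector gives per-branch values.
#' @param up_deact_vmax,up_deact_km deactivation parameters of the upstream
#'   stage(s).
#' @param down_vmax,down_km activation parameters of the downstream (C)
#'   stage; for the parallel motif a length-2 vector gives the two
#'   convergent activation routes.
#' @param down_deact_vmax,down_deact_km deactivation parameters of the
#'   downstream stage.
#' @param fb_vmax,fb_km feedback deactivation parameters (negative-feedback
#'   motif only; `fb_km` is the Michaelis constant of the output-mediated
#'   B-P to B deactivation).
#' @export
motif_params <- function(total_up = 1, total_down = 1, input_level = 1,
                         up_vmax = 1, up_km = 0.5,
                         up_deact_vmax = 0.5, up_deact_km = 0.5,
                         down_vmax = 1, down_km = 0.5,
                         down_deact_vmax = 0.5, down_deact_km = 0.5,
                         fb_vmax = 1, fb_km = 0.5) {
  p <- list(total_up = total_up, total_down = total_down,
            input_level = input_level,
            up_vmax = up_vmax, up_km = up_km,
            up_deact_vmax = up_deact_vmax, up_deact_km = up_deact_km,
            down_vmax = down_vmax, down_km = down_km,
            down_deact_vmax = down_deact_vmax,
            down_deact_km = down_deact_km,
            fb_vmax = fb_vmax, fb_km = fb_km)
  for (nm in names(p)) {
    lo_ok <- if (nm == "fb_vmax") p[[nm]] >= 0 else p[[nm]] > 0
    if (any(!is.finite(p[[nm]])) || !all(lo_ok))
      stop("motif_params: '", nm, "' must be positive", call. = FALSE)
  }
  structure(p, class = "motif_params")
}

two <- function(x) rep_len(x, 2)

#' Built-in signaling motifs
#'
#' `serial_motif()` is the two-stage cascade: a clamped input A activates
#' the B cycle, activated B (B_P) drives the C cycle, and activated C (C_P)
#' is the output. `parallel_motif()` has two independent upstream cycles
#' (B1, B2) whose active forms both activate C through separate saturating
#' routes, so their contributions add (logic OR: either branch alone
#' sustains the output). `negative_feedback_motif()` augments the serial
#' cascade with an extra B_P deactivation mediated by the output C_P
#' (Michaelis constant `fb_km`), closing a negative loop from output to the
#' upstream cycle.
#'
#' Inhibitor slots follow the competitive convention: the Michaelis
#' constants of the activation steps (`activation_B.km` and
#' `activation_C.km` for the serial family; `activation_B1.km` and
#' `activation_B2.km` for the parallel motif) are scaled up by a dose
#' factor > 1.
#'
#' @param params a [motif_params()].
#' @return a valid [network_model()] with output `"C_P"`.
#' @name motifs
#' @export
serial_motif <- function(params = motif_params()) {
  p <- params
  species <- dplyr::bind_rows(
    species_spec("B", p$total_up, pool_partner = "B_P",
                 pool_total = p$total_up),
    species_spec("B_P", 0),
    species_spec("C", p$total_down, pool_partner = "C_P",
                 pool_total = p$total_down),
    species_spec("C_P", 0))
  reactions <- dplyr::bind_rows(
    mm_activation("activation_B", "B", "B_P", modifier = "A",
                  vmax = p$up_vmax[1], km = p$up_km[1]),
    mm_deactivation("deactivation_B", "B_P", "B",
                    vmax = p$up_deact_vmax[1], km = p$up_deact_km[1]),
    mm_activation("activation_C", "C", "C_P", modifier = "B_P",
                  vmax = p$down_vmax[1], km = p$down_km[1]),
    mm_deactivation("deactivation_C", "C_P", "C",
                    vmax = p$down_deact_vmax[1], km = p$down_deact_km[1]))
  network_model(species, reactions, output = "C_P",
                inputs = c(A = p$input_level[1]))
}

#' @rdname motifs
#' @export
parallel_motif <- function(params = motif_params()) {
  p <- params
  uv <- two(p$up_vmax); uk <- two(p$up_km)
  udv <- two(p$up_deact_vmax); udk <- two(p$up_deact_km)
  dv <- two(p$down_vmax); dk <- two(p$down_km)
  tu <- two(p$total_up); il <- two(p$input_level)
  species <- dplyr::bind_rows(
    species_spec("B1", tu[1], pool_partner = "B1_P", pool_total = tu[1]),
    species_spec("B1_P", 0),
    species_spec("B2", tu[2], pool_partner = "B2_P", pool_total = tu[2]),
    species_spec("B2_P", 0),
    species_spec("C", p$total_down, pool_partner = "C_P",
                 pool_total = p$total_down),
    species_spec("C_P", 0))
  reactions <- dplyr::bind_rows(
    mm_activation("activation_B1", "B1", "B1_P", modifier = "A1",
                  vmax = uv[1], km = uk[1]),
    mm_deactivation("deactivation_B1", "B1_P", "B1",
                    vmax = udv[1], km = udk[1]),
    mm_activation("activation_B2", "B2", "B2_P", modifier = "A2",
                  vmax = uv[2], km = uk[2]),
    mm_deactivation("deactivation_B2", "B2_P", "B2",
                    vmax = udv[2], km = udk[2]),
    mm_activation("activation_C_via_B1", "C", "C_P", modifier = "B1_P",
                  vmax = dv[1], km = dk[1]),
    mm_activation("activation_C_via_B2", "C", "C_P", modifier = "B2_P",
                  vmax = dv[2], km = dk[2]),
    mm_deactivation("deactivation_C", "C_P", "C",
                    vmax = p$down_deact_vmax[1], km = p$down_deact_km[1]))
  network_model(species, reactions, output = "C_P",
                inputs = c(A1 = il[1], A2 = il[2]))
}

#' @rdname motifs
#' @export
negative_feedback_motif <- function(params = motif_params()) {
  m <- serial_motif(params)
  fb <- mm_deactivation("feedback_B", "B_P", "B", modifier = "C_P",
                        vmax = params$fb_vmax[1], km = params$fb_km[1])
  m$reactions <- dplyr::bind_rows(m$reactions, fb)
  m
}

#' Default inhibitor slots of a built-in motif
#'
#' @param motif `"serial"`, `"parallel"` or `"negative_feedback"`.
#' @return list with [perturbation()] templates `a` and `b`.
#' @export
motif_targets <- function(motif = c("serial", "parallel",
                                    "negative_feedback")) {
  motif <- match.arg(motif)
  if (motif == "parallel") {
    list(a = perturbation("activation_B1.km"),
         b = perturbation("activation_B2.km"))
  } else {
    list(a = perturbation("activation_B.km"),
         b = perturbation("activation_C.km"))
  }
}

#' Default competitive dose scales for motif scans
#'
#' Log-spaced apparent-Km fold increases from 1.2 to 8, covering a
#' competitive inhibitor from about 0.2 to 7 times its inhibition constant
#' -- the moderate-inhibition window around the IC50 that dose-finding
#' experiments typically probe. With the package-default kinetics the
#' serial cascade's Bliss synergy is a moderate-dose phenomenon (at
#' near-saturating doses of both inhibitors its sign crosses to weak
#' antagonism), so this is also the window over which the motif family's
#' qualitative claims are stated; the structural sign relations checked by
#' [corollary_check()] hold at any dose.
#'
#' @param n number of doses.
#' @export
motif_dose_scales <- function(n = 8) 10^seq(log10(1.2), log10(8),
                                            length.out = n)

#' Serialize a model to the synmotif-model/1 JSON format
#'
#' One JSON document per model: a `schema` tag, a `species` array (`name`,
#' `initial`, optional `pool_partner`/`pool_total`), a `reactions` array
#' (`label`, `kind`, optional `substrate`/`product`/`modifier`, and the
#' rate parameters `vmax`/`km` or `k`), the `output` species name, and an
#' `inputs` object of clamped concentrations. Round-trips are exact: all
#' numbers are written at full precision.
#'
#' @param model a [network_model()].
#' @param path file to write; `NULL` returns the JSON string.
#' @export
save_model <- function(model, path = NULL) {
  sp <- purrr::pmap(model$species, function(name, initial, pool_partner,
                                            pool_total) {
    rec <- list(name = name, initial = initial)
    if (!is.na(pool_partner)) {
      rec$pool_partner <- pool_partner
      rec$pool_total <- pool_total
    }
    rec
  })
  rx <- purrr::pmap(model$reactions, function(label, kind, substrate,
                                              product, modifier, vmax, km,
                                              k) {
    rec <- list(label = label, kind = kind)
    if (!is.na(substrate)) rec$substrate <- substrate
    if (!is.na(product)) rec$product <- product
    if (!is.na(modifier)) rec$modifier <- modifier
    if (kind %in% MM_KINDS) {
      rec$vmax <- vmax; rec$km <- km
    } else {
      rec$k <- k
    }
    rec
  })
  doc <- list(schema = "synmotif-model/1", species = sp, reactions = rx,
              output = model$output,
              inputs = as.list(model$inputs))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

schema_stop <- function(path, msg) {
  stop("model document invalid at ", path, ": ", msg, call. = FALSE)
}

need_field <- function(rec, field, path, type = "character") {
  if (is.null(rec[[field]]))
    schema_stop(paste0(path, ".", field), "missing required field")
  val <- rec[[field]]
  if (type == "number" && (!is.numeric(val) || length(val) != 1))
    schema_stop(paste0(path, ".", field), "must be a number")
  if (type == "character" && (!is.character(val) || length(val) != 1))
    schema_stop(paste0(path, ".", field), "must be a string")
  val
}

#' Load a model from the synmotif-model/1 JSON format
#'
#' @param source path to a JSON file, or a JSON string.
#' @return a [network_model()].
#' @export
load_model <- function(source) {
  doc <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  if (!identical(doc$schema, "synmotif-model/1"))
    schema_stop("$.schema", "expected \"synmotif-model/1\"")
  if (is.null(doc$species) || !length(doc$species))
    schema_stop("$.species", "missing or empty")
  if (is.null(doc$reactions))
    schema_stop("$.reactions", "missing (use [] for none)")
  if (is.null(doc$output)) schema_stop("$.output", "missing required field")

  species <- dplyr::bind_rows(purrr::imap(doc$species, function(rec, i) {
    path <- sprintf("$.species[%d]", i - 1L)
    species_spec(
      need_field(rec, "name", path),
      as.numeric(need_field(rec, "initial", path, "number")),
      pool_partner = if (is.null(rec$pool_partner)) NA_character_ else
        need_field(rec, "pool_partner", path),
      pool_total = if (is.null(rec$pool_total)) NA_real_ else
        as.numeric(need_field(rec, "pool_total", path, "number")))
  }))
  reactions <- dplyr::bind_rows(purrr::imap(doc$reactions, function(rec, i) {
    path <- sprintf("$.reactions[%d]", i - 1L)
    kind <- need_field(rec, "kind", path)
    if (!kind %in% ALL_KINDS) schema_stop(paste0(path, ".kind"),
                                          paste0("unknown kind '", kind, "'"))
    opt <- function(f) if (is.null(rec[[f]])) NA_character_ else
      need_field(rec, f, path)
    if (kind %in% MM_KINDS) {
      reaction_row(need_field(rec, "label", path), kind,
                   substrate = opt("substrate"), product = opt("product"),
                   modifier = opt("modifier"),
                   vmax = as.numeric(need_field(rec, "vmax", path, "number")),
                   km = as.numeric(need_field(rec, "km", path, "number")))
    } else {
      reaction_row(need_field(rec, "label", path), kind,
                   substrate = opt("substrate"), product = opt("product"),
                   modifier = opt("modifier"),
                   k = as.numeric(need_field(rec, "k", path, "number")))
    }
  }))
  inputs <- numeric(0)
  if (!is.null(doc$inputs) && length(doc$inputs)) {
    inputs <- vapply(doc$inputs, function(x) {
      if (!is.numeric(x)) schema_stop("$.inputs", "values must be numbers")
      as.numeric(x)
    }, numeric(1))
  }
  m <- network_model(species, reactions,
                     output = need_field(doc, "output", "$"),
                     inputs = inputs)
  v <- validate_model(m)
  if (length(v))
    stop("model document loads but fails validation:\n  - ",
         paste(v, collapse = "\n  - "), call. = FALSE)
  m
}

#' Seeded random motif fixtures
#'
#' Draws a motif of the requested kind with parameters log-uniform within
#' the given ranges. Identical seeds give identical models; the caller's
#' RNG state is left untouched. Ranges collapsed to a point reproduce the
#' package-default motif exactly.
#'
#' @param kind motif family.
#' @param seed integer seed.
#' @param ranges named list of `c(lo, hi)` ranges (log-uniform sampling) for
#'   any subset of the [motif_params()] fields; see [motif_ranges()] for the
#'   defaults.
#' @return a valid [network_model()].
#' @export
random_motif <- function(kind = c("serial", "parallel", "negative_feedback"),
                         seed, ranges = motif_ranges()) {
  kind <- match.arg(kind)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  defaults <- motif_params()
  draw <- function(nm, n = 1) {
    rg <- ranges[[nm]]
    if (is.null(rg)) return(rep_len(unclass(defaults)[[nm]], n))
    if (length(rg) != 2 || any(rg <= 0) || rg[1] > rg[2])
      stop("random_motif: range for '", nm,
           "' must be positive c(lo, hi) with lo <= hi", call. = FALSE)
    if (rg[1] == rg[2]) return(rep_len(rg[1], n))  # collapsed: exact value
    exp(stats::runif(n, log(rg[1]), log(rg[2])))
  }
  nb <- if (kind == "parallel") 2 else 1
  params <- motif_params(
    total_up = draw("total_up", nb), total_down = draw("total_down"),
    input_level = draw("input_level", nb),
    up_vmax = draw("up_vmax", nb), up_km = draw("up_km", nb),
    up_deact_vmax = draw("up_deact_vmax", nb),
    up_deact_km = draw("up_deact_km", nb),
    down_vmax = draw("down_vmax", nb), down_km = draw("down_km", nb),
    down_deact_vmax = draw("down_deact_vmax"),
    down_deact_km = draw("down_deact_km"),
    fb_vmax = draw("fb_vmax"), fb_km = draw("fb_km"))
  switch(kind,
         serial = serial_motif(params),
         parallel = parallel_motif(params),
         negative_feedback = negative_feedback_motif(params))
}

#' @rdname random_motif
#' @export
motif_ranges <- function() {
  list(total_up = c(0.5, 2), total_down = c(0.5, 2),
       input_level = c(0.5, 2),
       up_vmax = c(0.5, 2), up_km = c(0.2, 1.5),
       up_deact_vmax = c(0.25, 1), up_deact_km = c(0.2, 1.5),
       down_vmax = c(0.5, 2), down_km = c(0.2, 1.5),
       down_deact_vmax = c(0.25, 1), down_deact_km = c(0.2, 1.5),
       fb_vmax = c(0.5, 2), fb_km = c(0.2, 1.5))
}

#' Fetch a built-in motif by name
#'
#' @param name motif name.
#' @param params optional [motif_params()].
#' @export
builtin_model <- function(name = c("serial", "parallel",
                                   "negative_feedback"),
                          params = motif_params()) {
  name <- match.arg(name)
  switch(name,
         serial = serial_motif(params),
         parallel = parallel_motif(params),
         negative_feedback = negative_feedback_motif(params))
}
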