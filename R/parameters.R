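#' Default parameter sets
#'
#' Bundled rate constants for the meiotic-entry subsystem
#' (`model = "meiosis"`) and for the integrated cell-cycle + meiosis model
#' (`model = "integrated"`). Time unit is minutes; concentrations are
#' dimensionless. The values are the package's own calibration, chosen so
#' that the simulated dynamics reproduce the qualitative behaviour of the
#' wild type and of the mutant panel in the strain registry (see the methods
#' vignette for the calibration rationale per module).
#'
#' @param model `"meiosis"` or `"integrated"`.
#' @return A `msw_params` object: a named list of nonnegative numeric values.
#' @examples
#' p <- default_parameters()
#' p[["k_imste11"]]
#' @export
default_parameters <- function(model = c("meiosis", "integrated")) {
  model <- match.arg(model)
  p <- .meiosis_defaults
  if (model == "integrated") p <- c(p, .cellcycle_defaults)
  new_parameter_set(p, model = model)
}

# --- Meiotic-entry subsystem -------------------------------------------------
# Ste11 shuttling/synthesis, Mei2 phospho-cycle, PheS / Mat1-Pm / Mei3 cascade,
# Pat1 partitioning. All first-order rates in 1/min.
.meiosis_defaults <- c(
  # Ste11 nucleo-cytoplasmic shuttling
  k_imste11   = 0.65,   # basal nuclear import rate
  k_exste11   = 0.957088,   # basal nuclear export rate
  b_imphe     = 6,   # PheS boost of import (per unit PheS)
  b_impat     = 12,   # import inhibition by active Pat1
  h_impat     = 2,      # cooperativity of the Pat1 import gate
  b_imnut     = 2,   # cooperative Tor2*PKA inhibition of import
  b_extor     = 0.9375,   # Tor2 boost of export
  imp_boost_fixed = 0,  # phospho-mimetic clamp of the PheS import boost
  pat_imp_clamp   = 0,  # phospho-mimetic clamp of the Pat1 import inhibition
  # Ste11 synthesis (Rst2 arm + autoregulation, both gated by Rpol)
  ks_ste11r   = 1.2,   # Rst2-driven synthesis
  ks_ste11a   = 0.8,   # autoregulatory (Ste11n Hill) synthesis
  ks_ste11_0  = 0.005,  # constitutive leak
  k_mste11    = 0.0513787,   # half-saturation of Ste11 autoregulation (on Ste11n)
  hs          = 4,      # Hill coefficient of Ste11 autoregulation
  ste11_act   = 1,    # DNA-binding competence of Ste11 (0 in T82D mimic)
  kd_ste11    = 0.1,   # Ste11 degradation (both pools)
  # Rst2 (algebraic, PKA-suppressed) and Rpol (algebraic, Mei2-activated)
  j_rst2      = 0.9,
  h_rst2      = 10,
  a_rpol      = 0.0535865,   # basal Pol II CTD activity
  k_rpol      = 0.75,   # Mei2-dependent (CTDK-I) amplitude; 0 in lsk1 null
  j_rpol      = 0.16,
  h_rpol      = 2,
  # Mei2 synthesis and phospho-cycle
  ks_mei2     = 0.0588991,  # Ste11n-driven synthesis (max)
  a_mei2      = 0.0731125,   # basal fraction of Mei2 synthesis
  j_smei2     = 0.12,
  h_smei2     = 1,
  ks_mei2_const = 0,    # promoter-replacement constitutive synthesis
  kp_pat      = 0.552197,   # Pat1 phosphorylation of Mei2 (kcat)
  kp_tor      = 0.02,   # Tor2 phosphorylation of Mei2 (kcat, per unit Tor2)
  j_pmei2     = 0.01,   # Km, small: zero-order regime
  kdp_mei2    = 0.0423233,   # dephosphorylation Vmax
  j_dpmei2    = 0.01,
  kd_mei2a    = 0.015,  # degradation of active (unphosphorylated) Mei2
  kd_mei2p    = 0.05,  # degradation scale of phosphorylated Mei2
  w_dmei2     = 0.2,   # basal weight of phospho-Mei2 degradation
  b_dpat      = 3.10105,    # Pat1-dependent destabilisation of phospho-Mei2
  b_dtor      = 0.5,    # Tor2-dependent destabilisation of phospho-Mei2
  # Pheromone signalling (lumped Byr2-Byr1-Spk1; driven by nuclear Ste11)
  k_sphe      = 0.25,
  j_phe       = 0.0625,
  h_phe       = 8,
  j_phemei2   = 0.05,   # Mei2 requirement for mounting pheromone signalling
  kd_phe      = 0.0964772,
  phes_clamp  = 0,      # >0: PheS held at this level (constitutive Byr2)
  # Mat1-Pm (higher activation threshold, on nuclear Ste11)
  k_spm       = 0.00433138,
  j_pm        = 1.1,
  h_pm        = 8,
  kd_pm       = 0.0128,
  # Mei3 and the stoichiometric Pat1:Mei3 complex
  k_smei3     = 0.018,
  kd_mei3     = 0.0245171,
  k_as        = 5,
  k_dis       = 0.0005,
  kd_cpx      = 0.0005,
  # Pat1
  pat1_t      = 1,
  j_iphe      = 0.785953,    # PheS level halving free-Pat1 activity
  # Cdk1 coupling of the Ste11 autoregulatory term (integrated model)
  c_cdkste11  = 1,
  j_cdkste11  = 0.3,
  cdk_inh_clamp = 0     # >0: Cdk1 inhibition clamped at this strength
)

# --- Cell-cycle chassis (Novak-Tyson-style fission yeast cycle) -------------
# plus the Ppk18-Igo1 -> PP2A:B55 starvation branch, the intracellular
# nitrogen pool and PheS->Rum1 coupling.
.cellcycle_defaults <- c(
  k1 = 0.03, k2p = 0.03, k2pp = 1.0, k2ppp = 0.1,
  k3p = 1.0, k3pp = 10.0, j3 = 0.01,
  k4p = 2.0, k4 = 35.0, j4 = 0.01,
  k5p = 0.005, k5pp = 0.3, j5 = 0.3, k6 = 0.1,
  k7 = 1.0, k8 = 0.25, j7 = 0.001, j8 = 0.001,
  k9 = 0.1, k10 = 0.04, j9 = 0.01, j10 = 0.01,
  k11 = 0.1, k12 = 0.01, k12p = 1.0, k12pp = 3.0, kdiss = 0.001,
  k13 = 0.1, k14 = 0.1,
  k15 = 1.4, k16p = 1.0, k16pp = 2.0, j15 = 0.01, j16 = 0.01,
  vawee = 0.25, viwee = 1.0, jawee = 0.01, jiwee = 0.01,
  va25 = 1.0, vi25 = 0.25, ja25 = 0.01, ji25 = 0.01,
  kweep = 0.15, kwepp = 1.3, k25p = 0.05, k25pp = 5.0,
  mu = 0.0042,
  # starvation machinery
  kfill_n = 0.5,    # refilling of the nitrogen pool under rich conditions
  kdn = 0.004,      # first-order depletion of the pool under starvation
  ki_igo = 0.2,     # Ppk18-driven Igo1 phosphorylation when Tor2/PKA drop
  kd_igo = 0.05,    # Igo1 dephosphorylation
  j_igo = 0.05,     # Igo1-P level halving PP2A:B55 activity
  c_pherum1 = 0.25,  # PheS protection of Rum1 from degradation
  c_b55g1 = 2.0,    # B55 loss boosts Cdk-substrate phosphorylation (Ste9/Rum1)
  # division event thresholds on Cdk1:Cdc13
  div_hi = 0.4,     # mitotic threshold that must be exceeded
  div_lo = 0.15     # exit threshold whose downward crossing divides the cell
)

.integrated_names <- function() c(names(.meiosis_defaults), names(.cellcycle_defaults))

#' Construct and validate a parameter set
#'
#' @param values Named numeric vector or list of parameter values.
#' @param model `"meiosis"` or `"integrated"`; decides the required name set.
#' @return `msw_params` object (named list with a `model` attribute).
#' @export
new_parameter_set <- function(values, model = c("meiosis", "integrated")) {
  model <- match.arg(model)
  values <- unlist(values)
  required <- if (model == "meiosis") names(.meiosis_defaults) else .integrated_names()
  validate_parameters(values, required)
  out <- as.list(values[required])
  structure(out, class = "msw_params", model = model)
}

validate_parameters <- function(values, required) {
  if (is.null(names(values)) || any(names(values) == "")) {
    stop("parameter values must be named")
  }
  missing <- setdiff(required, names(values))
  extra <- setdiff(names(values), required)
  if (length(missing) || length(extra)) {
    stop(
      "parameter set does not match the model's parameter list.\n",
      if (length(missing)) paste0("  missing: ", paste(missing, collapse = ", "), "\n"),
      if (length(extra)) paste0("  unknown: ", paste(extra, collapse = ", "))
    )
  }
  bad <- names(values)[!is.finite(values) | values < 0]
  if (length(bad)) stop("parameters must be finite and >= 0: ", paste(bad, collapse = ", "))
  if (values[["hs"]] < 1) stop("Hill coefficient `hs` must be >= 1")
  invisible(TRUE)
}

#' @export
print.msw_params <- function(x, ...) {
  cat("<msw_params> model =", attr(x, "model"), "-", length(x), "parameters\n")
  print(utils::head(round(unlist(x), 5), 12))
  if (length(x) > 12) cat("...\n")
  invisible(x)
}

#' Load a parameter set from a file
#'
#' Accepts an XPPAUT-style `.ode` file (only `par`/`p` lines are read;
#' equations and options are ignored; names are case-insensitive) or a flat
#' key-value YAML/JSON file. Missing or unknown names are reported with a
#' full diff against the model's parameter list.
#'
#' @param source Path to a `.ode`, `.yml`/`.yaml` or `.json` file.
#' @param model `"meiosis"` or `"integrated"`.
#' @return `msw_params` object.
#' @export
load_parameters <- function(source, model = c("meiosis", "integrated")) {
  model <- match.arg(model)
  if (!file.exists(source)) stop("parameter file not found: ", source)
  ext <- tolower(tools::file_ext(source))
  vals <- switch(ext,
    "ode" = parse_ode_parameters(source),
    "yml" = ,
    "yaml" = unlist(yaml::read_yaml(source)),
    "json" = unlist(jsonlite::read_json(source, simplifyVector = TRUE)),
    stop("unsupported parameter file type: .", ext)
  )
  names(vals) <- normalize_param_names(names(vals), model)
  new_parameter_set(vals, model = model)
}

# map case-insensitive / underscore-free aliases onto canonical names
normalize_param_names <- function(nm, model) {
  required <- if (model == "meiosis") names(.meiosis_defaults) else .integrated_names()
  canon <- stats::setNames(required, gsub("_", "", tolower(required)))
  key <- gsub("_", "", tolower(nm))
  ifelse(key %in% names(canon), canon[key], nm)
}

parse_ode_parameters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[[i]])
    ln <- trimws(ln)
    if (!grepl("^(par|p)\\s", ln, ignore.case = TRUE)) next
    body <- sub("^(par|p)\\s+", "", ln, ignore.case = TRUE)
    pieces <- strsplit(body, ",")[[1]]
    for (pc in pieces) {
      pc <- trimws(pc)
      if (pc == "") next
      kv <- strsplit(pc, "=")[[1]]
      if (length(kv) != 2) {
        stop(sprintf("cannot parse parameter assignment on line %d: '%s'", i, pc))
      }
      val <- suppressWarnings(as.numeric(trimws(kv[[2]])))
      if (is.na(val)) {
        stop(sprintf("non-numeric parameter value on line %d: '%s'", i, pc))
      }
      out[trimws(kv[[1]])] <- val
    }
  }
  if (!length(out)) stop("no 'par' lines found in ", path)
  out
}

#' Write a parameter set to an XPPAUT-style .ode parameter file
#'
#' Only `par` lines are written (one per parameter); the file round-trips
#' through [load_parameters()] exactly.
#'
#' @param params `msw_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "msw_params"))
  hdr <- c(
    "# parameter file (XPPAUT 'par' dialect); time unit: minutes,",
    sprintf("# concentrations dimensionless; model = %s", attr(params, "model"))
  )
  lines <- sprintf("par %s=%.17g", names(params), unlist(params))
  writeLines(c(hdr, lines, "done"), path)
  invisible(path)
}

#' Parameter and state-variable manifest
#'
#' Plain-text table of every parameter (and dynamical variable) of the chosen
#' model with its default value and role, for documentation and audit.
#'
#' @param model `"meiosis"` or `"integrated"`.
#' @return A tibble with columns `name`, `kind`, `value`.
#' @export
parameter_manifest <- function(model = c("meiosis", "integrated")) {
  model <- match.arg(model)
  p <- default_parameters(model)
  vars <- if (model == "meiosis") meiosis_state_names() else integrated_state_names()
  dplyr::bind_rows(
    tibble::tibble(name = vars, kind = "state", value = NA_real_),
    tibble::tibble(name = names(p), kind = "parameter", value = unname(unlist(p)))
  )
}
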