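#' Strain registry for the in-silico genotype screen
#'
#' One row per experimental situation analysed during model construction:
#' strain name, growth condition, mating system, the parameter/input
#' overrides encoding the genotype, and the expected mating/meiosis calls.
#' Deletion strains zero the relevant synthesis rate or total exactly;
#' overexpression alleles scale the relevant synthesis rate 10-fold;
#' phospho-site-dead (A) alleles zero the corresponding site-specific rate;
#' phospho-mimetic (D) alleles clamp the modified process at its
#' kinase-saturated value. Heterothallic strains run without a mating
#' partner, so Mei3 synthesis is disabled. Two promoter-replacement rows are
#' marked provisional (their exact expression level is a convention).
#'
#' Override grammar (semicolon-separated): `name=value` sets a parameter,
#' `name*=factor` scales it, and `tor2@=level` / `pka@=level` clamp a
#' nutrient input for the whole run.
#'
#' @return Tibble with columns `strain`, `condition`, `mating_system`,
#'   `overrides`, `expected_mating`, `expected_meiosis`, `scored`,
#'   `provisional`.
#' @export
genotype_registry <- function() {
  reg <- tibble::tribble(
    ~strain, ~condition, ~mating_system, ~overrides, ~expected_mating, ~expected_meiosis, ~scored, ~provisional,
    # homothallic, nitrogen rich
    "pka1D_cyr1D",          "rich",    "homothallic", "pka@=0",                                            "+", "+", TRUE, FALSE,
    "tor2_51",              "rich",    "homothallic", "tor2@=0",                                           "+", "+", TRUE, FALSE,
    "tor2_51_cgs1D",        "rich",    "homothallic", "tor2@=0;pka@=1.2",                                  "-", "-", TRUE, FALSE,
    "tor2_51_pka1D",        "rich",    "homothallic", "tor2@=0;pka@=0",                                    "+", "+", TRUE, FALSE,
    "ste11_OE",             "rich",    "homothallic", "ks_ste11r*=10;ks_ste11a*=10;ks_ste11_0*=10",        "+", "+", TRUE, FALSE,
    "ste11_T82A",           "rich",    "homothallic", "c_cdkste11=0",                                      "-", "-", TRUE, FALSE,
    "ste11_T173A_S218A",    "rich",    "homothallic", "ks_ste11a=0",                                         "-", "-", TRUE, FALSE,
    "ste11_T305D_T317D",    "rich",    "homothallic", "b_imphe=0;imp_boost_fixed=@phe_sat",                      "+", "+", TRUE, FALSE,
    "wild_type_LMB",        "rich",    "homothallic", "k_exste11=0",                                       "+", "+", TRUE, FALSE,
    "pat1_114_30C",         "rich",    "homothallic", "pat1_t=0.5",                                        "+", "+", TRUE, FALSE,
    "mts2D",                "rich",    "homothallic", "kd_mei2a*=0.1;kd_mei2p*=0.1;kd_ste11*=0.1",         "+", "+", TRUE, FALSE,
    "tor2_ts6_mei2D",       "rich",    "homothallic", "tor2@=0;ks_mei2=0",                                 "-", "-", TRUE, FALSE,
    "byr2_DN",              "rich",    "homothallic", "phes_clamp=@phe_hyper;j_iphe*=0.3",                                     "-", "+", TRUE, FALSE,
    "byr2_DN_mei3D",        "rich",    "homothallic", "phes_clamp=@phe_hyper;j_iphe*=0.3;k_smei3=0",                           "-", "+", TRUE, FALSE,
    "nmt_tor2",             "rich",    "homothallic", "tor2@=1;b_extor*=2;kp_tor*=3.5",                      "-", "-", TRUE, FALSE,
    "nmt_tor2_cyr1D",       "rich",    "homothallic", "tor2@=1;b_extor*=2;kp_tor*=3.5;pka@=0",               "+", "+", TRUE, FALSE,
    # homothallic, nitrogen starved
    "wild_type",            "starved", "homothallic", "",                                                  "+", "+", TRUE, FALSE,
    "rst2D",                "starved", "homothallic", "ks_ste11r=0",                                       "-", "-", TRUE, FALSE,
    "cgs1D",                "starved", "homothallic", "pka@=1.2",                                          "-", "-", TRUE, FALSE,
    "mei2D",                "starved", "homothallic", "ks_mei2=0",                                         "-", "-", TRUE, FALSE,
    "mei3D",                "starved", "homothallic", "k_smei3=0",                                         "+", "-", TRUE, FALSE,
    "mat1pmD",              "starved", "homothallic", "k_spm=0",                                           "-", "-", TRUE, FALSE,
    "spk1D",                "starved", "homothallic", "k_sphe=0",                                          "-", "-", TRUE, FALSE,
    "ste11D",               "starved", "homothallic", "ks_ste11r=0;ks_ste11a=0;ks_ste11_0=0",              "-", "-", TRUE, FALSE,
    "ste11_T173D_S218D",    "starved", "homothallic", "pat_imp_clamp=@pat_max",                                   "-", "-", TRUE, FALSE,
    "ste11_T305A_T317A",    "starved", "homothallic", "b_imphe=0",                                         "+", "+", TRUE, FALSE,
    "ste11_T82D",           "starved", "homothallic", "ste11_act=0",                                "-", "-", TRUE, FALSE,
    "lsk1D",                "starved", "homothallic", "k_rpol=0",                                          "-", "-", TRUE, FALSE,
    "nmt1_ste11_lsk1D",     "starved", "homothallic", "k_rpol=0;ks_ste11r*=10;ks_ste11a*=10;ks_ste11_0*=10", "+", "+", TRUE, FALSE,
    "mei2_8A",              "starved", "homothallic", "b_dtor=0;kp_tor=0",                                          "+", "+", TRUE, FALSE,
    "mei2_8A_SATA",         "starved", "homothallic", "b_dtor=0;kp_tor=0;kp_pat=0",                                 "-", "+", TRUE, FALSE,
    "tor2_s65",             "starved", "homothallic", "tor2@=1;b_extor*=3;kp_tor*=3.5;b_dtor*=3",          "-", "-", TRUE, FALSE,
    "tor2_s65_pREP41_mei2", "starved", "homothallic", "tor2@=1;b_extor*=3;kp_tor*=3.5;b_dtor*=3;ks_mei2_const=@mei2oe", "+", "+", TRUE, FALSE,
    # heterothallic, nitrogen rich (no partner: Mei3 synthesis disabled)
    "pat1_114_34C",         "rich",    "heterothallic", "pat1_t=0.001",                                    "-", "+", TRUE, FALSE,
    "mei2D_pat1_114_34C",   "rich",    "heterothallic", "pat1_t=0.001;ks_mei2=0",                          "-", "-", TRUE, FALSE,
    "nmt_tor2_pat1_114_34C","rich",    "heterothallic", "pat1_t=0.001;tor2@=1;b_extor*=2;kp_tor*=3.5",       "-", "-", TRUE, FALSE,
    "ste11D_pat1_114_34C",  "rich",    "heterothallic", "pat1_t=0.001;ks_ste11r=0;ks_ste11a=0;ks_ste11_0=0", "-", "-", TRUE, FALSE,
    "lsk1D_pat1_114_34C",   "rich",    "heterothallic", "pat1_t=0.001;k_rpol=0",                           "-", "-", TRUE, FALSE,
    "mei2_SATA",            "rich",    "heterothallic", "kp_pat=0",                                        "-", "+", TRUE, FALSE,
    "mei2_L_SATA",          "rich",    "heterothallic", "kp_pat=0",                                        "-", "+", TRUE, TRUE,
    "mei2_L_SATA_lsk1D",    "rich",    "heterothallic", "kp_pat=0;k_rpol=0",                               "-", "-", TRUE, TRUE,
    "pat1D_mei2D_nmt1_mei2","rich",    "heterothallic", "pat1_t=0.001;ks_mei2=0;ks_mei2_const=@mei2oe",       "-", "+", TRUE, TRUE,
    "mei2D_nmt1_mei2",      "rich",    "heterothallic", "ks_mei2=0;ks_mei2_const=@mei2oe",                    "-", "-", TRUE, FALSE,
    # no expected phenotype pair printed: excluded from concordance scoring
    "cyr1D_M_factor",       "other",   "heterothallic", "pka@=0;phes@=1",                                          NA,  NA,  FALSE, FALSE,
    # homothallic temperature-shift variant used by the fig2c protocol
    "pat1_114_34C_h90",     "rich",    "homothallic",  "pat1_t=0.001;k_smei3=0",                           NA,  NA,  FALSE, FALSE
  )
  reg
}

#' Apply a genotype's overrides to a parameter set
#'
#' Returns a new parameter set with the strain's overrides applied (the
#' original is unchanged; the wild type is the identity). Input clamps
#' (`tor2@=`, `pka@=`) are attached as the `"inputs"` attribute and are
#' consumed by [genotype_schedule()]. Heterothallic strains additionally get
#' `k_smei3 = 0` (no mating partner, no Mei3 synthesis).
#'
#' @param params Base `msw_params`.
#' @param genotype Strain name from [genotype_registry()], or a one-row
#'   registry-shaped data frame.
#' @return List with `params` (`msw_params`), `inputs` (named list of input
#'   clamps) and `spec` (the registry row).
#' @export
apply_genotype <- function(params, genotype) {
  spec <- resolve_genotype(genotype)
  p <- unlist(params)
  p_base <- p  # macros are conventions relative to the unmodified base set
  inputs <- list()
  ov <- parse_overrides(spec$overrides)
  if (spec$mating_system == "heterothallic") {
    ov <- c(ov, list(list(target = "k_smei3", mode = "set", value = 0)))
  }
  for (o in ov) {
    if (o$target %in% c("tor2", "pka", "phes")) {
      inputs[[o$target]] <- as.numeric(o$value)
      next
    }
    if (!o$target %in% names(p)) {
      stop("genotype '", spec$strain, "' overrides unknown parameter: ", o$target)
    }
    val <- resolve_macro(o$value, p_base)
    p[[o$target]] <- switch(o$mode,
      set = val,
      scale = p[[o$target]] * val,
      stop("unknown override mode: ", o$mode)
    )
  }
  list(params = new_parameter_set(p, model = attr(params, "model")),
       inputs = inputs, spec = spec)
}

resolve_genotype <- function(genotype) {
  if (is.character(genotype)) {
    reg <- genotype_registry()
    row <- reg[reg$strain == genotype, ]
    if (!nrow(row)) stop("unregistered strain: ", genotype)
    return(row)
  }
  stopifnot(is.data.frame(genotype), nrow(genotype) == 1)
  genotype
}

# conventions expressed relative to the base calibration: 10x promoter
# overexpression, saturated-kinase clamps, hyperactive pheromone signalling
resolve_macro <- function(value, p) {
  if (!is.na(suppressWarnings(as.numeric(value)))) return(as.numeric(value))
  switch(as.character(value),
    "@mei2oe" = 10 * p[["ks_mei2"]] * p[["a_mei2"]],
    "@phe_sat" = p[["b_imphe"]] * p[["k_sphe"]] / p[["kd_phe"]],
    "@pat_max" = 8 * p[["b_impat"]],
    "@phe_hyper" = 4 * p[["k_sphe"]] / p[["kd_phe"]],
    stop("unknown override macro: ", value)
  )
}

parse_overrides <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) return(list())
  pieces <- strsplit(txt, ";", fixed = TRUE)[[1]]
  lapply(trimws(pieces), function(pc) {
    if (grepl("@=", pc, fixed = TRUE)) {
      kv <- strsplit(pc, "@=", fixed = TRUE)[[1]]
      list(target = trimws(kv[[1]]), mode = "set", value = as.numeric(kv[[2]]))
    } else if (grepl("*=", pc, fixed = TRUE)) {
      kv <- strsplit(pc, "*=", fixed = TRUE)[[1]]
      list(target = trimws(kv[[1]]), mode = "scale", value = trimws(kv[[2]]))
    } else {
      kv <- strsplit(pc, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("cannot parse override: '", pc, "'")
      list(target = trimws(kv[[1]]), mode = "set", value = trimws(kv[[2]]))
    }
  })
}

#' Build the nutrient schedule for a genotype run
#'
#' Encodes the growth condition (rich, or starvation at `t_starve`) and then
#' applies any genotype input clamps (for example a temperature-sensitive
#' Tor2 allele clamps `tor2` at 0 regardless of medium).
#'
#' @param genotype Strain name or registry row.
#' @param base_condition `"rich"` or `"starved"` (defaults to the registry
#'   condition).
#' @param t_starve Starvation onset (min) when starved.
#' @return `msw_schedule`.
#' @export
genotype_schedule <- function(genotype, base_condition = NULL, t_starve = 0) {
  spec <- resolve_genotype(genotype)
  cond <- base_condition %||% spec$condition
  if (cond == "other") cond <- "rich"
  sched <- if (cond == "rich") rich_schedule() else starvation_schedule(t_starve)
  if (spec$mating_system == "heterothallic") sched$phes_enabled <- FALSE
  ov <- parse_overrides(spec$overrides)
  for (o in ov) {
    if (o$target %in% c("tor2", "pka")) sched[[o$target]] <- o$value
    if (o$target == "phes") sched$phes_enabled <- as.numeric(o$value) > 0
  }
  validate_schedule(sched)
  sched
}

#' Classify the mating/meiosis phenotype of a trajectory
#'
#' Meiosis is called positive when active Mei2 at the end of the run exceeds
#' `meiosis_frac` of the wild-type starved plateau. Mating is called
#' positive when both pheromone signalling (PheS) and Mat1-Pm peak above
#' `mating_frac` of their wild-type plateaus *before* the meiotic
#' commitment time (the first crossing of the active-Mei2 threshold):
#' conjugation must precede meiotic entry, so a strain that activates Mei2
#' prematurely is scored non-mating even though the cascade may fire later.
#'
#' @param trajectory `msw_trajectory` of the strain run.
#' @param reference Output of [starved_reference()] for the base parameters.
#' @param mating_frac,meiosis_frac Classification thresholds (defaults 0.5).
#' @return One-row tibble (`PhenotypeCall`): `mating`, `meiosis`, commitment
#'   time and the evidence fractions.
#' @export
classify_phenotype <- function(trajectory, reference,
                               mating_frac = 0.5, meiosis_frac = 0.5) {
  need <- c("phes", "mat1pm", "mei2_active", "mei3_t")
  if (!all(need %in% names(trajectory))) {
    stop("trajectory lacks required observables: ",
         paste(setdiff(need, names(trajectory)), collapse = ", "))
  }
  thr_mei2 <- meiosis_frac * reference[["mei2_active"]]
  t_commit <- first_crossing(trajectory$time, trajectory$mei2_active, thr_mei2)
  win <- trajectory$time <= t_commit
  peak_phes <- max(trajectory$phes[win], 0)
  peak_pm <- max(trajectory$mat1pm[win], 0)
  fin <- trajectory[nrow(trajectory), ]
  mating <- peak_phes >= mating_frac * reference[["phes"]] &&
    peak_pm >= mating_frac * reference[["mat1pm"]]
  meiosis <- fin$mei2_active >= thr_mei2
  tibble::tibble(
    mating = if (mating) "+" else "-",
    meiosis = if (meiosis) "+" else "-",
    t_commit = t_commit,
    peak_phes_frac = peak_phes / reference[["phes"]],
    peak_mat1pm_frac = peak_pm / reference[["mat1pm"]],
    final_mei3_frac = fin$mei3_t / reference[["mei3_t"]],
    final_mei2_active_frac = fin$mei2_active / reference[["mei2_active"]]
  )
}

#' Run the genotype screen
#'
#' Simulates every requested strain under its registry condition (starting
#' from the wild-type nutrient-rich resting state, as in a medium/temperature
#' shift experiment), classifies the mating/meiosis phenotype against the
#' wild-type starved reference, and tabulates concordance with the expected
#' calls. Unregistered strain names are reported in the `unmapped` attribute
#' rather than silently skipped.
#'
#' @param strains Character vector of strain names (default: every scored
#'   registry strain).
#' @param params Base meiosis `msw_params`.
#' @param horizon Simulation horizon per strain (min).
#' @param mating_frac,meiosis_frac Classification thresholds.
#' @return A `msw_screen` tibble: one row per strain with predicted and
#'   expected calls, a `match` flag and the evidence fractions. Attributes:
#'   `concordance` (fraction, NA for an empty screen), `unmapped`,
#'   `thresholds`.
#' @export
run_screen <- function(strains = NULL, params = default_parameters(),
                       horizon = 600, mating_frac = 0.5, meiosis_frac = 0.5) {
  reg <- genotype_registry()
  if (is.null(strains)) strains <- reg$strain[reg$scored]
  unmapped <- setdiff(strains, reg$strain)
  strains <- intersect(strains, reg$strain)
  ref <- starved_reference(params)
  init <- meiosis_rich_state(params)
  rows <- purrr::map_dfr(strains, function(s) {
    gp <- apply_genotype(params, s)
    sched <- genotype_schedule(gp$spec)
    tr <- simulate_meiosis(gp$params, sched, t_end = horizon, dt = 1, init = init)
    call <- classify_phenotype(tr, ref, mating_frac, meiosis_frac)
    exp_mat <- gp$spec$expected_mating
    exp_mei <- gp$spec$expected_meiosis
    dplyr::bind_cols(
      tibble::tibble(
        strain = s, condition = gp$spec$condition,
        mating_system = gp$spec$mating_system,
        expected_mating = exp_mat, expected_meiosis = exp_mei,
        scored = gp$spec$scored, provisional = gp$spec$provisional
      ),
      call
    )
  })
  if (nrow(rows)) {
    rows$match <- !is.na(rows$expected_mating) &
      rows$mating == rows$expected_mating &
      rows$meiosis == rows$expected_meiosis
    scored <- rows$scored & !is.na(rows$expected_mating)
    concordance <- if (any(scored)) mean(rows$match[scored]) else NA_real_
  } else {
    concordance <- NA_real_
  }
  tibble::new_tibble(
    rows,
    class = "msw_screen",
    concordance = concordance,
    unmapped = unmapped,
    thresholds = c(mating_frac = mating_frac, meiosis_frac = meiosis_frac)
  )
}

#' @export
print.msw_screen <- function(x, ...) {
  conc <- attr(x, "concordance")
  cat("<msw_screen>", nrow(x), "strains; concordance:",
      if (is.na(conc)) "n/a" else sprintf("%.1f%%", 100 * conc), "\n")
  um <- attr(x, "unmapped")
  if (length(um)) cat("unmapped:", paste(um, collapse = ", "), "\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
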