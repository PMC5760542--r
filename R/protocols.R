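#' Wild-type starved reference levels
#'
#' Simulates the wild-type starvation response (Tor2 = 0, PKA = 0.75 from
#' t = 0) for the given base parameter set and returns the plateau values of
#' the ordered observables (PheS, Mat1-Pm, total Mei3, active Mei2). These
#' plateaus anchor all half-maximum crossing thresholds and the phenotype
#' classification, so mutants are always scored against the wild-type
#' response of the same base calibration.
#'
#' @param params Base (wild-type) meiosis `msw_params`.
#' @param horizon Simulation horizon (min); the plateau is the final value.
#' @return Named numeric vector: `phes`, `mat1pm`, `mei3_t`, `mei2_active`,
#'   plus `pat1_t` (total Pat1 of the base set).
#' @export
starved_reference <- function(params, horizon = 600) {
  key <- digest_params(params, horizon)
  cached <- .msw_cache[[key]]
  if (!is.null(cached)) return(cached)
  tr <- simulate_meiosis(params, starvation_schedule(0), t_end = horizon, dt = 1)
  ref <- c(
    phes = tr$phes[[nrow(tr)]],
    mat1pm = tr$mat1pm[[nrow(tr)]],
    mei3_t = tr$mei3_t[[nrow(tr)]],
    mei2_active = tr$mei2_active[[nrow(tr)]],
    pat1_t = unlist(params)[["pat1_t"]]
  )
  .msw_cache[[key]] <- ref
  ref
}

.msw_cache <- new.env(parent = emptyenv())

digest_params <- function(params, extra = NULL) {
  paste(c(format(unlist(params), digits = 17), format(extra)), collapse = "|")
}

#' Half-maximum first-crossing times of the meiotic cascade
#'
#' Returns the first time each cascade observable (PheS, Mat1-Pm, total Mei3,
#' active Mei2) crosses half of its wild-type starved plateau. In the wild
#' type the four crossings are strictly increasing: pheromone signalling
#' precedes Mat1-Pm (which has the higher Ste11 activation threshold), which
#' precedes Mei3 and finally active Mei2. Observables that never cross are
#' reported as `Inf`.
#'
#' @param trajectory `msw_trajectory` from a starvation (or other) protocol.
#' @param reference Output of [starved_reference()]; if `NULL`, computed from
#'   the trajectory's own parameter set (appropriate only for wild type).
#' @return A tibble with columns `observable`, `threshold`, `crossing_time`.
#' @export
sequential_order_check <- function(trajectory, reference = NULL) {
  if (is.null(reference)) reference <- starved_reference(attr(trajectory, "params"))
  obs <- c("phes", "mat1pm", "mei3_t", "mei2_active")
  thr <- 0.5 * reference[obs]
  tibble::tibble(
    observable = obs,
    threshold = unname(thr),
    crossing_time = vapply(
      obs, function(v) first_crossing(trajectory$time, trajectory[[v]], thr[[v]]),
      numeric(1)
    )
  )
}

#' Return-to-growth (commitment) experiment
#'
#' Starves the subsystem at t = 0 (Tor2 = 0, PKA = 0.75), then at `t_readd`
#' restores rich inputs (Tor2 = 1, PKA = 1) and disables pheromone signalling
#' (`k_sphe = 0`), mimicking nitrogen re-addition after conjugation. The
#' outcome is classified at the horizon: irreversible if free Pat1 remains
#' below `pat1_frac` of total Pat1 while active Mei2 exceeds `mei2_frac` of
#' the wild-type committed plateau; reversible otherwise.
#'
#' @param t_readd Re-addition time (min after starvation onset).
#' @param params Base meiosis `msw_params`.
#' @param horizon Total simulated time (min), must exceed `t_readd`.
#' @param pat1_frac,mei2_frac Verdict thresholds (defaults 0.1 and 0.5).
#' @return A one-row tibble (`msw_reversal`): `t_readd`, `verdict`,
#'   `final_pat1_free`, `final_mei2_active`.
#' @export
run_return_to_growth <- function(t_readd, params = default_parameters(),
                                 horizon = 700, pat1_frac = 0.1,
                                 mei2_frac = 0.5) {
  if (t_readd >= horizon) stop("t_readd must be earlier than the horizon")
  if (t_readd <= 0) stop("t_readd must be after starvation onset (t = 0)")
  ref <- starved_reference(params)
  phase1 <- simulate_meiosis(params, starvation_schedule(0),
                             t_end = t_readd, dt = 0.5)
  y <- as.numeric(phase1[nrow(phase1), meiosis_state_names()])
  p2 <- unlist(params)
  p2[["k_sphe"]] <- 0
  params2 <- new_parameter_set(p2, model = attr(params, "model"))
  phase2 <- simulate_meiosis(params2, rich_schedule(),
                             t_end = horizon - t_readd, dt = 0.5, init = y)
  fin <- phase2[nrow(phase2), ]
  irrev <- fin$pat1_free < pat1_frac * ref[["pat1_t"]] &&
    fin$mei2_active > mei2_frac * ref[["mei2_active"]]
  tibble::new_tibble(
    tibble::tibble(
      t_readd = t_readd,
      verdict = if (irrev) "irreversible" else "reversible",
      final_pat1_free = fin$pat1_free,
      final_mei2_active = fin$mei2_active
    ),
    class = "msw_reversal"
  )
}

#' Locate the commitment window by bisection
#'
#' Finds the flip between reversible and irreversible return-to-growth
#' outcomes by bisecting the re-addition time. Returns the latest re-addition
#' time still classified reversible and the earliest classified irreversible,
#' at the requested resolution. If both bracket endpoints give the same
#' verdict the outcome is degenerate (`flip = NA`), not an error: a mutant
#' such as mei3-null never commits.
#'
#' @param params Base meiosis `msw_params`.
#' @param resolution Bisection resolution (min).
#' @param t_min,t_max Bracket for the re-addition time (min).
#' @param horizon Passed to [run_return_to_growth()].
#' @return One-row tibble: `t_reversible_max`, `t_irreversible_min`,
#'   `degenerate` flag and the common `verdict` when degenerate.
#' @export
commitment_window <- function(params = default_parameters(), resolution = 1,
                              t_min = 135, t_max = 150, horizon = 700) {
  if (resolution <= 0) stop("resolution must be > 0")
  verdict_at <- function(t) {
    run_return_to_growth(t, params, horizon = horizon)$verdict
  }
  v_lo <- verdict_at(t_min)
  v_hi <- verdict_at(t_max)
  if (v_lo == v_hi) {
    return(tibble::tibble(
      t_reversible_max = NA_real_, t_irreversible_min = NA_real_,
      degenerate = TRUE, verdict = v_lo
    ))
  }
  lo <- t_min; hi <- t_max
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (verdict_at(mid) == v_lo) lo <- mid else hi <- mid
  }
  tibble::tibble(
    t_reversible_max = lo, t_irreversible_min = hi,
    degenerate = FALSE, verdict = NA_character_
  )
}

# --- named figure protocols --------------------------------------------------

#' Registry of named in-silico protocols
#'
#' One protocol per simulated figure panel: the subsystem nutrient-shift
#' experiments (fig2a-fig2d), the return-to-growth pair (fig4a, fig4b), the
#' integrated-model cell-cycle runs (fig5a, fig5b) and the starvation
#' division-count runs (fig6a, fig6b). Each entry names the genotype, model,
#' schedule and horizon; [run_protocol()] executes one by name.
#'
#' @return Tibble with one row per protocol.
#' @export
protocol_registry <- function() {
  tibble::tribble(
    ~name,    ~model,        ~genotype,            ~t_starve, ~t_readd, ~horizon,
    "fig2a",  "meiosis",     "wild_type",                 50,       NA,      600,
    "fig2b",  "meiosis",     "mei3D",                     50,       NA,      600,
    "fig2c",  "meiosis",     "pat1_114_34C_h90",          NA,       NA,      600,
    "fig2d",  "meiosis",     "pat1_114_30C",              NA,       NA,      600,
    "fig4a",  "meiosis",     "wild_type",                  0,      135,      700,
    "fig4b",  "meiosis",     "wild_type",                  0,      150,      700,
    "fig5a",  "integrated",  "wild_type",                 NA,       NA,      600,
    "fig5b",  "integrated",  "ste11_T82A",                NA,       NA,      600,
    "fig6a",  "integrated",  "wild_type",                150,       NA,      700,
    "fig6b",  "integrated",  "wild_type",                135,       NA,      700
  )
}

#' Run a named protocol
#'
#' @param name Protocol name from [protocol_registry()].
#' @param params Base parameter set appropriate for the protocol's model
#'   (defaults to the bundled calibration).
#' @return For fig4 protocols a `msw_reversal`; otherwise a `msw_trajectory`.
#' @export
run_protocol <- function(name, params = NULL) {
  reg <- protocol_registry()
  row <- reg[reg$name == name, ]
  if (!nrow(row)) {
    stop("unknown protocol '", name, "'; see protocol_registry()")
  }
  model <- row$model
  if (is.null(params)) params <- default_parameters(model)
  if (!is.na(row$t_readd)) {
    return(run_return_to_growth(row$t_readd, params, horizon = row$horizon))
  }
  gp <- apply_genotype(params, row$genotype)
  sched <- genotype_schedule(row$genotype, base_condition =
                               if (is.na(row$t_starve)) "rich" else "starved",
                             t_starve = if (is.na(row$t_starve)) 0 else row$t_starve)
  if (model == "meiosis") {
    simulate_meiosis(gp$params, sched, t_end = row$horizon,
                     init = meiosis_rich_state(params))
  } else {
    simulate_integrated(gp$params, sched, t_end = row$horizon)
  }
}
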