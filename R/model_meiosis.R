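#' State-variable names of the meiotic-entry subsystem
#'
#' The subsystem tracks cytoplasmic and nuclear Ste11, the active
#' (dephosphorylated) and Pat1-phosphorylated Mei2 pools, the lumped
#' pheromone-signalling activity PheS, Mat1-Pm, free Mei3 and the Pat1:Mei3
#' inhibitory complex. Free Pat1 is algebraic (`pat1_t - cpx`), so Pat1 mass
#' conservation holds exactly; Rst2 and Rpol are algebraic functions of PKA
#' and of total Mei2 respectively.
#'
#' @return Character vector of state names.
#' @export
meiosis_state_names <- function() {
  c("ste11c", "ste11n", "mei2a", "mei2p", "phes", "mat1pm", "mei3", "cpx")
}

# core derivative computation shared by the subsystem and integrated models.
# y: named-order numeric state; p: named numeric parameters; mpf: Cdk1:Cdc13
# activity gating the Ste11 autoregulatory synthesis (0 in the subsystem).
meiosis_core <- function(y, p, tor2, pka, phes_enabled, mpf = 0) {
  ste11c <- y[[1]]; ste11n <- y[[2]]; mei2a <- y[[3]]; mei2p <- y[[4]]
  phes <- y[[5]]; mat1pm <- y[[6]]; mei3 <- y[[7]]; cpx <- y[[8]]

  clamped <- p[["phes_clamp"]] > 0
  tf <- p[["ste11_act"]] * ste11n  # transcriptionally competent nuclear Ste11
  phes_eff <- if (clamped) p[["phes_clamp"]] else phes
  mei2t <- mei2a + mei2p
  ste11t <- ste11c + ste11n

  pat_free <- max(p[["pat1_t"]] - cpx, 0)
  pat_act <- pat_free / (1 + phes_eff / p[["j_iphe"]])

  rst2 <- 1 / (1 + (pka / p[["j_rst2"]])^p[["h_rst2"]])
  rpol <- p[["a_rpol"]] +
    p[["k_rpol"]] * hill_activation(mei2t, p[["j_rpol"]], p[["h_rpol"]])

  # Cdk1 inhibition of Ste11 promoter binding (autoregulatory arm only)
  cdk_term <- if (p[["cdk_inh_clamp"]] > 0) p[["cdk_inh_clamp"]] else
    p[["c_cdkste11"]] * (mpf / p[["j_cdkste11"]])^2
  vcdk <- 1 / (1 + cdk_term)

  syn_ste11 <- p[["ks_ste11_0"]] + rpol * vcdk *
    (p[["ks_ste11r"]] * rst2 +
     p[["ks_ste11a"]] * hill_activation(tf, p[["k_mste11"]], p[["hs"]]))

  pat_imp <- if (p[["pat_imp_clamp"]] > 0) p[["pat_imp_clamp"]] else
    p[["b_impat"]] * pat_act^p[["h_impat"]]
  imp <- p[["k_imste11"]] *
    (1 + p[["b_imphe"]] * phes_eff + p[["imp_boost_fixed"]]) /
    (1 + pat_imp + p[["b_imnut"]] * tor2 * pka)
  expo <- p[["k_exste11"]] * (1 + p[["b_extor"]] * tor2)

  syn_mei2 <- p[["ks_mei2"]] *
    (p[["a_mei2"]] + hill_activation(tf, p[["j_smei2"]], p[["h_smei2"]])) +
    p[["ks_mei2_const"]]
  vp <- (p[["kp_pat"]] * pat_act + p[["kp_tor"]] * tor2) *
    mei2a / (p[["j_pmei2"]] + mei2a)
  vdp <- p[["kdp_mei2"]] * mei2p / (p[["j_dpmei2"]] + mei2p)
  deg_p <- p[["kd_mei2p"]] *
    (p[["w_dmei2"]] + p[["b_dpat"]] * pat_act + p[["b_dtor"]] * tor2)

  dste11c <- syn_ste11 - imp * ste11c + expo * ste11n - p[["kd_ste11"]] * ste11c
  dste11n <- imp * ste11c - expo * ste11n - p[["kd_ste11"]] * ste11n
  dmei2a <- syn_mei2 - vp + vdp - p[["kd_mei2a"]] * mei2a
  dmei2p <- vp - vdp - deg_p * mei2p
  dphes <- if (clamped) 0 else {
    (if (phes_enabled) p[["k_sphe"]] else 0) *
      hill_activation(tf, p[["j_phe"]], p[["h_phe"]]) *
      hill_activation(mei2t + 1e-12, p[["j_phemei2"]], 2) -
      p[["kd_phe"]] * phes
  }
  dmat1pm <- p[["k_spm"]] * hill_activation(tf, p[["j_pm"]], p[["h_pm"]]) -
    p[["kd_pm"]] * mat1pm
  assoc <- p[["k_as"]] * mei3 * pat_free
  dmei3 <- p[["k_smei3"]] * mat1pm - p[["kd_mei3"]] * mei3 - assoc +
    p[["k_dis"]] * cpx
  dcpx <- assoc - p[["k_dis"]] * cpx - p[["kd_cpx"]] * cpx

  list(
    deriv = c(dste11c, dste11n, dmei2a, dmei2p, dphes, dmat1pm, dmei3, dcpx),
    obs = c(ste11_t = ste11t, mei2_t = mei2t, mei2_active = mei2a,
            mei3_t = mei3 + cpx, pat1_free = pat_free, pat1_activity = pat_act,
            rst2 = rst2, rpol = rpol, phes_eff = phes_eff)
  )
}

#' Right-hand side of the Ste11-Mei2-Pat1 subsystem ODEs
#'
#' Assembles d(state)/dt from Hill-type synthesis terms, the
#' Michaelis-Menten Mei2 phospho-cycle, mass-action Pat1:Mei3 complex
#' formation, and the nutrient inputs in force at time `t`.
#'
#' @param t Time (minutes).
#' @param state Named (or ordered per [meiosis_state_names()]) numeric state.
#' @param params `msw_params` for the meiosis model (or a named vector).
#' @param schedule `msw_schedule` of nutrient inputs.
#' @return Numeric derivative vector, in state order.
#' @export
meiosis_rhs <- function(t, state, params, schedule) {
  if (length(state) != 8L) {
    stop("meiosis_rhs: state must have the 8 subsystem components")
  }
  p <- unlist(params)
  u <- inputs_at(schedule, t)
  meiosis_core(as.numeric(state), p, u$tor2, u$pka, u$phes_enabled)$deriv
}

# piecewise integration restarting at schedule breakpoints, using the
# compiled subsystem right-hand side
integrate_piecewise <- function(y0, times, p, schedule,
                                rtol = 1e-8, atol = 1e-10) {
  brks <- schedule$time[schedule$time > times[1] & schedule$time < times[length(times)]]
  segs <- sort(unique(c(times[1], brks, times[length(times)])))
  out <- NULL
  y <- y0
  for (k in seq_len(length(segs) - 1)) {
    t0 <- segs[[k]]; t1 <- segs[[k + 1]]
    u <- inputs_at(schedule, t0)
    tt <- sort(unique(c(t0, times[times > t0 & times < t1], t1)))
    seg <- deSolve::lsoda(
      y, tt, func = "derivs_meiosis", dllname = "meioswitch",
      initfunc = "init_meiosis",
      parms = c(p, u$tor2, u$pka, as.numeric(u$phes_enabled), 0),
      rtol = rtol, atol = atol, maxsteps = 50000
    )
    y <- as.numeric(seg[nrow(seg), -1])
    out <- if (is.null(out)) seg else rbind(out[-nrow(out), , drop = FALSE], seg)
  }
  out
}

#' Simulate the Ste11-Mei2-Pat1 subsystem
#'
#' Integrates the subsystem with a stiff solver, restarting at every
#' schedule breakpoint (input steps are not smoothed). The default initial
#' condition is the nutrient-rich steady state found by damped Newton
#' iteration, so a simulation whose schedule starts rich shows the resting
#' mitotic state before any shift.
#'
#' @param params Meiosis `msw_params` (default [default_parameters()]).
#' @param schedule `msw_schedule` (default: starvation at t = 50 min).
#' @param t_end Horizon (minutes).
#' @param dt Output grid spacing (minutes).
#' @param init Optional initial state (named or ordered numeric, length 8).
#' @param rtol,atol Integrator tolerances.
#' @return A `msw_trajectory` tibble: `time`, the 8 state variables and the
#'   derived observables (`ste11_t`, `mei2_t`, `mei2_active`, `mei3_t`,
#'   `pat1_free`, `pat1_activity`, `rst2`, `rpol`).
#' @export
simulate_meiosis <- function(params = default_parameters(),
                             schedule = starvation_schedule(50),
                             t_end = 1000, dt = 0.5, init = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  validate_schedule(schedule)
  p <- unlist(params)
  if (is.null(init)) {
    init <- meiosis_rich_state(params)
  }
  y0 <- as.numeric(init)
  if (length(y0) != 8L) stop("init must have length 8")
  if (any(y0 < 0)) stop("initial state must be nonnegative")
  times <- seq(0, t_end, by = dt)
  raw <- integrate_piecewise(y0, times, p, schedule, rtol, atol)
  traj <- tibble::as_tibble(as.data.frame(raw))
  names(traj) <- c("time", meiosis_state_names())
  traj <- add_meiosis_observables(traj, p, schedule)
  new_trajectory(traj, model = "meiosis", params = params, schedule = schedule)
}

add_meiosis_observables <- function(traj, p, schedule) {
  u <- lapply(traj$time, function(t) inputs_at(schedule, t))
  pka <- vapply(u, `[[`, numeric(1), "pka")
  tor2 <- vapply(u, `[[`, numeric(1), "tor2")
  phes_eff <- if (p[["phes_clamp"]] > 0) rep(p[["phes_clamp"]], nrow(traj)) else traj$phes
  pat_free <- pmax(p[["pat1_t"]] - traj$cpx, 0)
  traj$ste11_t <- traj$ste11c + traj$ste11n
  traj$mei2_t <- traj$mei2a + traj$mei2p
  traj$mei2_active <- traj$mei2a
  traj$mei3_t <- traj$mei3 + traj$cpx
  traj$pat1_free <- pat_free
  traj$pat1_activity <- pat_free / (1 + phes_eff / p[["j_iphe"]])
  traj$rst2 <- 1 / (1 + (pka / p[["j_rst2"]])^p[["h_rst2"]])
  traj$rpol <- p[["a_rpol"]] + p[["k_rpol"]] *
    hill_activation(traj$mei2_t, p[["j_rpol"]], p[["h_rpol"]])
  traj$tor2 <- tor2
  traj$pka <- pka
  traj
}

#' Nutrient-rich resting state of the subsystem
#'
#' Finds the stable steady state under Tor2 = PKA = 1 by damped Newton
#' iteration from a mitotic-like seed (all meiotic regulators low, Pat1
#' fully active), falling back to a long relaxation integration if the
#' Newton step does not converge.
#'
#' @param params Meiosis `msw_params`.
#' @return Named numeric state (length 8).
#' @export
meiosis_rich_state <- function(params) {
  p <- unlist(params)
  rich <- rich_schedule()
  f <- function(y) meiosis_core(pmax(y, 0), p, 1, 1, TRUE)$deriv
  seed <- c(0.15, 0.01, 0.005, 0.05, 0.001, 0.001, 0.0005, 0.001)
  sol <- newton_solve(f, seed, tol = 1e-12, max_iter = 100)
  y <- sol$x
  if (!sol$converged || any(y < -1e-9)) {
    raw <- integrate_piecewise(seed, seq(0, 3000, by = 50), p, rich)
    y <- as.numeric(raw[nrow(raw), -1])
    sol <- newton_solve(f, y, tol = 1e-12, max_iter = 100)
    if (sol$converged) y <- sol$x
  }
  stats::setNames(pmax(y, 0), meiosis_state_names())
}
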