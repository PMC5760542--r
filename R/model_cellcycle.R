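#' State-variable names of the integrated model
#'
#' The integrated model concatenates the meiotic-entry subsystem with a
#' compact fission-yeast cell-cycle model: total Cdk1:Cdc13 (`cdc13t`), its
#' inhibitory-phosphorylated form (`prempf`), the APC/C activators Ste9 and
#' Slp1 (total and active, with the intermediary enzyme `iep`), the Cdk1
#' inhibitor Rum1, the G1/S starter kinase `sk`, cell mass, the intracellular
#' nitrogen pool sustaining cyclin synthesis under starvation, and
#' phosphorylated Igo1 (the Greatwall branch inhibiting PP2A:B55). Active
#' Cdk1:Cdc13 (`mpf`) is algebraic.
#'
#' @return Character vector of the 19 state names.
#' @export
integrated_state_names <- function() {
  c(meiosis_state_names(),
    "cdc13t", "prempf", "ste9", "slp1t", "slp1", "iep", "rum1t", "sk",
    "mass", "npool", "igo1p")
}

# active Cdk1:Cdc13 from total cyclin, inhibitory-phosphorylated pool and
# Rum1 (stoichiometric trimer, rapid-equilibrium approximation)
cc_active_mpf <- function(cdc13t, prempf, rum1t, kdiss) {
  ifelse(cdc13t <= 1e-12, 0, {
    sig <- cdc13t + rum1t + kdiss
    trim <- 2 * cdc13t * rum1t / (sig + sqrt(pmax(sig^2 - 4 * cdc13t * rum1t, 0)))
    pmax((cdc13t - prempf) * (cdc13t - trim) / cdc13t, 0)
  })
}

# reference R implementation of the cell-cycle derivative block (the
# compiled version in src/models.c is the production path; the test suite
# checks their agreement)
cellcycle_block <- function(y, p, tor2, pka, phes_eff) {
  cdc13t <- y[[9]]; prempf <- y[[10]]; ste9 <- y[[11]]; slp1t <- y[[12]]
  slp1 <- y[[13]]; iep <- y[[14]]; rum1t <- y[[15]]; sk <- y[[16]]
  mass <- y[[17]]; npool <- y[[18]]; igo1p <- y[[19]]
  mpf <- cc_active_mpf(cdc13t, prempf, rum1t, p[["kdiss"]])
  ext <- tor2 * pka
  nut <- ext + (1 - ext) * npool
  b55 <- 1 / (1 + igo1p / p[["j_igo"]])
  kwee <- p[["kweep"]] + (p[["kwepp"]] - p[["kweep"]]) *
    goldbeter_koshland(p[["vawee"]] * b55, p[["viwee"]] * mpf, p[["jawee"]], p[["jiwee"]])
  k25 <- p[["k25p"]] + (p[["k25pp"]] - p[["k25p"]]) *
    goldbeter_koshland(p[["va25"]] * mpf, p[["vi25"]] * b55, p[["ja25"]], p[["ji25"]])
  kdeg <- p[["k2p"]] + p[["k2pp"]] * ste9 + p[["k2ppp"]] * slp1
  fphe <- 1 / (1 + p[["c_pherum1"]] * phes_eff)
  eff <- 1 + p[["c_b55g1"]] * (1 - b55)
  tfsk <- goldbeter_koshland(p[["k15"]] * mass * nut,
                             p[["k16p"]] + p[["k16pp"]] * mpf,
                             p[["j15"]], p[["j16"]])
  list(
    deriv = c(
      p[["k1"]] * mass * nut - kdeg * cdc13t,
      kwee * (cdc13t - prempf) - k25 * prempf - kdeg * prempf,
      (p[["k3p"]] + p[["k3pp"]] * slp1) * (1 - ste9) / (p[["j3"]] + 1 - ste9) -
        (p[["k4p"]] * sk * eff + p[["k4"]] * mpf) * ste9 / (p[["j4"]] + ste9),
      p[["k5p"]] + p[["k5pp"]] * mpf^4 / (p[["j5"]]^4 + mpf^4) - p[["k6"]] * slp1t,
      p[["k7"]] * iep * (slp1t - slp1) / (p[["j7"]] + slp1t - slp1) -
        p[["k8"]] * slp1 / (p[["j8"]] + slp1) - p[["k6"]] * slp1,
      p[["k9"]] * mpf * (1 - iep) / (p[["j9"]] + 1 - iep) -
        p[["k10"]] * iep / (p[["j10"]] + iep),
      p[["k11"]] - (p[["k12"]] + p[["k12p"]] * sk * eff + p[["k12pp"]] * mpf) *
        fphe * rum1t,
      p[["k13"]] * tfsk - p[["k14"]] * sk,
      p[["mu"]] * ext * mass,
      p[["kfill_n"]] * ext * (1 - npool) - p[["kdn"]] * (1 - ext) * npool,
      p[["ki_igo"]] * (1 - ext) * (1 - igo1p) - p[["kd_igo"]] * igo1p
    ),
    mpf = mpf, b55 = b55
  )
}

#' Right-hand side of the integrated model
#'
#' Cell-cycle dynamics coupled to the meiotic subsystem through (i)
#' Cdk1:Cdc13 inhibition of the Ste11 autoregulatory synthesis term, (ii)
#' PheS protection of Rum1 from degradation, (iii) the intracellular
#' nitrogen pool sustaining cyclin synthesis under starvation, and (iv)
#' growth arrest when Tor2 and PKA are inactivated.
#'
#' @param t Time (minutes).
#' @param state Numeric state of length 19 (see [integrated_state_names()]).
#' @param params Integrated `msw_params`.
#' @param schedule `msw_schedule`.
#' @return Derivative vector (length 19).
#' @export
integrated_rhs <- function(t, state, params, schedule) {
  if (length(state) != 19L) {
    stop("integrated_rhs: state must have the 19 integrated-model components")
  }
  p <- unlist(params)
  u <- inputs_at(schedule, t)
  y <- as.numeric(state)
  cc <- cellcycle_block(y, p, u$tor2, u$pka,
                        if (p[["phes_clamp"]] > 0) p[["phes_clamp"]] else y[[5]])
  mei <- meiosis_core(y[1:8], p, u$tor2, u$pka, u$phes_enabled, mpf = cc$mpf)
  c(mei$deriv, cc$deriv)
}

integrated_parms <- function(p, u) {
  c(p, u$tor2, u$pka, as.numeric(u$phes_enabled))
}

#' Simulate the integrated cell-cycle + meiosis model
#'
#' Integrates with a stiff solver, restarting at schedule breakpoints and at
#' division events. A division is triggered at each downward crossing of
#' Cdk1:Cdc13 activity through the exit threshold (`div_lo`) after the
#' activity has exceeded the mitotic threshold (`div_hi`); the crossing time
#' is localised by bisection to 0.01 min and cell mass is halved exactly.
#'
#' @param params Integrated `msw_params`.
#' @param schedule `msw_schedule`.
#' @param t_end Horizon (min).
#' @param dt Output grid (min).
#' @param init Initial state (length 19); default: a cycling nutrient-rich
#'   state at a division event (see [integrated_rich_state()]).
#' @param rtol,atol Integrator tolerances.
#' @return `msw_trajectory` tibble with the 19 states, `mpf` and derived
#'   meiosis observables; attribute `events` holds the division/input log.
#' @export
simulate_integrated <- function(params = default_parameters("integrated"),
                                schedule = rich_schedule(),
                                t_end = 600, dt = 0.5, init = NULL,
                                rtol = 1e-8, atol = 1e-10) {
  validate_schedule(schedule)
  p <- unlist(params)
  if (is.null(init)) init <- integrated_rich_state(params)
  y <- as.numeric(init)
  if (length(y) != 19L) stop("init must have length 19")
  times <- seq(0, t_end, by = dt)
  brks <- schedule$time[schedule$time > 0 & schedule$time < t_end]
  div_hi <- p[["div_hi"]]; div_lo <- p[["div_lo"]]

  events <- list()
  if (length(brks)) events <- c(events, lapply(brks, function(b)
    list(time = b, type = "input_step")))
  out <- NULL
  t_now <- 0
  armed <- FALSE  # has Cdk1:Cdc13 exceeded the mitotic threshold?
  solve_seg <- function(y, tt, u) {
    deSolve::lsoda(y, tt, func = "derivs_integrated", dllname = "meioswitch",
                   initfunc = "init_integrated",
                   parms = integrated_parms(p, u),
                   rtol = rtol, atol = atol, maxsteps = 50000,
                   nout = 1, outnames = "mpf")
  }
  while (t_now < t_end - 1e-9) {
    t_stop <- min(c(brks[brks > t_now + 1e-9], t_end))
    u <- inputs_at(schedule, t_now)
    tt <- sort(unique(c(t_now, times[times > t_now & times < t_stop], t_stop)))
    if (length(tt) < 2) tt <- c(t_now, t_stop)
    seg <- solve_seg(y, tt, u)
    mpf <- seg[, "mpf"]
    # scan for a division event inside the segment
    ev_row <- NA
    for (i in seq_len(nrow(seg) - 1)) {
      if (!armed && mpf[[i + 1]] >= div_hi) armed <- TRUE
      if (armed && mpf[[i]] > div_lo && mpf[[i + 1]] <= div_lo) { ev_row <- i; break }
    }
    if (is.na(ev_row)) {
      out <- if (is.null(out)) seg else rbind(out[-nrow(out), , drop = FALSE], seg)
      y <- as.numeric(seg[nrow(seg), 1 + seq_len(19)])
      t_now <- t_stop
      next
    }
    # bisect the crossing time to < 0.01 min
    lo <- seg[ev_row, "time"]; hi <- seg[ev_row + 1, "time"]
    y_lo <- as.numeric(seg[ev_row, 1 + seq_len(19)])
    while (hi - lo > 0.01) {
      mid <- (lo + hi) / 2
      half <- solve_seg(y_lo, c(lo, mid), u)
      if (half[2, "mpf"] <= div_lo) hi <- mid
      else { y_lo <- as.numeric(half[2, 1 + seq_len(19)]); lo <- mid }
    }
    fin <- solve_seg(y_lo, c(lo, hi), u)
    y <- as.numeric(fin[2, 1 + seq_len(19)])
    y[[17]] <- y[[17]] / 2  # exact mass halving at division
    events <- c(events, list(list(time = hi, type = "division")))
    armed <- FALSE
    keep <- seg[seg[, "time"] <= lo, , drop = FALSE]
    out <- if (is.null(out)) keep else rbind(out[-nrow(out), , drop = FALSE], keep)
    t_now <- hi
  }
  traj <- tibble::as_tibble(as.data.frame(out))
  names(traj) <- c("time", integrated_state_names(), "mpf")
  traj <- traj[!duplicated(traj$time), ]
  traj <- add_meiosis_observables(traj, p, schedule)
  ev <- if (length(events)) {
    dplyr::arrange(dplyr::bind_rows(lapply(events, tibble::as_tibble)), .data$time)
  } else {
    tibble::tibble(time = numeric(), type = character())
  }
  new_trajectory(traj, model = "integrated", params = params,
                 schedule = schedule, events = ev)
}

#' Nutrient-rich cycling state of the integrated model
#'
#' Relaxes the integrated model onto its nutrient-rich limit cycle and
#' returns the state immediately after a division event, so that simulation
#' time 0 corresponds to cell birth. The cycle period is attached as an
#' attribute.
#'
#' @param params Integrated `msw_params`.
#' @return Named numeric state (length 19) with attribute `period` (min).
#' @export
integrated_rich_state <- function(params) {
  key <- digest_params(params, "rich-cycle")
  cached <- .msw_cache[[key]]
  if (!is.null(cached)) return(cached)
  p <- unlist(params)
  mei <- meiosis_rich_state(new_parameter_set(p[names(.meiosis_defaults)], "meiosis"))
  y0 <- c(as.numeric(mei),
          cdc13t = 0.2, prempf = 0.1, ste9 = 1, slp1t = 0.02, slp1 = 0.01,
          iep = 0.02, rum1t = 0.2, sk = 0.01, mass = 1, npool = 1, igo1p = 0)
  tr <- simulate_integrated(params, rich_schedule(), t_end = 1200, dt = 1,
                            init = y0)
  ev <- attr(tr, "events")
  div <- ev$time[ev$type == "division"]
  if (length(div) < 3) stop("no sustained division cycle under rich conditions")
  period <- mean(diff(utils::tail(div, 3)))
  t_birth <- utils::tail(div, 1)
  row <- tr[which.min(abs(tr$time - t_birth)), ]
  y <- as.numeric(row[1, integrated_state_names()])
  # mass halving happened at the event; take the first grid point after it
  y <- stats::setNames(y, integrated_state_names())
  out <- structure(y, period = period)
  .msw_cache[[key]] <- out
  out
}
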