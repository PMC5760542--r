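#' Detect division events on a simulated trajectory
#'
#' A division is recorded at each downward crossing of Cdk1:Cdc13 activity
#' through the exit threshold after the activity has exceeded the mitotic
#' threshold. [simulate_integrated()] already localises events by bisection
#' and records them; this detector re-derives the times from a dense
#' trajectory (its own or an imported one) and is used to cross-check the
#' event log.
#'
#' @param trajectory Data frame with columns `time` and `mpf` (and `mass`
#'   for the mass-drop cross-check).
#' @param div_hi,div_lo Mitotic and exit thresholds on Cdk1:Cdc13.
#' @return Numeric vector of division times, strictly increasing.
#' @export
detect_division_events <- function(trajectory,
                                   div_hi = default_parameters("integrated")[["div_hi"]],
                                   div_lo = default_parameters("integrated")[["div_lo"]]) {
  t <- trajectory$time
  if (any(diff(t) <= 0)) stop("trajectory time grid must be strictly increasing")
  mpf <- trajectory$mpf
  armed <- FALSE
  out <- numeric()
  for (i in seq_len(length(t) - 1)) {
    if (!armed && mpf[[i + 1]] >= div_hi) armed <- TRUE
    if (armed && mpf[[i]] > div_lo && mpf[[i + 1]] <= div_lo) {
      out <- c(out, t[[i]] + (mpf[[i]] - div_lo) / (mpf[[i]] - mpf[[i + 1]]) *
                 (t[[i + 1]] - t[[i]]))
      armed <- FALSE
    }
  }
  out
}

#' Division times recorded on an integrated-model run
#'
#' @param trajectory `msw_trajectory` from [simulate_integrated()].
#' @return Numeric vector of division times.
#' @export
division_times <- function(trajectory) {
  ev <- attr(trajectory, "events")
  if (is.null(ev)) return(numeric())
  ev$time[ev$type == "division"]
}

#' G1-arrest verdict over the final window of a trajectory
#'
#' True iff, over the last `window` minutes, Cdk1:Cdc13 stays below the exit
#' threshold while Rum1 stays above its nutrient-rich mid-cycle mean — the
#' signature of a starvation-induced G1 arrest with high Rum1.
#'
#' @param trajectory `msw_trajectory` from [simulate_integrated()].
#' @param window Window length (min), must not exceed the trajectory span.
#' @param rum1_ref Nutrient-rich mid-cycle mean Rum1; computed from a rich
#'   reference run of the same parameters when `NULL`.
#' @return One-row tibble: `arrested`, `mean_rum1`, `mean_cdk1`, `rum1_ref`.
#' @export
g1_arrest_detector <- function(trajectory, window = 100, rum1_ref = NULL) {
  span <- diff(range(trajectory$time))
  if (window > span) stop("window exceeds the trajectory span")
  p <- unlist(attr(trajectory, "params"))
  if (is.null(rum1_ref)) {
    pars <- attr(trajectory, "params")
    rich <- simulate_integrated(pars, rich_schedule(),
                                t_end = 300, dt = 1,
                                init = integrated_rich_state(pars))
    rum1_ref <- mean(rich$rum1t)
  }
  tail_i <- trajectory$time >= max(trajectory$time) - window
  mean_rum1 <- mean(trajectory$rum1t[tail_i])
  mean_cdk1 <- mean(trajectory$mpf[tail_i])
  arrested <- all(trajectory$mpf[tail_i] < p[["div_lo"]]) &&
    mean_rum1 > rum1_ref
  tibble::tibble(arrested = arrested, mean_rum1 = mean_rum1,
                 mean_cdk1 = mean_cdk1, rum1_ref = rum1_ref)
}
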