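#' Piecewise-constant nutrient input schedule
#'
#' Tor2 and PKA activities (model inputs; 1 = nutrient rich, reduced values =
#' starvation) and the PheS-enable flag are held constant between breakpoints.
#' Under the default starvation protocol PKA drops only to 0.75, encoding the
#' assumption that PKA activity is not completely inhibited by nitrogen
#' starvation.
#'
#' @param time Numeric vector of breakpoints (minutes), strictly increasing,
#'   first element 0.
#' @param tor2,pka Input activity levels per breakpoint, in `[0, 1.5]`
#'   (values above 1 encode overexpression).
#' @param phes_enabled Logical per breakpoint: can pheromone signalling be
#'   mounted (mating partner present / pathway intact)?
#' @return A `msw_schedule` tibble with one row per breakpoint.
#' @examples
#' starvation_schedule(t_starve = 50)
#' @export
nutrient_schedule <- function(time, tor2, pka, phes_enabled = TRUE) {
  n <- length(time)
  tor2 <- rep_len(tor2, n); pka <- rep_len(pka, n)
  phes_enabled <- rep_len(phes_enabled, n)
  if (n < 1 || time[[1]] != 0) stop("schedule must start at time 0")
  if (n > 1 && any(diff(time) <= 0)) stop("schedule times must be strictly increasing")
  if (any(tor2 < 0 | tor2 > 1.5) || any(pka < 0 | pka > 1.5)) {
    stop("input levels must lie in [0, 1.5]")
  }
  tibble::new_tibble(
    tibble::tibble(time = as.numeric(time), tor2 = tor2, pka = pka,
                   phes_enabled = as.logical(phes_enabled)),
    class = "msw_schedule"
  )
}

#' @rdname nutrient_schedule
#' @param t_starve Time (min) at which Tor2 and PKA are switched from rich to
#'   starved levels.
#' @param tor2_starved,pka_starved Starved input levels (defaults 0 and 0.75).
#' @export
starvation_schedule <- function(t_starve = 50, tor2_starved = 0, pka_starved = 0.75) {
  if (t_starve <= 0) {
    return(nutrient_schedule(0, tor2_starved, pka_starved, TRUE))
  }
  nutrient_schedule(c(0, t_starve), c(1, tor2_starved), c(1, pka_starved), TRUE)
}

#' @rdname nutrient_schedule
#' @export
rich_schedule <- function() nutrient_schedule(0, 1, 1, TRUE)

# inputs in force at time t (right-continuous)
inputs_at <- function(schedule, t) {
  i <- findInterval(t, schedule$time, rightmost.closed = FALSE)
  i <- max(i, 1L)
  list(tor2 = schedule$tor2[[i]], pka = schedule$pka[[i]],
       phes_enabled = schedule$phes_enabled[[i]])
}

validate_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule),
            all(c("time", "tor2", "pka", "phes_enabled") %in% names(schedule)))
  if (schedule$time[[1]] != 0) stop("schedule must start at t = 0")
  if (nrow(schedule) > 1 && any(diff(schedule$time) <= 0)) {
    stop("schedule times must be strictly increasing")
  }
  invisible(schedule)
}
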