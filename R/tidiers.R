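#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a bifurcation branch
#'
#' @param x `msw_branch`.
#' @param state_names Optional state-variable names.
#' @param ... Unused.
#' @return Tibble with one row per branch point.
#' @export
tidy.msw_branch <- function(x, state_names = NULL, ...) {
  branch_points(x, state_names)
}

#' @rdname tidy.msw_branch
#' @export
glance.msw_branch <- function(x, ...) {
  bf <- attr(x, "bifurcations")
  tibble::tibble(
    n_points = nrow(x),
    param_min = min(x$param), param_max = max(x$param),
    n_sn = sum(bf$type == "SN"), n_hb = sum(bf$type == "HB"),
    truncated = isTRUE(attr(x, "truncated"))
  )
}

#' Tidy a genotype screen
#'
#' @param x `msw_screen`.
#' @param ... Unused.
#' @return The screen as a plain tibble.
#' @export
tidy.msw_screen <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.msw_screen
#' @export
glance.msw_screen <- function(x, ...) {
  scored <- x$scored & !is.na(x$expected_mating)
  tibble::tibble(
    n_strains = nrow(x),
    n_scored = sum(scored),
    n_matched = sum(x$match[scored]),
    concordance = attr(x, "concordance")
  )
}

#' Tidy a trajectory (long form)
#'
#' @param x `msw_trajectory`.
#' @param ... Passed to [tidy_trajectory()].
#' @return Long tibble `time`, `variable`, `value`.
#' @export
tidy.msw_trajectory <- function(x, ...) tidy_trajectory(x, ...)

#' @rdname tidy.msw_trajectory
#' @export
glance.msw_trajectory <- function(x, ...) {
  ev <- attr(x, "events")
  tibble::tibble(
    model = attr(x, "model"),
    t_end = max(x$time),
    n_divisions = if (is.null(ev)) 0L else sum(ev$type == "division"),
    final_mei2_active = x$mei2_active[[nrow(x)]],
    final_pat1_free = x$pat1_free[[nrow(x)]]
  )
}
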