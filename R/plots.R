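#' Plot a simulated trajectory
#'
#' Time courses of the main observables (faceted free scales); division and
#' input-step events are drawn as vertical lines.
#'
#' @param object `msw_trajectory`.
#' @param variables Variables to show (defaults to the cascade observables,
#'   plus Cdk1:Cdc13, mass and Rum1 for integrated runs).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msw_trajectory <- function(object, variables = NULL, ...) {
  if (is.null(variables)) {
    variables <- c("ste11_t", "phes", "mat1pm", "mei3_t", "mei2_active",
                   "pat1_activity")
    if (attr(object, "model") == "integrated") {
      variables <- c(variables, "mpf", "rum1t", "mass")
    }
  }
  df <- tidy_trajectory(object, variables)
  df$variable <- factor(df$variable, levels = variables)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
  ev <- attr(object, "events")
  if (!is.null(ev) && nrow(ev)) {
    gg <- gg + ggplot2::geom_vline(
      data = ev, ggplot2::aes(xintercept = .data$time, linetype = .data$type),
      colour = "grey40", linewidth = 0.3
    )
  }
  gg
}

#' Plot one or more bifurcation branches
#'
#' Stable segments are drawn solid, unstable dashed; saddle-node and Hopf
#' points are marked.
#'
#' @param branches `msw_branch` or list of branches.
#' @param var Index or name of the state component for the y axis (or a
#'   function of the state matrix returning the ordinate).
#' @param state_names Optional state names for `var` lookup.
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_branches <- function(branches, var = 1, state_names = NULL,
                          xlab = "parameter", ylab = "steady state") {
  if (inherits(branches, "msw_branch")) branches <- list(branches)
  ordinate <- function(br) {
    st <- do.call(rbind, br$state)
    if (is.function(var)) var(st)
    else if (is.character(var)) st[, match(var, state_names)]
    else st[, var]
  }
  df <- dplyr::bind_rows(lapply(seq_along(branches), function(i) {
    br <- branches[[i]]
    tibble::tibble(branch = i, param = br$param, y = ordinate(br),
                   stable = br$stable)
  }))
  # split into runs of constant stability so linetype changes cleanly
  df <- dplyr::mutate(
    dplyr::group_by(df, .data$branch),
    seg = cumsum(c(0, diff(as.numeric(.data$stable)) != 0))
  )
  bifs <- dplyr::bind_rows(lapply(seq_along(branches), function(i) {
    bf <- attr(branches[[i]], "bifurcations")
    if (!nrow(bf)) return(NULL)
    st <- do.call(rbind, bf$state)
    tibble::tibble(branch = i, type = bf$type, param = bf$param,
                   y = if (is.function(var)) var(st)
                       else if (is.character(var)) st[, match(var, state_names)]
                       else st[, var])
  }))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$param, y = .data$y)) +
    ggplot2::geom_path(ggplot2::aes(
      group = interaction(.data$branch, .data$seg),
      linetype = .data$stable
    ), linewidth = 0.5) +
    ggplot2::scale_linetype_manual(
      values = c(`TRUE` = "solid", `FALSE` = "dashed"),
      labels = c(`TRUE` = "stable", `FALSE` = "unstable"), name = NULL
    ) +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(bifs) && nrow(bifs)) {
    gg <- gg + ggplot2::geom_point(
      data = bifs, ggplot2::aes(shape = .data$type), size = 2
    ) + ggplot2::scale_shape_manual(values = c(SN = 16, HB = 17), name = NULL)
  }
  gg
}

#' Plot a genotype screen as a concordance grid
#'
#' @param object `msw_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msw_screen <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("strain", "mating", "meiosis",
                                "expected_mating", "expected_meiosis", "match")],
    c("mating", "meiosis"), names_to = "trait", values_to = "predicted"
  )
  df$expected <- ifelse(df$trait == "mating", df$expected_mating,
                        df$expected_meiosis)
  df$strain <- factor(df$strain, levels = rev(unique(df$strain)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$strain)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$predicted == .data$expected),
                       colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$predicted), size = 2.6) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#8fd18f", `FALSE` = "#e88b8b"),
                               name = "matches expected") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8)
}
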