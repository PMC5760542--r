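# Damped Newton iteration for steady states; used by the rich-state seed,
# the multi-start oracle and the continuation corrector.
newton_solve <- function(f, x0, tol = 1e-10, max_iter = 50, damping = TRUE) {
  x <- x0
  for (i in seq_len(max_iter)) {
    fx <- f(x)
    nrm <- max(abs(fx))
    if (!is.finite(nrm)) return(list(x = x, converged = FALSE, iter = i))
    if (nrm < tol) return(list(x = x, converged = TRUE, iter = i))
    J <- fd_jacobian(f, x)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      step <- tryCatch(qr.solve(J + diag(1e-10, length(x)), fx),
                       error = function(e) NULL)
      if (is.null(step)) return(list(x = x, converged = FALSE, iter = i))
    }
    if (damping) {
      lam <- 1
      repeat {
        xn <- x - lam * step
        fn <- f(xn)
        if (all(is.finite(fn)) && max(abs(fn)) < nrm) break
        lam <- lam / 2
        if (lam < 1e-6) { xn <- x - lam * step; break }
      }
      x <- xn
    } else {
      x <- x - step
    }
  }
  fx <- f(x)
  list(x = x, converged = max(abs(fx)) < tol, iter = max_iter)
}

# trajectory container -------------------------------------------------------

new_trajectory <- function(traj, model, params, schedule, events = NULL) {
  tibble::new_tibble(
    traj,
    class = "msw_trajectory",
    model = model,
    params = params,
    schedule = schedule,
    events = events
  )
}

#' @export
print.msw_trajectory <- function(x, ...) {
  cat("<msw_trajectory> model =", attr(x, "model"),
      "-", nrow(x), "time points over", max(x$time), "min\n")
  ev <- attr(x, "events")
  if (!is.null(ev) && nrow(ev)) {
    cat("events:", paste(sprintf("%s@%.1f", ev$type, ev$time), collapse = ", "), "\n")
  }
  NextMethod()
}

#' Pivot a trajectory to tidy (long) form
#'
#' @param traj `msw_trajectory`.
#' @param variables Optional subset of variable names.
#' @return Tibble with columns `time`, `variable`, `value`.
#' @export
tidy_trajectory <- function(traj, variables = NULL) {
  cols <- setdiff(names(traj), "time")
  if (!is.null(variables)) cols <- intersect(cols, variables)
  tidyr::pivot_longer(tibble::as_tibble(traj)[c("time", cols)],
                      -"time", names_to = "variable", values_to = "value")
}

# first time a variable crosses `level` upward; +Inf if never
first_crossing <- function(time, x, level) {
  idx <- which(x[-1] >= level & x[-length(x)] < level)
  if (x[[1]] >= level) return(time[[1]])
  if (!length(idx)) return(Inf)
  i <- idx[[1]]
  # linear interpolation inside the bracketing step
  t0 <- time[[i]]; t1 <- time[[i + 1]]
  x0 <- x[[i]]; x1 <- x[[i + 1]]
  t0 + (level - x0) / (x1 - x0) * (t1 - t0)
}
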