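#' Multi-start steady-state search
#'
#' Finds equilibria of an autonomous vector field by damped Newton iteration
#' from Latin-hypercube-style random starts inside a box, deduplicating the
#' converged roots. This is the brute-force oracle against which the
#' continuation branches are cross-validated.
#'
#' @param rhs Function `rhs(state)` returning the derivative vector.
#' @param box Matrix or data frame with columns `lower`, `upper` (one row per
#'   state variable).
#' @param n_starts Number of random starts (>= 1).
#' @param seed Integer seed; the only source of randomness.
#' @param tol Residual tolerance: every returned state has
#'   `max(abs(rhs)) < tol`.
#' @param dedup_tol States closer than this (max-norm) are considered one
#'   equilibrium.
#' @param nonneg Project Newton iterates onto the nonnegative orthant.
#' @param extra_starts Additional deterministic start states tried before the
#'   random ones.
#' @param relax_time If positive, each start is first relaxed along the flow
#'   for this long (minutes) before Newton polishing; this finds attractors
#'   robustly in stiff systems (saddles are still reached by continuation).
#' @return Tibble with one row per equilibrium: `state` (list column of
#'   numeric vectors), `residual`. Empty tibble when nothing converges.
#' @export
find_steady_states <- function(rhs, box, n_starts = 50, seed = 1,
                               tol = 1e-9, dedup_tol = 1e-6, nonneg = TRUE,
                               extra_starts = list(), relax_time = 0) {
  if (n_starts < 1) stop("n_starts must be >= 1")
  box <- as.matrix(box)
  if (!all(is.finite(box))) stop("box must be finite")
  nvar <- nrow(box)
  set.seed(seed)
  starts <- c(extra_starts, lapply(seq_len(n_starts), function(i) {
    box[, 1] + stats::runif(nvar) * (box[, 2] - box[, 1])
  }))
  f <- if (nonneg) function(x) rhs(pmax(x, 0)) else rhs
  roots <- list()
  for (s in starts) {
    if (relax_time > 0) {
      # relax along the flow until the residual is small; take extra windows
      # only while they still help (slow modes), never more than four
      r_prev <- Inf
      for (seg in 1:4) {
        s_new <- tryCatch(suppressWarnings({
          out <- deSolve::lsoda(s, c(0, relax_time / 2, relax_time),
                                function(t, y, parms) list(f(y)),
                                rtol = 1e-6, atol = 1e-8, maxsteps = 20000)
          as.numeric(out[nrow(out), -1])
        }), error = function(e) NULL)
        if (is.null(s_new) || any(!is.finite(s_new))) break
        s <- s_new
        r_now <- max(abs(f(s)))
        if (r_now < 1e-7 || r_now > 0.3 * r_prev) break
        r_prev <- r_now
      }
      if (any(!is.finite(s))) next
    }
    sol <- newton_solve(f, s, tol = tol, max_iter = 60)
    if (!sol$converged && nonneg) {
      # equilibria on the nonnegative boundary defeat the projected Newton
      # (one-sided derivatives); freeze near-zero components and solve the
      # reduced system
      base <- pmax(sol$x, 0)
      frozen <- base < 1e-7
      if (any(frozen) && !all(frozen)) {
        embed <- function(xf) { z <- numeric(length(base)); z[!frozen] <- xf; z }
        red <- newton_solve(function(xf) rhs(pmax(embed(xf), 0))[!frozen],
                            base[!frozen], tol = tol, max_iter = 60)
        if (red$converged) {
          cand <- embed(pmax(red$x, 0))
          if (max(abs(rhs(cand))) < tol) sol <- list(x = cand, converged = TRUE)
        }
      }
    }
    if (!sol$converged) next
    x <- if (nonneg) pmax(sol$x, 0) else sol$x
    if (max(abs(rhs(x))) >= tol) next
    dup <- any(vapply(roots, function(r) max(abs(r - x)) < dedup_tol, logical(1)))
    if (!dup) roots[[length(roots) + 1]] <- x
  }
  if (!length(roots)) {
    return(tibble::tibble(state = list(), residual = numeric()))
  }
  ord <- order(vapply(roots, function(r) r[[1]], numeric(1)))
  tibble::tibble(
    state = roots[ord],
    residual = vapply(roots[ord], function(r) max(abs(rhs(r))), numeric(1))
  )
}

#' Linear stability of an equilibrium
#'
#' Central finite-difference Jacobian with per-component adaptive step;
#' stable iff every eigenvalue has real part below `-margin`.
#'
#' @param rhs Function `rhs(state)`.
#' @param state Equilibrium (checked: `max(abs(rhs)) < resid_tol`).
#' @param margin Stability margin on the leading real part (default 1e-8).
#' @param resid_tol Equilibrium residual tolerance (default 1e-8).
#' @return List with `stable`, `eigenvalues` (complex, sorted by decreasing
#'   real part) and `leading` (largest real part).
#' @export
jacobian_stability <- function(rhs, state, margin = 1e-8, resid_tol = 1e-8) {
  if (max(abs(rhs(state))) >= resid_tol) {
    stop("jacobian_stability: state is not an equilibrium at tolerance ", resid_tol)
  }
  J <- fd_jacobian(rhs, state)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  list(stable = Re(ev[[1]]) < -margin, eigenvalues = ev, leading = Re(ev[[1]]))
}

# one pseudo-arclength predictor-corrector step; returns NULL on failure.
# z = c(state, param); tang = unit tangent; plain Newton with a divergence
# guard (damping hurts near the slow modes of the cell-cycle block)
palc_step <- function(F, z, tang, h, tol = 1e-10, max_iter = 25) {
  pred <- z + h * tang
  zc <- pred
  res0 <- NULL
  for (i in seq_len(max_iter)) {
    res <- c(F(zc), sum((zc - pred) * tang))
    if (!all(is.finite(res))) return(NULL)
    nrm <- max(abs(res))
    if (nrm < tol) return(zc)
    if (is.null(res0)) res0 <- nrm
    if (i > 6 && nrm > 10 * res0) return(NULL)
    J <- fd_jacobian(function(w) c(F(w), sum((w - pred) * tang)), zc)
    step <- tryCatch(solve(J, res), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    if (max(abs(step)) > 1e3 * (1 + max(abs(z)))) return(NULL)
    zc <- zc - step
  }
  NULL
}

# unit tangent along the branch at z: solve the bordered system
# rbind(J, b) %*% t = e_{n+1}, with b the previous tangent (or the unit
# parameter direction initially); SVD null vector as fallback
branch_tangent <- function(F, z, prev_tang = NULL) {
  J <- fd_jacobian(F, z)            # n x (n+1)
  n1 <- ncol(J)
  b <- prev_tang %||% c(rep(0, n1 - 1), 1)
  t_raw <- tryCatch(solve(rbind(J, b), c(rep(0, nrow(J)), 1)),
                    error = function(e) NULL)
  if (is.null(t_raw) || !all(is.finite(t_raw))) {
    t_raw <- tryCatch({
      v <- svd(J, nu = 0)$v
      v[, ncol(v)]
    }, error = function(e) NULL)
    if (is.null(t_raw)) return(NULL)
  }
  if (!is.null(prev_tang) && sum(t_raw * prev_tang) < 0) t_raw <- -t_raw
  t_raw / sqrt(sum(t_raw^2))
}

#' Pseudo-arclength continuation of an equilibrium branch
#'
#' Follows a branch of steady states of `rhs(state, value)` as one parameter
#' varies, with a damped-Newton corrector orthogonal to the branch tangent.
#' Folds (saddle-nodes) are detected by sign changes of the parameter
#' component of the tangent and refined by bisection on the tangent sign;
#' Hopf points by a complex-conjugate eigenvalue pair crossing the imaginary
#' axis. Corrector divergence truncates the branch with a boundary marker
#' rather than failing.
#'
#' @param rhs Function `rhs(state, value)` returning the derivative vector.
#' @param param_range Length-2 numeric: parameter interval to scan.
#' @param start_state Equilibrium at `param_range[1]`.
#' @param max_steps Maximum continuation steps.
#' @param h0 Initial arclength step as a fraction of the parameter range
#'   (default 1e-3); adapted within `[h_min, h_max]` (fractions).
#' @param h_min,h_max Step-size bounds (fractions of the range).
#' @param tol Corrector tolerance.
#' @param stability Also classify stability along the branch (slower).
#' @return A `msw_branch`: tibble with `param`, `state` (list column),
#'   `stable`, `leading_re`; attributes `bifurcations` (tibble: `type`
#'   in `"SN"`/`"HB"`, `param`, `state`) and `truncated` flag.
#' @export
continue_branch <- function(rhs, param_range, start_state,
                            max_steps = 2000, h0 = 1e-3, h_min = 1e-5,
                            h_max = 1e-2, tol = 1e-10, stability = TRUE) {
  lo <- min(param_range); hi <- max(param_range)
  span <- hi - lo
  n <- length(start_state)
  F <- function(z) rhs(z[seq_len(n)], z[[n + 1]])
  z <- c(start_state, param_range[[1]])
  sol <- newton_solve(function(x) rhs(x, param_range[[1]]), start_state, tol = tol)
  if (!sol$converged) stop("start_state is not an equilibrium at the range start")
  z[seq_len(n)] <- sol$x

  dir0 <- sign(param_range[2] - param_range[1])
  tang <- branch_tangent(F, z)
  if (is.null(tang)) stop("cannot compute initial branch tangent")
  if (sign(tang[[n + 1]]) != dir0) tang <- -tang

  pts <- list(z)
  tangs <- list(tang)
  h <- h0 * span
  truncated <- FALSE
  for (k in seq_len(max_steps)) {
    zc <- palc_step(F, z, tang, h, tol = tol)
    if (is.null(zc)) {
      h <- h / 2
      if (h < h_min * span) { truncated <- TRUE; break }
      next
    }
    tang_new <- branch_tangent(F, zc, prev_tang = tang)
    if (is.null(tang_new)) { truncated <- TRUE; break }
    z <- zc; tang <- tang_new
    pts[[length(pts) + 1]] <- z
    tangs[[length(tangs) + 1]] <- tang
    h <- min(h * 1.3, h_max * span)
    if (z[[n + 1]] > hi + 1e-9 || z[[n + 1]] < lo - 1e-9) break
  }

  params <- vapply(pts, function(p) p[[n + 1]], numeric(1))
  states <- lapply(pts, function(p) p[seq_len(n)])
  ptang <- vapply(tangs, function(t) t[[n + 1]], numeric(1))

  stable <- rep(NA, length(pts))
  leading <- rep(NA_real_, length(pts))
  eigs <- vector("list", length(pts))
  if (stability) {
    for (i in seq_along(pts)) {
      J <- fd_jacobian(function(x) rhs(x, params[[i]]), states[[i]])
      ev <- eigen(J, only.values = TRUE)$values
      ev <- ev[order(-Re(ev))]
      eigs[[i]] <- ev
      leading[[i]] <- Re(ev[[1]])
      stable[[i]] <- leading[[i]] < -1e-8
    }
  }

  bifs <- list()
  # folds: sign change of the parameter tangent, refined by bisection
  for (i in seq_len(length(pts) - 1)) {
    if (sign(ptang[[i]]) != sign(ptang[[i + 1]]) && ptang[[i]] != 0) {
      fold <- refine_fold(F, pts[[i]], pts[[i + 1]], tangs[[i]], n, tol)
      bifs[[length(bifs) + 1]] <- list(type = "SN", param = fold[[n + 1]],
                                       state = list(fold[seq_len(n)]))
    }
  }
  if (stability) {
    # Hopf: a complex pair crosses the axis while the real leading eigenvalue
    # structure stays away from zero (not a fold)
    for (i in seq_len(length(pts) - 1)) {
      a <- eigs[[i]]; b <- eigs[[i + 1]]
      if (is.null(a) || is.null(b)) next
      ca <- a[abs(Im(a)) > 1e-8]; cb <- b[abs(Im(b)) > 1e-8]
      if (length(ca) && length(cb)) {
        ra <- max(Re(ca)); rb <- max(Re(cb))
        near_fold <- abs(ptang[[i]]) < 0.5 * sqrt(sum(vapply(
          seq_len(n), function(j) tangs[[i]][[j]]^2, numeric(1))))
        if (sign(ra) != sign(rb) && !near_fold) {
          w <- abs(ra) / (abs(ra) + abs(rb))
          bifs[[length(bifs) + 1]] <- list(
            type = "HB",
            param = (1 - w) * params[[i]] + w * params[[i + 1]],
            state = list((1 - w) * states[[i]] + w * states[[i + 1]])
          )
        }
      }
    }
  }

  br <- tibble::tibble(param = params, state = states,
                       stable = stable, leading_re = leading)
  bif_tbl <- if (length(bifs)) {
    dplyr::bind_rows(lapply(bifs, tibble::as_tibble))
  } else {
    tibble::tibble(type = character(), param = numeric(), state = list())
  }
  tibble::new_tibble(br, class = "msw_branch",
                     bifurcations = bif_tbl, truncated = truncated)
}

# bisection on the sign of the parameter tangent between two branch points
refine_fold <- function(F, z1, z2, tang, n, tol, rel_acc = 1e-6) {
  t1 <- branch_tangent(F, z1, tang)
  for (i in 1:40) {
    zm <- (z1 + z2) / 2
    zm_c <- palc_step(F, z1, branch_tangent(F, z1, t1),
                      sqrt(sum((zm - z1)^2)), tol = tol)
    if (is.null(zm_c)) break
    tm <- branch_tangent(F, zm_c, t1)
    if (is.null(tm)) break
    if (sign(tm[[n + 1]]) == sign(t1[[n + 1]])) { z1 <- zm_c; t1 <- tm }
    else z2 <- zm_c
    if (abs(z2[[n + 1]] - z1[[n + 1]]) <
        rel_acc * max(abs(z1[[n + 1]]), 1e-12)) break
  }
  (z1 + z2) / 2
}

#' @export
print.msw_branch <- function(x, ...) {
  bf <- attr(x, "bifurcations")
  cat("<msw_branch>", nrow(x), "points, param in [",
      signif(min(x$param), 4), ",", signif(max(x$param), 4), "]\n")
  if (nrow(bf)) {
    cat("bifurcations:",
        paste(sprintf("%s@%.5g", bf$type, bf$param), collapse = ", "), "\n")
  }
  if (isTRUE(attr(x, "truncated"))) cat("(branch truncated: corrector divergence)\n")
  NextMethod()
}

#' Flatten a branch to a plain tibble
#'
#' One row per branch point with the parameter value, stability flag and one
#' column per state variable; diff-able TSV-ready form.
#'
#' @param branch `msw_branch`.
#' @param state_names Optional state-variable names.
#' @return Tibble.
#' @export
branch_points <- function(branch, state_names = NULL) {
  n <- length(branch$state[[1]])
  nm <- state_names %||% paste0("x", seq_len(n))
  st <- do.call(rbind, branch$state)
  colnames(st) <- nm
  dplyr::bind_cols(
    tibble::tibble(param = branch$param, stable = branch$stable,
                   leading_re = branch$leading_re),
    tibble::as_tibble(st)
  )
}

#' Scan the Ste11 nuclear-import rate of the subsystem
#'
#' Builds the one-parameter bifurcation structure of the Ste11-Mei2-Pat1
#' subsystem with respect to `k_imste11` under fixed nutrient inputs:
#' continuation from the resting state at the lower end of the range, plus
#' additional branches seeded from multi-start equilibria not already
#' covered. Reproduces the sequential double-switch structure of the wild
#' type (Ste11 low / intermediate / high), its collapse without pheromone
#' signalling, and the reversibility of the upper switch without Mei3.
#'
#' @param params Meiosis `msw_params` (possibly with genotype overrides).
#' @param range Parameter interval for `k_imste11`.
#' @param tor2,pka Fixed nutrient inputs (default rich: 1, 1).
#' @param n_starts,seed Oracle settings for seeding extra branches.
#' @return List of `msw_branch` objects (usually one).
#' @export
scan_import_rate <- function(params = default_parameters(),
                             range = c(0.01, 3), tor2 = 1, pka = 1,
                             n_starts = 40, seed = 1) {
  p <- unlist(params)
  rhs <- function(y, val) {
    p2 <- p; p2[["k_imste11"]] <- val
    meiosis_core(pmax(y, 0), p2, tor2, pka, TRUE)$deriv
  }
  p_lo <- p; p_lo[["k_imste11"]] <- range[[1]]
  y0 <- meiosis_rich_state(new_parameter_set(p_lo, "meiosis"))
  branches <- list(continue_branch(rhs, range, as.numeric(y0)))
  # seed disconnected branches from oracle equilibria at mid-range
  mid <- mean(range)
  eq <- find_steady_states(function(y) rhs(y, mid), meiosis_box(p),
                           n_starts = n_starts, seed = seed, relax_time = 400)
  for (st in eq$state) {
    covered <- any(vapply(branches, function(br) {
      i <- which(abs(br$param - mid) < 0.02 * diff(range))
      length(i) && any(vapply(br$state[i], function(s)
        max(abs(s - st)) < 1e-3, logical(1)))
    }, logical(1)))
    if (!covered) {
      b_up <- continue_branch(rhs, c(mid, range[[2]]), st)
      b_dn <- continue_branch(rhs, c(mid, range[[1]]), st)
      branches <- c(branches, list(b_up, b_dn))
    }
  }
  branches
}

# search box for subsystem equilibria (bounds scale with the synthesis rates)
meiosis_box <- function(p) {
  smax <- (p[["ks_ste11_0"]] +
             (p[["a_rpol"]] + p[["k_rpol"]]) *
             (p[["ks_ste11r"]] + p[["ks_ste11a"]])) / p[["kd_ste11"]]
  mmax <- (p[["ks_mei2"]] * (p[["a_mei2"]] + 1) + p[["ks_mei2_const"]]) /
    min(p[["kd_mei2a"]], p[["kd_mei2p"]] * p[["w_dmei2"]])
  # start with the Mei3 pools and the Pat1:Mei3 complex near empty: the flow
  # builds the tightly bound complex quickly but drains it only on the slow
  # leak timescale, so complex-loaded random starts never settle in time
  cbind(lower = rep(0, 8),
        upper = c(2 * smax, 2 * smax, 2 * mmax, 2 * mmax,
                  2 * p[["k_sphe"]] / p[["kd_phe"]],
                  2 * p[["k_spm"]] / p[["kd_pm"]],
                  0.05 * p[["pat1_t"]], 0.02 * p[["pat1_t"]]))
}

#' Cell-mass bifurcation diagram of the integrated model
#'
#' Treats cell mass as the bifurcation parameter (growth frozen) and follows
#' the equilibria of the cell-cycle block, reporting Cdk1:Cdc13 activity
#' against mass with stability and SN/HB annotations. Under rich conditions
#' the diagram shows three stable branches (G1 low, S/G2 intermediate, M
#' high Cdk1); under starvation the intermediate branch disappears, and the
#' G1/S fold moves to smaller mass without pheromone signalling and to
#' larger mass with it.
#'
#' @param params Integrated `msw_params`.
#' @param mass_range Mass interval.
#' @param condition `"rich"` or `"starved"`.
#' @param phes For starved diagrams: frozen PheS level (0 = absent;
#'   `NULL` = the wild-type starved plateau).
#' @param npool Frozen nitrogen-pool level (default 1).
#' @param n_starts,seed Oracle settings for seeding branches.
#' @param h_max Arclength step-size cap passed to [continue_branch()].
#' @return List of `msw_branch` objects over the cell-cycle states, with a
#'   `cc_state_names` attribute.
#' @export
cellmass_diagram <- function(params = default_parameters("integrated"),
                             mass_range = c(0.3, 4),
                             condition = c("rich", "starved"),
                             phes = 0, npool = 1,
                             n_starts = 60, seed = 1, h_max = 2e-2) {
  condition <- match.arg(condition)
  p <- unlist(params)
  if (condition == "rich") {
    tor2 <- 1; pka <- 1; igo <- 0
  } else {
    tor2 <- 0; pka <- 0.75
    if (is.null(phes)) {
      mp <- new_parameter_set(p[names(.meiosis_defaults)], "meiosis")
      phes <- starved_reference(mp)[["phes"]]
    }
    # starved steady Igo1-P (Ppk18 active)
    igo <- p[["ki_igo"]] / (p[["ki_igo"]] + p[["kd_igo"]])
  }
  ext <- tor2 * pka
  nut <- ext + (1 - ext) * npool
  cc_names <- c("cdc13t", "prempf", "ste9", "slp1t", "slp1", "iep", "rum1t", "sk")
  rhs <- function(y, mass) {
    yy <- numeric(19)
    yy[9:16] <- pmax(y, 0)
    yy[17] <- mass; yy[18] <- npool; yy[19] <- igo
    cellcycle_block(yy, p, tor2, pka, phes)$deriv[1:8]
  }
  box <- cbind(lower = rep(0, 8),
               upper = c(6, 6, 1, 2.5, 2.5, 1, 15, 1.2))
  # archetype seeds: G1 (Rum1/Ste9 on, cyclin low), S/G2 (preMPF high) and
  # M (cyclin high, inhibitors off)
  archetypes <- list(
    c(0.02, 0.005, 1, 0.05, 0.01, 0.02, 10, 0),
    c(1.2, 1.1, 0.005, 0.1, 0.02, 0.05, 0.1, 1),
    c(1.5, 0.05, 0.002, 1, 0.5, 0.8, 0.05, 1)
  )
  branches <- list()
  anchors <- c(mass_range[[1]], mean(mass_range), mass_range[[2]])
  for (ai in seq_along(anchors)) {
    m0 <- anchors[[ai]]
    eq <- find_steady_states(function(y) rhs(y, m0), box,
                             n_starts = n_starts, seed = seed + ai,
                             extra_starts = archetypes, relax_time = 200)
    for (st in eq$state) {
      covered <- any(vapply(branches, function(br) {
        i <- which(abs(br$param - m0) < 0.02 * diff(mass_range))
        length(i) && any(vapply(br$state[i], function(s)
          max(abs(s - st)) < 1e-3, logical(1)))
      }, logical(1)))
      if (covered) next
      if (m0 > mass_range[[1]]) {
        branches <- c(branches,
                      list(continue_branch(rhs, c(m0, mass_range[[2]]), st,
                                           h_max = h_max),
                           continue_branch(rhs, c(m0, mass_range[[1]]), st,
                                           h_max = h_max)))
      } else {
        branches <- c(branches,
                      list(continue_branch(rhs, mass_range, st, h_max = h_max)))
      }
    }
  }
  for (i in seq_along(branches)) attr(branches[[i]], "cc_state_names") <- cc_names
  structure(branches, kdiss = p[["kdiss"]], cc_state_names = cc_names)
}

#' Cdk1 activity along a cell-mass branch
#'
#' @param branch A branch from [cellmass_diagram()].
#' @param kdiss Rum1:Cdk1 trimer dissociation constant of the parameter set.
#' @return Tibble `mass`, `mpf`, `stable`.
#' @export
branch_cdk_activity <- function(branch, kdiss) {
  st <- do.call(rbind, branch$state)
  tibble::tibble(
    mass = branch$param,
    mpf = cc_active_mpf(st[, 1], st[, 2], st[, 7], kdiss),
    stable = branch$stable
  )
}

#' Polished equilibrium on a branch at a given parameter value
#'
#' Takes the branch point nearest to `param`, fixes the parameter, and
#' Newton-polishes the state back onto the equilibrium manifold. Used for
#' oracle-versus-continuation cross-validation at machine accuracy.
#'
#' @param branch `msw_branch`.
#' @param rhs The `rhs(state, value)` used to build the branch.
#' @param param Parameter value.
#' @param near Optional state; among candidate branch points, prefer the
#'   one closest to it (disambiguates multivalued S-curves).
#' @return Polished state vector, or `NULL` if no branch point lies near
#'   `param` or polishing fails.
#' @export
branch_equilibrium_at <- function(branch, rhs, param, near = NULL) {
  span <- max(branch$param) - min(branch$param)
  idx <- which(abs(branch$param - param) < 0.05 * span)
  if (!length(idx)) return(NULL)
  if (!is.null(near)) {
    d <- vapply(branch$state[idx], function(s) max(abs(s - near)), numeric(1))
    idx <- idx[order(d)]
  } else {
    idx <- idx[order(abs(branch$param[idx] - param))]
  }
  for (i in utils::head(idx, 3)) {
    sol <- newton_solve(function(x) rhs(x, param), branch$state[[i]],
                        tol = 1e-11, max_iter = 50)
    if (sol$converged) return(sol$x)
  }
  NULL
}
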