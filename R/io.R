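#' Write a trajectory to CSV
#'
#' Writes both a wide table (one column per variable) and a tidy long table
#' (`time`, `variable`, `value`), plus an event log when the trajectory
#' carries division/input events.
#'
#' @param traj `msw_trajectory`.
#' @param out_dir Output directory (created if needed).
#' @param stem File-name stem (default `"trajectory"`).
#' @return Character vector of the files written, invisibly.
#' @export
write_trajectory <- function(traj, out_dir, stem = "trajectory") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wide <- file.path(out_dir, paste0(stem, "_wide.csv"))
  long <- file.path(out_dir, paste0(stem, "_tidy.csv"))
  utils::write.csv(as.data.frame(traj), wide, row.names = FALSE)
  utils::write.csv(as.data.frame(tidy_trajectory(traj)), long, row.names = FALSE)
  files <- c(wide, long)
  ev <- attr(traj, "events")
  if (!is.null(ev) && nrow(ev)) {
    evf <- file.path(out_dir, paste0(stem, "_events.csv"))
    utils::write.csv(as.data.frame(ev), evf, row.names = FALSE)
    files <- c(files, evf)
  }
  invisible(files)
}

#' Export bifurcation branches as TSV
#'
#' One row per branch point (`branch_id`, `param`, state components,
#' `stable`) plus a companion `<stem>_points.tsv` with the annotated
#' bifurcation points — a diff-able plain-text form whose invariants can be
#' re-verified after reloading.
#'
#' @param branches A `msw_branch` or list of them.
#' @param out_dir Output directory.
#' @param stem File-name stem.
#' @param state_names Optional state-variable names.
#' @return Character vector of the files written, invisibly.
#' @export
write_branches <- function(branches, out_dir, stem = "branch",
                           state_names = NULL) {
  if (inherits(branches, "msw_branch")) branches <- list(branches)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pts <- dplyr::bind_rows(lapply(seq_along(branches), function(i) {
    dplyr::mutate(branch_points(branches[[i]], state_names), branch_id = i,
                  .before = 1)
  }))
  bifs <- dplyr::bind_rows(lapply(seq_along(branches), function(i) {
    bf <- attr(branches[[i]], "bifurcations")
    if (!nrow(bf)) return(NULL)
    tibble::tibble(branch_id = i, type = bf$type, param = bf$param)
  }))
  f1 <- file.path(out_dir, paste0(stem, ".tsv"))
  f2 <- file.path(out_dir, paste0(stem, "_points.tsv"))
  utils::write.table(as.data.frame(pts), f1, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(as.data.frame(if (is.null(bifs) || !nrow(bifs))
    data.frame(branch_id = integer(), type = character(), param = numeric())
    else bifs), f2, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(f1, f2))
}

#' Write a screen report
#'
#' @param screen `msw_screen` from [run_screen()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen <- function(screen, path) {
  df <- as.data.frame(screen)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write run artifacts with a content-hash manifest
#'
#' Deterministic file names; the manifest lists every file with a content
#' hash (serialized-object hash of the file bytes), the parameter provenance
#' and the seed, so two runs with the same configuration produce
#' byte-identical outputs.
#'
#' @param artifacts Named list of objects; trajectories, screens and branch
#'   lists are dispatched to their writers, other objects are saved as CSV
#'   when data-frame-like.
#' @param out_dir Output directory.
#' @param params Parameter set used (recorded in the manifest).
#' @param seed Seed used (recorded in the manifest).
#' @return Tibble manifest (also written to `manifest.tsv`).
#' @export
write_report <- function(artifacts, out_dir, params = NULL, seed = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in names(artifacts)) {
    a <- artifacts[[nm]]
    files <- c(files, if (inherits(a, "msw_trajectory")) {
      write_trajectory(a, out_dir, stem = nm)
    } else if (inherits(a, "msw_screen")) {
      write_screen(a, file.path(out_dir, paste0(nm, ".csv")))
    } else if (inherits(a, "msw_branch") ||
               (is.list(a) && length(a) && inherits(a[[1]], "msw_branch"))) {
      write_branches(a, out_dir, stem = nm)
    } else if (is.data.frame(a)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(as.data.frame(a), f, row.names = FALSE)
      f
    } else {
      f <- file.path(out_dir, paste0(nm, ".txt"))
      writeLines(utils::capture.output(print(a)), f)
      f
    })
  }
  if (!is.null(params)) {
    pf <- file.path(out_dir, "parameters.ode")
    write_parameters(params, pf)
    files <- c(files, pf)
  }
  manifest <- tibble::tibble(
    file = basename(files),
    bytes = vapply(files, function(f) file.size(f), numeric(1)),
    sha = vapply(files, hash_file, character(1), USE.NAMES = FALSE),
    seed = seed
  )
  utils::write.table(as.data.frame(manifest), file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest
}

# content hash (md5 from base tools; no extra dependency)
hash_file <- function(path) {
  unname(tools::md5sum(path))
}
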