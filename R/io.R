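# Serialization: trajectories as CSV with a JSON sidecar, analysis reports
# as JSON (full double precision), and run manifests for reproducibility.

#' Write a trajectory to CSV
#'
#' Columns `time_min`, `day` and one column per state variable; a JSON
#' sidecar (`<path>.json`) records the model tag, step, delay and package
#' version.
#'
#' @param traj A `grn_trajectory`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "grn_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- list(model = attr(traj, "model"),
               step_min = attr(traj, "step_min"),
               delta_min = attr(traj, "delta_min"),
               package_version = as.character(utils::packageVersion("floradyn")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return A `grn_trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list(model = "unknown", step_min = NA_real_, delta_min = NA_real_)
  vars <- setdiff(names(df), c("time_min", "day"))
  .make_trajectory(df$time_min, as.matrix(df[vars]), meta$model,
                   meta$step_min, meta$delta_min)
}

#' Write an analysis report as JSON
#'
#' Serialises steady-state lists, stability reports, bifurcation results,
#' Lyapunov checks or plain lists to JSON at full double precision (values
#' survive a write/read round trip exactly).
#'
#' @param x Report object (any list-like structure of numerics/strings).
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(x, path) {
  x <- .unclass_deep(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       complex = "list")
  invisible(path)
}

.unclass_deep <- function(x) {
  if (is.complex(x)) {
    return(list(re = Re(x), im = Im(x)))
  }
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, .unclass_deep))
  }
  if (is.matrix(x)) return(apply(x, 1, identity, simplify = FALSE))
  x
}

#' Read a JSON report
#'
#' @param path JSON path.
#' @return Nested list with vectors simplified.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the configuration (flattened),
#' the seed, and the package version.
#'
#' @param config Named list describing the run.
#' @param path Output JSON path.
#' @param seed Seed used (if any).
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(config, path, seed = NULL) {
  man <- list(config = .unclass_deep(config), seed = seed,
              package_version = as.character(utils::packageVersion("floradyn")),
              r_version = R.version.string)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
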