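#' Write a trajectory set to delimited text
#'
#' State time series are written as tab-separated text with columns
#' `trajectory_id`, `time`, `state_1 .. state_n` (for PDE fields:
#' `trajectory_id`, `time`, `x`, `u` in long format), plus a YAML sidecar
#' `<path>.meta.yaml` holding step, noise level and role.
#'
#' @param ts a `trajectory_set`.
#' @param path output file path.
#' @param spatial_grid spatial grid for PDE field sets (switches to long
#'   format).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ts, path, spatial_grid = NULL) {
  rows <- lapply(seq_along(ts$trajectories), function(i) {
    tr <- ts$trajectories[[i]]
    if (is.null(spatial_grid)) {
      df <- data.frame(trajectory_id = i, time = tr$times)
      st <- as.data.frame(tr$states)
      names(st) <- paste0("state_", seq_len(ncol(st)))
      cbind(df, st)
    } else {
      data.frame(trajectory_id = i,
                 time = rep(tr$times, each = length(spatial_grid)),
                 x = rep(spatial_grid, length(tr$times)),
                 u = as.vector(t(tr$states)))
    }
  })
  df <- do.call(rbind, rows)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(schema = "sindyic/trajectories/v1",
               step = ts$step, noise_sd = ts$noise_sd, role = ts$role,
               n_trajectories = length(ts$trajectories),
               format = if (is.null(spatial_grid)) "wide" else "long")
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a trajectory set from delimited text
#'
#' Inverse of [write_trajectories()] (wide format). Malformed rows raise a
#' parse error naming the offending line; an empty file is an error.
#'
#' @param path file written by [write_trajectories()].
#' @return a `trajectory_set`.
#' @export
load_trajectories <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path)
  if (length(raw) <= 1L) stop("empty trajectory file: ", path)
  header <- strsplit(raw[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "trajectory_id" || header[2] != "time")
    stop("unrecognized header; expected trajectory_id, time, state_*")
  n_col <- length(header)
  fields <- strsplit(raw[-1], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != n_col)
  if (length(bad))
    stop(sprintf("parse error at line %d: expected %d columns, found %d",
                 bad[1] + 1L, n_col, lengths(fields)[bad[1]]))
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  num <- df[, -1, drop = FALSE]
  if (anyNA(num))
    stop(sprintf("parse error at line %d: non-numeric value",
                 which(!stats::complete.cases(num))[1] + 1L))
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  ids <- unique(df$trajectory_id)
  trajectories <- lapply(ids, function(id) {
    sub <- df[df$trajectory_id == id, , drop = FALSE]
    states <- as.matrix(sub[, -(1:2), drop = FALSE])
    dimnames(states) <- NULL
    new_trajectory(x0 = states[1, ], times = sub$time, states = states)
  })
  trajectory_set(trajectories,
                 noise_sd = if (!is.null(meta$noise_sd)) meta$noise_sd else 0,
                 step = if (!is.null(meta$step)) meta$step else NULL,
                 role = if (!is.null(meta$role)) meta$role else "training")
}

#' Write a selection report to disk
#'
#' Emits the ranked score table as tab-separated text plus a YAML summary
#' (selected model equations, category counts, configuration and seed).
#'
#' @param report a `selection_report`.
#' @param path base path; writes `<path>.tsv` and `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(report$scores, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mode <- switch(report$kind, ode = "derivative", map = "next_state", pde = "pde")
  cfg <- report$config
  summary <- list(
    schema = "sindyic/report/v1",
    n_candidates = nrow(report$scores),
    m_obs = report$scores$m_obs[1],
    counts = report$counts,
    selected = if (is.null(report$selected)) NULL else list(
      k = report$selected$k,
      equations = format_model(report$selected, report$library, mode)),
    truth_recovered = if (is.na(report$truth_recovered)) NULL
                      else report$truth_recovered,
    config = cfg[!vapply(cfg, is.null, TRUE)])
  yaml::write_yaml(summary, paste0(path, ".yaml"))
  invisible(path)
}

#' Read and write selection configurations as YAML
#'
#' @param path YAML file.
#' @return `read_config()` returns a `selection_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(selection_config, vals)
}

#' @rdname read_config
#' @param config a `selection_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], path)
  invisible(path)
}
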