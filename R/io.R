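# Trajectory tables, JSON run configurations, and the run() driver.
# Trajectories are plain CSV with a commented schema header so they can be
# inspected from any language; configurations are JSON written at full
# double precision (17 significant digits) for lossless round trips.

.traj_schema <- "ratemoments trajectory v1"

#' Write / read a statistic trajectory
#'
#' CSV with a commented header carrying the schema version, method tag and
#' cell count, then one row per time with columns \code{time},
#' \code{mean_x_j}, \code{var_x_j}, \code{cov_x_j_k} (pairs \eqn{j < k}),
#' \code{mean_nu_j}, \code{var_nu_j}, \code{cov_nu_j_k}. Values are written
#' with 17 significant digits, so write-then-read is lossless; columns are
#' mapped by name on read, so reordered (legacy) column layouts are
#' accepted.
#'
#' @param traj a \code{\link{stat_trajectory}}.
#' @param path file path.
#' @return \code{write_trajectory} returns \code{path} invisibly;
#'   \code{read_trajectory} returns a \code{stat_trajectory}.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "stat_trajectory"))
  df <- as.data.frame(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", .traj_schema),
               paste0("# method: ", traj$method),
               paste0("# n_cells: ", traj$n_cells)), con)
  writeLines(paste(colnames(df), collapse = ","), con)
  body <- apply(vapply(df, function(col) formatC(col, digits = 17,
                                                 format = "g"),
                       character(nrow(df))),
                1, paste, collapse = ",")
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5L || !identical(lines[1], paste0("# ", .traj_schema)))
    stop("read_trajectory: schema mismatch (expected '", .traj_schema,
         "', found '", if (length(lines)) lines[1] else "<empty>", "')")
  method <- sub("^# method: ", "", lines[2])
  n <- as.integer(sub("^# n_cells: ", "", lines[3]))
  if (is.na(n)) stop("read_trajectory: malformed n_cells header")
  df <- utils::read.csv(text = paste(lines[-(1:3)], collapse = "\n"),
                        check.names = FALSE)
  pr <- pair_index(n)
  pair_nm <- if (nrow(pr)) paste0(pr[, 1], "_", pr[, 2]) else character(0)
  need <- c("time", paste0("mean_x_", 1:n), paste0("var_x_", 1:n),
            if (nrow(pr)) paste0("cov_x_", pair_nm),
            paste0("mean_nu_", 1:n), paste0("var_nu_", 1:n),
            if (nrow(pr)) paste0("cov_nu_", pair_nm))
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("read_trajectory: schema mismatch, missing column(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  block <- function(stem, nm) unname(as.matrix(df[paste0(stem, "_", nm)]))
  stat_trajectory(df$time,
                  block("mean_x", 1:n), block("var_x", 1:n),
                  if (nrow(pr)) block("cov_x", pair_nm) else
                    matrix(0, nrow(df), 0),
                  block("mean_nu", 1:n), block("var_nu", 1:n),
                  if (nrow(pr)) block("cov_nu", pair_nm) else
                    matrix(0, nrow(df), 0),
                  method = method)
}

#' Read a matrix from headerless CSV
#'
#' Row-major plain CSV without a header, the interchange format for
#' correlation and coupling matrices.
#' @param path file path.
#' @return a numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE))
}

# ---- network <-> plain-list serialization ---------------------------------

.signal_to_list <- function(sig) c(list(kind = sig$kind), sig$params)

.signal_from_list <- function(x) do.call(input_signal, x)

#' Serialize a network specification to a plain list / JSON
#'
#' The list form round-trips through JSON bit-exactly for integer fields
#' and to 17 significant digits for reals.
#' @param spec a \code{\link{network_spec}}.
#' @return a plain list (for \code{network_to_list}); a
#'   \code{network_spec} (for \code{network_from_list}).
#' @export
network_to_list <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  fiv <- .fi_vectors(spec)
  out <- list(n_cells = spec$n_cells, tau = spec$tau, mu_bg = spec$mu_bg,
              sigma_bg = spec$sigma_bg,
              corr = apply(spec$corr, 1, identity, simplify = FALSE),
              coupling = apply(spec$coupling, 1, identity, simplify = FALSE),
              x_rev = fiv$x_rev, x_sp = fiv$x_sp)
  if (length(spec$inputs)) {
    out$inputs <- lapply(spec$inputs, .signal_to_list)
    out$input_mode <- as.list(spec$input_mode)
  }
  out
}

#' @rdname network_to_list
#' @param x a list as produced by \code{network_to_list} (or parsed from
#'   JSON).
#' @export
network_from_list <- function(x) {
  n <- as.integer(x$n_cells)
  asmat <- function(m) {
    if (is.list(m)) m <- do.call(rbind, m)
    matrix(as.numeric(m), n, n)
  }
  inputs <- if (!is.null(x$inputs)) lapply(x$inputs, .signal_from_list)
            else list()
  mode <- if (!is.null(x$input_mode)) unlist(x$input_mode) else NULL
  network_spec(as.numeric(x$tau), as.numeric(x$mu_bg),
               as.numeric(x$sigma_bg), asmat(x$corr), asmat(x$coupling),
               Map(fi_params, as.numeric(x$x_rev), as.numeric(x$x_sp)),
               inputs = inputs, input_mode = mode)
}

# ---- run configuration ----------------------------------------------------

#' Run configuration
#'
#' A self-describing recipe for a full run: where the network comes from
#' (sampled with a seed, or explicit), the input signals, which methods to
#' run, the time grid and all solver/MC settings. Round-trips losslessly
#' through JSON via \code{\link{write_config}} / \code{\link{read_config}}.
#'
#' @param seed master integer seed (fanned out to named substreams, see
#'   \code{\link{derive_seed}}).
#' @param network either \code{list(kind = "sampled", n_cells =,
#'   coupling_scale =)} or \code{list(kind = "explicit", spec =
#'   network_to_list(...))}.
#' @param inputs named list of input-signal definitions (as plain lists,
#'   see \code{\link{input_signal}}), keyed by \code{"mu_bg"} /
#'   \code{"sigma_bg"}.
#' @param method one of \code{"closure"}, \code{"qss"}, \code{"mc"},
#'   \code{"all"}.
#' @param times \code{list(from =, to =, by =)}.
#' @param quad_order,rtol,atol,firing_corr see \code{\link{closure_config}}.
#' @param mc \code{list(n_realizations =, dt =, group_size =, burn_in =)}
#'   (\code{dt}/\code{burn_in} may be \code{NULL} for defaults).
#' @param out_dir output directory, or \code{NULL} to skip writing.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(seed, network, inputs = list(mu_bg =
                         .signal_to_list(default_pulse())),
                       method = c("all", "closure", "qss", "mc"),
                       times = list(from = 0, to = 10, by = 0.1),
                       quad_order = 40L, rtol = 1e-8, atol = 1e-10,
                       firing_corr = "dynamic",
                       mc = list(n_realizations = 10000L, dt = 0.01,
                                 group_size = 1000L),
                       out_dir = NULL) {
  method <- match.arg(method)
  stopifnot(is.list(network), !is.null(network$kind),
            network$kind %in% c("sampled", "explicit"))
  structure(list(seed = as.integer(seed), network = network,
                 inputs = inputs, method = method, times = times,
                 quad_order = as.integer(quad_order), rtol = rtol,
                 atol = atol, firing_corr = firing_corr, mc = mc,
                 out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#' @param config a \code{\link{run_config}}.
#' @param path file path.
#' @return \code{read_config} returns a \code{run_config}.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
  x$out_dir <- x$out_dir %||% NULL
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# resolve the network named by a config (sampling if requested)
.resolve_network <- function(config) {
  inputs <- lapply(config$inputs, .signal_from_list)
  if (config$network$kind == "sampled") {
    sample_network(as.integer(config$network$n_cells),
                   coupling_scale = config$network$coupling_scale %||% 1,
                   seed = derive_seed(config$seed, "network"),
                   inputs = inputs)
  } else {
    spec <- network_from_list(config$network$spec)
    if (length(inputs)) spec <- set_inputs(spec, inputs)
    spec
  }
}

#' Execute a run configuration
#'
#' Resolves the network, runs the selected method(s), and (if
#' \code{out_dir} is set) writes one trajectory table per method, the fully
#' resolved configuration (including the explicit sampled network, so every
#' run is reproducible from its persisted config alone), and — when at
#' least two methods ran and one of them is Monte Carlo — an error report
#' comparing each approximate method against the MC reference.
#'
#' @param config a \code{\link{run_config}}.
#' @return invisibly, \code{list(spec, trajectories, reports)}.
#' @export
run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  spec <- .resolve_network(config)
  cc <- closure_config(config$quad_order, config$rtol, config$atol,
                       firing_corr = config$firing_corr)
  tms <- seq(config$times$from, config$times$to, by = config$times$by)
  methods <- if (config$method == "all") c("closure", "qss", "mc")
             else config$method
  trajectories <- list()
  bands <- NULL
  for (m in methods) {
    trajectories[[m]] <- switch(m,
      closure = integrate_closure(spec, cc, tms),
      qss = qss_trajectory(spec, tms, cc),
      mc = {
        est <- simulate_ensemble(spec, tms,
                                 n_realizations = config$mc$n_realizations,
                                 dt = config$mc$dt %||% NULL,
                                 seed = derive_seed(config$seed, "mc"),
                                 group_size = config$mc$group_size %||% 1000L,
                                 burn_in = config$mc$burn_in %||% NULL)
        bands <- est$bands
        est$trajectory
      })
  }
  reports <- list()
  if ("mc" %in% names(trajectories)) {
    for (m in setdiff(names(trajectories), "mc"))
      reports[[m]] <- error_report(trajectories[[m]], trajectories$mc,
                                   meta = list(method = m, seed = config$seed))
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    resolved <- config
    resolved$network <- list(kind = "explicit",
                             spec = network_to_list(spec))
    write_config(resolved, file.path(config$out_dir, "resolved_config.json"))
    for (m in names(trajectories))
      write_trajectory(trajectories[[m]],
                       file.path(config$out_dir,
                                 paste0("trajectory_", m, ".csv")))
    if (length(reports)) {
      for (m in names(reports))
        utils::write.csv(as.data.frame(reports[[m]]),
                         file.path(config$out_dir,
                                   paste0("errors_", m, "_vs_mc.csv")),
                         row.names = FALSE)
      summary <- lapply(reports, function(r)
        list(grand = r$grand, per_family = as.list(r$per_family)))
      jsonlite::write_json(summary,
                           file.path(config$out_dir, "error_summary.json"),
                           auto_unbox = TRUE, digits = I(17), pretty = TRUE)
    }
  }
  invisible(list(spec = spec, trajectories = trajectories,
                 reports = reports, bands = bands))
}
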