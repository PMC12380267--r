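#' Simulation settings
#'
#' The three numbers a user specifies before running a model: initial time,
#' reporting time step (temporal discretization of the *output*, not of the
#' solver, which steps adaptively), and end time. Axis labels annotate plots
#' and reports.
#'
#' @param start_time Initial time t0.
#' @param time_step Output grid spacing, > 0.
#' @param end_time Final time, >= `start_time`.
#' @param x_label,y_label Plot axis labels.
#' @param rel_tol,abs_tol Solver relative/absolute tolerances.
#' @param method `"ode45"` (adaptive explicit Runge-Kutta 5(4), the
#'   default) or `"lsoda"` (stiff-capable alternative).
#' @return An object of class `ode_sim_config`.
#' @export
sim_config <- function(start_time = 0, time_step = 0.1, end_time = 50,
                       x_label = "t", y_label = "population",
                       rel_tol = 1e-6, abs_tol = 1e-9, method = "ode45") {
  if (!is.numeric(time_step) || length(time_step) != 1 || time_step <= 0)
    stop_odegraph("odegraph_config_error", "time_step must be > 0")
  if (!is.numeric(start_time) || !is.numeric(end_time) ||
      !is.finite(start_time) || !is.finite(end_time) ||
      end_time < start_time)
    stop_odegraph("odegraph_config_error",
                  "need finite start_time <= end_time")
  if (!method %in% c("ode45", "lsoda"))
    stop_odegraph("odegraph_config_error",
                  sprintf("unknown solver method \"%s\"", method))
  structure(list(start_time = as.numeric(start_time),
                 time_step = as.numeric(time_step),
                 end_time = as.numeric(end_time),
                 x_label = as.character(x_label),
                 y_label = as.character(y_label),
                 rel_tol = as.numeric(rel_tol),
                 abs_tol = as.numeric(abs_tol),
                 method = method),
            class = "ode_sim_config")
}

#' Store simulation settings in a model
#'
#' @param graph A model graph.
#' @param config A [sim_config()].
#' @return The updated graph.
#' @export
set_sim_config <- function(graph, config) {
  stopifnot(is_model_graph(graph), inherits(config, "ode_sim_config"))
  graph$sim <- config
  graph
}

# Reporting grid built by count rather than accumulation, so grid points are
# start + k*step exactly; end_time is on the grid iff (end-start)/step is an
# integer (to within one part in 1e9 of a step).
time_grid <- function(config) {
  n <- floor((config$end_time - config$start_time) / config$time_step + 1e-9)
  config$start_time + seq(0, n) * config$time_step
}

refuse_invalid <- function(graph, what) {
  violations <- validate_model(graph)
  if (nrow(violations) > 0L)
    stop_odegraph("odegraph_validation_error",
                  sprintf("%s refused: model has %d validation violation(s); first: %s",
                          what, nrow(violations), violations$message[[1]]),
                  violations = violations)
  invisible(violations)
}

#' Compile a model's ODE right-hand side
#'
#' Builds each assigner's expression tree once and returns a derivative
#' function `f(t, state)` suitable for an initial-value-problem solver:
#' `state` is a named vector over the model's state variables, and the
#' returned derivatives follow [classify_terms()] order. Constants are bound
#' from their term values; state variables from the vector.
#'
#' @param graph A valid model graph ([validate_model()] must be clean).
#' @return A function `(t, state) -> named numeric vector`.
#' @export
compile_rhs <- function(graph) {
  stopifnot(is_model_graph(graph))
  refuse_invalid(graph, "compile_rhs")
  cls <- classify_terms(graph)
  nm <- term_name_map(graph)
  var_names <- unname(nm[cls$variables])
  constants <- vapply(cls$constants, function(id) graph$nodes[[id]]$value, 0.0)
  names(constants) <- nm[cls$constants]
  trees <- lapply(cls$variables, function(vid) {
    asn <- Filter(function(a) identical(a$target, vid),
                  assigner_nodes(graph))[[1]]
    build_expression_tree(graph, asn$id)
  })
  extensions <- graph$extensions
  function(t, state) {
    bindings <- c(as.list(state), as.list(constants))
    out <- vapply(trees, evaluate_tree, 0.0,
                  bindings = bindings, extensions = extensions)
    names(out) <- var_names
    out
  }
}

#' Simulate a model
#'
#' Integrates the compiled ODE system with an adaptive-step solver
#' (deSolve), reporting the solution on the fixed time grid implied by the
#' configuration. The solver's internal stepping is independent of the
#' reporting grid.
#'
#' @param graph A valid model graph.
#' @param config Simulation settings; defaults to the model's stored
#'   configuration.
#' @return An `ode_sim_result`: list with `times`, `trajectories` (matrix,
#'   one column per state variable), `variable_names`, and the axis labels.
#' @export
simulate_model <- function(graph, config = NULL) {
  stopifnot(is_model_graph(graph))
  if (is.null(config)) config <- graph$sim
  stopifnot(inherits(config, "ode_sim_config"))
  refuse_invalid(graph, "simulate")
  cls <- classify_terms(graph)
  nm <- term_name_map(graph)
  var_names <- unname(nm[cls$variables])
  y0 <- vapply(cls$variables, function(id) graph$nodes[[id]]$value, 0.0)
  names(y0) <- var_names
  times <- time_grid(config)
  if (length(times) < 2L) {
    traj <- matrix(y0, nrow = 1, dimnames = list(NULL, var_names))
    return(new_sim_result(times[1], traj, var_names, config))
  }
  rhs <- compile_rhs(graph)
  func <- function(t, y, parms) list(rhs(t, y))
  sol <- tryCatch(
    deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                 method = config$method,
                 rtol = config$rel_tol, atol = config$abs_tol),
    error = function(e) {
      if (inherits(e, "odegraph_error")) stop(e)
      stop_odegraph("odegraph_simulation_error",
                    sprintf("integration failed: %s", conditionMessage(e)))
    })
  sol <- unclass(sol)
  if (nrow(sol) < length(times) || any(!is.finite(sol)))
    stop_odegraph("odegraph_simulation_error", sprintf(
      "integration failed near t = %g (non-finite solution or premature stop)",
      sol[nrow(sol), 1]))
  new_sim_result(sol[, 1], sol[, -1, drop = FALSE], var_names, config)
}

new_sim_result <- function(times, trajectories, variable_names, config) {
  colnames(trajectories) <- variable_names
  structure(list(times = as.numeric(times),
                 trajectories = trajectories,
                 variable_names = variable_names,
                 x_label = config$x_label, y_label = config$y_label),
            class = "ode_sim_result")
}

#' @export
print.ode_sim_result <- function(x, ...) {
  cat(sprintf("<simulation result> %d variables x %d time points (t = %g..%g)\n",
              length(x$variable_names), length(x$times),
              x$times[1], x$times[length(x$times)]))
  cat("  final state:\n")
  final <- x$trajectories[nrow(x$trajectories), ]
  for (v in x$variable_names)
    cat(sprintf("    %s = %g\n", v, final[[v]]))
  invisible(x)
}

# Shortest decimal that round-trips the double exactly.
fmt_dbl <- function(x) {
  vapply(x, function(xi) {
    for (d in 15:17) {
      s <- sprintf("%.*g", d, xi)
      if (as.numeric(s) == xi) return(s)
    }
    sprintf("%.17g", xi)
  }, "")
}

csv_quote <- function(x) {
  needs <- grepl("[\",\n]", x)
  x[needs] <- paste0("\"", gsub("\"", "\"\"", x[needs]), "\"")
  x
}

#' Write simulation results to CSV
#'
#' Header is `t` followed by the variable names; one row per grid point.
#' Values are written as the shortest decimal that parses back to the exact
#' double, so reading the file reproduces the trajectories bit-for-bit.
#'
#' @param result An `ode_sim_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(result, path) {
  stopifnot(inherits(result, "ode_sim_result"))
  header <- paste(csv_quote(c("t", result$variable_names)), collapse = ",")
  body <- apply(cbind(result$times, result$trajectories), 1,
                function(row) paste(fmt_dbl(row), collapse = ","))
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    stop_odegraph("odegraph_io_error", sprintf("cannot write %s", path))
  invisible(path)
}

#' Read a simulation-results CSV back into a result object
#'
#' @param path A CSV written by [write_sim_csv()] (or by a generated
#'   simulation script, which uses the same layout).
#' @return An `ode_sim_result`.
#' @export
read_sim_csv <- function(path) {
  if (!file.exists(path))
    stop_odegraph("odegraph_io_error", sprintf("no such file: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  vars <- colnames(df)[-1]
  traj <- as.matrix(df[, -1, drop = FALSE])
  new_sim_result(df[[1]], traj, vars,
                 sim_config(start_time = min(df[[1]]), end_time = max(df[[1]]),
                            x_label = colnames(df)[1], y_label = "value"))
}

plot_result_pages <- function(result, title) {
  times <- result$times
  traj <- result$trajectories
  vars <- result$variable_names
  cols <- grDevices::hcl.colors(max(3L, length(vars)), "Dark 3")
  graphics::matplot(times, traj, type = "l", lty = 1, lwd = 2, col = cols,
                    xlab = result$x_label, ylab = result$y_label,
                    main = title)
  graphics::legend("topright", legend = vars, col = cols[seq_along(vars)],
                   lty = 1, lwd = 2, bty = "n")
  for (j in seq_along(vars))
    graphics::plot(times, traj[, j], type = "l", lwd = 2, col = cols[j],
                   xlab = result$x_label, ylab = result$y_label,
                   main = vars[j])
}

#' Render a multi-page PDF report of a simulation
#'
#' Page 1 overlays every state variable against time with the configured
#' axis labels; each subsequent page shows one variable on its own — the
#' same combined-then-individual layout a user steps through after running
#' a model. A result with k variables therefore yields k + 1 pages.
#'
#' @param graph The simulated model (for the title).
#' @param result An `ode_sim_result`.
#' @param path Output PDF path.
#' @return `path`, invisibly.
#' @export
render_report <- function(graph, result, path) {
  stopifnot(is_model_graph(graph), inherits(result, "ode_sim_result"))
  ok <- tryCatch({
    grDevices::pdf(path, width = 8, height = 5, onefile = TRUE)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_result_pages(result, graph$metadata$name)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop_odegraph("odegraph_io_error", sprintf("cannot write report %s", path))
  invisible(path)
}

# Page count of a PDF written by grDevices::pdf: page dictionaries are
# stored uncompressed, so counting "/Type /Page" objects (excluding the
# "/Type /Pages" tree node) is reliable for our own reports.
pdf_page_count <- function(path) {
  page  <- length(grepRaw("/Type /Page", readBin(path, "raw", file.size(path)),
                          all = TRUE, fixed = TRUE))
  pages <- length(grepRaw("/Type /Pages", readBin(path, "raw", file.size(path)),
                          all = TRUE, fixed = TRUE))
  page - pages
}
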