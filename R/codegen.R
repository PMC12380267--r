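# Code generation: turn a validated model graph into a complete, standalone
# R simulation script by substituting model content into a shipped template.
# The generated script depends only on deSolve and base graphics, runs with
# no arguments, and reproduces the in-process simulation exactly (same
# expressions, same solver, same reporting grid).

# Names the generated script uses internally, plus R's reserved words; term
# identifiers must not shadow any of these.
RESERVED_IDENTIFIERS <- c(
  "if", "else", "for", "while", "repeat", "function", "return", "break",
  "next", "in", "TRUE", "FALSE", "NULL", "Inf", "NaN", "NA",
  "t", "y", "constants", "state0", "times", "solution", "system", "node",
  "args", "csv_path", "report_path", "fmt", "labels", "lines",
  "palette_cols", "j"
)

#' Sanitize a display name into a code identifier
#'
#' Replaces every character outside letters, digits and underscore with an
#' underscore; prefixes `x` when the result would start with a digit or an
#' underscore (R identifiers may not); suffixes names that would shadow a
#' reserved word or collide with an already-taken identifier.
#'
#' @param name Non-empty display name (e.g. a term or model name).
#' @param taken Identifiers already in use in the same context.
#' @return A syntactically valid, collision-free R identifier.
#' @examples
#' sanitize_identifier("S eq")  # "S_eq"
#' sanitize_identifier("2nd")   # "x2nd"
#' @export
sanitize_identifier <- function(name, taken = character()) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  s <- gsub("[^A-Za-z0-9_]", "_", name)
  if (grepl("^[0-9_]", s)) s <- paste0("x", s)
  if (s %in% RESERVED_IDENTIFIERS) s <- paste0(s, "_")
  if (s %in% taken) {
    k <- 2L
    while (paste0(s, "_", k) %in% taken) k <- k + 1L
    s <- paste0(s, "_", k)
  }
  s
}

tree_operators <- function(tree) {
  if (tree$kind == "leaf") return(character())
  c(tree$op, unlist(lapply(tree$children, tree_operators)))
}

#' Extract the code-generation context from a model
#'
#' Assembles everything the script template needs: state variables with
#' initial values and constants (both in node-insertion order, with
#' sanitized identifiers), one rendered right-hand-side expression per ODE
#' aligned with the state variables, the source text of every extension
#' file whose functions the model uses, and the simulation settings. An
#' invalid model is refused with the same violations [validate_model()]
#' reports (in the condition's `violations` field).
#'
#' @param graph A valid model graph.
#' @return A list of class `ode_codegen_context`.
#' @export
build_context <- function(graph) {
  stopifnot(is_model_graph(graph))
  refuse_invalid(graph, "build_context")
  cls <- classify_terms(graph)
  nm <- term_name_map(graph)

  translate <- character()
  taken <- character()
  for (id in c(cls$variables, cls$constants)) {
    ident <- sanitize_identifier(nm[[id]], taken)
    taken <- c(taken, ident)
    translate[[nm[[id]]]] <- ident
  }

  populations <- lapply(cls$variables, function(id) list(
    identifier = translate[[nm[[id]]]], label = nm[[id]],
    initial_value = graph$nodes[[id]]$value))
  consts <- lapply(cls$constants, function(id) list(
    identifier = translate[[nm[[id]]]], label = nm[[id]],
    value = graph$nodes[[id]]$value))

  used_ops <- character()
  odes <- lapply(cls$variables, function(vid) {
    asn <- Filter(function(a) identical(a$target, vid),
                  assigner_nodes(graph))[[1]]
    tree <- build_expression_tree(graph, asn$id)
    used_ops <<- c(used_ops, tree_operators(tree))
    list(identifier = translate[[nm[[vid]]]],
         rhs_text = render_infix(tree, graph$extensions, translate))
  })
  used_ext <- setdiff(unique(used_ops), ARITH_OPS)
  ext_files <- unique(vapply(used_ext, function(op)
    graph$extensions[[op]]$source_file, ""))
  sources <- attr(graph$extensions, "sources")
  extension_sources <- unname(sources[names(sources) %in% ext_files])

  model_ident <- sanitize_identifier(graph$metadata$name)
  structure(list(
    model_name = graph$metadata$name,
    populations = populations,
    constants = consts,
    odes = odes,
    extension_sources = as.character(extension_sources),
    sim = graph$sim,
    csv_path = paste0(model_ident, ".csv"),
    report_path = paste0(model_ident, "_report.pdf")
  ), class = "ode_codegen_context")
}

#' Path of the default simulation-script template
#'
#' The template ships with the package and is written for clarity as much
#' as for generation: the emitted script reads as a worked example of
#' solving an ODE system in R. Users may substitute their own template with
#' the same placeholder vocabulary (see the package vignette).
#'
#' @return A file path.
#' @export
default_template <- function() {
  system.file("templates", "simulation_script.R.tmpl", package = "odegraph",
              mustWork = TRUE)
}

REQUIRED_PLACEHOLDERS <- c("populations", "constants", "odes",
                           "extension_sources", "start_time", "time_step",
                           "n_steps", "method_q", "rel_tol", "abs_tol",
                           "csv_path_q", "report_path_q")

#' Generate a standalone simulation script
#'
#' Substitutes the context into the template, producing a complete R script
#' that defines any extension functions, defines a `system(t, y, constants)`
#' derivative function that unpacks state names and then constant names,
#' integrates over the model's reporting grid, writes the results CSV, and
#' writes a combined plot plus one plot per variable to a PDF. Output paths
#' are baked in at generation time but overridable as script arguments.
#'
#' @param context A context from [build_context()].
#' @param template Template text (character; defaults to the contents of
#'   [default_template()]).
#' @return The script source, a character scalar.
#' @export
generate_source <- function(context, template = NULL) {
  stopifnot(inherits(context, "ode_codegen_context"))
  if (is.null(template))
    template <- paste(readLines(default_template(), warn = FALSE),
                      collapse = "\n")
  for (ph in REQUIRED_PLACEHOLDERS)
    if (!grepl(ph, template, fixed = TRUE))
      stop_odegraph("odegraph_template_error", sprintf(
        "template is missing required placeholder \"%s\"", ph))

  with_sep <- function(items, fields_fmt) {
    n <- length(items)
    lapply(seq_len(n), function(i) {
      it <- items[[i]]
      for (f in names(fields_fmt)) it[[f]] <- fields_fmt[[f]](it[[f]])
      it$sep <- if (i < n) "," else ""
      it
    })
  }
  sim <- context$sim
  n_steps <- floor((sim$end_time - sim$start_time) / sim$time_step + 1e-9)
  labels <- vapply(context$populations, `[[`, "", "label")
  data <- list(
    model_name = context$model_name,
    model_name_q = deparse(context$model_name),
    populations = with_sep(context$populations,
                           list(initial_value = fmt_dbl)),
    constants = with_sep(context$constants, list(value = fmt_dbl)),
    odes = with_sep(context$odes, list()),
    has_constants = length(context$constants) > 0L,
    no_constants = length(context$constants) == 0L,
    has_extensions = length(context$extension_sources) > 0L,
    extension_sources = lapply(context$extension_sources,
                               function(s) list(text = s)),
    start_time = fmt_dbl(sim$start_time),
    time_step = fmt_dbl(sim$time_step),
    end_time = fmt_dbl(sim$end_time),
    n_steps = format(n_steps, scientific = FALSE),
    method_q = deparse(sim$method),
    rel_tol = fmt_dbl(sim$rel_tol),
    abs_tol = fmt_dbl(sim$abs_tol),
    x_label_q = deparse(sim$x_label),
    y_label_q = deparse(sim$y_label),
    var_labels_q = paste(vapply(csv_quote(labels), deparse, ""),
                         collapse = ", "),
    csv_path_q = deparse(context$csv_path),
    report_path_q = deparse(context$report_path)
  )
  render_template(template, data)
}

#' Export a model as a runnable simulation script
#'
#' Convenience wrapper: [build_context()] then [generate_source()],
#' optionally writing the result to a file.
#'
#' @param graph A valid model graph.
#' @param path Optional output path for the script.
#' @param template Optional template text overriding the shipped one.
#' @return The script source, invisibly when `path` is given.
#' @export
generate_script <- function(graph, path = NULL, template = NULL) {
  src <- generate_source(build_context(graph), template)
  if (!is.null(path)) {
    writeLines(src, path)
    return(invisible(src))
  }
  src
}
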