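#' Create an empty ODE model graph
#'
#' A model graph is the unit of everything in this package: it holds Term,
#' Expression and Assigner nodes, the directed links between their pins, the
#' simulation settings and references to any extension files the model
#' depends on.
#'
#' Node kinds follow the fixed pin taxonomy:
#' * **Term** — a named quantity (state variable, parameter or constant);
#'   one output pin, no input pins.
#' * **Expression** — combines its inputs with a single operator (one of
#'   `add`, `subtract`, `multiply`, `divide`, or an extension function);
#'   N input pins, one output pin.
#' * **Assigner** — binds an expression as the right-hand side of one state
#'   variable's ODE; one input pin, no output pins.
#'
#' @param name Model display name.
#' @param notes Free-text notes stored with the model.
#' @param sim A [sim_config()] object; defaults to `sim_config()`.
#' @return An object of class `ode_model`.
#' @examples
#' g <- model_graph("decay")
#' g <- add_term(g, "X", 1)
#' g <- add_term(g, "k", 0.5)
#' @export
model_graph <- function(name = "model", notes = "", sim = sim_config()) {
  stopifnot(is.character(name), length(name) == 1)
  structure(
    list(
      metadata = list(name = name, notes = notes),
      nodes = list(),
      links = list(),
      sim = sim,
      extension_refs = character(),
      extensions = empty_registry(),
      counter = c(node = 0L, link = 0L),
      last_id = NA_character_
    ),
    class = "ode_model"
  )
}

is_model_graph <- function(x) inherits(x, "ode_model")

ARITH_OPS <- c("add", "subtract", "multiply", "divide")

next_node_id <- function(g) {
  repeat {
    g$counter[["node"]] <- g$counter[["node"]] + 1L
    id <- paste0("n", g$counter[["node"]])
    if (is.null(g$nodes[[id]])) break
  }
  list(graph = g, id = id)
}

insert_node <- function(g, node) {
  g$nodes[[node$id]] <- node
  g$last_id <- node$id
  g
}

#' Identifier of the most recently added node
#'
#' Builder functions ([add_term()], [add_expression()], [add_assigner()])
#' return the updated graph; this accessor retrieves the id of the node the
#' last such call created, for use in [connect()].
#'
#' @param graph A model graph.
#' @return A node id (character scalar).
#' @export
last_node_id <- function(graph) {
  stopifnot(is_model_graph(graph))
  graph$last_id
}

#' Add a Term node
#'
#' Terms represent the model's named quantities. A term later targeted by an
#' assigner is a state variable and its `value` is the initial condition;
#' any other term is a constant whose `value` holds throughout a simulation.
#' Term names must be unique because they become identifiers in generated
#' code; expression and assigner display names carry no such restriction.
#'
#' @param graph A model graph.
#' @param name Non-empty display name, unique among terms.
#' @param value Finite numeric value (initial condition or constant).
#' @return The updated graph; retrieve the new id with [last_node_id()].
#' @export
add_term <- function(graph, name, value) {
  stopifnot(is_model_graph(graph))
  if (!is.character(name) || length(name) != 1 || is.na(name) || !nzchar(name))
    stop_odegraph("odegraph_name_error", "term name must be a non-empty string")
  if (!is.numeric(value) || length(value) != 1)
    stop_odegraph("odegraph_value_error", "term value must be a single number")
  existing <- vapply(term_nodes(graph), `[[`, "", "name")
  if (name %in% existing)
    stop_odegraph("odegraph_name_collision",
                  sprintf("a term named \"%s\" already exists", name))
  res <- next_node_id(graph)
  insert_node(res$graph, list(
    id = res$id, kind = "term", name = name, value = as.numeric(value),
    position = NULL
  ))
}

#' Add an Expression node
#'
#' @param graph A model graph.
#' @param operator `"add"`, `"subtract"`, `"multiply"`, `"divide"`, or the
#'   name of an extension function already attached with
#'   [attach_extensions()].
#' @param name Display label (free text, need not be unique).
#' @param arity Number of input pins. Arithmetic operators need at least two
#'   operands; for an extension operator the arity must equal the function's
#'   declared parameter count (and defaults to it).
#' @return The updated graph.
#' @export
add_expression <- function(graph, operator, name = "", arity = NULL) {
  stopifnot(is_model_graph(graph))
  if (!is.character(operator) || length(operator) != 1)
    stop_odegraph("odegraph_operator_error", "operator must be a string")
  if (operator %in% ARITH_OPS) {
    if (is.null(arity)) arity <- 2L
    arity <- as.integer(arity)
    if (is.na(arity) || arity < 2L)
      stop_odegraph("odegraph_arity_error", sprintf(
        "arithmetic operator \"%s\" needs at least 2 operands, got %s",
        operator, arity))
  } else {
    ext <- graph$extensions[[operator]]
    if (is.null(ext))
      stop_odegraph("odegraph_operator_error", sprintf(
        "unknown operator \"%s\": not arithmetic and no such extension is attached",
        operator))
    if (is.null(arity)) arity <- ext$arity
    arity <- as.integer(arity)
    if (is.na(arity) || arity != ext$arity)
      stop_odegraph("odegraph_arity_error", sprintf(
        "extension \"%s\" has arity %d, requested %s",
        operator, ext$arity, arity))
  }
  res <- next_node_id(graph)
  insert_node(res$graph, list(
    id = res$id, kind = "expression", name = as.character(name),
    operator = operator, arity = arity, position = NULL
  ))
}

#' Add an Assigner node
#'
#' The assigner's single input pin receives the expression that becomes the
#' right-hand side of the target variable's ODE. At most one assigner may
#' target any given term: two right-hand sides for one ODE is meaningless,
#' so the duplicate is rejected at construction time.
#'
#' @param graph A model graph.
#' @param target Id of the Term node whose ODE this assigner defines.
#' @return The updated graph.
#' @export
add_assigner <- function(graph, target) {
  stopifnot(is_model_graph(graph))
  node <- graph$nodes[[target]]
  if (is.null(node))
    stop_odegraph("odegraph_unknown_node",
                  sprintf("no node with id \"%s\"", target))
  if (node$kind != "term")
    stop_odegraph("odegraph_type_error", sprintf(
      "assigner target must be a term node; \"%s\" is a %s node",
      target, node$kind))
  taken <- vapply(assigner_nodes(graph), `[[`, "", "target")
  if (target %in% taken)
    stop_odegraph("odegraph_duplicate_ode", sprintf(
      "term \"%s\" already has an assigner: one ODE per variable", node$name))
  res <- next_node_id(graph)
  insert_node(res$graph, list(
    id = res$id, kind = "assigner", name = paste(node$name, "ode"),
    target = target, position = NULL
  ))
}

node_arity <- function(node) {
  switch(node$kind, term = 0L, assigner = 1L, expression = node$arity)
}

#' Connect two nodes
#'
#' Links are always unidirectional: from the output pin of a Term or
#' Expression to a free input pin on an Expression or Assigner. Connections
#' that would close a directed cycle are rejected immediately — a link cycle
#' can never be evaluated (dynamic feedback lives in equations referencing
#' state variables, not in the link structure).
#'
#' @param graph A model graph.
#' @param source Id of a Term or Expression node (link origin).
#' @param destination Id of an Expression or Assigner node.
#' @param destination_pin 1-based input-pin index on the destination
#'   (serialized zero-based in the JSON IR).
#' @return The updated graph.
#' @export
connect <- function(graph, source, destination, destination_pin = 1L) {
  stopifnot(is_model_graph(graph))
  src <- graph$nodes[[source]]
  dst <- graph$nodes[[destination]]
  if (is.null(src))
    stop_odegraph("odegraph_unknown_node",
                  sprintf("no node with id \"%s\"", source))
  if (is.null(dst))
    stop_odegraph("odegraph_unknown_node",
                  sprintf("no node with id \"%s\"", destination))
  if (src$kind == "assigner")
    stop_odegraph("odegraph_no_output_pins",
                  "assigner nodes have no output pin (terminal nodes)")
  if (dst$kind == "term")
    stop_odegraph("odegraph_no_input_pins",
                  "term nodes have no input pins (initial nodes)")
  if (identical(source, destination))
    stop_odegraph("odegraph_cycle_error", "a node cannot feed itself")
  pin <- as.integer(destination_pin)
  if (is.na(pin) || pin < 1L || pin > node_arity(dst))
    stop_odegraph("odegraph_pin_range", sprintf(
      "destination pin %s out of range 1..%d for node \"%s\"",
      destination_pin, node_arity(dst), destination))
  for (lk in graph$links)
    if (identical(lk$destination, destination) && lk$destination_pin == pin)
      stop_odegraph("odegraph_pin_occupied", sprintf(
        "pin %d of node \"%s\" already holds a link", pin, destination))
  if (reaches(graph, from = destination, to = source))
    stop_odegraph("odegraph_cycle_error", sprintf(
      "linking \"%s\" -> \"%s\" would create a cycle", source, destination))
  graph$counter[["link"]] <- graph$counter[["link"]] + 1L
  id <- paste0("l", graph$counter[["link"]])
  graph$links[[id]] <- list(id = id, source = source,
                            destination = destination, destination_pin = pin)
  graph
}

# Depth-first reachability over links; graphs are small, no memoization.
reaches <- function(g, from, to) {
  seen <- character()
  frontier <- from
  while (length(frontier)) {
    cur <- frontier[[1]]
    frontier <- frontier[-1]
    if (identical(cur, to)) return(TRUE)
    if (cur %in% seen) next
    seen <- c(seen, cur)
    for (lk in g$links)
      if (identical(lk$source, cur)) frontier <- c(frontier, lk$destination)
  }
  FALSE
}

nodes_of_kind <- function(g, kind) Filter(function(n) n$kind == kind, g$nodes)
term_nodes <- function(g) nodes_of_kind(g, "term")
assigner_nodes <- function(g) nodes_of_kind(g, "assigner")

#' Look up a term node id by name
#'
#' @param graph A model graph.
#' @param name Term name.
#' @return The node id.
#' @export
term_id <- function(graph, name) {
  stopifnot(is_model_graph(graph))
  for (n in term_nodes(graph)) if (identical(n$name, name)) return(n$id)
  stop_odegraph("odegraph_unknown_node",
                sprintf("no term named \"%s\"", name))
}

#' Find node ids by name and/or kind
#'
#' @param graph A model graph.
#' @param name Optional display name to match exactly.
#' @param kind Optional kind: `"term"`, `"expression"` or `"assigner"`.
#' @return Character vector of matching node ids, in insertion order.
#' @export
find_nodes <- function(graph, name = NULL, kind = NULL) {
  stopifnot(is_model_graph(graph))
  hits <- Filter(function(n) {
    (is.null(name) || identical(n$name, name)) &&
      (is.null(kind) || identical(n$kind, kind))
  }, graph$nodes)
  vapply(hits, `[[`, "", "id", USE.NAMES = FALSE)
}

#' Partition terms into state variables and constants
#'
#' A term is a state variable if and only if some assigner targets it (its
#' value is then the initial condition); every other term is a constant.
#' Both lists preserve node-insertion order and together partition the
#' model's terms.
#'
#' @param graph A model graph.
#' @return A list with character-vector components `variables` and
#'   `constants` of term ids.
#' @export
classify_terms <- function(graph) {
  stopifnot(is_model_graph(graph))
  targeted <- vapply(assigner_nodes(graph), `[[`, "", "target")
  ids <- vapply(term_nodes(graph), `[[`, "", "id", USE.NAMES = FALSE)
  list(variables = ids[ids %in% targeted],
       constants = ids[!(ids %in% targeted)])
}

term_name_map <- function(g) {
  tn <- term_nodes(g)
  stats::setNames(vapply(tn, `[[`, "", "name", USE.NAMES = FALSE),
                  vapply(tn, `[[`, "", "id", USE.NAMES = FALSE))
}

incoming_link <- function(g, destination, pin) {
  for (lk in g$links)
    if (identical(lk$destination, destination) && lk$destination_pin == pin)
      return(lk)
  NULL
}

#' Validate a model graph for simulation
#'
#' Checks whether the graph describes a complete, simulatable ODE system.
#' Violations are returned as data, never raised: an empty result means the
#' model can be compiled and simulated.
#'
#' Checked violations: an expression input pin with no incoming link; an
#' assigner whose input pin is empty; a model with zero state variables; an
#' expression whose operator names an extension function that is not
#' attached; a term whose value is not finite. A term with no connections at
#' all is legal but reported in the `warnings` attribute.
#'
#' @param graph A model graph.
#' @return A data frame with columns `type`, `node_id`, `message` (zero rows
#'   when valid), with a character `warnings` attribute.
#' @export
validate_model <- function(graph) {
  stopifnot(is_model_graph(graph))
  v <- list()
  add_v <- function(type, node_id, message)
    v[[length(v) + 1L]] <<- data.frame(type = type, node_id = node_id,
                                       message = message)
  for (n in graph$nodes) {
    if (n$kind == "expression") {
      for (pin in seq_len(n$arity))
        if (is.null(incoming_link(graph, n$id, pin)))
          add_v("unconnected_pin", n$id, sprintf(
            "input pin %d of expression \"%s\" (%s) is unconnected",
            pin, n$name, n$id))
      if (!(n$operator %in% ARITH_OPS) &&
          is.null(graph$extensions[[n$operator]]))
        add_v("dangling_operator", n$id, sprintf(
          "expression \"%s\" uses extension operator \"%s\" which is not loaded",
          n$name, n$operator))
    } else if (n$kind == "assigner") {
      if (is.null(incoming_link(graph, n$id, 1L)))
        add_v("empty_assigner", n$id, sprintf(
          "assigner \"%s\" has no input expression", n$name))
    } else if (!is.finite(n$value)) {
      add_v("nonfinite_value", n$id, sprintf(
        "term \"%s\" has non-finite value %s", n$name, n$value))
    }
  }
  if (length(classify_terms(graph)$variables) == 0L)
    add_v("no_state_variables", NA_character_,
          "model has no state variables (no assigner targets any term)")
  out <- if (length(v)) do.call(rbind, v) else
    data.frame(type = character(), node_id = character(),
               message = character())
  # a term is participating if any link touches it OR an assigner targets it
  linked <- unique(c(
    unlist(lapply(graph$links, function(l) c(l$source, l$destination))),
    vapply(assigner_nodes(graph), `[[`, "", "target", USE.NAMES = FALSE)))
  orphans <- setdiff(vapply(term_nodes(graph), `[[`, "", "id"), linked)
  attr(out, "warnings") <- if (length(orphans))
    sprintf("term \"%s\" is not connected to anything",
            vapply(orphans, function(id) graph$nodes[[id]]$name, ""))
  else character()
  out
}

#' @export
print.ode_model <- function(x, ...) {
  cls <- classify_terms(x)
  cat(sprintf("<ode_model> %s\n", x$metadata$name))
  cat(sprintf("  nodes: %d (%d terms, %d expressions, %d assigners), links: %d\n",
              length(x$nodes), length(term_nodes(x)),
              length(nodes_of_kind(x, "expression")),
              length(assigner_nodes(x)), length(x$links)))
  nm <- term_name_map(x)
  cat(sprintf("  state variables: %s\n",
              paste(nm[cls$variables], collapse = ", ")))
  cat(sprintf("  constants: %s\n", paste(nm[cls$constants], collapse = ", ")))
  if (length(x$extension_refs))
    cat(sprintf("  extensions: %s\n", paste(x$extension_refs, collapse = ", ")))
  cat(sprintf("  simulation: t = %g..%g step %g\n",
              x$sim$start_time, x$sim$end_time, x$sim$time_step))
  invisible(x)
}
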