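# Expression trees: the recursive mathematical expression recovered from a
# model graph. A tree is either a leaf (a term reference) or a call node
# (operator + ordered children). Multi-operand arithmetic nodes evaluate as
# a left-to-right fold in pin order: ((p1 op p2) op p3) ..., so subtract and
# divide mean p1 - p2 - p3 and p1 / p2 / p3.

expr_leaf <- function(id, name) {
  structure(list(kind = "leaf", id = id, name = name), class = "ode_expr")
}

expr_call <- function(op, children) {
  stopifnot(length(children) >= 1)
  structure(list(kind = "call", op = op, children = children),
            class = "ode_expr")
}

#' Recover the expression tree rooted at a node
#'
#' Mirrors the link structure of the graph: each expression node becomes a
#' call whose children, ordered by input-pin index, are the trees of its
#' connected sources; each term becomes a leaf. An assigner root yields the
#' tree of its single input (the ODE right-hand side it holds).
#'
#' @param graph A model graph.
#' @param root Id of an expression or assigner node.
#' @return An `ode_expr` tree.
#' @export
build_expression_tree <- function(graph, root) {
  stopifnot(is_model_graph(graph))
  node <- graph$nodes[[root]]
  if (is.null(node))
    stop_odegraph("odegraph_unknown_node",
                  sprintf("no node with id \"%s\"", root))
  if (node$kind == "term") return(expr_leaf(node$id, node$name))
  n_pins <- node_arity(node)
  children <- vector("list", n_pins)
  for (pin in seq_len(n_pins)) {
    lk <- incoming_link(graph, node$id, pin)
    if (is.null(lk))
      stop_odegraph("odegraph_incomplete_expression", sprintf(
        "input pin %d of node \"%s\" (%s) is unconnected",
        pin, node$name, node$id))
    children[[pin]] <- build_expression_tree(graph, lk$source)
  }
  if (node$kind == "assigner") children[[1]] else
    expr_call(node$operator, children)
}

op_symbol <- c(add = " + ", subtract = " - ",
               multiply = " * ", divide = " / ")

# Precedence levels: additive < multiplicative < atomic (leaf or extension
# call). A child is parenthesized when its level is strictly lower than its
# parent's, or equal to it in any non-first operand position — the second
# clause keeps rendering faithful to the tree's grouping (a - (b + c) is not
# a - b + c) and makes the rendered text parse back to the exact same
# evaluation order.
op_precedence <- function(tree) {
  if (tree$kind == "leaf") return(3L)
  switch(tree$op, add = , subtract = 1L, multiply = , divide = 2L, 3L)
}

#' Render an expression tree as infix text
#'
#' Deterministic, minimally parenthesized rendering: operands joined by
#' `" + "`, `" - "`, `" * "`, `" / "` in pin order; extension operators
#' render through their display format (or standard `name(args)` notation).
#' The text is valid R and re-parses to the same evaluation order the tree
#' has.
#'
#' @param tree An `ode_expr` tree.
#' @param extensions An extension registry (see [load_extensions()]) for
#'   resolving display formats; optional.
#' @param translate Optional named character vector mapping leaf names to
#'   replacement identifiers (used by code generation).
#' @return A character scalar.
#' @export
render_infix <- function(tree, extensions = NULL, translate = NULL) {
  render_tree(tree, extensions, translate)
}

render_tree <- function(tree, extensions, translate, parent_prec = 0L,
                        position = 1L) {
  if (tree$kind == "leaf") {
    nm <- tree$name
    if (!is.null(translate) && nm %in% names(translate))
      nm <- translate[[nm]]
    return(nm)
  }
  prec <- op_precedence(tree)
  parts <- vapply(seq_along(tree$children), function(i) {
    render_tree(tree$children[[i]], extensions, translate,
                parent_prec = prec, position = i)
  }, "")
  txt <- if (tree$op %in% ARITH_OPS) {
    paste(parts, collapse = op_symbol[[tree$op]])
  } else {
    func <- if (!is.null(extensions)) extensions[[tree$op]] else NULL
    if (is.null(func)) {
      paste0(tree$op, "(", paste(parts, collapse = ", "), ")")
    } else {
      render_extension_call(func, parts)
    }
  }
  needs_parens <- prec < parent_prec || (prec == parent_prec && position > 1L)
  if (needs_parens) paste0("(", txt, ")") else txt
}

#' Evaluate an expression tree numerically
#'
#' Arithmetic nodes evaluate as a left fold over their operands in pin
#' order; extension nodes call the loaded function. Division by zero is
#' surfaced as an error naming the rendered offending subexpression rather
#' than silently producing a non-finite value.
#'
#' @param tree An `ode_expr` tree.
#' @param bindings Named numeric vector or list giving a value for every
#'   leaf (term) name in the tree.
#' @param extensions An extension registry supplying callables for
#'   extension operators.
#' @return A numeric scalar.
#' @export
evaluate_tree <- function(tree, bindings, extensions = NULL) {
  if (tree$kind == "leaf") {
    idx <- match(tree$name, names(bindings))
    if (is.na(idx))
      stop_odegraph("odegraph_unbound_symbol",
                    sprintf("no binding for term \"%s\"", tree$name))
    return(as.numeric(bindings[[idx]]))
  }
  vals <- vapply(tree$children, evaluate_tree, 0.0,
                 bindings = bindings, extensions = extensions)
  if (tree$op %in% ARITH_OPS) {
    f <- switch(tree$op, add = `+`, subtract = `-`,
                multiply = `*`, divide = `/`)
    acc <- vals[[1]]
    for (i in seq_along(vals)[-1]) {
      if (tree$op == "divide" && vals[[i]] == 0)
        stop_odegraph("odegraph_arithmetic_error", sprintf(
          "division by zero in \"%s\"", render_infix(tree, extensions)))
      acc <- f(acc, vals[[i]])
    }
    acc
  } else {
    func <- if (!is.null(extensions)) extensions[[tree$op]] else NULL
    if (is.null(func))
      stop_odegraph("odegraph_dangling_operator", sprintf(
        "extension operator \"%s\" is not loaded", tree$op))
    as.numeric(do.call(func$fn, as.list(vals)))
  }
}

#' Rendered right-hand sides of a model's ODEs
#'
#' Convenience view: one rendered equation per state variable, in
#' [classify_terms()] order.
#'
#' @param graph A model graph (need not be fully valid; only assigned
#'   variables with complete expressions render).
#' @return Named character vector: `names` are state-variable names, values
#'   their rendered d/dt right-hand sides.
#' @export
model_equations <- function(graph) {
  stopifnot(is_model_graph(graph))
  cls <- classify_terms(graph)
  nm <- term_name_map(graph)
  out <- character()
  for (vid in cls$variables) {
    asn <- Filter(function(a) identical(a$target, vid),
                  assigner_nodes(graph))[[1]]
    out[[nm[[vid]]]] <-
      render_infix(build_expression_tree(graph, asn$id), graph$extensions)
  }
  out
}

#' @export
print.ode_expr <- function(x, ...) {
  cat(render_infix(x), "\n")
  invisible(x)
}
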