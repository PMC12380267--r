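test_that("term creation enforces naming and value rules", {
  g <- model_graph("m")
  g <- add_term(g, "S", 99)
  expect_length(find_nodes(g, kind = "term"), 1)
  expect_error(add_term(g, "", 1), class = "odegraph_name_error")
  expect_error(add_term(g, "S", 2), class = "odegraph_name_collision")
  expect_error(add_term(g, "x", "one"), class = "odegraph_value_error")
  # expression display names may repeat; term names may not
  g <- add_expression(g, "add", "dup", 2)
  g <- add_expression(g, "add", "dup", 2)
  expect_length(find_nodes(g, name = "dup"), 2)
})

test_that("expression arity rules distinguish arithmetic and extensions", {
  g <- model_graph("m")
  g <- add_expression(g, "multiply", "infection", 3)
  expect_equal(g$nodes[[last_node_id(g)]]$arity, 3L)
  expect_error(add_expression(g, "add", "x", 1), class = "odegraph_arity_error")
  expect_error(add_expression(g, "nosuch", "x", 2),
               class = "odegraph_operator_error")
  ext <- system.file("extdata", "extensions", "math_nodes.R",
                     package = "odegraph")
  g <- attach_extensions(g, ext)
  g <- add_expression(g, "pow", "p")        # arity defaults to the function's
  expect_equal(g$nodes[[last_node_id(g)]]$arity, 2L)
  expect_error(add_expression(g, "pow", "p", 3),
               class = "odegraph_arity_error")
})

test_that("one assigner per variable, and only terms can be targeted", {
  g <- model_graph("m")
  g <- add_term(g, "I", 1)
  g <- add_expression(g, "add", "e", 2)
  e <- last_node_id(g)
  expect_error(add_assigner(g, e), class = "odegraph_type_error")
  expect_error(add_assigner(g, "zz9"), class = "odegraph_unknown_node")
  g <- add_assigner(g, term_id(g, "I"))
  expect_equal(g$nodes[[last_node_id(g)]]$name, "I ode")
  expect_error(add_assigner(g, term_id(g, "I")),
               class = "odegraph_duplicate_ode")
})

test_that("every forbidden connection has its own documented error", {
  g <- model_graph("m")
  g <- add_term(g, "a", 1); a <- last_node_id(g)
  g <- add_term(g, "b", 2); b <- last_node_id(g)
  g <- add_expression(g, "add", "e1", 2); e1 <- last_node_id(g)
  g <- add_expression(g, "add", "e2", 2); e2 <- last_node_id(g)
  g <- add_assigner(g, a); asn <- last_node_id(g)

  expect_error(connect(g, a, b, 1), class = "odegraph_no_input_pins")
  expect_error(connect(g, asn, e1, 1), class = "odegraph_no_output_pins")
  expect_error(connect(g, a, e1, 3), class = "odegraph_pin_range")
  expect_error(connect(g, a, e1, 0), class = "odegraph_pin_range")
  g <- connect(g, a, e1, 1)
  expect_error(connect(g, b, e1, 1), class = "odegraph_pin_occupied")
  g <- connect(g, e1, e2, 1)
  expect_error(connect(g, e2, e1, 2), class = "odegraph_cycle_error")
  expect_error(connect(g, e1, e1, 2), class = "odegraph_cycle_error")
  expect_error(connect(g, "zz9", e1, 2), class = "odegraph_unknown_node")
  # the allowed pair still works afterwards
  g <- connect(g, b, e1, 2)
  expect_length(g$links, 3)
})

test_that("successful connects always leave the link graph acyclic", {
  set.seed(101)
  for (rep in 1:20) {
    g <- random_graph()
    # Kahn's algorithm must consume every node
    ids <- find_nodes(g)
    edges <- lapply(g$links, function(l) c(l$source, l$destination))
    indeg <- stats::setNames(rep(0L, length(ids)), ids)
    for (e in edges) indeg[[e[2]]] <- indeg[[e[2]]] + 1L
    queue <- names(indeg)[indeg == 0L]
    seen <- 0L
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
      for (e in edges) if (e[1] == v) {
        indeg[[e[2]]] <- indeg[[e[2]]] - 1L
        if (indeg[[e[2]]] == 0L) queue <- c(queue, e[2])
      }
    }
    expect_equal(seen, length(ids))
  }
})

test_that("classify_terms partitions the terms in insertion order", {
  g <- build_sir()
  cls <- classify_terms(g)
  nm <- odegraph:::term_name_map(g)
  expect_equal(unname(nm[cls$variables]), c("S", "I", "R"))
  expect_equal(unname(nm[cls$constants]), c("b_d", "g"))

  g0 <- add_term(add_term(model_graph("m"), "a", 1), "b", 2)
  cls0 <- classify_terms(g0)
  expect_length(cls0$variables, 0)
  expect_length(cls0$constants, 2)

  set.seed(7)
  for (rep in 1:20) {
    gr <- random_graph()
    cl <- classify_terms(gr)
    expect_equal(length(cl$variables) + length(cl$constants),
                 length(find_nodes(gr, kind = "term")))
    expect_length(intersect(cl$variables, cl$constants), 0)
  }
})

test_that("validate_model reports each violation kind as data", {
  expect_identical(nrow(validate_model(build_sir())), 0L)

  g <- model_graph("m")
  g <- add_term(g, "X", 1)
  g <- add_expression(g, "multiply", "e", 3)
  e <- last_node_id(g)
  g <- connect(g, term_id(g, "X"), e, 1)
  g <- connect(g, term_id(g, "X"), e, 2)
  g <- add_assigner(g, term_id(g, "X"))
  v <- validate_model(g)  # pin 3 of e unconnected, assigner empty
  expect_setequal(v$type, c("unconnected_pin", "empty_assigner"))

  g2 <- add_term(model_graph("m"), "X", Inf)
  v2 <- validate_model(g2)
  expect_setequal(v2$type, c("nonfinite_value", "no_state_variables"))

  # dangling extension operator: built against a registry, then lost on
  # a round-trip without resolving extensions
  g3 <- build_immune_model()
  g3 <- deserialize_model(serialize_model(g3))
  expect_true("dangling_operator" %in% validate_model(g3)$type)

  # an orphan term is a warning, not a violation
  g4 <- add_term(build_sir(), "unused", 5)
  v4 <- validate_model(g4)
  expect_identical(nrow(v4), 0L)
  expect_match(attr(v4, "warnings"), "unused")
})

test_that("a clean validation implies the model simulates", {
  set.seed(11)
  for (rep in 1:10) {
    g <- random_graph()
    if (nrow(validate_model(g)) == 0L) {
      # random dynamics may legitimately diverge numerically; what a clean
      # validation rules out is any *structural* failure (incomplete
      # expressions, unbound symbols, dangling operators)
      out <- tryCatch(
        simulate_model(g, sim_config(0, 0.5, 1)),
        odegraph_simulation_error = function(e) "numeric",
        odegraph_arithmetic_error = function(e) "numeric")
      expect_true(inherits(out, "ode_sim_result") || identical(out, "numeric"))
    }
  }
})
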