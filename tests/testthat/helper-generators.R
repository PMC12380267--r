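# Shared test helpers: random model-graph and expression-tree generators
# (call set.seed() before use) and a harness that runs a generated script
# and compares its CSV against the in-process simulation.

rel_diff <- function(got, want) {
  max(abs(got - want) / pmax(abs(want), 1e-300))
}

random_tree <- function(depth = 3, vars = paste0("v", 1:4)) {
  if (depth <= 0 || stats::runif(1) < 0.3) {
    nm <- sample(vars, 1)
    return(odegraph:::expr_leaf(nm, nm))
  }
  op <- sample(c("add", "subtract", "multiply", "divide"), 1)
  n_children <- sample(2:3, 1)
  odegraph:::expr_call(op, lapply(seq_len(n_children), function(i)
    random_tree(depth - 1, vars)))
}

random_graph <- function() {
  g <- model_graph(paste0("model_", sample(1e6, 1)),
                   notes = paste(sample(letters, 6), collapse = ""))
  n_terms <- sample(2:5, 1)
  for (i in seq_len(n_terms))
    g <- add_term(g, paste0("t", i), stats::runif(1, -10, 10))
  terms <- find_nodes(g, kind = "term")
  exprs <- character()
  for (i in seq_len(sample(1:4, 1))) {
    op <- sample(c("add", "subtract", "multiply", "divide"), 1)
    arity <- sample(2:4, 1)
    g <- add_expression(g, op, paste0("e", i), arity)
    e <- last_node_id(g)
    pool <- c(terms, exprs)     # only earlier nodes: acyclic by construction
    for (pin in seq_len(arity))
      if (stats::runif(1) < 0.8) g <- connect(g, sample(pool, 1), e, pin)
    exprs <- c(exprs, e)
  }
  for (tid in sample(terms, sample(0:min(2, n_terms), 1))) {
    g <- add_assigner(g, tid)
    if (stats::runif(1) < 0.9)
      g <- connect(g, sample(c(terms, exprs), 1), last_node_id(g), 1)
  }
  for (id in find_nodes(g))
    if (stats::runif(1) < 0.3)
      g$nodes[[id]]$position <- round(stats::runif(2, 0, 500), 1)
  g$sim <- sim_config(start_time = stats::runif(1, 0, 2),
                      time_step = stats::runif(1, 0.01, 1),
                      end_time = stats::runif(1, 5, 50),
                      y_label = paste(sample(letters, 3), collapse = ""))
  g
}

# Generate the model's script, execute it in a fresh R process, and compare
# the CSV it writes against simulate_model() on the same graph.
export_equivalence <- function(graph) {
  script <- tempfile(fileext = ".R")
  csv <- tempfile(fileext = ".csv")
  pdf <- tempfile(fileext = ".pdf")
  on.exit(unlink(c(script, csv, pdf)))
  generate_script(graph, script)
  status <- system2("Rscript", c(script, csv, pdf),
                    stdout = NULL, stderr = NULL)
  in_process <- simulate_model(graph)
  exported <- read_sim_csv(csv)
  list(status = status,
       times_equal = isTRUE(all.equal(exported$times, in_process$times,
                                      tolerance = 0)),
       rel = rel_diff(exported$trajectories, in_process$trajectories),
       pages = odegraph:::pdf_page_count(pdf))
}

# Minimal single-variable linear decay model dX/dt = -k X, built as the
# subtraction fold (kX - kX) - kX since the operator set has no unary minus.
build_decay <- function(X0 = 1, k = 1, step = 0.1, end = 5) {
  g <- model_graph("decay", sim = sim_config(0, step, end))
  g <- add_term(g, "X", X0)
  g <- add_term(g, "k", k)
  g <- add_expression(g, "multiply", "loss", 2)
  e <- last_node_id(g)
  g <- connect(g, term_id(g, "k"), e, 1)
  g <- connect(g, term_id(g, "X"), e, 2)
  g <- add_expression(g, "subtract", "X eq", 3)
  s <- last_node_id(g)
  for (pin in 1:3) g <- connect(g, e, s, pin)
  g <- add_assigner(g, term_id(g, "X"))
  connect(g, s, last_node_id(g))
}
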