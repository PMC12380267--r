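leaf <- odegraph:::expr_leaf
call_ <- odegraph:::expr_call
lf <- function(nm) leaf(nm, nm)

test_that("expression trees mirror the link structure in pin order", {
  g <- build_sir()
  r_ode <- find_nodes(g, name = "R ode")[[1]]
  tree <- build_expression_tree(g, r_ode)     # assigner root -> input's tree
  expect_equal(tree$kind, "call")
  expect_equal(tree$op, "multiply")
  expect_equal(vapply(tree$children, `[[`, "", "name"), c("g", "I"))

  # a bare term as assigner input yields a leaf (identity assignment)
  g2 <- model_graph("m")
  g2 <- add_term(g2, "X", 1)
  g2 <- add_term(g2, "Y", 2)
  g2 <- add_assigner(g2, term_id(g2, "X"))
  g2 <- connect(g2, term_id(g2, "Y"), last_node_id(g2))
  t2 <- build_expression_tree(g2, find_nodes(g2, kind = "assigner")[[1]])
  expect_equal(t2$kind, "leaf")
  expect_equal(t2$name, "Y")

  # unconnected pin anywhere in the reachable subgraph is an error
  g3 <- add_expression(g2, "add", "e", 2)
  e <- last_node_id(g3)
  g3 <- connect(g3, term_id(g3, "Y"), e, 1)
  expect_error(build_expression_tree(g3, e),
               class = "odegraph_incomplete_expression")
})

test_that("infix rendering inserts parentheses exactly where grouping needs them", {
  expect_equal(render_infix(call_("multiply", list(lf("b_d"), lf("S"), lf("I")))),
               "b_d * S * I")
  expect_equal(render_infix(call_("subtract", list(
    call_("multiply", list(lf("b_d"), lf("S"), lf("I"))),
    call_("multiply", list(lf("g"), lf("I")))))),
    "b_d * S * I - g * I")
  expect_equal(render_infix(call_("multiply", list(
    lf("a"), call_("add", list(lf("b"), lf("c")))))),
    "a * (b + c)")
  # same-precedence child in non-first position keeps its grouping
  expect_equal(render_infix(call_("subtract", list(
    lf("a"), call_("add", list(lf("b"), lf("c")))))),
    "a - (b + c)")
  # distinct groupings over the same leaves never render identically
  left <- call_("add", list(call_("add", list(lf("a"), lf("b"))), lf("c")))
  right <- call_("add", list(lf("a"), call_("add", list(lf("b"), lf("c")))))
  expect_equal(render_infix(left), "a + b + c")
  expect_equal(render_infix(right), "a + (b + c)")
})

test_that("evaluation follows the left-fold rule and flags failures precisely", {
  expect_equal(evaluate_tree(call_("multiply", list(lf("b_d"), lf("S"), lf("I"))),
                             c(b_d = 1, S = 2, I = 3)), 6)
  expect_equal(evaluate_tree(call_("divide", list(lf("a"), lf("b"), lf("c"))),
                             c(a = 8, b = 2, c = 2)), 2)   # (8/2)/2
  expect_error(evaluate_tree(lf("missing"), c(x = 1)),
               class = "odegraph_unbound_symbol")
  err <- tryCatch(evaluate_tree(call_("divide", list(lf("x"), lf("y"))),
                                c(x = 1, y = 0)),
                  odegraph_arithmetic_error = function(e) e)
  expect_match(conditionMessage(err), "x / y", fixed = TRUE)
})

test_that("add and multiply are order-insensitive; subtract and divide are not", {
  set.seed(31)
  for (rep in 1:25) {
    vals <- round(stats::runif(2, 0.5, 5), 3)
    b <- c(a = vals[1], b = vals[2])
    for (op in c("add", "multiply")) {
      expect_identical(
        evaluate_tree(call_(op, list(lf("a"), lf("b"))), b),
        evaluate_tree(call_(op, list(lf("b"), lf("a"))), b))
    }
    if (vals[1] != vals[2]) {
      for (op in c("subtract", "divide")) {
        expect_false(
          evaluate_tree(call_(op, list(lf("a"), lf("b"))), b) ==
            evaluate_tree(call_(op, list(lf("b"), lf("a"))), b))
      }
    }
  }
})

test_that("rendered text re-parses to the same value as direct evaluation", {
  set.seed(53)
  vars <- paste0("v", 1:4)
  done <- 0
  while (done < 60) {
    tree <- random_tree(3, vars)
    b <- stats::setNames(as.list(round(stats::runif(4, 0.5, 2), 4)), vars)
    direct <- tryCatch(evaluate_tree(tree, b),
                       odegraph_arithmetic_error = function(e) NULL)
    if (is.null(direct)) next
    oracle <- eval(parse(text = render_infix(tree)), envir = b)
    expect_identical(direct, oracle)
    done <- done + 1
  }
})
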