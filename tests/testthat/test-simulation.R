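test_that("simulation settings are checked at construction", {
  expect_error(sim_config(time_step = 0), class = "odegraph_config_error")
  expect_error(sim_config(time_step = -1), class = "odegraph_config_error")
  expect_error(sim_config(start_time = 5, end_time = 1),
               class = "odegraph_config_error")
  expect_error(sim_config(method = "euler"), class = "odegraph_config_error")
})

test_that("the reporting grid is built by count, without float accumulation", {
  tg <- odegraph:::time_grid
  expect_length(tg(sim_config(0, 0.1, 5)), 51)
  expect_equal(tg(sim_config(0, 0.1, 5))[51], 5)        # end on the grid
  g2 <- tg(sim_config(0, 0.3, 1))                        # end off the grid
  expect_equal(g2, c(0, 0.3, 0.6, 0.9))
  expect_equal(tg(sim_config(2, 0.5, 2)), 2)             # degenerate interval
  # grid points are start + k*step exactly, not running sums
  g3 <- tg(sim_config(0, 0.1, 100))
  expect_identical(g3[1001], 0 + 1000 * 0.1)
})

test_that("compiled derivatives match hand substitution into the equations", {
  g <- build_sir(sir_params(b_d = 1, g = 1, S0 = 2, I0 = 3, R0 = 0))
  rhs <- compile_rhs(g)
  expect_equal(unname(rhs(0, c(S = 2, I = 3, R = 0))), c(-6, 3, 3))

  ext <- build_extended_sir(extended_sir_params(
    b = 1, b_d = 1, b_e = 1, n = 1, g = 1, p = 1, c = 1,
    S0 = 1, I0 = 1, R0 = 1, E0 = 1))
  d <- compile_rhs(ext)(0, c(S = 1, I = 1, R = 1, E = 1))
  expect_equal(unname(d["S"]), 1 - 1 - 1 - 1)
  # with no infection pressure, dR/dt reduces to -n*R exactly
  d0 <- compile_rhs(ext)(0, c(S = 1, I = 0, R = 3, E = 0))
  expect_identical(unname(d0["R"]), -3)

  # dX/dt = k with k = 0 is identically zero
  g0 <- model_graph("flat")
  g0 <- add_term(g0, "X", 5)
  g0 <- add_term(g0, "k", 0)
  g0 <- add_assigner(g0, term_id(g0, "X"))
  g0 <- connect(g0, term_id(g0, "k"), last_node_id(g0))
  expect_identical(unname(compile_rhs(g0)(0, c(X = 123))), 0)

  bad <- model_graph("incomplete")
  expect_error(compile_rhs(bad), class = "odegraph_validation_error")
})

test_that("linear decay matches its closed form on the whole grid", {
  g <- build_decay(X0 = 1, k = 1, step = 0.1, end = 5)
  res <- simulate_model(g)
  expect_identical(unname(res$trajectories[1, 1]), 1)  # exact initial value
  expect_lt(rel_diff(res$trajectories[, 1], exp(-res$times)), 1e-6)
})

test_that("a degenerate interval returns a single row of initial conditions", {
  g <- build_sir()
  res <- simulate_model(g, sim_config(3, 0.5, 3))
  expect_equal(res$times, 3)
  expect_identical(unname(res$trajectories[1, ]), c(990, 10, 0))
})

test_that("halving the reporting step does not change shared grid points", {
  g <- build_predator_prey()
  coarse <- simulate_model(g, sim_config(0, 0.2, 10))
  fine <- simulate_model(g, sim_config(0, 0.1, 10))
  shared <- seq(1, length(fine$times), by = 2)
  expect_equal(fine$times[shared], coarse$times)
  expect_lt(rel_diff(fine$trajectories[shared, ], coarse$trajectories), 1e-5)
})

test_that("the stiff solver alternative integrates the same model consistently", {
  g <- build_decay(step = 0.5, end = 5)
  a <- simulate_model(g, sim_config(0, 0.5, 5, method = "ode45"))
  b <- simulate_model(g, sim_config(0, 0.5, 5, method = "lsoda"))
  expect_lt(rel_diff(b$trajectories, a$trajectories), 1e-4)
})

test_that("CSV output is shaped and round-trips exactly", {
  g <- build_sir()
  res <- simulate_model(g, sim_config(0, 2, 100))       # 51 grid points
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_sim_csv(res, path)
  lines <- readLines(path)
  expect_length(lines, 52)
  expect_equal(lines[1], "t,S,I,R")
  expect_length(strsplit(lines[2], ",")[[1]], 4)
  back <- read_sim_csv(path)
  expect_identical(back$times, res$times)
  expect_identical(unname(back$trajectories), unname(res$trajectories))
  expect_error(write_sim_csv(res, file.path(tempfile(), "x", "y.csv")),
               class = "odegraph_io_error")
})

test_that("runaway dynamics surface as simulation errors, not silent NaNs", {
  # dX/dt = k / X with k < 0 reaches X = 0 in finite time (at t = 0.5 here)
  g <- model_graph("singular", sim = sim_config(0, 0.1, 0.6))
  g <- add_term(g, "X", 1)
  g <- add_term(g, "k", -1)
  g <- add_expression(g, "divide", "e", 2)
  e <- last_node_id(g)
  g <- connect(g, term_id(g, "k"), e, 1)
  g <- connect(g, term_id(g, "X"), e, 2)
  g <- add_assigner(g, term_id(g, "X"))
  g <- connect(g, e, last_node_id(g))
  expect_error(suppressWarnings(simulate_model(g)), class = "odegraph_error")
})

test_that("reports have one combined page plus one page per variable", {
  g <- build_decay()
  res <- simulate_model(g, sim_config(0, 0.5, 5))
  path <- tempfile(fileext = ".pdf")
  on.exit(unlink(path))
  render_report(g, res, path)
  expect_equal(odegraph:::pdf_page_count(path), 2)   # combined + X
})
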