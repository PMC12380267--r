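# Programmatic builders for the worked example models. These are the
# package's test corpus and its documentation examples: a classic SIR
# epidemic, an extended SIR with an environmental pathogen compartment, a
# simplified innate immune-regulation model (which exercises the extension
# system), and the Lotka-Volterra predator-prey model.
#
# Default parameter values are constants of this package, chosen once so
# that each model shows its characteristic qualitative behavior (epidemic
# wave; damped oscillation to the demographic equilibrium; resolved
# inflammation; neutral predator-prey cycles). See the vignette.

check_nonneg <- function(params) {
  bad <- names(params)[vapply(params, function(x)
    !is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0, TRUE)]
  if (length(bad))
    stop_odegraph("odegraph_value_error", sprintf(
      "parameter \"%s\" must be a non-negative finite number", bad[[1]]))
  params
}

# Add an expression node and connect its inputs (node ids) in pin order.
wire <- function(g, operator, name, inputs) {
  g <- add_expression(g, operator, name, length(inputs))
  e <- last_node_id(g)
  for (i in seq_along(inputs)) g <- connect(g, inputs[[i]], e, i)
  g$last_id <- e
  g
}

#' Parameters of the classic SIR model
#'
#' @param b_d Infection rate coefficient (per individual per unit time).
#' @param g Recovery rate coefficient (per unit time).
#' @param S0,I0,R0 Initial susceptible / infectious / recovered counts.
#' @return A named list of non-negative values.
#' @export
sir_params <- function(b_d = 0.001, g = 0.1, S0 = 990, I0 = 10, R0 = 0) {
  check_nonneg(list(b_d = b_d, g = g, S0 = S0, I0 = I0, R0 = R0))
}

#' Build the classic SIR model graph
#'
#' dS/dt = -b_d S I, dI/dt = b_d S I - g I, dR/dt = g I. The infection term
#' follows the Mass Action Law: new infections scale with the product of
#' susceptible and infectious counts. The expression nodes mirror the three
#' canonical sub-expressions (b_d*S*I; g*I; their difference). The pure-loss
#' right-hand side of S is written without unary minus — the operator set
#' has none — as the subtraction fold (x - x) - x = -x over the infection
#' expression.
#'
#' @param params A [sir_params()] list.
#' @return A validated model graph.
#' @export
build_sir <- function(params = sir_params()) {
  p <- params
  g <- model_graph("SIR", sim = sim_config(0, 0.5, 100,
                                           y_label = "individuals"))
  g <- add_term(g, "S", p$S0)
  g <- add_term(g, "I", p$I0)
  g <- add_term(g, "R", p$R0)
  g <- add_term(g, "b_d", p$b_d)
  g <- add_term(g, "g", p$g)
  ids <- lapply(c("S", "I", "R", "b_d", "g"), term_id, graph = g)
  names(ids) <- c("S", "I", "R", "b_d", "g")

  g <- wire(g, "multiply", "infection", c(ids$b_d, ids$S, ids$I))
  infection <- last_node_id(g)
  g <- wire(g, "multiply", "recover", c(ids$g, ids$I))
  recover <- last_node_id(g)
  g <- wire(g, "subtract", "I eq", c(infection, recover))
  i_eq <- last_node_id(g)
  g <- wire(g, "subtract", "S eq", c(infection, infection, infection))
  s_eq <- last_node_id(g)

  g <- add_assigner(g, ids$S); g <- connect(g, s_eq, last_node_id(g))
  g <- add_assigner(g, ids$I); g <- connect(g, i_eq, last_node_id(g))
  g <- add_assigner(g, ids$R); g <- connect(g, recover, last_node_id(g))
  g
}

#' Parameters of the extended SIR model
#'
#' Adds demography and an environmental pathogen compartment E to the SIR
#' framework: hosts are born susceptible at rate `b`, die naturally at rate
#' `n`, and are infected either by contact (`b_d`) or via the environment
#' (`b_e`); infected hosts shed pathogen at rate `p`, which decays at rate
#' `c`.
#'
#' @param b Birth rate (individuals per unit time).
#' @param b_d Direct-contact infection rate.
#' @param b_e Environmental infection rate.
#' @param n Natural death rate (must be > 0 for a demographic equilibrium).
#' @param g Recovery rate.
#' @param p Pathogen shedding rate.
#' @param c Pathogen decay rate.
#' @param S0,I0,R0,E0 Initial values.
#' @return A named list of non-negative values.
#' @export
extended_sir_params <- function(b = 2, b_d = 0.002, b_e = 5e-4, n = 0.01,
                                g = 0.1, p = 0.1, c = 0.5,
                                S0 = 195, I0 = 5, R0 = 0, E0 = 0) {
  check_nonneg(list(b = b, b_d = b_d, b_e = b_e, n = n, g = g, p = p, c = c,
                    S0 = S0, I0 = I0, R0 = R0, E0 = E0))
}

#' Build the extended SIR model graph
#'
#' dS/dt = b - b_d S I - b_e S E - n S; dI/dt = b_d S I + b_e S E - g I - n I;
#' dR/dt = g I - n R; dE/dt = p I - c E. Sub-expressions are named as in the
#' worked construction ("infection", "S death", "recover", "S eq", ...).
#' Summing the three host equations gives d(S+I+R)/dt = b - n (S+I+R), so
#' the host total relaxes to the demographic equilibrium b/n.
#'
#' @param params An [extended_sir_params()] list.
#' @return A validated model graph with 4 state variables and 7 constants.
#' @export
build_extended_sir <- function(params = extended_sir_params()) {
  p <- params
  g <- model_graph("extended SIR",
                   sim = sim_config(0, 1, 1500, y_label = "individuals"))
  for (tm in c("S", "I", "R", "E")) g <- add_term(g, tm, p[[paste0(tm, "0")]])
  for (tm in c("b", "b_d", "b_e", "n", "g", "p", "c"))
    g <- add_term(g, tm, p[[tm]])
  id <- function(nm) term_id(g, nm)

  g <- wire(g, "multiply", "infection", c(id("b_d"), id("S"), id("I")))
  infection <- last_node_id(g)
  g <- wire(g, "multiply", "env infection", c(id("b_e"), id("S"), id("E")))
  env_infection <- last_node_id(g)
  g <- wire(g, "multiply", "S death", c(id("n"), id("S")))
  s_death <- last_node_id(g)
  g <- wire(g, "subtract", "S eq",
            c(id("b"), infection, env_infection, s_death))
  s_eq <- last_node_id(g)

  g <- wire(g, "add", "new infections", c(infection, env_infection))
  new_inf <- last_node_id(g)
  g <- wire(g, "multiply", "recover", c(id("g"), id("I")))
  recover <- last_node_id(g)
  g <- wire(g, "multiply", "I death", c(id("n"), id("I")))
  i_death <- last_node_id(g)
  g <- wire(g, "subtract", "I eq", c(new_inf, recover, i_death))
  i_eq <- last_node_id(g)

  g <- wire(g, "multiply", "R death", c(id("n"), id("R")))
  r_death <- last_node_id(g)
  g <- wire(g, "subtract", "R eq", c(recover, r_death))
  r_eq <- last_node_id(g)

  g <- wire(g, "multiply", "shedding", c(id("p"), id("I")))
  shed <- last_node_id(g)
  g <- wire(g, "multiply", "decay", c(id("c"), id("E")))
  decay <- last_node_id(g)
  g <- wire(g, "subtract", "E eq", c(shed, decay))
  e_eq <- last_node_id(g)

  for (pair in list(c("S", s_eq), c("I", i_eq), c("R", r_eq), c("E", e_eq))) {
    g <- add_assigner(g, term_id(g, pair[[1]]))
    g <- connect(g, pair[[2]], last_node_id(g))
  }
  g
}

#' Parameters of the immune-regulation model
#'
#' A simplified model of innate immune response regulation after tissue
#' injury, tracking neutrophils (N), regulatory macrophages (M_reg),
#' pro-inflammatory cytokines (CH), anti-inflammatory cytokines (AC) and
#' tissue damage (TD). The anti-inflammatory mediator inhibits neutrophil
#' recruitment and cytokine production through the saturating factor
#' 1/(1 + alpha * AC), implemented as an extension node.
#'
#' @param beta_N Neutrophil activity coefficient (collateral damage and
#'   activity decay).
#' @param m_N Neutrophil natural death rate.
#' @param s_N Neutrophil source scaling on the inflammatory signal TD + CH.
#' @param alpha Anti-inflammatory inhibition strength.
#' @param gamma Regulatory-macrophage recruitment rate by neutrophils.
#' @param m_Mreg Regulatory-macrophage decay rate.
#' @param beta_C Pro-inflammatory cytokine production rate.
#' @param m_C Pro-inflammatory cytokine decay rate.
#' @param beta_AC Anti-inflammatory cytokine production rate.
#' @param m_AC Anti-inflammatory cytokine decay rate.
#' @param k Damage clearance rate by regulatory macrophages.
#' @param N0,Mreg0,CH0,AC0,TD0 Initial values (an injury is a positive TD0).
#' @return A named list of non-negative values.
#' @export
immune_params <- function(beta_N = 0.2, m_N = 0.1, s_N = 0.3, alpha = 2,
                          gamma = 0.15, m_Mreg = 0.05, beta_C = 0.8,
                          m_C = 0.6, beta_AC = 0.5, m_AC = 0.1, k = 0.4,
                          N0 = 0, Mreg0 = 0, CH0 = 0, AC0 = 0, TD0 = 10) {
  check_nonneg(list(beta_N = beta_N, m_N = m_N, s_N = s_N, alpha = alpha,
                    gamma = gamma, m_Mreg = m_Mreg, beta_C = beta_C,
                    m_C = m_C, beta_AC = beta_AC, m_AC = m_AC, k = k,
                    N0 = N0, Mreg0 = Mreg0, CH0 = CH0, AC0 = AC0, TD0 = TD0))
}

#' Path of the shipped inhibition extension file
#'
#' @return Path to the extension file defining the `inhibit` node used by
#'   [build_immune_model()].
#' @export
inhibition_extension <- function() {
  system.file("extdata", "extensions", "inhibition.R", package = "odegraph",
              mustWork = TRUE)
}

#' Build the immune-regulation model graph
#'
#' dN/dt = inhibit(s_N (TD + CH), AC, alpha) - beta_N N - m_N N;
#' dM_reg/dt = gamma N - m_Mreg M_reg;
#' dCH/dt = inhibit(beta_C N, AC, alpha) - m_C CH;
#' dAC/dt = beta_AC M_reg - m_AC AC;
#' dTD/dt = beta_N N - k M_reg TD,
#' where inhibit(x, ac, alpha) = x / (1 + alpha ac) comes from an extension
#' file, exercising the plugin path end to end (the model's serialized form
#' references the file). The beta_N*N expression node feeds both the N and
#' the TD equations, demonstrating expression reuse across ODEs.
#'
#' @param params An [immune_params()] list.
#' @param ext_path Path of the extension file to attach; defaults to the
#'   shipped copy ([inhibition_extension()]).
#' @return A validated model graph with 5 state variables.
#' @export
build_immune_model <- function(params = immune_params(),
                               ext_path = inhibition_extension()) {
  p <- params
  g <- model_graph("immune regulation",
                   sim = sim_config(0, 0.5, 300, y_label = "concentration"))
  g <- attach_extensions(g, ext_path)
  for (tm in c("N", "M_reg", "CH", "AC", "TD"))
    g <- add_term(g, tm, p[[paste0(sub("_", "", tm), "0")]])
  for (tm in c("beta_N", "m_N", "s_N", "alpha", "gamma", "m_Mreg", "beta_C",
               "m_C", "beta_AC", "m_AC", "k"))
    g <- add_term(g, tm, p[[tm]])
  id <- function(nm) term_id(g, nm)

  g <- wire(g, "add", "inflammatory signal", c(id("TD"), id("CH")))
  signal <- last_node_id(g)
  g <- wire(g, "multiply", "raw N source", c(id("s_N"), signal))
  raw_source <- last_node_id(g)
  g <- wire(g, "inhibit", "N migration", c(raw_source, id("AC"), id("alpha")))
  migration <- last_node_id(g)
  g <- wire(g, "multiply", "N activity", c(id("beta_N"), id("N")))
  n_activity <- last_node_id(g)
  g <- wire(g, "multiply", "N death", c(id("m_N"), id("N")))
  n_death <- last_node_id(g)
  g <- wire(g, "subtract", "N eq", c(migration, n_activity, n_death))
  n_eq <- last_node_id(g)

  g <- wire(g, "multiply", "Mreg recruitment", c(id("gamma"), id("N")))
  recruit <- last_node_id(g)
  g <- wire(g, "multiply", "Mreg decay", c(id("m_Mreg"), id("M_reg")))
  mreg_decay <- last_node_id(g)
  g <- wire(g, "subtract", "Mreg eq", c(recruit, mreg_decay))
  mreg_eq <- last_node_id(g)

  g <- wire(g, "multiply", "raw CH production", c(id("beta_C"), id("N")))
  raw_ch <- last_node_id(g)
  g <- wire(g, "inhibit", "CH production", c(raw_ch, id("AC"), id("alpha")))
  ch_prod <- last_node_id(g)
  g <- wire(g, "multiply", "CH decay", c(id("m_C"), id("CH")))
  ch_decay <- last_node_id(g)
  g <- wire(g, "subtract", "CH eq", c(ch_prod, ch_decay))
  ch_eq <- last_node_id(g)

  g <- wire(g, "multiply", "AC production", c(id("beta_AC"), id("M_reg")))
  ac_prod <- last_node_id(g)
  g <- wire(g, "multiply", "AC decay", c(id("m_AC"), id("AC")))
  ac_decay <- last_node_id(g)
  g <- wire(g, "subtract", "AC eq", c(ac_prod, ac_decay))
  ac_eq <- last_node_id(g)

  g <- wire(g, "multiply", "TD elimination", c(id("k"), id("M_reg"), id("TD")))
  td_elim <- last_node_id(g)
  g <- wire(g, "subtract", "TD_eq", c(n_activity, td_elim))
  td_eq <- last_node_id(g)

  for (pair in list(c("N", n_eq), c("M_reg", mreg_eq), c("CH", ch_eq),
                    c("AC", ac_eq), c("TD", td_eq))) {
    g <- add_assigner(g, term_id(g, pair[[1]]))
    g <- connect(g, pair[[2]], last_node_id(g))
  }
  g
}

#' Parameters of the Lotka-Volterra predator-prey model
#'
#' @param alpha Prey intrinsic growth rate.
#' @param beta Predation rate.
#' @param delta Predator growth per predation event.
#' @param gamma Predator death rate.
#' @param prey0,predator0 Initial population sizes.
#' @return A named list of non-negative values.
#' @export
predator_prey_params <- function(alpha = 2 / 3, beta = 4 / 3, delta = 1,
                                 gamma = 1, prey0 = 1, predator0 = 1) {
  check_nonneg(list(alpha = alpha, beta = beta, delta = delta, gamma = gamma,
                    prey0 = prey0, predator0 = predator0))
}

#' Build the Lotka-Volterra predator-prey model graph
#'
#' d(prey)/dt = alpha prey - beta prey predator;
#' d(predator)/dt = delta prey predator - gamma predator.
#' Along exact trajectories the quantity
#' delta x - gamma log x + beta y - alpha log y is conserved, which the test
#' suite uses as an accuracy probe for the integrator.
#'
#' @param params A [predator_prey_params()] list.
#' @return A validated model graph with 2 state variables and 4 constants.
#' @export
build_predator_prey <- function(params = predator_prey_params()) {
  p <- params
  g <- model_graph("predator-prey",
                   sim = sim_config(0, 0.05, 30, y_label = "population"))
  g <- add_term(g, "prey", p$prey0)
  g <- add_term(g, "predator", p$predator0)
  for (tm in c("alpha", "beta", "delta", "gamma")) g <- add_term(g, tm, p[[tm]])
  id <- function(nm) term_id(g, nm)

  g <- wire(g, "multiply", "prey growth", c(id("alpha"), id("prey")))
  growth <- last_node_id(g)
  g <- wire(g, "multiply", "predation",
            c(id("beta"), id("prey"), id("predator")))
  predation <- last_node_id(g)
  g <- wire(g, "subtract", "prey eq", c(growth, predation))
  prey_eq <- last_node_id(g)

  g <- wire(g, "multiply", "predator growth",
            c(id("delta"), id("prey"), id("predator")))
  pred_growth <- last_node_id(g)
  g <- wire(g, "multiply", "predator death", c(id("gamma"), id("predator")))
  pred_death <- last_node_id(g)
  g <- wire(g, "subtract", "predator eq", c(pred_growth, pred_death))
  pred_eq <- last_node_id(g)

  g <- add_assigner(g, id("prey")); g <- connect(g, prey_eq, last_node_id(g))
  g <- add_assigner(g, id("predator"))
  g <- connect(g, pred_eq, last_node_id(g))
  g
}
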