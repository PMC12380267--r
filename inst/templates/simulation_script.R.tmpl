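#!/usr/bin/env Rscript
# {{model_name}} -- standalone ODE simulation script.
# Generated from a node-graph model. Runs with no arguments, or:
#   Rscript <this script> [results.csv] [report.pdf]
suppressPackageStartupMessages(library(deSolve))
{{#if has_extensions}}

# Extension functions, embedded verbatim from the model's extension files.
# `node` marks a function as a graph node; at run time it is the identity.
node <- function(fn, format = NULL) fn
{{#for ext in extension_sources}}
{{ext.text}}
{{/for}}
{{/if}}

# State variables and their initial conditions
state0 <- c(
{{#for p in populations}}
  {{p.identifier}} = {{p.initial_value}}{{p.sep}}
{{/for}}
)
{{#if has_constants}}

# Model constants
constants <- c(
{{#for k in constants}}
  {{k.identifier}} = {{k.value}}{{k.sep}}
{{/for}}
)
{{/if}}

# Right-hand side of the ODE system: unpack the state vector, then the
# constants, then evaluate each d/dt expression.
system <- function(t, y, constants) {
{{#for p in populations}}
  {{p.identifier}} <- y[["{{p.identifier}}"]]
{{/for}}
{{#if has_constants}}
{{#for k in constants}}
  {{k.identifier}} <- constants[["{{k.identifier}}"]]
{{/for}}
{{/if}}
  list(c(
{{#for o in odes}}
    {{o.identifier}} = {{o.rhs_text}}{{o.sep}}
{{/for}}
  ))
}

# Reporting grid ({{start_time}} to {{end_time}} in steps of {{time_step}})
# and adaptive-step integration; the solver steps independently of the grid.
times <- {{start_time}} + seq(0, {{n_steps}}) * {{time_step}}
solution <- if (length(times) < 2) {
  cbind(time = times, t(state0))
} else {
  deSolve::ode(y = state0, times = times, func = system,
               parms = {{#if has_constants}}constants{{#else}}NULL{{/if}},
               method = {{method_q}}, rtol = {{rel_tol}}, atol = {{abs_tol}})
}

args <- commandArgs(trailingOnly = TRUE)
csv_path <- if (length(args) >= 1) args[[1]] else {{csv_path_q}}
report_path <- if (length(args) >= 2) args[[2]] else {{report_path_q}}

# Results CSV: header "t" + variable names, one row per grid point, values
# as the shortest decimal that parses back to the exact double.
fmt <- function(x) vapply(x, function(xi) {
  for (d in 15:17) {
    s <- sprintf("%.*g", d, xi)
    if (as.numeric(s) == xi) return(s)
  }
  sprintf("%.17g", xi)
}, "")
labels <- c({{var_labels_q}})
lines <- c(paste(c("t", labels), collapse = ","),
           apply(solution, 1, function(row) paste(fmt(row), collapse = ",")))
writeLines(lines, csv_path)

# Report: one combined plot, then one page per variable.
pdf(report_path, width = 8, height = 5, onefile = TRUE)
palette_cols <- hcl.colors(max(3, length(labels)), "Dark 3")
matplot(solution[, 1], solution[, -1, drop = FALSE], type = "l", lty = 1,
        lwd = 2, col = palette_cols, xlab = {{x_label_q}},
        ylab = {{y_label_q}}, main = {{model_name_q}})
legend("topright", legend = labels, col = palette_cols[seq_along(labels)],
       lty = 1, lwd = 2, bty = "n")
for (j in seq_along(labels))
  plot(solution[, 1], solution[, j + 1], type = "l", lwd = 2,
       col = palette_cols[j], xlab = {{x_label_q}}, ylab = {{y_label_q}},
       main = labels[j])
invisible(dev.off())
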