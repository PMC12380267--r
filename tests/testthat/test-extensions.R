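math_nodes <- system.file("extdata", "extensions", "math_nodes.R",
                          package = "odegraph")

test_that("decorated functions load in file order with arity from their parameters", {
  reg <- load_extensions(math_nodes)
  expect_equal(names(reg), c("sin", "pow"))
  expect_equal(reg$sin$arity, 1L)
  expect_null(reg$sin$format)
  expect_equal(reg$pow$arity, 2L)
  expect_equal(reg$pow$format, "$1 ^ $2")
  expect_equal(reg$pow$fn(2, 10), 1024)
  expect_match(reg$pow$source_text, "node\\(function")

  f <- tempfile(fileext = ".R")
  writeLines("plain <- function(x) x + 1", f)
  expect_length(load_extensions(f), 0)

  writeLines("three <- node(function(a, b, c) a + b * c)", f)
  expect_equal(load_extensions(f)$three$arity, 3L)
})

test_that("bad extension files are rejected with load-family errors", {
  f <- tempfile(fileext = ".R")
  writeLines("oops <- node(function() 1)", f)
  expect_error(load_extensions(f), class = "odegraph_arity_error")
  writeLines("this is not ( R", f)
  expect_error(load_extensions(f), class = "odegraph_load_error")
  writeLines("bad <- node(function(x) x, format = '$1 + $3')", f)
  expect_error(load_extensions(f), class = "odegraph_format_error")
  expect_error(load_extensions(tempfile()),
               class = "odegraph_resolution_error")

  # duplicate decorated name across two attached files
  g <- attach_extensions(model_graph("m"), math_nodes)
  f2 <- tempfile(fileext = ".R")
  writeLines("pow <- node(function(x, y) x^y)", f2)
  expect_error(attach_extensions(g, f2), class = "odegraph_collision_error")
})

test_that("undecorated helpers stay usable by decorated functions", {
  f <- tempfile(fileext = ".R")
  writeLines(c("half <- function(x) x / 2",
               "halved_square <- node(function(x) half(x * x))"), f)
  reg <- load_extensions(f)
  expect_equal(names(reg), "halved_square")
  expect_equal(reg$halved_square$fn(4), 8)
  # the whole file text (helper included) is retained for code generation
  expect_match(attr(reg, "sources")[[1]], "half <- function")
})

test_that("extension calls render via format or standard function notation", {
  reg <- load_extensions(math_nodes)
  expect_equal(render_extension_call(reg$sin, "x"), "sin(x)")
  expect_equal(render_extension_call(reg$pow, c("x", "2")), "x ^ 2")
  expect_error(render_extension_call(reg$pow, "x"),
               class = "odegraph_arity_error")

  f <- tempfile(fileext = ".R")
  writeLines("sq <- node(function(x) x * x, format = '$1 * $1')", f)
  sq <- load_extensions(f)$sq
  expect_equal(render_extension_call(sq, "(a + b)"), "(a + b) * (a + b)")

  # rendering totality: no placeholder survives for any argument set
  set.seed(91)
  for (rep in 1:20) {
    args <- replicate(2, paste(sample(c(letters, "$", "("), 4), collapse = ""))
    out <- render_extension_call(reg$pow, args)
    expect_false(grepl("$1", out, fixed = TRUE) || grepl("$2", out, fixed = TRUE))
  }
})

test_that("model extension references resolve, and dangling operators are caught", {
  expect_length(resolve_model_extensions(build_sir())$extensions, 0)

  imm <- deserialize_model(serialize_model(build_immune_model()))
  imm <- resolve_model_extensions(imm)   # refs are absolute (installed copy)
  expect_named(imm$extensions, "inhibit")

  gone <- imm
  gone$extension_refs <- file.path(tempdir(), "deleted.R")
  expect_error(resolve_model_extensions(gone),
               class = "odegraph_resolution_error")

  undef <- imm
  f <- tempfile(fileext = ".R")
  writeLines("other <- node(function(x) x)", f)
  undef$extension_refs <- f
  expect_error(resolve_model_extensions(undef),
               class = "odegraph_dangling_operator")
})
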