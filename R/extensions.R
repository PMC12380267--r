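# Plugin nodes: user-written R source files define new expression-node
# kinds by wrapping plain functions in node(). The function's parameter
# count becomes the node's input-pin arity; an optional display format
# ("$1 ^ $2") controls how calls render inside equations.

# Creation-order counter so load_extensions() can report functions in file
# order even though environments are unordered.
the <- new.env(parent = emptyenv())
the$node_seq <- 0L

#' Mark a function as an extension node
#'
#' Used inside extension files: every function wrapped in `node()` becomes
#' available as a new expression-node operator once the file is loaded with
#' [load_extensions()] or [attach_extensions()]. Undecorated functions in
#' the same file are not turned into nodes but remain callable by decorated
#' ones (their source travels with the file into generated code).
#'
#' @param fn A function of one or more arguments.
#' @param format Optional display template using positional placeholders
#'   `$1`, `$2`, ... (e.g. `"$1 ^ $2"`). When absent, calls render in
#'   standard function notation `name(arg1, arg2, ...)`.
#' @return `fn`, classed and annotated; calling it is unchanged.
#' @examples
#' pow <- node(function(x, y) x^y, format = "$1 ^ $2")
#' pow(2, 10)
#' @export
node <- function(fn, format = NULL) {
  stopifnot(is.function(fn))
  the$node_seq <- the$node_seq + 1L
  structure(fn, ode_node = TRUE, ode_format = format, ode_seq = the$node_seq,
            class = c("ode_node_fn", class(fn)))
}

empty_registry <- function() {
  structure(list(), class = "ode_ext_registry", sources = character())
}

#' Load extension functions from a plugin file
#'
#' Sources the file in a fresh environment (providing the [node()]
#' decorator) and collects every decorated function, in definition order.
#' Loading executes the file's code, so only load files you trust.
#'
#' @param path Path to an R source file.
#' @return An extension registry: a named list of extension functions, each
#'   with fields `name`, `arity`, `format`, `source_text` and `fn` (the
#'   callable). The full file text is kept in the `sources` attribute for
#'   embedding into generated code.
#' @export
load_extensions <- function(path) {
  if (!file.exists(path))
    stop_odegraph("odegraph_resolution_error",
                  sprintf("extension file not found: %s", path))
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  exprs <- tryCatch(parse(text = text, srcfile = path),
                    error = function(e) stop_odegraph(
                      "odegraph_load_error",
                      sprintf("cannot parse extension file %s: %s",
                              path, conditionMessage(e))))
  env <- new.env(parent = baseenv())
  env$node <- node
  tryCatch(for (e in exprs) eval(e, env),
           error = function(e) stop_odegraph(
             "odegraph_load_error",
             sprintf("error while loading extension file %s: %s",
                     path, conditionMessage(e))))
  nms <- ls(env, sorted = TRUE)
  decorated <- Filter(function(nm) isTRUE(attr(env[[nm]], "ode_node")), nms)
  decorated <- decorated[order(vapply(decorated,
                                      function(nm) attr(env[[nm]], "ode_seq"),
                                      0L))]
  reg <- empty_registry()
  for (nm in decorated) {
    fn <- env[[nm]]
    arity <- length(formals(fn))
    if (arity < 1L)
      stop_odegraph("odegraph_arity_error", sprintf(
        "extension function \"%s\" in %s takes no parameters; nodes need at least one input pin",
        nm, path))
    fmt <- attr(fn, "ode_format")
    if (!is.null(fmt)) check_format(fmt, arity, nm)
    reg[[nm]] <- structure(list(
      name = nm, arity = arity, format = fmt, source_file = path,
      source_text = paste0(nm, " <- node(", fn_source(fn),
                           if (!is.null(fmt))
                             paste0(", format = ", deparse(fmt)), ")"),
      fn = fn
    ), class = "ode_extension_function")
  }
  attr(reg, "sources") <- stats::setNames(text, path)
  class(reg) <- "ode_ext_registry"
  reg
}

fn_source <- function(fn) {
  bare <- fn
  attributes(bare) <- NULL
  paste(deparse(bare), collapse = "\n")
}

check_format <- function(fmt, arity, name) {
  refs <- regmatches(fmt, gregexpr("\\$[0-9]+", fmt))[[1]]
  ks <- as.integer(sub("\\$", "", refs))
  if (length(ks) && any(ks < 1L | ks > arity))
    stop_odegraph("odegraph_format_error", sprintf(
      "format of extension \"%s\" references $%d but arity is %d",
      name, ks[ks < 1L | ks > arity][[1]], arity))
}

merge_registries <- function(a, b) {
  dup <- intersect(names(a), names(b))
  if (length(dup))
    stop_odegraph("odegraph_collision_error", sprintf(
      "extension function \"%s\" is defined by more than one loaded file",
      dup[[1]]))
  out <- c(unclass(a), unclass(b))
  attr(out, "sources") <- c(attr(a, "sources"), attr(b, "sources"))
  class(out) <- "ode_ext_registry"
  out
}

#' Attach an extension file to a model
#'
#' Loads the file and records it in the model's extension references, so the
#' model can use its functions as expression operators and a saved model
#' remembers which files to reload.
#'
#' @param graph A model graph.
#' @param path Path to the extension file (stored verbatim in the model's
#'   extension references; keep it relative to the model file's directory
#'   when the model is meant to be shared).
#' @return The updated graph.
#' @export
attach_extensions <- function(graph, path) {
  stopifnot(is_model_graph(graph))
  reg <- load_extensions(path)
  graph$extensions <- merge_registries(graph$extensions, reg)
  graph$extension_refs <- c(graph$extension_refs, path)
  graph
}

#' Render a call to an extension function
#'
#' Default rendering is standard function notation `name(arg1, arg2, ...)`;
#' a `format` template replaces each `$k` placeholder with the k-th rendered
#' argument (placeholders may repeat).
#'
#' @param func An extension function (an entry of a registry).
#' @param rendered_args Character vector of rendered argument texts, one per
#'   input pin.
#' @return A character scalar.
#' @export
render_extension_call <- function(func, rendered_args) {
  stopifnot(inherits(func, "ode_extension_function"))
  if (length(rendered_args) != func$arity)
    stop_odegraph("odegraph_arity_error", sprintf(
      "extension \"%s\" has arity %d, got %d arguments",
      func$name, func$arity, length(rendered_args)))
  if (is.null(func$format))
    return(paste0(func$name, "(", paste(rendered_args, collapse = ", "), ")"))
  out <- func$format
  # Descending k so "$12" is consumed before "$1"; fixed matching keeps
  # regex metacharacters in the argument texts literal.
  for (k in rev(seq_along(rendered_args)))
    out <- gsub(paste0("$", k), rendered_args[[k]], out, fixed = TRUE)
  out
}

#' Load every extension file a model references
#'
#' Resolves the model's extension references (relative paths against
#' `base_dir`), loads each file, and checks that every extension operator
#' used by an expression node is actually defined.
#'
#' @param graph A model graph.
#' @param base_dir Directory against which relative references resolve
#'   (typically the model file's directory).
#' @return The graph with its in-memory registry populated.
#' @export
resolve_model_extensions <- function(graph, base_dir = ".") {
  stopifnot(is_model_graph(graph))
  reg <- empty_registry()
  for (ref in graph$extension_refs) {
    path <- if (is_absolute_path(ref)) ref else file.path(base_dir, ref)
    if (!file.exists(path))
      stop_odegraph("odegraph_resolution_error", sprintf(
        "extension file \"%s\" (resolved to %s) does not exist", ref, path))
    reg <- merge_registries(reg, load_extensions(path))
  }
  graph$extensions <- reg
  for (n in nodes_of_kind(graph, "expression"))
    if (!(n$operator %in% ARITH_OPS) && is.null(reg[[n$operator]]))
      stop_odegraph("odegraph_dangling_operator", sprintf(
        "expression \"%s\" uses operator \"%s\" which no referenced extension file defines",
        n$name, n$operator))
  graph
}

is_absolute_path <- function(p) grepl("^(/|~|[A-Za-z]:)", p)

#' @export
print.ode_ext_registry <- function(x, ...) {
  cat(sprintf("<extension registry> %d function(s)\n", length(x)))
  for (f in x)
    cat(sprintf("  %s/%d%s\n", f$name, f$arity,
                if (is.null(f$format)) "" else paste0("  format: ", f$format)))
  invisible(x)
}
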