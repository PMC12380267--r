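# JSON intermediate representation. The on-disk schema (format_version
# "1.0") is documented in inst/schema/model-ir.md and is deliberately
# self-contained: stable key order, node order = insertion order, doubles at
# full round-trip precision, destination pins zero-based.

IR_FORMAT_VERSION <- "1.0"

#' Serialize a model graph to JSON text
#'
#' Output is deterministic — stable key order and node/link order equal to
#' insertion order — so serializing the same graph twice yields
#' byte-identical text and file diffs are meaningful. Numbers are written
#' with 17 significant digits, enough to round-trip doubles exactly.
#'
#' @param graph A model graph.
#' @return A character scalar of pretty-printed JSON.
#' @seealso [deserialize_model()], [save_model()]
#' @export
serialize_model <- function(graph) {
  stopifnot(is_model_graph(graph))
  nodes <- lapply(unname(graph$nodes), function(n) {
    rec <- switch(n$kind,
      term = list(id = n$id, kind = "term", name = n$name, value = n$value),
      expression = list(id = n$id, kind = "expression", name = n$name,
                        operator = n$operator, arity = n$arity),
      assigner = list(id = n$id, kind = "assigner", name = n$name,
                      target = n$target))
    if (!is.null(n$position)) rec$position <- as.numeric(n$position)
    rec
  })
  links <- lapply(unname(graph$links), function(l) {
    list(source = l$source, destination = l$destination,
         destination_pin = l$destination_pin - 1L)
  })
  doc <- list(
    format_version = IR_FORMAT_VERSION,
    metadata = list(name = graph$metadata$name, notes = graph$metadata$notes),
    nodes = nodes,
    links = links,
    simulation = unclass(graph$sim),
    extensions = as.list(graph$extension_refs)
  )
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                                pretty = TRUE, null = "null"))
}

#' Write a model to a JSON file
#'
#' @param graph A model graph.
#' @param path Output file path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(graph, path) {
  writeLines(serialize_model(graph), path, useBytes = TRUE)
  invisible(path)
}

require_field <- function(rec, field, where) {
  if (is.null(rec[[field]]))
    stop_odegraph("odegraph_schema_error",
                  sprintf("missing required field \"%s\" in %s", field, where))
  rec[[field]]
}

#' Deserialize a model graph from JSON text
#'
#' The inverse of [serialize_model()]: `deserialize_model(serialize_model(g))`
#' is structurally equal to `g` (ids, kinds, names, values, links,
#' simulation settings, extension references, positions). Malformed input is
#' rejected with a specific error: unparseable JSON, an unknown
#' format_version, an unknown node kind, a missing required field (named in
#' the message), or a link endpoint that resolves to no node. Extension
#' files referenced by the model are not loaded here; call
#' [resolve_model_extensions()] (or use [load_model()]).
#'
#' @param text JSON text (character scalar, possibly multi-line).
#' @return A model graph.
#' @export
deserialize_model <- function(text) {
  doc <- tryCatch(
    jsonlite::fromJSON(paste(text, collapse = "\n"), simplifyVector = FALSE),
    error = function(e) stop_odegraph(
      "odegraph_parse_error",
      sprintf("not parseable as JSON: %s", conditionMessage(e))))
  if (!is.list(doc))
    stop_odegraph("odegraph_schema_error", "document root must be an object")
  ver <- require_field(doc, "format_version", "document")
  if (!identical(ver, IR_FORMAT_VERSION))
    stop_odegraph("odegraph_version_error", sprintf(
      "unknown format_version \"%s\" (this package reads \"%s\")",
      ver, IR_FORMAT_VERSION))
  meta <- require_field(doc, "metadata", "document")
  node_recs <- require_field(doc, "nodes", "document")
  link_recs <- require_field(doc, "links", "document")
  sim_rec <- require_field(doc, "simulation", "document")

  g <- model_graph(
    name = require_field(meta, "name", "metadata"),
    notes = if (is.null(meta$notes)) "" else meta$notes,
    sim = do.call(sim_config, sim_rec)
  )
  for (rec in node_recs) {
    id <- require_field(rec, "id", "node record")
    kind <- require_field(rec, "kind", "node record")
    if (!is.null(g$nodes[[id]]))
      stop_odegraph("odegraph_schema_error",
                    sprintf("duplicate node id \"%s\"", id))
    node <- switch(kind,
      term = list(id = id, kind = "term",
                  name = require_field(rec, "name", sprintf("term %s", id)),
                  value = as.numeric(
                    require_field(rec, "value", sprintf("term %s", id)))),
      expression = list(
        id = id, kind = "expression",
        name = if (is.null(rec$name)) "" else rec$name,
        operator = require_field(rec, "operator",
                                 sprintf("expression %s", id)),
        arity = as.integer(require_field(rec, "arity",
                                         sprintf("expression %s", id)))),
      assigner = list(
        id = id, kind = "assigner",
        name = if (is.null(rec$name)) "" else rec$name,
        target = require_field(rec, "target", sprintf("assigner %s", id))),
      stop_odegraph("odegraph_schema_error",
                    sprintf("unknown node kind \"%s\" (node %s)", kind, id)))
    if (!is.null(rec$position))
      node$position <- as.numeric(unlist(rec$position))
    g$nodes[[id]] <- node
    g$last_id <- id
  }
  for (n in assigner_nodes(g))
    if (is.null(g$nodes[[n$target]]) || g$nodes[[n$target]]$kind != "term")
      stop_odegraph("odegraph_reference_error", sprintf(
        "assigner \"%s\" targets \"%s\", which is not a term node in the document",
        n$id, n$target))
  targets <- vapply(assigner_nodes(g), `[[`, "", "target")
  if (anyDuplicated(targets))
    stop_odegraph("odegraph_reference_error", sprintf(
      "more than one assigner targets term \"%s\"",
      targets[duplicated(targets)][[1]]))
  # Node counter resumes past any numeric-suffixed ids already present.
  suffixes <- suppressWarnings(
    as.integer(sub("^n", "", grep("^n[0-9]+$", names(g$nodes), value = TRUE))))
  g$counter[["node"]] <- max(0L, suffixes)
  for (rec in link_recs) {
    src <- require_field(rec, "source", "link record")
    dst <- require_field(rec, "destination", "link record")
    pin <- require_field(rec, "destination_pin", "link record")
    for (endpoint in c(src, dst))
      if (is.null(g$nodes[[endpoint]]))
        stop_odegraph("odegraph_reference_error", sprintf(
          "link endpoint \"%s\" resolves to no node in the document",
          endpoint))
    # connect() re-enforces pin typing, occupancy and acyclicity, so a
    # structurally invalid document cannot yield an invalid graph.
    g <- connect(g, src, dst, as.integer(pin) + 1L)
  }
  if (!is.null(doc$extensions))
    g$extension_refs <- vapply(doc$extensions, as.character, "")
  g
}

#' Load a model from a JSON file
#'
#' Reads and deserializes the file and, by default, resolves the model's
#' extension references relative to the file's directory.
#'
#' @param path Path to a model JSON file.
#' @param resolve_extensions Load referenced extension files? (default TRUE;
#'   skipped automatically when the model references none).
#' @return A model graph.
#' @export
load_model <- function(path, resolve_extensions = TRUE) {
  if (!file.exists(path))
    stop_odegraph("odegraph_io_error", sprintf("no such file: %s", path))
  g <- deserialize_model(readLines(path, warn = FALSE))
  if (resolve_extensions && length(g$extension_refs))
    g <- resolve_model_extensions(g, base_dir = dirname(path))
  g
}

#' Structural equality of two model graphs
#'
#' Compares ids, kinds, names, values, operators, arities, targets, links,
#' positions, simulation settings and extension references — everything the
#' IR round-trips. The in-memory extension registry is not compared.
#'
#' @param a,b Model graphs.
#' @return TRUE or FALSE.
#' @export
model_identical <- function(a, b) {
  strip <- function(g) {
    g$extensions <- NULL
    g$counter <- NULL
    g$last_id <- NULL
    g$links <- lapply(unname(g$links), function(l) l[c(
      "source", "destination", "destination_pin")])
    g$nodes <- lapply(unname(g$nodes), function(n) {
      n <- Filter(Negate(is.null), n)
      n[order(names(n))]
    })
    g$sim <- unclass(g$sim)
    g$extension_refs <- as.character(g$extension_refs)
    g
  }
  isTRUE(all.equal(strip(a), strip(b), tolerance = 0))
}
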