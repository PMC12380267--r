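# A small text-template engine for code generation. Placeholder vocabulary:
#
#   {{name}}            insert a scalar (or {{item.field}} inside a loop)
#   {{#if name}}...{{#else}}...{{/if}}   conditional block
#   {{#for var in name}}...{{/for}}      iterate a list, binding `var`
#
# Block tags standing on their own line are trimmed together with that
# line's break, so templates can be indented naturally. This is all the
# expressive power code generation needs; values are prepared (formatted,
# quoted) by the caller, the engine only substitutes.

render_template <- function(template, data) {
  template <- gsub("(?m)^[ \t]*(\\{\\{[#/][^{}]*\\}\\})[ \t]*(\n|$)", "\\1",
                   template, perl = TRUE)
  toks <- tokenize_template(template)
  res <- render_seq(toks, 1L, data)
  if (!is.null(res$stopped_at))
    stop_odegraph("odegraph_template_error",
                  sprintf("unexpected \"%s\" tag", res$stopped_at))
  res$text
}

tokenize_template <- function(template) {
  m <- gregexpr("\\{\\{[^{}]*\\}\\}", template)[[1]]
  toks <- list()
  pos <- 1L
  if (m[1] != -1) {
    for (i in seq_along(m)) {
      start <- m[i]
      len <- attr(m, "match.length")[i]
      if (start > pos)
        toks[[length(toks) + 1L]] <-
          list(type = "text", value = substr(template, pos, start - 1L))
      tag <- trimws(substr(template, start + 2L, start + len - 3L))
      toks[[length(toks) + 1L]] <- list(type = "tag", value = tag)
      pos <- start + len
    }
  }
  if (pos <= nchar(template))
    toks[[length(toks) + 1L]] <-
      list(type = "text", value = substr(template, pos, nchar(template)))
  toks
}

tpl_lookup <- function(data, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  val <- data
  for (p in parts) {
    if (!is.list(val) || is.null(val[[p]]))
      stop_odegraph("odegraph_template_error",
                    sprintf("template references unknown value \"%s\"", path))
    val <- val[[p]]
  }
  val
}

tpl_truthy <- function(v) {
  if (is.null(v) || length(v) == 0L) return(FALSE)
  if (is.logical(v)) return(isTRUE(v[[1]]))
  if (is.character(v)) return(any(nzchar(v)))
  if (is.list(v)) return(length(v) > 0L)
  TRUE
}

# Renders tokens from `i` until a closing/else tag or end of input; returns
# the text, the index after the stopping tag, and which tag stopped it.
render_seq <- function(toks, i, data) {
  out <- character()
  while (i <= length(toks)) {
    tok <- toks[[i]]
    if (tok$type == "text") {
      out <- c(out, tok$value)
      i <- i + 1L
      next
    }
    tag <- tok$value
    if (tag %in% c("/if", "/for", "#else"))
      return(list(text = paste(out, collapse = ""), next_i = i + 1L,
                  stopped_at = tag))
    if (startsWith(tag, "#if ")) {
      var <- trimws(sub("^#if ", "", tag))
      body <- render_seq(toks, i + 1L, data)
      else_text <- ""
      stop_tag <- body$stopped_at
      j <- body$next_i
      if (identical(stop_tag, "#else")) {
        els <- render_seq(toks, j, data)
        if (!identical(els$stopped_at, "/if"))
          stop_odegraph("odegraph_template_error", "unterminated {{#else}}")
        else_text <- els$text
        j <- els$next_i
      } else if (!identical(stop_tag, "/if")) {
        stop_odegraph("odegraph_template_error",
                      sprintf("unterminated {{#if %s}}", var))
      }
      out <- c(out, if (tpl_truthy(tpl_lookup(data, var))) body$text
               else else_text)
      i <- j
    } else if (startsWith(tag, "#for ")) {
      spec <- trimws(sub("^#for ", "", tag))
      parts <- strsplit(spec, "[ \t]+in[ \t]+")[[1]]
      if (length(parts) != 2)
        stop_odegraph("odegraph_template_error",
                      sprintf("malformed loop tag \"{{%s}}\"", tag))
      items <- tpl_lookup(data, parts[[2]])
      # Locate the loop body once (rendered against empty bindings is
      # wasteful; instead scan for the matching {{/for}} by nesting depth).
      body_range <- find_block(toks, i + 1L, "#for", "/for")
      body_toks <- if (body_range$end > i + 1L)
        toks[seq(i + 1L, body_range$end - 1L)] else list()
      for (item in items) {
        child <- data
        child[[parts[[1]]]] <- item
        res <- render_seq(body_toks, 1L, child)
        out <- c(out, res$text)
      }
      i <- body_range$end + 1L
    } else {
      val <- tpl_lookup(data, tag)
      if (!is.character(val) && !is.numeric(val))
        stop_odegraph("odegraph_template_error",
                      sprintf("\"%s\" is not insertable text", tag))
      out <- c(out, paste(as.character(val), collapse = ""))
      i <- i + 1L
    }
  }
  list(text = paste(out, collapse = ""), next_i = i, stopped_at = NULL)
}

# Index of the tag closing the block that opened just before `from`,
# honoring nesting of the same block kind.
find_block <- function(toks, from, open_prefix, close_tag) {
  depth <- 1L
  i <- from
  while (i <= length(toks)) {
    tok <- toks[[i]]
    if (tok$type == "tag") {
      if (startsWith(tok$value, paste0(open_prefix, " "))) depth <- depth + 1L
      else if (identical(tok$value, close_tag)) {
        depth <- depth - 1L
        if (depth == 0L) return(list(end = i))
      }
    }
    i <- i + 1L
  }
  stop_odegraph("odegraph_template_error",
                sprintf("missing {{%s}} tag", close_tag))
}
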