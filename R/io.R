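#' Read and write causal-diagram JSON
#'
#' The on-disk schema is
#' `{"nodes": [{"name", "observed", "functional"}, ...],`
#' `"edges": [[parent, child], ...], "bidirected": [[a, b], ...]}`.
#' The optional `bidirected` field is sugar: each pair is expanded on load
#' into a fresh hidden root (reserved prefix `".h"`) with the two members as
#' children.
#'
#' @param path file path.
#' @param g a `causal_diagram`.
#' @return `read_causal_graph()` returns a `causal_diagram`;
#'   `write_causal_graph()` returns `path` invisibly.
#' @export
read_causal_graph <- function(path) {
  parse_graph_json(jsonlite::fromJSON(path, simplifyVector = FALSE))
}

parse_graph_json <- function(j) {
  nodes <- vapply(j$nodes, `[[`, character(1), "name")
  observed <- nodes[vapply(j$nodes, function(nd)
    isTRUE(nd$observed %||% TRUE), logical(1))]
  functional <- nodes[vapply(j$nodes, function(nd)
    isTRUE(nd$functional %||% FALSE), logical(1))]
  edges <- if (length(j$edges))
    do.call(rbind, lapply(j$edges, function(e) as.character(unlist(e))))
  else NULL
  if (length(j$bidirected)) {
    hid <- paste0(".h", seq_along(j$bidirected))
    for (i in seq_along(j$bidirected)) {
      pr <- as.character(unlist(j$bidirected[[i]]))
      edges <- rbind(edges, c(hid[i], pr[1L]), c(hid[i], pr[2L]))
    }
    nodes <- c(nodes, hid)
  }
  causal_diagram(nodes, edges, observed = observed, functional = functional)
}

#' @rdname read_causal_graph
#' @export
write_causal_graph <- function(g, path) {
  nodes <- lapply(g$nodes, function(v)
    list(name = v, observed = v %in% g$observed,
         functional = v %in% g$functional))
  edges <- lapply(seq_len(nrow(g$edges)), function(i)
    as.list(unname(g$edges[i, ])))
  jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' DOT export of a causal diagram
#'
#' Hidden variables are drawn as dashed circles and functional variables
#' with a double border, matching the usual figure conventions.
#'
#' @param g a `causal_diagram` or an `admg`.
#' @param path optional file path; when missing the DOT source is returned.
#' @return the DOT source, invisibly when written to a file.
#' @export
to_dot <- function(g, path = NULL) {
  lines <- c("digraph G {", "  rankdir=LR;")
  if (inherits(g, "admg")) {
    for (v in g$vertices) lines <- c(lines, sprintf("  \"%s\";", v))
    for (i in seq_len(nrow(g$directed)))
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\";",
                                g$directed[i, 1L], g$directed[i, 2L]))
    for (i in seq_len(nrow(g$bidirected)))
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [dir=both, style=dashed];",
        g$bidirected[i, 1L], g$bidirected[i, 2L]))
  } else {
    for (v in g$nodes) {
      attrs <- character()
      if (!v %in% g$observed) attrs <- c(attrs, "shape=circle, style=dashed")
      if (v %in% g$functional) attrs <- c(attrs, "peripheries=2")
      lines <- c(lines, sprintf("  \"%s\"%s;", v,
                                if (length(attrs))
                                  paste0(" [", paste(attrs, collapse = ", "),
                                         "]") else ""))
    }
    for (i in seq_len(nrow(g$edges)))
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\";",
                                g$edges[i, 1L], g$edges[i, 2L]))
  }
  lines <- c(lines, "}")
  src <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(src, path)
    return(invisible(src))
  }
  src
}

#' Read and write discrete-CBN JSON
#'
#' Schema: the graph schema of [read_causal_graph()] plus a `"cpts"` object
#' mapping each variable to `{"parents": [...], "card": k,`
#' `"table": {context-key: [probs]}}`, where a context key joins parent
#' states with `|` in the listed parent order (root variables use the key
#' `"."`).
#'
#' @param path file path.
#' @param m a `discrete_cbn`.
#' @return `read_cbn()` returns a `discrete_cbn`; `write_cbn()` returns
#'   `path` invisibly.
#' @export
read_cbn <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  g <- parse_graph_json(j)
  card <- stats::setNames(vapply(j$cpts, function(e)
    as.integer(e$card %||% 2L), integer(1)), names(j$cpts))[g$nodes]
  cpts <- stats::setNames(vector("list", length(g$nodes)), g$nodes)
  for (v in g$nodes) {
    e <- j$cpts[[v]]
    pars <- as.character(unlist(e$parents))
    nctx <- prod(card[pars])
    m <- matrix(0, nctx, card[[v]])
    keys <- context_keys(pars, card)
    for (i in seq_len(nctx))
      m[i, ] <- as.numeric(unlist(e$table[[keys[i]]]))
    cpts[[v]] <- if (length(pars)) cpt(v, pars, m, card)
                 else cpt(v, character(), m[1L, ], card)
  }
  discrete_cbn(g, cpts, card)
}

context_keys <- function(pars, card) {
  if (!length(pars)) return(".")
  grid <- expand.grid(lapply(card[pars], function(k)
    as.character(seq_len(k) - 1L)), stringsAsFactors = FALSE,
    KEEP.OUT.ATTRS = FALSE)
  apply(grid, 1L, paste, collapse = "|")
}

#' @rdname read_cbn
#' @export
write_cbn <- function(m, path) {
  g <- m$diagram
  nodes <- lapply(g$nodes, function(v)
    list(name = v, observed = v %in% g$observed,
         functional = v %in% g$functional))
  edges <- lapply(seq_len(nrow(g$edges)), function(i)
    as.list(unname(g$edges[i, ])))
  cpts <- lapply(stats::setNames(g$nodes, g$nodes), function(v) {
    ct <- m$cpts[[v]]
    keys <- context_keys(ct$parents, m$card)
    nctx <- prod(m$card[ct$parents])
    tabm <- matrix(ct$table, nrow = m$card[[v]])
    tab <- stats::setNames(lapply(seq_len(nctx), function(i)
      as.numeric(tabm[, i])), keys)
    list(parents = as.list(ct$parents), card = m$card[[v]], table = tab)
  })
  jsonlite::write_json(list(nodes = nodes, edges = edges, cpts = cpts),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
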