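#' Causal diagrams with hidden and functional variables
#'
#' A causal diagram is a DAG over named variables in which a subset is marked
#' *observed* (data on these variables is available) and a subset is marked
#' *functional* (the variable is a deterministic function of its parents,
#' although the function itself is unknown).  Hidden variables are kept as
#' explicit nodes; the compact bidirected-edge notation only appears in the
#' derived ADMG view produced by [latent_project()] or [as_admg()].
#'
#' @param nodes character vector of variable names.
#' @param edges the directed edges, as a two-column matrix / data frame of
#'   (parent, child) pairs, a list of length-2 character vectors, or a
#'   character vector of `"A -> B"` strings.
#' @param observed character vector, the observed variables (default: all).
#' @param functional character vector, the functional variables.  Root
#'   variables cannot be functional.
#' @return an object of class `causal_diagram` with fields `nodes`, `edges`
#'   (two-column character matrix), `observed` and `functional`.
#' @examples
#' m <- causal_diagram(c("C", "A", "X", "Y"),
#'                     c("C -> A", "C -> X", "A -> X", "A -> Y", "X -> Y"),
#'                     observed = c("C", "X", "Y"), functional = "A")
#' parents_of(m, "Y")
#' @export
causal_diagram <- function(nodes, edges = NULL, observed = nodes,
                           functional = character()) {
  nodes <- sort(unique(as.character(nodes)))
  edges <- normalize_edges(edges)
  observed <- sort(unique(as.character(observed)))
  functional <- sort(unique(as.character(functional)))
  g <- structure(list(nodes = nodes, edges = edges, observed = observed,
                      functional = functional),
                 class = "causal_diagram")
  validate_causal_diagram(g)
  g
}

normalize_edges <- function(edges) {
  if (is.null(edges) || (is.atomic(edges) && length(edges) == 0)) {
    m <- matrix(character(), 0L, 2L)
  } else if (is.character(edges) && is.null(dim(edges))) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("edge strings must have the form 'A -> B'", call. = FALSE)
    m <- do.call(rbind, lapply(parts, trimws))
  } else if (is.matrix(edges) || is.data.frame(edges)) {
    m <- as.matrix(edges)
    if (ncol(m) != 2L) stop("edge matrix must have two columns", call. = FALSE)
    m[] <- as.character(m)
  } else if (is.list(edges)) {
    if (any(lengths(edges) != 2L))
      stop("each edge must be a (parent, child) pair", call. = FALSE)
    m <- do.call(rbind, lapply(edges, as.character))
  } else stop("unrecognized edge specification", call. = FALSE)
  m <- unique(m)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  dimnames(m) <- list(NULL, c("from", "to"))
  m
}

validate_causal_diagram <- function(g) {
  stray <- setdiff(unique(as.vector(g$edges)), g$nodes)
  if (length(stray))
    stop("edge endpoints not in node set: ", paste(stray, collapse = ", "),
         call. = FALSE)
  if (any(g$edges[, 1L] == g$edges[, 2L]))
    stop("self loops are not allowed", call. = FALSE)
  if (length(setdiff(g$observed, g$nodes)))
    stop("observed variables must be nodes", call. = FALSE)
  if (length(setdiff(g$functional, g$nodes)))
    stop("functional variables must be nodes", call. = FALSE)
  topo_sort(g)  # errors on cycles
  roots <- g$nodes[!g$nodes %in% g$edges[, 2L]]
  badw <- intersect(g$functional, roots)
  if (length(badw))
    stop("root variables cannot be functional: ", paste(badw, collapse = ", "),
         call. = FALSE)
  invisible(g)
}

#' @export
print.causal_diagram <- function(x, ...) {
  cat("Causal diagram:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  observed:  ", paste(x$observed, collapse = " "), "\n")
  hid <- hidden_of(x)
  if (length(hid)) cat("  hidden:    ", paste(hid, collapse = " "), "\n")
  if (length(x$functional))
    cat("  functional:", paste(x$functional, collapse = " "), "\n")
  if (nrow(x$edges))
    cat("  edges:", paste(paste(x$edges[, 1L], "->", x$edges[, 2L]),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Hidden variables of a diagram
#' @param g a `causal_diagram`.
#' @return character vector of the unobserved variables.
#' @export
hidden_of <- function(g) setdiff(g$nodes, g$observed)

check_vars <- function(g, vars, what = "variable") {
  vars <- as.character(vars)
  bad <- setdiff(vars, g$nodes)
  if (length(bad))
    stop("unknown ", what, ": ", paste(bad, collapse = ", "), call. = FALSE)
  vars
}

#' @rdname parents_of
#' @export
children_of <- function(g, vars) {
  vars <- check_vars(g, vars)
  sort(unique(g$edges[g$edges[, 1L] %in% vars, 2L]))
}

#' Parents / children / ancestors / descendants
#'
#' Elementary kinship queries on a causal diagram.  `ancestors_of()` and
#' `descendants_of()` are inclusive of the query set by default.
#'
#' @param g a `causal_diagram`.
#' @param vars character vector of variable names.
#' @param include_self logical, include `vars` themselves in the closure.
#' @return sorted character vector.
#' @export
parents_of <- function(g, vars) {
  vars <- check_vars(g, vars)
  sort(unique(g$edges[g$edges[, 2L] %in% vars, 1L]))
}

pa_list <- function(g) {
  out <- split(g$edges[, 1L], factor(g$edges[, 2L], levels = g$nodes))
  lapply(out, as.character)
}

ch_list <- function(g) {
  out <- split(g$edges[, 2L], factor(g$edges[, 1L], levels = g$nodes))
  lapply(out, as.character)
}

closure_over <- function(step, start, include_self = TRUE) {
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(unlist(step[frontier], use.names = FALSE), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (!include_self) seen <- setdiff(seen, start)
  sort(unique(seen))
}

#' @rdname parents_of
#' @export
ancestors_of <- function(g, vars, include_self = TRUE) {
  vars <- check_vars(g, vars)
  closure_over(pa_list(g), vars, include_self)
}

#' @rdname parents_of
#' @export
descendants_of <- function(g, vars, include_self = TRUE) {
  vars <- check_vars(g, vars)
  closure_over(ch_list(g), vars, include_self)
}

#' Topological order of a diagram
#'
#' Kahn's algorithm with lexicographic tie-breaking, so the order is
#' deterministic for a given graph.
#'
#' @param g a `causal_diagram`.
#' @return character vector listing all nodes, parents before children.
#' @export
topo_sort <- function(g) {
  pa <- pa_list(g)
  indeg <- lengths(pa)
  ch <- ch_list(g)
  avail <- sort(names(indeg)[indeg == 0L])
  out <- character(0)
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, v)
    for (c in ch[[v]]) {
      indeg[[c]] <- indeg[[c]] - 1L
      if (indeg[[c]] == 0L) avail <- sort(c(avail, c))
    }
  }
  if (length(out) != length(g$nodes))
    stop("graph is cyclic", call. = FALSE)
  out
}

#' Mutilate a diagram (sever incoming edges of treatments)
#'
#' Removes every edge pointing into a variable of `x_vars`, the graph surgery
#' that defines an intervention do(x).  Node roles are unchanged.
#'
#' @param g a `causal_diagram`.
#' @param x_vars variables whose incoming edges are cut.
#' @return the mutilated `causal_diagram`.
#' @export
mutilate <- function(g, x_vars) {
  x_vars <- check_vars(g, x_vars, "treatment variable")
  keep <- !(g$edges[, 2L] %in% x_vars)
  structure(list(nodes = g$nodes, edges = g$edges[keep, , drop = FALSE],
                 observed = g$observed, functional = g$functional),
            class = "causal_diagram")
}

#' First-ancestor test
#'
#' A treatment `x` is a *first ancestor* of an outcome `y` (relative to the
#' full treatment set `x_set`) when some directed path from `x` to `y` avoids
#' every other treatment.  First ancestors drive the no-positivity
#' unidentifiability criterion of [never_identifiable_check()].
#'
#' @param g a `causal_diagram`.
#' @param x a treatment variable, member of `x_set`.
#' @param y an outcome variable.
#' @param x_set the full treatment set.
#' @return `TRUE` iff `x` reaches `y` by a directed path not intercepted by
#'   `x_set` minus `x`.
#' @export
first_ancestor <- function(g, x, y, x_set) {
  x <- check_vars(g, x)
  y <- check_vars(g, y)
  x_set <- check_vars(g, x_set)
  if (!x %in% x_set) stop("x must belong to x_set", call. = FALSE)
  blocked <- setdiff(x_set, x)
  ch <- ch_list(g)
  seen <- x
  frontier <- x
  while (length(frontier)) {
    nxt <- sort(unique(unlist(ch[frontier], use.names = FALSE)))
    if (y %in% nxt) return(TRUE)
    nxt <- setdiff(nxt, c(seen, blocked))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

#' Causal query (treatments and outcomes)
#'
#' @param x treatment variables.
#' @param y outcome variables.
#' @return an object of class `causal_query`.
#' @export
causal_query <- function(x, y) {
  x <- sort(unique(as.character(x)))
  y <- sort(unique(as.character(y)))
  if (length(intersect(x, y)))
    stop("treatments and outcomes must be disjoint", call. = FALSE)
  if (!length(x) || !length(y))
    stop("treatments and outcomes must be nonempty", call. = FALSE)
  structure(list(x = x, y = y), class = "causal_query")
}

#' @export
print.causal_query <- function(x, ...) {
  cat("Pr(", paste(x$y, collapse = ","), " | do(",
      paste(x$x, collapse = ","), "))\n", sep = "")
  invisible(x)
}

check_query <- function(g, query) {
  if (!inherits(query, "causal_query")) stop("need a causal_query")
  bad <- setdiff(c(query$x, query$y), g$observed)
  if (length(bad))
    stop("query variables must be observed: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(query)
}

same_diagram <- function(a, b) {
  identical(a$nodes, b$nodes) && identical(a$edges, b$edges) &&
    identical(a$observed, b$observed) && identical(a$functional, b$functional)
}
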