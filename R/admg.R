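#' Acyclic directed mixed graphs (ADMG view)
#'
#' The derived view of a causal diagram in which hidden variables have been
#' collapsed into bidirected edges: a bidirected pair `a <-> b` stands for a
#' fresh hidden root with exactly the two children `a` and `b`.  This is the
#' input format of the ID algorithm.
#'
#' @param vertices character vector of (observed) vertex names.
#' @param directed two-column matrix of directed edges (or `"A -> B"` strings).
#' @param bidirected two-column matrix of unordered bidirected pairs (or
#'   `"A <-> B"` strings).  Pairs are stored canonically with the
#'   lexicographically smaller name first.
#' @return an object of class `admg`.
#' @export
admg <- function(vertices, directed = NULL, bidirected = NULL) {
  vertices <- sort(unique(as.character(vertices)))
  directed <- normalize_edges(directed)
  bidirected <- normalize_bidirected(bidirected)
  a <- structure(list(vertices = vertices, directed = directed,
                      bidirected = bidirected), class = "admg")
  stray <- setdiff(unique(c(as.vector(directed), as.vector(bidirected))),
                   vertices)
  if (length(stray))
    stop("edge endpoints not in vertex set: ", paste(stray, collapse = ", "),
         call. = FALSE)
  # directed part must be acyclic
  topo_sort(causal_diagram(vertices, directed))
  a
}

normalize_bidirected <- function(b) {
  if (is.character(b) && is.null(dim(b)) && length(b)) {
    parts <- strsplit(b, "<->", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("bidirected strings must have the form 'A <-> B'", call. = FALSE)
    b <- do.call(rbind, lapply(parts, trimws))
  }
  m <- normalize_edges(b)
  if (nrow(m)) {
    if (any(m[, 1L] == m[, 2L]))
      stop("bidirected self loops are not allowed", call. = FALSE)
    m <- t(apply(m, 1L, sort))
    m <- unique(m)
    m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  }
  dimnames(m) <- list(NULL, c("a", "b"))
  m
}

#' @export
print.admg <- function(x, ...) {
  cat("ADMG:", length(x$vertices), "vertices\n")
  if (nrow(x$directed))
    cat("  directed:  ", paste(paste(x$directed[, 1L], "->", x$directed[, 2L]),
                               collapse = ", "), "\n")
  if (nrow(x$bidirected))
    cat("  bidirected:", paste(paste(x$bidirected[, 1L], "<->",
                                     x$bidirected[, 2L]), collapse = ", "),
        "\n")
  invisible(x)
}

#' Convert between causal diagrams and ADMG views
#'
#' `as_admg()` requires every hidden variable to be a root with exactly two
#' children (the shape produced by [latent_project()] and by
#' `as_causal_diagram()`); each such hidden root becomes a bidirected pair.
#' `as_causal_diagram()` expands each bidirected pair into a fresh hidden root
#' named with the reserved prefix `".h"` and a deterministic counter, so the
#' round trip diagram -> admg -> diagram is the identity up to those names.
#'
#' @param a an `admg`.
#' @param g a `causal_diagram` whose hidden variables are all roots with two
#'   children.
#' @return `as_causal_diagram()` a `causal_diagram`; `as_admg()` an `admg`.
#' @export
as_causal_diagram <- function(a) {
  stopifnot(inherits(a, "admg"))
  nb <- nrow(a$bidirected)
  hid <- if (nb) paste0(".h", seq_len(nb)) else character()
  edges <- a$directed
  if (nb) {
    extra <- rbind(cbind(hid, a$bidirected[, 1L]),
                   cbind(hid, a$bidirected[, 2L]))
    edges <- rbind(edges, extra)
  }
  causal_diagram(c(a$vertices, hid), edges, observed = a$vertices)
}

#' @rdname as_causal_diagram
#' @export
as_admg <- function(g) {
  stopifnot(inherits(g, "causal_diagram"))
  hid <- hidden_of(g)
  pa <- pa_list(g)
  ch <- ch_list(g)
  pairs <- matrix(character(), 0L, 2L)
  for (h in hid) {
    if (length(pa[[h]]))
      stop("hidden variable ", h, " is not a root; latent-project first",
           call. = FALSE)
    kids <- sort(unique(ch[[h]]))
    if (length(kids) != 2L)
      stop("hidden root ", h, " does not have exactly two children",
           call. = FALSE)
    pairs <- rbind(pairs, kids)
  }
  obs <- g$observed
  keep <- g$edges[, 1L] %in% obs & g$edges[, 2L] %in% obs
  admg(obs, g$edges[keep, , drop = FALSE], pairs)
}

admg_matrices <- function(a) {
  n <- length(a$vertices)
  D <- matrix(FALSE, n, n, dimnames = list(a$vertices, a$vertices))
  B <- D
  if (nrow(a$directed)) D[a$directed] <- TRUE
  if (nrow(a$bidirected)) {
    B[a$bidirected] <- TRUE
    B[a$bidirected[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  list(D = D, B = B)
}

#' Confounded components (c-components / districts) of an ADMG
#'
#' Connected components of the bidirected part of the graph.  Every vertex
#' belongs to exactly one component; vertices without bidirected edges form
#' singletons.
#'
#' @param a an `admg`.
#' @return a list of sorted character vectors partitioning the vertex set,
#'   ordered by their first element.
#' @export
c_components <- function(a) {
  stopifnot(inherits(a, "admg"))
  m <- admg_matrices(a)
  bidir_components(m$B, a$vertices)
}

bidir_components <- function(B, verts) {
  remaining <- sort(verts)
  out <- list()
  while (length(remaining)) {
    comp <- remaining[1L]
    frontier <- comp
    while (length(frontier)) {
      nbr <- rownames(B)[rowSums(B[, frontier, drop = FALSE]) > 0]
      nxt <- setdiff(intersect(nbr, remaining), comp)
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    comp <- sort(comp)
    out <- c(out, list(comp))
    remaining <- setdiff(remaining, comp)
  }
  out
}
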