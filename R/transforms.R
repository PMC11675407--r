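#' Functional elimination of a variable
#'
#' Removes `x` from the diagram after adding an edge from each of its parents
#' to each of its children.  For a functional variable this operation
#' preserves every D-separation statement among the remaining variables; for
#' a non-functional variable it is unsound, so by default only functional
#' variables may be eliminated.
#'
#' @param g a `causal_diagram`.
#' @param x the variable to eliminate.
#' @param force eliminate even if `x` is not functional (or is a root).  All
#'   independence-preservation guarantees are void in that case; intended for
#'   experimentation only.
#' @return the reduced `causal_diagram`.
#' @export
functional_eliminate <- function(g, x, force = FALSE) {
  x <- check_vars(g, x)
  stopifnot(length(x) == 1L)
  if (!force) {
    if (!x %in% g$functional)
      stop("refusing to functionally eliminate the non-functional variable '",
           x, "' (use force = TRUE to override; guarantees are void)",
           call. = FALSE)
    if (!length(parents_of(g, x)))
      stop("refusing to eliminate the root variable '", x, "'", call. = FALSE)
  }
  pa <- parents_of(g, x)
  ch <- children_of(g, x)
  keep <- g$edges[, 1L] != x & g$edges[, 2L] != x
  edges <- g$edges[keep, , drop = FALSE]
  if (length(pa) && length(ch)) {
    new <- cbind(rep(pa, each = length(ch)), rep(ch, times = length(pa)))
    edges <- rbind(edges, new)
  }
  causal_diagram(setdiff(g$nodes, x), edges,
                 observed = setdiff(g$observed, x),
                 functional = setdiff(g$functional, x))
}

#' Functional elimination of a set of variables
#'
#' Eliminates every variable in `ws`; the result does not depend on the
#' order of elimination, and the implementation uses the topological order of
#' `g` restricted to `ws` for reproducibility.
#'
#' @param g a `causal_diagram`.
#' @param ws variables to eliminate, a subset of `g$functional` unless
#'   `force = TRUE`.
#' @param force passed to [functional_eliminate()].
#' @return the reduced `causal_diagram`.
#' @export
functional_eliminate_set <- function(g, ws, force = FALSE) {
  ws <- check_vars(g, ws)
  ord <- intersect(topo_sort(g), ws)
  for (w in ord) g <- functional_eliminate(g, w, force = force)
  g
}

# observed (members of v) nodes reachable from the children of `start` by
# directed paths whose intermediate nodes all lie outside v
projection_reach <- function(ch, start, v) {
  out <- character()
  seen <- character()
  frontier <- ch[[start]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
    obs <- intersect(frontier, v)
    out <- c(out, obs)
    through <- setdiff(frontier, v)
    frontier <- sort(unique(unlist(ch[through], use.names = FALSE)))
  }
  sort(unique(out))
}

#' Latent projection onto an ADMG
#'
#' Collapses the hidden variables of a diagram: the projection has a directed
#' edge `u -> w` iff some directed path from `u` to `w` passes only through
#' hidden intermediates, and a bidirected edge `u <-> w` iff some path with
#' arrowheads into both endpoints passes only through hidden non-colliders
#' (equivalently, some hidden variable reaches both `u` and `w` by directed
#' paths through hidden intermediates).  d-separation among the projected
#' variables is preserved.
#'
#' @param g a `causal_diagram`.
#' @param v the variables to project onto, a subset of `g$observed`
#'   (default: all observed variables).
#' @return an `admg` over `v`.
#' @export
latent_project <- function(g, v = g$observed) {
  v <- sort(unique(check_vars(g, v)))
  if (length(setdiff(v, g$observed)))
    stop("can only project onto observed variables", call. = FALSE)
  ch <- ch_list(g)
  hidden <- setdiff(g$nodes, v)
  dir <- matrix(character(), 0L, 2L)
  for (u in v) {
    tgt <- projection_reach(ch, u, v)
    if (length(tgt)) dir <- rbind(dir, cbind(u, tgt))
  }
  bid <- matrix(character(), 0L, 2L)
  for (h in hidden) {
    r <- projection_reach(ch, h, v)
    if (length(r) >= 2L) {
      idx <- utils::combn(r, 2L)
      bid <- rbind(bid, t(idx))
    }
  }
  admg(v, dir, bid)
}

#' Functional projection onto an ADMG
#'
#' First functionally eliminates every functional variable outside `v`, then
#' latent-projects the result onto `v`.  Compared with classical latent
#' projection, the output exhibits every D-separation of the original diagram
#' as an ordinary d-separation (and never fewer independencies), which is
#' what lets the ID algorithm exploit functional dependencies.
#'
#' @param g a `causal_diagram`.
#' @param v the variables to project onto; defaults to the observed
#'   non-functional variables.  Functional variables outside `v` are
#'   eliminated rather than treated as ordinary hidden variables.
#' @return an `admg` over `v`.
#' @export
functional_project <- function(g, v = setdiff(g$observed, g$functional)) {
  v <- sort(unique(check_vars(g, v)))
  w <- setdiff(g$functional, v)
  g2 <- functional_eliminate_set(g, w)
  latent_project(g2, v)
}
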