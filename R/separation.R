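#' d-separation
#'
#' Tests whether every path between `xs` and `ys` is blocked by `zs`, using
#' Bayes-ball style reachability (a chain or fork is blocked when its middle
#' node is conditioned on; a collider is open only when the collider or one of
#' its descendants is conditioned on).
#'
#' @param g a `causal_diagram`.
#' @param xs,ys,zs disjoint variable sets; `zs` may be empty.
#' @return `TRUE` iff `xs` and `ys` are d-separated by `zs` in `g`.
#' @export
d_separated <- function(g, xs, ys, zs = character()) {
  xs <- sort(check_vars(g, xs))
  ys <- sort(check_vars(g, ys))
  zs <- sort(unique(as.character(zs)))
  if (length(zs)) zs <- check_vars(g, zs)
  if (length(intersect(xs, ys)) || length(intersect(xs, zs)) ||
      length(intersect(ys, zs)))
    stop("xs, ys and zs must be disjoint", call. = FALSE)
  !any(ys %in% dsep_reachable(g, xs, zs))
}

# nodes reachable from xs along active paths given conditioning set zs
dsep_reachable <- function(g, xs, zs) {
  pa <- pa_list(g)
  ch <- ch_list(g)
  anz <- if (length(zs)) closure_over(pa, zs, TRUE) else character()
  seen_up <- seen_down <- structure(logical(length(g$nodes)), names = g$nodes)
  reach <- seen_up
  qv <- xs
  qd <- rep("up", length(xs))
  while (length(qv)) {
    v <- qv[1L]; d <- qd[1L]
    qv <- qv[-1L]; qd <- qd[-1L]
    if (d == "up") {
      if (seen_up[[v]]) next
      seen_up[[v]] <- TRUE
      if (!v %in% zs) {
        reach[[v]] <- TRUE
        for (p in pa[[v]]) { qv <- c(qv, p); qd <- c(qd, "up") }
        for (c in ch[[v]]) { qv <- c(qv, c); qd <- c(qd, "down") }
      }
    } else {
      if (seen_down[[v]]) next
      seen_down[[v]] <- TRUE
      if (!v %in% zs) {
        reach[[v]] <- TRUE
        for (c in ch[[v]]) { qv <- c(qv, c); qd <- c(qd, "down") }
      }
      if (v %in% anz) {
        for (p in pa[[v]]) { qv <- c(qv, p); qd <- c(qd, "up") }
      }
    }
  }
  names(reach)[reach]
}

#' Functional closure of a conditioning set
#'
#' Least fixpoint of the rule "a functional variable all of whose parents are
#' already in the set is added to the set".  This is the conditioning-set
#' enlargement that reduces D-separation (separation in the presence of
#' deterministic nodes) to ordinary d-separation.
#'
#' @param g a `causal_diagram`.
#' @param w functional variables to close over; a subset of `g$functional`
#'   (default: all of them).
#' @param zs the initial conditioning set.
#' @param exclude variables never added to the closure (used to keep the
#'   endpoints of a separation query out of the conditioning set).
#' @return the closed conditioning set, a sorted character vector.
#' @export
functional_closure <- function(g, w = g$functional, zs, exclude = character()) {
  w <- sort(check_vars(g, w))
  if (length(setdiff(w, g$functional)))
    stop("w must be a subset of the functional variables", call. = FALSE)
  zs <- sort(unique(check_vars(g, zs)))
  pa <- pa_list(g)
  z2 <- zs
  repeat {
    cand <- setdiff(w, c(z2, exclude))
    add <- cand[vapply(cand, function(v)
      length(pa[[v]]) > 0L && all(pa[[v]] %in% z2), logical(1))]
    if (!length(add)) break
    z2 <- sort(c(z2, add))
  }
  z2
}

#' D-separation (d-separation with deterministic nodes)
#'
#' `xs` and `ys` are D-separated by `zs` given functional variables `w` iff
#' they are d-separated by the functional closure of `zs`: conditioning on all
#' parents of a functional variable fixes its value, so the variable behaves
#' as if it were conditioned on too.
#'
#' @inheritParams d_separated
#' @param w functional variables taken into account, a subset of
#'   `g$functional`.
#' @return `TRUE` iff `xs` and `ys` are D-separated by `zs` in `(g, w)`.
#' @export
D_separated <- function(g, w = g$functional, xs, ys, zs = character()) {
  xs <- sort(check_vars(g, xs))
  ys <- sort(check_vars(g, ys))
  z2 <- functional_closure(g, w, zs, exclude = c(xs, ys))
  d_separated(g, xs, ys, z2)
}
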