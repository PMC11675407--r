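#' Conditional probability tables
#'
#' A CPT stores `Pr(child | parents)` as an array whose first dimension is the
#' child and whose remaining dimensions are the parents (in the stored
#' order).  `values` may also be given as a matrix with one row per parent
#' instantiation (first parent varying fastest, as in [expand.grid()]) and
#' one column per child state.  Every row must sum to one; a *functional*
#' CPT has a single 1 in every row.
#'
#' @param child the child variable name.
#' @param parents character vector of parent names (possibly empty).
#' @param values numeric array, or context-by-state matrix, or a plain vector
#'   for a root variable.
#' @param card named integer vector of cardinalities (child and parents).
#' @return an object of class `cpt`.
#' @export
cpt <- function(child, parents, values, card) {
  parents <- as.character(parents)
  card <- card[c(child, parents)]
  k <- card[[child]]
  dims <- unname(card)
  states <- lapply(card, function(m) as.character(seq_len(m) - 1L))
  if (is.matrix(values) && length(parents)) {
    if (ncol(values) != k || nrow(values) != prod(card[parents]))
      stop("CPT matrix has wrong shape", call. = FALSE)
    arr <- array(t(values), dim = dims, dimnames = states)
  } else {
    arr <- array(as.numeric(values), dim = dims, dimnames = states)
  }
  ct <- structure(list(child = child, parents = parents, table = arr),
                  class = "cpt")
  validate_cpt(ct)
  ct
}

#' @rdname cpt
#' @param ct a `cpt`.
#' @param tol numeric tolerance for row sums.
#' @export
validate_cpt <- function(ct, tol = 1e-12) {
  tab <- ct$table
  if (any(tab < -tol) || any(tab > 1 + tol))
    stop("CPT entries must lie in [0, 1]", call. = FALSE)
  sums <- if (length(ct$parents) == 0L) sum(tab)
          else apply(tab, seq_along(dim(tab))[-1L], sum)
  if (any(abs(sums - 1) > tol))
    stop("CPT rows must sum to 1", call. = FALSE)
  invisible(ct)
}

#' @rdname cpt
#' @export
is_functional_cpt <- function(ct, tol = 1e-12) {
  all(abs(ct$table) < tol | abs(ct$table - 1) < tol)
}

#' Discrete causal Bayesian networks
#'
#' A fully parameterized model: a causal diagram plus one CPT per node.  The
#' induced joint distribution is the product of the CPTs.
#'
#' @param diagram a `causal_diagram`.
#' @param cpts named list of [cpt()] objects, one per node; each CPT's parent
#'   set must equal the node's parents in the diagram.
#' @param card named integer vector of cardinalities.
#' @return an object of class `discrete_cbn`.
#' @export
discrete_cbn <- function(diagram, cpts, card) {
  stopifnot(inherits(diagram, "causal_diagram"))
  if (!setequal(names(cpts), diagram$nodes))
    stop("need exactly one CPT per node", call. = FALSE)
  for (v in diagram$nodes) {
    ct <- cpts[[v]]
    if (!identical(sort(ct$parents), parents_of(diagram, v)))
      stop("CPT parents of ", v, " do not match the diagram", call. = FALSE)
    w_ok <- !(v %in% diagram$functional) || is_functional_cpt(ct)
    if (!w_ok)
      stop("variable ", v, " is marked functional but its CPT is not ",
           "deterministic", call. = FALSE)
  }
  structure(list(diagram = diagram, cpts = cpts[diagram$nodes],
                 card = card[diagram$nodes]),
            class = "discrete_cbn")
}

#' @export
print.discrete_cbn <- function(x, ...) {
  cat("Discrete CBN over", length(x$diagram$nodes), "variables",
      "(cardinalities", paste(unique(x$card), collapse = "/"), ")\n")
  invisible(x)
}

#' Random parameterization of a causal diagram
#'
#' Draws one CPT per node.  Rows of variables in `functional_w` are
#' deterministic (a uniformly random function of the parents); other rows are
#' symmetric-Dirichlet draws, floored at `1e-3` and renormalized when
#' `positive = TRUE` so that all conditionals are strictly positive and
#' numerically stable.  Reproducible from `seed`.
#'
#' @param g a `causal_diagram`.
#' @param cardinality state count, a scalar or named vector (default 2).
#' @param seed integer RNG seed.
#' @param functional_w variables given deterministic CPTs (default: the
#'   diagram's functional set).
#' @param positive draw strictly positive rows for non-functional variables.
#' @return a `discrete_cbn`.
#' @export
random_cbn <- function(g, cardinality = 2L, seed = 1L,
                       functional_w = g$functional, positive = TRUE) {
  functional_w <- sort(check_vars(g, functional_w))
  roots <- g$nodes[!g$nodes %in% g$edges[, 2L]]
  if (length(intersect(functional_w, roots)))
    stop("root variables cannot be functional", call. = FALSE)
  # the sampled model class is defined by functional_w, which may differ
  # from the diagram's qualitative labels (e.g. when parameterizing the
  # unrestricted class over the same graph)
  if (!identical(functional_w, g$functional))
    g <- causal_diagram(g$nodes, g$edges, observed = g$observed,
                        functional = functional_w)
  card <- if (length(cardinality) == 1L)
    stats::setNames(rep(as.integer(cardinality), length(g$nodes)), g$nodes)
  else cardinality[g$nodes]
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  cpts <- stats::setNames(vector("list", length(g$nodes)), g$nodes)
  for (v in g$nodes) {
    pars <- parents_of(g, v)
    k <- card[[v]]
    nctx <- prod(card[pars])
    if (v %in% functional_w) {
      hit <- sample.int(k, nctx, replace = TRUE)
      m <- matrix(0, nctx, k)
      m[cbind(seq_len(nctx), hit)] <- 1
    } else {
      m <- matrix(stats::rgamma(nctx * k, 1), nctx, k)
      if (positive) m <- pmax(m, 0) + 1e-3 * max(m)
      else {
        drop <- matrix(stats::runif(nctx * k) < 0.25, nctx, k)
        keepone <- cbind(seq_len(nctx), max.col(m))
        drop[keepone] <- FALSE
        m[drop] <- 0
      }
      m <- m / rowSums(m)
      if (positive) m <- pmax(m, 1e-3)
      m <- m / rowSums(m)
    }
    cpts[[v]] <- if (length(pars)) cpt(v, pars, m, card)
                 else cpt(v, character(), as.numeric(m[1L, ]), card)
  }
  discrete_cbn(g, cpts, card)
}

cbn_states <- function(m, vars) {
  lapply(stats::setNames(vars, vars),
         function(v) as.character(seq_len(m$card[[v]]) - 1L))
}

#' Exact joint distribution of a CBN (full enumeration)
#'
#' Multiplies the CPTs over every instantiation of all variables.  Intended
#' for small models (it enumerates the full joint); used as the brute-force
#' reference against the variable-elimination routines.
#'
#' @param m a `discrete_cbn`.
#' @return a numeric array over all variables (dimension names are the
#'   variables, dimnames the states).
#' @export
joint_distribution <- function(m) {
  vars <- m$diagram$nodes
  card <- unname(m$card[vars])
  total <- prod(card)
  idx <- arrayInd(seq_len(total), card)
  colnames(idx) <- vars
  val <- rep(1, total)
  for (v in vars) {
    ct <- m$cpts[[v]]
    val <- val * ct$table[idx[, c(v, ct$parents), drop = FALSE]]
  }
  array(val, dim = card, dimnames = cbn_states(m, vars))
}

#' Marginal of a named-dimension probability array
#' @param arr array with named dimnames.
#' @param vars variables to keep.
#' @return array over `sort(vars)`.
#' @export
array_marginal <- function(arr, vars) {
  all_vars <- names(dimnames(arr))
  vars <- sort(vars)
  if (setequal(vars, all_vars)) return(aperm(arr, match(vars, all_vars)))
  m <- apply(arr, match(vars, all_vars), sum)
  if (length(vars) == 1L)
    m <- array(m, dim = length(m), dimnames = dimnames(arr)[vars])
  m
}

## ---- factor-based variable elimination -------------------------------------

factor_from_cpt <- function(ct) {
  list(vars = c(ct$child, ct$parents), arr = ct$table)
}

factor_card <- function(f) {
  stats::setNames(dim(f$arr), f$vars)
}

factor_product <- function(f1, f2) {
  if (!length(f1$vars)) {
    f2$arr <- f2$arr * as.numeric(f1$arr)
    return(f2)
  }
  if (!length(f2$vars)) {
    f1$arr <- f1$arr * as.numeric(f2$arr)
    return(f1)
  }
  vars <- sort(union(f1$vars, f2$vars))
  card <- c(factor_card(f1), factor_card(f2))[vars]
  states <- c(dimnames(f1$arr) %||% list(), dimnames(f2$arr) %||% list())
  states <- states[vars]
  names(states) <- vars
  total <- prod(card)
  idx <- arrayInd(seq_len(total), unname(card))
  colnames(idx) <- vars
  val <- f1$arr[idx[, f1$vars, drop = FALSE]] *
    f2$arr[idx[, f2$vars, drop = FALSE]]
  list(vars = vars, arr = array(val, dim = unname(card), dimnames = states))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

factor_sumout <- function(f, v) {
  keep <- setdiff(f$vars, v)
  if (!length(keep))
    return(list(vars = character(), arr = sum(f$arr)))
  d <- match(v, f$vars)
  m <- apply(f$arr, match(keep, f$vars), sum)
  if (length(keep) == 1L)
    m <- array(m, dim = length(m), dimnames = dimnames(f$arr)[keep])
  list(vars = keep, arr = m)
}

ve_marginal <- function(factors, keep, elim_order) {
  for (v in elim_order) {
    rel <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(rel)) next
    f <- Reduce(factor_product, factors[rel])
    f <- factor_sumout(f, v)
    factors <- c(factors[!rel], list(f))
  }
  out <- Reduce(factor_product, factors)
  if (!length(out$vars)) return(out$arr)
  ord <- match(sort(out$vars), out$vars)
  aperm(out$arr, ord)
}

#' Joint distribution by variable elimination
#'
#' Same result as [joint_distribution()], computed with sum-product variable
#' elimination; also exposed so the two inference routes can be compared.
#'
#' @param m a `discrete_cbn`.
#' @param keep variables of the returned marginal (default: all).
#' @return a probability array over `sort(keep)`.
#' @export
cbn_marginal_ve <- function(m, keep = m$diagram$nodes) {
  keep <- check_vars(m$diagram, keep)
  factors <- lapply(m$cpts, factor_from_cpt)
  elim <- rev(setdiff(topo_sort(m$diagram), keep))
  ve_marginal(unname(factors), keep, elim)
}

#' Ground-truth causal effect by mutilation
#'
#' Computes `Pr(Y | do(x))` exactly: incoming edges of the treatments are
#' cut, their CPTs replaced by point masses on the treatment instantiation,
#' and the mutilated model is marginalized onto the outcomes by variable
#' elimination (restricted to the ancestors of `y_vars` for speed).
#'
#' @param m a `discrete_cbn`.
#' @param x_inst named character vector, the treatment instantiation
#'   (values are state labels such as `"0"`).
#' @param y_vars outcome variables.
#' @return probability array over `sort(y_vars)`.
#' @export
causal_effect_oracle <- function(m, x_inst, y_vars) {
  x_vars <- names(x_inst)
  x_vars_chk <- check_vars(m$diagram, x_vars)
  y_vars <- check_vars(m$diagram, y_vars)
  g2 <- mutilate(m$diagram, x_vars)
  factors <- list()
  an <- ancestors_of(g2, y_vars)
  for (v in an) {
    if (v %in% x_vars) {
      k <- m$card[[v]]
      p <- numeric(k)
      p[match(as.character(x_inst[[v]]), cbn_states(m, v)[[1L]])] <- 1
      if (anyNA(p)) stop("unknown treatment state", call. = FALSE)
      factors <- c(factors, list(list(
        vars = v,
        arr = array(p, dim = k, dimnames = cbn_states(m, v)))))
    } else {
      factors <- c(factors, list(factor_from_cpt(m$cpts[[v]])))
    }
  }
  elim <- rev(intersect(topo_sort(g2), setdiff(an, y_vars)))
  ve_marginal(factors, sort(y_vars), elim)
}

#' CPT-level functional elimination
#'
#' Eliminates a variable with a deterministic CPT from a fully parameterized
#' CBN: the graph is transformed by [functional_eliminate()], and each former
#' child's CPT is composed through the eliminated variable's function.  The
#' joint distribution over the remaining variables equals the marginal of the
#' original joint.
#'
#' @param m a `discrete_cbn`.
#' @param x the variable to eliminate; its CPT must be deterministic.
#' @return a `discrete_cbn` without `x`.
#' @export
cbn_functional_eliminate <- function(m, x) {
  x <- check_vars(m$diagram, x)
  ct <- m$cpts[[x]]
  if (!is_functional_cpt(ct))
    stop("CPT of ", x, " is not deterministic", call. = FALSE)
  if (!length(ct$parents))
    stop("cannot eliminate the root variable ", x, call. = FALSE)
  g2 <- if (x %in% m$diagram$functional) functional_eliminate(m$diagram, x)
        else functional_eliminate(m$diagram, x, force = TRUE)
  xpars <- ct$parents
  # the function: parent-context array of child state indices
  k <- m$card[[x]]
  perm <- aperm(ct$table, c(seq_along(dim(ct$table))[-1L], 1L))
  fx <- array(max.col(matrix(perm, ncol = k)),
              dim = unname(m$card[xpars]),
              dimnames = cbn_states(m, xpars))
  kids <- children_of(m$diagram, x)
  cpts2 <- m$cpts
  cpts2[[x]] <- NULL
  for (cvar in kids) {
    cold <- m$cpts[[cvar]]
    oldpars <- cold$parents
    newpars <- parents_of(g2, cvar)
    card2 <- m$card[c(cvar, newpars)]
    total <- prod(card2)
    idx <- arrayInd(seq_len(total), unname(card2))
    colnames(idx) <- c(cvar, newpars)
    xs <- fx[idx[, xpars, drop = FALSE]]
    oldidx <- matrix(0L, total, 1L + length(oldpars))
    oldidx[, 1L] <- idx[, cvar]
    for (j in seq_along(oldpars)) {
      p <- oldpars[j]
      oldidx[, 1L + j] <- if (p == x) xs else idx[, p]
    }
    val <- cold$table[oldidx]
    cpts2[[cvar]] <- structure(
      list(child = cvar, parents = newpars,
           table = array(val, dim = unname(card2),
                         dimnames = cbn_states(m, c(cvar, newpars)))),
      class = "cpt")
  }
  discrete_cbn(g2, cpts2, m$card[g2$nodes])
}

#' Conditional mutual information from a joint array
#'
#' `I(X; Y | Z)` in nats, computed from the exact joint; zero cells
#' contribute zero.
#'
#' @param arr probability array with named dimnames.
#' @param xs,ys,zs disjoint variable sets.
#' @return a non-negative numeric scalar (up to rounding).
#' @export
cond_mutual_info <- function(arr, xs, ys, zs = character()) {
  vars <- sort(c(xs, ys, zs))
  p <- array_marginal(arr, vars)
  pv <- names(dimnames(p))
  pxz <- array_marginal(p, sort(c(xs, zs)))
  pyz <- array_marginal(p, sort(c(ys, zs)))
  pz <- if (length(zs)) array_marginal(p, sort(zs)) else NULL
  total <- length(p)
  idx <- arrayInd(seq_len(total), dim(p))
  colnames(idx) <- pv
  pj <- as.vector(p)
  a <- pxz[idx[, sort(c(xs, zs)), drop = FALSE]]
  b <- pyz[idx[, sort(c(ys, zs)), drop = FALSE]]
  c0 <- if (length(zs)) pz[idx[, sort(zs), drop = FALSE]] else rep(1, total)
  ok <- pj > 0
  sum(pj[ok] * log(pj[ok] * c0[ok] / (a[ok] * b[ok])))
}
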