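#' Symbolic estimands
#'
#' An estimand is an expression tree over an observational distribution,
#' built from four node kinds: probability terms `P(S | Z)`, products, sums
#' over index variables, and quotients.  Estimand constructors track the free
#' variables of each subtree; a variable is free until it is bound by an
#' enclosing sum or fixed by the query instantiation at evaluation time.
#'
#' @param s,z variable sets of a probability term `P(S | Z)`.
#' @param over index variables bound by a sum.
#' @param body,terms,num,den sub-expressions.
#' @return an object of class `estimand`.
#' @name estimand
NULL

est_node <- function(kind, fields, free) {
  structure(c(list(kind = kind), fields), class = "estimand",
            free = sort(unique(free)))
}

#' @rdname estimand
#' @export
est_prob <- function(s, z = character()) {
  s <- sort(unique(as.character(s)))
  z <- sort(unique(as.character(z)))
  if (length(intersect(s, z))) stop("S and Z must be disjoint", call. = FALSE)
  est_node("prob", list(s = s, z = z), c(s, z))
}

#' @rdname estimand
#' @export
est_sum <- function(over, body) {
  over <- sort(unique(as.character(over)))
  if (!length(over)) return(body)
  est_node("sum", list(over = over, body = body),
           setdiff(est_free(body), over))
}

#' @rdname estimand
#' @export
est_prod <- function(terms) {
  terms <- terms[!vapply(terms, is.null, logical(1))]
  if (length(terms) == 1L) return(terms[[1L]])
  est_node("prod", list(terms = terms),
           unlist(lapply(terms, est_free), use.names = FALSE))
}

#' @rdname estimand
#' @export
est_quot <- function(num, den) {
  est_node("quot", list(num = num, den = den),
           c(est_free(num), est_free(den)))
}

#' @rdname estimand
#' @param vars variables pinned by `est_fix` to an arbitrary (first) state at
#'   evaluation time; used for interventions that provably do not affect the
#'   value of the expression.
#' @export
est_fix <- function(vars, body) {
  vars <- sort(unique(as.character(vars)))
  if (!length(vars)) return(body)
  est_node("fix", list(vars = vars, body = body),
           setdiff(est_free(body), vars))
}

#' Free and mentioned variables of an estimand
#' @param e an `estimand`.
#' @return sorted character vector.
#' @export
est_free <- function(e) attr(e, "free")

#' @rdname est_free
#' @export
est_vars <- function(e) {
  switch(e$kind,
         prob = c(e$s, e$z),
         sum  = sort(unique(c(e$over, est_vars(e$body)))),
         prod = sort(unique(unlist(lapply(e$terms, est_vars)))),
         quot = sort(unique(c(est_vars(e$num), est_vars(e$den)))),
         fix  = sort(unique(c(e$vars, est_vars(e$body)))))
}

#' Render an estimand as text
#' @param e an `estimand`.
#' @param lower print variable instantiations in lower case (the usual
#'   notation for summation indices and fixed values).
#' @return a character scalar.
#' @export
est_text <- function(e, lower = TRUE) {
  f <- function(v) if (lower) tolower(v) else v
  switch(e$kind,
         prob = paste0("P(", paste(f(e$s), collapse = ","),
                       if (length(e$z)) paste0("|", paste(f(e$z),
                                                          collapse = ",")),
                       ")"),
         sum  = paste0("sum_{", paste(f(e$over), collapse = ","), "} ",
                       est_text(e$body, lower)),
         prod = paste(vapply(e$terms, function(t) {
                  s <- est_text(t, lower)
                  if (t$kind %in% c("sum")) paste0("[", s, "]") else s
                }, character(1)), collapse = " "),
         quot = paste0(est_text(e$num, lower), " / (",
                       est_text(e$den, lower), ")"),
         fix  = est_text(e$body, lower))
}

#' @export
print.estimand <- function(x, ...) {
  cat(est_text(x), "\n")
  invisible(x)
}

#' Joint-distribution evaluator
#'
#' Wraps a joint probability array (dimensions named after variables, dimnames
#' giving the states) with a cache of marginal tables, used when evaluating
#' estimands.
#'
#' @param arr a numeric array whose `dimnames` are a named list (one entry per
#'   variable), summing to 1.
#' @return an object of class `joint_dist`.
#' @export
joint_dist <- function(arr) {
  if (inherits(arr, "joint_dist")) return(arr)
  dn <- dimnames(arr)
  if (is.null(dn) || is.null(names(dn)) || any(names(dn) == ""))
    stop("joint array must have named dimnames", call. = FALSE)
  structure(list(arr = arr, vars = names(dn), states = dn,
                 cache = new.env(parent = emptyenv())),
            class = "joint_dist")
}

jd_marginal <- function(jd, vars) {
  vars <- sort(vars)
  if (!length(vars)) return(1)
  key <- paste(vars, collapse = "\r")
  m <- jd$cache[[key]]
  if (is.null(m)) {
    m <- apply(jd$arr, match(vars, jd$vars), sum)
    if (length(vars) == 1L) m <- array(m, dim = length(m),
                                       dimnames = jd$states[vars])
    jd$cache[[key]] <- m
  }
  m
}

jd_prob <- function(jd, vars, env) {
  if (!length(vars)) return(1)
  m <- jd_marginal(jd, vars)
  vars <- sort(vars)
  idx <- vapply(seq_along(vars),
                function(i) match(env[[vars[i]]], jd$states[[vars[i]]]),
                integer(1))
  if (anyNA(idx)) stop("state not found in joint distribution", call. = FALSE)
  unname(m[matrix(idx, 1L)])
}

#' Evaluate an estimand on a joint distribution
#'
#' Probability terms are read off the supplied observational joint; a
#' conditional term whose conditioning event has probability zero evaluates
#' to zero (the 0 * undefined = 0 convention that makes identifying formulas
#' well defined under positivity constraints).
#'
#' @param e an `estimand`.
#' @param joint a [joint_dist()] or a named-dimension array.
#' @param assignment named character vector (or list) fixing the states of
#'   the free variables of `e`.
#' @return a numeric scalar.
#' @export
evaluate_estimand <- function(e, joint, assignment = character()) {
  jd <- joint_dist(joint)
  env <- as.list(assignment)
  miss <- setdiff(est_vars(e), jd$vars)
  if (length(miss))
    stop("variables missing from joint: ", paste(miss, collapse = ", "),
         call. = FALSE)
  need <- setdiff(est_free(e), names(env))
  if (length(need))
    stop("free variables not instantiated: ", paste(need, collapse = ", "),
         call. = FALSE)
  est_eval(e, env, jd)
}

est_eval <- function(e, env, jd) {
  switch(e$kind,
    prob = {
      pz <- jd_prob(jd, e$z, env)
      if (pz <= 0) return(0)
      jd_prob(jd, c(e$s, e$z), env) / pz
    },
    sum = {
      grid <- expand.grid(jd$states[e$over], stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      tot <- 0
      for (i in seq_len(nrow(grid))) {
        env2 <- env
        env2[e$over] <- as.list(grid[i, , drop = FALSE])
        tot <- tot + est_eval(e$body, env2, jd)
      }
      tot
    },
    prod = {
      p <- 1
      for (t in e$terms) {
        p <- p * est_eval(t, env, jd)
        if (p == 0) break
      }
      p
    },
    quot = {
      den <- est_eval(e$den, env, jd)
      if (den <= 0) return(0)
      est_eval(e$num, env, jd) / den
    },
    fix = {
      env2 <- env
      for (v in e$vars) env2[[v]] <- jd$states[[v]][1L]
      est_eval(e$body, env2, jd)
    })
}

#' Randomized numeric equivalence of two estimands
#'
#' Semi-decision procedure: draws `trials` strictly positive random joints
#' over the union of the variables mentioned by the two estimands, evaluates
#' both on every instantiation of their free variables, and reports whether
#' the maximum absolute difference stays below `tol`.
#'
#' By default the joints are unconstrained, which tests equality of the two
#' expressions as functions of an arbitrary distribution.  Two identifying
#' formulas for the same causal effect need only agree on distributions the
#' causal model can induce; pass `graph` to sample the joints as random
#' strictly positive parameterizations of that diagram instead (marginalized
#' onto the variables the estimands mention).
#'
#' @param e1,e2 estimands with the same free variables.
#' @param trials number of random joints.
#' @param tol numeric tolerance.
#' @param seed RNG seed.
#' @param cardinality number of states per variable in the random joints.
#' @param graph optional `causal_diagram` the joints are induced by.
#' @param functional_w deterministic variables when sampling from `graph`.
#' @return `TRUE` or `FALSE`.
#' @export
estimands_equivalent <- function(e1, e2, trials = 20L, tol = 1e-8,
                                 seed = 1L, cardinality = 2L, graph = NULL,
                                 functional_w = if (!is.null(graph))
                                   graph$functional else character()) {
  if (!setequal(est_free(e1), est_free(e2)))
    stop("estimands have different free variables", call. = FALSE)
  vars <- sort(unique(c(est_vars(e1), est_vars(e2))))
  free <- sort(est_free(e1))
  states <- stats::setNames(
    rep(list(as.character(seq_len(cardinality) - 1L)), length(vars)), vars)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  maxd <- 0
  for (t in seq_len(trials)) {
    if (is.null(graph)) {
      n <- cardinality^length(vars)
      p <- stats::rgamma(n, 1) + 1e-3
      p <- p / sum(p)
      arr <- array(p, dim = rep(cardinality, length(vars)), dimnames = states)
    } else {
      m <- random_cbn(graph, cardinality,
                      seed = as.integer(seed) + 613L * t,
                      functional_w = functional_w, positive = TRUE)
      arr <- array_marginal(joint_distribution(m), vars)
    }
    jd <- joint_dist(arr)
    grid <- expand.grid(states[free], stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    for (i in seq_len(max(1L, nrow(grid)))) {
      env <- if (length(free)) as.list(grid[i, , drop = FALSE]) else list()
      d <- abs(est_eval(e1, env, jd) - est_eval(e2, env, jd))
      maxd <- max(maxd, d)
      if (maxd > tol) return(FALSE)
    }
  }
  TRUE
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
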