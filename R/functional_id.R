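#' F-identifiability tuples
#'
#' Bundles a causal diagram (which carries the observed set `V` and the
#' functional set `W`) with a set of positivity constraints over `V`.
#' Functional variables may be observed or hidden.
#'
#' @param g a `causal_diagram`.
#' @param constraints a [constraint_set()] over `g$observed`.
#' @return an object of class `fid_tuple`.
#' @export
fid_tuple <- function(g, constraints = constraint_set()) {
  stopifnot(inherits(g, "causal_diagram"))
  if (!inherits(constraints, "constraint_set"))
    constraints <- constraint_set(constraints)
  bad <- setdiff(constraint_vars(constraints), g$observed)
  if (length(bad))
    stop("constraints mention non-observed variables: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(g = g, constraints = constraints), class = "fid_tuple")
}

#' @export
print.fid_tuple <- function(x, ...) {
  print(x$g)
  print(x$constraints)
  invisible(x)
}

#' Sufficient consistency check for constraints and functional variables
#'
#' Positivity constraints and functional dependencies can contradict each
#' other (e.g. `Pr(X, Y) > 0` is unsatisfiable when `Y` is a function of
#' `X`).  This check certifies consistency when, for every functional
#' variable `w`, some interceptor set exists that blocks all directed paths
#' from non-functional variables to `w` while sharing no constraint with `w`
#' (no single constraint mentions both `w` and an interceptor).  `FALSE`
#' means "not certified", not "inconsistent".
#'
#' @param t a [fid_tuple()].
#' @return `TRUE` if consistency is certified by the sufficient condition.
#' @export
consistent_sufficient <- function(t) {
  g <- t$g
  cs <- t$constraints
  pa <- pa_list(g)
  for (w in g$functional) {
    mentions_w <- Filter(function(c) w %in% c(c$s, c$z), cs)
    bad <- setdiff(sort(unique(unlist(lapply(mentions_w, function(c)
      c(c$s, c$z)), use.names = FALSE))), w)
    if (!length(bad)) next
    # a suitable interceptor set exists unless some non-functional variable
    # reaches w by a directed path lying entirely inside the co-mentioned set
    frontier <- intersect(pa[[w]], bad)
    seen <- character()
    ok <- TRUE
    while (length(frontier)) {
      if (any(!frontier %in% g$functional)) { ok <- FALSE; break }
      seen <- c(seen, frontier)
      frontier <- setdiff(
        intersect(sort(unique(unlist(pa[frontier], use.names = FALSE))), bad),
        seen)
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Never-identifiable criterion (first ancestors without positivity)
#'
#' A causal effect is not identifiable when some treatment is a first
#' ancestor of some outcome and the constraint set does not imply
#' `Pr(X) > 0` for that treatment: without positivity on the treatment, the
#' observational distribution carries no information about the intervention.
#'
#' @param g a `causal_diagram`.
#' @param v the observed variables (defaults to `g$observed`).
#' @param constraints a [constraint_set()].
#' @param query a [causal_query()].
#' @return `TRUE` iff the criterion fires (report NOT_IDENTIFIABLE without
#'   running any identification algorithm).
#' @export
never_identifiable_check <- function(g, v = g$observed, constraints, query) {
  check_query(g, query)
  for (x in query$x) {
    if (implies_positivity(constraints, positivity_constraint(x))) next
    for (y in query$y) {
      if (first_ancestor(g, x, y, query$x)) return(TRUE)
    }
  }
  FALSE
}

#' Eliminate the hidden functional variables
#'
#' Transforms the tuple by functionally eliminating every hidden functional
#' variable; F-identifiability of any causal effect is preserved in both
#' directions, and afterwards all remaining functional variables are
#' observed.
#'
#' @param t a [fid_tuple()].
#' @return the reduced `fid_tuple`.
#' @export
theorem2_reduce <- function(t) {
  g <- t$g
  wh <- setdiff(g$functional, g$observed)
  if (!length(wh)) return(t)
  fid_tuple(functional_eliminate_set(g, wh), t$constraints)
}

#' Observed functional variables eligible for elimination
#'
#' The maximal set of observed functional variables that are neither
#' treatments nor outcomes, are not mentioned by any positivity constraint
#' (separability), and whose parents are all observed.  Computed as a
#' fixpoint over simulated eliminations, since removing one variable can
#' expose the eligibility of another.
#'
#' @param t a [fid_tuple()].
#' @param query a [causal_query()].
#' @return sorted character vector.
#' @export
theorem3_eligible <- function(t, query) {
  g <- t$g
  cvars <- constraint_vars(t$constraints)
  removed <- character()
  repeat {
    wobs <- intersect(g$functional, g$observed)
    cand <- setdiff(wobs, c(query$x, query$y, cvars))
    add <- cand[vapply(cand, function(z)
      all(parents_of(g, z) %in% g$observed), logical(1))]
    add <- setdiff(add, removed)
    if (!length(add)) break
    for (z in add) g <- functional_eliminate(g, z)
    removed <- sort(c(removed, add))
  }
  removed
}

#' Eliminate the eligible observed functional variables
#'
#' Functionally eliminates the set returned by [theorem3_eligible()]; the
#' eliminated variables leave the observed set and the functional set, and
#' F-identifiability is preserved in both directions.  The eliminated
#' variables are exactly the observations that turn out to be dispensable on
#' the identifiable path.
#'
#' @inheritParams theorem3_eligible
#' @return a list with the reduced tuple (`tuple`) and the removed variables
#'   (`removed`).
#' @export
theorem3_reduce <- function(t, query) {
  z <- theorem3_eligible(t, query)
  stopifnot(!length(intersect(z, c(query$x, query$y,
                                   constraint_vars(t$constraints)))))
  if (!length(z)) return(list(tuple = t, removed = character()))
  g2 <- functional_eliminate_set(t$g, z)
  list(tuple = fid_tuple(g2, t$constraints), removed = z)
}

#' Hidden-parent condition for equivalence with classical identifiability
#'
#' When every remaining functional variable has at least one hidden parent,
#' F-identifiability coincides with classical identifiability of the same
#' tuple, so the ordinary project-ID machinery decides the question.
#'
#' @param t a [fid_tuple()].
#' @return `TRUE` iff every functional variable has a hidden parent (vacuously
#'   `TRUE` when no functional variables remain).
#' @export
theorem4_applicable <- function(t) {
  g <- t$g
  hid <- hidden_of(g)
  all(vapply(g$functional, function(w)
    length(intersect(parents_of(g, w), hid)) > 0L, logical(1)))
}

#' Pretend-observed closure of the observed set
#'
#' Least fixpoint adding any functional variable whose parents are already in
#' the set: conditioning on the parents of a deterministic variable fixes its
#' value, so under per-treatment positivity `{Pr(X) > 0}` F-identifiability
#' is equivalent to classical identifiability with this enlarged "observed"
#' set.  Under strictly stronger constraint sets only the "if" direction may
#' be used.
#'
#' @param t a [fid_tuple()].
#' @return the enlarged variable set, a sorted character vector.
#' @export
theorem5_pretend_observed <- function(t) {
  g <- t$g
  v2 <- g$observed
  pa <- pa_list(g)
  repeat {
    cand <- setdiff(g$functional, v2)
    add <- cand[vapply(cand, function(w)
      length(pa[[w]]) > 0L && all(pa[[w]] %in% v2), logical(1))]
    if (!length(add)) break
    v2 <- sort(c(v2, add))
  }
  v2
}

#' Decide F-identifiability of a causal effect
#'
#' Orchestrates the full pipeline:
#' 1. first-ancestor short-circuit ([never_identifiable_check()]);
#' 2. elimination of hidden functional variables ([theorem2_reduce()]);
#' 3. fixpoint elimination of eligible observed functional variables
#'    ([theorem3_reduce()]);
#' 4. if no functional variables remain, or every remaining one has a hidden
#'    parent ([theorem4_applicable()]), classical identifiability via latent
#'    projection + the ID algorithm — run only when the constraints imply
#'    strict positivity over the final observed set (otherwise the ID route
#'    is `INAPPLICABLE`);
#' 5. otherwise, under the exact per-treatment positivity regime, the
#'    pretend-observed reduction ([theorem5_pretend_observed()]) followed by
#'    a constructive zero-probability-context counterexample search; reaching
#'    no decision yields `UNKNOWN` with the unmet completeness condition
#'    named.
#'
#' @param t a [fid_tuple()].
#' @param query a [causal_query()] over observed variables.
#' @param assume_strict_positivity treat strict positivity over the
#'   post-reduction observed set as granted (the convention used in the
#'   random-graph experiments) instead of requiring the constraint set to
#'   imply it.
#' @param allow_theorem5 attempt the pretend-observed route when the ID route
#'   is inapplicable or incomplete.
#' @param build_estimand build the symbolic estimand on identifiable paths.
#' @param witness_seed seed for the counterexample construction on the
#'   pretend-observed route.
#' @return an [ident_decision()] whose `trace` records every reduction step
#'   (`prop1`, `theorem2`, `theorem3`, route taken, final observed set) plus
#'   a `dispensable` field listing eliminated observed functional variables.
#' @export
fid_check <- function(t, query, assume_strict_positivity = FALSE,
                      allow_theorem5 = TRUE, build_estimand = TRUE,
                      witness_seed = 1L) {
  stopifnot(inherits(t, "fid_tuple"))
  check_query(t$g, query)
  trace <- list(input_observed = t$g$observed,
                input_functional = t$g$functional)
  if (!consistent_sufficient(t))
    warning("consistency of the constraints with the functional set could ",
            "not be certified by the sufficient condition", call. = FALSE)
  if (!assume_strict_positivity &&
      never_identifiable_check(t$g, t$g$observed, t$constraints, query)) {
    trace$route <- "first_ancestor"
    return(ident_decision("NOT_IDENTIFIABLE",
      witness = paste("a treatment is a first ancestor of an outcome and",
                      "the constraints do not imply positivity for it"),
      trace = trace))
  }
  t2 <- theorem2_reduce(t)
  trace$theorem2_eliminated <- setdiff(t$g$nodes, t2$g$nodes)
  r3 <- theorem3_reduce(t2, query)
  trace$theorem3_eliminated <- r3$removed
  cur <- r3$tuple
  vfin <- cur$g$observed
  trace$final_observed <- vfin
  trace$final_functional <- cur$g$functional
  classical_eq <- length(cur$g$functional) == 0L || theorem4_applicable(cur)
  trace$theorem4_applies <- classical_eq
  pos_ok <- assume_strict_positivity ||
    implies_positivity(cur$constraints, positivity_constraint(vfin))
  if (pos_ok) {
    # a classical IDENTIFIABLE verdict is always sound for F-identifiability
    # (the functionally restricted model class is smaller); a classical FAIL
    # certifies F-unidentifiability only when the reduced tuple is
    # *equivalent* to a classical one (no functional variables left, or all
    # of them with a hidden parent)
    trace$route <- "project_id"
    adm <- latent_project(cur$g, vfin)
    dec <- id_algorithm(adm, query, build_estimand = build_estimand)
    if (dec$status == "IDENTIFIABLE" || classical_eq) {
      dec$trace <- c(trace, dec$trace)
      dec$trace$dispensable <-
        if (dec$status == "IDENTIFIABLE") r3$removed else character()
      return(dec)
    }
    # the functional-elimination steps preserve F-identifiability but can
    # destroy *classical* identifiability (they densify the graph), and on
    # this branch the classical FAIL is not definitive anyway; a classical
    # IDENTIFIABLE verdict at the earlier stage is still a sound
    # F-identifiability certificate
    pos_ok2 <- assume_strict_positivity ||
      implies_positivity(t2$constraints,
                         positivity_constraint(t2$g$observed))
    if (length(r3$removed) && pos_ok2) {
      adm2 <- latent_project(t2$g, t2$g$observed)
      dec2 <- id_algorithm(adm2, query, build_estimand = build_estimand)
      if (dec2$status == "IDENTIFIABLE") {
        trace$route <- "project_id_pre_reduction"
        dec2$trace <- c(trace, dec2$trace)
        dec2$trace$dispensable <- character()
        return(dec2)
      }
    }
    if (allow_theorem5 && treatment_regime(t$constraints, query))
      return(fid_theorem5_route(t, query, trace, witness_seed))
    return(unknown_completeness(cur, trace))
  }
  if (allow_theorem5 && treatment_regime(t$constraints, query))
    return(fid_theorem5_route(t, query, trace, witness_seed))
  if (classical_eq) {
    trace$route <- "project_id"
    return(ident_decision("INAPPLICABLE",
      witness = paste("the ID algorithm needs strict positivity over",
                      "{", paste(vfin, collapse = ","), "}, which the",
                      "constraint set does not imply"),
      trace = trace))
  }
  unknown_completeness(cur, trace)
}

unknown_completeness <- function(cur, trace) {
  culprits <- cur$g$functional[vapply(cur$g$functional, function(w)
    length(intersect(parents_of(cur$g, w), hidden_of(cur$g))) == 0L,
    logical(1))]
  trace$route <- "incomplete"
  ident_decision("UNKNOWN",
    witness = paste("completeness condition unmet: observed functional",
                    "variable(s) {", paste(culprits, collapse = ","),
                    "} neither satisfy the elimination conditions nor have",
                    "a hidden parent"),
    trace = trace)
}

fid_theorem5_route <- function(t, query, trace, witness_seed) {
  trace$route <- "theorem5"
  v2 <- theorem5_pretend_observed(t)
  trace$pretend_observed <- v2
  if (implies_positivity(t$constraints, positivity_constraint(
        intersect(v2, t$g$observed))) && setequal(v2, t$g$nodes)) {
    # degenerate: everything observed and strictly positive
    g2 <- causal_diagram(t$g$nodes, t$g$edges, observed = v2)
    adm <- latent_project(g2, v2)
    dec <- id_algorithm(adm, query)
    dec$trace <- c(trace, dec$trace)
    return(dec)
  }
  wit <- weak_positivity_witness(t$g, v2, query, seed = witness_seed)
  if (!is.null(wit)) {
    trace$witness_pair <- wit
    return(ident_decision("NOT_IDENTIFIABLE",
      witness = wit$description, trace = trace))
  }
  ident_decision("UNKNOWN",
    witness = paste("pretend-observed reduction applies but no decision",
                    "procedure under per-treatment positivity reached a",
                    "verdict"),
    trace = trace)
}

#' Dispensable observations
#'
#' Observed functional variables whose observation is not needed for the
#' causal effect to be F-identifiable: the variables eliminated on an
#' identifiable run of [fid_check()].  They are guaranteed absent from the
#' returned estimand.
#'
#' @inheritParams fid_check
#' @return sorted character vector (empty when the effect is not identified).
#' @export
dispensable_observations <- function(t, query,
                                     assume_strict_positivity = FALSE) {
  dec <- fid_check(t, query,
                   assume_strict_positivity = assume_strict_positivity,
                   build_estimand = FALSE)
  if (dec$status == "IDENTIFIABLE") dec$trace$dispensable else character()
}

#' Constructive non-identifiability witness under weak positivity
#'
#' Under the per-treatment regime `{Pr(X) > 0}`, identifiability can fail
#' through zero-probability contexts: if some non-treatment ancestor `D` of
#' the outcomes has both a treatment `X*` and a non-treatment `A` among its
#' parents, and `A` is an ancestor of `X*`, then a model in which `X*`
#' deterministically copies `A` makes the context `(a, x*)` with
#' mismatching values observationally impossible while the intervention
#' `do(x*)` still reaches it.  Two models differing only in `D`'s CPT rows at
#' those contexts induce identical joints but (generically) different causal
#' effects.  This is a best-effort search: `NULL` means no witness found,
#' never identifiability.
#'
#' @param g a `causal_diagram`.
#' @param v2 the (pretend-)observed variable set the joints must agree on.
#' @param query a [causal_query()].
#' @param seed RNG seed.
#' @param tries random parameterizations attempted per structural candidate.
#' @return `NULL`, or a list with the two CBNs (`m1`, `m2`), the achieved
#'   joint discrepancy and effect difference, and a description.
#' @export
weak_positivity_witness <- function(g, v2, query, seed = 1L, tries = 10L) {
  # the pretend-observed reduction targets *classical* identifiability, so
  # the witness models carry no functional restriction
  g <- causal_diagram(g$nodes, g$edges, observed = g$observed)
  pa <- pa_list(g)
  gx <- mutilate(g, query$x)
  anY <- setdiff(ancestors_of(gx, query$y), query$x)
  for (D in sort(anY)) {
    xs_cand <- intersect(pa[[D]], query$x)
    a_cand <- setdiff(pa[[D]], query$x)
    for (Xs in xs_cand) for (A in a_cand) {
      path <- directed_path(g, A, Xs,
                            avoid = c(setdiff(query$x, Xs), D, query$y))
      if (is.null(path)) next
      for (i in seq_len(tries)) {
        wit <- try_zero_context_pair(g, v2, query, D, Xs, A, path,
                                     seed = seed + 101L * i)
        if (!is.null(wit)) return(wit)
      }
    }
  }
  NULL
}

directed_path <- function(g, from, to, avoid = character()) {
  ch <- ch_list(g)
  prev <- list()
  frontier <- from
  seen <- from
  while (length(frontier)) {
    nxt <- character()
    for (u in frontier) for (v in sort(ch[[u]])) {
      if (v %in% seen) next
      if (v != to && v %in% avoid) next
      prev[[v]] <- u
      if (v == to) {
        path <- to
        while (path[1L] != from) path <- c(prev[[path[1L]]], path)
        return(path)
      }
      seen <- c(seen, v)
      nxt <- c(nxt, v)
    }
    frontier <- nxt
  }
  NULL
}

try_zero_context_pair <- function(g, v2, query, D, Xs, A, path, seed) {
  m1 <- random_cbn(g, 2L, seed = seed, functional_w = character(),
                   positive = TRUE)
  # every node after A on the path deterministically copies its predecessor
  for (j in seq_along(path)[-1L]) {
    v <- path[j]
    p <- path[j - 1L]
    ct <- m1$cpts[[v]]
    dims <- c(v, ct$parents)
    total <- prod(m1$card[dims])
    idx <- arrayInd(seq_len(total), unname(m1$card[dims]))
    colnames(idx) <- dims
    val <- as.numeric(idx[, v] == idx[, p])
    m1$cpts[[v]]$table <- array(val, dim = unname(m1$card[dims]),
                                dimnames = cbn_states(m1, dims))
  }
  # m2: redraw D's CPT rows at contexts where Xs disagrees with A
  m2 <- m1
  ctD <- m1$cpts[[D]]
  k <- m1$card[[D]]
  pidx <- arrayInd(seq_len(prod(m1$card[ctD$parents])),
                   unname(m1$card[ctD$parents]))
  colnames(pidx) <- ctD$parents
  tab2 <- ctD$table
  old <- get_rng_state()
  set.seed(seed + 7L)
  for (r in which(pidx[, Xs] != pidx[, A])) {
    row <- stats::rgamma(k, 1) + 1e-3
    row <- row / sum(row)
    cells <- cbind(seq_len(k),
                   matrix(pidx[r, ], k, ncol(pidx), byrow = TRUE))
    tab2[cells] <- row
  }
  restore_rng_state(old)
  m2$cpts[[D]]$table <- tab2
  # verify: identical joints on v2, per-treatment positivity, different effect
  j1 <- array_marginal(joint_distribution(m1), v2)
  j2 <- array_marginal(joint_distribution(m2), v2)
  joint_gap <- max(abs(j1 - j2))
  if (joint_gap > 1e-12) return(NULL)
  for (x in query$x) {
    px <- array_marginal(j1, intersect(x, v2))
    if (length(px) && min(px) <= 1e-9) return(NULL)
  }
  eff <- effect_gap(m1, m2, query)
  if (eff <= 1e-3) return(NULL)
  list(m1 = m1, m2 = m2, joint_gap = joint_gap, effect_gap = eff,
       description = paste0(
         "two parameterizations agree on Pr(",
         paste(v2, collapse = ","), ") but differ in Pr(",
         paste(query$y, collapse = ","), " | do(...)) by ",
         signif(eff, 3), "; zero-probability context of ", D,
         " via deterministic path ", paste(path, collapse = "->")))
}

effect_gap <- function(m1, m2, query) {
  states <- cbn_states(m1, query$x)
  grid <- expand.grid(states, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  gap <- 0
  for (i in seq_len(nrow(grid))) {
    xin <- stats::setNames(as.character(grid[i, ]), query$x)
    e1 <- causal_effect_oracle(m1, xin, query$y)
    e2 <- causal_effect_oracle(m2, xin, query$y)
    gap <- max(gap, max(abs(e1 - e2)))
  }
  gap
}
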