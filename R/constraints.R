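#' Positivity constraints
#'
#' A positivity constraint `Pr(S | Z) > 0` requires that, for every
#' instantiation, `Pr(s, z) > 0` whenever `Pr(z) > 0`.  With `z` empty the
#' constraint is on the marginal `Pr(S) > 0`.
#'
#' @param s nonempty variable set.
#' @param z conditioning variable set, disjoint from `s`.
#' @return an object of class `positivity_constraint`.
#' @export
positivity_constraint <- function(s, z = character()) {
  s <- sort(unique(as.character(s)))
  z <- sort(unique(as.character(z)))
  if (!length(s)) stop("S must be nonempty", call. = FALSE)
  if (length(intersect(s, z))) stop("S and Z must be disjoint", call. = FALSE)
  structure(list(s = s, z = z), class = "positivity_constraint")
}

#' @export
print.positivity_constraint <- function(x, ...) {
  cat("Pr(", paste(x$s, collapse = ","),
      if (length(x$z)) paste0(" | ", paste(x$z, collapse = ",")),
      ") > 0\n", sep = "")
  invisible(x)
}

#' Constraint sets
#'
#' An unordered collection of [positivity_constraint()]s.
#'
#' @param ... positivity constraints (or a single list of them).
#' @return an object of class `constraint_set`.
#' @export
constraint_set <- function(...) {
  cs <- list(...)
  if (length(cs) == 1L && is.list(cs[[1L]]) &&
      !inherits(cs[[1L]], "positivity_constraint"))
    cs <- cs[[1L]]
  ok <- vapply(cs, inherits, logical(1), "positivity_constraint")
  if (!all(ok)) stop("all elements must be positivity constraints",
                     call. = FALSE)
  structure(cs, class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  if (!length(x)) cat("(no positivity constraints)\n")
  for (c in x) print(c)
  invisible(x)
}

#' Variables mentioned by a constraint set
#' @param cs a `constraint_set`.
#' @return sorted character vector.
#' @export
constraint_vars <- function(cs) {
  sort(unique(as.character(
    unlist(lapply(cs, function(c) c(c$s, c$z)), use.names = FALSE))))
}

#' Separability of constraints from a functional set
#'
#' A constraint set is separable from the functional variables `w` when it
#' mentions none of them; separable constraints cannot rule out any candidate
#' function for the variables in `w`.
#'
#' @param cs a `constraint_set`.
#' @param w functional variables.
#' @return `TRUE` or `FALSE`.
#' @export
separable <- function(cs, w) {
  length(intersect(constraint_vars(cs), w)) == 0L
}

#' Syntactic implication between positivity constraints
#'
#' Sound but conservative closure under two rules: `Pr(S) > 0` implies
#' `Pr(T) > 0` for every `T` contained in `S`; and `Pr(S | Z) > 0` together
#' with an implied `Pr(Z) > 0` yields `Pr(S, Z) > 0`.  Anything not provable
#' by these rules is reported as not implied.
#'
#' @param cs a `constraint_set`.
#' @param target a `positivity_constraint`; a conditional target
#'   `Pr(S | Z) > 0` is implied when `Pr(S, Z) > 0` is.
#' @return `TRUE` if `cs` provably implies `target`.
#' @export
implies_positivity <- function(cs, target) {
  stopifnot(inherits(target, "positivity_constraint"))
  known <- lapply(Filter(function(c) length(c$z) == 0L, cs),
                  function(c) c$s)
  cond <- Filter(function(c) length(c$z) > 0L, cs)
  covered <- function(set) {
    any(vapply(known, function(k) all(set %in% k), logical(1)))
  }
  repeat {
    grew <- FALSE
    for (c in cond) {
      if (covered(c$z)) {
        joint <- sort(union(c$s, c$z))
        if (!covered(joint)) {
          known <- c(known, list(joint))
          grew <- TRUE
        }
      }
    }
    if (!grew) break
  }
  covered(sort(union(target$s, target$z)))
}

#' Standard positivity presets
#'
#' The three common constraint regimes: `"strict"` is `Pr(V) > 0` over the
#' observed variables; `"treatments"` is one marginal constraint
#' `Pr(X) > 0` per treatment variable; `"nonfunctional"` is
#' `Pr(V \ W) > 0` over the observed non-functional variables.  The last two
#' are always consistent with any functional set.
#'
#' @param kind one of `"strict"`, `"treatments"`, `"nonfunctional"`.
#' @param g a `causal_diagram`.
#' @param query a [causal_query()] (required for `"treatments"`).
#' @return a `constraint_set`.
#' @export
positivity_preset <- function(kind = c("strict", "treatments",
                                       "nonfunctional"),
                              g, query = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    strict = constraint_set(positivity_constraint(g$observed)),
    treatments = {
      if (is.null(query)) stop("'treatments' preset needs a query",
                               call. = FALSE)
      constraint_set(lapply(query$x, positivity_constraint))
    },
    nonfunctional = constraint_set(
      positivity_constraint(setdiff(g$observed, g$functional))))
}

# is cs exactly the per-treatment positivity regime {Pr(X) > 0, X in X}?
treatment_regime <- function(cs, query) {
  if (!length(cs)) return(FALSE)
  singles <- vapply(cs, function(c)
    length(c$z) == 0L && length(c$s) == 1L && c$s %in% query$x, logical(1))
  all(singles) && setequal(unlist(lapply(cs, `[[`, "s")), query$x)
}
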