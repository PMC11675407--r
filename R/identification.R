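#' The ID algorithm on an ADMG
#'
#' Recursive complete identification of `Pr(Y | do(x))` from the
#' observational distribution of the ADMG's vertices, assuming strict
#' positivity of that distribution.  Returns an [ident_decision] that is
#' either `IDENTIFIABLE` together with a symbolic [estimand], or
#' `NOT_IDENTIFIABLE` together with a hedge witness (the confounded component
#' that blocks identification).  Vertex choices are made in a fixed
#' topological-lexicographic order, so the output is deterministic.
#'
#' @param a an `admg`, e.g. from [latent_project()].
#' @param query a [causal_query()]; both variable sets must be vertices of
#'   `a`.
#' @param build_estimand when `FALSE`, only the decision is computed (faster
#'   for large screening experiments).
#' @return an object of class `ident_decision` with fields `status`,
#'   `estimand`, `witness` and `trace`.
#' @export
id_algorithm <- function(a, query, build_estimand = TRUE) {
  stopifnot(inherits(a, "admg"), inherits(query, "causal_query"))
  bad <- setdiff(c(query$x, query$y), a$vertices)
  if (length(bad))
    stop("query variables not in ADMG: ", paste(bad, collapse = ", "),
         call. = FALSE)
  m <- admg_matrices(a)
  P0 <- if (build_estimand) est_prob(a$vertices) else NULL
  res <- id_rec(query$y, query$x, P0, sort(a$vertices), m$D, m$B,
                build_estimand)
  if (res$ok) {
    expr <- res$expr
    if (build_estimand) {
      # interventions absorbed during the recursion have no causal path to y,
      # so the value is constant in them; pin them to an arbitrary state
      loose <- setdiff(est_free(expr), c(query$x, query$y))
      expr <- est_fix(loose, expr)
    }
    ident_decision("IDENTIFIABLE", estimand = expr,
                   trace = list(admg = a, query = query))
  } else {
    ident_decision("NOT_IDENTIFIABLE", witness = res$witness,
                   trace = list(admg = a, query = query))
  }
}

#' Identification decisions
#'
#' Container for the outcome of an identifiability test.  `status` is one of
#' `IDENTIFIABLE`, `NOT_IDENTIFIABLE`, `INAPPLICABLE` (the available
#' positivity constraints are too weak for the algorithm that would decide
#' the question) or `UNKNOWN` (no implemented criterion applies).
#'
#' @param status decision status string.
#' @param estimand the identifying formula (for `IDENTIFIABLE`).
#' @param witness the failure witness: a hedge, a first-ancestor trigger, or
#'   a reason string.
#' @param trace named list describing how the decision was reached.
#' @return an object of class `ident_decision`.
#' @export
ident_decision <- function(status = c("IDENTIFIABLE", "NOT_IDENTIFIABLE",
                                      "INAPPLICABLE", "UNKNOWN"),
                           estimand = NULL, witness = NULL, trace = list()) {
  status <- match.arg(status)
  structure(list(status = status, estimand = estimand, witness = witness,
                 trace = trace), class = "ident_decision")
}

#' @export
print.ident_decision <- function(x, ...) {
  cat("Decision:", x$status, "\n")
  if (!is.null(x$estimand)) cat("Estimand:", est_text(x$estimand), "\n")
  if (!is.null(x$witness)) {
    if (is.character(x$witness)) cat("Reason:", x$witness, "\n")
    else if (!is.null(x$witness$s))
      cat("Hedge witness: confounded component {",
          paste(x$witness$s, collapse = ","), "} inside {",
          paste(x$witness$c_root, collapse = ","), "}\n")
  }
  invisible(x)
}

anc_in_matrix <- function(D, targets) {
  seen <- targets
  frontier <- targets
  while (length(frontier)) {
    par <- rownames(D)[rowSums(D[, frontier, drop = FALSE]) > 0]
    nxt <- setdiff(par, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

topo_in_matrix <- function(D) {
  verts <- rownames(D)
  indeg <- colSums(D)
  avail <- sort(verts[indeg == 0])
  out <- character()
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, v)
    kids <- verts[D[v, ]]
    indeg[kids] <- indeg[kids] - 1L
    newly <- kids[indeg[kids] == 0L]
    if (length(newly)) avail <- sort(c(avail, newly))
  }
  out
}

id_rec <- function(y, x, P, V, D, B, build) {
  ok <- function(expr) list(ok = TRUE, expr = expr)
  # marginalize the current distribution expression onto `keep`, summing
  # only over variables of the *current* vertex set: free variables outside
  # V are fixed conditioning values inherited from an enclosing call and
  # must not be summed over
  marg_in <- function(P, keep) {
    est_sum(intersect(setdiff(V, keep), est_free(P)), P)
  }
  cond_in <- function(P, vi, pred) {
    num <- marg_in(P, c(vi, pred))
    if (!length(pred)) return(num)
    est_quot(num, marg_in(P, pred))
  }
  # 1: no intervention left -> marginalize
  if (!length(x)) {
    return(ok(if (build) marg_in(P, y) else NULL))
  }
  # 2: restrict to ancestors of y
  An <- anc_in_matrix(D, y)
  if (length(An) < length(V)) {
    return(id_rec(y, intersect(x, An),
                  if (build) marg_in(P, An) else NULL,
                  An, D[An, An, drop = FALSE], B[An, An, drop = FALSE],
                  build))
  }
  # 3: absorb variables that do not affect y once x is fixed
  D2 <- D
  D2[, x] <- FALSE
  An2 <- anc_in_matrix(D2, y)
  W <- setdiff(V, union(x, An2))
  if (length(W)) {
    return(id_rec(y, sort(union(x, W)), P, V, D, B, build))
  }
  Vmx <- setdiff(V, x)
  CC <- bidir_components(B, Vmx)
  # 4: factor over the confounded components of G minus X
  if (length(CC) > 1L) {
    parts <- vector("list", length(CC))
    for (i in seq_along(CC)) {
      S <- CC[[i]]
      r <- id_rec(S, setdiff(V, S), P, V, D, B, build)
      if (!r$ok) return(r)
      parts[[i]] <- r$expr
    }
    expr <- if (build)
      est_sum(setdiff(V, union(y, x)), est_prod(parts)) else NULL
    return(ok(expr))
  }
  # 5: a single confounded component S
  S <- CC[[1L]]
  CG <- bidir_components(B, V)
  if (length(CG) == 1L) {
    return(list(ok = FALSE, witness = list(c_root = V, s = S)))
  }
  pi <- topo_in_matrix(D)
  hit <- vapply(CG, function(cc) setequal(cc, S), logical(1))
  if (any(hit)) {
    expr <- NULL
    if (build) {
      terms <- lapply(S, function(vi) {
        pred <- pi[seq_len(match(vi, pi) - 1L)]
        cond_in(P, vi, pred)
      })
      expr <- est_sum(setdiff(S, y), est_prod(terms))
    }
    return(ok(expr))
  }
  contains <- vapply(CG, function(cc) all(S %in% cc), logical(1))
  Sp <- CG[[which(contains)[1L]]]
  Pp <- NULL
  if (build) {
    terms <- lapply(Sp, function(vi) {
      pred <- pi[seq_len(match(vi, pi) - 1L)]
      cond_in(P, vi, pred)
    })
    Pp <- est_prod(terms)
  }
  id_rec(y, intersect(x, Sp), Pp, Sp, D[Sp, Sp, drop = FALSE],
         B[Sp, Sp, drop = FALSE], build)
}
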