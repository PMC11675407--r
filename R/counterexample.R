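#' Best-effort unidentifiability counterexample search
#'
#' Tries to exhibit two discrete CBNs on `g` that induce the same
#' observational distribution over `v` yet different causal effects for
#' `query` — the direct Definition-1 certificate of unidentifiability.
#'
#' Strategy: draw a strictly positive base model, then exploit the fact that
#' both the observational joint `Pr(v)` and the causal effect are *linear* in
#' any single CPT.  For each perturbable CPT (not a treatment, not required
#' to stay deterministic) the linear map onto `Pr(v)` is assembled, its
#' nullspace intersected with the row-sum-preserving directions is computed
#' by SVD, and the nullspace direction with the largest causal-effect
#' component is followed as far as the CPT's `[0, 1]` box allows.  The
#' perturbed model matches `Pr(v)` to machine precision by construction; the
#' candidate pair is still verified numerically before being returned.
#'
#' A `NULL` result means only that no witness was found within the budget;
#' it is never a claim of identifiability.
#'
#' @param g a `causal_diagram`.
#' @param v the observed variables the joints must agree on.
#' @param query a [causal_query()].
#' @param functional_w variables whose CPTs must stay deterministic in both
#'   models (their mechanisms are redrawn across restarts but never
#'   perturbed continuously).
#' @param budget number of random restarts.
#' @param seed integer RNG seed.
#' @param joint_tol,effect_tol acceptance thresholds: maximum allowed
#'   discrepancy in `Pr(v)` and minimum required causal-effect difference.
#' @param hidden_cardinality state count for hidden variables.  Hidden
#'   mechanisms richer than the observed ones are what give unidentifiable
#'   structures their wiggle room; the default of 4 states (versus 2 for
#'   observed variables) is enough for the standard confounding
#'   constructions while keeping enumeration cheap.
#' @return `NULL`, or a list with components `m1`, `m2`, `target` (the
#'   perturbed CPT's variable), `joint_gap` and `effect_gap`.
#' @export
counterexample_search <- function(g, v = g$observed, query,
                                  functional_w = character(),
                                  budget = 10L, seed = 1L,
                                  joint_tol = 1e-9, effect_tol = 1e-3,
                                  hidden_cardinality = 4L) {
  v <- sort(check_vars(g, v))
  functional_w <- check_vars(g, functional_w)
  # the searched model class is defined by `functional_w` alone
  g <- causal_diagram(g$nodes, g$edges, observed = g$observed,
                      functional = functional_w)
  card <- stats::setNames(ifelse(g$nodes %in% v, 2L,
                                 as.integer(hidden_cardinality)), g$nodes)
  targets <- setdiff(g$nodes, c(functional_w, query$x))
  # prefer mechanisms entangled with hidden variables
  hid <- setdiff(g$nodes, v)
  entangled <- targets[vapply(targets, function(t)
    t %in% hid || length(intersect(parents_of(g, t), hid)) > 0L, logical(1))]
  targets <- c(entangled, setdiff(targets, entangled))
  for (i in seq_len(budget)) {
    m1 <- random_cbn(g, card, seed = as.integer(seed) + 211L * i,
                     functional_w = functional_w, positive = TRUE)
    for (t in targets) {
      res <- nullspace_perturbation(m1, t, v, query, joint_tol, effect_tol)
      if (!is.null(res))
        return(c(res, list(target = t)))
    }
  }
  NULL
}

nullspace_perturbation <- function(m1, target, v, query, joint_tol,
                                   effect_tol) {
  ct <- m1$cpts[[target]]
  nent <- length(ct$table)
  base <- m1
  pv_of <- function(vec) {
    base$cpts[[target]]$table[] <- vec
    as.vector(array_marginal(joint_distribution(base), v))
  }
  eff_of <- function(vec) {
    base$cpts[[target]]$table[] <- vec
    states <- cbn_states(base, query$x)
    grid <- expand.grid(states, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    unlist(lapply(seq_len(nrow(grid)), function(i) {
      xin <- stats::setNames(as.character(grid[i, ]), query$x)
      as.vector(causal_effect_oracle(base, xin, query$y))
    }))
  }
  A <- vapply(seq_len(nent), function(k) {
    e <- numeric(nent); e[k] <- 1; pv_of(e)
  }, numeric(length(pv_of(numeric(nent)))))
  Beff <- vapply(seq_len(nent), function(k) {
    e <- numeric(nent); e[k] <- 1; eff_of(e)
  }, numeric(length(eff_of(numeric(nent)))))
  if (is.null(dim(A))) A <- matrix(A, nrow = 1L)
  if (is.null(dim(Beff))) Beff <- matrix(Beff, nrow = 1L)
  # row-sum preservation: per parent context, perturbation sums to zero
  k <- dim(ct$table)[1L]
  nctx <- nent / k
  R <- matrix(0, nctx, nent)
  for (cx in seq_len(nctx)) R[cx, (cx - 1L) * k + seq_len(k)] <- 1
  M <- rbind(A, R)
  sv <- svd(M, nu = 0L, nv = ncol(M))
  tol <- max(dim(M)) * max(sv$d, 0) * .Machine$double.eps
  small <- c(sv$d < max(tol, 1e-11), rep(TRUE, ncol(M) - length(sv$d)))
  null_cols <- sv$v[, small, drop = FALSE]
  if (!ncol(null_cols)) return(NULL)
  proj <- Beff %*% null_cols
  norms <- sqrt(rowSums(proj^2))
  r <- which.max(norms)
  if (norms[r] < 1e-10) return(NULL)
  dir <- as.vector(null_cols %*% proj[r, ])
  dir <- dir / sqrt(sum(dir^2))
  tab <- as.vector(ct$table)
  up <- ifelse(dir > 0, (1 - tab) / dir, Inf)
  dn <- ifelse(dir < 0, -tab / dir, Inf)
  s <- 0.9 * min(c(up, dn))
  if (!is.finite(s) || s <= 0) return(NULL)
  m2 <- m1
  m2$cpts[[target]]$table[] <- tab + s * dir
  j1 <- array_marginal(joint_distribution(m1), v)
  j2 <- array_marginal(joint_distribution(m2), v)
  joint_gap <- max(abs(j1 - j2))
  if (joint_gap > joint_tol) return(NULL)
  egap <- effect_gap(m1, m2, query)
  if (egap < effect_tol) return(NULL)
  list(m1 = m1, m2 = m2, joint_gap = joint_gap, effect_gap = egap)
}
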