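#' Erdős–Rényi random DAGs
#'
#' Draws a DAG on `n` ordered vertices: each forward pair is an edge
#' independently with probability `p`, and vertices ending up with more than
#' `max_parents` parents have a uniformly chosen subset of their incoming
#' edges dropped until the cap holds.  Reproducible from `seed`.
#'
#' @param n number of variables; named `V001`, `V002`, ... so lexicographic
#'   order equals generation order.
#' @param p edge probability (default 0.1).
#' @param max_parents parent cap per variable (default 6).
#' @param seed integer RNG seed.
#' @return a `causal_diagram` with all variables observed and none
#'   functional (roles are assigned separately by [assign_roles()]).
#' @export
er_random_dag <- function(n, p = 0.1, max_parents = 6L, seed = 1L) {
  stopifnot(n >= 2L, p >= 0, p <= 1, max_parents >= 1L)
  nodes <- sprintf("V%03d", seq_len(n))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  edges <- cbind(nodes[e[, 1L]], nodes[e[, 2L]])
  if (nrow(edges)) {
    kept <- logical(nrow(edges))
    for (v in nodes) {
      inc <- which(edges[, 2L] == v)
      if (length(inc) > max_parents)
        inc <- sort(sample(inc, max_parents))
      kept[inc] <- TRUE
    }
    edges <- edges[kept, , drop = FALSE]
  }
  causal_diagram(nodes, edges)
}

#' Assign experiment roles to a random graph
#'
#' Samples the observed, treatment, outcome and functional variables for one
#' experimental unit: `round(frac_observed * n)` observed variables,
#' treatments and outcomes as disjoint subsets of the observed set, and
#' functional variables from the non-root variables.  The functional set is
#' drawn last, so graphs sharing a seed have identical observed/treatment/
#' outcome roles across functional fractions.
#'
#' @param g a `causal_diagram` (roles are overwritten).
#' @param frac_functional fraction of variables marked functional.
#' @param frac_observed,frac_treatment,frac_outcome role fractions
#'   (defaults 0.8 / 0.2 / 0.2).
#' @param seed integer RNG seed.
#' @return a list with `diagram` (roles set) and `query`.
#' @export
assign_roles <- function(g, frac_functional,
                         frac_observed = 0.8, frac_treatment = 0.2,
                         frac_outcome = 0.2, seed = 1L) {
  n <- length(g$nodes)
  n_obs <- round(frac_observed * n)
  n_x <- round(frac_treatment * n)
  n_y <- round(frac_outcome * n)
  n_w <- round(frac_functional * n)
  stopifnot(n_obs >= n_x + n_y, n_x >= 1L, n_y >= 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  obs <- sort(sample(g$nodes, n_obs))
  xs <- sort(sample(obs, n_x))
  ys <- sort(sample(setdiff(obs, xs), n_y))
  nonroot <- g$nodes[g$nodes %in% g$edges[, 2L]]
  fun <- sort(sample(nonroot, min(n_w, length(nonroot))))
  list(diagram = causal_diagram(g$nodes, g$edges, observed = obs,
                                functional = fun),
       query = causal_query(xs, ys))
}

#' Random-graph identifiability experiment
#'
#' Runs the screening experiment for one `(n, wfrac)` setting: generates
#' `n_graphs` random DAGs, assigns roles, and records
#' * `uid` — effects declared unidentifiable by classical latent projection
#'   + ID (functional labels ignored),
#' * `uid_fid` — unidentifiable effects that become identifiable under the
#'   functional-elimination pipeline (hidden-functional elimination, eligible
#'   observed-functional elimination, hidden-parent condition, then
#'   project-ID, with strict positivity assumed over the post-reduction
#'   observed set),
#' * `mean_obs` — the average number of observed variables passed to
#'   project-ID after the reductions.
#'
#' Per-graph seeds are derived from `seed` and the graph index, so individual
#' rows are independently reproducible and `uid` does not depend on `wfrac`.
#'
#' @param n number of variables per graph.
#' @param wfrac functional fraction (e.g. 0.25, 0.5, 0.75).
#' @param n_graphs number of random graphs (default 50).
#' @param seed integer base seed.
#' @param p,max_parents generator parameters, see [er_random_dag()].
#' @return a one-row data frame with columns `n`, `wfrac`, `n_graphs`,
#'   `uid`, `uid_fid`, `mean_obs`.
#' @export
run_table1 <- function(n, wfrac, n_graphs = 50L, seed = 1L, p = 0.1,
                       max_parents = 6L) {
  uid <- 0L
  uid_fid <- 0L
  obs_counts <- numeric(n_graphs)
  for (i in seq_len(n_graphs)) {
    si <- as.integer(seed) + 7919L * i
    g <- er_random_dag(n, p = p, max_parents = max_parents, seed = si)
    r <- assign_roles(g, frac_functional = wfrac, seed = si + 1L)
    adm <- latent_project(r$diagram, r$diagram$observed)
    dec <- id_algorithm(adm, r$query, build_estimand = FALSE)
    fdec <- fid_check(fid_tuple(r$diagram), r$query,
                      assume_strict_positivity = TRUE,
                      allow_theorem5 = FALSE, build_estimand = FALSE)
    obs_counts[i] <- length(fdec$trace$final_observed)
    if (dec$status == "NOT_IDENTIFIABLE") {
      uid <- uid + 1L
      if (fdec$status == "IDENTIFIABLE") uid_fid <- uid_fid + 1L
    }
  }
  data.frame(n = n, wfrac = wfrac, n_graphs = n_graphs, uid = uid,
             uid_fid = uid_fid, mean_obs = mean(obs_counts))
}

#' Full experiment grid
#'
#' Convenience wrapper running [run_table1()] over all combinations of the
#' supplied sizes and functional fractions.
#'
#' @param ns vector of graph sizes.
#' @param wfracs vector of functional fractions.
#' @inheritParams run_table1
#' @return a data frame with one row per combination.
#' @export
run_table1_grid <- function(ns = c(50L, 100L, 150L),
                            wfracs = c(0.25, 0.5, 0.75),
                            n_graphs = 50L, seed = 1L) {
  rows <- list()
  for (n in ns) for (w in wfracs)
    rows <- c(rows, list(run_table1(n, w, n_graphs = n_graphs, seed = seed)))
  do.call(rbind, rows)
}
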