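# Shared fixtures, built in code.

# Motivating graph: driving age A is a function of country C; C and A cause
# speed X; A and X cause accidents Y.  Observed {C, X, Y}.
m_graph <- function(functional = "A") {
  causal_diagram(c("C", "A", "X", "Y"),
                 c("C -> A", "C -> X", "A -> X", "A -> Y", "X -> Y"),
                 observed = c("C", "X", "Y"), functional = functional)
}

# Eight-variable graph reconstructed from its CPT factorization
# fA(A) fB(B,A) fX1(X1,B) fC(B,C) fD(D,X1,C) fE(E,D) fX2(X2,D) fY(Y,E,X2),
# with the non-root variables B and D hidden.
chain8_graph <- function() {
  causal_diagram(c("A", "B", "X1", "C", "D", "E", "X2", "Y"),
                 c("A -> B", "B -> X1", "B -> C", "X1 -> D", "C -> D",
                   "D -> E", "D -> X2", "E -> Y", "X2 -> Y"),
                 observed = c("A", "C", "E", "X1", "X2", "Y"))
}

# Fork C -> A -> {Y1, Y2}
fork_graph <- function(functional = character()) {
  causal_diagram(c("C", "A", "Y1", "Y2"),
                 c("C -> A", "A -> Y1", "A -> Y2"), functional = functional)
}

bow_admg <- function() admg(c("X", "Y"), "X -> Y", "X <-> Y")

# Random small diagram for property suites; deterministic in `seed`.
random_test_diagram <- function(seed, max_nodes = 10L, p = 0.3,
                                frac_hidden = 0.3, frac_functional = 0.3) {
  set.seed(seed)
  n <- sample(4:max_nodes, 1L)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  edges <- if (nrow(e)) cbind(nodes[e[, 1L]], nodes[e[, 2L]]) else NULL
  g0 <- causal_diagram(nodes, edges)
  nonroot <- nodes[nodes %in% g0$edges[, 2L]]
  nh <- rbinom(1L, n, frac_hidden)
  hidden <- if (nh) sample(nodes, min(nh, n - 2L)) else character()
  fun <- nonroot[runif(length(nonroot)) < frac_functional]
  causal_diagram(nodes, edges, observed = setdiff(nodes, hidden),
                 functional = fun)
}

# disjoint random variable-set triple from a pool; any set may be empty
# except xs and ys
random_disjoint_sets <- function(pool, allow_empty_z = TRUE) {
  stopifnot(length(pool) >= 2L)
  sizes <- c(1L, 1L, 0L)
  extra <- sample(0:(length(pool) - 2L), 1L)
  perm <- sample(pool)
  xs <- perm[1L]
  ys <- perm[2L]
  zs <- if (extra > 0L) perm[2L + seq_len(extra)] else character()
  list(xs = xs, ys = ys, zs = zs)
}

expect_set_equal <- function(a, b) {
  testthat::expect_true(setequal(a, b),
                        label = paste("sets equal:", paste(sort(a), collapse = ","),
                                      "vs", paste(sort(b), collapse = ",")))
}
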