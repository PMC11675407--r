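test_that("constraint containers validate their pieces", {
  expect_error(positivity_constraint(character()), "nonempty")
  expect_error(positivity_constraint("A", "A"), "disjoint")
  cs <- constraint_set(positivity_constraint(c("X", "Y")),
                       positivity_constraint("B", "A"))
  expect_equal(constraint_vars(cs), c("A", "B", "X", "Y"))
  expect_equal(constraint_vars(constraint_set()), character())
})

test_that("separability is the empty-intersection test", {
  cs <- constraint_set(positivity_constraint(c("X", "Y")))
  expect_true(separable(cs, "B"))
  expect_false(separable(constraint_set(positivity_constraint("B", "A")),
                         "B"))
  expect_true(separable(constraint_set(), c("A", "B")))
})

test_that("syntactic positivity implication is sound and conservative", {
  vall <- constraint_set(positivity_constraint(c("A", "X", "Y")))
  expect_true(implies_positivity(vall, positivity_constraint("X")))
  expect_true(implies_positivity(vall, positivity_constraint(c("A", "Y"))))
  expect_false(implies_positivity(constraint_set(),
                                  positivity_constraint("X")))
  chain <- constraint_set(positivity_constraint("S", "Z"),
                          positivity_constraint("Z"))
  expect_true(implies_positivity(chain, positivity_constraint(c("S", "Z"))))
  # not provable: conditional without positivity of the condition
  lone <- constraint_set(positivity_constraint("S", "Z"))
  expect_false(implies_positivity(lone, positivity_constraint("S")))
})

test_that("the conditional-chaining rule is sound over all supports", {
  # exhaustive oracle: positivity constraints over three binary variables
  # depend only on the support of the joint; enumerate all 255 nonempty
  # supports of (S, Z, U) and check that Pr(S|Z)>0 & Pr(Z)>0 => Pr(S,Z)>0
  grid <- expand.grid(S = 0:1, Z = 0:1, U = 0:1)
  for (mask in 1:255) {
    sup <- grid[bitwAnd(mask, 2^(0:7)) > 0, , drop = FALSE]
    # Pr(Z)>0 for every z means both z values occur in the support
    prz <- all(vapply(0:1, function(z) any(sup$Z == z), logical(1)))
    # Pr(S|Z)>0: for each z occurring, every s co-occurs with it
    prsgz <- all(vapply(0:1, function(z) {
      if (!any(sup$Z == z)) return(TRUE)
      all(vapply(0:1, function(s) any(sup$S == s & sup$Z == z), logical(1)))
    }, logical(1)))
    prsz <- all(vapply(0:1, function(s) vapply(0:1, function(z)
      any(sup$S == s & sup$Z == z), logical(1)), logical(2)))
    if (prsgz && prz) expect_true(prsz)
  }
})

test_that("the consistency sufficient condition matches the interceptor
           criterion", {
  m <- m_graph()  # A hidden functional, constraints on observed only
  expect_true(consistent_sufficient(
    fid_tuple(m, positivity_preset("strict", m))))
  # per-treatment positivity is always certified
  g <- causal_diagram(c("A", "B", "X", "Y"),
                      c("A -> B", "B -> Y", "A -> X", "X -> Y"),
                      functional = "B")
  q <- causal_query("X", "Y")
  expect_true(consistent_sufficient(
    fid_tuple(g, positivity_preset("treatments", g, q))))
  # constraint mentioning both B and its only interceptor A: not certified
  expect_false(consistent_sufficient(
    fid_tuple(g, constraint_set(positivity_constraint("B", "A")))))
  # constraint mentioning B alone: certified
  expect_true(consistent_sufficient(
    fid_tuple(g, constraint_set(positivity_constraint("B")))))
})

test_that("theorem 2 eliminates exactly the hidden functional variables", {
  m <- m_graph()
  t2 <- theorem2_reduce(fid_tuple(m))
  expect_equal(t2$g$nodes, c("C", "X", "Y"))
  expect_equal(t2$g$functional, character())
  expect_equal(t2$g$edges, normalize_edges(c("C -> X", "C -> Y", "X -> Y")))
  # all functional observed: identity
  g <- causal_diagram(c("A", "B"), "A -> B", functional = "B")
  expect_true(same_diagram(theorem2_reduce(fid_tuple(g))$g, g))
})

test_that("theorem 3 eligibility needs separability, observed parents and a
           non-query role", {
  g <- causal_diagram(c("A", "B", "X", "Y"),
                      c("A -> B", "B -> Y", "A -> X", "X -> Y"),
                      functional = "B")
  q <- causal_query("X", "Y")
  t1 <- fid_tuple(g, constraint_set(positivity_constraint("X")))
  expect_equal(theorem3_eligible(t1, q), "B")
  expect_equal(theorem3_eligible(
    fid_tuple(g, constraint_set(positivity_constraint("B"))), q),
    character())
  gh <- causal_diagram(g$nodes, g$edges, observed = c("B", "X", "Y"),
                       functional = "B")
  expect_equal(theorem3_eligible(
    fid_tuple(gh, constraint_set(positivity_constraint("X"))), q),
    character())
  r <- theorem3_reduce(t1, q)
  expect_equal(r$removed, "B")
  expect_equal(r$tuple$g$edges,
               normalize_edges(c("A -> X", "A -> Y", "X -> Y")))
  expect_equal(r$tuple$g$observed, c("A", "X", "Y"))
})

test_that("theorem 3 never removes query or constraint variables", {
  for (s in 1:40) {
    g <- random_test_diagram(s)
    obs <- g$observed
    if (length(obs) < 3L) next
    set.seed(s + 21)
    xs <- sample(obs, 1L)
    ys <- sample(setdiff(obs, xs), 1L)
    q <- causal_query(xs, ys)
    cvar <- sample(obs, 1L)
    t <- fid_tuple(g, constraint_set(positivity_constraint(cvar)))
    z <- theorem3_eligible(t, q)
    expect_length(intersect(z, c(xs, ys, cvar)), 0L)
    expect_true(all(z %in% intersect(g$functional, g$observed)))
  }
})

test_that("theorem 4 checks hidden parents of every functional variable", {
  gt <- causal_diagram(c("U", "A", "X", "Y"),
                       c("U -> A", "A -> Y", "X -> Y", "U -> X"),
                       observed = c("A", "X", "Y"), functional = "A")
  expect_true(theorem4_applicable(fid_tuple(gt)))
  g2 <- causal_diagram(c("P", "A", "Y"), c("P -> A", "A -> Y"),
                       functional = "A")
  expect_false(theorem4_applicable(fid_tuple(g2)))
  expect_true(theorem4_applicable(fid_tuple(fork_graph())))  # W empty
})

test_that("theorem 5 pretend-observed closure", {
  m <- m_graph()
  expect_equal(theorem5_pretend_observed(fid_tuple(m)),
               c("A", "C", "X", "Y"))
  g <- fork_graph()
  expect_equal(theorem5_pretend_observed(fid_tuple(g)), g$observed)
  # a functional variable with a hidden non-functional parent is never added
  gh <- causal_diagram(c("U", "A", "Y"), c("U -> A", "A -> Y"),
                       observed = c("A", "Y"), functional = "A")
  expect_equal(theorem5_pretend_observed(fid_tuple(gh)), c("A", "Y"))
})

test_that("fid_check identifies the motivating effect and matches the
           oracle", {
  m <- m_graph()
  q <- causal_query("X", "Y")
  dec <- fid_check(fid_tuple(m, positivity_preset("strict", m)), q)
  expect_equal(dec$status, "IDENTIFIABLE")
  bd <- est_sum("C", est_prod(list(est_prob("C"),
                                   est_prob("Y", c("C", "X")))))
  expect_true(estimands_equivalent(dec$estimand, bd, trials = 15L,
                                   tol = 1e-10, seed = 2L))
  maxd <- 0
  for (s in 1:30) {
    mm <- random_cbn(m, 2L, seed = s)  # A deterministic
    jv <- array_marginal(joint_distribution(mm), m$observed)
    for (xs in c("0", "1")) {
      eff <- causal_effect_oracle(mm, c(X = xs), "Y")
      for (ys in c("0", "1"))
        maxd <- max(maxd, abs(evaluate_estimand(
          dec$estimand, jv, c(X = xs, Y = ys)) - eff[[ys]]))
    }
  }
  expect_lt(maxd, 1e-10)
  # without the functional label the same tuple is unidentifiable
  m0 <- causal_diagram(m$nodes, m$edges, observed = m$observed)
  dec0 <- fid_check(fid_tuple(m0, positivity_preset("strict", m0)), q)
  expect_equal(dec0$status, "NOT_IDENTIFIABLE")
})

test_that("fid_check with empty W equals classical project-ID", {
  for (s in 1:30) {
    g <- random_test_diagram(s, frac_functional = 0)
    if (length(g$observed) < 3L) next
    set.seed(s + 77)
    xs <- sample(g$observed, 1L)
    ys <- sample(setdiff(g$observed, xs), 1L)
    q <- causal_query(xs, ys)
    cls <- id_algorithm(latent_project(g), q, build_estimand = FALSE)
    fid <- fid_check(fid_tuple(g, positivity_preset("strict", g)), q,
                     build_estimand = FALSE)
    expect_equal(fid$status, cls$status, label = paste("seed", s))
  }
})

test_that("prop-1 short-circuit fires without positivity", {
  m <- m_graph()
  q <- causal_query("X", "Y")
  dec <- fid_check(fid_tuple(m), q)
  expect_equal(dec$status, "NOT_IDENTIFIABLE")
  expect_equal(dec$trace$route, "first_ancestor")
})

test_that("the per-treatment regime decides the pretend-observed route where
           the ID route is inapplicable", {
  m <- m_graph()
  q <- causal_query("X", "Y")
  t <- fid_tuple(m, positivity_preset("treatments", m, q))
  dec_id <- fid_check(t, q, allow_theorem5 = FALSE)
  expect_equal(dec_id$status, "INAPPLICABLE")
  dec5 <- fid_check(t, q)
  expect_equal(dec5$status, "NOT_IDENTIFIABLE")
  expect_equal(dec5$trace$route, "theorem5")
  # the witness pair is a genuine certificate
  wp <- dec5$trace$witness_pair
  expect_lt(wp$joint_gap, 1e-12)
  expect_gt(wp$effect_gap, 1e-3)
})

test_that("dispensable observations are eliminated and absent from the
           estimand", {
  g <- causal_diagram(c("A", "B", "X", "Y"),
                      c("A -> B", "B -> Y", "A -> X", "X -> Y"),
                      functional = "B")
  q <- causal_query("X", "Y")
  t <- fid_tuple(g, constraint_set(positivity_constraint(c("A", "X", "Y"))))
  dec <- fid_check(t, q)
  expect_equal(dec$status, "IDENTIFIABLE")
  expect_equal(dec$trace$dispensable, "B")
  expect_false("B" %in% est_vars(dec$estimand))
  expect_equal(dispensable_observations(t, q), "B")
  # no observed functional variables: nothing dispensable
  m <- m_graph()
  expect_equal(dispensable_observations(
    fid_tuple(m, positivity_preset("strict", m)), q), character())
})

test_that("a long chain of functional mediators collapses to a constant
           number of needed observations", {
  # A -> X -> B1 -> ... -> Bn -> D -> Y with confounder C of X and Y;
  # every Bi observed functional.  All Bi are dispensable, leaving five
  # observed variables.
  n <- 6L
  bs <- sprintf("B%d", seq_len(n))
  nodes <- c("A", "C", "X", bs, "D", "Y")
  edges <- c("A -> X", "C -> X", "C -> Y",
             paste("X ->", bs[1L]),
             if (n > 1L) paste(bs[-n], "->", bs[-1L]),
             paste(bs[n], "-> D"), "D -> Y")
  g <- causal_diagram(nodes, edges, functional = bs)
  q <- causal_query("X", "Y")
  t <- fid_tuple(g, constraint_set(positivity_constraint(
    c("A", "C", "X", "D", "Y"))))
  dec <- fid_check(t, q)
  expect_equal(dec$status, "IDENTIFIABLE")
  expect_setequal(dec$trace$dispensable, bs)
  expect_equal(dec$trace$final_observed, c("A", "C", "D", "X", "Y"))
  expect_length(intersect(est_vars(dec$estimand), bs), 0L)
})

test_that("reduction traces replay to the final tuple", {
  for (s in 1:25) {
    g <- random_test_diagram(s)
    if (length(g$observed) < 3L) next
    set.seed(s + 400)
    xs <- sample(g$observed, 1L)
    ys <- sample(setdiff(g$observed, xs), 1L)
    q <- causal_query(xs, ys)
    t <- fid_tuple(g)
    dec <- fid_check(t, q, assume_strict_positivity = TRUE,
                     allow_theorem5 = FALSE, build_estimand = FALSE)
    g2 <- functional_eliminate_set(g, dec$trace$theorem2_eliminated)
    g3 <- functional_eliminate_set(g2, dec$trace$theorem3_eliminated)
    expect_equal(g3$observed, dec$trace$final_observed)
    expect_equal(g3$functional, dec$trace$final_functional)
  }
})
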