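test_that("CPT invariants: rows sum to one, functional rows are 0/1", {
  card <- c(A = 2L, B = 2L, C = 2L)
  # two variables with parent A: B noisy, C deterministic
  b <- cpt("B", "A", rbind(c(0.2, 0.8), c(0.6, 0.4)), card)
  c_ <- cpt("C", "A", rbind(c(0, 1), c(1, 0)), card)
  expect_false(is_functional_cpt(b))
  expect_true(is_functional_cpt(c_))
  expect_error(cpt("B", "A", rbind(c(0.2, 0.9), c(0.6, 0.4)), card),
               "sum to 1")
  expect_error(cpt("B", "A", rbind(c(-0.2, 1.2), c(0.6, 0.4)), card),
               "0, 1")
})

test_that("random parameterizations respect roles and are reproducible", {
  g <- m_graph()
  m1 <- random_cbn(g, 2L, seed = 7L)
  m2 <- random_cbn(g, 2L, seed = 7L)
  expect_identical(m1$cpts, m2$cpts)
  expect_true(is_functional_cpt(m1$cpts$A))
  expect_false(is_functional_cpt(m1$cpts$Y))
  expect_true(min(m1$cpts$Y$table) > 0)
  # all non-roots functional -> all their rows degenerate
  ch <- causal_diagram(c("A", "B", "C"), c("A -> B", "B -> C"),
                       functional = c("B", "C"))
  mm <- random_cbn(ch, 2L, seed = 1L, functional_w = c("B", "C"))
  expect_true(is_functional_cpt(mm$cpts$B) && is_functional_cpt(mm$cpts$C))
  expect_error(random_cbn(ch, 2L, functional_w = "A"), "root")
})

test_that("variable elimination agrees with brute-force enumeration", {
  for (s in 1:20) {
    g <- random_test_diagram(s, max_nodes = 8L)
    m <- random_cbn(g, 2L, seed = s)
    bf <- joint_distribution(m)
    ve <- cbn_marginal_ve(m)
    expect_lt(max(abs(bf - ve)), 1e-12)
    keep <- sort(sample(g$nodes, 2L))
    expect_lt(max(abs(array_marginal(bf, keep) - cbn_marginal_ve(m, keep))),
              1e-12)
  }
})

test_that("the mutilation oracle matches the truncated-product formula", {
  f <- chain8_graph()
  m <- random_cbn(f, 2L, seed = 11L, functional_w = character())
  eff <- causal_effect_oracle(m, c(X1 = "1", X2 = "0"), "Y")
  # brute force: sum over all non-treatment variables of the product of the
  # remaining CPTs with X1, X2 clamped
  grid <- expand.grid(cbn_states(m, setdiff(f$nodes, c("X1", "X2"))),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ref <- c("0" = 0, "1" = 0)
  for (i in seq_len(nrow(grid))) {
    env <- c(as.list(grid[i, ]), list(X1 = "1", X2 = "0"))
    p <- 1
    for (v in setdiff(f$nodes, c("X1", "X2"))) {
      ct <- m$cpts[[v]]
      p <- p * ct$table[matrix(match(
        unlist(env[c(v, ct$parents)]),
        c("0", "1")), 1L)]
    }
    ref[[env$Y]] <- ref[[env$Y]] + p
  }
  expect_lt(max(abs(eff - ref)), 1e-12)
  # intervening on a non-ancestor leaves the outcome untouched
  g2 <- causal_diagram(c("X", "Y"), NULL)
  m2 <- random_cbn(g2, 2L, seed = 2L)
  expect_lt(max(abs(causal_effect_oracle(m2, c(X = "1"), "Y") -
                      array_marginal(joint_distribution(m2), "Y"))), 1e-12)
  # a deterministic identity chain copies the intervention
  chg <- causal_diagram(c("X", "Y"), "X -> Y", functional = "Y")
  mc <- discrete_cbn(chg, list(
    X = cpt("X", character(), c(0.3, 0.7), c(X = 2L, Y = 2L)),
    Y = cpt("Y", "X", rbind(c(1, 0), c(0, 1)), c(X = 2L, Y = 2L))),
    c(X = 2L, Y = 2L))
  expect_equal(unname(causal_effect_oracle(mc, c(X = "1"), "Y")["1"]), 1)
})

test_that("CPT-level functional elimination preserves the joint marginal", {
  # identity composition
  ch <- causal_diagram(c("A", "B", "C"), c("A -> B", "B -> C"),
                       functional = "B")
  card <- c(A = 2L, B = 2L, C = 2L)
  m <- discrete_cbn(ch, list(
    A = cpt("A", character(), c(0.4, 0.6), card),
    B = cpt("B", "A", rbind(c(1, 0), c(0, 1)), card),
    C = cpt("C", "B", rbind(c(0.7, 0.3), c(0.2, 0.8)), card)), card)
  m2 <- cbn_functional_eliminate(m, "B")
  expect_equal(m2$cpts$C$parents, "A")
  expect_equal(unname(m2$cpts$C$table), unname(m$cpts$C$table))
  # eliminating a functional leaf drops its CPT
  lf <- causal_diagram(c("A", "B"), "A -> B", functional = "B")
  ml <- random_cbn(lf, 2L, seed = 3L)
  ml2 <- cbn_functional_eliminate(ml, "B")
  expect_equal(names(ml2$cpts), "A")
  # marginal preservation on random functional CBNs
  for (s in 1:100) {
    g <- random_test_diagram(s)
    if (!length(g$functional)) next
    m <- random_cbn(g, 2L, seed = s)
    w <- sort(g$functional)[1L]
    m2 <- cbn_functional_eliminate(m, w)
    ref <- array_marginal(joint_distribution(m), setdiff(g$nodes, w))
    expect_lt(max(abs(joint_distribution(m2) - ref)), 1e-12,
              label = paste("seed", s))
  }
  expect_error(cbn_functional_eliminate(
    random_cbn(ch, 2L, seed = 1L, functional_w = character()), "B"),
    "deterministic")
})

test_that("counterexample search certifies the standard unidentifiable
           structures and stays silent on identifiable ones", {
  bow <- as_causal_diagram(bow_admg())
  res <- counterexample_search(bow, c("X", "Y"), causal_query("X", "Y"),
                               budget = 5L, seed = 2L)
  expect_false(is.null(res))
  expect_lt(res$joint_gap, 1e-9)
  expect_gt(res$effect_gap, 1e-3)
  # the two models really are CBNs on the same diagram
  expect_true(same_diagram(res$m1$diagram, res$m2$diagram))
  # fully observed + strict positivity: provably identifiable, no witness
  ch <- causal_diagram(c("X", "Z", "Y"), c("X -> Z", "Z -> Y"))
  expect_null(counterexample_search(ch, c("X", "Z", "Y"),
                                    causal_query("X", "Y"),
                                    budget = 3L, seed = 1L))
  # the motivating graph: witness without functional knowledge, none with it
  m0 <- causal_diagram(c("C", "A", "X", "Y"),
                       c("C -> A", "C -> X", "A -> X", "A -> Y", "X -> Y"),
                       observed = c("C", "X", "Y"))
  q <- causal_query("X", "Y")
  found <- counterexample_search(m0, c("C", "X", "Y"), q, budget = 5L,
                                 seed = 3L)
  expect_false(is.null(found))
  expect_null(counterexample_search(m0, c("C", "X", "Y"), q,
                                    functional_w = "A", budget = 5L,
                                    seed = 3L))
})

test_that("deterministic-mechanism independence shows up as zero conditional
           mutual information", {
  f <- fork_graph(functional = "A")
  m <- random_cbn(f, 2L, seed = 9L)
  jt <- joint_distribution(m)
  # D-separation given C (closure adds A) -> exact independence
  expect_true(D_separated(f, "A", "Y1", "Y2", "C"))
  expect_lt(abs(cond_mutual_info(jt, "Y1", "Y2", c("C"))), 1e-12)
  # without determinism the same CMI is generically positive
  mnf <- random_cbn(f, 2L, seed = 9L, functional_w = character())
  expect_gt(cond_mutual_info(joint_distribution(mnf), "Y1", "Y2", "C"),
            1e-6)
})
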