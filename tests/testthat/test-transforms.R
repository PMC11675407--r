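test_that("functional elimination rewires parents to children", {
  m <- m_graph()
  g2 <- functional_eliminate(m, "A")
  expect_equal(g2$nodes, c("C", "X", "Y"))
  expect_equal(g2$edges, normalize_edges(c("C -> X", "C -> Y", "X -> Y")))
  ch <- causal_diagram(c("A", "B", "C"), c("A -> B", "B -> C"),
                       functional = "B")
  expect_equal(functional_eliminate(ch, "B")$edges,
               normalize_edges("A -> C"))
  # a functional leaf is simply dropped
  lf <- causal_diagram(c("A", "B"), "A -> B", functional = "B")
  g3 <- functional_eliminate(lf, "B")
  expect_equal(g3$nodes, "A")
  expect_equal(nrow(g3$edges), 0L)
  # strict mode refuses non-functional variables and roots
  expect_error(functional_eliminate(m, "X"), "non-functional")
  expect_silent(functional_eliminate(m, "X", force = TRUE))
})

test_that("set elimination is order independent and deduplicates edges", {
  ch <- causal_diagram(c("A", "B", "C", "D"),
                       c("A -> B", "B -> C", "C -> D"),
                       functional = c("B", "C"))
  r1 <- functional_eliminate(functional_eliminate(ch, "B"), "C")
  r2 <- functional_eliminate(functional_eliminate(ch, "C"), "B")
  expect_true(same_diagram(r1, r2))
  expect_equal(r1$edges, normalize_edges("A -> D"))
  expect_true(same_diagram(functional_eliminate_set(ch, character()), ch))
  dia <- causal_diagram(c("A", "B", "C", "D"),
                        c("A -> B", "A -> C", "B -> D", "C -> D"),
                        functional = c("B", "C"))
  out <- functional_eliminate_set(dia, c("B", "C"))
  expect_equal(out$edges, normalize_edges("A -> D"))
})

test_that("order invariance of multi-variable elimination holds on random
           diagrams", {
  for (s in 1:100) {
    g <- random_test_diagram(s)
    if (length(g$functional) < 2L) next
    set.seed(s + 40)
    ws <- sample(g$functional, min(3L, length(g$functional)))
    ref <- functional_eliminate_set(g, ws)
    for (r in 1:2) {
      perm <- sample(ws)
      alt <- g
      for (w in perm) alt <- functional_eliminate(alt, w)
      expect_true(same_diagram(alt, ref))
    }
  }
})

test_that("latent projection reproduces the worked eight-variable example", {
  f <- chain8_graph()
  a <- latent_project(f)
  expect_equal(a$vertices, sort(c("A", "C", "E", "X1", "X2", "Y")))
  expect_equal(a$directed,
               normalize_edges(c("A -> X1", "A -> C", "X1 -> E", "X1 -> X2",
                                 "C -> E", "C -> X2", "E -> Y", "X2 -> Y")))
  expect_equal(a$bidirected, normalize_bidirected(c("C <-> X1", "E <-> X2")))
})

test_that("latent projection of the motivating graph yields the bow", {
  m <- m_graph(functional = character())
  a <- latent_project(m)
  expect_equal(a$directed,
               normalize_edges(c("C -> X", "C -> Y", "X -> Y")))
  expect_equal(a$bidirected, normalize_bidirected("X <-> Y"))
  # all-observed graphs project to themselves
  g <- causal_diagram(c("A", "B", "C"), c("A -> B", "B -> C"))
  p <- latent_project(g)
  expect_equal(p$directed, g$edges)
  expect_equal(nrow(p$bidirected), 0L)
})

test_that("latent projection preserves d-separation among the kept
           variables", {
  for (s in 1:100) {
    g <- random_test_diagram(s)
    if (length(g$observed) < 2L) next
    a <- latent_project(g)
    ge <- as_causal_diagram(a)
    set.seed(s + 7100)
    tr <- random_disjoint_sets(g$observed)
    expect_identical(d_separated(g, tr$xs, tr$ys, tr$zs),
                     d_separated(ge, tr$xs, tr$ys, tr$zs),
                     label = paste("seed", s))
  }
})

test_that("functional projection drops the confounding due to functional
           hidden variables", {
  m <- m_graph()
  a <- functional_project(m, c("C", "X", "Y"))
  expect_equal(a$directed, normalize_edges(c("C -> X", "C -> Y", "X -> Y")))
  expect_equal(nrow(a$bidirected), 0L)
  # no functional variables: identical to classical projection
  g <- chain8_graph()
  expect_equal(functional_project(g, g$observed), latent_project(g))
})

test_that("functional projection output is edge-wise contained in classical
           projection output", {
  for (s in 1:100) {
    g <- random_test_diagram(s)
    wh <- setdiff(g$functional, g$observed)
    v <- g$observed
    if (length(v) < 2L) next
    cl <- latent_project(g, v)
    fp <- functional_project(g, v)
    key <- function(m) apply(m, 1, paste, collapse = ">")
    # directed reachability is untouched by elimination; confounding arcs
    # due to functional hidden variables disappear
    expect_equal(fp$directed, cl$directed)
    expect_true(all(key(fp$bidirected) %in% key(cl$bidirected)),
                label = paste("seed", s))
  }
})

test_that("elimination preserves D-separation among survivors", {
  for (s in 1:150) {
    g <- random_test_diagram(s)
    if (!length(g$functional)) next
    set.seed(s + 11)
    wsub <- sample(g$functional, sample(length(g$functional), 1L))
    g2 <- functional_eliminate_set(g, wsub)
    pool <- setdiff(g2$nodes, g2$functional)
    if (length(pool) < 2L) next
    tr <- random_disjoint_sets(pool)
    expect_identical(
      D_separated(g, g$functional, tr$xs, tr$ys, tr$zs),
      D_separated(g2, g2$functional, tr$xs, tr$ys, tr$zs),
      label = paste("seed", s))
  }
})

test_that("transforms preserve acyclicity", {
  for (s in 1:30) {
    g <- random_test_diagram(s)
    if (length(g$functional))
      expect_silent(topo_sort(functional_eliminate_set(g, g$functional)))
    expect_silent(topo_sort(as_causal_diagram(latent_project(g))))
  }
})
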