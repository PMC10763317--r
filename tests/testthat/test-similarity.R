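test_that("semantic contributions decay along the best root-ward path", {
  chain <- chain_ontology()
  p <- semantic_contributions(chain, "W", delta = 0.5)
  expect_equal(p$contributions[c("W", "mid", "root")],
               c(W = 1, mid = 0.5, root = 0.25))
  expect_equal(p$dv, 1.75)

  iso <- disease_ontology(data.frame(parent = character(0),
                                     child = character(0)), terms = "d")
  p_iso <- semantic_contributions(iso, "d")
  expect_equal(unname(p_iso$contributions), 1)
  expect_equal(p_iso$dv, 1)

  diamond <- diamond_ontology()
  p_d <- semantic_contributions(diamond, "c", delta = 0.5)
  expect_equal(p_d$contributions[c("c", "a", "b", "r")],
               c(c = 1, a = 0.5, b = 0.5, r = 0.25))
  expect_equal(p_d$dv, 2.25)

  expect_error(semantic_contributions(chain, "W", delta = 1), "delta")
  expect_error(semantic_contributions(chain, "W", delta = 0), "delta")
  expect_error(semantic_contributions(chain, "nope"), "unknown term")
})

test_that("disease semantic similarity matches its closed form", {
  chain <- chain_ontology()
  p <- semantic_contributions(chain, "W")
  expect_identical(disease_semantic_similarity(p, p), 1)

  # two roots of disconnected components share no terms
  two <- disease_ontology(data.frame(parent = c("r1", "r2"),
                                     child = c("x1", "x2")))
  pr1 <- semantic_contributions(two, "r1")
  pr2 <- semantic_contributions(two, "r2")
  expect_identical(disease_semantic_similarity(pr1, pr2), 0)

  # siblings a, b under a shared root: D(r) = 0.5 each, DV = 1.5 each
  sib <- disease_ontology(data.frame(parent = c("r", "r"),
                                     child = c("a", "b")))
  pa <- semantic_contributions(sib, "a")
  pb <- semantic_contributions(sib, "b")
  expect_equal(disease_semantic_similarity(pa, pb), 1 / 3)
  expect_equal(disease_semantic_similarity(pb, pa),
               disease_semantic_similarity(pa, pb))

  p_other <- semantic_contributions(sib, "a", delta = 0.4)
  expect_error(disease_semantic_similarity(pa, p_other), "decay")
})

test_that("similarity matrix equals element-wise pairwise calls", {
  sib <- disease_ontology(data.frame(parent = c("r", "r"),
                                     child = c("a", "b")))
  S1 <- disease_similarity_matrix(sib, "a")
  expect_equal(unname(S1), matrix(1))

  S <- disease_similarity_matrix(sib, c("a", "b"))
  expect_equal(unname(S), matrix(c(1, 1/3, 1/3, 1), 2))

  dag <- random_dag(12, seed = 5)
  ids <- dag$terms[c(2, 5, 9, 12)]
  M <- disease_similarity_matrix(dag, ids)
  profs <- lapply(ids, semantic_contributions, ontology = dag)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i != j) {
      expect_equal(M[i, j],
                   disease_semantic_similarity(profs[[i]], profs[[j]]))
    }
  }
  expect_true(isSymmetric(M))
  expect_equal(unname(diag(M)), rep(1, 4))
  expect_error(disease_similarity_matrix(dag, c("t02", "t02")), "duplicate")
  expect_error(disease_similarity_matrix(dag, "absent"), "absent")
})

test_that("semantic contributions agree with the path-enumeration oracle", {
  for (seed in 0:29) {
    dag <- random_dag(sample(5:30, 1), seed = seed)
    target <- sample(dag$terms, 1)
    p <- semantic_contributions(dag, target, delta = 0.5)
    oracle <- oracle_contributions(dag, target, delta = 0.5)
    expect_equal(sort(names(p$contributions)), sort(names(oracle)))
    expect_lt(max(abs(p$contributions[names(oracle)] - oracle)), 1e-12)
  }
})

test_that("functional similarity performs best-match averaging", {
  ds <- matrix(c(1, 0.4, 0.6,
                 0.4, 1, 0.2,
                 0.6, 0.2, 1), 3, byrow = TRUE,
               dimnames = list(c("d1", "e1", "e2"), c("d1", "e1", "e2")))
  expect_equal(functional_similarity("d1", "d1", ds), 1)
  expect_equal(functional_similarity("d1", c("e1", "e2"), ds),
               (0.6 + (0.4 + 0.6)) / 3)
  zero_ds <- diag(2); dimnames(zero_ds) <- list(c("x", "y"), c("x", "y"))
  expect_equal(functional_similarity("x", "y", zero_ds), 0)
  expect_equal(functional_similarity(character(0), "d1", ds), 0)
  expect_error(functional_similarity("d1", "zz", ds), "zz")
})

test_that("functional similarity matrix honours the empty-set convention", {
  ds <- diag(3)
  dimnames(ds) <- list(c("d1", "d2", "d3"), c("d1", "d2", "d3"))
  ds["d1", "d2"] <- ds["d2", "d1"] <- 0.5
  emap <- list(e1 = c("d1", "d2"), e2 = c("d1", "d2"), e3 = character(0))
  S <- functional_similarity_matrix(emap, ds)
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_true(isSymmetric(S))
  expect_equal(S["e1", "e2"], 1)         # identical disease sets
  expect_equal(unname(S["e3", c("e1", "e2")]), c(0, 0))

  # all entities sharing one set gives an all-ones matrix
  same <- list(a = "d1", b = "d1", c = "d1")
  expect_equal(unname(functional_similarity_matrix(same, ds)),
               matrix(1, 3, 3))
})

test_that("functional similarity is symmetric and bounded on random inputs", {
  set.seed(42)
  dag <- random_dag(15, seed = 9)
  ds <- disease_similarity_matrix(dag, dag$terms)
  for (i in 1:20) {
    s1 <- sample(dag$terms, sample(1:5, 1))
    s2 <- sample(dag$terms, sample(1:5, 1))
    v12 <- functional_similarity(s1, s2, ds)
    v21 <- functional_similarity(s2, s1, ds)
    expect_equal(v12, v21)
    expect_gte(v12, 0)
    expect_lte(v12, 1 + 1e-12)
  }
})
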