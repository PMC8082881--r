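test_that("semantic contributions follow the decay recursion on toy DAGs", {
  iso <- disease_dag(NULL, terms = "D")
  cm <- semantic_contributions(iso, "D")
  expect_equal(cm$contributions, c(D = 1))
  expect_equal(cm$semantic_value, 1)

  cm <- semantic_contributions(chain_dag(), "D", delta = 0.5)
  expect_equal(cm$contributions[c("D", "C", "R")], c(D = 1, C = 0.5, R = 0.25))
  expect_equal(cm$semantic_value, 1.75)

  cm <- semantic_contributions(diamond_dag(), "D", delta = 0.5)
  expect_equal(cm$contributions[c("D", "A", "B", "R")],
               c(D = 1, A = 0.5, B = 0.5, R = 0.25))
  expect_equal(cm$semantic_value, 2.25)
})

test_that("bad DAG inputs are rejected", {
  expect_error(semantic_contributions(chain_dag(), "missing"), "not in DAG")
  expect_error(disease_dag(data.frame(parent = c("A", "B"),
                                      child = c("B", "A"))), "cycle")
})

test_that("semantic similarity matches hand-computed values and bounds", {
  expect_equal(disease_semantic_similarity(chain_dag(), "D", "D"), 1)
  two <- disease_dag(data.frame(parent = c("R1", "R2"),
                                child = c("A", "B")))
  expect_equal(disease_semantic_similarity(two, "A", "B"), 0)
  expect_equal(disease_semantic_similarity(sibling_dag(), "A", "B"), 1 / 3)
})

test_that("contributions agree with exhaustive path enumeration on random DAGs", {
  for (seed in 1:10) {
    n <- withr::with_seed(seed, sample(2:12, 1))
    dag <- generate_random_dag(n, depth = 5, branching = 3, seed = seed * 7)
    delta <- c(0.3, 0.5, 0.7)[(seed %% 3) + 1]
    for (focus in dag$terms) {
      cm <- semantic_contributions(dag, focus, delta)
      for (d in names(cm$contributions)) {
        expect_equal(cm$contributions[[d]],
                     path_enum_contribution(dag, d, focus, delta),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("similarity matrix handles annotation, permutation and missing terms", {
  S <- disease_similarity_matrix(sibling_dag(), c("A", "B"))
  expect_equal(unclass(S), matrix(c(1, 1 / 3, 1 / 3, 1), 2, 2,
                                  dimnames = list(c("A", "B"), c("A", "B"))))
  S1 <- disease_similarity_matrix(sibling_dag(), "A")
  expect_equal(unname(unclass(S1)), matrix(1))
  expect_error(disease_similarity_matrix(sibling_dag(), character(0)), "empty")

  # permutation invariance after re-indexing
  synth <- small_synth(seed = 2)
  ids <- synth$dataset$disease_ids
  Sa <- disease_similarity_matrix(synth$dag, ids)
  perm <- withr::with_seed(4, sample(ids))
  Sb <- disease_similarity_matrix(synth$dag, perm)
  expect_equal(unclass(Sb[ids, ids]), unclass(Sa), tolerance = 1e-15)

  # unmapped disease: explicit missing marker, unit diagonal
  ann <- list(A = "A", B = "B")
  dag <- disease_dag(sibling_dag()$edges, annotation = ann)
  S2 <- disease_similarity_matrix(dag, c("A", "B", "unmapped"))
  expect_equal(S2["unmapped", "unmapped"], 1)
  expect_true(all(is.na(S2["unmapped", c("A", "B")])))

  # multi-term annotation takes the best-matching term pair
  dag3 <- disease_dag(sibling_dag()$edges,
                      annotation = list(x = c("A", "B"), y = "A"))
  S3 <- disease_similarity_matrix(dag3, c("x", "y"))
  expect_equal(S3["x", "y"], 1)
})

test_that("miRNA functional similarity is the best-match average", {
  ds <- tiny_dataset()
  SS <- structure(matrix(c(1, 1 / 3, 0,
                           1 / 3, 1, 0,
                           0, 0, 1), 3, 3, byrow = TRUE,
                         dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
                  class = c("similarity_matrix", "matrix", "array"))
  # m2 has {A}; identical singleton sets give 1
  expect_equal(mirna_functional_similarity(
    association_dataset(rbind(c(1, 0, 0), c(1, 0, 0)),
                        c("x", "y"), c("A", "B", "C")), SS, 1, 2), 1)
  # {A} vs {B}
  dsAB <- association_dataset(rbind(c(1, 0, 0), c(0, 1, 0)),
                              c("x", "y"), c("A", "B", "C"))
  expect_equal(mirna_functional_similarity(dsAB, SS, 1, 2), 1 / 3)
  # {A,B} vs {A}: (1 + 1/3 + 1) / 3
  dsABA <- association_dataset(rbind(c(1, 1, 0), c(1, 0, 0)),
                               c("x", "y"), c("A", "B", "C"))
  expect_equal(mirna_functional_similarity(dsABA, SS, 1, 2), 7 / 9)
  # empty disease set is a missing marker, not zero
  dsE <- association_dataset(rbind(c(1, 0, 0), c(0, 0, 0)),
                             c("x", "y"), c("A", "B", "C"))
  expect_true(is.na(mirna_functional_similarity(dsE, SS, 1, 2)))
})

test_that("similarity matrices are symmetric, bounded, with unit diagonal", {
  synth <- small_synth(seed = 5)
  SS <- disease_similarity_matrix(synth$dag, synth$dataset$disease_ids)
  expect_equal(unclass(SS), t(unclass(SS)))
  expect_true(all(SS >= 0 & SS <= 1, na.rm = TRUE))
  expect_true(all(diag(SS) == 1))
  FS <- suppressMessages(mirna_similarity_matrix(synth$dataset, SS))
  expect_equal(unclass(FS), t(unclass(FS)))
  expect_true(all(FS >= 0 & FS <= 1, na.rm = TRUE))
  expect_true(all(diag(FS) == 1))
})

test_that("similarity increases with the decay factor on shared-ancestor pairs", {
  prev <- -Inf
  for (delta in c(0.3, 0.5, 0.7)) {
    s <- disease_semantic_similarity(diamond_dag(), "A", "B", delta)
    expect_gt(s, prev)
    prev <- s
  }
  prev <- -Inf
  for (delta in c(0.3, 0.5, 0.7)) {
    s <- disease_semantic_similarity(sibling_dag(), "A", "B", delta)
    expect_gte(s, prev)
    prev <- s
  }
})

test_that("similarity matrix CSV round trip preserves values and missing cells", {
  synth <- small_synth(seed = 6)
  SS <- disease_similarity_matrix(synth$dag, synth$dataset$disease_ids)
  SS[1, 2] <- SS[2, 1] <- NA
  f <- withr::local_tempfile(fileext = ".csv")
  write_similarity_matrix(SS, f)
  back <- read_similarity_matrix(f)
  expect_equal(unclass(back), unclass(SS), tolerance = 1e-12)
})
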