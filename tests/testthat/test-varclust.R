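test_that("forced merges on a 3-item matrix", {
  D <- matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  for (meth in c("complete", "average", "mcquitty", "ward_d")) {
    tr <- agglomerate(D, meth)
    expect_equal(tr$merge[1, ], c(-1, -2))
    expect_equal(tr$height[1], .1)
  }
  expect_equal(agglomerate(D, "complete")$height[2], .9)
  expect_equal(agglomerate(D, "average")$height[2], .9)
})

test_that("all linkages reproduce the from-definition oracle", {
  set.seed(42)
  methods <- c("ward_d2", "ward_d", "complete", "average", "mcquitty")
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    D <- rand_dissim(n)
    for (meth in methods) {
      a <- agglomerate(as_dissimilarity(D), meth)
      b <- naive_agglomerate(D, meth)
      expect_identical(a$merge, b$merge)
      expect_equal(a$height, b$height, tolerance = 1e-9)
    }
  }
})

test_that("heights agree with stats::hclust on tie-free instances", {
  set.seed(5)
  map <- list(c("complete", "complete"), c("average", "average"),
              c("mcquitty", "mcquitty"), c("ward_d", "ward.D"),
              c("ward_d2", "ward.D2"))
  for (rep in 1:20) {
    D <- rand_dissim(sample(4:9, 1))
    for (mp in map) {
      a <- agglomerate(as_dissimilarity(D), mp[1])
      h <- stats::hclust(stats::as.dist(D), method = mp[2])
      expect_equal(a$height, h$height, tolerance = 1e-9)
    }
  }
})

test_that("heights are non-decreasing for monotone linkages", {
  set.seed(6)
  for (meth in c("ward_d2", "complete", "average", "mcquitty")) {
    tr <- agglomerate(rand_dissim(10), meth)
    expect_true(all(diff(tr$height) >= -1e-12))
  }
})

test_that("partitions are equivariant under item permutation", {
  set.seed(10)
  for (rep in 1:10) {
    n <- 9
    D <- rand_dissim(n)
    rownames(D) <- colnames(D) <- paste0("v", 1:n)
    perm <- sample(n)
    Dp <- D[perm, perm]
    for (meth in c("ward_d2", "complete")) {
      t1 <- agglomerate(as_dissimilarity(D), meth)
      t2 <- agglomerate(as_dissimilarity(Dp), meth)
      for (k in c(2, 3, 5)) {
        p1 <- cut_tree(t1, k)
        p2 <- cut_tree(t2, k)
        a2 <- p2$assignment[match(p1$labels, p2$labels)]
        expect_equal(adjusted_rand_index(p1$assignment, a2), 1)
      }
    }
  }
})

test_that("complete-linkage merge order survives monotone transforms", {
  set.seed(14)
  for (rep in 1:10) {
    D <- rand_dissim(8)
    t1 <- agglomerate(as_dissimilarity(D), "complete")
    t2 <- agglomerate(as_dissimilarity(D^3 + 0.5 * D), "complete")
    expect_identical(t1$merge, t2$merge)
  }
})

test_that("cut_tree produces exactly k deterministic clusters", {
  set.seed(3)
  D <- rand_dissim(12)
  tr <- agglomerate(D, "ward_d2")
  for (k in 1:12)
    expect_equal(length(unique(cut_tree(tr, k)$assignment)), k)
  expect_equal(unname(cut_tree(tr, 1)$assignment), rep(1L, 12))
  expect_equal(unname(cut_tree(tr, 12)$assignment), 1:12)
  # labels assigned by first-appearing leaf: leaf 1 is always cluster 1
  for (k in 2:11) expect_equal(unname(cut_tree(tr, k)$assignment[1]), 1L)
  expect_error(cut_tree(tr, 0), "k must be")
  expect_error(cut_tree(tr, 13), "k must be")
})

test_that("planted blocks are recovered at k = 7 (strong parameters)", {
  ok <- 0L
  for (s in 1:10) {
    sim <- simulate_checklist(simulation_config(seed = 300 + s))
    am <- suppressWarnings(association_matrix(sim$dataset))
    part <- cut_tree(agglomerate(to_dissimilarity(am), "ward_d2"), 7)
    if (adjusted_rand_index(part$assignment, sim$truth$block) == 1) ok <- ok + 1L
  }
  expect_gte(ok, 9)  # full 100-seed run lives in test-acceptance.R
})

test_that("diana splits tight pairs first and handles degenerate input", {
  D <- matrix(.95, 4, 4)
  D[1, 2] <- D[2, 1] <- .05
  D[3, 4] <- D[4, 3] <- .05
  diag(D) <- 0
  tr <- diana_tree(D)
  p2 <- cut_tree(tr, 2)
  expect_equal(unname(p2$assignment), c(1L, 1L, 2L, 2L))
  # exhaustive check: {1,2}|{3,4} has the smallest maximum within diameter
  # of all 2-subset splits, so the first (largest-height) split must be it
  expect_equal(tr$height[3], .95)
  D2 <- matrix(c(0, .4, .4, 0), 2)
  tr2 <- diana_tree(D2)
  expect_equal(tr2$height, .4)
  expect_equal(tr2$merge, matrix(c(-1L, -2L), 1))
  Dz <- matrix(0, 3, 3)
  trz <- diana_tree(Dz)
  expect_equal(trz$height, c(0, 0))
})

test_that("fanny separates duplicated pairs and keeps rows stochastic", {
  D <- matrix(c(0, .05, .9, .9,
                .05, 0, .9, .9,
                .9, .9, 0, .05,
                .9, .9, .05, 0), 4)
  fz <- fanny_fuzzy(D, 2)
  expect_equal(sort(as.vector(tapply(1:4, fz$hard, paste, collapse = ","))),
               c("1,2", "3,4"))
  expect_equal(unname(rowSums(fz$u)), rep(1, 4), tolerance = 1e-9)
  # objective beats the three alternative hard 2-partitions
  hard_obj <- function(groups) {
    U <- matrix(0, 4, 2)
    U[cbind(1:4, groups)] <- 1
    fanny_objective(U, D)
  }
  alt <- c(hard_obj(c(1, 2, 1, 2)), hard_obj(c(1, 2, 2, 1)),
           hard_obj(c(1, 1, 1, 2)))
  expect_true(all(fz$objective < alt))
  expect_true(fz$dunn > 0.5)  # memberships are crisp here
})

test_that("fanny degenerate and error contracts", {
  expect_error(fanny_fuzzy(rand_dissim(5), 1), "k must be")
  expect_error(fanny_fuzzy(rand_dissim(5), 5), "k must be")
  fz <- fanny_fuzzy(matrix(0, 4, 4), 2)
  expect_equal(unname(fz$u), matrix(1 / 2, 4, 2))
  expect_equal(fz$objective, 0)
})

test_that("newick export matches the dendrogram convention and round-trips", {
  D <- matrix(c(0, .8, .8, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  s <- export_newick(agglomerate(D, "complete"))
  phy <- ape::read.tree(text = s)
  expect_setequal(phy$tip.label, c("A", "B"))
  expect_equal(unname(phy$edge.length), c(.4, .4))
  set.seed(4)
  for (rep in 1:10) {
    D <- rand_dissim(8)
    rownames(D) <- colnames(D) <- paste0("t", 1:8)
    tr <- agglomerate(as_dissimilarity(D), "average")
    phy <- ape::read.tree(text = export_newick(tr))
    expect_setequal(phy$tip.label, paste0("t", 1:8))
    orig <- ape::as.phylo(as.hclust(tr))
    expect_equal(ape::dist.topo(ape::unroot(phy), ape::unroot(orig)), 0,
                 ignore_attr = TRUE)
  }
  sim <- simulate_checklist(simulation_config(n_subjects = 80, seed = 2))
  am <- suppressWarnings(association_matrix(sim$dataset))
  phy29 <- ape::read.tree(text = export_newick(agglomerate(to_dissimilarity(am))))
  expect_equal(ape::Ntip(phy29), 29)
})

test_that("input validation rejects bad matrices", {
  expect_error(agglomerate(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(agglomerate(matrix(c(0, -1, -1, 0), 2)), "non-negative")
  expect_error(agglomerate(matrix(0, 1, 1)), "at least 2")
})
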