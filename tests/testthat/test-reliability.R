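# build an n x k matrix whose sample covariance equals S exactly
exact_cov_data <- function(S, n = 50) {
  k <- ncol(S)
  Z0 <- scale(matrix(stats::rnorm(n * k), n, k), scale = FALSE)
  Z <- Z0 %*% solve(chol(stats::cov(Z0)))
  Z %*% chol(S)
}

test_that("alpha matches the compound-symmetry closed form", {
  set.seed(51)
  for (k in 2:10) for (rho in seq(0.1, 0.9, by = 0.2)) {
    S <- matrix(rho, k, k); diag(S) <- 1
    X <- exact_cov_data(S)
    a <- cronbach_alpha(X)
    expect_equal(a$alpha, k * rho / (1 + (k - 1) * rho), tolerance = 1e-10)
  }
})

test_that("alpha equals an independent KR-20 on binary data", {
  set.seed(52)
  for (rep in 1:10) {
    X <- matrix(stats::rbinom(80, 1, runif(1, .2, .8)), 20, 4)
    if (any(apply(X, 2, stats::sd) == 0)) next
    expect_equal(cronbach_alpha(X)$alpha, kr20_oracle(X), tolerance = 1e-12)
  }
})

test_that("duplicated items give alpha = 1; degenerate cases are NA", {
  set.seed(53)
  v <- stats::rbinom(40, 1, .5)
  expect_equal(cronbach_alpha(cbind(v, v, v))$alpha, 1, tolerance = 1e-12)
  expect_warning(a <- cronbach_alpha(cbind(rep(1, 10), rep(0, 10))),
                 "variance")
  expect_true(is.na(a$alpha))
  expect_error(cronbach_alpha(cbind(v)), "at least 2")
})

test_that("pairwise and listwise deletion agree on complete data", {
  set.seed(54)
  X <- matrix(stats::rbinom(200, 1, .4), 50, 4)
  expect_equal(cronbach_alpha(X, use = "pairwise")$alpha,
               cronbach_alpha(X, use = "complete")$alpha)
  Xm <- X; Xm[1, 1] <- NA
  ap <- cronbach_alpha(Xm, use = "pairwise")
  expect_equal(ap$n_used, 49)
})

test_that("reliability_report covers every cluster, NA for singletons", {
  sim <- simulate_checklist(simulation_config(n_subjects = 100, seed = 6))
  part <- as_partition(sim$truth$block, labels = sim$truth$item_id)
  rep_ <- reliability_report(sim$dataset, part)
  expect_equal(nrow(rep_), 7)
  expect_equal(rep_$n_items, c(4, 7, 6, 3, 3, 4, 2))
  expect_true(all(is.finite(rep_$alpha)))
  # direct recomputation per cluster
  for (cl in 1:7) {
    its <- sim$truth$item_id[sim$truth$block == cl]
    expect_equal(rep_$alpha[cl], cronbach_alpha(sim$dataset, its)$alpha)
  }
})

make_flag_fixture <- function() {
  labels <- paste0("i", 1:6)
  part <- as_partition(c(1, 1, 1, 2, 2, 2), labels = labels)
  P <- outer(part$assignment, part$assignment, "==") * 0.8
  diag(P) <- 1
  # item 1: weak at home (0.04 mean), strong toward cluster 2 (0.30)
  P[1, 2] <- P[2, 1] <- 0.03
  P[1, 3] <- P[3, 1] <- 0.05
  P[1, 4] <- P[4, 1] <- P[1, 5] <- P[5, 1] <- P[1, 6] <- P[6, 1] <- 0.30
  dimnames(P) <- list(labels, labels)
  cm <- structure(list(labels = labels, p = P, B = 100L, B_effective = 100L,
                       dropped = 0L, k = 2L, method = "ward_d2", seed = 1L),
                  class = "comembership_matrix")
  list(part = part, cm = cm, labels = labels)
}

test_that("flag_outliers fires on the two-condition rule only", {
  fx <- make_flag_fixture()
  fl <- flag_outliers(fx$cm, fx$part)
  expect_equal(fl$item_id, "i1")
  expect_equal(fl$within_mean, 0.04)
  expect_equal(fl$best_other_mean, 0.30)
  # t_within = 0 never flags
  expect_equal(nrow(flag_outliers(fx$cm, fx$part, t_within = 0)), 0)
  # a clean planted simulation yields zero flags at the defaults
  sim <- simulate_checklist(simulation_config(seed = 17))
  cm <- bootstrap_comembership(sim$dataset, B = 30, seed = 17)
  part <- as_partition(sim$truth$block, labels = sim$truth$item_id)
  expect_equal(nrow(flag_outliers(cm, part)), 0)
})

test_that("integration moves on agreement, logs conflicts, keeps a partition", {
  fx <- make_flag_fixture()
  set.seed(55)
  ds <- tiny_dataset(matrix(stats::rbinom(240, 1, .5), 40, 6,
                            dimnames = list(NULL, fx$labels)))
  # agreement: loading evidence also points to cluster 2
  fl <- flag_outliers(fx$cm, fx$part)
  fl$top_factor <- 2L; fl$loading_cluster <- 2L
  fin <- integrate_clusters(fx$part, fl, ds, names = c("one", "two"))
  expect_equal(unname(fin$partition$assignment[1]), 2L)
  expect_true(fin$log$moved)
  expect_setequal(fin$partition$labels, fx$labels)
  # conflict: loading points elsewhere -> stay + log
  fl2 <- fl; fl2$loading_cluster <- 1L
  fin2 <- integrate_clusters(fx$part, fl2, ds, names = c("one", "two"))
  expect_equal(unname(fin2$partition$assignment[1]), 1L)
  expect_false(fin2$log$moved)
  expect_match(fin2$log$evidence, "expert review")
  # no flags: identity with alphas attached
  fin3 <- integrate_clusters(fx$part, fl[0, ], ds, names = c("one", "two"))
  expect_equal(fin3$partition$assignment, fx$part$assignment)
  expect_equal(nrow(fin3$log), 0)
  # final alphas equal direct recomputation on final clusters
  for (cl in 1:2) {
    its <- fin$partition$labels[fin$partition$assignment == cl]
    expect_equal(fin$table$alpha[fin$table$cluster == cl],
                 cronbach_alpha(ds, its)$alpha)
  }
  expect_error(integrate_clusters(fx$part, fl, ds, names = "only_one"),
               "name map")
  expect_error(integrate_clusters(fx$part, fl, ds,
                                  names = c("dup", "dup")), "unique")
})

test_that("default names cover the k = 7 case", {
  sim <- simulate_checklist(simulation_config(n_subjects = 80, seed = 2))
  part <- as_partition(sim$truth$block, labels = sim$truth$item_id)
  fin <- integrate_clusters(part, NULL, sim$dataset)
  expect_equal(fin$table$name[1], "Scholastic")
  expect_equal(length(unique(fin$table$name)), 7)
})
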