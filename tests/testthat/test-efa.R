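test_that("pc extraction: spectrum identities", {
  L <- extract_factors(diag(4), 2, "pc")
  expect_equal(colSums(L$L^2), c(F1 = 1, F2 = 1))
  expect_equal(unname(crossprod(L$L)), diag(2), tolerance = 1e-10)
  # 2x2 with off-diagonal 0.8: top eigenpair (1.8, (1,1)/sqrt(2))
  S <- matrix(c(1, .8, .8, 1), 2)
  L1 <- extract_factors(S, 1, "pc")
  expect_equal(unname(L1$L[, 1]), rep(sqrt(1.8 / 2), 2), tolerance = 1e-10)
  # full-rank reconstruction
  set.seed(15)
  A <- crossprod(matrix(rnorm(49), 7))
  Dh <- diag(1 / sqrt(diag(A)))
  R <- Dh %*% A %*% Dh
  Lf <- extract_factors(R, 7, "pc")
  expect_lt(max(abs(tcrossprod(Lf$L) - R)), 1e-8)
  # all n factors reproduce the unit diagonal
  expect_equal(unname(Lf$communalities), rep(1, 7), tolerance = 1e-8)
})

test_that("m beyond the positive spectrum errors", {
  ones <- matrix(1, 3, 3)  # rank 1
  expect_error(extract_factors(ones, 2, "pc"), "positive eigenvalues")
})

test_that("paf converges on block matrices with bounded communalities", {
  R <- block_cs_matrix()
  L <- extract_factors(R, 7, "paf")
  expect_true(L$converged)
  expect_true(all(L$communalities <= 1 + 1e-8))
  # sign convention: largest-|.| entry of every column is positive
  for (j in 1:7) expect_gt(L$L[which.max(abs(L$L[, j])), j], 0)
})

test_that("varimax is a fixed point on optimal input and beats a grid oracle", {
  # single-plane case: criterion at the found rotation matches a brute-force
  # 1-D search over the rotation angle
  set.seed(23)
  for (rep in 1:5) {
    L0 <- matrix(rnorm(12), 6, 2)
    lmx <- structure(list(labels = paste0("i", 1:6), L = L0, m = 2L,
                          extraction = "pc", rotation = "none",
                          communalities = rowSums(L0^2)),
                     class = "loading_matrix")
    rot <- rotate_loadings(lmx, "varimax")
    grid_best <- max(vapply(seq(0, pi / 2, by = 0.001), function(th) {
      R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
      orthomax_criterion(L0 %*% R, gamma = 1)
    }, numeric(1)))
    expect_equal(orthomax_criterion(rot$L, 1), grid_best, tolerance = 1e-6)
    # rotating the optimum again changes nothing (up to sign/permutation)
    rot2 <- rotate_loadings(rot, "varimax")
    expect_equal(orthomax_criterion(rot2$L, 1), orthomax_criterion(rot$L, 1),
                 tolerance = 1e-10)
  }
})

test_that("varimax criterion matches stats::varimax (independent oracle)", {
  set.seed(31)
  L0 <- extract_factors(block_cs_matrix(), 7, "pc")
  mine <- rotate_loadings(L0, "varimax")
  base <- stats::varimax(L0$L, normalize = FALSE, eps = 1e-10)
  expect_equal(orthomax_criterion(mine$L, 1),
               orthomax_criterion(unclass(base$loadings), 1),
               tolerance = 1e-6)
})

test_that("orthogonal rotations preserve communalities; oblique recorded", {
  L0 <- extract_factors(block_cs_matrix(), 5, "pc")
  for (ro in c("varimax", "quartimax")) {
    r <- rotate_loadings(L0, ro)
    expect_equal(r$communalities, L0$communalities, tolerance = 1e-10)
    expect_equal(r$rotation, ro)
  }
  for (ro in c("promax", "oblimin")) {
    r <- rotate_loadings(L0, ro)
    expect_true(!is.null(r$Phi))
    expect_equal(unname(diag(r$Phi)), rep(1, 5), tolerance = 1e-8)
  }
  expect_error(rotate_loadings(L0, "cluster_target"), "target")
})

test_that("noiseless block matrix: m = 7 pc + varimax recovers the support", {
  R <- block_cs_matrix(rho_within = 0.7, rho_between = 0)
  blk <- attr(R, "blocks")
  L <- rotate_loadings(extract_factors(R, 7, "pc"), "varimax")
  tab <- threshold_loadings(L, 0.35)
  # support is exactly the planted block structure (one factor per block)
  expect_equal(unname(rowSums(tab$support)), rep(1, 29))
  fac <- apply(tab$support, 1, which.max)
  expect_equal(adjusted_rand_index(fac, blk), 1)
  expect_length(tab$cross_loading, 0)
})

test_that("threshold_loadings applies a strict cutoff and finds cross-loads", {
  L <- structure(list(labels = c("a", "b"), m = 2L,
                      L = matrix(c(.36, .5, .34, .5), 2,
                                 dimnames = list(c("a", "b"), c("F1", "F2"))),
                      extraction = "pc", rotation = "none",
                      communalities = c(1, 1)),
                 class = "loading_matrix")
  tab <- threshold_loadings(L, .35)
  expect_true(tab$support["a", "F1"])
  expect_false(tab$support["a", "F2"])   # 0.34 < cutoff, strictly
  expect_equal(tab$cross_loading, "b")
  expect_warning(threshold_loadings(L, .9), "no loadings")
})
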