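# Independent oracles and fixture builders. Everything here recomputes from
# definitions (no Lance-Williams shortcuts, no shared code paths with R/).

# random symmetric dissimilarity matrix with zero diagonal
rand_dissim <- function(n, min = 0, max = 1) {
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2, min, max)
  D + t(D)
}

# from-definition agglomeration oracle: at every step, inter-cluster
# distances are recomputed from the ORIGINAL matrix (complete: max; average:
# mean over cross pairs; mcquitty: leaf-weight-halving WPGMA mean; ward:
# closed-form merge cost from cluster sums), with the same lexicographic
# (min leaf, max leaf) tie-break.
naive_agglomerate <- function(D, method) {
  n <- nrow(D)
  S <- if (method == "ward_d2") D^2 else D
  clusters <- as.list(seq_len(n))
  ids <- -seq_len(n)
  wts <- lapply(seq_len(n), function(i) 1)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  cdist <- function(A, B, wA, wB) {
    switch(method,
      complete = max(S[A, B]),
      average  = mean(S[A, B]),
      mcquitty = sum(outer(wA, wB) * S[A, B, drop = FALSE]),
      ward_d = , ward_d2 = {
        nA <- length(A); nB <- length(B)
        sAB <- sum(S[A, B]); sAA <- sum(S[A, A]) / 2; sBB <- sum(S[B, B]) / 2
        2 * (nA * nB / (nA + nB)) * (sAB / (nA * nB) - sAA / nA^2 - sBB / nB^2)
      })
  }
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- NULL; bestval <- Inf; bestkey <- c(Inf, Inf)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      v <- cdist(clusters[[i]], clusters[[j]], wts[[i]], wts[[j]])
      key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
      better <- v < bestval - 1e-12 ||
        (abs(v - bestval) <= 1e-12 &&
           (key[1] < bestkey[1] ||
              (key[1] == bestkey[1] && key[2] < bestkey[2])))
      if (better) { bestval <- v; best <- c(i, j); bestkey <- key }
    }
    i <- best[1]; j <- best[2]
    pair <- c(ids[i], ids[j])
    pair <- pair[order(pair >= 0, abs(pair))]
    merge[step, ] <- pair
    height[step] <- if (method == "ward_d2") sqrt(bestval) else bestval
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    wts[[i]] <- c(unlist(wts[[i]]) / 2, unlist(wts[[j]]) / 2)
    ids[i] <- step
    clusters[[j]] <- NULL; ids <- ids[-j]; wts[[j]] <- NULL
  }
  list(merge = merge, height = height)
}

# brute-force 2x2 pair counts with pairwise deletion
loop_pair_table <- function(x, y) {
  a <- b <- c <- d <- 0L
  for (i in seq_along(x)) {
    if (is.na(x[i]) || is.na(y[i])) next
    if (x[i] == 1 && y[i] == 1) a <- a + 1L
    else if (x[i] == 1 && y[i] == 0) b <- b + 1L
    else if (x[i] == 0 && y[i] == 1) c <- c + 1L
    else d <- d + 1L
  }
  list(a = a, b = b, c = c, d = d, n_complete = a + b + c + d)
}

# KR-20 from prevalences (n-divisor variances throughout)
kr20_oracle <- function(X) {
  k <- ncol(X); n <- nrow(X)
  p <- colMeans(X)
  score <- rowSums(X)
  var_n <- function(v) mean((v - mean(v))^2)
  (k / (k - 1)) * (1 - sum(p * (1 - p)) / var_n(score))
}

# FANNY objective, recomputed independently
fanny_objective <- function(U, D, r = 2) {
  Ur <- U^r
  sum(vapply(seq_len(ncol(U)), function(v) {
    num <- 0
    for (i in seq_len(nrow(U))) for (j in seq_len(nrow(U)))
      num <- num + Ur[i, v] * Ur[j, v] * D[i, j]
    num / (2 * sum(Ur[, v]))
  }, numeric(1)))
}

# orthomax criterion (gamma = 1 is varimax), for rotation oracles
orthomax_criterion <- function(L, gamma = 1) {
  n <- nrow(L)
  L2 <- L^2
  sum(colSums(L2^2) - (gamma / n) * colSums(L2)^2)
}

# analytic block compound-symmetry correlation matrix
block_cs_matrix <- function(block_sizes = c(4, 7, 6, 3, 3, 4, 2),
                            rho_within = 0.7, rho_between = 0) {
  blk <- rep(seq_along(block_sizes), block_sizes)
  R <- outer(blk, blk, function(a, b) ifelse(a == b, rho_within, rho_between))
  diag(R) <- 1
  dimnames(R) <- list(paste0("v", seq_along(blk)), paste0("v", seq_along(blk)))
  attr(R, "blocks") <- blk
  R
}

# small binary dataset builder
tiny_dataset <- function(mat, sections = NULL) {
  ids <- colnames(mat)
  if (is.null(ids)) ids <- paste0("it", seq_len(ncol(mat)))
  checklist_dataset(mat, items = data.frame(
    item_id = ids, label = ids,
    section = sections %||% rep(3L, ncol(mat))), )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
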