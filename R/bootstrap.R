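#' Bootstrap co-clustering stability at fixed k
#'
#' Resamples SUBJECTS with replacement (sample size = original n), recomputes
#' the phi-squared association matrix on each replicate (pairwise deletion and
#' the degenerate-margin phi2 = 0 rule apply), re-clusters the items with the
#' given linkage, cuts at fixed `k`, and records for every item pair whether
#' they share a cluster. The returned proportion matrix is the robustness
#' evidence used downstream: a high `p[i, j]` means the pair co-clusters in
#' most resampled datasets.
#'
#' A replicate is dropped (and counted) only when some item pair has zero
#' complete observations; if more than `max_drop_frac` of replicates drop, the
#' run fails with diagnostics. Per-replicate RNG substreams derive from `seed`,
#' so results are reproducible and independent of execution order.
#'
#' @param ds a [checklist_dataset()].
#' @param method linkage passed to [agglomerate()].
#' @param k fixed number of clusters (default 7).
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param max_drop_frac maximum tolerated fraction of dropped replicates.
#' @return a `comembership_matrix`: list with `labels`, `p` (symmetric,
#'   diagonal 1, entries multiples of 1/B_effective), `B`, `B_effective`,
#'   `dropped`, `k`, `method`, `seed`.
#' @export
bootstrap_comembership <- function(ds, method = "ward_d2", k = 7L, B = 1000L,
                                   seed = 1L, max_drop_frac = 0.05) {
  stopifnot(inherits(ds, "checklist_dataset"), k >= 1, B >= 1)
  X <- ds$responses
  n <- nrow(X); p <- ncol(X)
  if (k > p) stop("k exceeds item count")
  co <- matrix(0, p, p)
  dropped <- 0L
  for (b in seq_len(B)) {
    idx <- .with_seed(.substream(seed, 10L + b), {
      sample.int(n, n, replace = TRUE)
    })
    Xb <- X[idx, , drop = FALSE]
    am <- tryCatch(
      suppressWarnings(association_matrix(Xb, min_pairs = 1L,
                                          warn_degenerate = FALSE)),
      error = function(e) NULL)
    if (is.null(am)) { dropped <- dropped + 1L; next }
    part <- cut_tree(agglomerate(to_dissimilarity(am), method), k)
    same <- outer(part$assignment, part$assignment, "==")
    co <- co + same
  }
  B_eff <- B - dropped
  if (dropped > max_drop_frac * B)
    stop("bootstrap failed: ", dropped, "/", B, " replicates dropped ",
         "(item pair(s) with zero complete observations)")
  if (B_eff == 0) stop("no valid bootstrap replicates")
  pm <- co / B_eff
  diag(pm) <- 1
  dimnames(pm) <- list(colnames(X), colnames(X))
  structure(list(labels = colnames(X), p = pm, B = as.integer(B),
                 B_effective = as.integer(B_eff), dropped = dropped,
                 k = as.integer(k), method = method, seed = as.integer(seed)),
            class = "comembership_matrix")
}

#' @export
print.comembership_matrix <- function(x, ...) {
  cat("<comembership_matrix> ", length(x$labels), " items; B = ", x$B,
      " (", x$dropped, " dropped), k = ", x$k, ", method = ", x$method,
      "\n", sep = "")
  invisible(x)
}

#' Per-item co-membership summary against a partition
#'
#' For each item: the mean co-clustering proportion to the other members of
#' its own cluster, and the strongest competing cluster (maximal mean
#' proportion to another cluster's members). Items whose within mean is low
#' while a competitor is high are stability outliers — candidates for
#' reassignment review.
#'
#' @param p a `comembership_matrix`.
#' @param part a `partition` over the same items.
#' @return data.frame: `item_id`, `cluster`, `within_mean` (`NA` for a
#'   singleton cluster), `best_other`, `best_other_mean`.
#' @export
within_cluster_summary <- function(p, part) {
  stopifnot(inherits(p, "comembership_matrix"), inherits(part, "partition"))
  if (!identical(sort(p$labels), sort(part$labels)))
    stop("item sets differ between co-membership matrix and partition")
  asg <- part$assignment[match(p$labels, part$labels)]
  k <- part$k
  res <- lapply(seq_along(p$labels), function(i) {
    own <- which(asg == asg[i]); own <- setdiff(own, i)
    wm <- if (length(own)) mean(p$p[i, own]) else NA_real_
    others <- setdiff(seq_len(k), asg[i])
    om <- vapply(others, function(cl) {
      mem <- which(asg == cl)
      if (length(mem)) mean(p$p[i, mem]) else NA_real_
    }, numeric(1))
    best <- if (length(om)) which.max(om) else NA_integer_
    data.frame(item_id = p$labels[i], cluster = asg[i],
               within_mean = wm,
               best_other = if (length(om)) others[best] else NA_integer_,
               best_other_mean = if (length(om)) om[best] else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
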