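#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 = identical up to relabelling, ~0 = chance.
#'
#' @param a,b integer/character label vectors of equal length, or `partition`
#'   objects over the same items.
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (inherits(a, "partition")) a <- a$assignment
  if (inherits(b, "partition")) b <- b$assignment
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)  # both partitions trivial
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

#' Mean silhouette widths over cuts of a merge tree
#'
#' For each k in `k_range` the tree is cut and the mean silhouette width
#' computed on the item dissimilarity: \eqn{s(i) = (b_i - a_i)/\max(a_i, b_i)}
#' with \eqn{a_i} the mean dissimilarity to the item's own cluster and
#' \eqn{b_i} the smallest mean dissimilarity to another cluster; singletons
#' score 0. A diagnostic for choosing k — the pipeline never lets it override
#' a configured k, it is printed alongside.
#'
#' @param d a `dissimilarity_matrix` (or symmetric matrix).
#' @param tree a `merge_tree` over the same items.
#' @param k_range integer vector within 2..n-1.
#' @return data.frame: `k`, `mean_silhouette`, `best` (logical marking the
#'   maximizer).
#' @export
select_k_diagnostic <- function(d, tree, k_range = 2:10) {
  d <- as_dissimilarity(d)
  n <- length(d$labels)
  k_range <- as.integer(k_range)
  if (any(k_range < 2) || any(k_range > n - 1))
    stop("k_range must lie within 2..n-1")
  ms <- vapply(k_range, function(k) {
    part <- cut_tree(tree, k)
    mean(.silhouette_widths(d$d, part$assignment))
  }, numeric(1))
  data.frame(k = k_range, mean_silhouette = ms,
             best = seq_along(ms) == which.max(ms))
}

.silhouette_widths <- function(D, asg) {
  n <- length(asg)
  vapply(seq_len(n), function(i) {
    own <- which(asg == asg[i])
    if (length(own) == 1) return(0)
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(asg), asg[i]), function(cl)
      mean(D[i, asg == cl]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

#' Build a partition object from explicit labels
#'
#' @param assignment integer cluster indices (1..k), optionally named by item.
#' @param labels item ids (defaults to names of `assignment`).
#' @param k number of clusters (defaults to `max(assignment)`).
#' @return a `partition`.
#' @export
as_partition <- function(assignment, labels = NULL, k = NULL) {
  labels <- labels %||% names(assignment) %||%
    paste0("item", seq_along(assignment))
  assignment <- as.integer(assignment)
  k <- as.integer(k %||% max(assignment))
  if (any(assignment < 1 | assignment > k)) stop("assignments outside 1..k")
  if (any(tabulate(assignment, k) == 0)) stop("empty cluster in partition")
  names(assignment) <- labels
  structure(list(labels = labels, assignment = assignment, k = k),
            class = "partition")
}

#' Write a partition as two-column delimited text
#' @param part a `partition`
#' @param path output path
#' @param sep delimiter
#' @return `path` invisibly
#' @export
write_partition <- function(part, path, sep = "\t") {
  stopifnot(inherits(part, "partition"))
  utils::write.table(
    data.frame(item_id = part$labels, cluster = part$assignment),
    path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
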