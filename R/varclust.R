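#' Agglomerative clustering of items from a dissimilarity matrix
#'
#' Greedy agglomeration under a Lance--Williams update. Supported linkages:
#' `complete` (max), `average` (UPGMA, size-weighted mean), `mcquitty`
#' (WPGMA, unweighted mean of the two merged clusters' distances), `ward_d`
#' (Ward coefficients on the dissimilarities as given) and `ward_d2` (Ward on
#' squared dissimilarities, heights reported square-rooted — the conventional
#' Ward variant and the default elsewhere in the package).
#'
#' Tie-break: when several pairs share the minimal distance, the pair with the
#' lexicographically smallest (min leaf index, max leaf index) — leaves indexed
#' by input order — is merged, so results are deterministic across platforms.
#'
#' @param d a `dissimilarity_matrix` (or symmetric matrix).
#' @param method linkage name.
#' @return a `merge_tree`: list with `labels`, `merge` (n-1 x 2 matrix in
#'   hclust convention: negative entries are leaves, positive entries earlier
#'   merges), `height`, `order` (leaf display order) and `method`.
#' @export
agglomerate <- function(d, method = c("ward_d2", "ward_d", "complete",
                                      "average", "mcquitty")) {
  method <- match.arg(method)
  d <- as_dissimilarity(d)
  n <- length(d$labels)
  if (n < 2) stop("need at least 2 items")
  W <- d$d
  if (method == "ward_d2") W <- W^2
  # active cluster state: id in hclust convention, size, representative leaf
  id <- -seq_len(n); size <- rep(1L, n); rep_leaf <- seq_len(n)
  active <- rep(TRUE, n)
  W_work <- W
  diag(W_work) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  children <- vector("list", n - 1L)  # leaf sets per merge, for `order`
  leafset <- as.list(seq_len(n))
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- W_work[act, act, drop = FALSE]
    mval <- min(sub)
    cand <- which(sub == mval & upper.tri(sub), arr.ind = TRUE)
    # tie-break on (min rep, max rep) of the candidate pairs
    reps <- cbind(pmin(rep_leaf[act[cand[, 1]]], rep_leaf[act[cand[, 2]]]),
                  pmax(rep_leaf[act[cand[, 1]]], rep_leaf[act[cand[, 2]]]))
    pick <- order(reps[, 1], reps[, 2])[1]
    i <- act[min(cand[pick, ])]; j <- act[max(cand[pick, ])]
    ni <- size[i]; nj <- size[j]; dij <- W_work[i, j]
    ks <- setdiff(act, c(i, j))
    if (length(ks)) {
      dik <- W_work[i, ks]; djk <- W_work[j, ks]
      newd <- switch(method,
        complete = pmax(dik, djk),
        average  = (ni * dik + nj * djk) / (ni + nj),
        mcquitty = (dik + djk) / 2,
        ward_d   = ,
        ward_d2  = {
          nk <- size[ks]
          ((ni + nk) * dik + (nj + nk) * djk - nk * dij) / (ni + nj + nk)
        })
      W_work[i, ks] <- newd; W_work[ks, i] <- newd
    }
    active[j] <- FALSE
    W_work[j, ] <- Inf; W_work[, j] <- Inf
    mi <- id[i]; mj <- id[j]
    # hclust convention: leaves (negative) before merges, both ascending
    pair <- c(mi, mj)
    pair <- pair[order(pair >= 0, abs(pair))]
    merge[step, ] <- pair
    height[step] <- if (method == "ward_d2") sqrt(dij) else dij
    children[[step]] <- list(leafset[[i]], leafset[[j]])
    leafset[[i]] <- c(leafset[[i]], leafset[[j]])
    id[i] <- step
    size[i] <- ni + nj
    rep_leaf[i] <- min(rep_leaf[i], rep_leaf[j])
  }
  structure(list(labels = d$labels, merge = merge, height = height,
                 order = .tree_order(merge, n), method = method),
            class = "merge_tree")
}

# leaf display order by recursive traversal of the merge matrix
.tree_order <- function(merge, n) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(nrow(merge))
}

#' @export
print.merge_tree <- function(x, ...) {
  cat("<merge_tree> ", length(x$labels), " items, method = ", x$method,
      ", heights [", format(min(x$height), digits = 3), ", ",
      format(max(x$height), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Convert a merge tree to a base-R hclust object
#' @param x a `merge_tree`
#' @param ... unused
#' @return an `hclust` object
#' @export
as.hclust.merge_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = "1 - phi2"),
            class = "hclust")
}

#' Divisive (DIANA-style) hierarchical clustering of items
#'
#' Kaufman--Rousseeuw divisive analysis: starting from one all-item cluster,
#' repeatedly split the cluster with the largest diameter. A split seeds a
#' splinter group with the object of maximal average dissimilarity to the rest,
#' then iteratively moves the object whose average dissimilarity to the
#' splinter group is most below its average dissimilarity to the remainder,
#' until no object prefers the splinter. Node heights are cluster diameters.
#'
#' @param d a `dissimilarity_matrix` (or symmetric matrix).
#' @return a `merge_tree` with `method = "diana"`.
#' @export
diana_tree <- function(d) {
  d <- as_dissimilarity(d)
  D <- d$d
  n <- length(d$labels)
  if (n < 2) stop("need at least 2 items")
  nodes <- list()  # each: list(members, left, right, height)
  split_cluster <- function(S) {
    # returns list(A, B): the binary split of index set S (|S| >= 2)
    if (length(S) == 2) return(list(S[1], S[2]))
    sub <- D[S, S, drop = FALSE]
    avg_all <- rowSums(sub) / (length(S) - 1)
    seed <- S[which.max(avg_all)]           # ties: first index wins
    splinter <- seed
    remainder <- setdiff(S, seed)
    repeat {
      if (length(remainder) <= 1) break
      a <- vapply(remainder, function(i)
        mean(D[i, setdiff(remainder, i)]), numeric(1))
      b <- vapply(remainder, function(i)
        mean(D[i, splinter]), numeric(1))
      diff <- a - b
      best <- which.max(diff)
      if (diff[best] <= 0) break
      splinter <- c(splinter, remainder[best])
      remainder <- remainder[-best]
    }
    list(sort(splinter), sort(remainder))
  }
  build <- function(S) {
    # recursively split S, appending internal nodes; returns nothing
    if (length(S) < 2) return(invisible())
    halves <- split_cluster(S)
    diam <- max(D[S, S])
    nodes[[length(nodes) + 1L]] <<- list(members = sort(S),
                                         left = halves[[1]],
                                         right = halves[[2]],
                                         height = diam)
    build(halves[[1]]); build(halves[[2]])
  }
  build(seq_len(n))
  # assemble hclust-style merge matrix: ascending height, children before
  # parents (smaller sets first on ties)
  ord <- order(vapply(nodes, `[[`, numeric(1), "height"),
               vapply(nodes, function(nd) length(nd$members), integer(1)),
               vapply(nodes, function(nd) min(nd$members), integer(1)))
  nodes <- nodes[ord]
  key <- function(s) paste(s, collapse = ",")
  row_of <- new.env(parent = emptyenv())
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (r in seq_along(nodes)) {
    nd <- nodes[[r]]
    enc <- function(s) {
      if (length(s) == 1) return(-s)
      get(key(s), envir = row_of)
    }
    pair <- c(enc(nd$left), enc(nd$right))
    pair <- pair[order(pair >= 0, abs(pair))]
    merge[r, ] <- pair
    height[r] <- nd$height
    assign(key(nd$members), r, envir = row_of)
  }
  structure(list(labels = d$labels, merge = merge, height = height,
                 order = .tree_order(merge, n), method = "diana"),
            class = "merge_tree")
}

#' Fuzzy clustering (FANNY-style) of items
#'
#' Minimizes the fuzzy objective
#' \deqn{\sum_v \frac{\sum_{i,j} u_{iv}^r u_{jv}^r d(i,j)}{2 \sum_j u_{jv}^r}}
#' over row-stochastic memberships `u` by iterative membership updates
#' (Kaufman--Rousseeuw). Returns graded memberships rather than a hard
#' partition; `harden = apply(u, 1, which.max)` recovers one.
#'
#' @param d a `dissimilarity_matrix` (or symmetric matrix).
#' @param k number of clusters, 2..n-1.
#' @param r membership exponent (> 1, default 2; memberships approach uniform
#'   as r grows).
#' @param tol objective-change convergence tolerance.
#' @param max_iter maximum update sweeps; non-convergence flags the result
#'   rather than erroring.
#' @return a `fuzzy_membership`: list with `labels`, `u` (item x cluster,
#'   rows sum to 1), `objective`, `dunn` (normalized Dunn partition
#'   coefficient), `converged`, `iterations`, `hard` (argmax assignment).
#' @export
fanny_fuzzy <- function(d, k, r = 2, tol = 1e-9, max_iter = 500L) {
  d <- as_dissimilarity(d)
  D <- d$d
  n <- length(d$labels)
  if (k < 2 || k > n - 1) stop("k must be in 2..n-1, got ", k)
  if (r <= 1) stop("membership exponent r must exceed 1")
  objective <- function(U) {
    Ur <- U^r
    num <- colSums(Ur * (D %*% Ur))
    den <- colSums(Ur)
    sum(ifelse(den > 0, num / (2 * den), 0))
  }
  if (max(D) == 0) {
    U <- matrix(1 / k, n, k, dimnames = list(d$labels, NULL))
    return(structure(list(labels = d$labels, u = U, objective = 0,
                          dunn = 0, converged = TRUE, iterations = 0L,
                          hard = rep(1L, n)),
                     class = "fuzzy_membership"))
  }
  # deterministic warm start from an average-linkage hard cut
  hard0 <- cut_tree(agglomerate(d, "average"), k)$assignment
  U <- matrix(0.1 / (k - 1), n, k)
  U[cbind(seq_len(n), hard0)] <- 0.9
  obj <- objective(U)
  converged <- FALSE
  it <- 0L
  expo <- 1 / (r - 1)
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      Ur <- U^r
      den <- colSums(Ur)
      num <- colSums(Ur * (D %*% Ur))
      a <- as.numeric(D[i, ] %*% Ur) / den - num / (2 * den^2)
      if (all(a <= 1e-15)) next
      a <- pmax(a, 1e-15)
      w <- (1 / a)^expo
      U[i, ] <- w / sum(w)
    }
    new_obj <- objective(U)
    if (abs(obj - new_obj) < tol) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  dunn_raw <- sum(U^2) / n
  rownames(U) <- d$labels
  structure(list(labels = d$labels, u = U, objective = obj,
                 dunn = (dunn_raw - 1 / k) / (1 - 1 / k),
                 converged = converged, iterations = it,
                 hard = apply(U, 1, which.max)),
            class = "fuzzy_membership")
}

#' Cut a merge tree into a flat k-cluster partition
#'
#' Undoes the last k-1 merges. Cluster indices are assigned by order of the
#' first-appearing leaf in the input ordering, so partitions are comparable
#' across runs and methods.
#'
#' @param tree a `merge_tree`.
#' @param k number of clusters, 1..n.
#' @return a `partition`: list with `labels`, `assignment` (integer 1..k per
#'   item) and `k`.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "merge_tree"))
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must be in 1..", n, ", got ", k)
  grp <- -seq_len(n)  # start: each leaf its own group keyed by merge id
  if (n - k >= 1) {
    node_members <- vector("list", n - k)
    assign_grp <- seq_len(n)
    for (s in seq_len(n - k)) {
      kids <- tree$merge[s, ]
      mem <- unlist(lapply(kids, function(x)
        if (x < 0) -x else node_members[[x]]))
      node_members[[s]] <- mem
      assign_grp[mem] <- n + s
    }
  } else assign_grp <- seq_len(n)
  # relabel clusters 1..k by first-appearing leaf
  first_seen <- unique(assign_grp)
  assignment <- match(assign_grp, first_seen)
  names(assignment) <- tree$labels
  structure(list(labels = tree$labels, assignment = assignment, k = as.integer(k)),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("<partition> k = ", x$k, "; sizes: ",
      paste(tabulate(x$assignment, x$k), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Export a merge tree as a Newick string
#'
#' Branch lengths follow the dendrogram convention (leaf depth = merge height
#' / 2), so a two-leaf tree merged at height h renders as `(A:h/2,B:h/2);`.
#'
#' @param tree a `merge_tree`.
#' @param path optional file to write to.
#' @return the Newick string (invisibly if `path` given).
#' @export
export_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "merge_tree"))
  phy <- ape::as.phylo(as.hclust.merge_tree(tree))
  s <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
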