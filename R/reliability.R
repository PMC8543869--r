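#' Cronbach's alpha for a set of items
#'
#' \eqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i var(x_i)}{var(\sum_i x_i)}\right)}
#' computed from the item covariance matrix. For dichotomous items this is
#' exactly KR-20. With missing data the covariance matrix is assembled from
#' pairwise-complete observations by default (mirroring the pairwise-deletion
#' philosophy of the association step); `use = "complete"` switches to
#' listwise deletion.
#'
#' @param ds a [checklist_dataset()] or numeric matrix (subjects x items).
#' @param items item ids (or column indices) to score; default all.
#' @param use `"pairwise"` (default) or `"complete"`.
#' @return list with `alpha` (NA if the total-score variance is zero or the
#'   item count < 2 — with a warning), `n_items`, `n_used` (minimum pairwise n,
#'   or the listwise n).
#' @export
cronbach_alpha <- function(ds, items = NULL, use = c("pairwise", "complete")) {
  use <- match.arg(use)
  X <- if (inherits(ds, "checklist_dataset")) ds$responses else as.matrix(ds)
  if (!is.null(items)) {
    j <- if (is.character(items)) match(items, colnames(X)) else items
    if (anyNA(j)) stop("unknown item(s): ",
                       paste(items[is.na(j)], collapse = ", "))
    X <- X[, j, drop = FALSE]
  }
  k <- ncol(X)
  if (k < 2) stop("alpha requires at least 2 items")
  storage.mode(X) <- "double"
  if (use == "pairwise") {
    S <- stats::cov(X, use = "pairwise.complete.obs")
    O <- (!is.na(X)) * 1
    n_used <- min(crossprod(O))
  } else {
    cc <- stats::complete.cases(X)
    if (sum(cc) < 2) stop("fewer than 2 complete cases")
    S <- stats::cov(X[cc, , drop = FALSE])
    n_used <- sum(cc)
  }
  tot <- sum(S)
  if (!is.finite(tot) || tot <= 0) {
    warning("total-score variance is zero or undefined; alpha is NA")
    return(list(alpha = NA_real_, n_items = k, n_used = n_used))
  }
  list(alpha = k / (k - 1) * (1 - sum(diag(S)) / tot),
       n_items = k, n_used = n_used)
}

#' Reliability report over the clusters of a partition
#'
#' @param ds a [checklist_dataset()].
#' @param part a `partition` over the dataset's items.
#' @param use passed to [cronbach_alpha()].
#' @return data.frame: `cluster`, `n_items`, `items` (semicolon-joined),
#'   `alpha` (NA for singleton clusters), `n_used`.
#' @export
reliability_report <- function(ds, part, use = "pairwise") {
  stopifnot(inherits(part, "partition"))
  rows <- lapply(seq_len(part$k), function(cl) {
    its <- part$labels[part$assignment == cl]
    if (length(its) >= 2) {
      a <- cronbach_alpha(ds, its, use = use)
      data.frame(cluster = cl, n_items = length(its),
                 items = paste(its, collapse = ";"),
                 alpha = a$alpha, n_used = a$n_used,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cluster = cl, n_items = length(its),
                 items = paste(its, collapse = ";"),
                 alpha = NA_real_, n_used = NA_integer_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

# factor -> cluster correspondence implied by a Procrustes alignment:
# factor f maps to the cluster with the largest |T[c, f]|.
.aligned_cluster <- function(alignment, factor_idx) {
  which.max(abs(alignment$T[, factor_idx]))
}

#' Flag items whose bootstrap evidence contradicts their cluster
#'
#' An item is flagged when its mean co-clustering proportion with its own
#' cluster is below `t_within` AND some other cluster attracts it at least
#' `r_ratio` times as strongly. The evidence record carries the item's
#' maximal-|loading| factor and, when an alignment is supplied, the cluster
#' that factor aligns to — the inputs of the integration rule.
#'
#' @param p a `comembership_matrix`.
#' @param part a `partition`.
#' @param L a `loading_matrix` (optional but needed for loading evidence).
#' @param alignment a `congruence_result` from [match_score()] (optional).
#' @param t_within within-cluster mean threshold (default 0.10).
#' @param r_ratio competing-cluster ratio (default 2).
#' @return data.frame of flagged items with columns `item_id`, `cluster`,
#'   `within_mean`, `best_other`, `best_other_mean`, `top_factor`,
#'   `loading_cluster` (NA without an alignment); zero rows when nothing
#'   is flagged.
#' @export
flag_outliers <- function(p, part, L = NULL, alignment = NULL,
                          t_within = 0.10, r_ratio = 2.0) {
  summ <- within_cluster_summary(p, part)
  flagged <- !is.na(summ$within_mean) &
    summ$within_mean < t_within &
    !is.na(summ$best_other_mean) &
    summ$best_other_mean >= r_ratio * summ$within_mean
  out <- summ[flagged, , drop = FALSE]
  out$top_factor <- rep(NA_integer_, nrow(out))
  out$loading_cluster <- rep(NA_integer_, nrow(out))
  if (!is.null(L) && nrow(out)) {
    for (r in seq_len(nrow(out))) {
      i <- match(out$item_id[r], L$labels)
      f <- which.max(abs(L$L[i, ]))
      out$top_factor[r] <- f
      if (!is.null(alignment))
        out$loading_cluster[r] <- .aligned_cluster(alignment, f)
    }
  }
  rownames(out) <- NULL
  out
}

#' Integrate clustering, bootstrap and factor evidence into a final table
#'
#' Encodes the integration rule: a flagged item is moved to the cluster its
#' strongest factor aligns with ONLY IF the same cluster also carries its
#' highest cross-cluster co-membership; when the two evidence sources point to
#' different clusters the item stays put and the conflict is logged for expert
#' review — the rule surfaces disagreement, it never adjudicates it. Alphas
#' are recomputed on the final clusters.
#'
#' @param part the input `partition`.
#' @param flags output of [flag_outliers()].
#' @param ds the [checklist_dataset()] (for recomputing alphas).
#' @param names optional character vector of cluster names (length k). When
#'   k = 7 and no names are given, the conventional seven labels of the
#'   checklist's natural clusters are used; otherwise `cluster_1..k`.
#' @param use alpha deletion mode, passed on.
#' @return a `final_cluster_table`: list with `table` (data.frame: name,
#'   cluster, n_items, items, alpha), `partition` (the final `partition`),
#'   `log` (data.frame of reassignments and conflicts).
#' @export
integrate_clusters <- function(part, flags, ds, names = NULL,
                               use = "pairwise") {
  stopifnot(inherits(part, "partition"))
  k <- part$k
  if (!is.null(names)) names <- as.character(unlist(names))
  if (is.null(names) || length(names) == 0) {
    names <- if (k == 7)
      c("Scholastic", "Neuropsychological", "ASD-like",
        "Dysregulated behaviour", "Overactive/Impulsive", "Mood/Anxiety",
        "Eat/Sleep")
    else paste0("cluster_", seq_len(k))
  }
  if (length(names) < k || anyNA(names))
    stop("name map must cover all ", k, " clusters")
  if (anyDuplicated(names)) stop("cluster names must be unique")
  asg <- part$assignment
  log <- data.frame(item = character(0), from = integer(0), to = integer(0),
                    moved = logical(0), evidence = character(0),
                    stringsAsFactors = FALSE)
  if (!is.null(flags) && nrow(flags)) {
    for (r in seq_len(nrow(flags))) {
      it <- flags$item_id[r]
      i <- match(it, part$labels)
      from <- asg[i]
      load_to <- flags$loading_cluster[r]
      boot_to <- flags$best_other[r]
      if (!is.na(load_to) && !is.na(boot_to) && load_to == boot_to &&
          load_to != from) {
        asg[i] <- load_to
        log <- rbind(log, data.frame(
          item = it, from = from, to = load_to, moved = TRUE,
          evidence = sprintf(
            "loading factor %d and co-membership both favour cluster %d (within %.3f, other %.3f)",
            flags$top_factor[r], load_to, flags$within_mean[r],
            flags$best_other_mean[r]),
          stringsAsFactors = FALSE))
      } else {
        log <- rbind(log, data.frame(
          item = it, from = from, to = from, moved = FALSE,
          evidence = sprintf(
            "conflicting evidence (loading -> %s, co-membership -> %s); retained for expert review",
            ifelse(is.na(load_to), "?", load_to),
            ifelse(is.na(boot_to), "?", boot_to)),
          stringsAsFactors = FALSE))
      }
    }
  }
  final_part <- structure(list(labels = part$labels, assignment = asg, k = k),
                          class = "partition")
  rel <- reliability_report(ds, final_part, use = use)
  tab <- data.frame(name = names[rel$cluster], rel,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, partition = final_part, log = log),
            class = "final_cluster_table")
}

#' @export
print.final_cluster_table <- function(x, ...) {
  cat("<final_cluster_table> ", nrow(x$table), " clusters, ",
      sum(x$table$n_items), " items; ", sum(x$log$moved),
      " item(s) reassigned, ", sum(!x$log$moved), " conflict(s) logged\n",
      sep = "")
  print(x$table[, c("name", "n_items", "alpha")], digits = 3)
  invisible(x)
}
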