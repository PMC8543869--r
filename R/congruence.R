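#' Tucker congruence coefficient between two loading columns
#'
#' \eqn{\sum_i x_i y_i / \sqrt{\sum_i x_i^2 \sum_i y_i^2}} — a cosine-type
#' similarity; 1 means proportional vectors.
#'
#' @param x,y numeric vectors of equal length, both non-zero.
#' @return value in \[-1, 1\].
#' @export
tucker <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0) stop("tucker congruence undefined for a zero vector")
  sum(x * y) / sqrt(sx * sy)
}

#' Cluster indicator matrix from a partition
#'
#' Column j is the 0/1 membership indicator of cluster j; optionally each
#' column is normalized to unit length so cluster size does not inflate
#' congruence values.
#'
#' @param part a `partition`.
#' @param normalize divide each column by its Euclidean norm.
#' @return item x k matrix.
#' @export
indicator_matrix <- function(part, normalize = TRUE) {
  stopifnot(inherits(part, "partition"))
  k <- part$k
  sizes <- tabulate(part$assignment, k)
  if (any(sizes == 0)) stop("empty cluster in partition")
  M <- matrix(0, length(part$labels), k,
              dimnames = list(part$labels, paste0("C", seq_len(k))))
  M[cbind(seq_along(part$assignment), part$assignment)] <- 1
  if (normalize) M <- sweep(M, 2, sqrt(sizes), "/")
  M
}

#' Orthogonal Procrustes alignment of a congruence matrix
#'
#' Pads the factor x cluster congruence matrix `C` with zero rows or columns
#' to a square matrix (whenever the factor and cluster counts differ), then
#' finds the orthogonal `T` maximizing `trace(T C)` via the singular value
#' decomposition (`T = V U'` for `C = U S V'`). The optimal diagonal sum equals
#' the sum of singular values of the padded matrix. Reflections are allowed
#' (no determinant constraint), which absorbs factor sign indeterminacy.
#'
#' @param C numeric matrix (factors x clusters).
#' @return a `congruence_result`: list with `C_raw` (padded input), `T`,
#'   `C_aligned = T %*% C`, `diag_sum`, `padding` (zero rows/cols added).
#' @export
procrustes_align <- function(C) {
  C <- as.matrix(C)
  f <- nrow(C); k <- ncol(C)
  s <- max(f, k)
  pad <- 2L * s - f - k
  Cp <- matrix(0, s, s)
  Cp[seq_len(f), seq_len(k)] <- C
  if (all(Cp == 0)) {
    return(structure(list(C_raw = Cp, T = diag(s), C_aligned = Cp,
                          diag_sum = 0, padding = pad),
                     class = "congruence_result"))
  }
  sv <- svd(Cp)
  Tm <- sv$v %*% t(sv$u)
  Ca <- Tm %*% Cp
  structure(list(C_raw = Cp, T = Tm, C_aligned = Ca,
                 diag_sum = sum(diag(Ca)), padding = pad),
            class = "congruence_result")
}

#' @export
print.congruence_result <- function(x, ...) {
  cat("<congruence_result> ", nrow(x$C_raw), "x", ncol(x$C_raw),
      " (", x$padding, " zero-padded); aligned diagonal sum = ",
      format(x$diag_sum, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Congruence of a factor solution with a cluster solution
#'
#' Builds the column-normalized indicator matrix of the partition, computes
#' the Tucker congruence of every (factor, cluster) column pair, and
#' Procrustes-aligns the resulting congruence matrix. The aligned diagonal sum
#' (at most k, the cluster count) is the match score used to rank candidate
#' factor solutions.
#'
#' @param lm_ a `loading_matrix`.
#' @param part a `partition` over the same items.
#' @return a `congruence_result`.
#' @export
match_score <- function(lm_, part) {
  stopifnot(inherits(lm_, "loading_matrix"), inherits(part, "partition"))
  if (!identical(sort(lm_$labels), sort(part$labels)))
    stop("item sets differ between loadings and partition")
  Ind <- indicator_matrix(part, normalize = TRUE)
  Ind <- Ind[match(lm_$labels, rownames(Ind)), , drop = FALSE]
  L <- lm_$L
  nl <- sqrt(colSums(L^2))
  # a zero loading column (it arises from zero-padding when factors < clusters)
  # carries zero congruence with every cluster rather than being an error
  C <- crossprod(sweep(L, 2, ifelse(nl > 0, nl, 1), "/"), Ind)
  C[nl == 0, ] <- 0
  procrustes_align(C)
}

#' Grid search over factor solutions for the best cluster match
#'
#' Evaluates [match_score()] for every (extraction, rotation, m) combination
#' and ranks the results by aligned diagonal sum, descending; ties break by
#' lexical (extraction, rotation, m) order so the ranking is deterministic.
#' Failing combinations are recorded with an `NA` score and the search
#' continues. Duplicate combinations are deduplicated.
#'
#' @param m_assoc an `association_matrix`.
#' @param part a `partition` of the same items.
#' @param m_range factor counts to try (default 4:7).
#' @param extractions extraction methods (default `c("pc", "paf")`).
#' @param rotations rotation names (default all supported).
#' @return a `congruence_grid`: list with `results` (ranked data.frame:
#'   extraction, rotation, m, diag_sum, error), `winner` (the best
#'   `loading_matrix`), `winner_score` (its `congruence_result`).
#' @export
grid_search <- function(m_assoc, part, m_range = 4:7,
                        extractions = c("pc", "paf"),
                        rotations = c("none", "varimax", "quartimax",
                                      "promax", "oblimin", "cluster_target")) {
  stopifnot(length(m_range) > 0, length(extractions) > 0, length(rotations) > 0)
  grid <- unique(expand.grid(extraction = extractions, rotation = rotations,
                             m = as.integer(m_range),
                             stringsAsFactors = FALSE))
  res <- vector("list", nrow(grid))
  fits <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    ex <- grid$extraction[g]; ro <- grid$rotation[g]; m <- grid$m[g]
    out <- tryCatch({
      L <- extract_factors(m_assoc, m, ex)
      L <- rotate_loadings(L, ro, target = if (ro == "cluster_target") part)
      sc <- match_score(L, part)
      list(diag_sum = sc$diag_sum, fit = list(loadings = L, score = sc),
           error = NA_character_)
    }, error = function(e) list(diag_sum = NA_real_, fit = NULL,
                                error = conditionMessage(e)))
    res[[g]] <- data.frame(extraction = ex, rotation = ro, m = m,
                           diag_sum = out$diag_sum, error = out$error,
                           stringsAsFactors = FALSE)
    fits[[g]] <- out$fit
  }
  results <- do.call(rbind, res)
  ord <- order(-ifelse(is.na(results$diag_sum), -Inf, results$diag_sum),
               results$extraction, results$rotation, results$m)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  best <- fits[[ord[1]]]
  structure(list(results = results,
                 winner = best$loadings, winner_score = best$score),
            class = "congruence_grid")
}

#' @export
print.congruence_grid <- function(x, ...) {
  cat("<congruence_grid> ", nrow(x$results), " combinations; best: ",
      x$results$extraction[1], " / ", x$results$rotation[1], " / m = ",
      x$results$m[1], " (diag_sum = ",
      format(x$results$diag_sum[1], digits = 5), ")\n", sep = "")
  invisible(x)
}
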