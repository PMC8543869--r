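#' 2x2 cross-classification of two binary vectors with pairwise deletion
#'
#' Counts are computed only over positions where both values are observed —
#' the pairwise-deletion rule used throughout the pipeline.
#'
#' @param x,y binary vectors (0/1/`NA`) of equal length.
#' @return a `pair_table` list with counts `a` (1,1), `b` (1,0), `c` (0,1),
#'   `d` (0,0) and `n_complete = a+b+c+d`.
#' @export
pair_table <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  c <- sum(x == 0 & y == 1)
  d <- sum(x == 0 & y == 0)
  structure(list(a = a, b = b, c = c, d = d, n_complete = a + b + c + d),
            class = "pair_table")
}

#' Mean squared contingency coefficient of a 2x2 table
#'
#' \eqn{\phi^2 = (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}, the Pearson
#' \eqn{\chi^2} statistic of the table divided by `n_complete`. Ranges 0..1 for
#' 2x2 tables, so `1 - phi2` is a valid dissimilarity. If any margin is zero
#' (an item constant within the complete pairs) the coefficient is defined as 0
#' with a warning: a constant item carries no association evidence. This
#' degenerate rule matters for bootstrap replicates, where resampling can
#' flatten an item.
#'
#' @param t a [pair_table()] (or a list with fields a, b, c, d).
#' @param warn_degenerate warn when a margin is zero.
#' @return phi-squared value in \[0, 1\].
#' @export
phi2 <- function(t, warn_degenerate = TRUE) {
  a <- as.numeric(t$a); b <- as.numeric(t$b)
  c <- as.numeric(t$c); d <- as.numeric(t$d)
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  if (den == 0) {
    if (warn_degenerate)
      warning("degenerate 2x2 margins (constant item); phi2 defined as 0")
    return(0)
  }
  (a * d - b * c)^2 / den
}

#' Phi-squared association matrix over all item pairs
#'
#' Computes the symmetric item-by-item matrix of mean squared contingency
#' coefficients with pairwise deletion, plus the complete-pair count behind
#' each entry. Internally uses cross-product identities over the observedness
#' mask, which reproduces [pair_table()] + [phi2()] entry by entry.
#'
#' @param ds a [checklist_dataset()], or a 0/1/`NA` matrix.
#' @param min_pairs minimum complete pairs required per item pair (default 2);
#'   a pair below the threshold is an error naming the pair.
#' @param warn_degenerate warn on zero-margin (constant-item) pairs.
#' @return an `association_matrix`: list with `labels`, `phi2` (symmetric,
#'   unit diagonal, entries in \[0,1\]) and `n_pairs` (complete-pair counts).
#' @export
association_matrix <- function(ds, min_pairs = 2L, warn_degenerate = TRUE) {
  X <- if (inherits(ds, "checklist_dataset")) ds$responses else as.matrix(ds)
  if (ncol(X) < 2) stop("need at least 2 items")
  labels <- colnames(X) %||% paste0("item", seq_len(ncol(X)))
  O <- !is.na(X)
  X0 <- X; X0[!O] <- 0L
  storage.mode(X0) <- "double"; storage.mode(O) <- "double"
  a  <- crossprod(X0)            # both 1
  n  <- crossprod(O)             # complete pairs
  r1 <- crossprod(X0, O)         # i = 1, j observed  (a + b)
  b <- r1 - a
  c <- t(r1) - a                 # j = 1, i observed minus a
  d <- n - a - b - c
  low <- which(n < min_pairs & upper.tri(n), arr.ind = TRUE)
  if (nrow(low))
    stop("item pair (", labels[low[1, 1]], ", ", labels[low[1, 2]],
         ") has only ", n[low[1, , drop = FALSE]],
         " complete observations (< min_pairs = ", min_pairs, ")")
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  ph <- matrix(0, ncol(X), ncol(X))
  pos <- den > 0
  ph[pos] <- ((a * d - b * c)^2 / den)[pos]
  deg <- !pos & upper.tri(pos)
  if (any(deg) && warn_degenerate)
    warning(sum(deg), " item pair(s) with degenerate margins; phi2 set to 0")
  ph <- (ph + t(ph)) / 2         # enforce exact symmetry against fp noise
  diag(ph) <- 1
  dimnames(ph) <- dimnames(n) <- list(labels, labels)
  structure(list(labels = labels, phi2 = ph, n_pairs = n),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("<association_matrix> ", length(x$labels), " items; off-diagonal phi2 in [",
      format(min(x$phi2[upper.tri(x$phi2)]), digits = 3), ", ",
      format(max(x$phi2[upper.tri(x$phi2)]), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Dissimilarity derived from a phi-squared association matrix
#'
#' `d = 1 - phi2` elementwise (zero diagonal). The transform is monotone, so
#' hierarchical merge order is unaffected by the choice against alternatives
#' such as `sqrt(1 - phi2)`, which is offered for sensitivity checks.
#'
#' @param m an `association_matrix`.
#' @param form `"one_minus"` (default) or `"sqrt_one_minus"`.
#' @return a `dissimilarity_matrix`: list with `labels` and symmetric `d`
#'   with zero diagonal, entries in \[0, 1\].
#' @export
to_dissimilarity <- function(m, form = c("one_minus", "sqrt_one_minus")) {
  stopifnot(inherits(m, "association_matrix"))
  form <- match.arg(form)
  d <- 1 - m$phi2
  if (form == "sqrt_one_minus") d <- sqrt(pmax(d, 0))
  diag(d) <- 0
  structure(list(labels = m$labels, d = d, form = form),
            class = "dissimilarity_matrix")
}

# Coerce a plain symmetric matrix into the dissimilarity container (validated).
as_dissimilarity <- function(d, labels = NULL) {
  if (inherits(d, "dissimilarity_matrix")) return(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12)
    stop("dissimilarity must be a symmetric square matrix")
  if (any(d < 0)) stop("dissimilarity entries must be non-negative")
  labels <- labels %||% rownames(d) %||% paste0("item", seq_len(nrow(d)))
  dimnames(d) <- list(labels, labels)
  diag(d) <- 0
  structure(list(labels = labels, d = d, form = "as_is"),
            class = "dissimilarity_matrix")
}
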