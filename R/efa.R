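#' Factor extraction from an association matrix
#'
#' Runs on the phi-squared matrix exactly as the pipeline's analysis step
#' specifies. Note this input is a *similarity* (entries in 0..1), not a
#' signed Pearson correlation matrix; loadings are interpreted accordingly and
#' the extraction records the fact in the object.
#'
#' `pc`: eigendecomposition; loading column j is eigenvector j scaled by
#' sqrt(eigenvalue j). `paf`: principal axis factoring — the diagonal is
#' replaced by communalities and the reduced matrix re-decomposed until the
#' largest communality change is below `tol` (or `max_iter`).
#'
#' Sign convention: every loading column is flipped so its largest-magnitude
#' entry is positive, making results deterministic across eigensolvers.
#'
#' @param m_assoc an `association_matrix` (or symmetric matrix with unit
#'   diagonal).
#' @param m number of factors.
#' @param extraction `"pc"` or `"paf"`.
#' @param tol,max_iter `paf` convergence controls.
#' @return a `loading_matrix`: list with `labels`, `L` (items x m), `m`,
#'   `extraction`, `rotation` (`"none"`), `communalities`, and for `paf`
#'   `converged`/`iterations`.
#' @export
extract_factors <- function(m_assoc, m, extraction = c("pc", "paf"),
                            tol = 1e-6, max_iter = 200L) {
  extraction <- match.arg(extraction)
  S <- if (inherits(m_assoc, "association_matrix")) m_assoc$phi2 else as.matrix(m_assoc)
  labels <- rownames(S) %||% paste0("item", seq_len(nrow(S)))
  n <- nrow(S)
  if (m < 1 || m > n) stop("m must be in 1..", n)
  converged <- TRUE; iters <- 0L
  if (extraction == "pc") {
    eg <- eigen(S, symmetric = TRUE)
    if (sum(eg$values > 1e-12) < m)
      stop("m = ", m, " exceeds the number of positive eigenvalues (",
           sum(eg$values > 1e-12), ")")
    L <- eg$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(eg$values[seq_len(m)], 0)), m)
  } else {
    h2 <- apply(abs(S - diag(diag(S))), 1, max)  # initial communalities
    Sr <- S
    for (iters in seq_len(max_iter)) {
      diag(Sr) <- h2
      eg <- eigen(Sr, symmetric = TRUE)
      L <- eg$vectors[, seq_len(m), drop = FALSE] %*%
        diag(sqrt(pmax(eg$values[seq_len(m)], 0)), m)
      h2_new <- rowSums(L^2)
      delta <- max(abs(h2_new - h2))
      h2 <- h2_new
      if (delta < tol) break
    }
    converged <- delta < tol
  }
  L <- .fix_signs(L)
  dimnames(L) <- list(labels, paste0("F", seq_len(m)))
  structure(list(labels = labels, L = L, m = as.integer(m),
                 extraction = extraction, rotation = "none",
                 communalities = rowSums(L^2),
                 converged = converged, iterations = iters),
            class = "loading_matrix")
}

# flip each column so its largest-|.| entry is positive
.fix_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' @export
print.loading_matrix <- function(x, ...) {
  cat("<loading_matrix> ", length(x$labels), " items x ", ncol(x$L),
      " factors; extraction = ", x$extraction, ", rotation = ", x$rotation,
      "\n", sep = "")
  invisible(x)
}

# orthomax criterion (gamma = 1 varimax, 0 quartimax), to be maximized
.orthomax_crit <- function(L, gamma) {
  n <- nrow(L)
  L2 <- L^2
  sum(colSums(L2^2) - (gamma / n) * colSums(L2)^2)
}

# pairwise plane rotations to an orthomax stationary point
.orthomax <- function(L, gamma, eps = 1e-10, max_sweeps = 200L) {
  n <- nrow(L); m <- ncol(L)
  if (m < 2) return(list(L = L, R = diag(m)))
  R <- diag(m)
  crit <- .orthomax_crit(L, gamma)
  for (sweep in seq_len(max_sweeps)) {
    for (p in seq_len(m - 1)) for (q in (p + 1):m) {
      x <- L[, p]; y <- L[, q]
      u <- x^2 - y^2; v <- 2 * x * y
      A <- sum(u); B <- sum(v)
      C <- sum(u^2 - v^2); D <- sum(2 * u * v)
      num <- D - 2 * A * B * gamma / n
      den <- C - (A^2 - B^2) * gamma / n
      theta <- atan2(num, den) / 4
      if (abs(theta) < 1e-14) next
      cs <- cos(theta); sn <- sin(theta)
      L[, p] <- cs * x + sn * y
      L[, q] <- -sn * x + cs * y
      rp <- R[, p]; rq <- R[, q]
      R[, p] <- cs * rp + sn * rq
      R[, q] <- -sn * rp + cs * rq
    }
    new_crit <- .orthomax_crit(L, gamma)
    if (new_crit - crit < eps) break
    crit <- new_crit
  }
  list(L = L, R = R)
}

# quartimin criterion value and gradient (for oblimin gradient projection)
.quartimin_fg <- function(L) {
  L2 <- L^2
  N <- matrix(1, ncol(L), ncol(L)); diag(N) <- 0
  M <- L2 %*% N
  list(f = sum(L2 * M) / 4, G = L * M)
}

# oblique gradient-projection rotation (Bernaards & Jennrich) for quartimin
.gp_oblq <- function(A, tol = 1e-8, max_iter = 1000L) {
  m <- ncol(A)
  Tm <- diag(m)
  al <- 1
  Ti <- solve(Tm)
  L <- A %*% t(Ti)
  fg <- .quartimin_fg(L)
  f <- fg$f
  G <- -t(t(L) %*% fg$G %*% Ti)
  for (it in seq_len(max_iter)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G), m)
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    for (half in seq_len(30)) {
      X <- Tm - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), m)
      Tti <- solve(Tt)
      Lt <- A %*% t(Tti)
      fg_t <- .quartimin_fg(Lt)
      if (fg_t$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tm <- Tt; Ti <- Tti; L <- Lt; f <- fg_t$f
    G <- -t(t(L) %*% fg_t$G %*% Ti)
  }
  list(L = L, T = Tm, Phi = t(Tm) %*% Tm)
}

#' Rotate a loading matrix
#'
#' Orthogonal rotations (`varimax`, `quartimax`) maximize the orthomax
#' criterion by pairwise plane rotations and preserve per-item communalities.
#' `promax` is the classical oblique follow-up: varimax, then least-squares
#' fit to the power-`promax_power` target. `oblimin` is quartimin by oblique
#' gradient projection. `cluster_target` is the Orthogonal Procrustes rotation
#' of the loadings toward a column-normalized cluster indicator matrix — the
#' rotation that seeks the factor solution best matching a cluster-analysis
#' solution; it is recorded under its own name so results are never conflated
#' with varimax.
#'
#' @param lm_ a `loading_matrix`.
#' @param rotation one of `"none"`, `"varimax"`, `"quartimax"`, `"promax"`,
#'   `"oblimin"`, `"cluster_target"`.
#' @param target item x cluster indicator matrix (or a `partition`), required
#'   for `cluster_target`.
#' @param normalize apply Kaiser row normalization for the orthomax rotations.
#' @param promax_power promax target power (default 4).
#' @return a `loading_matrix` with rotated `L`; oblique rotations carry the
#'   factor correlation matrix as `Phi`.
#' @export
rotate_loadings <- function(lm_, rotation = c("none", "varimax", "quartimax",
                                              "promax", "oblimin",
                                              "cluster_target"),
                            target = NULL, normalize = FALSE,
                            promax_power = 4) {
  stopifnot(inherits(lm_, "loading_matrix"))
  rotation <- match.arg(rotation)
  L <- lm_$L
  out <- lm_
  if (rotation == "none") return(out)
  kaiser <- function(L) sqrt(rowSums(L^2))
  if (rotation %in% c("varimax", "quartimax")) {
    w <- if (normalize) pmax(kaiser(L), 1e-12) else rep(1, nrow(L))
    r <- .orthomax(L / w, gamma = if (rotation == "varimax") 1 else 0)
    L <- .fix_signs(r$L * w)
  } else if (rotation == "promax") {
    vm <- .orthomax(L, gamma = 1)
    xx <- .fix_signs(vm$L)
    Q <- xx * abs(xx)^(promax_power - 1)
    U <- qr.coef(qr(xx), Q)
    d <- diag(solve(t(U) %*% U))
    U <- U %*% diag(sqrt(d), ncol(U))
    L <- .fix_signs(xx %*% U)
    out$Phi <- solve(t(U) %*% U)
  } else if (rotation == "oblimin") {
    r <- .gp_oblq(L)
    L <- .fix_signs(r$L)
    out$Phi <- r$Phi
  } else if (rotation == "cluster_target") {
    if (is.null(target)) stop("cluster_target rotation requires a target")
    Tg <- if (inherits(target, "partition"))
      indicator_matrix(target, normalize = TRUE) else as.matrix(target)
    if (nrow(Tg) != nrow(L)) stop("target row count must match items")
    m <- ncol(L); k <- ncol(Tg); s <- max(m, k)
    Lp <- cbind(L, matrix(0, nrow(L), s - m))
    Tp <- cbind(Tg, matrix(0, nrow(Tg), s - k))
    sv <- svd(t(Lp) %*% Tp, nu = s, nv = s)
    R <- sv$u %*% t(sv$v)
    L <- Lp %*% R
    colnames(L) <- paste0("F", seq_len(s))
    out$m <- as.integer(s)
  }
  if (is.null(colnames(L))) colnames(L) <- paste0("F", seq_len(ncol(L)))
  rownames(L) <- lm_$labels
  out$L <- L
  out$rotation <- rotation
  out$communalities <- rowSums(L^2)
  out
}

#' Threshold a loading matrix for display
#'
#' Retains entries with `|loading| > cutoff` (strict) and lists items retained
#' on two or more factors as cross-loading.
#'
#' @param lm_ a `loading_matrix`.
#' @param cutoff display threshold (default 0.35).
#' @return a `loading_table`: list with `display` (matrix with `NA` below
#'   cutoff), `cutoff`, `cross_loading` (character vector of item ids),
#'   `support` (logical matrix of retained cells).
#' @export
threshold_loadings <- function(lm_, cutoff = 0.35) {
  stopifnot(inherits(lm_, "loading_matrix"), cutoff >= 0)
  keep <- abs(lm_$L) > cutoff
  disp <- lm_$L
  disp[!keep] <- NA_real_
  if (!any(keep)) warning("no loadings exceed the cutoff ", cutoff)
  structure(list(display = disp, cutoff = cutoff,
                 cross_loading = lm_$labels[rowSums(keep) >= 2],
                 support = keep),
            class = "loading_table")
}

#' @export
print.loading_table <- function(x, ...) {
  cat("<loading_table> cutoff ", x$cutoff, "; ",
      sum(x$support), " loadings displayed; cross-loading items: ",
      if (length(x$cross_loading)) paste(x$cross_loading, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}
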