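#' Simulation configuration for planted-block binary checklist data
#'
#' The generator emulates the statistical structure the clustering analysis
#' assumes: items are driven by correlated Gaussian latents with block
#' compound-symmetry correlation (`rho_within` inside a block, `rho_between`
#' across blocks), dichotomized at the threshold \eqn{\Phi^{-1}(1 - p_j)} so
#' item j has endorsement probability \eqn{p_j}, then masked missing completely
#' at random. Defaults mirror the study design being emulated: n = 453
#' subjects, seven item blocks of sizes 4, 7, 6, 3, 3, 4, 2 (29 items).
#'
#' @param n_subjects number of subjects (default 453).
#' @param block_sizes integer vector of planted block sizes
#'   (default `c(4, 7, 6, 3, 3, 4, 2)`).
#' @param rho_within latent correlation within a block, in \[0, 1).
#' @param rho_between latent correlation across blocks, in \[0, rho_within\].
#' @param prevalences per-item endorsement probability in (0, 1); scalar is
#'   recycled.
#' @param missing_rate probability each cell is masked missing, in \[0, 1).
#' @param seed integer seed; latent draws and the missingness mask use
#'   independent substreams derived from it, so changing `missing_rate` does
#'   not change the latent data.
#' @return a `simulation_config` list, validated.
#' @export
simulation_config <- function(n_subjects = 453L,
                              block_sizes = c(4L, 7L, 6L, 3L, 3L, 4L, 2L),
                              rho_within = 0.7,
                              rho_between = 0.05,
                              prevalences = 0.3,
                              missing_rate = 0.05,
                              seed = 1L) {
  p <- sum(block_sizes)
  stopifnot(n_subjects >= 1, all(block_sizes >= 1),
            rho_within >= 0, rho_within < 1,
            rho_between >= 0, rho_between <= rho_within,
            all(prevalences > 0), all(prevalences < 1),
            missing_rate >= 0, missing_rate < 1)
  prevalences <- rep_len(prevalences, p)
  cfg <- list(n_subjects = as.integer(n_subjects),
              block_sizes = as.integer(block_sizes),
              rho_within = rho_within, rho_between = rho_between,
              prevalences = prevalences, missing_rate = missing_rate,
              seed = as.integer(seed))
  # fail fast on a non-PD implied correlation matrix
  R <- .block_corr(cfg$block_sizes, rho_within, rho_between)
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-12)
    stop("implied latent correlation matrix is not positive definite ",
         "(min eigenvalue ", format(ev), ")")
  class(cfg) <- "simulation_config"
  cfg
}

.block_corr <- function(block_sizes, rho_within, rho_between) {
  blk <- rep(seq_along(block_sizes), block_sizes)
  R <- outer(blk, blk, function(a, b) ifelse(a == b, rho_within, rho_between))
  diag(R) <- 1
  R
}

# Run code with a seeded RNG, restoring the caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# Derive a bounded substream seed from a master seed and a stream index.
.substream <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 100003) %% 2147483647)
}

#' Simulate a binary checklist dataset with planted block structure
#'
#' @param cfg a [simulation_config()].
#' @return a list with elements `dataset` (a [checklist_dataset()]) and
#'   `truth` (data.frame `item_id`, `block` — the planted partition).
#'   Identical `cfg` (including seed) gives bit-identical output.
#' @examples
#' sim <- simulate_checklist(simulation_config(n_subjects = 50, seed = 7))
#' table(sim$truth$block)
#' @export
simulate_checklist <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  p <- sum(cfg$block_sizes)
  R <- .block_corr(cfg$block_sizes, cfg$rho_within, cfg$rho_between)
  U <- chol(R)
  Z <- .with_seed(.substream(cfg$seed, 1L), {
    matrix(stats::rnorm(cfg$n_subjects * p), cfg$n_subjects, p)
  })
  latent <- Z %*% U
  thr <- stats::qnorm(1 - cfg$prevalences)
  X <- matrix(0L, cfg$n_subjects, p)
  X[sweep(latent, 2, thr, ">")] <- 1L
  if (cfg$missing_rate > 0) {
    mask <- .with_seed(.substream(cfg$seed, 2L), {
      matrix(stats::runif(cfg$n_subjects * p) < cfg$missing_rate,
             cfg$n_subjects, p)
    })
    X[mask] <- NA_integer_
  }
  blk <- rep(seq_along(cfg$block_sizes), cfg$block_sizes)
  ids <- sprintf("b%d_i%02d", blk, seq_len(p))
  items <- data.frame(item_id = ids, label = ids, section = 3L,
                      stringsAsFactors = FALSE)
  ds <- checklist_dataset(X, items = items,
                          subject_ids = sprintf("s%04d", seq_len(cfg$n_subjects)))
  list(dataset = ds,
       truth = data.frame(item_id = ids, block = blk,
                          stringsAsFactors = FALSE))
}

#' Write a checklist-shaped fixture file
#'
#' Produces a delimited file emulating the full instrument layout: 19 items in
#' section 3 (behavioural), 4 in section 5 (academic), 6 in section 7
#' (neuropsychological) — the 29 analysis variables — plus decoy items in
#' sections 1, 2, 4 and 6 that a correct Step-1 selection must drop. The 29
#' analysis items carry the planted seven-block structure; decoys are
#' independent noise. A truth sidecar (`<path>.truth.tsv`) records the planted
#' block of each analysis item.
#'
#' @param seed integer seed.
#' @param path output file path (default a tempfile).
#' @param n_subjects number of subjects.
#' @return the fixture path, invisibly; attributes `truth` and `meta` hold the
#'   planted partition and item metadata.
#' @export
make_checklist_fixture <- function(seed = 1L, path = tempfile(fileext = ".csv"),
                                   n_subjects = 453L) {
  cfg <- simulation_config(n_subjects = n_subjects, seed = seed)
  sim <- simulate_checklist(cfg)
  sec <- rep(c(3L, 5L, 7L), c(19L, 4L, 6L))
  ord <- order(sec)  # already ordered; keep explicit
  resp <- sim$dataset$responses
  ids29 <- sprintf("sec%d__q%02d", sec, seq_len(29))
  # decoy items: independent noise in non-analysis sections
  dec_sec <- c(1L, 1L, 2L, 4L, 4L, 6L)
  dec <- .with_seed(.substream(seed, 3L), {
    matrix(stats::rbinom(n_subjects * length(dec_sec), 1L, 0.4),
           n_subjects, length(dec_sec))
  })
  dec_ids <- sprintf("sec%d__d%02d", dec_sec, seq_along(dec_sec))
  all_resp <- cbind(resp[, ord, drop = FALSE], dec)
  items <- data.frame(
    item_id = c(ids29, dec_ids),
    label = c(ids29, dec_ids),
    section = c(sec, dec_sec),
    stringsAsFactors = FALSE)
  ds <- checklist_dataset(all_resp, items = items,
                          subject_ids = sim$dataset$subject_ids)
  write_checklist(ds, path)
  truth <- data.frame(item_id = ids29, block = sim$truth$block[ord],
                      stringsAsFactors = FALSE)
  utils::write.table(truth, paste0(path, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  attr(path, "truth") <- truth
  attr(path, "meta") <- items
  invisible(path)
}
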