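#' Default pipeline configuration
#'
#' Returns the full configuration list with the analysis defaults: select
#' checklist sections 3/5/7, phi-squared association with pairwise deletion,
#' Ward (d-squared variant) clustering cut at k = 7, 1000-fold subject
#' bootstrap at the same fixed k, an EFA grid over pc/paf extraction, all
#' rotations, 4..7 factors with display cutoff 0.35, and the two-threshold
#' integration rule. Every field can be overridden via `modifyList()`-style
#' nesting in a JSON config file.
#'
#' @param ... named overrides merged over the defaults (top-level keys).
#' @return a nested list, class `pipeline_config`.
#' @export
pipeline_defaults <- function(...) {
  cfg <- list(
    input = NULL,                    # path to a checklist file, or NULL
    simulate = NULL,                 # simulation_config fields, or NULL
    sections = c(3L, 5L, 7L),        # NULL skips Step-1 selection
    association = list(min_pairs = 2L, form = "one_minus"),
    clustering = list(method = "ward_d2", k = 7L,
                      diagnostics = c("diana", "fanny"),
                      k_range = 2:10),
    bootstrap = list(B = 1000L, k = 7L, seed = 1L, method = "ward_d2"),
    efa = list(extractions = c("pc", "paf"),
               rotations = c("none", "varimax", "quartimax", "promax",
                             "oblimin", "cluster_target"),
               m_range = 4:7, cutoff = 0.35),
    integration = list(t_within = 0.10, r_ratio = 2.0, names = NULL),
    out_dir = NULL)
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON file; keys mirror [pipeline_defaults()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON has no NULL scalar: empty objects/arrays stand for "unset"
  empty <- vapply(raw, function(x)
    is.null(x) || (is.list(x) && length(x) == 0), logical(1))
  do.call(pipeline_defaults, raw[!empty])
}

.stage <- function(report, name, value) {
  report$stages[[name]] <- value
  report
}

#' Run the full analysis pipeline
#'
#' Executes the eight analysis stages end to end: variable selection,
#' phi-squared association, hierarchical clustering (with DIANA and FANNY as
#' diagnostics only), the fixed-k cut, bootstrap co-membership, the EFA
#' congruence grid search, reliability of clusters and factors, outlier
#' flagging, and rule-based integration into the final cluster table. With
#' `out_dir` set, all artifacts (matrices, Newick dendrogram, partition,
#' ranked grid, final table, machine-readable report) are written as delimited
#' or JSON text. The run is deterministic given the config (the bootstrap
#' seed lives in the config).
#'
#' @param config a `pipeline_config`; see [pipeline_defaults()].
#' @return a `run_report` list: config echo, per-stage summaries, warnings,
#'   and the main result objects.
#' @export
run_pipeline <- function(config = pipeline_defaults()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(package_version = as.character(utils::packageVersion("tandclust")),
                 config = unclass(config), stages = list(), warnings = character(0),
                 artifacts = character(0))
  wrn <- function(msg) report$warnings <<- c(report$warnings, msg)

  # ---- input -------------------------------------------------------------
  if (!is.null(config$input)) {
    ds <- read_checklist(config$input)
  } else if (!is.null(config$simulate)) {
    sim <- simulate_checklist(do.call(simulation_config, config$simulate))
    ds <- sim$dataset
    report$stages$simulate <- list(truth = sim$truth)
  } else stop("config must provide either input or simulate")
  if (!is.null(config$sections)) ds <- select_variables(ds, config$sections)
  report <- .stage(report, "select", list(
    n_subjects = n_subjects(ds), n_items = n_items(ds),
    items = ds$items$item_id, missing_cells = sum(is.na(ds$responses))))

  # ---- association -------------------------------------------------------
  am <- withCallingHandlers(
    association_matrix(ds, min_pairs = config$association$min_pairs),
    warning = function(w) { wrn(conditionMessage(w)); invokeRestart("muffleWarning") })
  dm <- to_dissimilarity(am, config$association$form)
  report <- .stage(report, "association", list(
    min_pairs = config$association$min_pairs,
    phi2_range = range(am$phi2[upper.tri(am$phi2)]),
    n_pairs_min = min(am$n_pairs[upper.tri(am$n_pairs)])))

  # ---- clustering --------------------------------------------------------
  k <- config$clustering$k
  tree <- agglomerate(dm, config$clustering$method)
  part <- cut_tree(tree, k)
  diag_list <- list()
  if ("diana" %in% config$clustering$diagnostics)
    diag_list$diana <- cut_tree(diana_tree(dm), k)$assignment
  if ("fanny" %in% config$clustering$diagnostics)
    diag_list$fanny <- fanny_fuzzy(dm, k)$hard
  kr <- config$clustering$k_range
  kr <- kr[kr >= 2 & kr <= n_items(ds) - 1]
  sil <- select_k_diagnostic(dm, tree, kr)
  report <- .stage(report, "cluster", list(
    method = config$clustering$method, k = k,
    assignment = stats::setNames(part$assignment, part$labels),
    sizes = tabulate(part$assignment, k),
    silhouette = sil, diagnostics = diag_list))

  # ---- bootstrap ---------------------------------------------------------
  cm <- NULL
  if (!is.null(config$bootstrap) && config$bootstrap$B > 0) {
    cm <- bootstrap_comembership(ds, method = config$bootstrap$method,
                                 k = config$bootstrap$k,
                                 B = config$bootstrap$B,
                                 seed = config$bootstrap$seed)
    report <- .stage(report, "bootstrap", list(
      B = cm$B, B_effective = cm$B_effective, dropped = cm$dropped,
      k = cm$k, method = cm$method, seed = cm$seed,
      summary = within_cluster_summary(cm, part)))
  } else {
    wrn("bootstrap disabled (B = 0): integration uses loading evidence only")
  }

  # ---- EFA + congruence grid --------------------------------------------
  grid <- grid_search(am, part, m_range = config$efa$m_range,
                      extractions = config$efa$extractions,
                      rotations = config$efa$rotations)
  ltab <- threshold_loadings(grid$winner, config$efa$cutoff)
  report <- .stage(report, "efa", list(
    ranking = grid$results,
    winner = grid$results[1, c("extraction", "rotation", "m", "diag_sum")],
    cross_loading = ltab$cross_loading,
    note = "input is a phi-squared similarity matrix, not a signed correlation matrix"))

  # ---- reliability (clusters and factors) --------------------------------
  rel_clusters <- reliability_report(ds, part)
  fac_part <- .factor_partition(grid$winner)
  rel_factors <- if (!is.null(fac_part)) reliability_report(ds, fac_part)
  report <- .stage(report, "reliability",
                   list(clusters = rel_clusters, factors = rel_factors))

  # ---- integration -------------------------------------------------------
  flags <- if (!is.null(cm))
    flag_outliers(cm, part, L = grid$winner, alignment = grid$winner_score,
                  t_within = config$integration$t_within,
                  r_ratio = config$integration$r_ratio)
  else flag_outliers_empty()
  final <- integrate_clusters(part, flags, ds,
                              names = config$integration$names)
  report <- .stage(report, "integration",
                   list(flags = flags, table = final$table, log = final$log))

  report$dataset <- ds
  report$association <- am
  report$tree <- tree
  report$partition <- part
  report$comembership <- cm
  report$grid <- grid
  report$final <- final
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) report <- .write_artifacts(report, config)
  report
}

# hard partition by dominant |loading| per item (for factor-wise alpha)
.factor_partition <- function(L) {
  asg <- apply(abs(L$L), 1, which.max)
  k <- ncol(L$L)
  if (any(tabulate(asg, k) == 0)) return(NULL)  # a factor owns no item
  as_partition(asg, labels = L$labels, k = k)
}

flag_outliers_empty <- function() {
  data.frame(item_id = character(0), cluster = integer(0),
             within_mean = numeric(0), best_other = integer(0),
             best_other_mean = numeric(0), top_factor = integer(0),
             loading_cluster = integer(0), stringsAsFactors = FALSE)
}

.write_artifacts <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  art <- character(0)
  write_matrix(report$association$phi2, p("phi2.tsv")); art <- c(art, p("phi2.tsv"))
  write_matrix(report$association$n_pairs, p("n_pairs.tsv")); art <- c(art, p("n_pairs.tsv"))
  export_newick(report$tree, p("dendrogram.nwk")); art <- c(art, p("dendrogram.nwk"))
  write_partition(report$partition, p("partition.tsv")); art <- c(art, p("partition.tsv"))
  if (!is.null(report$comembership)) {
    write_matrix(report$comembership$p, p("comembership.tsv"))
    art <- c(art, p("comembership.tsv"))
  }
  utils::write.table(report$grid$results, p("efa_grid.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  art <- c(art, p("efa_grid.tsv"))
  utils::write.table(
    data.frame(item_id = rownames(report$grid$winner$L),
               report$grid$winner$L, check.names = FALSE),
    p("loadings.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  art <- c(art, p("loadings.tsv"))
  utils::write.table(report$final$table, p("final_clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  art <- c(art, p("final_clusters.tsv"))
  utils::write.table(report$final$log, p("reassignment_log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  art <- c(art, p("reassignment_log.tsv"))
  report$artifacts <- art
  jsonlite::write_json(.machine_report(report), p("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  report$artifacts <- c(art, p("report.json"))
  report
}

# machine-readable payload: everything numeric in the human summary, no
# timestamps, so identical config + seed gives byte-identical output
.machine_report <- function(report) {
  list(package_version = report$package_version,
       config = report$config,
       stages = report$stages,
       warnings = report$warnings,
       artifacts = report$artifacts)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> tandclust ", x$package_version, "\n", sep = "")
  s <- x$stages
  cat("  data: ", s$select$n_subjects, " subjects x ", s$select$n_items,
      " items (", s$select$missing_cells, " missing cells)\n", sep = "")
  cat("  clustering: ", s$cluster$method, ", k = ", s$cluster$k,
      "; sizes ", paste(s$cluster$sizes, collapse = " "), "\n", sep = "")
  best_k <- s$cluster$silhouette$k[s$cluster$silhouette$best]
  cat("  silhouette-preferred k: ", best_k, "\n", sep = "")
  if (!is.null(s$bootstrap))
    cat("  bootstrap: B = ", s$bootstrap$B, " (", s$bootstrap$dropped,
        " dropped), k = ", s$bootstrap$k, "\n", sep = "")
  cat("  EFA winner: ", s$efa$winner$extraction, " / ", s$efa$winner$rotation,
      " / m = ", s$efa$winner$m, " (diag_sum = ",
      format(s$efa$winner$diag_sum, digits = 5), ")\n", sep = "")
  if (nrow(s$integration$log))
    cat("  integration: ", sum(s$integration$log$moved), " moved, ",
        sum(!s$integration$log$moved), " conflict(s)\n", sep = "")
  print(x$final)
  if (length(x$warnings))
    cat("  warnings: ", length(x$warnings), "\n", sep = "")
  invisible(x)
}
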