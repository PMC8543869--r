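#' Construct a checklist dataset
#'
#' A `checklist_dataset` holds a subjects-by-items matrix of dichotomous
#' responses together with per-item metadata (a stable `item_id`, a free-text
#' `label`, and the checklist `section` the item belongs to). Missing responses
#' are carried as `NA` — an explicit mask, never a sentinel value — because all
#' downstream association computations use pairwise deletion.
#'
#' @param responses integer/numeric matrix, rows = subjects, columns = items;
#'   entries must be 0, 1 or `NA`.
#' @param items data.frame with columns `item_id`, `label`, `section`
#'   (one row per response column). If `NULL`, metadata are derived from
#'   column names.
#' @param subject_ids character vector of unique subject identifiers; defaults
#'   to the matrix rownames or `s1..sn`.
#' @return An object of class `checklist_dataset` with elements `responses`
#'   (integer matrix with `NA` for missing), `items` (metadata data.frame) and
#'   `subject_ids`.
#' @examples
#' m <- matrix(c(1, 0, 1, NA, 0, 1), nrow = 3,
#'             dimnames = list(NULL, c("a", "b")))
#' ds <- checklist_dataset(m, items = data.frame(
#'   item_id = c("a", "b"), label = c("a", "b"), section = c(3L, 5L)))
#' n_items(ds)
#' @export
checklist_dataset <- function(responses, items = NULL, subject_ids = NULL) {
  responses <- as.matrix(responses)
  if (is.null(subject_ids)) {
    subject_ids <- rownames(responses)
    if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(nrow(responses)))
  }
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids))
    stop("duplicate subject ids: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (length(subject_ids) != nrow(responses))
    stop("subject_ids length does not match response rows")
  if (is.null(items)) {
    ids <- colnames(responses)
    if (is.null(ids)) ids <- paste0("item", seq_len(ncol(responses)))
    items <- data.frame(item_id = ids, label = ids, section = NA_integer_,
                        stringsAsFactors = FALSE)
  }
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  if (!all(c("item_id", "section") %in% names(items)))
    stop("items metadata must have columns item_id and section")
  if (is.null(items$label)) items$label <- items$item_id
  items$item_id <- as.character(items$item_id)
  items$section <- as.integer(items$section)
  if (anyDuplicated(items$item_id))
    stop("duplicate item_id in metadata")
  if (nrow(items) != ncol(responses))
    stop("items metadata rows (", nrow(items), ") != response columns (",
         ncol(responses), ")")
  bad <- which(!(is.na(responses) | responses == 0 | responses == 1))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(responses))
    stop("non-binary response value '", responses[bad[1]], "' at row ",
         ij[1], ", column ", ij[2], " (", items$item_id[ij[2]], ")")
  }
  storage.mode(responses) <- "integer"
  dimnames(responses) <- list(subject_ids, items$item_id)
  structure(list(responses = responses, items = items,
                 subject_ids = subject_ids),
            class = "checklist_dataset")
}

#' @export
print.checklist_dataset <- function(x, ...) {
  cat("<checklist_dataset> ", length(x$subject_ids), " subjects x ",
      nrow(x$items), " items; ", sum(is.na(x$responses)),
      " missing cells\n", sep = "")
  sec <- table(x$items$section, useNA = "ifany")
  cat("  sections: ", paste(names(sec), sec, sep = ":", collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Number of items / subjects in a checklist dataset
#' @param ds a `checklist_dataset`
#' @return integer count
#' @export
n_items <- function(ds) nrow(ds$items)

#' @rdname n_items
#' @export
n_subjects <- function(ds) length(ds$subject_ids)

# Parse "sec<k>__<label>" header convention; returns NA section if absent.
.parse_item_header <- function(x) {
  m <- regmatches(x, regexec("^sec([0-9]+)__(.*)$", x))
  sec <- vapply(m, function(g) if (length(g) == 3) as.integer(g[2]) else NA_integer_,
                integer(1))
  lab <- vapply(seq_along(m), function(i)
    if (length(m[[i]]) == 3) m[[i]][3] else x[i], character(1))
  data.frame(item_id = x, label = lab, section = sec, stringsAsFactors = FALSE)
}

#' Read a checklist-shaped delimited file
#'
#' Reads a wide table (header row, one subject-id column, remaining columns
#' items coded 0/1 with empty cells or `na` sentinels for missing). Item
#' section metadata comes either from a sidecar file (two or three columns:
#' `item_id`, `section`, optional `label`) or from the in-header convention
#' `sec<k>__<label>` (for example `sec3__anxiety`). Any cell that is not
#' 0, 1 or missing is a parse error naming its row and column; values are
#' never imputed.
#'
#' @param path path to the delimited file.
#' @param sep field delimiter; `NULL` auto-detects between tab and comma from
#'   the header line.
#' @param id_col name (or 1-based index) of the subject-id column.
#' @param na strings (besides the empty cell) to read as missing.
#' @param meta optional path to the item-metadata sidecar.
#' @param meta_sep delimiter for the sidecar (default same as `sep`).
#' @return a [checklist_dataset()].
#' @export
read_checklist <- function(path, sep = NULL, id_col = 1L,
                           na = c("", "NA"), meta = NULL, meta_sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (is.character(id_col)) {
    id_col <- match(id_col, names(raw))
    if (is.na(id_col)) stop("subject-id column not found")
  }
  subject_ids <- raw[[id_col]]
  item_cols <- setdiff(seq_along(raw), id_col)
  ids <- names(raw)[item_cols]
  resp <- matrix(NA_integer_, nrow(raw), length(item_cols))
  for (j in seq_along(item_cols)) {
    v <- trimws(raw[[item_cols[j]]])
    v[v %in% na] <- NA
    ok <- is.na(v) | v %in% c("0", "1")
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop("malformed cell value '", v[i], "' at data row ", i,
           ", column '", ids[j], "'")
    }
    resp[, j] <- as.integer(v)
  }
  if (!is.null(meta)) {
    if (is.null(meta_sep)) meta_sep <- sep
    md <- utils::read.table(meta, header = TRUE, sep = meta_sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(c("item_id", "section") %in% names(md)))
      stop("metadata sidecar must have item_id and section columns")
    idx <- match(ids, md$item_id)
    if (anyNA(idx)) stop("metadata sidecar missing items: ",
                         paste(ids[is.na(idx)], collapse = ", "))
    items <- data.frame(item_id = ids,
                        label = if (is.null(md$label)) ids else md$label[idx],
                        section = as.integer(md$section[idx]),
                        stringsAsFactors = FALSE)
  } else {
    items <- .parse_item_header(ids)
  }
  checklist_dataset(resp, items = items, subject_ids = subject_ids)
}

#' Write a checklist dataset to a delimited file
#'
#' Inverse of [read_checklist()]: values and the missingness mask round-trip
#' exactly. Section metadata is encoded in the header as `sec<k>__<item_id>`
#' unless already present in the item ids.
#'
#' @param ds a `checklist_dataset`.
#' @param path output path.
#' @param sep field delimiter.
#' @param na string written for missing cells.
#' @return `path`, invisibly.
#' @export
write_checklist <- function(ds, path, sep = ",", na = "") {
  stopifnot(inherits(ds, "checklist_dataset"))
  hdr <- ifelse(grepl("^sec[0-9]+__", ds$items$item_id) | is.na(ds$items$section),
                ds$items$item_id,
                paste0("sec", ds$items$section, "__", ds$items$item_id))
  df <- data.frame(subject_id = ds$subject_ids,
                   ds$responses, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("subject_id", hdr)
  utils::write.table(df, path, sep = sep, na = na, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Restrict a dataset to items from given checklist sections
#'
#' Keeps items whose `section` is in `sections`, preserving column order.
#' The canonical use selects sections 3, 5 and 7 of the instrument
#' (behavioural, academic and neuropsychological skills), which yields the
#' 29 dichotomous variables the downstream analysis runs on.
#'
#' @param ds a `checklist_dataset`.
#' @param sections integer vector of section numbers to keep.
#' @return a `checklist_dataset` with the retained items.
#' @export
select_variables <- function(ds, sections) {
  stopifnot(inherits(ds, "checklist_dataset"))
  if (length(sections) == 0) stop("sections must be non-empty")
  keep <- which(ds$items$section %in% as.integer(sections))
  if (length(keep) == 0)
    stop("no items in sections {", paste(sections, collapse = ","), "}")
  checklist_dataset(ds$responses[, keep, drop = FALSE],
                    items = ds$items[keep, , drop = FALSE],
                    subject_ids = ds$subject_ids)
}

#' Write / read a labelled square matrix as delimited text
#'
#' Used for association, dissimilarity and co-membership matrices. The file
#' has a header row and a leading label column; values round-trip to within
#' 1e-12 (17 significant digits are written).
#'
#' @param m square numeric matrix with row/column labels.
#' @param path output path.
#' @param sep delimiter.
#' @return `path` invisibly (`write_matrix`); a labelled matrix (`read_matrix`).
#' @export
write_matrix <- function(m, path, sep = "\t") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m))
    stop("matrix must be square, got ", nrow(m), "x", ncol(m))
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) %||% paste0("v", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  df <- data.frame(item_id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
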