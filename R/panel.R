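# Sample panels: a labeled collection of contact matrices sharing one
# fragment map. Labels are two-level: MLL status (fusion / wt) and fusion
# subtype (AF9, ENL, AF6, AFX, AF4, or none), plus the leukemia type
# (AML / ALL / EC) kept as annotation.

.MLL_STATUS <- c("fusion", "wt")
.SUBTYPES <- c("AF9", "ENL", "AF6", "AFX", "AF4", "none")
.LEUK_TYPES <- c("AML", "ALL", "EC")

#' Create a sample panel
#'
#' @param matrices named list of [contact_matrix()] objects, one per sample;
#'   names are the sample ids. All matrices must share one dimension.
#' @param meta data frame with one row per sample: columns `sample_id`,
#'   `mll_status` (`fusion`/`wt`), `subtype` (`AF9`, `ENL`, `AF6`, `AFX`,
#'   `AF4`, `none`), `leukemia_type` (`AML`/`ALL`/`EC`).
#' @param fragments optional shared [fragment_map()].
#' @return An object of class `sample_panel`.
#' @export
sample_panel <- function(matrices, meta, fragments = NULL) {
  stopifnot(is.list(matrices), all(vapply(matrices, inherits, TRUE,
                                          "contact_matrix")))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "mll_status", "subtype", "leukemia_type")
  if (!all(req %in% names(meta))) {
    stop("meta must have columns ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) stop("sample ids must be unique")
  if (is.null(names(matrices))) names(matrices) <- meta$sample_id
  if (!setequal(names(matrices), meta$sample_id)) {
    stop("matrix names and meta$sample_id must agree")
  }
  matrices <- matrices[meta$sample_id]
  ns <- vapply(matrices, n_frag, 1L)
  if (length(ns) > 1 && length(unique(ns)) != 1) {
    stop("all matrices must share one fragment map")
  }
  if (!all(meta$mll_status %in% .MLL_STATUS)) {
    stop("mll_status must be 'fusion' or 'wt'")
  }
  if (!all(meta$subtype %in% .SUBTYPES)) {
    stop("subtype must be one of ", paste(.SUBTYPES, collapse = ", "))
  }
  if (!all(meta$leukemia_type %in% .LEUK_TYPES)) {
    stop("leukemia_type must be one of ", paste(.LEUK_TYPES, collapse = ", "))
  }
  if (is.null(fragments) && length(matrices)) {
    fragments <- matrices[[1]]$fragments
  }
  structure(list(matrices = matrices, meta = meta, fragments = fragments),
            class = "sample_panel")
}

#' @export
length.sample_panel <- function(x) length(x$matrices)

#' Subset a sample panel by sample
#' @param x a [sample_panel()].
#' @param i sample indices, logical mask, or sample ids.
#' @param ... ignored.
#' @return a [sample_panel()] with the selected samples.
#' @export
`[.sample_panel` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$meta$sample_id)
  sample_panel(x$matrices[i], x$meta[i, , drop = FALSE], x$fragments)
}

#' Class labels of a panel
#' @param panel a [sample_panel()].
#' @param label_field `"mll_status"` or `"subtype"` (or `"leukemia_type"`).
#' @return character vector of per-sample labels.
#' @export
panel_labels <- function(panel, label_field = "mll_status") {
  stopifnot(label_field %in% names(panel$meta))
  panel$meta[[label_field]]
}

#' @export
print.sample_panel <- function(x, ...) {
  cat(sprintf("5C sample panel: %d samples, %d fragments\n",
              length(x), n_frag(x$matrices[[1]])))
  cat("MLL status: ", paste(sprintf("%s=%d", names(table(x$meta$mll_status)),
                                    table(x$meta$mll_status)), collapse = ", "), "\n")
  st <- table(x$meta$subtype[x$meta$subtype != "none"])
  if (length(st)) {
    cat("Fusion subtypes: ",
        paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a sample panel from a metadata CSV
#'
#' The CSV must have columns `sample_id`, `path`, `mll_status`, `subtype`,
#' `leukemia_type`; `path` points to each sample's contact matrix file,
#' relative paths resolved against the CSV's directory.
#'
#' @param csv_path metadata CSV path.
#' @param dialect matrix file dialect, see [read_contact_matrix()].
#' @return a [sample_panel()].
#' @export
read_panel <- function(csv_path, dialect = c("my5c", "plain")) {
  dialect <- match.arg(dialect)
  meta <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  req <- c("sample_id", "path", "mll_status", "subtype", "leukemia_type")
  if (!all(req %in% names(meta))) {
    stop("panel CSV must have columns ", paste(req, collapse = ", "))
  }
  base <- dirname(normalizePath(csv_path))
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", meta$path), meta$path,
                  file.path(base, meta$path))
  mats <- lapply(paths, read_contact_matrix, dialect = dialect)
  names(mats) <- meta$sample_id
  sample_panel(mats, meta[, setdiff(names(meta), "path")])
}

#' Write a sample panel to a directory
#'
#' Writes one matrix file per sample plus a `panel.csv` metadata table (and
#' `fragments.bed` when a fragment map is attached and rtracklayer is
#' available), the layout read back by [read_panel()].
#'
#' @param panel a [sample_panel()].
#' @param dir output directory (created if needed).
#' @param dialect matrix file dialect.
#' @return the metadata CSV path, invisibly.
#' @export
write_panel <- function(panel, dir, dialect = c("my5c", "plain")) {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s.matrix.tsv", panel$meta$sample_id)
  for (k in seq_along(panel$matrices)) {
    m <- panel$matrices[[k]]
    if (is.null(m$fragments)) m$fragments <- panel$fragments
    write_contact_matrix(m, file.path(dir, files[k]), dialect = dialect)
  }
  meta <- cbind(panel$meta[, "sample_id", drop = FALSE], path = files,
                panel$meta[, setdiff(names(panel$meta), "sample_id"),
                           drop = FALSE])
  csv <- file.path(dir, "panel.csv")
  utils::write.csv(meta, csv, row.names = FALSE, quote = FALSE)
  if (!is.null(panel$fragments) &&
      requireNamespace("rtracklayer", quietly = TRUE)) {
    write_fragment_map(panel$fragments, file.path(dir, "fragments.bed"))
  }
  invisible(csv)
}
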