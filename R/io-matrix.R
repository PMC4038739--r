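# Tab-delimited contact matrix IO.
#
# Two dialects:
#  * "my5c": row/column headers of the form NAME|ASSEMBLY|chrom:start-end,
#    the convention of the my5C analysis platform. Only the chrom:start-end
#    part is interpreted (to rebuild the fragment map); NAME and ASSEMBLY are
#    carried opaquely.
#  * "plain": a bare numeric matrix, no headers.
# Unmeasured cells are the token "NA" (empty or non-numeric cells also read
# as unmeasured).

.parse_my5c_header <- function(h) {
  parts <- strsplit(h, "|", fixed = TRUE)[[1]]
  if (length(parts) < 3) {
    stop(sprintf("malformed my5c header '%s' (expected NAME|ASSEMBLY|chrom:start-end)", h))
  }
  loc <- parts[length(parts)]
  m <- regmatches(loc, regexec("^([^:]+):([0-9]+)-([0-9]+)$", loc))[[1]]
  if (length(m) != 4) {
    stop(sprintf("malformed my5c coordinate field '%s'", loc))
  }
  list(name = parts[1], chrom = m[2],
       start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Read a tab-delimited 5C contact matrix
#'
#' @param path path to a tab-delimited matrix file.
#' @param dialect `"my5c"` (headers `NAME|ASSEMBLY|chrom:start-end` on rows
#'   and columns) or `"plain"` (bare numeric matrix).
#' @return a [contact_matrix()]; for the my5c dialect the fragment map is
#'   rebuilt from the headers. Non-numeric or empty cells become unmeasured;
#'   asymmetric measured cells are averaged with a warning.
#' @seealso [write_contact_matrix()]
#' @export
read_contact_matrix <- function(path, dialect = c("my5c", "plain")) {
  dialect <- match.arg(dialect)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character", stringsAsFactors = FALSE)
  if (dialect == "plain") {
    vals <- suppressWarnings(apply(as.matrix(tab), c(1, 2), as.numeric))
    if (nrow(vals) != ncol(vals)) {
      stop(sprintf("non-square matrix in '%s': %d rows x %d columns",
                   path, nrow(vals), ncol(vals)))
    }
    return(contact_matrix(vals))
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) stop(sprintf("'%s' is not a my5c matrix", path))
  col_headers <- as.character(tab[1, -1])
  row_headers <- as.character(tab[-1, 1])
  if (length(col_headers) != length(row_headers)) {
    stop(sprintf("non-square matrix in '%s': %d row headers, %d column headers",
                 path, length(row_headers), length(col_headers)))
  }
  body <- as.matrix(tab[-1, -1, drop = FALSE])
  vals <- suppressWarnings(apply(body, c(1, 2), as.numeric))
  info <- lapply(row_headers, .parse_my5c_header)
  fm <- fragment_map(chrom = vapply(info, `[[`, "", "chrom"),
                     start = vapply(info, `[[`, 1L, "start"),
                     end = vapply(info, `[[`, 1L, "end"),
                     name = vapply(info, `[[`, "", "name"))
  contact_matrix(vals, fragments = fm)
}

#' Write a tab-delimited 5C contact matrix
#'
#' Unmeasured cells are written as the token `NA`. The output is readable by
#' [read_contact_matrix()] with the same dialect (round-trip exact to
#' representation precision) and, for the my5c dialect, by the my5C platform.
#'
#' @param m a [contact_matrix()].
#' @param path output path.
#' @param dialect `"my5c"` or `"plain"`.
#' @param assembly genome assembly string embedded in my5c headers.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(m, path, dialect = c("my5c", "plain"),
                                 assembly = "hg19") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(m, "contact_matrix"))
  n <- n_frag(m)
  body <- format(m$values, digits = 15, trim = TRUE, scientific = FALSE)
  body[is.na(m$values)] <- "NA"
  if (dialect == "plain") {
    utils::write.table(body, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  fm <- m$fragments
  if (is.null(fm)) {
    # no map attached: synthesize placeholder coordinates so headers parse
    fm <- fragment_map(chrom = "chrU",
                       start = (seq_len(n) - 1L) * 1000L + 1L,
                       end = seq_len(n) * 1000L)
  }
  headers <- sprintf("%s|%s|%s:%d-%d", fm$name, assembly, fm$chrom,
                     fm$start, fm$end)
  out <- rbind(c("5C_matrix", headers), cbind(headers, body))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
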