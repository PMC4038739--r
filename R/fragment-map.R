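# Fragment maps: the ordered restriction fragments (e.g. BglII fragments of a
# 5C design region) that index the rows/columns of every contact matrix.

#' Create a fragment map
#'
#' A fragment map describes the ordered restriction fragments of the assayed
#' region. Fragments are numbered consecutively from 1, left to right along
#' the chromosome, and index the rows and columns of a [contact_matrix()].
#'
#' @param chrom character vector of chromosome names (recycled if length 1).
#' @param start,end integer vectors of 1-based inclusive fragment coordinates.
#' @param orientation primer orientation per fragment: `"FOR"`, `"REV"` or
#'   `"NONE"`. Defaults to `"NONE"`.
#' @param name optional fragment names; defaults to `frag_<index>`.
#'
#' @return An object of class `fragment_map`: a data frame with columns
#'   `index`, `name`, `chrom`, `start`, `end`, `orientation`.
#' @examples
#' fm <- fragment_map("chr7", start = c(1, 101, 251), end = c(100, 250, 400))
#' fm
#' @export
fragment_map <- function(chrom, start, end, orientation = "NONE", name = NULL) {
  n <- length(start)
  if (length(end) != n) stop("'start' and 'end' must have equal length")
  chrom <- rep_len(as.character(chrom), n)
  orientation <- rep_len(as.character(orientation), n)
  if (!all(orientation %in% c("FOR", "REV", "NONE"))) {
    stop("orientation must be one of 'FOR', 'REV', 'NONE'")
  }
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("fragment start must be < end")
  if (is.unsorted(start, strictly = TRUE)) {
    stop("fragments must be sorted by start coordinate")
  }
  same <- chrom[-n] == chrom[-1]
  if (n > 1 && any(same & (start[-1] <= end[-n]))) {
    stop("fragments must be non-overlapping")
  }
  if (is.null(name)) name <- sprintf("frag_%d", seq_len(n))
  fm <- data.frame(index = seq_len(n), name = as.character(name),
                   chrom = chrom, start = start, end = end,
                   orientation = orientation, stringsAsFactors = FALSE)
  class(fm) <- c("fragment_map", "data.frame")
  fm
}

#' Number of fragments in a fragment map
#' @param fm a [fragment_map()].
#' @return integer fragment count.
#' @export
n_fragments <- function(fm) nrow(fm)

#' Read a fragment map from a BED file
#'
#' BED uses 0-based half-open coordinates; they are converted to the 1-based
#' inclusive convention used internally. Strand `+`/`-`/`.` maps to
#' orientation `FOR`/`REV`/`NONE`.
#'
#' @param path path to a BED file (at least 3 columns; name and strand used
#'   when present).
#' @return a [fragment_map()].
#' @export
read_fragment_map <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading BED fragment maps requires the 'rtracklayer' package")
  }
  gr <- rtracklayer::import(path, format = "BED")
  o <- order(as.character(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr))
  gr <- gr[o]
  strand <- as.character(GenomicRanges::strand(gr))
  orientation <- c(`+` = "FOR", `-` = "REV", `*` = "NONE")[strand]
  nm <- gr$name
  if (is.null(nm) || anyNA(nm)) nm <- NULL
  fragment_map(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
               orientation = unname(orientation), name = nm)
}

#' Write a fragment map to a BED file
#'
#' @param fm a [fragment_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragment_map <- function(fm, path) {
  stopifnot(inherits(fm, "fragment_map"))
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("writing BED fragment maps requires the 'rtracklayer' package")
  }
  strand <- c(FOR = "+", REV = "-", NONE = "*")[fm$orientation]
  gr <- GenomicRanges::GRanges(fm$chrom,
                               IRanges::IRanges(fm$start, fm$end),
                               strand = unname(strand))
  gr$name <- fm$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @export
print.fragment_map <- function(x, ...) {
  cat(sprintf("Fragment map: %d fragments on %s (%s-%s bp)\n",
              nrow(x), paste(unique(x$chrom), collapse = ","),
              format(min(x$start), big.mark = ","),
              format(max(x$end), big.mark = ",")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more fragments\n", nrow(x) - 6))
  invisible(x)
}
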