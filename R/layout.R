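#' Genome layout: ordered scaffolds with fixed-width bins
#'
#' A layout holds the ordered set of (haplotype-resolved) scaffolds the
#' analysis runs over, together with the bin width used for read-depth
#' binning. Bins are 1-based inclusive: bin k of a scaffold spans
#' `[(k-1)*w + 1, min(k*w, length)]`, so the last bin of each scaffold may be
#' truncated.
#'
#' @param scaffold character vector of unique scaffold names.
#' @param length integer vector of scaffold lengths in bp (all > 0).
#' @param bin_width bin width in bp (default 100 kb).
#' @return A `genome_layout`: a data.frame with columns `scaffold`, `length`
#'   and a `bin_width` attribute.
#' @examples
#' genome_layout(c("Chr01_A", "Chr01_B"), c(25e6, 18e6))
#' @export
genome_layout <- function(scaffold, length, bin_width = 1e5) {
  scaffold <- as.character(scaffold)
  length <- as.numeric(length)
  stopifnot(length(scaffold) == base::length(length))
  if (anyDuplicated(scaffold)) stop("scaffold names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("scaffold lengths must be positive")
  }
  if (!is.numeric(bin_width) || bin_width < 1) stop("bin_width must be >= 1")
  out <- data.frame(scaffold = scaffold, length = length,
                    stringsAsFactors = FALSE)
  attr(out, "bin_width") <- as.numeric(bin_width)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d scaffolds, %.1f Mb total, bin width %g bp\n",
              nrow(x), sum(x$length) / 1e6, bin_width(x)))
  invisible(x)
}

#' Bin width of a layout or profile
#' @param x a `genome_layout`, bin-count table or dosage profile.
#' @return bin width in bp.
#' @export
bin_width <- function(x) {
  w <- attr(x, "bin_width")
  if (is.null(w)) stop("object carries no bin_width attribute")
  w
}

#' Enumerate the bins of a layout
#'
#' @param layout a `genome_layout`.
#' @return data.frame with columns `scaffold`, `bin` (1-based index within
#'   scaffold), `bin_start`, `bin_end` (1-based inclusive bp).
#' @export
layout_bins <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  w <- bin_width(layout)
  n <- as.integer(ceiling(layout$length / w))
  scaffold <- rep(layout$scaffold, n)
  bin <- unlist(lapply(n, seq_len), use.names = FALSE)
  bin_start <- (bin - 1) * w + 1
  bin_end <- pmin(bin * w, rep(layout$length, n))
  data.frame(scaffold = scaffold, bin = bin, bin_start = bin_start,
             bin_end = bin_end, stringsAsFactors = FALSE)
}

#' Read a scaffold-length table into a layout
#'
#' Expects a TSV with columns `scaffold` and `length` (header required),
#' e.g. a full haplotype-resolved assembly index.
#'
#' @param path TSV file path.
#' @inheritParams genome_layout
#' @return a `genome_layout`.
#' @export
layout_from_tsv <- function(path, bin_width = 1e5) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("scaffold", "length") %in% names(tab))) {
    stop("layout TSV needs columns 'scaffold' and 'length'")
  }
  genome_layout(tab$scaffold, tab$length, bin_width = bin_width)
}

#' Desk-scale demonstration layout
#'
#' A deterministic hexaploid-like layout: 12 chromosomes with 6 haplotype
#' scaffolds each (named `Chr01_A` ... `Chr12_F`), lengths varying between
#' 10 and 30 Mb. Intended for simulation and testing at desk scale; a
#' full-size assembly layout can be loaded with [layout_from_tsv()].
#'
#' @inheritParams genome_layout
#' @return a `genome_layout` of 72 scaffolds (~1.4 Gb).
#' @export
demo_layout <- function(bin_width = 1e5) {
  chrom <- rep(1:12, each = 6)
  hap <- rep(1:6, times = 12)
  # deterministic pseudo-varied lengths in [10, 30] Mb
  len <- (10 + ((chrom * 7 + hap * 5) %% 21)) * 1e6
  nm <- sprintf("Chr%02d_%s", chrom, LETTERS[hap])
  genome_layout(nm, len, bin_width = bin_width)
}
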