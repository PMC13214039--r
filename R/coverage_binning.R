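#' Build a bin-count table
#'
#' Low-level constructor used by the readers and the simulator; validates
#' that bins exactly tile the provided layout.
#'
#' @param bins data.frame with columns `scaffold`, `bin_start`, `bin_end`,
#'   `count`.
#' @param layout a [genome_layout()] the bins must tile.
#' @param sample,tissue optional metadata strings.
#' @return a `bin_count_table`.
#' @export
bin_count_table <- function(bins, layout, sample = NA_character_,
                            tissue = NA_character_) {
  ref <- layout_bins(layout)
  if (nrow(bins) != nrow(ref) ||
      !all(bins$scaffold == ref$scaffold) ||
      !all(bins$bin_start == ref$bin_start) ||
      !all(bins$bin_end == ref$bin_end)) {
    stop("bins do not tile the layout exactly")
  }
  if (any(bins$count < 0)) stop("counts must be non-negative")
  out <- bins[, c("scaffold", "bin_start", "bin_end", "count")]
  attr(out, "bin_width") <- bin_width(layout)
  attr(out, "sample") <- sample
  attr(out, "tissue") <- tissue
  class(out) <- c("bin_count_table", "data.frame")
  out
}

#' Count reads per bin from a coordinate-sorted alignment file
#'
#' Each mapped read with mapping quality at or above `min_mapq` increments
#' the bin containing its leftmost aligned base. Reads mapped to scaffolds
#' absent from the layout are ignored and tallied in the `skipped_reads`
#' attribute. Input must be coordinate-sorted (checked from the data).
#'
#' @param file path to a BAM file, or a SAM text file (converted on the fly
#'   via [Rsamtools::asBam()]).
#' @param layout a [genome_layout()].
#' @param min_mapq minimum mapping quality (default 40).
#' @param sample,tissue optional metadata recorded on the result.
#' @return a `bin_count_table` with a `skipped_reads` attribute.
#' @export
bin_counts_from_alignments <- function(file, layout, min_mapq = 40,
                                       sample = NA_character_,
                                       tissue = NA_character_) {
  stopifnot(inherits(layout, "genome_layout"))
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile()
    file <- Rsamtools::asBam(file, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    what = c("rname", "pos", "mapq"))
  aln <- Rsamtools::scanBam(file, param = param)[[1]]
  rname <- as.character(aln$rname)
  pos <- aln$pos
  mapq <- aln$mapq
  bins <- layout_bins(layout)
  counts <- integer(nrow(bins))
  skipped <- 0L
  if (length(pos) == 0) {
    warning("no mapped reads in ", file, "; returning all-zero counts")
  } else {
    # coordinate-sorted: scaffold blocks contiguous, positions nondecreasing
    blocks <- rle(rname)$values
    if (anyDuplicated(blocks)) stop("alignments are not coordinate-sorted")
    for (sc in blocks) {
      if (is.unsorted(pos[rname == sc])) {
        stop("alignments are not coordinate-sorted")
      }
    }
    keep <- !is.na(mapq) & mapq >= min_mapq
    rname <- rname[keep]; pos <- pos[keep]
    known <- rname %in% layout$scaffold
    skipped <- sum(!known)
    rname <- rname[known]; pos <- pos[known]
    if (length(pos)) {
      w <- bin_width(layout)
      key <- paste0(rname, ":", floor((pos - 1) / w) + 1)
      binkey <- paste0(bins$scaffold, ":", bins$bin)
      tab <- table(key)
      idx <- match(names(tab), binkey)
      ok <- !is.na(idx)
      counts[idx[ok]] <- as.integer(tab[ok])
    }
  }
  bins$count <- counts
  out <- bin_count_table(bins, layout, sample = sample, tissue = tissue)
  attr(out, "skipped_reads") <- skipped
  out
}

#' Normalize a mutant bin-count table against a control
#'
#' Computes the per-bin ratio of mutant to control counts, then scales by
#' the genome-wide median ratio so unaffected regions sit at dosage 1. The
#' median (not the mean) is used as the library-size factor because mutant
#' genomes carry megabase deletions that would bias a mean. Bins whose
#' control count falls below `min_control_frac` of the control's median
#' count are masked (dosage NA): a near-zero control denominator carries no
#' dosage information. Masked bins are transparent to downstream
#' segmentation.
#'
#' @param sample,control `bin_count_table`s on the same layout and bin
#'   width.
#' @param min_control_frac mask bins with control count below this fraction
#'   of the control median (default 0.25).
#' @return a `dosage_profile` data.frame (scaffold, bin_start, bin_end,
#'   dosage, masked) with `bin_width`, `sample`, `control` and
#'   `scale_factor` attributes. The median of unmasked dosages is exactly 1.
#' @export
normalize_to_control <- function(sample, control, min_control_frac = 0.25) {
  if (nrow(sample) != nrow(control) ||
      !all(sample$scaffold == control$scaffold) ||
      !all(sample$bin_start == control$bin_start)) {
    stop("sample and control are on different layouts")
  }
  if (!isTRUE(all.equal(attr(sample, "bin_width"),
                        attr(control, "bin_width")))) {
    stop("sample and control have different bin widths")
  }
  floor_count <- min_control_frac * stats::median(control$count)
  masked <- control$count < floor_count | control$count <= 0
  if (all(masked)) stop("all bins masked; control coverage too low")
  ratio <- ifelse(masked, NA_real_, sample$count / control$count)
  s <- stats::median(ratio[!masked])
  if (!is.finite(s) || s <= 0) stop("degenerate scaling factor")
  out <- data.frame(scaffold = sample$scaffold,
                    bin_start = sample$bin_start,
                    bin_end = sample$bin_end,
                    dosage = ratio / s, masked = masked,
                    stringsAsFactors = FALSE)
  attr(out, "bin_width") <- attr(sample, "bin_width")
  attr(out, "sample") <- attr(sample, "sample")
  attr(out, "control") <- attr(control, "sample")
  attr(out, "scale_factor") <- s
  class(out) <- c("dosage_profile", "data.frame")
  out
}

#' @export
print.dosage_profile <- function(x, ...) {
  cat(sprintf(
    "dosage_profile: %d bins on %d scaffolds (%d masked), median dosage %.3f\n",
    nrow(x), length(unique(x$scaffold)), sum(x$masked),
    stats::median(x$dosage[!x$masked])))
  invisible(x)
}

#' Read / write bin-count and dosage-profile TSVs
#'
#' Plain TSV interchange formats: bin counts as
#' `scaffold  bin_start  bin_end  count`, dosage profiles as
#' `scaffold  bin_start  bin_end  dosage  masked`.
#'
#' @param x table to write.
#' @param path file path.
#' @return the read table, or `path` invisibly for writers.
#' @name profile_io
NULL

#' @rdname profile_io
#' @export
write_bin_counts <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname profile_io
#' @param layout a [genome_layout()] the counts must tile.
#' @param sample,tissue optional metadata strings.
#' @export
read_bin_counts <- function(path, layout, sample = NA_character_,
                            tissue = NA_character_) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  bin_count_table(tab, layout, sample = sample, tissue = tissue)
}

#' @rdname profile_io
#' @export
write_dosage_profile <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname profile_io
#' @param bin_width bin width in bp of the stored profile.
#' @export
read_dosage_profile <- function(path, bin_width = 1e5) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("scaffold", "bin_start", "bin_end", "dosage", "masked")
  if (!all(need %in% names(tab))) {
    stop("dosage profile TSV needs columns: ", paste(need, collapse = ", "))
  }
  tab$masked <- as.logical(tab$masked)
  attr(tab, "bin_width") <- bin_width
  class(tab) <- c("dosage_profile", "data.frame")
  tab
}
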