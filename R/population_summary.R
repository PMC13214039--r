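#' Dose-response summary of a population call set
#'
#' Aggregates per-individual indel calls by radiation dose: sample counts,
#' per-sample deletion/insertion rates, totals, mean sizes, and the SEM of
#' per-individual indel counts. Individuals with no calls still count in
#' the denominator, so rates are population rates.
#'
#' @param calls data.frame of calls with columns `individual`, `type` and
#'   `size_mb`.
#' @param individuals data.frame with columns `individual` and `dose`
#'   (Gy), one row per sequenced individual (including indel-free ones).
#' @return data.frame, one row per dose: `dose`, `n_samples`,
#'   `del_per_sample`, `del_total`, `del_mean_size_mb`, `ins_per_sample`,
#'   `ins_total`, `ins_mean_size_mb`, `all_per_sample`, `all_total`,
#'   `sem_per_individual`. Rates are unrounded; round to two decimals for
#'   report tables.
#' @export
dose_response_table <- function(calls, individuals) {
  stopifnot(all(c("individual", "dose") %in% names(individuals)))
  if (anyDuplicated(individuals$individual)) {
    stop("individuals must be unique")
  }
  if (nrow(calls) && !all(calls$individual %in% individuals$individual)) {
    stop("calls reference unknown individuals")
  }
  doses <- sort(unique(individuals$dose))
  rows <- lapply(doses, function(dg) {
    ids <- individuals$individual[individuals$dose == dg]
    n <- length(ids)
    cc <- calls[calls$individual %in% ids, , drop = FALSE]
    del <- cc[cc$type == "deletion", , drop = FALSE]
    ins <- cc[cc$type == "insertion", , drop = FALSE]
    per_ind <- table(factor(cc$individual, levels = ids))
    data.frame(
      dose = dg, n_samples = n,
      del_per_sample = if (n) nrow(del) / n else NA_real_,
      del_total = nrow(del),
      del_mean_size_mb = if (nrow(del)) mean(del$size_mb) else 0,
      ins_per_sample = if (n) nrow(ins) / n else NA_real_,
      ins_total = nrow(ins),
      ins_mean_size_mb = if (nrow(ins)) mean(ins$size_mb) else 0,
      all_per_sample = if (n) nrow(cc) / n else NA_real_,
      all_total = nrow(cc),
      sem_per_individual = if (n > 1) stats::sd(per_ind) / sqrt(n)
                           else NA_real_)
  })
  do.call(rbind, rows)
}

.calls_granges <- function(calls) {
  GenomicRanges::GRanges(calls$scaffold,
                         IRanges::IRanges(calls$start, calls$end))
}

#' Per-layer indel summary with genome and transcript coverage
#'
#' For each (layer, type) stratum: call count, mean size with standard
#' error, percent of the genome covered by at least one call of the
#' stratum (interval-union length over total layout length), and, when an
#' annotation is supplied, percent of transcripts overlapped by at least
#' one call. Calls whose dosage fell in a no-call gap are reported as an
#' explicit `"unclassified"` stratum rather than forced into a layer.
#'
#' @param calls classified call table (`scaffold`, `start`, `end`, `type`,
#'   `layer`, `size_mb`).
#' @param layout a [genome_layout()].
#' @param annotation optional gene table from [read_gene_annotation()].
#' @return data.frame, one row per (layer, type) plus an `all` row with
#'   overall coverage.
#' @export
layer_summary <- function(calls, layout, annotation = NULL) {
  total_len <- sum(layout$length)
  n_genes <- if (!is.null(annotation)) nrow(annotation) else NA_integer_
  gene_gr <- if (!is.null(annotation)) {
    GenomicRanges::GRanges(annotation$scaffold,
                           IRanges::IRanges(annotation$start,
                                            annotation$end))
  }
  layer <- ifelse(calls$layer == "no-call", "unclassified", calls$layer)
  strata <- unique(data.frame(layer = layer, type = calls$type,
                              stringsAsFactors = FALSE))
  strata <- strata[order(strata$layer, strata$type), , drop = FALSE]
  one <- function(sel, lab_layer, lab_type) {
    cc <- calls[sel, , drop = FALSE]
    gr <- GenomicRanges::reduce(.calls_granges(cc))
    pct_genome <- 100 * sum(as.numeric(GenomicRanges::width(gr))) / total_len
    pct_tx <- if (!is.null(gene_gr)) {
      100 * sum(IRanges::overlapsAny(gene_gr, gr)) / n_genes
    } else NA_real_
    data.frame(layer = lab_layer, type = lab_type, n = nrow(cc),
               mean_size_mb = mean(cc$size_mb),
               se_size_mb = if (nrow(cc) > 1) {
                 stats::sd(cc$size_mb) / sqrt(nrow(cc))
               } else NA_real_,
               pct_genome = pct_genome, pct_transcripts = pct_tx,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    one(layer == strata$layer[i] & calls$type == strata$type[i],
        strata$layer[i], strata$type[i])
  })
  rows[[length(rows) + 1]] <- one(rep(TRUE, nrow(calls)), "all", "all")
  do.call(rbind, rows)
}

#' Breakpoint (border) density along the genome
#'
#' Counts indel borders in fixed windows. A border is a call boundary that
#' is not a scaffold end: whole-arm and whole-scaffold events contribute
#' only their interior edge (or none), since a scaffold end is not a
#' chromosomal breakpoint.
#'
#' @param calls call table (`scaffold`, `start`, `end`).
#' @param layout a [genome_layout()].
#' @param window window size in bp (default 1 Mb).
#' @return list with `windows` (data.frame: scaffold, window_start,
#'   window_end, n_borders), `zero_fraction` (fraction of windows with no
#'   border) and `n_borders` (total).
#' @export
border_density <- function(calls, layout, window = 1e6) {
  nwin <- as.integer(ceiling(layout$length / window))
  wins <- data.frame(
    scaffold = rep(layout$scaffold, nwin),
    win = unlist(lapply(nwin, seq_len), use.names = FALSE))
  wins$window_start <- (wins$win - 1) * window + 1
  wins$window_end <- pmin(wins$win * window,
                          rep(layout$length, nwin))
  wins$n_borders <- 0L
  if (nrow(calls)) {
    lens <- layout$length[match(calls$scaffold, layout$scaffold)]
    borders <- rbind(
      data.frame(scaffold = calls$scaffold, pos = calls$start)[
        calls$start > 1, , drop = FALSE],
      data.frame(scaffold = calls$scaffold, pos = calls$end)[
        calls$end < lens, , drop = FALSE])
    if (nrow(borders)) {
      key <- paste0(borders$scaffold, ":",
                    floor((borders$pos - 1) / window) + 1)
      tab <- table(key)
      idx <- match(names(tab), paste0(wins$scaffold, ":", wins$win))
      ok <- !is.na(idx)
      wins$n_borders[idx[ok]] <- as.integer(tab[ok])
    }
  }
  list(windows = wins[, c("scaffold", "window_start", "window_end",
                          "n_borders")],
       zero_fraction = mean(wins$n_borders == 0),
       n_borders = sum(wins$n_borders))
}

#' Regions deleted in every listed individual
#'
#' Intersects, per scaffold, the union of each individual's deletion
#' intervals — the search used to pin a shared phenotype on a single
#' haplotypic region (e.g. two low-menthol mutants sharing one deleted
#' segment of the same chromosome 11 haplotype).
#'
#' @param calls call table with `individual`, `scaffold`, `start`, `end`,
#'   `type` and (if `layer_filter` is used) `layer`.
#' @param individuals character vector (length >= 2) of individual ids.
#' @param layer_filter optional layer value to restrict to (e.g. `"L1"`).
#' @return data.frame of shared intervals (`scaffold`, `start`, `end`,
#'   `size_mb`), empty if none.
#' @export
shared_deleted_regions <- function(calls, individuals,
                                   layer_filter = NULL) {
  if (length(individuals) < 2) stop("need at least two individuals")
  sets <- lapply(individuals, function(id) {
    cc <- calls[calls$individual == id & calls$type == "deletion", ,
                drop = FALSE]
    if (!is.null(layer_filter)) {
      cc <- cc[cc$layer %in% layer_filter, , drop = FALSE]
    }
    GenomicRanges::reduce(.calls_granges(cc))
  })
  shared <- Reduce(function(a, b) suppressWarnings(
    GenomicRanges::intersect(a, b)), sets)
  if (length(shared) == 0) {
    return(data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), size_mb = numeric(),
                      stringsAsFactors = FALSE))
  }
  data.frame(scaffold = as.character(GenomicRanges::seqnames(shared)),
             start = GenomicRanges::start(shared),
             end = GenomicRanges::end(shared),
             size_mb = GenomicRanges::width(shared) / 1e6,
             stringsAsFactors = FALSE)
}

#' Read a gene annotation from GFF3 or BED
#'
#' Keeps `gene` records (GFF3; all records for BED) as a plain table for
#' overlap reporting.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file.
#' @param feature_type GFF3 feature type to keep (default `"gene"`; set
#'   NULL to keep all).
#' @return data.frame with columns `id`, `scaffold`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_annotation <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (!is.null(feature_type) && "type" %in% names(df)) {
    df <- df[df$type %in% feature_type, , drop = FALSE]
  }
  id <- if ("ID" %in% names(df)) df$ID
        else if ("Name" %in% names(df)) df$Name
        else if ("name" %in% names(df)) df$name
        else sprintf("gene_%05d", seq_len(nrow(df)))
  out <- data.frame(id = as.character(id),
                    scaffold = as.character(df$seqnames),
                    start = df$start, end = df$end,
                    strand = as.character(df$strand),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) stop("gene ids must be unique")
  out
}

#' Genes overlapping a set of intervals
#'
#' Returns every gene overlapping any interval by at least 1 bp
#' (1-based inclusive coordinates), deduplicated and sorted by position.
#' Intervals on scaffolds absent from the annotation are skipped with a
#' warning.
#'
#' @param annotation gene table from [read_gene_annotation()].
#' @param intervals data.frame with `scaffold`, `start`, `end`.
#' @return subset of `annotation`, coordinate-sorted.
#' @export
genes_in_intervals <- function(annotation, intervals) {
  unknown <- setdiff(unique(intervals$scaffold),
                     unique(annotation$scaffold))
  if (length(unknown)) {
    warning("skipping intervals on scaffolds without annotation: ",
            paste(unknown, collapse = ", "))
    intervals <- intervals[!intervals$scaffold %in% unknown, ,
                           drop = FALSE]
  }
  if (nrow(intervals) == 0 || nrow(annotation) == 0) {
    return(annotation[0, , drop = FALSE])
  }
  gene_gr <- GenomicRanges::GRanges(
    annotation$scaffold, IRanges::IRanges(annotation$start, annotation$end))
  iv_gr <- GenomicRanges::GRanges(
    intervals$scaffold, IRanges::IRanges(intervals$start, intervals$end))
  hit <- IRanges::overlapsAny(gene_gr, iv_gr)
  out <- annotation[hit, , drop = FALSE]
  out[order(out$scaffold, out$start), , drop = FALSE]
}
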