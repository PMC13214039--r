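#' Classify a call's layer of origin from its dosage band
#'
#' Maps a mean normalized dosage onto the layer bands of [dosage_bands()].
#' With defaults, deletions classify as: `d < 0.15` all layers,
#' `0.15 <= d < 0.5` L2/3, `0.5 <= d <= 0.85` L1, otherwise no-call;
#' insertions as `(1.15, 1.45]` L1, `(1.45, 1.85]` L23, `> 1.85` all.
#'
#' @param dosage mean normalized dosage (vectorized).
#' @param type `"deletion"` or `"insertion"` (recycled).
#' @param bands a [dosage_bands()].
#' @return character vector in `{"L1", "L23", "all", "no-call"}`.
#' @examples
#' classify_call(c(0.70, 0.38, 0.0), "deletion")
#' @export
classify_call <- function(dosage, type = "deletion",
                          bands = dosage_bands()) {
  stopifnot(inherits(bands, "dosage_bands"))
  n <- max(length(dosage), length(type))
  dosage <- rep_len(dosage, n)
  type <- rep_len(type, n)
  dc <- bands$del_cuts
  ic <- bands$ins_cuts
  out <- character(n)
  del <- type == "deletion"
  out[del] <- ifelse(dosage[del] < dc[["all_max"]], "all",
              ifelse(dosage[del] < dc[["l23_max"]], "L23",
              ifelse(dosage[del] <= dc[["l1_max"]], "L1", "no-call")))
  ins <- !del
  out[ins] <- ifelse(dosage[ins] > ic[["l23_max"]], "all",
              ifelse(dosage[ins] > ic[["l1_max"]], "L23",
              ifelse(dosage[ins] > ic[["min"]], "L1", "no-call")))
  out
}

#' Annotate an indel call table with layer assignments
#'
#' @param calls call table from [detect_indels()] (needs `type` and
#'   `mean_dosage` columns).
#' @param bands a [dosage_bands()].
#' @return `calls` with a `layer` column appended.
#' @export
classify_calls <- function(calls, bands = dosage_bands()) {
  calls$layer <- classify_call(calls$mean_dosage, calls$type, bands)
  calls
}

#' Corroborate a leaf layer call with root-tissue dosage
#'
#' Adventitious roots are pure L3, so a deletion restricted to the leaf
#' epidermis (leaf dosage ~0.7) is absent from roots (root dosage ~1),
#' while an L2/3 deletion (leaf ~0.3) is fully deleted in roots (root ~0).
#' The assignment is concordant when the root dosage confirms the leaf
#' band; otherwise the leaf-derived layer is kept and the discordance
#' flagged, since root data serve as confirmation rather than primary
#' evidence. Insertions use the mirrored expectations (L1 insertion absent
#' from roots, L2/3 insertion at root dosage ~2).
#'
#' @param leaf_dosage,root_dosage mean dosages over the same interval in
#'   leaf and root libraries of one individual (vectorized).
#' @param type `"deletion"` or `"insertion"` (recycled).
#' @param bands a [dosage_bands()].
#' @return data.frame with columns `layer` and `concordant`.
#' @examples
#' infer_layer_leaf_root(0.70, 1.08)  # L1, concordant
#' infer_layer_leaf_root(0.35, 0.14)  # L23, concordant
#' @export
infer_layer_leaf_root <- function(leaf_dosage, root_dosage,
                                  type = "deletion",
                                  bands = dosage_bands()) {
  n <- max(length(leaf_dosage), length(root_dosage), length(type))
  leaf_dosage <- rep_len(leaf_dosage, n)
  root_dosage <- rep_len(root_dosage, n)
  type <- rep_len(type, n)
  leaf_layer <- classify_call(leaf_dosage, type, bands)
  hw <- bands$half_width
  # expected root dosage: L1 events invisible (1), L23 events fully dosed
  conc <- rep(FALSE, n)
  del <- type == "deletion"
  conc[del & leaf_layer == "L1" & root_dosage >= 1 - hw] <- TRUE
  conc[del & leaf_layer == "L23" & root_dosage <= hw] <- TRUE
  conc[del & leaf_layer == "all" & root_dosage < bands$del_cuts[["all_max"]] &
         leaf_dosage < bands$del_cuts[["all_max"]]] <- TRUE
  ins <- !del
  conc[ins & leaf_layer == "L1" & abs(root_dosage - 1) <= hw] <- TRUE
  conc[ins & leaf_layer == "L23" & root_dosage >= 2 - hw] <- TRUE
  conc[ins & leaf_layer == "all" & root_dosage > bands$ins_cuts[["l23_max"]]] <-
    TRUE
  data.frame(layer = leaf_layer, concordant = conc,
             stringsAsFactors = FALSE)
}

#' Classify an individual as chimeric, homogeneous or indel-free
#'
#' An individual is homogeneous when it carries at least one indel and
#' every indel is present in all layers (dosage near 0 or 2); such clones
#' have lost their layer structure through layer invasion. Any
#' layer-specific call makes the individual chimeric; no calls at all is
#' `"no-indel"`.
#'
#' @param layers character vector of per-call layer assignments for one
#'   individual (values from [classify_call()]).
#' @return one of `"chimeric"`, `"homogeneous"`, `"no-indel"`.
#' @export
classify_individual <- function(layers) {
  if (length(layers) == 0) return("no-indel")
  if (all(layers == "all")) "homogeneous" else "chimeric"
}

#' Derive compound full-loss regions from overlapping L1 and L23 deletions
#'
#' Where an L1-only and an L2/3-only deletion overlap on one scaffold of
#' the same individual, the overlap has lost every copy in every layer even
#' though neither parent call is a full deletion. Both parent calls are
#' kept; this returns the derived zero-copy intervals as extra records.
#'
#' @param calls classified call table with columns `individual` (optional),
#'   `scaffold`, `start`, `end`, `type`, `layer`.
#' @return data.frame of compound full-loss intervals (`individual`,
#'   `scaffold`, `start`, `end`), empty if none.
#' @export
compound_full_loss <- function(calls) {
  if (!"individual" %in% names(calls)) calls$individual <- "sample"
  out <- list()
  dels <- calls[calls$type == "deletion" & calls$layer %in% c("L1", "L23"), ,
                drop = FALSE]
  for (id in unique(dels$individual)) {
    a <- dels[dels$individual == id & dels$layer == "L1", , drop = FALSE]
    b <- dels[dels$individual == id & dels$layer == "L23", , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) next
    ga <- GenomicRanges::reduce(GenomicRanges::GRanges(
      a$scaffold, IRanges::IRanges(a$start, a$end)))
    gb <- GenomicRanges::reduce(GenomicRanges::GRanges(
      b$scaffold, IRanges::IRanges(b$start, b$end)))
    ov <- suppressWarnings(GenomicRanges::intersect(ga, gb))
    if (length(ov) == 0) next
    out[[length(out) + 1]] <- data.frame(
      individual = id, scaffold = as.character(GenomicRanges::seqnames(ov)),
      start = GenomicRanges::start(ov), end = GenomicRanges::end(ov),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(individual = character(), scaffold = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write layer assignments in the published indel-table column layout
#'
#' Columns: individual, dose_gy, scaffold, start, end, size_mb, type,
#' leaf_dosage, root_dosage, layer.
#'
#' @param assignments data.frame carrying those columns.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  cols <- c("individual", "dose_gy", "scaffold", "start", "end", "size_mb",
            "type", "leaf_dosage", "root_dosage", "layer")
  keep <- intersect(cols, names(assignments))
  utils::write.table(assignments[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
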