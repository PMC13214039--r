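#' Cell-layer mixture model of a tissue
#'
#' Shoot apical meristems are organized in clonally distinct layers: L1
#' produces the epidermis (including glandular trichomes), while L2 and L3
#' produce the inner tissues. Because bulk DNA from an organ is a mixture of
#' cells from these layers, a mutation confined to one layer shows up at a
#' fractional dosage proportional to that layer's cell fraction. L2 and L3
#' are merged into one `L23` compartment here, since read-depth data from
#' leaves cannot separate them; adventitious roots regenerate from L3 only
#' and are modeled as pure `L23` (specifically L3-derived, see `l3_only`).
#'
#' @param tissue `"leaf"` or `"root"`.
#' @param l1 L1 cell fraction; defaults to 0.30 for leaf and 0 for root. The
#'   leaf default reflects the characteristic dosage bands of epidermis-only
#'   deletions (~0.7) in mint; other species differ (potato is closer to
#'   0.2/0.8), so the fraction is configurable.
#' @return A `layer_model` with fields `tissue`, `fractions` (named numeric
#'   `c(L1=, L23=)` summing to 1) and `l3_only` (TRUE for root, flagging that
#'   its L23 compartment is purely L3-derived).
#' @examples
#' layer_model("leaf")
#' layer_model("root")
#' layer_model("leaf", l1 = 0.2)  # potato-like
#' @export
layer_model <- function(tissue = c("leaf", "root"), l1 = NULL) {
  tissue <- match.arg(tissue)
  if (is.null(l1)) l1 <- if (tissue == "leaf") 0.30 else 0
  if (!is.numeric(l1) || length(l1) != 1 || l1 < 0 || l1 > 1) {
    stop("l1 must be a single fraction in [0, 1]")
  }
  structure(
    list(tissue = tissue, fractions = c(L1 = l1, L23 = 1 - l1),
         l3_only = (tissue == "root")),
    class = "layer_model"
  )
}

#' @export
print.layer_model <- function(x, ...) {
  cat(sprintf("layer_model: %s (L1 = %.2f, L23 = %.2f%s)\n", x$tissue,
              x$fractions[["L1"]], x$fractions[["L23"]],
              if (x$l3_only) ", pure L3" else ""))
  invisible(x)
}

.valid_layers <- c("L1", "L23")

#' A large-scale indel event with a layer of origin
#'
#' @param type `"deletion"` or `"insertion"`.
#' @param layers character vector, non-empty subset of `c("L1", "L23")`;
#'   both together means the event is present in all three meristem layers.
#' @param scaffold scaffold name (optional until placement).
#' @param start,end 1-based inclusive bp coordinates.
#' @param copies integer copies changed per affected cell (default 1, i.e.
#'   one haplotype relative to a one-copy control baseline).
#' @return an `indel_event` list.
#' @export
indel_event <- function(type = c("deletion", "insertion"), layers,
                        scaffold = NA_character_, start = NA_real_,
                        end = NA_real_, copies = 1L) {
  type <- match.arg(type)
  layers <- unique(as.character(layers))
  if (length(layers) == 0 || !all(layers %in% .valid_layers)) {
    stop("layers must be a non-empty subset of {L1, L23}")
  }
  if (!is.na(start) && start < 1) stop("start must be >= 1")
  if (!is.na(start) && !is.na(end) && end < start) stop("end must be >= start")
  structure(list(type = type, layers = layers, scaffold = scaffold,
                 start = start, end = end, copies = as.integer(copies)),
            class = "indel_event")
}

#' Expected normalized dosage of an indel in a given tissue
#'
#' The forward model: a single-copy event confined to layer set S changes
#' the normalized dosage by the summed cell fraction of S in the sampled
#' tissue, i.e. `d = 1 + s * copies * f` with `s = -1` for deletions and
#' `+1` for insertions and `f = sum(fractions[S])`. An L1-only deletion in
#' leaf tissue (f = 0.3) therefore sits at 0.7, an L2/3-only deletion at
#' 0.3, and a deletion present in all layers at 0.
#'
#' @param event an [indel_event()], or a list with `type`, `layers`, `copies`.
#' @param model a [layer_model()].
#' @return expected dosage (dimensionless; in [0, 2] for single-copy events).
#' @examples
#' expected_dosage(indel_event("deletion", "L1"), layer_model("leaf"))   # 0.7
#' expected_dosage(indel_event("deletion", "L23"), layer_model("root"))  # 0
#' @export
expected_dosage <- function(event, model) {
  stopifnot(inherits(model, "layer_model"))
  if (!all(event$layers %in% .valid_layers)) {
    stop("unknown layer in event: ", paste(event$layers, collapse = ","))
  }
  f <- sum(model$fractions[event$layers])
  s <- if (event$type == "deletion") -1 else 1
  copies <- if (is.null(event$copies)) 1L else event$copies
  1 + s * copies * f
}

# vectorized over comma-joined layer strings, used by the simulator
.dosage_vec <- function(type, layers_str, fractions, copies = 1L) {
  f <- vapply(strsplit(layers_str, ",", fixed = TRUE),
              function(l) sum(fractions[l]), numeric(1))
  s <- ifelse(type == "deletion", -1, 1)
  1 + s * copies * f
}

#' Dosage bands for layer classification
#'
#' Layer-specific events cluster at characteristic normalized dosages: in
#' leaf tissue, single-copy deletions sit near 0 (all layers), 0.3 (L2/3
#' only) or 0.7 (L1 only); insertions mirror these around 1 (1.3, 1.7, 2.0).
#' A band is the interval of half-width `half_width` around each center;
#' where adjacent centers are closer than two half-widths the midpoint
#' separates them. Dosages outside every band are no-calls: the observed
#' distribution is genuinely multimodal with empty space between bands, so
#' forcing an assignment would hide failed normalization or partial sectors.
#'
#' With the defaults (centers 0 / 0.3 / 0.7, half-width 0.15) the deletion
#' cuts are: `d < 0.15` all layers, `0.15 <= d < 0.5` L2/3, `0.5 <= d <= 0.85`
#' L1, `d > 0.85` no-call; insertion cuts mirror around 1.
#'
#' @param l1 leaf L1 cell fraction used to place the band centers.
#' @param half_width band half-width (default 0.15).
#' @return a `dosage_bands` object with deletion/insertion centers and the
#'   derived classification cut points.
#' @export
dosage_bands <- function(l1 = 0.30, half_width = 0.15) {
  stopifnot(l1 > 0, l1 < 1, half_width > 0)
  del_centers <- c(all = 0, L23 = l1, L1 = 1 - l1)
  ins_centers <- c(L1 = 1 + l1, L23 = 2 - l1, all = 2)
  if (any(diff(unname(del_centers)) <= 0)) stop("band centers must be ordered")
  # cuts: midpoint between L23 and L1 centers; half_width elsewhere
  del_cuts <- c(all_max = del_centers[["all"]] + half_width,
                l23_max = mean(del_centers[c("L23", "L1")]),
                l1_max = del_centers[["L1"]] + half_width)
  if (del_cuts[["all_max"]] >= del_cuts[["l23_max"]] ||
      del_cuts[["l23_max"]] >= del_cuts[["l1_max"]]) {
    stop("bands overlap; reduce half_width")
  }
  ins_cuts <- c(min = ins_centers[["L1"]] - half_width,
                l1_max = ins_centers[["L1"]] + half_width,
                l23_max = ins_centers[["L23"]] + half_width)
  structure(list(del_centers = del_centers, ins_centers = ins_centers,
                 half_width = half_width, del_cuts = del_cuts,
                 ins_cuts = ins_cuts),
            class = "dosage_bands")
}
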