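#' Segmentation parameters for read-depth indel detection
#'
#' Controls the run-seeding / flank-extension / gap-bridging segmentation of
#' a normalized dosage profile. Defaults follow the parameterization used
#' for low-pass hexaploid mutant libraries: a deletion is seeded by five or
#' more consecutive bins at dosage <= 0.80, an insertion by bins >= 1.15,
#' and seeds are then grown outward under a relaxed cut.
#'
#' @param pen score budget: maximum cumulative number of non-passing bins a
#'   flank may absorb during extension (default 25).
#' @param min_size minimum run/call length in bins (default 5).
#' @param del_cut seeding dosage cut for deletions (default 0.80).
#' @param ins_cut seeding dosage cut for insertions (default 1.15).
#' @param gap_bins same-type calls on one scaffold separated by at most this
#'   many bins are merged (default 30).
#' @param post_core_cut relaxed dosage cut used during extension and final
#'   trimming; deletions extend through bins <= `post_core_cut`, insertions
#'   through bins >= `2 - post_core_cut` (default 0.85).
#' @param post_run_bins after a failing look-ahead window, the flank
#'   re-qualifies only if the next `post_run_bins` bins pass the relaxed cut
#'   at the `extend_frac` rate (default 10).
#' @param extend_win look-ahead window length in bins (default 10).
#' @param extend_frac fraction of a window's unmasked bins that must pass
#'   the relaxed cut for the window to be absorbed (default 0.6).
#' @return a `detection_params` list.
#' @export
detection_params <- function(pen = 25, min_size = 5, del_cut = 0.80,
                             ins_cut = 1.15, gap_bins = 30,
                             post_core_cut = 0.85, post_run_bins = 10,
                             extend_win = 10, extend_frac = 0.6) {
  if (!(0 < del_cut && del_cut < post_core_cut && post_core_cut < 1 &&
        1 < ins_cut)) {
    stop("need 0 < del_cut < post_core_cut < 1 < ins_cut")
  }
  if (min_size < 1) stop("min_size must be >= 1")
  if (!(0 < extend_frac && extend_frac <= 1)) {
    stop("extend_frac must be in (0, 1]")
  }
  structure(list(pen = pen, min_size = as.integer(min_size),
                 del_cut = del_cut, ins_cut = ins_cut,
                 gap_bins = as.integer(gap_bins),
                 post_core_cut = post_core_cut,
                 post_run_bins = as.integer(post_run_bins),
                 extend_win = as.integer(extend_win),
                 extend_frac = extend_frac),
            class = "detection_params")
}

# maximal runs of TRUE of length >= min_size; returns data.frame(lo, hi)
.runs_of <- function(pass, min_size) {
  r <- rle(pass)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1
  keep <- r$values & r$lengths >= min_size
  data.frame(lo = lo[keep], hi = hi[keep])
}

#' Seed candidate indel runs in a dosage profile
#'
#' Returns every maximal run of at least `min_size` consecutive unmasked
#' bins at or beyond the seeding cut (dosage <= `del_cut` for deletions,
#' >= `ins_cut` for insertions). Masked bins are transparent: they are
#' skipped entirely and do not break a run.
#'
#' @param profile a `dosage_profile`.
#' @param params a [detection_params()].
#' @return data.frame with columns `scaffold`, `type`, `lo`, `hi` where
#'   `lo`/`hi` index the scaffold's unmasked bins (1-based), plus
#'   `start`/`end` in bp.
#' @export
seed_runs <- function(profile, params = detection_params()) {
  out <- list()
  for (sc in unique(profile$scaffold)) {
    p <- profile[profile$scaffold == sc & !profile$masked, , drop = FALSE]
    if (nrow(p) == 0) next
    for (type in c("deletion", "insertion")) {
      pass <- if (type == "deletion") p$dosage <= params$del_cut
              else p$dosage >= params$ins_cut
      runs <- .runs_of(pass, params$min_size)
      if (nrow(runs) == 0) next
      runs$scaffold <- sc
      runs$type <- type
      runs$start <- p$bin_start[runs$lo]
      runs$end <- p$bin_end[runs$hi]
      out[[length(out) + 1]] <- runs
    }
  }
  if (length(out) == 0) {
    return(data.frame(lo = integer(), hi = integer(), scaffold = character(),
                      type = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$scaffold, res$start), ]
}

# extend one flank of a seed over the unmasked-bin pass vector.
# edge: current outermost absorbed index; dir: +1 right, -1 left.
.extend_flank <- function(pass, edge, dir, params) {
  n <- length(pass)
  budget <- 0
  repeat {
    if (dir > 0) {
      if (edge >= n) break
      win <- seq.int(edge + 1, min(n, edge + params$extend_win))
    } else {
      if (edge <= 1) break
      win <- seq.int(max(1, edge - params$extend_win), edge - 1)
    }
    absorb <- mean(pass[win]) >= params$extend_frac
    if (!absorb) {
      # re-qualification look-ahead beyond the failing window
      beyond <- if (dir > 0 && max(win) < n) {
        seq.int(max(win) + 1, min(n, max(win) + params$post_run_bins))
      } else if (dir < 0 && min(win) > 1) {
        seq.int(max(1, min(win) - params$post_run_bins), min(win) - 1)
      } else integer(0)
      absorb <- length(beyond) > 0 &&
        mean(pass[beyond]) >= params$extend_frac
    }
    if (!absorb) break
    budget <- budget + sum(!pass[win])
    edge <- if (dir > 0) max(win) else min(win)
    if (budget > params$pen) break
  }
  edge
}

# trim a provisional flank edge back toward the seed. The final boundary is
# the outermost bin that (i) passes the relaxed cut together with its inward
# neighbor (an isolated noise outlier cannot set a boundary) and (ii) keeps
# at least `frac` of the bins between the seed edge and itself passing (a
# distant noisy pair cannot drag the boundary across a non-passing stretch).
.trim_edge <- function(pass, prov, seed_edge, dir, frac) {
  if (dir > 0) {
    if (prov <= seed_edge) return(seed_edge)
    idx <- seq.int(seed_edge + 1, prov)
    cumfrac <- cumsum(pass[idx]) / seq_along(idx)
    ok <- pass[idx] & pass[idx - 1] & cumfrac >= frac
  } else {
    if (prov >= seed_edge) return(seed_edge)
    idx <- seq.int(seed_edge - 1, prov)     # walks outward, descending
    cumfrac <- cumsum(pass[idx]) / seq_along(idx)
    ok <- pass[idx] & pass[idx + 1] & cumfrac >= frac
  }
  if (any(ok)) idx[max(which(ok))] else seed_edge
}

#' Extend seeds, bridge gaps and emit indel calls
#'
#' Each seed is grown outward in look-ahead windows of `extend_win` bins: a
#' window is absorbed when at least `extend_frac` of its bins pass the
#' relaxed cut (`post_core_cut` for deletions, `2 - post_core_cut` for
#' insertions); a failing window is still absorbed if the `post_run_bins`
#' bins beyond it re-qualify at the same rate. A flank stops when it fails
#' to re-qualify or when its cumulative count of absorbed non-passing bins
#' exceeds `pen`. Final boundaries are then trimmed back to the outermost
#' bin that passes the relaxed cut together with its inward neighbor while
#' keeping at least `extend_frac` of the bins back to the seed passing (the
#' stopping window is considered provisionally during this trim); this
#' keeps an isolated noise outlier from setting a boundary in either
#' direction. Same-type calls on one scaffold separated by at
#' most `gap_bins` (unmasked) bins are merged and their mean dosage
#' recomputed over the merged interval. Where a deletion and an insertion
#' call overlap, the call with the larger `|mean_dosage - 1|` wins and the
#' other is truncated away from the overlap. Calls shorter than `min_size`
#' bins after trimming are dropped.
#'
#' @param seeds output of [seed_runs()].
#' @param profile the `dosage_profile` the seeds came from.
#' @param params a [detection_params()].
#' @return data.frame of calls: `scaffold`, `start`, `end` (bp, bin
#'   aligned), `type`, `n_bins`, `mean_dosage`, `size_mb`.
#' @export
extend_and_merge <- function(seeds, profile, params = detection_params()) {
  empty <- data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), type = character(),
                      n_bins = integer(), mean_dosage = numeric(),
                      size_mb = numeric(), stringsAsFactors = FALSE)
  if (nrow(seeds) == 0) return(empty)
  calls <- list()
  ins_relaxed <- 2 - params$post_core_cut
  for (sc in unique(seeds$scaffold)) {
    p <- profile[profile$scaffold == sc & !profile$masked, , drop = FALSE]
    d <- p$dosage
    for (type in c("deletion", "insertion")) {
      sd_runs <- seeds[seeds$scaffold == sc & seeds$type == type, ,
                       drop = FALSE]
      if (nrow(sd_runs) == 0) next
      pass <- if (type == "deletion") d <= params$post_core_cut
              else d >= ins_relaxed
      n_bins_sc <- length(d)
      iv <- matrix(NA_integer_, nrow(sd_runs), 2)
      for (i in seq_len(nrow(sd_runs))) {
        lo <- .extend_flank(pass, sd_runs$lo[i], -1L, params)
        hi <- .extend_flank(pass, sd_runs$hi[i], +1L, params)
        # the stopping window is considered provisionally, then both flanks
        # are trimmed back to the outermost passing bin; an isolated noisy
        # passing bin does not set a boundary (a run of two is required)
        lo <- .trim_edge(pass, max(1L, lo - params$extend_win),
                         sd_runs$lo[i], -1L, params$extend_frac)
        hi <- .trim_edge(pass, min(n_bins_sc, hi + params$extend_win),
                         sd_runs$hi[i], +1L, params$extend_frac)
        iv[i, ] <- c(lo, hi)
      }
      # sort, then merge overlaps and gaps <= gap_bins (in unmasked bins)
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      merged <- iv[1, , drop = FALSE]
      for (i in seq_len(nrow(iv))[-1]) {
        last <- nrow(merged)
        if (iv[i, 1] - merged[last, 2] - 1 <= params$gap_bins) {
          merged[last, 2] <- max(merged[last, 2], iv[i, 2])
        } else {
          merged <- rbind(merged, iv[i, , drop = FALSE])
        }
      }
      for (i in seq_len(nrow(merged))) {
        lo <- merged[i, 1]; hi <- merged[i, 2]
        calls[[length(calls) + 1]] <- data.frame(
          scaffold = sc, lo = lo, hi = hi, start = p$bin_start[lo],
          end = p$bin_end[hi], type = type,
          mean_dosage = mean(d[lo:hi]), stringsAsFactors = FALSE)
      }
    }
  }
  calls <- do.call(rbind, calls)
  calls <- .resolve_opposite_overlaps(calls, profile, params)
  if (is.null(calls) || nrow(calls) == 0) return(empty)
  w <- attr(profile, "bin_width")
  if (is.null(w)) stop("profile carries no bin_width attribute")
  # a scaffold's last bin may be truncated, hence the ceiling
  calls$n_bins <- as.integer(ceiling((calls$end - calls$start + 1) / w))
  calls <- calls[calls$hi - calls$lo + 1 >= params$min_size, , drop = FALSE]
  calls$size_mb <- (calls$end - calls$start + 1) / 1e6
  rownames(calls) <- NULL
  calls[, c("scaffold", "start", "end", "type", "n_bins", "mean_dosage",
            "size_mb")]
}

# opposite-type overlap: the call with larger |mean - 1| wins; loser is
# truncated off the overlap (dropped if nothing remains)
.resolve_opposite_overlaps <- function(calls, profile, params) {
  if (is.null(calls) || nrow(calls) < 2) return(calls)
  drop <- rep(FALSE, nrow(calls))
  for (sc in unique(calls$scaffold)) {
    idx <- which(calls$scaffold == sc & !drop)
    if (length(idx) < 2) next
    p <- profile[profile$scaffold == sc & !profile$masked, , drop = FALSE]
    for (a in idx) for (b in idx) {
      if (a >= b || drop[a] || drop[b]) next
      if (calls$type[a] == calls$type[b]) next
      if (calls$lo[a] > calls$hi[b] || calls$lo[b] > calls$hi[a]) next
      loser <- if (abs(calls$mean_dosage[a] - 1) >=
                   abs(calls$mean_dosage[b] - 1)) b else a
      winner <- if (loser == a) b else a
      if (calls$lo[loser] < calls$lo[winner]) {
        calls$hi[loser] <- calls$lo[winner] - 1L
      } else {
        calls$lo[loser] <- calls$hi[winner] + 1L
      }
      if (calls$lo[loser] > calls$hi[loser]) {
        drop[loser] <- TRUE
      } else {
        calls$start[loser] <- p$bin_start[calls$lo[loser]]
        calls$end[loser] <- p$bin_end[calls$hi[loser]]
        calls$mean_dosage[loser] <-
          mean(p$dosage[calls$lo[loser]:calls$hi[loser]])
      }
    }
  }
  calls[!drop, , drop = FALSE]
}

#' Detect large indels in a normalized dosage profile
#'
#' Convenience wrapper running [seed_runs()] then [extend_and_merge()].
#'
#' @inheritParams seed_runs
#' @return data.frame of indel calls (see [extend_and_merge()]).
#' @examples
#' layout <- genome_layout("chr", 2e6)
#' prof <- profile_from_indel_table(
#'   data.frame(scaffold = "chr", start = 500001, end = 1500000,
#'              mean_dosage = 0.7),
#'   layout)
#' detect_indels(prof)
#' @export
detect_indels <- function(profile, params = detection_params()) {
  extend_and_merge(seed_runs(profile, params), profile, params)
}

#' Mean dosage of a profile over an interval
#'
#' Arithmetic mean of the unmasked bin dosages whose bin midpoint lies in
#' `[start, end]` on `scaffold`.
#'
#' @param profile a `dosage_profile`.
#' @param scaffold scaffold name.
#' @param start,end interval in bp (1-based inclusive).
#' @return mean dosage; `NA` with a warning if every overlapping bin is
#'   masked or the interval covers no bins.
#' @export
mean_dosage <- function(profile, scaffold, start, end) {
  mid <- (profile$bin_start + profile$bin_end) / 2
  sel <- profile$scaffold == scaffold & mid >= start & mid <= end
  if (!any(sel)) {
    warning("interval overlaps no bins")
    return(NA_real_)
  }
  d <- profile$dosage[sel & !profile$masked]
  if (length(d) == 0) {
    warning("all bins in interval are masked")
    return(NA_real_)
  }
  mean(d)
}

#' Write indel calls as a BED-like TSV
#'
#' Columns: scaffold, start (0-based BED), end, name, type, n_bins,
#' mean_dosage, size_mb.
#'
#' @param calls call table from [detect_indels()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  out <- data.frame(scaffold = calls$scaffold, start = calls$start - 1,
                    end = calls$end,
                    name = sprintf("indel_%03d", seq_len(nrow(calls))),
                    type = calls$type, n_bins = calls$n_bins,
                    mean_dosage = calls$mean_dosage,
                    size_mb = calls$size_mb)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
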