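# Independent brute-force oracles and small profile builders used across
# the suite. The oracles deliberately use naive position-by-position scans
# so they share no code path with the implementation they check.

# a single-scaffold dosage profile from a vector of bin dosages
flat_profile <- function(dosage, masked = rep(FALSE, length(dosage)),
                         scaffold = "sc1", bin_width = 1e5) {
  n <- length(dosage)
  out <- data.frame(scaffold = scaffold,
                    bin_start = (seq_len(n) - 1) * bin_width + 1,
                    bin_end = seq_len(n) * bin_width,
                    dosage = dosage, masked = masked,
                    stringsAsFactors = FALSE)
  attr(out, "bin_width") <- bin_width
  class(out) <- c("dosage_profile", "data.frame")
  out
}

# naive enumeration of all maximal threshold-passing runs of unmasked bins
brute_force_seeds <- function(profile, params = detection_params()) {
  out <- list()
  for (sc in unique(profile$scaffold)) {
    p <- profile[profile$scaffold == sc & !profile$masked, , drop = FALSE]
    for (type in c("deletion", "insertion")) {
      pass <- if (type == "deletion") p$dosage <= params$del_cut
              else p$dosage >= params$ins_cut
      n <- length(pass)
      i <- 1
      while (i <= n) {
        if (isTRUE(pass[i])) {
          j <- i
          while (j < n && isTRUE(pass[j + 1])) j <- j + 1
          if (j - i + 1 >= params$min_size) {
            out[[length(out) + 1]] <- data.frame(
              scaffold = sc, type = type, lo = i, hi = j,
              stringsAsFactors = FALSE)
          }
          i <- j + 1
        } else {
          i <- i + 1
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(scaffold = character(), type = character(),
                      lo = integer(), hi = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# per-bin brute-force intersection of deletion sets across individuals
brute_force_shared <- function(calls, individuals, layout, grain = 1e5) {
  bins <- layout_bins(genome_layout(layout$scaffold, layout$length,
                                    bin_width = grain))
  deleted_all <- rep(TRUE, nrow(bins))
  for (id in individuals) {
    cc <- calls[calls$individual == id & calls$type == "deletion", ,
                drop = FALSE]
    del <- rep(FALSE, nrow(bins))
    for (k in seq_len(nrow(cc))) {
      del <- del | (bins$scaffold == cc$scaffold[k] &
                      bins$bin_start >= cc$start[k] &
                      bins$bin_end <= cc$end[k])
    }
    deleted_all <- deleted_all & del
  }
  bins[deleted_all, , drop = FALSE]
}

# P011 rows of the packaged indel table, shaped for profile reconstruction
p011_rows <- function() {
  tab <- mint_indel_table()
  p <- tab[tab$individual == "P011",
           c("scaffold", "start", "end", "leaf_dosage")]
  names(p)[4] <- "mean_dosage"
  p
}
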