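#' Packaged worked-example tables
#'
#' Small plain-text fixtures shipped under `inst/extdata`: the indel list
#' of the two low-menthol mutant individuals (P011/P028) with leaf and root
#' dosages, the population lesion summary by radiation dose, the per-layer
#' lesion summary, and a reconstructed essential-oil composition table
#' (means only; marked synthetic because replicate-level values are not
#' published).
#'
#' @return data.frames; see each loader.
#' @name fixtures
NULL

.extdata <- function(file) {
  system.file("extdata", file, package = "chimeradose", mustWork = TRUE)
}

#' @rdname fixtures
#' @export
mint_indel_table <- function() {
  tab <- utils::read.delim(.extdata("p11_p28_indels.tsv"),
                           stringsAsFactors = FALSE)
  tab$layer <- sub("^L2/3$", "L23", tab$layer)
  tab
}

#' @rdname fixtures
#' @export
mint_dose_table <- function() {
  utils::read.delim(.extdata("dose_lesion_summary.tsv"),
                    stringsAsFactors = FALSE)
}

#' @rdname fixtures
#' @export
mint_layer_table <- function() {
  utils::read.delim(.extdata("layer_lesion_summary.tsv"),
                    stringsAsFactors = FALSE)
}

#' @rdname fixtures
#' @export
mint_oil_profiles <- function() {
  read_oil_profiles(.extdata("oil_profiles_synthetic.tsv"))
}

#' Synthetic scaffold layout for the P011/P028 reconstruction
#'
#' The scaffolds named in [mint_indel_table()] with synthetic lengths:
#' true scaffold lengths are not published, so indels whose end coordinate
#' is not bin-aligned (clearly running to the scaffold end) set the
#' scaffold length, and all other scaffolds get a 3 Mb margin beyond the
#' outermost indel. Sufficient for rebuilding the per-bin dosage profiles
#' of both individuals.
#'
#' @inheritParams genome_layout
#' @return a [genome_layout()] of the 11 scaffolds carrying indels.
#' @export
fixture_layout <- function(bin_width = 1e5) {
  genome_layout(
    c("Chr02_A", "Chr03_B", "Chr03_E", "Chr04_A", "Chr04_K", "Chr05_F",
      "Chr06_C", "Chr07_B", "Chr08_A", "Chr11_D", "Chr12_F"),
    c(30400000, 32857933, 21400000, 34843660, 10000000, 10700000,
      13200000, 6200000, 22800000, 10000000, 8900000),
    bin_width = bin_width)
}

#' Expand an aggregate dose table into a per-individual call set
#'
#' Builds the smallest population consistent with an aggregate lesion
#' summary: for each dose stratum the printed number of individuals is
#' created, the printed deletion/insertion totals are distributed
#' round-robin across them, and every call takes the stratum's printed
#' mean size. Used to exercise the aggregation stage against printed
#' derived numbers; the distribution across individuals is immaterial for
#' totals and per-sample rates.
#'
#' @param dose_tab table in the layout of [mint_dose_table()].
#' @return list with `individuals` (individual, dose) and `calls`
#'   (individual, type, size_mb) data.frames.
#' @export
population_from_dose_table <- function(dose_tab = mint_dose_table()) {
  individuals <- list(); calls <- list()
  for (i in seq_len(nrow(dose_tab))) {
    r <- dose_tab[i, ]
    ids <- sprintf("d%g_%03d", r$dose_gy, seq_len(r$n_samples))
    individuals[[i]] <- data.frame(individual = ids, dose = r$dose_gy,
                                   stringsAsFactors = FALSE)
    mk <- function(total, type, size) {
      if (total == 0) return(NULL)
      data.frame(individual = ids[(seq_len(total) - 1) %% length(ids) + 1],
                 type = type, size_mb = size, stringsAsFactors = FALSE)
    }
    calls[[i]] <- rbind(mk(r$del_total, "deletion", r$del_mean_size_mb),
                        mk(r$ins_total, "insertion", r$ins_mean_size_mb))
  }
  list(individuals = do.call(rbind, individuals),
       calls = do.call(rbind, calls))
}
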