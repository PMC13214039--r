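#' Read essential-oil composition profiles
#'
#' Long-format TSV with columns `sample`, `compound`, `abundance_pct` and
#' optionally `replicate`; replicate measurements are averaged per
#' (sample, compound). Abundances are percent of total oil.
#'
#' @param path TSV file.
#' @return data.frame (`sample`, `compound`, `abundance_pct`,
#'   `n_replicates`).
#' @export
read_oil_profiles <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "compound", "abundance_pct")
  if (!all(need %in% names(tab))) {
    stop("oil profile TSV needs columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$abundance_pct < 0)) stop("abundances must be >= 0")
  agg <- stats::aggregate(abundance_pct ~ sample + compound, tab, mean)
  nrep <- stats::aggregate(abundance_pct ~ sample + compound, tab, length)
  agg$n_replicates <- nrep$abundance_pct
  tot <- stats::aggregate(abundance_pct ~ sample, agg, sum)
  if (any(tot$abundance_pct > 100 + 1e-6)) {
    warning("some samples sum to more than 100% of total oil")
  }
  agg[order(agg$sample, agg$compound), ]
}

#' Compound-wise fold changes between two oil profiles
#'
#' Fold change is reported as the larger over the smaller abundance (so a
#' 10-fold reduction and a 10-fold increase both read 10) with a
#' `direction` column giving the sign of mutant minus control. Compounds
#' with a zero abundance on either side have an undefined ratio and are
#' flagged; compounds present in only one profile are dropped with a
#' warning.
#'
#' @param profiles long table from [read_oil_profiles()] (or with the same
#'   columns).
#' @param control,mutant sample ids to compare.
#' @return data.frame: `compound`, `control_pct`, `mutant_pct`, `fold`
#'   (rounded to one decimal), `direction` (`"increased"`, `"decreased"`,
#'   `"unchanged"`), `undefined` (logical).
#' @examples
#' tab <- data.frame(sample = rep(c("BM", "P28"), each = 2),
#'                   compound = rep(c("menthyl_acetate", "menthone"), 2),
#'                   abundance_pct = c(9.5, 12.8, 0.89, 46.5))
#' fold_changes(tab, "BM", "P28")
#' @export
fold_changes <- function(profiles, control, mutant) {
  c_tab <- profiles[profiles$sample == control, , drop = FALSE]
  m_tab <- profiles[profiles$sample == mutant, , drop = FALSE]
  if (nrow(c_tab) == 0 || nrow(m_tab) == 0) {
    stop("control or mutant sample not found in profiles")
  }
  only <- union(setdiff(c_tab$compound, m_tab$compound),
                setdiff(m_tab$compound, c_tab$compound))
  if (length(only)) {
    warning("compounds present in only one profile omitted: ",
            paste(only, collapse = ", "))
  }
  shared <- intersect(c_tab$compound, m_tab$compound)
  cv <- c_tab$abundance_pct[match(shared, c_tab$compound)]
  mv <- m_tab$abundance_pct[match(shared, m_tab$compound)]
  undef <- cv == 0 | mv == 0
  fold <- ifelse(undef, NA_real_,
                 round(pmax(cv, mv) / pmin(cv, mv), 1))
  direction <- ifelse(mv > cv, "increased",
                      ifelse(mv < cv, "decreased", "unchanged"))
  data.frame(compound = shared, control_pct = cv, mutant_pct = mv,
             fold = fold, direction = direction, undefined = undef,
             stringsAsFactors = FALSE)
}

#' Pearson correlation matrix over oil profiles
#'
#' Pairwise Pearson correlations with two-sided p-values from the
#' t-distribution on n-2 degrees of freedom. `margin = "sample"`
#' correlates samples across their shared compounds (chemotype
#' similarity); `margin = "compound"` correlates compounds across samples
#' (e.g. the inverse relationship of a substrate and its product). Pairs
#' with fewer than 3 shared observations, or with zero variance on either
#' side, get `NA` and are flagged.
#'
#' @param profiles long table from [read_oil_profiles()].
#' @param margin `"sample"` or `"compound"`.
#' @return list with matrices `r` (unit diagonal, symmetric), `p`, `n`
#'   (observations per pair), and logical `flagged` (undefined pairs).
#' @export
correlation_matrix <- function(profiles, margin = c("sample", "compound")) {
  margin <- match.arg(margin)
  wide <- stats::reshape(
    profiles[, c("sample", "compound", "abundance_pct")],
    idvar = if (margin == "sample") "compound" else "sample",
    timevar = if (margin == "sample") "sample" else "compound",
    direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub("^abundance_pct\\.", "", colnames(mat))
  k <- ncol(mat)
  r <- matrix(NA_real_, k, k); diag(r) <- 1
  p <- matrix(NA_real_, k, k); nn <- matrix(0L, k, k)
  dimnames(r) <- dimnames(p) <- dimnames(nn) <-
    list(colnames(mat), colnames(mat))
  diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    ok <- stats::complete.cases(mat[, i], mat[, j])
    nn[i, j] <- nn[j, i] <- sum(ok)
    if (sum(ok) < 3 || stats::sd(mat[ok, i]) == 0 ||
        stats::sd(mat[ok, j]) == 0) next
    ct <- stats::cor.test(mat[ok, i], mat[ok, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  diag(nn) <- colSums(!is.na(mat))
  flagged <- is.na(r) | (is.na(p) & !diag(k))
  list(r = r, p = p, n = nn, flagged = flagged)
}
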