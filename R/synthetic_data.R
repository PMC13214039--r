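#' Simulation configuration for an irradiated clonal population
#'
#' Captures the statistical structure of a gamma-irradiated mutant
#' collection: a zero-inflated event count per individual whose mean tracks
#' the radiation dose, a strong deletion bias, an L1-over-L2/3 bias among
#' layer-specific events, a small fraction of homogenized (non-chimeric)
#' individuals, lognormal megabase event sizes, and a preference for
#' terminal-arm placement.
#'
#' `lambda` is the target mean number of indels per individual at each dose.
#' Draws are zero-inflated: with probability `pi0` an individual carries no
#' indel at all; otherwise the count is Poisson with rate `lambda/(1-pi0)`,
#' so the population mean equals `lambda` while the zero fraction at 45 Gy
#' is ~0.15 (a plain Poisson at these rates would give essentially no
#' indel-free individuals, contradicting observed populations).
#'
#' @param dose radiation dose in Gy; one of 15, 30, 45, 60 (or any value if
#'   `lambda` is given explicitly).
#' @param n_individuals number of individuals to simulate.
#' @param lambda mean indels per individual; default looked up per dose
#'   (15 Gy: 2.62, 30: 4.71, 45: 5.66, 60: 7.00).
#' @param pi0 zero-inflation mass (default 0.145).
#' @param p_deletion probability an event is a deletion (default 0.963).
#' @param p_all probability a (non-homogenized) event hits all layers
#'   (default 0.036).
#' @param p_l1 probability a layer-specific event is L1-only (default 0.622).
#' @param p_homogenized probability an individual is homogenized, i.e. all
#'   its events present in every layer (default 11/261).
#' @param mean_size mean event size in bp (default 6.4 Mb).
#' @param sigma_log lognormal log-sd of event sizes (default 0.8).
#' @param terminal_bias probability an event is anchored at a scaffold end
#'   (default 0.6); otherwise placement is uniform.
#' @param depth mean reads per bin when rendering counts (default 200).
#' @param overdispersion negative-binomial overdispersion of bin counts
#'   (variance = mu + overdispersion * mu^2); 0 gives Poisson counts.
#' @param min_size minimum event size in bp (default 5 bins at 100 kb).
#' @param max_retries placement retries before giving up on an event.
#' @return a `sim_config` list.
#' @export
sim_config <- function(dose = 45, n_individuals = 50, lambda = NULL,
                       pi0 = 0.145, p_deletion = 0.963, p_all = 0.036,
                       p_l1 = 0.622, p_homogenized = 11 / 261,
                       mean_size = 6.4e6, sigma_log = 0.8,
                       terminal_bias = 0.6, depth = 200,
                       overdispersion = 0, min_size = 5e5,
                       max_retries = 100L) {
  if (is.null(lambda)) {
    rates <- c("15" = 2.62, "30" = 4.71, "45" = 5.66, "60" = 7.00)
    key <- as.character(dose)
    if (!key %in% names(rates)) {
      stop("no default lambda for dose ", dose, " Gy; supply lambda")
    }
    lambda <- unname(rates[key])
  }
  probs <- c(pi0, p_deletion, p_all, p_l1, p_homogenized, terminal_bias)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (lambda < 0 || depth <= 0) stop("lambda must be >= 0 and depth > 0")
  if (pi0 >= 1) stop("pi0 must be < 1")
  structure(list(dose = dose, n_individuals = as.integer(n_individuals),
                 lambda = lambda, pi0 = pi0, p_deletion = p_deletion,
                 p_all = p_all, p_l1 = p_l1, p_homogenized = p_homogenized,
                 mean_size = mean_size, sigma_log = sigma_log,
                 terminal_bias = terminal_bias, depth = depth,
                 overdispersion = overdispersion, min_size = min_size,
                 max_retries = as.integer(max_retries)),
            class = "sim_config")
}

# deterministic per-individual substream seed, kept below 2^31
.substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(index)) %% 2147483629)
}

# events (data.frame) overlap check within identical layer sets on a scaffold
.overlaps_same_layers <- function(events, scaffold, start, end, layers_str) {
  if (nrow(events) == 0) return(FALSE)
  same <- events$scaffold == scaffold & events$layers == layers_str
  any(same & events$start <= end & events$end >= start)
}

#' Simulate the indel complement of one individual
#'
#' Draws a zero-inflated Poisson event count, then assigns each event a
#' type, layer set, lognormal size and genomic placement (terminal-anchored
#' with probability `terminal_bias`, else uniform). Events of the same layer
#' set may not overlap on a scaffold; different layer sets may (which is how
#' compound full-loss regions arise). Homogenized individuals carry all
#' their events in every layer.
#'
#' @param config a [sim_config()].
#' @param layout a [genome_layout()].
#' @param seed integer seed for this individual's substream.
#' @return list with `events` (data.frame: scaffold, start, end, type,
#'   layers (comma-joined), copies) and `homogenized` flag.
#' @export
simulate_individual <- function(config, layout, seed = 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(layout, "genome_layout"))
  set.seed(seed)
  homog <- stats::runif(1) < config$p_homogenized
  n <- if (stats::runif(1) < config$pi0) 0L else {
    stats::rpois(1, config$lambda / (1 - config$pi0))
  }
  events <- data.frame(scaffold = character(), start = numeric(),
                       end = numeric(), type = character(),
                       layers = character(), copies = integer(),
                       stringsAsFactors = FALSE)
  if (n == 0) return(list(events = events, homogenized = homog))
  meanlog <- log(config$mean_size) - config$sigma_log^2 / 2
  for (i in seq_len(n)) {
    type <- if (stats::runif(1) < config$p_deletion) "deletion" else "insertion"
    layers <- if (homog) "L1,L23" else if (stats::runif(1) < config$p_all) {
      "L1,L23"
    } else if (stats::runif(1) < config$p_l1) "L1" else "L23"
    placed <- FALSE
    for (try in seq_len(config$max_retries)) {
      sc <- sample.int(nrow(layout), 1, prob = layout$length)
      len <- layout$length[sc]
      size <- round(stats::rlnorm(1, meanlog, config$sigma_log))
      size <- max(size, config$min_size)
      if (size > len) next
      if (stats::runif(1) < config$terminal_bias) {
        start <- if (stats::runif(1) < 0.5) 1 else len - size + 1
      } else {
        start <- floor(stats::runif(1, 1, len - size + 1))
      }
      end <- start + size - 1
      if (.overlaps_same_layers(events, layout$scaffold[sc], start, end,
                                layers)) next
      events <- rbind(events, data.frame(
        scaffold = layout$scaffold[sc], start = start, end = end,
        type = type, layers = layers, copies = 1L, stringsAsFactors = FALSE))
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place event after ", config$max_retries, " retries")
    }
  }
  list(events = events, homogenized = homog)
}

#' Simulate a whole mutant population with ground truth
#'
#' @inheritParams simulate_individual
#' @param seed global seed; each individual uses a substream derived
#'   deterministically from `(seed, index)`, so individual i is reproducible
#'   independently of the others.
#' @return a `truth_set`: list with `individuals` (data.frame: individual,
#'   dose, homogenized, n_events), `events` (data.frame with an `individual`
#'   column), `config`, `layout`.
#' @export
simulate_population <- function(config, layout, seed = 1L) {
  ids <- sprintf("sim%03d", seq_len(config$n_individuals))
  evs <- vector("list", length(ids))
  homog <- logical(length(ids))
  for (i in seq_along(ids)) {
    one <- simulate_individual(config, layout, .substream_seed(seed, i))
    homog[i] <- one$homogenized
    if (nrow(one$events)) one$events$individual <- ids[i]
    evs[[i]] <- one$events
  }
  events <- do.call(rbind, evs[vapply(evs, nrow, 1L) > 0])
  if (is.null(events)) {
    events <- data.frame(scaffold = character(), start = numeric(),
                         end = numeric(), type = character(),
                         layers = character(), copies = integer(),
                         individual = character(), stringsAsFactors = FALSE)
  }
  individuals <- data.frame(
    individual = ids, dose = config$dose, homogenized = homog,
    n_events = vapply(evs, nrow, 1L), stringsAsFactors = FALSE)
  structure(list(individuals = individuals, events = events,
                 config = config, layout = layout, seed = seed),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set: %d individuals at %g Gy, %d events (%.1f/ind)\n",
              nrow(x$individuals), x$config$dose, nrow(x$events),
              nrow(x$events) / max(1, nrow(x$individuals))))
  invisible(x)
}

#' Per-bin expected dosage implied by a set of truth events
#'
#' Applies the layer mixture model bin by bin: each event shifts the dosage
#' of the bins it covers by `s * copies * f * overlap_fraction`, where f is
#' the summed cell fraction of its layer set in the given tissue. Bins only
#' partially covered by an event get a proportionally attenuated shift;
#' dosage is floored at 0.
#'
#' @param events event data.frame as produced by [simulate_individual()]
#'   (columns scaffold, start, end, type, layers, copies); may be empty or
#'   NULL for a control individual.
#' @param layout a [genome_layout()].
#' @param model a [layer_model()] for the sampled tissue.
#' @return data.frame of layout bins with a `dosage` column.
#' @export
truth_profile <- function(events, layout, model) {
  stopifnot(inherits(model, "layer_model"))
  bins <- layout_bins(layout)
  bins$dosage <- 1
  if (is.null(events) || nrow(events) == 0) return(bins)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    sel <- which(bins$scaffold == ev$scaffold & bins$bin_start <= ev$end &
                   bins$bin_end >= ev$start)
    if (length(sel) == 0) next
    ov <- (pmin(bins$bin_end[sel], ev$end) -
             pmax(bins$bin_start[sel], ev$start) + 1) /
      (bins$bin_end[sel] - bins$bin_start[sel] + 1)
    layers <- strsplit(ev$layers, ",", fixed = TRUE)[[1]]
    f <- sum(model$fractions[layers])
    s <- if (ev$type == "deletion") -1 else 1
    bins$dosage[sel] <- bins$dosage[sel] + s * ev$copies * f * ov
  }
  bins$dosage <- pmax(bins$dosage, 0)
  bins
}

#' Render sequencing bin counts from truth events
#'
#' Emulates low-pass whole-genome sequencing of an individual: each bin's
#' read count is Poisson (or negative binomial when `overdispersion > 0`)
#' with mean `depth * dosage * bin_fill`, where `bin_fill` accounts for
#' truncated terminal bins. Pass `events = NULL` for a control library
#' (dosage 1 everywhere).
#'
#' @inheritParams truth_profile
#' @param depth mean reads per full-width bin at dosage 1.
#' @param seed integer seed.
#' @param overdispersion negative-binomial overdispersion (0 = Poisson).
#' @return a bin-count table: data.frame (scaffold, bin_start, bin_end,
#'   count) with `bin_width`, `tissue` attributes.
#' @export
render_bin_counts <- function(events, layout, model, depth = 200,
                              seed = 1L, overdispersion = 0) {
  stopifnot(depth > 0)
  set.seed(seed)
  bins <- truth_profile(events, layout, model)
  w <- bin_width(layout)
  fill <- (bins$bin_end - bins$bin_start + 1) / w
  mu <- depth * bins$dosage * fill
  count <- if (overdispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / overdispersion)
  } else {
    stats::rpois(length(mu), mu)
  }
  out <- data.frame(scaffold = bins$scaffold, bin_start = bins$bin_start,
                    bin_end = bins$bin_end, count = count,
                    stringsAsFactors = FALSE)
  attr(out, "bin_width") <- w
  attr(out, "tissue") <- model$tissue
  class(out) <- c("bin_count_table", "data.frame")
  out
}

#' Reconstruct a dosage profile from a printed indel table
#'
#' Rebuilds the per-bin normalized dosage profile implied by a table of
#' indel intervals with mean dosages (e.g. a published per-individual indel
#' list): bins whose midpoint falls inside a row's interval take that row's
#' mean dosage; all other bins sit at the 1.0 baseline, optionally jittered
#' with Gaussian noise of sd `baseline_noise_sd`. Event bins keep the
#' printed mean exactly (it is already a measured average), so the
#' reconstruction is deterministic inside events.
#'
#' @param rows data.frame with columns `scaffold`, `start`, `end`,
#'   `mean_dosage` (bp coordinates, 1-based inclusive).
#' @param layout a [genome_layout()] covering the listed scaffolds.
#' @param baseline_noise_sd sd of Gaussian jitter on baseline bins
#'   (default 0 = noiseless).
#' @param seed integer seed used when jitter is requested.
#' @return a `dosage_profile` data.frame (scaffold, bin_start, bin_end,
#'   dosage, masked).
#' @export
profile_from_indel_table <- function(rows, layout, baseline_noise_sd = 0,
                                     seed = 1L) {
  stopifnot(inherits(layout, "genome_layout"))
  need <- c("scaffold", "start", "end", "mean_dosage")
  if (!all(need %in% names(rows))) {
    stop("rows need columns: ", paste(need, collapse = ", "))
  }
  if (!all(rows$scaffold %in% layout$scaffold)) {
    stop("rows reference scaffolds absent from layout")
  }
  lens <- layout$length[match(rows$scaffold, layout$scaffold)]
  if (any(rows$start < 1) || any(rows$end > lens)) {
    stop("rows extend beyond scaffold bounds")
  }
  for (sc in unique(rows$scaffold)) {
    r <- rows[rows$scaffold == sc, , drop = FALSE]
    if (nrow(r) > 1) {
      r <- r[order(r$start), ]
      if (any(r$start[-1] <= r$end[-nrow(r)])) {
        stop("overlapping rows on scaffold ", sc)
      }
    }
  }
  bins <- layout_bins(layout)
  bins$dosage <- 1
  if (baseline_noise_sd > 0) {
    set.seed(seed)
    bins$dosage <- pmax(0, bins$dosage +
                          stats::rnorm(nrow(bins), 0, baseline_noise_sd))
  }
  mid <- (bins$bin_start + bins$bin_end) / 2
  for (i in seq_len(nrow(rows))) {
    sel <- bins$scaffold == rows$scaffold[i] & mid >= rows$start[i] &
      mid <= rows$end[i]
    bins$dosage[sel] <- rows$mean_dosage[i]
  }
  out <- data.frame(scaffold = bins$scaffold, bin_start = bins$bin_start,
                    bin_end = bins$bin_end, dosage = bins$dosage,
                    masked = FALSE, stringsAsFactors = FALSE)
  attr(out, "bin_width") <- bin_width(layout)
  class(out) <- c("dosage_profile", "data.frame")
  out
}

#' Write truth events as a BED-like TSV
#'
#' Columns: scaffold, start (0-based, BED-style), end, type, layers,
#' expected leaf dosage, individual.
#'
#' @param truth a `truth_set` from [simulate_population()].
#' @param path output file.
#' @param model layer model used for the expected-dosage column.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path, model = layer_model("leaf")) {
  ev <- truth$events
  d <- .dosage_vec(ev$type, ev$layers, model$fractions, ev$copies)
  out <- data.frame(scaffold = ev$scaffold, start = ev$start - 1,
                    end = ev$end, type = ev$type, layers = ev$layers,
                    expected_dosage = d, individual = ev$individual)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
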