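#' Planted channel-coupling graph
#'
#' Synthetic cohorts separate their two classes by spatial structure: each
#' class mixes channel signals along a known ("planted") set of edges, so a
#' learned adjacency or a classifier can be checked against ground truth.
#'
#' @param n_channels Number of channels (graph nodes).
#' @param edges Two-column matrix (or list of length-2 vectors) of unordered
#'   1-based channel pairs; no self-pairs. May be empty.
#' @param coupling Coupling strength in (0, 1): each channel receives this
#'   fraction of every planted neighbour's signal before rescaling.
#' @return Object of class `"planted_graph"`.
#' @export
planted_graph <- function(n_channels, edges = NULL, coupling = 0.6) {
  if (!is_count(n_channels) || n_channels < 1) stopf("`n_channels` must be a positive integer")
  edges <- normalize_pairs(edges, n_channels)
  if (!is.numeric(coupling) || coupling <= 0 || coupling >= 1) {
    stopf("`coupling` must lie in (0, 1)")
  }
  structure(list(n_channels = as.integer(n_channels), edges = edges,
                 coupling = coupling),
            class = "planted_graph")
}

# Canonical pair matrix: integer, 2 columns, i < j, unique, range-checked.
normalize_pairs <- function(pairs, n_nodes) {
  if (is.null(pairs) || (is.list(pairs) && length(pairs) == 0L)) {
    return(matrix(integer(0), ncol = 2L))
  }
  if (is.list(pairs)) pairs <- do.call(rbind, lapply(pairs, as.integer))
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) == 0L) return(matrix(integer(0), ncol = 2L))
  if (any(pairs < 1L) || any(pairs > n_nodes)) stopf("edge channel out of range 1..%d", n_nodes)
  if (any(pairs[, 1L] == pairs[, 2L])) stopf("self-pairs are not allowed")
  pairs <- t(apply(pairs, 1L, sort))
  unique(pairs)
}

adjacency01 <- function(graph) {
  a <- matrix(0, graph$n_channels, graph$n_channels)
  if (nrow(graph$edges)) {
    a[graph$edges] <- 1
    a[graph$edges[, 2:1, drop = FALSE]] <- 1
  }
  a
}

#' Synthetic cohort configuration
#'
#' Describes a two-class cohort of synthetic fNIRS recordings. Each channel's
#' oxygenated-hemoglobin trace is a sum of slow sinusoids with random
#' frequencies in `osc_band_hz` and random phases; class structure is planted
#' by one-shot linear mixing along the class graph's edges
#' (`x_i <- x_i + coupling * sum_j x_j` over planted neighbours `j`, then
#' rescaled to unit variance) before additive Gaussian noise. Deoxygenated
#' hemoglobin is `-hb_ratio` times the oxygenated trace plus independent
#' noise, and total hemoglobin is their exact sum.
#'
#' @param n_asd,n_td Subjects per class (labels 1 and 0).
#' @param m Samples per subject (default 6857, about 8 min at 0.07 s).
#' @param n_channels Channels per subject (default 44).
#' @param graph_asd,graph_td [planted_graph()]s for the two classes; defaults
#'   plant the 11 strong frontotemporal pairs of [strong_pairs_44()] in the
#'   ASD class and no edges in the TD class.
#' @param osc_band_hz Oscillation frequency band in Hz (default 0.01-0.1,
#'   spontaneous hemodynamic fluctuation timescales).
#' @param noise_sd Additive Gaussian noise standard deviation (signal is unit
#'   variance per channel).
#' @param hb_ratio Anticorrelation ratio of Hb to HbO2 (default 0.3).
#' @param sampling_interval_s Sampling interval in seconds (default 0.07).
#' @param seed Integer seed; the cohort is a pure function of this config.
#' @return Object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_asd = 25L, n_td = 22L, m = 6857L, n_channels = 44L,
                          graph_asd = NULL, graph_td = NULL,
                          osc_band_hz = c(0.01, 0.1), noise_sd = 0.3,
                          hb_ratio = 0.3, sampling_interval_s = 0.07,
                          seed = 1L) {
  if (is.null(graph_asd)) {
    graph_asd <- if (n_channels == 44L) planted_graph(44L, strong_pairs_44())
                 else planted_graph(n_channels)
  }
  if (is.null(graph_td)) graph_td <- planted_graph(n_channels)
  if (graph_asd$n_channels != n_channels || graph_td$n_channels != n_channels) {
    stopf("planted graphs must match `n_channels`")
  }
  if (n_asd + n_td < 1L) stopf("cohort must contain at least one subject")
  if (length(osc_band_hz) != 2L || osc_band_hz[1] <= 0 ||
      osc_band_hz[2] <= osc_band_hz[1]) {
    stopf("`osc_band_hz` must be an increasing positive (low, high) pair")
  }
  if (noise_sd <= 0) stopf("`noise_sd` must be positive")
  structure(list(n_asd = as.integer(n_asd), n_td = as.integer(n_td),
                 m = as.integer(m), n_channels = as.integer(n_channels),
                 graph_asd = graph_asd, graph_td = graph_td,
                 osc_band_hz = osc_band_hz, noise_sd = noise_sd,
                 hb_ratio = hb_ratio,
                 sampling_interval_s = sampling_interval_s,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Sum of n_comp random sinusoids in the band, one column per channel.
oscillation_matrix <- function(m, n_channels, band, dt, n_comp = 3L) {
  t_s <- (seq_len(m) - 1L) * dt
  x <- matrix(0, m, n_channels)
  for (ch in seq_len(n_channels)) {
    freq <- stats::runif(n_comp, band[1], band[2])
    phase <- stats::runif(n_comp, 0, 2 * pi)
    amp <- stats::runif(n_comp, 0.5, 1)
    x[, ch] <- colSums(amp * sin(outer(2 * pi * freq, t_s) + phase))
  }
  x
}

#' Generate one synthetic subject
#'
#' @param cfg A [cohort_config()].
#' @param graph [planted_graph()] used for mixing (usually one of the config's
#'   class graphs).
#' @param label Class label 0/1 attached to the recording.
#' @param subject_id Identifier.
#' @param seed Integer seed for this subject's private RNG stream.
#' @return A [subject_recording()] whose HbT columns equal HbO2 + Hb exactly.
#' @export
generate_subject <- function(cfg, graph, label, subject_id, seed) {
  with_seed(seed, {
    base <- oscillation_matrix(cfg$m, cfg$n_channels, cfg$osc_band_hz,
                               cfg$sampling_interval_s)
    mix <- diag(cfg$n_channels) + graph$coupling * adjacency01(graph)
    hbo <- base %*% mix
    hbo <- sweep(hbo, 2L, pmax(apply(hbo, 2L, stats::sd), 1e-12), "/")
    hbo <- hbo + matrix(stats::rnorm(length(hbo), 0, cfg$noise_sd),
                        nrow(hbo), ncol(hbo))
    hb <- -cfg$hb_ratio * hbo + matrix(stats::rnorm(length(hbo), 0, cfg$noise_sd),
                                       nrow(hbo), ncol(hbo))
    values <- matrix(0, cfg$m, 3L * cfg$n_channels)
    values[, attr_cols(cfg$n_channels, "HbO2")] <- hbo
    values[, attr_cols(cfg$n_channels, "Hb")] <- hb
    values[, attr_cols(cfg$n_channels, "HbT")] <- hbo + hb
    subject_recording(values, label = label, subject_id = subject_id,
                      sampling_interval_s = cfg$sampling_interval_s,
                      check_hbt = TRUE)
  })
}

#' Generate a labelled synthetic cohort
#'
#' ASD-labelled subjects (label 1) are mixed along `cfg$graph_asd`,
#' TD-labelled subjects (label 0) along `cfg$graph_td`. Each subject draws
#' from its own RNG stream derived from `cfg$seed`, so the cohort is
#' reproducible and individual subjects do not depend on generation order.
#'
#' @param cfg A [cohort_config()].
#' @return List of [subject_recording()]s (ASD subjects first), with the
#'   manifest data frame as attribute `"manifest"`.
#' @export
simulate_cohort <- function(cfg) {
  n_total <- cfg$n_asd + cfg$n_td
  seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max, n_total))
  ids <- c(sprintf("asd%02d", seq_len(cfg$n_asd)),
           sprintf("td%02d", seq_len(cfg$n_td)))
  labels <- rep(c(1L, 0L), c(cfg$n_asd, cfg$n_td))
  subjects <- lapply(seq_len(n_total), function(i) {
    generate_subject(cfg,
                     graph = if (labels[i] == 1L) cfg$graph_asd else cfg$graph_td,
                     label = labels[i], subject_id = ids[i], seed = seeds[i])
  })
  attr(subjects, "manifest") <- data.frame(subject_id = ids, label = labels,
                                           stringsAsFactors = FALSE)
  subjects
}
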