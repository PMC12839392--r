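#' Default concentration levels per modality
#'
#' Low / mid / high stimulus levels for each taste axis, centered on the
#' hedonic optima (mid = optimum).  Na+ and H+ in mM, sweet and bitter in
#' model units.
#'
#' @return Named list of length-3 numeric vectors.
#' @export
default_levels <- function() {
  list(Na = c(low = 30, mid = 100, high = 300),
       H = c(low = 0.01, mid = 0.1, high = 1),
       sweet = c(low = 3000, mid = 15000, high = 45000),
       bitter = c(low = 0.3, mid = 1, high = 3))
}

#' Stimulus specification
#'
#' Recipe for a deterministic stimulus set: pure tastes (one per selected
#' modality), a mixture of the selected modalities, or a concentration
#' sweep along one modality.
#'
#' @param kind `"pure"`, `"mixed"` or `"sweep"`.
#' @param modalities subset of `c("Na", "H", "sweet", "bitter")`; all four
#'   for `"pure"`, at least two for `"mixed"`, exactly one for `"sweep"`.
#' @param level `"low"`, `"mid"` or `"high"`.
#' @param n number of sweep points.
#' @param levels level table, see [default_levels()].
#' @param seed optional seed (kept for reproducibility bookkeeping; the
#'   constructions are deterministic).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("pure", "mixed", "sweep"),
                          modalities = NULL, level = "mid", n = 5,
                          levels = default_levels(), seed = NULL) {
  kind <- match.arg(kind)
  all_mod <- c("Na", "H", "sweet", "bitter")
  if (is.null(modalities))
    modalities <- if (kind == "sweep") "Na" else all_mod
  stopifnot(all(modalities %in% all_mod))
  if (kind == "mixed" && length(modalities) < 2)
    stop("a mixture needs at least two modalities")
  if (kind == "sweep" && length(modalities) != 1)
    stop("a sweep runs along exactly one modality")
  structure(list(kind = kind, modalities = modalities, level = level,
                 n = n, levels = levels, seed = seed),
            class = "stimulus_spec")
}

make_stimulus <- function(values) {
  do.call(tastant_stimulus, as.list(setNames(
    values[c("Na", "H", "sweet", "bitter")],
    c("c_Na", "c_H", "c_sweet", "c_bitter"))))
}

#' Generate tastant stimuli from a specification
#'
#' Pure stimuli have exactly one nonzero component; mixtures have all the
#' selected modalities nonzero; sweeps are log-spaced between the low and
#' high level of the chosen modality.  Deterministic under the spec.
#'
#' @param spec a [stimulus_spec()].
#' @return List of [tastant_stimulus()] objects.
#' @export
generate_stimuli <- function(spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  base <- c(Na = 0, H = 0, sweet = 0, bitter = 0)
  if (spec$kind == "pure") {
    lapply(spec$modalities, function(m) {
      v <- base
      v[m] <- spec$levels[[m]][[spec$level]]
      make_stimulus(v)
    })
  } else if (spec$kind == "mixed") {
    v <- base
    for (m in spec$modalities) v[m] <- spec$levels[[m]][[spec$level]]
    list(make_stimulus(v))
  } else {
    m <- spec$modalities
    rng <- spec$levels[[m]][c("low", "high")]
    conc <- exp(seq(log(rng[1]), log(rng[2]), length.out = spec$n))
    lapply(conc, function(ci) {
      v <- base
      v[m] <- ci
      make_stimulus(v)
    })
  }
}

#' Default classification panel
#'
#' Six stimulus classes: the four pure tastes at mid concentration plus a
#' high-concentration sweet-sour mixture and a mid-concentration
#' salty-bitter mixture.
#'
#' @return List of [tastant_stimulus()] objects.
#' @export
taste_panel <- function() {
  c(generate_stimuli(stimulus_spec("pure")),
    generate_stimuli(stimulus_spec("mixed", c("H", "sweet"),
                                   level = "high")),
    generate_stimuli(stimulus_spec("mixed", c("Na", "bitter"),
                                   level = "mid")))
}

#' Random stimulus panel
#'
#' Draws `n` stimuli from the current RNG stream, stratified over three
#' kinds: pure tastes (one modality at a random level, probability 0.4),
#' mixtures of two or three modalities at independent random levels
#' (probability 0.3), and palatable mixtures near the hedonic optimum
#' (every component at its optimum scaled by an independent
#' Uniform(0.8, 1.2) factor, probability 0.3).  The third stratum is what
#' makes hedonic encoding a nondegenerate task: stimuli far from the
#' four-dimensional optimum all have pleasantness near zero, so a panel
#' without near-optimal mixtures carries almost no hedonic contrast.
#'
#' @param n panel size.
#' @param p hedonic parameters locating the palatability optimum.
#' @return List of [tastant_stimulus()] objects.
#' @export
random_taste_panel <- function(n, p = hedonic_params()) {
  lv <- default_levels()
  mods <- names(lv)
  lapply(seq_len(n), function(i) {
    v <- c(Na = 0, H = 0, sweet = 0, bitter = 0)
    kind <- sample(c("pure", "mixed", "palatable"), 1,
                   prob = c(0.4, 0.3, 0.3))
    if (kind == "palatable") {
      v[] <- as.numeric(p$theta) * runif(4, 0.8, 1.2)
    } else {
      pick <- if (kind == "pure") sample(mods, 1)
              else sample(mods, sample(2:3, 1))
      for (m in pick) v[m] <- lv[[m]][[sample(c("low", "mid", "high"), 1)]]
    }
    make_stimulus(v)
  })
}

#' Entropy estimation settings
#'
#' @param bin time bin, ms.
#' @param window stimulation window length, ms (multiple of `bin`).
#' @param offset window start relative to stimulus onset, ms.
#' @return An object of class `entropy_config`.
#' @export
entropy_config <- function(bin = 3, window = 60, offset = 0) {
  stopifnot(bin > 0, window > 0, offset >= 0)
  if (abs(window %% bin) > 1e-9) stop("window must be a multiple of bin")
  structure(list(bin = bin, window = window, offset = offset),
            class = "entropy_config")
}

trial_raster <- function(trial) {
  if (inherits(trial, "network_response"))
    output_raster(trial$rasters, trial$cfg)
  else trial
}

#' Shannon entropy of the spike timing distribution
#'
#' Rebins the output-population spike times of repeated trials at `cfg$bin`
#' over the stimulation window and estimates, for every (neuron, bin) slot,
#' the across-trial firing probability.  The entropy is the sum of the
#' per-slot binary entropies (independent-Bernoulli plug-in estimator), so
#' the theoretical maximum equals the slot count — e.g. 1200 bits for 60
#' output neurons at 3 ms bins over a 60 ms window — attained when every
#' slot fires with probability one half.
#'
#' @param trials list (length >= 2) of trials: `network_response` objects
#'   or lists of per-neuron spike-time vectors for the output population.
#' @param cfg an [entropy_config()].
#' @return Entropy, bits.
#' @export
spike_pattern_entropy <- function(trials, cfg = entropy_config()) {
  if (length(trials) < 2) stop("at least two trials are required")
  for (tr in trials)
    if (inherits(tr, "network_response") &&
        cfg$offset + cfg$window > tr$cfg$duration + 1e-9)
      stop("entropy window exceeds the simulated duration")
  rasters <- lapply(trials, trial_raster)
  m <- length(rasters[[1]])
  if (any(vapply(rasters, length, integer(1)) != m))
    stop("trials must share the output population size")
  n_bins <- round(cfg$window / cfg$bin)
  counts <- matrix(0, nrow = n_bins, ncol = m)
  for (r in rasters) {
    for (j in seq_len(m)) {
      t <- r[[j]]
      t <- t[t >= cfg$offset & t < cfg$offset + cfg$window]
      if (length(t))
        counts[unique(floor((t - cfg$offset) / cfg$bin) + 1), j] <-
          counts[unique(floor((t - cfg$offset) / cfg$bin) + 1), j] + 1
    }
  }
  p <- counts / length(rasters)
  hb <- function(q) ifelse(q <= 0 | q >= 1, 0,
                           -q * log2(q) - (1 - q) * log2(1 - q))
  sum(hb(p))
}

# Per-class, per-trial input spike trains (shared across network variants,
# since transduction does not depend on the synaptic genome).
make_trial_trains <- function(cfg, panel, n_trials, noise_sd, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(panel, function(stim)
    lapply(seq_len(n_trials), function(t)
      simulate_input_trains(cfg, stim, noise_sd = noise_sd,
                            seed = sample.int(2^31 - 1, 1))))
}

#' Decode stimulus identity from output patterns
#'
#' Nearest-centroid decoding of the network's fingerprints: for each class,
#' odd-indexed noisy trials form the training set whose mean output pattern
#' is the class centroid; even-indexed trials are assigned to the class
#' whose centroid is nearest in (expected) Hamming distance.  Returns the
#' fraction of held-out trials classified correctly.
#'
#' @param net a trained or untrained `taste_network`.
#' @param panel list of at least two stimulus classes.
#' @param n_trials trials per class (>= 2; half train, half test).
#' @param decoder decoding rule; only `"nearest_centroid"` is implemented.
#' @param noise_sd input-cell noise SD, pA (the variability source across
#'   trials).
#' @param seed seed for the trial noise.
#' @param trial_trains optional precomputed output of the internal trial
#'   generator, to share trials across perturbed network variants.
#' @return Accuracy fraction in \[0, 1\].
#' @export
classify_stimuli <- function(net, panel, n_trials = 8,
                             decoder = "nearest_centroid", noise_sd = 30,
                             seed = NULL, trial_trains = NULL) {
  decoder <- match.arg(decoder, "nearest_centroid")
  if (length(panel) < 2) stop("the panel must contain at least two classes")
  stopifnot(n_trials >= 2)
  if (is.null(trial_trains))
    trial_trains <- make_trial_trains(net$cfg, panel, n_trials, noise_sd,
                                      seed)
  pats <- lapply(trial_trains, function(cls)
    lapply(cls, function(tr)
      as.numeric(simulate_network(net, NULL, input_trains = tr)$output)))
  train_idx <- seq(1, n_trials, by = 2)
  test_idx <- setdiff(seq_len(n_trials), train_idx)
  centroids <- lapply(pats, function(cls)
    Reduce(`+`, cls[train_idx]) / length(train_idx))
  correct <- 0
  total <- 0
  for (ci in seq_along(pats)) {
    for (ti in test_idx) {
      d <- vapply(centroids, function(ce)
        sum(abs(pats[[ci]][[ti]] - ce)), numeric(1))
      correct <- correct + (which.min(d) == ci)
      total <- total + 1
    }
  }
  correct / total
}

#' Robustness analysis settings
#'
#' @param perturb_fraction multiplicative perturbation half-width `f`:
#'   every synaptic and intrinsic parameter is scaled by an independent
#'   Uniform(1-f, 1+f) factor.
#' @param n_draws number of perturbation draws.
#' @param n_trials trials per class for the decoder.
#' @param noise_sd input-cell noise SD, pA.
#' @param panel stimulus classes.
#' @param seed seed.
#' @return An object of class `robustness_config`.
#' @export
robustness_config <- function(perturb_fraction = 0.2, n_draws = 20,
                              n_trials = 8, noise_sd = 30,
                              panel = taste_panel(), seed = NULL) {
  stopifnot(perturb_fraction >= 0, n_draws >= 1, n_trials >= 2)
  structure(list(perturb_fraction = perturb_fraction, n_draws = n_draws,
                 n_trials = n_trials, noise_sd = noise_sd, panel = panel,
                 seed = seed), class = "robustness_config")
}

# One perturbed copy of a network: receptor counts, phosphorylation
# fractions and intrinsic Izhikevich parameters each scaled by independent
# Uniform(1-f, 1+f) factors.
perturb_network <- function(net, f) {
  if (f == 0) return(net)
  for (l in seq_along(net$W)) {
    N <- net$W[[l]]$N
    net$W[[l]]$N <- pmax(round(N * runif(length(N), 1 - f, 1 + f)), 0)
    P <- net$W[[l]]$Phos
    net$W[[l]]$Phos <- pmin(pmax(P * runif(length(P), 1 - f, 1 + f), 0), 1)
  }
  for (l in seq_along(net$izh)) {
    for (nm in c("a", "b", "c", "d")) {
      x <- net$izh[[l]][[nm]]
      net$izh[[l]][[nm]] <- x * runif(length(x), 1 - f, 1 + f)
    }
  }
  net
}

#' Classification robustness under parameter perturbation
#'
#' Measures baseline decoding accuracy of a (trained) network, then redraws
#' the network `n_draws` times with every AMPA receptor count,
#' phosphorylation fraction and intrinsic neuron parameter independently
#' scaled by Uniform(1-f, 1+f), re-decoding the same noisy trials each
#' time.  Reports the mean accuracy decrease.
#'
#' @param net a `taste_network`.
#' @param cfg a [robustness_config()].
#' @return List with `baseline`, `perturbed` (per-draw accuracies),
#'   `mean_perturbed` and `mean_drop` (percentage points / 100).
#' @export
robustness_experiment <- function(net, cfg = robustness_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  trial_trains <- make_trial_trains(net$cfg, cfg$panel, cfg$n_trials,
                                    cfg$noise_sd)
  baseline <- classify_stimuli(net, cfg$panel, cfg$n_trials,
                               trial_trains = trial_trains)
  perturbed <- vapply(seq_len(cfg$n_draws), function(i) {
    pn <- perturb_network(net, cfg$perturb_fraction)
    classify_stimuli(pn, cfg$panel, cfg$n_trials,
                     trial_trains = trial_trains)
  }, numeric(1))
  list(baseline = baseline, perturbed = perturbed,
       mean_perturbed = mean(perturbed),
       mean_drop = baseline - mean(perturbed))
}

#' Fingerprint sparsity and class separation
#'
#' Summary statistics of a network's output code on a stimulus panel:
#' `sparsity` is the mean fraction of active (bin, neuron) slots per
#' trial; `separation` is the mean pairwise density-normalized distance
#' between class centroid patterns, `sum|a - b| / sum max(a, b)` (the
#' Soergel form of the Hamming/Jaccard distance; 0 when both classes are
#' silent).  The normalization matters: raw per-slot Hamming distance is
#' dominated by overall firing density, so unstructured dense noise would
#' trivially score as "separated", whereas this measure scores the
#' selectivity of the code — disjoint sparse assemblies reach 1, shared
#' dense activity stays low.  Used to contrast trained against untrained
#' networks.
#'
#' @param net a `taste_network`.
#' @param panel stimulus classes.
#' @param n_trials trials per class.
#' @param noise_sd input-cell noise SD, pA.
#' @param seed seed.
#' @return List with `sparsity` and `separation`.
#' @export
fingerprint_summary <- function(net, panel, n_trials = 4, noise_sd = 30,
                                seed = NULL) {
  trial_trains <- make_trial_trains(net$cfg, panel, n_trials, noise_sd,
                                    seed)
  pats <- lapply(trial_trains, function(cls)
    lapply(cls, function(tr)
      as.numeric(simulate_network(net, NULL, input_trains = tr)$output)))
  sparsity <- mean(vapply(pats, function(cls)
    mean(vapply(cls, mean, numeric(1))), numeric(1)))
  centroids <- lapply(pats, function(cls) Reduce(`+`, cls) / length(cls))
  n <- length(centroids)
  soergel <- function(a, b) {
    denom <- sum(pmax(a, b))
    if (denom == 0) 0 else sum(abs(a - b)) / denom
  }
  dists <- c()
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      dists <- c(dists, soergel(centroids[[i]], centroids[[j]]))
  list(sparsity = sparsity, separation = mean(dists))
}
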