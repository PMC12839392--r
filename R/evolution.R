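#' Synchrony context
#'
#' Normalization constants for the spike-synchrony index: the binning
#' resolution and the maximum observed interspike interval `D` across all
#' trials of the batch being scored.
#'
#' @param dt_bin temporal resolution, ms.
#' @param D maximum observed pre/post interspike interval, ms (> 0).
#' @return An object of class `sync_context`.
#' @export
sync_context <- function(dt_bin = 5, D) {
  stopifnot(dt_bin > 0, D > 0)
  structure(list(dt_bin = dt_bin, D = D), class = "sync_context")
}

#' Spike-synchrony index of a pre/post train pair
#'
#' `S = 0.5 - (d + dt_bin) / D` where `d` is the minimal absolute time
#' difference between any presynaptic and any postsynaptic spike
#' (bin-resolution times).  Near-coincident firing gives values approaching
#' `0.5 - dt_bin/D`; widely separated firing gives negative values.  When
#' either train carries no spikes there is no interval to measure and the
#' index is defined as 0 (no evidence, no plasticity).
#'
#' @param pre,post [spike_train()] objects.
#' @param ctx a [sync_context()].
#' @return Scalar synchrony score.
#' @export
sync_index <- function(pre, post, ctx) {
  tp <- spike_times(pre)
  tq <- spike_times(post)
  if (length(tp) == 0 || length(tq) == 0) return(0)
  d <- min(abs(outer(tp, tq, "-")))
  0.5 - (d + ctx$dt_bin) / ctx$D
}

#' Phosphorylation increment from synchrony scores
#'
#' Hebbian phosphorylation update `eta * mean(S_j) * (1 - phos)`: saturates
#' as the phosphorylated fraction approaches 1, scales with the average
#' pre/post synchrony over the scored train pairs.  The caller clamps
#' `phos + delta` to \[0, 1\].
#'
#' @param phos current phosphorylation fraction (scalar or vector).
#' @param sync_scores numeric vector of synchrony indices (length >= 1).
#' @param eta learning rate.
#' @return Increment(s), same shape as `phos`.
#' @export
phos_update <- function(phos, sync_scores, eta = 0.05) {
  if (length(sync_scores) == 0) stop("at least one synchrony score required")
  stopifnot(all(phos >= 0 & phos <= 1), eta > 0)
  eta * mean(sync_scores) * (1 - phos)
}

#' Genetic algorithm configuration
#'
#' @param pop_size population size.
#' @param selection_fraction fraction of top performers kept each
#'   generation.
#' @param mutation_sigma_fraction Gaussian mutation scale as a fraction of
#'   each receptor count.
#' @param eta phosphorylation learning rate.
#' @param n_pairs_per_eval stimulus pairs per fitness evaluation.
#' @param generations number of generations to run.
#' @param panel_size number of distinct stimuli from which evaluation pairs
#'   are drawn.
#' @param resample_pairs if `TRUE`, redraw the evaluation pairs every
#'   generation; the default keeps one fixed panel per run so that fitness
#'   trajectories are comparable across generations.
#' @param init_scale_range range of the per-individual global synaptic
#'   density factor applied to the initial receptor counts.  Sampling each
#'   founder at a different overall density gives the population variance
#'   in aggregate synaptic strength that per-locus initialization alone
#'   cannot provide (locus averages concentrate sharply over ~10^3 edges),
#'   so that selection can act on both structure and overall gain.
#' @param seed integer run seed (drives stimulus sampling, initialization
#'   and the variation operators).
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 100, selection_fraction = 0.5,
                      mutation_sigma_fraction = 0.1, eta = 0.05,
                      n_pairs_per_eval = 10, generations = 50,
                      panel_size = 8, resample_pairs = FALSE,
                      init_scale_range = c(0.1, 1.2), seed = NULL) {
  stopifnot(pop_size >= 2, selection_fraction > 0, selection_fraction <= 1,
            mutation_sigma_fraction >= 0, eta >= 0, n_pairs_per_eval >= 1,
            generations >= 1, panel_size >= 2,
            length(init_scale_range) == 2, all(init_scale_range >= 0))
  structure(list(pop_size = pop_size,
                 selection_fraction = selection_fraction,
                 mutation_sigma_fraction = mutation_sigma_fraction,
                 eta = eta, n_pairs_per_eval = n_pairs_per_eval,
                 generations = generations, panel_size = panel_size,
                 resample_pairs = resample_pairs,
                 init_scale_range = init_scale_range, seed = seed),
            class = "ga_config")
}

#' Genome of an individual
#'
#' Flat view of the evolvable synaptic parameters: all per-edge AMPA
#' receptor counts and all phosphorylation fractions.
#'
#' @param n_total nonnegative numeric vector of receptor counts.
#' @param phos vector of fractions in \[0, 1\], same length.
#' @return An object of class `genome`.
#' @export
genome <- function(n_total, phos) {
  if (length(n_total) != length(phos))
    stop("genome fields must have equal length")
  if (any(n_total < 0)) stop("receptor counts must be nonnegative")
  if (any(phos < 0 | phos > 1)) stop("phos must lie in [0, 1]")
  structure(list(n_total = n_total, phos = phos), class = "genome")
}

# taste_network weights <-> flat genome
as_genome <- function(W) {
  genome(unlist(lapply(W, function(w) as.numeric(w$N))),
         unlist(lapply(W, function(w) as.numeric(w$Phos))))
}

genome_to_weights <- function(g, template) {
  W <- template
  off <- 0
  for (l in seq_along(W)) {
    n <- length(W[[l]]$N)
    idx <- off + seq_len(n)
    W[[l]]$N <- matrix(g$n_total[idx], nrow = nrow(W[[l]]$N))
    W[[l]]$Phos <- matrix(g$phos[idx], nrow = nrow(W[[l]]$Phos))
    off <- off + n
  }
  W
}

#' Rank selection: keep the top performers
#'
#' Keeps the `ceiling(length(pop) * fraction)` individuals with the highest
#' fitness; ties are broken by original index order (stable).
#'
#' @param pop list of individuals, each with a set `fitness` field.
#' @param fraction fraction to keep.
#' @return The surviving individuals, best first.
#' @export
select_top_half <- function(pop, fraction = 0.5) {
  fit <- vapply(pop, function(ind) {
    if (is.null(ind$fitness) || is.na(ind$fitness))
      stop("all individuals must be evaluated before selection")
    ind$fitness
  }, numeric(1))
  k <- ceiling(length(pop) * fraction)
  pop[order(-fit)[seq_len(k)]]
}

#' Uniform crossover of two genomes
#'
#' Each receptor count is drawn from either parent with probability 1/2.
#' Phosphorylation fractions are not mixed (they are adapted online by the
#' synchrony rule, not evolved); the child inherits the first parent's.
#'
#' @param p1,p2 [genome()] objects of equal length.
#' @param seed optional seed.
#' @return A child [genome()].
#' @export
crossover_uniform <- function(p1, p2, seed = NULL) {
  if (length(p1$n_total) != length(p2$n_total))
    stop("parent genomes must have equal length")
  if (!is.null(seed)) set.seed(seed)
  take1 <- runif(length(p1$n_total)) < 0.5
  genome(ifelse(take1, p1$n_total, p2$n_total), p1$phos)
}

#' Gaussian mutation of receptor counts
#'
#' Perturbs each receptor count with zero-mean Gaussian noise of standard
#' deviation `sigma_fraction * count`, rounds to the nearest integer and
#' clamps at zero.  Phosphorylation fractions are untouched.
#'
#' @param g a [genome()].
#' @param sigma_fraction mutation scale.
#' @param seed optional seed.
#' @return Mutated [genome()].
#' @export
mutate_gaussian <- function(g, sigma_fraction = 0.1, seed = NULL) {
  stopifnot(sigma_fraction >= 0)
  if (sigma_fraction == 0) return(g)
  if (!is.null(seed)) set.seed(seed)
  n <- g$n_total
  n2 <- round(n + rnorm(length(n), sd = sigma_fraction * n))
  genome(pmax(n2, 0), g$phos)
}

# Bin-resolution spike times of raw raster times.
bin_times <- function(times, dt_bin) unique(floor(times / dt_bin) * dt_bin)

# Per-gap matrices of minimal pre/post spike-time differences for one
# simulated response (bin resolution).  NA where either train is silent.
response_min_dists <- function(resp) {
  cfg <- resp$cfg
  pre <- lapply(resp$input_trains, bin_times, dt_bin = cfg$dt_bin)
  out <- vector("list", length(resp$rasters))
  for (l in seq_along(resp$rasters)) {
    post <- lapply(resp$rasters[[l]], bin_times, dt_bin = cfg$dt_bin)
    out[[l]] <- cpp_min_cross_dist(pre, post)
    pre <- post
  }
  out
}

# Largest observed |t_pre - t_post| over all connected spike pairs of a
# response (bin resolution): the normalizer D of the synchrony index.
# Layers are all-to-all connected, so the per-gap maximum is attained at
# the extreme spike times of the two populations.
response_max_interval <- function(resp) {
  cfg <- resp$cfg
  pre <- unlist(lapply(resp$input_trains, bin_times, dt_bin = cfg$dt_bin))
  best <- -Inf
  for (l in seq_along(resp$rasters)) {
    post <- unlist(lapply(resp$rasters[[l]], bin_times,
                          dt_bin = cfg$dt_bin))
    if (length(pre) && length(post))
      best <- max(best, max(pre) - min(post), max(post) - min(pre))
    pre <- post
  }
  if (is.finite(best)) best else NA_real_
}

# Evaluate one individual on the panel: returns per-stimulus responses,
# output patterns and fitness.
eval_individual <- function(ind, net_template, input_trains, pairs,
                            pair_idx, stim_ids, task, din_max) {
  net <- net_template
  net$W <- ind$W
  responses <- lapply(stim_ids, function(s)
    simulate_network(net, NULL, input_trains = input_trains[[s]]))
  names(responses) <- as.character(stim_ids)
  outputs <- lapply(seq_len(nrow(pair_idx)), function(i)
    list(responses[[as.character(pair_idx[i, 1])]]$output,
         responses[[as.character(pair_idx[i, 2])]]$output))
  fit <- task_loss(pairs, outputs, task = task, din_max = din_max)
  list(fitness = fit, responses = responses)
}

#' Train the taste network with the genetic algorithm
#'
#' Evolutionary loop over the synaptic genome: every generation, each
#' individual's network is simulated on a fixed panel of tastant stimuli and
#' scored with [task_loss()]; the top fraction survives (rank selection,
#' elitist retention), phosphorylation fractions receive the mean
#' synchrony-driven increment of the survivors (shared plasticity field,
#' clamped to \[0, 1\]), and the population is refilled by uniform crossover
#' of random survivor pairs followed by Gaussian mutation of the receptor
#' counts.  Fully seeded and reproducible.
#'
#' @param ga a [ga_config()].
#' @param net_cfg a [network_config()].
#' @param task 1 (hedonic-distance encoding) or 2 (pure/mixed
#'   discrimination).
#' @param progress print per-generation best fitness.
#' @return An object of class `gust_evolution`: list with `best_network`
#'   (a trained `taste_network`), `best_fitness`, `history` (best fitness
#'   per generation, generation 0 first), `panel`, `pairs`, and the
#'   configurations used.
#' @export
evolve <- function(ga = ga_config(), net_cfg = network_config(), task = 1,
                   progress = FALSE) {
  if (!is.null(ga$seed)) set.seed(ga$seed)
  task <- as.integer(task)
  stopifnot(task %in% c(1L, 2L))

  panel <- random_taste_panel(ga$panel_size)
  draw_pairs <- function() {
    idx <- t(replicate(ga$n_pairs_per_eval,
                       sample.int(length(panel), 2, replace = FALSE)))
    list(idx = idx,
         pairs = lapply(seq_len(nrow(idx)), function(i)
           stimulus_pair(panel[[idx[i, 1]]], panel[[idx[i, 2]]])))
  }
  pr <- draw_pairs()
  din_max <- NULL
  if (task == 2L)
    din_max <- max(vapply(pr$pairs, input_distance_task2, numeric(1)))

  # input transduction is genome-independent: simulate each panel stimulus once
  input_trains <- lapply(panel, function(s)
    simulate_input_trains(net_cfg, s))

  template <- build_network(net_cfg, seed = sample.int(2^31 - 1, 1))
  init_seeds <- sample.int(2^31 - 1, ga$pop_size)
  init_scales <- runif(ga$pop_size, ga$init_scale_range[1],
                       ga$init_scale_range[2])
  pop <- lapply(seq_len(ga$pop_size), function(i) {
    net <- build_network(net_cfg, seed = init_seeds[i],
                         scale = init_scales[i])
    list(W = net$W, fitness = NA_real_)
  })

  history <- numeric(ga$generations + 1)
  best <- NULL
  evals <- vector("list", ga$pop_size)

  for (gen in 0:ga$generations) {
    if (gen > 0 && ga$resample_pairs) {
      pr <- draw_pairs()
      if (task == 2L)
        din_max <- max(vapply(pr$pairs, input_distance_task2, numeric(1)))
    }
    stim_ids <- sort(unique(as.integer(pr$idx)))
    for (i in seq_along(pop)) {
      ev <- eval_individual(pop[[i]], template, input_trains, pr$pairs,
                            pr$idx, stim_ids, task, din_max)
      pop[[i]]$fitness <- ev$fitness
      evals[[i]] <- ev$responses
    }
    fits <- vapply(pop, `[[`, numeric(1), "fitness")
    gb <- which.max(fits)
    history[gen + 1] <- fits[gb]
    if (is.null(best) || fits[gb] >= best$fitness)
      best <- pop[[gb]]
    if (progress)
      message(sprintf("generation %d: best fitness %.4f", gen, fits[gb]))
    if (gen == ga$generations) break

    ord <- order(-fits)
    k <- ceiling(ga$pop_size * ga$selection_fraction)
    surv_ids <- ord[seq_len(k)]
    survivors <- pop[surv_ids]

    # synchrony-driven shared phosphorylation update from the survivors
    if (ga$eta > 0) {
      dmats <- lapply(surv_ids, function(i)
        lapply(evals[[i]], response_min_dists))
      D <- suppressWarnings(max(vapply(surv_ids, function(i)
        max(vapply(evals[[i]], response_max_interval, numeric(1)),
            na.rm = TRUE), numeric(1)), na.rm = TRUE))
      if (is.finite(D) && D > 0) {
        delta <- NULL
        for (si in seq_along(survivors)) {
          meanS <- lapply(seq_along(template$W), function(l) {
            ds <- lapply(dmats[[si]], `[[`, l)
            S <- lapply(ds, function(d) {
              s <- 0.5 - (d + net_cfg$dt_bin) / D
              s[is.na(s)] <- 0
              s
            })
            Reduce(`+`, S) / length(S)
          })
          dphos <- lapply(seq_along(meanS), function(l)
            ga$eta * meanS[[l]] * (1 - survivors[[si]]$W[[l]]$Phos))
          delta <- if (is.null(delta)) dphos
                   else lapply(seq_along(delta), function(l)
                     delta[[l]] + dphos[[l]])
        }
        delta <- lapply(delta, `/`, length(survivors))
        pop <- lapply(pop, function(ind) {
          for (l in seq_along(ind$W))
            ind$W[[l]]$Phos <- pmin(pmax(ind$W[[l]]$Phos + delta[[l]], 0), 1)
          ind
        })
        survivors <- pop[surv_ids]
      }
    }

    # elitist refill: survivors unchanged, offspring by crossover + mutation
    offspring <- vector("list", ga$pop_size - k)
    for (o in seq_along(offspring)) {
      par <- sample.int(k, 2, replace = k < 2)
      g1 <- as_genome(survivors[[par[1]]]$W)
      g2 <- as_genome(survivors[[par[2]]]$W)
      child <- mutate_gaussian(crossover_uniform(g1, g2),
                               ga$mutation_sigma_fraction)
      offspring[[o]] <- list(W = genome_to_weights(child, template$W),
                             fitness = NA_real_)
    }
    pop <- c(survivors, offspring)
  }

  best_net <- template
  best_net$W <- best$W
  structure(list(best_network = best_net, best_fitness = best$fitness,
                 history = history, panel = panel, pairs = pr$pairs,
                 ga = ga, net_cfg = net_cfg, task = task),
            class = "gust_evolution")
}
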