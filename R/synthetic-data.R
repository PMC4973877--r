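#' Generate one oddball stimulus block
#'
#' Either a Bernoulli sequence (i.i.d. draws with probability `p_high` for
#' the high tone -- the analytic model) or a fixed-count random permutation
#' with exactly `round(p_high * n_stimuli)` high tones (how oddball blocks
#' are delivered experimentally).  The default emulates the experimental
#' design: blocks of 400 tones, fixed counts.
#'
#' @param p_high probability of the high tone, in `(0, 1)`.
#' @param n_stimuli number of tones in the block.
#' @param mode `"fixed_count_permutation"` or `"bernoulli"`.
#' @param seed integer seed; the same seed reproduces the same block.
#' @param symbols tone labels, low first.
#' @return Character vector of tone symbols.
#' @export
generate_block <- function(p_high, n_stimuli = 400,
                           mode = c("fixed_count_permutation", "bernoulli"),
                           seed = 1, symbols = c("low", "high")) {
  if (p_high <= 0 || p_high >= 1) .stop_param("p_high must be in (0, 1)")
  if (n_stimuli < 1) .stop_param("n_stimuli must be >= 1")
  mode <- match.arg(mode)
  rng <- .seeded_rng(seed)
  if (mode == "bernoulli") {
    high <- rng$runif(n_stimuli) < p_high
  } else {
    n_high <- round(p_high * n_stimuli)
    high <- rng$sample_vec(rep(c(TRUE, FALSE), c(n_high, n_stimuli - n_high)))
  }
  symbols[high + 1L]
}

#' Define a synthetic surprise-coding neuron
#'
#' Ground-truth generative model for spike counts: on each trial a latent
#' representation state is *sampled* from the encoder `P(m | k)` of the
#' generating bank member, the prediction error `-log2 P(tone | m)` is
#' computed, and a count is drawn with mean `a * error + b` under Poisson or
#' Gaussian noise.  Sampling the latent state (rather than using the
#' expected error) makes the generated data genuinely probabilistic in the
#' state, which is exactly the uncertainty the analysis-side weighted
#' regression is built to handle.
#'
#' @param a slope, spikes per bit.
#' @param b baseline, spikes.
#' @param noise `"gaussian"` or `"poisson"`.
#' @param sigma Gaussian noise standard deviation (ignored for Poisson).
#' @param N_star memory duration of the generating representation.
#' @param complexity_star complexity (bits) of the generating representation.
#' @return An object of class `synthetic_neuron`.
#' @export
synthetic_neuron <- function(a = 2, b = 3, noise = c("gaussian", "poisson"),
                             sigma = 1, N_star = 10, complexity_star = 2) {
  noise <- match.arg(noise)
  structure(list(a = a, b = b, noise = noise, sigma = sigma,
                 N_star = as.integer(N_star),
                 complexity_star = complexity_star),
            class = "synthetic_neuron")
}

#' Generate spike counts for tone sequences from a synthetic neuron
#'
#' @param blocks a data frame with columns `block_id`, `condition`,
#'   `trial_index`, `tone` (e.g. built from [generate_block()] calls), or
#'   the `trials` component of an experiment.
#' @param neuron a [synthetic_neuron()].
#' @param bank a `rep_bank` containing the generating representation
#'   (`N_star` curve; the member nearest `complexity_star` is used).
#' @param seed integer seed for latent-state sampling and count noise.
#' @return The input data frame with a `spike_count` column appended; the
#'   generating representation and the Gaussian clip rate are attached as
#'   attributes `gen_rep` and `clip_rate`.
#' @export
generate_counts <- function(blocks, neuron, bank, seed = 1) {
  stopifnot(inherits(neuron, "synthetic_neuron"), inherits(bank, "rep_bank"))
  if (neuron$N_star > bank$n_max)
    .stop_param("bank has no curve for N = %d", neuron$N_star)
  rep_ <- curve_at_complexity(bank$curves[[neuron$N_star]],
                              neuron$complexity_star)
  symbols <- colnames(rep_$decoder)
  N <- rep_$N
  rng <- .seeded_rng(seed)
  out <- blocks
  out$spike_count <- NA_real_
  clip <- 0L
  for (b in unique(blocks$block_id)) {
    inb <- which(blocks$block_id == b)
    tb <- blocks$tone[inb]
    high <- as.integer(tb == symbols[2])
    cs <- c(0, cumsum(high))
    n <- length(tb)
    ## k from the N preceding within-block stimuli (truncated at block start;
    ## such early trials fall inside the analysis burn-in anyway)
    lo <- pmax(seq_len(n) - N, 1L)
    k <- cs[seq_len(n)] - cs[lo]
    M <- length(rep_$marginal)
    m <- vapply(seq_len(n), function(i)
      rng$sample_int(M, 1L, prob = rep_$encoder[k[i] + 1, ]), 0L)
    err <- -log2(rep_$decoder[cbind(m, match(tb, symbols))])
    mu <- neuron$a * err + neuron$b
    if (neuron$noise == "poisson") {
      clip <- clip + sum(mu < 0)
      y <- rng$rpois(n, pmax(mu, 0))
    } else {
      y <- round(rng$rnorm(n, mu, neuron$sigma))
      clip <- clip + sum(y < 0)
      y <- pmax(y, 0)
    }
    out$spike_count[inb] <- y
  }
  attr(out, "gen_rep") <- rep_
  attr(out, "clip_rate") <- clip / nrow(blocks)
  out
}

#' Generate a suite of synthetic oddball experiments
#'
#' Each experiment mirrors the recording design: paired oddball blocks of
#' 400 tones.  The `"main"` design uses the three blocks of the main
#' analysis (high-tone probabilities 10%, 50%, 90%); `"all_conditions"` adds
#' the 30% and 70% blocks.  Counts are generated for each neuron from its
#' ground-truth surprise-coding model, and the ground truth is stored with
#' the data.
#'
#' @param bank a `rep_bank`.
#' @param design `"main"` or `"all_conditions"`.
#' @param n_neurons number of neurons to simulate.
#' @param seed root seed; block sequences and each neuron's counts derive
#'   deterministic sub-seeds from it.
#' @param neuron a [synthetic_neuron()] used for every neuron (or a list of
#'   length `n_neurons`).
#' @param n_stimuli tones per block.
#' @param mode block generation mode, see [generate_block()].
#' @return A list of `synthetic_experiment` objects, each with `trials`
#'   (a trial table with `neuron_id`), and `ground_truth`.
#' @export
experiment_suite <- function(bank, design = c("main", "all_conditions"),
                             n_neurons = 1, seed = 1,
                             neuron = synthetic_neuron(),
                             n_stimuli = 400,
                             mode = "fixed_count_permutation") {
  design <- match.arg(design)
  conds <- if (design == "main") c(0.1, 0.5, 0.9) else c(0.1, 0.3, 0.5, 0.7, 0.9)
  if (!is.list(neuron) || inherits(neuron, "synthetic_neuron"))
    neuron <- rep(list(neuron), n_neurons)
  lapply(seq_len(n_neurons), function(i) {
    blocks <- do.call(rbind, lapply(seq_along(conds), function(j) {
      tones <- generate_block(conds[j], n_stimuli, mode = mode,
                              seed = seed * 1000L + i * 10L + j)
      data.frame(neuron_id = paste0("syn", i),
                 block_id = sprintf("b%02.0f", 100 * conds[j]),
                 condition = conds[j],
                 trial_index = seq_along(tones) - 1L,
                 tone = tones)
    }))
    trials <- generate_counts(blocks, neuron[[i]], bank,
                              seed = seed * 1000L + i * 10L + 9L)
    structure(list(trials = trials,
                   ground_truth = c(unclass(neuron[[i]]),
                                    list(design = design, seed = seed,
                                         mode = mode))),
              class = "synthetic_experiment")
  })
}

#' Write the ground truth of a synthetic experiment to a sidecar JSON
#'
#' @param experiment a `synthetic_experiment`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
ground_truth_to_json <- function(experiment, path) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  jsonlite::write_json(experiment$ground_truth, path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
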