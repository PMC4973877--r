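#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults matching
#' the reference analysis: bank of 50 memory durations x 200 complexity
#' levels, 50-trial burn-in, 0-330 ms counting window, 20 permutations,
#' population filter `rmax2 >= 0.1`, good-representation threshold at 90% of
#' `rmax2`.
#'
#' @param n_max,n_beta bank dimensions.
#' @param burn_in leading trials discarded per block.
#' @param window spike counting window in ms (used when spike times are
#'   supplied).
#' @param n_perm permutations for the significance test.
#' @param seed root seed; all randomness in a run derives from it.
#' @param min_rmax2 population-map inclusion threshold.
#' @param good_frac good-representation threshold as a fraction of `rmax2`.
#' @param simulate `NULL`, or a list with fields `n_neurons`, `design` and
#'   optionally `neuron` (a [synthetic_neuron()]) to generate data instead
#'   of reading it.
#' @param trials_path TSV of recorded trials (ignored when `simulate` is
#'   set).
#' @param bank_path optional JSON of a prebuilt bank (built fresh if `NULL`).
#' @return A `run_config` list.
#' @export
run_config <- function(n_max = 50, n_beta = 200, burn_in = 50,
                       window = c(0, 330), n_perm = 20, seed = 1,
                       min_rmax2 = 0.1, good_frac = 0.9,
                       simulate = NULL, trials_path = NULL,
                       bank_path = NULL) {
  structure(list(n_max = n_max, n_beta = n_beta, burn_in = burn_in,
                 window = window, n_perm = n_perm, seed = seed,
                 min_rmax2 = min_rmax2, good_frac = good_frac,
                 simulate = simulate, trials_path = trials_path,
                 bank_path = bank_path),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Builds (or loads) the representation bank, obtains trials (simulated or
#' from TSV), then for every neuron x test-frequency case runs the grid
#' search, the permutation significance test, the noise-variance /
#' explainable-variance partition, and the SSA index; finally assembles
#' population maps over all cases.  One failing case is logged and skipped;
#' the run continues.  The whole run is deterministic given the
#' configuration (including its seed).
#'
#' @param config a [run_config()].
#' @param out_dir output directory; created if missing.  Writes
#'   `summary.json`, `cases.tsv`, and `population_fraction.tsv`.
#' @param bank optionally, a prebuilt `rep_bank` (overrides config paths).
#' @param verbose print progress.
#' @return Invisibly, a list with `cases`, `maps`, `summary`, `bank`.
#' @export
run_pipeline <- function(config, out_dir, bank = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  if (is.null(bank)) {
    bank <- if (!is.null(config$bank_path)) bank_from_json(config$bank_path)
            else build_bank(config$n_max, config$n_beta, verbose = verbose)
  }

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    neuron <- if (is.null(sim$neuron)) synthetic_neuron() else sim$neuron
    exps <- experiment_suite(bank, design = sim$design %||% "main",
                             n_neurons = sim$n_neurons %||% 1,
                             seed = config$seed, neuron = neuron)
    trials <- do.call(rbind, lapply(exps, `[[`, "trials"))
  } else {
    if (is.null(config$trials_path))
      .stop_param("config needs either simulate or trials_path")
    trials <- read_trials(config$trials_path)
    if ("spike_times" %in% names(trials))
      trials <- count_in_window(trials, config$window)
  }

  symbols <- sort(unique(trials$tone))
  neurons <- unique(trials$neuron_id)
  cases <- list()
  grids <- list()
  for (id in neurons) {
    tn <- trials[trials$neuron_id == id, ]
    for (freq in symbols) {
      label <- paste(id, freq, sep = "/")
      res <- tryCatch({
        perm <- permutation_test(tn, bank, freq, n_perm = config$n_perm,
                                 seed = config$seed + match(id, neurons) * 100 +
                                   match(freq, symbols),
                                 burn_in = config$burn_in,
                                 good_frac = config$good_frac)
        g <- perm$grid
        nv <- noise_variance(tn, freq, burn_in = config$burn_in)
        retained <- tn$trial_index >= config$burn_in & tn$tone == freq
        vd <- explainable_fraction(g$rmax2, tn$spike_count[retained], nv)
        si <- tryCatch(ssa_index(tn), error = function(e) NULL)
        si_f <- if (!is.null(si)) si$si[si$freq == freq] else NA_real_
        grids[[label]] <- g
        list(neuron = id, freq = freq, rmax2 = g$rmax2,
             argmax_N = g$argmax$N, argmax_complexity = g$argmax$complexity,
             argmax_power = g$argmax$power, slope = g$argmax$slope,
             significant = perm$significant,
             permuted_max = max(perm$permuted),
             fraction_explained = vd$fraction_explained,
             fraction_explainable_conservative =
               vd$fraction_explainable_conservative,
             fraction_explainable_unbiased = vd$fraction_explainable_unbiased,
             si = si_f, flags = paste(vd$flags, collapse = ";"))
      }, error = function(e) {
        say("case %s failed: %s", label, conditionMessage(e))
        NULL
      })
      if (!is.null(res)) cases[[label]] <- res
      say("case %s done", label)
    }
  }
  if (!length(cases)) .stop_param("every case failed")
  case_df <- do.call(rbind, lapply(cases, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  maps <- tryCatch(population_maps(grids, min_rmax2 = config$min_rmax2),
                   error = function(e) NULL)

  summary <- list(
    config = unclass(config)[c("n_max", "n_beta", "burn_in", "n_perm",
                               "seed", "min_rmax2", "good_frac")],
    n_cases = nrow(case_df),
    n_significant = sum(case_df$significant),
    fraction_significant = mean(case_df$significant),
    median_rmax2 = stats::median(case_df$rmax2),
    cases = cases)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(case_df, file.path(out_dir, "cases.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(maps))
    write.table(maps$fraction, file.path(out_dir, "population_fraction.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(list(cases = case_df, maps = maps, summary = summary,
                 bank = bank))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
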