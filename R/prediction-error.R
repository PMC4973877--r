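#' Per-state prediction errors for one trial
#'
#' Given a reduced representation, a past count `k`, and the tone that
#' actually occurred, returns the set of possible prediction errors -- one
#' per representation state `m` -- together with the probability of being in
#' each state.  The error in state `m` is the surprise
#' `-log2 P(tone | m)` under the state's predictive distribution, and the
#' state probabilities are the encoder row `P(m | k)`.
#'
#' @param rep an `ib_rep`.
#' @param k count of high tones among the last `N` stimuli, `0 <= k <= N`.
#' @param tone the observed tone symbol (must match a decoder column).
#' @param drop_below state-weight threshold; lighter states are dropped and
#'   the remaining weights renormalised.
#' @return A data frame with columns `state`, `weight`, `error_bits`.
#' @export
per_state_errors <- function(rep, k, tone, drop_below = 1e-12) {
  stopifnot(inherits(rep, "ib_rep"))
  if (length(k) != 1L || k < 0 || k > rep$N || k != round(k))
    .stop_param("k must be an integer in [0, %d]", rep$N)
  if (!tone %in% colnames(rep$decoder))
    .stop_param("unknown tone '%s' (alphabet: %s)", tone,
                paste(colnames(rep$decoder), collapse = ", "))
  w <- rep$encoder[k + 1, ]
  if (abs(sum(w) - 1) > 1e-9)
    .stop_param("encoder row for k = %d does not sum to 1", k)
  e <- -log2(rep$decoder[, tone])
  keep <- w >= drop_below
  w <- w[keep] / sum(w[keep])
  data.frame(state = which(keep), weight = unname(w),
             error_bits = unname(e[keep]))
}

#' Expected prediction error for one trial
#'
#' State-probability-weighted average of the per-state surprises; this is the
#' expected value of the prediction error given that the last `N` stimuli
#' contained `k` high tones and the observed tone occurred.  Averaged over
#' the stationary joint distribution of `(k, tone)`, the expected prediction
#' error equals `H(future) - I(m; future)`.
#'
#' @inheritParams per_state_errors
#' @return Expected error in bits (strictly positive, finite).
#' @export
expected_error <- function(rep, k, tone) {
  pse <- per_state_errors(rep, k, tone)
  sum(pse$weight * pse$error_bits)
}

#' Prediction-error trace along a stimulus sequence
#'
#' Walks a tone sequence (optionally split into blocks) and produces, for
#' every retained trial, the state-probability weights and per-state errors
#' needed by the weighted regression, plus the expected error.  The past
#' count `k` is always computed from the `N` stimuli immediately preceding
#' the trial *within the same block*; representation state never crosses a
#' block boundary, and the first `burn_in` trials of each block are dropped
#' so that every retained trial has a fully defined past.
#'
#' @param rep an `ib_rep`.
#' @param tones character vector of tone symbols.
#' @param blocks optional block identifier per trial (same length as
#'   `tones`); `NULL` treats the whole sequence as one block.
#' @param burn_in number of leading trials discarded per block; must be at
#'   least `rep$N`.
#' @return An object of class `pe_trace`: data frame `trials` with columns
#'   `block`, `trial_index` (0-based within block), `tone`, `k`,
#'   `expected_error`, `n_states`, plus matrices `weights` and `errors`
#'   (retained trials x states) and the generating `rep` dimensions.
#' @export
trace_sequence <- function(rep, tones, blocks = NULL, burn_in = 50) {
  stopifnot(inherits(rep, "ib_rep"))
  if (burn_in < rep$N)
    .stop_param("burn_in (%d) must be >= N (%d): shorter burn-in leaves ill-defined pasts",
                burn_in, rep$N)
  if (is.null(blocks)) blocks <- rep_len("b1", length(tones))
  if (length(blocks) != length(tones))
    .stop_param("blocks and tones must have equal length")
  symbols <- colnames(rep$decoder)
  if (!all(tones %in% symbols))
    .stop_param("tones contain symbols outside the alphabet (%s)",
                paste(symbols, collapse = ", "))
  out <- lapply(unique(blocks), function(b) {
    tb <- tones[blocks == b]
    n <- length(tb)
    if (n <= burn_in)
      .stop_param("block '%s' has %d trials; more than burn_in = %d are required",
                  b, n, burn_in)
    high <- as.integer(tb == symbols[2])
    cs <- c(0L, cumsum(high))       # cs[i + 1] = highs among first i trials
    idx <- (burn_in + 1):n          # 1-based positions of retained trials
    k <- cs[idx] - cs[idx - rep$N]
    data.frame(block = b, trial_index = idx - 1L, tone = tb[idx], k = k)
  })
  tr <- do.call(rbind, out)
  W <- rep$encoder[tr$k + 1, , drop = FALSE]
  E <- matrix(0, nrow(tr), ncol(rep$encoder))
  for (s in symbols) {
    rows <- tr$tone == s
    if (any(rows)) E[rows, ] <- matrix(-log2(rep$decoder[, s]), sum(rows),
                                       ncol(rep$encoder), byrow = TRUE)
  }
  tr$expected_error <- rowSums(W * E)
  tr$n_states <- rowSums(W >= 1e-12)
  rownames(tr) <- NULL
  structure(list(trials = tr, weights = unname(W), errors = E,
                 N = rep$N, burn_in = as.integer(burn_in)),
            class = "pe_trace")
}

#' @export
print.pe_trace <- function(x, ...) {
  cat(sprintf("Prediction-error trace: %d retained trials (N = %d, burn-in %d), mean error %.3f bits\n",
              nrow(x$trials), x$N, x$burn_in, mean(x$trials$expected_error)))
  invisible(x)
}

#' Write a prediction-error trace to TSV
#'
#' @param trace a `pe_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
trace_to_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "pe_trace"))
  write.table(trace$trials, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
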