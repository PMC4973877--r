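#' Noise-variance estimate by conditioning on the recent stimulus context
#'
#' The noise variance is the trial-to-trial variability of the spike counts
#' that no stimulus-driven model could explain.  Ideally it is the variance
#' conditioned on the full past sequence; with a single presentation of each
#' long sequence that is not estimable, so the variance is conditioned on
#' the `context_len` immediately preceding tones (at most
#' `2^context_len = 128` contexts for the default 7) *and* on the block, which
#' partially accounts for the more remote past.  The estimate is the
#' group-size-weighted average of the within-group variances of the retained
#' trials of the analysed tone.  Two versions are returned: `unbiased`
#' (divisor `n - 1`; singleton groups excluded) and the conservative
#' `biased` (divisor `n`; singleton groups contribute 0), which can only
#' underestimate the noise.
#'
#' @param trials trial table for one neuron (all tones; columns `block_id`,
#'   `trial_index`, `tone`, `spike_count`).
#' @param test_freq tone whose responses are analysed.
#' @param context_len number of preceding stimuli defining the context.
#' @param burn_in leading trials discarded per block (must be >=
#'   `context_len` so every retained trial has a full context).
#' @return A list: `unbiased`, `biased`, `n_groups`, `n_singleton`,
#'   `flagged` (`TRUE` when all groups are singletons and the unbiased
#'   estimate is undefined).
#' @export
noise_variance <- function(trials, test_freq, context_len = 7, burn_in = 50) {
  if (burn_in < context_len)
    .stop_param("burn_in (%d) must be >= context_len (%d)", burn_in, context_len)
  gsize <- c()
  gvar <- c()
  for (b in unique(trials$block_id)) {
    tb <- trials[trials$block_id == b, ]
    tb <- tb[order(tb$trial_index), ]
    n <- nrow(tb)
    if (n <= burn_in) next
    idx <- (burn_in + 1):n
    idx <- idx[tb$tone[idx] == test_freq]
    if (!length(idx)) next
    ## context id: the exact preceding context_len-gram, encoded in binary
    ## (which symbol maps to 1 is irrelevant -- only group identity matters)
    is_high <- as.integer(tb$tone == sort(unique(trials$tone))[1])
    ctx <- vapply(idx, function(i)
      sum(is_high[(i - context_len):(i - 1)] * 2^(0:(context_len - 1))), 0)
    grp <- split(tb$spike_count[idx], ctx)
    gsize <- c(gsize, vapply(grp, length, 0L))
    gvar <- c(gvar, vapply(grp, function(y)
      if (length(y) > 1) var(y) else NA_real_, 0))
  }
  if (!length(gsize)) .stop_param("no retained trials of tone '%s'", test_freq)
  multi <- gsize > 1
  flagged <- !any(multi)
  unb <- if (flagged) NA_real_ else
    sum(gsize[multi] * gvar[multi]) / sum(gsize[multi])
  biased_v <- ifelse(multi, gvar * (gsize - 1) / gsize, 0)
  bia <- sum(gsize * biased_v) / sum(gsize)
  list(unbiased = unb, biased = bia, n_groups = length(gsize),
       n_singleton = sum(!multi), flagged = flagged)
}

#' Partition response variance into explained, explainable, and noise parts
#'
#' The fraction of explained variance is the best weighted r2 divided by the
#' total variance scale, i.e. `rmax2` itself.  The fraction of *explainable*
#' variance divides the predictor variance by the total variance minus the
#' noise variance -- the ceiling any stimulus-driven model could reach.  Both
#' noise estimates from [noise_variance()] are applied: the unbiased
#' estimate may over-correct, yielding fractions below 0 or above 1, which
#' are reported as-is and flagged; the conservative (biased) estimate
#' under-corrects and stays in `[0, 1]` on well-sampled data.
#'
#' @param r2 fraction of explained variance (typically `rmax2` from
#'   [grid_search()]).
#' @param counts the spike counts entering the fit (used for the total
#'   variance).
#' @param noise a list with `unbiased` and `biased` noise-variance
#'   estimates, as returned by [noise_variance()].
#' @return An object of class `variance_decomposition` with fields
#'   `total_variance`, `predictor_variance`, `noise`,
#'   `fraction_explained`, `fraction_explainable_unbiased`,
#'   `fraction_explainable_conservative`, `flags`.
#' @export
explainable_fraction <- function(r2, counts, noise) {
  tot <- var(counts)
  pred <- r2 * tot
  frac <- function(nv) {
    if (is.na(nv)) return(NA_real_)
    denom <- tot - nv
    if (denom <= 0) return(NA_real_)
    pred / denom
  }
  fu <- frac(noise$unbiased)
  fc <- frac(noise$biased)
  flags <- character()
  if (is.na(fu)) flags <- c(flags, "unbiased_undefined")
  else if (fu < 0 || fu > 1) flags <- c(flags, "unbiased_outside_unit")
  if (is.na(fc)) flags <- c(flags, "conservative_undefined")
  structure(list(total_variance = tot, predictor_variance = pred,
                 noise = noise, fraction_explained = r2,
                 fraction_explainable_unbiased = fu,
                 fraction_explainable_conservative = fc,
                 flags = flags),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(
    "Variance partition: explained %.3f; explainable %.3f (conservative) / %.3f (unbiased)%s\n",
    x$fraction_explained, x$fraction_explainable_conservative,
    x$fraction_explainable_unbiased,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Stimulus-specific adaptation index
#'
#' Per tone frequency `f`, computes the mean response when `f` was the
#' deviant (rare tone, 10% block) and when it was the standard (common tone,
#' 90% block), and the standard contrast
#' `SI(f) = (d(f) - s(f)) / (d(f) + s(f))`.  `SI > 0` means a stronger
#' response to the tone when rare -- the signature of stimulus-specific
#' adaptation.
#'
#' @param trials trial table for one neuron with a `condition` column giving
#'   the high-tone probability of each block; must include blocks where each
#'   analysed frequency appears at 10% and at 90%.
#' @param high_tone the tone symbol whose probability the `condition` column
#'   states (the other tone occurs with one minus that probability).
#' @param rare,common probabilities identifying the deviant and standard
#'   blocks for the high tone (defaults 0.1 and 0.9).
#' @return An object of class `ssa_result`: data frame with columns `freq`,
#'   `deviant_mean`, `standard_mean`, `si`, `flagged`.
#' @export
ssa_index <- function(trials, high_tone = "high", rare = 0.1, common = 0.9) {
  symbols <- unique(trials$tone)
  if (!high_tone %in% symbols)
    .stop_param("high_tone '%s' does not occur in the trials", high_tone)
  rows <- lapply(sort(symbols), function(f) {
    ## the high tone occurs with probability `condition`; the other tone
    ## with 1 - condition.  A tone is deviant in the block where its own
    ## probability is `rare`.
    p_f <- if (f == high_tone) trials$condition else 1 - trials$condition
    d_set <- trials$tone == f & abs(p_f - rare) < 1e-9
    s_set <- trials$tone == f & abs(p_f - common) < 1e-9
    if (!any(d_set) || !any(s_set))
      .stop_param("frequency '%s' is missing a %g%% or %g%% block",
                  f, 100 * rare, 100 * common)
    d <- mean(trials$spike_count[d_set])
    s <- mean(trials$spike_count[s_set])
    flagged <- (d + s) == 0
    data.frame(freq = f, deviant_mean = d, standard_mean = s,
               si = if (flagged) NA_real_ else (d - s) / (d + s),
               flagged = flagged)
  })
  structure(do.call(rbind, rows), class = c("ssa_result", "data.frame"))
}
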