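#' Weighted linear regression of spike counts on prediction errors
#'
#' Each trial is expanded into its set of per-state (error, count) pairs,
#' weighted by the state probabilities `P(m | past)`; weighted least squares
#' is then applied to the expanded set.  The goodness of fit is the weighted
#' coefficient of determination
#' `r2 = 1 - SS_res,w / SS_tot,w` (deviations taken around the weighted
#' mean).  With a deterministic representation every trial has a single
#' state, and the fit reduces exactly to ordinary least squares of counts on
#' expected errors.
#'
#' @param trials a data frame with a `spike_count` column plus `block_id` and
#'   `trial_index` used to align to the trace (typically the trials of one
#'   neuron whose tone equals the test frequency).
#' @param trace a [trace_sequence()] result computed from the full tone
#'   sequence of the same blocks.
#' @return An object of class `fit_result`: `slope` (spikes per bit),
#'   `intercept` (spikes), `weighted_r2`, `n_trials`.
#' @export
weighted_regression <- function(trials, trace) {
  stopifnot(inherits(trace, "pe_trace"))
  key_tr <- paste(trials$block_id, trials$trial_index)
  key_pe <- paste(trace$trials$block, trace$trials$trial_index)
  pos <- match(key_tr, key_pe)
  if (anyNA(pos))
    .stop_param("%d trials have no matching trace entry (burn-in or block mismatch)",
                sum(is.na(pos)))
  if (nrow(trials) < 3) .stop_param("at least 3 trials are required")
  .wls_expand(trials$spike_count, trace$weights[pos, , drop = FALSE],
              trace$errors[pos, , drop = FALSE])
}

## closed-form WLS on the (trial x state) expansion:
## observations (E[i,m], y[i]) with weights W[i,m]; rows of W sum to 1.
.wls_expand <- function(y, W, E) {
  n <- length(y)
  sw <- n # total weight: each row sums to 1
  swx <- sum(W * E)
  swxx <- sum(W * E * E)
  swy <- sum(y)
  swyy <- sum(y * y)
  swxy <- sum(y * rowSums(W * E))
  sxx <- swxx - swx^2 / sw
  syy <- swyy - swy^2 / sw
  sxy <- swxy - swx * swy / sw
  if (syy <= 0) {
    warning("zero spike-count variance; weighted_r2 set to 0")
    return(structure(list(slope = 0, intercept = mean(y), weighted_r2 = 0,
                          n_trials = n), class = "fit_result"))
  }
  if (sxx <= .Machine$double.eps * max(1, swxx)) {
    ## constant predictor: no explainable structure
    return(structure(list(slope = NA_real_, intercept = mean(y),
                          weighted_r2 = 0, n_trials = n),
                     class = "fit_result"))
  }
  slope <- sxy / sxx
  intercept <- (swy - slope * swx) / sw
  r2 <- sxy^2 / (sxx * syy)
  structure(list(slope = slope, intercept = intercept,
                 weighted_r2 = r2, n_trials = n),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Weighted fit: slope %.3f spikes/bit, intercept %.3f spikes, r2 = %.4f (n = %d)\n",
              x$slope, x$intercept, x$weighted_r2, x$n_trials))
  invisible(x)
}

## Per-N sufficient statistics of the test-frequency trials:
## counts and response sums per past-count value k, enough to evaluate the
## weighted regression for every representation of that N in O(M^2).
.grid_kstats <- function(blocks, tones, counts, idx_test, N, burn_in, high_symbol) {
  n_k <- integer(N + 1)
  sy <- numeric(N + 1)
  syy <- numeric(N + 1)
  for (b in unique(blocks)) {
    inb <- blocks == b
    tb <- tones[inb]
    yb <- counts[inb]
    testb <- idx_test[inb]
    cs <- c(0L, cumsum(as.integer(tb == high_symbol)))
    idx <- (burn_in + 1):length(tb)
    idx <- idx[testb[idx]]
    if (!length(idx)) next
    k <- cs[idx] - cs[idx - N]
    tab <- tabulate(k + 1L, N + 1L)
    n_k <- n_k + tab
    sy <- sy + vapply(0:N, function(kk) sum(yb[idx][k == kk]), 0)
    syy <- syy + vapply(0:N, function(kk) sum(yb[idx][k == kk]^2), 0)
  }
  list(n_k = n_k, sy = sy, syy = syy)
}

## weighted r2 / slope for one representation from k-aggregated stats
.wls_from_kstats <- function(rep, ks, tone) {
  e <- -log2(rep$decoder[, tone])
  enc <- rep$encoder
  cm <- as.vector(ks$n_k %*% enc)         # total weight per state
  sym <- as.vector(ks$sy %*% enc)         # weighted response sum per state
  sw <- sum(ks$n_k)
  swx <- sum(cm * e)
  swxx <- sum(cm * e * e)
  swy <- sum(ks$sy)
  swyy <- sum(ks$syy)
  swxy <- sum(sym * e)
  sxx <- swxx - swx^2 / sw
  syy <- swyy - swy^2 / sw
  sxy <- swxy - swx * swy / sw
  if (syy <= 0 || sxx <= .Machine$double.eps * max(1, swxx))
    return(c(r2 = 0, slope = NA_real_))
  c(r2 = sxy^2 / (sxx * syy), slope = sxy / sxx)
}

#' Grid search of the representation bank against one neuron's responses
#'
#' Evaluates the weighted regression of spike counts on prediction errors for
#' every representation in the bank (all memory durations and complexity
#' levels), for the trials whose tone equals the test frequency.  Records
#' the full r2 surface, the best score `rmax2`, its argmax (ties broken
#' toward the smallest `N`, then the smallest complexity -- the most
#' parsimonious representation), and the set of "good" representations
#' achieving at least `good_frac * rmax2`.
#'
#' @param trials trial table for one neuron: columns `block_id`,
#'   `trial_index`, `tone`, `spike_count` (all trials of all blocks, both
#'   tones -- the full sequence is needed to compute pasts).
#' @param bank a `rep_bank`.
#' @param test_freq the tone whose responses are analysed (`"low"` or
#'   `"high"`).
#' @param burn_in leading trials discarded per block.
#' @param good_frac fraction of `rmax2` defining the good-representation set.
#' @return An object of class `grid_result`: `r2` matrix (`n_max x n_beta`),
#'   `rmax2`, `argmax` (list: `N`, `index`, `complexity`, `power`, `slope`),
#'   `good_set` logical matrix, `complexity` and `power` matrices, and
#'   bookkeeping fields.
#' @export
grid_search <- function(trials, bank, test_freq, burn_in = 50,
                        good_frac = 0.9) {
  stopifnot(inherits(bank, "rep_bank"))
  symbols <- colnames(bank$curves[[1]]$points[[1]]$decoder)
  if (!test_freq %in% symbols)
    .stop_param("test_freq must be one of: %s", paste(symbols, collapse = ", "))
  blocks <- trials$block_id
  tones <- trials$tone
  counts <- trials$spike_count
  idx_test <- tones == test_freq
  n_retained <- sum(vapply(unique(blocks), function(b) {
    inb <- blocks == b
    n <- sum(inb)
    if (n <= burn_in) 0L else sum(idx_test[inb][(burn_in + 1):n])
  }, 0L))
  r2 <- matrix(NA_real_, bank$n_max, bank$n_beta)
  slope <- matrix(NA_real_, bank$n_max, bank$n_beta)
  cxm <- matrix(NA_real_, bank$n_max, bank$n_beta)
  pwm <- matrix(NA_real_, bank$n_max, bank$n_beta)
  for (N in seq_len(bank$n_max)) {
    ks <- .grid_kstats(blocks, tones, counts, idx_test, N, burn_in, symbols[2])
    cv <- bank$curves[[N]]
    for (j in seq_along(cv$points)) {
      f <- .wls_from_kstats(cv$points[[j]], ks, test_freq)
      r2[N, j] <- f["r2"]
      slope[N, j] <- f["slope"]
    }
    cxm[N, ] <- cv$complexity
    pwm[N, ] <- cv$power
  }
  rmax2 <- max(r2)
  ## argmax with ties toward smallest N, then smallest complexity
  hits <- which(r2 == rmax2, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], cxm[hits]), , drop = FALSE]
  iN <- hits[1, 1]
  ij <- hits[1, 2]
  good <- r2 >= good_frac * rmax2
  structure(list(r2 = r2, rmax2 = rmax2,
                 argmax = list(N = as.integer(iN), index = as.integer(ij),
                               complexity = cxm[iN, ij], power = pwm[iN, ij],
                               slope = slope[iN, ij]),
                 good_set = good, complexity = cxm, power = pwm,
                 test_freq = test_freq, n_trials = n_retained,
                 good_frac = good_frac),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf(
    "Grid result (%s tone, %d trials): rmax2 = %.4f at N = %d, complexity %.3f bits (good set: %d/%d)\n",
    x$test_freq, x$n_trials, x$rmax2, x$argmax$N, x$argmax$complexity,
    sum(x$good_set), length(x$good_set)))
  invisible(x)
}

#' Permutation test of the best grid score
#'
#' The observed `rmax2` is the maximum over the whole bank, so its null
#' distribution is assessed by permutation: the tone sequence is randomly
#' permuted within each block (responses stay attached to their trial
#' slots, and tone probabilities per block are preserved), and the full grid
#' search is recomputed.  The effect is significant at nominal
#' `p < 1 / (n_perm + 1)` if the observed `rmax2` strictly exceeds all
#' permuted values.
#'
#' @inheritParams grid_search
#' @param n_perm number of permutations (>= 1; default 20 gives p < 0.048).
#' @param seed integer seed governing all permutations.
#' @return An object of class `permutation_result`: `observed`, `permuted`
#'   (length `n_perm`), `significant`, and the observed `grid`.
#' @export
permutation_test <- function(trials, bank, test_freq, n_perm = 20, seed = 1,
                             burn_in = 50, good_frac = 0.9) {
  if (n_perm < 1) .stop_param("n_perm must be >= 1")
  obs <- grid_search(trials, bank, test_freq, burn_in, good_frac)
  perm_vals <- numeric(n_perm)
  rng <- .seeded_rng(seed)
  for (i in seq_len(n_perm)) {
    pt <- trials
    for (b in unique(pt$block_id)) {
      inb <- pt$block_id == b
      pt$tone[inb] <- rng$sample_vec(pt$tone[inb])
    }
    perm_vals[i] <- grid_search(pt, bank, test_freq, burn_in, good_frac)$rmax2
  }
  structure(list(observed = obs$rmax2, permuted = perm_vals,
                 significant = obs$rmax2 > max(perm_vals), grid = obs,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: observed rmax2 = %.4f vs max permuted %.4f over %d permutations -> %ssignificant\n",
              x$observed, max(x$permuted), x$n_perm,
              if (x$significant) "" else "NOT "))
  invisible(x)
}

## self-contained RNG stream so package functions never disturb the caller's
## .Random.seed
.seeded_rng <- function(seed) {
  env <- new.env()
  local_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      assign("state", get(".Random.seed", globalenv()), env)
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    if (is.null(env$state)) set.seed(seed)
    else assign(".Random.seed", env$state, globalenv())
    expr
  }
  list(
    sample_vec = function(x) local_seed(sample(x)),
    sample_int = function(n, size, prob = NULL)
      local_seed(sample.int(n, size, replace = TRUE, prob = prob)),
    rpois = function(n, lambda) local_seed(rpois(n, lambda)),
    rnorm = function(n, mean, sd) local_seed(rnorm(n, mean, sd)),
    runif = function(n) local_seed(runif(n))
  )
}

#' Test whether evoked responses exceed the spontaneous rate
#'
#' One-sided rank-based two-sample comparison (Wilcoxon/Mann-Whitney) of
#' evoked versus spontaneous spike counts at level `alpha`.
#'
#' @param evoked evoked spike counts.
#' @param spontaneous spontaneous spike counts.
#' @param alpha significance level.
#' @return `TRUE` if evoked counts are significantly larger.
#' @export
response_significance <- function(evoked, spontaneous, alpha = 0.05) {
  if (!length(evoked) || !length(spontaneous))
    .stop_param("both samples must be nonempty")
  if (length(unique(c(evoked, spontaneous))) == 1L) return(FALSE)
  p <- suppressWarnings(
    wilcox.test(evoked, spontaneous, alternative = "greater", exact = FALSE)$p.value)
  isTRUE(p < alpha)
}

#' Population maps of good representations
#'
#' For each representation in the bank, computes the fraction of analysed
#' cases (neuron x test-frequency combinations with `rmax2 >= min_rmax2`)
#' whose good-representation set contains it.  The fractions are reported on
#' the native (memory duration x complexity index) grid and projected onto
#' three binned planes: complexity x predictive power, duration x
#' complexity, and duration x predictive power.  A projected cell holds the
#' maximum fraction over the representations falling in it, so a cell is
#' "good for most cases" whenever some representation at those coordinates
#' is.
#'
#' @param grids list of `grid_result` objects (one per case), all from the
#'   same bank.
#' @param min_rmax2 minimum `rmax2` for a case to enter the analysis.
#' @param n_bins number of bins per projected axis.
#' @return An object of class `population_maps`: `fraction` matrix
#'   (`n_max x n_beta`), binned matrices `cx_pw`, `N_cx`, `N_pw` with bin
#'   break attributes, and `n_cases`.
#' @export
population_maps <- function(grids, min_rmax2 = 0.1, n_bins = 40) {
  keep <- vapply(grids, function(g) g$rmax2 >= min_rmax2, TRUE)
  if (!any(keep))
    .stop_param("no case passes the rmax2 >= %.2f filter", min_rmax2)
  grids <- grids[keep]
  frac <- Reduce(`+`, lapply(grids, function(g) g$good_set * 1)) / length(grids)
  cx <- grids[[1]]$complexity
  pw <- grids[[1]]$power
  Nm <- row(frac)
  bin_map <- function(xv, yv, xbr, ybr) {
    xi <- findInterval(xv, xbr, rightmost.closed = TRUE, all.inside = TRUE)
    yi <- findInterval(yv, ybr, rightmost.closed = TRUE, all.inside = TRUE)
    m <- matrix(0, length(xbr) - 1, length(ybr) - 1)
    for (q in seq_along(xv)) m[xi[q], yi[q]] <- max(m[xi[q], yi[q]], frac[q])
    attr(m, "xbreaks") <- xbr
    attr(m, "ybreaks") <- ybr
    m
  }
  cx_br <- seq(0, max(cx), length.out = n_bins + 1)
  pw_br <- seq(0, max(pw), length.out = n_bins + 1)
  N_br <- seq(0.5, nrow(frac) + 0.5, by = 1)
  structure(list(fraction = frac,
                 cx_pw = bin_map(cx, pw, cx_br, pw_br),
                 N_cx = bin_map(Nm, cx, N_br, cx_br),
                 N_pw = bin_map(Nm, pw, N_br, pw_br),
                 n_cases = length(grids), min_rmax2 = min_rmax2),
            class = "population_maps")
}

#' Extract a contour mask from a population map
#'
#' @param map a binned matrix from [population_maps()].
#' @param level fraction threshold (default 0.5, the 50% contour).
#' @return Logical matrix marking cells at or above `level`.
#' @export
map_contour <- function(map, level = 0.5) {
  m <- map >= level
  attributes(m) <- attributes(map)
  m
}
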