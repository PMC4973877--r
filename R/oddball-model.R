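#' Define an oddball sequence world
#'
#' An oddball "world" is a stationary Bernoulli model of a two-tone sequence:
#' before a block starts, the probability `p` of the high tone is drawn from a
#' Beta prior (uniform by default), and tones are then drawn i.i.d. with that
#' probability.  Under this model the number of high tones among the last `N`
#' stimuli is a minimal sufficient statistic for predicting the next tone.
#'
#' @param N memory duration: number of past stimuli retained (integer >= 1).
#' @param symbols ordered pair of tone labels, low tone first.
#' @param prior shape parameters `c(a, b)` of the Beta prior on the high-tone
#'   probability.  The default `c(1, 1)` is the uniform prior; alternative
#'   priors are supported but the uniform prior is the reference analysis.
#' @return An object of class `oddball_world`.
#' @examples
#' w <- oddball_world(4)
#' posterior_next(0:4, w)
#' @export
oddball_world <- function(N, symbols = c("low", "high"), prior = c(1, 1)) {
  if (length(N) != 1L || !is.numeric(N) || is.na(N) || N < 1 || N != round(N))
    .stop_param("N must be a single integer >= 1 (got %s)", format(N))
  if (length(symbols) != 2L || anyDuplicated(symbols))
    .stop_param("exactly two distinct symbols are required")
  if (length(prior) != 2L || any(prior <= 0))
    .stop_param("prior must be two positive Beta shape parameters")
  structure(list(N = as.integer(N), symbols = as.character(symbols),
                 prior = as.numeric(prior)),
            class = "oddball_world")
}

#' @export
print.oddball_world <- function(x, ...) {
  cat(sprintf("Oddball world: N = %d, symbols = (%s), Beta(%g, %g) prior on p\n",
              x$N, paste(x$symbols, collapse = ", "), x$prior[1], x$prior[2]))
  invisible(x)
}

#' Joint distribution of the past-count sufficient statistic and the next tone
#'
#' Computes the exact joint probability of `k` (the number of high tones among
#' the last `N` stimuli) and the next tone, after marginalising the unknown
#' tone probability over its prior.  For the uniform prior this is
#' `P(k, high) = (k + 1) / ((N + 1)(N + 2))` and
#' `P(k, low) = (N - k + 1) / ((N + 1)(N + 2))`; the marginal of `k` is
#' uniform, `1 / (N + 1)`.
#'
#' @param world an [oddball_world()].
#' @return An object of class `joint_table` with elements `N`, `symbols`,
#'   `p_joint` (an `(N + 1) x 2` matrix over `(k, future)`), `p_k`, and
#'   `p_future_given_k`.
#' @examples
#' jt <- joint_suffstat(oddball_world(4))
#' jt$p_joint["k=0", "high"]  # 1/30
#' @export
joint_suffstat <- function(world) {
  stopifnot(inherits(world, "oddball_world"))
  N <- world$N
  a <- world$prior[1]
  b <- world$prior[2]
  k <- 0:N
  ## P(k, high) = C(N,k) * B(k+a+1, N-k+b) / B(a,b); uniform prior reduces to
  ## (k+1)/((N+1)(N+2)).  Computed in log space for numerical safety.
  lC <- lchoose(N, k)
  p_high <- exp(lC + lbeta(k + a + 1, N - k + b) - lbeta(a, b))
  p_low  <- exp(lC + lbeta(k + a, N - k + b + 1) - lbeta(a, b))
  pj <- cbind(p_low, p_high)
  dimnames(pj) <- list(paste0("k=", k), world$symbols)
  pj <- pj / sum(pj) # remove last-digit rounding; analytically already 1
  p_k <- rowSums(pj)
  structure(list(N = N, symbols = world$symbols, p_joint = pj, p_k = p_k,
                 p_future_given_k = pj / p_k),
            class = "joint_table")
}

#' @export
print.joint_table <- function(x, ...) {
  cat(sprintf("Joint table over (k, next tone), N = %d\n", x$N))
  print(round(x$p_joint, 5))
  invisible(x)
}

#' Predictive probability of the high tone given the past count
#'
#' Posterior-predictive probability that the next tone is the high tone, given
#' that `k` of the last `N` tones were high.  For the uniform prior this is
#' `(k + 1) / (N + 2)` (Laplace's rule of succession); it is strictly
#' increasing in `k` and never reaches 0 or 1, so the surprise of any outcome
#' is finite.
#'
#' @param k count of high tones in the past window; vectorised, `0 <= k <= N`.
#' @param world an [oddball_world()].
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
posterior_next <- function(k, world) {
  stopifnot(inherits(world, "oddball_world"))
  if (any(k < 0 | k > world$N | k != round(k)))
    .stop_param("k must be integers in [0, %d]", world$N)
  (k + world$prior[1]) / (world$N + sum(world$prior))
}

#' Joint distribution over full past sequences and the next tone
#'
#' Expands the sufficient-statistic joint table onto the full alphabet of
#' `2^N` ordered past sequences.  All orderings with the same count `k` are
#' exchangeable, so each sequence with `k` high tones has probability
#' `P(k, future) / choose(N, k)`.  This representation exists as a small-`N`
#' oracle (for entropies of the full past and cross-checks); the analysis
#' itself runs on the sufficient-statistic alphabet.
#'
#' @param world an [oddball_world()]; requires `N <= 20`.
#' @return A list with `p_joint` (a `2^N x 2` matrix, rows named by the tone
#'   sequence), `k` (high-tone count per sequence), and `N`.
#' @export
sequence_joint <- function(world) {
  stopifnot(inherits(world, "oddball_world"))
  N <- world$N
  if (N > 20)
    .stop_param("sequence_joint enumerates 2^N pasts; N = %d exceeds the N <= 20 limit", N)
  jt <- joint_suffstat(world)
  ## enumerate all binary pasts; bit j of i gives the tone at position j
  idx <- 0:(2^N - 1)
  bits <- vapply(idx, function(i) as.integer(intToBits(i)[1:N]), integer(N))
  bits <- if (N == 1) matrix(bits, nrow = 1) else bits
  k <- colSums(bits)
  pj <- jt$p_joint[k + 1, , drop = FALSE] / choose(N, k)
  labels <- apply(bits + 1, 2, function(b)
    paste(substr(world$symbols[b], 1, 1), collapse = ""))
  dimnames(pj) <- list(labels, world$symbols)
  list(N = N, p_joint = pj, k = k)
}

#' Entropies and mutual information of a joint table
#'
#' All quantities in bits.  For the uniform-prior model the entropy of the
#' sufficient statistic is exactly `log2(N + 1)` (uniform marginal over `k`),
#' the entropy of the next tone is 1 bit (symmetry), and the predictive
#' information is
#' `I(k; future) = H(future) - sum_k p(k) H_b((k + 1) / (N + 2))`.
#'
#' @param joint a `joint_table` from [joint_suffstat()].
#' @return A list with `H_past_summary` (entropy of `k`), `H_future`, and
#'   `I_k_future`.
#' @examples
#' info_quantities(joint_suffstat(oddball_world(10)))$I_k_future  # ~0.223
#' @export
info_quantities <- function(joint) {
  stopifnot(inherits(joint, "joint_table"))
  list(H_past_summary = .ent2(joint$p_k),
       H_future = .ent2(colSums(joint$p_joint)),
       I_k_future = .mi2(joint$p_joint))
}

#' Serialise a joint table to JSON
#'
#' @param joint a `joint_table`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly if written to file.
#' @export
joint_to_json <- function(joint, path = NULL) {
  stopifnot(inherits(joint, "joint_table"))
  x <- list(N = joint$N, symbols = joint$symbols,
            p_joint = as.vector(joint$p_joint))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
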