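## Banks are expensive to build, so they are cached per test run.
.bank_cache <- new.env()

## medium bank for recovery / property tests
test_bank <- function() {
  if (is.null(.bank_cache$A))
    .bank_cache$A <- build_bank(n_max = 20, n_beta = 50)
  .bank_cache$A
}

## small bank for calibration loops
small_bank <- function() {
  if (is.null(.bank_cache$B))
    .bank_cache$B <- build_bank(n_max = 8, n_beta = 15)
  .bank_cache$B
}

cached_curve <- function(N, n_points = 200) {
  key <- sprintf("cv%d_%d", N, n_points)
  if (is.null(.bank_cache[[key]]))
    .bank_cache[[key]] <- sweep_beta(joint_suffstat(oddball_world(N)),
                                     n_points = n_points)
  .bank_cache[[key]]
}

## deterministic sufficient-statistic representation (identity encoder)
suffstat_rep <- function(N) {
  ib_fixed_point(joint_suffstat(oddball_world(N)), beta = 1e6,
                 init = diag(N + 1))
}

## all set partitions of 1..n as membership vectors (restricted growth
## strings) -- oracle for hard-clustering dominance
set_partitions <- function(n) {
  out <- list()
  grow <- function(a, mx) {
    i <- length(a) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- a
      return(invisible())
    }
    for (g in seq_len(mx + 1L)) grow(c(a, g), max(mx, g))
  }
  grow(integer(0), 0L)
  out
}

## numeric-quadrature oracle for the posterior predictive of the high tone:
## P(high | k) = integral p * p^k (1-p)^(N-k) dp / integral p^k (1-p)^(N-k) dp
posterior_oracle <- function(k, N) {
  num <- stats::integrate(function(p) p^(k + 1) * (1 - p)^(N - k), 0, 1,
                          rel.tol = 1e-12)$value
  den <- stats::integrate(function(p) p^k * (1 - p)^(N - k), 0, 1,
                          rel.tol = 1e-12)$value
  num / den
}

## simple three-block oddball trial table with externally supplied counts
make_trials <- function(tones_by_block, counts_by_block,
                        conditions = NULL) {
  blocks <- names(tones_by_block)
  do.call(rbind, lapply(seq_along(blocks), function(i) {
    tones <- tones_by_block[[i]]
    data.frame(neuron_id = "n1", block_id = blocks[i],
               condition = if (is.null(conditions)) NA_real_ else conditions[i],
               trial_index = seq_along(tones) - 1L,
               tone = tones,
               spike_count = counts_by_block[[i]])
  }))
}
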