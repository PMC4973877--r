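#' Solve the Information Bottleneck self-consistent equations at one beta
#'
#' Finds a fixed point of the three Information Bottleneck equations for the
#' encoder `P(m|k)`, marginal `P(m)` and decoder `P(future|m)` on the
#' sufficient-statistic alphabet `k = 0..N`.  The tradeoff multiplier `beta`
#' controls the balance between the complexity `I(k; m)` (penalised) and the
#' predictive power `I(m; future)` (rewarded): `beta = 0` collapses the
#' encoder to a single effective state, `beta -> Inf` recovers the
#' deterministic sufficient-statistic encoder.
#'
#' @param joint a `joint_table` from [joint_suffstat()].
#' @param beta nonnegative tradeoff multiplier.
#' @param n_states number of representation states `M`; defaults to the input
#'   alphabet size `N + 1` (more states cannot help).
#' @param init initial encoder, an `(N + 1) x n_states` row-stochastic
#'   matrix; defaults to uniform rows plus a fixed deterministic perturbation
#'   that breaks state symmetry.
#' @param tol convergence threshold: largest per-row total-variation change
#'   of the encoder between successive iterations.
#' @param max_iter iteration cap.  Non-convergence is flagged on the result
#'   (with the last iterate and residual), not raised as an error.
#' @return An object of class `ib_rep`: `N`, `beta`, `encoder`, `decoder`,
#'   `marginal`, `complexity` (bits), `predictive_power` (bits),
#'   `converged`, `residual`, `n_iter`.
#' @examples
#' jt <- joint_suffstat(oddball_world(4))
#' r <- ib_fixed_point(jt, beta = 100)
#' c(r$complexity, r$predictive_power)
#' @export
ib_fixed_point <- function(joint, beta, n_states = NULL, init = NULL,
                           tol = 1e-10, max_iter = 1e5) {
  stopifnot(inherits(joint, "joint_table"))
  if (length(beta) != 1L || is.na(beta) || beta < 0)
    .stop_param("beta must be a single nonnegative number")
  K <- joint$N + 1L
  if (is.null(n_states)) n_states <- K
  if (n_states < 1) .stop_param("n_states must be >= 1")
  if (is.null(init)) {
    init <- matrix(1 / n_states, K, n_states) + .ib_perturbation(K, n_states)
    init <- init / rowSums(init)
  }
  if (!is.matrix(init) || nrow(init) != K || ncol(init) != n_states ||
      any(init < 0) || any(abs(rowSums(init) - 1) > 1e-8))
    .stop_param("init must be a %d x %d row-stochastic matrix", K, n_states)
  fp <- .ib_core(joint$p_future_given_k, joint$p_k, beta, init,
                 tol, as.integer(max_iter))
  .ib_rep_from_core(fp, joint, beta)
}

## fixed deterministic symmetry-breaking pattern, amplitude eps
.ib_perturbation <- function(K, M, eps = 0.01) {
  eps * (0.5 + 0.5 * sin(outer(seq_len(K), seq_len(M)) + seq_len(K)))
}

.ib_rep_from_core <- function(fp, joint, beta) {
  enc <- fp$encoder
  dec <- fp$decoder
  pm <- fp$marginal
  dimnames(enc) <- list(rownames(joint$p_joint), NULL)
  colnames(dec) <- joint$symbols
  ## complexity I(k;m) and predictive power I(m;future), bits
  cx <- .mi2(enc * joint$p_k)
  pw <- .mi2(dec * pm)
  structure(list(N = joint$N, beta = beta, encoder = enc, decoder = dec,
                 marginal = pm, p_input = joint$p_k,
                 complexity = cx, predictive_power = pw,
                 converged = fp$converged, residual = fp$residual,
                 n_iter = fp$iterations),
            class = "ib_rep")
}

#' @export
print.ib_rep <- function(x, ...) {
  cat(sprintf(
    "IB representation: N = %d, beta = %.4g, complexity = %.4f bits,\n  predictive power = %.4f bits, %d effective states%s\n",
    x$N, x$beta, x$complexity, x$predictive_power, effective_states(x),
    if (x$converged) "" else sprintf(" [NOT converged, residual %.2g]", x$residual)))
  invisible(x)
}

#' Trace the complexity/predictive-power tradeoff curve for one memory length
#'
#' Deterministic-annealing sweep over the tradeoff multiplier: beta ascends a
#' geometric grid, each solution warm-starts the next (with a small fixed
#' perturbation allowing cluster splits), and the grid is extended and
#' refined adaptively until the curve spans the complexity range
#' `[~0, log2(N + 1)]` with no gap larger than `gap` bits.  From the solved
#' family, `n_points` representations are selected with complexities closest
#' to a uniform grid over the attained range.  The procedure involves no
#' random numbers, so the curve is reproducible bit-for-bit.
#'
#' @param joint a `joint_table`.
#' @param n_points number of representations returned (>= 2).
#' @param gap largest allowed complexity gap between neighbouring solutions,
#'   in bits, before adaptive beta refinement stops.
#' @param tol,max_iter passed to the fixed-point solver.
#' @param beta_min starting (smallest) beta of the annealing schedule.
#' @param explore_iter iteration budget for exploration solves along the
#'   annealing path; selected points that did not converge within it are
#'   re-polished with `polish_iter` iterations.  Near-critical betas can
#'   remain flagged as unconverged at residuals around `1e-6`, which moves
#'   information quantities by far less than the curve resolution.
#' @param polish_iter iteration budget for the polish pass.
#' @return An object of class `tradeoff_curve`: `N`, `points` (list of
#'   `ib_rep` sorted by complexity), and vectors `complexity`, `power`,
#'   `beta`.
#' @examples
#' \donttest{
#' cv <- sweep_beta(joint_suffstat(oddball_world(4)), n_points = 50)
#' power_at_complexity(cv, 1.0)  # ~0.134
#' }
#' @export
sweep_beta <- function(joint, n_points = 200, gap = 0.1, tol = 1e-10,
                       max_iter = 1e5, beta_min = 0.8,
                       explore_iter = 10000, polish_iter = 20000) {
  stopifnot(inherits(joint, "joint_table"))
  if (n_points < 2) .stop_param("n_points must be >= 2")
  K <- joint$N + 1L
  max_cx <- log2(K)
  pert <- .ib_perturbation(K, K)
  fresh <- matrix(1 / K, K, K) + pert
  fresh <- fresh / rowSums(fresh)
  iden <- diag(K)

  solve_one <- function(beta, enc0, iter) {
    fp <- .ib_core(joint$p_future_given_k, joint$p_k, beta, enc0,
                   tol, as.integer(iter))
    .ib_rep_from_core(fp, joint, beta)
  }
  ## Warm starts can show hysteresis: the iterate sticks to a branch with
  ## merged states well past that branch's critical beta.  Each beta is
  ## therefore solved from three inits -- the annealing warm start, a fresh
  ## near-uniform init, and the identity encoder -- and the fixed point with
  ## the lowest Lagrangian I(k;m) - beta * I(m;future) wins.  Exploration
  ## solves use a capped iteration budget; the selected curve points are
  ## polished at the full budget afterwards.
  solve_at <- function(beta, warm, iter = explore_iter) {
    enc0 <- 0.95 * warm + 0.05 * pert
    enc0 <- enc0 / rowSums(enc0)
    cands <- list(solve_one(beta, enc0, iter))
    wcx <- cands[[1]]$complexity
    ## alternative inits only where their branch can win: the fresh init
    ## near the first transitions, the identity init near the top
    if (wcx < 2) cands <- c(cands, list(solve_one(beta, fresh, iter)))
    if (wcx > 0.5 * max_cx) cands <- c(cands, list(solve_one(beta, iden, iter)))
    lag <- vapply(cands, function(r) r$complexity - beta * r$predictive_power, 0)
    cands[[which.min(lag)]]
  }

  ## ascend a geometric beta grid until >99.9% of max complexity is reached
  reps <- list()
  beta <- beta_min
  warm <- matrix(1 / K, K, K)
  repeat {
    r <- solve_at(beta, warm)
    reps[[length(reps) + 1L]] <- r
    warm <- r$encoder
    if (r$complexity >= 0.999 * max_cx || beta > 1e8) break
    beta <- beta * 1.25
  }
  if (reps[[length(reps)]]$complexity < 0.999 * max_cx)
    reps[[length(reps) + 1L]] <- solve_one(1e8, iden, max_iter)
  if (reps[[1]]$complexity >= 0.01) {
    ## starting beta was past the first transition; prepend smaller betas
    beta <- beta_min
    pre <- list()
    while (beta > 1e-3) {
      beta <- beta / 2
      r <- solve_at(beta, matrix(1 / K, K, K))
      pre[[length(pre) + 1L]] <- r
      if (r$complexity < 0.01) break
    }
    reps <- c(rev(pre), reps)
  }

  ## adaptive refinement: bisect (in log beta) any complexity gap > `gap`
  for (round in 1:8) {
    cx <- vapply(reps, `[[`, 0, "complexity")
    o <- order(cx)
    reps <- reps[o]
    cx <- cx[o]
    wide <- which(diff(cx) > gap)
    if (!length(wide)) break
    add <- lapply(wide, function(i) {
      b <- sqrt(reps[[i]]$beta * reps[[i + 1]]$beta)
      solve_at(b, reps[[i]]$encoder)
    })
    reps <- c(reps, add)
  }

  ## keep the solutions nearest a uniform complexity grid, polish them at
  ## the full iteration budget
  cx <- vapply(reps, `[[`, 0, "complexity")
  o <- order(cx)
  reps <- reps[o]
  cx <- cx[o]
  targets <- seq(0, max(cx), length.out = n_points)
  pick <- unique(vapply(targets, function(t) which.min(abs(cx - t)), 0L))
  reps <- lapply(reps[pick], function(r)
    if (r$converged) r else solve_one(r$beta, r$encoder, polish_iter))
  cx <- vapply(reps, `[[`, 0, "complexity")
  o <- order(cx)
  reps <- reps[o]
  cx <- cx[o]

  ## Remaining gaps sit at first-order transitions, where no single fixed
  ## point exists at intermediate complexity.  The information curve is
  ## nevertheless attained there by time-sharing: concatenating the state
  ## spaces of the two bracketing solutions with weights (t, 1 - t) gives a
  ## valid representation whose complexity and power interpolate linearly,
  ## staying on the concave envelope.
  fill <- list()
  for (i in which(diff(cx) > gap)) {
    width <- cx[i + 1] - cx[i]
    nmid <- ceiling(width / (gap / 2)) - 1
    ts <- seq_len(nmid) / (nmid + 1)
    fill <- c(fill, lapply(ts, function(t) .ib_mix(reps[[i]], reps[[i + 1]], t)))
  }
  reps <- c(reps, fill)
  cx <- vapply(reps, `[[`, 0, "complexity")
  o <- order(cx)
  reps <- reps[o]
  cx <- cx[o]
  if (max(diff(cx)) > gap)
    warning(sprintf("N = %d: residual complexity gap %.3f bits after refinement",
                    joint$N, max(diff(cx))))

  ## final selection: n_points nearest a uniform complexity target grid
  targets <- seq(0, max(cx), length.out = n_points)
  pick <- vapply(targets, function(t) which.min(abs(cx - t)), 0L)
  pts <- reps[pick]
  structure(list(N = joint$N, points = pts,
                 complexity = vapply(pts, `[[`, 0, "complexity"),
                 power = vapply(pts, `[[`, 0, "predictive_power"),
                 beta = vapply(pts, `[[`, 0, "beta")),
            class = "tradeoff_curve")
}

## time-sharing mixture of two representations: weight (1 - t) on `lo`,
## t on `hi`; the combined state space is the concatenation of both.
.ib_mix <- function(lo, hi, t) {
  enc <- cbind((1 - t) * lo$encoder, t * hi$encoder)
  dec <- rbind(lo$decoder, hi$decoder)
  pm <- c((1 - t) * lo$marginal, t * hi$marginal)
  structure(list(N = lo$N, p_input = lo$p_input,
                 beta = exp((1 - t) * log(lo$beta) + t * log(hi$beta)),
                 encoder = enc, decoder = dec, marginal = pm,
                 complexity = (1 - t) * lo$complexity + t * hi$complexity,
                 predictive_power = (1 - t) * lo$predictive_power +
                   t * hi$predictive_power,
                 converged = lo$converged && hi$converged,
                 residual = max(lo$residual, hi$residual),
                 n_iter = 0L, timeshare = t),
            class = "ib_rep")
}

#' @export
print.tradeoff_curve <- function(x, ...) {
  cat(sprintf(
    "Tradeoff curve: N = %d, %d points, complexity in [%.4f, %.4f] bits, max power %.4f bits\n",
    x$N, length(x$points), min(x$complexity), max(x$complexity), max(x$power)))
  invisible(x)
}

#' Extract the curve point at a requested complexity
#'
#' Returns the representation on the curve whose complexity is nearest to
#' `bits`.  For a scalar predictive-power readout at exactly the requested
#' complexity, use [power_at_complexity()], which linearly interpolates
#' between the two bracketing curve points.
#'
#' @param curve a `tradeoff_curve`.
#' @param bits requested complexity in bits, within the curve range.
#' @return An `ib_rep`.
#' @export
curve_at_complexity <- function(curve, bits) {
  stopifnot(inherits(curve, "tradeoff_curve"))
  hi <- max(curve$complexity)
  if (length(bits) != 1L || is.na(bits) || bits < 0 || bits > hi)
    .stop_param("bits must lie in [0, %.4f] for this curve", hi)
  curve$points[[which.min(abs(curve$complexity - bits))]]
}

#' Interpolated predictive power at a given complexity
#'
#' @param curve a `tradeoff_curve`.
#' @param bits complexity in bits, within the curve range.
#' @return Predictive power in bits, linearly interpolated between the
#'   bracketing curve points.
#' @export
power_at_complexity <- function(curve, bits) {
  stopifnot(inherits(curve, "tradeoff_curve"))
  hi <- max(curve$complexity)
  if (any(bits < 0 | bits > hi))
    .stop_param("bits must lie in [0, %.4f] for this curve", hi)
  approx(curve$complexity, curve$power, xout = bits, ties = max)$y
}

#' Count the effective states of a representation
#'
#' Duplicate states -- numerically identical clusters that the solver never
#' separated -- are merged, and states with marginal mass at most
#' `mass_threshold` are then discarded; the count of remaining states is
#' returned.  Two states are duplicates when both their decoders
#' `P(future|m)` and their input posteriors `P(k|m)` agree to within
#' `merge_tol` in total variation: sharing a decoder alone is not enough
#' (distinct pasts can make identical predictions, as the full-past
#' representation shows).
#'
#' @param rep an `ib_rep`.
#' @param mass_threshold minimum marginal probability for a state to count.
#' @param merge_tol total-variation threshold under which two states are
#'   considered duplicates.
#' @return Integer state count.
#' @export
effective_states <- function(rep, mass_threshold = 1e-3, merge_tol = 1e-6) {
  stopifnot(inherits(rep, "ib_rep"))
  pm <- rep$marginal
  dec <- rep$decoder
  ## posterior over inputs per state, P(k|m)
  post <- t(rep$encoder * rep$p_input)
  alive <- pm > 0
  post[alive, ] <- post[alive, ] / pm[alive]
  M <- length(pm)
  grp <- integer(M)
  g <- 0L
  for (m in seq_len(M)) {
    if (grp[m] != 0L) next
    g <- g + 1L
    grp[m] <- g
    if (m < M) for (j in (m + 1):M) {
      if (grp[j] == 0L &&
          0.5 * sum(abs(dec[m, ] - dec[j, ])) < merge_tol &&
          0.5 * sum(abs(post[m, ] - post[j, ])) < merge_tol)
        grp[j] <- g
    }
  }
  mass <- vapply(split(pm, grp), sum, 0)
  sum(mass > mass_threshold)
}

#' Build the full bank of optimal reduced representations
#'
#' One tradeoff curve per memory length `N = 1..n_max`, each with `n_beta`
#' representations spanning the complexity range, mirroring the grid used in
#' the population analysis (default 50 x 200 = 10,000 representations).
#'
#' @param n_max largest memory duration.
#' @param n_beta representations per curve.
#' @param prior Beta prior passed to [oddball_world()].
#' @param gap,tol,max_iter passed to [sweep_beta()].
#' @param verbose print progress per curve.
#' @return An object of class `rep_bank`: list of curves indexed by `N`,
#'   plus `n_max`, `n_beta`.
#' @export
build_bank <- function(n_max = 50, n_beta = 200, prior = c(1, 1), gap = 0.1,
                       tol = 1e-10, max_iter = 1e5, verbose = FALSE) {
  curves <- vector("list", n_max)
  for (N in seq_len(n_max)) {
    jt <- joint_suffstat(oddball_world(N, prior = prior))
    curves[[N]] <- sweep_beta(jt, n_points = n_beta, gap = gap, tol = tol,
                              max_iter = max_iter)
    if (verbose) message(sprintf("N = %d done (%d points)", N, n_beta))
  }
  structure(list(curves = curves, n_max = as.integer(n_max),
                 n_beta = as.integer(n_beta)),
            class = "rep_bank")
}

#' @export
print.rep_bank <- function(x, ...) {
  cat(sprintf("Representation bank: N = 1..%d, %d points per curve (%d representations)\n",
              x$n_max, x$n_beta, x$n_max * x$n_beta))
  invisible(x)
}

#' Serialise a representation bank to JSON
#'
#' @param bank a `rep_bank`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
bank_to_json <- function(bank, path) {
  stopifnot(inherits(bank, "rep_bank"))
  out <- list(n_max = bank$n_max, n_beta = bank$n_beta,
              symbols = colnames(bank$curves[[1]]$points[[1]]$decoder),
              curves = lapply(bank$curves, function(cv)
                lapply(cv$points, function(r)
                  list(N = r$N, beta = r$beta,
                       encoder = as.vector(r$encoder),
                       decoder = as.vector(r$decoder),
                       marginal = r$marginal,
                       p_input = r$p_input,
                       complexity = r$complexity,
                       predictive_power = r$predictive_power,
                       converged = r$converged))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a representation bank from JSON
#'
#' @param path file written by [bank_to_json()].
#' @return A `rep_bank`.
#' @export
bank_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  curves <- lapply(x$curves, function(cv) {
    pts <- lapply(cv, function(r) {
      K <- r$N + 1L
      marg <- unlist(r$marginal)
      M <- length(marg)
      dec <- matrix(unlist(r$decoder), M, 2)
      colnames(dec) <- unlist(x$symbols)
      structure(list(N = as.integer(r$N), beta = r$beta,
                     encoder = matrix(unlist(r$encoder), K, M),
                     decoder = dec,
                     marginal = marg,
                     p_input = unlist(r$p_input),
                     complexity = r$complexity,
                     predictive_power = r$predictive_power,
                     converged = isTRUE(r$converged),
                     residual = NA_real_, n_iter = NA_integer_),
                class = "ib_rep")
    })
    structure(list(N = pts[[1]]$N, points = pts,
                   complexity = vapply(pts, `[[`, 0, "complexity"),
                   power = vapply(pts, `[[`, 0, "predictive_power"),
                   beta = vapply(pts, `[[`, 0, "beta")),
              class = "tradeoff_curve")
  })
  structure(list(curves = curves, n_max = as.integer(x$n_max),
                 n_beta = as.integer(x$n_beta)),
            class = "rep_bank")
}
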