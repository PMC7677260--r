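#' Differential-evolution MCMC with sampling from past states
#'
#' A DREAM-ZS-style sampler: each chain proposes jumps formed from the
#' difference of two states drawn from a growing archive of past states,
#' scaled by 2.38/sqrt(2d) (with periodic full-length jumps, gamma = 1,
#' for mode hopping), plus a small jitter; with probability
#' `p_snooker` a snooker update is used instead (a jump along the line
#' from an archived state through the current state, with the
#' dimension-dependent Jacobian in the acceptance ratio). The archive
#' is seeded with Latin-hypercube draws from the prior box and appended
#' with the current chain states every `archive_stride` iterations.
#' Bounds are enforced by rejection (the log-posterior is `-Inf`
#' outside). Runs are bit-reproducible given `seed`.
#'
#' @param logpost function(theta numeric vector) -> log-posterior.
#' @param lower,upper prior box bounds (numeric vectors of length d).
#' @param n_chains number of parallel chains (>= 3).
#' @param n_iter iterations per chain.
#' @param seed integer RNG seed.
#' @param thin store every `thin`-th state.
#' @param init optional d x n_chains matrix of starting states; default
#'   the best prior draws from the initial archive.
#' @param archive optional matrix (states x d) carried over from a
#'   previous run (used when extending a run).
#' @param p_snooker probability of a snooker update, default 0.1.
#' @param shift_idx optional indices of time-lag coordinates; when
#'   given, a symmetric single-coordinate shift of one lag by a half or
#'   full grid step (+-5 or +-10 min) is proposed with probability
#'   `p_shift`, letting chains hop between the lag posterior's
#'   half-interval modes.
#' @param p_shift probability of the lag-shift move, default 0.1 when
#'   `shift_idx` is given.
#' @param archive_stride append chain states to the archive every this
#'   many iterations.
#' @param jitter_sd sd of the proposal jitter relative to the box width.
#' @param param_names optional parameter names for the output.
#' @return object of class `posterior_chains`: list with `samples`
#'   (array n_stored x d x n_chains), `logpost` (n_stored x n_chains),
#'   `accept_rate`, `archive`, `last_state`, `lower`, `upper`, `seed`,
#'   `thin`.
#' @export
run_sampler <- function(logpost, lower, upper, n_chains = 3, n_iter = 5000,
                        seed = 1, thin = 1, init = NULL, archive = NULL,
                        p_snooker = 0.1, archive_stride = 10,
                        jitter_sd = 1e-6, param_names = NULL,
                        shift_idx = NULL, p_shift = 0.1) {
  stopifnot(n_chains >= 3, length(lower) == length(upper), all(lower < upper))
  d <- length(lower)
  set.seed(seed)
  width <- upper - lower
  m0 <- max(10L * d, 100L)
  Z0 <- lhs::randomLHS(m0, d)
  Z <- sweep(sweep(Z0, 2, width, "*"), 2, lower, "+")
  if (!is.null(archive)) Z <- rbind(archive, Z)
  # chain starts: best of a batch of prior draws unless given
  if (is.null(init)) {
    n_try <- min(nrow(Z), max(5L * n_chains, 50L))
    cand <- Z[seq_len(n_try), , drop = FALSE]
    lp_cand <- apply(cand, 1, logpost)
    if (!any(is.finite(lp_cand))) {
      stop("could not initialise: log-posterior is -Inf at every prior draw")
    }
    ord <- order(lp_cand, decreasing = TRUE)[seq_len(n_chains)]
    X <- t(cand[ord, , drop = FALSE])
    lpX <- lp_cand[ord]
  } else {
    X <- init
    lpX <- apply(X, 2, logpost)
    if (!all(is.finite(lpX))) stop("supplied initial states have non-finite log-posterior")
  }
  n_store <- floor(n_iter / thin)
  samples <- array(NA_real_, c(n_store, d, n_chains))
  lp_store <- matrix(NA_real_, n_store, n_chains)
  # preallocate archive growth
  n_app <- floor(n_iter / archive_stride) * n_chains
  Zbig <- matrix(NA_real_, nrow(Z) + n_app, d)
  Zbig[seq_len(nrow(Z)), ] <- Z
  nZ <- nrow(Z)
  gamma0 <- 2.38 / sqrt(2 * d)
  eff_shift <- if (is.null(shift_idx)) 0 else p_shift
  n_acc <- 0L
  for (it in seq_len(n_iter)) {
    for (ch in seq_len(n_chains)) {
      x <- X[, ch]
      u_move <- stats::runif(1)
      if (u_move < eff_shift) {
        j <- if (length(shift_idx) == 1L) shift_idx else sample(shift_idx, 1L)
        prop <- x
        prop[j] <- x[j] + sample(c(-10, -5, 5, 10), 1L)
        if (prop[j] < lower[j] || prop[j] > upper[j]) next
        lp_prop <- logpost(prop)
        if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lpX[ch]) {
          X[, ch] <- prop; lpX[ch] <- lp_prop; n_acc <- n_acc + 1L
        }
      } else if (u_move < eff_shift + p_snooker) {
        r <- sample.int(nZ, 3L)
        z <- Zbig[r[1L], ]
        e <- x - z
        en2 <- sum(e * e)
        if (en2 < 1e-300) next
        pr1 <- sum(Zbig[r[2L], ] * e) / en2 * e
        pr2 <- sum(Zbig[r[3L], ] * e) / en2 * e
        gs <- stats::runif(1, 1.2, 2.2)
        prop <- x + gs * (pr1 - pr2)
        if (any(prop < lower | prop > upper)) next
        lp_prop <- logpost(prop)
        if (is.finite(lp_prop)) {
          jac <- (d - 1) / 2 * (log(sum((prop - z)^2)) - log(en2))
          if (log(stats::runif(1)) < lp_prop - lpX[ch] + jac) {
            X[, ch] <- prop; lpX[ch] <- lp_prop; n_acc <- n_acc + 1L
          }
        }
      } else {
        r <- sample.int(nZ, 2L)
        # DREAM-style crossover: jump in a random subspace of dimensions
        cr <- sample(c(0.34, 0.67, 1), 1L)
        mask <- stats::runif(d) < cr
        if (!any(mask)) mask[sample.int(d, 1L)] <- TRUE
        d_eff <- sum(mask)
        gam <- if (it %% 10L == 0L) 1 else 2.38 / sqrt(2 * d_eff)
        jump <- (Zbig[r[1L], ] - Zbig[r[2L], ]) * mask
        prop <- x + gam * jump + stats::rnorm(d, 0, jitter_sd) * width * mask
        if (any(prop < lower | prop > upper)) next
        lp_prop <- logpost(prop)
        if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lpX[ch]) {
          X[, ch] <- prop; lpX[ch] <- lp_prop; n_acc <- n_acc + 1L
        }
      }
    }
    if (it %% archive_stride == 0L) {
      Zbig[nZ + seq_len(n_chains), ] <- t(X)
      nZ <- nZ + n_chains
    }
    if (it %% thin == 0L) {
      k <- it %/% thin
      samples[k, , ] <- X
      lp_store[k, ] <- lpX
    }
  }
  if (!is.null(param_names)) dimnames(samples)[[2]] <- param_names
  structure(list(
    samples = samples, logpost = lp_store,
    accept_rate = n_acc / (n_iter * n_chains),
    archive = Zbig[seq_len(nZ), , drop = FALSE],
    last_state = X, last_logpost = lpX,
    lower = lower, upper = upper, seed = seed, thin = thin
  ), class = "posterior_chains")
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat(sprintf("<posterior_chains: %d chains x %d stored states x %d parameters, accept %.1f%%>\n",
              dim(x$samples)[3], dim(x$samples)[1], dim(x$samples)[2],
              100 * x$accept_rate))
  invisible(x)
}

# second-half retained states as a list of matrices (one per chain)
retained_states <- function(chains) {
  n <- dim(chains$samples)[1]
  keep <- seq.int(floor(n / 2) + 1L, n)
  lapply(seq_len(dim(chains$samples)[3]),
         function(ch) chains$samples[keep, , ch, drop = FALSE][, , 1, drop = TRUE])
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computed per parameter on the second halves of the chains; the model
#' is flagged converged when every R-hat is below `threshold`.
#' Parameters with zero between- and within-chain variance (constant
#' chains) are reported as 1 with a warning.
#'
#' @param chains a [run_sampler()] result (or array n x d x m).
#' @param threshold convergence threshold, default 1.1.
#' @return list with `rhat` (named numeric) and `converged` (logical).
#' @export
gelman_rubin <- function(chains, threshold = 1.1) {
  arr <- if (inherits(chains, "posterior_chains")) chains$samples else chains
  stopifnot(length(dim(arr)) == 3, dim(arr)[3] >= 2, dim(arr)[1] >= 4)
  n_all <- dim(arr)[1]
  keep <- seq.int(floor(n_all / 2) + 1L, n_all)
  arr <- arr[keep, , , drop = FALSE]
  n <- dim(arr)[1]; d <- dim(arr)[2]; m <- dim(arr)[3]
  rhat <- numeric(d)
  for (j in seq_len(d)) {
    ch <- arr[, j, ]
    means <- colMeans(ch)
    vars <- apply(ch, 2, stats::var)
    W <- mean(vars)
    B_n <- stats::var(means)  # B/n
    if (W < 1e-300 && B_n < 1e-300) {
      warning("constant chains for parameter ", j, "; R-hat reported as 1")
      rhat[j] <- 1
    } else if (W < 1e-300) {
      rhat[j] <- Inf
    } else {
      v_hat <- (n - 1) / n * W + B_n * (1 + 1 / m)
      rhat[j] <- sqrt(v_hat / W)
    }
  }
  names(rhat) <- dimnames(arr)[[2]]
  list(rhat = rhat, converged = max(rhat) < threshold)
}

#' Maximum a posteriori estimate from stored chains
#'
#' The retained (second-half) state with the highest stored
#' log-posterior; ties broken by the earliest (chain, iteration).
#'
#' @param chains a [run_sampler()] result.
#' @return named parameter vector with attribute `logpost`.
#' @export
map_estimate <- function(chains) {
  n <- dim(chains$samples)[1]
  keep <- seq.int(floor(n / 2) + 1L, n)
  best <- -Inf; best_state <- NULL
  for (ch in seq_len(dim(chains$samples)[3])) {
    lp <- chains$logpost[keep, ch]
    i <- which.max(lp)  # earliest max within the chain
    if (lp[i] > best) {
      best <- lp[i]
      best_state <- chains$samples[keep[i], , ch]
    }
  }
  nm <- dimnames(chains$samples)[[2]]
  if (!is.null(nm)) names(best_state) <- nm
  attr(best_state, "logpost") <- best
  best_state
}

#' Draw parameter vectors from the retained posterior states
#'
#' Uniform resampling with replacement from the pooled second halves of
#' all chains, seeded for reproducibility.
#'
#' @param chains a [run_sampler()] result.
#' @param n number of draws (default 3000).
#' @param seed RNG seed.
#' @return matrix n x d (named columns).
#' @export
posterior_draws <- function(chains, n = 3000, seed = 1) {
  pool <- do.call(rbind, retained_states(chains))
  if (n == 0L) return(pool[0, , drop = FALSE])
  if (nrow(pool) < 10 * n) {
    warning("thin posterior: only ", nrow(pool), " retained states for ", n, " draws")
  }
  set.seed(seed)
  out <- pool[sample.int(nrow(pool), n, replace = TRUE), , drop = FALSE]
  colnames(out) <- dimnames(chains$samples)[[2]]
  out
}

#' Fit the hierarchical sap flow model by adaptive DE-MC
#'
#' Compiles the log-posterior, runs [run_sampler()] in rounds of
#' `block_iter` iterations (each round resuming from the previous
#' chains' final states and archive) until the Gelman-Rubin diagnostic
#' on the accumulated chains falls below 1.1 or `max_rounds` is
#' reached.
#'
#' @param data list of [tree_dataset()] objects.
#' @param priors a [prior_spec()]; default built from the data's tree
#'   labels.
#' @param Ca scalar CO2 concentration, or `NULL` to use per-row values.
#' @param n_chains,block_iter,max_rounds,thin sampler schedule.
#' @param seed integer seed (each round r uses `seed + r - 1`).
#' @param init optional d x n_chains start matrix.
#' @param polish_map refine the maximum a posteriori estimate by a
#'   bounded quasi-Newton search started from the best sampled state
#'   (default TRUE); the refined vector is returned as element `map`.
#' @param ... passed to [run_sampler()].
#' @return `posterior_chains` with extra elements `rhat`, `converged`
#'   and `map`.
#' @export
fit_sapflow_model <- function(data, priors = NULL, Ca = NULL, n_chains = 3,
                              block_iter = 4000, max_rounds = 6, thin = 5,
                              seed = 1, init = NULL, polish_map = TRUE, ...) {
  ids <- tree_ids_by_group(data)
  if (is.null(priors)) priors <- prior_spec(ids$young, ids$old)
  lp <- make_log_posterior(data, priors, Ca = Ca)
  nm <- attr(lp, "param_names")
  pp <- priors[match(nm, priors$name), ]
  chains <- NULL; round_samples <- list(); round_lps <- list()
  archive <- NULL
  span_start <- 1L  # first round after the most recent chain reset
  for (r in seq_len(max_rounds)) {
    chains <- run_sampler(lp, pp$lower, pp$upper, n_chains = n_chains,
                          n_iter = block_iter, seed = seed + r - 1L,
                          thin = thin, init = init, archive = archive,
                          param_names = nm, shift_idx = grep("^chi_", nm), ...)
    round_samples[[r]] <- chains$samples
    round_lps[[r]] <- chains$logpost
    init <- chains$last_state
    archive <- chains$archive
    # outlier-chain handling: a chain whose recent log-posterior lags far
    # behind the best is stuck in a minor mode; restart it at the best
    # chain's state (classic DREAM device); earlier rounds then count as
    # burn-in for the convergence diagnosis
    nb <- nrow(chains$logpost)
    recent <- colMeans(chains$logpost[seq.int(max(1, nb - nb %/% 4), nb), ,
                                      drop = FALSE])
    best <- which.max(recent)
    stuck <- recent < recent[best] - 25
    if (any(stuck)) {
      init[, stuck] <- init[, best]
      span_start <- r + 1L
      next
    }
    span <- Reduce(abind3, round_samples[span_start:r])
    gr <- gelman_rubin(span)
    if (gr$converged) break
  }
  if (span_start > length(round_samples)) span_start <- length(round_samples)
  chains$samples <- Reduce(abind3, round_samples[span_start:length(round_samples)])
  chains$logpost <- do.call(rbind, round_lps[span_start:length(round_lps)])
  if (!exists("gr", inherits = FALSE)) gr <- gelman_rubin(chains$samples)
  chains$rhat <- gr$rhat
  chains$converged <- gr$converged
  chains$param_names <- nm
  map <- map_estimate(chains)
  if (polish_map) {
    # the posterior top is typically a near-flat ridge (see the methods
    # vignette); polish from both the best stored state and the
    # componentwise median of the retained states, keep the higher mode
    med <- apply(do.call(rbind, retained_states(chains)), 2, stats::median)
    pm1 <- optimise_mode_global(lp, map, pp$lower, pp$upper, nm)
    pm2 <- optimise_mode_global(lp, stats::setNames(med, nm),
                                pp$lower, pp$upper, nm)
    pm <- if (pm2$value >= pm1$value - 2) pm2 else pm1
    map <- stats::setNames(pm$theta, nm)
    attr(map, "logpost") <- pm$value
  }
  chains$map <- map
  chains
}

# Global posterior-mode search. The lag posterior is multimodal (modes
# every half grid step, see the methods vignette), so a plain gradient
# polish can stall in the wrong 10-min bracket: alternate a per-tree
# profile sweep of each chi over its prior range with a joint bounded
# quasi-Newton refinement.
optimise_mode_global <- function(lp, theta0, lower, upper, nm, rounds = 2) {
  chi_idx <- grep("^chi_", nm)
  th <- stats::setNames(as.numeric(theta0), nm)
  best <- lp(th)
  for (r in seq_len(rounds)) {
    for (j in chi_idx) {
      grid <- seq(lower[j] + 0.25, upper[j] - 0.25, by = 2.5)
      vals <- vapply(grid, function(g) { t2 <- th; t2[j] <- g; lp(t2) }, numeric(1))
      if (max(vals) > best) {
        th[j] <- grid[which.max(vals)]
        best <- max(vals)
      }
    }
    om <- optimise_mode(lp, th, lower, upper, free = rep(TRUE, length(nm)),
                        maxit = 600)
    if (om$value > best) {
      th <- stats::setNames(om$theta, nm)
      best <- om$value
    }
  }
  list(theta = th, value = best)
}

# bind two (n x d x m) arrays along iterations
abind3 <- function(a, b) {
  stopifnot(dim(a)[2] == dim(b)[2], dim(a)[3] == dim(b)[3])
  out <- array(NA_real_, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]),
               dimnames = dimnames(a))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}
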