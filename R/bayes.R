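# Bayesian MCMC over the CTMC rates.
#
# Each rate gets an independent exponential prior (default rate 2, prior
# mean 0.5 per tree unit). Sampling is univariate slice sampling within
# Gibbs on the positive half-line: stepping-out then shrinkage, one recorded
# sample ("generation") per full sweep. Chains are replicated across a tree
# sample with a fresh random resolution of conflicting tip records per tree,
# the first burn-in fraction discarded, and the remainder pooled.

active_params <- function(scs) {
  if (scs) c("fission", "fusion", "sa_fusion", "reversion")
  else c("fission", "fusion")
}

#' Log prior density of the rate parameters
#'
#' Independent exponential(rate = `r`) priors on each active rate:
#' `sum(log(r) - r * rate)`; `-Inf` if any rate is negative.
#'
#' @param params Named list or vector of rates.
#' @param prior_rate Exponential rate parameter; must be positive.
#' @param which Names of the active parameters.
#' @return Log prior density.
#' @export
log_prior <- function(params, prior_rate = 2,
                      which = c("fission", "fusion", "sa_fusion",
                                "reversion")) {
  stopifnot(prior_rate > 0)
  v <- unlist(params)[which]
  if (any(v < 0)) return(-Inf)
  sum(log(prior_rate) - prior_rate * v)
}

# One univariate slice-sampling update (Neal 2003: stepping out +
# shrinkage) of x > 0 under log density f, bounded below at 0.
slice_update <- function(x0, f, fx0, w = 0.5, max_steps = 30L) {
  logy <- fx0 - rexp(1)
  u <- runif(1) * w
  L <- max(0, x0 - u)
  R <- x0 + (w - u)
  steps <- max_steps
  while (L > 0 && steps > 0 && f(L) > logy) {
    L <- max(0, L - w); steps <- steps - 1L
  }
  steps <- max_steps
  while (steps > 0 && f(R) > logy) {
    R <- R + w; steps <- steps - 1L
  }
  repeat {
    x1 <- runif(1, L, R)
    fx1 <- f(x1)
    if (fx1 >= logy) return(list(x = x1, fx = fx1))
    if (x1 < x0) L <- x1 else R <- x1
  }
}

#' Run one MCMC chain on one tree
#'
#' Initializes each active rate from its prior (retrying up to
#' `max_init_tries` times if the likelihood is degenerate) and records one
#' sample per slice-sampling sweep.
#'
#' @param states Resolved tip states for the tree.
#' @param tree A rooted `phylo`.
#' @param space A `karyo_space`.
#' @param n_generations Number of recorded sweeps (>= 2).
#' @param prior_rate Exponential prior rate (default 2).
#' @param seed Integer seed; identical seeds give identical chains.
#' @param root_mode Root treatment, see [log_likelihood()].
#' @param likelihood Set `FALSE` to sample the prior only (sampler
#'   calibration).
#' @param slice_w Initial slice width in rate units.
#' @param max_init_tries Attempts at a finite-posterior initialization.
#' @return Data frame of class `karyo_chain`: one row per generation with
#'   the sampled rates and `log_posterior`.
#' @export
mcmc_run <- function(states, tree, space, n_generations, prior_rate = 2,
                     seed = 1L, root_mode = "fitzjohn", likelihood = TRUE,
                     slice_w = 0.5, max_init_tries = 100L) {
  stopifnot(n_generations >= 2)
  scs <- !identical(space$systems, "none")
  pars <- active_params(scs)
  set.seed(as.integer(seed))

  lik_fn <- if (likelihood) make_loglik(states, tree, space, root_mode)
  log_post <- function(theta) {
    lp <- log_prior(theta, prior_rate, which = pars)
    if (!is.finite(lp)) return(-Inf)
    if (!likelihood) return(lp)
    prm <- as.list(setNames(rep(0, 4),
                            c("fission", "fusion", "sa_fusion", "reversion")))
    prm[pars] <- as.list(theta[pars])
    ll <- lik_fn(build_rate_matrix(prm, space))
    if (!is.finite(ll)) return(-Inf)
    lp + ll
  }

  theta <- NULL
  for (try in seq_len(max_init_tries)) {
    cand <- setNames(rexp(length(pars), prior_rate), pars)
    lp0 <- log_post(cand)
    if (is.finite(lp0)) { theta <- cand; break }
  }
  if (is.null(theta)) {
    stop("could not initialize MCMC: log posterior is -Inf after ",
         max_init_tries, " prior draws", call. = FALSE)
  }

  out <- matrix(NA_real_, n_generations, length(pars) + 1,
                dimnames = list(NULL, c(pars, "log_posterior")))
  for (g in seq_len(n_generations)) {
    for (p in pars) {
      f <- function(x) {
        th <- theta; th[p] <- x
        log_post(th)
      }
      upd <- slice_update(theta[[p]], f, lp0, w = slice_w)
      theta[p] <- upd$x
      lp0 <- upd$fx
    }
    out[g, ] <- c(theta, lp0)
  }
  chain <- as.data.frame(out)
  attr(chain, "seed") <- as.integer(seed)
  attr(chain, "params") <- pars
  class(chain) <- c("karyo_chain", "data.frame")
  chain
}

# Deterministic per-tree seed splitting from a master seed (kept < 2^31).
split_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 1009) %% 2147483647)
}

#' Pooled posterior across a tree sample
#'
#' For each tree: resolve conflicting tip records with a fresh tree-specific
#' seed, run one chain, discard the first `burn_in` fraction, and pool. With
#' `n` trees and `g` generations the pooled sample has
#' `n * ceiling((1 - burn_in) * g)` rows (e.g. 100 trees x 100 generations
#' x 50% burn-in = 5,000).
#'
#' @param datasets List of matched datasets ([match_tips()] output).
#' @param space A `karyo_space`.
#' @param n_generations Generations per tree.
#' @param burn_in Fraction in `[0, 1)` discarded from the start of each
#'   chain.
#' @param prior_rate Exponential prior rate.
#' @param seed Master seed; per-tree seeds are split deterministically.
#' @param root_mode Root treatment.
#' @param ... Passed to [mcmc_run()].
#' @return Pooled `karyo_chain` data frame with extra columns `tree` and
#'   `generation`.
#' @export
multi_tree_posterior <- function(datasets, space, n_generations,
                                 burn_in = 0.5, prior_rate = 2, seed = 1L,
                                 root_mode = "fitzjohn", ...) {
  stopifnot(length(datasets) >= 1, burn_in >= 0, burn_in < 1)
  keep <- ceiling((1 - burn_in) * n_generations)
  pooled <- lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    seed_i <- split_seed(seed, i)
    states <- resolve_tip_states(ds, seed = seed_i)
    chain <- tryCatch(
      mcmc_run(states, ds$tree, space, n_generations,
               prior_rate = prior_rate, seed = seed_i,
               root_mode = root_mode, ...),
      error = function(e) {
        stop("MCMC failed on tree ", i, ": ", conditionMessage(e),
             call. = FALSE)
      })
    tail_rows <- chain[seq.int(n_generations - keep + 1L, n_generations), ,
                       drop = FALSE]
    cbind(tree = i, generation = seq.int(n_generations - keep + 1L,
                                         n_generations), tail_rows)
  })
  res <- do.call(rbind, pooled)
  rownames(res) <- NULL
  attr(res, "params") <- active_params(!identical(space$systems, "none"))
  attr(res, "burn_in") <- burn_in
  attr(res, "seed") <- as.integer(seed)
  class(res) <- c("karyo_chain", "data.frame")
  res
}

#' Highest posterior density interval
#'
#' Shortest contiguous window of the sorted samples containing
#' `ceiling(mass * n)` samples (ties broken by the first such window).
#'
#' @param samples Numeric vector (n >= 2 after dropping `NA`).
#' @param mass Credibility mass in (0, 1), default 0.95.
#' @return List with `lower`, `upper`, `mass` and `mean` (posterior mean).
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  samples <- samples[!is.na(samples)]
  if (length(samples) < 2) {
    stop("hpd_interval needs at least 2 non-missing samples", call. = FALSE)
  }
  stopifnot(mass > 0, mass < 1)
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- which.min(widths)
  list(lower = x[i], upper = x[i + m - 1L], mass = mass,
       mean = mean(samples))
}

hpd_disjoint <- function(a, b) a$lower > b$upper || a$upper < b$lower

#' Compare rate posteriors between groups
#'
#' Per-group posterior mean and HPD interval for each shared parameter, plus
#' pairwise verdicts: two groups are called `"different"` for a parameter
#' iff their HPD intervals are disjoint (the non-overlap criterion),
#' otherwise `"not different"`.
#'
#' @param chains Named list mapping group to a pooled `karyo_chain`.
#' @param mass HPD mass.
#' @return List with `summary` (data frame: group, parameter, mean, lower,
#'   upper) and `verdicts` (data frame: parameter, group1, group2, verdict).
#' @export
compare_rates <- function(chains, mass = 0.95) {
  stopifnot(length(chains) >= 2, !is.null(names(chains)))
  pars <- Reduce(intersect, lapply(chains, function(ch) attr(ch, "params")))
  summ <- do.call(rbind, lapply(names(chains), function(gr) {
    do.call(rbind, lapply(pars, function(p) {
      h <- hpd_interval(chains[[gr]][[p]], mass)
      data.frame(group = gr, parameter = p, mean = h$mean,
                 lower = h$lower, upper = h$upper,
                 stringsAsFactors = FALSE)
    }))
  }))
  groups <- names(chains)
  pairs <- utils::combn(groups, 2)
  verdicts <- do.call(rbind, lapply(pars, function(p) {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      h1 <- hpd_interval(chains[[g1]][[p]], mass)
      h2 <- hpd_interval(chains[[g2]][[p]], mass)
      data.frame(parameter = p, group1 = g1, group2 = g2,
                 verdict = if (hpd_disjoint(h1, h2)) "different"
                           else "not different",
                 stringsAsFactors = FALSE)
    }))
  }))
  list(summary = summ, verdicts = verdicts)
}
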