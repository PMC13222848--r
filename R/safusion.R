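# Test for an excess of sex chromosome-autosome fusions.
#
# Null model: a fusion strikes a uniform random unordered pair of
# chromosomes, so the chance it involves the sex chromosome depends only on
# the karyotype. Averaging that per-state expectation over the time each
# state is occupied on a stochastic map gives a duration-weighted null
# proportion; the observed proportion is SA-fusions / all fusions on the
# same map. Distributions are built over maps and compared by 95% HPD
# overlap.

#' Expected SA-fusion proportion for one karyotype state
#'
#' Probability that a random fusion involves the sex chromosome, in a state
#' with `k` haploid autosomes. Two formulations of the random-pair null:
#'
#' * `"haploid"` (default): one fused sex element among the haploid
#'   complement of `k + 1` chromosomes; `k` of the `choose(k+1, 2)`
#'   unordered pairs involve it, giving `2 / (k + 1)`.
#' * `"diploid"`: `2k` autosomes plus X and Y; fusible pairs exclude the
#'   `k` homologous autosome pairs and the X-Y pair, giving
#'   `4k / (choose(2k + 2, 2) - k - 1)`.
#'
#' Both give 0.2 at `k = 9`. The proportion is strictly decreasing in `k`.
#'
#' @param k Haploid autosome count (>= 1), vectorized.
#' @param scs System of the state (kept for symmetry; the same complement
#'   argument applies to simple and neo states).
#' @param formulation `"haploid"` or `"diploid"`.
#' @return Expected SA-fusion proportion in (0, 1].
#' @export
expected_sa_proportion <- function(k, scs = "simple",
                                   formulation = c("haploid", "diploid")) {
  formulation <- match.arg(formulation)
  if (any(k < 1)) stop("k must be >= 1", call. = FALSE)
  switch(formulation,
    haploid = 2 / (k + 1),
    diploid = 4 * k / (choose(2 * k + 2, 2) - k - 1))
}

#' Duration-weighted null SA-fusion proportion of a map
#'
#' `sum_s duration(s) * expected_sa_proportion(k_s) / sum_s duration(s)`
#' over the eligible states of an event tally. By default only
#' simple-system states are eligible: the model permits no SA-fusion out of
#' a neo state, so neo durations contribute to neither sum
#' (`include_neo = TRUE` adds them to both).
#'
#' @param tally An `event_tally`.
#' @param formulation Passed to [expected_sa_proportion()].
#' @param include_neo Include neo-system state durations.
#' @return Null proportion in (0, 1].
#' @export
weighted_null_proportion <- function(tally,
                                     formulation = c("haploid", "diploid"),
                                     include_neo = FALSE) {
  formulation <- match.arg(formulation)
  space <- attr(tally, "space")
  st <- space$states
  eligible <- if (include_neo) rep(TRUE, nrow(st)) else st$system != "neo"
  dur <- tally$duration[eligible]
  if (sum(dur) <= 0) {
    stop("zero eligible state duration: cannot form the null expectation",
         call. = FALSE)
  }
  e <- expected_sa_proportion(st$k[eligible], st$system[eligible],
                              formulation)
  sum(dur * e) / sum(dur)
}

#' Observed SA-fusion proportion of a map
#'
#' `n_sa_fusion / (n_sa_fusion + n_autosomal_fusion)`; `NA` when the map
#' contains no fusion of either kind (such maps are excluded from the
#' observed distribution and counted).
#'
#' @param tally An `event_tally`.
#' @return Proportion in `[0, 1]`, or `NA_real_`.
#' @export
observed_sa_proportion <- function(tally) {
  denom <- tally$n_sa_fusion + tally$n_autosomal_fusion
  if (denom == 0) return(NA_real_)
  tally$n_sa_fusion / denom
}

#' HPD-overlap test for SA-fusion excess
#'
#' Builds the observed and duration-weighted null proportion distributions
#' over a set of stochastic-map tallies, computes both HPD intervals, and
#' issues a verdict: `"excess"` iff the observed HPD lies entirely above
#' the null HPD, `"deficit"` iff entirely below, otherwise
#' `"indistinguishable"` (overlapping intervals).
#'
#' @param tallies List of `event_tally` objects (>= 2 with a defined
#'   observed proportion).
#' @param mass HPD mass, default 0.95.
#' @param formulation,include_neo Passed to [weighted_null_proportion()].
#' @return Object of class `sa_fusion_result`: `observed`, `null`
#'   (proportion vectors), `observed_hpd`, `null_hpd`, `verdict`,
#'   `n_maps_excluded`.
#' @export
sa_fusion_test <- function(tallies, mass = 0.95,
                           formulation = c("haploid", "diploid"),
                           include_neo = FALSE) {
  formulation <- match.arg(formulation)
  obs <- vapply(tallies, observed_sa_proportion, numeric(1))
  nul <- vapply(tallies, weighted_null_proportion, numeric(1),
                formulation = formulation, include_neo = include_neo)
  excluded <- is.na(obs)
  if (sum(!excluded) < 2) {
    stop("need >= 2 maps with at least one fusion event (",
         sum(!excluded), " usable of ", length(obs), ")", call. = FALSE)
  }
  obs_hpd <- hpd_interval(obs[!excluded], mass)
  null_hpd <- hpd_interval(nul, mass)
  verdict <- if (obs_hpd$lower > null_hpd$upper) "excess"
             else if (obs_hpd$upper < null_hpd$lower) "deficit"
             else "indistinguishable"
  res <- list(observed = obs[!excluded], null = nul,
              observed_hpd = obs_hpd, null_hpd = null_hpd,
              verdict = verdict, n_maps_excluded = sum(excluded))
  class(res) <- "sa_fusion_result"
  res
}

#' @export
print.sa_fusion_result <- function(x, ...) {
  cat(sprintf(
    "SA-fusion test: observed %.3f [%.3f, %.3f] vs null %.3f [%.3f, %.3f] -> %s (%d map(s) excluded)\n",
    x$observed_hpd$mean, x$observed_hpd$lower, x$observed_hpd$upper,
    x$null_hpd$mean, x$null_hpd$lower, x$null_hpd$upper,
    x$verdict, x$n_maps_excluded))
  invisible(x)
}

#' Count trees with an SA-fusion excess verdict
#'
#' @param results Named or unnamed list of `sa_fusion_result`, one per tree.
#' @return List with `n_excess`, `n_trees`, and a per-tree `table`
#'   (data frame: tree, verdict, observed/null means).
#' @export
per_tree_tally <- function(results) {
  stopifnot(length(results) >= 1)
  tab <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(tree = i, verdict = r$verdict,
               observed_mean = r$observed_hpd$mean,
               null_mean = r$null_hpd$mean, stringsAsFactors = FALSE)
  }))
  list(n_excess = sum(tab$verdict == "excess"), n_trees = nrow(tab),
       table = tab)
}
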