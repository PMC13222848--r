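# Bounded CTMC of karyotype evolution.
#
# States are pairs (k, system) with k the haploid autosome number in
# [k_min, k_max] and system either "none" (basic, chromosome-number-only
# model) or one of "simple"/"neo" (sex-chromosome-system model). XY and XO
# tips both occupy the "simple" system; neo-XY tips occupy "neo".
#
# Index order is systems-major: all "simple" states by increasing k, then
# all "neo" states (basic model: single block).

#' Build the model state space
#'
#' @param k_min,k_max Inclusive bounds on haploid autosome number;
#'   `k_min >= 1`.
#' @param scs Logical; `TRUE` for the sex-chromosome-system model (states
#'   duplicated into simple/neo blocks), `FALSE` for the basic model.
#' @return An object of class `karyo_space`: a list with `k_min`, `k_max`,
#'   `systems`, `n_k`, `size` and a `states` data frame (`k`, `system`,
#'   `label`) in index order.
#' @export
build_state_space <- function(k_min, k_max, scs = TRUE) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (is.na(k_min) || k_min < 1) stop("k_min must be >= 1", call. = FALSE)
  if (k_max < k_min) stop("k_max must be >= k_min", call. = FALSE)
  systems <- if (scs) c("simple", "neo") else "none"
  ks <- k_min:k_max
  states <- data.frame(
    k = rep(ks, times = length(systems)),
    system = rep(systems, each = length(ks)),
    stringsAsFactors = FALSE)
  states$label <- paste0(states$k, "/", states$system)
  space <- list(k_min = k_min, k_max = k_max, systems = systems,
                n_k = length(ks), size = nrow(states), states = states)
  class(space) <- "karyo_space"
  space
}

#' @export
print.karyo_space <- function(x, ...) {
  cat("karyotype state space: k in [", x$k_min, ", ", x$k_max, "], systems {",
      paste(x$systems, collapse = ", "), "}, ", x$size, " states\n", sep = "")
  invisible(x)
}

#' Map (k, system) pairs to state indices
#'
#' @param space A `karyo_space`.
#' @param k Integer vector of autosome counts.
#' @param system Character vector of systems (recycled); SCS labels `"XY"`
#'   and `"XO"` map to `"simple"`, `"neoXY"` to `"neo"`.
#' @return Integer state indices.
#' @export
state_index <- function(space, k, system = "none") {
  system <- rep_len(as.character(system), length(k))
  if (identical(space$systems, "none")) {
    system[] <- "none"  # basic model ignores the sex chromosome system
  } else {
    system[system %in% c("XY", "XO")] <- "simple"
    system[system == "neoXY"] <- "neo"
  }
  si <- match(system, space$systems)
  if (anyNA(si)) {
    stop("system(s) not in state space: ",
         paste(unique(system[is.na(si)]), collapse = ", "), call. = FALSE)
  }
  k <- as.integer(k)
  if (any(k < space$k_min | k > space$k_max)) {
    bad <- which(k < space$k_min | k > space$k_max)
    stop("autosome count(s) outside [k_min, k_max]: ",
         paste(k[bad], collapse = ", "), call. = FALSE)
  }
  (si - 1L) * space$n_k + (k - space$k_min + 1L)
}

#' Rate parameters of the karyotype CTMC
#'
#' All rates are per tree unit (1 unit = 10^8 years). `fission` moves
#' k -> k+1 within a system, `fusion` moves k -> k-1 within a system,
#' `sa_fusion` moves (k, simple) -> (k-1, neo) (a sex chromosome-autosome
#' fusion creating a neo-XY system), and `reversion` moves
#' (k, neo) -> (k, simple). The basic model uses only `fission` and
#' `fusion`.
#'
#' @param fission,fusion,sa_fusion,reversion Non-negative finite rates.
#' @return A named list of class `karyo_rates`.
#' @export
rate_params <- function(fission, fusion, sa_fusion = 0, reversion = 0) {
  p <- list(fission = fission, fusion = fusion,
            sa_fusion = sa_fusion, reversion = reversion)
  v <- unlist(p)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("all rates must be finite and non-negative", call. = FALSE)
  }
  class(p) <- "karyo_rates"
  p
}

#' Build the CTMC rate matrix
#'
#' Assembles the generator Q over the given state space: off-diagonal
#' entries are the four move rates where the move stays inside the space
#' (no fission above `k_max`, no fusion or SA-fusion below `k_min`, no
#' SA-fusion out of neo states), and each diagonal is minus its row sum.
#'
#' @param params A `karyo_rates` object (or list with the same names).
#' @param space A `karyo_space`.
#' @return Dense square matrix with state labels as dimnames and the space
#'   attached as attribute `"space"`.
#' @export
build_rate_matrix <- function(params, space) {
  v <- unlist(params[c("fission", "fusion", "sa_fusion", "reversion")])
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("all rates must be finite and non-negative", call. = FALSE)
  }
  S <- space$size
  Q <- matrix(0, S, S, dimnames = list(space$states$label,
                                       space$states$label))
  st <- space$states
  for (i in seq_len(S)) {
    k <- st$k[i]; sys <- st$system[i]
    if (k < space$k_max) {
      Q[i, state_index(space, k + 1L, sys)] <- params$fission
    }
    if (k > space$k_min) {
      Q[i, state_index(space, k - 1L, sys)] <- params$fusion
    }
    if (sys == "simple" && k > space$k_min) {
      Q[i, state_index(space, k - 1L, "neo")] <- params$sa_fusion
    }
    if (sys == "neo") {
      Q[i, state_index(space, k, "simple")] <- params$reversion
    }
  }
  diag(Q) <- -rowSums(Q)
  attr(Q, "space") <- space
  attr(Q, "params") <- params
  Q
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param Q Rate matrix from [build_rate_matrix()] (any square generator).
#' @param t Non-negative elapsed time in tree units.
#' @return Stochastic matrix of the same dimension.
#' @export
transition_probs <- function(Q, t) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0) {
    stop("t must be a single non-negative number", call. = FALSE)
  }
  P <- expm_ctmc_cpp(unclass(Q), t)
  dimnames(P) <- dimnames(Q)
  attr(P, "space") <- attr(Q, "space")
  P
}

# Internal: run the pruning kernel over a tree and resolved tip states.
# Returns partial likelihood vectors per node (edge-scaled), the log scale
# factor, per-edge P matrices (optional) and the postorder edge table.
ctmc_prune <- function(states, tree, Q, keep_P = FALSE) {
  space <- attr(Q, "space")
  stopifnot(!is.null(space))
  tree <- ape::reorder.phylo(tree, "postorder")
  idx <- match(tree$tip.label, states$species)
  if (anyNA(idx)) {
    stop("no resolved state for tip(s): ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  tip_state <- tryCatch(
    state_index(space, states$haploid_autosomes[idx], states$scs[idx]),
    error = function(e) {
      stop("tip state outside the model state space (",
           conditionMessage(e), ")", call. = FALSE)
    })
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  res <- ctmc_pruning_cpp(tree$edge, tree$edge.length,
                          as.integer(tip_state), n_tip, n_node,
                          unclass(Q), keep_P)
  res$tree <- tree
  res$root <- n_tip + 1L
  res$tip_state <- tip_state
  res
}

# Internal: precompute everything likelihood evaluation needs that does not
# depend on Q (postorder edges, tip state indices), returning a closure
# Q -> log-likelihood. Used by the MCMC loop where log_likelihood() would
# redo the tree preprocessing at every evaluation.
make_loglik <- function(states, tree, space, root_mode = "fitzjohn",
                        root_state = NULL) {
  tree <- ape::reorder.phylo(tree, "postorder")
  idx <- match(tree$tip.label, states$species)
  stopifnot(!anyNA(idx))
  tip_state <- state_index(space, states$haploid_autosomes[idx],
                           states$scs[idx])
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  function(Q) {
    res <- ctmc_pruning_cpp(tree$edge, tree$edge.length,
                            as.integer(tip_state), n_tip, n_node,
                            unclass(Q), FALSE)
    if (isTRUE(res$impossible)) return(-Inf)
    root_log_lik(res$partial[root, ], res$log_scale, root_mode, root_state)
  }
}

root_log_lik <- function(root_partial, log_scale, root_mode, root_state) {
  pr <- root_partial
  tot <- sum(pr)
  if (!(tot > 0)) return(-Inf)
  switch(root_mode,
    fitzjohn = log(sum(pr^2) / tot) + log_scale,
    flat = log(mean(pr)) + log_scale,
    fixed = {
      if (is.null(root_state)) stop("root_mode 'fixed' needs root_state")
      if (pr[root_state] <= 0) -Inf else log(pr[root_state]) + log_scale
    },
    stop("unknown root_mode: ", root_mode))
}

#' Log-likelihood of resolved tip states under the CTMC
#'
#' Felsenstein pruning with per-branch matrix exponentials (cached by unique
#' branch length). The root state is handled per `root_mode`: `"fitzjohn"`
#' (default) weights each root state by its share of the conditional
#' likelihood, `"flat"` averages uniformly, `"fixed"` conditions on
#' `root_state`.
#'
#' @param states Resolved tip states ([resolve_tip_states()] output).
#' @param tree A rooted `phylo` with branch lengths.
#' @param Q Rate matrix with attached state space.
#' @param root_mode One of `"fitzjohn"`, `"flat"`, `"fixed"`.
#' @param root_state State index for `root_mode = "fixed"`.
#' @return Log-likelihood (`-Inf` for probability-zero data).
#' @export
log_likelihood <- function(states, tree, Q,
                           root_mode = c("fitzjohn", "flat", "fixed"),
                           root_state = NULL) {
  root_mode <- match.arg(root_mode)
  pr <- ctmc_prune(states, tree, Q, keep_P = FALSE)
  if (isTRUE(pr$impossible)) return(-Inf)
  root_log_lik(pr$partial[pr$root, ], pr$log_scale, root_mode, root_state)
}
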