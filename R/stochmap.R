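# Stochastic character mapping by endpoint-conditioned uniformization.
#
# Node states are sampled first by a backward (pruning) / forward
# (preorder) pass; branch interiors are then filled in by uniformization
# with dominating rate Omega = max(-diag(Q)): the number of (real +
# virtual) jumps is drawn from its exact conditional distribution given the
# branch endpoints, intermediate states by the forward-backward rule on the
# uniformized chain R = I + Q/Omega, jump times uniformly. This always
# terminates, unlike rejection sampling on long constrained branches.

# Sample the jump count N | (a, b, t): P(N = n) prop. to
# dpois(n, Omega t) * R^n[a, b]. Rpow is an environment caching powers.
sample_jump_count <- function(a, b, t, omega, Rpow, p_ab, max_n = 10000L) {
  u <- runif(1) * p_ab
  acc <- 0
  n <- 0L
  repeat {
    Rn <- uniformized_power(Rpow, n)
    acc <- acc + stats::dpois(n, omega * t) * Rn[a, b]
    if (acc >= u || n >= max_n) return(n)
    n <- n + 1L
  }
}

uniformized_power <- function(Rpow, n) {
  key <- as.character(n)
  if (!is.null(Rpow$cache[[key]])) return(Rpow$cache[[key]])
  Rn <- if (n == 0L) diag(nrow(Rpow$R)) else uniformized_power(Rpow, n - 1L) %*% Rpow$R
  Rpow$cache[[key]] <- Rn
  Rn
}

# Endpoint-conditioned path on one branch: returns the ordered sequence of
# real (state-changing) jumps as data.frame(time, from, to), times in (0, t).
sample_branch_path <- function(a, b, t, Q, omega, Rpow, p_ab) {
  if (omega <= 0 || t <= 0) {
    if (a != b) stop("impossible endpoint pair on a zero-rate/zero-length branch")
    return(data.frame(time = numeric(), from = integer(), to = integer()))
  }
  n <- sample_jump_count(a, b, t, omega, Rpow, p_ab)
  if (n == 0L) {
    return(data.frame(time = numeric(), from = integer(), to = integer()))
  }
  states <- integer(n + 1L)
  states[1L] <- a
  states[n + 1L] <- b
  if (n > 1L) {
    for (j in seq_len(n - 1L)) {
      Rrem <- uniformized_power(Rpow, n - j)
      w <- Rpow$R[states[j], ] * Rrem[, b]
      states[j + 1L] <- sample.int(length(w), 1L, prob = w)
    }
  }
  times <- sort(runif(n, 0, t))
  real <- which(states[-1L] != states[-(n + 1L)])
  data.frame(time = times[real], from = states[real], to = states[real + 1L])
}

#' Sample stochastic character maps
#'
#' Draws full character histories conditional on the resolved tip states and
#' the rate matrix. The pruning pass, per-edge transition matrices and
#' uniformized-chain powers are computed once and shared across the
#' `n_maps` draws.
#'
#' @param states Resolved tip states.
#' @param tree Rooted `phylo` with branch lengths.
#' @param Q Rate matrix with attached state space.
#' @param n_maps Number of maps to draw.
#' @param seed Integer seed.
#' @param root_mode Root-state distribution for the draw: `"fitzjohn"`
#'   (default; weights proportional to squared root partials), `"flat"`, or
#'   `"fixed"` with `root_state`.
#' @param root_state State index when `root_mode = "fixed"`.
#' @return List of `stochastic_map` objects. Each has `segments`
#'   (data frame: `edge`, `state`, `duration` in branch order),
#'   `events` (data frame: `edge`, `time` within the branch, `from`, `to`),
#'   `node_states` (integer per node) and the tree/space as attributes.
#' @export
sample_history <- function(states, tree, Q, n_maps = 1L, seed = 1L,
                           root_mode = c("fitzjohn", "flat", "fixed"),
                           root_state = NULL) {
  root_mode <- match.arg(root_mode)
  stopifnot(n_maps >= 1)
  space <- attr(Q, "space")
  pr <- ctmc_prune(states, tree, Q, keep_P = TRUE)
  if (isTRUE(pr$impossible)) {
    stop("tip configuration has probability zero under Q", call. = FALSE)
  }
  tree <- pr$tree  # postorder
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- pr$root
  S <- space$size

  root_w <- pr$partial[root, ]
  root_w <- switch(root_mode,
    fitzjohn = root_w^2,
    flat = root_w,
    fixed = {
      w <- numeric(S); w[root_state] <- root_w[root_state]; w
    })
  if (sum(root_w) <= 0) stop("root distribution degenerate", call. = FALSE)

  omega <- max(-diag(Q))
  Rpow <- new.env(parent = emptyenv())
  Rpow$R <- if (omega > 0) diag(S) + unclass(Q) / omega else diag(S)
  Rpow$cache <- list()
  # preorder = reversed postorder edge list
  edges_pre <- rev(seq_len(nrow(tree$edge)))

  set.seed(as.integer(seed))
  maps <- vector("list", n_maps)
  for (m in seq_len(n_maps)) {
    node_state <- integer(n_node)
    node_state[seq_len(n_tip)] <- pr$tip_state
    node_state[root] <- sample.int(S, 1L, prob = root_w)
    seg_list <- vector("list", nrow(tree$edge))
    ev_list <- vector("list", nrow(tree$edge))
    for (e in edges_pre) {
      parent <- tree$edge[e, 1L]
      child <- tree$edge[e, 2L]
      len <- tree$edge.length[e]
      P <- pr$P[[e]]
      a <- node_state[parent]
      if (child > n_tip) {
        w <- P[a, ] * pr$partial[child, ]
        node_state[child] <- sample.int(S, 1L, prob = w)
      }
      b <- node_state[child]
      path <- sample_branch_path(a, b, len, Q, omega, Rpow, P[a, b])
      if (nrow(path) > 0) {
        bounds <- c(0, path$time, len)
        seg_states <- c(path$from, b)
      } else {
        bounds <- c(0, len)
        seg_states <- a
      }
      seg_list[[e]] <- data.frame(edge = e, state = seg_states,
                                  duration = diff(bounds))
      if (nrow(path) > 0) {
        ev_list[[e]] <- cbind(edge = e, path)
      }
    }
    events <- do.call(rbind, ev_list[!vapply(ev_list, is.null, logical(1))])
    if (is.null(events)) {
      events <- data.frame(edge = integer(), time = numeric(),
                           from = integer(), to = integer())
    }
    map <- list(segments = do.call(rbind, seg_list),
                events = events,
                node_states = node_state)
    attr(map, "space") <- space
    attr(map, "tree") <- tree
    class(map) <- "stochastic_map"
    maps[[m]] <- map
  }
  maps
}

#' Tally events and state durations of a stochastic map
#'
#' Classifies every transition of the map as fission (k -> k+1 within a
#' system), autosomal fusion (k -> k-1 within a system), SA-fusion
#' ((k, simple) -> (k-1, neo)) or reversion ((k, neo) -> (k, simple)), and
#' accumulates the total time spent in each state.
#'
#' @param map A `stochastic_map`.
#' @param space A `karyo_space` (defaults to the map's own).
#' @return Object of class `event_tally`: counts `n_fission`,
#'   `n_autosomal_fusion`, `n_sa_fusion`, `n_reversion`, a `duration`
#'   vector named by state label, and `total_duration`.
#' @export
tally_events <- function(map, space = attr(map, "space")) {
  st <- space$states
  ev <- map$events
  n <- c(fission = 0L, autosomal_fusion = 0L, sa_fusion = 0L,
         reversion = 0L)
  if (nrow(ev) > 0) {
    dk <- st$k[ev$to] - st$k[ev$from]
    sys_from <- st$system[ev$from]
    sys_to <- st$system[ev$to]
    cls <- ifelse(dk == 1L & sys_from == sys_to, "fission",
           ifelse(dk == -1L & sys_from == sys_to, "autosomal_fusion",
           ifelse(dk == -1L & sys_from == "simple" & sys_to == "neo",
                  "sa_fusion",
           ifelse(dk == 0L & sys_from == "neo" & sys_to == "simple",
                  "reversion", NA_character_))))
    if (anyNA(cls)) {
      bad <- which(is.na(cls))[1]
      stop("corrupt map: transition ", st$label[ev$from[bad]], " -> ",
           st$label[ev$to[bad]], " matches no allowed move", call. = FALSE)
    }
    tab <- table(factor(cls, levels = names(n)))
    n[] <- as.integer(tab)
  }
  dur <- setNames(numeric(nrow(st)), st$label)
  agg <- tapply(map$segments$duration, map$segments$state, sum)
  dur[as.integer(names(agg))] <- agg
  tally <- list(n_fission = n[["fission"]],
                n_autosomal_fusion = n[["autosomal_fusion"]],
                n_sa_fusion = n[["sa_fusion"]],
                n_reversion = n[["reversion"]],
                duration = dur,
                total_duration = sum(dur))
  attr(tally, "space") <- space
  class(tally) <- "event_tally"
  tally
}

#' Export the event and duration tables of a set of maps
#'
#' @param maps List of `stochastic_map` objects.
#' @return List of two data frames: `events` (`map_id`, `edge`, `time`,
#'   `from_k`, `from_system`, `to_k`, `to_system`) and `durations`
#'   (`map_id`, `k`, `system`, `time`).
#' @export
map_tables <- function(maps) {
  space <- attr(maps[[1]], "space")
  st <- space$states
  ev <- do.call(rbind, lapply(seq_along(maps), function(i) {
    e <- maps[[i]]$events
    if (nrow(e) == 0) return(NULL)
    data.frame(map_id = i, edge = e$edge, time = e$time,
               from_k = st$k[e$from], from_system = st$system[e$from],
               to_k = st$k[e$to], to_system = st$system[e$to])
  }))
  if (is.null(ev)) {
    ev <- data.frame(map_id = integer(), edge = integer(), time = numeric(),
                     from_k = integer(), from_system = character(),
                     to_k = integer(), to_system = character())
  }
  dur <- do.call(rbind, lapply(seq_along(maps), function(i) {
    tl <- tally_events(maps[[i]], space)
    data.frame(map_id = i, k = st$k, system = st$system,
               time = unname(tl$duration))
  }))
  list(events = ev, durations = dur)
}
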