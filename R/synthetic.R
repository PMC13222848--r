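# Synthetic data with the statistical structure the analysis assumes:
# birth-death trees (branch lengths in units of 10^8 years), karyotype
# histories simulated forward under the CTMC (Gillespie along branches,
# boundary moves suppressed exactly as in the inference model), and tip
# tables with a configurable fraction of conflicting multi-record tips.

#' Simulate a birth-death tree
#'
#' Wraps `ape::rphylo()` (conditioned on the extant tip count) and
#' optionally rescales all branch lengths so the root-to-tip depth matches
#' `depth` tree units — mimicking a dated phylogeny with a calibrated root
#' age.
#'
#' @param n_tips Number of extant tips (>= 3).
#' @param birth,death Speciation and extinction rates per tree unit;
#'   `birth > death >= 0`.
#' @param seed Integer seed; identical seeds give identical trees.
#' @param depth Optional target root depth in tree units.
#' @return An ultrametric `phylo` with `n_tips` tips.
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0, seed = 1L,
                          depth = NULL) {
  stopifnot(n_tips >= 3, birth > death, death >= 0)
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_tips, birth = birth, death = death)
  if (!is.null(depth)) {
    d0 <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * depth / d0
  }
  tr
}

# Gillespie path from `state` over duration `len` under Q.
# Returns list(path = data.frame(time, from, to), end = final state).
gillespie_branch <- function(state, len, Q) {
  t <- 0
  path <- list()
  repeat {
    rate <- -Q[state, state]
    if (rate <= 0) break
    t <- t + rexp(1, rate)
    if (t >= len) break
    w <- Q[state, ]
    w[state] <- 0
    nxt <- sample.int(length(w), 1L, prob = w)
    path[[length(path) + 1L]] <- data.frame(time = t, from = state,
                                            to = nxt)
    state <- nxt
  }
  list(path = if (length(path)) do.call(rbind, path)
              else data.frame(time = numeric(), from = integer(),
                              to = integer()),
       end = state)
}

#' Simulate a karyotype history on a tree
#'
#' Forward (unconditioned) simulation: the root starts in `root_state` and
#' each branch evolves by the Gillespie algorithm under `Q`. Moves that
#' would leave the bounded state space have rate zero by construction of
#' `Q`, matching the inference model exactly.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param Q Rate matrix with attached state space.
#' @param root_state List/vector with `k` and `system` (or a single state
#'   index).
#' @param seed Integer seed.
#' @return List with `map` (a `stochastic_map` holding the true history),
#'   and `tip_states` (data frame `species`, `haploid_autosomes`, `scs`).
#' @export
simulate_history <- function(tree, Q, root_state, seed = 1L) {
  space <- attr(Q, "space")
  stopifnot(!is.null(space))
  root_idx <- if (is.numeric(root_state) && length(root_state) == 1) {
    as.integer(root_state)
  } else {
    state_index(space, root_state$k, root_state$system)
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  set.seed(as.integer(seed))
  node_state <- integer(n_node)
  node_state[root] <- root_idx
  seg_list <- vector("list", nrow(tree$edge))
  ev_list <- vector("list", nrow(tree$edge))
  for (e in rev(seq_len(nrow(tree$edge)))) {  # preorder
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    sim <- gillespie_branch(node_state[parent], len, Q)
    node_state[child] <- sim$end
    path <- sim$path
    if (nrow(path) > 0) {
      bounds <- c(0, path$time, len)
      seg_states <- c(path$from, sim$end)
      ev_list[[e]] <- cbind(edge = e, path)
    } else {
      bounds <- c(0, len)
      seg_states <- node_state[parent]
    }
    seg_list[[e]] <- data.frame(edge = e, state = seg_states,
                                duration = diff(bounds))
  }
  events <- do.call(rbind, ev_list[!vapply(ev_list, is.null, logical(1))])
  if (is.null(events)) {
    events <- data.frame(edge = integer(), time = numeric(),
                         from = integer(), to = integer())
  }
  map <- list(segments = do.call(rbind, seg_list), events = events,
              node_states = node_state)
  attr(map, "space") <- space
  attr(map, "tree") <- tree
  class(map) <- "stochastic_map"

  st <- space$states
  tips <- node_state[seq_len(n_tip)]
  tip_states <- data.frame(
    species = tree$tip.label,
    haploid_autosomes = st$k[tips],
    scs = ifelse(st$system[tips] == "neo", "neoXY", "XY"),
    stringsAsFactors = FALSE)
  list(map = map, tip_states = tip_states)
}

#' Default simulation configuration
#'
#' The defaults describe a Scarabaeoidea-like world: 200 tips, tree depth
#' 1.84 units (a root age of ~184 My), root karyotype (9, XY), rates
#' fission 0.3, fusion 0.7, SA-fusion 0.6, reversion 0.2 per tree unit
#' (0.002-0.007 per My), and 17.5% of tips carrying a second conflicting
#' record (37/211 in the empirical data shape this emulates).
#'
#' @param n_tips,n_trees Tips per tree and number of trees.
#' @param birth,death Birth-death rates per tree unit.
#' @param depth Root depth in tree units.
#' @param params `karyo_rates` truth.
#' @param root_k,root_system Root karyotype.
#' @param k_min,k_max State-space bounds used for simulation.
#' @param multi_record_fraction Fraction of tips with a duplicate record.
#' @param jitter_sd Lognormal sd of per-branch length jitter applied to
#'   trees 2..n_trees, emulating posterior branch-length uncertainty.
#' @param seed Master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tips = 200, n_trees = 1, birth = 3, death = 0.5,
                       depth = 1.84,
                       params = rate_params(0.3, 0.7, 0.6, 0.2),
                       root_k = 9, root_system = "XY",
                       k_min = 1, k_max = 25,
                       multi_record_fraction = 0.175,
                       jitter_sd = 0.1, seed = 1L) {
  cfg <- list(n_tips = n_tips, n_trees = n_trees, birth = birth,
              death = death, depth = depth, params = params,
              root_k = root_k, root_system = root_system,
              k_min = k_min, k_max = k_max,
              multi_record_fraction = multi_record_fraction,
              jitter_sd = jitter_sd, seed = as.integer(seed))
  stopifnot(cfg$n_tips >= 3, cfg$multi_record_fraction >= 0,
            cfg$multi_record_fraction <= 1,
            root_k >= k_min, root_k <= k_max)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a full synthetic dataset
#'
#' Simulates one true tree and karyotype history, derives the tip karyotype
#' table (adding, for a binomial fraction of tips, a second conflicting
#' record whose count differs by 1), and emulates a posterior tree sample
#' by jittering branch lengths of the true tree. Optionally writes a Newick
#' tree file, a karyotype CSV and a truth JSON.
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created); `NULL` for in-memory only.
#' @return List with `trees` (`multiPhylo`), `records` (karyotype table),
#'   `truth` (list: params, root state, true map, true tip states), and
#'   `files` (paths, if written).
#' @export
make_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  space <- build_state_space(config$k_min, config$k_max, scs = TRUE)
  Q <- build_rate_matrix(config$params, space)
  tree <- simulate_tree(config$n_tips, config$birth, config$death,
                        seed = config$seed, depth = config$depth)
  hist <- simulate_history(tree, Q,
                           list(k = config$root_k,
                                system = config$root_system),
                           seed = split_seed(config$seed, 1L))
  records <- hist$tip_states
  records$source <- "simulated"

  set.seed(split_seed(config$seed, 2L))
  multi <- runif(config$n_tips) < config$multi_record_fraction
  if (any(multi)) {
    dup <- records[multi, , drop = FALSE]
    shift <- sample(c(-1L, 1L), nrow(dup), replace = TRUE)
    dup$haploid_autosomes <- as.integer(
      pmin(pmax(dup$haploid_autosomes + shift, config$k_min), config$k_max))
    dup$source <- "simulated_conflict"
    records <- rbind(records, dup)
    records <- records[order(records$species), , drop = FALSE]
    rownames(records) <- NULL
  }

  trees <- vector("list", config$n_trees)
  trees[[1]] <- tree
  if (config$n_trees > 1) {
    set.seed(split_seed(config$seed, 3L))
    for (i in 2:config$n_trees) {
      tr <- tree
      tr$edge.length <- tr$edge.length *
        exp(rnorm(length(tr$edge.length), 0, config$jitter_sd))
      trees[[i]] <- tr
    }
  }
  class(trees) <- "multiPhylo"

  truth <- list(params = unclass(config$params),
                root = list(k = config$root_k, system = config$root_system),
                map = hist$map, tip_states = hist$tip_states,
                seed = config$seed)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(trees = file.path(dir, "trees.nwk"),
                  karyotypes = file.path(dir, "karyotypes.csv"),
                  truth = file.path(dir, "truth.json"))
    ape::write.tree(trees, files$trees)
    write_karyotype_table(records, files$karyotypes)
    jsonlite::write_json(
      list(params = unclass(config$params),
           root = list(k = config$root_k, system = config$root_system),
           seed = config$seed,
           n_true_events = nrow(hist$map$events)),
      files$truth, auto_unbox = TRUE, digits = NA)
  }
  list(trees = trees, records = records, truth = truth, files = files)
}
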