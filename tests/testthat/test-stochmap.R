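test_that("zero-rate maps are constant with empty event lists", {
  sp <- build_state_space(4, 12, scs = TRUE)
  Q0 <- build_rate_matrix(rate_params(0, 0, 0, 0), sp)
  tr <- tiny_tree()
  maps <- sample_history(tiny_states(k = c(9, 9, 9)), tr, Q0, n_maps = 5,
                         seed = 2)
  for (m in maps) {
    expect_equal(nrow(m$events), 0)
    expect_equal(unique(m$segments$state), state_index(sp, 9, "XY"))
  }
  # probability-zero configurations are refused
  expect_error(sample_history(tiny_states(k = c(9, 9, 10)), tr, Q0, 1, 1),
               "probability zero")
})

test_that("per-branch segment durations sum to branch lengths", {
  set.seed(6)
  sp <- build_state_space(2, 10, scs = TRUE)
  Q <- build_rate_matrix(rate_params(1.5, 1.5, 0.8, 0.5), sp)
  tr <- random_tree(6, depth = 2)
  st <- data.frame(species = tr$tip.label,
                   haploid_autosomes = sample(4:8, 6, replace = TRUE),
                   scs = sample(c("XY", "neoXY"), 6, replace = TRUE))
  maps <- sample_history(st, tr, Q, n_maps = 20, seed = 3)
  tr_post <- ape::reorder.phylo(tr, "postorder")
  for (m in maps) {
    by_edge <- tapply(m$segments$duration, m$segments$edge, sum)
    expect_equal(as.numeric(by_edge[as.character(seq_len(nrow(tr_post$edge)))]),
                 tr_post$edge.length, tolerance = 1e-9)
    # consecutive segments on an edge always change state
    for (e in unique(m$segments$edge)) {
      s <- m$segments$state[m$segments$edge == e]
      if (length(s) > 1) expect_true(all(diff(s) != 0))
    }
  }
  # reproducibility
  expect_identical(sample_history(st, tr, Q, n_maps = 3, seed = 9),
                   sample_history(st, tr, Q, n_maps = 3, seed = 9))
})

test_that("event counts match the endpoint-conditioned expectation oracle", {
  # single branch, 2-state chain, constrained endpoints: compare the mean
  # number of real jumps against the occupancy-integral formula
  sp <- build_state_space(5, 6, scs = FALSE)
  Q <- build_rate_matrix(rate_params(0.9, 0.6), sp)
  tr <- ape::read.tree(text = "(A:1.4,B:0.8);")
  st <- data.frame(species = c("A", "B"), haploid_autosomes = c(6L, 5L),
                   scs = "XY")
  n_maps <- 4000
  maps <- sample_history(st, tr, Q, n_maps = n_maps, seed = 10,
                         root_mode = "fixed",
                         root_state = state_index(sp, 5))
  counts <- vapply(maps, function(m) nrow(m$events), numeric(1))
  # both branches start at the fixed root state 5
  expected <- oracle_branch_events(Q, a = 1, b = 2, t = 1.4) +
    oracle_branch_events(Q, a = 1, b = 1, t = 0.8)
  se <- sd(counts) / sqrt(n_maps)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("node-state marginals converge to pruning marginals", {
  # on a cherry the root marginal is exact: w(s)*L_root(s) normalized
  sp <- build_state_space(1, 4, scs = FALSE)
  Q <- build_rate_matrix(rate_params(0.7, 0.9), sp)
  tr <- ape::read.tree(text = "(A:0.6,B:1.1);")
  st <- data.frame(species = c("A", "B"), haploid_autosomes = c(2L, 4L),
                   scs = "XY")
  L <- oracle_root_lik(st, tr, Q)
  marg <- L^2 / sum(L^2)  # fitzjohn root weights times conditionals
  n_maps <- 4000
  maps <- sample_history(st, tr, Q, n_maps = n_maps, seed = 4)
  root <- ape::Ntip(tr) + 1L
  freq <- tabulate(vapply(maps, function(m) m$node_states[root],
                          numeric(1)), nbins = sp$size) / n_maps
  for (s in seq_len(sp$size)) {
    se <- sqrt(marg[s] * (1 - marg[s]) / n_maps)
    expect_lt(abs(freq[s] - marg[s]), 4 * se + 1e-12)
  }
})

test_that("tally classifies events and conserves durations", {
  sp <- build_state_space(4, 12, scs = TRUE)

  # hand-built map: one SA-fusion then one fission
  i9s <- state_index(sp, 9, "XY")
  i8n <- state_index(sp, 8, "neoXY")
  i9n <- state_index(sp, 9, "neoXY")
  map <- structure(list(
    segments = data.frame(edge = 1, state = c(i9s, i8n, i9n),
                          duration = c(0.2, 0.3, 0.5)),
    events = data.frame(edge = 1, time = c(0.2, 0.5),
                        from = c(i9s, i8n), to = c(i8n, i9n)),
    node_states = c(i9s, i9n)), class = "stochastic_map")
  attr(map, "space") <- sp
  tl <- tally_events(map)
  expect_equal(tl$n_sa_fusion, 1L)
  expect_equal(tl$n_fission, 1L)
  expect_equal(tl$n_autosomal_fusion, 0L)
  expect_equal(tl$n_reversion, 0L)
  expect_equal(unname(tl$duration[c(i9s, i8n, i9n)]), c(0.2, 0.3, 0.5))
  expect_equal(tl$total_duration, 1.0)

  # empty event list: all counts zero, duration mass on the constant state
  map0 <- structure(list(
    segments = data.frame(edge = 1, state = i9s, duration = 0.7),
    events = data.frame(edge = integer(), time = numeric(),
                        from = integer(), to = integer()),
    node_states = c(i9s, i9s)), class = "stochastic_map")
  attr(map0, "space") <- sp
  tl0 <- tally_events(map0)
  expect_equal(tl0$n_fission + tl0$n_autosomal_fusion + tl0$n_sa_fusion +
                 tl0$n_reversion, 0L)
  expect_equal(unname(tl0$duration[i9s]), 0.7)

  # a jump matching no allowed move is a corrupt map
  bad <- map
  bad$events$to[1] <- state_index(sp, 6, "neoXY")
  expect_error(tally_events(bad), "corrupt map")
})

test_that("simulated maps tally to rate x occupancy within Monte-Carlo error", {
  # forward-simulated histories, tallied through tally_events: mean count of
  # each class ~= rate * expected occupancy of eligible states. With bounds
  # far away, fission occupancy is the whole tree length.
  sp <- build_state_space(1, 40, scs = TRUE)
  Q <- build_rate_matrix(rate_params(0.5, 0.4, 0.3, 0.6), sp)
  tr <- random_tree(8, depth = 1)
  tot_len <- sum(tr$edge.length)
  n_rep <- 400
  tallies <- lapply(seq_len(n_rep), function(i) {
    h <- simulate_history(tr, Q, list(k = 20, system = "XY"), seed = i)
    tally_events(h$map)
  })
  n_fis <- vapply(tallies, `[[`, numeric(1), "n_fission")
  expect_lt(abs(mean(n_fis) - 0.5 * tot_len),
            3 * sd(n_fis) / sqrt(n_rep))
  # SA-fusions and reversions only accrue on their eligible occupancy
  occ_simple <- vapply(tallies, function(tl) {
    sum(tl$duration[sp$states$system == "simple"])
  }, numeric(1))
  n_sa <- vapply(tallies, `[[`, numeric(1), "n_sa_fusion")
  se <- sd(n_sa - 0.3 * occ_simple) / sqrt(n_rep)
  expect_lt(abs(mean(n_sa) - 0.3 * mean(occ_simple)), 3 * se)
})

test_that("no neo segments arise when the neo block is unreachable", {
  sp <- build_state_space(2, 10, scs = TRUE)
  Q <- build_rate_matrix(rate_params(1, 1, 0, 0), sp)
  tr <- random_tree(5)
  set.seed(3)
  st <- data.frame(species = tr$tip.label,
                   haploid_autosomes = sample(4:8, 5, replace = TRUE),
                   scs = "XY")
  maps <- sample_history(st, tr, Q, n_maps = 25, seed = 6)
  for (m in maps) {
    expect_true(all(sp$states$system[m$segments$state] == "simple"))
  }
})
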