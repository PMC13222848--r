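test_that("state space has the right size, order and bounds", {
  expect_equal(build_state_space(4, 21, scs = TRUE)$size, 36)
  expect_equal(build_state_space(4, 21, scs = FALSE)$size, 18)
  expect_equal(build_state_space(5, 5, scs = TRUE)$size, 2)
  expect_error(build_state_space(0, 5), "k_min")

  sp <- build_state_space(4, 6, scs = TRUE)
  # systems-major indexing: simple block first
  expect_equal(sp$states$label,
               c("4/simple", "5/simple", "6/simple",
                 "4/neo", "5/neo", "6/neo"))
  expect_equal(state_index(sp, 5, "XY"), 2L)
  expect_equal(state_index(sp, 5, "XO"), 2L)   # XO occupies the simple block
  expect_equal(state_index(sp, 5, "neoXY"), 5L)
  expect_error(state_index(sp, 3, "XY"), "outside")
})

test_that("rate matrix matches the hand-enumerated generator", {
  # basic 3-state birth-death generator, delta = 1 (up), phi = 2 (down)
  sp <- build_state_space(1, 3, scs = FALSE)
  Q <- build_rate_matrix(rate_params(1, 2), sp)
  expected <- matrix(c(-1, 1, 0,
                        2, -3, 1,
                        0, 2, -2), 3, 3, byrow = TRUE)
  expect_equal(unclass(Q), expected, ignore_attr = TRUE)

  # all rates zero -> zero matrix
  Q0 <- build_rate_matrix(rate_params(0, 0, 0, 0), sp)
  expect_true(all(Q0 == 0))

  # SCS space: no SA-fusion exit from (k_min, simple), no fission above
  # k_max, reversion present at every neo state
  sps <- build_state_space(4, 6, scs = TRUE)
  Qs <- build_rate_matrix(rate_params(0.1, 0.2, 0.3, 0.4), sps)
  expect_equal(Qs["4/simple", "4/neo"], 0)    # would need k_min - 1
  expect_equal(Qs["5/simple", "4/neo"], 0.3)
  expect_equal(Qs["6/simple", "5/neo"], 0.3)
  expect_equal(sum(Qs["6/simple", ]), 0)  # no fission exit above k_max
  expect_equal(Qs["5/neo", "5/simple"], 0.4)
  expect_equal(Qs["5/neo", "4/simple"], 0)    # reversion keeps k
  expect_error(build_rate_matrix(list(fission = -1, fusion = 0,
                                      sa_fusion = 0, reversion = 0), sps),
               "non-negative")
})

test_that("Q is a proper generator for random parameter draws", {
  set.seed(11)
  sp <- build_state_space(2, 12, scs = TRUE)
  for (i in seq_len(200)) {
    Q <- build_rate_matrix(rate_params(rexp(1), rexp(1), rexp(1), rexp(1)),
                           sp)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    off <- Q; diag(off) <- 0
    expect_true(all(off >= 0))
  }
})

test_that("transition probabilities behave like a CTMC semigroup", {
  sp <- build_state_space(3, 8, scs = TRUE)
  Q <- build_rate_matrix(rate_params(0.4, 0.6, 0.5, 0.3), sp)

  expect_error(transition_probs(Q, -1), "non-negative")
  expect_equal(unclass(transition_probs(Q, 0)), diag(sp$size),
               ignore_attr = TRUE)

  # small-t Taylor expansion: P = I + Qt + O(t^2)
  t <- 1e-4
  P <- transition_probs(Q, t)
  expect_lt(max(abs(P - (diag(sp$size) + unclass(Q) * t))),
            10 * max(abs(Q))^2 * t^2)

  # rows sum to one and entries lie in [0, 1]
  P1 <- transition_probs(Q, 1.7)
  expect_lt(max(abs(rowSums(P1) - 1)), 1e-10)
  expect_true(all(P1 >= 0 & P1 <= 1))

  # long-time limit: every row approaches the stationary distribution
  # (left null vector of Q)
  ev <- eigen(t(unclass(Q)))
  i0 <- which.min(abs(ev$values))
  pi0 <- Re(ev$vectors[, i0]); pi0 <- pi0 / sum(pi0)
  Pinf <- transition_probs(Q, 1e4 / min(c(0.4, 0.6, 0.5, 0.3)))
  expect_lt(max(abs(sweep(Pinf, 2, pi0))), 1e-8)
})

test_that("pruning likelihood equals the exhaustive-enumeration oracle", {
  set.seed(31)
  for (rep in seq_len(10)) {
    n_tip <- sample(3:5, 1)
    scs <- rep %% 2 == 0
    k_max <- if (scs) sample(3:6, 1) else sample(3:12, 1)
    sp <- build_state_space(1, k_max, scs = scs)
    Q <- build_rate_matrix(rate_params(rexp(1), rexp(1),
                                       if (scs) rexp(1) else 0,
                                       if (scs) rexp(1) else 0), sp)
    tr <- random_tree(n_tip)
    states <- data.frame(
      species = tr$tip.label,
      haploid_autosomes = sample(seq_len(k_max), n_tip, replace = TRUE),
      scs = if (scs) sample(c("XY", "neoXY"), n_tip, replace = TRUE)
            else "XY")
    for (mode in c("fitzjohn", "flat")) {
      expect_equal(log_likelihood(states, tr, Q, root_mode = mode),
                   oracle_loglik(states, tr, Q, root_mode = mode),
                   tolerance = 1e-10)
    }
  }
})

test_that("degenerate likelihoods behave as probabilities demand", {
  sp <- build_state_space(4, 21, scs = TRUE)
  Q0 <- build_rate_matrix(rate_params(0, 0, 0, 0), sp)
  tr <- tiny_tree()

  # no change possible, all tips equal, flat root: log(1/S)
  expect_equal(log_likelihood(tiny_states(k = c(9, 9, 9)), tr, Q0,
                              root_mode = "flat"),
               log(1 / sp$size))
  # two tips in different states: impossible
  expect_identical(log_likelihood(tiny_states(k = c(9, 9, 10)), tr, Q0),
                   -Inf)
  # tip outside bounds is an error naming the offender
  expect_error(log_likelihood(tiny_states(k = c(3, 9, 9)), tr, Q0),
               "state space")
  # invariant to tip ordering
  Q <- build_rate_matrix(rate_params(0.5, 0.5, 0.2, 0.1), sp)
  st <- tiny_states(k = c(8, 9, 10), scs = c("XY", "neoXY", "XY"))
  expect_equal(log_likelihood(st, tr, Q),
               log_likelihood(st[c(3, 1, 2), ], tr, Q))
})

test_that("time-rate scaling identity holds", {
  set.seed(17)
  sp <- build_state_space(2, 9, scs = TRUE)
  tr <- random_tree(6)
  st <- data.frame(species = tr$tip.label,
                   haploid_autosomes = sample(3:8, 6, replace = TRUE),
                   scs = sample(c("XY", "neoXY"), 6, replace = TRUE))
  for (i in 1:5) {
    r <- rexp(4)
    Q1 <- build_rate_matrix(rate_params(r[1], r[2], r[3], r[4]), sp)
    Q2 <- build_rate_matrix(rate_params(2 * r[1], 2 * r[2], 2 * r[3],
                                        2 * r[4]), sp)
    tr2 <- tr; tr2$edge.length <- tr$edge.length / 2
    expect_equal(log_likelihood(st, tr, Q1), log_likelihood(st, tr2, Q2),
                 tolerance = 1e-9)
  }
})

test_that("basic model equals SCS model with the neo block switched off", {
  set.seed(23)
  tr <- random_tree(6)
  st <- data.frame(species = tr$tip.label,
                   haploid_autosomes = sample(3:8, 6, replace = TRUE),
                   scs = "XY")
  sp_b <- build_state_space(1, 10, scs = FALSE)
  sp_s <- build_state_space(1, 10, scs = TRUE)
  for (i in 1:5) {
    r <- rexp(2)
    Qb <- build_rate_matrix(rate_params(r[1], r[2]), sp_b)
    Qs <- build_rate_matrix(rate_params(r[1], r[2], 0, 0), sp_s)
    # with rho = sigma = 0 and all tips simple the neo block is unreachable:
    # the flat-root SCS likelihood is exactly half the basic one (the root
    # prior spreads over twice as many states, half with zero likelihood)
    expect_equal(log_likelihood(st, tr, Qs, root_mode = "flat"),
                 log_likelihood(st, tr, Qb, root_mode = "flat") + log(0.5),
                 tolerance = 1e-9)
    # FitzJohn weighting marginalizes the unreachable block away entirely
    expect_equal(log_likelihood(st, tr, Qs, root_mode = "fitzjohn"),
                 log_likelihood(st, tr, Qb, root_mode = "fitzjohn"),
                 tolerance = 1e-9)
  }
})
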