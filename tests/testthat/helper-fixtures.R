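# Shared fixtures and independent oracles. Everything is built in code; no
# stored data files.

# -- tiny fixtures -----------------------------------------------------------

tiny_tree <- function() {
  ape::read.tree(text = "(A:1,(B:0.5,C:0.5):0.5);")
}

tiny_states <- function(k = c(9, 9, 10), scs = c("XY", "XY", "XY")) {
  data.frame(species = c("A", "B", "C"), haploid_autosomes = k, scs = scs,
             stringsAsFactors = FALSE)
}

write_karyo_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

random_tree <- function(n_tips, depth = 1) {
  tr <- ape::rcoal(n_tips)
  tr$edge.length <- tr$edge.length * depth / max(ape::node.depth.edgelength(tr))
  tr
}

# -- oracle: exhaustive-enumeration likelihood -------------------------------

# Vector of root-conditional likelihoods L(s) = P(tip data | root state s),
# by brute-force summation over all internal-node state assignments.
# Independent of the pruning kernel: uses only transition_probs products.
oracle_root_lik <- function(states, tree, Q) {
  space <- attr(Q, "space")
  tree <- ape::reorder.phylo(tree, "postorder")
  S <- nrow(Q)
  n_tip <- length(tree$tip.label)
  idx <- match(tree$tip.label, states$species)
  tip_state <- state_index(space, states$haploid_autosomes[idx],
                           states$scs[idx])
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) transition_probs(Q, tree$edge.length[e]))
  root <- n_tip + 1L
  L <- numeric(S)
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), length(internal))))
  for (g in seq_len(nrow(grid))) {
    assign <- integer(n_tip + tree$Nnode)
    assign[seq_len(n_tip)] <- tip_state
    assign[internal] <- grid[g, ]
    p <- 1
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * P[[e]][assign[tree$edge[e, 1]], assign[tree$edge[e, 2]]]
    }
    L[assign[root]] <- L[assign[root]] + p
  }
  L
}

oracle_loglik <- function(states, tree, Q, root_mode = "fitzjohn",
                          root_state = NULL) {
  L <- oracle_root_lik(states, tree, Q)
  tot <- sum(L)
  if (tot <= 0) return(-Inf)
  switch(root_mode,
         fitzjohn = log(sum(L^2) / tot),
         flat = log(mean(L)),
         fixed = log(L[root_state]))
}

# -- oracle: exhaustive-window HPD -------------------------------------------

oracle_hpd <- function(x, mass) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(Inf, NA, NA)
  for (i in seq_len(n - m + 1)) {
    w <- x[i + m - 1] - x[i]
    if (w < best[1]) best <- c(w, x[i], x[i + m - 1])
  }
  best[2:3]
}

# -- oracle: expected transition counts on an endpoint-conditioned branch ----

# E[# i->j real jumps | X(0)=a, X(t)=b] = q_ij Int_0^t P_ai(u) P_jb(t-u) du
#                                        / P_ab(t),
# summed over all i != j; trapezoid quadrature on a fine grid using only
# matrix exponentials.
oracle_branch_events <- function(Q, a, b, t, n_grid = 400) {
  u <- seq(0, t, length.out = n_grid + 1)
  Pu <- lapply(u, function(uu) transition_probs(Q, uu))
  Pt <- Pu[[n_grid + 1]]
  S <- nrow(Q)
  integrand <- vapply(seq_along(u), function(m) {
    acc <- 0
    for (i in seq_len(S)) for (j in seq_len(S)) {
      if (i != j && Q[i, j] > 0) {
        acc <- acc + Q[i, j] * Pu[[m]][a, i] * Pu[[n_grid + 1 - m + 1]][j, b]
      }
    }
    acc
  }, numeric(1))
  h <- t / n_grid
  integral <- h * (sum(integrand) - 0.5 * integrand[1] -
                     0.5 * integrand[n_grid + 1])
  integral / Pt[a, b]
}

# Batch-means Monte-Carlo standard error for a (possibly autocorrelated)
# chain mean.
batch_se <- function(x, n_batch = 50) {
  n <- length(x)
  b <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch),
                  function(i) mean(x[((i - 1) * b + 1):(i * b)]), numeric(1))
  stats::sd(means) / sqrt(n_batch)
}
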