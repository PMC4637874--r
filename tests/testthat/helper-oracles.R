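# Shared fixtures and independent oracles for the test suite.
#
# The enumeration oracle computes site likelihoods by summing over every
# assignment of states to internal nodes (and to gapped leaves), entirely
# independently of the pruning engine.

# Exhaustive site log-likelihood for one alignment column.
# classes: the engine's mixture-class list (weights, eigs, emap, freq);
# transition probabilities are recomputed here from matrix exponentials via
# repeated squaring of a Taylor series, NOT from the engine's eigen path.
oracle_site_lnl <- function(tree, aln, classes, site) {
  ti <- phyloconverge:::tree_index(tree)
  S <- length(classes[[1L]]$freq)
  int_nodes <- (ti$ntip + 1L):ti$nnodes_all
  lik_total <- 0
  for (cl in classes) {
    Ps <- lapply(seq_len(nrow(ti$edge)), function(e) {
      eg <- cl$eigs[[cl$emap[e]]]
      Q <- (eg$V1 %*% (eg$lambda * eg$V2))  # reconstruct Q from eigen pairs
      expm_taylor(Q * ti$el[e] * cl$rate)
    })
    leaf_state <- aln$x[match(ti$tip.label, aln$taxa), site]
    # enumerate internal assignments (vectorized over the grid rows)
    grid <- as.matrix(expand.grid(rep(list(seq_len(S)), length(int_nodes))))
    colnames(grid) <- as.character(int_nodes)
    pr <- cl$freq[grid[, as.character(ti$root)]]
    for (e in seq_len(nrow(ti$edge))) {
      par <- ti$edge[e, 1L]; ch <- ti$edge[e, 2L]
      ps <- grid[, as.character(par)]
      if (ch <= ti$ntip) {
        st <- leaf_state[ch]
        if (!is.na(st)) pr <- pr * Ps[[e]][cbind(ps, st)]
      } else {
        pr <- pr * Ps[[e]][cbind(ps, grid[, as.character(ch)])]
      }
    }
    lik_total <- lik_total + cl$w * sum(pr)
  }
  log(lik_total)
}

# Matrix exponential by scaling-and-squaring Taylor series (oracle path).
expm_taylor <- function(A, order = 24L) {
  n <- nrow(A)
  s <- max(0L, ceiling(log2(max(1e-16, max(abs(A))))) + 4L)
  A <- A / 2^s
  E <- diag(n)
  term <- diag(n)
  for (k in seq_len(order)) {
    term <- term %*% A / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

# Exhaustive marginal posterior over states at one internal node.
oracle_node_posterior <- function(tree, aln, classes, site, node) {
  ti <- phyloconverge:::tree_index(tree)
  S <- length(classes[[1L]]$freq)
  int_nodes <- (ti$ntip + 1L):ti$nnodes_all
  post <- numeric(S)
  for (cl in classes) {
    Ps <- lapply(seq_len(nrow(ti$edge)), function(e) {
      eg <- cl$eigs[[cl$emap[e]]]
      Q <- (eg$V1 %*% (eg$lambda * eg$V2))
      expm_taylor(Q * ti$el[e] * cl$rate)
    })
    leaf_state <- aln$x[match(ti$tip.label, aln$taxa), site]
    grid <- as.matrix(expand.grid(rep(list(seq_len(S)), length(int_nodes))))
    colnames(grid) <- as.character(int_nodes)
    pr <- cl$freq[grid[, as.character(ti$root)]]
    for (e in seq_len(nrow(ti$edge))) {
      par <- ti$edge[e, 1L]; ch <- ti$edge[e, 2L]
      ps <- grid[, as.character(par)]
      if (ch <= ti$ntip) {
        st <- leaf_state[ch]
        if (!is.na(st)) pr <- pr * Ps[[e]][cbind(ps, st)]
      } else {
        pr <- pr * Ps[[e]][cbind(ps, grid[, as.character(ch)])]
      }
    }
    tgt <- grid[, as.character(node)]
    for (s in seq_len(S)) post[s] <- post[s] + cl$w * sum(pr[tgt == s])
  }
  post / sum(post)
}

# Random rooted binary tree with n leaves and exp-distributed branch lengths.
random_tree <- function(n, mean_bl = 0.15) {
  tr <- ape::rtree(n, rooted = TRUE, br = function(k) stats::rexp(k, 1 / mean_bl))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# Random AA alignment (uniform states, occasional gaps).
random_aa_alignment <- function(taxa, L, gap_frac = 0.1) {
  x <- matrix(sample.int(20L, length(taxa) * L, replace = TRUE),
              nrow = length(taxa))
  if (gap_frac > 0)
    x[sample.int(length(x), round(gap_frac * length(x)))] <- NA_integer_
  rownames(x) <- taxa
  phyloconverge:::alignment_from_states(x, "aa")
}

# The bundled study scaffold at two sizes.
toy20 <- function() toy_species_tree()

toy12 <- function() {
  st <- toy_species_tree()
  keep <- c("dolphin", "killer_whale", "minke_whale", "cow", "pig",
            "walrus", "seal", "dog", "horse", "human", "mouse", "manatee")
  list(tree = ape::keep.tip(st$tree, keep),
       groups = list(cetaceans = c("dolphin", "killer_whale", "minke_whale"),
                     pinnipeds = c("walrus", "seal"),
                     sirenians = "manatee"))
}

toy8 <- function() {
  st <- toy_species_tree()
  keep <- c("dolphin", "minke_whale", "cow", "walrus", "dog", "horse",
            "manatee", "hyrax")
  list(tree = ape::keep.tip(st$tree, keep),
       groups = list(cetaceans = c("dolphin", "minke_whale"),
                     pinnipeds = "walrus",
                     sirenians = "manatee"))
}

toy6 <- function() {
  st <- toy_species_tree()
  keep <- c("dolphin", "minke_whale", "cow", "walrus", "dog", "manatee")
  list(tree = ape::keep.tip(st$tree, keep),
       groups = list(cetaceans = c("dolphin", "minke_whale"),
                     pinnipeds = "walrus",
                     sirenians = "manatee"))
}
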