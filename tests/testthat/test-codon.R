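# Codon models: GY94 construction, F3x4, LRT machinery, and model
# reductions. Heavier recovery simulations live in the acceptance suite.

test_that("F3x4 gives uniform sense-codon frequencies for uniform input", {
  # an alignment containing every sense codon equally often
  x <- matrix(rep(1:61, 8), nrow = 8, byrow = TRUE)
  rownames(x) <- paste0("t", 1:8)
  aln <- phyloconverge:::alignment_from_states(x, "codon")
  fr <- f3x4_frequencies(aln)
  # uniform codon usage is not exactly uniform nucleotide usage (stop
  # codons are absent), so compare against the F3x4 recomputation
  nf <- matrix(0, 3, 4)
  for (pos in 1:3) nf[pos, ] <- tabulate(CODON61_NUC[x, pos], nbins = 4)
  nf <- nf / rowSums(nf)
  expected <- nf[1, CODON61_NUC[, 1]] * nf[2, CODON61_NUC[, 2]] *
    nf[3, CODON61_NUC[, 3]]
  expect_equal(fr, expected / sum(expected), tolerance = 1e-12)
  expect_equal(sum(fr), 1, tolerance = 1e-12)

  # uniform nucleotide composition at every codon position -> exactly 1/61
  # after stop exclusion (TGC/CAT/ATG/GCA cover T,C,A,G at each position)
  u <- matrix(match(c("TGC", "CAT", "ATG", "GCA"), CODON61), nrow = 2,
              ncol = 4, byrow = TRUE, dimnames = list(c("a", "b"), NULL))
  ualn <- phyloconverge:::alignment_from_states(u, "codon")
  expect_equal(f3x4_frequencies(ualn), rep(1 / 61, 61), tolerance = 1e-12)
})

test_that("omega = 0 removes every nonsynonymous rate", {
  Q <- phyloconverge:::codon_q_raw(2, 0, rep(1 / 61, 61))
  cp <- phyloconverge:::codon_pairs
  expect_true(all(Q[cbind(cp$I, cp$J)][cp$ns] == 0))
  expect_true(all(Q[cbind(cp$I, cp$J)][!cp$ns] > 0))
})

test_that("GY94 entries match a hand-built construction", {
  # hand oracle: enumerate codon pairs from scratch with string operations
  kappa <- 2; omega <- 0.3
  freq <- rep(1 / 61, 61)
  Q <- phyloconverge:::codon_q_raw(kappa, omega, freq)
  hand_entry <- function(ci, cj) {
    a <- strsplit(ci, "")[[1]]; b <- strsplit(cj, "")[[1]]
    d <- which(a != b)
    if (length(d) != 1) return(0)
    ts <- paste0(sort(c(a[d], b[d])), collapse = "") %in% c("AG", "CT")
    ns <- GENETIC_CODE_STD[[ci]] != GENETIC_CODE_STD[[cj]]
    (1 / 61) * (if (ts) kappa else 1) * (if (ns) omega else 1)
  }
  set.seed(2)
  for (i in sample(61, 12)) for (j in sample(61, 12)) {
    if (i == j) next
    expect_equal(Q[i, j], hand_entry(CODON61[i], CODON61[j]),
                 tolerance = 1e-12)
  }
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
})

test_that("the scaled codon model is reversible with unit expected rate", {
  set.seed(3)
  aln_x <- matrix(sample.int(61L, 6 * 100, replace = TRUE), nrow = 6,
                  dimnames = list(paste0("t", 1:6), NULL))
  aln <- phyloconverge:::alignment_from_states(aln_x, "codon")
  m <- codon_model(kappa = 3, omega = 0.5, freq = f3x4_frequencies(aln))
  expect_equal(-sum(m$freq * diag(m$Q)), 1, tolerance = 1e-10)
  A <- m$freq * m$Q
  expect_equal(max(abs(A - t(A))), 0, tolerance = 1e-12)
  P <- transition_matrix(m, 0.2)
  expect_equal(max(abs(rowSums(P) - 1)), 0, tolerance = 1e-10)
})

test_that("likelihood ratio tests follow the chi-square convention", {
  same <- likelihood_ratio_test(-100, -100, 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  crit <- likelihood_ratio_test(-100, -100 + 3.841 / 2, 1)
  expect_equal(crit$p, 0.05, tolerance = 1e-3)
  expect_error(likelihood_ratio_test(-100, -101, 1), "re-optimize")
  expect_error(likelihood_ratio_test(-100, -99, 0), "positive")
})

test_that("with a single omega = 1 class all model families coincide", {
  set.seed(4)
  st <- toy6()
  cm <- codon_model(kappa = 2, omega = 0.3)
  sim <- simulate_alignment(simulation_spec(st$tree, cm, 60, seed = 5))
  cs <- phyloconverge:::codon_setup(st$tree, sim$alignment)
  fg <- phyloconverge:::foreground_edges(cs$ti$tree, st$groups)
  one <- list(list(w = 1, omega_bg = 1, omega_fg = 1))
  base <- phyloconverge:::cs_lnl(cs, one, kappa = 2)
  # branch model with both omegas at 1
  branch <- phyloconverge:::cs_lnl(
    cs, list(list(w = 1, omega_bg = 1, omega_fg = 1)), 2, fg_edges = fg)
  # M8-style mixture collapsed onto omega = 1 in every class
  m8ish <- phyloconverge:::cs_lnl(
    cs, lapply(rep(0.1, 10), function(w)
      list(w = w, omega_bg = 1, omega_fg = 1)), 2)
  cmcish <- phyloconverge:::cs_lnl(
    cs, list(list(w = 0.5, omega_bg = 1, omega_fg = 1),
             list(w = 0.3, omega_bg = 1, omega_fg = 1),
             list(w = 0.2, omega_bg = 1, omega_fg = 1)), 2, fg_edges = fg)
  expect_equal(branch, base, tolerance = 1e-4)
  expect_equal(m8ish, base, tolerance = 1e-4)
  expect_equal(cmcish, base, tolerance = 1e-4)
})

test_that("beta categories integrate to the distribution mean", {
  for (pq in list(c(2, 2), c(0.3, 1.7), c(5, 1))) {
    om <- phyloconverge:::beta_category_means(pq[1], pq[2], 10)
    expect_length(om, 10L)
    expect_true(all(diff(om) > 0))
    expect_equal(mean(om), pq[1] / sum(pq), tolerance = 1e-10)
  }
})

test_that("branch model recovers elevated foreground omega and flags dS-free data", {
  set.seed(6)
  st <- toy12()
  cm <- codon_model(kappa = 2.5, omega = 0.2)
  sim <- simulate_alignment(simulation_spec(st$tree, cm, 250, seed = 7,
                                            omega_fg = 0.9,
                                            fg_groups = st$groups))
  bm <- fit_branch_model(st$tree, sim$alignment, st$groups)
  expect_gt(bm$delta_omega, 0)
  expect_gt(bm$omega_fg, bm$omega_bg)
  expect_lte(bm$lrt$p, 0.05)
  expect_true(bm$rapid)
  # multi-start lnL spread stays within tolerance of the best
  expect_lt(max(bm$alt$multi_start_lnl) - min(bm$alt$multi_start_lnl), 2)

  # invariant columns: no synonymous variation -> flagged, no call
  x0 <- matrix(rep(sim$alignment$x[1, 1:30], each = 12), nrow = 12,
               dimnames = list(rownames(sim$alignment$x), NULL))
  aln0 <- phyloconverge:::alignment_from_states(x0, "codon")
  bm0 <- fit_branch_model(st$tree, aln0, st$groups)
  expect_true("no_synonymous_variation" %in% bm0$flags)
  expect_true(is.na(bm0$rapid))
})

test_that("all-identical sequences make M7/M8 unidentifiable", {
  st <- toy6()
  x0 <- matrix(rep.int(5L, 6 * 20), nrow = 6,
               dimnames = list(st$tree$tip.label, NULL))
  aln0 <- phyloconverge:::alignment_from_states(x0, "codon")
  out <- fit_sites_m7_m8(st$tree, aln0)
  expect_true("unidentifiable" %in% out$flags)
  expect_null(out$site_omega)
})

test_that("clade model C assigns sites by the posterior > 0.5 rule", {
  set.seed(8)
  st <- toy6()
  cm <- codon_model(kappa = 2, omega = 0.1)
  L <- 150
  om_site <- rep(c(0.05, 1), c(100, 50))
  sim <- simulate_alignment(simulation_spec(st$tree, cm, L, seed = 9,
                                            omega_site = om_site))
  cc <- fit_clade_model_c(st$tree, sim$alignment, st$groups)
  post <- cc$site_posterior
  expect_equal(max(abs(colSums(post) - 1)), 0, tolerance = 1e-8)
  assigned <- !is.na(cc$site_category)
  expect_true(all(post[cbind(cc$site_category[assigned] + 1L,
                             which(assigned))] > 0.5))
})
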