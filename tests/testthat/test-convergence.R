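# Convergence hypotheses, dSSLS, and empirical significance.

test_that("three focal lineages yield 9 valid alternative topologies", {
  st <- toy20()
  hyps <- generate_alternative_topologies(st$tree, st$groups)
  expect_length(hyps, 9L)
  focal <- unlist(st$groups, use.names = FALSE)
  for (h in hyps) {
    expect_setequal(h$ha$tip.label, st$tree$tip.label)
    expect_true(phyloconverge:::is_monophyletic(h$ha, focal))
    expect_true(ape::is.binary.phylo(h$ha))
  }
  # all 9 are topologically distinct
  for (i in 1:8) for (j in (i + 1):9)
    expect_gt(phangorn::RF.dist(hyps[[i]]$ha, hyps[[j]]$ha), 0)
})

test_that("two focal lineages yield 2 topologies; degenerate inputs error", {
  st <- toy20()
  two <- st$groups[c("cetaceans", "pinnipeds")]
  expect_length(generate_alternative_topologies(st$tree, two), 2L)
  # sister taxa: already monophyletic
  expect_error(
    generate_alternative_topologies(st$tree,
                                    list(a = "dolphin", b = "killer_whale")),
    "already monophyletic")
  expect_error(
    generate_alternative_topologies(st$tree, list(a = "dolphin", b = "yeti")),
    "not in tree")
})

test_that("dSSLS is zero when H_A equals H_0 and antisymmetric under swap", {
  set.seed(31)
  st <- toy8()
  sim <- simulate_alignment(simulation_spec(
    st$tree, aa_model("JTT", alpha = 0.8, k = 2), 100, seed = 7))
  m <- aa_model("JTT", alpha = 0.8, k = 2)
  hyps <- generate_alternative_topologies(st$tree, st$groups)
  self_hyp <- structure(list(id = "SELF", h0 = st$tree, ha = st$tree,
                             focal = character(0)),
                        class = "convergence_hypothesis")
  d0 <- compute_delta_ssls(sim$alignment, self_hyp, m)
  expect_lt(max(abs(d0$per_site)), 1e-6)

  h <- hyps[[1L]]
  fwd <- compute_delta_ssls(sim$alignment, h, m)
  swapped <- structure(list(id = "SWAP", h0 = h$ha, ha = h$h0,
                            focal = h$focal), class = "convergence_hypothesis")
  # swapping H_0 and H_A negates per-site values (same two fits, reversed)
  bwd <- compute_delta_ssls(sim$alignment, swapped, m)
  expect_equal(bwd$per_site, -fwd$per_site, tolerance = 2e-4)
  expect_equal(d0$mean, mean(d0$per_site), tolerance = 1e-10)
})

test_that("the empirical cdf P follows the interpolation and clamp rules", {
  null <- c(1, 2, 3, 4)
  expect_equal(empirical_p(2.5, null), 0.375)           # interpolated
  expect_equal(empirical_p(0.5, null), 1)               # below all nulls
  expect_equal(empirical_p(9999, 1:2500), 1 / 2501)     # clamped floor
  # P non-increasing in the observed value; cdf non-decreasing
  obs <- seq(0, 5, by = 0.25)
  p <- empirical_p(obs, null)
  expect_true(all(diff(p) <= 1e-12))
  expect_true(all(p >= 1 / 5 & p <= 1))
})

test_that("null distribution simulation is seed-deterministic", {
  set.seed(77)
  st <- toy6()
  sim <- simulate_alignment(simulation_spec(
    st$tree, aa_model("JTT", alpha = 1, k = 2), 60, seed = 3))
  fit <- optimize_likelihood(st$tree, sim$alignment,
                             aa_model("JTT", alpha = 1, k = 2), tol = 1e-4)
  hyps <- generate_alternative_topologies(st$tree, st$groups)[1:2]
  n1 <- simulate_null_distribution(list(fit), hyps, R = 2, seed = 9)
  n2 <- simulate_null_distribution(list(fit), hyps, R = 2, seed = 9)
  expect_identical(n1$values, n2$values)
  expect_length(n1$values[[1L]], 2L)
  expect_false(is.unsorted(n1$values[[1L]]))
})

test_that("gene calling honors the aggregation rules", {
  tab <- data.frame(
    gene = rep(c("g1", "g2"), each = 9),
    hypothesis = rep(sprintf("H%02d", 1:9), 2),
    mean_dssls = c(0.5, rep(0.2, 8), rep(0.4, 9)),
    p = c(0.04, rep(0.2, 8), rep(0.01, 9)))
  any_call <- call_convergent_genes(tab, 0.05, "any")
  expect_true(any_call$call[any_call$gene == "g1"])
  expect_true(any_call$call[any_call$gene == "g2"])
  all_call <- call_convergent_genes(tab, 0.05, "all")
  expect_false(all_call$call[all_call$gene == "g1"])
  expect_true(all_call$call[all_call$gene == "g2"])
  mean_call <- call_convergent_genes(tab, 0.05, "mean")
  expect_false(mean_call$call[mean_call$gene == "g1"])
  expect_true(mean_call$call[mean_call$gene == "g2"])
  expect_error(call_convergent_genes(tab, 0.05, "median"))
})
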