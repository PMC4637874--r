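# Marginal ancestral reconstruction and substitution classification.

test_that("agreeing descendants dominate the root posterior", {
  x <- matrix(match("L", AA_STATES), 2, 1, dimnames = list(c("A", "B"), NULL))
  aln <- phyloconverge:::alignment_from_states(x, "aa")
  tr <- read_tree("(A:0.1,B:0.1);")
  m <- aa_model("WAG", alpha = 1, k = 1)
  asr <- marginal_ancestral_reconstruction(tr, aln, m, optimize = FALSE)
  expect_equal(AA_STATES[asr$map[1, 1]], "L")
  expect_gt(asr$map_posterior[1, 1], 0.9)
})

test_that("marginal posteriors equal exhaustive Bayes on a 4-leaf tree", {
  set.seed(19)
  tr <- random_tree(4)
  aln <- random_aa_alignment(tr$tip.label, 4, gap_frac = 0.2)
  m <- aa_model("JTT", alpha = 1, k = 1)
  asr <- marginal_ancestral_reconstruction(tr, aln, m, optimize = FALSE)
  classes <- phyloconverge:::aa_classes(m, nrow(tr$edge))
  for (site in 1:4) {
    for (vi in seq_along(asr$node_ids)) {
      ora <- oracle_node_posterior(tr, aln, classes, site, asr$node_ids[vi])
      expect_equal(unname(asr$post[, site, vi]), ora, tolerance = 1e-8)
    }
  }
  sums <- apply(asr$post, c(2, 3), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-8)
})

test_that("a fully missing site falls back to the stationary prior", {
  set.seed(4)
  tr <- random_tree(5)
  aln <- random_aa_alignment(tr$tip.label, 3, gap_frac = 0)
  aln$x[, 2] <- NA_integer_
  m <- aa_model("WAG", alpha = 1, k = 2)
  asr <- marginal_ancestral_reconstruction(tr, aln, m, optimize = FALSE)
  for (vi in seq_along(asr$node_ids))
    expect_equal(unname(asr$post[, 2, vi]), m$freq, tolerance = 1e-8)
})

test_that("unrooted trees are rejected with advice to root", {
  tr <- ape::unroot(read_tree("((A:1,B:1):1,(C:1,D:1):1);"))
  aln <- random_aa_alignment(c("A", "B", "C", "D"), 5)
  expect_error(
    marginal_ancestral_reconstruction(tr, aln, aa_model("WAG", k = 1)),
    "root")
})

# Hand-built scenario: 8 focal leaves carry K, background varies.
classification_fixture <- function(bg_states, anc_override = NULL) {
  st <- toy12()
  m <- aa_model("JTT", alpha = 1, k = 1)
  sim <- simulate_alignment(simulation_spec(st$tree, m, 6, seed = 50))
  aln <- sim$alignment
  focal <- unlist(st$groups, use.names = FALSE)
  bg <- setdiff(aln$taxa, focal)
  # site 3: planted parallel K with ancestral state R everywhere else
  aln$x[, 3] <- match("R", AA_STATES)
  aln$x[focal, 3] <- match("K", AA_STATES)
  for (nm in names(bg_states)) aln$x[nm, 3] <- match(bg_states[[nm]], AA_STATES)
  list(st = st, aln = aln, m = m)
}

test_that("parallel calls require shared derived state differing from ancestors", {
  fx <- classification_fixture(list())
  asr <- marginal_ancestral_reconstruction(fx$st$tree, fx$aln, fx$m,
                                           optimize = FALSE)
  cfg <- focal_group_config(fx$st$tree, fx$st$groups)
  calls <- call_parallel_substitutions(asr, cfg)
  expect_true(3 %in% calls$site)
  row <- calls[calls$site == 3, ]
  expect_equal(row$derived, "K")
  expect_true(row$unique)
  expect_true(row$strict_parallel)

  # a terrestrial leaf carrying the derived state spoils uniqueness only
  fx2 <- classification_fixture(list(mouse = "K"))
  asr2 <- marginal_ancestral_reconstruction(fx$st$tree, fx2$aln, fx$m,
                                            optimize = FALSE)
  calls2 <- call_parallel_substitutions(asr2, cfg)
  row2 <- calls2[calls2$site == 3, ]
  expect_equal(nrow(row2), 1L)
  expect_false(row2$unique)
  expect_length(call_parallel_substitutions(asr2, cfg,
                                            require_unique = TRUE)$site |>
                  intersect(3), 0L)
})

test_that("unique calls demand absence from background and ancestors", {
  fx <- classification_fixture(list())
  asr <- marginal_ancestral_reconstruction(fx$st$tree, fx$aln, fx$m,
                                           optimize = FALSE)
  cfg <- focal_group_config(fx$st$tree, fx$st$groups)
  uni <- call_unique_substitutions(asr, cfg)
  expect_true(3 %in% uni$site)

  fx2 <- classification_fixture(list(mouse = "K"))
  asr2 <- marginal_ancestral_reconstruction(fx$st$tree, fx2$aln, fx$m,
                                            optimize = FALSE)
  expect_false(3 %in% call_unique_substitutions(asr2, cfg)$site)

  # a gapped focal leaf is missing data, not a mismatch
  fx3 <- classification_fixture(list())
  fx3$aln$x["seal", 3] <- NA_integer_
  asr3 <- marginal_ancestral_reconstruction(fx$st$tree, fx3$aln, fx$m,
                                            optimize = FALSE)
  uni3 <- call_unique_substitutions(asr3, cfg)
  expect_true(3 %in% uni3$site)
  expect_equal(uni3$missing_leaves[uni3$site == 3], 1L)
})

test_that("backward annotation follows the reference-fraction rule", {
  calls <- data.frame(site = c(1L, 2L, 3L), ref_pos = 1:3,
                      category = "parallel", derived = c("E", "E", "E"))
  rx <- matrix(match(c("E", "A", NA,
                       "E", "A", NA,
                       "D", "A", NA,
                       "E", "A", NA), AA_STATES),
               nrow = 4, byrow = TRUE,
               dimnames = list(paste0("ref", 1:4), NULL))
  ref <- phyloconverge:::alignment_from_states(rx, "aa")
  out <- call_backward_substitutions(calls, ref, n_columns = 3)
  expect_true(out$backward[1])        # 3/4 reference taxa match
  expect_false(out$backward[2])       # none match
  expect_true(out$no_reference_data[3])
  expect_false(out$backward[3])
  expect_error(call_backward_substitutions(calls, ref, n_columns = 99),
               "columns")
})

test_that("planted parallel sites are recovered with no false calls nearby", {
  set.seed(60)
  st <- toy12()
  m <- aa_model("JTT", alpha = 1, k = 2)
  sim <- simulate_alignment(simulation_spec(st$tree, m, 300, seed = 61))
  sites <- seq(20, 300, by = 20)  # 15 planted sites
  feats <- data.frame(site = sites,
                      target = rep(c("W", "K", "L"), 5),
                      kind = "parallel")
  pl <- plant_convergent_sites(sim$alignment, st$groups, feats, seed = 62)
  asr <- marginal_ancestral_reconstruction(st$tree, pl$alignment, m)
  cfg <- focal_group_config(st$tree, st$groups)
  calls <- call_parallel_substitutions(asr, cfg)
  expect_gte(length(intersect(calls$site, sites)), 13L)
})
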