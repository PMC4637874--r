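# Sequence simulator and study fixture generator.

test_that("pairwise divergence matches the equal-rates closed form", {
  tr <- read_tree("(A:0.15,B:0.15);")
  m <- aa_model("POISSON", alpha = 1, k = 1)
  sim <- simulate_alignment(simulation_spec(tr, m, 5000, seed = 11))
  pdiff <- mean(sim$alignment$x[1, ] != sim$alignment$x[2, ])
  pexp <- (19 / 20) * (1 - exp(-20 * 0.3 / 19))
  expect_lt(abs(pdiff - pexp), 0.03)
})

test_that("zero branch lengths copy the root; same seed repeats exactly", {
  tr <- read_tree("((A:0,B:0):0,C:0);")
  m <- aa_model("WAG", alpha = 1, k = 1)
  sim <- simulate_alignment(simulation_spec(tr, m, 50, seed = 12))
  root_states <- sim$node_states[4L, ]
  for (i in 1:3) expect_equal(unname(sim$alignment$x[i, ]), root_states)
  expect_equal(nrow(sim$events), 0L)

  st <- toy8()
  s1 <- simulate_alignment(simulation_spec(st$tree, m, 80, seed = 13))
  s2 <- simulate_alignment(simulation_spec(st$tree, m, 80, seed = 13))
  f1 <- tempfile(); f2 <- tempfile()
  write_alignment(s1$alignment, f1); write_alignment(s2$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical FASTA
})

test_that("event-log substitution counts track branch lengths", {
  tr <- read_tree("(A:0.4,B:0.1);")
  m <- aa_model("POISSON", alpha = 1, k = 1)
  sim <- simulate_alignment(simulation_spec(tr, m, 10000, seed = 14,
                                            method = "gillespie"))
  cnt <- table(factor(sim$events$edge, levels = 1:2))
  el <- phyloconverge:::tree_index(tr)$el
  for (e in 1:2)
    expect_lt(abs(cnt[[e]] / 10000 - el[e]), 0.1 * max(el[e], 0.05))
})

test_that("simulated frequencies converge to the stationary distribution", {
  tr <- read_tree("(A:10,B:10);")
  m <- aa_model("JTT", alpha = 1, k = 1)
  sim <- simulate_alignment(simulation_spec(tr, m, 10000, seed = 15))
  obs <- tabulate(sim$alignment$x, nbins = 20)
  chi <- stats::chisq.test(obs, p = m$freq)
  expect_gt(chi$p.value, 0.01)
})

test_that("codon simulation with omega = 0 yields no nonsynonymous changes", {
  st <- toy8()
  cm <- codon_model(kappa = 2, omega = 0)
  for (method in c("matrix", "gillespie")) {
    sim <- simulate_alignment(simulation_spec(st$tree, cm, 100, seed = 16,
                                              method = method))
    expect_equal(sum(sim$events$nonsyn), 0L)
  }
})

test_that("planted features construct the expected classifier inputs", {
  st <- toy12()
  m <- aa_model("JTT", alpha = 1, k = 1)
  sim <- simulate_alignment(simulation_spec(st$tree, m, 40, seed = 17))
  focal <- unlist(st$groups, use.names = FALSE)
  bg <- setdiff(sim$alignment$taxa, focal)

  # no features: unchanged
  pl0 <- plant_convergent_sites(sim$alignment, st$groups,
                                data.frame(site = integer(0),
                                           target = character(0),
                                           kind = character(0)))
  expect_identical(pl0$alignment$x, sim$alignment$x)

  feats <- data.frame(site = c(5L, 9L), target = c("L", "W"),
                      kind = c("parallel", "unique"))
  pl <- plant_convergent_sites(sim$alignment, st$groups, feats, seed = 18)
  expect_true(all(AA_STATES[pl$alignment$x[focal, 5]] == "L"))
  expect_true(all(AA_STATES[pl$alignment$x[focal, 9]] == "W"))
  expect_false(any(AA_STATES[pl$alignment$x[bg, 9]] == "W", na.rm = TRUE))
  expect_error(plant_convergent_sites(sim$alignment, st$groups,
                                      data.frame(site = 999L, target = "L",
                                                 kind = "parallel")),
               "out of range")
  expect_error(plant_convergent_sites(sim$alignment, st$groups,
                                      data.frame(site = 5L, target = "B",
                                                 kind = "parallel")),
               "invalid planted state")
})

test_that("toy studies are complete, truthful, and seed-deterministic", {
  st <- toy8()
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  unlink(c(d1, d2), recursive = TRUE)
  cfg <- c(h0 = 3, ha = 2, fgw = 2, parallel = 1)
  generate_toy_study(d1, n_genes = cfg, seed = 19, codon_range = c(40, 60),
                     tree = st$tree, groups = st$groups)
  generate_toy_study(d2, n_genes = cfg, seed = 19, codon_range = c(40, 60),
                     tree = st$tree, groups = st$groups)
  truth <- utils::read.delim(file.path(d1, "truth.tsv"))
  expect_equal(nrow(truth), 8L)
  expect_equal(sum(truth$regime != "h0"), 5L)
  expect_equal(length(list.files(file.path(d1, "genes"))), 8L)
  # identical checksums across same-seed runs
  files <- list.files(d1, recursive = TRUE)
  expect_identical(
    unname(tools::md5sum(file.path(d1, files))),
    unname(tools::md5sum(file.path(d2, files))))
})
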