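# Pruning-engine correctness: degenerate cases, enumeration oracle,
# re-rooting invariance, and an independent cross-check against phangorn.

test_that("single-leaf likelihood is the stationary log-frequency", {
  m <- aa_model("WAG", alpha = 1, k = 1)
  x <- matrix(c(3L, 7L, NA), nrow = 1, dimnames = list("A", NULL))
  aln <- phyloconverge:::alignment_from_states(x, "aa")
  tr <- ape::read.tree(text = "(A:1);")
  p <- site_log_likelihoods(tr, aln, m)
  expect_equal(p$site_lnl, c(log(m$freq[3]), log(m$freq[7]), 0),
               tolerance = 1e-12)
})

test_that("all-gap columns contribute zero log-likelihood and totals add up", {
  set.seed(11)
  tr <- random_tree(5)
  aln <- random_aa_alignment(tr$tip.label, 30)
  aln$x[, 7] <- NA_integer_
  m <- aa_model("JTT", alpha = 0.8, k = 4)
  p <- site_log_likelihoods(tr, aln, m)
  expect_equal(p$site_lnl[7], 0, tolerance = 1e-12)
  expect_equal(sum(p$site_lnl), p$lnl, tolerance = 1e-8)
  expect_true(all(p$site_lnl <= 1e-12))
})

test_that("pruning equals exhaustive enumeration on small random trees", {
  set.seed(42)
  for (case in 1:12) {
    n <- sample(3:5, 1)
    k <- sample(1:2, 1)
    tr <- random_tree(n)
    aln <- random_aa_alignment(tr$tip.label, 3, gap_frac = 0.15)
    m <- aa_model(sample(c("JTT", "WAG", "POISSON"), 1), alpha = 0.6, k = k)
    p <- site_log_likelihoods(tr, aln, m)
    classes <- phyloconverge:::aa_classes(m, nrow(tr$edge))
    for (s in 1:3) {
      expect_equal(p$site_lnl[s], oracle_site_lnl(tr, aln, classes, s),
                   tolerance = 1e-8)
    }
  }
})

test_that("likelihood is invariant to re-rooting under a reversible model", {
  set.seed(5)
  tr <- random_tree(6)
  aln <- random_aa_alignment(tr$tip.label, 25)
  m <- aa_model("WAG", alpha = 0.5, k = 2)
  base <- site_log_likelihoods(tr, aln, m)$lnl
  ut <- ape::unroot(tr)
  for (node in c(2L, 4L)) {
    rr <- ape::root(ut, outgroup = node, resolve.root = TRUE)
    rr$edge.length[is.na(rr$edge.length)] <- 0
    expect_equal(site_log_likelihoods(rr, aln, m)$lnl, base,
                 tolerance = 1e-8)
  }
})

test_that("engine agrees with phangorn's pml on gamma-mixture models", {
  set.seed(9)
  tr <- random_tree(8)
  aln <- random_aa_alignment(tr$tip.label, 60, gap_frac = 0.05)
  for (spec in list(c("WAG", 1), c("JTT", 4))) {
    m <- aa_model(spec[1], alpha = 0.63, k = as.integer(spec[2]))
    mine <- site_log_likelihoods(tr, aln, m)
    ch <- phyloconverge:::alignment_chars(aln)
    pd <- phangorn::phyDat(ch, type = "AA")
    fp <- phangorn::pml(tr, pd, model = spec[1], k = as.integer(spec[2]),
                        shape = 0.63)
    expect_equal(mine$lnl, as.numeric(fp$logLik), tolerance = 1e-6)
    idx <- attr(pd, "index")
    expect_equal(mine$site_lnl, fp$siteLik[idx], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("taxon mismatches are reported by name", {
  tr <- read_tree("((A:1,B:1):1,C:1);")
  aln <- random_aa_alignment(c("A", "B", "Z"), 5)
  m <- aa_model("WAG", k = 1)
  expect_error(site_log_likelihoods(tr, aln, m), "Z")
})
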