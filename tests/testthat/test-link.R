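# Sitewise convergence-selection link: joins and locus-wise regressions.

make_tables <- function(n_genes = 3, n_sites = 100, m8_sites = NULL,
                        seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  ssls <- expand.grid(gene = genes, site = seq_len(n_sites),
                      stringsAsFactors = FALSE)
  ssls$dssls <- stats::rnorm(nrow(ssls))
  m8 <- ssls[, c("gene", "site")]
  m8$omega <- stats::rexp(nrow(m8), 2)
  if (!is.null(m8_sites)) m8 <- m8[m8$site %in% m8_sites, ]
  cmc <- ssls[, c("gene", "site")]
  cmc$category <- sample(0:2, nrow(cmc), replace = TRUE)
  list(ssls = ssls, m8 = m8, cmc = cmc)
}

test_that("the site join keeps exactly the complete rows", {
  tb <- make_tables(1, 100)
  j <- join_site_metrics(tb$ssls, tb$m8, tb$cmc)
  expect_equal(nrow(j), 100L)
  expect_equal(attr(j, "dropped"), 0L)

  tb2 <- make_tables(1, 100, m8_sites = 1:80)
  j2 <- join_site_metrics(tb2$ssls, tb2$m8, tb2$cmc)
  expect_equal(nrow(j2), 80L)
  expect_equal(attr(j2, "dropped"), 20L)

  # a gene whose M8 LRT failed contributes no rows at all
  tb3 <- make_tables(2, 50)
  tb3$m8 <- tb3$m8[tb3$m8$gene == "g01", ]
  j3 <- join_site_metrics(tb3$ssls, tb3$m8, tb3$cmc)
  expect_setequal(unique(j3$gene), "g01")

  dup <- rbind(tb$m8, tb$m8[1, ])
  expect_error(join_site_metrics(tb$ssls, dup, tb$cmc), "duplicate")
})

test_that("a planted linear relationship is recovered", {
  set.seed(7)
  omega <- stats::rexp(200, 1)
  d <- data.frame(gene = "g1", site = 1:200,
                  dssls = 2 * omega + stats::rnorm(200, sd = 0.5),
                  omega = omega, category = 2L)
  fit <- fit_locus_regressions(d, min_sites = 10)
  expect_equal(nrow(fit$loci), 1L)
  expect_lt(abs(fit$loci$slope - 2), 0.3)
  expect_equal(fit$loci$classification, "positive")
})

test_that("independent metrics are significant at about the nominal rate", {
  set.seed(8)
  rows <- lapply(1:1000, function(i) {
    om <- stats::rexp(30, 1)
    data.frame(gene = sprintf("g%04d", i), site = 1:30,
               dssls = stats::rnorm(30), omega = om, category = 1L)
  })
  fit <- fit_locus_regressions(do.call(rbind, rows), min_sites = 10)
  rate <- mean(fit$loci$classification != "ns")
  expect_lt(abs(rate - 0.05), 0.02)
})

test_that("thresholds, degenerate groups and invariances are honored", {
  set.seed(9)
  om <- stats::rexp(20, 1)
  d <- rbind(
    data.frame(gene = "small", site = 1:5, dssls = stats::rnorm(5),
               omega = stats::rexp(5), category = 0L),
    data.frame(gene = "flat", site = 1:20, dssls = stats::rnorm(20),
               omega = 1, category = 0L),
    data.frame(gene = "ok", site = 1:20, dssls = 0.5 * om + stats::rnorm(20),
               omega = om, category = 0L))
  fit <- fit_locus_regressions(d, min_sites = 10)
  expect_setequal(fit$loci$gene, "ok")
  expect_setequal(fit$skipped$reason, c("too_few_sites", "zero_omega_variance"))

  # slope invariant under dssls shift; scales inversely with omega scaling
  d2 <- d[d$gene == "ok", ]
  f0 <- fit_locus_regressions(d2, min_sites = 10)$loci$slope
  d2$dssls <- d2$dssls + 5
  expect_equal(fit_locus_regressions(d2, min_sites = 10)$loci$slope, f0,
               tolerance = 1e-10)
  d2$omega <- d2$omega * 3
  expect_equal(fit_locus_regressions(d2, min_sites = 10)$loci$slope, f0 / 3,
               tolerance = 1e-10)

  # cohort fractions sum to one within each category
  s <- fit$summary
  expect_equal(s$frac_positive + s$frac_negative + s$frac_ns,
               rep(1, nrow(s)), tolerance = 1e-12)
})
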