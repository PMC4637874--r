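# Locus-wise link between sitewise convergence support and sitewise
# selection pressure: per (gene, site) join of dSSLS, M8 posterior-mean
# omega (only from genes where M8 is favored) and the Clade Model C site
# category, then OLS regressions of dSSLS on omega within each
# (gene, category) stratum.

#' Join per-site convergence and selection metrics
#'
#' Inner join of the three per-site tables on (gene, site); sites missing
#' any metric are dropped and counted. Only genes where the M8 model was
#' favored contribute omega values, so genes absent from `m8_table` drop
#' out entirely.
#'
#' @param ssls_table Data frame: `gene`, `site`, `dssls`.
#' @param m8_table Data frame: `gene`, `site`, `omega`.
#' @param cmc_table Data frame: `gene`, `site`, `category` (0/1/2 or NA).
#' @return Data frame `gene`, `site`, `dssls`, `omega`, `category`, with
#'   attribute `dropped` (rows lost from `ssls_table`).
#' @export
join_site_metrics <- function(ssls_table, m8_table, cmc_table) {
  for (tb in list(ssls_table, m8_table, cmc_table)) {
    if (anyDuplicated(paste(tb$gene, tb$site)))
      stop("duplicate (gene, site) keys in input table")
  }
  j <- merge(ssls_table, m8_table, by = c("gene", "site"))
  j <- merge(j, cmc_table, by = c("gene", "site"))
  j <- j[order(j$gene, j$site), , drop = FALSE]
  rownames(j) <- NULL
  attr(j, "dropped") <- nrow(ssls_table) - nrow(j)
  j
}

#' Locus-wise regressions of convergence support on selection pressure
#'
#' Ordinary least squares `dssls ~ omega` within each (gene, category)
#' group, with a two-sided t-test on the slope. Groups below `min_sites`
#' sites or with zero variance in omega are skipped (flagged). The cohort
#' summary reports, per category, the fraction of loci with significantly
#' positive and negative slopes.
#'
#' @param join_table Output of [join_site_metrics()].
#' @param min_sites Minimum sites per (gene, category) group.
#' @param alpha Significance level for slope classification.
#' @return A `locus_regressions` object: `loci` (gene, category, slope,
#'   intercept, p, n_sites, classification), `summary` (per category:
#'   n_loci, n_positive, n_negative, n_ns, fractions), `skipped`.
#' @export
fit_locus_regressions <- function(join_table, min_sites = 10L, alpha = 0.05) {
  jt <- join_table[!is.na(join_table$category), , drop = FALSE]
  key <- interaction(jt$gene, jt$category, drop = TRUE)
  rows <- list()
  skipped <- list()
  for (grp in split(jt, key)) {
    gene <- grp$gene[1L]
    categ <- grp$category[1L]
    if (nrow(grp) < min_sites) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene = gene, category = categ, reason = "too_few_sites")
      next
    }
    if (stats::var(grp$omega) < 1e-12) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene = gene, category = categ, reason = "zero_omega_variance")
      next
    }
    fit <- stats::lm(dssls ~ omega, data = grp)
    sm <- summary(fit)$coefficients
    slope <- sm["omega", "Estimate"]
    p <- sm["omega", "Pr(>|t|)"]
    cls <- if (p <= alpha) { if (slope > 0) "positive" else "negative" } else "ns"
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, category = categ, slope = slope,
      intercept = stats::coef(fit)[[1L]], p = p, n_sites = nrow(grp),
      classification = cls)
  }
  loci <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), category = integer(0), slope = numeric(0),
               intercept = numeric(0), p = numeric(0), n_sites = integer(0),
               classification = character(0))
  rownames(loci) <- NULL
  summ <- do.call(rbind, lapply(split(loci, loci$category), function(d) {
    n <- nrow(d)
    npos <- sum(d$classification == "positive")
    nneg <- sum(d$classification == "negative")
    nsig <- npos + nneg
    data.frame(category = d$category[1L], n_loci = n,
               n_positive = npos, n_negative = nneg, n_ns = n - nsig,
               frac_positive = npos / n, frac_negative = nneg / n,
               frac_ns = (n - nsig) / n,
               frac_positive_of_significant = if (nsig) npos / nsig else NA_real_)
  }))
  rownames(summ) <- NULL
  structure(list(loci = loci, summary = summ,
                 skipped = if (length(skipped)) do.call(rbind, skipped) else
                   data.frame(gene = character(0), category = integer(0),
                              reason = character(0))),
            class = "locus_regressions")
}

#' @export
print.locus_regressions <- function(x, ...) {
  cat(sprintf("Locus-wise dSSLS ~ omega regressions: %d loci (%d skipped)\n",
              nrow(x$loci), nrow(x$skipped)))
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}
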