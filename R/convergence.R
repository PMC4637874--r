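# Likelihood convergence scan: sitewise log-likelihood support (SSLS) under
# the species tree H0 versus alternative topologies HA that force the focal
# lineages into a monophyletic clade; dSSLS = lnL(HA) - lnL(H0) per site,
# gene-level mean dSSLS, and significance from a simulation-based empirical
# null distribution.

#' Enumerate alternative convergence topologies
#'
#' Prunes the focal lineages from the species tree and regrafts them as a
#' single monophyletic clade: every internal resolution of the focal clade
#' is combined with every attachment point at which one of the lineages was
#' originally attached. Three focal lineages give 3 resolutions x 3
#' attachment branches = 9 alternative topologies; two give 2.
#' Regrafted branch lengths are starting values only (fresh stems of 0.1 and
#' internal focal branches of 0.05) and are re-optimized downstream.
#'
#' @param species_tree Rooted binary [ape::phylo] (the H0 topology).
#' @param focal_groups Named list of leaf-name vectors, one per focal
#'   lineage; each must be monophyletic in `species_tree`. A plain character
#'   vector is treated as one-leaf lineages.
#' @return A list of `convergence_hypothesis` objects: `id`, `h0`, `ha`,
#'   `focal` (all focal leaves).
#' @export
generate_alternative_topologies <- function(species_tree, focal_groups) {
  if (!is.list(focal_groups))
    focal_groups <- as.list(stats::setNames(focal_groups, focal_groups))
  if (is.null(names(focal_groups)))
    names(focal_groups) <- paste0("G", seq_along(focal_groups))
  ng <- length(focal_groups)
  if (ng < 2L) stop("need at least 2 focal lineages")
  all_focal <- unlist(focal_groups, use.names = FALSE)
  miss <- setdiff(all_focal, species_tree$tip.label)
  if (length(miss)) stop("focal taxa not in tree: ", paste(miss, collapse = ", "))
  if (anyDuplicated(all_focal)) stop("focal groups overlap")
  if (is_monophyletic(species_tree, all_focal))
    stop("focal taxa already monophyletic; H_A degenerate")
  for (nm in names(focal_groups)) {
    g <- focal_groups[[nm]]
    if (length(g) > 1L && !is_monophyletic(species_tree, g))
      stop("focal lineage '", nm, "' is not monophyletic in the species tree")
  }

  backbone <- ape::drop.tip(species_tree, all_focal)
  subtrees <- lapply(focal_groups, function(g) focal_subtree(species_tree, g))

  # attachment node in the backbone: the MRCA of the (non-focal) leaves of
  # the original sister subtree of each lineage
  attach_nodes <- vapply(names(focal_groups), function(nm) {
    g <- focal_groups[[nm]]
    mr <- mrca_node(species_tree, g)
    par <- species_tree$edge[species_tree$edge[, 2L] == mr, 1L]
    sib <- setdiff(species_tree$edge[species_tree$edge[, 1L] == par, 2L], mr)
    sib_leaves <- setdiff(clade_leaves(species_tree, sib), all_focal)
    if (!length(sib_leaves))
      stop("lineage '", nm, "' has no non-focal sister taxa to attach to")
    if (length(sib_leaves) == 1L) match(sib_leaves, backbone$tip.label)
    else mrca_node(backbone, sib_leaves)
  }, integer(1))

  resolutions <- focal_resolutions(names(focal_groups))
  hyps <- list()
  id <- 0L
  for (ri in seq_along(resolutions)) {
    clade <- build_focal_clade(resolutions[[ri]], subtrees)
    for (ai in seq_along(attach_nodes)) {
      id <- id + 1L
      ha <- regraft_clade(backbone, clade, attach_nodes[ai])
      ha <- validate_tree(ha)
      stopifnot(is_monophyletic(ha, all_focal))
      hyps[[id]] <- structure(
        list(id = sprintf("H%02d", id), h0 = species_tree, ha = ha,
             focal = all_focal,
             resolution = paste(resolutions[[ri]], collapse = "|"),
             attachment = names(attach_nodes)[ai]),
        class = "convergence_hypothesis")
    }
  }
  hyps
}

is_monophyletic <- function(tree, leaves) {
  if (length(leaves) == 1L) return(TRUE)
  mr <- mrca_node(tree, leaves)
  setequal(clade_leaves(tree, mr), leaves)
}

# Newick-less extraction of a focal lineage as a phylo (or leaf marker).
focal_subtree <- function(tree, leaves) {
  if (length(leaves) == 1L) return(leaves)
  ape::extract.clade(tree, mrca_node(tree, leaves))
}

# Nested resolutions of >= 2 groups; for 3 groups the 3 rooted shapes.
focal_resolutions <- function(nms) {
  if (length(nms) == 2L) return(list(nms))
  if (length(nms) == 3L)
    return(list(c(nms[1L], nms[2L], nms[3L]),
                c(nms[1L], nms[3L], nms[2L]),
                c(nms[2L], nms[3L], nms[1L])))
  stop("only 2 or 3 focal lineages are supported")
}

# Assemble ((A,B),C)-style focal clade with fresh internal branch lengths.
build_focal_clade <- function(order_nms, subtrees) {
  part <- function(x) {
    if (is.character(x)) paste0(x, ":0.05")
    else {
      tx <- ape::write.tree(x)
      paste0(sub(";$", "", tx), ":0.05")
    }
  }
  txt <- if (length(order_nms) == 2L)
    sprintf("(%s,%s);", part(subtrees[[order_nms[1L]]]),
            part(subtrees[[order_nms[2L]]]))
  else
    sprintf("((%s,%s):0.05,%s);", part(subtrees[[order_nms[1L]]]),
            part(subtrees[[order_nms[2L]]]), part(subtrees[[order_nms[3L]]]))
  ape::read.tree(text = txt)
}

# Attach the focal clade onto the branch above `node` with a 0.1 stem,
# splitting that branch at its midpoint. When the attachment point is the
# backbone root (the original sister clade spans the whole backbone), the
# clade joins a fresh root above the backbone instead.
regraft_clade <- function(backbone, clade, node) {
  e <- which(backbone$edge[, 2L] == node)
  if (!length(e)) {
    btxt <- sub(";$", "", ape::write.tree(backbone))
    ctxt <- sub(";$", "", ape::write.tree(clade))
    return(ape::read.tree(text = sprintf("(%s:0.05,%s:0.1);", btxt, ctxt)))
  }
  clade$root.edge <- 0.1
  ape::bind.tree(backbone, clade, where = node,
                 position = backbone$edge.length[e] / 2)
}

#' @export
print.convergence_hypothesis <- function(x, ...) {
  cat(sprintf("Convergence hypothesis %s: focal clade (%s), attached at %s\n",
              x$id, x$resolution, x$attachment))
  invisible(x)
}

#' Sitewise likelihood support for convergence (dSSLS)
#'
#' Re-optimizes branch lengths and Gamma shape independently under the
#' species topology H0 and the alternative topology HA, then returns
#' per-site dSSLS = lnL(HA) - lnL(H0). Genes fitting the convergence
#' topology better score positive.
#'
#' @param alignment Amino-acid `phylo_alignment`.
#' @param hypothesis A `convergence_hypothesis`.
#' @param model An `aa_model` (starting values for alpha).
#' @param h0_fit Optional precomputed `phylo_fit` of H0 for this alignment
#'   (reused across the hypothesis set).
#' @param ... Passed to [optimize_likelihood()].
#' @return A `delta_ssls` object: `per_site`, `mean` (over non-all-missing
#'   sites), `lnl_h0`, `lnl_ha`, `hypothesis_id`.
#' @export
compute_delta_ssls <- function(alignment, hypothesis, model,
                               h0_fit = NULL, ...) {
  stopifnot(inherits(hypothesis, "convergence_hypothesis"))
  if (is.null(h0_fit))
    h0_fit <- optimize_likelihood(hypothesis$h0, alignment, model, ...)
  ha_fit <- tryCatch(
    optimize_likelihood(hypothesis$ha, alignment, model, ...),
    error = function(e) stop("optimizer failure under hypothesis ",
                             hypothesis$id, ": ", conditionMessage(e)))
  per_site <- ha_fit$profile$site_lnl - h0_fit$profile$site_lnl
  informative <- colSums(!is.na(alignment$x)) > 0L
  structure(list(per_site = per_site,
                 mean = mean(per_site[informative]),
                 informative = informative,
                 lnl_h0 = h0_fit$logLik, lnl_ha = ha_fit$logLik,
                 hypothesis_id = hypothesis$id,
                 h0_fit = h0_fit),
            class = "delta_ssls")
}

#' @export
print.delta_ssls <- function(x, ...) {
  cat(sprintf("dSSLS (%s): mean = %.5f over %d sites (lnL H_A %.3f vs H_0 %.3f)\n",
              x$hypothesis_id, x$mean, length(x$per_site), x$lnl_ha, x$lnl_h0))
  invisible(x)
}

#' Scan one gene against a hypothesis set
#'
#' Fits H0 once, then every HA, returning per-hypothesis `delta_ssls` plus
#' the across-hypothesis mean profile.
#'
#' @inheritParams compute_delta_ssls
#' @param hypotheses List of `convergence_hypothesis`.
#' @return A `ssls_scan`: `by_hypothesis` (list of `delta_ssls`), `mean_site`
#'   (per-site dSSLS averaged over hypotheses), `mean_gene` (per-hypothesis
#'   gene means), `h0_fit`.
#' @export
delta_ssls_scan <- function(alignment, hypotheses, model, ...) {
  h0_fit <- optimize_likelihood(hypotheses[[1L]]$h0, alignment, model, ...)
  res <- lapply(hypotheses, function(h)
    compute_delta_ssls(alignment, h, model, h0_fit = h0_fit, ...))
  names(res) <- vapply(hypotheses, `[[`, character(1), "id")
  site_mat <- do.call(cbind, lapply(res, `[[`, "per_site"))
  structure(list(by_hypothesis = res,
                 mean_site = rowMeans(site_mat),
                 mean_gene = vapply(res, `[[`, numeric(1), "mean"),
                 h0_fit = h0_fit),
            class = "ssls_scan")
}

#' @export
print.ssls_scan <- function(x, ...) {
  cat(sprintf("dSSLS scan over %d hypotheses; gene means:\n",
              length(x$by_hypothesis)))
  print(round(x$mean_gene, 5))
  invisible(x)
}

#' Simulate the null distribution of mean dSSLS
#'
#' For each of `R` replicates and each template gene fit, simulates an
#' alignment of the template's length on its fitted H0 tree and model, then
#' records the simulated gene-mean dSSLS under every hypothesis. This is the
#' parametric null ("no convergence") against which observed means are
#' ranked.
#'
#' @param gene_fits List of `phylo_fit` objects fitted under H0 (the
#'   templates, carrying length and model heterogeneity of the data).
#' @param hypotheses List of `convergence_hypothesis`.
#' @param R Replicates per template (>= 2 total null values required).
#' @param seed Random seed (mandatory, for reproducibility).
#' @param site_level Also pool per-site dSSLS values into a site-level null.
#' @return A `null_distribution`: per-hypothesis sorted vectors of simulated
#'   gene-mean dSSLS (`values[[hyp]]`), replicate count `R_total`, and
#'   optionally `site_values`.
#' @export
simulate_null_distribution <- function(gene_fits, hypotheses, R, seed,
                                       site_level = FALSE) {
  if (!length(gene_fits)) stop("'gene_fits' is empty")
  if (R < 2L && length(gene_fits) * R < 2L) stop("need at least 2 null values")
  if (missing(seed)) stop("a random seed is required")
  set.seed(seed)
  ids <- vapply(hypotheses, `[[`, character(1), "id")
  vals <- stats::setNames(rep(list(numeric(0)), length(ids)), ids)
  site_vals <- stats::setNames(rep(list(numeric(0)), length(ids)), ids)
  for (r in seq_len(R)) {
    for (gf in gene_fits) {
      spec <- simulation_spec(gf$tree, gf$model, gf$n_sites,
                              seed = sample.int(2^31 - 1L, 1L))
      sim <- simulate_alignment(spec)
      scan <- delta_ssls_scan(sim$alignment, hypotheses, gf$model)
      for (id in ids) {
        vals[[id]] <- c(vals[[id]], scan$by_hypothesis[[id]]$mean)
        if (site_level)
          site_vals[[id]] <- c(site_vals[[id]],
                               scan$by_hypothesis[[id]]$per_site)
      }
    }
  }
  structure(list(values = lapply(vals, sort),
                 site_values = if (site_level) lapply(site_vals, sort),
                 R_total = R * length(gene_fits),
                 n_templates = length(gene_fits), R = R, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Null distribution: %d values per hypothesis (%d templates x %d replicates)\n",
              x$R_total, x$n_templates, x$R))
  invisible(x)
}

#' Empirical P from a simulated null
#'
#' The null cdf is the stepwise empirical cdf with plotting positions `i/R`
#' at the i-th order statistic and linear interpolation between order
#' statistics; `P = 1 - cdf(observed)`, clamped to the resolution floor
#' `1/(R+1)` so a value beyond all null samples is never reported as 0.
#'
#' @param observed Observed (gene-mean) dSSLS value(s).
#' @param null Sorted numeric vector of null values, or a
#'   `null_distribution` plus `hypothesis` id.
#' @param hypothesis Hypothesis id when `null` is a `null_distribution`.
#' @return P value(s) in `[1/(R+1), 1]`.
#' @export
empirical_p <- function(observed, null, hypothesis = NULL) {
  if (inherits(null, "null_distribution")) {
    if (is.null(hypothesis)) hypothesis <- names(null$values)[1L]
    null <- null$values[[hypothesis]]
  }
  if (!length(null)) stop("empty null distribution")
  x <- sort(null)
  R <- length(x)
  cdf <- stats::approx(x, seq_len(R) / R, xout = observed,
                       yleft = 0, yright = 1, ties = "max")$y
  pmin(1, pmax(1 - cdf, 1 / (R + 1)))
}

#' Call convergence genes from a scored table
#'
#' @param site_supports Data frame with columns `gene`, `hypothesis`,
#'   `mean_dssls`, `p`.
#' @param alpha Significance level.
#' @param aggregation `"any"` flags genes supported (positive mean dSSLS,
#'   `p <= alpha`) under at least one hypothesis; `"all"` requires support
#'   under every hypothesis; `"mean"` averages dSSLS and P across
#'   hypotheses.
#' @return Data frame: `gene`, `n_hyp`, `n_support`, `mean_dssls`, `min_p`,
#'   `call`.
#' @export
call_convergent_genes <- function(site_supports, alpha = 0.05,
                                  aggregation = c("any", "all", "mean")) {
  aggregation <- match.arg(aggregation)
  need <- c("gene", "hypothesis", "mean_dssls", "p")
  if (!all(need %in% names(site_supports)))
    stop("site_supports needs columns: ", paste(need, collapse = ", "))
  sp <- split(site_supports, site_supports$gene)
  rows <- lapply(sp, function(d) {
    support <- d$p <= alpha & d$mean_dssls > 0
    call <- switch(aggregation,
                   any = any(support),
                   all = all(support),
                   mean = mean(d$mean_dssls) > 0 && mean(d$p) <= alpha)
    data.frame(gene = d$gene[1L], n_hyp = nrow(d), n_support = sum(support),
               mean_dssls = mean(d$mean_dssls), min_p = min(d$p),
               call = call)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
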