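# Codon model fitting and likelihood-ratio tests: one-ratio and branch
# models (rapidly evolving genes), branch-site model A (lineage-specific
# positive selection), M7/M8 (sitewise omega) and Clade Model C vs M1a.
#
# Strategy: branch lengths are estimated once per gene under the one-ratio
# model (full smoothing sweeps); richer models then hold the relative branch
# lengths fixed and optimize their parameters together with a global tree
# scale. Nesting is preserved (every richer model contains the one-ratio
# configuration at scale 1), so LRTs remain valid and conservative.
# Every fit with a free positive-selection omega runs a small multi-start
# grid (0.8 / 1.0 / 1.5) and keeps the best likelihood.

codon_setup <- function(tree, alignment) {
  stopifnot(inherits(alignment, "phylo_alignment"))
  if (alignment$alphabet != "codon") stop("codon models need a codon alignment")
  tree <- prune_to_taxa(tree, alignment$taxa)
  tree$edge.length[tree$edge.length < BL_MIN] <- BL_MIN
  ti <- tree_index(tree)
  cp <- compress_patterns(alignment)
  list(ti = ti, cp = cp, lp = leaf_partials(ti, cp$pat), wt = cp$wt,
       freq = f3x4_frequencies(alignment), L = alignment$L,
       syn_var = has_synonymous_variation(alignment),
       cache = new.env(parent = emptyenv()))
}

# Any column with two codons encoding the same amino acid? Without any
# synonymous variation dS is unidentifiable and omega estimates meaningless.
has_synonymous_variation <- function(aln) {
  for (j in seq_len(aln$L)) {
    st <- unique(aln$x[, j])
    st <- st[!is.na(st)]
    if (length(st) > 1L && anyDuplicated(CODON61_AA[st])) return(TRUE)
  }
  FALSE
}

cs_lnl <- function(cs, site_classes, kappa, scale = 1, scale_fg = NULL,
                   fg_edges = integer(0), keep_parts = FALSE) {
  classes <- codon_classes(kappa, site_classes, cs$freq, nrow(cs$ti$edge),
                           fg_edges, cache = cs$cache)
  el <- cs$ti$el * scale
  if (!is.null(scale_fg) && length(fg_edges))
    el[fg_edges] <- cs$ti$el[fg_edges] * scale_fg
  pk <- peel_all(cs$ti, cs$lp, classes, el = el, wt = cs$wt)
  if (keep_parts) pk else pk$lnl
}

# ---- model definitions -----------------------------------------------------
# Each definition maps a named parameter vector to site classes (lists of
# w / omega_bg / omega_fg). Proportions use stick-breaking parameters so
# box constraints suffice.

codon_model_defs <- list(
  m0 = list(
    par = c(kappa = 2, omega = 0.4),
    lower = c(0.05, 1e-4), upper = c(50, 20),
    classes = function(p) list(list(w = 1, omega_bg = p[["omega"]],
                                    omega_fg = p[["omega"]]))),
  branch = list(
    par = c(kappa = 2, omega_bg = 0.2, omega_fg = 0.4),
    lower = c(0.05, 1e-4, 1e-4), upper = c(50, 20, 20),
    sel_par = "omega_fg",
    classes = function(p) list(list(w = 1, omega_bg = p[["omega_bg"]],
                                    omega_fg = p[["omega_fg"]]))),
  m1a = list(
    par = c(kappa = 2, p0 = 0.8, omega0 = 0.1),
    lower = c(0.05, 1e-3, 1e-4), upper = c(50, 1 - 1e-3, 1 - 1e-4),
    classes = function(p) list(
      list(w = p[["p0"]], omega_bg = p[["omega0"]], omega_fg = p[["omega0"]]),
      list(w = 1 - p[["p0"]], omega_bg = 1, omega_fg = 1))),
  bsA = list(
    par = c(kappa = 2, ptot = 0.9, f0 = 0.8, omega0 = 0.1, omega2 = 1.5),
    lower = c(0.05, 1e-3, 1e-3, 1e-4, 1), upper = c(50, 1 - 1e-3, 1 - 1e-3,
                                                    1 - 1e-4, 30),
    sel_par = "omega2",
    classes = function(p) {
      p0 <- p[["ptot"]] * p[["f0"]]; p1 <- p[["ptot"]] - p0
      p2a <- (1 - p[["ptot"]]) * p[["f0"]]
      p2b <- (1 - p[["ptot"]]) * (1 - p[["f0"]])
      list(list(w = p0, omega_bg = p[["omega0"]], omega_fg = p[["omega0"]]),
           list(w = p1, omega_bg = 1, omega_fg = 1),
           list(w = p2a, omega_bg = p[["omega0"]], omega_fg = p[["omega2"]]),
           list(w = p2b, omega_bg = 1, omega_fg = p[["omega2"]]))
    }),
  bsA_null = list(
    par = c(kappa = 2, ptot = 0.9, f0 = 0.8, omega0 = 0.1),
    lower = c(0.05, 1e-3, 1e-3, 1e-4), upper = c(50, 1 - 1e-3, 1 - 1e-3,
                                                 1 - 1e-4),
    classes = function(p) {
      p <- c(p, omega2 = 1)
      codon_model_defs$bsA$classes(p)
    }),
  m7 = list(
    par = c(kappa = 2, pshape = 0.5, qshape = 1.5),
    lower = c(0.05, 0.005, 0.005), upper = c(50, 99, 99),
    classes = function(p) {
      om <- beta_category_means(p[["pshape"]], p[["qshape"]], 10L)
      lapply(om, function(w) list(w = 0.1, omega_bg = w, omega_fg = w))
    }),
  m8 = list(
    par = c(kappa = 2, pshape = 0.5, qshape = 1.5, p0 = 0.9, omega_s = 1.5),
    lower = c(0.05, 0.005, 0.005, 1e-3, 1), upper = c(50, 99, 99, 1 - 1e-6, 30),
    sel_par = "omega_s",
    classes = function(p) {
      om <- beta_category_means(p[["pshape"]], p[["qshape"]], 10L)
      cls <- lapply(om, function(w)
        list(w = p[["p0"]] / 10, omega_bg = w, omega_fg = w))
      c(cls, list(list(w = 1 - p[["p0"]], omega_bg = p[["omega_s"]],
                       omega_fg = p[["omega_s"]])))
    }),
  cmc = list(
    par = c(kappa = 2, ptot = 0.8, f0 = 0.8, omega0 = 0.1,
            omega2_fg = 1.5, omega2_bg = 0.5),
    lower = c(0.05, 1e-3, 1e-3, 1e-4, 1e-4, 1e-4),
    upper = c(50, 1 - 1e-6, 1 - 1e-3, 1 - 1e-4, 30, 30),
    sel_par = "omega2_fg",
    classes = function(p) {
      p0 <- p[["ptot"]] * p[["f0"]]; p1 <- p[["ptot"]] - p0
      list(list(w = p0, omega_bg = p[["omega0"]], omega_fg = p[["omega0"]]),
           list(w = p1, omega_bg = 1, omega_fg = 1),
           list(w = 1 - p[["ptot"]], omega_bg = p[["omega2_bg"]],
                omega_fg = p[["omega2_fg"]]))
    })
)

# Optimize one model definition on fixed relative branch lengths plus a
# free global scale, with multi-start over the selection parameter.
fit_codon_variant <- function(cs, def_name, fg_edges = integer(0),
                              starts = c(0.8, 1.0, 1.5), start_par = NULL,
                              extra_starts = list(), start_scale = 1,
                              start_scale_fg = NULL, fixed = NULL,
                              control = list(rel.tol = 1e-9)) {
  def <- codon_model_defs[[def_name]]
  base <- def$par
  if (!is.null(start_par)) {
    start_par <- unlist(start_par)
    shared <- intersect(names(base), names(start_par))
    base[shared] <- pmin(pmax(start_par[shared], def$lower[match(shared, names(base))]),
                         def$upper[match(shared, names(base))])
  }
  fixed <- unlist(fixed)
  if (length(fixed)) base[names(fixed)] <- fixed
  free <- if (length(fixed)) setdiff(names(base), names(fixed)) else names(base)
  fidx <- match(free, names(base))
  start_list <- if (!is.null(def$sel_par)) {
    lapply(starts, function(s) {
      b <- base
      b[def$sel_par] <- max(def$lower[match(def$sel_par, names(base))],
                            min(def$upper[match(def$sel_par, names(base))], s))
      b
    })
  } else list(base)
  for (es in extra_starts) {
    b <- base
    es <- unlist(es)
    shared <- intersect(names(base), names(es))
    b[shared] <- pmin(pmax(es[shared], def$lower[match(shared, names(base))]),
                      def$upper[match(shared, names(base))])
    start_list <- c(start_list, list(b))
  }

  npar <- length(free)
  nscale <- if (length(fg_edges)) 2L else 1L  # bg scale (+ fg scale)
  obj <- function(th) {
    p <- base
    p[fidx] <- th[seq_len(npar)]
    -cs_lnl(cs, def$classes(p), p[["kappa"]], scale = exp(th[[npar + 1L]]),
            scale_fg = if (nscale == 2L) exp(th[[npar + 2L]]),
            fg_edges = fg_edges)
  }
  lower <- c(def$lower[fidx], rep(log(0.02), nscale))
  upper <- c(def$upper[fidx], rep(log(50), nscale))
  sfg <- if (is.null(start_scale_fg)) start_scale else start_scale_fg
  # coarse pass over all starts, then one refinement from the best
  best <- NULL
  trace <- numeric(0)
  coarse <- if (length(start_list) > 1L)
    list(rel.tol = 1e-5, iter.max = 60L, eval.max = 200L) else control
  for (sp in start_list) {
    th0 <- c(unname(sp[fidx]), log(start_scale), if (nscale == 2L) log(sfg))
    o <- stats::nlminb(th0, obj, lower = lower, upper = upper,
                       control = coarse)
    trace <- c(trace, -o$objective)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (length(start_list) > 1L) {
    o <- stats::nlminb(best$par, obj, lower = lower, upper = upper,
                       control = control)
    if (o$objective <= best$objective) best <- o
  }
  par <- base
  par[fidx] <- best$par[seq_len(npar)]
  scale <- exp(best$par[[npar + 1L]])
  scale_fg <- if (nscale == 2L) exp(best$par[[npar + 2L]])
  pk <- cs_lnl(cs, def$classes(par), par[["kappa"]], scale = scale,
               scale_fg = scale_fg, fg_edges = fg_edges, keep_parts = TRUE)
  np <- npar + nscale + nrow(cs$ti$edge)  # free params + scale(s) + branches
  structure(list(model = def_name, logLik = pk$lnl, params = as.list(par),
                 scale = scale, scale_fg = scale_fg, np = np,
                 site_class_post = site_class_posteriors(pk, cs),
                 classes = def$classes(par),
                 multi_start_lnl = trace, fg_edges = fg_edges),
            class = "codon_fit")
}

# NEB site-class posteriors (classes x sites), expanded to alignment columns.
site_class_posteriors <- function(pk, cs) {
  m <- do.call(rbind, lapply(pk$class_site_ll, function(v)
    exp(v - pk$site_lnl)))
  m[, cs$cp$index, drop = FALSE]
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$logLik, df = object$np, class = "logLik")
}

#' @export
coef.codon_fit <- function(object, ...) unlist(object$params)

#' @export
print.codon_fit <- function(x, ...) {
  cat(sprintf("Codon model %s: lnL = %.4f\n", x$model, x$logLik))
  cat("  ", paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)),
                  collapse = ", "), "\n")
  invisible(x)
}

#' One-ratio (M0) codon model fit
#'
#' Estimates branch lengths, kappa and a single omega by alternating
#' depth-first branch smoothing with bounded quasi-Newton updates of
#' (kappa, omega).
#'
#' @param tree Rooted binary starting tree.
#' @param alignment Codon `phylo_alignment`.
#' @param kappa,omega Starting values.
#' @param tol Convergence tolerance on lnL between rounds.
#' @param max_rounds Cap on alternation rounds.
#' @return A `codon_fit` with additional elements `tree` (fitted branch
#'   lengths) and `setup` (reusable internals for richer models).
#' @export
fit_codon_m0 <- function(tree, alignment, kappa = 2, omega = 0.4,
                         tol = 1e-4, max_rounds = 10L) {
  cs <- codon_setup(tree, alignment)
  par <- c(kappa = kappa, omega = omega)
  def <- codon_model_defs$m0
  lnl_par <- function(p, el) {
    classes <- codon_classes(p[["kappa"]], def$classes(p), cs$freq,
                             nrow(cs$ti$edge), cache = cs$cache)
    peel_all(cs$ti, cs$lp, classes, el = el, wt = cs$wt)$lnl
  }
  el <- cs$ti$el
  cur <- lnl_par(par, el)
  btol <- 2e-2
  for (round in seq_len(max_rounds)) {
    prev <- cur
    classes <- codon_classes(par[["kappa"]], def$classes(par), cs$freq,
                             nrow(cs$ti$edge), cache = cs$cache)
    ti2 <- cs$ti; ti2$el <- el
    el <- smooth_branches(ti2, cs$lp, classes, el, cs$wt, tol = btol)
    o <- stats::nlminb(unname(par), function(th) {
      p <- th; names(p) <- names(par)
      -lnl_par(p, el)
    }, lower = def$lower, upper = def$upper,
    control = list(rel.tol = 1e-9))
    par[] <- o$par
    cur <- -o$objective
    if (cur - prev < tol && btol <= 1e-3) break
    if (cur - prev < 1) btol <- max(btol / 10, 1e-3)
  }
  cs$ti$el <- el
  fitted_tree <- cs$ti$tree
  fitted_tree$edge.length <- el
  pk <- cs_lnl(cs, def$classes(par), par[["kappa"]], keep_parts = TRUE)
  structure(list(model = "m0", logLik = pk$lnl, params = as.list(par),
                 scale = 1, np = 2L + nrow(cs$ti$edge),
                 tree = fitted_tree, setup = cs,
                 site_class_post = site_class_posteriors(pk, cs),
                 classes = def$classes(par)),
            class = "codon_fit")
}

#' Likelihood-ratio test between nested fits
#'
#' @param lnl0,lnl1 Null and alternative maximized log-likelihoods
#'   (`lnl1 >= lnl0 - 1e-6`; small negative differences are clamped to 0).
#' @param df Degrees of freedom (> 0).
#' @return An `lrt_result`: `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(lnl0, lnl1, df) {
  if (df <= 0) stop("'df' must be positive")
  if (lnl1 < lnl0 - 1e-3)
    stop("nesting violated (alternative lnL below null); re-optimize")
  stat <- max(0, 2 * (lnl1 - lnl0))
  structure(list(statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 lnl0 = lnl0, lnl1 = lnl1),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: 2dlnL = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Branch model scan for rapidly evolving genes
#'
#' Fits the one-ratio null and a two-ratio model with a foreground omega on
#' the flagged (e.g. marine) lineages. A gene is called rapidly evolving
#' when the foreground-background difference is positive and the df = 1 LRT
#' is significant.
#'
#' @param tree Rooted species tree.
#' @param alignment Codon `phylo_alignment`.
#' @param foreground List of leaf-name vectors: the foreground lineages
#'   (clade edges, stems included).
#' @param alpha Significance level for the rapid call.
#' @param starts Multi-start grid for the foreground omega.
#' @param m0 Optional precomputed [fit_codon_m0()] result.
#' @param include_stem Flag foreground clade stems too (default TRUE).
#' @return A `branch_model_fit`: `null`, `alt` (`codon_fit`s), `lrt`,
#'   `omega_fg`, `omega_bg`, `delta_omega`, `rapid`, `flags`.
#' @export
fit_branch_model <- function(tree, alignment, foreground, alpha = 0.05,
                             starts = c(0.8, 1.0, 1.5), m0 = NULL,
                             include_stem = TRUE) {
  if (is.null(m0)) m0 <- fit_codon_m0(tree, alignment)
  cs <- m0$setup
  fg <- foreground_edges(cs$ti$tree, foreground, include_stem = include_stem)
  if (!length(fg)) stop("no foreground branches flagged")
  start_par <- c(kappa = m0$params$kappa, omega_bg = m0$params$omega)
  alt <- fit_codon_variant(cs, "branch", fg_edges = fg, starts = starts,
                           start_par = start_par)
  lrt <- likelihood_ratio_test(m0$logLik, alt$logLik, df = 1L)
  d_omega <- alt$params$omega_fg - alt$params$omega_bg
  flags <- character(0)
  rapid <- d_omega > 0 && lrt$p <= alpha
  if (!cs$syn_var) {
    flags <- c(flags, "no_synonymous_variation")
    rapid <- NA
  }
  structure(list(null = m0, alt = alt, lrt = lrt,
                 omega_fg = alt$params$omega_fg,
                 omega_bg = alt$params$omega_bg,
                 delta_omega = d_omega, rapid = rapid, flags = flags),
            class = "branch_model_fit")
}

#' @export
print.branch_model_fit <- function(x, ...) {
  cat(sprintf("Branch model: omega_fg = %.4f, omega_bg = %.4f (d = %+.4f)\n",
              x$omega_fg, x$omega_bg, x$delta_omega))
  print(x$lrt)
  cat(sprintf("  rapidly evolving: %s%s\n", x$rapid,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Branch-site model A scan for lineage-specific positive selection
#'
#' Model A allows a class of sites with omega >= 1 on one foreground
#' lineage; the null fixes that omega at 1. The LRT statistic is compared
#' to a chi-square with 1 df (conservative; `mixture = TRUE` uses the
#' 50:50 mixture of 0 and chi-square 1).
#'
#' @inheritParams fit_branch_model
#' @param foreground A single lineage (leaf-name vector).
#' @param mixture Use the 50:50 mixture null for the LRT p-value.
#' @return A `branch_site_fit`: `null`, `alt`, `lrt`, `psg` (p <= alpha),
#'   `site_posterior` (posterior probability of the selected classes per
#'   site), `flags`.
#' @export
fit_branch_site_model <- function(tree, alignment, foreground, alpha = 0.05,
                                  starts = c(1, 1.5, 3), m0 = NULL,
                                  mixture = FALSE, include_stem = TRUE) {
  if (is.list(foreground) && length(foreground) != 1L)
    stop("branch-site model takes exactly one foreground lineage per run")
  if (!is.list(foreground)) foreground <- list(foreground)
  if (is.null(m0)) m0 <- fit_codon_m0(tree, alignment)
  cs <- m0$setup
  fg <- foreground_edges(cs$ti$tree, foreground, include_stem = include_stem)
  start_par <- c(kappa = m0$params$kappa,
                 omega0 = min(0.9, m0$params$omega))
  kfix <- c(kappa = m0$params$kappa)
  null <- fit_codon_variant(cs, "bsA_null", fg_edges = fg,
                            start_par = start_par, fixed = kfix)
  alt <- fit_codon_variant(cs, "bsA", fg_edges = fg, starts = starts,
                           start_par = c(unlist(null$params), omega2 = 1),
                           start_scale = null$scale,
                           start_scale_fg = null$scale_fg, fixed = kfix)
  lrt <- likelihood_ratio_test(null$logLik, alt$logLik, df = 1L)
  if (mixture) lrt$p <- lrt$p / 2
  flags <- if (!cs$syn_var) "no_synonymous_variation" else character(0)
  psg <- if (length(flags)) NA else lrt$p <= alpha
  sel_post <- colSums(alt$site_class_post[3:4, , drop = FALSE])
  structure(list(null = null, alt = alt, lrt = lrt, psg = psg,
                 omega2 = alt$params$omega2, site_posterior = sel_post,
                 flags = flags),
            class = "branch_site_fit")
}

#' @export
print.branch_site_fit <- function(x, ...) {
  cat(sprintf("Branch-site model A: omega2 = %.4f\n", x$omega2))
  print(x$lrt)
  cat(sprintf("  positively selected gene: %s\n", x$psg))
  invisible(x)
}

#' M7 vs M8 sitewise selection scan
#'
#' M7 draws omega from a Beta(p, q) discretized into 10 equal-probability
#' categories; M8 adds a proportion of sites at omega >= 1. Sitewise omega
#' (the NEB posterior mean over classes under M8) is emitted only when the
#' df = 2 LRT favors M8 at `alpha`.
#'
#' @inheritParams fit_branch_model
#' @return An `m7m8_fit`: `m7`, `m8`, `lrt`, `favored`, `site_omega`
#'   (posterior-mean omega per site, or NULL), `flags`.
#' @export
fit_sites_m7_m8 <- function(tree, alignment, alpha = 0.05,
                            starts = c(1, 1.5, 3), m0 = NULL) {
  if (nrow(alignment$x) < 6L)
    warning("fewer than 6 taxa: sitewise selection estimates are weak")
  if (is.null(m0)) m0 <- fit_codon_m0(tree, alignment)
  cs <- m0$setup
  flags <- character(0)
  if (all_identical_sequences(alignment)) {
    return(structure(list(m7 = NULL, m8 = NULL, lrt = NULL, favored = FALSE,
                          site_omega = NULL, flags = "unidentifiable"),
                     class = "m7m8_fit"))
  }
  kfix <- c(kappa = m0$params$kappa)
  m7 <- fit_codon_variant(cs, "m7", fixed = kfix)
  m8 <- fit_codon_variant(cs, "m8", starts = starts,
                          start_par = c(pshape = m7$params$pshape,
                                        qshape = m7$params$qshape),
                          extra_starts = list(c(p0 = 1 - 1e-6, omega_s = 1)),
                          start_scale = m7$scale, fixed = kfix)
  lrt <- likelihood_ratio_test(m7$logLik, m8$logLik, df = 2L)
  bhit <- any(abs(unlist(m8$params[c("pshape", "qshape")]) -
                    c(0.005, 0.005)) < 1e-9) ||
    any(abs(unlist(m8$params[c("pshape", "qshape")]) - 99) < 1e-6)
  if (bhit) flags <- c(flags, "beta_shape_bound")
  favored <- lrt$p <= alpha
  site_omega <- NULL
  if (favored) {
    om <- vapply(m8$classes, `[[`, numeric(1), "omega_bg")
    site_omega <- as.numeric(om %*% m8$site_class_post)
  }
  structure(list(m7 = m7, m8 = m8, lrt = lrt, favored = favored,
                 site_omega = site_omega, flags = flags),
            class = "m7m8_fit")
}

all_identical_sequences <- function(aln) {
  for (j in seq_len(aln$L)) {
    st <- unique(aln$x[, j])
    st <- st[!is.na(st)]
    if (length(st) > 1L) return(FALSE)
  }
  TRUE
}

#' @export
print.m7m8_fit <- function(x, ...) {
  if (is.null(x$lrt)) { cat("M7/M8: unidentifiable (no variation)\n"); return(invisible(x)) }
  cat(sprintf("M7 lnL = %.4f; M8 lnL = %.4f\n", x$m7$logLik, x$m8$logLik))
  print(x$lrt)
  cat(sprintf("  M8 favored: %s\n", x$favored))
  invisible(x)
}

#' Clade Model C vs M1a
#'
#' Three site classes: purifying (0 < omega0 < 1), neutral (omega = 1), and
#' a divergent class whose omega differs between the focal (e.g. marine)
#' and background partitions. Sites are assigned to the class with
#' posterior probability > 0.5, otherwise unassigned.
#'
#' @inheritParams fit_branch_model
#' @return A `clade_model_fit`: `null` (M1a), `alt` (CmC), `lrt` (df = 3),
#'   `site_category` (0/1/2 per site, NA when unassigned), `omega2_fg`,
#'   `omega2_bg`, `flags`.
#' @export
fit_clade_model_c <- function(tree, alignment, foreground, alpha = 0.05,
                              starts = c(0.8, 1.0, 1.5), m0 = NULL,
                              include_stem = TRUE) {
  if (is.null(m0)) m0 <- fit_codon_m0(tree, alignment)
  cs <- m0$setup
  fg <- foreground_edges(cs$ti$tree, foreground, include_stem = include_stem)
  kfix <- c(kappa = m0$params$kappa)
  null <- fit_codon_variant(cs, "m1a", fixed = kfix)
  alt <- fit_codon_variant(cs, "cmc", fg_edges = fg, starts = starts,
                           start_par = c(omega0 = min(0.9, null$params$omega0)),
                           fixed = kfix,
                           extra_starts = list(c(
                             ptot = 1 - 1e-6, f0 = null$params$p0,
                             omega2_fg = 1, omega2_bg = 1)),
                           start_scale = null$scale)
  lrt <- likelihood_ratio_test(null$logLik, alt$logLik, df = 3L)
  post <- alt$site_class_post
  cat_idx <- max.col(t(post), ties.method = "first") - 1L
  assigned <- post[cbind(cat_idx + 1L, seq_len(ncol(post)))] > 0.5
  cat_idx[!assigned] <- NA_integer_
  flags <- if (!cs$syn_var) "no_synonymous_variation" else character(0)
  structure(list(null = null, alt = alt, lrt = lrt,
                 site_category = cat_idx,
                 site_posterior = post,
                 omega2_fg = alt$params$omega2_fg,
                 omega2_bg = alt$params$omega2_bg,
                 significant = lrt$p <= alpha, flags = flags),
            class = "clade_model_fit")
}

#' @export
print.clade_model_fit <- function(x, ...) {
  cat(sprintf("Clade Model C: omega2_fg = %.4f, omega2_bg = %.4f\n",
              x$omega2_fg, x$omega2_bg))
  print(x$lrt)
  tb <- table(factor(x$site_category, levels = 0:2), useNA = "ifany")
  cat("  site categories:", paste(sprintf("%s=%d", names(tb), tb),
                                  collapse = " "), "\n")
  invisible(x)
}
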