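# Maximum-likelihood fitting: branch lengths by one-dimensional smoothing
# sweeps on each edge (Brent on the edge's flanking partials, so partials
# stay fresh along a depth-first traversal), alternated with Brent updates
# of the Gamma shape, until the log-likelihood improvement between sweeps
# falls below tolerance.

BL_MIN <- 1e-6
BL_MAX <- 20
ALPHA_MIN <- 0.02
ALPHA_MAX <- 100

# Brent on log-scale; returns argmax and objective. Boundary candidates are
# only probed when the interior optimum sits near an end of the interval.
brent_max <- function(f, lower, upper, tol = 1e-3) {
  g <- function(x) f(exp(x))
  lo <- log(lower); hi <- log(upper)
  o <- stats::optimize(g, c(lo, hi), maximum = TRUE, tol = tol)
  best_x <- exp(o$maximum); best_v <- o$objective
  if (o$maximum - lo < 4 * tol) {
    vl <- f(lower)
    if (vl >= best_v) { best_x <- lower; best_v <- vl }
  } else if (hi - o$maximum < 4 * tol) {
    vu <- f(upper)
    if (vu >= best_v) { best_x <- upper; best_v <- vu }
  }
  list(x = best_x, value = best_v)
}

# Safeguarded Newton on one branch length: ascent steps with halving,
# clamped to [BL_MIN, BL_MAX]; falls back to Brent when curvature is
# unusable. Guaranteed not to decrease the objective.
edge_optimum <- function(fgh, t0, tol = 1e-3, max_iter = 10L) {
  t <- max(BL_MIN, min(BL_MAX, t0))
  cur <- fgh(t)
  for (it in seq_len(max_iter)) {
    if (!is.finite(cur$h) || cur$h >= 0) {
      o <- brent_max(function(x) fgh(x, deriv = FALSE)$f, BL_MIN, BL_MAX,
                     tol = tol)
      if (o$value >= cur$f) return(o$x) else return(t)
    }
    step <- -cur$g / cur$h
    if (abs(step) < 1e-9) break
    repeat {
      t_new <- max(BL_MIN, min(BL_MAX, t + step))
      nxt <- fgh(t_new)
      if (nxt$f >= cur$f - 1e-12) break
      step <- step / 4
      if (abs(step) < 1e-9) { t_new <- t; nxt <- cur; break }
    }
    done <- abs(t_new - t) < 1e-8 ||
      (t_new == BL_MIN && nxt$g < 0) || (t_new == BL_MAX && nxt$g > 0)
    t <- t_new; cur <- nxt
    if (done) break
  }
  t
}

# One depth-first smoothing pass over all edges; mutates el in place and
# returns it. classes/el describe the process; lp are leaf partials and wt
# the site-pattern weights.
smooth_branches <- function(ti, lp, classes, el, wt, tol = 1e-3) {
  ncls <- length(classes)
  S <- nrow(lp[[1L]]); L <- ncol(lp[[1L]])
  peels <- lapply(classes, function(cl) peel_class(ti, lp, cl, el))
  D <- lapply(peels, `[[`, "D")
  lsD <- lapply(peels, `[[`, "lsD")

  refresh <- function(v) {
    for (ci in seq_len(ncls)) {
      cl <- classes[[ci]]
      acc <- NULL
      ls <- numeric(L)
      for (ch in ti$children[[v]]) {
        e <- ti$einc[ch]
        contrib <- edge_prob(cl, e, el[e]) %*% D[[ci]][[ch]]
        acc <- if (is.null(acc)) contrib else acc * contrib
        ls <- ls + lsD[[ci]][, ch]
      }
      r <- rescale_cols(acc, S)
      D[[ci]][[v]] <<- r$m
      lsD[[ci]][, v] <<- ls + r$ls
    }
  }

  rec <- function(p, Up, lsUp) {
    kids <- ti$children[[p]]
    for (j in seq_along(kids)) {
      ch <- kids[j]
      e <- ti$einc[ch]
      W <- vector("list", ncls); lsW <- vector("list", ncls)
      for (ci in seq_len(ncls)) {
        cl <- classes[[ci]]
        w <- Up[[ci]]; ls <- lsUp[[ci]]
        for (j2 in seq_along(kids)) if (j2 != j) {
          sib <- kids[j2]
          es <- ti$einc[sib]
          w <- w * (edge_prob(cl, es, el[es]) %*% D[[ci]][[sib]])
          ls <- ls + lsD[[ci]][, sib]
        }
        r <- rescale_cols(w, S)
        W[[ci]] <- r$m; lsW[[ci]] <- ls + r$ls
      }
      # log-constant per class (site scalers), normalized per site
      gc <- lapply(seq_len(ncls), function(ci)
        log(classes[[ci]]$w) + lsW[[ci]] + lsD[[ci]][, ch])
      M <- Reduce(pmax, gc)
      A <- lapply(gc, function(g) exp(g - M))
      fgh <- function(t, deriv = TRUE) {
        Sv <- 0; Gv <- 0; Hv <- 0
        for (ci in seq_len(ncls)) {
          cl <- classes[[ci]]
          eg <- cl$eigs[[cl$emap[e]]]
          E <- exp(eg$lambda * (t * cl$rate))
          PD <- (eg$V1 %*% (E * eg$V2)) %*% D[[ci]][[ch]]
          v <- colSums(W[[ci]] * PD)
          v[v < 1e-300] <- 1e-300
          Sv <- Sv + A[[ci]] * v
          if (deriv) {
            lE <- eg$lambda * cl$rate * E
            PD1 <- (eg$V1 %*% (lE * eg$V2)) %*% D[[ci]][[ch]]
            Gv <- Gv + A[[ci]] * colSums(W[[ci]] * PD1)
            PD2 <- (eg$V1 %*% ((eg$lambda * cl$rate * lE) * eg$V2)) %*%
              D[[ci]][[ch]]
            Hv <- Hv + A[[ci]] * colSums(W[[ci]] * PD2)
          }
        }
        f <- sum(wt * (log(Sv) + M))
        if (!is.finite(f)) stop("non-finite likelihood at branch length ", t)
        if (!deriv) return(list(f = f))
        r1 <- Gv / Sv
        list(f = f, g = sum(wt * r1), h = sum(wt * (Hv / Sv - r1 * r1)))
      }
      el[e] <<- edge_optimum(fgh, el[e], tol = tol)
      for (ci in seq_len(ncls)) {
        cl <- classes[[ci]]
        P <- edge_prob(cl, e, el[e])
        r <- rescale_cols(crossprod(P, W[[ci]]), S)
        Up_ch <- r$m; ls_ch <- lsW[[ci]] + r$ls
        if (ci == 1L) { Uc <- vector("list", ncls); lsUc <- vector("list", ncls) }
        Uc[[ci]] <- Up_ch; lsUc[[ci]] <- ls_ch
      }
      if (ch > ti$ntip) {
        rec(ch, Uc, lsUc)
        refresh(ch)
      }
    }
    refresh(p)
  }

  Uroot <- lapply(classes, function(cl) matrix(cl$freq, S, L))
  lsUroot <- lapply(classes, function(cl) numeric(L))
  rec(ti$root, Uroot, lsUroot)
  el
}

#' Fit branch lengths and Gamma shape by maximum likelihood
#'
#' Coordinate-wise bounded optimization: depth-first Brent sweeps over branch
#' lengths (each edge optimized against its flanking partial vectors),
#' alternating with Brent updates of the Gamma shape `alpha`, repeated until
#' the log-likelihood improves by less than `tol` between sweeps. The
#' log-likelihood is non-decreasing across sweeps by construction.
#'
#' @param tree Rooted binary starting tree ([ape::phylo]); branch lengths are
#'   the starting values.
#' @param alignment A `phylo_alignment` (amino acids).
#' @param model An `aa_model`; its `alpha` is the starting value.
#' @param free Character vector among `"branch_lengths"`, `"alpha"`.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_sweeps Cap on optimization sweeps.
#' @return An object of class `phylo_fit` with elements `tree` (fitted
#'   branch lengths), `model` (fitted alpha), `profile`
#'   (`site_lik_profile`), `logLik`, and `iterations`.
#' @examples
#' \donttest{
#' tr <- read_tree("((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);")
#' sim <- simulate_alignment(simulation_spec(tr, aa_model("WAG"), 200, seed = 1))
#' fit <- optimize_likelihood(tr, sim$alignment, aa_model("WAG", alpha = 0.8))
#' }
#' @export
optimize_likelihood <- function(tree, alignment, model,
                                free = c("branch_lengths", "alpha"),
                                tol = 1e-6, max_sweeps = 25L) {
  stopifnot(inherits(alignment, "phylo_alignment"))
  if (nrow(alignment$x) < 2L) stop("need at least 2 taxa")
  if (all(is.na(alignment$x))) stop("alignment has no non-missing column")
  free <- match.arg(free, several.ok = TRUE)
  tree <- prune_to_taxa(tree, alignment$taxa)
  tree$edge.length[tree$edge.length < BL_MIN] <- BL_MIN
  ti <- tree_index(tree)
  cp <- compress_patterns(alignment)
  lp <- leaf_partials(ti, cp$pat)
  wt <- cp$wt
  el <- ti$el
  alpha <- model$alpha
  lnl_of <- function(el, alpha) {
    m <- set_alpha(model, alpha)
    peel_all(ti, lp, aa_classes(m, nrow(ti$edge)), el, wt = wt)$lnl
  }
  cur <- lnl_of(el, alpha)
  if (!is.finite(cur))
    stop(sprintf("non-finite likelihood at start (alpha = %g)", alpha))
  iter <- 0L
  btol <- 2e-2  # coarse first, refined as the sweep improvement shrinks
  repeat {
    iter <- iter + 1L
    prev <- cur
    if ("branch_lengths" %in% free) {
      m <- set_alpha(model, alpha)
      el <- smooth_branches(ti, lp, aa_classes(m, nrow(ti$edge)), el, wt,
                            tol = btol)
    }
    if ("alpha" %in% free && model$k > 1L) {
      cand <- brent_max(function(a) lnl_of(el, a), ALPHA_MIN, ALPHA_MAX,
                        tol = if (btol > 1e-3) 5e-2 else 5e-3)
      # keep the current shape unless the Brent candidate improves on it
      if (cand$value >= lnl_of(el, alpha)) alpha <- cand$x
    }
    cur <- lnl_of(el, alpha)
    if (cur < prev - 1e-8)
      stop("log-likelihood decreased during optimization; parameter snapshot: ",
           sprintf("alpha = %g, lnL %g -> %g", alpha, prev, cur))
    done <- cur - prev < tol && btol <= 1e-3
    if (done || iter >= max_sweeps) break
    if (cur - prev < 0.1) btol <- max(btol / 10, 1e-3)
  }
  fitted_tree <- ti$tree
  fitted_tree$edge.length <- el
  fitted_model <- set_alpha(model, alpha)
  pk <- peel_all(ti, lp, aa_classes(fitted_model, nrow(ti$edge)), el, wt = wt)
  structure(list(tree = fitted_tree, model = fitted_model,
                 profile = new_site_lik_profile(pk$site_lnl[cp$index],
                                                fitted_model),
                 logLik = pk$lnl, iterations = iter,
                 n_sites = alignment$L, n_taxa = nrow(alignment$x)),
            class = "phylo_fit")
}

#' @export
logLik.phylo_fit <- function(object, ...) {
  p <- nrow(object$tree$edge) + if (object$model$k > 1L) 1L else 0L
  structure(object$logLik, df = p, nobs = object$n_sites, class = "logLik")
}

#' @export
coef.phylo_fit <- function(object, ...) {
  c(alpha = object$model$alpha,
    tree_length = sum(object$tree$edge.length))
}

#' @export
print.phylo_fit <- function(x, ...) {
  cat(sprintf("ML fit: %s + Gamma(k = %d) on %d taxa, %d sites\n",
              x$model$name, x$model$k, x$n_taxa, x$n_sites))
  cat(sprintf("  lnL = %.4f  alpha = %.4f  tree length = %.4f  (%d sweeps)\n",
              x$logLik, x$model$alpha, sum(x$tree$edge.length), x$iterations))
  invisible(x)
}

#' Select an amino-acid model by AIC
#'
#' Fits each candidate model (branch lengths and alpha free) and returns the
#' one minimizing `AIC = 2p - 2 lnL`, with the AIC differences of all
#' candidates reported.
#'
#' @param alignment A `phylo_alignment`.
#' @param tree Starting tree.
#' @param candidates Character vector of model names (see [aa_model()]).
#' @param k Gamma categories for every candidate.
#' @return List with `best` (model name), `fit` (its `phylo_fit`), and
#'   `table` (data frame: model, lnL, params, AIC, dAIC).
#' @export
select_model <- function(alignment, tree, candidates = c("JTT", "WAG"),
                         k = 4L) {
  if (length(candidates) < 2L) stop("need at least 2 candidate models")
  fits <- lapply(candidates, function(nm)
    optimize_likelihood(tree, alignment, aa_model(nm, alpha = 1, k = k)))
  ll <- vapply(fits, `[[`, numeric(1), "logLik")
  p <- vapply(fits, function(f) attr(logLik(f), "df"), numeric(1))
  aic <- 2 * p - 2 * ll
  tab <- data.frame(model = candidates, lnL = ll, params = p, AIC = aic,
                    dAIC = aic - min(aic))
  best <- which.min(aic)
  list(best = candidates[best], fit = fits[[best]], table = tab)
}
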