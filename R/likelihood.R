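# Felsenstein pruning engine shared by the amino-acid and codon stages.
#
# A fitted substitution process is represented as a list of mixture classes;
# each class carries a weight `w`, a rate multiplier `rate`, root frequencies
# `freq`, a list of eigendecompositions `eigs` and an integer map `emap`
# giving, for every edge of the postorder edge matrix, which decomposition
# applies on that edge. Homogeneous models use a single decomposition on all
# edges; branch/branch-site/clade models switch matrices on flagged edges.
#
# Conditional (down) partials are S x L x nodes arrays per class, rescaled
# per column with cumulative log-scalers tracked per node, so likelihoods of
# long alignments never underflow.

# Mixture classes for an aa_model: k discrete-Gamma categories.
aa_classes <- function(model, nedges) {
  lapply(seq_len(model$k), function(i)
    list(w = 1 / model$k, rate = model$rates[i], freq = model$freq,
         eigs = list(model$eig), emap = rep(1L, nedges)))
}

# 0/1 leaf partials; missing observations are all-ones (marginalized out).
leaf_partials <- function(ti, aln) {
  S <- length(aln$states)
  L <- aln$L
  idx <- match(ti$tip.label, aln$taxa)
  if (anyNA(idx))
    stop("taxa missing from alignment: ",
         paste(ti$tip.label[is.na(idx)], collapse = ", "))
  lp <- vector("list", ti$ntip)
  for (i in seq_len(ti$ntip)) {
    m <- matrix(0, S, L)
    st <- aln$x[idx[i], ]
    obs <- !is.na(st)
    m[cbind(st[obs], which(obs))] <- 1
    m[, !obs] <- 1
    lp[[i]] <- m
  }
  lp
}

edge_prob <- function(cl, e, t) prob_matrix(cl$eigs[[cl$emap[e]]], t * cl$rate)

# Column-wise rescaling; returns the rescaled matrix and log-scalers.
rescale_cols <- function(m, S) {
  s <- colSums(m)
  s[s <= 0] <- 1e-300
  list(m = m * rep.int(1 / s, rep.int(S, length(s))), ls = log(s))
}

logsumexp_rows <- function(lst) {
  m <- Reduce(pmax, lst)
  m + log(Reduce(`+`, lapply(lst, function(v) exp(v - m))))
}

# Postorder peel for one class. Returns down partials D (S x L x nnodes,
# tips included unscaled), per-node cumulative log-scalers lsD (L x nnodes),
# and the per-site log-likelihood for this class.
peel_class <- function(ti, lp, cl, el) {
  S <- nrow(lp[[1L]]); L <- ncol(lp[[1L]]); nn <- ti$nnodes_all
  D <- vector("list", nn)
  lsD <- matrix(0, L, nn)
  for (i in seq_len(ti$ntip)) D[[i]] <- lp[[i]]
  ctr <- 0L
  for (v in ti$int_postorder) {
    acc <- NULL
    for (ch in ti$children[[v]]) {
      e <- ti$einc[ch]
      P <- edge_prob(cl, e, el[e])
      contrib <- P %*% D[[ch]]
      acc <- if (is.null(acc)) contrib else acc * contrib
      lsD[, v] <- lsD[, v] + lsD[, ch]
    }
    ctr <- ctr + 1L
    if (ctr %% 4L == 0L || v == ti$root) {  # rescale periodically
      r <- rescale_cols(acc, S)
      D[[v]] <- r$m
      lsD[, v] <- lsD[, v] + r$ls
    } else D[[v]] <- acc
  }
  sitell <- log(colSums(cl$freq * D[[ti$root]])) + lsD[, ti$root]
  list(D = D, lsD = lsD, sitell = sitell)
}

# Full mixture likelihood over site patterns with weights wt.
# keep = TRUE retains per-class peel state for reuse by the ancestral-
# reconstruction pass.
peel_all <- function(ti, lp, classes, el = ti$el, wt = NULL, keep = FALSE) {
  per <- lapply(classes, function(cl) peel_class(ti, lp, cl, el))
  parts <- mapply(function(p, cl) log(cl$w) + p$sitell, per, classes,
                  SIMPLIFY = FALSE)
  site_lnl <- logsumexp_rows(parts)
  if (is.null(wt)) wt <- rep(1, length(site_lnl))
  out <- list(site_lnl = site_lnl, lnl = sum(site_lnl * wt),
              class_site_ll = parts)
  if (keep) out$per_class <- per
  out
}

# Collapse duplicate alignment columns into patterns: x_pat (taxa x P),
# wt (pattern multiplicities), index (site -> pattern).
compress_patterns <- function(aln) {
  x <- aln$x
  key <- apply(x, 2L, paste, collapse = ".")
  first <- !duplicated(key)
  index <- match(key, key[first])
  pat <- aln
  pat$x <- x[, first, drop = FALSE]
  pat$L <- sum(first)
  list(pat = pat, wt = as.numeric(tabulate(index, nbins = sum(first))),
       index = index)
}

# Preorder (up/outside) partials for one class, given its peel state.
# U[[v]] is the outside partial at node v (S x L) with log-scalers lsU.
above_class <- function(ti, cl, el, peel) {
  S <- length(cl$freq); L <- length(peel$sitell); nn <- ti$nnodes_all
  U <- vector("list", nn)
  lsU <- matrix(0, L, nn)
  U[[ti$root]] <- matrix(cl$freq, S, L)
  for (p in ti$int_preorder) {
    kids <- ti$children[[p]]
    contrib <- lapply(kids, function(ch) {
      e <- ti$einc[ch]
      edge_prob(cl, e, el[e]) %*% peel$D[[ch]]
    })
    for (j in seq_along(kids)) {
      ch <- kids[j]
      W <- U[[p]]
      wls <- lsU[, p]
      for (j2 in seq_along(kids)) if (j2 != j) {
        W <- W * contrib[[j2]]
        wls <- wls + peel$lsD[, kids[j2]]
      }
      e <- ti$einc[ch]
      P <- edge_prob(cl, e, el[e])
      r <- rescale_cols(crossprod(P, W), S)
      U[[ch]] <- r$m
      lsU[, ch] <- wls + r$ls
    }
  }
  list(U = U, lsU = lsU)
}

#' Per-site log-likelihoods under a tree and model
#'
#' Computes sitewise log-likelihood support (SSLS): the log-likelihood
#' contribution of every alignment column under the pruning algorithm, with
#' gamma-rate mixing and gaps treated as missing data.
#'
#' @param tree A rooted binary [ape::phylo] with branch lengths.
#' @param alignment A `phylo_alignment` whose taxa all appear as tree leaves.
#' @param model An `aa_model` (or codon model class list, internally).
#' @return An object of class `site_lik_profile`: `site_lnl` (length-L
#'   vector), `lnl` (their sum), and a `params` snapshot.
#' @export
site_log_likelihoods <- function(tree, alignment, model) {
  stopifnot(inherits(alignment, "phylo_alignment"))
  if (inherits(model, "aa_model") && alignment$alphabet != "aa")
    stop("model alphabet (aa) does not match alignment alphabet (",
         alignment$alphabet, ")")
  if (length(tree$tip.label) == 1L) {
    st <- alignment$x[1L, ]
    site <- ifelse(is.na(st), 0, log(model$freq[st]))
    return(new_site_lik_profile(site, model))
  }
  miss <- setdiff(alignment$taxa, tree$tip.label)
  if (length(miss))
    stop("alignment taxa missing from tree: ", paste(miss, collapse = ", "))
  tree <- prune_to_taxa(tree, alignment$taxa)
  ti <- tree_index(tree)
  cp <- compress_patterns(alignment)
  lp <- leaf_partials(ti, cp$pat)
  classes <- aa_classes(model, nrow(ti$edge))
  pk <- peel_all(ti, lp, classes, wt = cp$wt)
  new_site_lik_profile(pk$site_lnl[cp$index], model)
}

new_site_lik_profile <- function(site_lnl, model) {
  structure(list(site_lnl = site_lnl, lnl = sum(site_lnl),
                 params = list(model = model$name, alpha = model$alpha,
                               k = model$k, frequencies = model$frequencies)),
            class = "site_lik_profile")
}

#' @export
print.site_lik_profile <- function(x, ...) {
  cat(sprintf("Site log-likelihood profile: %d sites, total lnL = %.4f\n",
              length(x$site_lnl), x$lnl))
  invisible(x)
}

# Drop tree leaves absent from the given taxon set.
prune_to_taxa <- function(tree, taxa) {
  extra <- setdiff(tree$tip.label, taxa)
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  tree
}
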