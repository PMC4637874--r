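# Empirical-Bayes marginal ancestral sequence reconstruction and the
# classification of substitutions into parallel / unique / backward
# categories over configured focal lineages.

#' Marginal ancestral sequence reconstruction
#'
#' Empirical-Bayes marginal reconstruction: for every internal node and
#' site, the posterior over the 20 states is proportional to the product of
#' the partial likelihoods above and below the node, mixed over Gamma rate
#' categories at their weights, and normalized. Branch lengths should be
#' fitted first (pass a `phylo_fit` or let the function run
#' [optimize_likelihood()] itself).
#'
#' @param tree Rooted binary tree, or `NULL` when `fit` is given.
#' @param alignment Amino-acid `phylo_alignment`.
#' @param model An `aa_model` (ignored when `fit` is given).
#' @param fit Optional `phylo_fit` from [optimize_likelihood()].
#' @param optimize Fit branch lengths and alpha first (default TRUE when no
#'   `fit` is supplied).
#' @return An `ancestral_reconstruction`: `post` (states x sites x internal
#'   nodes posterior array), `map` (internal nodes x sites MAP state
#'   indices), `map_posterior`, `ambiguous` (MAP posterior < 0.5 or tied),
#'   `tree` (the fitted tree), `alignment`, `node_ids` (ape node numbers).
#' @export
marginal_ancestral_reconstruction <- function(tree = NULL, alignment, model,
                                              fit = NULL, optimize = TRUE) {
  if (is.null(fit)) {
    if (is.null(tree)) stop("supply 'tree' or 'fit'")
    if (!ape::is.rooted(tree))
      stop("tree is unrooted; root it before ancestral reconstruction")
    fit <- if (optimize) optimize_likelihood(tree, alignment, model)
    else {
      tree <- prune_to_taxa(tree, alignment$taxa)
      structure(list(tree = tree, model = model), class = "phylo_fit")
    }
  }
  tree <- fit$tree
  model <- fit$model
  ti <- tree_index(tree)
  cp <- compress_patterns(alignment)
  lp <- leaf_partials(ti, cp$pat)
  classes <- aa_classes(model, nrow(ti$edge))
  pk <- peel_all(ti, lp, classes, wt = cp$wt, keep = TRUE)
  S <- model$nstates
  P <- cp$pat$L
  int_nodes <- (ti$ntip + 1L):ti$nnodes_all
  post <- array(0, dim = c(S, alignment$L, length(int_nodes)),
                dimnames = list(model$states, NULL, NULL))
  ups <- lapply(seq_along(classes), function(ci)
    above_class(ti, classes[[ci]], ti$el, pk$per_class[[ci]]))
  for (vi in seq_along(int_nodes)) {
    v <- int_nodes[vi]
    acc <- matrix(0, S, P)
    for (ci in seq_along(classes)) {
      num <- ups[[ci]]$U[[v]] * pk$per_class[[ci]]$D[[v]]
      lw <- log(classes[[ci]]$w) + ups[[ci]]$lsU[, v] +
        pk$per_class[[ci]]$lsD[, v] - pk$site_lnl
      acc <- acc + num * rep(exp(lw), each = S)
    }
    acc <- acc / rep(colSums(acc), each = S)
    post[, , vi] <- acc[, cp$index]
  }
  map_from_post(post, model$states, tree, alignment, int_nodes)
}

# MAP states with deterministic alphabetical tie-breaking and ambiguity
# flags (ties or MAP posterior < 0.5).
map_from_post <- function(post, states, tree, alignment, node_ids) {
  S <- dim(post)[1L]; L <- dim(post)[2L]; NN <- dim(post)[3L]
  ord <- order(states)
  map <- matrix(0L, NN, L)
  mp <- matrix(0, NN, L)
  tie <- matrix(FALSE, NN, L)
  for (vi in seq_len(NN)) {
    pm <- post[ord, , vi, drop = TRUE]
    if (is.null(dim(pm))) pm <- matrix(pm, nrow = S)
    idx <- max.col(t(pm), ties.method = "first")
    map[vi, ] <- ord[idx]
    mx <- pm[cbind(idx, seq_len(L))]
    mp[vi, ] <- mx
    tie[vi, ] <- colSums(abs(pm - rep(mx, each = S)) < 1e-12) > 1L
  }
  structure(list(post = post, map = map, map_posterior = mp,
                 ambiguous = tie | mp < 0.5,
                 tree = tree, alignment = alignment, node_ids = node_ids,
                 states = states),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat(sprintf("Marginal ancestral reconstruction: %d internal nodes x %d sites\n",
              length(x$node_ids), ncol(x$map)))
  cat(sprintf("  mean MAP posterior %.3f; %.2f%% sites flagged ambiguous\n",
              mean(x$map_posterior), 100 * mean(x$ambiguous)))
  invisible(x)
}

# MAP state (index into states) at an internal ape node id.
asr_state <- function(asr, node, site) {
  vi <- match(node, asr$node_ids)
  if (is.na(vi)) stop("node ", node, " has no reconstruction")
  asr$map[vi, site]
}

asr_posterior <- function(asr, node, site) {
  vi <- match(node, asr$node_ids)
  asr$map_posterior[vi, site]
}

#' Configure focal lineages for substitution classification
#'
#' @param tree Rooted species tree (the tree used for the reconstruction).
#' @param groups Named list of focal leaf-name vectors (each monophyletic).
#' @param background Background (e.g. terrestrial) leaf names; defaults to
#'   all non-focal leaves.
#' @return A `focal_group_config`: per group its leaves, MRCA, ancestral
#'   node (the MRCA's parent, the ancestor shared with the terrestrial
#'   sister), and sister node; plus the background set.
#' @export
focal_group_config <- function(tree, groups, background = NULL) {
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  all_focal <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_focal)) stop("focal groups overlap")
  if (is.null(background)) background <- setdiff(tree$tip.label, all_focal)
  if (!length(background)) stop("background taxon set is empty")
  root <- length(tree$tip.label) + 1L
  info <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    mr <- mrca_node(tree, g)
    if (mr == root) stop("group '", nm, "' spans the root; no ancestral reference")
    par <- tree$edge[tree$edge[, 2L] == mr, 1L]
    sib <- setdiff(tree$edge[tree$edge[, 1L] == par, 2L], mr)
    list(name = nm, leaves = g, mrca = mr, ancestor = par, sister = sib)
  })
  names(info) <- names(groups)
  mrcas <- vapply(info, `[[`, integer(1), "mrca")
  for (i in seq_along(info)) for (j in seq_along(info)) if (i != j) {
    anc <- phangorn::Ancestors(tree, mrcas[j], type = "all")
    if (mrcas[i] %in% anc && mrcas[i] > length(tree$tip.label))
      stop("group '", names(info)[i], "' is ancestral to group '",
           names(info)[j], "'")
  }
  structure(list(groups = info, background = background, tree = tree),
            class = "focal_group_config")
}

# Consensus derived state per group at one site: integer state, NA if no
# data, -1L if heterogeneous.
group_derived_state <- function(x, leaves, site) {
  st <- x[leaves, site]
  st <- st[!is.na(st)]
  if (!length(st)) return(NA_integer_)
  u <- unique(st)
  if (length(u) > 1L) return(-1L)
  u
}

#' Classify parallel substitutions from an ancestral reconstruction
#'
#' A site carries a parallel substitution when every focal group shows the
#' same derived amino acid, and in each group that residue differs from the
#' reconstructed state at the group's ancestral node (the ancestor shared
#' with its terrestrial sister). Sites where a group is internally
#' heterogeneous or fully missing are skipped (counted in the attribute
#' `skipped`). With `require_unique`, the derived residue must additionally
#' be absent from every background leaf and every group's sister-lineage
#' reconstruction; both plain and unique status are reported per call.
#'
#' @param asr An `ancestral_reconstruction` on the species tree.
#' @param config A [focal_group_config()].
#' @param require_unique Only return calls that are also unique.
#' @return Data frame of calls: `site`, `ref_pos`, `category`
#'   (`"parallel"`), `unique`, `strict_parallel`, `derived`, per-group
#'   ancestral states, `min_posterior`, `low_confidence`.
#' @export
call_parallel_substitutions <- function(asr, config, require_unique = FALSE) {
  aln <- asr$alignment
  x <- aln$x
  L <- aln$L
  gl <- config$groups
  refpos <- ref_positions(aln)
  skipped <- 0L
  rows <- list()
  for (site in seq_len(L)) {
    d <- vapply(gl, function(g) group_derived_state(x, g$leaves, site),
                integer(1))
    if (anyNA(d)) { next }
    if (any(d == -1L)) { skipped <- skipped + 1L; next }
    if (length(unique(d)) != 1L) next
    dv <- d[1L]
    anc <- vapply(gl, function(g) asr_state(asr, g$ancestor, site), integer(1))
    if (any(anc == dv)) next
    post <- vapply(gl, function(g) asr_posterior(asr, g$ancestor, site),
                   numeric(1))
    sis <- vapply(gl, function(g) {
      if (g$sister > length(config$tree$tip.label))
        asr_state(asr, g$sister, site)
      else {
        st <- x[config$tree$tip.label[g$sister], site]
        if (is.na(st)) 0L else st
      }
    }, integer(1))
    bg_states <- x[config$background, site]
    bg_states <- bg_states[!is.na(bg_states)]
    uniq <- !any(bg_states == dv) && !any(sis == dv)
    if (require_unique && !uniq) next
    rows[[length(rows) + 1L]] <- data.frame(
      site = site, ref_pos = refpos[site], category = "parallel",
      unique = uniq, strict_parallel = length(unique(anc)) == 1L,
      derived = AA_STATES[dv],
      ancestral = paste(AA_STATES[anc], collapse = ","),
      min_posterior = min(post), low_confidence = min(post) < 0.5)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = integer(0), ref_pos = integer(0),
               category = character(0), unique = logical(0),
               strict_parallel = logical(0), derived = character(0),
               ancestral = character(0), min_posterior = numeric(0),
               low_confidence = logical(0))
  attr(out, "skipped_heterogeneous") <- skipped
  out
}

#' Classify unique substitutions
#'
#' A derived residue shared by all focal leaves (each group homogeneous)
#' that is absent from every background leaf and from each group's
#' ancestral node. Gaps are missing data: a group needs at least one
#' non-missing leaf, and a gapped leaf is never counted as a mismatch.
#'
#' @inheritParams call_parallel_substitutions
#' @return Data frame: `site`, `ref_pos`, `category` (`"unique"`),
#'   `derived`, `ancestral`, `min_posterior`, `low_confidence`,
#'   `missing_leaves` (count of gapped focal leaves).
#' @export
call_unique_substitutions <- function(asr, config) {
  if (!length(config$background)) stop("background taxon set is empty")
  aln <- asr$alignment
  x <- aln$x
  gl <- config$groups
  refpos <- ref_positions(aln)
  rows <- list()
  for (site in seq_len(aln$L)) {
    d <- vapply(gl, function(g) group_derived_state(x, g$leaves, site),
                integer(1))
    if (anyNA(d) || any(d == -1L) || length(unique(d)) != 1L) next
    dv <- d[1L]
    bg <- x[config$background, site]
    bg <- bg[!is.na(bg)]
    if (any(bg == dv)) next
    anc <- vapply(gl, function(g) asr_state(asr, g$ancestor, site), integer(1))
    if (any(anc == dv)) next
    post <- vapply(gl, function(g) asr_posterior(asr, g$ancestor, site),
                   numeric(1))
    nmiss <- sum(is.na(x[unlist(lapply(gl, `[[`, "leaves")), site]))
    rows[[length(rows) + 1L]] <- data.frame(
      site = site, ref_pos = refpos[site], category = "unique",
      derived = AA_STATES[dv],
      ancestral = paste(AA_STATES[anc], collapse = ","),
      min_posterior = min(post), low_confidence = min(post) < 0.5,
      missing_leaves = nmiss)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(site = integer(0), ref_pos = integer(0),
               category = character(0), derived = character(0),
               ancestral = character(0), min_posterior = numeric(0),
               low_confidence = logical(0), missing_leaves = integer(0))
}

#' Annotate backward substitutions against a distant reference clade
#'
#' A parallel or unique call is annotated as backward when the focal
#' derived residue is also the prevailing state in a distant reference
#' clade (e.g. non-mammal vertebrates): it occurs in at least `threshold`
#' of the non-missing reference taxa at that column.
#'
#' @param calls Data frame from [call_parallel_substitutions()] or
#'   [call_unique_substitutions()].
#' @param reference_alignment Amino-acid `phylo_alignment` of reference
#'   taxa, aligned to the same columns.
#' @param n_columns Column count of the focal alignment (for validation).
#' @param threshold Minimum fraction of non-missing reference taxa.
#' @return `calls` with added `backward` and `no_reference_data` columns.
#' @export
call_backward_substitutions <- function(calls, reference_alignment,
                                        n_columns = NULL, threshold = 0.5) {
  stopifnot(inherits(reference_alignment, "phylo_alignment"))
  if (!is.null(n_columns) && reference_alignment$L != n_columns)
    stop("reference alignment has ", reference_alignment$L,
         " columns, expected ", n_columns)
  calls$backward <- FALSE
  calls$no_reference_data <- FALSE
  if (!nrow(calls)) return(calls)
  for (i in seq_len(nrow(calls))) {
    col <- reference_alignment$x[, calls$site[i]]
    col <- col[!is.na(col)]
    if (!length(col)) { calls$no_reference_data[i] <- TRUE; next }
    calls$backward[i] <-
      mean(AA_STATES[col] == calls$derived[i]) >= threshold
  }
  calls
}
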