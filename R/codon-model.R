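# Goldman-Yang codon substitution models over the 61 sense codons.
# Instantaneous rates: zero for multi-nucleotide changes; single-nucleotide
# changes get target frequency pi_j, a factor kappa for transitions and
# omega for nonsynonymous changes. Matrices are scaled so branch lengths are
# expected substitutions per codon site.

# Single-nucleotide-difference structure of the 61x61 matrix, built once.
codon_pairs <- local({
  I <- integer(0); J <- integer(0); ts <- logical(0); ns <- logical(0)
  for (i in 1:61) for (j in 1:61) {
    if (i == j) next
    d <- which(CODON61_NUC[i, ] != CODON61_NUC[j, ])
    if (length(d) != 1L) next
    a <- NUC[CODON61_NUC[i, d]]; b <- NUC[CODON61_NUC[j, d]]
    I <- c(I, i); J <- c(J, j)
    ts <- c(ts, is_transition(a, b))
    ns <- c(ns, CODON61_AA[i] != CODON61_AA[j])
  }
  list(I = I, J = J, ts = ts, ns = ns)
})

# Unscaled GY94 rate matrix (diagonal set; no normalization).
codon_q_raw <- function(kappa, omega, freq) {
  Q <- matrix(0, 61, 61, dimnames = list(CODON61, CODON61))
  r <- freq[codon_pairs$J] *
    ifelse(codon_pairs$ts, kappa, 1) *
    ifelse(codon_pairs$ns, omega, 1)
  Q[cbind(codon_pairs$I, codon_pairs$J)] <- r
  diag(Q) <- -rowSums(Q)
  Q
}

codon_rate <- function(Q, freq) -sum(freq * diag(Q))

#' F3x4 codon frequencies
#'
#' Equilibrium codon frequencies from position-specific nucleotide
#' frequencies observed in a codon alignment; stop codons are excluded and
#' the 61 sense-codon frequencies renormalized. A zero nucleotide frequency
#' receives a pseudocount of 1e-6.
#'
#' @param aln A codon-mode `phylo_alignment`.
#' @return Numeric vector of 61 frequencies summing to 1.
#' @export
f3x4_frequencies <- function(aln) {
  stopifnot(inherits(aln, "phylo_alignment"), aln$alphabet == "codon")
  x <- aln$x[!is.na(aln$x)]
  nf <- matrix(0, 3, 4)
  for (pos in 1:3)
    nf[pos, ] <- tabulate(CODON61_NUC[x, pos], nbins = 4L)
  if (any(nf == 0)) nf[nf == 0] <- 1e-6
  nf <- nf / rowSums(nf)
  fr <- nf[1L, CODON61_NUC[, 1L]] * nf[2L, CODON61_NUC[, 2L]] *
    nf[3L, CODON61_NUC[, 3L]]
  fr / sum(fr)
}

#' Construct a one-ratio codon substitution model
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio dN/dS (>= 0).
#' @param freq Codon frequencies (61 values, e.g. from
#'   [f3x4_frequencies()]); defaults to uniform.
#' @return A `codon_model` with scaled rate matrix `Q` (one expected
#'   substitution per codon per unit branch length) and its
#'   eigendecomposition.
#' @export
codon_model <- function(kappa = 2, omega = 0.2, freq = NULL) {
  if (kappa <= 0) stop("'kappa' must be > 0")
  if (omega < 0) stop("'omega' must be >= 0")
  if (is.null(freq)) freq <- rep(1 / 61, 61)
  if (length(freq) != 61L) stop("'freq' must have 61 entries")
  freq <- freq / sum(freq)
  Q <- codon_q_raw(kappa, omega, freq)
  mu <- codon_rate(Q, freq)
  Q <- Q / mu
  structure(list(type = "codon", states = CODON61, nstates = 61L,
                 kappa = kappa, omega = omega, freq = freq,
                 Q = Q, eig = decompose_q(Q, freq),
                 alpha = NA_real_, k = 1L, rates = 1,
                 name = sprintf("GY94(kappa=%.3g, omega=%.3g)", kappa, omega)),
            class = "codon_model")
}

#' @export
print.codon_model <- function(x, ...) {
  cat(sprintf("Codon model %s, 61 sense codons\n", x$name))
  invisible(x)
}

# Build engine mixture classes for a general codon site/branch model.
#
# site_classes: list of list(w, omega_bg, omega_fg); fg_edges: edge indices
# (into the postorder edge matrix) using the foreground omega. All matrices
# share one scale factor: the mixture-average background rate, so relative
# rates between classes are preserved and omega ratios stay interpretable.
#
# An optional cache environment memoizes eigendecompositions of the raw
# (unscaled) Q by (kappa, omega): rescaling only multiplies eigenvalues.
codon_classes <- function(kappa, site_classes, freq, nedges,
                          fg_edges = integer(0), cache = NULL) {
  omegas <- unique(unlist(lapply(site_classes, function(s)
    c(s$omega_bg, s$omega_fg))))
  raw <- lapply(omegas, function(w) {
    key <- sprintf("%.14g_%.14g", kappa, w)
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    Q <- codon_q_raw(kappa, w, freq)
    val <- list(eig = decompose_q(Q, freq), mu = codon_rate(Q, freq))
    if (!is.null(cache)) cache[[key]] <- val
    val
  })
  mus <- vapply(raw, `[[`, numeric(1), "mu")
  w_bg <- vapply(site_classes, `[[`, numeric(1), "w")
  mu_mix <- sum(w_bg * mus[match(
    vapply(site_classes, `[[`, numeric(1), "omega_bg"), omegas)])
  eigs <- lapply(raw, function(r) {
    e <- r$eig
    e$lambda <- e$lambda / mu_mix
    e
  })
  lapply(site_classes, function(s) {
    ib <- match(s$omega_bg, omegas)
    ifg <- match(s$omega_fg, omegas)
    emap <- rep(ib, nedges)
    if (length(fg_edges)) emap[fg_edges] <- ifg
    list(w = s$w, rate = 1, freq = freq, eigs = eigs, emap = emap,
         omega_bg = s$omega_bg, omega_fg = s$omega_fg)
  })
}

# Beta(p, q) discretized into k equal-probability categories (category
# means, via the incomplete-beta identity).
beta_category_means <- function(p, q, k = 10L) {
  br <- stats::qbeta(seq_len(k - 1L) / k, p, q)
  cdf1 <- c(0, stats::pbeta(br, p + 1, q), 1)
  k * diff(cdf1) * p / (p + q)
}

# Foreground edge indices for a postorder-indexed tree: all edges inside
# (and optionally the stem of) each focal group's clade.
foreground_edges <- function(tree, groups, include_stem = TRUE) {
  ti <- tree_index(tree)
  tr <- ti$tree
  nodes <- integer(0)
  for (g in groups) {
    mr <- mrca_node(tr, g)
    desc <- if (mr > ti$ntip)
      phangorn::Descendants(tr, mr, type = "all") else integer(0)
    nodes <- c(nodes, if (include_stem) mr else integer(0), desc)
  }
  which(ti$edge[, 2L] %in% unique(nodes))
}
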