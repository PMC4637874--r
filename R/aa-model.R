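# Amino-acid substitution models with discrete-Gamma rate heterogeneity.
#
# States follow the standard PAML ordering used by the published JTT/WAG
# matrices: A R N D C Q E G H I L K M F P S T W Y V.

AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Discrete-Gamma rate multipliers
#'
#' Discretizes a Gamma(shape = `alpha`, rate = `alpha`) distribution (mean 1)
#' into `k` equal-probability categories, returning the category means
#' (the codeml-style discretization). With `k = 1` the single category is the
#' distribution mean, 1.
#'
#' @param alpha Gamma shape parameter; must be > 0. Small values give strong
#'   rate heterogeneity across sites, large values approach rate homogeneity.
#' @param k Number of rate categories (>= 1).
#' @return Numeric vector of `k` strictly increasing rate multipliers with
#'   mean 1; each category carries equal weight `1/k`.
#' @examples
#' discrete_gamma_rates(0.5, 4)
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single finite value > 0")
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  if (k == 1L) return(1.0)
  # Mean of Gamma(a, a) within each equal-probability bin, via the identity
  # E[X; X in bin] = (a/a) * [pgamma(q, a+1, a)] differences.
  q <- stats::qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  p <- c(0, stats::pgamma(q, shape = alpha + 1, rate = alpha), 1)
  r <- k * diff(p)
  r / mean(r) * 1  # guard against last-digit drift; mean is 1 by construction
}

# Fetch published exchangeabilities + frequencies for a named AA model.
# phangorn ships the JTT/WAG constants; getModelAA() assigns Q (190 lower-
# triangle exchangeabilities) and bf into the calling frame.
aa_model_constants <- function(name) {
  if (name == "POISSON") {
    return(list(exch = rep(1, 190), freq = rep(1 / 20, 20)))
  }
  Q <- NULL; bf <- NULL
  phangorn:::getModelAA(name, bf = TRUE, Q = TRUE)
  list(exch = Q, freq = as.numeric(bf))
}

# Build a scaled reversible rate matrix from lower-triangle exchangeabilities
# and equilibrium frequencies: Q_ij = s_ij * pi_j, diagonal set so rows sum
# to 0, scaled so the expected rate -sum(pi_i Q_ii) equals 1.
build_rate_matrix <- function(exch, freq, states) {
  s <- length(freq)
  S <- matrix(0, s, s)
  S[lower.tri(S)] <- exch
  S <- S + t(S)
  Q <- S * rep(freq, each = s)  # Q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(states, states)
  Q
}

# Eigendecomposition of a reversible Q via the symmetrized form
# B = diag(sqrt(pi)) Q diag(1/sqrt(pi)). P(t) = V1 diag(exp(lambda t)) V2.
decompose_q <- function(Q, freq) {
  sp <- sqrt(freq)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(lambda = e$values,
       V1 = e$vectors / sp,              # diag(1/sqrt(pi)) %*% V
       V2 = t(e$vectors * sp),           # t(V) %*% diag(sqrt(pi))
       freq = freq)
}

#' Construct an amino-acid substitution model
#'
#' Builds a reversible 20-state substitution model (JTT, WAG, or the
#' equal-rates Poisson model) with discrete-Gamma rate heterogeneity.
#' The rate matrix is scaled to one expected substitution per site per unit
#' branch length.
#'
#' @param name One of `"JTT"`, `"WAG"`, `"POISSON"`.
#' @param alpha Gamma shape for among-site rate variation (> 0).
#' @param k Number of discrete rate categories (>= 1); 4 by default.
#' @param frequencies `"model"` uses the published equilibrium frequencies;
#'   `"empirical"` estimates them from `data` (counts over non-missing
#'   residues, the +F option).
#' @param data An `phylo_alignment` (amino-acid) used when
#'   `frequencies = "empirical"`.
#' @return An object of class `aa_model` holding the scaled rate matrix `Q`,
#'   frequencies `freq`, eigendecomposition, `alpha`, `k`, and the rate
#'   multipliers.
#' @examples
#' m <- aa_model("WAG", alpha = 0.7, k = 4)
#' m
#' @export
aa_model <- function(name = c("JTT", "WAG", "POISSON"), alpha = 1, k = 4L,
                     frequencies = c("model", "empirical"), data = NULL) {
  name <- match.arg(name)
  frequencies <- match.arg(frequencies)
  if (!is.numeric(alpha) || alpha <= 0) stop("'alpha' must be > 0")
  cst <- aa_model_constants(name)
  freq <- cst$freq
  if (frequencies == "empirical") {
    if (is.null(data)) stop("empirical frequencies require 'data'")
    freq <- empirical_aa_freq(data)
  }
  freq <- freq / sum(freq)
  Q <- build_rate_matrix(cst$exch, freq, AA_STATES)
  structure(list(name = name, type = "aa", states = AA_STATES,
                 nstates = 20L, Q = Q, freq = freq,
                 eig = decompose_q(Q, freq),
                 alpha = alpha, k = as.integer(k),
                 rates = discrete_gamma_rates(alpha, k),
                 frequencies = frequencies),
            class = "aa_model")
}

empirical_aa_freq <- function(aln) {
  stopifnot(inherits(aln, "phylo_alignment"), aln$alphabet == "aa")
  cnt <- tabulate(aln$x[!is.na(aln$x)], nbins = 20L)
  cnt <- cnt + 1e-6  # pseudocount so absent residues keep a nonzero rate
  cnt / sum(cnt)
}

# Update the Gamma shape of an existing model without re-deriving Q.
set_alpha <- function(model, alpha) {
  model$alpha <- alpha
  model$rates <- discrete_gamma_rates(alpha, model$k)
  model
}

#' Transition probability matrix
#'
#' Computes `P(t) = exp(Q t r)` for a model's rate matrix by
#' eigendecomposition, for one rate multiplier `rate`.
#'
#' @param model An `aa_model` or `codon_model`.
#' @param t Branch length in expected substitutions per site (>= 0).
#' @param rate Rate-category multiplier (default 1).
#' @return A stochastic matrix: rows sum to 1, entries in `[0, 1]`.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("branch length 't' must be a single finite value >= 0")
  P <- prob_matrix(model$eig, t * rate)
  P / rowSums(P)
}

# Internal fast path: P(t) from a cached eigendecomposition. Tiny negative
# entries from the eigendecomposition are clamped; row normalization (an
# O(1e-15) correction) is applied only in the exported transition_matrix().
prob_matrix <- function(eig, t) {
  P <- eig$V1 %*% (exp(eig$lambda * t) * eig$V2)
  P[P < 0] <- 0
  P
}

#' @export
print.aa_model <- function(x, ...) {
  cat(sprintf("Amino-acid model: %s + Gamma(alpha = %.4g, k = %d), %s frequencies\n",
              x$name, x$alpha, x$k, x$frequencies))
  cat(sprintf("  rate multipliers: %s\n",
              paste(sprintf("%.4f", x$rates), collapse = " ")))
  invisible(x)
}
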