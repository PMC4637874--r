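# Sequence-evolution simulator: exact transition-probability sampling at
# branch endpoints (with an optional Gillespie mode when true event paths
# are needed), plus planted convergence features and the study-shaped
# fixture generator.

#' Specify a simulation
#'
#' @param tree Rooted binary [ape::phylo] with branch lengths.
#' @param model `aa_model` (sites draw a Gamma rate category) or
#'   `codon_model` (optionally with per-site and foreground omegas).
#' @param length Number of columns (residues or codons).
#' @param seed Mandatory random seed.
#' @param omega_site Optional per-site background omega vector (codon mode;
#'   recycled to `length`).
#' @param omega_fg Optional foreground omega (scalar or per-site; codon
#'   mode), applied on `fg_edges`.
#' @param fg_groups Optional list of leaf-name vectors whose clades (stem
#'   included) evolve under `omega_fg`.
#' @param method `"matrix"` (endpoint sampling; the event log is recovered
#'   by endpoint comparison) or `"gillespie"` (explicit event paths).
#' @return A `simulation_spec`.
#' @export
simulation_spec <- function(tree, model, length, seed,
                            omega_site = NULL, omega_fg = NULL,
                            fg_groups = NULL,
                            method = c("matrix", "gillespie")) {
  if (missing(seed)) stop("a random seed is required")
  method <- match.arg(method)
  stopifnot(inherits(model, c("aa_model", "codon_model")))
  structure(list(tree = tree, model = model, L = as.integer(length),
                 seed = as.integer(seed), omega_site = omega_site,
                 omega_fg = omega_fg, fg_groups = fg_groups,
                 method = method),
            class = "simulation_spec")
}

#' Simulate an alignment along a tree
#'
#' Draws the root sequence from the model's equilibrium frequencies and
#' evolves it down every branch with the exact transition probabilities
#' `P(t)` of the (possibly site- and branch-heterogeneous) process. The
#' event log lists per-branch state changes for planted-truth evaluation;
#' identical seeds give identical output.
#'
#' @param spec A [simulation_spec()].
#' @return List: `alignment` (a `phylo_alignment`), `node_states` (states at
#'   every node, internal nodes included), `events` (data frame: edge,
#'   child, site, from, to, nonsyn), `spec`.
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  model <- spec$model
  ti <- tree_index(spec$tree)
  L <- spec$L
  S <- model$nstates

  if (inherits(model, "aa_model")) {
    site_grp <- sample.int(model$k, L, replace = TRUE)
    grp_procs <- lapply(seq_len(model$k), function(i)
      list(eig_bg = model$eig, eig_fg = model$eig, rate = model$rates[i]))
    fg_edges <- integer(0)
  } else {
    ob <- if (is.null(spec$omega_site)) model$omega else
      rep_len(spec$omega_site, L)
    ob <- rep_len(ob, L)
    of <- if (is.null(spec$omega_fg)) ob else rep_len(spec$omega_fg, L)
    key <- paste(ob, of)
    site_grp <- match(key, unique(key))
    uk <- !duplicated(key)
    Qb <- lapply(ob[uk], function(w) codon_q_raw(model$kappa, w, model$freq))
    Qf <- lapply(of[uk], function(w) codon_q_raw(model$kappa, w, model$freq))
    mus <- vapply(Qb, codon_rate, numeric(1), freq = model$freq)
    mu_mix <- mean(mus[site_grp])
    grp_procs <- lapply(seq_along(Qb), function(i)
      list(eig_bg = decompose_q(Qb[[i]] / mu_mix, model$freq),
           eig_fg = decompose_q(Qf[[i]] / mu_mix, model$freq),
           Qb = Qb[[i]] / mu_mix, Qf = Qf[[i]] / mu_mix, rate = 1))
    fg_edges <- if (is.null(spec$fg_groups)) integer(0) else
      foreground_edges(ti$tree, spec$fg_groups)
  }

  states <- matrix(NA_integer_, ti$nnodes_all, L)
  states[ti$root, ] <- sample.int(S, L, replace = TRUE, prob = model$freq)
  events <- list()
  for (e in rev(seq_len(nrow(ti$edge)))) {  # preorder over postorder edges
    par <- ti$edge[e, 1L]; ch <- ti$edge[e, 2L]
    t <- ti$el[e]
    fg <- e %in% fg_edges
    new <- integer(L)
    for (g in unique(site_grp)) {
      gs <- which(site_grp == g)
      pr <- grp_procs[[g]]
      if (spec$method == "matrix") {
        P <- prob_matrix(if (fg) pr$eig_fg else pr$eig_bg, t * pr$rate)
        ps <- states[par, gs]
        for (s in unique(ps)) {
          w <- gs[ps == s]
          new[w] <- sample.int(S, length(w), replace = TRUE, prob = P[s, ])
        }
      } else {
        Q <- if (fg) pr$Qf else pr$Qb
        if (inherits(model, "aa_model")) Q <- model$Q * pr$rate
        for (site in gs) {
          s <- states[par, site]
          tt <- 0
          repeat {
            rate <- -Q[s, s]
            if (rate <= 0) break
            tt <- tt + stats::rexp(1L, rate)
            if (tt > t) break
            s_new <- sample.int(S, 1L, prob = pmax(Q[s, ], 0) / rate)
            events[[length(events) + 1L]] <-
              data.frame(edge = unname(e), child = unname(ch),
                         site = unname(site), from = unname(s),
                         to = unname(s_new))
            s <- s_new
          }
          new[site] <- s
        }
      }
    }
    if (spec$method == "matrix") {
      chg <- which(new != states[par, ])
      if (length(chg))
        events[[length(events) + 1L]] <-
          data.frame(edge = unname(e), child = unname(ch),
                     site = unname(chg),
                     from = unname(states[par, chg]), to = unname(new[chg]))
    }
    states[ch, ] <- new
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(edge = integer(0), child = integer(0), site = integer(0),
               from = integer(0), to = integer(0))
  if (inherits(model, "codon_model") && nrow(ev))
    ev$nonsyn <- CODON61_AA[ev$from] != CODON61_AA[ev$to]
  else ev$nonsyn <- logical(nrow(ev))
  x <- states[seq_len(ti$ntip), , drop = FALSE]
  rownames(x) <- ti$tip.label
  aln <- alignment_from_states(x, if (inherits(model, "aa_model")) "aa" else "codon")
  list(alignment = aln, node_states = states, events = ev, spec = spec)
}

#' Plant convergent substitution features into an alignment
#'
#' Overrides simulated states at chosen sites: every leaf of every focal
#' group is set to the target amino acid (in codon mode, to that amino
#' acid's first codon), creating ground-truth parallel substitutions. For
#' `"unique"` features, background leaves that already carry the target
#' state are resampled to a different state (logged). Surrounding columns
#' are untouched.
#'
#' @param alignment A `phylo_alignment`.
#' @param groups List of focal-group leaf-name vectors.
#' @param features Data frame with columns `site` (column index) , `target`
#'   (amino-acid letter), `kind` (`"parallel"` or `"unique"`).
#' @param seed Seed for background resampling.
#' @return List: `alignment` (modified), `truth` (the feature table with a
#'   `resampled` count column).
#' @export
plant_convergent_sites <- function(alignment, groups, features, seed = 1L) {
  stopifnot(inherits(alignment, "phylo_alignment"))
  if (!nrow(features)) return(list(alignment = alignment, truth = features))
  set.seed(seed)
  x <- alignment$x
  focal <- unlist(groups, use.names = FALSE)
  bg <- setdiff(alignment$taxa, focal)
  resampled <- integer(nrow(features))
  for (i in seq_len(nrow(features))) {
    site <- features$site[i]
    if (site < 1L || site > alignment$L) stop("planted site out of range: ", site)
    aa <- features$target[i]
    if (!aa %in% AA_STATES) stop("invalid planted state: ", aa)
    target_state <- if (alignment$alphabet == "aa") match(aa, AA_STATES)
    else which(CODON61_AA == aa)[1L]
    x[focal, site] <- target_state
    if (features$kind[i] == "unique") {
      if (alignment$alphabet == "aa") {
        hit <- bg[!is.na(x[bg, site]) & AA_STATES[x[bg, site]] == aa]
        pool <- which(AA_STATES != aa)
      } else {
        hit <- bg[!is.na(x[bg, site]) & CODON61_AA[x[bg, site]] == aa]
        pool <- which(CODON61_AA != aa)
      }
      if (length(pool) < 2L) stop("impossible unique constraint at site ", site)
      if (length(hit)) {
        x[hit, site] <- sample(pool, length(hit), replace = TRUE)
        resampled[i] <- length(hit)
      }
    }
  }
  out <- alignment
  out$x <- x
  truth <- features
  truth$resampled <- resampled
  list(alignment = out, truth = truth)
}

# Built-in 20-taxon mammal-like species tree: three non-sister marine
# lineages (cetaceans; pinnipeds; sirenian) among terrestrial relatives.
TOY_SPECIES_TREE <- paste0(
  "((((((dolphin:0.025,killer_whale:0.025):0.02,minke_whale:0.045):0.06,",
  "cow:0.105):0.02,(pig:0.1,alpaca:0.1):0.025):0.02,",
  "((((walrus:0.03,seal:0.03):0.05,(dog:0.07,cat:0.07):0.01):0.035,",
  "horse:0.115):0.01,bat:0.125):0.02):0.015,",
  "((((human:0.05,macaque:0.05):0.02,marmoset:0.07):0.05,",
  "(mouse:0.13,rabbit:0.11):0.02):0.025,",
  "(elephant:0.09,(manatee:0.07,hyrax:0.08):0.02):0.05):0.01);")

TOY_FOCAL_GROUPS <- list(
  cetaceans = c("dolphin", "killer_whale", "minke_whale"),
  pinnipeds = c("walrus", "seal"),
  sirenians = "manatee")

#' The bundled toy species tree and focal lineages
#'
#' A 20-taxon mammal-like rooted tree with three independently derived
#' marine lineages (cetaceans, pinnipeds, a sirenian) placed among
#' terrestrial relatives, used as the default study scaffold.
#'
#' @return List with `tree` ([ape::phylo]) and `groups` (named list of
#'   focal-lineage leaf sets).
#' @export
toy_species_tree <- function() {
  list(tree = read_tree(TOY_SPECIES_TREE), groups = TOY_FOCAL_GROUPS)
}

#' Generate a complete synthetic study on disk
#'
#' Writes per-gene codon FASTA alignments, the species tree, a truth table
#' enumerating every planted signal, and a reproducibility manifest. Gene
#' regimes: `h0` (species topology, background omega), `ha` (a convergence
#' topology), `fgw` (species topology, elevated foreground omega on the
#' marine lineages), `parallel` / `unique` (species topology plus planted
#' substitutions).
#'
#' @param dir Output directory (created).
#' @param n_genes Named vector/list of gene counts per regime, e.g.
#'   `c(h0 = 70, ha = 10, fgw = 15, parallel = 5)`.
#' @param seed Mandatory seed; all per-gene seeds derive from it.
#' @param codon_range Gene lengths (codons) are drawn uniformly in this
#'   range.
#' @param omega_bg,omega_fg,kappa Codon-model parameters.
#' @param n_planted_sites Planted sites per parallel/unique gene.
#' @param tree,groups Species tree and focal lineages; default
#'   [toy_species_tree()].
#' @return Invisibly, the study manifest (list).
#' @export
generate_toy_study <- function(dir, n_genes = c(h0 = 70, ha = 10, fgw = 15,
                                                parallel = 5),
                               seed, codon_range = c(300, 900),
                               omega_bg = 0.2, omega_fg = 0.8, kappa = 2.5,
                               n_planted_sites = 3L,
                               tree = NULL, groups = NULL) {
  if (missing(seed)) stop("a random seed is required")
  if (is.null(tree)) { st <- toy_species_tree(); tree <- st$tree }
  if (is.null(groups)) groups <- TOY_FOCAL_GROUPS
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "genes"), showWarnings = FALSE)
  set.seed(seed)
  regimes <- rep(names(n_genes), unlist(n_genes))
  ng <- length(regimes)
  gene_seeds <- sample.int(2^31 - 2L, ng)
  lens <- sample(seq(codon_range[1L], codon_range[2L]), ng, replace = TRUE)
  hyps <- generate_alternative_topologies(tree, groups)
  ha_pick <- sample.int(length(hyps), ng, replace = TRUE)
  plant_targets <- sample(AA_STATES, ng * n_planted_sites, replace = TRUE)
  truth <- list()
  for (i in seq_len(ng)) {
    gene <- sprintf("gene%03d", i)
    reg <- regimes[i]
    sim_tree <- if (reg == "ha") hyps[[ha_pick[i]]]$ha else tree
    cm <- codon_model(kappa = kappa, omega = omega_bg)
    spec <- simulation_spec(
      sim_tree, cm, lens[i], seed = gene_seeds[i],
      omega_fg = if (reg == "fgw") omega_fg else NULL,
      fg_groups = if (reg == "fgw") groups else NULL)
    sim <- simulate_alignment(spec)
    aln <- sim$alignment
    planted <- ""
    if (reg %in% c("parallel", "unique")) {
      sites <- sort(sample.int(lens[i], n_planted_sites))
      feats <- data.frame(
        site = sites,
        target = plant_targets[(i - 1L) * n_planted_sites +
                                 seq_len(n_planted_sites)],
        kind = if (reg == "unique") "unique" else "parallel")
      pl <- plant_convergent_sites(aln, groups, feats,
                                   seed = gene_seeds[i] %% 100000L + 1L)
      aln <- pl$alignment
      planted <- paste(sprintf("%d:%s", feats$site, feats$target),
                       collapse = ",")
    }
    write_alignment(aln, file.path(dir, "genes", paste0(gene, ".fasta")))
    truth[[i]] <- data.frame(
      gene = gene, regime = reg, n_codons = lens[i],
      hypothesis = if (reg == "ha") hyps[[ha_pick[i]]]$id else "",
      planted_sites = planted, seed = gene_seeds[i])
  }
  truth <- do.call(rbind, truth)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_tree(tree, file.path(dir, "species_tree.nwk"))
  manifest <- list(seed = seed, n_genes = as.list(n_genes),
                   codon_range = codon_range, omega_bg = omega_bg,
                   omega_fg = omega_fg, kappa = kappa,
                   n_planted_sites = n_planted_sites,
                   groups = groups,
                   package_version = as.character(utils::packageVersion("phyloconverge")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
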