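# Study orchestration: input filters, per-gene fan-out over the
# convergence, reconstruction and selection stages, multiple-testing
# adjustment, candidate intersection and report tables. Per-gene results
# are checkpointed as JSON so interrupted runs resume; reports are always
# rebuilt from checkpoints, making resumed and fresh runs identical.

#' Filter coding-sequence alignments
#'
#' Applies the input filters: a CDS alignment is excluded when shorter than
#' 150 nucleotides, when its length is not divisible by 3, or when the file
#' cannot be parsed. When several files share a gene id (same basename up
#' to a trailing `.N` transcript suffix), only the longest CDS is retained.
#'
#' @param paths Character vector of FASTA files (nucleotide CDS).
#' @return List with `retained` (named vector: gene id -> path) and
#'   `excluded` (data frame: file, reason).
#' @export
filter_genes <- function(paths) {
  ids <- sub("\\.[0-9]+$", "", sub("\\.(fa|fasta|fas)$", "",
                                   basename(paths), ignore.case = TRUE))
  lens <- integer(length(paths))
  excl <- list()
  ok <- logical(length(paths))
  for (i in seq_along(paths)) {
    n <- tryCatch({
      recs <- seqinr::read.fasta(paths[i], seqtype = "DNA", as.string = FALSE,
                                 forceDNAtolower = FALSE)
      ll <- unique(lengths(recs))
      if (length(ll) != 1L) stop("ragged rows")
      ll
    }, error = function(e) {
      excl[[length(excl) + 1L]] <<-
        data.frame(file = paths[i], reason = paste0("unreadable: ",
                                                    conditionMessage(e)))
      NA_integer_
    })
    if (is.na(n)) next
    lens[i] <- n
    if (n < 150L) {
      excl[[length(excl) + 1L]] <- data.frame(file = paths[i],
                                              reason = "length < 150")
    } else if (n %% 3L != 0L) {
      excl[[length(excl) + 1L]] <- data.frame(file = paths[i],
                                              reason = "not divisible by 3")
    } else ok[i] <- TRUE
  }
  retained <- character(0)
  for (id in unique(ids[ok])) {
    cand <- which(ok & ids == id)
    best <- cand[which.max(lens[cand])]
    if (length(cand) > 1L) {
      for (j in setdiff(cand, best))
        excl[[length(excl) + 1L]] <-
          data.frame(file = paths[j], reason = "shorter transcript of same gene")
    }
    retained[id] <- paths[best]
  }
  list(retained = retained,
       excluded = if (length(excl)) do.call(rbind, excl) else
         data.frame(file = character(0), reason = character(0)))
}

#' Adjust p-values for multiple testing
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"benjamini_hochberg"`.
#' @return Adjusted p-values, order preserved.
#' @export
adjust_pvalues <- function(p, method = c("benjamini_hochberg", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = if (method == "bonferroni") "bonferroni" else "BH")
}

#' Configure a study run
#'
#' Validates paths and collects every tunable of [run_study()].
#'
#' @param study_dir Directory produced by [generate_toy_study()] (or laid
#'   out the same way: `genes/*.fasta`, `species_tree.nwk`,
#'   `manifest.json` with the focal groups).
#' @param out_dir Output directory.
#' @param seed Mandatory seed controlling the simulation null and every
#'   derived per-gene seed.
#' @param groups Focal groups; default read from the study manifest.
#' @param alpha Significance level used throughout.
#' @param aggregation Convergence-call aggregation (`"any"`, `"all"`,
#'   `"mean"`).
#' @param mt_method Multiple-testing method for adjusted columns.
#' @param n_hypotheses Optional cap on the number of alternative
#'   topologies (the first n of the enumeration).
#' @param topology_dir Optional directory of user-supplied alternative
#'   topologies (Newick, one per file), overriding the generated set.
#' @param null_templates,null_replicates Size of the simulation null
#'   (templates x replicates values per hypothesis).
#' @param aa_model_name,gamma_k Amino-acid model for the convergence and
#'   reconstruction stages.
#' @param stages Named logical toggles: `convergence`, `asr`, `branch`,
#'   `branch_site`, `sites`, `link`.
#' @return A validated `study_config`.
#' @export
study_config <- function(study_dir, out_dir, seed, groups = NULL,
                         alpha = 0.05, aggregation = "any",
                         mt_method = "benjamini_hochberg",
                         n_hypotheses = NULL, topology_dir = NULL,
                         null_templates = 5L, null_replicates = 10L,
                         aa_model_name = "JTT", gamma_k = 4L,
                         stages = list()) {
  if (missing(seed)) stop("a seed is required")
  if (!dir.exists(study_dir)) stop("no such study directory: ", study_dir)
  if (!file.exists(file.path(study_dir, "species_tree.nwk")))
    stop("study directory lacks species_tree.nwk")
  if (!dir.exists(file.path(study_dir, "genes")))
    stop("study directory lacks genes/")
  if (!is.null(topology_dir) && !dir.exists(topology_dir))
    stop("no such topology directory: ", topology_dir)
  if (is.null(groups)) {
    mf <- file.path(study_dir, "manifest.json")
    if (!file.exists(mf))
      stop("no manifest.json in study directory; pass 'groups'")
    groups <- lapply(jsonlite::read_json(mf)$groups, unlist)
  }
  st <- list(convergence = TRUE, asr = TRUE, branch = TRUE,
             branch_site = TRUE, sites = TRUE, link = TRUE)
  st[names(stages)] <- stages
  structure(list(study_dir = study_dir, out_dir = out_dir,
                 seed = as.integer(seed), groups = groups, alpha = alpha,
                 aggregation = aggregation, mt_method = mt_method,
                 n_hypotheses = n_hypotheses, topology_dir = topology_dir,
                 null_templates = as.integer(null_templates),
                 null_replicates = as.integer(null_replicates),
                 aa_model_name = aa_model_name, gamma_k = as.integer(gamma_k),
                 stages = st),
            class = "study_config")
}

gene_seed <- function(seed, i) {
  as.integer((as.numeric(seed %% 100003L) * 10007 + i * 7919) %% 2147483629) + 1L
}

# One gene through every enabled stage; returns a JSON-serializable list.
run_gene <- function(gene, path, tree, hyps, config) {
  aln <- read_alignment(path, alphabet = "codon")
  aa <- translate_alignment(aln)
  res <- list(gene = gene, n_codons = aln$L, n_taxa = nrow(aln$x))
  st <- config$stages
  model <- aa_model(config$aa_model_name, alpha = 1, k = config$gamma_k)
  h0_fit <- NULL
  if (st$convergence || st$asr) {
    h0_fit <- optimize_likelihood(tree, aa, model, tol = 1e-4)
    res$h0_lnl <- h0_fit$logLik
    res$h0_alpha <- h0_fit$model$alpha
    res$h0_tree <- write_tree(h0_fit$tree)
  }
  if (st$convergence) {
    scans <- lapply(hyps, function(h)
      compute_delta_ssls(aa, h, h0_fit$model, h0_fit = h0_fit, tol = 1e-4))
    res$mean_dssls <- lapply(stats::setNames(scans, vapply(hyps, `[[`,
                                                           character(1), "id")),
                             `[[`, "mean")
    site_mat <- vapply(scans, `[[`, numeric(aa$L), "per_site")
    res$site_mean_dssls <- rowMeans(matrix(site_mat, nrow = aa$L))
  }
  if (st$asr) {
    asr <- marginal_ancestral_reconstruction(fit = h0_fit, alignment = aa,
                                             model = h0_fit$model)
    cfg <- focal_group_config(h0_fit$tree, config$groups)
    par_calls <- call_parallel_substitutions(asr, cfg)
    uni_calls <- call_unique_substitutions(asr, cfg)
    res$n_parallel <- nrow(par_calls)
    res$n_parallel_unique <- sum(par_calls$unique)
    res$n_unique <- nrow(uni_calls)
    res$parallel_sites <- par_calls$site
    res$asr_skipped_heterogeneous <- attr(par_calls, "skipped_heterogeneous")
  }
  m0 <- NULL
  if (st$branch || st$branch_site || st$sites) {
    m0 <- fit_codon_m0(tree, aln)
    res$m0_omega <- m0$params$omega
    res$m0_kappa <- m0$params$kappa
  }
  if (st$branch) {
    bm <- fit_branch_model(tree, aln, config$groups, alpha = config$alpha,
                           m0 = m0)
    res$omega_fg <- bm$omega_fg
    res$omega_bg <- bm$omega_bg
    res$delta_omega <- bm$delta_omega
    res$branch_p <- bm$lrt$p
    res$rapid <- bm$rapid
    res$branch_flags <- bm$flags
  }
  if (st$branch_site) {
    res$psg <- lapply(config$groups, function(g) {
      bs <- fit_branch_site_model(tree, aln, g, alpha = config$alpha, m0 = m0)
      list(p = bs$lrt$p, psg = bs$psg, omega2 = bs$omega2)
    })
  }
  if (st$sites) {
    m78 <- fit_sites_m7_m8(tree, aln, alpha = config$alpha, m0 = m0)
    res$m8_p <- if (is.null(m78$lrt)) NA else m78$lrt$p
    res$m8_favored <- m78$favored
    res$site_omega <- m78$site_omega
    cmcf <- fit_clade_model_c(tree, aln, config$groups, alpha = config$alpha,
                              m0 = m0)
    res$cmc_p <- cmcf$lrt$p
    res$cmc_omega2_fg <- cmcf$omega2_fg
    res$cmc_omega2_bg <- cmcf$omega2_bg
    res$site_category <- cmcf$site_category
  }
  res
}

#' Run a complete study
#'
#' Executes every enabled stage for every retained gene, with per-gene
#' JSON checkpoints under `out_dir/checkpoints/` (a rerun skips finished
#' genes and produces identical reports for the same seed), then builds
#' the simulation null, assigns empirical P values, calls convergent and
#' rapidly evolving genes, intersects them into the candidate set, fits
#' the locus-wise regressions, and writes the report tables.
#'
#' @param config A [study_config()].
#' @return Invisibly, a list with the main tables (`gene_report`,
#'   `convergence`, `cohort`, `regressions`).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ckdir <- file.path(out, "checkpoints")
  dir.create(ckdir, showWarnings = FALSE)
  tree <- read_tree(file = file.path(config$study_dir, "species_tree.nwk"))
  flt <- filter_genes(sort(list.files(file.path(config$study_dir, "genes"),
                                      pattern = "\\.(fa|fasta|fas)$",
                                      full.names = TRUE)))
  genes <- names(flt$retained)
  utils::write.table(flt$excluded, file.path(out, "excluded_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hyps <- load_hypotheses(tree, config)
  hyp_ids <- vapply(hyps, `[[`, character(1), "id")

  t_start <- proc.time()[["elapsed"]]
  for (i in seq_along(genes)) {
    ck <- file.path(ckdir, paste0(genes[i], ".json"))
    if (file.exists(ck)) next
    set.seed(gene_seed(config$seed, i))
    t0 <- proc.time()[["elapsed"]]
    res <- run_gene(genes[i], flt$retained[[i]], tree, hyps, config)
    res$stage_seconds <- round(proc.time()[["elapsed"]] - t0, 3)
    jsonlite::write_json(res, ck, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  results <- lapply(genes, function(g)
    jsonlite::read_json(file.path(ckdir, paste0(g, ".json")),
                        simplifyVector = TRUE))
  names(results) <- genes

  conv <- build_convergence_table(results, hyp_ids, hyps, tree, config)
  report <- build_gene_report(results, conv$calls, config)
  reg <- build_link_tables(results, config)
  cohort <- build_cohort_summary(report, reg, config)

  wt <- function(d, f) utils::write.table(d, file.path(out, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(report, "gene_report.tsv")
  if (!is.null(conv$table)) {
    wt(conv$table, "convergence_by_hypothesis.tsv")
    nulls <- do.call(cbind, conv$null$values)
    wt(as.data.frame(nulls), "null_distribution.tsv")
  }
  if (!is.null(reg)) {
    wt(reg$join, "site_metrics.tsv")
    wt(reg$fit$loci, "locus_regressions.tsv")
    wt(reg$fit$summary, "regression_summary.tsv")
  }
  wt(cohort, "cohort_summary.tsv")
  manifest <- list(seed = config$seed,
                   config_hash = config_hash(config),
                   n_genes = length(genes),
                   hypotheses = hyp_ids,
                   aggregation = config$aggregation,
                   alpha = config$alpha,
                   mt_method = config$mt_method,
                   elapsed_seconds = round(proc.time()[["elapsed"]] - t_start, 1),
                   package_version =
                     as.character(utils::packageVersion("phyloconverge")))
  jsonlite::write_json(manifest[-match("elapsed_seconds", names(manifest))],
                       file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(gene_report = report, convergence = conv$table,
                 cohort = cohort, regressions = reg))
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

load_hypotheses <- function(tree, config) {
  if (!is.null(config$topology_dir)) {
    files <- sort(list.files(config$topology_dir, pattern = "\\.nwk$|\\.tre$",
                             full.names = TRUE))
    if (!length(files)) stop("topology_dir contains no Newick files")
    hyps <- lapply(seq_along(files), function(i) {
      ha <- read_tree(file = files[i])
      structure(list(id = sprintf("U%02d", i), h0 = tree, ha = ha,
                     focal = unlist(config$groups, use.names = FALSE),
                     resolution = "user", attachment = basename(files[i])),
                class = "convergence_hypothesis")
    })
  } else {
    hyps <- generate_alternative_topologies(tree, config$groups)
  }
  if (!is.null(config$n_hypotheses))
    hyps <- hyps[seq_len(min(config$n_hypotheses, length(hyps)))]
  hyps
}

build_convergence_table <- function(results, hyp_ids, hyps, tree, config) {
  if (!config$stages$convergence)
    return(list(table = NULL, calls = NULL, null = NULL))
  genes <- names(results)
  # simulation null from the first template genes' fitted H0 models
  tpl_idx <- seq_len(min(config$null_templates, length(genes)))
  templates <- lapply(genes[tpl_idx], function(g) {
    r <- results[[g]]
    m <- aa_model(config$aa_model_name, alpha = r$h0_alpha,
                  k = config$gamma_k)
    ftree <- read_tree(r$h0_tree)
    structure(list(tree = ftree, model = m, n_sites = r$n_codons),
              class = "phylo_fit")
  })
  null <- simulate_null_distribution(templates, hyps,
                                     R = config$null_replicates,
                                     seed = config$seed + 1L)
  rows <- list()
  for (g in genes) {
    md <- unlist(results[[g]]$mean_dssls)
    for (h in hyp_ids) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, hypothesis = h, mean_dssls = md[[h]],
        p = empirical_p(md[[h]], null, hypothesis = h))
    }
  }
  tab <- do.call(rbind, rows)
  calls <- call_convergent_genes(tab, alpha = config$alpha,
                                 aggregation = config$aggregation)
  list(table = tab, calls = calls, null = null)
}

na_or <- function(x, default = NA) if (is.null(x)) default else x

build_gene_report <- function(results, calls, config) {
  genes <- names(results)
  grp_names <- names(config$groups)
  rows <- lapply(genes, function(g) {
    r <- results[[g]]
    row <- data.frame(gene = g, n_codons = r$n_codons,
                      mean_dssls = if (!is.null(r$mean_dssls))
                        mean(unlist(r$mean_dssls)) else NA,
                      convergent = NA,
                      omega_fg = na_or(r$omega_fg), omega_bg = na_or(r$omega_bg),
                      delta_omega = na_or(r$delta_omega),
                      branch_p = na_or(r$branch_p), rapid = na_or(r$rapid),
                      n_parallel = na_or(r$n_parallel),
                      n_parallel_unique = na_or(r$n_parallel_unique),
                      n_unique = na_or(r$n_unique),
                      m8_p = na_or(r$m8_p), m8_favored = na_or(r$m8_favored),
                      cmc_p = na_or(r$cmc_p))
    for (gn in grp_names) {
      row[[paste0("psg_", gn)]] <- if (!is.null(r$psg)) r$psg[[gn]]$psg else NA
      row[[paste0("psg_p_", gn)]] <- if (!is.null(r$psg)) r$psg[[gn]]$p else NA
    }
    row
  })
  report <- do.call(rbind, rows)
  if (!is.null(calls))
    report$convergent <- calls$call[match(report$gene, calls$gene)]
  report$branch_p_bh <- adjust_pvalues(report$branch_p, "benjamini_hochberg")
  report$branch_p_bonferroni <- adjust_pvalues(report$branch_p, "bonferroni")
  report$candidate <- ifelse(is.na(report$rapid) | is.na(report$convergent),
                             NA, report$rapid & report$convergent)
  report
}

build_link_tables <- function(results, config) {
  if (!config$stages$link || !config$stages$convergence ||
      !config$stages$sites) return(NULL)
  genes <- names(results)
  ssls <- list(); m8 <- list(); cmc <- list()
  for (g in genes) {
    r <- results[[g]]
    if (!is.null(r$site_mean_dssls))
      ssls[[g]] <- data.frame(gene = g, site = seq_along(r$site_mean_dssls),
                              dssls = r$site_mean_dssls)
    if (isTRUE(r$m8_favored) && !is.null(r$site_omega))
      m8[[g]] <- data.frame(gene = g, site = seq_along(r$site_omega),
                            omega = r$site_omega)
    if (!is.null(r$site_category))
      cmc[[g]] <- data.frame(gene = g, site = seq_along(r$site_category),
                             category = r$site_category)
  }
  if (!length(m8)) return(NULL)
  join <- join_site_metrics(do.call(rbind, ssls), do.call(rbind, m8),
                            do.call(rbind, cmc))
  list(join = join, fit = fit_locus_regressions(join, alpha = config$alpha))
}

frac <- function(num, den) if (den > 0) num / den else NA_real_

build_cohort_summary <- function(report, reg, config) {
  rows <- list()
  add <- function(metric, value, denom = NA)
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric, value = value,
                                             denominator = denom)
  n <- nrow(report)
  add("n_genes", n)
  if (config$stages$branch) {
    tested <- sum(!is.na(report$rapid))
    add("n_rapid", sum(report$rapid, na.rm = TRUE), tested)
    add("frac_rapid", frac(sum(report$rapid, na.rm = TRUE), tested), tested)
    rapid_fg1 <- sum(report$rapid & report$omega_fg > 1, na.rm = TRUE)
    add("frac_rapid_omega_fg_gt1",
        frac(rapid_fg1, sum(report$rapid, na.rm = TRUE)),
        sum(report$rapid, na.rm = TRUE))
  }
  if (config$stages$convergence) {
    add("n_convergent", sum(report$convergent, na.rm = TRUE), n)
    add("frac_convergent", frac(sum(report$convergent, na.rm = TRUE), n), n)
  }
  if (config$stages$branch && config$stages$convergence) {
    add("n_candidate", sum(report$candidate, na.rm = TRUE), n)
  }
  if (config$stages$asr) {
    has_par <- report$n_parallel > 0
    add("frac_genes_with_parallel", frac(sum(has_par, na.rm = TRUE), n), n)
    if (config$stages$branch) {
      nr <- sum(report$rapid, na.rm = TRUE)
      add("frac_rapid_with_parallel",
          frac(sum(has_par & report$rapid, na.rm = TRUE), nr), nr)
    }
    if (config$stages$convergence) {
      nc <- sum(report$convergent, na.rm = TRUE)
      add("frac_convergent_with_parallel",
          frac(sum(has_par & report$convergent, na.rm = TRUE), nc), nc)
    }
    if (config$stages$branch && config$stages$convergence) {
      ncand <- sum(report$candidate, na.rm = TRUE)
      add("frac_candidate_with_parallel",
          frac(sum(has_par & report$candidate, na.rm = TRUE), ncand), ncand)
    }
  }
  if (config$stages$branch_site) {
    psg_cols <- paste0("psg_", names(config$groups))
    psg_any <- Reduce(`|`, lapply(psg_cols, function(cn) report[[cn]]))
    add("frac_psg_any_lineage", frac(sum(psg_any, na.rm = TRUE), n), n)
    if (config$stages$branch) {
      nr <- sum(report$rapid, na.rm = TRUE)
      add("frac_rapid_psg_any",
          frac(sum(psg_any & report$rapid, na.rm = TRUE), nr), nr)
    }
  }
  if (!is.null(reg)) {
    for (i in seq_len(nrow(reg$fit$summary))) {
      s <- reg$fit$summary[i, ]
      add(sprintf("regression_frac_negative_cat%s", s$category),
          s$frac_negative, s$n_loci)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
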