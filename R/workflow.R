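# Workflow layer: orchestrates the full study sequence (pairwise
# correlations -> path analysis -> transition rates -> ancestral
# reconstruction -> sensitivity variants) on a species table and tree(s).

#' Pairwise phylogenetic correlations
#'
#' Fits the six pairwise BPMMs between number of worker castes, colony size,
#' mating frequency and queen number (castes modelled as Poisson counts with
#' a log link, the log10 continuous traits as Gaussian), plus the worker-CV
#' models when CV data exist. With a `multiPhylo` the chains are fitted per
#' tree and pooled before estimation.
#'
#' @param data species table (from [build_species_table()] or
#'   [generate_species_table()]).
#' @param trees `phylo` or `multiPhylo`.
#' @param n_iter,burn,thin chain settings per tree.
#' @return data frame: response, predictor, family, n, slope mode, 95% CI,
#'   significance (CI excluding 0), marginal R2 (Gaussian only).
#' @export
run_correlations <- function(data, trees, n_iter = 4000, burn = 1000, thin = 3) {
  models <- list(
    list(y = "castes", x = "log10_colony_size", family = "poisson_log"),
    list(y = "castes", x = "log10_mating_frequency", family = "poisson_log"),
    list(y = "castes", x = "log10_queen_number", family = "poisson_log"),
    list(y = "log10_mating_frequency", x = "log10_queen_number", family = "gaussian"),
    list(y = "log10_colony_size", x = "log10_mating_frequency", family = "gaussian"),
    list(y = "log10_colony_size", x = "log10_queen_number", family = "gaussian"))
  if (!is.null(data$sqrt_worker_cv) && any(!is.na(data$sqrt_worker_cv)))
    models <- c(models, list(
      list(y = "sqrt_worker_cv", x = "log10_colony_size", family = "gaussian"),
      list(y = "sqrt_worker_cv", x = "log10_mating_frequency", family = "gaussian")))
  rows <- lapply(models, function(mdl) {
    miss <- setdiff(c(mdl$y, mdl$x), names(data))
    if (length(miss) > 0)
      return(data.frame(response = mdl$y, predictor = mdl$x,
                        family = mdl$family, n = NA, mode = NA, lower = NA,
                        upper = NA, significant = NA, r2_median = NA,
                        note = paste("missing columns:", paste(miss, collapse = ","))))
    d <- complete_cases_for(data, c("species", mdl$y, mdl$x))
    ch <- fit_pooled(d, mdl, trees, n_iter, burn, thin)
    s <- posterior_mode_ci(ch$beta[, 2])
    r2 <- if (mdl$family == "gaussian") marginal_r2(ch)$median else NA_real_
    data.frame(response = mdl$y, predictor = mdl$x, family = mdl$family,
               n = nrow(d), mode = s$mode, lower = s$lower, upper = s$upper,
               significant = s$lower > 0 | s$upper < 0, r2_median = r2,
               note = "")
  })
  do.call(rbind, rows)
}

fit_pooled <- function(d, mdl, trees, n_iter, burn, thin) {
  tr_list <- if (inherits(trees, "multiPhylo")) trees else list(trees)
  X <- cbind(`(Intercept)` = 1, slope = d[[mdl$x]])
  colnames(X)[2] <- mdl$x
  y <- d[[mdl$y]]
  chains <- lapply(tr_list, function(tr) {
    trp <- prune_to_taxa(tr, d$species)
    dd <- d[match(normalize_species_names(trp$tip.label),
                  normalize_species_names(d$species)), , drop = FALSE]
    Xp <- X[match(dd$species, d$species), , drop = FALSE]
    fit_bpmm(dd[[mdl$y]], Xp, dd$species, trp, family = mdl$family,
             n_iter = n_iter, burn = burn, thin = thin)
  })
  if (length(chains) == 1) chains[[1]] else pool_across_trees(chains)
}

#' The three causal analyses and their agreement
#'
#' Runs phylogenetic path analysis (binary castes response), the
#' transition-rate analysis (binarized colony size x castes: stepping-stone
#' Bayes factor plus RJ-MCMC zero-rate proportions on the 0.001-rescaled
#' tree), and hidden-rate-model ancestral reconstruction with the
#' ancestral-value regression on log10 colony size. Reports, per method,
#' whether the colony-size -> castes direction is supported.
#'
#' @param data species table.
#' @param tree a `phylo` (consensus-tree style input).
#' @param stones,ss_iter stepping-stone settings.
#' @param rj_iter,rj_burn,rj_thin RJ-MCMC settings.
#' @param asr_iter ancestral-regression chain length.
#' @param branch_scale branch-length rescaling applied before the
#'   transition-rate stage. The 0.001 default suits absolute-time (Myr)
#'   trees, bringing rates into the range the uniform(0, 100) hyper-prior
#'   covers; for trees already near unit height use 1.
#' @return list with `path`, `transition`, `asr` result objects and
#'   `support` (logical per method) with an agreement summary.
#' @export
run_causality <- function(data, tree, stones = 16, ss_iter = 100,
                          rj_iter = 4000, rj_burn = 1000, rj_thin = 3,
                          asr_iter = 6000, branch_scale = 0.001) {
  # (1) path analysis
  path <- run_candidate_set(data, tree, response_mode = "castes_binary")
  top <- path$ranking$model[1]
  path_support <- top %in% c("model1", "model3")

  # (2) transition rates on the binarized traits
  d <- complete_cases_for(data, c("species", "colony_size", "castes_binary"))
  d <- binarize_traits(d, colony_rule = "median")
  tr <- prune_to_taxa(tree, d$species)
  d <- d[match(normalize_species_names(tr$tip.label),
               normalize_species_names(d$species)), , drop = FALSE]
  tr_scaled <- scale_branches(tr, branch_scale)
  ts <- data.frame(species = d$species,
                   trait1 = as.integer(d$colony_size_class == "large"),
                   trait2 = as.integer(d$castes_binary == "multiple"))
  ml_dep <- stepping_stone_logml(tr_scaled, ts, "dependent",
                                 n_stones = stones, n_iter = ss_iter)
  ml_ind <- stepping_stone_logml(tr_scaled, ts, "independent",
                                 n_stones = stones, n_iter = ss_iter)
  bf <- bayes_factor(ml_dep$log_ml, ml_ind$log_ml)
  rj <- rjmcmc_sample(tr_scaled, ts, "dependent", n_iter = rj_iter,
                      burn = rj_burn, thin = rj_thin)
  zr_small_gain <- zero_rate_proportion(rj, "q12")
  transition <- list(bf = bf$bf, evidence = bf$evidence,
                     log_ml_dependent = ml_dep$log_ml,
                     log_ml_independent = ml_ind$log_ml,
                     zero_rate_small_gain = zr_small_gain,
                     rate_summary = apply(rj$rates, 2, mean), n = nrow(d))
  trans_support <- bf$bf > 2 && zr_small_gain > 0.5

  # (3) ancestral state reconstruction
  st <- data.frame(species = d$species,
                   state = ifelse(d$castes_binary == "multiple", 2L, 1L))
  hrm <- hrm_fit(tr, st, n_obs = 2, n_rate_classes = 2,
                 structure = "equal_rates")
  marg <- marginal_states(hrm, tr, st)
  cls <- classify_nodes(marg, tr, st)
  anc <- ancestral_value_regression(
    tr, data.frame(species = d$species, value = d$log10_colony_size),
    cls, n_iter = asr_iter)
  m1 <- anc$means$mode[anc$means$category == 1]
  m2 <- anc$means$mode[anc$means$category == 2]
  asr_support <- length(m1) == 1 && length(m2) == 1 && m2 > m1 &&
    !is.na(anc$pmcmc_1_vs_2) && anc$pmcmc_1_vs_2 < 0.05
  support <- c(path_analysis = path_support, transition_rates = trans_support,
               ancestral_reconstruction = asr_support)
  list(path = path, transition = transition,
       asr = list(hrm = hrm, classification = cls, regression = anc,
                  n_origins = cls$n_origins),
       support = support, n_methods_agreeing = sum(support))
}

#' Sensitivity variants
#'
#' Re-runs the transition-rate comparison under the median, 40th- and
#' 60th-quantile colony-size thresholds, and the caste-count BPMM under the
#' obligate-binary recodings of mating and queen categories. Each variant
#' appears exactly once in the returned table.
#'
#' @param data species table.
#' @param tree a `phylo`.
#' @param stones,ss_iter stepping-stone settings per variant.
#' @param n_iter,burn,thin BPMM settings for the recoding variants.
#' @param branch_scale branch rescaling before the transition-rate variants
#'   (see [run_causality()]).
#' @return data frame with one row per variant: variant id, statistic type,
#'   value, and the conclusion it supports.
#' @export
run_sensitivity <- function(data, tree, stones = 16, ss_iter = 80,
                            n_iter = 3000, burn = 500, thin = 2,
                            branch_scale = 0.001) {
  rows <- list()
  d0 <- complete_cases_for(data, c("species", "colony_size", "castes_binary"))
  for (rule in c("median", "q40", "q60")) {
    d <- binarize_traits(d0, colony_rule = rule)
    tr <- prune_to_taxa(tree, d$species)
    d <- d[match(normalize_species_names(tr$tip.label),
                 normalize_species_names(d$species)), , drop = FALSE]
    trs <- scale_branches(tr, branch_scale)
    ts <- data.frame(species = d$species,
                     trait1 = as.integer(d$colony_size_class == "large"),
                     trait2 = as.integer(d$castes_binary == "multiple"))
    bf <- bayes_factor(
      stepping_stone_logml(trs, ts, "dependent", n_stones = stones,
                           n_iter = ss_iter)$log_ml,
      stepping_stone_logml(trs, ts, "independent", n_stones = stones,
                           n_iter = ss_iter)$log_ml)
    rows[[length(rows) + 1L]] <-
      data.frame(variant = paste0("colony_threshold_", rule),
                 statistic = "bayes_factor", value = bf$bf,
                 conclusion = bf$evidence)
  }
  for (v in c("mating_category", "queen_category")) {
    if (is.null(data[[v]])) next
    rec <- collapse_categories(data[[v]], "obligate_binary")
    if (!any(rec == "obligate", na.rm = TRUE)) {
      warning("no obligate species for ", v, "; variant skipped")
      rows[[length(rows) + 1L]] <-
        data.frame(variant = paste0("obligate_binary_", v),
                   statistic = "skipped", value = NA_real_,
                   conclusion = "no obligate species")
      next
    }
    d <- data[!is.na(rec) & !is.na(data$castes), , drop = FALSE]
    x <- as.integer(collapse_categories(d[[v]], "obligate_binary") == "obligate")
    tr <- prune_to_taxa(tree, d$species)
    d2 <- d[match(normalize_species_names(tr$tip.label),
                  normalize_species_names(d$species)), , drop = FALSE]
    x2 <- x[match(d2$species, d$species)]
    ch <- fit_bpmm(d2$castes, cbind(1, obligate = x2), d2$species, tr,
                   family = "poisson_log", n_iter = n_iter, burn = burn,
                   thin = thin)
    s <- posterior_mode_ci(ch$beta[, 2])
    rows[[length(rows) + 1L]] <-
      data.frame(variant = paste0("obligate_binary_", v),
                 statistic = "slope_mode", value = s$mode,
                 conclusion = if (s$lower > 0 | s$upper < 0)
                   "significant" else "not significant")
  }
  do.call(rbind, rows)
}
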