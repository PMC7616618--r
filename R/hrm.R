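# Hidden rate models: the observed character (e.g. single vs multiple worker
# castes) evolves under a Markov process whose rates switch among latent rate
# classes along the tree. Expanded state index = (class - 1) * n_obs + obs.

hrm_param_count <- function(n_obs, n_classes, structure) {
  per_class <- switch(structure,
                      equal_rates = 1L,
                      symmetric = as.integer(n_obs * (n_obs - 1) / 2),
                      all_rates_different = as.integer(n_obs * (n_obs - 1)))
  as.integer(n_classes * per_class + (n_classes > 1))
}

# Build the expanded generator from a parameter vector: per-class observed
# transition rates (structure-dependent) followed by a single class-switch
# rate shared by all class pairs (observed state preserved).
hrm_build_q <- function(par, n_obs, n_classes, structure) {
  k <- n_obs * n_classes
  Q <- matrix(0, k, k)
  per_class <- switch(structure,
                      equal_rates = 1L,
                      symmetric = n_obs * (n_obs - 1) / 2,
                      all_rates_different = n_obs * (n_obs - 1))
  pos <- 0L
  for (cl in seq_len(n_classes)) {
    rates <- par[pos + seq_len(per_class)]
    pos <- pos + per_class
    off <- (cl - 1) * n_obs
    idx <- 0L
    for (i in seq_len(n_obs)) for (j in seq_len(n_obs)) {
      if (i == j) next
      r <- switch(structure,
                  equal_rates = rates[1],
                  symmetric = {
                    a <- min(i, j); b <- max(i, j)
                    rates[(a - 1) * n_obs - a * (a - 1) / 2 + (b - a)]
                  },
                  all_rates_different = { idx <- idx + 1L; rates[idx] })
      Q[off + i, off + j] <- r
    }
  }
  if (n_classes > 1) {
    eta <- par[pos + 1L]
    for (cl1 in seq_len(n_classes)) for (cl2 in seq_len(n_classes)) {
      if (cl1 == cl2) next
      for (i in seq_len(n_obs))
        Q[(cl1 - 1) * n_obs + i, (cl2 - 1) * n_obs + i] <- eta
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

hrm_tip_likelihoods <- function(tree, states, n_obs, n_classes) {
  key <- normalize_species_names(states$species)
  idx <- match(normalize_species_names(tree$tip.label), key)
  if (any(is.na(idx))) stop("tips without state data")
  s <- states$state[idx]
  if (any(!is.na(s) & !(s %in% seq_len(n_obs)))) stop("states must be in 1..n_obs")
  L <- matrix(0, length(s), n_obs * n_classes)
  for (i in seq_along(s)) {
    if (is.na(s[i])) L[i, ] <- 1
    else for (cl in seq_len(n_classes)) L[i, (cl - 1) * n_obs + s[i]] <- 1
  }
  L
}

#' Fit a hidden rate model by maximum likelihood
#'
#' Multi-start optimization of the expanded-state pruning likelihood. With
#' one rate class the model reduces exactly to the standard Markov model on
#' the observed states. AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1) with n the
#' number of tips.
#'
#' @param tree rooted `phylo`.
#' @param states data frame with `species` and `state` (integers 1..n_obs,
#'   NA allowed).
#' @param n_obs number of observed states (2 for single/multiple castes; 4
#'   for caste counts).
#' @param n_rate_classes 1, 2 or 3 latent rate classes.
#' @param structure `"equal_rates"`, `"symmetric"` or
#'   `"all_rates_different"` for the observed transitions within each class.
#' @param n_starts random restarts.
#' @return object of class `hrm_model` with `Q`, `par`, `loglik`, `k`,
#'   `aicc`, `converged` and the model description.
#' @export
hrm_fit <- function(tree, states, n_obs = 2, n_rate_classes = 1,
                    structure = c("equal_rates", "symmetric",
                                  "all_rates_different"),
                    n_starts = 3) {
  structure <- match.arg(structure)
  npar <- hrm_param_count(n_obs, n_rate_classes, structure)
  tipL <- hrm_tip_likelihoods(tree, states, n_obs, n_rate_classes)
  pt <- ape::reorder.phylo(tree, "postorder")
  k_states <- n_obs * n_rate_classes
  pr <- rep(1 / k_states, k_states)
  nll <- function(logp) {
    p <- exp(logp)
    if (any(!is.finite(p)) || any(p > 1e4)) return(1e10)
    Q <- hrm_build_q(p, n_obs, n_rate_classes, structure)
    ll <- cpp_ctmc_loglik(pt$edge, pt$edge.length, Q, tipL, pr, pt$Nnode)
    if (!is.finite(ll)) 1e10 else -ll
  }
  td <- sum(pt$edge.length)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- log(rexp(npar, rate = td / (2 * length(pt$tip.label))) + 1e-4)
    fit <- tryCatch(
      if (npar == 1)
        optim(start, nll, method = "Brent", lower = log(1e-8),
              upper = log(1e4))
      else
        optim(start, nll, method = "Nelder-Mead",
              control = list(maxit = 3000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("HRM optimization failed")
  par <- exp(best$par)
  n <- ape::Ntip(tree)
  k <- npar
  ll <- -best$value
  aicc <- -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  out <- list(Q = hrm_build_q(par, n_obs, n_rate_classes, structure),
              par = par, loglik = ll, k = k, aicc = aicc,
              n_obs = n_obs, n_rate_classes = n_rate_classes,
              model_structure = structure,
              converged = best$convergence == 0)
  class(out) <- "hrm_model"
  out
}

#' AICc
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @param n sample size (tips).
#' @export
aicc <- function(loglik, k, n) {
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Select the best hidden rate model across a tree sample
#'
#' Fits every candidate (rate classes x structure) on every tree; the winner
#' is the candidate with the lowest AICc on the largest fraction of trees
#' (ties broken toward fewer parameters).
#'
#' @param trees `multiPhylo` (or single `phylo`).
#' @param states as in [hrm_fit()].
#' @param n_obs observed state count.
#' @param classes integer vector of rate-class counts to try.
#' @param structures character vector of structures to try.
#' @return list with `winner` (name), `win_fraction`, `table` (per-tree AICc
#'   matrix), `fits` (fits of the winner per tree).
#' @export
select_hrm <- function(trees, states, n_obs = 2, classes = 1:2,
                       structures = c("equal_rates", "all_rates_different")) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  cand <- expand.grid(classes = classes, structure = structures,
                      stringsAsFactors = FALSE)
  cand$name <- paste0(cand$structure, "_", cand$classes, "class")
  aics <- matrix(NA_real_, length(trees), nrow(cand),
                 dimnames = list(NULL, cand$name))
  fits <- vector("list", length(trees))
  for (t in seq_along(trees)) {
    fits[[t]] <- lapply(seq_len(nrow(cand)), function(i)
      hrm_fit(trees[[t]], states, n_obs, cand$classes[i], cand$structure[i]))
    aics[t, ] <- vapply(fits[[t]], `[[`, numeric(1), "aicc")
  }
  kpar <- vapply(seq_len(nrow(cand)), function(i)
    hrm_param_count(n_obs, cand$classes[i], cand$structure[i]), integer(1))
  wins <- apply(aics, 1, function(a) {
    best <- which(a <= min(a) + 1e-9)
    best[which.min(kpar[best])]
  })
  tab <- tabulate(wins, nbins = nrow(cand))
  wi <- which.max(tab)
  list(winner = cand$name[wi], win_fraction = tab[wi] / length(trees),
       table = aics,
       fits = lapply(seq_along(trees), function(t) fits[[t]][[wi]]))
}

#' Marginal ancestral state probabilities
#'
#' Per-node marginal probabilities of the observed states under a fitted
#' hidden rate model, combining up-pass and down-pass partial likelihoods
#' and marginalizing over the latent rate classes.
#'
#' @param model an `hrm_model`.
#' @param tree the tree used for fitting.
#' @param states tip states as in [hrm_fit()].
#' @return matrix ((ntips + nnodes) x n_obs) of marginal probabilities in
#'   postorder-stable ape numbering (tips first).
#' @export
marginal_states <- function(model, tree, states) {
  n_obs <- model$n_obs
  ncl <- model$n_rate_classes
  tipL <- hrm_tip_likelihoods(tree, states, n_obs, ncl)
  m <- ctmc_marginals_matrix(tree, model$Q, tipL, "uniform")
  obs <- matrix(0, nrow(m), n_obs)
  for (cl in seq_len(ncl))
    obs <- obs + m[, (cl - 1) * n_obs + seq_len(n_obs), drop = FALSE]
  obs
}

#' Classify nodes by own state and descendant states
#'
#' Binary observed character (1 = single caste, 2 = multiple castes).
#' Assigns each node its argmax marginal state (exact ties go to the
#' single-caste state, with a warning), then classifies every internal node:
#' category 1 = single, all descendants single; 2 = single, at least one
#' descendant multiple; 3 = multiple, all descendants multiple; 4 =
#' multiple, at least one descendant single. An origin is an edge whose
#' parent is single and child multiple.
#'
#' @param marginals matrix from [marginal_states()] (2 columns).
#' @param tree the tree.
#' @param states tip states (used for tip assignments where observed).
#' @return list with `assigned` (state 1/2 for all tips+nodes), `category`
#'   (per internal node), `n_origins`.
#' @export
classify_nodes <- function(marginals, tree, states) {
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  if (any(abs(marginals[, 1] - 0.5) < 1e-12))
    warning("marginal tie at 0.5 assigned to the single-caste state")
  assigned <- ifelse(marginals[, 2] > 0.5, 2L, 1L)
  key <- normalize_species_names(states$species)
  idx <- match(normalize_species_names(tree$tip.label), key)
  obs <- states$state[idx]
  assigned[seq_len(ntip)][!is.na(obs)] <- obs[!is.na(obs)]
  pt <- ape::reorder.phylo(tree, "postorder")
  any_single <- logical(ntot); any_multi <- logical(ntot)
  any_single[seq_len(ntip)] <- assigned[seq_len(ntip)] == 1L
  any_multi[seq_len(ntip)] <- assigned[seq_len(ntip)] == 2L
  for (e in seq_len(nrow(pt$edge))) {
    par <- pt$edge[e, 1]; chi <- pt$edge[e, 2]
    any_single[par] <- any_single[par] || any_single[chi] ||
      (chi > ntip && assigned[chi] == 1L)
    any_multi[par] <- any_multi[par] || any_multi[chi] ||
      (chi > ntip && assigned[chi] == 2L)
  }
  nodes <- (ntip + 1):ntot
  category <- integer(tree$Nnode)
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    if (assigned[v] == 1L) category[i] <- if (any_multi[v]) 2L else 1L
    else category[i] <- if (any_single[v]) 4L else 3L
  }
  n_origins <- sum(assigned[pt$edge[, 1]] == 1L & assigned[pt$edge[, 2]] == 2L)
  list(assigned = assigned, category = category, n_origins = n_origins)
}

#' Ancestral trait values at classified nodes
#'
#' Estimates the continuous trait (log10 colony size or mating frequency) at
#' ancestral nodes of each classification category. A Gaussian phylogenetic
#' mixed model (intercept + phylogenetic random effect + residual,
#' inverse-Wishart variance priors) is fitted to the tip values by Gibbs
#' sampling; at every retained iteration the ancestral field at the internal
#' nodes is drawn from its exact conditional distribution given the sampled
#' tip-level effects (node-inclusive phylogenetic covariance), and the mean
#' ancestral value of each node category is recorded. The category-1 vs
#' category-2 contrast (trait values in lineages that never produced
#' multiple castes vs values immediately before an origin) is summarized by
#' pMCMC over the paired draws.
#'
#' @param tree a `phylo`.
#' @param tip_values data frame `species`, `value` (analysis scale, e.g.
#'   log10).
#' @param classification result of [classify_nodes()].
#' @param n_iter,burn,thin chain settings.
#' @return list with `means` (per-category posterior mode + 95% HPD, plus
#'   back-transformed `mode_bt` = 10^mode), `pmcmc_1_vs_2`, `draws`
#'   (per-category mean ancestral values per iteration), `v_a`, `v_r`.
#' @export
ancestral_value_regression <- function(tree, tip_values, classification,
                                       n_iter = 6000, burn = 1000, thin = 5) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  ntot <- ntip + nnode
  key <- normalize_species_names(tip_values$species)
  idx <- match(normalize_species_names(tree$tip.label), key)
  y <- tip_values$value[idx]
  if (any(is.na(y))) {
    keep <- which(!is.na(y))
    if (length(keep) < 5) stop("too few tips with trait values")
  } else keep <- seq_len(ntip)
  node_cat <- classification$category
  levels_present <- sort(unique(node_cat))
  if (length(levels_present) < 1) stop("no classified nodes")

  Afull <- phylo_covariance(tree, include_internal_nodes = TRUE)
  tips <- keep
  nodes <- (ntip + 1):ntot
  Att <- Afull[tips, tips]
  Ant <- Afull[nodes, tips]
  Ann <- Afull[nodes, nodes]
  ridge <- 1e-8 * mean(diag(Att))
  Att_inv <- chol2inv(chol(Att + diag(ridge, length(tips))))
  K <- Ant %*% Att_inv
  Cn <- Ann - K %*% t(Ant)
  chCn <- chol(Cn + diag(1e-8 * mean(diag(Afull)), nnode))

  yk <- y[tips]
  n <- length(tips)
  W <- cbind(1, diag(n))
  WtW <- crossprod(W)
  b0 <- mean(yk); g <- rep(0, n)
  v_a <- stats::var(yk) / 2 + 1e-3
  v_r <- v_a

  n_keep <- floor((n_iter - burn) / thin)
  out_mu <- matrix(NA_real_, n_keep, length(levels_present),
                   dimnames = list(NULL, paste0("category", levels_present)))
  out_va <- numeric(n_keep); out_vr <- numeric(n_keep)
  kept <- 0L
  for (it in seq_len(n_iter)) {
    prec <- WtW / v_r
    prec[1, 1] <- prec[1, 1] + 1e-8
    prec[-1, -1] <- prec[-1, -1] + Att_inv / v_a
    rhs <- crossprod(W, yk) / v_r
    ch <- chol(prec)
    m0 <- backsolve(ch, forwardsolve(t(ch), rhs))
    draw <- m0 + backsolve(ch, rnorm(n + 1))
    b0 <- draw[1]; g <- draw[-1]
    qg <- drop(t(g) %*% Att_inv %*% g)
    v_a <- 1 / rgamma(1, (0.002 + n) / 2, rate = (0.002 + qg) / 2)
    e <- yk - b0 - g
    v_r <- 1 / rgamma(1, (0.002 + n) / 2, rate = (0.002 + sum(e^2)) / 2)
    if (it > burn && (it - burn) %% thin == 0 && kept < n_keep) {
      kept <- kept + 1L
      # ancestral field at the nodes, conditional on the tip-level draw
      v_node <- b0 + drop(K %*% g) +
        sqrt(v_a) * drop(crossprod(chCn, rnorm(nnode)))
      # per-draw intercept-free regression of node values on category:
      # category means carry the node-level scatter, so contrasts are
      # calibrated against between-node variation rather than the tight
      # conditional uncertainty of the realized field
      cat_means <- vapply(levels_present, function(cc)
        mean(v_node[node_cat == cc]), numeric(1))
      ss <- sum((v_node - cat_means[match(node_cat, levels_present)])^2)
      s2n <- 1 / rgamma(1, (0.002 + nnode) / 2, rate = (0.002 + ss) / 2)
      n_per <- vapply(levels_present, function(cc) sum(node_cat == cc),
                      numeric(1))
      out_mu[kept, ] <- rnorm(length(cat_means), cat_means,
                              sqrt(s2n / n_per))
      out_va[kept] <- v_a; out_vr[kept] <- v_r
    }
  }
  means <- do.call(rbind, lapply(seq_along(levels_present), function(j) {
    s <- posterior_mode_ci(out_mu[, j])
    data.frame(category = levels_present[j], mode = s$mode,
               lower = s$lower, upper = s$upper,
               mode_bt = 10^s$mode, lower_bt = 10^s$lower,
               upper_bt = 10^s$upper)
  }))
  pm <- NA_real_
  if (all(c(1, 2) %in% levels_present)) {
    pm <- pmcmc_compare(out_mu[, "category2"], out_mu[, "category1"])
  }
  list(means = means, pmcmc_1_vs_2 = pm, draws = out_mu,
       v_a = out_va, v_r = out_vr)
}
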