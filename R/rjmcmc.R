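# Rate priors: each transition rate is exponential with mean m, where the
# hyper-parameter m is itself uniform on (0, 100); the gamma variant keeps the
# same hyper-prior on the mean with shape 2.

rate_prior_logpdf <- function(r, m, prior = c("exp", "gamma")) {
  prior <- match.arg(prior)
  if (prior == "exp") sum(dexp(r, rate = 1 / m, log = TRUE))
  else sum(stats::dgamma(r, shape = 2, rate = 2 / m, log = TRUE))
}

rate_prior_draw <- function(n, m, prior = c("exp", "gamma")) {
  prior <- match.arg(prior)
  if (prior == "exp") rexp(n, rate = 1 / m)
  else rgamma(n, shape = 2, rate = 2 / m)
}

# Pre-processed likelihood closure for the pair model on a fixed tree or a
# tree sample (a tree index can be resampled each MCMC iteration).
make_pair_loglik <- function(tree, tip_states, kind, root_prior = "uniform") {
  trees <- if (inherits(tree, "multiPhylo")) tree else list(tree)
  pts <- lapply(trees, ape::reorder.phylo, order = "postorder")
  tipLs <- lapply(pts, pair_tip_likelihoods, tip_states = tip_states)
  function(rates, tree_index = 1L) {
    Q <- rate_model(kind, rates)$Q
    pt <- pts[[tree_index]]
    pr <- resolve_root_prior(root_prior, Q)
    cpp_ctmc_loglik(pt$edge, pt$edge.length, Q, tipLs[[tree_index]], pr, pt$Nnode)
  }
}

#' Reversible-jump MCMC over transition rates
#'
#' Samples the posterior of the pair-model transition rates with a
#' reversible-jump move that can set individual rates exactly to zero, so the
#' posterior probability that a transition does not occur is directly
#' estimable as the proportion of visited models with that rate at zero.
#' Rates carry an exponential (or gamma) prior whose mean is a uniform(0, 100)
#' hyper-parameter. When `tree` is a `multiPhylo`, a tree is drawn uniformly
#' at each iteration (phylogenetic uncertainty propagated by tree resampling).
#'
#' @inheritParams pruning_loglik
#' @param kind `"independent"` or `"dependent"`.
#' @param prior `"exp"` or `"gamma"` rate prior (both hyper-seeded).
#' @param n_iter,burn,thin chain settings (post-burn draws kept every `thin`).
#' @param rw_sd log-scale random-walk step.
#' @return object of class `rj_chain`: `rates` (draws x rates matrix, zeros
#'   retained), `hyper_mean`, `loglik`, `tree_index`, `ess`, `accept_rate`.
#' @export
rjmcmc_sample <- function(tree, tip_states, kind = c("independent", "dependent"),
                          prior = c("exp", "gamma"), n_iter = 11000, burn = 1000,
                          thin = 5, rw_sd = 0.6, root_prior = "uniform") {
  kind <- match.arg(kind)
  prior <- match.arg(prior)
  p <- if (kind == "independent") 4L else 8L
  if (all(is.na(tip_states$trait1)) || all(is.na(tip_states$trait2)))
    stop("a trait is entirely missing")
  ll_fun <- make_pair_loglik(tree, tip_states, kind, root_prior)
  n_trees <- if (inherits(tree, "multiPhylo")) length(tree) else 1L

  m <- runif(1, 1, 50)
  r <- rate_prior_draw(p, m, prior)
  z <- rep(TRUE, p)
  ti <- if (n_trees > 1) sample.int(n_trees, 1) else 1L
  ll <- ll_fun(r * z, ti)
  n_keep <- floor((n_iter - burn) / thin)
  draws <- matrix(NA_real_, n_keep, p)
  hm <- numeric(n_keep); lls <- numeric(n_keep); tis <- integer(n_keep)
  kept <- 0L; acc <- 0L; prop <- 0L

  for (it in seq_len(n_iter)) {
    if (n_trees > 1) {
      ti_new <- sample.int(n_trees, 1)
      ll_new <- ll_fun(r * z, ti_new)
      if (log(runif(1)) < ll_new - ll) { ti <- ti_new; ll <- ll_new }
    }
    # hyper mean: log random walk under its conditional prior
    m_new <- exp(log(m) + rnorm(1, 0, 0.4))
    if (m_new < 100) {
      a <- rate_prior_logpdf(r[z], m_new, prior) - rate_prior_logpdf(r[z], m, prior) +
        log(m_new) - log(m)
      if (length(r[z]) == 0 || log(runif(1)) < a) m <- m_new
    }
    # within-model rate updates
    for (j in which(z)) {
      r_new <- r; r_new[j] <- exp(log(r[j]) + rnorm(1, 0, rw_sd))
      ll_new <- ll_fun(r_new * z, ti)
      a <- ll_new - ll +
        rate_prior_logpdf(r_new[j], m, prior) - rate_prior_logpdf(r[j], m, prior) +
        log(r_new[j]) - log(r[j])
      prop <- prop + 1L
      if (is.finite(ll_new) && log(runif(1)) < a) { r <- r_new; ll <- ll_new; acc <- acc + 1L }
    }
    # reversible jump: toggle one rate's inclusion (proposal from the prior
    # cancels the prior density, leaving the likelihood ratio)
    j <- sample.int(p, 1)
    z_new <- z; r_new <- r
    if (z[j]) {
      z_new[j] <- FALSE
    } else {
      z_new[j] <- TRUE
      r_new[j] <- rate_prior_draw(1, m, prior)
    }
    ll_new <- ll_fun(r_new * z_new, ti)
    if (is.finite(ll_new) && log(runif(1)) < ll_new - ll) {
      z <- z_new; r <- r_new; ll <- ll_new
    }
    if (it > burn && (it - burn) %% thin == 0 && kept < n_keep) {
      kept <- kept + 1L
      draws[kept, ] <- r * z
      hm[kept] <- m; lls[kept] <- ll; tis[kept] <- ti
    }
  }
  colnames(draws) <- names(rate_model(kind, rep(1, p))$rates)
  ess <- apply(draws, 2, effective_size)
  structure(list(rates = draws, hyper_mean = hm, loglik = lls,
                 tree_index = tis, ess = ess,
                 accept_rate = if (prop > 0) acc / prop else NA_real_,
                 kind = kind, prior = prior),
            class = "rj_chain")
}

#' Proportion of posterior models with a rate at zero
#'
#' @param chain an `rj_chain`.
#' @param rate_index column index or name of the rate.
#' @export
zero_rate_proportion <- function(chain, rate_index) {
  x <- chain$rates[, rate_index]
  if (length(x) == 0) stop("empty chain")
  mean(x == 0)
}

#' Generic stepping-stone log marginal-likelihood estimator
#'
#' Path-sampling estimator over power posteriors p(theta | y)^beta with powers
#' beta_k = (k/K)^(1/alpha) (default alpha = 0.4 concentrates stones near the
#' prior, where the integrand varies fastest). Each stone is sampled by
#' Metropolis-Hastings warm-started from the previous stone, mixing
#' random-walk moves with independence draws from the prior.
#'
#' @param log_lik function(theta) -> log-likelihood.
#' @param sample_prior function(n = 1) -> one draw of theta (vector).
#' @param log_prior function(theta) -> log prior density.
#' @param propose function(theta, j) -> list(theta, log_hastings); proposal
#'   updating coordinate `j` (a full sweep over coordinates is made per
#'   iteration, so mixing does not degrade with dimension).
#' @param n_par number of coordinates swept per iteration.
#' @param n_stones number of stones K (>= 8).
#' @param n_iter,burn per-stone sampling settings.
#' @param alpha power-spacing parameter.
#' @return list with `log_ml`, `per_stone` (data frame of powers and mean
#'   log-likelihoods), and settings.
#' @export
stepping_stone <- function(log_lik, sample_prior, log_prior, propose, n_par,
                           n_stones = 32, n_iter = 120, burn = 30, alpha = 0.4) {
  if (n_stones < 8) stop("use at least 8 stones")
  K <- n_stones
  betas <- (0:K / K)^(1 / alpha)
  theta <- sample_prior()
  ll <- log_lik(theta)
  lp <- log_prior(theta)
  log_ml <- 0
  per_stone <- data.frame(power = betas[-(K + 1)], mean_loglik = NA_real_)
  # anneal from the posterior (power 1) down to the prior: the chain starts
  # in the data mode after an initial burn and only has to diffuse outward,
  # which mixes far better than heating up from the prior
  for (it in seq_len(2 * burn)) {
    for (j in seq_len(n_par)) {
      mv <- propose(theta, j)
      ll_new <- log_lik(mv$theta)
      lp_new <- log_prior(mv$theta)
      a <- ll_new - ll + lp_new - lp + mv$log_hastings
      if (is.finite(ll_new) && is.finite(lp_new) && log(runif(1)) < a) {
        theta <- mv$theta; ll <- ll_new; lp <- lp_new
      }
    }
  }
  for (k in rev(seq_len(K))) {
    b <- betas[k]; b_next <- betas[k + 1]
    lls <- numeric(n_iter)
    for (it in seq_len(burn + n_iter)) {
      if (runif(1) < 0.2) {
        cand <- sample_prior()
        ll_new <- log_lik(cand)
        # prior proposal: prior terms cancel
        if (is.finite(ll_new) && log(runif(1)) < b * (ll_new - ll)) {
          theta <- cand; ll <- ll_new; lp <- log_prior(cand)
        }
      }
      for (j in seq_len(n_par)) {
        mv <- propose(theta, j)
        ll_new <- log_lik(mv$theta)
        lp_new <- log_prior(mv$theta)
        a <- b * (ll_new - ll) + lp_new - lp + mv$log_hastings
        if (is.finite(ll_new) && is.finite(lp_new) && log(runif(1)) < a) {
          theta <- mv$theta; ll <- ll_new; lp <- lp_new
        }
      }
      if (it > burn) lls[it - burn] <- ll
    }
    d <- b_next - b
    mx <- max(lls)
    log_ml <- log_ml + d * mx + log(mean(exp(d * (lls - mx))))
    per_stone$mean_loglik[k] <- mean(lls)
  }
  list(log_ml = log_ml, per_stone = per_stone,
       settings = list(n_stones = K, n_iter = n_iter, burn = burn, alpha = alpha))
}

#' Stepping-stone marginal likelihood of the pair model
#'
#' Runs the generic stepping-stone estimator on the independent or dependent
#' pair model with the hyper-seeded exponential (or gamma) rate prior; the
#' parameter vector is (hyper mean, rates).
#'
#' @inheritParams rjmcmc_sample
#' @param n_stones,n_iter,burn stepping-stone settings.
#' @return list with `log_ml`, `per_stone`, `kind`, settings.
#' @export
stepping_stone_logml <- function(tree, tip_states,
                                 kind = c("independent", "dependent"),
                                 prior = c("exp", "gamma"), n_stones = 32,
                                 n_iter = 120, burn = 30,
                                 root_prior = "uniform") {
  kind <- match.arg(kind)
  prior <- match.arg(prior)
  p <- if (kind == "independent") 4L else 8L
  ll_base <- make_pair_loglik(tree, tip_states, kind, root_prior)
  n_trees <- if (inherits(tree, "multiPhylo")) length(tree) else 1L
  log_lik <- function(theta) {
    ti <- if (n_trees > 1) sample.int(n_trees, 1) else 1L
    ll_base(theta[-1], ti)
  }
  sample_prior <- function() {
    m <- runif(1, 0, 100)
    c(m, rate_prior_draw(p, m, prior))
  }
  log_prior <- function(theta) {
    if (theta[1] <= 0 || theta[1] >= 100) return(-Inf)
    -log(100) + rate_prior_logpdf(theta[-1], theta[1], prior)
  }
  propose <- function(theta, j) {
    new <- theta
    new[j] <- theta[j] * exp(rnorm(1, 0, 0.6))
    list(theta = new, log_hastings = log(new[j]) - log(theta[j]))
  }
  res <- stepping_stone(log_lik, sample_prior, log_prior, propose,
                        n_par = p + 1, n_stones = n_stones, n_iter = n_iter,
                        burn = burn)
  res$kind <- kind
  res
}

#' Bayes factor between dependent and independent models
#'
#' BF = 2 (log ml_dependent - log ml_independent), with the conventional
#' evidence labels: BF > 2 positive, > 5 strong, > 10 very strong evidence for
#' the dependent (correlated-evolution) model.
#'
#' @param log_ml_dependent,log_ml_independent log marginal likelihoods.
#' @return list with `bf` and `evidence` label.
#' @export
bayes_factor <- function(log_ml_dependent, log_ml_independent) {
  if (!is.finite(log_ml_dependent) || !is.finite(log_ml_independent))
    stop("log marginal likelihoods must be finite")
  bf <- 2 * (log_ml_dependent - log_ml_independent)
  evidence <- if (bf > 10) "very strong" else if (bf > 5) "strong"
              else if (bf > 2) "positive" else "no support"
  list(bf = bf, evidence = evidence)
}
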