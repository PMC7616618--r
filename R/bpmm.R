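#' Bayesian phylogenetic mixed model
#'
#' Fits y = X b + a + e with a phylogenetically structured random effect
#' a ~ N(0, V_A A) (A the Brownian covariance from the tree) and residual
#' e ~ N(0, V_R I). The Gaussian family uses a blocked Gibbs sampler
#' (joint normal update of fixed and random effects, conjugate
#' inverse-Wishart updates of the variances). The Poisson log-link family
#' adds a latent log-rate per species updated by Metropolis-within-Gibbs,
#' with the observation-level residual acting as additive overdispersion on
#' the log scale.
#'
#' Priors: diffuse normal on fixed effects; inverse-Wishart (V, nu) on
#' variances, default (1, 0.002). `prior = "px_fisher"` and `"px_chisq"`
#' select parameter-expanded priors for the phylogenetic variance
#' (working scale parameter alpha ~ N(alpha_mu, alpha_V)), useful when
#' discrete-response chains mix poorly.
#'
#' @param y numeric response (counts for `"poisson_log"`).
#' @param X fixed-effect design matrix (include or omit the intercept as the
#'   model requires; rows aligned with `species`).
#' @param species species names matching the tree tips.
#' @param tree a `phylo`, or a precomputed covariance matrix with dimnames.
#' @param family `"gaussian"` or `"poisson_log"`.
#' @param prior `"iw"`, `"px_fisher"` or `"px_chisq"`, or a list with
#'   elements `V`, `nu`, and optionally `alpha_mu`, `alpha_V`.
#' @param n_iter,burn,thin chain settings (defaults are test-scale; the
#'   long-chain settings used for real data are reached by raising them).
#' @return object of class `bpmm_chain`: matrices `beta` (draws x p), vectors
#'   `v_a`, `v_r`, `fixed_var` (variance of the fixed-effect predictions per
#'   draw), plus the design and settings.
#' @export
fit_bpmm <- function(y, X, species, tree, family = c("gaussian", "poisson_log"),
                     prior = "iw", n_iter = 11000, burn = 1000, thin = 10) {
  family <- match.arg(family)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || length(species) != n) stop("misaligned inputs")
  A <- if (inherits(tree, "phylo")) phylo_covariance(tree) else tree
  key <- normalize_species_names(rownames(A))
  idx <- match(normalize_species_names(species), key)
  if (any(is.na(idx)))
    stop("species not on the tree: ",
         paste(utils::head(species[is.na(idx)], 5), collapse = ", "))
  A <- A[idx, idx, drop = FALSE]
  pr <- resolve_bpmm_prior(prior)
  px <- pr$kind != "iw"

  Ainv <- chol2inv(chol(A + diag(1e-8 * mean(diag(A)), n)))
  p <- ncol(X)
  W <- cbind(X, diag(n))
  WtW <- crossprod(W)

  # state
  b <- rep(0, p); u <- rep(0, n); alpha <- 1
  v_u <- stats::var(if (family == "gaussian") y else log1p(y)) / 2 + 0.1
  v_r <- v_u
  eta <- if (family == "poisson_log") log1p(y) else NULL

  n_keep <- floor((n_iter - burn) / thin)
  out_b <- matrix(NA_real_, n_keep, p,
                  dimnames = list(NULL, colnames(X) %||% paste0("b", 1:p)))
  out_va <- numeric(n_keep); out_vr <- numeric(n_keep)
  out_fv <- numeric(n_keep)
  kept <- 0L

  for (it in seq_len(n_iter)) {
    resp <- if (family == "gaussian") y else eta
    # joint update of (b, u): alpha folded into the prior precision of u
    prior_prec_u <- Ainv / (v_u * alpha^2)
    prec <- WtW / v_r
    prec[1:p, 1:p] <- prec[1:p, 1:p] + diag(1e-8, p)
    prec[(p + 1):(p + n), (p + 1):(p + n)] <-
      prec[(p + 1):(p + n), (p + 1):(p + n)] + prior_prec_u
    rhs <- crossprod(W, resp) / v_r
    ch <- chol(prec)
    mu <- backsolve(ch, forwardsolve(t(ch), rhs))
    draw <- mu + backsolve(ch, rnorm(p + n))
    b <- draw[1:p]
    au <- draw[(p + 1):(p + n)]       # au = alpha * u (the realized effect)
    u <- au / alpha
    a_eff <- au

    if (px) {
      # parameter-expanded move: regress residual on u to redraw alpha
      res0 <- resp - X %*% b
      prec_a <- sum(u^2) / v_r + 1 / pr$alpha_V
      mean_a <- (sum(u * res0) / v_r + pr$alpha_mu / pr$alpha_V) / prec_a
      alpha <- rnorm(1, mean_a, sqrt(1 / prec_a))
      a_eff <- alpha * u
    }

    # variance updates
    qu <- drop(t(u) %*% Ainv %*% u)
    v_u <- 1 / rgamma(1, shape = (pr$nu + n) / 2, rate = (pr$nu * pr$V + qu) / 2)
    e <- resp - X %*% b - a_eff
    v_r <- 1 / rgamma(1, shape = (0.002 + n) / 2,
                      rate = (0.002 * 1 + sum(e^2)) / 2)

    if (family == "poisson_log") {
      mu_eta <- drop(X %*% b + a_eff)
      prop_eta <- eta + rnorm(n, 0, 0.4)
      log_acc <- (y * prop_eta - exp(prop_eta)) - (y * eta - exp(eta)) -
        (prop_eta - mu_eta)^2 / (2 * v_r) + (eta - mu_eta)^2 / (2 * v_r)
      take <- log(runif(n)) < log_acc
      eta[take] <- prop_eta[take]
    }

    if (it > burn && (it - burn) %% thin == 0 && kept < n_keep) {
      kept <- kept + 1L
      out_b[kept, ] <- b
      out_va[kept] <- v_u * alpha^2
      out_vr[kept] <- v_r
      out_fv[kept] <- stats::var(drop(X %*% b))
    }
  }
  structure(list(beta = out_b, v_a = out_va, v_r = out_vr,
                 fixed_var = out_fv, family = family, X = X,
                 species = species, prior = pr,
                 settings = list(n_iter = n_iter, burn = burn, thin = thin)),
            class = "bpmm_chain")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_bpmm_prior <- function(prior) {
  if (is.character(prior)) {
    prior <- switch(prior,
      iw = list(kind = "iw", V = 1, nu = 0.002),
      px_fisher = list(kind = "px_fisher", V = 1, nu = 1, alpha_mu = 0, alpha_V = 1000),
      px_chisq = list(kind = "px_chisq", V = 1, nu = 1000, alpha_mu = 0, alpha_V = 1),
      stop("unknown prior"))
  }
  prior$kind <- prior$kind %||% "iw"
  prior
}

#' Pool BPMM chains fitted on different trees
#'
#' Concatenates posterior draws across per-tree chains (identical
#' parameterizations required), recording the tree index of every draw, so
#' that parameter estimation integrates over phylogenetic uncertainty.
#'
#' @param chains list of `bpmm_chain` objects.
#' @return a `bpmm_chain` with an added `tree_index` vector.
#' @export
pool_across_trees <- function(chains) {
  if (length(chains) == 0) stop("no chains")
  cols <- colnames(chains[[1]]$beta)
  if (!all(vapply(chains, function(ch) identical(colnames(ch$beta), cols), logical(1))))
    stop("chains have mismatched parameters")
  pooled <- chains[[1]]
  pooled$beta <- do.call(rbind, lapply(chains, `[[`, "beta"))
  pooled$v_a <- unlist(lapply(chains, `[[`, "v_a"))
  pooled$v_r <- unlist(lapply(chains, `[[`, "v_r"))
  pooled$fixed_var <- unlist(lapply(chains, `[[`, "fixed_var"))
  pooled$tree_index <- rep(seq_along(chains),
                           vapply(chains, function(ch) nrow(ch$beta), integer(1)))
  pooled
}

#' Summarize a BPMM chain
#'
#' Posterior modes with 95% HPD intervals per fixed effect and variance
#' component, plus phylogenetic heritability.
#'
#' @param chain a `bpmm_chain`.
#' @return data frame of parameter summaries.
#' @export
summary_bpmm <- function(chain) {
  rows <- lapply(colnames(chain$beta), function(p) {
    s <- posterior_mode_ci(chain$beta[, p])
    data.frame(parameter = p, mode = s$mode, lower = s$lower, upper = s$upper)
  })
  va <- posterior_mode_ci(chain$v_a)
  vr <- posterior_mode_ci(chain$v_r)
  h2 <- phylo_heritability(chain$v_a, chain$v_r)
  out <- rbind(do.call(rbind, rows),
               data.frame(parameter = "V_A", mode = va$mode, lower = va$lower, upper = va$upper),
               data.frame(parameter = "V_R", mode = vr$mode, lower = vr$lower, upper = vr$upper),
               data.frame(parameter = "phylo_h2_pct", mode = h2$mode,
                          lower = h2$lower, upper = h2$upper))
  rownames(out) <- NULL
  out
}

#' Marginal R-squared of a Gaussian BPMM
#'
#' Per draw: var(X b) / (var(X b) + V_A + V_R). With pooled multi-tree chains
#' the median is taken per tree and then across trees (both the per-tree
#' medians and the pooled median are returned).
#'
#' @param chain a `bpmm_chain` (Gaussian family only).
#' @return list with `r2_draws`, `median` and, when tree indices are present,
#'   `per_tree_medians`.
#' @export
marginal_r2 <- function(chain) {
  if (chain$family != "gaussian")
    stop("marginal R2 is reported for Gaussian models only")
  r2 <- chain$fixed_var / (chain$fixed_var + chain$v_a + chain$v_r)
  out <- list(r2_draws = r2, median = stats::median(r2))
  if (!is.null(chain$tree_index)) {
    per_tree <- tapply(r2, chain$tree_index, stats::median)
    out$per_tree_medians <- as.numeric(per_tree)
    out$median <- stats::median(out$per_tree_medians)
  }
  out
}
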