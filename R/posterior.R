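# Posterior summaries and convergence diagnostics shared by the MCMC stages.

effective_size <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3 || stats::var(x) == 0) return(as.numeric(n))
  a <- stats::acf(x, lag.max = min(n - 1, 10 * floor(log10(n)) * 10 + 50),
                  plot = FALSE)$acf[-1]
  # sum consecutive positive autocorrelations (Geyer-style truncation)
  s <- 0
  for (rho in a) {
    if (rho < 0.05) break
    s <- s + rho
  }
  max(1, n / (1 + 2 * s))
}

#' Posterior mode and 95% highest-density interval
#'
#' The point estimate is the kernel-density peak of the draws; the interval is
#' the highest-posterior-density interval.
#'
#' @param samples numeric vector of posterior draws (>= 100).
#' @param prob interval mass (default 0.95).
#' @return list with `mode`, `lower`, `upper`.
#' @export
posterior_mode_ci <- function(samples, prob = 0.95) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 100) stop("need at least 100 draws")
  if (stats::var(samples) == 0)
    return(list(mode = samples[1], lower = samples[1], upper = samples[1]))
  d <- stats::density(samples, n = 1024)
  mode <- d$x[which.max(d$y)]
  s <- sort(samples)
  n <- length(s)
  k <- max(1, floor(prob * n))
  widths <- s[(k + 1):n] - s[1:(n - k)]
  i <- which.min(widths)
  list(mode = mode, lower = s[i], upper = s[i + k])
}

#' pMCMC for a pairwise factor-level comparison
#'
#' The proportion of paired posterior draws in which one level exceeds the
#' other, taking the smaller of the two directions.
#'
#' @param samples_a,samples_b equal-length vectors of paired draws.
#' @return p-value-like proportion in \[0, 0.5\] (doubled to a two-sided
#'   value by convention is left to the caller; this is the printed form).
#' @export
pmcmc_compare <- function(samples_a, samples_b) {
  if (length(samples_a) != length(samples_b)) stop("paired draws required")
  p_gt <- mean(samples_a > samples_b)
  min(p_gt, 1 - p_gt)
}

#' Phylogenetic heritability from variance-component draws
#'
#' phylo h2 = V_A / (V_A + V_R) * 100 per draw, summarized by posterior mode
#' and 95% HPD interval.
#'
#' @param v_a,v_r draws of the phylogenetic and residual variances.
#' @return list with `draws` (percent scale), `mode`, `lower`, `upper`.
#' @export
phylo_heritability <- function(v_a, v_r) {
  if (any(v_a < 0) || any(v_r < 0)) stop("variances must be non-negative")
  h <- v_a / (v_a + v_r) * 100
  if (length(h) >= 100) c(list(draws = h), posterior_mode_ci(h))
  else list(draws = h, mode = stats::median(h), lower = min(h), upper = max(h))
}

#' Convergence diagnostics for MCMC chains
#'
#' Effective sample sizes from the autocorrelation time, the Gelman-Rubin
#' potential scale reduction factor when two or more chains are supplied, and
#' lag-1 autocorrelations. A warning is raised when any ESS falls below
#' `ess_floor` (default 300).
#'
#' @param chains a matrix of draws (one chain) or a list of such matrices
#'   with identical columns.
#' @param ess_floor minimum acceptable ESS before warning.
#' @return data frame with per-parameter `ess`, `psrf` (NA for one chain),
#'   `lag1_autocorr`.
#' @export
diagnostics <- function(chains, ess_floor = 300) {
  if (!is.list(chains)) chains <- list(chains)
  chains <- lapply(chains, function(ch) {
    ch <- as.matrix(ch)
    if (is.null(colnames(ch))) colnames(ch) <- paste0("par", seq_len(ncol(ch)))
    ch
  })
  pars <- colnames(chains[[1]])
  if (!all(vapply(chains, function(ch) identical(colnames(ch), pars), logical(1))))
    stop("chains have mismatched parameters")
  all_draws <- do.call(rbind, chains)
  ess <- vapply(pars, function(p) sum(vapply(chains, function(ch)
    effective_size(ch[, p]), numeric(1))), numeric(1))
  lag1 <- vapply(pars, function(p) {
    x <- all_draws[, p]
    if (stats::var(x) == 0) 0 else stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
  }, numeric(1))
  psrf <- rep(NA_real_, length(pars))
  if (length(chains) >= 2) {
    psrf <- vapply(pars, function(p) gelman_rubin(lapply(chains, function(ch) ch[, p])),
                   numeric(1))
  }
  if (any(ess < ess_floor))
    warning("effective sample size below ", ess_floor, " for: ",
            paste(pars[ess < ess_floor], collapse = ", "))
  data.frame(parameter = pars, ess = ess, psrf = psrf,
             lag1_autocorr = lag1, row.names = NULL)
}

gelman_rubin <- function(chain_list) {
  m <- length(chain_list)
  n <- min(lengths(chain_list))
  x <- vapply(chain_list, function(v) v[seq_len(n)], numeric(n))
  means <- colMeans(x)
  vars <- apply(x, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  vhat <- (n - 1) / n * W + B / n
  sqrt(vhat / W)
}
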