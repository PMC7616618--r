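#' Rate model for paired binary traits
#'
#' Builds the 4-state generator for two binary traits evolving on a tree, in
#' the fixed state order (0,0), (0,1), (1,0), (1,1) where the first position
#' is trait 1 (e.g. colony-size class: 0 = small, 1 = large) and the second
#' trait 2 (e.g. castes: 0 = single, 1 = multiple). Double transitions have
#' rate zero. The dependent model has 8 free rates (each single-trait change
#' conditioned on the other trait's state); the independent model is the
#' constrained case with 4 rates where conditioned pairs are equal.
#'
#' @param kind `"independent"` or `"dependent"`.
#' @param rates non-negative numeric vector: for `"independent"` length 4
#'   (`gain1`, `loss1`, `gain2`, `loss2`); for `"dependent"` length 8
#'   (`q12`, `q13`, `q21`, `q24`, `q31`, `q34`, `q42`, `q43`).
#' @return object of class `rate_model` with elements `kind`, `rates`, `Q`.
#' @export
rate_model <- function(kind = c("independent", "dependent"), rates) {
  kind <- match.arg(kind)
  n_expect <- if (kind == "independent") 4L else 8L
  if (length(rates) != n_expect)
    stop(kind, " model needs ", n_expect, " rates")
  if (any(rates < 0)) stop("rates must be non-negative")
  nm <- if (kind == "independent") c("gain1", "loss1", "gain2", "loss2")
        else c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")
  rates <- setNames(as.numeric(rates), nm)
  q8 <- if (kind == "independent")
    c(q12 = unname(rates["gain2"]), q13 = unname(rates["gain1"]),
      q21 = unname(rates["loss2"]), q24 = unname(rates["gain1"]),
      q31 = unname(rates["loss1"]), q34 = unname(rates["gain2"]),
      q42 = unname(rates["loss1"]), q43 = unname(rates["loss2"]))
  else rates
  Q <- matrix(0, 4, 4, dimnames = rep(list(c("00", "01", "10", "11")), 2))
  Q[1, 2] <- q8["q12"]; Q[1, 3] <- q8["q13"]
  Q[2, 1] <- q8["q21"]; Q[2, 4] <- q8["q24"]
  Q[3, 1] <- q8["q31"]; Q[3, 4] <- q8["q34"]
  Q[4, 2] <- q8["q42"]; Q[4, 3] <- q8["q43"]
  diag(Q) <- -rowSums(Q)
  structure(list(kind = kind, rates = rates, Q = Q), class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("Paired binary-trait CTMC (", x$kind, " model)\n", sep = "")
  print(round(x$rates, 6))
  invisible(x)
}

# Per-tip partial-likelihood rows over the 4 pair states. A missing trait
# leaves likelihood 1 over the compatible states (standard ambiguity coding).
pair_tip_likelihoods <- function(tree, tip_states) {
  ts <- align_tip_states(tree, tip_states)
  L <- matrix(0, nrow = nrow(ts), ncol = 4)
  t1 <- ts$trait1; t2 <- ts$trait2
  for (i in seq_len(nrow(ts))) {
    ok1 <- if (is.na(t1[i])) c(TRUE, TRUE) else c(t1[i] == 0, t1[i] == 1)
    ok2 <- if (is.na(t2[i])) c(TRUE, TRUE) else c(t2[i] == 0, t2[i] == 1)
    # state order (t1,t2): (0,0),(0,1),(1,0),(1,1)
    L[i, ] <- as.numeric(c(ok1[1] & ok2[1], ok1[1] & ok2[2],
                           ok1[2] & ok2[1], ok1[2] & ok2[2]))
  }
  L
}

align_tip_states <- function(tree, tip_states) {
  if (is.null(tip_states$species)) stop("tip_states needs a 'species' column")
  key <- normalize_species_names(tip_states$species)
  want <- normalize_species_names(tree$tip.label)
  idx <- match(want, key)
  if (any(is.na(idx)))
    stop("tips without trait data: ",
         paste(utils::head(tree$tip.label[is.na(idx)], 5), collapse = ", "))
  bad1 <- !(tip_states$trait1 %in% c(0, 1, NA))
  bad2 <- !(tip_states$trait2 %in% c(0, 1, NA))
  if (any(bad1) || any(bad2)) stop("trait states must be 0, 1 or NA")
  tip_states[idx, , drop = FALSE]
}

resolve_root_prior <- function(root_prior, Q) {
  k <- nrow(Q)
  if (is.character(root_prior)) {
    if (root_prior == "uniform") return(rep(1 / k, k))
    if (root_prior == "stationary") {
      # left null vector of Q
      e <- eigen(t(Q))
      i <- which.min(abs(e$values))
      v <- abs(Re(e$vectors[, i]))
      return(v / sum(v))
    }
    stop("unknown root prior")
  }
  if (length(root_prior) != k || any(root_prior < 0)) stop("bad root prior")
  root_prior / sum(root_prior)
}

#' Pruning-algorithm log-likelihood for paired binary traits
#'
#' Felsenstein's pruning algorithm over the 4-state pair alphabet: equals the
#' log of the sum, over all internal-node state assignments, of products of
#' branch transition probabilities and the root prior.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param model a `rate_model` (or bare 4x4 generator matrix).
#' @param tip_states data frame with columns `species`, `trait1`, `trait2`
#'   (0/1/NA).
#' @param root_prior `"uniform"` (default), `"stationary"`, or a length-4
#'   probability vector.
#' @return log-likelihood (scalar; `-Inf` for impossible data).
#' @export
pruning_loglik <- function(tree, model, tip_states, root_prior = "uniform") {
  Q <- if (inherits(model, "rate_model")) model$Q else model
  tipL <- pair_tip_likelihoods(tree, tip_states)
  ctmc_loglik_matrix(tree, Q, tipL, root_prior)
}

# General k-state pruning likelihood given a tip-likelihood matrix aligned to
# tree$tip.label. Shared by the pair model and the hidden-rate machinery.
ctmc_loglik_matrix <- function(tree, Q, tipL, root_prior = "uniform") {
  pt <- ape::reorder.phylo(tree, "postorder")
  pr <- resolve_root_prior(root_prior, Q)
  cpp_ctmc_loglik(pt$edge, pt$edge.length, Q, tipL, pr, pt$Nnode)
}

ctmc_marginals_matrix <- function(tree, Q, tipL, root_prior = "uniform") {
  pt <- ape::reorder.phylo(tree, "postorder")
  pr <- resolve_root_prior(root_prior, Q)
  cpp_ctmc_marginals(pt$edge, pt$edge.length, Q, tipL, pr, pt$Nnode)
}

#' Maximum-likelihood fit of the pair CTMC
#'
#' Multi-start optimization of the independent (4-rate) or dependent (8-rate)
#' model on the log-rate scale. The independent model is nested in the
#' dependent model, so the dependent maximum log-likelihood is never lower.
#'
#' @inheritParams pruning_loglik
#' @param kind `"independent"` or `"dependent"`.
#' @param n_starts number of random restarts.
#' @param upper upper bound on rates during optimization.
#' @return list with `model` (fitted `rate_model`), `loglik`, `converged`, and
#'   `constant_trait` flag (boundary fits on invariant traits).
#' @export
fit_ml <- function(tree, tip_states, kind = c("independent", "dependent"),
                   root_prior = "uniform", n_starts = 5, upper = 1e3) {
  kind <- match.arg(kind)
  npar <- if (kind == "independent") 4L else 8L
  tipL <- pair_tip_likelihoods(tree, tip_states)
  pt <- ape::reorder.phylo(tree, "postorder")
  constant1 <- length(unique(na.omit(tip_states$trait1))) < 2
  constant2 <- length(unique(na.omit(tip_states$trait2))) < 2
  nll <- function(logr) {
    r <- exp(logr)
    if (any(!is.finite(r)) || any(r > upper)) return(1e10)
    Q <- rate_model(kind, r)$Q
    pr <- resolve_root_prior(root_prior, Q)
    ll <- cpp_ctmc_loglik(pt$edge, pt$edge.length, Q, tipL, pr, pt$Nnode)
    if (!is.finite(ll)) 1e10 else -ll
  }
  td <- sum(pt$edge.length)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- log(rexp(npar, rate = td / (2 * length(pt$tip.label))) + 1e-4)
    fit <- tryCatch(optim(start, nll, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-10)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("optimization failed in all starts")
  rates <- exp(best$par)
  rates[rates < 1e-7] <- 0
  list(model = rate_model(kind, rates),
       loglik = -best$value,
       converged = best$convergence == 0,
       constant_trait = constant1 || constant2)
}

#' Simulate paired binary traits down a tree
#'
#' Exact stochastic simulation (exponential waiting times along each branch)
#' of the 4-state pair CTMC. Returns the tip states together with an event
#' log of every transition (edge, time, from, to), which recovery tests use
#' to assert properties of the generating history.
#'
#' @inheritParams pruning_loglik
#' @param root_state state index 1..4 (order (0,0),(0,1),(1,0),(1,1)), or
#'   `NULL` to draw from `root_prior`.
#' @return list with `tip_states` (data frame `species`, `trait1`, `trait2`),
#'   `node_states` (state index per node), `events` (data frame).
#' @export
simulate_pair_ctmc <- function(tree, model, root_state = NULL,
                               root_prior = "uniform") {
  Q <- if (inherits(model, "rate_model")) model$Q else model
  k <- nrow(Q)
  pt <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(pt)
  ntot <- ntip + pt$Nnode
  if (is.null(root_state)) {
    pr <- resolve_root_prior(root_prior, Q)
    root_state <- sample.int(k, 1, prob = pr)
  }
  state <- integer(ntot)
  state[ntip + 1L] <- root_state
  events <- list()
  # pre-order over edges
  ord <- rev(seq_len(nrow(pt$edge)))
  for (e in ord) {
    par <- pt$edge[e, 1]; chi <- pt$edge[e, 2]
    s <- state[par]
    t_left <- pt$edge.length[e]
    t_used <- 0
    repeat {
      out <- -Q[s, s]
      if (out <= 0) break
      w <- rexp(1, out)
      if (w > t_left) break
      t_left <- t_left - w
      t_used <- t_used + w
      probs <- Q[s, ]; probs[s] <- 0
      s_new <- sample.int(k, 1, prob = probs)
      events[[length(events) + 1L]] <-
        data.frame(edge = e, child = chi, time = t_used, from = s, to = s_new)
      s <- s_new
    }
    state[chi] <- s
  }
  st <- state[seq_len(ntip)]
  # state index -> (trait1, trait2): 1=(0,0) 2=(0,1) 3=(1,0) 4=(1,1)
  tip_states <- data.frame(species = pt$tip.label,
                           trait1 = as.integer(st >= 3),
                           trait2 = as.integer(st %in% c(2, 4)),
                           stringsAsFactors = FALSE)
  list(tip_states = tip_states,
       node_states = state,
       events = if (length(events)) do.call(rbind, events)
                else data.frame(edge = integer(), child = integer(),
                                time = numeric(), from = integer(),
                                to = integer()))
}

#' Brute-force pair-CTMC likelihood by enumeration
#'
#' Direct sum over all internal-node state assignments; exponential in the
#' number of internal nodes, usable only on very small trees. Serves as the
#' independent oracle for [pruning_loglik()].
#'
#' @inheritParams pruning_loglik
#' @export
enumeration_loglik <- function(tree, model, tip_states, root_prior = "uniform") {
  Q <- if (inherits(model, "rate_model")) model$Q else model
  tipL <- pair_tip_likelihoods(tree, tip_states)
  enumeration_loglik_matrix(tree, Q, tipL, root_prior)
}

enumeration_loglik_matrix <- function(tree, Q, tipL, root_prior = "uniform") {
  k <- nrow(Q)
  pt <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(pt)
  nnode <- pt$Nnode
  if (nnode > 6) stop("enumeration oracle restricted to small trees")
  pr <- resolve_root_prior(root_prior, Q)
  P <- lapply(seq_len(nrow(pt$edge)), function(e) cpp_expm(Q, pt$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign_int <- grid[g, ]
    lik_internal <- pr[assign_int[1]]  # root is node ntip+1
    state_of <- function(v) assign_int[v - ntip]
    # tips: sum over compatible tip states
    contrib <- lik_internal
    for (e in seq_len(nrow(pt$edge))) {
      par <- pt$edge[e, 1]; chi <- pt$edge[e, 2]
      sp <- state_of(par)
      if (chi <= ntip) {
        contrib <- contrib * sum(P[[e]][sp, ] * tipL[chi, ])
      } else {
        contrib <- contrib * P[[e]][sp, state_of(chi)]
      }
      if (contrib == 0) break
    }
    total <- total + contrib
  }
  if (total <= 0) -Inf else log(total)
}
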