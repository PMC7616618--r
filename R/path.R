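#' Construct a causal DAG
#'
#' @param edges character vector of `"A -> B"` edge specifications, or a
#'   two-column matrix (from, to).
#' @param vertices optional vertex set (isolated vertices allowed).
#' @return object of class `causal_dag` with `vertices` and an `edges`
#'   two-column character matrix. Cyclic inputs are rejected.
#' @export
causal_dag <- function(edges, vertices = NULL) {
  if (is.character(edges) && !is.matrix(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    if (any(lengths(parts) != 2)) stop("edges must look like 'A -> B'")
    em <- t(vapply(parts, function(p) trimws(p), character(2)))
  } else em <- as.matrix(edges)
  colnames(em) <- c("from", "to")
  verts <- sort(unique(c(vertices, em)))
  dag <- structure(list(vertices = verts, edges = em), class = "causal_dag")
  if (is.null(topological_order(dag))) stop("graph is cyclic")
  dag
}

topological_order <- function(dag) {
  verts <- dag$vertices
  em <- dag$edges
  indeg <- setNames(integer(length(verts)), verts)
  for (v in em[, "to"]) indeg[v] <- indeg[v] + 1L
  order <- character(0)
  avail <- sort(names(indeg)[indeg == 0])
  while (length(avail) > 0) {
    v <- avail[1]; avail <- avail[-1]
    order <- c(order, v)
    kids <- em[em[, "from"] == v, "to"]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0) avail <- sort(c(avail, k))
    }
  }
  if (length(order) != length(verts)) NULL else order
}

dag_parents <- function(dag, v) sort(unique(dag$edges[dag$edges[, "to"] == v, "from"]))

topological_depth <- function(dag) {
  ord <- topological_order(dag)
  depth <- setNames(integer(length(dag$vertices)), dag$vertices)
  for (v in ord) {
    pa <- dag_parents(dag, v)
    depth[v] <- if (length(pa) == 0) 0L else max(depth[pa]) + 1L
  }
  depth
}

#' d-separation basis set of a DAG
#'
#' One conditional-independence claim per non-adjacent vertex pair,
#' conditioning on the union of both vertices' parent sets. The regression
#' response is the topologically deeper vertex (ties broken by taking the
#' lexicographically later name), so every claim is testable as a single
#' phylogenetic regression.
#'
#' @param dag a `causal_dag`.
#' @return list of claims, each `list(response, predictor, conditioning)`,
#'   in a deterministic order.
#' @export
basis_set <- function(dag) {
  verts <- dag$vertices
  adj <- paste(dag$edges[, 1], dag$edges[, 2])
  adj <- c(adj, paste(dag$edges[, 2], dag$edges[, 1]))
  depth <- topological_depth(dag)
  claims <- list()
  for (i in seq_along(verts)) for (j in seq_along(verts)) {
    if (i >= j) next
    a <- verts[i]; b <- verts[j]
    if (paste(a, b) %in% adj) next
    resp <- if (depth[a] > depth[b]) a
            else if (depth[b] > depth[a]) b
            else max(a, b)
    pred <- setdiff(c(a, b), resp)
    cond <- setdiff(sort(unique(c(dag_parents(dag, a), dag_parents(dag, b)))),
                    c(resp, pred))
    claims[[length(claims) + 1L]] <-
      list(response = resp, predictor = pred, conditioning = cond)
  }
  claims
}

#' The four built-in candidate causal models
#'
#' Candidate DAGs over complexity (number of worker castes or worker-size
#' CV), colony size, queen mating frequency and queen number. Every model
#' includes queen_number -> mating_frequency and colony_size ->
#' mating_frequency; they differ in what drives complexity:
#' model 1, colony size only; model 2, complexity drives colony size;
#' model 3, both colony size and mating frequency; model 4, mating frequency
#' only.
#'
#' @return named list of four `causal_dag` objects.
#' @export
candidate_dags <- function() {
  base <- c("queen_number -> mating_frequency", "colony_size -> mating_frequency")
  list(
    model1 = causal_dag(c(base, "colony_size -> complexity")),
    model2 = causal_dag(c(base, "complexity -> colony_size")),
    model3 = causal_dag(c(base, "colony_size -> complexity",
                          "mating_frequency -> complexity")),
    model4 = causal_dag(c(base, "mating_frequency -> complexity"))
  )
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' GLS under the lambda-scaled Brownian covariance; lambda estimated by
#' profile maximum likelihood on \[0, 1\] (or fixed). With lambda = 0 the fit
#' is exactly ordinary least squares.
#'
#' @param y numeric response.
#' @param X design matrix (with intercept column if desired).
#' @param tree `phylo` whose tips match `rownames(X)`/`names(y)`, or a
#'   covariance matrix; rows must align with `y`.
#' @param lambda `"ML"` or a fixed value in \[0, 1\].
#' @return list with `coefficients` data frame (estimate, se, t, p),
#'   `lambda`, `loglik`, `sigma2`, `n`.
#' @export
pgls_fit <- function(y, X, tree, lambda = "ML") {
  X <- as.matrix(X)
  n <- length(y)
  A <- if (inherits(tree, "phylo")) phylo_covariance(tree) else tree
  if (nrow(A) != n) stop("covariance does not match data; align rows first")
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  off <- A; diag(off) <- 0
  Adiag <- diag(diag(A))
  profile <- function(lam) {
    V <- Adiag + lam * off
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    Xi <- backsolve(ch, X, transpose = TRUE)
    yi <- backsolve(ch, y, transpose = TRUE)
    fit <- lm.fit(Xi, yi)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(ch))) + n)
    list(ll = ll, fit = fit, ch = ch, sigma2 = sigma2, Xi = Xi)
  }
  if (identical(lambda, "ML")) {
    opt <- optimize(function(l) -profile(l)$ll, c(0, 1), tol = 1e-6)
    # compare against the boundaries explicitly
    cand <- c(0, opt$minimum, 1)
    lls <- vapply(cand, function(l) profile(l)$ll, numeric(1))
    lambda <- cand[which.max(lls)]
  }
  pr <- profile(lambda)
  p <- ncol(X)
  sigma2_u <- sum(pr$fit$residuals^2) / (n - p)
  XtXi <- chol2inv(qr.R(qr(pr$Xi)))
  se <- sqrt(diag(XtXi) * sigma2_u)
  est <- pr$fit$coefficients
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  list(coefficients = data.frame(term = colnames(X) %||% paste0("b", 1:p),
                                 estimate = est, se = se, t = tval, p = pval,
                                 row.names = NULL),
       lambda = lambda, loglik = pr$ll, sigma2 = pr$sigma2, n = n)
}

#' Phylogenetically corrected logistic regression
#'
#' Logistic regression with a phylogenetic random effect b ~ N(0, s2 A),
#' fitted by Laplace approximation: penalized IRLS finds the joint mode of
#' fixed and random effects, the approximate marginal likelihood is profiled
#' over s2 >= 0, and Wald tests use the curvature at the mode. At s2 = 0 the
#' fit coincides with ordinary logistic regression. Complete separation is
#' detected and handled with a ridge-penalized fit (flagged).
#'
#' @param y binary 0/1 response.
#' @param X design matrix (rows aligned with `y` and the covariance).
#' @param tree `phylo` or covariance matrix aligned with `y`.
#' @return list with `coefficients` (estimate, se, z, p), `sigma2`,
#'   `separation` flag, `loglik`.
#' @export
phylo_logistic_fit <- function(y, X, tree) {
  X <- as.matrix(X)
  n <- length(y)
  if (length(unique(y)) < 2) stop("response is constant")
  A <- if (inherits(tree, "phylo")) phylo_covariance(tree) else tree
  if (nrow(A) != n) stop("covariance does not match data; align rows first")
  A <- A / mean(diag(A))
  p <- ncol(X)
  eA <- eigen(A, symmetric = TRUE)
  eval_s2 <- function(s2, ridge = 0) {
    # joint penalized IRLS over (beta, a)
    beta <- rep(0, p); a <- rep(0, n)
    if (s2 > 0) {
      Kinv <- eA$vectors %*% (t(eA$vectors) / pmax(eA$values * s2, 1e-10))
    } else Kinv <- NULL
    for (it in 1:50) {
      eta <- drop(X %*% beta + a)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      z <- eta + (y - mu) / w
      if (is.null(Kinv)) {
        fit <- tryCatch(lm.wfit(X, z, w), error = function(e) NULL)
        if (is.null(fit)) return(NULL)
        beta_new <- fit$coefficients
        if (ridge > 0) {
          H <- crossprod(X, w * X) + diag(ridge, p)
          beta_new <- drop(solve(H, crossprod(X, w * z)))
        }
        a_new <- rep(0, n)
      } else {
        W <- cbind(X, diag(n))
        Hmat <- crossprod(W, w * W)
        Hmat[(p + 1):(p + n), (p + 1):(p + n)] <-
          Hmat[(p + 1):(p + n), (p + 1):(p + n)] + Kinv
        if (ridge > 0) Hmat[1:p, 1:p] <- Hmat[1:p, 1:p] + diag(ridge, p)
        rhs <- crossprod(W, w * z)
        sol <- tryCatch(solve(Hmat, rhs), error = function(e) NULL)
        if (is.null(sol)) return(NULL)
        beta_new <- sol[1:p]; a_new <- sol[(p + 1):(p + n)]
      }
      done <- max(abs(c(beta_new - beta, a_new - a))) < 1e-7
      beta <- beta_new; a <- a_new
      if (done) break
    }
    eta <- drop(X %*% beta + a)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    ll_data <- sum(y * eta - log1p(exp(eta)))
    if (s2 > 0) {
      pen <- -0.5 * drop(t(a) %*% Kinv %*% a)
      # Laplace: ll_data + pen - 0.5 log det(I + s2 A W)
      M <- diag(n) + s2 * (A * rep(w, each = n))
      ld <- determinant(M, logarithm = TRUE)$modulus
      ll <- ll_data + pen - 0.5 * as.numeric(ld)
    } else ll <- ll_data
    list(beta = beta, a = a, w = w, ll = ll, mu = mu, eta = eta)
  }
  # profile s2 over a coarse grid then refine
  grid <- c(0, 0.1, 0.3, 1, 3, 10)
  fits <- lapply(grid, eval_s2)
  lls <- vapply(fits, function(f) if (is.null(f)) -Inf else f$ll, numeric(1))
  i <- which.max(lls)
  s2 <- grid[i]
  if (i > 1 && i < length(grid)) {
    o <- optimize(function(s) {
      f <- eval_s2(s)
      if (is.null(f)) Inf else -f$ll
    }, c(grid[i - 1], grid[i + 1]))
    if (-o$objective > lls[i]) s2 <- o$minimum
  }
  best <- eval_s2(s2)
  separation <- max(abs(best$eta)) > 15
  ridge <- 0
  if (separation) {
    ridge <- 1
    best <- eval_s2(s2, ridge = ridge)
  }
  # Wald covariance of beta from the joint curvature at the mode
  w <- best$w
  if (s2 > 0) {
    Kinv <- eA$vectors %*% (t(eA$vectors) / pmax(eA$values * s2, 1e-10))
    W <- cbind(X, diag(n))
    Hmat <- crossprod(W, w * W)
    Hmat[(p + 1):(p + n), (p + 1):(p + n)] <-
      Hmat[(p + 1):(p + n), (p + 1):(p + n)] + Kinv
    if (ridge > 0) Hmat[1:p, 1:p] <- Hmat[1:p, 1:p] + diag(ridge, p)
    cov_all <- solve(Hmat)
    covb <- cov_all[1:p, 1:p, drop = FALSE]
  } else {
    H <- crossprod(X, w * X) + diag(ridge, p)
    covb <- solve(H)
  }
  se <- sqrt(diag(covb))
  zval <- best$beta / se
  pval <- 2 * pnorm(-abs(zval))
  list(coefficients = data.frame(term = colnames(X) %||% paste0("b", 1:p),
                                 estimate = best$beta, se = se, z = zval,
                                 p = pval, row.names = NULL),
       sigma2 = s2, separation = separation, loglik = best$ll)
}

# Fit one conditional-independence claim; returns its p-value.
fit_claim <- function(claim, data, A, binary_vertex = NULL) {
  vars <- c(claim$predictor, claim$conditioning)
  Xc <- cbind(`(Intercept)` = 1,
              as.matrix(data[, vars, drop = FALSE]))
  y <- data[[claim$response]]
  if (!is.null(binary_vertex) && claim$response == binary_vertex) {
    fit <- phylo_logistic_fit(y, Xc, A)
  } else {
    fit <- pgls_fit(y, Xc, A)
  }
  fit$coefficients$p[fit$coefficients$term == claim$predictor][1]
}

#' d-separation test of a causal DAG
#'
#' Fisher's C = -2 sum(log p_i) over the k basis-set claims, compared to a
#' chi-square with 2k degrees of freedom; small p rejects the DAG.
#'
#' @param dag a `causal_dag` whose vertices name columns of `data`.
#' @param data data frame (continuous columns standardized internally).
#' @param tree `phylo` or covariance aligned with `data` rows.
#' @param binary_vertex name of a binary 0/1 vertex fitted by phylogenetic
#'   logistic regression when it is a claim's response (`NULL` for none).
#' @return list with `C`, `p`, `k` (number of claims), `claim_p` vector.
#' @export
dsep_test <- function(dag, data, tree, binary_vertex = NULL) {
  claims <- basis_set(dag)
  if (length(claims) == 0)
    return(list(C = 0, p = 1, k = 0L, claim_p = numeric(0)))
  A <- if (inherits(tree, "phylo")) phylo_covariance(tree) else tree
  ps <- vapply(claims, fit_claim, numeric(1), data = data, A = A,
               binary_vertex = binary_vertex)
  ps <- pmin(pmax(ps, 1e-300), 1)
  C <- -2 * sum(log(ps))
  list(C = C, p = pchisq(C, df = 2 * length(ps), lower.tail = FALSE),
       k = length(ps), claim_p = ps)
}

#' C-statistic information criterion (small-sample)
#'
#' CICc = C + 2 q n / (n - 1 - q) for a model with q parameters fitted to n
#' species.
#'
#' @param C Fisher's C.
#' @param q parameter count (number of edges).
#' @param n species count; must exceed q + 1.
#' @export
cicc <- function(C, q, n) {
  if (n <= q + 1) stop("n must exceed q + 1")
  C + 2 * q * n / (n - 1 - q)
}

#' Rank candidate models by CICc
#'
#' Delta CICc relative to the best model, CICc weights
#' w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2), and the supported set
#' (delta < 2, treated as equal support).
#'
#' @param cicc_values named numeric vector of CICc scores.
#' @return data frame with `model`, `cicc`, `delta`, `omega`, `supported`,
#'   sorted by CICc.
#' @export
rank_models <- function(cicc_values) {
  d <- cicc_values - min(cicc_values)
  w <- exp(-d / 2) / sum(exp(-d / 2))
  out <- data.frame(model = names(cicc_values), cicc = as.numeric(cicc_values),
                    delta = as.numeric(d), omega = as.numeric(w),
                    supported = as.numeric(d) < 2, row.names = NULL)
  out[order(out$cicc), ]
}

# Per-model standardized path coefficients: one regression per child vertex
# on its parents.
fit_paths <- function(dag, data, A, binary_vertex = NULL) {
  rows <- list()
  for (v in dag$vertices) {
    pa <- dag_parents(dag, v)
    if (length(pa) == 0) next
    Xc <- cbind(`(Intercept)` = 1, as.matrix(data[, pa, drop = FALSE]))
    y <- data[[v]]
    if (!is.null(binary_vertex) && v == binary_vertex) {
      fit <- phylo_logistic_fit(y, Xc, A)
    } else {
      fit <- pgls_fit(y, Xc, A)
    }
    cf <- fit$coefficients
    for (pv in pa) {
      i <- which(cf$term == pv)[1]
      rows[[length(rows) + 1L]] <-
        data.frame(from = pv, to = v, beta = cf$estimate[i],
                   var = cf$se[i]^2)
    }
  }
  if (length(rows) == 0) data.frame(from = character(), to = character(),
                                    beta = numeric(), var = numeric())
  else do.call(rbind, rows)
}

#' Model-averaged path coefficients
#'
#' Full averaging over the supported model set: weights renormalized over the
#' supported models; a path absent from a model contributes coefficient and
#' variance zero. 95% CIs by normal approximation on the averaged variance.
#'
#' @param path_tables named list of per-model path data frames (from
#'   `fit_paths`), restricted to the supported set.
#' @param omega weights of those models (renormalized internally).
#' @return data frame `from`, `to`, `beta`, `var`, `lower`, `upper`.
#' @export
average_paths <- function(path_tables, omega) {
  if (length(path_tables) == 0) stop("empty supported set")
  w <- omega / sum(omega)
  all_edges <- unique(do.call(rbind, lapply(path_tables, function(t)
    t[, c("from", "to")])))
  rows <- lapply(seq_len(nrow(all_edges)), function(i) {
    f <- all_edges$from[i]; t2 <- all_edges$to[i]
    beta <- 0; v <- 0
    for (m in seq_along(path_tables)) {
      tb <- path_tables[[m]]
      j <- which(tb$from == f & tb$to == t2)
      if (length(j) == 1) {
        beta <- beta + w[m] * tb$beta[j]
        v <- v + w[m] * tb$var[j]
      } # absent path: contributes zero
    }
    data.frame(from = f, to = t2, beta = beta, var = v,
               lower = beta - 1.96 * sqrt(v), upper = beta + 1.96 * sqrt(v))
  })
  do.call(rbind, rows)
}

#' Run the full phylogenetic path analysis
#'
#' Evaluates the four built-in candidate DAGs on a species table: d-sep test
#' per model, CICc ranking, and model-averaged standardized path
#' coefficients over the supported set. Continuous variables are z-scored;
#' the binary caste response (when `response_mode = "castes_binary"`) is
#' fitted by phylogenetic logistic regression.
#'
#' @param data species table with the transformed trait columns.
#' @param tree a `phylo` covering the species.
#' @param response_mode `"castes_binary"`, `"worker_cv"`, or
#'   `"worker_cv_monomorphic_only"`.
#' @return list with `ranking` (data frame incl. C, p, q, n), `fits`
#'   (per-model path tables), `averaged` (averaged coefficients), `n`.
#' @export
run_candidate_set <- function(data, tree,
                              response_mode = c("castes_binary", "worker_cv",
                                                "worker_cv_monomorphic_only")) {
  response_mode <- match.arg(response_mode)
  cols <- c(complexity = switch(response_mode,
                                castes_binary = "castes_binary",
                                "sqrt_worker_cv"),
            colony_size = "log10_colony_size",
            mating_frequency = "log10_mating_frequency",
            queen_number = "log10_queen_number")
  if (response_mode == "worker_cv_monomorphic_only")
    data <- data[!is.na(data$castes) & data$castes == 1, , drop = FALSE]
  d0 <- complete_cases_for(data, unname(cols))
  if (nrow(d0) < 10) stop("too few complete cases for path analysis")
  tr <- prune_to_taxa(tree, d0$species)
  d0 <- d0[match(normalize_species_names(tr$tip.label),
                 normalize_species_names(d0$species)), , drop = FALSE]
  binary <- response_mode == "castes_binary"
  dat <- data.frame(row.names = seq_len(nrow(d0)))
  for (v in names(cols)) {
    x <- d0[[cols[v]]]
    if (v == "complexity" && binary) {
      dat[[v]] <- as.integer(x == "multiple")
    } else {
      dat[[v]] <- as.numeric(scale(as.numeric(x)))
    }
  }
  A <- phylo_covariance(tr)
  dags <- candidate_dags()
  bv <- if (binary) "complexity" else NULL
  n <- nrow(dat)
  res <- lapply(dags, function(dg) {
    ds <- dsep_test(dg, dat, A, binary_vertex = bv)
    q <- nrow(dg$edges)
    list(dsep = ds, q = q, cicc = cicc(ds$C, q, n))
  })
  ciccs <- vapply(res, `[[`, numeric(1), "cicc")
  ranking <- rank_models(ciccs)
  ranking$C <- vapply(res[ranking$model], function(r) r$dsep$C, numeric(1))
  ranking$p_C <- vapply(res[ranking$model], function(r) r$dsep$p, numeric(1))
  ranking$q <- vapply(res[ranking$model], `[[`, numeric(1), "q")
  ranking$n <- n
  fits <- lapply(dags, fit_paths, data = dat, A = A, binary_vertex = bv)
  supported <- ranking$model[ranking$supported]
  averaged <- average_paths(fits[supported],
                            ranking$omega[ranking$supported])
  list(ranking = ranking, fits = fits, averaged = averaged, n = n,
       response_mode = response_mode)
}
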