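test_that("DAG construction and basis sets follow d-separation", {
  chain <- causal_dag(c("A -> B", "B -> C"))
  bs <- basis_set(chain)
  expect_length(bs, 1)
  expect_equal(bs[[1]]$response, "C")
  expect_equal(bs[[1]]$predictor, "A")
  expect_equal(bs[[1]]$conditioning, "B")
  # complete DAG: no claims
  full <- causal_dag(c("A -> B", "A -> C", "B -> C"))
  expect_length(basis_set(full), 0)
  expect_error(causal_dag(c("A -> B", "B -> A")), "cyclic")
  # built-in candidate set: claims are deterministic across calls
  dags <- candidate_dags()
  expect_named(dags, paste0("model", 1:4))
  b1 <- basis_set(dags$model1)
  expect_identical(b1, basis_set(dags$model1))
  expect_length(b1, 3)
  # every candidate includes the two always-present drivers of mating
  for (d in dags) {
    e <- paste(d$edges[, 1], d$edges[, 2])
    expect_true(all(c("queen_number mating_frequency",
                      "colony_size mating_frequency") %in% e))
  }
})

test_that("PGLS matches OLS at lambda 0 and an independent GLS oracle", {
  set.seed(31)
  tr <- unit_yule(80)
  A <- phylo_covariance(tr)
  x <- rnorm(80)
  y <- 0.5 * x + drop(crossprod(chol(0.6 * A + diag(0.4, 80)), rnorm(80)))
  f0 <- pgls_fit(y, cbind(1, x = x), A, lambda = 0)
  ols <- lm(y ~ x)
  expect_equal(unname(f0$coefficients$estimate), unname(coef(ols)),
               tolerance = 1e-10)
  expect_equal(f0$coefficients$se,
               unname(summary(ols)$coefficients[, 2]), tolerance = 1e-10)
  # profile-ML lambda and coefficients agree with nlme::gls + corPagel
  fit <- pgls_fit(y, cbind(1, x = x), A)
  d <- data.frame(y = y, x = x, sp = tr$tip.label)
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corPagel(0.5, tr, form = ~sp),
                 method = "ML")
  expect_equal(fit$coefficients$estimate[2], unname(coef(g)[2]),
               tolerance = 1e-4)
  expect_equal(fit$lambda, unname(coef(g$modelStruct$corStruct)),
               tolerance = 1e-3)
  expect_equal(fit$coefficients$se[2], sqrt(vcov(g)[2, 2]), tolerance = 1e-3)
  expect_error(pgls_fit(y, cbind(1, x, x), A), "singular")
})

test_that("phylogenetic logistic regression reduces to glm without signal", {
  set.seed(32)
  n <- 200
  x <- rnorm(n)
  y <- rbinom(n, 1, stats::plogis(-0.3 + 1.2 * x))
  A <- diag(n)
  f <- phylo_logistic_fit(y, cbind(1, x = x), A)
  g <- glm(y ~ x, family = binomial)
  expect_lt(abs(f$coefficients$estimate[2] - coef(g)[2]), 0.15)
  expect_false(f$separation)
  expect_error(phylo_logistic_fit(rep(1, n), cbind(1, x), A), "constant")
  # separation detected and handled by a penalized fit
  ys <- as.integer(x > 0)
  fs <- phylo_logistic_fit(ys, cbind(1, x = x), A)
  expect_true(fs$separation)
  expect_true(all(is.finite(fs$coefficients$se)))
})

test_that("Fisher's C arithmetic and the chi-square reference", {
  # all claims at p = 1: C = 0
  expect_equal(-2 * sum(log(c(1, 1, 1))), 0)
  d <- causal_dag(c("A -> B", "B -> C"))
  # two p = 0.5 claims: C = 2.7726, df = 4, survival e^(-x/2)(1 + x/2)
  C <- -2 * sum(log(c(0.5, 0.5)))
  expect_equal(C, 2.772589, tolerance = 1e-6)
  p <- pchisq(C, df = 4, lower.tail = FALSE)
  expect_equal(p, exp(-C / 2) * (1 + C / 2), tolerance = 1e-9)
  expect_equal(p, 0.5966, tolerance = 1e-4)
  # C additive over independent claim groups
  p_all <- c(0.2, 0.7, 0.4)
  expect_equal(-2 * sum(log(p_all)),
               -2 * sum(log(p_all[1:2])) + -2 * log(p_all[3]))
})

test_that("CICc formula and guards", {
  expect_equal(cicc(2, 3, 10), 2 + 2 * 3 * 10 / (10 - 1 - 3))
  expect_equal(cicc(2, 3, 10), 12)
  expect_equal(cicc(0, 0, 10), 0)
  expect_equal(cicc(1, 2, 1e9), 1 + 4, tolerance = 1e-6)
  expect_error(cicc(2, 9, 10), "exceed")
})

test_that("model ranking produces normalized CICc weights", {
  r <- rank_models(c(a = 10, b = 10))
  expect_equal(r$omega, c(0.5, 0.5))
  r2 <- rank_models(c(a = 10, b = 12))
  expect_equal(r2$omega[r2$model == "a"], exp(0) / (exp(0) + exp(-1)),
               tolerance = 1e-9)
  expect_equal(r2$omega[r2$model == "a"], 0.731, tolerance = 1e-3)
  expect_true(all(r2$supported == (r2$delta < 2)))
  # weights invariant to adding a constant; always sum to 1
  r3 <- rank_models(c(a = 110, b = 112))
  expect_equal(r3$omega, r2$omega)
  set.seed(33)
  for (i in 1:10) {
    w <- rank_models(setNames(runif(4, 0, 30), letters[1:4]))$omega
    expect_equal(sum(w), 1)
  }
})

test_that("path averaging uses renormalized weights and the zero convention", {
  t1 <- data.frame(from = "x", to = "y", beta = 1.0, var = 0.04)
  t2 <- data.frame(from = "z", to = "y", beta = 0.5, var = 0.01)
  avg <- average_paths(list(t1, t2), omega = c(0.6, 0.4))
  # x->y present only in model 1: averaged beta = 0.6 * 1.0
  expect_equal(avg$beta[avg$from == "x"], 0.6)
  expect_equal(avg$var[avg$from == "x"], 0.6 * 0.04)
  # single supported model: identity
  one <- average_paths(list(t1), omega = 1)
  expect_equal(one$beta, t1$beta)
  expect_equal(one$var, t1$var)
  # a path absent everywhere would average to zero by construction
  expect_error(average_paths(list(), 1), "empty")
})

test_that("candidate-set run ranks models and averages supported paths", {
  set.seed(34)
  d <- generate_species_table("size_complexity_true", n_species = 150)
  res <- run_candidate_set(d$table, d$tree, "castes_binary")
  expect_equal(sum(res$ranking$omega), 1)
  expect_true(all(res$ranking$cicc >= res$ranking$C))
  expect_equal(nrow(res$ranking), 4)
  # model 4 (mating only) should fail against size-driven data
  expect_false(res$ranking$model[1] == "model4")
  expect_true(all(c("from", "to", "beta", "lower", "upper") %in%
                    names(res$averaged)))
  # monomorphic-subset mode equals the plain CV mode on all-monomorphic data
  tab <- d$table
  tab$castes <- 1L
  tab$castes_binary <- "single"
  a <- run_candidate_set(tab, d$tree, "worker_cv")
  b <- run_candidate_set(tab, d$tree, "worker_cv_monomorphic_only")
  expect_equal(a$ranking$cicc, b$ranking$cicc)
  expect_equal(a$n, b$n)
})
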