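test_that("rate model builds valid generators and nests independence", {
  ri <- rate_model("independent", c(gain1 = 1, loss1 = 2, gain2 = 3, loss2 = 4))
  expect_equal(unname(rowSums(ri$Q)), rep(0, 4))
  expect_equal(ri$Q[1, 4], 0)  # no double transitions
  expect_equal(ri$Q[1, 3], 1)  # gain of trait1 while trait2 = 0
  expect_equal(ri$Q[2, 4], 1)  # same rate while trait2 = 1
  rd <- rate_model("dependent", 1:8)
  expect_equal(unname(rowSums(rd$Q)), rep(0, 4))
  expect_error(rate_model("independent", 1:8), "4 rates")
  expect_error(rate_model("dependent", c(-1, 1:7)), "non-negative")
})

test_that("pruning likelihood matches closed forms", {
  tr <- parse_newick("(A:1,B:1);")
  ts <- data.frame(species = c("A", "B"), trait1 = c(0, 0), trait2 = c(0, 0))
  # no change possible: root must be (0,0), uniform prior over 4 states
  expect_equal(pruning_loglik(tr, rate_model("independent", rep(0, 4)), ts),
               log(0.25))
  # symmetric 2-state trait1 (q = 1), trait2 frozen: marginal trait1
  # likelihood 0.5 (p00(1)^2 + p10(1)^2) times the 1/2 root mass on trait2
  p00 <- 0.5 * (1 + exp(-2)); p10 <- 0.5 * (1 - exp(-2))
  ll <- pruning_loglik(tr, rate_model("independent", c(1, 1, 0, 0)), ts)
  expect_equal(ll, log(0.5 * (p00^2 + p10^2)) + log(0.5), tolerance = 1e-10)
  expect_equal(exp(ll) / 0.5, 0.25458, tolerance = 1e-5)
  expect_error(
    pruning_loglik(tr, rate_model("independent", rep(1, 4)),
                   data.frame(species = c("A", "B"), trait1 = c(0, 2),
                              trait2 = c(0, 0))),
    "states must be")
})

test_that("pruning equals brute-force enumeration on small random trees", {
  set.seed(101)
  for (i in 1:100) {
    tr <- ape::rtree(sample(3:5, 1))
    kind <- sample(c("independent", "dependent"), 1)
    rm <- rate_model(kind, runif(if (kind == "independent") 4 else 8, 0, 3))
    n <- ape::Ntip(tr)
    ts <- data.frame(species = tr$tip.label,
                     trait1 = rbinom(n, 1, 0.5), trait2 = rbinom(n, 1, 0.5))
    # occasional missing data exercises the ambiguity path
    if (runif(1) < 0.2) ts$trait1[1] <- NA
    expect_equal(pruning_loglik(tr, rm, ts), enumeration_loglik(tr, rm, ts),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to tip ordering", {
  set.seed(7)
  tr <- ape::rtree(8)
  rm <- rate_model("dependent", runif(8, 0, 2))
  ts <- data.frame(species = tr$tip.label, trait1 = rbinom(8, 1, 0.5),
                   trait2 = rbinom(8, 1, 0.5))
  perm <- sample(8)
  expect_equal(pruning_loglik(tr, rm, ts), pruning_loglik(tr, rm, ts[perm, ]))
})

test_that("ML fit recovers structure: nesting and boundary cases", {
  set.seed(8)
  tr <- unit_yule(120)
  sim <- simulate_pair_ctmc(tr, rate_model("dependent", fig5_rates()),
                            root_state = 1)
  fd <- fit_ml(tr, sim$tip_states, "dependent", n_starts = 4)
  fi <- fit_ml(tr, sim$tip_states, "independent", n_starts = 3)
  expect_gte(fd$loglik, fi$loglik - 1e-6)
  # the generating zero rate is recovered near zero
  expect_lt(fd$model$rates["q12"], 0.2)
  # constant trait flagged
  ts_const <- sim$tip_states
  ts_const$trait2 <- 0
  fc <- fit_ml(tr, ts_const, "independent", n_starts = 2)
  expect_true(fc$constant_trait)
})

test_that("simulation matches the matrix-exponential law on one branch", {
  set.seed(9)
  tr <- parse_newick("(A:1,B:0.001);")
  rm <- rate_model("dependent", runif(8, 0.3, 1.5))
  P <- antphylo:::cpp_expm(rm$Q, 1)
  sims <- replicate(600, {
    s <- simulate_pair_ctmc(tr, rm, root_state = 1)
    st <- s$tip_states[s$tip_states$species == "A", ]
    1 + st$trait2 + 2 * st$trait1
  })
  freq <- tabulate(sims, 4) / 600
  for (s in 1:4) expect_lt(abs(freq[s] - P[1, s]), 4 * sqrt(P[1, s] * (1 - P[1, s]) / 600) + 0.01)
  # all-zero rates: tips equal the root state
  s0 <- simulate_pair_ctmc(tr, rate_model("independent", rep(0, 4)), root_state = 3)
  expect_equal(s0$tip_states$trait1, c(1, 1))
  expect_equal(s0$tip_states$trait2, c(0, 0))
  expect_equal(nrow(s0$events), 0)
})

test_that("hard-zero gain in the small class is honoured along histories", {
  set.seed(10)
  tr <- unit_yule(80)
  sim <- simulate_pair_ctmc(tr, rate_model("dependent", fig5_rates()),
                            root_state = 1)
  # every gain of trait2 (events x->x+1 in second position) happened while
  # trait1 was 1: transitions 1->2 (from state (0,0) to (0,1)) are impossible
  gains_from_small <- sum(sim$events$from == 1 & sim$events$to == 2)
  expect_equal(gains_from_small, 0)
})

test_that("bayes factor arithmetic and evidence labels", {
  expect_equal(bayes_factor(-9, -10), list(bf = 2, evidence = "no support"))
  expect_equal(bayes_factor(-10, -10)$bf, 0)
  expect_equal(bayes_factor(-5, -7.5)$evidence, "positive")
  expect_equal(bayes_factor(-5, -8)$evidence, "strong")
  expect_equal(bayes_factor(0, -10.415)$bf, 20.83)
  expect_equal(bayes_factor(0, -10.415)$evidence, "very strong")
  expect_error(bayes_factor(Inf, 0), "finite")
})

test_that("zero-rate proportion counts exact zeros", {
  ch <- list(rates = cbind(q12 = c(rep(0, 60), rep(1, 40)), q13 = rep(1, 100)))
  class(ch) <- "rj_chain"
  expect_equal(zero_rate_proportion(ch, "q12"), 0.6)
  expect_equal(zero_rate_proportion(ch, "q13"), 0)
  expect_equal(zero_rate_proportion(ch, 1), 0.6)
})
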