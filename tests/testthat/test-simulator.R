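test_that("Yule trees have the right shape and are seed-reproducible", {
  set.seed(51)
  tr <- simulate_yule(5)
  expect_equal(ape::Ntip(tr), 5)
  expect_equal(nrow(tr$edge), 8)  # 2n - 2
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  set.seed(99); a <- write_newick(simulate_yule(20))
  set.seed(99); b <- write_newick(simulate_yule(20))
  expect_identical(a, b)
  expect_error(simulate_yule(1), "at least 2")
  # depth grows roughly like log(n)/birth_rate
  set.seed(52)
  d10 <- mean(replicate(20, max(ape::node.depth.edgelength(simulate_yule(10)))))
  d80 <- mean(replicate(20, max(ape::node.depth.edgelength(simulate_yule(80)))))
  expect_gt(d80, d10)
})

test_that("continuous simulation respects the causal graph and lambda", {
  set.seed(53)
  tr <- unit_yule(40)
  V <- phylo_covariance(tr)
  # zero effects, lambda = 1: cross-replicate covariance tracks the tree
  reps <- replicate(300, simulate_continuous(
    tr, effects = list(x = c()), sigma2 = 1, lambda = 1)$x)
  emp <- cov(t(reps))
  expect_gt(cor(emp[upper.tri(emp)], V[upper.tri(V)]), 0.8)
  # lambda = 0: iid residuals
  reps0 <- replicate(300, simulate_continuous(
    tr, effects = list(x = c()), sigma2 = 1, lambda = 0)$x)
  emp0 <- cov(t(reps0))
  expect_lt(mean(abs(emp0[upper.tri(emp0)])), 0.1)
  # a 0.5 effect is recovered by PGLS
  set.seed(54)
  tr2 <- unit_yule(150)
  d <- simulate_continuous(tr2, effects = list(x = c(), y = c(x = 0.5)),
                           sigma2 = c(1, 0.3), lambda = 1)
  f <- pgls_fit(d$y, cbind(1, x = d$x), phylo_covariance(tr2))
  expect_lt(abs(f$coefficients$estimate[2] - 0.5),
            3 * f$coefficients$se[2] + 0.05)
  expect_error(simulate_continuous(tr, effects = list(x = c(y = 1), y = c(x = 1))),
               "cyclic")
})

test_that("synthetic species tables emulate the empirical trait regime", {
  meds <- vapply(1:4, function(s) {
    set.seed(s)
    median(generate_species_table("paper_like", n_species = 400)$table$colony_size)
  }, numeric(1))
  expect_true(all(meds > 200 & meds < 450))
  set.seed(5)
  d <- generate_species_table("paper_like", n_species = 400)
  tab <- d$table
  # point masses and skews
  expect_gt(mean(tab$mating_frequency == 1), 0.2)
  expect_gt(mean(tab$queen_number == 1), 0.3)
  expect_gt(mean(tab$castes == 1), 0.5)
  expect_true(all(tab$mating_frequency >= 1))
  expect_true(all(tab$queen_number >= 1))
  expect_gt(max(tab$colony_size) / min(tab$colony_size), 1e3)
  # same seed -> identical table
  set.seed(5)
  d2 <- generate_species_table("paper_like", n_species = 400)
  expect_identical(d$table, d2$table)
  # tree and table share the species set
  expect_setequal(tab$species, d$tree$tip.label)
  # the table passes the curation pipeline unchanged
  out <- binarize_traits(transform_traits(tab))
  expect_false(any(is.na(out$log10_colony_size)))
  expect_true(all(out$colony_size_class %in% c("small", "large")))
  # truth record carries the generating parameters
  expect_equal(d$truth$preset, "paper_like")
  expect_true(is.numeric(d$truth$b_size_mating))
})

test_that("causal presets wire the intended driver", {
  set.seed(6)
  d <- generate_species_table("size_complexity_true", n_species = 250)
  tab <- d$table
  m <- glm(I(castes_binary == "multiple") ~ scale(log10_colony_size),
           family = binomial, data = tab)
  expect_gt(coef(m)[2], 0.5)
  expect_equal(d$truth$driver, "colony_size")
  # null preset: once phylogeny is accounted for, size does not predict
  # castes (a naive non-phylogenetic test may still correlate them, which is
  # exactly the artefact the comparative methods exist to remove)
  set.seed(6)
  dn <- generate_species_table("null", n_species = 250)
  tab <- complete_cases_for(dn$table, c("species", "castes_binary",
                                        "log10_colony_size"))
  f <- phylo_logistic_fit(as.integer(tab$castes_binary == "multiple"),
                          cbind(1, s = as.numeric(scale(tab$log10_colony_size))),
                          phylo_covariance(dn$tree))
  expect_gt(f$coefficients$p[2], 0.01)
})
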