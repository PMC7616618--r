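test_that("harmonic-mean mating frequency follows the curation rule", {
  expect_equal(aggregate_mating_frequency(c(2, 2, 2)), 2)
  expect_equal(aggregate_mating_frequency(c(1, 2)), 2 / (1 + 0.5))
  expect_equal(aggregate_mating_frequency(1), 1)
  expect_true(is.na(aggregate_mating_frequency(numeric(0))))
  expect_error(aggregate_mating_frequency(c(0.5, 2)), "must be >= 1")
  # harmonic <= arithmetic, equality iff all equal
  set.seed(1)
  for (i in 1:20) {
    x <- 1 + rexp(sample(2:8, 1))
    expect_lte(aggregate_mating_frequency(x), mean(x))
  }
})

test_that("colony size aggregation weights by sample size", {
  expect_equal(aggregate_colony_size(500, 1), 500)
  expect_equal(aggregate_colony_size(c(100, 400), c(1, 3)), 325)
  expect_equal(aggregate_colony_size(c(10, 30), c(NA, NA)), 20)
  expect_true(is.na(aggregate_colony_size(numeric(0))))
  expect_error(aggregate_colony_size(c(-5, 10)), "positive")
})

test_that("worker-size CV is scale invariant and uses the sample sd", {
  expect_equal(worker_size_cv(c(2, 2, 2)), 0)
  expect_equal(worker_size_cv(c(9, 11)), sqrt(2) / 10)
  expect_equal(worker_size_cv(c(1, 2, 3)), 0.5)
  expect_true(is.na(worker_size_cv(1.5)))
  expect_error(worker_size_cv(c(-1, 2)), "positive")
  set.seed(2)
  for (i in 1:10) {
    x <- rlnorm(5); k <- runif(1, 0.1, 50)
    expect_equal(worker_size_cv(k * x), worker_size_cv(x))
  }
})

test_that("caste criteria map morphometric evidence to counts", {
  expect_identical(apply_caste_criteria(size_variation = "limited"), 1L)
  expect_identical(apply_caste_criteria(scaling = "monophasic_allometric"), 1L)
  expect_identical(
    apply_caste_criteria(scaling = "non_allometric", n_scaling_relationships = 2), 2L)
  expect_identical(apply_caste_criteria(literature_caste_count = 3), 3L)
  expect_error(
    apply_caste_criteria(size_variation = "limited", n_scaling_relationships = 3),
    "contradictory")
})

test_that("exclusion rules drop derived life histories but keep temporary parasites", {
  rec <- data.frame(
    species = c("a b", "c d", "e f", "g h"),
    exclusion_flags = c("supercolonial", "", "gamergate", "temporary_social_parasite"),
    stringsAsFactors = FALSE)
  out <- apply_exclusions(rec)
  expect_setequal(out$retained$species, c("c d", "g h"))
  expect_setequal(out$excluded$species, c("a b", "e f"))
  expect_equal(nrow(out$retained) + nrow(out$excluded), nrow(rec))
  expect_error(apply_exclusions(data.frame(species = "x", exclusion_flags = "weird")),
               "unknown exclusion flag")
})

test_that("binarization assigns ties to small/low and partitions species", {
  tab <- data.frame(colony_size = c(100, 300, 301, 5000),
                    mating_frequency = c(1, 2, 2.1, 6))
  out <- binarize_traits(tab, colony_rule = "median")
  thr <- attr(out, "colony_size_threshold")
  expect_equal(out$colony_size_class, ifelse(tab$colony_size <= thr, "small", "large"))
  expect_equal(out$mating_class, c("low", "low", "high", "high"))
  # every non-missing species in exactly one class
  expect_false(any(is.na(out$colony_size_class)))
  # median rule on a synthetic table splits roughly in half
  set.seed(3)
  d <- generate_species_table("paper_like", n_species = 200)$table
  b <- binarize_traits(d)
  expect_gt(mean(b$colony_size_class == "small"), 0.4)
  expect_lt(mean(b$colony_size_class == "small"), 0.62)
  expect_error(binarize_traits(data.frame(colony_size = NA_real_)), "missing")
})

test_that("trait transforms use log10 and square root", {
  tab <- data.frame(colony_size = 1000, mating_frequency = 1,
                    queen_number = 10, worker_cv = 0.25, castes = 3L)
  out <- transform_traits(tab)
  expect_equal(out$log10_colony_size, 3)
  expect_equal(out$log10_mating_frequency, 0)
  expect_equal(out$log10_queen_number, 1)
  expect_equal(out$sqrt_worker_cv, 0.5)
  expect_equal(out$castes_binary, "multiple")
  expect_error(transform_traits(data.frame(colony_size = -1)), "non-positive")
})

test_that("category collapse merges facultative with absent", {
  expect_equal(collapse_categories("facultative_polyandry", "obligate_binary"),
               "not_obligate")
  expect_equal(collapse_categories("obligate_polygyny", "obligate_binary"),
               "obligate")
  expect_equal(collapse_categories("monandry", "three_level"), "monandry")
  expect_error(collapse_categories("weird", "obligate_binary"), "unknown category")
})

test_that("species table construction aggregates repeated observations", {
  obs <- data.frame(
    species = c("X y", "X y", "X y", "Z w", "Z w"),
    castes = c(1, NA, NA, 2, NA),
    colony_size = c(100, 400, NA, 50, NA),
    colony_size_n = c(1, 3, NA, NA, NA),
    mating_frequency = c(1, 2, NA, NA, 3),
    head_width_mm = c(1, 2, 3, NA, NA),
    exclusion_flags = "",
    stringsAsFactors = FALSE)
  tab <- build_species_table(obs)
  xy <- tab[tab$species == "x_y", ]
  expect_equal(xy$colony_size, 325)
  expect_equal(xy$mating_frequency, 2 / 1.5)
  expect_equal(xy$worker_cv, 0.5)
  expect_equal(xy$n_colony_size_obs, 2)
  expect_equal(tab[tab$species == "z_w", "mating_frequency"], 3)
  # complete-case subsetting is per-analysis
  cc <- complete_cases_for(tab, c("log10_colony_size", "log10_mating_frequency"))
  expect_equal(nrow(cc), 2)
})
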