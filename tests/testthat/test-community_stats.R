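test_that("importance values match hand arithmetic", {
  one <- census_collection(
    data.frame(plot_id = "p", census_label = "t", species = "A",
               stems = 7L, basal_area_m2 = 0.4),
    toy_meta_df("p"))
  expect_equal(importance_values(one, "p", "t")$iv, 100)

  two <- census_collection(
    data.frame(plot_id = "p", census_label = "t", species = c("A", "B"),
               stems = c(4L, 4L), basal_area_m2 = c(0.2, 0.2)),
    toy_meta_df("p"))
  expect_equal(importance_values(two, "p", "t")$iv, c(50, 50))

  # counts 6,3,1 and basal areas 0.5,0.3,0.2: sp1 IV = (60 + 50)/2 = 55
  toy <- census_collection(
    data.frame(plot_id = "p", census_label = "t",
               species = c("sp1", "sp2", "sp3"), stems = c(6L, 3L, 1L),
               basal_area_m2 = c(0.5, 0.3, 0.2)),
    toy_meta_df("p"))
  iv <- importance_values(toy, "p", "t")
  expect_equal(iv$iv[iv$species == "sp1"], 55)
  expect_equal(iv$iv[iv$species == "sp2"], (30 + 30) / 2)
  expect_equal(iv$iv[iv$species == "sp3"], (10 + 20) / 2)
  expect_equal(iv$species, c("sp1", "sp2", "sp3"))  # sorted by descending IV

  expect_error(importance_values(toy, "p", "nope"),
               class = "bcri_design_error")
})

test_that("importance value columns sum to 100 on random stands", {
  for (seed in 1:5) {
    coll <- simulate_censuses(sim_config(seed = seed))
    gaps <- coll$meta$plot_id[coll$meta$treatment == "gap"]
    iv <- importance_values(coll, gaps, "post")
    expect_equal(sum(iv$relative_density), 100, tolerance = 1e-9)
    expect_equal(sum(iv$relative_ba), 100, tolerance = 1e-9)
    expect_equal(sum(iv$iv), 100, tolerance = 1e-9)
    expect_true(all(diff(iv$iv) <= 1e-12))
  }
})

test_that("change tests: identical gap and control changes give t = 0, p = 1", {
  coll <- mirrored_pairs_collection()
  res <- change_tests(coll, variables = c("stem_density", "basal_area"))
  expect_equal(res$t, c(0, 0))
  expect_equal(res$p_two_tailed, c(1, 1))
  expect_equal(res$df, c(1L, 1L))
})

test_that("basal area is converted to m2/ha with the plot area", {
  mk <- function(plot, label, ba)
    data.frame(plot_id = plot, census_label = label, species = "A",
               stems = 5L, basal_area_m2 = ba)
  census <- rbind(mk("g1", "pre", 0.3), mk("g1", "post", 0.6),
                  mk("c1", "pre", 0.3), mk("c1", "post", 0.3),
                  mk("g2", "pre", 0.3), mk("g2", "post", 0.6),
                  mk("c2", "pre", 0.3), mk("c2", "post", 0.3))
  meta <- data.frame(plot_id = c("g1", "c1", "g2", "c2"),
                     pair_id = rep(c("pair1", "pair2"), each = 2),
                     treatment = rep(c("gap", "control"), 2),
                     area_m2 = 100, forest_type = "f")
  coll <- census_collection(census, meta)
  res <- change_tests(coll, variables = "basal_area")
  # 0.6 - 0.3 = 0.3 m2 over 100 m2 -> +30 m2/ha
  expect_equal(res$gap_change, 30)
  expect_equal(res$control_change, 0)
  expect_equal(res$gap_se, 0)
})

test_that("change tests detect an imposed gap-only basal-area loss", {
  # generator defaults put pre-gap basal area near 67 m2/ha and post-gap
  # near 37 while controls gain slightly: effect sizes like a real felling
  # experiment, so the paired test should reject at alpha = 0.05
  coll <- simulate_censuses(sim_config(seed = 31))
  res <- change_tests(coll, variables = c("stem_density", "basal_area"),
                      endemics = NULL)
  ba <- res[res$variable == "basal_area", ]
  expect_lt(ba$gap_change, 0)
  expect_lt(ba$p_two_tailed, 0.05)
  expect_equal(ba$df, 3L)
})

test_that("change test t equals the independent paired formula", {
  coll <- simulate_censuses(sim_config(seed = 32))
  res <- change_tests(coll, variables = "stem_density")
  per_plot <- function(plot, label) {
    rows <- coll$census[coll$census$plot_id == plot &
                          coll$census$census_label == label, ]
    sum(rows$stems)
  }
  gd <- sapply(paste0("g", 1:4), function(p)
    per_plot(p, "post") - per_plot(p, "pre"))
  cd <- sapply(paste0("c", 1:4), function(p)
    per_plot(p, "post") - per_plot(p, "pre"))
  ora <- paired_t_oracle(gd, cd)
  expect_equal(res$t, ora$t)
  expect_equal(res$p_two_tailed, ora$p)
})

test_that("exclusion variants and endemics behave as configured", {
  coll <- simulate_censuses(sim_config(seed = 33))
  res <- change_tests(coll, variables = "stem_density",
                      exclude_species = "alien_invader")
  expect_equal(res$variable,
               c("stem_density", "stem_density without alien_invader"))
  # removing the invader lowers the post-gap counts, so the excluded
  # variant shows a smaller (or negative) gap change
  expect_lt(res$gap_change[2], res$gap_change[1])

  expect_error(change_tests(coll, variables = "endemic_density"),
               class = "bcri_config_error")
  res2 <- change_tests(coll, variables = "endemic_density",
                       endemics = c("sp01", "sp02", "sp03"))
  expect_true(is.finite(res2$p_two_tailed))

  single <- worked_example_collection()
  single$meta$pair_id[3:4] <- NA
  single$meta$treatment[4] <- "reference"
  small <- census_collection(single$census, single$meta)
  expect_error(change_tests(small, variables = "stem_density"),
               class = "bcri_design_error")
})

test_that("rarefaction expectation matches exhaustive enumeration", {
  counts <- c(5, 3, 2)
  ora <- rarefy_enum_oracle(counts, 4)  # all choose(10, 4) subsamples
  r <- rarefy(counts, 4)
  expect_equal(r$expected_species, ora$expected)
  expect_equal(r$variance, ora$variance)
  # and the closed form: 3 - (C(5,4) + C(7,4) + C(8,4))/C(10,4)
  expect_equal(r$expected_species, 3 - (5 + 35 + 70) / 210)
})

test_that("rarefaction boundary and error cases", {
  counts <- c(5, 3, 2)
  expect_equal(rarefy(counts, 10)$expected_species, 3)
  expect_equal(rarefy(counts, 1)$expected_species, 1)
  expect_equal(rarefy(counts, 1)$variance, 0, tolerance = 1e-12)
  expect_error(rarefy(counts, 0), class = "bcri_domain_error")
  expect_error(rarefy(counts, 11), class = "bcri_domain_error")
  expect_error(rarefy(counts, 2.5), class = "bcri_domain_error")
  expect_error(rarefy(c(2.5, 1), 2), class = "bcri_validation_error")
})

test_that("rarefaction is monotone and agrees with vegan on random stands", {
  skip_if_not_installed("vegan")
  set.seed(501)
  for (i in 1:5) {
    counts <- rpois(12, 4); counts[1] <- counts[1] + 1
    N <- sum(counts)
    es <- sapply(1:N, function(n) rarefy(counts, n)$expected_species)
    expect_true(all(diff(es) >= -1e-12))
    expect_equal(es[N], sum(counts > 0))
    for (n in unique(c(2, floor(N / 2), N - 1))) {
      # vegan warns when a random stand happens to lack singleton counts;
      # irrelevant to the expectation/variance being compared
      vr <- suppressWarnings(vegan::rarefy(matrix(counts, nrow = 1), n,
                                           se = TRUE))
      r <- rarefy(counts, n)
      expect_equal(r$expected_species, unname(vr[1, 1]), tolerance = 1e-10)
      expect_equal(sqrt(r$variance), unname(vr[2, 1]), tolerance = 1e-8)
    }
  }
})

test_that("resampling rarefaction approximates the analytic expectation", {
  counts <- c(12, 6, 4, 2, 1)
  a <- rarefy(counts, 10)
  r1 <- rarefy(counts, 10, method = "resample", n_resample = 2000, seed = 99)
  r2 <- rarefy(counts, 10, method = "resample", n_resample = 2000, seed = 99)
  expect_identical(r1, r2)  # seeded
  expect_equal(r1$expected_species, a$expected_species, tolerance = 0.05)
})
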