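test_that("bray_curtis matches hand-evaluated cases", {
  expect_equal(bray_curtis(c(5, 3, 2), c(5, 3, 2)), 1)
  expect_equal(bray_curtis(c(5, 0), c(0, 3)), 0)
  expect_equal(bray_curtis(c(5, 3, 2), c(10, 6, 4)), 2 / 3)
  expect_equal(bray_curtis(c(4, 1, 0), c(2, 3, 5)), 0.4)
})

test_that("degenerate similarity inputs raise typed errors", {
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), class = "bcri_shape_error")
  expect_error(bray_curtis(c(0, 0), c(0, 0)),
               class = "bcri_undefined_input_error")
  expect_error(horn_morisita(c(0, 0), c(0, 0)),
               class = "bcri_undefined_input_error")
  expect_error(chao_jaccard(c(0, 0), c(0, 0)),
               class = "bcri_undefined_input_error")
  expect_error(bray_curtis(c(-1, 2), c(1, 2)),
               class = "bcri_validation_error")
  # one empty community is defined: similarity 0
  expect_equal(bray_curtis(c(1, 2), c(0, 0)), 0)
  expect_equal(horn_morisita(c(1, 2), c(0, 0)), 0)
})

test_that("horn_morisita matches hand-evaluated cases", {
  expect_equal(horn_morisita(c(4, 1, 7), c(4, 1, 7)), 1)
  expect_equal(horn_morisita(c(4, 1, 0), c(2, 3, 5)), 22 / 53)
})

test_that("chao_jaccard matches hand-evaluated cases", {
  expect_equal(chao_jaccard(c(5, 3, 2), c(5, 3, 2)), 1)
  expect_equal(chao_jaccard(c(5, 0, 2), c(0, 3, 0)), 0)
  expect_equal(chao_jaccard(c(5, 3, 2), c(10, 6, 4), corrected = FALSE), 1)
  # shared species 1 and 2: U = 5/5 = 1, V = 5/10 -> J = 0.5/(1.5 - 0.5)
  expect_equal(chao_jaccard(c(4, 1, 0), c(2, 3, 5), corrected = FALSE), 0.5)
  expect_error(chao_jaccard(c(1.5, 2), c(1, 2), corrected = TRUE),
               class = "bcri_validation_error")
  expect_equal(chao_jaccard(c(1.5, 2), c(1, 2), corrected = FALSE),
               chao_uncorr_oracle(c(1.5, 2), c(1, 2)))
})

test_that("the separation property holds: scaling fools proportionate indices only", {
  # a community with twice the stems of every species: the recovery-relevant
  # difference that proportionate indices cannot see
  set.seed(401)
  for (i in 1:25) {
    x <- rpois(10, 4) + 1
    for (k in c(2, 3, 7.5)) {
      expect_equal(bray_curtis(x, k * x), 2 / (1 + k))
      expect_lt(bray_curtis(x, k * x), 1)
      expect_equal(horn_morisita(x, k * x), 1)
      expect_equal(chao_jaccard(x, k * x, corrected = FALSE), 1)
    }
  }
})

test_that("indices agree with independent brute-force oracles on random vectors", {
  set.seed(402)
  for (i in 1:300) {
    p <- random_count_pair()
    expect_equal(bray_curtis(p$x, p$y), bc_oracle(p$x, p$y))
    expect_equal(horn_morisita(p$x, p$y),
                 min(max(mh_oracle(p$x, p$y), 0), 1))
    expect_equal(chao_jaccard(p$x, p$y, corrected = FALSE),
                 chao_uncorr_oracle(p$x, p$y))
  }
})

test_that("indices are symmetric, bounded, 1 on identity, 0 on disjoint support", {
  set.seed(403)
  idx <- list(bray_curtis,
              horn_morisita,
              function(a, b) chao_jaccard(a, b, corrected = FALSE),
              function(a, b) chao_jaccard(a, b, corrected = TRUE))
  for (i in 1:60) {
    p <- random_count_pair()
    for (f in idx) {
      v <- f(p$x, p$y)
      expect_gte(v, 0); expect_lte(v, 1)
      expect_equal(v, f(p$y, p$x))
      expect_equal(f(p$x, p$x), 1)
    }
    half <- seq_along(p$x) <= length(p$x) / 2
    a <- ifelse(half, p$x + 1, 0)
    b <- ifelse(half, 0, p$y + 1)
    expect_equal(bray_curtis(a, b), 0)
    expect_equal(chao_jaccard(a, b), 0)
  }
})

test_that("corrected chao_jaccard and horn_morisita agree with vegan", {
  skip_if_not_installed("vegan")
  set.seed(404)
  for (i in 1:100) {
    p <- random_count_pair(n_species = 15, lambda = 2)
    m <- rbind(p$x, p$y)
    expect_equal(chao_jaccard(p$x, p$y, corrected = TRUE),
                 1 - as.numeric(vegan::vegdist(m, method = "chao")),
                 tolerance = 1e-12)
    expect_equal(horn_morisita(p$x, p$y),
                 1 - as.numeric(vegan::vegdist(m, method = "horn")),
                 tolerance = 1e-12)
    expect_equal(bray_curtis(p$x, p$y),
                 1 - as.numeric(vegan::vegdist(m, method = "bray")),
                 tolerance = 1e-12)
  }
})

test_that("tanner_index composes its Bray-Curtis components", {
  w <- worked_example_collection()
  t1 <- tanner_index(w, "g1", "pre", "g1", "pre")
  expect_equal(t1, list(bc_density = 1, bc_ba = 1, bc_ri = 1))

  # identical stems, doubled basal areas: density similarity perfect, size
  # structure off by the doubled-community factor
  cen <- rbind(
    data.frame(plot_id = "a", census_label = "t", species = c("A", "B"),
               stems = c(5L, 3L), basal_area_m2 = c(0.1, 0.2)),
    data.frame(plot_id = "b", census_label = "t", species = c("A", "B"),
               stems = c(5L, 3L), basal_area_m2 = c(0.2, 0.4)))
  meta <- rbind(toy_meta_df("a"), toy_meta_df("b", "control"))
  coll <- census_collection(cen, meta)
  tt <- tanner_index(coll, "a", "t", "b", "t")
  expect_equal(tt$bc_density, 1)
  expect_equal(tt$bc_ba, 2 / 3)
  expect_equal(tt$bc_ri, 5 / 6)

  # hand-built worked example, checked against direct formula evaluation
  tg <- tanner_index(w, "g1", "pre", "g1", "post")
  expect_equal(tg$bc_density, bc_oracle(c(10, 5, 5, 0), c(6, 4, 0, 10)))
  expect_equal(tg$bc_ba,
               bc_oracle(c(0.30, 0.10, 0.10, 0), c(0.06, 0.04, 0, 0.05)))
  expect_equal(tg$bc_ri, (tg$bc_density + tg$bc_ba) / 2)
})

test_that("tanner bc_ri lies between its components on random data", {
  for (seed in 1:5) {
    coll <- simulate_censuses(sim_config(seed = seed))
    for (g in c("g1", "g3")) {
      tt <- tanner_index(coll, g, "pre", g, "post")
      expect_gte(tt$bc_ri, min(tt$bc_density, tt$bc_ba))
      expect_lte(tt$bc_ri, max(tt$bc_density, tt$bc_ba))
    }
  }
})

test_that("pairwise_similarity preserves input order and handles edge lists", {
  w <- worked_example_collection()
  empty <- data.frame(plot_a = character(0), census_a = character(0),
                      plot_b = character(0), census_b = character(0))
  expect_equal(nrow(pairwise_similarity(w, empty, "tanner")), 0)

  cmp <- data.frame(plot_a = c("g1", "g1", "g2", "c1"),
                    census_a = c("pre", "pre", "pre", "pre"),
                    plot_b = c("g1", "g1", "g2", "c1"),
                    census_b = c("pre", "post", "post", "pre"))
  res <- pairwise_similarity(w, cmp, "bray_curtis_density")
  expect_equal(nrow(res), 4)
  expect_equal(res$value[1], 1)
  expect_equal(res$value[4], 1)
  expect_equal(res$value[2],
               bray_curtis(abundance_vectors(w, "g1", "pre"),
                           abundance_vectors(w, "g1", "post")))
  expect_error(pairwise_similarity(w, cmp[, -1], "tanner"),
               class = "bcri_format_error")
  cmp$plot_a[1] <- "nope"
  expect_error(pairwise_similarity(w, cmp, "tanner"),
               class = "bcri_lookup_error")
})
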