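test_that("zscore_columns standardizes with population sd", {
  z <- zscore_columns(matrix(c(1, 3), 2, 1, dimnames = list(NULL, "v")))
  expect_equal(as.vector(z$z), c(-1, 1))

  set.seed(2)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
  zs <- zscore_columns(x)
  expect_true(all(abs(colMeans(zs$z)) < 1e-10))
  # idempotence on an already standardized column
  z2 <- zscore_columns(zs$z)
  expect_equal(z2$z, zs$z, tolerance = 1e-12)
  # round trip
  back <- sweep(sweep(zs$z, 2, zs$sds, "*"), 2, zs$means, "+")
  expect_equal(back, x, tolerance = 1e-9)

  xc <- cbind(x, fixed = 5)
  expect_error(zscore_columns(xc), "fixed")
})

test_that("build_worst_case picks extremes by orientation", {
  ea <- data.frame(ea_id = 1:5, a = c(1, 4, 2, 5, 3), b = c(9, 7, 8, 6, 5))
  sp_hi <- rbind(variable_spec("a", "higher-is-worse", "hazard"),
                 variable_spec("b", "higher-is-worse", "hazard"))
  expect_equal(build_worst_case(ea, sp_hi)$raw, c(a = 5, b = 9))

  sp_mix <- rbind(variable_spec("a", "higher-is-worse", "hazard"),
                  variable_spec("b", "lower-is-worse", "hazard"))
  expect_equal(build_worst_case(ea, sp_mix)$raw, c(a = 5, b = 5))

  expect_error(build_worst_case(ea, variable_spec("zzz")), "lacks")
})

test_that("cosine_similarity matches direct arithmetic", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 3), c(4, 5, 6)),
               32 / (sqrt(14) * sqrt(77)))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(cosine_similarity(1:2, 1:3), "equal length")
})

test_that("similarity_rank_index matches the brute-force oracle", {
  set.seed(14)
  ea <- data.frame(ea_id = 1:20, a = rnorm(20), b = runif(20),
                   c = rpois(20, 4))
  specs <- rbind(variable_spec("a", "higher-is-worse", "exposure"),
                 variable_spec("b", "lower-is-worse", "exposure"),
                 variable_spec("c", "higher-is-worse", "exposure"))
  ix <- similarity_rank_index(ea, specs)
  orc <- oracle_cosine_ranks(as.matrix(ea[, c("a", "b", "c")]),
                             specs$orientation)
  expect_equal(ix$similarity, unname(orc$cos))
  expect_equal(ix$rank, orc$rank)
  expect_equal(ix$score, orc$score)
  expect_setequal(ix$rank, 1:20)
  expect_equal(range(ix$score), c(0, 1))
})

test_that("index ranks are scale invariant and endpoints behave", {
  set.seed(15)
  ea <- data.frame(ea_id = 1:12, a = rnorm(12), b = runif(12))
  specs <- rbind(variable_spec("a"), variable_spec("b"))
  r1 <- similarity_rank_index(ea, specs)$rank
  ea2 <- ea; ea2$a <- ea2$a * 1000; ea2$b <- ea2$b * 0.01
  expect_identical(similarity_rank_index(ea2, specs)$rank, r1)

  # an EA equal to the worst case gets rank 1, score 1
  ea$a[4] <- max(ea$a); ea$b[4] <- max(ea$b)
  ix <- similarity_rank_index(ea, specs)
  expect_equal(ix$rank[4], 1L)
  expect_equal(ix$score[4], 1)

  # N = 2: scores exactly {1, 0}
  ix2 <- similarity_rank_index(data.frame(ea_id = 1:2, a = c(1, 2)),
                               variable_spec("a"))
  expect_setequal(ix2$score, c(0, 1))
})

test_that("single-variable index orders by the raw variable", {
  set.seed(16)
  ea <- data.frame(ea_id = 1:15, tt = runif(15, 5, 300))
  ix <- similarity_rank_index(ea, variable_spec("tt", "higher-is-worse",
                                                "scarcity"))
  expect_identical(order(-ix$score), order(-ea$tt))
  # lower-is-worse flips the ordering
  ixl <- similarity_rank_index(ea, variable_spec("tt", "lower-is-worse",
                                                 "scarcity"))
  expect_identical(order(-ixl$score), order(ea$tt))
})

test_that("landscape metrics: closed forms and checkerboard oracle", {
  ear <- grid_layer(matrix(1L, 4, 4), 500)
  mono <- grid_layer(matrix(3, 4, 4), 500)
  m <- landscape_metrics(mono, ear)
  expect_equal(m$shannon, 0)
  expect_equal(m$edge_density, 0)

  half <- grid_layer(matrix(rep(c(1, 2), each = 8), 4, 4), 500)
  expect_equal(landscape_metrics(half, ear)$shannon, log(2))

  chk <- grid_layer((outer(1:4, 1:4, "+") %% 2) + 1, 500)
  # 4x4 checkerboard: 12 horizontal + 12 vertical differing pairs
  mc <- landscape_metrics(chk, ear)
  area <- 16 * 500^2
  expect_equal(mc$edge_density, 24 * 500 / area)
  expect_equal(mc$shannon, log(2))
})

test_that("build_all_indices wires variables to the right indices", {
  set.seed(20)
  n <- 10
  ea <- data.frame(
    ea_id = 1:n, poverty = runif(n), prop_firewood = runif(n),
    prop_candles_paraffin = runif(n), prop_elderly = runif(n, 0, .2),
    prop_children_youth = runif(n, .3, .7),
    building_density = runif(n, 5, 300),
    building_occupancy = runif(n, 2, 6), poultry = rbinom(n, 1, .5),
    prop_builtup = runif(n), prop_cropland = runif(n),
    prop_trees = runif(n))
  richness <- data.frame(ea_id = 1:n, mean = runif(n, 2, 9))
  counts <- data.frame(ea_id = 1:n, cases = rpois(n, 3))
  tt <- data.frame(ea_id = 1:n, minutes = runif(n, 0, 200))
  frag <- data.frame(ea_id = 1:n, shannon = runif(n, 0, 1.3),
                     edge_density = runif(n, 0, .002))
  # make EA 3 the worst case on both hazard variables
  richness$mean[3] <- 9.5; counts$cases[3] <- max(counts$cases) + 5
  ix <- build_all_indices(ea, richness, counts, tt, frag)
  expect_named(ix, c("hazard", "exposure", "susceptibility", "scarcity"))
  expect_equal(ix$hazard$score[ix$hazard$ea_id == 3], 1)
  # scarcity is single-variable: ordering equals travel-time ordering
  expect_identical(order(-ix$scarcity$score), order(-tt$minutes))
  expect_error(build_all_indices(ea, richness[-1, ], counts, tt, frag),
               "mismatch")
})

test_that("planted separation: urban susceptibility below rural-poor", {
  cfg <- landscape_config()
  ge <- generate_eas(cfg, generate_rasters(cfg))
  tab <- ge$eas$table
  sp <- default_variable_specs()
  sus <- similarity_rank_index(
    tab, sp[sp$index == "susceptibility", ], "susceptibility")
  sc <- sus$score[match(tab$ea_id, sus$ea_id)]
  expect_lt(median(sc[tab$archetype == "urban"]),
            median(sc[tab$archetype == "rural_poor"]))
})
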