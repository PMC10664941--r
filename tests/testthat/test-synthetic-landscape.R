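test_that("config validation catches bad inputs", {
  expect_error(landscape_config(grid_rows = 10), "at least 20")
  expect_error(landscape_config(archetype_mix = c(
    urban = .5, peri_urban = .5, commercial_protected = .2,
    rural_poor = 0)), "sum to 1")
  expect_error(landscape_config(elevation_rate_effect = 1), "\\[0, 1\\)")
  expect_error(landscape_config(elevation_range = c(100, 50)), "increasing")
  expect_error(landscape_config(n_species = 0), "n_species")
})

test_that("elevation spans the configured range and is monotone sans noise", {
  cfg <- landscape_config()
  ras <- generate_rasters(cfg)
  e <- ras$elevation$values
  expect_lt(abs(min(e) - 71) / 71, 0.01)
  expect_lt(abs(max(e) - 1499) / 1499, 0.01)

  cfg0 <- landscape_config(elevation_noise = 0)
  e0 <- generate_rasters(cfg0)$elevation$values
  expect_true(all(apply(e0, 1L, function(r) all(diff(r) < 0))))
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- tiny_config(seed = 7L)
  a <- simulate_landscape(cfg)
  b <- simulate_landscape(cfg)
  expect_identical(a$rasters$elevation$values, b$rasters$elevation$values)
  expect_identical(a$rasters$landcover$values, b$rasters$landcover$values)
  expect_identical(a$eas$table, b$eas$table)
  expect_identical(a$species$occurrences, b$species$occurrences)
  expect_identical(a$facilities, b$facilities)
  expect_identical(a$cases, b$cases)
})

test_that("EA tiling is exact and covers the grid", {
  cfg <- tiny_config()
  cfg$n_eas <- 4L
  ras <- generate_rasters(cfg)
  ge <- generate_eas(cfg, ras)
  expect_equal(nrow(ge$eas$table), 4L)
  ids <- ge$eas$raster$values
  expect_true(all(ids %in% 1:4))
  expect_setequal(unique(as.vector(ids)), 1:4)
  # block bounds partition the grid: total cells match
  tab <- ge$eas$table
  areas <- (tab$row1 - tab$row0 + 1) * (tab$col1 - tab$col0 + 1)
  expect_equal(sum(areas), prod(dim(ids)))
})

test_that("degenerate archetype mix gives all rural-poor with high poverty", {
  cfg <- tiny_config()
  cfg$archetype_mix <- c(urban = 0, peri_urban = 0,
                         commercial_protected = 0, rural_poor = 1)
  ge <- generate_eas(cfg, generate_rasters(cfg))
  expect_true(all(ge$eas$table$archetype == "rural_poor"))

  ged <- generate_eas(tiny_config(), generate_rasters(tiny_config()))
  expect_gte(mean(ge$eas$table$poverty), mean(ged$eas$table$poverty))
})

test_that("planted archetype separation: between > within variance", {
  cfg <- landscape_config()
  ge <- generate_eas(cfg, generate_rasters(cfg))
  tab <- ge$eas$table
  grand <- mean(tab$poverty)
  grp <- split(tab$poverty, tab$archetype)
  between <- sum(vapply(grp, function(g)
    length(g) * (mean(g) - grand)^2, 1)) / nrow(tab)
  within <- sum(vapply(grp, function(g)
    sum((g - mean(g))^2), 1)) / nrow(tab)
  expect_gt(between, within)
})

test_that("species layers: zero weights flatten suitability to 0.5", {
  cfg <- tiny_config()
  ras <- generate_rasters(cfg)
  w <- matrix(0, cfg$n_species, 7)
  sp <- generate_species_layers(cfg, ras, weights = w)
  for (s in sp$suitability)
    expect_true(all(abs(s$values - 0.5) < 1e-12))
  expect_true(all(vapply(sp$suitability, function(s)
    all(s$values >= 0 & s$values <= 1), TRUE)))
})

test_that("facility placement honours the count and urban weighting", {
  cfg <- tiny_config()
  eas <- generate_eas(cfg, generate_rasters(cfg))$eas
  expect_error(generate_facilities(
    landscape_config(n_facilities = 0), eas), "at least one")

  cfg1 <- tiny_config()
  cfg1$n_facilities <- 1L
  expect_equal(nrow(generate_facilities(cfg1, eas)), 1L)

  cfgd <- landscape_config()
  easd <- generate_eas(cfgd, generate_rasters(cfgd))$eas
  fac <- generate_facilities(cfgd, easd)
  expect_equal(nrow(fac), 20L)
  # placement-weight oracle: expected urban/peri share from the weights
  w <- c(urban = 10, peri_urban = 5, commercial_protected = 1,
         rural_poor = 1)[easd$table$archetype]
  share <- sum(w[easd$table$archetype %in% c("urban", "peri_urban")]) / sum(w)
  expect_gte(share, 0.6)
  # every facility cell actually lies inside its EA block
  tab <- easd$table[match(fac$ea_id, easd$table$ea_id), ]
  expect_true(all(fac$row >= tab$row0 & fac$row <= tab$row1 &
                    fac$col >= tab$col0 & fac$col <= tab$col1))
})

test_that("case registry conserves counts and carries valid EA ids", {
  cfg <- tiny_config()
  ge <- generate_eas(cfg, generate_rasters(cfg))
  cases <- generate_cases(cfg, ge$eas, ge$truth)
  cnt <- attr(cases, "ea_counts")
  expect_equal(sum(cnt$cases), nrow(cases))
  expect_true(all(cases$ea_id %in% ge$eas$table$ea_id))

  cfg0 <- tiny_config()
  cfg0$baseline_rate <- 0
  cases0 <- generate_cases(cfg0, ge$eas,
                           generate_eas(cfg0, generate_rasters(cfg0))$truth)
  expect_equal(nrow(cases0), 0L)
})

test_that("planted elevation effect appears exactly in the truth rates", {
  cfg <- landscape_config()
  ge <- generate_eas(cfg, generate_rasters(cfg))
  tr <- ge$truth
  # within one archetype the rate ratio across 100 m is exactly 1 - 0.038
  rp <- tr[tr$archetype == "rural_poor", ]
  i <- 1L; j <- 2L
  ratio <- (rp$expected_rate[i] / rp$expected_rate[j])
  expected <- (1 - cfg$elevation_rate_effect)^(
    (rp$mean_elevation[i] - rp$mean_elevation[j]) / 100)
  expect_equal(ratio, expected, tolerance = 1e-12)
})

test_that("attribute tables are recovered within 3 MC standard errors", {
  n <- 10000L
  reg <- simulate_registry(landscape_config(), n_target = n)
  expect_equal(nrow(reg), n)
  tbl <- default_attribute_tables()
  mc_ok <- function(obs_p, p)
    abs(obs_p - p) <= 3 * sqrt(p * (1 - p) / n)
  expect_true(mc_ok(mean(reg$hour >= 18 & reg$hour < 22), 0.30))
  expect_true(mc_ok(mean(reg$sex == "male"), tbl$sex[["male"]]))
  expect_true(mc_ok(mean(reg$month == "Jan"), tbl$month[["Jan"]]))
  expect_true(mc_ok(mean(reg$first_aid_any), tbl$first_aid_any))
  expect_true(mc_ok(mean(reg$antivenom), tbl$antivenom))
  expect_true(mc_ok(mean(is.na(reg$syndrome)),
                    tbl$syndrome[["not recorded"]]))
  # January is the modal month
  expect_equal(names(which.max(table(reg$month))), "Jan")
  # vials: only with antivenom, range 1-25, mean ~5
  expect_true(all(is.na(reg$vials[!reg$antivenom])))
  v <- reg$vials[reg$antivenom]
  expect_true(all(v >= 1 & v <= 25))
  expect_lt(abs(mean(v) - 5), 3 * sd(v) / sqrt(length(v)))
})
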