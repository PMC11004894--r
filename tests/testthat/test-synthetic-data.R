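test_that("polygon segmentation tiles fields exactly and conserves area", {
  # interior polygon area is the product of the three machine factors
  ly <- field_layout("A", "test", width = 10, length = 20)
  cfg <- sim_config(swath_width = 2, harvester_speed = 1,
                    measurement_interval = 1)
  polys <- segment_polygons(ly, cfg)
  expect_true(all(abs(polys$area - 2) < 1e-12))  # 2 x 1 x 1, no truncation
  expect_equal(sum(polys$area), 10 * 20)

  # truncated edges: areas still sum to the exact geometric field area
  for (dims in list(c(37.3, 101.9), c(8, 9.5), c(50, 50))) {
    ly2 <- field_layout("B", "control", width = dims[1], length = dims[2])
    cfg2 <- sim_config(swath_width = 7.2, harvester_speed = 2,
                       measurement_interval = 3)
    p2 <- segment_polygons(ly2, cfg2)
    expect_equal(sum(p2$area), dims[1] * dims[2], tolerance = 1e-10)
    # centroids inside the field
    expect_true(all(p2$x > 0 & p2$x < dims[1]))
    expect_true(all(p2$y > 0 & p2$y < dims[2]))
    # interior polygons carry the nominal area
    nominal <- 7.2 * 2 * 3
    expect_true(any(abs(p2$area - nominal) < 1e-12))
    expect_true(all(p2$area <= nominal + 1e-12))
  }

  # a field smaller than one polygon is a degenerate geometry
  small <- field_layout("S", "test", width = 1, length = 100)
  expect_error(segment_polygons(small, cfg2), "smaller than one polygon")
})

test_that("a measurement record round-trips through the CSV and GeoJSON writers", {
  # the worked example: one polygon of 86.6 m^2 yielding 4040 kg/ha
  m <- structure(data.frame(field_id = "F01", group = "test",
                            x = 12.5, y = 30.25, area = 86.6,
                            dry_yield = 4040, stringsAsFactors = FALSE),
                 class = c("yield_measurements", "data.frame"))
  csv <- withr::local_tempfile(fileext = ".csv")
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_measurements_csv(m, csv)
  write_measurements_geojson(m, gj)
  expect_identical(readLines(csv)[1],
                   "field_id,group,x,y,area_m2,dry_yield_kg_ha")
  for (back in list(read_measurements(csv), read_measurements(gj))) {
    expect_equal(back$dry_yield, 4040)
    expect_equal(back$area, 86.6)
    expect_equal(back$x, 12.5)
    expect_identical(back$group, "test")
  }
})

test_that("fertility surface has the configured marginal sd and short-range correlation", {
  # short correlation length relative to the field so the empirical sd has
  # enough effectively independent patches to estimate
  ly <- field_layout("A", "test", width = 300, length = 300)
  cfg <- sim_config(fertility_scale = 10, fertility_sd = 350, seed = 11)
  surf <- simulate_fertility_surface(ly, cfg)

  set.seed(99)
  xs <- runif(10000, 0, 300); ys <- runif(10000, 0, 300)
  vals <- surf(xs, ys)
  expect_lt(abs(sd(vals) - 350) / 350, 0.10)  # within 10% of configured sd
  expect_lt(abs(mean(vals)), 3 * 350 / sqrt(100))  # mean near 0 (few eff. dof)

  # points closer than the correlation length move together
  v0 <- surf(xs[1:500], ys[1:500])
  v_near <- surf(xs[1:500] + 5, ys[1:500])
  expect_gt(cor(v0, v_near), 0.5)

  # determinism and the zero-variance degenerate case
  surf2 <- simulate_fertility_surface(ly, cfg)
  expect_identical(surf(xs[1:50], ys[1:50]), surf2(xs[1:50], ys[1:50]))
  flat <- simulate_fertility_surface(ly, sim_config(fertility_sd = 0, seed = 11))
  expect_identical(flat(xs[1:50], ys[1:50]), rep(0, 50))
})

test_that("simulated measurements recover the configured effect and respect group labels", {
  ly <- tiny_layouts(2, width = 60, length = 200)
  # all randomness off: yields are exactly the group means
  m0 <- flat_measurements(ly, effect = 0, seed = 3)
  expect_true(all(m0$dry_yield == 2550))
  m1 <- flat_measurements(ly, effect = 1000, seed = 3)
  expect_true(all(m1$dry_yield[m1$group == "test"] == 3550))
  expect_true(all(m1$dry_yield[m1$group == "control"] == 2550))

  # group labels partition measurements exactly as the layouts specify
  lab <- setNames(ly$group, ly$field_id)
  expect_identical(unname(lab[m1$field_id]), m1$group)

  # with noise on, the mean difference sits within 3 SE of the truth
  m2 <- simulate_measurements(ly, sim_config(
    treatment_effect = 1000, noise_sd = 400, fertility_sd = 0,
    outlier_rate = 0, seed = 21))
  dt <- m2$dry_yield[m2$group == "test"]; dc <- m2$dry_yield[m2$group == "control"]
  se <- sqrt(var(dt) / length(dt) + var(dc) / length(dc))
  expect_lt(abs(mean(dt) - mean(dc) - 1000), 3 * se)

  # determinism: same config, same dataset
  expect_identical(m2, simulate_measurements(ly, sim_config(
    treatment_effect = 1000, noise_sd = 400, fertility_sd = 0,
    outlier_rate = 0, seed = 21)))

  # outliers appear at roughly the configured rate
  m3 <- simulate_measurements(ly, sim_config(
    noise_sd = 100, fertility_sd = 0, outlier_rate = 0.05,
    outlier_magnitude = 10, seed = 4))
  n_far <- sum(abs(m3$dry_yield - ave(m3$dry_yield, m3$group)) > 500)
  expect_gt(n_far, 0.02 * nrow(m3))
  expect_lt(n_far, 0.10 * nrow(m3))
})

test_that("layout and config invariants are enforced", {
  expect_error(field_layout(c("A", "A"), "test", width = 10, length = 10),
               "unique")
  expect_error(field_layout("A", "test", width = -1, length = 10), "positive")
  expect_error(sim_config(swath_width = 0), "positive")
  expect_error(sim_config(outlier_rate = 1.5), "0, 1")
  expect_error(sim_config(noise_sd = -1), ">= 0")
  only_test <- field_layout("A", "test", width = 60, length = 120)
  expect_error(simulate_measurements(only_test, sim_config()),
               "test and one control")
})

test_that("simulation config reads from YAML with defaults for absent keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("baseline_mean: 3000", "treatment_effect: 500", "seed: 9"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$baseline_mean, 3000)
  expect_equal(cfg$treatment_effect, 500)
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$swath_width, sim_config()$swath_width)
  writeLines(c("baseline_mean: 3000", "bogus_key: 1"), path)
  expect_warning(read_sim_config(path), "bogus_key")
})
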