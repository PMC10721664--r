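test_that("shell mesh is valid and subdivision quadruples the triangle count", {
  m0 <- biv_shell_mesh(0)
  expect_equal(nrow(m0$triangles), 8)
  expect_setequal(unique(m0$labels), c("LV", "RV"))
  expect_silent(validate_mesh(m0))

  m2 <- biv_shell_mesh(2)
  expect_equal(nrow(m2$triangles), 16 * nrow(m0$triangles))
  expect_silent(validate_mesh(m2))

  expect_error(biv_shell_mesh(2, lv_axis = 0), class = "crt80_validation_error")
  expect_error(biv_shell_mesh(-1), class = "crt80_validation_error")
})

test_that("LV area fraction approaches the analytic half-ellipsoid ratio", {
  a_lv <- 45; a_rv <- 30; b <- 35; c_ <- 60
  mesh <- biv_shell_mesh(4, a_lv, a_rv, b, c_)
  a <- triangle_areas(mesh)
  lv_frac <- sum(a[mesh$labels == "LV"]) / sum(a)
  s_lv <- ellipsoid_area(a_lv, b, c_) / 2
  s_rv <- ellipsoid_area(a_rv, b, c_) / 2
  expect_equal(lv_frac, s_lv / (s_lv + s_rv), tolerance = 0.02)
})

test_that("single-source propagation follows the shortest-path closed form", {
  mesh <- two_tri_mesh()  # unit square, edges of length 1 and one diagonal
  cfg <- sim_config(data.frame(vertex = 1, delay_ms = 0), base_velocity = 2)
  map <- simulate_activation(mesh, cfg)
  # vertex 4 is reached via the 2-3 diagonal (sqrt(2)) or two unit edges (2)
  expect_equal(map$times, c(0, 1, 1, 2) / 2)
})

test_that("multiple sites superpose as the delayed minimum of single sources", {
  mesh <- random_grid_mesh(10, 8, seed = 21)
  s1 <- 3L; s2 <- 61L
  one <- function(site) {
    simulate_activation(mesh, sim_config(data.frame(vertex = site, delay_ms = 0)))$times
  }
  both <- simulate_activation(
    mesh, sim_config(data.frame(vertex = c(s1, s2), delay_ms = c(0, 30))))
  expected <- pmin(one(s1) + 0, one(s2) + 30)
  expect_equal(both$times, expected - min(expected))
})

test_that("simulator equals the independent Bellman-Ford oracle exactly", {
  for (seed in c(5, 6, 7)) {
    mesh <- random_grid_mesh(9, 9, seed = seed)
    set.seed(seed + 100)
    nv <- nrow(mesh$vertices)
    cfg <- sim_config(
      data.frame(vertex = sample.int(nv, 2L), delay_ms = c(0, 15)),
      base_velocity = runif(1, 0.5, 1.2),
      chamber_scale = c(LV = runif(1, 0.7, 1.3), RV = runif(1, 0.7, 1.3)),
      seam_scale = runif(1, 0.2, 1),
      scar_patches = list(list(vertex = sample.int(nv, 1L),
                               radius_mm = 2.5, scale = 0.4))
    )
    map <- simulate_activation(mesh, cfg)
    expect_equal(map$times, oracle_activation_times(mesh, cfg), tolerance = 0)
  }
})

test_that("delay translation and velocity scaling behave exactly", {
  mesh <- random_grid_mesh(8, 6, seed = 31)
  sites <- data.frame(vertex = c(2L, 40L), delay_ms = c(0, 12))
  base <- simulate_activation(mesh, sim_config(sites))
  # adding a constant to every onset delay is removed by re-referencing
  shifted <- sites; shifted$delay_ms <- shifted$delay_ms + 25
  expect_equal(simulate_activation(mesh, sim_config(shifted))$times, base$times)
  # halving the velocity doubles all travel times (zero delays)
  s0 <- data.frame(vertex = 5L, delay_ms = 0)
  t1 <- simulate_activation(mesh, sim_config(s0, base_velocity = 0.8))$times
  t2 <- simulate_activation(mesh, sim_config(s0, base_velocity = 0.4))$times
  expect_equal(t2, 2 * t1)
})

test_that("preset maps give bundle-branch ordering and the LV-first offset", {
  mesh <- biv_shell_mesh(2)
  for (seed in 1:10) {
    lb <- chamber_metrics(preset_activation_map(mesh, "LBBB", seed = seed))
    expect_gt(lb$times["LV", "0.8"], lb$times["RV", "0.8"])
    rb <- chamber_metrics(preset_activation_map(mesh, "RBBB", seed = seed))
    expect_gt(rb$times["RV", "0.8"], rb$times["LV", "0.8"])
  }
  # BIVP_LV30: the LV site fires 30 ms before the RV site
  m <- preset_activation_map(mesh, "BIVP_LV30")
  cfg <- attr(m, "config")
  expect_equal(cfg$breakthrough$delay_ms, c(0, 30))
  lm <- crt80:::mesh_landmarks(mesh)
  expect_equal(cfg$breakthrough$vertex, c(lm$lv_free_wall, lm$rv_apex))
  expect_equal(m$setting, "BIVP_LV30")
  expect_equal(lv_offset_ms("BIVP_LV30"), 30)
  expect_equal(lv_offset_ms("BIVP"), 0)

  expect_error(preset_activation_map(mesh, "NOPE"), class = "crt80_config_error")
})

test_that("preset maps tagged with their pacing setting", {
  mesh <- biv_shell_mesh(1)
  expect_equal(preset_activation_map(mesh, "LBBB")$setting, "INTRINSIC")
  expect_equal(preset_activation_map(mesh, "LVP")$setting, "LVP")
})

test_that("linear activation maps are linear in every scope", {
  mesh <- biv_shell_mesh(4)
  dur <- 140
  map <- linear_activation_map(mesh, "BIV", dur)
  for (sc in c("LV", "RV", "BIV")) {
    cv <- activation_curve(map, sc)
    # fraction at half the duration is one half, up to discretisation
    expect_equal(curve_value_at(cv, dur / 2), 0.5, tolerance = 0.02)
    expect_equal(time_to_fraction(cv, 0.8) / time_to_fraction(cv, 1), 0.8,
                 tolerance = 0.01)
  }
  expect_error(linear_activation_map(mesh, "BIV", -5),
               class = "crt80_validation_error")
})

test_that("simulation config validation", {
  expect_error(sim_config(data.frame(vertex = integer(0), delay_ms = numeric(0))),
               class = "crt80_validation_error")
  expect_error(sim_config(data.frame(vertex = 1, delay_ms = -1)),
               class = "crt80_validation_error")
  expect_error(sim_config(data.frame(vertex = 1, delay_ms = 0), base_velocity = 0),
               class = "crt80_validation_error")
  expect_error(sim_config(data.frame(vertex = 1, delay_ms = 0), seam_scale = -1),
               class = "crt80_validation_error")
})
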