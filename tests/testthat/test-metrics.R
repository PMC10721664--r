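test_that("two equal-area elements give the two-step curve", {
  fx <- strip_fixture(c(10, 20, 60), c("LV", "LV", "RV"))
  cv <- activation_curve(fx$map, "LV")
  expect_equal(cv$event_times, c(10, 20))
  expect_equal(cv$cum_fraction, c(0.5, 1.0))
})

test_that("BIV curve is the area-weighted mixture of LV and RV curves", {
  mesh <- biv_shell_mesh(2)
  map <- preset_activation_map(mesh, "LBBB", seed = 9)
  lv <- activation_curve(map, "LV")
  rv <- activation_curve(map, "RV")
  biv <- activation_curve(map, "BIV")
  a <- triangle_areas(mesh)
  s_lv <- sum(a[mesh$labels == "LV"]); s_rv <- sum(a[mesh$labels == "RV"])
  for (t in c(biv$event_times, 25.5, 80.1)) {
    mix <- (s_lv * curve_value_at(lv, t) + s_rv * curve_value_at(rv, t)) /
      (s_lv + s_rv)
    expect_equal(curve_value_at(biv, t), mix, tolerance = 1e-12)
  }
})

test_that("curves equal a brute-force sort-and-accumulate oracle", {
  mesh <- random_grid_mesh(14, 13, seed = 41)  # ~300 triangles
  set.seed(42)
  map <- activation_map(mesh, c(0, runif(nrow(mesh$vertices) - 1L, 0, 120)))
  a <- triangle_areas(mesh)
  tt <- (map$times[mesh$triangles[, 1L]] + map$times[mesh$triangles[, 2L]] +
           map$times[mesh$triangles[, 3L]]) / 3
  for (sc in c("LV", "RV", "BIV")) {
    keep <- if (sc == "BIV") rep(TRUE, length(tt)) else mesh$labels == sc
    cv <- activation_curve(map, sc)
    # oracle: at each distinct element time, total area activated so far
    ut <- sort(unique(tt[keep]))
    frac <- vapply(ut, function(t) sum(a[keep & tt <= t]), 0) / sum(a[keep])
    expect_equal(cv$event_times, ut)
    expect_equal(cv$cum_fraction, frac, tolerance = 1e-12)
    expect_true(all(diff(cv$cum_fraction) >= 0))
    expect_equal(cv$cum_fraction[length(cv$cum_fraction)], 1, tolerance = 1e-10)
  }
})

test_that("time_to_fraction uses step-function infimum semantics", {
  fx <- strip_fixture(c(5, 10, 15, 20, 25, 30, 40, 50, 90, 130, 110, 130),
                      c(rep("RV", 10), rep("LV", 2)))
  rv <- activation_curve(fx$map, "RV")
  expect_equal(time_to_fraction(rv, 0.8), 50)  # 80% of area exactly at 50 ms
  expect_equal(time_to_fraction(rv, 1), 130)   # completion = last event
  expect_equal(time_to_fraction(rv, 0.05), 5)

  # degenerate single-element scope: every fraction gives its time
  fx1 <- strip_fixture(c(10, 40, 70), c("RV", "LV", "LV"))
  rv1 <- activation_curve(fx1$map, "RV")
  for (f in c(0.1, 0.5, 0.8, 1)) expect_equal(time_to_fraction(rv1, f), 10)

  expect_error(time_to_fraction(rv, 0), class = "crt80_domain_error")
  expect_error(time_to_fraction(rv, 1.2), class = "crt80_domain_error")

  # monotone in f on random curves
  mesh <- random_grid_mesh(6, 6, seed = 51)
  for (seed in 1:5) {
    set.seed(seed)
    map <- activation_map(mesh, c(0, runif(nrow(mesh$vertices) - 1L, 0, 100)))
    cv <- activation_curve(map, "BIV")
    fs <- seq(0.05, 1, by = 0.05)
    ts <- vapply(fs, time_to_fraction, 0, curve = cv)
    expect_true(all(diff(ts) >= 0))
  }
})

test_that("chamber metrics reproduce the two worked patient examples", {
  # LBBB patient: 80% of RV activation in 50 ms, completion 80 ms later
  fx <- strip_fixture(c(5, 10, 15, 20, 25, 30, 40, 50, 90, 130, 110, 130),
                      c(rep("RV", 10), rep("LV", 2)))
  cm <- chamber_metrics(fx$map)
  expect_equal(cm$times["RV", "0.8"], 50)
  expect_equal(cm$qrs_ms, 130)
  expect_equal(round(cm$ratios["RV", "0.8"], 2), 0.38)

  # RBBB patient: 80% of LV activation within 60 ms, rest in the last 70 ms
  fx2 <- strip_fixture(c(6, 12, 18, 24, 30, 36, 48, 60, 95, 130, 110, 130),
                       c(rep("LV", 10), rep("RV", 2)))
  cm2 <- chamber_metrics(fx2$map)
  expect_equal(cm2$times["LV", "0.8"], 60)
  expect_equal(round(cm2$ratios["LV", "0.8"], 2), 0.46)
})

test_that("chamber metrics invariants: monotone fractions, BIV completion, QRS modes", {
  mesh <- biv_shell_mesh(2)
  map <- preset_activation_map(mesh, "RBBB", seed = 3)
  cm <- chamber_metrics(map)
  for (sc in c("LV", "RV", "BIV")) expect_true(all(diff(cm$times[sc, ]) >= 0))
  expect_equal(cm$times["BIV", "1"], max(cm$times["LV", "1"], cm$times["RV", "1"]))
  expect_true(all(cm$lvrv_diff_ms >= 0))
  # supplied QRS overrides the map-derived completion time
  cm2 <- chamber_metrics(map, qrs_source = "supplied", qrs_ms = 160)
  expect_equal(cm2$ratios["LV", "0.8"], cm2$times["LV", "0.8"] / 160)
  expect_identical(cm$times, cm2$times)
  expect_error(chamber_metrics(map, qrs_source = "supplied"),
               class = "crt80_config_error")
  expect_error(chamber_metrics(map, fractions = c(0.5, 1.2)),
               class = "crt80_domain_error")
})

test_that("|LVRVDIFF| is symmetric and matches the direct difference", {
  mesh <- biv_shell_mesh(1)
  swapped <- tri_mesh(mesh$vertices, mesh$triangles,
                      ifelse(mesh$labels == "LV", "RV", "LV"))
  for (seed in c(2, 8)) {
    map <- preset_activation_map(mesh, "LBBB", seed = seed)
    cm <- chamber_metrics(map)
    expect_equal(lvrv_diff(cm),
                 abs(cm$times["LV", "0.8"] - cm$times["RV", "0.8"]))
    # swapping the chamber labels leaves the absolute difference unchanged
    cm_sw <- chamber_metrics(activation_map(swapped, map$times))
    expect_equal(lvrv_diff(cm_sw), lvrv_diff(cm))
    expect_equal(lvrv_diff(cm, f = 0.7), unname(cm$lvrv_diff_ms["0.7"]))
  }
})

test_that("fractional change: identity, worked values, sign, domain", {
  expect_equal(fractional_change(100, 100), 0)
  expect_equal(fractional_change(86, 100), -0.14)
  expect_equal(fractional_change(114, 100), 0.14)
  expect_error(fractional_change(5, 0), class = "crt80_domain_error")
})

test_that("area and element-count weighting agree exactly on uniform meshes", {
  # strip triangles all have area 1/2
  fx <- strip_fixture(c(4, 9, 14, 19, 30, 31), c("LV", "LV", "LV", "RV", "RV", "RV"))
  for (sc in c("LV", "RV", "BIV")) {
    ca <- activation_curve(fx$map, sc, weighting = "area")
    cc <- activation_curve(fx$map, sc, weighting = "count")
    expect_identical(ca$event_times, cc$event_times)
    expect_equal(ca$cum_fraction, cc$cum_fraction, tolerance = 1e-15)
  }
  # but differ on a non-uniform mesh
  mesh <- biv_shell_mesh(2)
  map <- preset_activation_map(mesh, "LBBB", seed = 4)
  ca <- activation_curve(map, "LV", weighting = "area")
  cc <- activation_curve(map, "LV", weighting = "count")
  expect_false(isTRUE(all.equal(ca$cum_fraction, cc$cum_fraction)))
})

test_that("mesh refinement changes LV80 only within the granularity bound", {
  coarse <- biv_shell_mesh(2)
  fine <- biv_shell_mesh(3)
  dur <- 150
  m_c <- linear_activation_map(coarse, "BIV", dur)
  m_f <- linear_activation_map(fine, "BIV", dur)
  lv_c <- time_to_fraction(activation_curve(m_c, "LV"), 0.8)
  lv_f <- time_to_fraction(activation_curve(m_f, "LV"), 0.8)
  a <- triangle_areas(coarse)
  gran <- max(a[coarse$labels == "LV"]) / sum(a[coarse$labels == "LV"])
  # coarse-mesh granularity (area fraction) times the map's time span
  expect_lt(abs(lv_c - lv_f), gran * dur)
})
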