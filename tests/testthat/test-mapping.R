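test_that("inverse-distance interpolation reproduces single-source and symmetric cases", {
  targets <- rbind(c(0, 0, 0), c(5, 0, 0))
  # one source: every covered target takes its value
  v1 <- deepmapr:::idw_interpolate(targets, rbind(c(1, 0, 0)), 2,
                                   radius = 10)
  expect_equal(v1, c(2, 2))
  # two equidistant sources of 1 and 3 mV: midpoint reads their mean
  v2 <- deepmapr:::idw_interpolate(rbind(c(0, 0, 0)),
                                   rbind(c(-4, 0, 0), c(4, 0, 0)),
                                   c(1, 3), radius = 10)
  expect_equal(v2, 2)
  # empty source set: all no-data
  v3 <- deepmapr:::idw_interpolate(targets,
                                   matrix(numeric(0), 0, 3), numeric(0),
                                   radius = 10)
  expect_true(all(is.na(v3)))
})

test_that("a constant amplitude field interpolates to the same constant everywhere covered", {
  sim <- clean_sim(c(0, 0, 0, 0))
  tr <- classify_train(detect_pacing_artifacts(sim$recording))
  mesh <- generate_mesh(30)
  vm <- build_voltage_map(sim$recording, tr, mesh)
  ev <- vm$electrode_voltage
  expect_equal(unname(ev), rep(ev[[1]], length(ev)),
               tolerance = 1e-9)  # identical clean channels
  covered <- vm$vertex_voltage[!is.na(vm$vertex_voltage)]
  expect_gt(length(covered), 0)
  expect_equal(covered, rep(ev[[1]], length(covered)), tolerance = 1e-9)
})

test_that("sphere radius grows strictly with the decrement and hidden points give no sphere", {
  mesh <- generate_mesh(30)
  pts <- deep_points(c("a", "b", "c"),
                     rbind(c(0, 0, 28), c(28, 0, 0), c(0, 28, 0)),
                     c(15, 45, 8))
  pts <- apply_display_threshold(pts, 10)
  sph <- place_deep_spheres(pts, mesh)
  expect_identical(sort(sph$channel), c("a", "b"))
  expect_lt(sph$radius_mm[sph$channel == "a"],
            sph$radius_mm[sph$channel == "b"])
  # strict monotonicity across a sweep of decrements
  vals <- seq(11, 80, by = 3)
  pts2 <- apply_display_threshold(
    deep_points(sprintf("c%d", seq_along(vals)),
                matrix(rep(c(0, 0, 28), each = length(vals)), ncol = 3),
                vals), 10)
  r <- place_deep_spheres(pts2, mesh)$radius_mm
  expect_true(all(diff(r[order(vals)]) > 0))
})

test_that("sphere centres lie on the mesh surface", {
  mesh <- generate_mesh(c(32, 28, 26))
  set.seed(2)
  u <- matrix(rnorm(30), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 26
  pts <- apply_display_threshold(
    deep_points(sprintf("c%d", 1:10), u, runif(10, 12, 70)), 10)
  sph <- place_deep_spheres(pts, mesh)
  centres <- as.matrix(sph[, c("cx", "cy", "cz")])
  d <- deepmapr:::nearest_vertices(mesh, centres)$distance
  expect_true(all(d < 1e-9))   # centres are mesh vertices by construction
})

test_that("points beyond the projection limit are excluded with a warning", {
  mesh <- generate_mesh(30)
  pts <- apply_display_threshold(
    deep_points(c("near", "far"), rbind(c(0, 0, 29), c(80, 0, 0)),
                c(20, 30)), 10)
  expect_warning(sph <- place_deep_spheres(pts, mesh), "far")
  expect_identical(sph$channel, "near")
})

test_that("map export and re-import agree to six significant digits in both formats", {
  sim <- clean_sim(c(0, 25, 60))
  tr <- classify_train(detect_pacing_artifacts(sim$recording))
  mesh <- generate_mesh(30, electrodes = sim$recording$positions)
  fit <- deep_detect(sim$recording, mesh = mesh)
  td <- withr::local_tempdir()
  for (fmt in c("vtk", "ply")) {
    base <- file.path(td, fmt)
    export_map(fit$voltage_map, fit$spheres, base, fmt)
    imp <- import_map(base, fmt)
    expect_equal(imp$vertex_voltage, fit$voltage_map$vertex_voltage,
                 tolerance = 1e-6)
    expect_equal(unname(imp$vertices),
                 unname(fit$voltage_map$mesh$vertices), tolerance = 1e-6)
    expect_identical(imp$faces[, 1:3], fit$voltage_map$mesh$faces[, 1:3])
    expect_equal(imp$spheres$radius_mm, fit$spheres$radius_mm,
                 tolerance = 1e-6)
  }
})

test_that("zero spheres still export valid files and unknown formats are errors", {
  sim <- clean_sim(c(0, 0))
  tr <- classify_train(detect_pacing_artifacts(sim$recording))
  mesh <- generate_mesh(30)
  vm <- build_voltage_map(sim$recording, tr, mesh)
  empty <- place_deep_spheres(
    apply_display_threshold(deep_points(character(0),
                                        matrix(numeric(0), ncol = 3),
                                        numeric(0)), 10), mesh)
  td <- withr::local_tempdir()
  export_map(vm, empty, file.path(td, "e"), "vtk")
  imp <- import_map(file.path(td, "e"), "vtk")
  expect_identical(nrow(imp$spheres), 0L)
  expect_error(export_map(vm, empty, file.path(td, "x"), "xyz"),
               class = "unsupported_format")
  expect_match(tryCatch(export_map(vm, empty, file.path(td, "x"), "xyz"),
                        error = conditionMessage),
               "vtk, ply")
})
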