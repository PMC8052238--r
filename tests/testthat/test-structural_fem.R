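materials <- derive_material_table(36.44, 133.9)

test_that("a single-material block under uniform traction is exact", {
  sec <- fe_rect_section(4)
  model <- build_fe_model(sec, materials, pressure = -2) # 2 kPa tension
  field <- solve_linear_elastic(model)
  expect_equal(unname(field$stress[, "xx"]), rep(2, nrow(model$elements)),
               tolerance = 1e-12)
  expect_lt(max(abs(field$stress[, "yy"])), 1e-10)
  expect_lt(max(abs(field$stress[, "xy"])), 1e-10)
})

test_that("zero pressure gives identically zero response", {
  model <- build_fe_model(fe_annulus_section(1, 2, nr = 6, ntheta = 12),
                          materials, pressure = 0)
  field <- solve_linear_elastic(model)
  expect_true(all(field$displacements == 0))
  expect_true(all(field$von_mises == 0))
})

test_that("the response is linear in the applied pressure", {
  sec <- fe_annulus_section(1, 2, nr = 8, ntheta = 16)
  f1 <- solve_linear_elastic(build_fe_model(sec, materials, pressure = 1))
  f2 <- solve_linear_elastic(build_fe_model(sec, materials, pressure = 2))
  expect_equal(f2$von_mises, 2 * f1$von_mises, tolerance = 1e-12)
  expect_equal(f2$displacements, 2 * f1$displacements, tolerance = 1e-12)
})

test_that("stress in a traction-loaded homogeneous annulus is E-independent", {
  sec <- fe_annulus_section(1, 2, nr = 8, ntheta = 16)
  f1 <- solve_linear_elastic(build_fe_model(sec, materials, pressure = 1))
  doubled <- derive_material_table(2 * 36.44, 2 * 133.9)
  f2 <- solve_linear_elastic(build_fe_model(sec, doubled, pressure = 1))
  expect_lt(max(abs(f2$von_mises - f1$von_mises)) / max(f1$von_mises),
            1e-10)
})

test_that("reactions balance the applied pressure load", {
  sec <- fe_annulus_section(1, 2, nr = 12, ntheta = 24)
  field <- solve_linear_elastic(build_fe_model(sec, materials, pressure = 3))
  expect_lt(field$equilibrium_residual, 1e-8)
})

test_that("boundary sets partition the section boundary", {
  sec <- fe_annulus_section(1, 2, nr = 6, ntheta = 10)
  b <- sec$boundary
  # every boundary edge is in exactly one set, and the counts close
  expect_equal(sum(b$set == "inner"), 10)
  expect_equal(sum(b$set == "outer"), 10)
  expect_equal(sum(b$set == "cut"), 12)
  expect_equal(nrow(b), 10 + 10 + 12)
  expect_false(any(duplicated(b[, c("n1", "n2")])))
})

test_that("an element class without a material aborts naming the class", {
  sec <- fe_annulus_section(1, 2, nr = 4, ntheta = 8,
                            class_fn = function(x, y) {
                              if (y > x) 7L else 9L
                            })
  expect_error(build_fe_model(sec, materials), "class 7")
})

test_that("slice sections reproduce the rasterized patch area", {
  gen <- generate_phantom_stack(one_patch_spec(n_slices = 8))
  sl <- gen$slices[[4]] # class-6 patch present
  sec <- fe_section_from_slice(sl, nr = 14, ntheta = 144)
  model <- build_fe_model(sec, materials, pressure = 1)
  # element-area histogram vs pixel-count area of the patch, within 5%
  a6_fem <- sum(model$elem_area[model$elem_class == 6L]) * 1e6 # mm^2 -> um^2
  a6_pix <- sum(sl$labels == 6L) * sl$pixel_pitch^2
  expect_lt(abs(a6_fem - a6_pix) / a6_pix, 0.05)
  # solvable: pins remove rigid-body modes
  field <- solve_linear_elastic(model)
  expect_lt(field$equilibrium_residual, 1e-8)
  expect_true(all(field$von_mises >= 0))
})

test_that("forcing every class to the reference gives a null comparison", {
  sec <- fe_annulus_section(1, 2, nr = 8, ntheta = 16)
  model <- build_fe_model(sec, materials, pressure = 1)
  cmp <- compare_homo_hetero(model, materials)
  expect_lt(max(abs(cmp$delta_vm)), 1e-12)
})

test_that("a soft inclusion perturbs stresses only near its interface", {
  sector_fn <- function(x, y) {
    th <- atan2(y, x)
    if (th > pi / 8 && th < pi / 4) 6L else 9L
  }
  sec <- fe_annulus_section(1, 2, nr = 24, ntheta = 48,
                            class_fn = sector_fn)
  model <- build_fe_model(sec, materials, pressure = 1)
  cmp <- compare_homo_hetero(model, materials)
  # the maximum difference concentrates within 2 element layers of the
  # class interface
  expect_lte(cmp$max_delta_distance, 2)
  # far from the inclusion the fields agree within discretization
  # tolerance (a small fraction of the peak difference)
  far <- cmp$interface_distance > 4
  expect_lt(mean(abs(cmp$delta_vm[far])), 0.1 * max(abs(cmp$delta_vm)))
  # the stiffer region carries at least its homogeneous share of stress
  pc <- cmp$per_class
  expect_gte(pc$mean_vm_heterogeneous[pc$class_id == 9],
             pc$mean_vm_homogeneous[pc$class_id == 9])
})

test_that("results export as a legacy VTK unstructured grid", {
  sec <- fe_annulus_section(1, 2, nr = 4, ntheta = 8)
  model <- build_fe_model(sec, materials, pressure = 1)
  field <- solve_linear_elastic(model)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(model, field, path)
  lines <- readLines(path)
  expect_match(lines[1], "vtk DataFile")
  expect_true(any(grepl("^CELL_DATA", lines)))
  expect_true(any(grepl("von_mises", lines)))
})
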