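test_that("material table reproduces the published per-class moduli", {
  mt <- derive_material_table(36.44, 133.9, poisson = 0.45)
  get <- function(cl) mt$modulus_kPa[mt$class_id == cl]
  # two-decimal display values; full precision stored
  expect_equal(round(get(1), 2), 85.17)
  expect_equal(round(get(3), 2), 109.54)
  expect_equal(round(get(5), 2), 72.99)
  expect_equal(round(get(6), 2), 18.22)
  expect_equal(get(8), 36.44)
  expect_equal(get(9), 133.9)
  # the stored values satisfy the combination rules exactly
  expect_identical(get(1), (36.44 + 133.9) / 2)
  expect_identical(get(3), 36.44 / 4 + 3 * 133.9 / 4)
  expect_identical(get(5), (get(3) + 36.44) / 2)
  expect_identical(get(6), 36.44 / 2)
  expect_true(all(mt$poisson == 0.45))
  expect_setequal(mt$class_id, c(1L, 3L, 5L, 6L, 8L, 9L))
  expect_identical(attr(mt, "default_class"), 9L)
  expect_setequal(mt$provenance[mt$class_id %in% c(8, 9)], "literature")
})

test_that("equal literature inputs collapse the convex combinations", {
  mt <- derive_material_table(50, 50)
  # classes 1, 3 and 5 are convex combinations of the inputs; class 6 is
  # half of class 8 by its rule
  for (cl in c(1L, 3L, 5L, 8L, 9L)) {
    expect_equal(mt$modulus_kPa[mt$class_id == cl], 50)
  }
  expect_equal(mt$modulus_kPa[mt$class_id == 6L], 25)
})

test_that("derived moduli are monotone in the inputs and bounded", {
  set.seed(42)
  for (i in 1:25) {
    e8 <- runif(1, 5, 200); e9 <- runif(1, 5, 200)
    mt <- derive_material_table(e8, e9)
    lo <- min(e8, e9) / 2; hi <- max(e8, e9)
    expect_true(all(mt$modulus_kPa >= lo - 1e-12))
    expect_true(all(mt$modulus_kPa <= hi + 1e-12))
    # bumping either input never decreases any derived modulus
    for (d in list(c(1, 0), c(0, 1))) {
      mt2 <- derive_material_table(e8 + 10 * d[1], e9 + 10 * d[2])
      expect_true(all(mt2$modulus_kPa >= mt$modulus_kPa - 1e-12))
    }
  }
})

test_that("classes without a rule must be supplied explicitly", {
  mt <- derive_material_table(36.44, 133.9)
  expect_error(material_for_class(mt, 2L), "class 2")
  expect_error(material_for_class(mt, 7L), "class 7")
  mt2 <- derive_material_table(36.44, 133.9, extra = c("2" = 55, "7" = 40))
  expect_equal(material_for_class(mt2, 2L)$modulus_kPa, 55)
  expect_equal(mt2$provenance[mt2$class_id == 7], "config")
})

test_that("validation errors name the offending field", {
  expect_error(derive_material_table(-1, 133.9), "E_white_thrombus")
  expect_error(derive_material_table(36.44, 0), "E_intact_wall")
  expect_error(derive_material_table(36.44, 133.9, poisson = 0.5), "poisson")
  expect_error(derive_material_table(36.44, 133.9, poisson = 0), "poisson")
})

test_that("materials config round-trips to machine precision", {
  mt <- derive_material_table(36.44, 133.9, extra = c("4" = 77.7))
  path <- withr::local_tempfile(fileext = ".cfg")
  write_materials_config(mt, path)
  mt2 <- read_materials_config(path)
  expect_identical(mt2$modulus_kPa, mt$modulus_kPa)
  expect_identical(mt2$poisson, mt$poisson)
  expect_identical(mt2$class_id, mt$class_id)
  expect_identical(attr(mt2, "default_class"), attr(mt, "default_class"))
})

test_that("palette is a bijection that round-trips label arrays", {
  pal <- class_palette()
  expect_identical(sort(pal$id), c(0:9, 10L, 11L))
  expect_false(any(duplicated(pal[, c("r", "g", "b")])))
  lab <- matrix(sample(c(0:9, 10L, 11L), 100, replace = TRUE), 10, 10)
  expect_identical(palette_to_labels(labels_to_palette(lab)), lab)
})

test_that("segmentation figure colors map to the documented classes", {
  # blue, green, yellow, red, pink, gray -> MH, degenerated wall, white
  # thrombus, red thrombus, decellularized OT/MH, mixed textures
  pal <- class_palette()
  lookup <- function(r, g, b) {
    pal$id[pal$r == r & pal$g == g & pal$b == b]
  }
  expect_identical(
    c(lookup(0, 0, 255), lookup(0, 128, 0), lookup(255, 255, 0),
      lookup(255, 0, 0), lookup(255, 192, 203), lookup(128, 128, 128)),
    c(3L, 4L, 8L, 6L, 5L, 1L)
  )
})

test_that("colors outside the palette raise a lookup error", {
  arr <- array(0, c(2, 2, 3))
  arr[1, 1, ] <- c(12, 34, 56)
  expect_error(palette_to_labels(arr), "rgb\\(12,34,56\\)")
})
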