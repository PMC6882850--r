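make_cube <- function(values, wl = seq(450, 900, 5), kind = "raw") {
  hypercube(values, wl, kind = kind)
}

test_that("reflectance calibration matches its defining identity", {
  d <- c(4, 5, 91)
  dark <- make_cube(array(10, d), kind = "dark")
  white <- make_cube(array(110, d), kind = "white")
  raw_w <- make_cube(array(110, d))
  raw_d <- make_cube(array(10, d))
  raw_m <- make_cube(array(60, d))
  expect_equal(unique(as.vector(calibrate_reflectance(raw_w, white, dark)$values)), 1)
  expect_equal(unique(as.vector(calibrate_reflectance(raw_d, white, dark)$values)), 0)
  expect_equal(unique(as.vector(calibrate_reflectance(raw_m, white, dark)$values)), 0.5)
})

test_that("calibration is invariant to a common positive gain", {
  d <- c(3, 3, 91)
  set.seed(4)
  dark <- array(runif(prod(d), 90, 110), d)
  white <- dark + array(runif(prod(d), 500, 4000), d)
  raw <- dark + array(runif(prod(d)), d) * (white - dark)
  r1 <- calibrate_reflectance(make_cube(raw), make_cube(white, kind = "white"),
                              make_cube(dark, kind = "dark"))
  g <- 2.7
  r2 <- calibrate_reflectance(make_cube(g * raw), make_cube(g * white, kind = "white"),
                              make_cube(g * dark, kind = "dark"))
  expect_equal(r1$values, r2$values, tolerance = 1e-12)
})

test_that("invalid denominators are masked, not propagated, and mismatches error", {
  d <- c(2, 2, 3)
  wl <- c(450, 455, 460)
  dark <- array(10, d)
  white <- array(110, d)
  white[1, 1, 2] <- 5                      # white below dark at one voxel
  raw <- array(60, d)
  out <- calibrate_reflectance(
    hypercube(raw, wl), hypercube(white, wl, "white"), hypercube(dark, wl, "dark")
  )
  expect_true(is.na(out$values[1, 1, 2]))
  expect_equal(attr(out, "n_invalid"), 1L)
  expect_false(any(is.infinite(out$values)))

  expect_error(calibrate_reflectance(
    hypercube(array(1, c(2, 2, 2)), wl[1:2]),
    hypercube(white, wl, "white"), hypercube(dark, wl, "dark")
  ), "shape")
  wl2 <- wl + 1
  expect_error(calibrate_reflectance(
    hypercube(raw, wl2), hypercube(white, wl, "white"),
    hypercube(dark, wl, "dark")
  ), "wavelength")
  swapped_white <- array(10, d)
  swapped_dark <- array(110, d)
  expect_error(calibrate_reflectance(
    hypercube(raw, wl), hypercube(swapped_white, wl, "white"),
    hypercube(swapped_dark, wl, "dark")
  ), "all voxels")
})

test_that("pathology maps paint runs exactly and reject bad annotations", {
  ann <- tibble::tibble(row = 5, col_start = 1, col_end = 10, class = "dysplasia")
  pm <- build_pathology_map(ann, shape = c(20, 30))
  expect_equal(sum(pm$labels == "dysplasia"), 10)
  expect_equal(sum(pm$labels != "unlabeled"), 10)

  empty <- build_pathology_map(tibble::tibble(), shape = c(5, 5))
  expect_true(all(empty$labels == "unlabeled"))

  two <- build_pathology_map(tibble::tibble(
    row = c(2, 2, 7), col_start = c(1, 12, 3), col_end = c(8, 20, 9),
    class = c("normal", "carcinoma", "cis")
  ), shape = c(10, 25))
  expect_equal(as.vector(table(two$labels)[c("carcinoma", "cis", "normal")]),
               c(9, 7, 8))

  expect_error(build_pathology_map(tibble::tibble(
    row = c(2, 2), col_start = c(1, 5), col_end = c(6, 9),
    class = c("normal", "cis")
  ), shape = c(10, 10)), "overlap")
  expect_error(build_pathology_map(tibble::tibble(
    row = 99, col_start = 1, col_end = 2, class = "cis"
  ), shape = c(10, 10)), "row")
})

test_that("signatures average labeled pixels and omit absent classes", {
  wl <- seq(450, 900, 5)
  B <- length(wl)
  v <- array(0, c(2, 2, B))
  s <- seq(0.1, 0.9, length.out = B)
  t <- rev(s)
  v[1, 1, ] <- s
  v[1, 2, ] <- t
  v[2, 1, ] <- 5
  cube <- hypercube(v, wl, "reflectance")
  lab <- matrix("unlabeled", 2, 2)
  lab[1, 1] <- "normal"
  sig1 <- extract_spectral_signatures(cube, lab)
  expect_equal(sig1$reflectance, s)

  lab[1, 2] <- "normal"
  sig2 <- extract_spectral_signatures(cube, lab)
  expect_equal(sig2$reflectance, (s + t) / 2)
  expect_setequal(unique(sig2$class), "normal")   # absent classes omitted

  expect_error(extract_spectral_signatures(cube, matrix("unlabeled", 2, 2)),
               "no labeled")
})

test_that("signature extraction commutes with band subsetting", {
  spec <- spectrum_spec(noise_sd = 0.01, seed = 2)
  layout <- matrix("cis", 10, 10)
  cubes <- generate_hypercube(spec, layout)
  refl <- calibrate_reflectance(cubes$raw, cubes$white, cubes$dark)
  full <- extract_spectral_signatures(refl, layout)
  bands <- 10:30
  sub <- hypercube(refl$values[, , bands], refl$wavelengths[bands], "reflectance")
  sub_sig <- extract_spectral_signatures(sub, layout)
  expect_equal(sub_sig$reflectance, full$reflectance[bands])
})

test_that("hypercubes round-trip through multi-page TIFF with sidecar", {
  spec <- spectrum_spec(noise_sd = 0.002, seed = 8)
  layout <- matrix("normal", 6, 6)
  cubes <- generate_hypercube(spec, layout)
  path <- file.path(withr::local_tempdir(), "cube.tif")
  write_hypercube_tiff(cubes$raw, path)
  back <- read_hypercube_tiff(path)
  expect_equal(back$wavelengths, cubes$raw$wavelengths)
  expect_equal(back$values, cubes$raw$values, tolerance = 1e-6)
  expect_equal(back$kind, "raw")
})
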