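test_that("crop generation is deterministic and honours the empty case", {
  spec <- tissue_spec("normal", seed = 3)
  a <- generate_he_image(spec)
  b <- generate_he_image(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$nuclei, b$truth$nuclei)

  empty <- generate_he_image(tissue_spec("normal", n_nuclei = 0, seed = 1))
  expect_equal(nrow(empty$truth$nuclei), 0)
  expect_true(all(empty$truth$labels == 0L))
  # no nuclei-coloured (blue-dominant) pixels anywhere
  blue <- empty$image[, , 3]
  red <- empty$image[, , 1]
  expect_true(all(blue - red < 20))
})

test_that("requested nuclei are rendered as distinct components when spacing allows", {
  spec <- tissue_spec("normal", n_nuclei = 30, crowding = 0.75,
                      image_width = 448, image_height = 288, seed = 11)
  crop <- generate_he_image(spec)
  expect_equal(nrow(crop$truth$nuclei), 30)
  comp <- EBImage::bwlabel(crop$truth$labels > 0)
  expect_equal(max(comp), 30)
  # every centroid lies inside the epithelium mask
  cent <- crop$truth$nuclei
  expect_true(all(crop$truth$epithelium_mask[cbind(round(cent$y), round(cent$x))]))
})

test_that("infeasible placement fails loudly instead of silently under-delivering", {
  spec <- tissue_spec("normal", n_nuclei = 500, seed = 1)
  expect_error(generate_he_image(spec), "place")
})

test_that("boundary irregularity strictly lengthens outlines at fixed axes", {
  irr <- c(0, 0.1, 0.2, 0.35)
  for (lobes in c(3L, 5L, 7L)) {
    per <- vapply(irr, function(a) {
      histospectra:::polygon_perimeter(
        nucleus_outline(20, 13, orientation = 0.4, irregularity = a,
                        lobes = lobes, phase = 1, n = 720)
      )
    }, numeric(1))
    expect_true(all(diff(per) > 0))
  }
})

test_that("higher crowding reduces nearest-centroid distances", {
  nn_dist <- function(crowding, seed) {
    crop <- generate_he_image(
      tissue_spec("normal", crowding = crowding, n_nuclei = 20, seed = seed)
    )
    xy <- cbind(crop$truth$nuclei$x, crop$truth$nuclei$y)
    d <- as.matrix(dist(xy))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  for (seed in 1:3) {
    expect_gt(nn_dist(0.8, seed), nn_dist(2.5, seed))
  }
})

test_that("class spectra keep neoplastic amplitudes above normal with a 540 nm dip", {
  spec <- spectrum_spec()
  spectra <- class_spectra(spec)
  amp <- tapply(spectra$reflectance, spectra$class, mean)
  expect_true(all(amp[c("dysplasia", "cis", "carcinoma")] > amp["normal"]))
  nrm <- spectra[spectra$class == "normal", ]
  dip_band <- nrm$reflectance[nrm$wavelength == 540]
  shoulder <- nrm$reflectance[nrm$wavelength %in% c(480, 620)]
  expect_true(all(dip_band < shoulder))
})

test_that("hypercube generation satisfies its reference-cube contract", {
  spec <- spectrum_spec(noise_sd = 0)
  layout <- matrix("background", 12, 12)
  layout[4:9, 4:9] <- "carcinoma"
  cubes <- generate_hypercube(spec, layout)
  expect_true(all(cubes$white$values > cubes$dark$values))
  expect_error(generate_hypercube(spec, matrix("tumour", 4, 4)), "unknown")

  # zero-noise calibration inverts generation exactly, at every pixel
  refl <- calibrate_reflectance(cubes$raw, cubes$white, cubes$dark)
  truth <- class_spectra(spec)
  carc <- truth$reflectance[truth$class == "carcinoma"]
  bg <- truth$reflectance[truth$class == "background"]
  expect_equal(as.numeric(refl$values[5, 5, ]), carc, tolerance = 1e-10)
  expect_equal(as.numeric(refl$values[1, 1, ]), bg, tolerance = 1e-10)
})

test_that("noisy per-class signature means meet the standard-error bound", {
  spec <- spectrum_spec(noise_sd = 0.01, seed = 9)
  layout <- matrix("normal", 50, 50)
  layout[, 26:50] <- "carcinoma"          # 1250 pixels per class
  cubes <- generate_hypercube(spec, layout)
  refl <- calibrate_reflectance(cubes$raw, cubes$white, cubes$dark)
  sig <- extract_spectral_signatures(refl, layout)
  truth <- class_spectra(spec)
  for (cl in c("normal", "carcinoma")) {
    got <- sig$reflectance[sig$class == cl]
    want <- truth$reflectance[truth$class == cl]
    expect_true(all(sig$n_pixels[sig$class == cl] >= 500))
    expect_true(all(abs(got - want) < 3 * 0.01 / sqrt(500)))
  }
})

test_that("paired datasets are subject-structured with correct bookkeeping", {
  b <- generate_paired_dataset(n_subjects = 3, images_per_class = 2, seed = 5,
                               image_width = 256, image_height = 176,
                               cube_side = 24)
  expect_equal(nrow(b$manifest), 3 * 2 * 4)
  expect_setequal(unique(b$manifest$subject_id), 1:3)
  expect_equal(sum(b$manifest$label == "normal"), 6)
  expect_equal(length(b$images), nrow(b$manifest))
  expect_true(all(c("image_id", "class", "wavelength", "reflectance") %in%
                    names(b$signatures)))
  expect_error(generate_paired_dataset(n_subjects = 1), "n_subjects")
  expect_error(generate_paired_dataset(images_per_class = 0), "images_per_class")
})

test_that("effect size zero collapses all classes onto the normal parameters", {
  for (cl in c("dysplasia", "cis", "carcinoma")) {
    s <- tissue_spec(cl, effect_size = 0)
    n <- tissue_spec("normal")
    expect_equal(s$n_nuclei, n$n_nuclei)
    expect_equal(s$nucleus_axes_mean, n$nucleus_axes_mean)
    expect_equal(s$epithelium_band, n$epithelium_band)
    expect_equal(s$boundary_irregularity, n$boundary_irregularity)
    expect_equal(s$crowding, n$crowding)
  }
})
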