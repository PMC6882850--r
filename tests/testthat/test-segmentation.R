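palette <- default_stain_colors()

test_that("blue-ratio transform matches its closed form", {
  px <- function(col) {
    r <- blue_ratio_image(flat_rgb(1, 1, col))
    as.numeric(r)
  }
  expect_equal(px(c(0, 0, 255)), (255 / 1) / 256)
  expect_equal(px(c(255, 255, 255)), (255 / 511) / 766, tolerance = 1e-10)
  expect_gt(px(palette$nuclei), px(palette$cytoplasm))
  expect_true(all(blue_ratio_image(flat_rgb(4, 4, c(10, 200, 30))) >= 0))
})

test_that("epithelium segmentation recovers the synthetic band and is hole-free", {
  for (cl in c("normal", "carcinoma")) {
    crop <- generate_he_image(tissue_spec(cl, seed = 13))
    mask <- segment_epithelium(crop$image)
    expect_gte(dice_overlap(mask, crop$truth$epithelium_mask), 0.90)
    filled <- histospectra:::fill_holes(mask)
    expect_identical(mask, filled)           # no holes survive
  }
  expect_warning(
    empty <- segment_epithelium(flat_rgb(40, 40, c(255, 255, 255))),
    "uniform"
  )
  expect_false(any(empty))
  expect_error(segment_epithelium(matrix(1, 5, 5)), "RGB")
})

test_that("k-means partition recovers an exact three-colour epithelium", {
  H <- 40; W <- 60
  img <- flat_rgb(H, W, palette$cytoplasm)
  nuc <- disk_mask(H, W, 15, 12, 6) | disk_mask(H, W, 45, 25, 7)
  bg <- disk_mask(H, W, 30, 30, 5)
  img <- paint_mask(img, nuc, palette$nuclei)
  img <- paint_mask(img, bg, palette$background)
  epi <- matrix(TRUE, H, W)
  parts <- partition_epithelium(img, epi)
  expect_identical(parts$nuclei, nuc)
  expect_identical(parts$background, bg)
  expect_identical(parts$cytoplasm, !nuc & !bg)
  expect_error(partition_epithelium(img, matrix(FALSE, H, W)), "empty")
})

test_that("partition handles degenerate colour counts with empty missing roles", {
  img <- flat_rgb(20, 20, palette$nuclei)
  img <- paint_mask(img, disk_mask(20, 20, 10, 10, 4), palette$background)
  parts <- partition_epithelium(img, matrix(TRUE, 20, 20))
  expect_true(any(parts$nuclei))
  expect_true(any(parts$background))
  expect_false(any(parts$cytoplasm))       # only two colours present
})

test_that("raw nuclei recall on synthetic crops is high before cleanup", {
  crop <- generate_he_image(tissue_spec("dysplasia", seed = 17))
  epi <- segment_epithelium(crop$image)
  parts <- partition_epithelium(crop$image, epi)
  truth <- crop$truth$labels > 0 & crop$truth$epithelium_mask & epi
  recall <- sum(parts$nuclei & truth) / sum(truth)
  expect_gte(recall, 0.9)
})

test_that("morphological cleanup follows fill-dilate-open and the 50 px rule", {
  # a 21 px seed becomes exactly the 49 px opening-invariant disc, then the
  # fewer-than-50-pixels rule discards it; one step larger survives
  small <- disk_mask(40, 40, 20, 20, 2.3)
  expect_equal(sum(refine_nuclei_mask(small)), 0)
  larger <- disk_mask(40, 40, 20, 20, 3)
  out <- refine_nuclei_mask(larger)
  expect_gte(sum(out), 50)

  # hole filling: solid disk with a punched hole comes back solid
  holed <- disk_mask(40, 40, 20, 20, 10)
  holed[19:21, 19:21] <- FALSE
  expect_true(all(refine_nuclei_mask(holed)[holed]))

  # two disks of radius 6 separated by a 3 px gap merge under dilation r=2
  # and persist the r=4 opening as a single component
  two <- disk_mask(60, 80, 30, 30, 6) | disk_mask(60, 80, 45, 30, 6)
  merged <- refine_nuclei_mask(two)
  expect_equal(max(histospectra:::label_components(merged)), 1L)
})

test_that("large-cluster splitting triggers on the stated size and solidity", {
  H <- 60; W <- 90
  img <- flat_rgb(H, W, palette$cytoplasm)
  # single convex blob above 500 px: solidity ~1, must pass through unchanged
  conv <- disk_mask(H, W, 30, 30, 15)
  img1 <- paint_shaded_disk(img, 30, 30, 15, palette$nuclei)
  out1 <- split_large_clusters(conv, img1)
  expect_identical(out1, histospectra:::as_binary(conv))

  # dumbbell of two fused shaded blobs (union > 500 px, solidity < 0.9):
  # colour re-clustering drops the bright rims and separates the cores
  m <- disk_mask(H, W, 30, 30, 12) | disk_mask(H, W, 52, 30, 12)
  img2 <- paint_shaded_disk(img, 30, 30, 12, palette$nuclei)
  img2 <- paint_shaded_disk(img2, 52, 30, 12, palette$nuclei * c(1.1, 1.1, 1.05))
  expect_gt(sum(m), 500)
  expect_lt(histospectra:::region_solidity(row(m)[m], col(m)[m]), 0.9)
  out2 <- split_large_clusters(m, img2)
  expect_equal(max(histospectra:::label_components(out2)), 2L)

  # idempotence: a second pass changes nothing
  expect_identical(split_large_clusters(out2, img2), out2)

  # red blob (R/B = 2) above the 1.2 cutoff is removed as a false detection
  red <- disk_mask(H, W, 30, 60, 10)
  img3 <- paint_mask(img, red, c(200, 50, 100))
  expect_false(any(split_large_clusters(red, img3)))
})

test_that("small-cluster watershed splits touching nuclei and keeps the 50 px rule", {
  H <- 50; W <- 80
  img <- flat_rgb(H, W, palette$cytoplasm)
  # isolated convex nucleus of ~120 px: below the 150 px trigger, unchanged
  small <- disk_mask(H, W, 20, 25, 6)
  img1 <- paint_shaded_disk(img, 20, 25, 6, palette$nuclei)
  expect_lt(sum(small), 150)
  expect_identical(split_small_clusters(small, img1),
                   histospectra:::as_binary(small))

  # two touching ~200 px shaded nuclei: union solidity < 0.9, watershed on
  # the smoothed blue-ratio landscape separates them
  m <- disk_mask(H, W, 25, 25, 8) | disk_mask(H, W, 40, 25, 8)
  img2 <- paint_shaded_disk(img, 25, 25, 8, palette$nuclei)
  img2 <- paint_shaded_disk(img2, 40, 25, 8, palette$nuclei)
  out <- split_small_clusters(m, img2)
  expect_equal(max(histospectra:::label_components(out)), 2L)
  # all surviving fragments respect the 50 px survival threshold
  sizes <- histospectra:::component_sizes(histospectra:::label_components(out))
  expect_true(all(sizes >= 50))
})

test_that("finalisation applies the R/B <= 1 rule and fits ellipses", {
  H <- 50; W <- 70
  img <- flat_rgb(H, W, palette$cytoplasm)
  blue <- disk_mask(H, W, 18, 25, 8)
  pink <- disk_mask(H, W, 50, 25, 8)
  img <- paint_mask(img, blue, c(60, 60, 120))    # R/B = 0.5, retained
  img <- paint_mask(img, pink, c(130, 90, 100))   # R/B = 1.3, removed
  fin <- finalize_nuclei(blue | pink, img)
  expect_equal(nrow(fin$records), 1)
  expect_lte(fin$records$red_blue_ratio, 1)
  expect_equal(fin$records$x, 25, tolerance = 0.5)
  expect_equal(fin$records$major, 16, tolerance = 1.5)
  expect_equal(fin$records$minor, 16, tolerance = 1.5)
  expect_lte(fin$records$eccentricity, 0.3)

  empty <- finalize_nuclei(matrix(FALSE, 10, 10), flat_rgb(10, 10, c(1, 1, 1)))
  expect_equal(nrow(empty$records), 0)
  expect_true(all(empty$labels == 0L))
})

test_that("the full cascade yields a consistent partition with clean nuclei", {
  crop <- generate_he_image(tissue_spec("cis", seed = 23))
  tm <- segment_tissue(crop$image)
  nuc <- tm$nuclei_labels > 0L
  # nuclei confined to the epithelium; compartments partition the epithelium
  expect_true(all(tm$epithelium[nuc]))
  expect_false(any(nuc & tm$cytoplasm))
  expect_false(any(nuc & tm$background))
  expect_true(all((nuc | tm$cytoplasm | tm$background) == tm$epithelium))
  # every final nucleus: >= 25 px and mean R/B <= 1
  expect_true(all(tm$nuclei$area >= 25))
  expect_true(all(tm$nuclei$red_blue_ratio <= 1))
  expect_true(all(tm$nuclei$minor <= tm$nuclei$major))
  expect_true(all(tm$nuclei$solidity <= 1))
})
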