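test_that("colour features are normalised proportions with invariance to gain", {
  set.seed(2)
  H <- 40; W <- 40
  rgb <- array(runif(H * W * 3, 40, 110), c(H, W, 3))   # dark: no white removal
  mask <- matrix(TRUE, H, W)
  ft <- color_features(rgb, mask)
  expect_equal(nrow(ft), 71)
  for (ch in c("r", "g", "b")) {
    expect_equal(sum(ft$value[grepl(paste0("trgb_", ch, "_bin"), ft$feature)]), 1)
  }
  expect_equal(sum(ft$value[grepl("rbdiff_bin", ft$feature)]), 1)

  # standardisation cancels global intensity scaling (float path, no clipping)
  ft_scaled <- color_features(rgb * 1.5, mask)
  trgb <- grepl("trgb_", ft$feature)
  expect_equal(ft$value[trgb], ft_scaled$value[trgb])
})

test_that("constant-colour regions degrade gracefully with flags", {
  rgb <- flat_rgb(20, 20, c(80, 90, 100))
  ft <- color_features(rgb, matrix(TRUE, 20, 20))
  expect_true(all(is.finite(ft$value)))
  trgb_r <- ft[grepl("trgb_r_bin", ft$feature), ]
  expect_false(any(trgb_r$valid))
  expect_equal(sum(trgb_r$value), 1)                   # central-bin mass
  expect_equal(ft$value[ft$feature == "rbdiff_sd"], 0)
  expect_false(ft$valid[ft$feature == "rbdiff_skewness"])

  empty <- color_features(rgb, matrix(FALSE, 20, 20))
  expect_true(all(empty$value == 0))
  expect_false(any(empty$valid))
})

test_that("white pixels above the luminance cutoff are excluded", {
  rgb <- flat_rgb(10, 10, c(100, 100, 100))
  rgb[1:5, , ] <- 255                                   # Y = 255 > 180
  ft <- color_features(rgb, matrix(TRUE, 10, 10))
  # with white rows removed the remaining region is constant -> flagged sd 0
  expect_equal(ft$value[ft$feature == "rbdiff_sd"], 0)
  expect_false(any(ft$valid[grepl("trgb_r_bin", ft$feature)]))
})

test_that("GLCM features match hand-counted co-occurrence on a checkerboard", {
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2 + 1)
  lev <- cb
  storage.mode(lev) <- "integer"
  P <- co_occurrence(lev, c(0L, 1L), 2L)
  expect_equal(sum(P), 1)
  # every horizontal neighbour pair differs by one level -> contrast 1
  contrast <- sum(outer(1:2, 1:2, function(i, j) (i - j)^2) * P)
  expect_equal(contrast, 1)

  ft <- glcm_features(matrix(c(1, 2), 16, 16), matrix(TRUE, 16, 16))
  expect_equal(nrow(ft), 19)
  expect_equal(sum(grepl("glcm_", ft$feature)), 19)
})

test_that("constant regions give ASM 1, contrast 0 and flagged correlation", {
  ft <- glcm_features(matrix(7, 10, 10), matrix(TRUE, 10, 10))
  expect_equal(ft$value[ft$feature == "glcm_asm"], 1)
  expect_equal(ft$value[ft$feature == "glcm_contrast"], 0)
  expect_false(ft$valid[ft$feature == "glcm_correlation"])
})

test_that("the Gabor bank has 28 filters and responds maximally to a matched grating", {
  H <- 96; W <- 192
  grating <- matrix(rep(sin(2 * pi * 8 * sqrt(2) * (seq_len(W)) / W), each = H),
                    H, W) + 2
  ft <- gabor_features(grating, matrix(TRUE, H, W))
  expect_equal(nrow(ft), 56)
  en <- ft[grepl("_energy$", ft$feature), ]
  expect_equal(nrow(en), 28)
  # orientation 0 (o1), third frequency (8*sqrt2 after 2,4,8 doublings)
  expect_equal(en$feature[which.max(en$value)], "gabor_o1_f3_energy")

  const <- gabor_features(matrix(5, 32, 32), matrix(TRUE, 32, 32))
  expect_true(all(const$value[grepl("_entropy$", const$feature)] == 0))
})

test_that("LBP histograms are rotation-invariant proportions", {
  set.seed(7)
  img <- matrix(runif(48 * 48), 48, 48)
  mask <- matrix(TRUE, 48, 48)
  h <- lbp_features(img, mask)
  expect_equal(nrow(h), 10)
  expect_equal(sum(h$value), 1)
  rot90 <- t(img[nrow(img):1, ])
  h_rot <- lbp_features(rot90, mask)
  expect_equal(h$value, h_rot$value)

  const <- lbp_features(matrix(3, 20, 20), matrix(TRUE, 20, 20))
  expect_equal(sum(const$value == 1), 1)               # single bin holds all mass
})

test_that("fractal dimension reproduces closed-form patterns", {
  line <- matrix(FALSE, 128, 128); line[64, ] <- TRUE
  expect_equal(as.numeric(fractal_dimension(line)), 1, tolerance = 0.1)
  square <- matrix(TRUE, 128, 128)
  expect_equal(as.numeric(fractal_dimension(square)), 2, tolerance = 0.1)
  carpet <- sierpinski_carpet(4)
  expect_equal(as.numeric(fractal_dimension(carpet)), log(8) / log(3),
               tolerance = 0.1)
  empty <- fractal_dimension(matrix(FALSE, 10, 10))
  expect_equal(as.numeric(empty), 0)
  expect_false(attr(empty, "valid"))
})

test_that("mSFTA decomposes into 8 binary images and 64 features", {
  set.seed(9)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  mask <- matrix(TRUE, 64, 64)
  ft <- msfta_features(img, mask)
  expect_equal(nrow(ft), 64)
  expect_equal(sum(grepl("msfta_above_", ft$feature)), 32)
  expect_equal(sum(grepl("msfta_band_", ft$feature)), 32)
  thr <- histospectra:::multiotsu_thresholds(img, 4)
  expect_equal(length(thr), 4)                          # 2 * n_t = 8 binaries
  expect_true(all(diff(thr) > 0))
  expect_true(all(is.finite(ft$value)))

  # degenerate: two grey levels collapse duplicate thresholds -> flags, no NaN
  two <- matrix(rep(c(10, 200), 50), 10, 10)
  ft2 <- msfta_features(two, matrix(TRUE, 10, 10))
  expect_equal(nrow(ft2), 64)
  expect_true(all(is.finite(ft2$value)))
  expect_true(any(!ft2$valid))
})

test_that("multi-level Otsu matches exhaustive search on small histograms", {
  set.seed(3)
  vals <- c(rnorm(200, 40, 6), rnorm(200, 120, 8), rnorm(150, 210, 7))
  vals <- pmin(pmax(round(vals), 0), 255)
  got <- histospectra:::multiotsu_thresholds(vals, 2)
  # brute-force search over all threshold pairs on the 256-bin histogram
  counts <- tabulate(vals + 1, 256)
  p <- counts / sum(counts)
  lv <- 0:255
  best <- c(-Inf, NA, NA)
  score <- function(sel) {
    w <- sum(p[sel]); if (w == 0) return(0)
    sum(p[sel] * lv[sel])^2 / w
  }
  for (t1 in 10:120) for (t2 in (t1 + 1):240) {
    s <- score(lv <= t1) + score(lv > t1 & lv <= t2) + score(lv > t2)
    if (s > best[1]) best <- c(s, t1, t2)
  }
  expect_equal(got, best[2:3])
})

test_that("morphometric block has 44 entries with correct geometry", {
  rec_circle <- tibble::tibble(
    label = 1L, x = 20, y = 20, major = 16, minor = 16, orientation = 0,
    area = 201L, perimeter = 2 * pi * 8, solidity = 1, eccentricity = 0,
    red_blue_ratio = 0.6
  )
  cyto <- matrix(TRUE, 40, 40)
  ft <- morphometric_features(rec_circle, cyto)
  expect_equal(nrow(ft), 44)
  expect_equal(ft$value[ft$feature == "morph_eccentricity_mean"], 0)
  expect_equal(ft$value[ft$feature == "morph_compactness_mean"],
               (2 * pi * 8)^2 / (4 * pi * 201), tolerance = 0.1)
  expect_false(ft$valid[ft$feature == "morph_area_sd"])     # single nucleus
  expect_equal(ft$value[ft$feature == "morph_nc_ratio"], 201 / 1600)

  two <- dplyr::bind_rows(rec_circle, dplyr::mutate(rec_circle, label = 2L, x = 50))
  ft2 <- morphometric_features(two, cyto)
  expect_equal(ft2$value[ft2$feature == "morph_neighborhood_radius"], 15)

  none <- morphometric_features(rec_circle[0, ], cyto)
  expect_true(all(none$value == 0))
  expect_false(any(none$valid))
})

test_that("topology features match brute-force triangle geometry", {
  tri <- topology_features(cbind(c(0, 3, 3), c(0, 0, 4)))
  expect_equal(nrow(tri), 8)
  v <- setNames(tri$value, tri$feature)
  expect_equal(unname(v["topo_area_mean"]), 6)
  expect_equal(unname(v["topo_area_max"]), 6)
  expect_equal(unname(v["topo_area_min"]), 6)
  expect_equal(unname(v["topo_perimeter_mean"]), 12)
  expect_equal(unname(v["topo_area_disorder"]), 0)

  sq <- topology_features(cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)))
  vs <- setNames(sq$value, sq$feature)
  expect_equal(unname(vs["topo_area_mean"]), 0.5)
  expect_equal(unname(vs["topo_area_disorder"]), 0)

  degenerate <- topology_features(cbind(c(0, 1, 2), c(0, 1, 2)))   # collinear
  expect_true(all(degenerate$value == 0))
  expect_false(any(degenerate$valid))
  expect_false(any(topology_features(cbind(0:1, 0:1))$valid))
})

test_that("clustered nuclei have higher perimeter disorder than a jittered grid", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- expand.grid(x = seq(10, 90, by = 10), y = seq(10, 90, by = 10))
    grid_pts <- cbind(g$x + runif(81, -1, 1), g$y + runif(81, -1, 1))
    centers <- cbind(runif(5, 20, 80), runif(5, 20, 80))
    clustered <- centers[rep(1:5, each = 16), ] + matrix(rnorm(160, 0, 3), 80, 2)
    d_grid <- topology_features(grid_pts)
    d_clu <- topology_features(clustered)
    get <- function(ft, nm) ft$value[ft$feature == nm]
    expect_gt(get(d_clu, "topo_perimeter_disorder"),
              get(d_grid, "topo_perimeter_disorder"))
  }
})

test_that("the assembled bank has 712 uniquely named features in stable order", {
  crop <- generate_he_image(tissue_spec("dysplasia", seed = 29))
  masks <- segment_tissue(crop$image)
  ft <- extract_features(crop$image, masks)
  expect_equal(nrow(ft), 712)
  counts <- table(ft$compartment)
  expect_equal(unname(counts[c("epithelium", "cytoplasm", "nuclei")]),
               c(220L, 220L, 272L), ignore_attr = TRUE)
  fam <- table(ft$compartment, ft$family)
  expect_true(all(fam[, "color"] == 71))
  expect_true(all(fam[, "texture"] == 149))
  expect_equal(unname(fam["nuclei", "morphometry"]), 44L)
  expect_equal(unname(fam["nuclei", "topology"]), 8L)
  expect_false(anyDuplicated(ft$feature) > 0)
  expect_true(all(is.finite(ft$value)))

  # stable ordering across runs
  ft2 <- extract_features(crop$image, masks)
  expect_identical(ft$feature, ft2$feature)

  # empty nuclei: degenerate blocks, length still 712
  empty_masks <- list(
    epithelium = masks$epithelium,
    cytoplasm = masks$cytoplasm,
    nuclei_labels = matrix(0L, nrow(masks$epithelium), ncol(masks$epithelium)),
    nuclei = masks$nuclei[0, ]
  )
  ft3 <- extract_features(crop$image, empty_masks)
  expect_equal(nrow(ft3), 712)
  morpho <- ft3[ft3$family %in% c("morphometry", "topology"), ]
  expect_true(all(morpho$value == 0))
  expect_false(any(morpho$valid))
})

test_that("feature responses track the generative dials with the expected signs", {
  # raising boundary irregularity raises the epithelium fractal dimension;
  # raising crowding lowers the mean Delaunay perimeter
  fd_of <- function(irr, seed) {
    crop <- generate_he_image(tissue_spec("normal", boundary_irregularity = irr,
                                          seed = seed))
    masks <- segment_tissue(crop$image)
    ft <- msfta_features(histospectra:::luminance(crop$image), masks$epithelium)
    mean(ft$value[grepl("boundary_fd", ft$feature) & ft$valid])
  }
  perim_of <- function(crowd, seed) {
    crop <- generate_he_image(tissue_spec("normal", crowding = crowd,
                                          n_nuclei = 25, seed = seed))
    ft <- topology_features(cbind(crop$truth$nuclei$x, crop$truth$nuclei$y))
    ft$value[ft$feature == "topo_perimeter_mean"]
  }
  fd_votes <- vapply(1:10, function(s) fd_of(0.4, s) > fd_of(0.02, s), logical(1))
  per_votes <- vapply(1:10, function(s) {
    suppressWarnings(perim_of(2.4, s) < perim_of(0.8, s))
  }, logical(1))
  expect_gte(sum(fd_votes), 9)
  expect_gte(sum(per_votes), 9)
})
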