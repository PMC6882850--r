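#' Specification for one synthetic H&E-style crop
#'
#' Describes the geometry and staining of a synthetic haematoxylin-eosin
#' tongue-epithelium crop: an epithelial band occupying the top fraction of
#' the image, filled with pink cytoplasm, scattered white empty spaces, and
#' blue-purple nuclei drawn as radially-shaded, sinusoidally-perturbed
#' ellipses. Class defaults reproduce the qualitative ordering of squamous
#' neoplasia grades: neoplastic classes receive more, larger, more irregular
#' and more crowded nuclei, and a thicker epithelial band, than normal.
#'
#' @param pathology_class One of `"normal"`, `"dysplasia"`, `"cis"`,
#'   `"carcinoma"`.
#' @param image_width,image_height Canvas size in pixels.
#' @param epithelium_band Fraction of the image height occupied by the
#'   epithelial band (from the top). Default depends on class.
#' @param n_nuclei Number of nuclei to place. Default depends on class.
#' @param nucleus_axes_mean,nucleus_axes_sd Mean and standard deviation of the
#'   nucleus major/minor axis lengths, in pixels (length-2 vectors).
#' @param boundary_irregularity Amplitude of the sinusoidal radial
#'   perturbation of each nucleus outline, as a fraction of the minor axis
#'   length. Zero gives exact ellipses.
#' @param crowding Dimensionless density knob: the minimum centroid spacing is
#'   `1.5 * mean_axis / crowding`, so larger values pack nuclei closer
#'   together.
#' @param n_white_spaces Number of small unstained (white) spaces rendered in
#'   the band, emulating lumina/keratin gaps.
#' @param stain_colors Named list with `nuclei`, `cytoplasm` and `background`
#'   RGB triples on the 0-255 scale.
#' @param noise_sd Per-channel Gaussian pixel noise, 8-bit units.
#' @param effect_size Interpolation factor between the normal-class parameters
#'   (0) and the full class defaults (1); values above 1 extrapolate.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#'
#' @return A `tissue_spec` list.
#' @export
tissue_spec <- function(pathology_class = c("normal", "dysplasia", "cis", "carcinoma"),
                        image_width = 320L,
                        image_height = 208L,
                        epithelium_band = NULL,
                        n_nuclei = NULL,
                        nucleus_axes_mean = NULL,
                        nucleus_axes_sd = c(1.5, 1.0),
                        boundary_irregularity = NULL,
                        crowding = NULL,
                        n_white_spaces = 5L,
                        stain_colors = default_stain_colors(),
                        noise_sd = 3,
                        effect_size = 1,
                        seed = 1L) {
  pathology_class <- match.arg(pathology_class)
  defaults <- class_architecture()[[pathology_class]]
  normal <- class_architecture()[["normal"]]
  interp <- function(x0, x1) x0 + effect_size * (x1 - x0)
  spec <- list(
    pathology_class = pathology_class,
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    epithelium_band = epithelium_band %||%
      interp(normal$band, defaults$band),
    n_nuclei = n_nuclei %||%
      as.integer(round(interp(normal$n_nuclei, defaults$n_nuclei))),
    nucleus_axes_mean = nucleus_axes_mean %||%
      interp(normal$axes, defaults$axes),
    nucleus_axes_sd = nucleus_axes_sd,
    boundary_irregularity = boundary_irregularity %||%
      interp(normal$irregularity, defaults$irregularity),
    crowding = crowding %||% interp(normal$crowding, defaults$crowding),
    n_white_spaces = as.integer(n_white_spaces),
    stain_colors = stain_colors,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  validate_tissue_spec(spec)
  structure(spec, class = "tissue_spec")
}

# Qualitative grade ordering: denser, larger, more irregular, more crowded
# nuclei and a thicker band with increasing neoplastic grade.
class_architecture <- function() {
  list(
    normal = list(band = 0.45, n_nuclei = 22, axes = c(19, 13),
                  irregularity = 0.05, crowding = 1.0),
    dysplasia = list(band = 0.52, n_nuclei = 30, axes = c(20, 13.5),
                     irregularity = 0.15, crowding = 1.3),
    cis = list(band = 0.58, n_nuclei = 36, axes = c(21, 14),
               irregularity = 0.25, crowding = 1.6),
    carcinoma = list(band = 0.65, n_nuclei = 42, axes = c(22, 15),
                     irregularity = 0.35, crowding = 2.0)
  )
}

#' Default stain palette for synthetic crops
#'
#' Blue-purple nuclei, pink cytoplasm, near-white stroma/background. The
#' palette satisfies the colour-ratio rules used by segmentation: nuclei are
#' blue-dominant (red/blue 0.75, highest blue-ratio), cytoplasm has
#' red/blue above 1.2 (the false-detection cue), and the background is the
#' brightest cluster. The nuclei red value is kept moderate and the
#' cytoplasm clearly darker than the background so that the global red
#' channel histogram is dominated by the tissue-versus-background gap, which
#' is what the epithelium threshold relies on.
#'
#' @return Named list of RGB triples (0-255).
#' @export
default_stain_colors <- function() {
  list(
    nuclei = c(120, 80, 160),
    cytoplasm = c(198, 140, 162),
    background = c(250, 240, 245)
  )
}

validate_tissue_spec <- function(spec) {
  stopifnot(
    spec$image_width > 0, spec$image_height > 0,
    spec$epithelium_band > 0, spec$epithelium_band <= 1,
    spec$n_nuclei >= 0,
    all(spec$nucleus_axes_mean > 0),
    spec$boundary_irregularity >= 0,
    spec$crowding > 0
  )
  invisible(spec)
}

#' Polar outline of a perturbed-ellipse nucleus
#'
#' The outline used by the renderer: an ellipse with semi-axes
#' `major/2`, `minor/2` plus a sinusoidal radial perturbation of amplitude
#' `irregularity * minor` with `lobes` lobes. Useful for geometric checks
#' (perimeter grows monotonically with `irregularity` at fixed axes).
#'
#' @param major,minor Axis lengths in pixels.
#' @param orientation Rotation in radians.
#' @param irregularity Radial perturbation amplitude as fraction of the minor
#'   axis length.
#' @param lobes Integer number of sinusoidal lobes.
#' @param phase Phase offset in radians.
#' @param center Length-2 numeric, the (x, y) centroid.
#' @param n Number of polygon vertices.
#'
#' @return Tibble with columns `x`, `y`.
#' @export
nucleus_outline <- function(major, minor, orientation = 0, irregularity = 0,
                            lobes = 5L, phase = 0, center = c(0, 0), n = 360L) {
  a <- major / 2
  b <- minor / 2
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r_ell <- a * b / sqrt((b * cos(t))^2 + (a * sin(t))^2)
  r <- pmax(r_ell + irregularity * minor * sin(lobes * t + phase), 0.5)
  x <- r * cos(t)
  y <- r * sin(t)
  tibble::tibble(
    x = center[1] + x * cos(orientation) - y * sin(orientation),
    y = center[2] + x * sin(orientation) + y * cos(orientation)
  )
}

polygon_perimeter <- function(xy) {
  dx <- diff(c(xy$x, xy$x[1]))
  dy <- diff(c(xy$y, xy$y[1]))
  sum(sqrt(dx^2 + dy^2))
}

# Rejection-sample nucleus centroids with a minimum-spacing constraint.
# Crowding above 1 mimics proliferating nests: with probability
# 1 - 1/crowding a new nucleus is seeded near an existing one (at one to two
# spacing units), concentrating centroids into clusters the way neoplastic
# nuclei crowd. Hard cap of 100 * n attempts; fewer than 50% placed errors.
place_centroids <- function(n, x_range, y_range, min_spacing, crowding = 1) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  xs <- numeric(0)
  ys <- numeric(0)
  attempts <- 0L
  cap <- 100L * n
  p_cluster <- max(0, 1 - 1 / crowding)
  while (length(xs) < n && attempts < cap) {
    attempts <- attempts + 1L
    # fall back to uniform proposals once nest neighbourhoods saturate
    use_cluster <- attempts <= cap / 2 && length(xs) > 0L &&
      runif(1) < p_cluster
    if (use_cluster) {
      anchor <- sample.int(length(xs), 1L)
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, min_spacing, 2 * min_spacing)
      x <- min(max(xs[anchor] + rad * cos(ang), x_range[1]), x_range[2])
      y <- min(max(ys[anchor] + rad * sin(ang), y_range[1]), y_range[2])
    } else {
      x <- runif(1, x_range[1], x_range[2])
      y <- runif(1, y_range[1], y_range[2])
    }
    if (length(xs) == 0L || min((xs - x)^2 + (ys - y)^2) >= min_spacing^2) {
      xs <- c(xs, x)
      ys <- c(ys, y)
    }
  }
  if (length(xs) < n / 2) {
    stop(sprintf(
      paste0("could only place %d of %d nuclei at minimum spacing %.1f px; ",
             "reduce n_nuclei or increase crowding"),
      length(xs), n, min_spacing
    ), call. = FALSE)
  }
  if (length(xs) < n) {
    warning(sprintf("placed %d of %d requested nuclei", length(xs), n),
            call. = FALSE)
  }
  cbind(x = xs, y = ys)
}

#' Render a synthetic H&E crop with ground truth
#'
#' Draws the epithelial band (cytoplasm colour with white empty spaces) over a
#' white below-band background and paints each nucleus as a filled
#' perturbed ellipse with a radial chromatin gradient: a darker blue core
#' fading towards a lighter rim, plus a per-nucleus colour jitter. The
#' gradient is what gives the blue-ratio landscape one regional maximum per
#' nucleus, which the watershed-based cluster splitting relies on.
#'
#' @param spec A [tissue_spec()].
#'
#' @return A list of class `he_crop` with elements `image` (H x W x 3 array,
#'   0-255), and `truth`: a list with `nuclei` (tibble of centroids, axes,
#'   orientation and perturbation parameters), `labels` (integer matrix,
#'   0 = background), `epithelium_mask` (logical matrix) and `class_label`.
#' @export
generate_he_image <- function(spec) {
  validate_tissue_spec(spec)
  with_local_seed(spec$seed, {
    H <- spec$image_height
    W <- spec$image_width
    bh <- max(1L, round(spec$epithelium_band * H))
    cols <- spec$stain_colors
    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) {
      img[, , ch] <- cols$background[ch]
      img[seq_len(bh), , ch] <- cols$cytoplasm[ch]
    }
    epithelium_mask <- matrix(FALSE, H, W)
    epithelium_mask[seq_len(bh), ] <- TRUE

    # unstained empty spaces inside the band
    if (spec$n_white_spaces > 0L && bh > 12L) {
      for (i in seq_len(spec$n_white_spaces)) {
        wx <- runif(1, 8, W - 8)
        wy <- runif(1, 6, bh - 6)
        wa <- runif(1, 3, 6)
        wb <- runif(1, 2, 4)
        img <- paint_ellipse(img, wx, wy, wa, wb, runif(1, 0, pi),
                             cols$background)
      }
    }

    mean_axis <- mean(spec$nucleus_axes_mean)
    min_spacing <- 1.5 * mean_axis / spec$crowding
    margin <- spec$nucleus_axes_mean[1] / 2 + 2
    labels <- matrix(0L, H, W)
    nuclei <- tibble::tibble(
      id = integer(0), x = numeric(0), y = numeric(0),
      major = numeric(0), minor = numeric(0), orientation = numeric(0),
      irregularity = numeric(0), lobes = integer(0), phase = numeric(0)
    )
    if (spec$n_nuclei > 0L) {
      if (bh <= 2 * margin || W <= 2 * margin) {
        stop("epithelium band too thin for the requested nucleus size",
             call. = FALSE)
      }
      centers <- place_centroids(
        spec$n_nuclei,
        x_range = c(margin, W - margin),
        y_range = c(margin, bh - margin),
        min_spacing = min_spacing,
        crowding = spec$crowding
      )
      n <- nrow(centers)
      major <- pmax(rnorm(n, spec$nucleus_axes_mean[1], spec$nucleus_axes_sd[1]), 9)
      minor <- pmax(rnorm(n, spec$nucleus_axes_mean[2], spec$nucleus_axes_sd[2]), 8)
      swap <- minor > major
      tmp <- major[swap]; major[swap] <- minor[swap]; minor[swap] <- tmp
      orientation <- runif(n, 0, pi)
      lobes <- sample(3:7, n, replace = TRUE)
      phase <- runif(n, 0, 2 * pi)
      for (i in seq_len(n)) {
        base_col <- cols$nuclei + rnorm(3, 0, 6)
        # brightness ramp core -> rim: keeps red/blue constant within the
        # nucleus while giving the blue-ratio one regional maximum per core
        painted <- paint_nucleus(
          img, labels, i,
          cx = centers[i, "x"], cy = centers[i, "y"],
          a = major[i] / 2, b = minor[i] / 2,
          theta = orientation[i],
          amp = spec$boundary_irregularity * minor[i],
          lobes = lobes[i], phase = phase[i],
          core = 0.85 * base_col, rim = 1.30 * base_col
        )
        img <- painted$img
        labels <- painted$labels
      }
      nuclei <- tibble::tibble(
        id = seq_len(n),
        x = centers[, "x"], y = centers[, "y"],
        major = major, minor = minor, orientation = orientation,
        irregularity = spec$boundary_irregularity,
        lobes = lobes, phase = phase
      )
    }

    if (spec$noise_sd > 0) {
      img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    }
    img <- round(pmin(pmax(img, 0), 255))

    structure(list(
      image = img,
      truth = list(
        nuclei = nuclei,
        labels = labels,
        epithelium_mask = epithelium_mask,
        class_label = spec$pathology_class
      ),
      spec = spec
    ), class = "he_crop")
  })
}

# Paint a flat-colour ellipse (used for white spaces).
paint_ellipse <- function(img, cx, cy, a, b, theta, color) {
  box <- pixel_box(img, cx, cy, a + 1)
  if (is.null(box)) return(img)
  u <- (box$dx * cos(theta) + box$dy * sin(theta)) / a
  v <- (-box$dx * sin(theta) + box$dy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  for (ch in 1:3) {
    plane <- img[box$rows, box$cols, ch]
    plane[inside] <- color[ch]
    img[box$rows, box$cols, ch] <- plane
  }
  img
}

# Paint one radially-shaded perturbed-ellipse nucleus and record its label.
paint_nucleus <- function(img, labels, id, cx, cy, a, b, theta, amp,
                          lobes, phase, core, rim) {
  box <- pixel_box(img, cx, cy, a + amp + 1)
  if (is.null(box)) return(list(img = img, labels = labels))
  u <- box$dx * cos(theta) + box$dy * sin(theta)
  v <- -box$dx * sin(theta) + box$dy * cos(theta)
  t <- atan2(v, u)
  rr <- sqrt(u^2 + v^2)
  r_ell <- a * b / sqrt((b * cos(t))^2 + (a * sin(t))^2)
  r_out <- pmax(r_ell + amp * sin(lobes * t + phase), 0.5)
  inside <- rr <= r_out
  frac <- pmin(rr / pmax(r_out, 1e-6), 1)[inside]^1.5
  for (ch in 1:3) {
    plane <- img[box$rows, box$cols, ch]
    plane[inside] <- core[ch] + (rim[ch] - core[ch]) * frac
    img[box$rows, box$cols, ch] <- plane
  }
  lab <- labels[box$rows, box$cols]
  lab[inside] <- id
  labels[box$rows, box$cols] <- lab
  list(img = img, labels = labels)
}

pixel_box <- function(img, cx, cy, radius) {
  H <- dim(img)[1]
  W <- dim(img)[2]
  rows <- max(1L, floor(cy - radius)):min(H, ceiling(cy + radius))
  cols <- max(1L, floor(cx - radius)):min(W, ceiling(cx + radius))
  if (length(rows) == 0L || length(cols) == 0L) return(NULL)
  dx <- matrix(cols, length(rows), length(cols), byrow = TRUE) - cx
  dy <- matrix(rows, length(rows), length(cols)) - cy
  list(rows = rows, cols = cols, dx = dx, dy = dy)
}

#' Specification of synthetic class reflectance spectra
#'
#' Class spectra are a logistic-rising baseline multiplied by a class
#' amplitude, minus a Gaussian absorption dip centred near 540 nm where
#' haemoglobin absorbs. Neoplastic classes have larger amplitudes than
#' normal tissue, matching the empirical ordering of tongue reflectance.
#'
#' @param wavelengths Wavelength grid in nm (default 450-900 nm, 5-nm steps,
#'   91 bands).
#' @param baseline_amplitude Named per-class amplitudes in reflectance units.
#' @param hemoglobin_dip_center,dip_width Dip centre and Gaussian width, nm.
#' @param dip_depth Fractional depth of the dip.
#' @param noise_sd Per-voxel reflectance noise used by [generate_hypercube()].
#' @param seed Integer seed.
#'
#' @return A `spectrum_spec` list.
#' @export
spectrum_spec <- function(wavelengths = seq(450, 900, by = 5),
                          baseline_amplitude = c(
                            normal = 0.35, dysplasia = 0.45,
                            cis = 0.50, carcinoma = 0.55, background = 0.08
                          ),
                          hemoglobin_dip_center = 540,
                          dip_width = 25,
                          dip_depth = 0.35,
                          noise_sd = 0.005,
                          seed = 1L) {
  stopifnot(all(diff(wavelengths) > 0), dip_width > 0,
            dip_depth >= 0, dip_depth < 1, noise_sd >= 0)
  structure(list(
    wavelengths = wavelengths,
    baseline_amplitude = baseline_amplitude,
    hemoglobin_dip_center = hemoglobin_dip_center,
    dip_width = dip_width,
    dip_depth = dip_depth,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "spectrum_spec")
}

#' Noise-free class spectra implied by a spectrum specification
#'
#' @param spec A [spectrum_spec()].
#' @return Tibble with columns `class`, `wavelength`, `reflectance`.
#' @export
class_spectra <- function(spec) {
  stopifnot(inherits(spec, "spectrum_spec"))
  wl <- spec$wavelengths
  base <- 0.25 + 0.75 * stats::plogis((wl - 580) / 60)
  dip <- spec$dip_depth *
    exp(-(wl - spec$hemoglobin_dip_center)^2 / (2 * spec$dip_width^2))
  purrr::map_dfr(names(spec$baseline_amplitude), function(cl) {
    tibble::tibble(
      class = cl,
      wavelength = wl,
      reflectance = spec$baseline_amplitude[[cl]] * base * (1 - dip)
    )
  })
}

#' Generate a raw/white/dark hypercube triple for a class layout
#'
#' Builds reference cubes with a smoothly varying illumination (white) and
#' sensor offset (dark), then composes the raw cube as
#' `dark + reflectance * (white - dark) + noise`, where each pixel's
#' reflectance spectrum is its class spectrum. Calibrating the raw cube with
#' the returned references therefore recovers the class spectra exactly at
#' `noise_sd = 0`.
#'
#' @param spec A [spectrum_spec()].
#' @param class_layout Character matrix of class labels per pixel; values must
#'   be names of `spec$baseline_amplitude`.
#'
#' @return List with `raw`, `white`, `dark` [hypercube()] objects.
#' @export
generate_hypercube <- function(spec, class_layout) {
  stopifnot(inherits(spec, "spectrum_spec"), is.matrix(class_layout))
  classes <- unique(as.vector(class_layout))
  unknown <- setdiff(classes, names(spec$baseline_amplitude))
  if (length(unknown) > 0L) {
    stop("class_layout contains unknown classes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  H <- nrow(class_layout)
  W <- ncol(class_layout)
  wl <- spec$wavelengths
  B <- length(wl)

  white_band <- 3000 + 1500 * exp(-((wl - 650) / 180)^2)
  dark_band <- 100 + 15 * (wl - min(wl)) / (max(wl) - min(wl))
  gain <- outer(1 + 0.03 * sin(2 * pi * seq_len(H) / H),
                1 + 0.03 * cos(2 * pi * seq_len(W) / W))
  white <- outer(gain, white_band)
  dark <- outer(matrix(1, H, W), dark_band) +
    outer(0.02 * gain, rep(100, B)) - 2
  if (any(white <= dark)) {
    stop("internal error: white reference not strictly above dark reference",
         call. = FALSE)
  }

  spectra <- class_spectra(spec)
  refl <- array(0, dim = c(H, W, B))
  for (cl in classes) {
    s <- spectra$reflectance[spectra$class == cl]
    idx <- which(class_layout == cl)
    for (b in seq_len(B)) {
      plane <- refl[, , b]
      plane[idx] <- s[b]
      refl[, , b] <- plane
    }
  }
  raw <- with_local_seed(spec$seed, {
    noise <- if (spec$noise_sd > 0) {
      array(rnorm(H * W * B, 0, spec$noise_sd), dim = c(H, W, B))
    } else {
      0
    }
    dark + (refl + noise) * (white - dark)
  })
  list(
    raw = hypercube(raw, wl, kind = "raw"),
    white = hypercube(white, wl, kind = "white"),
    dark = hypercube(dark, wl, kind = "dark")
  )
}

#' Generate a subject-structured paired synthetic dataset
#'
#' Produces, for each subject, one or more H&E crops per pathology class
#' (with ground truth) together with a matching small hyperspectral cube per
#' crop and its extracted spectral signature. Subjects carry mild random
#' effects on nuclear density and spectral amplitude so that
#' leave-one-subject-out cross-validation has genuine between-subject
#' structure. `effect_size` scales the normal-versus-neoplastic difference in
#' both tissue architecture and spectral amplitude; at 0 all classes are
#' generated from identical parameters and the labels are uninformative.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param images_per_class Images per subject and class (>= 1).
#' @param effect_size Dimensionless scaling of class differences.
#' @param seed Integer master seed; all per-image seeds derive from it.
#' @param classes Pathology classes to generate.
#' @param image_width,image_height Crop size in pixels.
#' @param cube_side Side length of the square synthetic cube per image.
#' @param spectrum Base [spectrum_spec()]; per-image amplitudes are scaled.
#' @param keep_cubes Keep the raw/white/dark cubes in the result (memory
#'   heavy); signatures are always kept.
#' @param dir Optional directory; when given, crops (PNG), ground truth
#'   (JSON + 16-bit label TIFF), cubes (multi-page TIFF + wavelength JSON
#'   sidecar) and the manifest (CSV) are written there.
#'
#' @return A list of class `synthetic_bundle` with `images`, `truths`,
#'   `signatures` (tibble: image_id, class, wavelength, reflectance),
#'   `manifest` (tibble: image_id, subject_id, class, label) and the
#'   generation parameters.
#' @export
generate_paired_dataset <- function(n_subjects = 10L,
                                    images_per_class = 1L,
                                    effect_size = 1,
                                    seed = 1L,
                                    classes = c("normal", "dysplasia", "cis", "carcinoma"),
                                    image_width = 320L,
                                    image_height = 200L,
                                    cube_side = 36L,
                                    spectrum = spectrum_spec(),
                                    keep_cubes = FALSE,
                                    dir = NULL) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (images_per_class < 1L) stop("images_per_class must be >= 1", call. = FALSE)
  grid <- expand.grid(
    rep = seq_len(images_per_class),
    class = classes,
    subject = seq_len(n_subjects),
    stringsAsFactors = FALSE
  )
  n_images <- nrow(grid)
  setup <- with_local_seed(seed, {
    list(
      image_seeds = sample.int(.Machine$integer.max - 1L, n_images),
      arch_scale = rnorm(n_subjects, 1, 0.05),
      amp_scale = rnorm(n_subjects, 1, 0.05),
      image_jitter = rnorm(n_images, 1, 0.04)
    )
  })

  images <- vector("list", n_images)
  truths <- vector("list", n_images)
  cubes <- if (keep_cubes) vector("list", n_images) else NULL
  signatures <- vector("list", n_images)
  layout <- matrix("background", cube_side, cube_side)
  inner <- 4:(cube_side - 3)
  amp0 <- spectrum$baseline_amplitude

  for (i in seq_len(n_images)) {
    subj <- grid$subject[i]
    cl <- grid$class[i]
    jit <- setup$image_jitter[i] * setup$arch_scale[subj]
    base_spec <- tissue_spec(cl, image_width = image_width,
                             image_height = image_height,
                             effect_size = effect_size,
                             seed = setup$image_seeds[i])
    spec_i <- tissue_spec(
      cl,
      image_width = image_width, image_height = image_height,
      effect_size = effect_size,
      n_nuclei = max(1L, as.integer(round(base_spec$n_nuclei * jit))),
      nucleus_axes_mean = base_spec$nucleus_axes_mean * sqrt(jit),
      seed = setup$image_seeds[i]
    )
    crop <- generate_he_image(spec_i)
    images[[i]] <- crop$image
    truths[[i]] <- crop$truth

    amp_cl <- amp0[["normal"]] + effect_size * (amp0[[cl]] - amp0[["normal"]])
    amp <- amp0
    amp[[cl]] <- amp_cl * setup$amp_scale[subj] * setup$image_jitter[i]
    spec_cube <- spectrum_spec(
      wavelengths = spectrum$wavelengths,
      baseline_amplitude = amp,
      hemoglobin_dip_center = spectrum$hemoglobin_dip_center,
      dip_width = spectrum$dip_width,
      dip_depth = spectrum$dip_depth,
      noise_sd = spectrum$noise_sd,
      seed = setup$image_seeds[i]
    )
    layout_i <- layout
    layout_i[inner, inner] <- cl
    cube <- generate_hypercube(spec_cube, layout_i)
    if (keep_cubes) cubes[[i]] <- cube
    refl <- calibrate_reflectance(cube$raw, cube$white, cube$dark)
    pmap <- build_pathology_map(
      tibble::tibble(row = inner, col_start = inner[1], col_end = inner[length(inner)],
                     class = cl),
      shape = c(cube_side, cube_side)
    )
    sig <- extract_spectral_signatures(refl, pmap)
    sig$image_id <- i
    signatures[[i]] <- sig
  }

  manifest <- tibble::tibble(
    image_id = seq_len(n_images),
    subject_id = grid$subject,
    class = grid$class,
    label = ifelse(grid$class == "normal", "normal", "neoplastic")
  )
  bundle <- structure(list(
    images = images,
    truths = truths,
    cubes = cubes,
    signatures = dplyr::bind_rows(signatures),
    manifest = manifest,
    spectrum = spectrum,
    effect_size = effect_size,
    seed = as.integer(seed)
  ), class = "synthetic_bundle")
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}
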