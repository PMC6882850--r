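# Readers/writers for the package's on-disk formats: PNG crops, 16-bit label
# TIFFs, multi-page float TIFF hypercubes with a JSON wavelength sidecar,
# signature CSVs (rows = classes, columns = wavelengths) and bundle manifests.

#' Write / read an RGB crop as PNG
#'
#' @param image H x W x 3 array on the 0-255 scale.
#' @param path File path.
#' @return `read_crop_png` returns the image array (0-255).
#' @export
write_crop_png <- function(image, path) {
  assert_rgb_image(image)
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' @rdname write_crop_png
#' @export
read_crop_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] > 3L) img <- img[, , 1:3]
  round(img * 255)
}

#' Write / read an integer label image as 16-bit TIFF
#'
#' @param labels Integer matrix (0 = background), values below 65536.
#' @param path File path.
#' @return `read_label_tiff` returns the integer label matrix.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  storage.mode(m) <- "double"
  m <- round(m * 65535)
  storage.mode(m) <- "integer"
  m
}

#' Write / read a hypercube as multi-page TIFF with JSON sidecar
#'
#' Bands are stored as 32-bit float TIFF pages, rescaled to [0, 1] by a
#' factor recorded in the sidecar together with the wavelength axis and cube
#' kind. Masked voxels are stored as 0 and re-masked on read via an index
#' list in the sidecar.
#'
#' @param cube A [hypercube()].
#' @param path TIFF path; the sidecar is written at `<path>.json`.
#' @return `read_hypercube_tiff` returns the [hypercube()].
#' @export
write_hypercube_tiff <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  v <- cube$values
  na_idx <- which(is.na(v))
  v[na_idx] <- 0
  scale <- max(v, 1e-12)
  pages <- lapply(seq_len(dim(v)[3]), function(b) v[, , b] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(wavelengths = cube$wavelengths, kind = cube$kind, scale = scale,
         masked = na_idx),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_hypercube_tiff
#' @export
read_hypercube_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  v <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))) *
    meta$scale
  if (length(meta$masked) > 0L) v[meta$masked] <- NA_real_
  hypercube(v, meta$wavelengths, kind = meta$kind)
}

#' Write spectral signatures as CSV (rows = classes, columns = wavelengths)
#'
#' @param signatures A [extract_spectral_signatures()] tibble.
#' @param path CSV path.
#' @export
write_signatures_csv <- function(signatures, path) {
  ids <- setdiff(names(signatures), c("wavelength", "reflectance", "n_pixels"))
  wide <- tidyr::pivot_wider(
    as.data.frame(signatures)[, c(ids, "wavelength", "reflectance")],
    names_from = "wavelength", values_from = "reflectance"
  )
  write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic bundle to disk
#'
#' Crops go to `crops/*.png`, ground truth to `truth/*.json` plus 16-bit
#' label TIFFs, cubes (when kept in the bundle) to `cubes/*.tif` with JSON
#' wavelength sidecars, signatures and the manifest to CSV.
#'
#' @param bundle A [generate_paired_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  for (sub in c("crops", "truth", "cubes")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  manifest <- bundle$manifest
  manifest$image_path <- NA_character_
  manifest$cube_path <- NA_character_
  for (i in seq_along(bundle$images)) {
    stem <- sprintf("img%03d", i)
    img_path <- file.path(dir, "crops", paste0(stem, ".png"))
    write_crop_png(bundle$images[[i]], img_path)
    manifest$image_path[i] <- img_path
    truth <- bundle$truths[[i]]
    write_label_tiff(truth$labels, file.path(dir, "truth", paste0(stem, "_labels.tif")))
    jsonlite::write_json(
      list(class_label = truth$class_label, nuclei = truth$nuclei),
      file.path(dir, "truth", paste0(stem, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "columns"
    )
    if (!is.null(bundle$cubes)) {
      cube_path <- file.path(dir, "cubes", paste0(stem, "_raw.tif"))
      write_hypercube_tiff(bundle$cubes[[i]]$raw, cube_path)
      write_hypercube_tiff(bundle$cubes[[i]]$white,
                           file.path(dir, "cubes", paste0(stem, "_white.tif")))
      write_hypercube_tiff(bundle$cubes[[i]]$dark,
                           file.path(dir, "cubes", paste0(stem, "_dark.tif")))
      manifest$cube_path[i] <- cube_path
    }
  }
  write_signatures_csv(bundle$signatures, file.path(dir, "signatures.csv"))
  write.csv(
    manifest[, c("image_path", "cube_path", "subject_id", "class", "image_id", "label")],
    file.path(dir, "manifest.csv"), row.names = FALSE
  )
  invisible(dir)
}
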