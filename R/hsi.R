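#' Hypercube container
#'
#' A hyperspectral cube: an H x W x B array of intensities with a strictly
#' increasing wavelength axis. `kind` records the processing state:
#' `"raw"`, `"white"` and `"dark"` are camera counts, `"reflectance"` is the
#' calibrated relative reflectance. Masked (invalid) reflectance voxels are
#' stored as `NA` and skipped by downstream averaging; no other non-finite
#' values are permitted.
#'
#' @param values H x W x B numeric array.
#' @param wavelengths Numeric vector of length B, strictly increasing, nm.
#' @param kind One of `"raw"`, `"white"`, `"dark"`, `"reflectance"`.
#'
#' @return A `hypercube` object.
#' @export
hypercube <- function(values, wavelengths,
                      kind = c("raw", "white", "dark", "reflectance")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be an H x W x B array", call. = FALSE)
  }
  if (dim(values)[3] != length(wavelengths)) {
    stop("third dimension must match length(wavelengths)", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (kind != "reflectance" && anyNA(values)) {
    stop("raw/reference cubes must not contain NA", call. = FALSE)
  }
  if (any(!is.finite(values) & !is.na(values))) {
    stop("cube values must be finite (NA marks masked voxels)", call. = FALSE)
  }
  structure(
    list(values = values, wavelengths = as.numeric(wavelengths), kind = kind),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube [%s]> %d x %d pixels, %d bands (%g-%g nm)",
              x$kind, d[1], d[2], d[3],
              min(x$wavelengths), max(x$wavelengths)))
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat(sprintf(", %d masked voxels", n_na))
  cat("\n")
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$values)

#' Calibrate a raw hypercube to relative reflectance
#'
#' Voxel-wise relative reflectance against white and dark reference cubes:
#' \deqn{I_{ref}(x,y,\lambda) = \frac{I_{raw}(x,y,\lambda) -
#'   I_{dark}(x,y,\lambda)}{I_{white}(x,y,\lambda) - I_{dark}(x,y,\lambda)}}
#' Voxels where the denominator is not positive are masked (`NA`) rather than
#' propagated as infinities. Values above 1 (specular highlights) are kept
#' and reported, not clipped. The transform is invariant to a common positive
#' gain applied to all three cubes.
#'
#' @param raw,white,dark [hypercube()] objects with identical shapes and
#'   wavelength grids.
#'
#' @return A `hypercube` of kind `"reflectance"` with attribute `n_invalid`,
#'   the number of masked voxels.
#' @export
calibrate_reflectance <- function(raw, white, dark) {
  for (cube in list(raw, white, dark)) {
    if (!inherits(cube, "hypercube")) {
      stop("inputs must be hypercube objects", call. = FALSE)
    }
  }
  if (!identical(dim(raw$values), dim(white$values)) ||
      !identical(dim(raw$values), dim(dark$values))) {
    stop("raw, white and dark cubes must share the same shape", call. = FALSE)
  }
  if (!isTRUE(all.equal(raw$wavelengths, white$wavelengths)) ||
      !isTRUE(all.equal(raw$wavelengths, dark$wavelengths))) {
    stop("raw, white and dark cubes must share the wavelength grid",
         call. = FALSE)
  }
  denom <- white$values - dark$values
  invalid <- denom <= 0
  if (all(invalid)) {
    stop("all voxels have white - dark <= 0; cannot calibrate", call. = FALSE)
  }
  ref <- (raw$values - dark$values) / denom
  ref[invalid] <- NA_real_
  out <- hypercube(ref, raw$wavelengths, kind = "reflectance")
  attr(out, "n_invalid") <- sum(invalid)
  out
}

#' Build a line-based pathology map
#'
#' Paints per-row class runs onto an unlabeled image, mirroring the mapping
#' of graded tissue sections onto straight lines across the dorsal tongue
#' surface. Runs are inclusive column ranges and must not overlap within a
#' row.
#'
#' @param line_annotations Tibble/data frame with columns `row`, `col_start`,
#'   `col_end`, `class`.
#' @param shape Length-2 integer vector, the (rows, cols) of the map.
#'
#' @return A `pathology_map`: list with `labels` (character matrix with
#'   `"unlabeled"` elsewhere) and the annotation table.
#' @export
build_pathology_map <- function(line_annotations, shape) {
  stopifnot(length(shape) == 2L)
  ann <- tibble::as_tibble(line_annotations)
  labels <- matrix("unlabeled", shape[1], shape[2])
  if (nrow(ann) > 0L) {
    required <- c("row", "col_start", "col_end", "class")
    if (!all(required %in% names(ann))) {
      stop("annotations need columns row, col_start, col_end, class",
           call. = FALSE)
    }
    if (any(ann$row < 1 | ann$row > shape[1])) {
      stop("annotation row outside the image", call. = FALSE)
    }
    if (any(ann$col_start < 1 | ann$col_end > shape[2] |
            ann$col_start > ann$col_end)) {
      stop("annotation columns outside the image", call. = FALSE)
    }
    for (r in unique(ann$row)) {
      runs <- ann[ann$row == r, , drop = FALSE]
      runs <- runs[order(runs$col_start), , drop = FALSE]
      if (nrow(runs) > 1L &&
          any(runs$col_start[-1] <= runs$col_end[-nrow(runs)])) {
        stop(sprintf("overlapping runs on row %d", r), call. = FALSE)
      }
      for (i in seq_len(nrow(runs))) {
        labels[r, runs$col_start[i]:runs$col_end[i]] <- runs$class[i]
      }
    }
  }
  structure(list(labels = labels, annotations = ann), class = "pathology_map")
}

#' Extract per-class spectral signatures
#'
#' Averages the reflectance spectra of all labeled, unmasked pixels of each
#' pathology class present in the map. Classes absent from the map are
#' omitted, not zero-filled.
#'
#' @param cube A reflectance [hypercube()].
#' @param map A [build_pathology_map()] result, or a character matrix of the
#'   same H x W shape as the cube.
#'
#' @return Tibble of class `spectral_signature` with columns `class`,
#'   `wavelength`, `reflectance`, `n_pixels`.
#' @export
extract_spectral_signatures <- function(cube, map) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$kind != "reflectance") {
    stop("signatures are extracted from a reflectance cube", call. = FALSE)
  }
  labels <- if (inherits(map, "pathology_map")) map$labels else map
  d <- dim(cube$values)
  if (!identical(dim(labels), d[1:2])) {
    stop("cube and pathology map must share the spatial shape", call. = FALSE)
  }
  classes <- setdiff(sort(unique(as.vector(labels))), "unlabeled")
  if (length(classes) == 0L) {
    stop("no labeled pixels in the pathology map", call. = FALSE)
  }
  B <- d[3]
  flat <- matrix(cube$values, d[1] * d[2], B)
  out <- purrr::map_dfr(classes, function(cl) {
    idx <- which(labels == cl)
    spectra <- flat[idx, , drop = FALSE]
    valid <- colSums(!is.na(spectra))
    if (all(valid == 0L)) {
      stop(sprintf("all labeled pixels of class '%s' are masked", cl),
           call. = FALSE)
    }
    tibble::tibble(
      class = cl,
      wavelength = cube$wavelengths,
      reflectance = colMeans(spectra, na.rm = TRUE),
      n_pixels = as.integer(valid)
    )
  })
  class(out) <- c("spectral_signature", class(out))
  out
}

#' Plot spectral signatures
#'
#' @param object A [extract_spectral_signatures()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectral_signature
#' @export
autoplot.spectral_signature <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength, .data$reflectance,
                                       colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "relative reflectance",
                  colour = "pathology") +
    ggplot2::theme_minimal()
}
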