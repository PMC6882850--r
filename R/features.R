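texture_features <- function(gray, mask) {
  dplyr::bind_rows(
    glcm_features(gray, mask),
    gabor_features(gray, mask),
    lbp_features(gray, mask),
    msfta_features(gray, mask)
  )
}

#' Extract the compartment-tagged feature bank from one crop
#'
#' Computes, for each requested compartment (epithelium, cytoplasm, nuclei),
#' 71 colour and 149 texture features (GLCM 19 + Gabor 56 + LBP 10 + mSFTA
#' 64) on the masked image, and for the nuclei additionally 44 morphometric
#' and 8 Delaunay-topology features. With all compartments and families the
#' result is the full 712-feature bank (220 + 220 + 272), asserted at run
#' time. Texture families are computed on the luminance image; feature names
#' are `{compartment}.{family}.{feature}` and their order is stable across
#' runs.
#'
#' @param rgb H x W x 3 array, 8-bit.
#' @param masks A [segment_tissue()] result (`tissue_masks`), or a list with
#'   `epithelium`, `cytoplasm`, `nuclei_labels` and `nuclei` records.
#' @param compartments,families Subsets to compute (cost control); defaults
#'   give the full bank.
#' @return Tibble with columns `feature`, `compartment`, `family`, `value`,
#'   `valid`.
#' @export
extract_features <- function(rgb, masks,
                             compartments = c("epithelium", "cytoplasm", "nuclei"),
                             families = c("color", "texture", "morphometry", "topology")) {
  assert_rgb_image(rgb)
  compartments <- match.arg(compartments, several.ok = TRUE)
  families <- match.arg(families, several.ok = TRUE)
  gray <- luminance(rgb)
  nuclei_mask <- masks$nuclei_labels > 0L
  comp_masks <- list(
    epithelium = masks$epithelium,
    cytoplasm = masks$cytoplasm,
    nuclei = nuclei_mask
  )
  full <- setequal(compartments, c("epithelium", "cytoplasm", "nuclei")) &&
    setequal(families, c("color", "texture", "morphometry", "topology"))
  out <- list()
  for (comp in compartments) {
    mask <- comp_masks[[comp]]
    blocks <- list()
    if ("color" %in% families) {
      blocks <- c(blocks, list(color_features(rgb, mask)))
    }
    if ("texture" %in% families) {
      blocks <- c(blocks, list(texture_features(gray, mask)))
    }
    if (comp == "nuclei") {
      if ("morphometry" %in% families) {
        blocks <- c(blocks, list(
          morphometric_features(masks$nuclei, masks$cytoplasm)
        ))
      }
      if ("topology" %in% families) {
        blocks <- c(blocks, list(
          topology_features(cbind(masks$nuclei$x, masks$nuclei$y))
        ))
      }
    }
    if (length(blocks) == 0L) next
    tbl <- dplyr::bind_rows(blocks)
    tbl$compartment <- comp
    tbl$feature <- paste(comp, tbl$family, tbl$feature, sep = ".")
    out <- c(out, list(tbl))
  }
  out <- dplyr::bind_rows(out)[, c("feature", "compartment", "family",
                                   "value", "valid")]
  if (anyDuplicated(out$feature)) {
    stop("internal error: duplicated feature names", call. = FALSE)
  }
  if (full) {
    counts <- table(out$compartment)
    if (!identical(nrow(out), 712L) ||
        counts[["epithelium"]] != 220L || counts[["cytoplasm"]] != 220L ||
        counts[["nuclei"]] != 272L) {
      stop(sprintf(
        "feature-bank contract violated: %d features (epithelium %d, cytoplasm %d, nuclei %d), expected 712 (220/220/272)",
        nrow(out), counts[["epithelium"]], counts[["cytoplasm"]],
        counts[["nuclei"]]
      ), call. = FALSE)
    }
  }
  out
}

#' Pivot a long feature table to a samples-by-features matrix
#'
#' @param features Long tibble from [extract_features()] rows bound over
#'   images, with an `image_id` column.
#' @return Tibble with one row per `image_id` and one column per feature.
#' @export
features_wide <- function(features) {
  tidyr::pivot_wider(
    features[, c("image_id", "feature", "value")],
    names_from = "feature", values_from = "value"
  )
}

#' Segment and featurise every crop of a bundle
#'
#' Convenience batch runner: segments each image of a synthetic bundle (or
#' any list of RGB arrays) and extracts features, returning a long tibble
#' keyed by `image_id`. Images whose segmentation or extraction fails are
#' reported with a warning and skipped.
#'
#' @param images List of RGB arrays, or a `synthetic_bundle`.
#' @param compartments,families Passed to [extract_features()].
#' @param seg_params Passed to [segment_tissue()].
#' @return Long feature tibble with `image_id` column.
#' @export
extract_features_batch <- function(images,
                                   compartments = c("epithelium", "cytoplasm", "nuclei"),
                                   families = c("color", "texture", "morphometry", "topology"),
                                   seg_params = segmentation_params()) {
  if (inherits(images, "synthetic_bundle")) images <- images$images
  out <- vector("list", length(images))
  for (i in seq_along(images)) {
    res <- tryCatch({
      masks <- segment_tissue(images[[i]], params = seg_params)
      ft <- extract_features(images[[i]], masks,
                             compartments = compartments, families = families)
      ft$image_id <- i
      ft
    }, error = function(e) {
      warning(sprintf("image %d failed: %s", i, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    out[[i]] <- res
  }
  dplyr::bind_rows(out)
}
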