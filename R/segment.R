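# Pixel classification and DCWL computation: the colour-threshold area
# analysis applied to each micrograph.  Pixels are converted from sRGB to
# hue-saturation-value, matched against the class bands in fixed priority
# red -> blue -> white, and the degree of cell wall lignification (DCWL) is
# the red wall area divided by the total (red + blue) wall area.

PIXEL_LEVELS <- c("RED", "BLUE", "WHITE", "UNCLASSIFIED")

as_rgb_array <- function(image) {
  if (inherits(image, "micrograph")) image <- image$image
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop("image must be a height x width x 3 RGB array (0-255)", call. = FALSE)
  }
  image
}

#' Classify micrograph pixels into stain classes
#'
#' Converts the image to HSV and assigns each pixel to the first matching
#' class in the fixed priority red, blue, white; pixels matching no class are
#' UNCLASSIFIED.  Pixels outside the region of interest are excluded from all
#' downstream counts (the ROI is how cracks or slide artefacts are masked
#' out).
#'
#' @param image A `micrograph` or an 8-bit RGB array (`height x width x 3`,
#'   values 0-255).
#' @param thresholds A [color_thresholds()] object.
#' @param roi Optional logical matrix of the image dimensions; `FALSE` pixels
#'   are excluded.  Default: the full frame.
#' @return A `pixel_class_map`: integer matrix with levels
#'   1 = RED, 2 = BLUE, 3 = WHITE, 4 = UNCLASSIFIED and `NA` outside the ROI.
#' @export
classify_pixels <- function(image, thresholds = default_color_thresholds(),
                            roi = NULL) {
  img <- as_rgb_array(image)
  validate_color_thresholds(thresholds)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (!is.null(roi)) {
    if (!is.matrix(roi) || !identical(dim(roi), c(h, w))) {
      stop("roi must be a logical matrix with the image dimensions", call. = FALSE)
    }
    roi <- roi > 0
    if (!any(roi)) stop("empty roi: no pixels to classify", call. = FALSE)
  }

  rgb <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  hue <- hsv[1, ] * 360
  sat <- hsv[2, ]
  val <- hsv[3, ]

  lab <- rep(4L, h * w)
  for (i in seq_along(PIXEL_LEVELS[1:3])) {
    cls <- tolower(PIXEL_LEVELS[i])
    t <- thresholds[[cls]]
    hit <- lab == 4L &
      hue_in_ranges(hue %% 360, t$hue) &
      sat >= t$sat[1] & sat <= t$sat[2] &
      val >= t$val[1] & val <= t$val[2]
    lab[hit] <- i
  }
  lab <- matrix(lab, nrow = h, ncol = w)
  if (!is.null(roi)) lab[!roi] <- NA_integer_
  structure(lab, class = "pixel_class_map", levels = PIXEL_LEVELS)
}

#' Count pixels per stain class
#'
#' @param cmap A `pixel_class_map` from [classify_pixels()].
#' @return An `area_summary` list with `red_px`, `blue_px`, `white_px`,
#'   `unclassified_px` and `roi_px` (their sum).
#' @export
measure_areas <- function(cmap) {
  stopifnot(inherits(cmap, "pixel_class_map"))
  counts <- tabulate(cmap[!is.na(cmap)], nbins = 4L)
  out <- structure(list(red_px = counts[1], blue_px = counts[2],
                        white_px = counts[3], unclassified_px = counts[4],
                        roi_px = sum(counts)),
                   class = "area_summary")
  stopifnot(out$roi_px == sum(!is.na(cmap)))
  out
}

#' Degree of cell wall lignification from class areas
#'
#' DCWL = red wall area / (red + blue wall area), a dimensionless index from
#' 0 (almost completely blue stained, near un-lignified) to 1 (almost
#' completely red, near fully lignified).  White and unclassified pixels do
#' not enter the ratio.
#'
#' @param areas An `area_summary` from [measure_areas()].
#' @param image_id Identifier carried into the record.
#' @return A `dcwl_record` list with `dcwl`, `areas` and `image_id`.
#' @export
compute_dcwl <- function(areas, image_id = "") {
  stopifnot(inherits(areas, "area_summary"))
  denom <- areas$red_px + areas$blue_px
  if (denom == 0) {
    stop(paste0("undefined DCWL: no red or blue wall pixels found",
                " (check the colour thresholds against the image)"),
         call. = FALSE)
  }
  structure(list(dcwl = areas$red_px / denom, areas = areas,
                 image_id = image_id),
            class = "dcwl_record")
}

#' @export
print.dcwl_record <- function(x, ...) {
  cat(sprintf("DCWL = %.4f  (red %d px, blue %d px, white %d px, other %d px)\n",
              x$dcwl, x$areas$red_px, x$areas$blue_px, x$areas$white_px,
              x$areas$unclassified_px))
  invisible(x)
}

#' One-call DCWL measurement of an image
#'
#' Convenience wrapper: classify, count, divide.
#'
#' @inheritParams classify_pixels
#' @param image_id Identifier for the output record.
#' @return A `dcwl_record`.
#' @export
dcwl_from_image <- function(image, thresholds = default_color_thresholds(),
                            roi = NULL, image_id = "") {
  compute_dcwl(measure_areas(classify_pixels(image, thresholds, roi)),
               image_id = image_id)
}

#' Software white-balance normalisation against a reference patch
#'
#' Scales each channel by a gain that maps the reference patch mean to a
#' neutral grey of the patch's own brightness, the software analogue of
#' adjusting the camera white balance before imaging so colour hue does not
#' drift between pictures.
#'
#' @param image A `micrograph` or RGB array (0-255).
#' @param reference_patch Either a logical matrix of the image dimensions or
#'   a list `list(rows = c(r0, r1), cols = c(c0, c1))` selecting a rectangle
#'   that should be neutral white (e.g. empty slide background).
#' @return The normalised RGB array, clipped to `[0, 255]`.
#' @export
normalize_white_balance <- function(image, reference_patch) {
  img <- as_rgb_array(image)
  mask <- if (is.matrix(reference_patch)) {
    if (!identical(dim(reference_patch), dim(img)[1:2])) {
      stop("reference patch mask must match the image dimensions", call. = FALSE)
    }
    reference_patch > 0
  } else {
    m <- matrix(FALSE, dim(img)[1], dim(img)[2])
    m[reference_patch$rows[1]:reference_patch$rows[2],
      reference_patch$cols[1]:reference_patch$cols[2]] <- TRUE
    m
  }
  if (!any(mask)) stop("empty reference patch", call. = FALSE)
  ch_means <- vapply(1:3, function(ch) mean(img[, , ch][mask]), numeric(1))
  if (any(ch_means <= 1)) {
    stop("reference patch is black in at least one channel", call. = FALSE)
  }
  if (any(ch_means >= 254.5)) {
    stop("reference patch is saturated in at least one channel", call. = FALSE)
  }
  target <- mean(ch_means)
  out <- img
  for (ch in 1:3) {
    out[, , ch] <- as.integer(round(pmin(pmax(
      img[, , ch] * (target / ch_means[ch]), 0), 255)))
  }
  out
}

#' Segment a set of image files and tabulate DCWL
#'
#' @param paths Character vector of PNG/TIFF image files.
#' @param thresholds A [color_thresholds()] object.
#' @param roi Optional logical ROI matrix applied to every image, or a path
#'   to a binary PNG mask.
#' @param out_csv Optional path; when given the table is also written as CSV.
#' @return `data.frame` with columns `image_id`, `red_px`, `blue_px`,
#'   `white_px`, `unclassified_px`, `dcwl`.
#' @export
segment_images <- function(paths, thresholds = default_color_thresholds(),
                           roi = NULL, out_csv = NULL) {
  if (is.character(roi)) {
    roi <- round(png::readPNG(roi) * 255) > 127
    if (length(dim(roi)) == 3L) roi <- roi[, , 1]
  }
  rows <- lapply(paths, function(p) {
    rec <- dcwl_from_image(read_micrograph_image(p), thresholds, roi,
                           image_id = tools::file_path_sans_ext(basename(p)))
    data.frame(image_id = rec$image_id, red_px = rec$areas$red_px,
               blue_px = rec$areas$blue_px, white_px = rec$areas$white_px,
               unclassified_px = rec$areas$unclassified_px, dcwl = rec$dcwl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
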