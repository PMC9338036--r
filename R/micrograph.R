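# Synthetic double-stained wood-anatomy micrographs with per-pixel ground
# truth.  Cells are rendered as annuli (lumen disc plus wall ring) placed by
# rejection sampling without overlap; each cell's whole wall is drawn either
# red (lignified) or blue (less lignified), mimicking the appearance of
# Safranin/Astra-Blue double-stained cross-sections.

# Ground-truth label codes (also used in the label PNG written to disk).
LABEL_BACKGROUND <- 0L
LABEL_LUMEN <- 1L
LABEL_BLUE_WALL <- 2L
LABEL_RED_WALL <- 3L

#' Describe one woody cell type for the micrograph generator
#'
#' @param name Cell type, one of `"vessel"`, `"fibre"`, `"parenchyma"`.
#'   Vessels are wide conducting cells, fibres are narrow thick-walled
#'   mechanical cells, parenchyma are thin-walled storage cells.
#' @param mean_lumen_radius_px Mean lumen (cavity) radius in pixels; the
#'   realised radius of each cell is jittered by +/- 15%.
#' @param wall_thickness_px Wall ring thickness in pixels (> 0).
#' @param count Number of cells of this type to place.
#' @param lignification_prob Probability that a cell of this type has a fully
#'   lignified (red) wall, or `"inherit"` to use the image-level
#'   `lignified_wall_fraction`.
#' @return A `cell_type_spec` list.
#' @seealso [micrograph_spec()], [generate_micrograph()]
#' @export
cell_type_spec <- function(name, mean_lumen_radius_px, wall_thickness_px,
                           count, lignification_prob = "inherit") {
  name <- match.arg(name, c("vessel", "fibre", "parenchyma"))
  stop_if_not_scalar_number(mean_lumen_radius_px, "mean_lumen_radius_px", lo = 0.5)
  stop_if_not_scalar_number(wall_thickness_px, "wall_thickness_px", lo = .Machine$double.eps)
  stop_if_not_scalar_number(count, "count", lo = 0)
  if (!identical(lignification_prob, "inherit")) {
    stop_if_not_scalar_number(lignification_prob, "lignification_prob", 0, 1)
  }
  structure(list(name = name,
                 mean_lumen_radius_px = mean_lumen_radius_px,
                 wall_thickness_px = wall_thickness_px,
                 count = as.integer(count),
                 lignification_prob = lignification_prob),
            class = "cell_type_spec")
}

#' Default cell-type mix for a 256 x 256 canvas
#'
#' A handful of wide vessels, many narrow fibres and some thin-walled
#' parenchyma, roughly matching the tissue proportions of angiosperm
#' secondary xylem viewed in cross-section.
#'
#' @param scale Multiplier applied to all cell counts (use < 1 for smaller
#'   canvases).
#' @return List of [cell_type_spec()] objects.
#' @export
default_cell_types <- function(scale = 1) {
  list(
    cell_type_spec("vessel", mean_lumen_radius_px = 9, wall_thickness_px = 2.5,
                   count = round(10 * scale)),
    cell_type_spec("fibre", mean_lumen_radius_px = 3.2, wall_thickness_px = 2.2,
                   count = round(140 * scale)),
    cell_type_spec("parenchyma", mean_lumen_radius_px = 5, wall_thickness_px = 1.4,
                   count = round(35 * scale))
  )
}

#' Specification of a synthetic micrograph
#'
#' @param width_px,height_px Canvas size in pixels (>= 32).
#' @param cell_types List of [cell_type_spec()] objects.
#' @param lignified_wall_fraction Target fraction of wall pixels rendered red
#'   (lignified), in `[0, 1]`.  Matched in expectation through per-cell
#'   Bernoulli assignment; the realised fraction is recorded as ground truth.
#' @param hue_jitter_deg Per-pixel hue jitter (degrees) around the class
#'   centre hues (red 0 deg, blue 220 deg).
#' @param noise_sd Standard deviation of additive Gaussian per-channel noise
#'   on the 0-255 scale, truncated to `[0, 255]` after addition.
#' @param seed Integer seed; a fixed (spec, seed) pair yields a bit-identical
#'   image and label map.
#' @return A `micrograph_spec` list.
#' @export
micrograph_spec <- function(width_px = 256, height_px = 256,
                            cell_types = default_cell_types(),
                            lignified_wall_fraction = 0.5,
                            hue_jitter_deg = 10, noise_sd = 0, seed = 1L) {
  stop_if_not_scalar_number(width_px, "width_px", lo = 32)
  stop_if_not_scalar_number(height_px, "height_px", lo = 32)
  stop_if_not_scalar_number(lignified_wall_fraction, "lignified_wall_fraction", 0, 1)
  stop_if_not_scalar_number(hue_jitter_deg, "hue_jitter_deg", lo = 0)
  stop_if_not_scalar_number(noise_sd, "noise_sd", lo = 0)
  stopifnot(length(cell_types) >= 1L,
            all(vapply(cell_types, inherits, logical(1), "cell_type_spec")))
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 cell_types = cell_types,
                 lignified_wall_fraction = lignified_wall_fraction,
                 hue_jitter_deg = hue_jitter_deg,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "micrograph_spec")
}

# Rejection-sampled non-overlapping disc centres.  Larger cells are placed
# first, which markedly improves feasible packing densities.
place_cells <- function(spec) {
  types <- spec$cell_types
  order_idx <- order(vapply(types, function(ct)
    ct$mean_lumen_radius_px + ct$wall_thickness_px, numeric(1)),
    decreasing = TRUE)
  n_total <- sum(vapply(types, `[[`, integer(1), "count"))
  if (n_total == 0L) stop("degenerate micrograph spec: no cells requested", call. = FALSE)
  budget <- 400L * n_total
  cx <- cy <- r_in <- r_out <- numeric(n_total)
  type_of <- character(n_total)
  k <- 0L
  for (ti in order_idx) {
    ct <- types[[ti]]
    if (ct$count == 0L) next
    for (i in seq_len(ct$count)) {
      placed <- FALSE
      while (budget > 0L) {
        budget <- budget - 1L
        rl <- ct$mean_lumen_radius_px * stats::runif(1, 0.85, 1.15)
        ro <- rl + ct$wall_thickness_px
        if (2 * ro + 2 >= min(spec$width_px, spec$height_px)) {
          stop("placement infeasible: cell larger than canvas", call. = FALSE)
        }
        x <- stats::runif(1, ro + 1, spec$width_px - ro)
        y <- stats::runif(1, ro + 1, spec$height_px - ro)
        if (k > 0L) {
          d2 <- (cx[seq_len(k)] - x)^2 + (cy[seq_len(k)] - y)^2
          if (any(d2 < (r_out[seq_len(k)] + ro + 0.5)^2)) next
        }
        k <- k + 1L
        cx[k] <- x; cy[k] <- y; r_in[k] <- rl; r_out[k] <- ro
        type_of[k] <- ct$name
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf(
          "placement infeasible: could not fit %d cells in a %dx%d canvas",
          n_total, spec$width_px, spec$height_px), call. = FALSE)
      }
    }
  }
  data.frame(cx = cx, cy = cy, r_in = r_in, r_out = r_out,
             type = type_of, stringsAsFactors = FALSE)
}

#' Generate a synthetic double-stained micrograph with ground truth
#'
#' Renders non-overlapping annular cells on a near-white background.  Each
#' cell's wall is drawn entirely red (lignified) with probability given by
#' its cell type (or the global `lignified_wall_fraction`), otherwise
#' entirely blue.  The per-pixel ground-truth label map is recorded before
#' noise is added, so `true_dcwl` is exact by construction.
#'
#' @param spec A [micrograph_spec()].
#' @return An object of class `micrograph`: a list with elements
#'   \describe{
#'     \item{image}{`height x width x 3` integer array, 8-bit RGB (0-255).}
#'     \item{label_map}{`height x width` integer matrix with codes
#'       0 = background, 1 = lumen, 2 = blue wall, 3 = red wall.}
#'     \item{true_dcwl}{Realised red / (red + blue) wall-pixel fraction.}
#'     \item{spec}{The generating spec.}
#'   }
#' @examples
#' m <- generate_micrograph(micrograph_spec(
#'   width_px = 96, height_px = 96,
#'   cell_types = default_cell_types(scale = 0.15),
#'   lignified_wall_fraction = 0.75, seed = 42))
#' m$true_dcwl
#' @export
generate_micrograph <- function(spec) {
  stopifnot(inherits(spec, "micrograph_spec"))
  with_seed(spec$seed, {
    cells <- place_cells(spec)
    lab <- matrix(LABEL_BACKGROUND, nrow = spec$height_px, ncol = spec$width_px)

    prob_of <- function(type) {
      ct <- Find(function(z) z$name == type, spec$cell_types)
      if (identical(ct$lignification_prob, "inherit"))
        spec$lignified_wall_fraction else ct$lignification_prob
    }
    # uniform-threshold coupling: for a fixed seed the set of lignified
    # cells grows monotonically with the target fraction
    lignified <- stats::runif(nrow(cells)) <
      vapply(cells$type, prob_of, numeric(1))

    for (i in seq_len(nrow(cells))) {
      ro <- cells$r_out[i]; rl <- cells$r_in[i]
      xs <- max(1L, floor(cells$cx[i] - ro)):min(spec$width_px, ceiling(cells$cx[i] + ro))
      ys <- max(1L, floor(cells$cy[i] - ro)):min(spec$height_px, ceiling(cells$cy[i] + ro))
      d2 <- outer((ys - cells$cy[i])^2, (xs - cells$cx[i])^2, `+`)
      block <- lab[ys, xs, drop = FALSE]
      wall_code <- if (lignified[i]) LABEL_RED_WALL else LABEL_BLUE_WALL
      block[d2 <= ro^2] <- wall_code
      block[d2 <= rl^2] <- LABEL_LUMEN
      lab[ys, xs] <- block
    }

    n_red <- sum(lab == LABEL_RED_WALL)
    n_blue <- sum(lab == LABEL_BLUE_WALL)
    if (n_red + n_blue == 0L) {
      stop("degenerate micrograph spec: no wall pixels were rendered", call. = FALSE)
    }

    img <- render_labels(lab, spec)
    structure(list(image = img, label_map = lab,
                   true_dcwl = n_red / (n_red + n_blue), spec = spec),
              class = "micrograph")
  })
}

# Render an RGB image from a label map.  Class appearance (HSV):
#   red wall   H = 0 +/- jitter,   S ~ U(0.65, 0.90), V ~ U(0.45, 0.75)
#   blue wall  H = 220 +/- jitter, S ~ U(0.65, 0.90), V ~ U(0.45, 0.75)
#   lumen/background near-white:   S ~ U(0, 0.05),    V ~ U(0.95, 1)
# With the default jitter these fall inside the default threshold bands.
render_labels <- function(lab, spec) {
  n <- length(lab)
  h <- numeric(n); s <- numeric(n); v <- numeric(n)

  jitter_hue <- function(centre, k) {
    (centre + stats::runif(k, -spec$hue_jitter_deg, spec$hue_jitter_deg)) %% 360
  }
  idx_red <- which(lab == LABEL_RED_WALL)
  idx_blue <- which(lab == LABEL_BLUE_WALL)
  idx_white <- which(lab == LABEL_LUMEN | lab == LABEL_BACKGROUND)
  if (length(idx_red)) {
    h[idx_red] <- jitter_hue(0, length(idx_red))
    s[idx_red] <- stats::runif(length(idx_red), 0.65, 0.90)
    v[idx_red] <- stats::runif(length(idx_red), 0.45, 0.75)
  }
  if (length(idx_blue)) {
    h[idx_blue] <- jitter_hue(220, length(idx_blue))
    s[idx_blue] <- stats::runif(length(idx_blue), 0.65, 0.90)
    v[idx_blue] <- stats::runif(length(idx_blue), 0.45, 0.75)
  }
  if (length(idx_white)) {
    h[idx_white] <- stats::runif(length(idx_white), 0, 360)
    s[idx_white] <- stats::runif(length(idx_white), 0, 0.05)
    v[idx_white] <- stats::runif(length(idx_white), 0.95, 1)
  }

  rgb01 <- grDevices::col2rgb(grDevices::hsv(h / 360, s, v))
  img <- array(0L, dim = c(nrow(lab), ncol(lab), 3L))
  for (ch in 1:3) {
    chan <- matrix(rgb01[ch, ], nrow = nrow(lab), ncol = ncol(lab))
    if (spec$noise_sd > 0) {
      chan <- chan + stats::rnorm(n, 0, spec$noise_sd)
      chan <- pmin(pmax(chan, 0), 255)
    }
    img[, , ch] <- as.integer(round(chan))
  }
  img
}

#' Ground-truth lignified wall fraction
#'
#' The realised red / (red + blue) wall-pixel ratio of a label map: the exact
#' quantity the colour-threshold segmentation estimates.
#'
#' @param x A `micrograph`, or an integer label matrix using the codes of
#'   [generate_micrograph()].
#' @return Fraction in `[0, 1]`.
#' @export
true_dcwl <- function(x) {
  lab <- if (inherits(x, "micrograph")) x$label_map else x
  stopifnot(is.matrix(lab))
  n_red <- sum(lab == LABEL_RED_WALL)
  n_blue <- sum(lab == LABEL_BLUE_WALL)
  if (n_red + n_blue == 0L) {
    stop("undefined lignification index: label map contains no wall pixels",
         call. = FALSE)
  }
  n_red / (n_red + n_blue)
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("synthetic micrograph %dx%d px, true DCWL = %.4f\n",
              ncol(x$label_map), nrow(x$label_map), x$true_dcwl))
  invisible(x)
}

#' Write a micrograph, its label map and a JSON sidecar to disk
#'
#' The image is written as 8-bit RGB PNG (or TIFF if `name` ends in
#' `.tif`/`.tiff` and the tiff package is available), the label map as a
#' single-channel PNG with raw values 0 = background, 1 = lumen,
#' 2 = blue wall, 3 = red wall, and `<name>.json` records `true_dcwl` and
#' the generating spec.
#'
#' @param m A `micrograph`.
#' @param dir Output directory (created if missing).
#' @param name Image file name, default `"micrograph.png"`.
#' @return Invisibly, the paths written.
#' @export
write_micrograph <- function(m, dir, name = "micrograph.png") {
  stopifnot(inherits(m, "micrograph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, name)
  base <- tools::file_path_sans_ext(name)
  ext <- tolower(tools::file_ext(name))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required to write TIFF images", call. = FALSE)
    }
    tiff::writeTIFF(m$image / 255, img_path, bits.per.sample = 8L)
  } else {
    png::writePNG(m$image / 255, img_path)
  }
  lab_path <- file.path(dir, paste0(base, "_labels.png"))
  png::writePNG(m$label_map / 255, lab_path)
  json_path <- file.path(dir, paste0(base, ".json"))
  sidecar <- list(true_dcwl = m$true_dcwl,
                  label_codes = list(background = 0, lumen = 1,
                                     blue_wall = 2, red_wall = 3),
                  spec = unclass(m$spec))
  sidecar$spec$cell_types <- lapply(sidecar$spec$cell_types, unclass)
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(image = img_path, labels = lab_path, sidecar = json_path))
}

#' Read an RGB micrograph image from disk
#'
#' @param path PNG or TIFF file, 8-bit per channel.
#' @return `height x width x 3` integer array on the 0-255 scale.
#' @export
read_micrograph_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required to read TIFF images", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  array(as.integer(round(raw * 255)), dim = dim(raw))
}
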