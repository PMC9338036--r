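# Hue/saturation/brightness threshold configuration for the three stain
# classes (red = lignified wall, blue = less-lignified wall, white = lumina
# and intercellular spaces).

#' Colour-class thresholds in HSB space
#'
#' Each class is a list with `hue` (a list of `[lo, hi]` intervals in degrees
#' on `[0, 360)`; a band crossing 0 is expressed as two intervals, e.g.
#' `[330, 360]` and `[0, 25]`), `sat` and `val` (each `[lo, hi]` on `[0, 1]`).
#' The classes need not partition colour space; pixels matching none are
#' UNCLASSIFIED.
#'
#' @param red,blue,white Class definitions as described above.
#' @return A validated `color_thresholds` object.
#' @seealso [default_color_thresholds()], [read_color_thresholds()]
#' @export
color_thresholds <- function(red, blue, white) {
  out <- structure(list(red = red, blue = blue, white = white),
                   class = "color_thresholds")
  validate_color_thresholds(out)
  out
}

#' Default thresholds for Safranin/Astra-Blue stained sections
#'
#' Red: hue in `[330, 360) U [0, 25]`, saturation >= 0.15, value in
#' `[0.15, 0.95]`.  Blue: hue in `[170, 260]`, same saturation/value bands.
#' White: saturation <= 0.10 and value >= 0.90, any hue.  The bands are wide
#' enough to capture light-to-dark shades of each stain while staying
#' mutually separable; every value can be overridden via configuration.
#'
#' @return A `color_thresholds` object.
#' @export
default_color_thresholds <- function() {
  color_thresholds(
    red = list(hue = list(c(330, 360), c(0, 25)), sat = c(0.15, 1), val = c(0.15, 0.95)),
    blue = list(hue = list(c(170, 260)), sat = c(0.15, 1), val = c(0.15, 0.95)),
    white = list(hue = list(c(0, 360)), sat = c(0, 0.10), val = c(0.90, 1))
  )
}

validate_color_thresholds <- function(x) {
  if (!all(c("red", "blue", "white") %in% names(x))) {
    stop("thresholds must define classes 'red', 'blue' and 'white'", call. = FALSE)
  }
  for (cls in c("red", "blue", "white")) {
    t <- x[[cls]]
    if (!is.list(t$hue) || length(t$hue) == 0L) {
      stop(sprintf("class '%s': 'hue' must be a list of [lo, hi] intervals", cls),
           call. = FALSE)
    }
    for (iv in t$hue) {
      if (length(iv) != 2L || !is.numeric(iv) || iv[1] > iv[2] ||
          iv[1] < 0 || iv[2] > 360) {
        stop(sprintf("class '%s': malformed hue interval [%s]", cls,
                     paste(iv, collapse = ", ")), call. = FALSE)
      }
    }
    for (band in c("sat", "val")) {
      iv <- t[[band]]
      if (length(iv) != 2L || !is.numeric(iv) || iv[1] > iv[2] ||
          iv[1] < 0 || iv[2] > 1) {
        stop(sprintf("class '%s': malformed '%s' range", cls, band), call. = FALSE)
      }
    }
  }
  invisible(x)
}

#' Read colour thresholds from a YAML or JSON file
#'
#' The file holds one mapping per class (`red`, `blue`, `white`) with keys
#' `hue` (list of two-element intervals), `sat` and `val`.  An optional
#' top-level `scale` field selects the unit convention: `"degrees"` (the
#' default: hue in degrees, saturation/value in `[0, 1]`) or `"imagej"`
#' (all three channels on the 0-255 byte scale, as in ImageJ's colour
#' threshold dialog; values are converted on read).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `color_thresholds` object.
#' @export
read_color_thresholds <- function(path) {
  if (!file.exists(path)) stop(sprintf("threshold config not found: %s", path),
                               call. = FALSE)
  raw <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  scale <- raw$scale %||% "degrees"
  raw$scale <- NULL
  if (!scale %in% c("degrees", "imagej")) {
    stop("threshold 'scale' must be 'degrees' or 'imagej'", call. = FALSE)
  }
  cls <- lapply(raw[c("red", "blue", "white")], function(t) {
    hue <- lapply(t$hue, as.numeric)
    sat <- as.numeric(t$sat)
    val <- as.numeric(t$val)
    if (scale == "imagej") {
      # ImageJ hue bytes 0..255 span the circle; 255 maps to 360 degrees.
      hue <- lapply(hue, function(iv) iv / 255 * 360)
      sat <- sat / 255
      val <- val / 255
    }
    list(hue = hue, sat = sat, val = val)
  })
  color_thresholds(red = cls$red, blue = cls$blue, white = cls$white)
}

#' Write colour thresholds to YAML
#'
#' @param x A `color_thresholds` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_color_thresholds <- function(x, path) {
  validate_color_thresholds(x)
  out <- lapply(unclass(x), function(t) {
    list(hue = lapply(t$hue, as.numeric), sat = as.numeric(t$sat),
         val = as.numeric(t$val))
  })
  out$scale <- "degrees"
  yaml::write_yaml(out, path)
  invisible(path)
}

# TRUE where hue (degrees, [0, 360)) falls in any listed interval.  360 is
# treated as identical to 0 so a band written [330, 360] closes the circle.
hue_in_ranges <- function(h, ranges) {
  hit <- rep(FALSE, length(h))
  for (iv in ranges) {
    hit <- hit | (h >= iv[1] & h <= iv[2])
    if (iv[2] >= 360) hit <- hit | (h == 0)
  }
  hit
}
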