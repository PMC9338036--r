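# Shared fixtures and independent oracles for the test suite.

# Small, fast micrograph spec used throughout.
tiny_spec <- function(fraction = 0.5, noise_sd = 0, seed = 1,
                      width = 160, height = 160, scale = 0.45, ...) {
  micrograph_spec(width_px = width, height_px = height,
                  cell_types = default_cell_types(scale = scale),
                  lignified_wall_fraction = fraction,
                  noise_sd = noise_sd, seed = seed, ...)
}

# A 1 x n RGB image from HSV triplets (degrees, [0,1], [0,1]).
image_from_hsv <- function(h, s, v) {
  rgb <- grDevices::col2rgb(grDevices::hsv(h / 360, s, v))
  img <- array(0L, dim = c(1L, length(h), 3L))
  for (ch in 1:3) img[1, , ch] <- as.integer(rgb[ch, ])
  img
}

# Independent local weighted-least-squares oracle for loess_fit: explicit
# normal equations per evaluation point.
loess_oracle <- function(x, y, span, degree, x0) {
  n <- length(x)
  d <- abs(x - x0)
  k <- max(degree + 1, ceiling(span * n))
  dmax <- sort(d)[min(k, n)]
  if (dmax == 0) return(mean(y[d == 0]))
  w <- (1 - pmin(d / dmax, 1)^3)^3
  use <- w > 0
  B <- outer(x[use] - x0, 0:degree, `^`)
  W <- diag(w[use], nrow = sum(use))
  drop(solve(t(B) %*% W %*% B, t(B) %*% W %*% y[use]))[1]
}

# Independent explained-variance oracle for rda: explicit projection matrix
# onto the column space of [1 X].
projector_fraction <- function(Y, X) {
  Y <- as.matrix(Y)
  Xd <- cbind(1, as.matrix(X))
  H <- Xd %*% solve(t(Xd) %*% Xd) %*% t(Xd)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Yhat <- H %*% Y
  Yhat_c <- scale(Yhat, center = TRUE, scale = FALSE)
  sum(Yhat_c^2) / sum(Yc^2)
}

# Bare pixel-class map with the documented level codes, for unit tests that
# bypass classification.
make_class_map <- function(m) {
  structure(m, class = "pixel_class_map",
            levels = c("RED", "BLUE", "WHITE", "UNCLASSIFIED"))
}
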