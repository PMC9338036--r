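# Descriptive and inferential statistics for DCWL across lifeforms and
# environmental gradients: group comparison, class-binned means, locally
# weighted polynomial regression on the class means, Pearson correlations,
# percentile trimming and per-family summaries.

#' Compare DCWL between trees/shrubs and herbs
#'
#' Welch's two-sample t test between the self-supporting lifeforms (trees and
#' shrubs pooled) and herbs.  Group SDs use the n-1 denominator; the degrees
#' of freedom follow Welch-Satterthwaite and the p value is two-sided.
#'
#' @param samples `data.frame` with columns `lifeform` and a value column.
#' @param group_a,group_b Character vectors of lifeforms forming the two
#'   groups.
#' @param value Name of the value column (default `"dcwl"`).
#' @return A `group_comparison` list: `mean_a`, `sd_a`, `n_a`, `mean_b`,
#'   `sd_b`, `n_b`, `t_stat`, `df`, `p_value`.
#' @export
lifeform_comparison <- function(samples, group_a = c("tree", "shrub"),
                                group_b = "herb", value = "dcwl") {
  stopifnot(is.data.frame(samples), "lifeform" %in% names(samples),
            value %in% names(samples))
  a <- samples[[value]][samples$lifeform %in% group_a]
  b <- samples[[value]][samples$lifeform %in% group_b]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least two members", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
                 mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
                 t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 groups = list(a = group_a, b = group_b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group A (%s): mean %.3f, sd %.3f, n %d\n",
              paste(x$groups$a, collapse = "/"), x$mean_a, x$sd_a, x$n_a))
  cat(sprintf("group B (%s): mean %.3f, sd %.3f, n %d\n",
              paste(x$groups$b, collapse = "/"), x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("Welch t(%.1f) = %.2f, p = %.3g\n", x$df, x$t_stat, x$p_value))
  invisible(x)
}

#' Mean response per equal-width class
#'
#' Divides `x` into half-open classes `[origin + k*w, origin + (k+1)*w)` and
#' returns the mean of `y` in each nonempty class -- the class-mean reduction
#' used before fitting the loess curves (10 cm height, 1 deg C temperature,
#' 100 m elevation and 2 deg latitude classes in the default pipeline).
#'
#' @param x,y Equal-length numeric vectors (`y` is typically DCWL).
#' @param bin_width Class width (> 0).
#' @param origin Left edge of the class containing `origin`.
#' @return A `binned_series` data frame with `bin_left`, `bin_center`,
#'   `mean_y` and `n`; empty classes are omitted.
#' @export
bin_means <- function(x, y, bin_width, origin = 0) {
  if (length(x) != length(y)) stop("x and y must have the same length", call. = FALSE)
  if (length(x) < 1L) stop("need at least one observation", call. = FALSE)
  stop_if_not_scalar_number(bin_width, "bin_width", lo = .Machine$double.eps)
  k <- floor((x - origin) / bin_width)
  agg_mean <- tapply(y, k, mean)
  agg_n <- tapply(y, k, length)
  kk <- as.numeric(names(agg_mean))
  out <- data.frame(bin_left = origin + kk * bin_width,
                    bin_center = origin + (kk + 0.5) * bin_width,
                    mean_y = as.numeric(agg_mean),
                    n = as.integer(agg_n))
  out <- out[order(out$bin_left), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("binned_series", "data.frame"),
            bin_width = bin_width, origin = origin)
}

#' Locally weighted polynomial regression (tricube weights)
#'
#' At each evaluation point the `ceiling(span * n)` nearest observations
#' receive tricube weights `(1 - (d/dmax)^3)^3` and a polynomial of the given
#' degree is fitted by weighted least squares; the fitted value is the local
#' intercept.  This is the curve drawn through the class means of the
#' gradient plots.
#'
#' @param x,y Observations (typically class centres and class means).
#' @param span Fraction of points in each local neighbourhood, in `(0, 1]`.
#' @param degree Local polynomial degree, 1 or 2.
#' @param eval_x Evaluation grid; default 200 equally spaced points over
#'   `range(x)`.
#' @return A `loess_fit` list with `x`, `fitted`, `span`, `degree`.
#' @export
loess_fit <- function(x, y, span = 0.75, degree = 2, eval_x = NULL) {
  stopifnot(length(x) == length(y), degree %in% c(1, 2))
  stop_if_not_scalar_number(span, "span", lo = 1e-8, hi = 1)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (length(unique(x)) < degree + 2) {
    stop(sprintf("need at least %d distinct x values for degree %d",
                 degree + 2, degree), call. = FALSE)
  }
  if (is.null(eval_x)) eval_x <- seq(min(x), max(x), length.out = 200)

  fitted <- vapply(eval_x, function(x0) {
    d <- abs(x - x0)
    k <- max(degree + 1L, ceiling(span * n))
    repeat {
      dmax <- sort(d, partial = min(k, n))[min(k, n)]
      if (dmax == 0) {
        # all neighbours coincide with x0: local fit degenerates to a mean
        return(mean(y[d == 0]))
      }
      w <- (1 - pmin(d / dmax, 1)^3)^3
      use <- which(w > 0)
      if (length(use) >= degree + 1L || k >= n) break
      k <- k + 1L  # widen until the local system is determined
    }
    B <- outer(x[use] - x0, 0:degree, `^`)
    fit <- stats::lm.wfit(B, y[use], w[use])
    unname(fit$coefficients[1])
  }, numeric(1))

  structure(list(x = eval_x, fitted = fitted, span = span, degree = degree,
                 n = n), class = "loess_fit")
}

#' Pearson correlation with two-sided t-based p value
#'
#' Thin wrapper around [stats::cor.test()] with the preconditions of the
#' pipeline made explicit (n >= 3, nonzero variance in both arguments).
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p_value`, `n`, `df`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least three complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       df = unname(ct$parameter))
}

#' Trim a table (or vector) to a percentile band of a value
#'
#' Keeps records whose value lies within `[P_lo, P_hi]`, with percentiles by
#' linear interpolation between order statistics ([stats::quantile()]
#' type 7).  Used to display the distribution limited to the 2nd-98th DCWL
#' percentile band.
#'
#' @param values Numeric vector the percentiles are computed on.
#' @param lo_pct,hi_pct Percentile bounds, `0 <= lo < hi <= 100`.
#' @param data Optional data frame with `nrow(data) == length(values)`; when
#'   given, the retained rows are returned instead of the values.
#' @return The retained values (or rows), with the computed bounds attached
#'   as attribute `"bounds"`.
#' @export
percentile_trim <- function(values, lo_pct = 2, hi_pct = 98, data = NULL) {
  stopifnot(lo_pct >= 0, hi_pct <= 100, lo_pct < hi_pct)
  q <- stats::quantile(values, c(lo_pct, hi_pct) / 100, names = FALSE, type = 7)
  keep <- values >= q[1] & values <= q[2]
  out <- if (is.null(data)) values[keep] else data[keep, , drop = FALSE]
  attr(out, "bounds") <- q
  out
}

#' Per-family DCWL summaries split by lifeform group
#'
#' Families with more than `min_species` species (strict inequality) are
#' summarised within the two lifeform groups (trees/shrubs pooled vs herbs):
#' count, median, interquartile range and the 5th/95th percentiles -- the
#' numbers behind a family box-and-whisker display.
#'
#' @param samples `data.frame` with `family`, `lifeform` and a value column.
#' @param min_species Family size threshold (default 25; a family must
#'   exceed it to be reported).
#' @param value Name of the value column.
#' @return `data.frame` with one row per (family, group) combination present.
#' @export
family_summary <- function(samples, min_species = 25, value = "dcwl") {
  stopifnot(is.data.frame(samples),
            all(c("family", "lifeform", value) %in% names(samples)))
  fam_n <- table(samples$family)
  keep_fams <- names(fam_n)[fam_n > min_species]
  sub <- samples[samples$family %in% keep_fams, , drop = FALSE]
  sub$group <- ifelse(sub$lifeform %in% c("tree", "shrub"),
                      "trees_shrubs", "herbs")
  pieces <- split(sub[[value]], list(sub$family, sub$group), drop = TRUE)
  rows <- lapply(names(pieces), function(nm) {
    v <- pieces[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    q <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE, type = 7)
    data.frame(family = parts[1], group = parts[2], n = length(v),
               median = q[3], iqr = q[4] - q[2], p5 = q[1], p95 = q[5],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(family = character(), group = character(), n = integer(),
                      median = numeric(), iqr = numeric(), p5 = numeric(),
                      p95 = numeric(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$family, out$group), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "families") <- sort(keep_fams)
  out
}

#' Binned means plus loess curve for one gradient
#'
#' Convenience wrapper combining [bin_means()] and [loess_fit()]: the curve
#' is fitted to the class means, as in the gradient figures.
#'
#' @param samples `data.frame` holding the predictor and value columns.
#' @param var Predictor column name (e.g. `"temp_warmest_quarter"`,
#'   `"elevation"`, `"latitude"`, `"height_cm"`).
#' @param bin_width Class width; defaults per variable: 10 cm height,
#'   1 deg C temperature, 100 m elevation, 2 deg latitude.
#' @param origin Bin origin (default 0).
#' @param span,degree Loess parameters (defaults 0.75 and 2).
#' @param value Value column name.
#' @return List with the `binned_series` and the `loess_fit` (the latter
#'   `NULL` when there are too few classes to fit).
#' @export
gradient_curve <- function(samples, var, bin_width = NULL, origin = 0,
                           span = 0.75, degree = 2, value = "dcwl") {
  defaults <- c(height_cm = 10, temp_warmest_quarter = 1, elevation = 100,
                latitude = 2)
  if (is.null(bin_width)) {
    if (!var %in% names(defaults)) {
      stop("no default bin width for this variable; supply bin_width", call. = FALSE)
    }
    bin_width <- defaults[[var]]
  }
  b <- bin_means(samples[[var]], samples[[value]], bin_width, origin)
  fit <- if (length(unique(b$bin_center)) >= degree + 2) {
    loess_fit(b$bin_center, b$mean_y, span = span, degree = degree)
  }
  list(bins = b, loess = fit, var = var, bin_width = bin_width)
}
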