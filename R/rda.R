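# Redundancy analysis (RDA), partial RDA, variance partitioning and
# Monte-Carlo permutation tests, implemented from first principles.  RDA is
# the PCA of the fitted values of a multivariate linear regression of the
# response matrix on the constraints; the constrained fraction is the ratio
# of fitted to total variance.  Partial RDA first residualises response and
# constraints on the covariates.  Significance uses reduced-model residual
# permutation with the add-one p-value convention.

as_num_matrix <- function(x, name) {
  m <- as.matrix(x)
  if (is.null(colnames(m))) colnames(m) <- paste0(name, seq_len(ncol(m)))
  storage.mode(m) <- "double"
  if (anyNA(m)) stop(sprintf("'%s' contains missing values", name), call. = FALSE)
  m
}

#' Centre and scale columns to mean 0, sample SD 1
#'
#' Both the response and the explanatory variables are standardised before
#' ordination so the explained fractions are comparable across variables
#' with different units.
#'
#' @param m Numeric matrix or data frame.
#' @return Matrix of z-scored columns.
#' @export
standardize <- function(m) {
  m <- as_num_matrix(m, "m")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant column(s) cannot be standardized: %s",
                 paste(colnames(m)[sds == 0], collapse = ", ")), call. = FALSE)
  }
  scale(m, center = TRUE, scale = sds)
}

# Core least-squares machinery: fitted values of Y on [1 X], with a rank
# check that names the collinear columns.
fit_constraints <- function(Y, X) {
  Xd <- cbind(`(Intercept)` = 1, X)
  q <- qr(Xd)
  if (q$rank < ncol(Xd)) {
    bad <- colnames(Xd)[q$pivot[(q$rank + 1):ncol(Xd)]]
    stop(sprintf("constraint matrix is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  list(qr = q, fitted = qr.fitted(q, Y))
}

ss_centered <- function(M) sum(scale(M, center = TRUE, scale = FALSE)^2)

#' Redundancy analysis of a response matrix on constraints
#'
#' Fits a multivariate least-squares regression of `Y` on `X` (with
#' intercept); the canonical eigenvalues are the eigenvalues of the
#' covariance of the fitted values, and the constrained fraction is the
#' ratio of fitted to total variance (the multivariate R^2).
#'
#' @param Y Response matrix (or vector / data frame), rows = observations.
#' @param X Constraint matrix; must have full column rank.
#' @param permutations If > 0, a Monte-Carlo permutation test of the
#'   constraints is run with this many permutations.
#' @param seed Seed for the permutation test.
#' @return An `rda_result` list: `constrained_fraction`,
#'   `canonical_eigenvalues`, `total_variance`, `pseudo_F`, `p_value`,
#'   `n_permutations`, `df_constraints`, `df_residual`.
#' @export
rda <- function(Y, X, permutations = 0, seed = 1L) {
  Y <- as_num_matrix(Y, "Y")
  X <- as_num_matrix(X, "X")
  n <- nrow(Y)
  stopifnot(nrow(X) == n)
  if (n <= ncol(X) + 1L) stop("need n > ncol(X) + 1 observations", call. = FALSE)

  fit <- fit_constraints(Y, X)
  tot <- ss_centered(Y)
  if (tot == 0) stop("response has zero variance", call. = FALSE)
  Yhat_c <- scale(fit$fitted, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Yhat_c) / (n - 1), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev <- ev[seq_len(min(ncol(Y), ncol(X)))]

  explained <- sum(Yhat_c^2)
  frac <- explained / tot
  df_c <- ncol(X)
  df_r <- n - df_c - 1L
  pseudo_F <- (explained / df_c) / ((tot - explained) / df_r)

  out <- structure(list(constrained_fraction = frac,
                        canonical_eigenvalues = ev,
                        total_variance = tot / (n - 1),
                        pseudo_F = pseudo_F,
                        p_value = NA_real_,
                        n_permutations = 0L,
                        df_constraints = df_c, df_residual = df_r),
                   class = "rda_result")
  if (permutations > 0) {
    pt <- permutation_test(Y, X, Z = NULL, n_perm = permutations, seed = seed)
    out$p_value <- pt$p_value
    out$n_permutations <- pt$n_permutations
  }
  out
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("constrained fraction = %.4f (pseudo-F = %.3f, df = %d/%d)\n",
              x$constrained_fraction, x$pseudo_F, x$df_constraints,
              x$df_residual))
  if (!is.na(x$p_value)) {
    cat(sprintf("permutation p = %.4g (%d permutations)\n",
                x$p_value, x$n_permutations))
  }
  invisible(x)
}

#' Partial redundancy analysis
#'
#' Residualises both `Y` and `X` on the covariates `Z` (with intercept) and
#' runs [rda()] on the residuals.  The constrained fraction is reported
#' relative to the total variance of `Y` after `Z`
#' (`constrained_fraction`), and additionally on the scale of the original
#' total variance of `Y` (`constrained_fraction_total`), which is the
#' additive scale used by [variance_partition()].
#'
#' @inheritParams rda
#' @param Z Covariate matrix, or `NULL` for an ordinary RDA.
#' @return An `rda_result`; see [rda()].
#' @export
partial_rda <- function(Y, X, Z = NULL, permutations = 0, seed = 1L) {
  if (is.null(Z) || (is.matrix(Z) && ncol(Z) == 0L)) {
    out <- rda(Y, X, permutations = permutations, seed = seed)
    out$constrained_fraction_total <- out$constrained_fraction
    return(out)
  }
  Y <- as_num_matrix(Y, "Y")
  X <- as_num_matrix(X, "X")
  Z <- as_num_matrix(Z, "Z")
  n <- nrow(Y)
  stopifnot(nrow(X) == n, nrow(Z) == n)

  fitZ <- fit_constraints(cbind(Y, X), Z)
  res <- cbind(Y, X) - fitZ$fitted
  Yres <- res[, seq_len(ncol(Y)), drop = FALSE]
  Xres <- res[, ncol(Y) + seq_len(ncol(X)), drop = FALSE]
  colnames(Xres) <- colnames(X)

  # X entirely within span(Z) leaves nothing to constrain
  if (all(abs(Xres) < 1e-10)) {
    tot_orig <- ss_centered(Y)
    out <- structure(list(constrained_fraction = 0,
                          canonical_eigenvalues = rep(0, min(ncol(Y), ncol(X))),
                          total_variance = ss_centered(Yres) / (n - 1),
                          pseudo_F = 0, p_value = NA_real_,
                          n_permutations = 0L,
                          df_constraints = ncol(X),
                          df_residual = n - ncol(X) - ncol(Z) - 1L,
                          constrained_fraction_total = 0),
                     class = "rda_result")
    return(out)
  }

  fit <- fit_constraints(Yres, Xres)
  tot_res <- sum(Yres^2)           # Z-residuals are already centred
  tot_orig <- ss_centered(Y)
  Yhat <- fit$fitted
  explained <- sum(scale(Yhat, center = TRUE, scale = FALSE)^2)
  ev <- eigen(crossprod(scale(Yhat, center = TRUE, scale = FALSE)) / (n - 1),
              symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)[seq_len(min(ncol(Y), ncol(X)))]

  df_c <- ncol(X)
  df_r <- n - ncol(X) - ncol(Z) - 1L
  pseudo_F <- (explained / df_c) / ((tot_res - explained) / df_r)

  out <- structure(list(constrained_fraction = explained / tot_res,
                        canonical_eigenvalues = ev,
                        total_variance = tot_res / (n - 1),
                        pseudo_F = pseudo_F,
                        p_value = NA_real_, n_permutations = 0L,
                        df_constraints = df_c, df_residual = df_r,
                        constrained_fraction_total = explained / tot_orig),
                   class = "rda_result")
  if (permutations > 0) {
    pt <- permutation_test(Y, X, Z = Z, n_perm = permutations, seed = seed)
    out$p_value <- pt$p_value
    out$n_permutations <- pt$n_permutations
  }
  out
}

#' Monte-Carlo permutation test for (partial) RDA
#'
#' Reduced-model residual permutation: the response is residualised on the
#' covariates (or merely centred when there are none), the rows of these
#' residuals are permuted, and the pseudo-F statistic
#' `(SS_constrained / df_c) / (SS_residual / df_r)` is recomputed for each
#' permutation.  The p value uses the add-one convention
#' `(1 + #[F_perm >= F_obs]) / (n_perm + 1)`, so it is never zero and its
#' support at 999 permutations is `{1/1000, 2/1000, ..., 1}`.
#'
#' @inheritParams partial_rda
#' @param n_perm Number of permutations (999 in the default pipeline).
#' @param seed Integer seed for the permutation draws.
#' @return List with `pseudo_F`, `p_value`, `n_permutations`, `seed`.
#' @export
permutation_test <- function(Y, X, Z = NULL, n_perm = 999, seed = 1L) {
  stopifnot(n_perm >= 1)
  Y <- as_num_matrix(Y, "Y")
  X <- as_num_matrix(X, "X")
  n <- nrow(Y)
  have_Z <- !is.null(Z) && ncol(as.matrix(Z)) > 0L
  if (have_Z) {
    Z <- as_num_matrix(Z, "Z")
    fitZ <- fit_constraints(cbind(Y, X), Z)
    res <- cbind(Y, X) - fitZ$fitted
    Yres <- res[, seq_len(ncol(Y)), drop = FALSE]
    Xres <- res[, ncol(Y) + seq_len(ncol(X)), drop = FALSE]
    df_r <- n - ncol(X) - ncol(Z) - 1L
  } else {
    Yres <- scale(Y, center = TRUE, scale = FALSE)
    Xres <- X
    df_r <- n - ncol(X) - 1L
  }
  df_c <- ncol(X)

  # Orthonormal basis of the centred constraint space: explained SS is the
  # squared norm of the projection onto it.
  Xc <- scale(Xres, center = TRUE, scale = FALSE)
  qx <- qr(Xc)
  if (qx$rank < ncol(Xc)) {
    stop("constraint matrix is rank deficient after residualisation", call. = FALSE)
  }
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]

  ss_exp <- function(M) {
    Mc <- scale(M, center = TRUE, scale = FALSE)
    sum((crossprod(Q, Mc))^2)
  }
  tot <- sum(scale(Yres, center = TRUE, scale = FALSE)^2)
  f_stat <- function(expl) (expl / df_c) / ((tot - expl) / df_r)
  F_obs <- f_stat(ss_exp(Yres))

  F_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      f_stat(ss_exp(Yres[sample.int(n), , drop = FALSE]))
    }, numeric(1))
  })
  p <- (1 + sum(F_perm >= F_obs)) / (n_perm + 1)
  list(pseudo_F = F_obs, p_value = p, n_permutations = as.integer(n_perm),
       seed = as.integer(seed))
}

#' Variance partitioning across explanatory variables via partial RDA
#'
#' Standardises the response and all explanatory variables, then for each
#' variable computes its marginal explained fraction (`rda(Y, v)`), its
#' unique fraction (the gain of the full model over the model without it,
#' i.e. the partial-RDA explained variance expressed on the scale of the
#' total variance of `Y`) and the shared fraction `marginal - unique`.
#' Significance of each unique contribution is assessed by a reduced-model
#' permutation test of `v` given all other variables.
#'
#' Shared fractions can be negative (suppression); they are reported as
#' computed, with a warning.
#'
#' @param Y Response (vector, matrix or data frame), e.g. DCWL.
#' @param variables Data frame or matrix of at least two explanatory
#'   columns (e.g. elevation, latitude, warmest-quarter temperature, plant
#'   height).
#' @param permutations Permutations per significance test (default 999).
#' @param seed Base seed; each variable's test uses `seed + its index`.
#' @return A `partition_table` data frame with one row per variable
#'   (`marginal_fraction`, `unique_fraction`, `shared_fraction`, `pseudo_F`,
#'   `p_value`) and attributes `total_explained` (full-model fraction) and
#'   `shared_total` (total minus the sum of uniques).
#' @export
variance_partition <- function(Y, variables, permutations = 999, seed = 1L) {
  vars <- as_num_matrix(variables, "variables")
  if (ncol(vars) < 2L) stop("need at least two explanatory variables", call. = FALSE)
  Ys <- standardize(as_num_matrix(Y, "Y"))
  Xs <- standardize(vars)

  full <- rda(Ys, Xs)
  total_explained <- full$constrained_fraction

  rows <- lapply(seq_len(ncol(Xs)), function(j) {
    v <- Xs[, j, drop = FALSE]
    others <- Xs[, -j, drop = FALSE]
    marginal <- rda(Ys, v)$constrained_fraction
    unique_f <- total_explained - rda(Ys, others)$constrained_fraction
    pt <- permutation_test(Ys, v, Z = others, n_perm = permutations,
                           seed = as.integer(seed) + j)
    data.frame(variable = colnames(Xs)[j],
               marginal_fraction = marginal,
               unique_fraction = unique_f,
               shared_fraction = marginal - unique_f,
               pseudo_F = pt$pseudo_F, p_value = pt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$shared_fraction < -1e-10)) {
    warning("negative shared fraction(s): suppression among explanatory variables",
            call. = FALSE)
  }
  structure(out, class = c("partition_table", "data.frame"),
            total_explained = total_explained,
            shared_total = total_explained - sum(out$unique_fraction),
            n_permutations = as.integer(permutations))
}

#' @export
print.partition_table <- function(x, ...) {
  cat(sprintf("variance partitioning (total explained = %.4f):\n",
              attr(x, "total_explained")))
  print.data.frame(x, digits = 4)
  cat(sprintf("jointly shared (total - sum of uniques) = %.4f\n",
              attr(x, "shared_total")))
  invisible(x)
}
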