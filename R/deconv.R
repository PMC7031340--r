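#' Deconvolution configuration
#'
#' @param nu_grid candidate \eqn{\nu} values for the support-vector
#'   regression, each in (0,1); the \eqn{\nu} minimizing reconstruction RMSE
#'   is kept per sample
#' @param n_permutations permutations for the goodness-of-fit p-value
#' @param seed integer seed for the permutation null
#' @return list of class \code{deconv_config}
#' @export
deconv_config <- function(nu_grid = c(0.25, 0.5, 0.75),
                          n_permutations = 100L, seed = 1L) {
  if (any(nu_grid <= 0 | nu_grid >= 1)) stop("nu values must lie in (0,1)")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  structure(list(nu_grid = nu_grid,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "deconv_config")
}

# Single-sample nu-SVR fit on standardized data.
# X: standardized signature matrix; y: standardized mixture vector.
# Returns raw weights, clipped+normalized fractions, r and RMSE of the
# reconstruction, for the best nu on the grid.
.svr_fit_one <- function(y, X, nu_grid) {
  best <- NULL
  for (nu in nu_grid) {
    fit <- e1071::svm(x = X, y = y, type = "nu-regression",
                      kernel = "linear", nu = nu, scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    k <- drop(X %*% w) + fit$rho * -1  # svm stores negative intercept in rho
    rmse <- sqrt(mean((k - y)^2))
    if (is.null(best) || rmse < best$rmse)
      best <- list(w = w, rmse = rmse, r = suppressWarnings(stats::cor(k, y)),
                   nu = nu)
  }
  w <- best$w
  w[w < 0] <- 0
  frac <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
  list(fractions = frac, r = best$r, rmse = best$rmse, nu = best$nu)
}

.standardize_inputs <- function(y, S) {
  list(y = (y - mean(y)) / stats::sd(y),
       X = (S - mean(S)) / stats::sd(as.vector(S)))
}

#' Estimate cell-type compositions of bulk samples
#'
#' CIBERSORT-style deconvolution: bulk and signature profiles are restricted
#' to the shared signature genes and standardized; a linear-kernel
#' \eqn{\nu}-support-vector regression of each sample on the signature
#' columns is fitted for every \eqn{\nu} in the grid; the fit with the
#' smallest reconstruction RMSE is kept; negative coefficients are clipped to
#' zero and the rest normalized to sum to 1. A nonnegative-least-squares mode
#' (\code{method = "nnls"}) is provided as an independent cross-check.
#'
#' @param bulk genes x samples nonnegative matrix (TPM-like or summed
#'   normalized expression)
#' @param signature genes x cell types signature matrix
#'   (\code{\link{build_signature_matrix}})
#' @param config \code{\link{deconv_config}}
#' @param method "svr" (default) or "nnls"
#' @param compute_pvalues when TRUE, a permutation p-value is computed per
#'   sample via \code{\link{deconvolution_pvalue}}
#' @return object of class \code{composition_matrix}: \code{fractions}
#'   (samples x types, rows sum to 1), per-sample \code{p_value}, \code{r},
#'   \code{rmse}, chosen \code{nu}, and the \code{resolution} tag inherited
#'   from the signature matrix
#' @export
deconvolute <- function(bulk, signature, config = deconv_config(),
                        method = c("svr", "nnls"), compute_pvalues = FALSE) {
  method <- match.arg(method)
  bulk <- as.matrix(bulk)
  S <- as.matrix(signature)
  shared <- intersect(rownames(S), rownames(bulk))
  miss_frac <- 1 - length(shared) / nrow(S)
  if (miss_frac >= 0.10)
    stop(sprintf("%.0f%% of signature genes missing from bulk matrix",
                 100 * miss_frac))
  if (miss_frac > 0)
    warning(sprintf("%d signature genes missing from bulk; dropped",
                    nrow(S) - length(shared)))
  S <- S[shared, , drop = FALSE]
  if (qr(S)$rank < ncol(S))
    warning("signature matrix is rank-deficient; estimates may be unstable")
  n_samples <- ncol(bulk)
  types <- colnames(S)
  frac <- matrix(NA_real_, n_samples, length(types),
                 dimnames = list(colnames(bulk), types))
  r <- rmse <- nu <- pv <- rep(NA_real_, n_samples)
  for (s in seq_len(n_samples)) {
    y <- bulk[shared, s]
    if (all(y == 0)) stop(sprintf("sample '%s' is all zero", colnames(bulk)[s]))
    if (method == "svr") {
      st <- .standardize_inputs(y, S)
      fit <- .svr_fit_one(st$y, st$X, config$nu_grid)
    } else {
      w <- pracma::lsqnonneg(S, y)$x
      k <- drop(S %*% w)
      fit <- list(fractions = if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w)),
                  r = suppressWarnings(stats::cor(k, y)),
                  rmse = sqrt(mean((k - y)^2)), nu = NA_real_)
    }
    frac[s, ] <- fit$fractions
    r[s] <- fit$r; rmse[s] <- fit$rmse; nu[s] <- fit$nu
  }
  out <- structure(list(fractions = frac, p_value = pv, r = r, rmse = rmse,
                        nu = nu, method = method,
                        resolution = attr(signature, "resolution") %||% "high"),
                   class = "composition_matrix")
  if (compute_pvalues) {
    for (s in seq_len(n_samples))
      out$p_value[s] <- deconvolution_pvalue(bulk[shared, s], S, config,
                                             seed = config$seed + s)
  }
  out
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat(sprintf("composition_matrix: %d samples x %d cell types (%s, %s)\n",
              nrow(x$fractions), ncol(x$fractions), x$method, x$resolution))
  print(utils::head(round(x$fractions, 3)))
  invisible(x)
}

#' Permutation p-value for a single deconvolution
#'
#' Builds the null distribution of the goodness-of-fit correlation r by
#' re-deconvoluting gene-permuted versions of the mixture vector (at the
#' \eqn{\nu} selected for the observed sample) and reports
#' \code{p = (# null r >= observed r + 1) / (n_permutations + 1)}.
#' Invariant to positive rescaling of the sample.
#'
#' @param y named mixture vector over (a superset of) the signature genes
#' @param signature genes x cell types signature matrix
#' @param config \code{\link{deconv_config}}
#' @param seed overrides \code{config$seed} when given
#' @return p-value in \code{(0, 1]} with granularity
#'   \code{1/(n_permutations+1)}
#' @export
deconvolution_pvalue <- function(y, signature, config = deconv_config(),
                                 seed = NULL) {
  S <- as.matrix(signature)
  if (!is.null(names(y))) y <- y[rownames(S)]
  if (anyNA(y)) stop("mixture vector lacks some signature genes")
  st <- .standardize_inputs(y, S)
  obs <- .svr_fit_one(st$y, st$X, config$nu_grid)
  with_seed(seed %||% config$seed, {
    null_r <- vapply(seq_len(config$n_permutations), function(i) {
      yp <- st$y[sample.int(length(st$y))]
      .svr_fit_one(yp, st$X, obs$nu)$r
    }, 0)
    (sum(null_r >= obs$r) + 1) / (config$n_permutations + 1)
  })
}

#' Cell types estimable from a composition matrix
#'
#' A type is estimable when its fraction exceeds \code{min_fraction}
#' (strictly) in strictly more than \code{min_sample_fraction} of the
#' samples. Defaults reproduce the >0.05\% in >5\% of samples rule.
#'
#' @param comp \code{composition_matrix} or bare samples x types matrix
#' @param min_fraction fraction cutoff (default 0.0005)
#' @param min_sample_fraction sample-fraction cutoff (default 0.05)
#' @return character vector of estimable cell types
#' @export
estimable_cell_types <- function(comp, min_fraction = 5e-4,
                                 min_sample_fraction = 0.05) {
  frac <- if (inherits(comp, "composition_matrix")) comp$fractions else as.matrix(comp)
  if (nrow(frac) == 0L) stop("empty composition matrix")
  hit <- colMeans(frac > min_fraction)
  colnames(frac)[hit > min_sample_fraction]
}

#' Per-sample compositional heterogeneity
#'
#' For each sample, the mean over cell types of the squared distance of its
#' fraction from the across-sample mean fraction, plus its log2. A sample
#' exactly at the mean yields \code{-Inf} on the log scale (with a warning).
#'
#' @param comp \code{composition_matrix} or samples x types matrix (>= 2 rows)
#' @return data.frame with columns \code{sample}, \code{sq_dist},
#'   \code{log2_sq_dist}
#' @export
heterogeneity <- function(comp) {
  frac <- if (inherits(comp, "composition_matrix")) comp$fractions else as.matrix(comp)
  if (nrow(frac) < 2L) stop("need >= 2 samples")
  ctr <- sweep(frac, 2, colMeans(frac))
  d <- rowMeans(ctr^2)
  if (any(d == 0))
    warning("sample(s) identical to the mean composition; log2 distance is -Inf")
  data.frame(sample = rownames(frac) %||% as.character(seq_len(nrow(frac))),
             sq_dist = unname(d), log2_sq_dist = log2(unname(d)),
             stringsAsFactors = FALSE)
}

#' Permutation-calibrated correlation between two estimate sets
#'
#' For every pair of cell types (one from each composition matrix) computes
#' the observed Pearson correlation across samples, a permutation null by
#' shuffling the sample order of the second matrix, the Z-score
#' \code{(observed - null mean)/null sd}, the empirical p-value
#' \code{(# null r > observed + 1)/(n_permutations + 1)} and its BH
#' adjustment over all pairs. Zero-variance columns yield NA rows excluded
#' from the BH family.
#'
#' @param compA,compB composition matrices (or bare matrices) over the same
#'   samples
#' @param n_permutations permutation count (default 1000)
#' @param seed integer seed
#' @return data.frame with columns \code{cell_type_A, cell_type_B, r,
#'   perm_mean_r, perm_sd_r, z, p_empirical, p_adjusted}
#' @export
compare_estimates <- function(compA, compB, n_permutations = 1000L, seed = 1L) {
  A <- if (inherits(compA, "composition_matrix")) compA$fractions else as.matrix(compA)
  B <- if (inherits(compB, "composition_matrix")) compB$fractions else as.matrix(compB)
  if (nrow(A) != nrow(B)) stop("compA and compB must share samples")
  n <- nrow(A)
  okA <- apply(A, 2, stats::sd) > 0
  okB <- apply(B, 2, stats::sd) > 0
  obs <- suppressWarnings(stats::cor(A, B))
  with_seed(seed, {
    null_r <- array(NA_real_, c(n_permutations, ncol(A), ncol(B)))
    for (i in seq_len(n_permutations)) {
      Bp <- B[sample.int(n), , drop = FALSE]
      null_r[i, , ] <- suppressWarnings(stats::cor(A, Bp))
    }
    grid <- expand.grid(a = seq_len(ncol(A)), b = seq_len(ncol(B)))
    rows <- lapply(seq_len(nrow(grid)), function(k) {
      a <- grid$a[k]; b <- grid$b[k]
      if (!okA[a] || !okB[b])
        return(data.frame(cell_type_A = colnames(A)[a],
                          cell_type_B = colnames(B)[b], r = NA_real_,
                          perm_mean_r = NA_real_, perm_sd_r = NA_real_,
                          z = NA_real_, p_empirical = NA_real_,
                          p_adjusted = NA_real_, stringsAsFactors = FALSE))
      nr <- null_r[, a, b]
      data.frame(cell_type_A = colnames(A)[a], cell_type_B = colnames(B)[b],
                 r = obs[a, b], perm_mean_r = mean(nr), perm_sd_r = stats::sd(nr),
                 z = (obs[a, b] - mean(nr)) / stats::sd(nr),
                 p_empirical = (sum(nr > obs[a, b]) + 1) / (n_permutations + 1),
                 p_adjusted = NA_real_, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    ok <- !is.na(out$p_empirical)
    out$p_adjusted[ok] <- stats::p.adjust(out$p_empirical[ok], "BH")
    out
  })
}

#' Accuracy of estimated against known compositions
#'
#' @param comp \code{composition_matrix} (or matrix) of estimates
#' @param truth \code{known_composition} (or matrix) of true fractions over
#'   the same samples and types
#' @return data.frame with per-type Pearson \code{r} (NA for constant truth
#'   columns) and \code{rmse}
#' @export
evaluate_recovery <- function(comp, truth) {
  est <- if (inherits(comp, "composition_matrix")) comp$fractions else as.matrix(comp)
  tr <- if (inherits(truth, "known_composition")) truth$fractions else as.matrix(truth)
  types <- intersect(colnames(est), colnames(tr))
  if (length(types) == 0L) stop("no shared cell types between estimate and truth")
  if (nrow(est) != nrow(tr)) stop("sample mismatch between estimate and truth")
  data.frame(
    cell_type = types,
    r = vapply(types, function(t) {
      if (stats::sd(tr[, t]) == 0 || stats::sd(est[, t]) == 0) NA_real_
      else stats::cor(est[, t], tr[, t])
    }, 0),
    rmse = vapply(types, function(t) sqrt(mean((est[, t] - tr[, t])^2)), 0),
    row.names = NULL, stringsAsFactors = FALSE)
}
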