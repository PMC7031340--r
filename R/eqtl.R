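#' Filter genes by expression level
#'
#' Keeps genes whose expression exceeds \code{min_tpm} (strictly) in at least
#' \code{min_fraction} of samples; defaults reproduce the TPM > 0.5 in >= 20\%
#' of samples inclusion rule.
#'
#' @param tpm genes x samples nonnegative matrix
#' @param min_tpm expression cutoff (default 0.5)
#' @param min_fraction minimum fraction of samples (default 0.20)
#' @return character vector of retained gene ids
#' @export
filter_expressed_genes <- function(tpm, min_tpm = 0.5, min_fraction = 0.20) {
  tpm <- as.matrix(tpm)
  keep <- rowMeans(tpm > min_tpm) >= min_fraction
  rownames(tpm)[keep]
}

#' Rank-based inverse-normal transform per gene
#'
#' Each gene's values across samples are replaced by the normal quantiles of
#' their (average-tie) ranks with the Blom offset:
#' \code{qnorm((rank - 3/8) / (n + 1/4))}. An across-sample quantile-matching
#' mode (\code{mode = "quantile"}), which forces every sample to a common
#' empirical distribution before the per-gene transform, is available.
#' Constant genes become all zeros with a warning.
#'
#' @param expr genes x samples matrix (>= 2 samples)
#' @param mode "rint" (default) or "quantile"
#' @return transformed matrix, same dimnames
#' @export
quantile_normalize <- function(expr, mode = c("rint", "quantile")) {
  mode <- match.arg(mode)
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("need >= 2 samples")
  if (mode == "quantile") {
    # classic across-sample quantile matching to the mean sorted profile
    ranks <- apply(expr, 2, rank, ties.method = "average")
    ref <- rowMeans(apply(expr, 2, sort))
    expr <- apply(ranks, 2, function(r) stats::approx(seq_along(ref), ref, r)$y)
  }
  n <- ncol(expr)
  const <- apply(expr, 1, function(x) length(unique(x)) == 1L)
  if (any(const)) warning(sprintf("%d constant gene(s) set to zero", sum(const)))
  out <- t(apply(expr, 1, function(x)
    stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))))
  out[const, ] <- 0
  dimnames(out) <- dimnames(expr)
  out
}

# greedy sliding-window LD pruning on a variants x individuals dosage matrix;
# returns indices of retained variants
.ld_prune <- function(dos, prune_r2 = 0.2, prune_window = 50L) {
  m <- nrow(dos)
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (!keep[i] || i == m) next
    j_max <- min(m, i + prune_window)
    for (j in seq.int(i + 1L, j_max)) {
      if (!keep[j]) next
      r <- suppressWarnings(stats::cor(dos[i, ], dos[j, ]))
      if (!is.na(r) && r^2 > prune_r2) keep[j] <- FALSE
    }
  }
  which(keep)
}

#' Genotype principal components
#'
#' LD-prunes variants with a greedy sliding window (dropping one of any pair
#' with r-squared above \code{prune_r2}), mean-imputes missing dosages,
#' centers, and returns the leading left singular vectors of the individuals
#' x variants matrix scaled by their singular values.
#'
#' @param dosages variants x individuals matrix in \{0,1,2,NA\}
#' @param n_pcs number of components (default 5)
#' @param prune_r2 LD r-squared threshold (default 0.2)
#' @param prune_window window size in variants (default 50)
#' @return individuals x \code{n_pcs} matrix with columns \code{PC1..PCk}
#' @export
genotype_pcs <- function(dosages, n_pcs = 5L, prune_r2 = 0.2,
                         prune_window = 50L) {
  dos <- as.matrix(dosages)
  if (ncol(dos) < n_pcs) stop("fewer individuals than requested PCs")
  keep <- .ld_prune(dos, prune_r2, prune_window)
  if (length(keep) < n_pcs)
    stop("fewer variants than requested PCs after LD pruning")
  dos <- dos[keep, , drop = FALSE]
  if (anyNA(dos)) {
    rm_ <- rowMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- rm_[idx[, 1]]
  }
  G <- scale(t(dos), center = TRUE, scale = FALSE)  # individuals x variants
  sv <- svd(G, nu = n_pcs, nv = 0)
  pcs <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  dimnames(pcs) <- list(colnames(dosages), paste0("PC", seq_len(n_pcs)))
  pcs
}

#' Cis variants for a gene
#'
#' Same-chromosome variants within the closed interval
#' \code{[anchor - window, anchor + window]} (1-based) with MAF strictly
#' above \code{maf_min}. Defaults reproduce the MAF > 1\%, +/- 1 Mb rule.
#'
#' @param gene_record one-row data.frame with \code{chrom} and \code{anchor}
#' @param variant_table data.frame with \code{variant, chrom, pos, maf}
#' @param window half-width in bp (default 1e6)
#' @param maf_min MAF cutoff, strict (default 0.01)
#' @return character vector of variant ids (possibly empty)
#' @export
cis_variants <- function(gene_record, variant_table, window = 1e6,
                         maf_min = 0.01) {
  stopifnot(all(c("chrom", "anchor") %in% names(gene_record)))
  keep <- variant_table$chrom == gene_record$chrom &
    variant_table$pos >= gene_record$anchor - window &
    variant_table$pos <= gene_record$anchor + window &
    variant_table$maf > maf_min
  variant_table$variant[keep]
}

#' Single gene-variant association by LMM or OLS
#'
#' Fits \code{expression ~ genotype + covariates} with an optional random
#' intercept over \code{grouping}, by maximum likelihood, and returns the
#' genotype effect with its standard error and Wald p-value. When the
#' grouping is absent, has one observation per level, or its variance
#' component is estimated at zero, the fit degrades to ordinary least
#' squares. Missing dosages are mean-imputed.
#'
#' @param expr numeric expression vector (one value per sample)
#' @param dosage numeric dosage vector in \{0,1,2,NA\}, aligned with
#'   \code{expr}
#' @param covariates data.frame of fixed covariates (may be NULL)
#' @param grouping factor for the random intercept, or NULL
#' @return one-row data.frame: \code{beta, se, p, n, method}
#' @export
fit_association <- function(expr, dosage, covariates = NULL, grouping = NULL) {
  if (anyNA(dosage)) dosage[is.na(dosage)] <- mean(dosage, na.rm = TRUE)
  ok <- !is.na(expr)
  if (sum(ok) < 10L) stop("fewer than 10 complete observations")
  if (stats::sd(dosage[ok]) == 0)
    return(data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                      n = sum(ok), method = "skipped_constant_dosage",
                      stringsAsFactors = FALSE))
  dat <- data.frame(.y = expr, .g = dosage)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
    X <- stats::model.matrix(~ ., data = cbind(data.frame(.g = dosage), covariates))
    if (qr(X)$rank < ncol(X)) {
      qrX <- qr(X)
      bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
      stop(sprintf("singular covariates: %s", paste(bad, collapse = ", ")))
    }
  }
  fixed <- stats::as.formula(paste(".y ~ .g",
    if (!is.null(covariates)) paste("+", paste(names(covariates), collapse = " + "))
    else ""))
  use_lmm <- !is.null(grouping) && nlevels(factor(grouping)) < length(expr)
  if (use_lmm) {
    dat$.grp <- factor(grouping)
    form <- stats::update(fixed, . ~ . + (1 | .grp))
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(form, data = dat, REML = FALSE)))
    if (isTRUE(lme4::isSingular(fit, tol = 1e-5))) use_lmm <- FALSE
    else {
      co <- summary(fit)$coefficients
      beta <- co[".g", "Estimate"]; se <- co[".g", "Std. Error"]
      p <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
      return(data.frame(beta = beta, se = se, p = p, n = nrow(dat),
                        method = "lmm", stringsAsFactors = FALSE))
    }
  }
  fit <- stats::lm(fixed, data = dat)
  co <- suppressWarnings(summary(fit))$coefficients  # degenerate fits warn
  if (!(".g" %in% rownames(co)) || stats::sd(expr[ok]) == 0)
    return(data.frame(beta = 0, se = NA_real_, p = 1, n = nrow(dat),
                      method = "ols", stringsAsFactors = FALSE))
  beta <- co[".g", "Estimate"]; se <- co[".g", "Std. Error"]
  p <- co[".g", "Pr(>|t|)"]
  if (is.nan(p)) { beta <- 0; p <- 1 }
  data.frame(beta = beta, se = se, p = p, n = nrow(dat), method = "ols",
             stringsAsFactors = FALSE)
}

#' Map all cis associations for a set of genes
#'
#' Convenience driver: for each annotated gene, finds its cis variants and
#' fits \code{\link{fit_association}} for each.
#'
#' @param expr genes x samples matrix (typically
#'   \code{\link{quantile_normalize}}d)
#' @param dosages variants x individuals matrix
#' @param gene_annot data.frame \code{gene, chrom, anchor}
#' @param variant_table data.frame \code{variant, chrom, pos, maf}
#' @param covariates per-sample covariate data.frame (row order = columns of
#'   \code{expr})
#' @param sample_individual individual id per sample (maps expression columns
#'   onto dosage columns)
#' @param grouping random-intercept factor per sample, or NULL
#' @param window,maf_min cis-window parameters (see \code{\link{cis_variants}})
#' @return data.frame of associations: \code{gene, variant, pos, beta, se, p}
#' @export
map_cis_associations <- function(expr, dosages, gene_annot, variant_table,
                                 covariates = NULL, sample_individual = NULL,
                                 grouping = NULL, window = 1e6,
                                 maf_min = 0.01) {
  expr <- as.matrix(expr)
  if (is.null(sample_individual)) sample_individual <- colnames(expr)
  idx <- match(sample_individual, colnames(dosages))
  if (anyNA(idx)) stop("some samples map to individuals absent from dosages")
  pos_of <- stats::setNames(variant_table$pos, variant_table$variant)
  out <- list()
  for (gi in seq_len(nrow(gene_annot))) {
    g <- gene_annot$gene[gi]
    if (!(g %in% rownames(expr))) next
    vids <- cis_variants(gene_annot[gi, ], variant_table, window, maf_min)
    if (length(vids) == 0L) next
    y <- expr[g, ]
    rows <- lapply(vids, function(v) {
      a <- fit_association(y, dosages[v, idx], covariates, grouping)
      cbind(data.frame(gene = g, variant = v, pos = unname(pos_of[v]),
                       stringsAsFactors = FALSE), a)
    })
    out[[g]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-gene lead variants and eGene calls
#'
#' Within each gene, nominal p-values are Bonferroni-corrected by the number
#' of cis variants tested and the variant with the smallest corrected p
#' (ties: smaller nominal p, then smaller position) is retained as lead.
#' Benjamini-Hochberg is then applied across all genes' lead corrected
#' p-values; eGenes are leads with q-value at or below \code{fdr_level}
#' (default 10\%).
#'
#' @param associations data.frame from \code{\link{map_cis_associations}}
#'   (columns \code{gene, variant, pos, p})
#' @param fdr_level BH FDR level (default 0.10)
#' @return data.frame: \code{gene, variant, pos, beta, se, p_nominal,
#'   n_tested, p_bonferroni, q_value, egene}
#' @export
lead_and_call_egenes <- function(associations, fdr_level = 0.10) {
  a <- associations[!is.na(associations$p), , drop = FALSE]
  if (nrow(a) == 0L) stop("no testable associations")
  leads <- do.call(rbind, lapply(split(a, a$gene), function(d) {
    n_tested <- nrow(d)
    d$p_bonferroni <- pmin(1, d$p * n_tested)
    d <- d[order(d$p_bonferroni, d$p, d$pos), , drop = FALSE]
    lead <- d[1L, ]
    data.frame(gene = lead$gene, variant = lead$variant, pos = lead$pos,
               beta = lead$beta, se = lead$se, p_nominal = lead$p,
               n_tested = n_tested, p_bonferroni = lead$p_bonferroni,
               stringsAsFactors = FALSE)
  }))
  leads$q_value <- stats::p.adjust(leads$p_bonferroni, "BH")
  leads$egene <- leads$q_value <= fdr_level
  rownames(leads) <- NULL
  leads
}
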