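#' Genotype x cell-type interaction test for one gene/variant/type
#'
#' Compares, by maximum likelihood, the nested models
#' \deqn{H_0: expression ~ genotype + covariates + cell_populations}
#' \deqn{H_1: H_0 + genotype : cell_population}
#' (each with an optional random intercept). The test statistic is the
#' 1-df likelihood-ratio chi-squared \code{2 (logLik H1 - logLik H0)}; both
#' AICs and \code{dAIC = AIC_interaction - AIC_no_interaction} are recorded
#' (negative dAIC favors the interaction model; for 1 df,
#' \code{dAIC = 2 - chisq}).
#'
#' One column of the composition matrix (by default the most abundant type)
#' is dropped from the fixed effects to avoid the sum-to-one collinearity.
#'
#' @param expr expression vector per sample
#' @param dosage genotype dosage per sample (NA mean-imputed)
#' @param covariates data.frame of fixed covariates, or NULL
#' @param compositions samples x cell types fraction matrix (all included
#'   types; the interaction column may be one of them)
#' @param cell_type the type whose fraction enters the interaction
#' @param grouping random-intercept factor, or NULL (OLS)
#' @param drop_type composition column excluded from the fixed effects;
#'   default = most abundant type
#' @return one-row data.frame: \code{cell_type, gamma, chisq, p, aic_h1,
#'   aic_h0, delta_aic, converged}
#' @export
interaction_test <- function(expr, dosage, covariates = NULL, compositions,
                             cell_type, grouping = NULL, drop_type = NULL) {
  compositions <- as.matrix(compositions)
  if (!(cell_type %in% colnames(compositions)))
    stop(sprintf("cell type '%s' not in composition matrix", cell_type))
  if (stats::sd(compositions[, cell_type]) == 0)
    stop(sprintf("composition of '%s' is constant across samples", cell_type))
  if (anyNA(dosage)) dosage[is.na(dosage)] <- mean(dosage, na.rm = TRUE)
  if (is.null(drop_type))
    drop_type <- colnames(compositions)[which.max(colMeans(compositions))]
  comp_cols <- setdiff(colnames(compositions), drop_type)
  dat <- data.frame(.y = expr, .g = dosage, check.names = FALSE)
  cn <- paste0("comp_", comp_cols)
  dat[cn] <- compositions[, comp_cols, drop = FALSE]
  ct_col <- paste0("comp_", cell_type)
  if (!(ct_col %in% names(dat))) {  # interaction with the dropped type
    ct_col <- ".ct"
    dat$.ct <- compositions[, cell_type]
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
  }
  rhs0 <- paste(c(".g", cn,
                  if (!is.null(covariates)) names(covariates)), collapse = " + ")
  # H1 adds exactly one parameter (the interaction), keeping the LRT at 1 df
  rhs1 <- paste(rhs0, "+", sprintf(".g:%s", ct_col))
  use_lmm <- !is.null(grouping) && nlevels(factor(grouping)) < length(expr)
  fit2 <- function(rhs) {
    if (use_lmm) {
      dat$.grp <- factor(grouping)
      f <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .grp)"))
      suppressWarnings(suppressMessages(lme4::lmer(f, data = dat, REML = FALSE)))
    } else stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
  }
  h0 <- tryCatch(fit2(rhs0), error = function(e) NULL)
  h1 <- tryCatch(fit2(rhs1), error = function(e) NULL)
  if (is.null(h0) || is.null(h1))
    return(data.frame(cell_type = cell_type, gamma = NA_real_,
                      chisq = NA_real_, p = NA_real_, aic_h1 = NA_real_,
                      aic_h0 = NA_real_, delta_aic = NA_real_,
                      converged = FALSE, stringsAsFactors = FALSE))
  ll0 <- as.numeric(stats::logLik(h0)); ll1 <- as.numeric(stats::logLik(h1))
  chisq <- max(0, 2 * (ll1 - ll0))
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  cf <- if (use_lmm) lme4::fixef(h1) else stats::coef(h1)
  iname <- grep(paste0("^\\.g:|:", "\\.g$"), names(cf), value = TRUE)
  gamma <- if (length(iname)) unname(cf[iname[1]]) else NA_real_
  data.frame(cell_type = cell_type, gamma = gamma, chisq = chisq, p = p,
             aic_h1 = stats::AIC(h1), aic_h0 = stats::AIC(h0),
             delta_aic = stats::AIC(h1) - stats::AIC(h0),
             converged = TRUE, stringsAsFactors = FALSE)
}

#' Interaction tests for a gene across all cell types
#'
#' @inheritParams interaction_test
#' @param gene,variant identifiers copied into the output
#' @param cell_types types to test (default: every composition column; the
#'   type dropped from the main effects is still interaction-testable)
#' @return data.frame with one row per tested cell type
#' @export
interaction_scan <- function(gene, variant, expr, dosage, covariates = NULL,
                             compositions, grouping = NULL,
                             cell_types = NULL, drop_type = NULL) {
  compositions <- as.matrix(compositions)
  if (is.null(drop_type))
    drop_type <- colnames(compositions)[which.max(colMeans(compositions))]
  if (is.null(cell_types))
    cell_types <- colnames(compositions)
  rows <- lapply(cell_types, function(ct)
    tryCatch(interaction_test(expr, dosage, covariates, compositions, ct,
                              grouping, drop_type),
             error = function(e)
               data.frame(cell_type = ct, gamma = NA_real_, chisq = NA_real_,
                          p = NA_real_, aic_h1 = NA_real_, aic_h0 = NA_real_,
                          delta_aic = NA_real_, converged = FALSE,
                          stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  cbind(data.frame(gene = gene, variant = variant, stringsAsFactors = FALSE), out)
}

#' Call cell-type-associated and cell-type-specific eGenes
#'
#' Per gene, the most significant converged cell-type test is retained and
#' the retained p-values are BH-adjusted across genes. A cell type passes
#' for a gene when the gene-level adjusted p-value is below \code{fdr_level}
#' and that type's own \code{delta_aic} is negative. A gene is
#' cell-type-associated when at least one type passes and cell-type-specific
#' when exactly one does.
#'
#' @param results data.frame from \code{\link{interaction_scan}} over many
#'   genes (columns \code{gene, cell_type, p, delta_aic, converged})
#' @param fdr_level BH level on the adjusted chi-squared p (default 0.1)
#' @return data.frame: \code{gene, best_cell_type, best_p, adj_p, associated,
#'   specific, n_passing, passing_types}
#' @export
classify_cell_type_calls <- function(results, fdr_level = 0.1) {
  res <- results[results$converged & !is.na(results$p), , drop = FALSE]
  if (nrow(res) == 0L) stop("no converged interaction results")
  by_gene <- split(res, res$gene)
  best <- do.call(rbind, lapply(by_gene, function(d) {
    d <- d[order(d$p, d$cell_type), , drop = FALSE]
    d[1L, c("gene", "cell_type", "p")]
  }))
  best$adj_p <- stats::p.adjust(best$p, "BH")
  adj_of <- stats::setNames(best$adj_p, best$gene)
  out <- do.call(rbind, lapply(by_gene, function(d) {
    g <- d$gene[1L]
    pass <- adj_of[[g]] < fdr_level & d$delta_aic < 0
    data.frame(gene = g,
               best_cell_type = best$cell_type[best$gene == g],
               best_p = best$p[best$gene == g],
               adj_p = unname(adj_of[[g]]),
               associated = any(pass), specific = sum(pass) == 1L,
               n_passing = sum(pass),
               passing_types = paste(sort(d$cell_type[pass]), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Does cell-type abundance drive the number of calls?
#'
#' Spearman rank correlation between each cell type's mean estimated
#' fraction and its number of passing calls.
#'
#' @param calls output of \code{\link{classify_cell_type_calls}}
#' @param comp \code{composition_matrix} or samples x types matrix
#' @return list with the per-type summary data.frame (\code{cell_type,
#'   mean_fraction, n_calls}) and \code{rho}, \code{p} (NA sentinels with
#'   fewer than 3 types or zero variance)
#' @export
abundance_bias_check <- function(calls, comp) {
  frac <- if (inherits(comp, "composition_matrix")) comp$fractions else as.matrix(comp)
  if (ncol(frac) < 2L) stop("need >= 2 cell types")
  counts <- table(unlist(strsplit(
    calls$passing_types[calls$passing_types != ""], ",")))
  summ <- data.frame(cell_type = colnames(frac),
                     mean_fraction = unname(colMeans(frac)),
                     n_calls = as.integer(counts[colnames(frac)]),
                     stringsAsFactors = FALSE)
  summ$n_calls[is.na(summ$n_calls)] <- 0L
  if (ncol(frac) < 3L || stats::sd(summ$n_calls) == 0 ||
      stats::sd(summ$mean_fraction) == 0)
    return(list(summary = summ, rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(stats::cor.test(summ$mean_fraction, summ$n_calls,
                                         method = "spearman"))
  list(summary = summ, rho = unname(ct$estimate), p = ct$p.value)
}

#' Permutation sanity check of composition-covariate eQTL models
#'
#' For each top gene/variant pair, refits the composition-covariate model
#' after permuting whole composition rows across samples,
#' \code{n_permutations} times, and averages the genotype p-value, beta and
#' standard error over permutations. Across genes, observed and
#' permutation-averaged values are compared with paired t-tests.
#'
#' @param hits data.frame with columns \code{gene, variant} (top hit per
#'   gene)
#' @param expr genes x samples matrix
#' @param dosages variants x individuals matrix
#' @param sample_individual individual id per expression column
#' @param covariates per-sample covariate data.frame or NULL
#' @param compositions samples x cell types matrix entering the model (minus
#'   the dropped column)
#' @param grouping random-intercept factor or NULL
#' @param n_permutations number of row permutations (>= 2; the reference
#'   analysis uses 1000)
#' @param seed integer seed
#' @return list with \code{per_gene} (observed and permutation-mean p, beta,
#'   se per gene) and \code{tests} (paired t statistic and p per metric)
#' @export
permutation_check <- function(hits, expr, dosages, sample_individual,
                              covariates = NULL, compositions,
                              grouping = NULL, n_permutations = 1000L,
                              seed = 1L) {
  if (n_permutations < 2L) stop("n_permutations must be >= 2")
  if (nrow(hits) < 2L) stop("need >= 2 genes for the paired comparison")
  compositions <- as.matrix(compositions)
  drop_type <- colnames(compositions)[which.max(colMeans(compositions))]
  comp_cols <- setdiff(colnames(compositions), drop_type)
  # constant columns carry no information and would be collinear with the
  # intercept; permuting them is a no-op by construction
  comp_cols <- comp_cols[apply(compositions[, comp_cols, drop = FALSE], 2,
                               stats::sd) > 0]
  idx <- match(sample_individual, colnames(dosages))
  n <- ncol(expr)
  base_cov <- function(cmp) {
    cv <- NULL
    if (length(comp_cols)) {
      cv <- as.data.frame(cmp[, comp_cols, drop = FALSE])
      names(cv) <- paste0("comp_", comp_cols)
    }
    if (!is.null(covariates)) {
      cov_df <- as.data.frame(covariates)
      cv <- if (is.null(cv)) cov_df else cbind(cov_df, cv)
    }
    cv
  }
  with_seed(seed, {
    perms <- replicate(n_permutations, sample.int(n), simplify = FALSE)
    per_gene <- do.call(rbind, lapply(seq_len(nrow(hits)), function(i) {
      g <- hits$gene[i]; v <- hits$variant[i]
      y <- expr[g, ]; d <- dosages[v, idx]
      obs <- fit_association(y, d, base_cov(compositions), grouping)
      pm <- vapply(perms, function(pp) {
        a <- fit_association(y, d, base_cov(compositions[pp, , drop = FALSE]),
                             grouping)
        c(a$p, a$beta, a$se)
      }, numeric(3))
      data.frame(gene = g, variant = v,
                 p_obs = obs$p, p_perm = mean(pm[1, ]),
                 beta_obs = obs$beta, beta_perm = mean(pm[2, ]),
                 se_obs = obs$se, se_perm = mean(pm[3, ]),
                 stringsAsFactors = FALSE)
    }))
    tpair <- function(a, b) {
      if (stats::sd(a - b) == 0)
        return(data.frame(t = 0, p = 1))
      tt <- stats::t.test(a, b, paired = TRUE)
      data.frame(t = unname(tt$statistic), p = tt$p.value)
    }
    tests <- rbind(
      cbind(metric = "p", tpair(per_gene$p_obs, per_gene$p_perm)),
      cbind(metric = "beta", tpair(per_gene$beta_obs, per_gene$beta_perm)),
      cbind(metric = "se", tpair(per_gene$se_obs, per_gene$se_perm)))
    list(per_gene = per_gene, tests = tests)
  })
}
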