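#' Wakefield log approximate Bayes factor per variant
#'
#' With \code{z = beta/se} and shrinkage \code{r = prior_sd^2 / (prior_sd^2 +
#' se^2)}, the log-ABF is \code{0.5 * (log(1 - r) + r * z^2)}. When only a
#' p-value is available, \code{z} is recovered from the two-sided normal
#' quantile and \code{se} approximated from MAF and sample size
#' (\code{se ~ 1/sqrt(2 p (1-p) N)}; for case-control traits the effective N
#' is \code{N * s * (1-s)} with case fraction \code{s}).
#'
#' @param stats data.frame with either \code{beta} and \code{se}, or \code{p}
#'   plus \code{maf} and \code{n} (and optionally \code{case_fraction})
#' @param trait_type "quantitative" (prior sd 0.15) or "cc" (0.2 on the
#'   log-odds scale)
#' @param prior_sd overrides the trait-type default prior on the effect size
#' @return numeric vector of log-ABFs, one per row
#' @export
variant_abf <- function(stats, trait_type = c("quantitative", "cc"),
                        prior_sd = NULL) {
  trait_type <- match.arg(trait_type)
  if (is.null(prior_sd)) prior_sd <- if (trait_type == "cc") 0.2 else 0.15
  if (all(c("beta", "se") %in% names(stats)) && !anyNA(stats$se)) {
    se <- stats$se
    if (any(se <= 0)) stop("standard errors must be strictly positive")
    z <- stats$beta / se
  } else {
    if (!all(c("p", "maf", "n") %in% names(stats)))
      stop("need beta+se, or p+maf+n")
    z <- stats::qnorm(stats$p / 2, lower.tail = FALSE)
    n_eff <- if (trait_type == "cc" && "case_fraction" %in% names(stats))
      stats$n * stats$case_fraction * (1 - stats$case_fraction) else stats$n
    se <- 1 / sqrt(2 * stats$maf * (1 - stats$maf) * n_eff)
    if (any(se <= 0)) stop("standard errors must be strictly positive")
  }
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * (log(1 - r) + r * z^2)
}

#' Colocalization posteriors over five hypotheses
#'
#' Assembles log evidence for H0 (no association), H1/H2 (association with
#' one trait only), H3 (two distinct causal variants) and H4 (one shared
#' causal variant) from per-variant log approximate Bayes factors, assuming
#' at most one causal variant per trait. H3 sums over ordered variant pairs
#' i != j; with a single variant H3 is structurally zero. Posteriors are
#' normalized by log-sum-exp.
#'
#' @param labf1,labf2 log-ABF vectors over the same variants (length >= 1)
#' @param p1,p2 prior probability a variant is causal for trait 1 / trait 2
#'   (default 1e-4)
#' @param p12 prior probability a variant is causal for both (default 1e-5)
#' @return one-row data.frame of class \code{coloc_result}: \code{n_variants,
#'   pp0, pp1, pp2, pp3, pp4} summing to 1
#' @export
coloc_posteriors <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  m <- length(labf1)
  if (m == 0L) stop("empty variant list")
  if (length(labf2) != m) stop("labf1 and labf2 must cover the same variants")
  s1 <- logsumexp(labf1)
  s2 <- logsumexp(labf2)
  s12 <- logsumexp(labf1 + labf2)
  lh0 <- 0
  lh1 <- log(p1) + s1
  lh2 <- log(p2) + s2
  # sum over i != j of ABF1_i * ABF2_j = (sum_i ABF1_i)(sum_j ABF2_j) - sum_i ABF1_i ABF2_i
  lh3 <- if (m < 2L) -Inf else log(p1) + log(p2) + logdiffexp(s1 + s2, s12)
  lh4 <- log(p12) + s12
  lh <- c(lh0, lh1, lh2, lh3, lh4)
  pp <- exp(lh - logsumexp(lh))
  out <- data.frame(n_variants = m, pp0 = pp[1], pp1 = pp[2], pp2 = pp[3],
                    pp3 = pp[4], pp4 = pp[5])
  class(out) <- c("coloc_result", "data.frame")
  out
}

#' Colocalize one locus from summary statistics
#'
#' Convenience wrapper: joins eQTL and GWAS summary tables on variant id,
#' computes log-ABFs for each and returns \code{\link{coloc_posteriors}}.
#'
#' @param eqtl,gwas data.frames with \code{variant} and either
#'   \code{beta, se} or \code{p, maf, n}
#' @param gwas_trait_type "quantitative" or "cc"
#' @param p1,p2,p12 causal priors
#' @return \code{coloc_result} row (plus the shared variant count)
#' @export
colocalize_locus <- function(eqtl, gwas, gwas_trait_type = "quantitative",
                             p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  shared <- intersect(eqtl$variant, gwas$variant)
  if (length(shared) == 0L) stop("no shared variants between eQTL and GWAS")
  e <- eqtl[match(shared, eqtl$variant), , drop = FALSE]
  g <- gwas[match(shared, gwas$variant), , drop = FALSE]
  coloc_posteriors(variant_abf(e, "quantitative"),
                   variant_abf(g, gwas_trait_type), p1, p2, p12)
}

#' Loci colocalized above a PP4 threshold
#'
#' @param coloc_table data.frame with \code{locus} (or \code{gene}) and
#'   \code{pp4}
#' @param pp4_threshold strict threshold (default 0.5)
#' @return character vector of locus ids with \code{pp4 > threshold}
#' @export
call_colocalized <- function(coloc_table, pp4_threshold = 0.5) {
  if (nrow(coloc_table) == 0L) stop("empty colocalization table")
  id <- coloc_table$locus %||% coloc_table$gene
  id[coloc_table$pp4 > pp4_threshold]
}

#' PP4-threshold-scan enrichment of cell-type-associated eQTLs
#'
#' For each cell type and each PP4 threshold (default 0 to 1 by 0.05, 21
#' values), builds the 2x2 table of loci classified by (1) significant
#' association with that cell type at \code{assoc_fdr} and (2) PP4 strictly
#' above the threshold, then reports the odds ratio (Haldane-Anscombe 0.5
#' correction when any cell is zero) and the two-sided Fisher exact p-value.
#'
#' @param coloc_table data.frame with \code{locus}/\code{gene} and \code{pp4}
#' @param calls data.frame from \code{\link{classify_cell_type_calls}} with
#'   \code{gene, adj_p, passing_types}
#' @param assoc_fdr FDR cutoff used inside the contingency table (default
#'   0.05)
#' @param thresholds PP4 thresholds (default \code{seq(0, 1, 0.05)})
#' @return data.frame: \code{cell_type, threshold, n11, n10, n01, n00,
#'   odds_ratio, fisher_p}
#' @export
enrichment_scan <- function(coloc_table, calls, assoc_fdr = 0.05,
                            thresholds = seq(0, 1, by = 0.05)) {
  id <- coloc_table$locus %||% coloc_table$gene
  common <- intersect(id, calls$gene)
  if (length(common) == 0L) stop("no loci joinable between tables")
  pp4 <- coloc_table$pp4[match(common, id)]
  cl <- calls[match(common, calls$gene), , drop = FALSE]
  types <- sort(unique(unlist(strsplit(cl$passing_types[cl$passing_types != ""], ","))))
  if (length(types) == 0L) types <- character()
  out <- list()
  for (ct in types) {
    has_type <- vapply(strsplit(cl$passing_types, ","), function(x) ct %in% x, TRUE)
    assoc <- cl$adj_p < assoc_fdr & has_type
    for (th in thresholds) {
      colc <- pp4 > th
      n11 <- sum(assoc & colc); n10 <- sum(assoc & !colc)
      n01 <- sum(!assoc & colc); n00 <- sum(!assoc & !colc)
      tab <- matrix(c(n11, n01, n10, n00), 2)
      or <- if (any(tab == 0)) ((n11 + 0.5) * (n00 + 0.5)) /
        ((n10 + 0.5) * (n01 + 0.5)) else (n11 * n00) / (n10 * n01)
      fp <- stats::fisher.test(tab)$p.value
      out[[length(out) + 1L]] <- data.frame(
        cell_type = ct, threshold = th, n11 = n11, n10 = n10, n01 = n01,
        n00 = n00, odds_ratio = or, fisher_p = fp, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(cell_type = character(), threshold = numeric(),
                      n11 = integer(), n10 = integer(), n01 = integer(),
                      n00 = integer(), odds_ratio = numeric(),
                      fisher_p = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
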