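#' Simulate a labeled single-cell RNA-seq dataset
#'
#' Draws a genes x cells count matrix from a negative-binomial model in which
#' each cell type carries a disjoint set of marker genes whose mean expression
#' is scaled by \code{2^marker_log2fc} in that type. The marker assignment is
#' recorded in the returned object so downstream signature selection can be
#' checked against ground truth.
#'
#' @param n_cell_types number of cell types (>= 1)
#' @param n_genes total number of genes
#' @param cells_per_type cells simulated per type (recycled to length
#'   \code{n_cell_types})
#' @param n_markers_per_type markers planted per type; marker sets are disjoint
#' @param marker_log2fc log2 fold change of a marker in its own type; 0 plants
#'   no signal
#' @param dispersion negative-binomial dispersion (\code{size = 1/dispersion});
#'   0.5 is typical droplet-scRNA-seq overdispersion
#' @param seed integer seed; identical seeds give bit-identical output
#' @return an object of class \code{sc_dataset}: list with \code{counts}
#'   (genes x cells integer matrix), \code{genes}, \code{cell_labels} (one per
#'   cell), \code{normalized} (NULL until \code{\link{lognormalize}}),
#'   \code{species_tag} and \code{marker_truth} (list cell type -> marker ids)
#' @export
simulate_scrna <- function(n_cell_types, n_genes, cells_per_type,
                           n_markers_per_type, marker_log2fc = 2,
                           dispersion = 0.5, seed = 1L,
                           species_tag = "synthetic") {
  n_cell_types <- stopifnot_scalar_count(n_cell_types, "n_cell_types")
  n_genes <- stopifnot_scalar_count(n_genes, "n_genes")
  if (any(cells_per_type < 1)) stop("cells_per_type must be >= 1")
  if (n_markers_per_type * n_cell_types > n_genes)
    stop("n_markers_per_type * n_cell_types exceeds n_genes; cannot assign disjoint marker sets")
  cells_per_type <- rep_len(as.integer(cells_per_type), n_cell_types)
  with_seed(seed, {
    genes <- sprintf("gene%05d", seq_len(n_genes))
    types <- sprintf("CT%d", seq_len(n_cell_types))
    labels <- rep(types, times = cells_per_type)
    n_cells <- length(labels)
    cells <- sprintf("cell%05d", seq_len(n_cells))
    # baseline per-gene mean on a right-skewed scale, as in real droplet data
    mu0 <- exp(stats::rnorm(n_genes, mean = 0, sd = 1))
    marker_idx <- matrix(sample.int(n_genes, n_markers_per_type * n_cell_types),
                         nrow = n_markers_per_type)
    marker_truth <- stats::setNames(
      lapply(seq_len(n_cell_types), function(t) genes[marker_idx[, t]]), types)
    counts <- matrix(0L, n_genes, n_cells, dimnames = list(genes, cells))
    size <- 1 / dispersion
    for (t in seq_len(n_cell_types)) {
      mu <- mu0
      mu[marker_idx[, t]] <- mu[marker_idx[, t]] * 2^marker_log2fc
      cols <- which(labels == types[t])
      counts[, cols] <- stats::rnbinom(n_genes * length(cols), size = size,
                                       mu = rep(mu, times = length(cols)))
    }
    structure(list(counts = counts, genes = genes,
                   cell_labels = stats::setNames(labels, cells),
                   normalized = NULL, species_tag = species_tag,
                   marker_truth = marker_truth),
              class = "sc_dataset")
  })
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("sc_dataset: %d genes x %d cells, %d cell types (%s)%s\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_labels)), x$species_tag,
              if (is.null(x$normalized)) "" else ", normalized"))
  invisible(x)
}

#' Simulate an ortholog map with controlled relation classes
#'
#' Emits a source -> target gene map containing the requested proportions of
#' one-to-many and many-to-one relations plus unmapped sources; the remainder
#' are one-to-one. Relation classes are attached for test oracles.
#'
#' @param gene_ids source gene identifiers (nonempty)
#' @param frac_one_to_many,frac_many_to_one,frac_unmapped fractions in [0,1]
#'   summing to at most 1
#' @param seed integer seed
#' @return data.frame with columns \code{source}, \code{target} (NA for
#'   unmapped sources) and \code{class}; one row per (source, target) pair
#' @export
simulate_ortholog_map <- function(gene_ids, frac_one_to_many = 0,
                                  frac_many_to_one = 0, frac_unmapped = 0,
                                  seed = 1L) {
  if (length(gene_ids) == 0L) stop("gene_ids must be nonempty")
  fr <- c(frac_one_to_many, frac_many_to_one, frac_unmapped)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("fractions must lie in [0,1] and sum to at most 1")
  n <- length(gene_ids)
  with_seed(seed, {
    ord <- sample(gene_ids)
    n_un <- floor(frac_unmapped * n)
    n_1m <- floor(frac_one_to_many * n)
    n_m1 <- floor(frac_many_to_one * n)
    n_m1 <- n_m1 - (n_m1 %% 2L)  # many:1 sources come in pairs
    i <- 0L
    take <- function(k) { out <- ord[i + seq_len(k)]; i <<- i + k; out }
    un <- take(n_un); om <- take(n_1m); mo <- take(n_m1); oo <- take(n - i)
    tgt <- function(g, suffix = "") paste0("H_", g, suffix)
    rows <- list(
      if (length(un)) data.frame(source = un, target = NA_character_,
                                 class = "unmapped"),
      if (length(om)) data.frame(source = rep(om, each = 2L),
                                 target = as.vector(rbind(tgt(om, "a"), tgt(om, "b"))),
                                 class = "one_to_many"),
      if (length(mo)) data.frame(source = mo,
                                 target = rep(tgt(mo[seq(1, length(mo), 2)], "s"),
                                              each = 2L),
                                 class = "many_to_one"),
      if (length(oo)) data.frame(source = oo, target = tgt(oo),
                                 class = "one_to_one"))
    out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    rownames(out) <- NULL
    out
  })
}

#' Build pseudo-bulk samples with known compositions
#'
#' For each sample and each cell type a cell count is drawn uniformly between
#' \code{min_cells} and the total number of cells of that type, cells are
#' sampled without replacement, and the pseudo-bulk value of each gene is the
#' sum of normalized expression over all selected cells. The drawn counts,
#' normalized to 1, are the known composition of that sample.
#'
#' @param sc \code{sc_dataset} with a normalized layer
#'   (\code{\link{lognormalize}} first)
#' @param n_samples number of pseudo-bulk samples (default 100)
#' @param min_cells minimum cells drawn per type (default 50)
#' @param seed integer seed
#' @return list with \code{bulk} (genes x samples matrix) and
#'   \code{composition}, a \code{known_composition} object holding
#'   \code{fractions} (samples x types), \code{counts} and \code{selected}
#'   (per-sample list of selected cell indices per type)
#' @export
make_pseudobulk <- function(sc, n_samples = 100L, min_cells = 50L, seed = 1L) {
  stopifnot(inherits(sc, "sc_dataset"))
  if (is.null(sc$normalized))
    stop("sc has no normalized layer; run lognormalize() first")
  n_samples <- stopifnot_scalar_count(n_samples, "n_samples")
  types <- sort(unique(unname(sc$cell_labels)))
  by_type <- lapply(types, function(t) which(sc$cell_labels == t))
  names(by_type) <- types
  avail <- vapply(by_type, length, 0L)
  if (any(avail < min_cells))
    stop(sprintf("min_cells=%d exceeds cell count of type(s): %s", min_cells,
                 paste(types[avail < min_cells], collapse = ", ")))
  with_seed(seed, {
    samples <- sprintf("PB%03d", seq_len(n_samples))
    bulk <- matrix(0, nrow(sc$normalized), n_samples,
                   dimnames = list(rownames(sc$normalized), samples))
    cnt <- matrix(0L, n_samples, length(types), dimnames = list(samples, types))
    selected <- vector("list", n_samples)
    names(selected) <- samples
    for (s in seq_len(n_samples)) {
      sel <- lapply(types, function(t) {
        k <- if (avail[[t]] == min_cells) min_cells
             else sample(seq.int(min_cells, avail[[t]]), 1L)
        sample(by_type[[t]], k, replace = FALSE)
      })
      names(sel) <- types
      cnt[s, ] <- vapply(sel, length, 0L)
      bulk[, s] <- rowSums(sc$normalized[, unlist(sel), drop = FALSE])
      selected[[s]] <- sel
    }
    frac <- cnt / rowSums(cnt)
    comp <- structure(list(fractions = frac, counts = cnt, selected = selected),
                      class = "known_composition")
    list(bulk = bulk, composition = comp)
  })
}

#' Constructor for a planted eQTL effect
#'
#' @param gene,variant identifiers that must exist in the cohort
#' @param beta_main additive genotype effect per alt-allele dosage
#' @param gamma_interaction genotype x composition interaction coefficient;
#'   nonzero values require \code{target_cell_type}
#' @param target_cell_type cell type whose fraction enters the interaction
#' @param noise_sd residual standard deviation of the gene's expression
#' @return list of class \code{planted_effect}
#' @export
planted_effect <- function(gene, variant, beta_main = 0,
                           gamma_interaction = 0, target_cell_type = NULL,
                           noise_sd = 1) {
  if (gamma_interaction != 0 && is.null(target_cell_type))
    stop("nonzero gamma_interaction requires target_cell_type")
  structure(list(gene = gene, variant = variant, beta_main = beta_main,
                 gamma_interaction = gamma_interaction,
                 target_cell_type = target_cell_type, noise_sd = noise_sd),
            class = "planted_effect")
}

#' Simulate a cis-eQTL cohort with planted effects
#'
#' Genotype dosages are drawn binomial(2, MAF) under Hardy-Weinberg
#' equilibrium; expression follows the generative model
#' \code{intercept + beta_main * dosage + gamma * dosage * composition[target]
#' + age and sex effects + individual intercept + Gaussian noise}, shifted per
#' gene to be nonnegative. When a signature matrix is supplied, additional
#' rows for its genes are generated as mixtures of the signature columns
#' weighted by the true compositions, so the cohort's bulk expression can be
#' deconvoluted.
#'
#' @param n_individuals number of genotyped individuals
#' @param samples_per_individual expression samples per individual (random
#'   intercept used when > 1)
#' @param n_genes number of eQTL test genes
#' @param n_variants_per_gene cis variants simulated per gene
#' @param maf_range target minor-allele-frequency range; lower bound must
#'   exceed 0.01 (variants below 1\% MAF are outside the analysis)
#' @param compositions samples x cell types matrix of true fractions, or NULL
#' @param planted list of \code{\link{planted_effect}} objects
#' @param covariate_effect_sizes named vector \code{c(age=, sex=)} on the
#'   expression scale
#' @param base_noise_sd residual sd of unplanted genes
#' @param random_intercept_sd sd of the per-individual intercept (0 disables)
#' @param signature_matrix optional genes x cell types matrix; requires
#'   \code{compositions}
#' @param signature_scale multiplier applied to the signature mixture rows
#' @param seed integer seed
#' @return object of class \code{eqtl_cohort}: dosages (variants x
#'   individuals), variant table, expression (genes x samples), gene
#'   annotation, covariates, sample map, compositions, and a \code{truth} list
#'   recording every generative parameter
#' @export
simulate_eqtl_cohort <- function(n_individuals, samples_per_individual = 1L,
                                 n_genes = 10L, n_variants_per_gene = 20L,
                                 maf_range = c(0.05, 0.5), compositions = NULL,
                                 planted = list(),
                                 covariate_effect_sizes = c(age = 0, sex = 0),
                                 base_noise_sd = 1, random_intercept_sd = 0,
                                 signature_matrix = NULL, signature_scale = 1,
                                 seed = 1L) {
  n_individuals <- stopifnot_scalar_count(n_individuals, "n_individuals")
  if (maf_range[1] <= 0.01)
    stop("maf_range lower bound must exceed 0.01 (MAF > 1% inclusion rule)")
  if (maf_range[2] > 0.5) stop("maf_range upper bound must be <= 0.5")
  if (!is.null(signature_matrix) && is.null(compositions))
    stop("signature_matrix requires compositions")
  if (inherits(planted, "planted_effect")) planted <- list(planted)
  with_seed(seed, {
    inds <- sprintf("I%04d", seq_len(n_individuals))
    n_samples <- n_individuals * samples_per_individual
    samples <- sprintf("S%04d", seq_len(n_samples))
    sample_map <- data.frame(sample = samples,
                             individual = rep(inds, each = samples_per_individual),
                             stringsAsFactors = FALSE)
    genes <- sprintf("eg%03d", seq_len(n_genes))
    # genes spaced 3 Mb apart so +/-1 Mb cis windows never overlap
    anchors <- 2e6 + (seq_len(n_genes) - 1L) * 3e6
    gene_annot <- data.frame(gene = genes, chrom = "1", anchor = anchors,
                             stringsAsFactors = FALSE)
    n_var <- n_genes * n_variants_per_gene
    vid <- sprintf("var%05d", seq_len(n_var))
    vpos <- as.integer(rep(anchors, each = n_variants_per_gene) +
      round(stats::runif(n_var, -9e5, 9e5)))
    target_maf <- stats::runif(n_var, maf_range[1], maf_range[2])
    dos <- matrix(stats::rbinom(n_var * n_individuals, 2L,
                                rep(target_maf, times = n_individuals)),
                  n_var, n_individuals, dimnames = list(vid, inds))
    af <- rowMeans(dos) / 2
    emp_maf <- pmin(af, 1 - af)
    variants <- data.frame(variant = vid, chrom = "1", pos = vpos,
                           ref = "A", alt = "G", maf = emp_maf,
                           target_maf = target_maf, stringsAsFactors = FALSE)
    covariates <- data.frame(individual = inds,
                             age = round(stats::runif(n_individuals, 25, 70)),
                             sex = stats::rbinom(n_individuals, 1L, 0.5),
                             stringsAsFactors = FALSE)
    if (!is.null(compositions)) {
      compositions <- as.matrix(compositions)
      if (nrow(compositions) != n_samples)
        stop("compositions must have one row per sample")
      rownames(compositions) <- samples
    }
    ind_of <- match(sample_map$individual, inds)
    rint <- if (random_intercept_sd > 0)
      stats::rnorm(n_individuals, 0, random_intercept_sd) else numeric(n_individuals)
    planted_by_gene <- stats::setNames(
      lapply(planted, identity),
      vapply(planted, function(p) p$gene, ""))
    if (length(planted)) {
      bad <- vapply(planted, function(p)
        !(p$gene %in% genes) || !(p$variant %in% vid), TRUE)
      if (any(bad)) stop("planted effects reference unknown genes or variants")
    }
    age_c <- covariates$age - mean(covariates$age)
    expr <- matrix(0, n_genes, n_samples, dimnames = list(genes, samples))
    intercepts <- stats::runif(n_genes, 5, 10)
    for (g in seq_len(n_genes)) {
      p <- planted_by_gene[[genes[g]]]
      sdg <- if (is.null(p)) base_noise_sd else p$noise_sd
      y <- intercepts[g] +
        covariate_effect_sizes[["age"]] * age_c[ind_of] +
        covariate_effect_sizes[["sex"]] * covariates$sex[ind_of] +
        rint[ind_of] + stats::rnorm(n_samples, 0, sdg)
      if (!is.null(p)) {
        d <- dos[p$variant, ind_of]
        y <- y + p$beta_main * d
        if (p$gamma_interaction != 0)
          y <- y + p$gamma_interaction * d * compositions[, p$target_cell_type]
      }
      if (min(y) < 0) y <- y - min(y)
      expr[g, ] <- y
    }
    if (!is.null(signature_matrix)) {
      S <- as.matrix(signature_matrix)
      mix <- signature_scale * (S %*% t(compositions[, colnames(S), drop = FALSE]))
      mix <- mix + matrix(stats::rnorm(length(mix), 0, 0.01 * mean(mix)),
                          nrow(mix))
      mix[mix < 0] <- 0
      colnames(mix) <- samples
      expr <- rbind(expr, mix)
    }
    structure(list(dosages = dos, variants = variants, expression = expr,
                   genes = gene_annot, covariates = covariates,
                   sample_map = sample_map, compositions = compositions,
                   truth = list(planted = planted, intercepts = intercepts,
                                target_maf = target_maf,
                                covariate_effect_sizes = covariate_effect_sizes,
                                base_noise_sd = base_noise_sd,
                                random_intercept_sd = random_intercept_sd,
                                seed = seed)),
              class = "eqtl_cohort")
  })
}

#' Simulate Dirichlet cell-type compositions
#'
#' @param n_samples rows to draw
#' @param cell_types character vector of type labels
#' @param alpha Dirichlet concentration (scalar or per-type)
#' @param seed integer seed
#' @return samples x types matrix with rows summing to 1
#' @export
simulate_compositions <- function(n_samples, cell_types, alpha = 1, seed = 1L) {
  k <- length(cell_types)
  alpha <- rep_len(alpha, k)
  with_seed(seed, {
    g <- matrix(stats::rgamma(n_samples * k, shape = rep(alpha, each = n_samples)),
                n_samples, k, dimnames = list(sprintf("S%04d", seq_len(n_samples)),
                                              cell_types))
    g / rowSums(g)
  })
}

#' Simulate paired eQTL and GWAS summary statistics for one locus
#'
#' Marginal effects decay with distance from the causal variant through a
#' single-parameter neighbor correlation \code{ld_rho^|i-j|}; standard errors
#' scale as \code{1/sqrt(2 p (1-p) n)}. With \code{shared_causal} both traits
#' center on the same causal variant, otherwise on two distinct ones.
#'
#' @param cohort \code{eqtl_cohort} providing the locus's variants
#' @param locus gene id in the cohort's annotation
#' @param shared_causal logical
#' @param n_gwas GWAS sample size (>= 2)
#' @param effect causal-variant effect size on the standardized trait scale
#' @param ld_rho neighbor LD correlation in (0,1)
#' @param trait_type "quantitative" or "cc" (case-control)
#' @param causal_variant optional variant id pinning the eQTL-side causal
#'   variant (e.g. a planted effect's variant); default random
#' @param seed integer seed
#' @return list with \code{eqtl} and \code{gwas} summary data.frames (variant,
#'   beta, se, maf, n) and a \code{truth} record of the causal indices
#' @export
simulate_gwas_pair <- function(cohort, locus, shared_causal = TRUE,
                               n_gwas = 50000L, effect = 0.3, ld_rho = 0.8,
                               trait_type = "quantitative",
                               causal_variant = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "eqtl_cohort"))
  if (n_gwas < 2) stop("n_gwas must be >= 2")
  g <- cohort$genes[cohort$genes$gene == locus, ]
  if (nrow(g) != 1L) stop(sprintf("locus '%s' not found", locus))
  vt <- cohort$variants
  keep <- vt$chrom == g$chrom & abs(vt$pos - g$anchor) <= 1e6
  vt <- vt[keep, ][order(vt$pos[keep]), ]
  m <- nrow(vt)
  if (m < 2 && !shared_causal)
    stop("distinct causal variants require >= 2 variants at the locus")
  n_eqtl <- ncol(cohort$dosages)
  with_seed(seed, {
    ci_e <- if (is.null(causal_variant)) sample.int(m, 1L)
            else match(causal_variant, vt$variant)
    if (is.na(ci_e)) stop("causal_variant not found at the locus")
    ci_g <- if (shared_causal) ci_e else sample(setdiff(seq_len(m), ci_e), 1L)
    r_e <- ld_rho^abs(seq_len(m) - ci_e)
    r_g <- ld_rho^abs(seq_len(m) - ci_g)
    # single-causal-variant summary statistics: the expected marginal z-score
    # of a linked variant is r times the causal z (independent of its own
    # MAF), and estimation noise shares the LD correlation across variants
    Lc <- chol(ld_rho^abs(outer(seq_len(m), seq_len(m), "-")))
    mk <- function(r, ci, n) {
      se <- 1 / sqrt(2 * vt$maf * (1 - vt$maf) * n)
      z_causal <- effect / se[ci]
      z <- r * z_causal + drop(stats::rnorm(m) %*% Lc)
      data.frame(variant = vt$variant, beta = z * se,
                 se = se, maf = vt$maf, n = n, stringsAsFactors = FALSE)
    }
    eqtl <- mk(r_e, ci_e, n_eqtl)
    gwas <- mk(r_g, ci_g, n_gwas)
    gwas$trait_type <- trait_type
    list(eqtl = eqtl, gwas = gwas,
         truth = list(causal_eqtl = vt$variant[ci_e],
                      causal_gwas = vt$variant[ci_g],
                      shared = shared_causal))
  })
}
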