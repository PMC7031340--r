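#' Generate a coherent demo input bundle with ground truth
#'
#' Emits every file the pipeline consumes, simulated with known truth: a
#' labeled 5-type scRNA-seq dataset (2000 genes x 1500 cells), a 100-sample
#' pseudo-bulk set with known compositions, a 200-individual eQTL cohort
#' whose bulk expression embeds both the signature mixture structure (so its
#' compositions are recoverable by deconvolution) and 6 planted main-effect
#' eQTLs plus 4 planted genotype x cell-type interaction eQTLs among 50 cis
#' genes, and GWAS summary statistics for 10 loci of which 5 share their
#' causal variant with a planted eQTL. A \code{truth.json} records all
#' planted structure.
#'
#' @param dir output directory (created if needed)
#' @param seed integer seed driving every generator
#' @return invisibly, the list of written paths
#' @export
make_demo_dataset <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  sc <- simulate_scrna(n_cell_types = 5, n_genes = 2000, cells_per_type = 300,
                       n_markers_per_type = 40, marker_log2fc = 3,
                       dispersion = 0.5, seed = seed)
  scn <- lognormalize(sc)
  de <- rank_markers(scn)
  sig <- select_signature_genes(de)
  S <- build_signature_matrix(scn, sig)
  types <- colnames(S)
  comp_true <- simulate_compositions(200, types, alpha = 1, seed = seed + 1L)

  main_genes <- sprintf("eg%03d", 1:6)
  int_genes <- sprintf("eg%03d", 7:10)
  pv <- function(g) sprintf("var%05d", (as.integer(sub("eg", "", g)) - 1L) * 60L + 30L)
  planted <- c(
    lapply(main_genes, function(g)
      planted_effect(g, pv(g), beta_main = 0.8, noise_sd = 1)),
    lapply(seq_along(int_genes), function(i)
      # gamma = 3 x residual sd: with 5-type Dirichlet(1) compositions at
      # n = 200 this places the planted interaction at z ~ 4.5, the same
      # standardized strength as gamma = 2 in a 3-type n = 300 design
      planted_effect(int_genes[i], pv(int_genes[i]), beta_main = 0.4,
                     gamma_interaction = 3, target_cell_type = types[i],
                     noise_sd = 1)))
  cohort <- simulate_eqtl_cohort(
    n_individuals = 200, samples_per_individual = 1, n_genes = 50,
    n_variants_per_gene = 60, maf_range = c(0.10, 0.5),
    compositions = comp_true, planted = planted,
    covariate_effect_sizes = c(age = 0.01, sex = 0.3),
    base_noise_sd = 1, signature_matrix = S, signature_scale = 100,
    seed = seed + 2L)

  pb <- make_pseudobulk(scn, n_samples = 100, min_cells = 50, seed = seed + 3L)

  shared_loci <- main_genes[1:5]
  null_loci <- sprintf("eg%03d", 41:45)
  gwas <- do.call(rbind, c(
    lapply(seq_along(shared_loci), function(i) {
      g <- simulate_gwas_pair(cohort, shared_loci[i], shared_causal = TRUE,
                              n_gwas = 50000, effect = 0.3,
                              causal_variant = pv(shared_loci[i]),
                              seed = seed + 10L + i)$gwas
      cbind(locus = shared_loci[i], g)
    }),
    lapply(seq_along(null_loci), function(i) {
      g <- simulate_gwas_pair(cohort, null_loci[i], shared_causal = FALSE,
                              n_gwas = 50000, effect = 0.3,
                              seed = seed + 20L + i)$gwas
      cbind(locus = null_loci[i], g)
    })))

  # the demo ships the normalized layer directly (already_normalized = TRUE)
  write_sc_dataset(scn, p("sc_counts.tsv"), p("sc_labels.tsv"),
                   layer = "normalized")
  write_matrix_tsv(cohort$expression, p("bulk_expression.tsv"))
  write_matrix_tsv(pb$bulk, p("pseudobulk.tsv"))
  write_matrix_tsv(pb$composition$fractions, p("pseudobulk_truth.tsv"),
                   id = "sample")
  write_vcf(cohort$dosages, cohort$variants, p("genotypes.vcf"))
  write_tsv_table(cohort$covariates, p("covariates.tsv"))
  write_tsv_table(cohort$sample_map, p("sample_map.tsv"))
  write_tsv_table(cohort$genes, p("genes.tsv"))
  write_tsv_table(gwas, p("gwas.tsv"))
  truth <- list(
    seed = seed,
    main_eqtls = data.frame(gene = main_genes,
                            variant = vapply(main_genes, pv, "")),
    interaction_eqtls = data.frame(gene = int_genes,
                                   variant = vapply(int_genes, pv, ""),
                                   cell_type = types[seq_along(int_genes)]),
    null_genes = setdiff(sprintf("eg%03d", 1:50), c(main_genes, int_genes)),
    gwas_shared = shared_loci, gwas_distinct = null_loci,
    cell_types = types)
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(list.files(dir, full.names = TRUE))
}

#' Default pipeline configuration for a demo bundle
#'
#' @param input_dir directory written by \code{\link{make_demo_dataset}}
#' @param out_dir output directory for stage results
#' @param seed integer seed
#' @return nested config list accepted by \code{\link{run_all}}
#' @export
demo_config <- function(input_dir, out_dir, seed = 1L) {
  p <- function(f) file.path(input_dir, f)
  list(
    out_dir = out_dir, seed = seed,
    stages = list(signatures = TRUE, deconv = TRUE, eqtl = TRUE,
                  interaction = TRUE, coloc = TRUE),
    inputs = list(sc_counts = p("sc_counts.tsv"), sc_labels = p("sc_labels.tsv"),
                  ortholog_map = "", collapse_map = "",
                  bulk = p("bulk_expression.tsv"), vcf = p("genotypes.vcf"),
                  covariates = p("covariates.tsv"),
                  sample_map = p("sample_map.tsv"),
                  gene_annot = p("genes.tsv"), gene_annot_format = "tsv",
                  gwas = p("gwas.tsv")),
    params = list(
      filter = list(min_genes = 0, min_umi = 0, already_normalized = TRUE),
      normalize = list(scale_total = 1e4),
      signature = list(top_n = 200, max_adj_p = 0.05, min_lfc = 0.25),
      deconv = list(nu_grid = c(0.25, 0.5, 0.75), n_permutations = 100,
                    compute_pvalues = FALSE),
      eqtl = list(min_tpm = 0.5, min_fraction = 0.20, n_pcs = 5,
                  prune_r2 = 0.2, prune_window = 50, window = 1e6,
                  maf_min = 0.01, fdr_level = 0.10,
                  random_effect = "none", use_compositions = TRUE),
      interaction = list(fdr_level = 0.1, egene_only = TRUE),
      coloc = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, pp4_threshold = 0.5,
                   assoc_fdr = 0.05)))
}

.required_config <- list(
  top = c("out_dir", "seed", "stages", "inputs", "params"),
  stages = c("signatures", "deconv", "eqtl", "interaction", "coloc"),
  inputs = c("sc_counts", "sc_labels", "bulk", "vcf", "covariates",
             "sample_map", "gene_annot", "gwas"),
  params = c("filter", "normalize", "signature", "deconv", "eqtl",
             "interaction", "coloc"))

validate_config <- function(config) {
  miss <- setdiff(.required_config$top, names(config))
  if (length(miss)) stop("config missing fields: ", paste(miss, collapse = ", "))
  for (sec in c("stages", "inputs", "params")) {
    miss <- setdiff(.required_config[[sec]], names(config[[sec]]))
    if (length(miss))
      stop(sprintf("config$%s missing: %s", sec, paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

.stage_log <- function(manifest, stage, files) {
  manifest$stages[[stage]] <- list(
    outputs = files,
    rows = vapply(files, function(f)
      if (file.exists(f)) length(readLines(f)) - 1L else NA_integer_, 0L),
    md5 = vapply(files, function(f)
      if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_, ""))
  manifest
}

#' Run the full analysis chain
#'
#' Executes signatures -> deconvolution -> eQTL mapping -> interaction
#' testing -> colocalization/enrichment in order, each stage reading only
#' files and writing its outputs (plus a manifest with row counts and
#' checksums) under \code{config$out_dir}. Stages can be toggled off; later
#' stages then consume whatever earlier outputs exist.
#'
#' @param config nested list (see \code{\link{demo_config}}), or a path to a
#'   YAML file with the same structure
#' @return the manifest list, invisibly; also written as
#'   \code{manifest.json}
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  o <- function(f) file.path(out, f)
  yaml::write_yaml(config, o("config.yaml"))
  manifest <- list(stages = list(), started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  pr <- config$params
  msg <- function(...) message(sprintf("[decoqtl] %s", sprintf(...)))

  if (isTRUE(config$stages$signatures)) {
    msg("stage signatures")
    sc <- read_sc_dataset(config$inputs$sc_counts, config$inputs$sc_labels)
    if (isTRUE(pr$filter$already_normalized)) {
      # counts file already holds the normalized layer (e.g. demo bundle)
      sc$normalized <- sc$counts
    } else {
      sc <- filter_cells(sc, pr$filter$min_genes, pr$filter$min_umi)
      sc <- lognormalize(sc, pr$normalize$scale_total)
    }
    de <- rank_markers(sc)
    sig <- select_signature_genes(de, pr$signature$top_n,
                                  pr$signature$max_adj_p, pr$signature$min_lfc)
    if (nzchar(config$inputs$ortholog_map %||% "")) {
      omap <- read_tsv_table(config$inputs$ortholog_map)
      sig <- map_orthologs(sig, omap)
    }
    S <- build_signature_matrix(sc, sig)
    write_signature_sets(sig, o("signature_sets.tsv"))
    write_matrix_tsv(S, o("signature_matrix.tsv"))
    manifest <- .stage_log(manifest, "signatures",
                           c(o("signature_sets.tsv"), o("signature_matrix.tsv")))
  }

  if (isTRUE(config$stages$deconv)) {
    msg("stage deconv")
    S <- read_matrix_tsv(o("signature_matrix.tsv"))
    bulk <- read_matrix_tsv(config$inputs$bulk)
    cfg <- deconv_config(pr$deconv$nu_grid, pr$deconv$n_permutations,
                         config$seed)
    comp <- deconvolute(bulk, S, cfg,
                        compute_pvalues = isTRUE(pr$deconv$compute_pvalues))
    if (nzchar(config$inputs$collapse_map %||% "")) {
      cmap <- read_tsv_table(config$inputs$collapse_map)
      comp <- collapse_compositions(comp, cmap)
    }
    write_composition(comp, o("compositions.tsv"))
    manifest <- .stage_log(manifest, "deconv", o("compositions.tsv"))
  }

  if (isTRUE(config$stages$eqtl)) {
    msg("stage eqtl")
    pe <- pr$eqtl
    expr <- read_matrix_tsv(config$inputs$bulk)
    keep <- filter_expressed_genes(expr, pe$min_tpm, pe$min_fraction)
    qn <- quantile_normalize(expr[keep, , drop = FALSE])
    geno <- read_vcf_dosages(config$inputs$vcf)
    annot <- read_gene_annot(config$inputs$gene_annot,
                             config$inputs$gene_annot_format %||% "tsv")
    covs <- read_tsv_table(config$inputs$covariates)
    smap <- read_tsv_table(config$inputs$sample_map)
    samples <- colnames(qn)
    indiv <- smap$individual[match(samples, smap$sample)]
    pcs <- genotype_pcs(geno$dosages, pe$n_pcs, pe$prune_r2, pe$prune_window)
    cov_df <- data.frame(age = covs$age[match(indiv, covs$individual)],
                         sex = covs$sex[match(indiv, covs$individual)])
    cov_df <- cbind(cov_df, as.data.frame(pcs[indiv, , drop = FALSE]))
    rownames(cov_df) <- samples
    comp_cols <- NULL
    if (isTRUE(pe$use_compositions) && file.exists(o("compositions.tsv"))) {
      comp <- read_composition(o("compositions.tsv"))
      est <- estimable_cell_types(comp)
      frac <- comp$fractions[samples, est, drop = FALSE]
      drop_type <- est[which.max(colMeans(frac))]
      comp_cols <- setdiff(est, drop_type)
      add <- as.data.frame(frac[, comp_cols, drop = FALSE])
      names(add) <- paste0("comp_", comp_cols)
      cov_df <- cbind(cov_df, add)
    }
    grouping <- switch(pe$random_effect %||% "none",
                       individual = if (anyDuplicated(indiv)) factor(indiv) else NULL,
                       sex = factor(cov_df$sex),
                       NULL)
    assoc <- map_cis_associations(qn, geno$dosages, annot, geno$variants,
                                  covariates = cov_df,
                                  sample_individual = indiv,
                                  grouping = grouping, window = pe$window,
                                  maf_min = pe$maf_min)
    leads <- lead_and_call_egenes(assoc, pe$fdr_level)
    write_matrix_tsv(qn, o("normalized_expression.tsv"))
    write_tsv_table(data.frame(sample = samples, cov_df, check.names = FALSE),
                    o("covariates_assembled.tsv"))
    write_tsv_table(assoc, o("associations.tsv"))
    write_tsv_table(leads, o("leads.tsv"))
    manifest <- .stage_log(manifest, "eqtl",
                           c(o("associations.tsv"), o("leads.tsv"),
                             o("normalized_expression.tsv"),
                             o("covariates_assembled.tsv")))
  }

  if (isTRUE(config$stages$interaction)) {
    msg("stage interaction")
    leads <- read_tsv_table(o("leads.tsv"))
    if (isTRUE(pr$interaction$egene_only))
      leads <- leads[leads$egene, , drop = FALSE]
    qn <- read_matrix_tsv(o("normalized_expression.tsv"))
    comp <- read_composition(o("compositions.tsv"))
    geno <- read_vcf_dosages(config$inputs$vcf)
    smap <- read_tsv_table(config$inputs$sample_map)
    samples <- colnames(qn)
    indiv <- smap$individual[match(samples, smap$sample)]
    ca <- read_tsv_table(o("covariates_assembled.tsv"))
    base_cov <- ca[match(samples, ca$sample),
                   !grepl("^(sample|comp_)", names(ca)), drop = FALSE]
    est <- estimable_cell_types(comp)
    frac <- comp$fractions[samples, est, drop = FALSE]
    res <- do.call(rbind, lapply(seq_len(nrow(leads)), function(i)
      interaction_scan(leads$gene[i], leads$variant[i],
                       qn[leads$gene[i], ],
                       geno$dosages[leads$variant[i], match(indiv, colnames(geno$dosages))],
                       covariates = base_cov, compositions = frac)))
    calls <- classify_cell_type_calls(res, pr$interaction$fdr_level)
    write_tsv_table(res, o("interactions.tsv"))
    write_tsv_table(calls, o("calls.tsv"))
    manifest <- .stage_log(manifest, "interaction",
                           c(o("interactions.tsv"), o("calls.tsv")))
  }

  if (isTRUE(config$stages$coloc)) {
    msg("stage coloc")
    pc <- pr$coloc
    gwas <- read_tsv_table(config$inputs$gwas)
    assoc <- read_tsv_table(o("associations.tsv"))
    coloc_tab <- do.call(rbind, lapply(unique(gwas$locus), function(l) {
      gl <- gwas[gwas$locus == l, , drop = FALSE]
      el <- assoc[assoc$gene == l & !is.na(assoc$se), c("variant", "beta", "se")]
      if (nrow(el) == 0L) return(NULL)
      cp <- colocalize_locus(el, gl,
                             gwas_trait_type = gl$trait_type[1] %||% "quantitative",
                             p1 = pc$p1, p2 = pc$p2, p12 = pc$p12)
      cbind(data.frame(locus = l, stringsAsFactors = FALSE), cp)
    }))
    write_tsv_table(coloc_tab, o("coloc.tsv"))
    files <- o("coloc.tsv")
    if (file.exists(o("calls.tsv"))) {
      calls <- read_tsv_table(o("calls.tsv"))
      calls$passing_types[is.na(calls$passing_types)] <- ""
      enr <- enrichment_scan(coloc_tab, calls, pc$assoc_fdr)
      write_tsv_table(enr, o("enrichment.tsv"))
      files <- c(files, o("enrichment.tsv"))
    }
    manifest <- .stage_log(manifest, "coloc", files)
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  skipped <- names(Filter(function(x) !isTRUE(x), config$stages))
  manifest$skipped_stages <- if (length(skipped)) skipped else list()
  jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
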