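#' Filter low-quality cells
#'
#' Removes cells with fewer than \code{min_genes} detected genes or fewer than
#' \code{min_umi} total counts. Defaults follow the liver QC thresholds
#' (500 detected genes, 1000 UMI); skin-style QC corresponds to
#' \code{min_genes = 200, min_umi = 0}. The gene set is unchanged.
#'
#' @param sc \code{sc_dataset} with counts
#' @param min_genes minimum detected (nonzero) genes per cell
#' @param min_umi minimum total counts per cell
#' @return filtered \code{sc_dataset}
#' @export
filter_cells <- function(sc, min_genes = 500L, min_umi = 1000L) {
  stopifnot(inherits(sc, "sc_dataset"))
  detected <- colSums(sc$counts > 0)
  total <- colSums(sc$counts)
  keep <- detected >= min_genes & total >= min_umi
  if (!any(keep)) stop("all cells removed by QC thresholds")
  sc$counts <- sc$counts[, keep, drop = FALSE]
  sc$cell_labels <- sc$cell_labels[keep]
  if (!is.null(sc$normalized))
    sc$normalized <- sc$normalized[, keep, drop = FALSE]
  sc
}

#' Log-normalize single-cell counts
#'
#' Per cell, counts are scaled to a common total (\code{scale_total}) and
#' transformed as \code{log(1 + x)}; stored as the \code{normalized} layer.
#'
#' @param sc \code{sc_dataset} with counts and no normalized layer
#' @param scale_total per-cell library-size target (default 10000)
#' @return \code{sc_dataset} with the normalized layer filled
#' @export
lognormalize <- function(sc, scale_total = 1e4) {
  stopifnot(inherits(sc, "sc_dataset"))
  if (!is.null(sc$normalized))
    stop("dataset already has a normalized layer; lognormalize is not idempotent")
  tot <- colSums(sc$counts)
  if (any(tot == 0))
    stop("zero-count cell(s) present; filter_cells() first")
  sc$normalized <- log1p(sweep(sc$counts, 2, tot / scale_total, "/"))
  sc
}

#' Highly variable genes by standardized log dispersion
#'
#' Genes are placed into 20 equal-frequency bins of mean normalized
#' expression; within each bin the log dispersion (variance/mean) is
#' z-scored, and genes whose z-score exceeds \code{dispersion_threshold}
#' (default 0.5) are returned.
#'
#' @param sc \code{sc_dataset} with a normalized layer
#' @param dispersion_threshold z-score cutoff
#' @param n_bins number of mean-expression bins
#' @return character vector of gene ids
#' @export
variable_genes <- function(sc, dispersion_threshold = 0.5, n_bins = 20L) {
  stopifnot(inherits(sc, "sc_dataset"))
  if (is.null(sc$normalized)) stop("normalized layer required")
  m <- rowMeans(sc$normalized)
  v <- apply(sc$normalized, 1, stats::var)
  disp <- ifelse(m > 0, v / m, 0)
  ldisp <- log(disp + 1e-12)
  if (nrow(sc$normalized) < n_bins) {
    warning("fewer genes than bins; using a single bin")
    bins <- rep(1L, length(m))
  } else {
    qs <- unique(stats::quantile(m, probs = seq(0, 1, length.out = n_bins + 1L)))
    bins <- if (length(qs) < 2L) rep(1L, length(m))
            else cut(m, breaks = qs, include.lowest = TRUE, labels = FALSE)
  }
  z <- stats::ave(ldisp, bins, FUN = function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  rownames(sc$normalized)[z > dispersion_threshold]
}

# Vectorized two-sided Wilcoxon rank-sum over the rows of m (normal
# approximation, tie-corrected, continuity-corrected) -- same statistic as
# stats::wilcox.test(exact = FALSE). Ranks and tie corrections are computed
# once per gene because one-vs-rest marker testing reuses them across types.
.rank_sum_prep <- function(m) {
  ranks <- t(apply(m, 1, rank))
  ties <- apply(m, 1, function(x) {
    tt <- tabulate(match(x, unique(x)))
    sum(tt^3 - tt)
  })
  list(ranks = ranks, ties = ties, n = ncol(m))
}

.rank_sum_p <- function(prep, in_group) {
  n <- prep$n
  n1 <- sum(in_group); n2 <- n - n1
  W <- rowSums(prep$ranks[, in_group, drop = FALSE]) - n1 * (n1 + 1) / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - prep$ties / (n * (n - 1)))
  z <- W - n1 * n2 / 2
  zc <- pmax(0, abs(z) - 0.5)  # continuity correction
  p <- 2 * stats::pnorm(zc / sqrt(sigma2), lower.tail = FALSE)
  p[sigma2 <= 0] <- 1
  pmin(1, unname(p))
}

#' One-vs-rest marker ranking
#'
#' For each cell type and each gene, tests in-type versus all other cells on
#' the normalized layer with a two-sided Wilcoxon rank-sum test, and computes
#' \code{avg_log2fc = log2(mean(expm1(in)) + 1) - log2(mean(expm1(rest)) + 1)}.
#' P-values are Benjamini-Hochberg adjusted within each cell type.
#'
#' @param sc \code{sc_dataset} with a normalized layer
#' @param min_cells cell types with fewer cells are skipped with a warning
#' @return \code{data.frame} (class \code{de_table}) with columns
#'   \code{cell_type, gene, avg_log2fc, p_value, adjusted_p_value}
#' @export
rank_markers <- function(sc, min_cells = 3L) {
  stopifnot(inherits(sc, "sc_dataset"))
  if (is.null(sc$normalized)) stop("normalized layer required")
  labels <- unname(sc$cell_labels)
  types <- sort(unique(labels))
  if (length(types) < 2L) stop("at least two cell types required")
  expm <- expm1(sc$normalized)
  prep <- .rank_sum_prep(sc$normalized)
  out <- vector("list", length(types))
  for (i in seq_along(types)) {
    t <- types[i]
    ing <- labels == t
    if (sum(ing) < min_cells) {
      warning(sprintf("cell type '%s' has < %d cells; skipped", t, min_cells))
      next
    }
    p <- .rank_sum_p(prep, ing)
    lfc <- log2(rowMeans(expm[, ing, drop = FALSE]) + 1) -
      log2(rowMeans(expm[, !ing, drop = FALSE]) + 1)
    out[[i]] <- data.frame(cell_type = t, gene = rownames(sc$normalized),
                           avg_log2fc = unname(lfc), p_value = p,
                           adjusted_p_value = stats::p.adjust(p, "BH"),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  class(res) <- c("de_table", "data.frame")
  res
}

#' Select per-type signature genes from a marker table
#'
#' Keeps, per cell type, genes with \code{adjusted_p_value < max_adj_p} and
#' \code{avg_log2fc > min_lfc}, sorted by ascending p-value (ties: larger
#' fold change first, then gene id), truncated to the \code{top_n} most
#' significant.
#'
#' @param de marker table from \code{\link{rank_markers}}
#' @param top_n maximum genes per type (default 200)
#' @param max_adj_p adjusted p-value cutoff (default 0.05)
#' @param min_lfc average log2 fold-change cutoff (default 0.25)
#' @return named list cell type -> ordered character vector of gene ids
#' @export
select_signature_genes <- function(de, top_n = 200L, max_adj_p = 0.05,
                                   min_lfc = 0.25) {
  if (nrow(de) == 0L) stop("empty marker table")
  types <- sort(unique(de$cell_type))
  out <- lapply(types, function(t) {
    d <- de[de$cell_type == t & de$adjusted_p_value < max_adj_p &
              de$avg_log2fc > min_lfc, , drop = FALSE]
    if (nrow(d) == 0L) return(character())
    d <- d[order(d$p_value, -d$avg_log2fc, d$gene), , drop = FALSE]
    utils::head(d$gene, top_n)
  })
  names(out) <- types
  out
}

#' Map signature gene sets through an ortholog table
#'
#' Applies, in rank order within each set: (1) genes without a target are
#' dropped; (2) a source with several targets keeps exactly one, the
#' lexicographically first target id; (3) after mapping, duplicate targets
#' are removed keeping the first (most significant) occurrence.
#'
#' @param sig named list of ordered gene vectors
#' @param ortholog_map data.frame with columns \code{source}, \code{target}
#'   (NA target = unmapped)
#' @return named list of mapped, deduplicated, rank-ordered gene vectors
#' @export
map_orthologs <- function(sig, ortholog_map) {
  stopifnot(is.list(sig), all(c("source", "target") %in% names(ortholog_map)))
  mp <- ortholog_map[!is.na(ortholog_map$target), c("source", "target")]
  pick <- function(g) {
    tg <- sort(mp$target[mp$source == g])
    if (length(tg) == 0L) NA_character_ else tg[1L]
  }
  lapply(sig, function(genes) {
    if (length(genes) == 0L) return(character())
    mapped <- vapply(genes, pick, "")
    mapped <- mapped[!is.na(mapped)]
    unname(mapped[!duplicated(mapped)])
  })
}

#' Build a signature matrix of mean normalized expression
#'
#' Entry (g, t) is the mean normalized expression of signature gene g over
#' the cells labeled t; rows are the union of all signature sets.
#'
#' @param sc \code{sc_dataset} with a normalized layer
#' @param sig named list of signature gene vectors (all present in \code{sc})
#' @param resolution provenance tag ("high", "collapsed" or "low")
#' @return genes x cell types numeric matrix with a \code{resolution} attribute
#' @export
build_signature_matrix <- function(sc, sig, resolution = "high") {
  stopifnot(inherits(sc, "sc_dataset"))
  if (is.null(sc$normalized)) stop("normalized layer required")
  genes <- unique(unlist(sig, use.names = FALSE))
  missing <- setdiff(genes, rownames(sc$normalized))
  if (length(missing))
    stop(sprintf("signature genes absent from dataset: %s",
                 paste(missing, collapse = ", ")))
  labels <- unname(sc$cell_labels)
  types <- sort(unique(labels))
  S <- vapply(types, function(t)
    rowMeans(sc$normalized[genes, labels == t, drop = FALSE]),
    numeric(length(genes)))
  S <- matrix(S, nrow = length(genes), dimnames = list(genes, types))
  attr(S, "resolution") <- resolution
  S
}

#' Collapse composition estimates into broader classes
#'
#' Sums the fraction columns of fine-grained cell types that map to the same
#' collapsed class; per-sample sums are preserved exactly.
#'
#' @param comp \code{composition_matrix} (see \code{\link{deconvolute}}) or a
#'   bare samples x types matrix
#' @param collapse_map named character vector or two-column data.frame mapping
#'   every fine type to a collapsed class
#' @return same shape of object with collapsed columns and the
#'   \code{resolution} tag set to "collapsed"
#' @export
collapse_compositions <- function(comp, collapse_map) {
  if (is.data.frame(collapse_map))
    collapse_map <- stats::setNames(collapse_map[[2]], collapse_map[[1]])
  frac <- if (inherits(comp, "composition_matrix")) comp$fractions else as.matrix(comp)
  unmapped <- setdiff(colnames(frac), names(collapse_map))
  if (length(unmapped))
    stop(sprintf("collapse map does not cover: %s", paste(unmapped, collapse = ", ")))
  classes <- collapse_map[colnames(frac)]
  uc <- unique(unname(classes))
  out <- vapply(uc, function(k)
    rowSums(frac[, classes == k, drop = FALSE]), numeric(nrow(frac)))
  out <- matrix(out, nrow = nrow(frac), dimnames = list(rownames(frac), uc))
  if (inherits(comp, "composition_matrix")) {
    comp$fractions <- out
    comp$resolution <- "collapsed"
    comp
  } else out
}
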