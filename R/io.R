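# File IO: all tables are tab-delimited with a header row and ids in
# column 1. Matrices are written with the id column named explicitly so a
# write -> read -> write round trip is byte-identical.

#' Write / read a data.frame as TSV
#' @param x data.frame
#' @param path file path
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write / read a numeric matrix as TSV with row ids in column 1
#' @param m matrix with rownames
#' @param path file path
#' @param id name of the id column (default "gene")
#' @export
write_matrix_tsv <- function(m, path, id = "gene") {
  df <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  names(df)[1] <- id
  write_tsv_table(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a single-cell dataset as counts TSV + label TSV
#' @param sc \code{sc_dataset}
#' @param counts_path,labels_path output paths
#' @param layer "counts" (default) or "normalized"
#' @export
write_sc_dataset <- function(sc, counts_path, labels_path,
                             layer = c("counts", "normalized")) {
  layer <- match.arg(layer)
  write_matrix_tsv(sc[[layer]], counts_path, id = "gene")
  write_tsv_table(data.frame(cell = colnames(sc$counts),
                             cell_type = unname(sc$cell_labels)),
                  labels_path)
  invisible(NULL)
}

#' Read a single-cell dataset from counts (TSV or MatrixMarket) + labels TSV
#'
#' For MatrixMarket input (\code{.mtx}), gene and cell ids are read from the
#' sibling files \code{<prefix>_genes.tsv} and \code{<prefix>_cells.tsv}
#' (one id per line, no header).
#'
#' @param counts_path counts file (genes x cells)
#' @param labels_path two-column TSV (cell, cell_type)
#' @param species_tag free-text provenance tag
#' @return \code{sc_dataset}
#' @export
read_sc_dataset <- function(counts_path, labels_path, species_tag = "unknown") {
  if (grepl("\\.mtx$", counts_path)) {
    m <- as.matrix(Matrix::readMM(counts_path))
    prefix <- sub("\\.mtx$", "", counts_path)
    rownames(m) <- readLines(paste0(prefix, "_genes.tsv"))
    colnames(m) <- readLines(paste0(prefix, "_cells.tsv"))
  } else {
    m <- read_matrix_tsv(counts_path)
  }
  lab <- read_tsv_table(labels_path)
  if (!all(colnames(m) %in% lab$cell)) stop("label file does not cover all cells")
  labels <- stats::setNames(lab$cell_type[match(colnames(m), lab$cell)],
                            colnames(m))
  structure(list(counts = m, genes = rownames(m), cell_labels = labels,
                 normalized = NULL, species_tag = species_tag),
            class = "sc_dataset")
}

#' Write genotypes as minimal VCF 4.2
#'
#' Unphased GT-only records; dosage 0/1/2 becomes 0/0, 0/1, 1/1; NA becomes
#' ./..
#'
#' @param dosages variants x individuals matrix in \{0,1,2,NA\}
#' @param variants data.frame \code{variant, chrom, pos, ref, alt}
#' @param path output path
#' @export
write_vcf <- function(dosages, variants, path) {
  stopifnot(nrow(dosages) == nrow(variants))
  gt <- matrix(c("0/0", "0/1", "1/1")[as.matrix(dosages) + 1L], nrow(dosages))
  gt[is.na(gt)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(dosages)), collapse = "\t")),
             con)
  body <- cbind(variants$chrom, variants$pos, variants$variant, variants$ref,
                variants$alt, ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read dosages and a variant table from a VCF
#'
#' GT fields are converted to alt-allele dosages (missing calls to NA); MAF
#' is computed from non-missing calls.
#'
#' @param path VCF file (plain text or gzipped)
#' @return list with \code{dosages} (variants x individuals) and
#'   \code{variants} (\code{variant, chrom, pos, ref, alt, maf})
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x) & !grepl("\\.", x)
    out[ok] <- vapply(strsplit(gsub("\\|", "/", x[ok]), "/"),
                      function(a) sum(a == "1"), 0)
    out
  }
  dos <- t(apply(gt, 1, count_alt))
  colnames(dos) <- colnames(gt)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  af <- rowMeans(dos, na.rm = TRUE) / 2
  variants <- data.frame(variant = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, maf = pmin(af, 1 - af),
                         stringsAsFactors = FALSE)
  rownames(dos) <- variants$variant
  list(dosages = dos, variants = variants)
}

#' Read gene annotation as anchor TSV or BED
#'
#' TSV dialect: columns \code{gene, chrom, anchor} with a 1-based anchor.
#' BED dialect: 0-based half-open \code{chrom start end name}; the anchor is
#' the 1-based start (TSS for + strand annotations).
#'
#' @param path file path
#' @param format "tsv" or "bed"
#' @return data.frame \code{gene, chrom, anchor}
#' @export
read_gene_annot <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    an <- read_tsv_table(path)
    stopifnot(all(c("gene", "chrom", "anchor") %in% names(an)))
    an[, c("gene", "chrom", "anchor")]
  } else {
    bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    data.frame(gene = bed[[4]], chrom = as.character(bed[[1]]),
               anchor = bed[[2]] + 1L, stringsAsFactors = FALSE)
  }
}

#' Write signature gene sets as a rank table
#' @param sig named list of ordered gene vectors
#' @param path output TSV (columns cell_type, rank, gene)
#' @export
write_signature_sets <- function(sig, path) {
  rows <- lapply(names(sig), function(t) {
    if (length(sig[[t]]) == 0L) return(NULL)
    data.frame(cell_type = t, rank = seq_along(sig[[t]]), gene = sig[[t]],
               stringsAsFactors = FALSE)
  })
  write_tsv_table(do.call(rbind, rows), path)
}

#' @rdname write_signature_sets
#' @export
read_signature_sets <- function(path) {
  df <- read_tsv_table(path)
  lapply(split(df, df$cell_type), function(d) d$gene[order(d$rank)])
}

#' Write a composition matrix with its fit statistics
#' @param comp \code{composition_matrix}
#' @param path output TSV (sample, one column per type, p_value, r, rmse)
#' @export
write_composition <- function(comp, path) {
  df <- data.frame(sample = rownames(comp$fractions),
                   as.data.frame(comp$fractions, check.names = FALSE),
                   p_value = comp$p_value, r = comp$r, rmse = comp$rmse,
                   check.names = FALSE)
  write_tsv_table(df, path)
}

#' @rdname write_composition
#' @export
read_composition <- function(path) {
  df <- read_tsv_table(path)
  tcols <- setdiff(names(df), c("sample", "p_value", "r", "rmse"))
  frac <- as.matrix(df[, tcols, drop = FALSE])
  rownames(frac) <- df$sample
  structure(list(fractions = frac, p_value = df$p_value, r = df$r,
                 rmse = df$rmse, nu = NULL, method = "file",
                 resolution = "file"),
            class = "composition_matrix")
}
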