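test_that("cell QC filters by detected genes and UMI, keeping the gene set", {
  sc <- simulate_scrna(2, 50, 20, 5, seed = 1)
  # zero thresholds: identity
  expect_identical(filter_cells(sc, 0, 0)$counts, sc$counts)
  # force one cell below thresholds
  sc$counts[, 1] <- 0L
  sc$counts[1, 1] <- 5L
  f <- filter_cells(sc, min_genes = 2, min_umi = 10)
  expect_equal(ncol(f$counts), 39L)
  expect_equal(nrow(f$counts), 50L)
  expect_error(filter_cells(sc, 1e6, 1e9), "all cells removed")
})

test_that("log normalization matches hand arithmetic and rejects reruns", {
  sc <- simulate_scrna(2, 2, 2, 1, seed = 1)
  sc$counts <- matrix(c(2L, 8L, 5L, 0L), 2, 2,
                      dimnames = list(c("g1", "g2"), c("c1", "c2")))
  n <- lognormalize(sc, scale_total = 10)
  expect_equal(n$normalized["g1", "c1"], log1p(2 / 10 * 10))
  expect_equal(n$normalized["g2", "c1"], log1p(8))
  expect_equal(n$normalized["g1", "c2"], log1p(10))
  expect_equal(n$normalized["g2", "c2"], 0)
  expect_error(lognormalize(n), "not idempotent")
  sc$counts[, 2] <- 0L
  expect_error(lognormalize(sc), "zero-count")
})

test_that("variable-gene selection matches a brute-force bin/z-score oracle", {
  sc <- make_tiny_sc(2, 60, 50, 5, seed = 9)
  got <- variable_genes(sc, dispersion_threshold = 0.5)
  m <- rowMeans(sc$normalized)
  v <- apply(sc$normalized, 1, var)
  ldisp <- log(ifelse(m > 0, v / m, 0) + 1e-12)
  qs <- quantile(m, seq(0, 1, length.out = 21))
  bins <- cut(m, unique(qs), include.lowest = TRUE, labels = FALSE)
  want <- character()
  for (b in unique(bins)) {
    i <- which(bins == b)
    z <- (ldisp[i] - mean(ldisp[i])) / sd(ldisp[i])
    want <- c(want, rownames(sc$normalized)[i][z > 0.5])
  }
  expect_setequal(got, want)
  expect_setequal(variable_genes(sc, -Inf), rownames(sc$normalized))
  # identical expression for all genes: nothing is variable
  flat <- sc
  flat$normalized <- matrix(1, 60, ncol(sc$normalized),
                            dimnames = dimnames(sc$normalized))
  expect_length(variable_genes(flat, 0.5), 0)
})

test_that("marker p-values agree with wilcox.test and rank planted markers first", {
  sc <- make_tiny_sc(2, 30, 25, 4, lfc = 3, seed = 21)
  de <- rank_markers(sc)
  ing <- unname(sc$cell_labels) == "CT1"
  for (g in rownames(sc$normalized)[c(1, 7, 20, 30)]) {
    w <- wilcox.test(sc$normalized[g, ing], sc$normalized[g, !ing],
                     exact = FALSE, correct = TRUE)
    expect_equal(de$p_value[de$cell_type == "CT1" & de$gene == g],
                 w$p.value, tolerance = 1e-10)
  }
  # planted markers rank at the top of their own type
  sig <- select_signature_genes(de, top_n = 10)
  expect_true(all(sc$marker_truth$CT1 %in% sig$CT1))
  expect_true(all(sc$marker_truth$CT2 %in% sig$CT2))
  expect_true(all(de$adjusted_p_value >= de$p_value))
})

test_that("label permutation calibrates marker p-values", {
  sc <- make_tiny_sc(2, 1000, 150, 10, lfc = 0, seed = 31)
  de <- rank_markers(sc)
  p <- de$p_value[de$cell_type == "CT1"]
  frac_sig <- mean(de$adjusted_p_value < 0.05)
  expect_lte(frac_sig, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(de)))
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("signature selection equals brute-force filter/sort/truncate and is order-invariant", {
  set.seed(42)
  de <- data.frame(
    cell_type = sample(c("A", "B"), 300, TRUE),
    gene = sprintf("g%03d", sample(300)),
    avg_log2fc = round(runif(300, -1, 2), 2),
    p_value = round(runif(300)^2, 4), stringsAsFactors = FALSE)
  de$adjusted_p_value <- pmin(1, de$p_value * 1.5)
  got <- select_signature_genes(de, top_n = 20, max_adj_p = 0.3, min_lfc = 0.25)
  for (t in c("A", "B")) {
    d <- de[de$cell_type == t & de$adjusted_p_value < 0.3 & de$avg_log2fc > 0.25, ]
    d <- d[order(d$p_value, -d$avg_log2fc, d$gene), ]
    expect_identical(got[[t]], head(d$gene, 20))
  }
  shuf <- de[sample(nrow(de)), ]
  expect_identical(select_signature_genes(shuf, 20, 0.3, 0.25), got)
  expect_error(select_signature_genes(de[0, ]), "empty")
})

test_that("ortholog mapping applies drop/pick-one/dedup rules in rank order", {
  sig <- list(A = c("m1", "m2", "m3", "m4", "m5"))
  map <- data.frame(
    source = c("m1", "m2", "m2", "m3", "m5"),
    target = c("H1", "Hb", "Ha", "H1", NA))
  got <- map_orthologs(sig, map)
  # m1 -> H1; m2 -> Ha (lexicographic first); m3 -> H1 (duplicate, dropped);
  # m4 unmapped; m5 target NA
  expect_identical(got$A, c("H1", "Ha"))
  # identity map leaves sets unchanged
  idm <- data.frame(source = sig$A, target = sig$A)
  expect_identical(map_orthologs(sig, idm)$A, sig$A)
  # fully unmapped set becomes empty
  expect_identical(map_orthologs(sig, data.frame(source = "x", target = "y"))$A,
                   character())
  # no duplicates, ever (property over random maps)
  for (s in 1:20) {
    m <- simulate_ortholog_map(sig$A, 0.4, 0.4, 0.2, seed = s)
    out <- map_orthologs(sig, m)$A
    expect_equal(anyDuplicated(out), 0L)
  }
})

test_that("signature matrix equals per-type means and flags missing genes", {
  sc <- make_tiny_sc(3, 40, 10, 4, seed = 2)
  sig <- list(CT1 = rownames(sc$normalized)[1:5],
              CT2 = rownames(sc$normalized)[6:10])
  S <- build_signature_matrix(sc, sig)
  labels <- unname(sc$cell_labels)
  for (g in rownames(S)) for (t in colnames(S)) {
    vals <- sc$normalized[g, labels == t]
    expect_equal(S[g, t], sum(vals) / length(vals))
  }
  expect_error(build_signature_matrix(sc, list(A = "nope")), "nope")
  # planted markers peak in their own type's column
  de <- rank_markers(sc)
  sg <- select_signature_genes(de, top_n = 4)
  Sm <- build_signature_matrix(sc, sg)
  for (t in names(sg)) for (g in intersect(sg[[t]], unlist(sc$marker_truth[t])))
    expect_equal(colnames(Sm)[which.max(Sm[g, ])], t)
})

test_that("composition collapsing sums member columns and preserves row sums", {
  set.seed(5)
  frac <- simulate_compositions(20, sprintf("T%d", 1:6), seed = 5)
  cmap <- c(T1 = "X", T2 = "X", T3 = "Y", T4 = "Y", T5 = "Y", T6 = "Z")
  out <- collapse_compositions(frac, cmap)
  expect_equal(out[, "X"], frac[, "T1"] + frac[, "T2"])
  expect_equal(out[, "Y"], rowSums(frac[, c("T3", "T4", "T5")]))
  expect_true(all(abs(rowSums(out) - rowSums(frac)) < 1e-12))
  # identity and all-to-one maps
  idm <- setNames(colnames(frac), colnames(frac))
  expect_equal(collapse_compositions(frac, idm)[, colnames(frac)], frac)
  allm <- setNames(rep("all", 6), colnames(frac))
  expect_true(all(abs(collapse_compositions(frac, allm) - 1) < 1e-12))
  expect_error(collapse_compositions(frac, cmap[-1]), "cover")
})
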