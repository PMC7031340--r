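test_that("expression filter matches a counting oracle", {
  set.seed(1)
  tpm <- matrix(rexp(100, 1), 10, 10,
                dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:10)))
  tpm[1, ] <- 0
  got <- filter_expressed_genes(tpm, 0.5, 0.2)
  want <- character()
  for (g in rownames(tpm))
    if (sum(tpm[g, ] > 0.5) >= 0.2 * 10) want <- c(want, g)
  expect_identical(got, want)
  expect_false("g01" %in% got)   # all-zero gene dropped
})

test_that("inverse-normal transform matches Blom quantiles and rank invariance", {
  x <- matrix(c(5, 1, 9), 1, dimnames = list("g", c("a", "b", "c")))
  got <- quantile_normalize(rbind(x, x))  # needs >= 2 rows only for generality
  want <- qnorm((c(2, 1, 3) - 3 / 8) / (3 + 1 / 4))
  expect_equal(unname(got[1, ]), want)
  # monotone transform of a gene leaves its output unchanged
  set.seed(3)
  m <- matrix(rnorm(200), 2, 100)
  expect_equal(quantile_normalize(exp(m)), quantile_normalize(m))
  # output per gene is a permutation of the fixed reference quantile vector
  q <- quantile_normalize(m)
  ref <- sort(qnorm((seq_len(100) - 3 / 8) / (100 + 1 / 4)))
  expect_equal(sort(q[1, ]), ref)
  expect_equal(sort(q[2, ]), ref)
  # already-normal gene barely changes
  z <- matrix(rnorm(2000), 2, 1000)
  qz <- quantile_normalize(z)
  expect_gte(cor(z[1, ], qz[1, ]), 0.99)
  expect_warning(quantile_normalize(rbind(m, 0)), "constant")
})

test_that("genotype PCs reproduce the eigendecomposition after pruning", {
  set.seed(9)
  dos <- matrix(rbinom(50 * 20, 2, 0.3), 50, 20,
                dimnames = list(sprintf("v%02d", 1:50), sprintf("i%02d", 1:20)))
  dos[3, ] <- dos[2, ]   # identical pair: one must be pruned
  pcs <- genotype_pcs(dos, n_pcs = 4, prune_r2 = 0.95)
  G <- t(dos[decoqtl:::.ld_prune(dos, 0.95, 50), ])
  G <- scale(G, center = TRUE, scale = FALSE)
  ev <- eigen(tcrossprod(G))
  for (k in 1:4) {
    v <- ev$vectors[, k] * sqrt(ev$values[k])
    expect_equal(abs(sum(pcs[, k] * v)) / sum(v * v), 1, tolerance = 1e-8)
  }
  expect_error(genotype_pcs(dos[1:3, ], n_pcs = 5), "fewer")
  # missing dosages are mean-imputed, not fatal
  dos[5, 2] <- NA
  expect_silent(genotype_pcs(dos, n_pcs = 2, prune_r2 = 0.95))
})

test_that("cis window is closed, MAF-strict, and matches a scan oracle", {
  vt <- data.frame(variant = sprintf("v%d", 1:6), chrom = c(rep("1", 5), "2"),
                   pos = c(1e6, 2e6, 3e6, 3e6 + 1, 5e5, 2e6),
                   maf = c(0.2, 0.2, 0.2, 0.2, 0.01, 0.2))
  g <- data.frame(gene = "g", chrom = "1", anchor = 2e6)
  got <- cis_variants(g, vt, window = 1e6, maf_min = 0.01)
  # v1 and v3 at exactly anchor +/- window: included; v4 one past: excluded;
  # v5 at MAF exactly 0.01: excluded (strict); v6 wrong chromosome
  expect_setequal(got, c("v1", "v2", "v3"))
  want <- character()
  for (i in seq_len(nrow(vt)))
    if (vt$chrom[i] == "1" && abs(vt$pos[i] - 2e6) <= 1e6 && vt$maf[i] > 0.01)
      want <- c(want, vt$variant[i])
  expect_setequal(got, want)
})

test_that("association fit equals closed-form OLS and flips with the allele", {
  set.seed(21)
  n <- 60
  d <- rbinom(n, 2, 0.4)
  cov <- data.frame(age = rnorm(n, 50, 8), sex = rbinom(n, 1, 0.5))
  y <- 1 + 0.7 * d + 0.02 * cov$age + rnorm(n)
  got <- fit_association(y, d, cov)
  X <- cbind(1, d, cov$age, cov$sex)
  bh <- solve(crossprod(X), crossprod(X, y))
  expect_equal(got$beta, bh[2], tolerance = 1e-8)
  s2 <- sum((y - X %*% bh)^2) / (n - ncol(X))
  expect_equal(got$se, sqrt(s2 * solve(crossprod(X))[2, 2]), tolerance = 1e-8)
  # allele flip: beta changes sign, p unchanged
  flip <- fit_association(y, 2 - d, cov)
  expect_equal(flip$beta, -got$beta, tolerance = 1e-8)
  expect_equal(flip$p, got$p, tolerance = 1e-8)
  # constant expression
  cst <- fit_association(rep(2, n), d, NULL)
  expect_equal(cst$beta, 0)
  expect_equal(cst$p, 1)
  # constant dosage is a skip signal, singular covariates an error
  expect_equal(fit_association(y, rep(1, n), cov)$method,
               "skipped_constant_dosage")
  cov2 <- cov; cov2$age2 <- cov$age
  expect_error(fit_association(y, d, cov2), "singular")
})

test_that("random intercept absorbs duplicated samples", {
  set.seed(4)
  n <- 40
  d <- rbinom(n, 2, 0.3)
  y <- 0.5 * d + rnorm(n)
  base <- fit_association(y, d, NULL)
  dup <- fit_association(rep(y, 2), rep(d, 2), NULL,
                         grouping = factor(rep(seq_len(n), 2)))
  expect_equal(dup$method, "lmm")
  expect_equal(dup$beta, base$beta, tolerance = 1e-4)
})

test_that("planted effects are recovered without bias", {
  est <- replicate(200, {
    d <- rbinom(300, 2, 0.3)
    y <- 0.5 * d + rnorm(300)
    fit_association(y, d, NULL)$beta
  })
  mc_se <- sd(est) / sqrt(200)
  expect_lt(abs(mean(est) - 0.5), 2 * mc_se)
})

test_that("lead selection and eGene calling follow Bonferroni-then-BH", {
  a <- data.frame(gene = c("g1", "g2", "g3"),
                  variant = c("v1", "v2", "v3"), pos = 1:3,
                  beta = 0.1, se = 0.1,
                  p = c(0.001, 0.02, 0.9))
  leads <- lead_and_call_egenes(a, fdr_level = 0.10)
  expect_equal(leads$p_bonferroni, c(0.001, 0.02, 0.9))
  expect_equal(leads$q_value, c(0.003, 0.03, 0.9))
  expect_equal(sum(leads$egene), 2L)
  # Bonferroni multiplies by per-gene variant count; BH equals brute force
  set.seed(6)
  big <- data.frame(gene = rep(sprintf("g%02d", 1:20), each = 5),
                    variant = sprintf("v%03d", 1:100), pos = rep(1:5, 20),
                    beta = 0, se = 1, p = runif(100)^1.5)
  lg <- lead_and_call_egenes(big)
  for (g in lg$gene) {
    d <- big[big$gene == g, ]
    expect_equal(lg$n_tested[lg$gene == g], 5L)
    expect_equal(lg$p_bonferroni[lg$gene == g], min(pmin(1, d$p * 5)))
  }
  expect_equal(lg$q_value, bh_bruteforce(lg$p_bonferroni))
  expect_true(all(lg$q_value >= lg$p_bonferroni))
  # all nominal p = 1: zero eGenes
  a$p <- 1
  expect_equal(sum(lead_and_call_egenes(a)$egene), 0L)
})

test_that("composition covariates change statistics but never the tested set", {
  comp <- simulate_compositions(80, c("A", "B", "C"), seed = 5)
  co <- simulate_eqtl_cohort(80, n_genes = 2, n_variants_per_gene = 8,
                             compositions = comp, seed = 11)
  qn <- quantile_normalize(co$expression)
  base_cov <- data.frame(age = co$covariates$age, sex = co$covariates$sex)
  a1 <- map_cis_associations(qn, co$dosages, co$genes, co$variants,
                             covariates = base_cov,
                             sample_individual = co$sample_map$individual)
  with_comp <- cbind(base_cov, comp_A = comp[, "A"], comp_B = comp[, "B"])
  a2 <- map_cis_associations(qn, co$dosages, co$genes, co$variants,
                             covariates = with_comp,
                             sample_individual = co$sample_map$individual)
  expect_identical(a1[, c("gene", "variant")], a2[, c("gene", "variant")])
  expect_false(identical(a1$p, a2$p))
})

test_that("lead calls are calibrated under a global null", {
  co <- simulate_eqtl_cohort(200, n_genes = 300, n_variants_per_gene = 6,
                             maf_range = c(0.1, 0.5), seed = 17)
  qn <- quantile_normalize(co$expression)
  a <- map_cis_associations(qn, co$dosages, co$genes, co$variants,
                            sample_individual = co$sample_map$individual)
  leads <- lead_and_call_egenes(a)
  frac <- mean(leads$p_bonferroni < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(leads)))
})
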