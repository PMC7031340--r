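sim_int_gene <- function(n = 300, gamma = 0, beta = 0.3, seed = 1,
                         k_types = 3) {
  set.seed(seed)
  comp <- simulate_compositions(n, sprintf("CT%d", seq_len(k_types)),
                                seed = seed)
  d <- rbinom(n, 2, 0.3)
  y <- 1 + beta * d + 0.5 * comp[, 1] + gamma * d * comp[, 2] + rnorm(n)
  list(y = y, d = d, comp = comp)
}

test_that("chi-squared is nonnegative and dAIC = 2 - chisq to 1e-8", {
  for (s in 1:10) {
    g <- sim_int_gene(120, gamma = runif(1, 0, 2), seed = s)
    r <- interaction_test(g$y, g$d, NULL, g$comp, "CT2")
    expect_gte(r$chisq, 0)
    expect_equal(r$delta_aic, 2 - r$chisq, tolerance = 1e-8)
  }
  # same identity under a random-intercept fit on genuine replicates
  set.seed(3)
  n <- 80
  comp <- simulate_compositions(n, c("CT1", "CT2", "CT3"), seed = 3)
  d <- rbinom(n, 2, 0.3)
  u <- rnorm(n, 0, 0.8)                       # individual intercepts
  mu <- 0.3 * d + 1.5 * d * comp[, "CT2"] + u
  y2 <- rep(mu, 2) + rnorm(2 * n, 0, 0.5)     # two samples per individual
  r <- interaction_test(y2, rep(d, 2), NULL, rbind(comp, comp), "CT2",
                        grouping = factor(rep(seq_len(n), 2)))
  expect_true(r$converged)
  expect_equal(r$delta_aic, 2 - r$chisq, tolerance = 1e-8)
  expect_equal(r$gamma, 1.5, tolerance = 0.5)
  expect_error(interaction_test(g$y, g$d, NULL,
                                cbind(g$comp[, 1:2], CTc = 0.2), "CTc"),
               "constant")
})

test_that("interaction p-values are uniform under the null", {
  p <- vapply(1:200, function(s) {
    g <- sim_int_gene(300, gamma = 0, seed = s)
    interaction_test(g$y, g$d, NULL, g$comp, "CT2")$p
  }, 0)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  t1 <- mean(p < 0.05)
  expect_lt(t1, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("strong planted interactions are detected with correct type", {
  hits <- 0L; best <- 0L
  for (s in 1:50) {
    g <- sim_int_gene(300, gamma = 2, seed = 1000 + s)
    res <- interaction_scan("g", "v", g$y, g$d, NULL, g$comp)
    cl <- classify_cell_type_calls(res, fdr_level = 0.1)
    if (cl$associated && grepl("CT2", cl$passing_types)) hits <- hits + 1L
    if (cl$best_cell_type == "CT2") best <- best + 1L
  }
  expect_gte(hits, 45L)
  expect_gte(best, 40L)
})

test_that("power rises with the planted interaction strength", {
  grid <- c(0.5, 1, 1.5, 2)
  power <- vapply(grid, function(gam) {
    mean(vapply(1:60, function(s) {
      g <- sim_int_gene(300, gamma = gam, seed = 5000 + s * 7 + round(gam * 100))
      interaction_test(g$y, g$d, NULL, g$comp, "CT2")$p < 0.05
    }, TRUE))
  }, 0)
  inversions <- sum(diff(power) < -0.05)
  expect_lte(inversions, 1L)
  expect_gt(power[4], power[1])
})

test_that("classification enumerates passing types per gene", {
  # delta_aic values consistent with the 1-df identity dAIC = 2 - chisq
  res <- data.frame(
    gene = c("gA", "gA", "gA", "gB", "gB", "gC", "gC"),
    cell_type = c("T1", "T2", "T3", "T1", "T2", "T1", "T2"),
    p = c(1e-6, 1e-5, 0.5, 1e-4, 0.9, 0.4, 0.6),
    delta_aic = c(-20, -15, 1.5, -12, 1.98, 1.3, 1.7),
    converged = TRUE)
  calls <- classify_cell_type_calls(res, fdr_level = 0.1)
  gA <- calls[calls$gene == "gA", ]
  expect_true(gA$associated); expect_false(gA$specific)
  expect_equal(gA$n_passing, 2L)
  gB <- calls[calls$gene == "gB", ]
  expect_true(gB$associated); expect_true(gB$specific)
  expect_equal(gB$passing_types, "T1")
  gC <- calls[calls$gene == "gC", ]
  expect_false(gC$associated); expect_false(gC$specific)
  # BH is over per-gene best p-values
  expect_equal(sort(unique(calls$adj_p)),
               sort(bh_bruteforce(c(1e-6, 1e-4, 0.4))))
  # invariance to cell-type (row) ordering
  calls2 <- classify_cell_type_calls(res[sample(nrow(res)), ], 0.1)
  expect_equal(calls, calls2)
  # specific implies associated, always
  expect_true(all(!calls$specific | calls$associated))
})

test_that("abundance bias check detects proportional calls and nulls", {
  frac <- simulate_compositions(50, sprintf("T%d", 1:5), alpha = c(5, 4, 3, 2, 1),
                                seed = 2)
  mk_calls <- function(counts) {
    data.frame(gene = sprintf("g%d", seq_len(sum(counts))),
               adj_p = 0.01, associated = TRUE, specific = TRUE,
               passing_types = rep(sprintf("T%d", 1:5), counts))
  }
  ab <- abundance_bias_check(mk_calls(c(10, 8, 6, 4, 2)), frac)
  expect_gt(ab$rho, 0.8)
  # identical call counts: zero-variance sentinel
  ab0 <- abundance_bias_check(mk_calls(rep(4, 5)), frac)
  expect_true(is.na(ab0$rho))
  # permuted counts: small average association
  rhos <- vapply(1:30, function(s) {
    set.seed(s)
    abundance_bias_check(mk_calls(sample(c(10, 8, 6, 4, 2))), frac)$rho
  }, 0)
  expect_lt(abs(mean(rhos)), 0.35)
})

test_that("permutation check separates confounded hits from their null", {
  set.seed(30)
  n <- 150
  comp <- simulate_compositions(n, c("A", "B", "C"), seed = 30)
  n_genes <- 12
  expr <- matrix(NA_real_, n_genes, n,
                 dimnames = list(sprintf("g%d", 1:n_genes), sprintf("s%d", 1:n)))
  dos <- matrix(NA_real_, n_genes, n,
                dimnames = list(sprintf("v%d", 1:n_genes), sprintf("s%d", 1:n)))
  for (i in 1:n_genes) {
    d <- rbinom(n, 2, 0.3)
    dos[i, ] <- d
    # composition-confounded: expression depends on genotype AND composition
    expr[i, ] <- 0.4 * d + 5 * comp[, "B"] + rnorm(n, 0, 1)
  }
  hits <- data.frame(gene = rownames(expr), variant = rownames(dos))
  pc <- permutation_check(hits, expr, dos, sample_individual = colnames(dos),
                          compositions = comp, n_permutations = 30, seed = 2)
  # modeling the true composition gives smaller p than its permuted versions
  expect_lt(pc$tests$p[pc$tests$metric == "p"], 0.05)
  expect_lt(mean(pc$per_gene$p_obs), mean(pc$per_gene$p_perm))
  expect_error(permutation_check(hits, expr, dos, colnames(dos),
                                 compositions = comp, n_permutations = 1),
               "n_permutations")
})

test_that("constant compositions make permutation a no-op", {
  set.seed(31)
  n <- 60
  comp <- matrix(1 / 3, n, 3, dimnames = list(NULL, c("A", "B", "C")))
  expr <- matrix(rnorm(2 * n), 2, n,
                 dimnames = list(c("g1", "g2"), sprintf("s%d", 1:n)))
  dos <- matrix(rbinom(2 * n, 2, 0.4), 2, n,
                dimnames = list(c("v1", "v2"), sprintf("s%d", 1:n)))
  hits <- data.frame(gene = c("g1", "g2"), variant = c("v1", "v2"))
  pc <- permutation_check(hits, expr, dos, colnames(dos),
                          compositions = comp, n_permutations = 5, seed = 3)
  expect_equal(pc$per_gene$p_obs, pc$per_gene$p_perm)
  expect_equal(pc$per_gene$beta_obs, pc$per_gene$beta_perm)
  expect_true(all(pc$tests$p == 1))
})
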