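test_that("spearman_rho matches hand-computed rank correlations", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1.0)
  expect_equal(spearman_rho(1:3, c(2, 1, 3)), 0.5)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1.0)
  expect_true(is.na(spearman_rho(c(1, 1, 1), c(1, 2, 3))))
  expect_error(spearman_rho(1:3, 1:4), "equal length")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("spearman_rho agrees with the standard implementation", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (i %% 3 == 0) x <- round(x)  # induce ties
    if (length(unique(x)) < 2L) next
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("exact permutation p-values have their enumerated values", {
  expect_equal(spearman_pvalue(1, 3, "exact"), 1 / 3)
  # rho = 0 at n = 5: every permutation attains |rho| >= 0
  x <- 1:5
  y <- c(10, 50, 40, 30, 20)
  expect_equal(spearman_rho(x, y), 0)
  expect_equal(spearman_pvalue(0, 5, "exact"), 1.0)
})

test_that("exact p-values match brute-force enumeration, ties included", {
  set.seed(6)
  for (i in 1:30) {
    n <- sample(4:7, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (i > 20) {  # tied cases condition on the observed tie pattern
      x <- round(x * 2) / 2
      y <- round(y * 2) / 2
    }
    rho <- spearman_rho(x, y)
    if (is.na(rho)) next
    p <- spearman_pvalue(rho, n, "exact", rank(x), rank(y))
    expect_equal(p, oracle_spearman_exact(x, y), tolerance = 1e-12,
                 label = paste("pair", i))
  }
})

test_that("t approximation matches cor.test and handles |rho| = 1", {
  set.seed(7)
  x <- rnorm(15)
  y <- rnorm(15)
  rho <- spearman_rho(x, y)
  ct <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(spearman_pvalue(rho, 15, "t_approx"), ct$p.value,
               tolerance = 1e-6)
  expect_equal(spearman_pvalue(1, 10, "t_approx"), .Machine$double.xmin)
  expect_error(spearman_pvalue(0.5, 5, "bogus"))
})

test_that("auto method switches between exact and approximate regimes", {
  # n <= 8, no ties: exact
  expect_equal(spearman_pvalue(1, 4, "auto"), 2 / 24)
  # n > 8: t approximation
  expect_equal(spearman_pvalue(0.5, 20, "auto"),
               spearman_pvalue(0.5, 20, "t_approx"))
})

make_two_gene_net <- function(hA, hB, dA, dB) {
  genes <- c("GA", "GB")
  m <- rbind(GA = c(hA, dA), GB = c(hB, dB))
  colnames(m) <- c(paste0("H", seq_along(hA)), paste0("D", seq_along(dA)))
  expr <- expression_set(m, setNames(
    rep(c("healthy", "disease"), c(length(hA), length(dA))),
    colnames(m)))
  ppi <- ppi_network("GA", "GB", 950)
  list(expr = expr, wdrn = build_wdrn(ppi, "GA"))
}

test_that("edges are classified by the one-condition-significant rule", {
  set.seed(10)
  # disease perfectly monotone (p = 2/5040), healthy scrambled
  net <- make_two_gene_net(hA = rnorm(7), hB = rnorm(7),
                           dA = 1:7, dB = 2 * (1:7) + 3)
  ec <- classify_edges(net$wdrn, net$expr)
  expect_equal(ec$status, "gained")
  expect_equal(ec$rho_disease, 1)
  expect_lt(ec$p_disease, 0.05)
  expect_gte(ec$p_healthy, 0.05)
  expect_equal(ec$perturbation, ec$rho_disease - ec$rho_healthy)

  # significant in both conditions is not differential
  net2 <- make_two_gene_net(hA = 1:7, hB = (1:7)^2,
                            dA = 1:7, dB = 3 * (1:7))
  expect_equal(classify_edges(net2$wdrn, net2$expr)$status, "none")

  # significant in neither condition
  net3 <- make_two_gene_net(hA = rnorm(7), hB = rnorm(7),
                            dA = rnorm(7), dB = rnorm(7))
  ec3 <- classify_edges(net3$wdrn, net3$expr)
  expect_true(ec3$status %in% c("none", "gained", "lost"))
  if (ec3$p_healthy >= 0.05 && ec3$p_disease >= 0.05)
    expect_equal(ec3$status, "none")
})

test_that("degenerate inputs are tolerated, bad alpha is not", {
  net <- make_two_gene_net(hA = rep(1, 5), hB = rnorm(5),
                           dA = rnorm(5), dB = rnorm(5))
  ec <- classify_edges(net$wdrn, net$expr)
  expect_true(is.na(ec$rho_healthy))
  expect_equal(ec$status, "none")
  expect_error(classify_edges(net$wdrn, net$expr, alpha = 0), "alpha")
  expect_error(classify_edges(net$wdrn, net$expr, alpha = 1), "alpha")

  # gene missing from the expression set: edge skipped with a warning
  ppi <- ppi_network(c("GA", "GA"), c("GB", "GZ"), c(950, 950))
  wdrn <- build_wdrn(ppi, "GA")
  expect_warning(ec2 <- classify_edges(wdrn, net$expr), "skipped")
  expect_equal(nrow(ec2), 1L)
})

test_that("swapping conditions maps gained to lost and negates perturbation", {
  tis <- simulate_tissue(sim_config(n_genes = 100, n_ppi_edges = 250,
                                    seed = 31))
  w <- build_wdrn(filter_ppi(tis$ppi), tis$truth$true_degs)
  fwd <- classify_edges(w, tis$expr)
  flipped <- tis$expr
  flipped$condition <- factor(
    ifelse(flipped$condition == "healthy", "disease", "healthy"),
    levels = c("healthy", "disease"))
  rev <- classify_edges(w, flipped)
  expect_identical(rev$status[fwd$status == "gained"],
                   rep("lost", sum(fwd$status == "gained")))
  expect_identical(rev$status[fwd$status == "lost"],
                   rep("gained", sum(fwd$status == "lost")))
  expect_equal(rev$perturbation, -fwd$perturbation, tolerance = 1e-12)
})

test_that("the differential network is a DEG-adjacent subset of the WDRN", {
  tis <- simulate_tissue(sim_config(seed = 17))
  w <- build_wdrn(filter_ppi(tis$ppi), tis$truth$true_degs)
  ec <- classify_edges(w, tis$expr)
  dn <- build_dn(ec, w)
  expect_lte(nrow(dn$edges), nrow(w$edges))
  expect_true(all(pair_key(dn$edges$gene_a, dn$edges$gene_b) %in%
                    pair_key(w$edges$gene_a, w$edges$gene_b)))
  deg_nodes <- dn$nodes$gene_id[dn$nodes$is_deg]
  for (i in seq_len(nrow(dn$edges)))
    expect_true(dn$edges$gene_a[i] %in% deg_nodes ||
                  dn$edges$gene_b[i] %in% deg_nodes)

  # empty case
  empty <- build_dn(ec[ec$status == "impossible", ], w)
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(nrow(empty$nodes), 0L)
})
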