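make_expr <- function(mat_h, mat_d) {
  m <- cbind(mat_h, mat_d)
  colnames(m) <- c(paste0("H", seq_len(ncol(mat_h))),
                   paste0("D", seq_len(ncol(mat_d))))
  expression_set(m, setNames(rep(c("healthy", "disease"),
                                 c(ncol(mat_h), ncol(mat_d))),
                             colnames(m)))
}

test_that("log2 fold change is disease mean minus healthy mean", {
  h <- rbind(G1 = c(7, 7, 7), G2 = c(1, 1, 1), G3 = c(5.0, 5.4, 5.2))
  d <- rbind(G1 = c(7, 7, 7), G2 = c(2, 2, 2), G3 = c(4.0, 4.4, 4.2))
  expr <- make_expr(h, d)
  lfc <- log2_fold_change(expr)
  expect_equal(unname(lfc), c(0, 1, -1))
})

test_that("two-sample fold-change arithmetic matches direct computation", {
  h <- rbind(G1 = c(5.0, 5.4), G2 = c(1, 2))
  d <- rbind(G1 = c(4.0, 4.4), G2 = c(1, 2))
  expect_equal(unname(log2_fold_change(make_expr(h, d)))[1], -1.0)
})

test_that("DEG thresholds are strict inequalities", {
  set.seed(1)
  # G1: log2fc exactly 0.5 with a clearly small p; G2: big shift, noisy;
  # G3: a real DEG; plus null filler so moderation is estimable
  h <- rbind(G1 = c(1.0, 1.2, 0.8, 1.1, 0.9, 1.0),
             G2 = c(8, 2, 9, 1, 8, 3),
             G3 = c(5, 5.1, 4.9, 5, 5.2, 4.8),
             matrix(rnorm(40 * 6, 8, 0.3), 40, 6,
                    dimnames = list(paste0("N", 1:40), NULL)))
  d <- h
  d["G1", ] <- h["G1", ] + 0.5
  d["G2", ] <- h["G2", ] + 0.8
  d["G3", ] <- h["G3", ] + 2
  expr <- make_expr(h, d)
  degs <- call_degs(expr, method = "welch")
  expect_equal(degs$log2fc[degs$gene_id == "G1"], 0.5)
  expect_false(degs$is_deg[degs$gene_id == "G1"])   # |lfc| not > 0.5
  expect_gt(degs$p[degs$gene_id == "G2"], 0.05)
  expect_false(degs$is_deg[degs$gene_id == "G2"])   # p not < 0.05
  expect_true(degs$is_deg[degs$gene_id == "G3"])
})

test_that("moderated t with d0 = 0 equals the ordinary pooled t", {
  set.seed(42)
  h <- matrix(rnorm(50 * 4, 6, 1), 50, 4)
  d <- matrix(rnorm(50 * 5, 6.5, 1.3), 50, 5)
  lfc <- rowMeans(d) - rowMeans(h)
  v1 <- apply(h, 1, var)
  v2 <- apply(d, 1, var)
  s2 <- (3 * v1 + 4 * v2) / 7
  res <- dcnet:::moderated_t(lfc, s2, 7, 4, 5, d0 = 0, s0_sq = 1)
  oracle_t <- vapply(seq_len(50), function(i)
    unname(t.test(d[i, ], h[i, ], var.equal = TRUE)$statistic),
    numeric(1))
  oracle_p <- vapply(seq_len(50), function(i)
    t.test(d[i, ], h[i, ], var.equal = TRUE)$p.value, numeric(1))
  expect_equal(res$t, oracle_t, tolerance = 1e-10)
  expect_equal(res$p, oracle_p, tolerance = 1e-10)
})

test_that("infinite prior df pools every variance completely", {
  res <- dcnet:::moderated_t(c(1, 2), c(0.5, 2), 4, 3, 3,
                             d0 = Inf, s0_sq = 0.8)
  expect_equal(res$posterior_var, c(0.8, 0.8))
  # equal sample variances give the complete-pooling convention
  mod <- estimate_moderation(rep(0.3, 10), residual_df = 4)
  expect_true(is.infinite(mod$d0))
  expect_equal(mod$s0_sq, 0.3, tolerance = 1e-12)
  expect_equal(mod$posterior_var, rep(0.3, 10))
})

test_that("moderation parameters are recovered from scaled-F variances", {
  set.seed(7)
  # true prior: d0 = 4, s0^2 = 0.25; sample variances on df = 4
  s2 <- 0.25 * rf(500, df1 = 4, df2 = 4)
  mod <- estimate_moderation(s2, residual_df = 4)
  expect_gte(mod$d0, 2)
  expect_lte(mod$d0, 8)
  expect_gte(mod$s0_sq, 0.15)
  expect_lte(mod$s0_sq, 0.40)
})

test_that("moderation agrees with the established empirical-Bayes fit", {
  set.seed(8)
  s2 <- 0.3 * rf(300, df1 = 4, df2 = 6)
  mod <- estimate_moderation(s2, residual_df = 4)
  sq <- limma::squeezeVar(s2, df = 4)
  expect_equal(mod$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_sq, sq$var.prior, tolerance = 1e-6)
  expect_equal(mod$posterior_var, sq$var.post, tolerance = 1e-6)
})

test_that("p-values are invariant to condition swap with negated log2fc", {
  set.seed(3)
  h <- matrix(rnorm(30 * 5, 7, 1), 30, 5,
              dimnames = list(paste0("G", 1:30), NULL))
  d <- matrix(rnorm(30 * 6, 7.4, 1), 30, 6,
              dimnames = list(paste0("G", 1:30), NULL))
  a <- call_degs(make_expr(h, d))
  b <- call_degs(make_expr(d, h))
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
  expect_identical(a$is_deg, b$is_deg)
})

test_that("sample order within a condition does not matter", {
  set.seed(4)
  h <- matrix(rnorm(20 * 6, 7, 1), 20, 6,
              dimnames = list(paste0("G", 1:20), NULL))
  d <- matrix(rnorm(20 * 6, 7.5, 1), 20, 6,
              dimnames = list(paste0("G", 1:20), NULL))
  a <- call_degs(make_expr(h, d))
  b <- call_degs(make_expr(h[, c(3, 1, 2, 6, 5, 4)],
                           d[, c(2, 1, 4, 3, 6, 5)]))
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$t, b$t, tolerance = 1e-12)
})

test_that("expression parsing reports offending rows and samples", {
  dir <- withr::local_tempdir()
  expr_path <- file.path(dir, "e.tsv")
  cond_path <- file.path(dir, "c.tsv")
  writeLines(c("gene_id\tS1\tS2\tS3\tS4",
               "GA\t1\t2\t3\t4",
               "GB\t1\t2\t3\t4",
               "GC\t5\t6\t7\t8"), expr_path)
  writeLines(c("sample_id\tcondition", "S1\thealthy", "S2\thealthy",
               "S3\tdisease", "S4\tdisease"), cond_path)
  expr <- read_expression(expr_path, cond_path)
  expect_equal(dim(expr), c(3L, 4L))

  writeLines(c("gene_id\tS1\tS2\tS3\tS4",
               "GA\t1\t2\t3\t4",
               "GA\t1\t2\t3\t4"), expr_path)
  expect_error(read_expression(expr_path, cond_path), "GA")

  writeLines(c("gene_id\tS1\tS2\tS3\tS4",
               "GA\t1\tx\t3\t4"), expr_path)
  expect_error(read_expression(expr_path, cond_path), "S2")

  writeLines(c("gene_id\tS1\tS2\tS3\tS5",
               "GA\t1\t2\t3\t4"), expr_path)
  expect_error(read_expression(expr_path, cond_path), "S5")

  writeLines(c("gene_id\tS1\tS2\tS3\tS4",
               "GA\t1\t2\t3\t4"), expr_path)
  writeLines(c("sample_id\tcondition", "S1\thealthy", "S2\thealthy",
               "S3\tdisease", "S4\tsick"), cond_path)
  expect_error(read_expression(expr_path, cond_path), "sick")
})

test_that("too few samples per condition is an error", {
  h <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("G", 1:5), NULL))
  d <- matrix(rnorm(5), 5, 1, dimnames = list(paste0("G", 1:5), NULL))
  expect_error(call_degs(make_expr(h, d)), "at least 2 samples")
})
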