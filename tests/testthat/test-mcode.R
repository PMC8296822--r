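test_that("vertex weights on canonical small graphs", {
  tri <- clique_edges(c("A", "B", "C"))
  expect_equal(unname(vertex_weights(tri)), rep(2, 3))
  single <- data.frame(gene_a = "A", gene_b = "B")
  expect_equal(unname(vertex_weights(single)), c(1, 1))
  # star: center and leaves against the brute-force oracle
  star <- data.frame(gene_a = rep("C0", 5), gene_b = paste0("L", 1:5))
  A <- matrix(0L, 6, 6, dimnames = list(c("C0", paste0("L", 1:5)),
                                        c("C0", paste0("L", 1:5))))
  A["C0", paste0("L", 1:5)] <- 1L
  A[paste0("L", 1:5), "C0"] <- 1L
  w <- vertex_weights(star)
  for (v in rownames(A))
    expect_equal(w[[v]], oracle_vertex_weight(A, v), label = v)
  # isolated vertex
  expect_equal(vertex_weights(single, vertices = c("A", "B", "Z"))[["Z"]], 0)
})

test_that("vertex weights match the brute-force k-core oracle", {
  set.seed(12)
  for (g in 1:25) {
    n <- sample(3:8, 1)
    gr <- random_graph(n, runif(1, 0.2, 0.8))
    w <- vertex_weights(gr$edges, vertices = rownames(gr$A))
    for (v in rownames(gr$A))
      expect_equal(w[[v]], oracle_vertex_weight(gr$A, v),
                   label = paste("graph", g, "vertex", v))
  }
})

test_that("a clique is found whole and sparse structure is discarded", {
  k5 <- clique_edges(paste0("K", 1:5))
  path <- data.frame(gene_a = paste0("P", 1:9), gene_b = paste0("P", 2:10))
  mods <- find_modules(rbind(k5, path))
  expect_equal(nrow(mods), 1L)
  expect_equal(mods$score, 5)
  expect_equal(mods$density, 1)
  expect_identical(mods$members, paste(paste0("K", 1:5), collapse = ";"))

  expect_equal(nrow(find_modules(data.frame(gene_a = character(),
                                            gene_b = character()))), 0L)

  two_k4 <- rbind(clique_edges(paste0("A", 1:4)),
                  clique_edges(paste0("B", 1:4)))
  mods2 <- find_modules(two_k4)
  expect_equal(nrow(mods2), 2L)
  expect_equal(mods2$score, c(4, 4))
  expect_length(intersect(strsplit(mods2$members[1], ";")[[1]],
                          strsplit(mods2$members[2], ";")[[1]]), 0)
})

test_that("module detection is deterministic and relabeling-equivariant", {
  set.seed(14)
  gr <- random_graph(12, 0.45)
  m1 <- find_modules(gr$edges, min_component_score = 1)
  m2 <- find_modules(gr$edges, min_component_score = 1)
  expect_identical(m1, m2)
  # order-preserving relabeling V01.. -> W01.. keeps the same structure
  relab <- gr$edges
  relab$gene_a <- sub("^V", "W", relab$gene_a)
  relab$gene_b <- sub("^V", "W", relab$gene_b)
  m3 <- find_modules(relab, min_component_score = 1)
  expect_identical(sub("W", "V", m3$members), m1$members)
  expect_error(find_modules(gr$edges, vwp = 1), "vwp")
})

test_that("modules are vertex-disjoint subsets of the graph", {
  set.seed(15)
  for (g in 1:5) {
    gr <- random_graph(15, 0.4)
    mods <- find_modules(gr$edges, min_component_score = 0)
    members <- unlist(strsplit(mods$members, ";"))
    expect_equal(anyDuplicated(members), 0L)
    expect_true(all(members %in% rownames(gr$A)))
  }
})

test_that("haircut trims singly-connected members", {
  # K4 with a pendant vertex: the pendant must not survive the haircut
  g <- rbind(clique_edges(paste0("K", 1:4)),
             data.frame(gene_a = "K1", gene_b = "PENDANT"))
  mods <- find_modules(g, vwp = 0.9)
  expect_equal(mods$n_members, 4L)
  expect_false(grepl("PENDANT", mods$members))
  no_cut <- find_modules(g, vwp = 0.9, haircut = FALSE)
  expect_true(grepl("PENDANT", no_cut$members))
})

test_that("hub selection uses degree with threshold and fallback rules", {
  leaves <- sprintf("L%02d", 1:12)
  star <- data.frame(gene_a = rep("CEN", 12), gene_b = leaves)
  modules <- data.frame(module_id = 1L, seed = "CEN", n_members = 13L,
                        density = 2 * 12 / (13 * 12), score = 2,
                        members = paste(sort(c("CEN", leaves)),
                                        collapse = ";"))
  hubs <- select_hubs(star, modules)
  expect_equal(hubs$gene_id, "CEN")
  expect_equal(hubs$hub_score, 12L)
  expect_equal(hubs$rule, "threshold")

  # nobody above the threshold: unique max selected as fallback
  k6 <- clique_edges(paste0("M", 1:6))   # all degrees 5
  modules6 <- data.frame(module_id = 1L, seed = "M1", n_members = 6L,
                         density = 1, score = 6,
                         members = paste(paste0("M", 1:6), collapse = ";"))
  hubs6 <- select_hubs(k6, modules6)
  expect_equal(nrow(hubs6), 1L)
  expect_equal(hubs6$hub_score, 5L)
  expect_equal(hubs6$rule, "fallback_max")
  expect_equal(hubs6$gene_id, "M1")  # lexicographic tie-break

  expect_equal(nrow(select_hubs(k6, modules6[0, ])), 0L)
})

test_that("network merging annotates tissues and conserves structure", {
  net <- function(edges, degs = character()) {
    ids <- sort(unique(c(edges$gene_a, edges$gene_b)))
    list(edges = edges,
         nodes = data.frame(gene_id = ids, is_deg = ids %in% degs))
  }
  e1 <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"))
  same <- merge_networks(list(t1 = net(e1, "A"), t2 = net(e1, "B"),
                              t3 = net(e1, "A")))
  expect_equal(nrow(same$edges), 2L)
  expect_true(all(same$edges$tissues == "t1;t2;t3"))
  expect_equal(same$nodes$deg_in[same$nodes$gene_id == "A"], "t1;t3")

  e2 <- data.frame(gene_a = "X", gene_b = "Y")
  disj <- merge_networks(list(t1 = net(e1), t2 = net(e2)))
  expect_equal(nrow(disj$edges), 3L)

  e3 <- data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"))
  shared <- merge_networks(list(t1 = net(e1), t2 = net(e3)))
  expect_equal(nrow(shared$edges), 3L)  # 2 + 2 - 1 shared
  expect_equal(shared$edges$tissues[shared$edges$gene_a == "A"], "t1;t2")
  expect_error(merge_networks(list(net(e1))), "at least two")
})
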