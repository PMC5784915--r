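test_that("rank comparison computes log ratios with antisymmetry", {
  net <- random_network(fixture_spec(30, seed = 51))
  model <- build_transition(net)
  pr <- pagerank(model)
  same <- compare_ranks(pr, pr)
  expect_true(all(same$table$log_k_ratio == 0))

  tc <- two_condition_pair(fixture_spec(40, seed = 53), 0.6, seed = 53)
  pa <- pagerank(build_transition(tc$net_a))
  pb <- pagerank(build_transition(tc$net_b))
  ab <- compare_ranks(pa, pb)
  ba <- compare_ranks(pb, pa)
  expect_equal(ab$table$log_k_ratio, -ba$table$log_k_ratio)
  expect_error(compare_ranks(pa, pagerank(build_transition(
    net_from(c("zz1>zz2"))))), "no nodes")
})

test_that("deleting a node's in-edges worsens its PageRank log-ratio", {
  net_a <- random_network(fixture_spec(40, seed = 57))
  victim <- net_a$nodes[which.max(network_degrees(net_a)$in_degree)]
  edges_b <- net_a$edges[net_a$edges$to != victim, ]
  net_b <- directed_network(edges_b, nodes = net_a$nodes)
  pa <- pagerank(build_transition(net_a))
  pb <- pagerank(build_transition(net_b))
  cmp <- compare_ranks(pa, pb)
  lr <- cmp$table$log_k_ratio[cmp$table$node == victim]
  expect_gt(lr, 0)  # K index grows when incoming regulation disappears
})

test_that("sigma selections are consistent with the log-ratio table", {
  tc <- two_condition_pair(fixture_spec(50, seed = 59), 0.8, seed = 59)
  pa <- pagerank(build_transition(tc$net_a))
  pb <- pagerank(build_transition(tc$net_b))
  ca <- cheirank(tc$net_a); cb <- cheirank(tc$net_b)
  cmp <- compare_ranks(pa, pb, ca, cb)
  s <- cmp$sigma[["k"]]
  up2 <- cmp$table$node[cmp$table$log_k_ratio > 2 * s]
  expect_setequal(cmp$selected$k$`2sigma`$up, up2)
  expect_true(all(cmp$selected$k$`2sigma`$up %in% cmp$selected$k$`1sigma`$up))
  expect_true("k_star" %in% names(cmp$sigma))
})

test_that("hidden-interaction classification is exhaustive and thresholded", {
  net <- random_network(fixture_spec(40, seed = 61))
  model <- build_transition(net)
  rgm <- compute_reduced(model, net$nodes[1:6])

  solo <- infer_hidden(rgm, threshold = 0)
  expect_true(all(solo$class == "common"))
  off <- rgm$g_qrnd[row(rgm$g_qrnd) != col(rgm$g_qrnd)]
  expect_equal(nrow(solo), sum(off > 0))  # threshold 0 keeps all positives

  same <- infer_hidden(rgm, rgm, threshold = 1e-4)
  expect_true(all(same$class == "common"))

  # monotonicity: raising the threshold never adds pairs
  lo <- infer_hidden(rgm, threshold = 1e-4)
  hi <- infer_hidden(rgm, threshold = 1e-2)
  expect_true(all(paste(hi$source, hi$target) %in% paste(lo$source, lo$target)))
  expect_true(all(lo$score_a > 1e-4))

  # top_k caps each class
  capped <- infer_hidden(rgm, threshold = 0, top_k = 3)
  expect_lte(nrow(capped), 3)
})

test_that("hidden pairs use the column-to-row (source-to-target) convention", {
  # chain A -> x -> B outside the subset: hidden link must be A -> B, not B -> A
  edges <- c("A>x", "x>B", "B>y", "C>A", "y>C")
  net <- net_from(edges)
  model <- build_transition(net)
  rgm <- compute_reduced(model, c("A", "B", "C"))
  hid <- infer_hidden(rgm, threshold = 0.01)
  expect_true(any(hid$source == "A" & hid$target == "B"))
  ab <- hid$score_a[hid$source == "A" & hid$target == "B"]
  ba <- rgm$g_qrnd["A", match("B", rgm$subset)]
  expect_gt(ab, ba)  # the A->B relay dominates the reverse direction
})

test_that("local subnetwork ranks follow the reduced-matrix eigenvector", {
  one <- compute_reduced(build_transition(net_from(c("A>B", "B>A", "B>C"))), "C")
  loc1 <- local_pagerank_ranks(one)
  expect_equal(loc1$k_local, 1L)

  # symmetric pair ties broken lexicographically
  sym <- net_from(c("H>A", "H>B", "A>H", "B>H"))
  rgm_sym <- compute_reduced(build_transition(sym), c("B", "A"))
  loc_sym <- local_pagerank_ranks(rgm_sym)
  expect_equal(loc_sym$k_local[loc_sym$node == "A"], 1L)
  expect_equal(loc_sym$k_local[loc_sym$node == "B"], 2L)
})

test_that("connectivity summary counts weak components", {
  star <- data.frame(from = rep("C0", 4), to = paste0("L", 1:4))
  s <- connectivity_summary(c("C0", paste0("L", 1:4)), star)
  expect_equal(s$lcc_size, 5)
  expect_equal(s$n_orphan, 0)

  nodes <- c("a", "b", "c", "d", "e")
  pairs <- data.frame(from = c("a", "c"), to = c("b", "d"))
  s2 <- connectivity_summary(nodes, pairs)
  expect_equal(s2$lcc_size, 2)
  expect_equal(s2$n_orphan, 1)
  expect_equal(s2$n_connected, 4)

  # direction reversal leaves weak connectivity unchanged
  rev_pairs <- data.frame(from = pairs$to, to = pairs$from)
  expect_equal(connectivity_summary(nodes, rev_pairs), s2)

  # a hidden edge bridging two components grows the LCC by the smaller one
  bridge <- data.frame(from = "b", to = "c")
  s3 <- connectivity_summary(nodes, pairs, bridge)
  expect_equal(s3$lcc_size_with_hidden, 4)
  expect_equal(s3$lcc_gain, 2)

  expect_error(connectivity_summary(c("a"), data.frame(from = "a", to = "zz")),
               "outside")
})

test_that("shortest and second-shortest paths match brute-force enumeration", {
  # direct edge plus detours
  net <- net_from(c("s>t", "s>m1", "m1>t", "s>m2", "m2>t", "m2>m1"))
  sp <- short_paths(net, "s", "t")
  expect_equal(sp$shortest, list(c("s", "t")))
  expect_setequal(vapply(sp$second_shortest, paste, "", collapse = "-"),
                  c("s-m1-t", "s-m2-t"))

  # disconnected pair
  disc <- net_from(c("a>b", "c>d"))
  empty <- short_paths(disc, "a", "d")
  expect_false(empty$found)
  expect_length(empty$shortest, 0)

  # 6-node fixture vs exhaustive enumeration
  net6 <- net_from(c("u>v", "v>w", "w>z", "u>x", "x>y", "y>z", "v>y", "x>w"))
  got <- short_paths(net6, "u", "z")
  all_paths <- enumerate_paths_oracle(net6, "u", "z", max_len = 6)
  lens <- vapply(all_paths, length, 0L) - 1L
  lmin <- min(lens)
  key <- function(p) paste(p, collapse = "-")
  expect_setequal(vapply(got$shortest, key, ""),
                  vapply(all_paths[lens == lmin], key, ""))
  expect_setequal(vapply(got$second_shortest, key, ""),
                  vapply(all_paths[lens == lmin + 1], key, ""))
})
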