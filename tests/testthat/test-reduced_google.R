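test_that("block operators agree with dense slicing and inherit stochasticity", {
  net <- net_from(c("A>B", "B>C", "C>A", "A>C"))
  model <- build_transition(net)
  G <- dense_google_oracle(net)
  part <- partition(model, "A")
  r <- 1; s <- 2:3
  # 1x1, 1x2, 2x1, 2x2 slices of dense G
  expect_equal(g_block_apply(part, "rr", 1), unname(G[r, r]), tolerance = 1e-14)
  v2 <- c(0.3, 0.7)
  expect_equal(g_block_apply(part, "rs", v2), unname(as.vector(G[r, s] %*% v2)),
               tolerance = 1e-14)
  expect_equal(g_block_apply(part, "sr", 1), unname(as.vector(G[s, r])),
               tolerance = 1e-14)
  expect_equal(g_block_apply(part, "ss", v2), unname(as.vector(G[s, s] %*% v2)),
               tolerance = 1e-14)

  # stacked blocks applied to a stacked vector = full G then split
  net2 <- random_network(fixture_spec(25, seed = 21, dangling_fraction = 0.3))
  model2 <- build_transition(net2)
  part2 <- partition(model2, net2$nodes[c(3, 11, 17)])
  v <- runif(25); vr <- v[part2$r]; vs <- v[part2$s]
  full <- apply_google(model2, v)
  expect_lt(max(abs(g_block_apply(part2, "rr", vr) + g_block_apply(part2, "rs", vs)
                    - full[part2$r])), 1e-12)
  expect_lt(max(abs(g_block_apply(part2, "sr", vr) + g_block_apply(part2, "ss", vs)
                    - full[part2$s])), 1e-12)

  # transposed application matches t(dense block)
  G2 <- dense_google_oracle(net2)
  w <- runif(22)
  expect_lt(max(abs(g_block_apply(part2, "ss", w, transpose = TRUE) -
                    as.vector(crossprod(G2[part2$s, part2$s], w)))), 1e-12)

  # ones-vector over the stacked column blocks sums to 1 (stochasticity)
  er <- rep(1, 3); es <- rep(1, 22)
  col_sums <- g_block_apply(part2, "rr", diag(3)[, 1])  # placeholder
  for (j in 1:3) {
    ej <- as.numeric(seq_len(3) == j)
    expect_equal(sum(g_block_apply(part2, "rr", ej)) +
                 sum(g_block_apply(part2, "sr", ej)), 1, tolerance = 1e-12)
  }
  expect_error(partition(model2, c(net2$nodes[1], "NOPE")), "NOPE")
  expect_error(partition(model2, character(0)), "empty")
})

test_that("scattering eigenpair satisfies its defining relations", {
  # N_s = 1: lambda_c is the scalar G_ss entry
  net <- net_from(c("A>B", "B>A", "B>C", "C>A"))
  model <- build_transition(net)
  part <- partition(model, c("A", "B"))
  eig <- scattering_eigenpair(part)
  G <- dense_google_oracle(net)
  expect_equal(eig$lambda_c, unname(G[3, 3]), tolerance = 1e-12)
  expect_equal(eig$psi_r, 1)
  expect_equal(eig$psi_l, 1)

  # dense 6-node net, N_r = 2: lambda_c matches the dominant eigenvalue of
  # the dense 4x4 G_ss block
  net6 <- random_network(fixture_spec(6, seed = 13, dangling_fraction = 0.3,
                                      mean_out_degree = 2))
  model6 <- build_transition(net6)
  part6 <- partition(model6, net6$nodes[1:2])
  eig6 <- scattering_eigenpair(part6)
  Gss <- dense_google_oracle(net6)[3:6, 3:6]
  lam_dense <- max(Re(eigen(Gss)$values))
  expect_equal(eig6$lambda_c, lam_dense, tolerance = 1e-9)
  # eigen relations and normalizations
  gss_psi <- g_block_apply(part6, "ss", eig6$psi_r)
  expect_lt(max(abs(gss_psi - eig6$lambda_c * eig6$psi_r)), 1e-10)
  psi_l_g <- g_block_apply(part6, "ss", eig6$psi_l, transpose = TRUE)
  expect_lt(max(abs(psi_l_g - eig6$lambda_c * eig6$psi_l)), 1e-10)
  expect_equal(sum(eig6$psi_r), 1, tolerance = 1e-12)
  expect_equal(sum(eig6$psi_l * eig6$psi_r), 1, tolerance = 1e-12)

  # identity 1 - lambda_c = ||G_rs psi_R||_1 on random instances
  for (seed in 1:6) {
    m <- random_model(30, seed = seed)
    p <- partition(m, m$nodes[1:4])
    e <- scattering_eigenpair(p)
    expect_lt(abs((1 - e$lambda_c) - e$one_minus_lambda_c), 1e-10)
  }
})

test_that("series decomposition equals the dense-inverse oracle", {
  net <- random_network(fixture_spec(20, seed = 31, dangling_fraction = 0.25))
  model <- build_transition(net)
  subset <- net$nodes[c(2, 7, 9, 14, 19)]
  rgm <- compute_reduced(model, subset)
  GR <- direct_oracle(model, subset)
  expect_lt(max(abs(reduced_matrix(rgm) - GR)), 1e-8)

  # the dense oracle itself agrees with a truncated plain Neumann series
  G <- dense_google_oracle(net)
  r_idx <- match(subset, net$nodes)
  expect_lt(max(abs(GR - series_reduced_oracle(G, r_idx, L = 500))), 1e-8)

  # scalar-resolvent case N_s = 1
  small <- net_from(c("A>B", "B>C", "C>A"))
  msmall <- build_transition(small)
  Gs <- dense_google_oracle(small)
  GR1 <- direct_oracle(msmall, c("A", "B"))
  g <- Gs[3, 3]
  expect_equal(GR1,
               Gs[1:2, 1:2] + Gs[1:2, 3, drop = FALSE] %*%
                 Gs[3, 1:2, drop = FALSE] / (1 - g),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("reduced matrix is column-stochastic and preserves global PageRank", {
  net <- random_network(fixture_spec(40, seed = 17))
  model <- build_transition(net)
  subset <- net$nodes[c(1, 5, 9, 22, 30, 38)]
  rgm <- compute_reduced(model, subset)
  GR <- reduced_matrix(rgm)
  expect_lt(max(abs(colSums(GR) - 1)), 1e-8)

  pr <- pagerank(model, tol = 1e-14)
  p_r <- pr$p[subset] / sum(pr$p[subset])
  expect_lt(max(abs(as.vector(GR %*% p_r) - p_r)), 1e-8)

  # rank order under G_R's leading eigenvector equals global order on subset
  loc <- local_pagerank_ranks(rgm)
  expect_equal(order(loc$k_local), order(-pr$p[subset], subset, method = "radix"))
})

test_that("G_pr is numerically rank one and weights sum to one", {
  for (seed in c(2, 4, 6)) {
    net <- random_network(fixture_spec(30, seed = seed))
    model <- build_transition(net)
    rgm <- compute_reduced(model, net$nodes[1:5])
    sv <- svd(rgm$g_pr)$d
    expect_lt(sv[2], 1e-10 * sv[1])
    expect_equal(sum(rgm$weights), 1, tolerance = 1e-10)
    expect_true(rgm$lambda_c > 0 && rgm$lambda_c < 1)
  }
})

test_that("whole-network subset degenerates to the full Google matrix", {
  net <- net_from(c("A>B", "B>C", "C>A", "A>C"))
  model <- build_transition(net)
  rgm <- compute_reduced(model, net$nodes)
  expect_equal(reduced_matrix(rgm), dense_google_oracle(net),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(max(abs(rgm$g_pr)), 0)
  expect_equal(max(abs(rgm$g_qr)), 0)
  expect_equal(unname(rgm$weights), c(1, 0, 0))
})

test_that("deflated series increments decay geometrically below ~alpha", {
  net <- random_network(fixture_spec(50, seed = 23))
  model <- build_transition(net, alpha = 0.85)
  part <- partition(model, net$nodes[1:5])
  eig <- scattering_eigenpair(part)
  qc <- function(v) v - eig$psi_r * sum(eig$psi_l * v)
  g <- g_block_apply(part, "sr", as.numeric(seq_len(5) == 1))
  v <- qc(g)
  incs <- numeric(60)
  for (l in 1:60) {
    v <- qc(g_block_apply(part, "ss", v))
    incs[l] <- sum(abs(v))
  }
  ratios <- incs[21:60] / incs[20:59]
  expect_lt(max(ratios), 0.85 + 0.05)
})

test_that("PageRank mass on the subset approximates 1 - lambda_c", {
  net <- random_network(fixture_spec(80, seed = 29))
  model <- build_transition(net)
  subset <- net$nodes[seq(1, 80, by = 16)]
  rgm <- compute_reduced(model, subset)
  sigma_p <- subset_pagerank_mass(pagerank(model), subset)
  ratio <- (1 - rgm$lambda_c) / sigma_p
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})
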