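#' Block partition of the Google matrix for a node subset
#'
#' Splits G into the four blocks
#' \preformatted{G = | G_rr  G_rs |
#'     | G_sr  G_ss |}
#' where "r" indexes the chosen subset (N_r nodes, in the order given) and
#' "s" the complementary "scattering" network (N_s = N - N_r nodes, through
#' which indirect paths run).  Blocks are blocks of G itself, so each
#' includes the teleportation term (1 - alpha)/N and the dangling-column
#' correction; they are kept matrix-free (sparse slice + rank-one uniform
#' contributions) and applied through [g_block_apply()].
#'
#' @param model A `google_model` from [build_transition()].
#' @param subset Character vector of subset node labels (all must be network
#'   nodes), or a `gene_set`.
#' @return A `block_partition`: list with index vectors `r`, `s`, the sparse
#'   S-slices, dangling masks per side, and the parent model parameters.
#' @export
partition <- function(model, subset) {
  stopifnot(inherits(model, "google_model"))
  if (inherits(subset, "gene_set")) subset <- subset$labels
  subset <- as.character(subset)
  if (length(subset) == 0) stop("subset is empty", call. = FALSE)
  if (anyDuplicated(subset) > 0) stop("subset labels must be unique", call. = FALSE)
  miss <- setdiff(subset, model$nodes)
  if (length(miss) > 0) {
    stop("subset labels not in the network: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  r <- match(subset, model$nodes)
  s <- setdiff(seq_len(model$n), r)
  structure(
    list(
      r = r, s = s, n = model$n, alpha = model$alpha,
      labels_r = subset, labels_s = model$nodes[s],
      S_rr = model$S[r, r, drop = FALSE], S_rs = model$S[r, s, drop = FALSE],
      S_sr = model$S[s, r, drop = FALSE], S_ss = model$S[s, s, drop = FALSE],
      dang_r = model$dangling[r], dang_s = model$dangling[s]
    ),
    class = "block_partition"
  )
}

#' Apply one block of G to a vector
#'
#' Computes `G_xy v` for `block` one of `"rr"`, `"rs"`, `"sr"`, `"ss"`
#' without densifying: alpha * (sparse slice + uniform dangling columns) plus
#' the (1 - alpha)/N teleportation term.  Applying the stacked blocks to a
#' stacked vector reproduces applying the full G and splitting.
#'
#' @param part A `block_partition`.
#' @param block One of `"rr"`, `"rs"`, `"sr"`, `"ss"`.
#' @param v Numeric vector matching the block's column side.
#' @param transpose If `TRUE`, apply the transposed block `t(G_xy) v`
#'   (`v` then matches the row side).
#' @return Numeric vector.
#' @export
g_block_apply <- function(part, block, v, transpose = FALSE) {
  stopifnot(inherits(part, "block_partition"))
  block <- match.arg(block, c("rr", "rs", "sr", "ss"))
  Ssub <- part[[paste0("S_", block)]]
  col_side <- substr(block, 2, 2)
  dang_cols <- if (col_side == "r") part$dang_r else part$dang_s
  n_rows <- nrow(Ssub)
  a <- part$alpha
  if (!transpose) {
    if (length(v) != ncol(Ssub)) stop("block/vector size mismatch", call. = FALSE)
    a * (as.vector(Ssub %*% v) + sum(v[dang_cols]) / part$n) +
      (1 - a) * sum(v) / part$n
  } else {
    if (length(v) != n_rows) stop("block/vector size mismatch", call. = FALSE)
    out <- a * as.vector(Matrix::crossprod(Ssub, v))
    out[dang_cols] <- out[dang_cols] + a * sum(v) / part$n
    out + (1 - a) * sum(v) / part$n
  }
}

# dense realization of one block (N_r small; used for G_rr, G_rs, G_sr)
g_block_dense <- function(part, block) {
  Ssub <- as.matrix(part[[paste0("S_", block)]])
  col_side <- substr(block, 2, 2)
  dang_cols <- if (col_side == "r") part$dang_r else part$dang_s
  Ssub[, dang_cols] <- Ssub[, dang_cols] + 1 / part$n
  part$alpha * Ssub + (1 - part$alpha) / part$n
}

#' Leading eigenpair of the scattering block
#'
#' Power iteration for the leading eigenvalue lambda_c of G_ss and its right
#' and left eigenvectors psi_R, psi_L (both nonnegative; lambda_c is real
#' since G_ss is a nonnegative substochastic block).  Normalizations:
#' sum(psi_R) = 1 and psi_L . psi_R = 1.  The complementary mass
#' 1 - lambda_c is additionally computed as ||G_rs psi_R||_1 — the norm of
#' the projection of G psi_R onto the reduced space — which stays accurate
#' even for lambda_c close to 1; the two estimates are checked against each
#' other.
#'
#' @param part A `block_partition` with N_s >= 1.
#' @param tol L1 convergence tolerance for the power iteration.
#' @param max_iter Iteration cap.
#' @return List with `lambda_c`, `psi_r`, `psi_l`, `one_minus_lambda_c`
#'   (the norm-based estimate) and `iterations`.
#' @export
scattering_eigenpair <- function(part, tol = 1e-12, max_iter = 100000) {
  stopifnot(inherits(part, "block_partition"))
  ns <- length(part$s)
  if (ns < 1) stop("scattering block is empty (N_r = N)", call. = FALSE)
  gss <- function(v) g_block_apply(part, "ss", v)
  gss_t <- function(v) g_block_apply(part, "ss", v, transpose = TRUE)

  v <- rep(1 / ns, ns)
  lam <- NA_real_
  for (it in seq_len(max_iter)) {
    v_new <- gss(v)
    lam <- sum(v_new)
    v_new <- v_new / lam
    if (sum(abs(v_new - v)) < tol) { v <- v_new; break }
    v <- v_new
  }
  if (it == max_iter && sum(abs(gss(v) / lam - v)) >= tol) {
    stop("power iteration for psi_R did not converge in ", max_iter,
         " iterations", call. = FALSE)
  }
  w <- rep(1 / ns, ns)
  for (jt in seq_len(max_iter)) {
    w_new <- gss_t(w)
    w_new <- w_new / sum(w_new)
    if (sum(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  if (jt == max_iter && sum(abs(gss_t(w) / sum(gss_t(w)) - w)) >= tol) {
    stop("power iteration for psi_L did not converge in ", max_iter,
         " iterations", call. = FALSE)
  }
  psi_r <- v / sum(v)                      # E_s^T psi_R = 1
  psi_l <- w / sum(w * psi_r)              # psi_L^T psi_R = 1
  if (lam >= 1) {
    stop("internal inconsistency: lambda_c >= 1 (", format(lam),
         "), impossible for alpha < 1", call. = FALSE)
  }
  one_minus <- sum(abs(g_block_apply(part, "rs", psi_r)))
  if (abs((1 - lam) - one_minus) > max(10 * tol, 1e-8)) {
    warning("lambda_c estimates disagree: 1 - lambda = ", format(1 - lam),
            " vs ||G_rs psi_R||_1 = ", format(one_minus), call. = FALSE)
  }
  list(lambda_c = lam, psi_r = psi_r, psi_l = psi_l,
       one_minus_lambda_c = one_minus, iterations = max(it, jt))
}

#' Reduced Google matrix with its three-component decomposition
#'
#' For a subset of N_r nodes embedded in a network of N nodes, computes the
#' exact reduced Google matrix
#' \deqn{G_R = G_{rr} + G_{rs} (1 - G_{ss})^{-1} G_{sr}}
#' through its analytic decomposition G_R = G_rr + G_pr + G_qr:
#' * `g_rr` — direct links among the subset (the corresponding block of G);
#' * `g_pr` — rank-one projector component
#'   psi~_R psi~_L^T / (1 - lambda_c), with psi~_R = G_rs psi_R and
#'   psi~_L^T = psi_L^T G_sr, driven by the leading eigenpair of the
#'   scattering block;
#' * `g_qr` — the hidden-link component
#'   G_rs \[Q_c sum_l Gbar_ss^l\] G_sr with Q_c = 1 - psi_R psi_L^T and
#'   Gbar_ss = Q_c G_ss Q_c, accumulated column by column as a deflated
#'   Neumann series until the L1 increment drops below `tol`.
#'
#' G_qr splits into its diagonal part `g_qrd` (probability of returning to
#' the same node through the scattering network) and the off-diagonal part
#' `g_qrnd` whose entries score indirect (hidden) interactions between
#' distinct subset members.  Occasional small negative entries of G_qr
#' (possible through Q_c) are retained verbatim; their total weight is
#' reported, not clipped.
#'
#' Column convention: entry \[i, j\] is the transition probability from
#' subset node j (column) to subset node i (row); columns of
#' `g_rr + g_pr + g_qr` sum to 1.
#'
#' The degenerate case `subset` = all nodes returns G_R = G with
#' `g_pr = g_qr = 0` and weights (1, 0, 0).
#'
#' @inheritParams partition
#' @param tol L1 tolerance for the eigenpair iteration and the series
#'   truncation; default 1e-12.
#' @param max_terms Series term cap; the deflated series typically converges
#'   within a few hundred terms since the remaining eigenvalues of Gbar_ss
#'   sit below alpha.
#' @return A `reduced_google`: list with dense N_r x N_r matrices `g_rr`,
#'   `g_pr`, `g_qr`, `g_qrd`, `g_qrnd`, scalars `lambda_c`,
#'   `one_minus_lambda_c`, eigenvectors `psi_r`, `psi_l`, named `weights`
#'   (`w_rr`, `w_pr`, `w_qr`, summing to 1), `negative_weight`, `n_terms`
#'   (largest series length used), `subset`, `alpha`, `n`.
#' @export
compute_reduced <- function(model, subset, tol = 1e-12, max_terms = 10000) {
  stopifnot(inherits(model, "google_model"))
  if (inherits(subset, "gene_set")) subset <- subset$labels
  subset <- as.character(subset)
  n <- model$n
  nr <- length(subset)
  if (nr == n && setequal(subset, model$nodes)) {
    # no scattering nodes: G_R is the full G
    G <- dense_google(model)[subset, subset, drop = FALSE]
    zero <- array(0, dim(G), dimnames = dimnames(G))
    return(structure(
      list(g_rr = G, g_pr = zero, g_qr = zero, g_qrd = zero, g_qrnd = zero,
           lambda_c = NA_real_, one_minus_lambda_c = NA_real_,
           psi_r = numeric(0), psi_l = numeric(0),
           weights = c(w_rr = 1, w_pr = 0, w_qr = 0),
           negative_weight = 0, n_terms = 0L,
           subset = subset, alpha = model$alpha, n = n),
      class = "reduced_google"
    ))
  }
  part <- partition(model, subset)
  eig <- scattering_eigenpair(part, tol = tol)
  psi_r <- eig$psi_r; psi_l <- eig$psi_l

  G_rr <- g_block_dense(part, "rr")
  G_rs <- g_block_dense(part, "rs")
  G_sr <- g_block_dense(part, "sr")
  dimnames(G_rr) <- list(subset, subset)

  psi_tr <- as.vector(G_rs %*% psi_r)        # = G_rs psi_R, length N_r
  psi_tl <- as.vector(crossprod(G_sr, psi_l))  # = (psi_L^T G_sr)^T
  one_minus <- eig$one_minus_lambda_c        # = sum(psi_tr), cancellation-safe
  G_pr <- outer(psi_tr, psi_tl) / one_minus
  dimnames(G_pr) <- list(subset, subset)

  qc <- function(v) v - psi_r * sum(psi_l * v)
  G_qr <- matrix(0, nr, nr, dimnames = list(subset, subset))
  n_terms <- 0L
  for (j in seq_len(nr)) {
    v <- qc(G_sr[, j])
    acc <- v
    converged <- FALSE
    for (l in seq_len(max_terms)) {
      v <- qc(g_block_apply(part, "ss", v))
      acc <- acc + v
      if (sum(abs(v)) < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      stop("deflated Neumann series did not converge within ", max_terms,
           " terms (last L1 increment ", format(sum(abs(v))), ")",
           call. = FALSE)
    }
    n_terms <- max(n_terms, l)
    G_qr[, j] <- as.vector(G_rs %*% acc)
  }
  G_qrd <- G_qr * diag(nr)
  G_qrnd <- G_qr - G_qrd

  weights <- c(w_rr = sum(G_rr), w_pr = sum(G_pr), w_qr = sum(G_qr)) / nr
  structure(
    list(g_rr = G_rr, g_pr = G_pr, g_qr = G_qr, g_qrd = G_qrd, g_qrnd = G_qrnd,
         lambda_c = eig$lambda_c, one_minus_lambda_c = one_minus,
         psi_r = psi_r, psi_l = psi_l,
         weights = weights,
         negative_weight = sum(abs(G_qr[G_qr < 0])) / nr,
         n_terms = n_terms,
         subset = subset, alpha = model$alpha, n = n),
    class = "reduced_google"
  )
}

#' @exportS3Method base::print
print.reduced_google <- function(x, ...) {
  cat("<reduced_google> N_r = ", length(x$subset), " of N = ", x$n,
      ", lambda_c = ", format(x$lambda_c, digits = 6), "\n",
      "  weights: W_rr = ", format(x$weights[["w_rr"]], digits = 4),
      ", W_pr = ", format(x$weights[["w_pr"]], digits = 4),
      ", W_qr = ", format(x$weights[["w_qr"]], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Reduced Google matrix G_R of a `reduced_google` object
#'
#' @param rgm A `reduced_google`.
#' @return Dense N_r x N_r matrix `g_rr + g_pr + g_qr`.
#' @export
reduced_matrix <- function(rgm) {
  stopifnot(inherits(rgm, "reduced_google"))
  rgm$g_rr + rgm$g_pr + rgm$g_qr
}

#' Direct dense-inverse computation of G_R (oracle)
#'
#' Computes G_R = G_rr + G_rs (1 - G_ss)^{-1} G_sr by an explicit dense
#' solve.  Exact up to linear-algebra round-off and entirely independent of
#' the deflated-series path of [compute_reduced()]; restricted to N <= 2000
#' where the dense resolvent is feasible.
#'
#' @inheritParams partition
#' @return Dense N_r x N_r matrix with subset labels as dimnames.
#' @export
direct_oracle <- function(model, subset) {
  stopifnot(inherits(model, "google_model"))
  if (inherits(subset, "gene_set")) subset <- subset$labels
  subset <- as.character(subset)
  if (model$n > 2000) stop("direct_oracle() requires N <= 2000", call. = FALSE)
  G <- dense_google(model)
  r <- match(subset, model$nodes)
  if (anyNA(r)) stop("subset labels not in the network", call. = FALSE)
  s <- setdiff(seq_len(model$n), r)
  if (length(s) == 0) return(G[r, r, drop = FALSE])
  X <- solve(diag(length(s)) - G[s, s, drop = FALSE], G[s, r, drop = FALSE])
  GR <- G[r, r, drop = FALSE] + G[r, s, drop = FALSE] %*% X
  dimnames(GR) <- list(subset, subset)
  GR
}
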