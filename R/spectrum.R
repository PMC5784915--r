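#' Leading complex spectrum of the Google matrix
#'
#' Computes the `k` largest-modulus eigenvalues and eigenvectors of the
#' (non-symmetric) Google operator.  The eigenvalue of largest modulus is
#' exactly 1 with the nonnegative PageRank eigenvector; every other
#' eigenvalue of G equals alpha times an eigenvalue of S, since all
#' non-leading eigenvectors are orthogonal to the uniform left eigenvector.
#' Eigenvector localization is summarized by the inverse participation ratio
#' ([ipr()]).
#'
#' Small operators (N below `dense_cutoff`) are diagonalized densely;
#' larger ones go through the implicitly restarted Arnoldi iteration
#' (`igraph::arpack`), applied matrix-free, with a restart at a larger
#' subspace if the first pass fails.
#'
#' @param model A `google_model`.
#' @param k Number of eigenpairs, `1 <= k < N`.
#' @param dense_cutoff Size below which a dense eigendecomposition is used.
#' @return A `spectrum_result`: list with complex `values` (decreasing
#'   modulus), `vectors` (N x k complex matrix, phase fixed so the
#'   largest-modulus component of each vector is real positive), `ipr`,
#'   `residuals` and `nodes`.
#' @export
leading_spectrum <- function(model, k, dense_cutoff = 300) {
  stopifnot(inherits(model, "google_model"))
  n <- model$n
  if (k < 1 || k >= n) stop("need 1 <= k < N", call. = FALSE)
  if (n <= dense_cutoff) {
    e <- eigen(dense_google(model))
    ord <- order(-Mod(e$values))
    values <- e$values[ord][seq_len(k)]
    vectors <- e$vectors[, ord, drop = FALSE][, seq_len(k), drop = FALSE]
  } else {
    fn <- function(x, extra) apply_google(model, x)
    res <- NULL
    for (ncv in unique(pmin(n, c(max(2L * k + 5L, 25L), max(4L * k + 10L, 60L))))) {
      res <- tryCatch(
        igraph::arpack(fn, options = list(n = n, nev = k, ncv = ncv,
                                          which = "LM", maxiter = 5000),
                       sym = FALSE, complex = TRUE),
        error = function(e) NULL
      )
      if (!is.null(res)) break
    }
    if (is.null(res)) {
      stop("Arnoldi iteration failed even with an enlarged subspace",
           call. = FALSE)
    }
    ord <- order(-Mod(res$values))
    values <- res$values[ord][seq_len(k)]
    vectors <- res$vectors[, ord, drop = FALSE][, seq_len(k), drop = FALSE]
  }
  vectors <- matrix(as.complex(vectors), nrow = n)
  # deterministic phase: largest-modulus component real positive, unit norm
  for (j in seq_len(k)) {
    v <- vectors[, j]
    v <- v / sqrt(sum(Mod(v)^2))
    top <- which.max(Mod(v))
    v <- v * Conj(v[top]) / Mod(v[top])
    vectors[, j] <- v
  }
  residuals <- vapply(seq_len(k), function(j) {
    gv <- apply_google_complex(model, vectors[, j])
    sqrt(sum(Mod(gv - values[j] * vectors[, j])^2))
  }, 0)
  if (any(residuals > 1e-8)) {
    warning("eigenpair residual above 1e-8 (max ",
            format(max(residuals)), ")", call. = FALSE)
  }
  structure(
    list(values = values, vectors = vectors,
         ipr = apply(vectors, 2, ipr), residuals = residuals,
         nodes = model$nodes),
    class = "spectrum_result"
  )
}

# complex-vector G application (real operator applied to Re and Im parts)
apply_google_complex <- function(model, v) {
  complex(real = apply_google(model, Re(v)),
          imaginary = apply_google(model, Im(v)))
}

#' @exportS3Method base::print
print.spectrum_result <- function(x, ...) {
  cat("<spectrum_result> ", length(x$values), " leading eigenvalues, |lambda| in [",
      format(min(Mod(x$values)), digits = 4), ", ",
      format(max(Mod(x$values)), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Inverse participation ratio of an eigenvector
#'
#' The effective number of nodes supporting an amplitude vector: after
#' normalizing sum(|psi|^2) = 1,
#' \deqn{\xi = (\sum_n |\psi_n|^2)^2 / \sum_n |\psi_n|^4 = 1 / \sum_n |\psi_n|^4.}
#' A single-spike vector gives xi = 1 (fully localized), the uniform vector
#' gives xi = N.  Scale-invariant and permutation-invariant.
#'
#' @param psi Numeric or complex non-zero vector.
#' @return Scalar in \[1, N\].
#' @export
ipr <- function(psi) {
  a2 <- Mod(psi)^2
  tot <- sum(a2)
  if (tot == 0) stop("IPR of the zero vector is undefined", call. = FALSE)
  a2 <- a2 / tot
  1 / sum(a2^2)
}
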