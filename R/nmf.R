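#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius reconstruction error \eqn{\|X - WH\|_F^2} with
#' the Lee-Seung multiplicative update rules, restarted from several random
#' initializations; the restart with the lowest final error is returned.
#' Within every restart the error is non-increasing from iteration to
#' iteration. A restart stops early once the relative error improvement
#' stays below `tol` for `conv_window` consecutive iterations.
#'
#' The returned factors are gauge-normalized: each column of W is scaled to
#' unit maximum and the compensating scale is pushed into the rows of H, so
#' cluster weights in W are comparable across clusters while the product
#' W H (and the error) is unchanged. The choice is recorded in
#' `$normalization`.
#'
#' @param X Non-negative matrix or an [build_matrix()] `assoc_matrix`.
#' @param K Factorization rank (number of clusters), `1 <= K <= min(dim(X))`.
#' @param n_restarts Number of random initializations.
#' @param max_iter Maximum iterations per restart.
#' @param conv_window Convergence stability window (iterations).
#' @param tol Relative improvement threshold for convergence.
#' @param seed Integer seed; fixed seed gives an identical fit.
#' @return Object of class `nmf_fit`: `W` (rows = trait features), `H`
#'   (columns = variants), `K`, `frobenius_error`, `n_iter`,
#'   `restart_errors`, `error_path` (per-iteration error of the winning
#'   restart), `normalization`.
#' @export
nmf <- function(X, K, n_restarts = 30L, max_iter = 10000L, conv_window = 80L,
                tol = 1e-6, seed = 1L) {
  X <- as_matrix_input(X)
  check_number(K, "K", lower = 1, upper = min(dim(X)))
  K <- as.integer(K)
  eps <- 1e-12

  with_seed(seed, {
    best <- NULL
    restart_errors <- numeric(n_restarts)
    scale0 <- sqrt(mean(X) / K + eps)
    for (r in seq_len(n_restarts)) {
      W <- matrix(stats::runif(nrow(X) * K, 0, scale0), nrow(X), K)
      H <- matrix(stats::runif(K * ncol(X), 0, scale0), K, ncol(X))
      err <- sqrt(sum((X - W %*% H)^2))
      path <- numeric(max_iter + 1L)
      path[1L] <- err
      stable <- 0L
      it <- 0L
      while (it < max_iter) {
        it <- it + 1L
        H <- H * (crossprod(W, X)) / (crossprod(W) %*% H + eps)
        W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
        new_err <- sqrt(sum((X - W %*% H)^2))
        improve <- (err - new_err) / max(err, eps)
        stable <- if (improve < tol) stable + 1L else 0L
        err <- new_err
        path[it + 1L] <- err
        if (stable >= conv_window) break
      }
      path <- path[seq_len(it + 1L)]
      restart_errors[r] <- err
      if (is.null(best) || err < best$frobenius_error) {
        best <- list(W = W, H = H, frobenius_error = err, n_iter = it,
                     error_path = path)
      }
    }
    W <- best$W
    H <- best$H
    d <- apply(W, 2, max)
    d[d == 0] <- 1
    W <- sweep(W, 2, d, "/")
    H <- sweep(H, 1, d, "*")
    dimnames(W) <- list(rownames(X), sprintf("cluster_%d", seq_len(K)))
    dimnames(H) <- list(colnames(W), colnames(X))
    structure(list(W = W, H = H, K = K,
                   frobenius_error = best$frobenius_error,
                   n_iter = best$n_iter, restart_errors = restart_errors,
                   error_path = best$error_path,
                   normalization = "W columns scaled to unit max; H rows compensated",
                   seed = as.integer(seed)),
              class = "nmf_fit")
  })
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("NMF fit: K = %d, Frobenius error %.4g after %d iterations (%d restarts)\n",
              x$K, x$frobenius_error, x$n_iter, length(x$restart_errors)))
  invisible(x)
}

# Mean silhouette width of variants assigned to their argmax cluster,
# Euclidean distance on unit-normalized H columns. Degenerate
# clusterings (any empty cluster, or a single occupied cluster) score -1.
silhouette_of_fit <- function(H) {
  assign <- apply(H, 2, which.max)
  K <- nrow(H)
  if (length(unique(assign)) < K || K < 2) return(-1)
  nrm <- sqrt(colSums(H^2))
  nrm[nrm == 0] <- 1
  Hn <- sweep(H, 2, nrm, "/")
  sil <- cluster::silhouette(assign, stats::dist(t(Hn)))
  mean(sil[, "sil_width"])
}

#' Scan factorization ranks and select the cluster count
#'
#' Runs [nmf()] for every K in `K_range` and records the Frobenius error
#' and the mean silhouette width of the implied hard assignment (variants
#' assigned to the cluster with their largest H weight; Euclidean distance
#' between unit-normalized H columns). The selected K maximizes the mean
#' silhouette; ties are broken by lower Frobenius error, then smaller K.
#' Ranks with a degenerate assignment (an empty cluster) get silhouette -1
#' and so are never preferred over a valid rank.
#'
#' @param X Non-negative matrix or `assoc_matrix`.
#' @param K_range Length-2 integer range, clipped to the matrix dimensions.
#' @param n_restarts,max_iter,conv_window,tol Passed to [nmf()].
#' @param seed Integer seed (per-K seeds are derived from it).
#' @param keep_fits Keep every per-K fit (default keeps only the selected).
#' @return Object of class `rank_scan`: `table` (K, frobenius_error,
#'   mean_silhouette), `selected_K`, `fit` (the [nmf()] fit at the selected
#'   K) and optionally `fits`.
#' @export
rank_scan <- function(X, K_range = c(2L, 20L), n_restarts = 30L,
                      max_iter = 10000L, conv_window = 80L, tol = 1e-6,
                      seed = 1L, keep_fits = FALSE) {
  X <- as_matrix_input(X)
  ks <- seq(max(1L, K_range[1]), min(K_range[2], min(dim(X))))
  if (!length(ks)) stop_param("empty K range after clipping")
  tab <- data.frame(K = ks, frobenius_error = NA_real_,
                    mean_silhouette = NA_real_)
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    fit <- nmf(X, ks[i], n_restarts = n_restarts, max_iter = max_iter,
               conv_window = conv_window, tol = tol,
               seed = seed + 1000L * ks[i])
    tab$frobenius_error[i] <- fit$frobenius_error
    tab$mean_silhouette[i] <- silhouette_of_fit(fit$H)
    fits[[i]] <- fit
  }
  ord <- order(-tab$mean_silhouette, tab$frobenius_error, tab$K)
  selected <- tab$K[ord[1]]
  structure(list(table = tab, selected_K = selected,
                 fit = fits[[match(selected, ks)]],
                 fits = if (keep_fits) fits else NULL),
            class = "rank_scan")
}

#' @export
print.rank_scan <- function(x, ...) {
  cat(sprintf("Rank scan over K = %d..%d; selected K = %d\n",
              min(x$table$K), max(x$table$K), x$selected_K))
  print(x$table, row.names = FALSE)
  invisible(x)
}
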