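#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

stop_param <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_param(sprintf("`%s` must be a single number in [%s, %s]",
                       name, format(lower), format(upper)))
  }
  x
}

#' Labels at or above the 90th percentile of a weight vector
#'
#' Selects the "top decile" of a cluster: every element whose weight is
#' greater than or equal to the 90th percentile of that cluster's weights.
#' The percentile uses linear interpolation between order statistics
#' (the default quantile definition), so ties at the threshold are all
#' included.
#'
#' @param weights Named numeric vector of non-negative cluster weights.
#' @param prob Percentile defining membership (default 0.9).
#' @return Character vector of the selected names (or indices if unnamed).
#' @examples
#' top_decile(c(a = 1, b = 5, c = 10, d = 10))
#' @export
top_decile <- function(weights, prob = 0.9) {
  if (length(weights) == 0L) stop_param("`weights` must be non-empty")
  if (is.null(names(weights))) names(weights) <- as.character(seq_along(weights))
  thr <- stats::quantile(weights, prob, names = FALSE, type = 7)
  names(weights)[weights >= thr]
}

#' Best-permutation cluster assignment accuracy
#'
#' Compares a predicted cluster assignment with a reference assignment by
#' maximizing agreement over all relabellings (Hungarian-style matching;
#' solved by exhaustive permutation search for small K, greedy matching on
#' the contingency table otherwise).
#'
#' @param predicted,reference Vectors of equal length giving cluster labels.
#' @return Fraction of elements agreeing under the best label matching.
#' @export
cluster_match_accuracy <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop_param("`predicted` and `reference` must have the same length")
  }
  p <- as.integer(factor(predicted))
  r <- as.integer(factor(reference))
  tab <- table(factor(p, levels = seq_len(max(p))),
               factor(r, levels = seq_len(max(r))))
  k <- max(nrow(tab), ncol(tab))
  m <- matrix(0, k, k)
  m[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  best <- if (k <= 8L) {
    perms <- permutations_of(k)
    max(vapply(perms, function(pp) sum(m[cbind(seq_len(k), pp)]), numeric(1)))
  } else {
    # greedy: repeatedly take the largest remaining cell
    tot <- 0
    mm <- m
    for (i in seq_len(k)) {
      idx <- arrayInd(which.max(mm), dim(mm))
      tot <- tot + mm[idx]
      mm[idx[1], ] <- -1
      mm[, idx[2]] <- -1
    }
    tot
  }
  best / length(p)
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (s in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}
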