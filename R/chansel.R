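#' Build the cohort tensor for one stimulus category
#'
#' Stacks one stimulus segment per subject into a 3-way array
#' `[F x C x S]` (time points x channels x subjects).  All subjects must
#' share the segment length and channel count.
#'
#' @param segments list of `stimulus_segment` (one per subject) or numeric
#'   matrices `[F x C]`.
#' @return numeric 3-way array.
#' @export
cohort_tensor <- function(segments) {
  mats <- lapply(segments, function(s) if (is.matrix(s)) s else s$signal)
  dims <- vapply(mats, dim, integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1) {
    stop("inconsistent segment dimensions across subjects: F in {",
         paste(unique(dims[1, ]), collapse = ","), "}, C in {",
         paste(unique(dims[2, ]), collapse = ","), "}")
  }
  arr <- array(unlist(mats), dim = c(dims[1, 1], dims[2, 1], length(mats)))
  if (any(!is.finite(arr))) stop("tensor contains non-finite values")
  arr
}

# column-wise Khatri-Rao product
khatri_rao <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  out <- vapply(seq_len(ncol(A)),
                function(t) kronecker(A[, t], B[, t]),
                numeric(nrow(A) * nrow(B)))
  matrix(out, nrow = nrow(A) * nrow(B))
}

#' CANDECOMP/PARAFAC decomposition by alternating least squares
#'
#' Approximates a 3-way tensor as a sum of `T` rank-one outer products
#' `sum_t lambda_t a_t o b_t o d_t`, with all factor columns normalised to
#' unit Euclidean length and the scale absorbed into the weight vector
#' `lambda`.  Alternating least squares with seeded Gaussian restarts; the
#' relative Frobenius reconstruction error is non-increasing across
#' iterations, and iteration stops when its change falls below `tol`.
#' Sign indeterminacy is resolved by making the largest-magnitude entry of
#' each channel-factor column positive.
#'
#' @param X numeric 3-way array `[F x C x S]`.
#' @param T_rank decomposition rank (>= 1).
#' @param tol relative-error change tolerance (default 1e-6).
#' @param max_iter iteration cap per restart (default 200).
#' @param seed integer seed for the random initial factors.
#' @param n_restarts random restarts; best final error kept (default 5).
#' @return a `cpd_result`: factor matrices `A` (`F x T`), `B` (`C x T`),
#'   `D` (`S x T`), weights `lambda`, `T_rank`, `rel_error`, per-iteration
#'   `error_trace`, `iterations`, `converged`.
#' @export
cpd_als <- function(X, T_rank, tol = 1e-6, max_iter = 200, seed = 1,
                    n_restarts = 5) {
  stopifnot(length(dim(X)) == 3, T_rank >= 1)
  if (all(X == 0)) stop("degenerate tensor: all entries zero")
  if (any(!is.finite(X))) stop("tensor contains non-finite values")
  dims <- dim(X)
  X1 <- matrix(aperm(X, c(1, 2, 3)), dims[1], dims[2] * dims[3]) # F x (C*S)
  X2 <- matrix(aperm(X, c(2, 1, 3)), dims[2], dims[1] * dims[3]) # C x (F*S)
  X3 <- matrix(aperm(X, c(3, 1, 2)), dims[3], dims[1] * dims[2]) # S x (F*C)
  normX <- sqrt(sum(X^2))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1)
    A <- matrix(stats::rnorm(dims[1] * T_rank), dims[1], T_rank)
    B <- matrix(stats::rnorm(dims[2] * T_rank), dims[2], T_rank)
    D <- matrix(stats::rnorm(dims[3] * T_rank), dims[3], T_rank)
    err_prev <- Inf
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      A <- X1 %*% khatri_rao(D, B) %*% solve_gram(D, B)
      B <- X2 %*% khatri_rao(D, A) %*% solve_gram(D, A)
      D <- X3 %*% khatri_rao(B, A) %*% solve_gram(B, A)
      # residual via the mode-3 unfolding
      recon <- D %*% t(khatri_rao(B, A))
      err <- sqrt(sum((X3 - recon)^2)) / normX
      trace <- c(trace, err)
      if (is.finite(err_prev) && abs(err_prev - err) < tol) {
        converged <- TRUE
        err_prev <- err
        break
      }
      err_prev <- err
    }
    if (is.null(best) || err_prev < best$rel_error) {
      best <- list(A = A, B = B, D = D, rel_error = err_prev,
                   error_trace = trace, iterations = length(trace),
                   converged = converged)
    }
  }
  # normalise columns, absorb scale into lambda, fix signs on B
  norms <- function(M) apply(M, 2, function(v) sqrt(sum(v^2)))
  nA <- norms(best$A); nB <- norms(best$B); nD <- norms(best$D)
  nA[nA == 0] <- 1; nB[nB == 0] <- 1; nD[nD == 0] <- 1
  A <- sweep(best$A, 2, nA, `/`)
  B <- sweep(best$B, 2, nB, `/`)
  D <- sweep(best$D, 2, nD, `/`)
  lambda <- nA * nB * nD
  for (t in seq_len(T_rank)) {
    s <- sign(B[which.max(abs(B[, t])), t])
    if (s < 0) { B[, t] <- -B[, t]; A[, t] <- -A[, t] }
  }
  structure(list(A = A, B = B, D = D, lambda = lambda, T_rank = T_rank,
                 rel_error = best$rel_error,
                 error_trace = best$error_trace,
                 iterations = best$iterations, converged = best$converged),
            class = "cpd_result")
}

# (M1'M1 * M2'M2)^-1 with a ridge fallback for near-singular Grams
solve_gram <- function(M1, M2) {
  G <- crossprod(M1) * crossprod(M2)
  tryCatch(solve(G), error = function(e)
    solve(G + diag(1e-10 * max(diag(G)), nrow(G))))
}

#' @export
print.cpd_result <- function(x, ...) {
  cat("cpd_result: rank", x$T_rank, "| rel_error",
      signif(x$rel_error, 4), "|", x$iterations, "iterations\n")
  invisible(x)
}

#' Rank channels from the channel factor matrix
#'
#' Computes the Pearson correlation matrix `P` between the channels' rows
#' of the CPD channel factor `B`, averages each row of `P` (diagonal
#' included), and orders channels by descending row mean; ties are broken
#' by ascending channel index.  A zero-variance channel row has undefined
#' correlations and is ranked last, with a warning.
#'
#' @param B channel factor matrix `[C x T]`, `C >= 2`, `T >= 2`.
#' @return a `channel_ranking`: `P`, `row_means`, `order` (permutation of
#'   `1..C`), and `top_k()` is available via [select_channels()].
#' @export
rank_channels <- function(B) {
  B <- as.matrix(B)
  C <- nrow(B)
  if (C < 2 || ncol(B) < 2) stop("need C >= 2 channels and T >= 2 components")
  vars <- apply(B, 1, stats::var)
  degenerate <- vars == 0 | is.na(vars)
  if (any(degenerate)) {
    warning("zero-variance channel row(s) ranked last: ",
            paste(which(degenerate), collapse = ", "))
  }
  P <- suppressWarnings(stats::cor(t(B)))
  # correlations with degenerate channels are undefined (NA) and excluded
  # from the other channels' row means
  row_means <- rowMeans(P, na.rm = TRUE)
  key <- row_means
  key[degenerate] <- -Inf
  ord <- order(-key, seq_len(C))
  structure(list(P = P, row_means = row_means, order = ord),
            class = "channel_ranking")
}

#' @export
print.channel_ranking <- function(x, ...) {
  cat("channel_ranking:", paste(x$order, collapse = " > "), "\n")
  invisible(x)
}

#' Select the most informative channels for a stimulus category
#'
#' Builds the cohort tensor for the category, decomposes it with
#' [cpd_als()], ranks channels from the channel factor matrix, and returns
#' the top `k`.  Applied separately per stimulus category, yielding one
#' channel set per stimulus.
#'
#' @param segments list of per-subject `stimulus_segment`s (already of the
#'   requested category) or matrices.
#' @param T_rank CPD rank (default 10; must be >= 2).
#' @param k number of channels to keep (default 7; `k <= C`).
#' @param ... passed to [cpd_als()] (`tol`, `max_iter`, `seed`,
#'   `n_restarts`).
#' @return list with `top_k` (selected channel indices, ranking order),
#'   `ranking` (`channel_ranking`), and `cpd` (`cpd_result`).
#' @export
select_channels <- function(segments, T_rank = 10, k = 7, ...) {
  X <- cohort_tensor(segments)
  if (k > dim(X)[2]) stop("k = ", k, " exceeds C = ", dim(X)[2])
  cpd <- cpd_als(X, T_rank, ...)
  ranking <- rank_channels(cpd$B)
  list(top_k = ranking$order[seq_len(k)], ranking = ranking, cpd = cpd)
}
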