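#' Binarize hemodynamic signals by their mean
#'
#' Each channel is thresholded at its own mean computed over the segment
#' being analysed (per stimulus, per participant, per channel): samples
#' strictly above the mean become spin +1 ("active", displayed as "1"),
#' all others -1 ("0").  Equality with the threshold maps to -1; this tie
#' rule is deterministic and documented rather than meaningful.
#'
#' @param x a `stimulus_segment`, a `recording`, or a numeric matrix
#'   `[time x channels]`.
#' @param channels optional channel selector (indices or names) applied
#'   before thresholding; defaults to all columns.
#' @return a `binary_states` object: list with `spins` (`[F x C]`, +-1),
#'   `channels`, and `F`.
#' @export
binarize <- function(x, channels = NULL) {
  sig <- if (is.matrix(x)) x else x$signal
  if (is.null(sig) || !is.numeric(sig)) stop("no numeric signal to binarize")
  if (!is.null(channels)) sig <- sig[, channels, drop = FALSE]
  if (nrow(sig) < 1) stop("empty signal")
  vars <- apply(sig, 2, stats::var)
  if (nrow(sig) == 1) vars <- rep(0, ncol(sig))
  bad <- which(is.na(vars) | vars == 0)
  if (length(bad) > 0) {
    nm <- colnames(sig)[bad]
    if (is.null(nm)) nm <- bad
    stop("zero-variance channel(s), mean threshold undefined: ",
         paste(nm, collapse = ", "))
  }
  mu <- colMeans(sig)
  spins <- ifelse(sweep(sig, 2, mu, `-`) > 0, 1, -1)
  binary_states(spins, channels = colnames(sig))
}

#' Construct a binary state series
#' @param spins matrix `[F x C]` with entries +-1.
#' @param channels optional channel labels.
#' @export
binary_states <- function(spins, channels = NULL) {
  spins <- as.matrix(spins)
  if (!all(spins %in% c(-1, 1))) stop("spins must be +1/-1")
  structure(list(spins = spins, channels = channels,
                 F = nrow(spins), C = ncol(spins)),
            class = "binary_states")
}

#' @export
print.binary_states <- function(x, ...) {
  cat("binary_states:", x$F, "samples x", x$C, "channels\n")
  invisible(x)
}

#' Empirical state statistics
#'
#' Computes, from a binary state series over C channels, the empirical
#' probability of each of the 2^C states (occurrence counts divided by the
#' number of samples F), the per-channel activation rates `<sigma_m>` and
#' the pairwise co-occurrences `<sigma_m sigma_n>` as time averages over
#' spins in \{-1, +1\}.
#'
#' @param states a `binary_states` object or +-1 spin matrix.
#' @return an `empirical_stats` object: `Pe` (length 2^C, sums to 1),
#'   `counts`, `act` (length C), `cooc` (`[C x C]`, unit diagonal), `F`, `C`.
#' @export
empirical_stats <- function(states) {
  spins <- if (inherits(states, "binary_states")) states$spins else as.matrix(states)
  F_ <- nrow(spins); C <- ncol(spins)
  if (F_ < 1) stop("need at least one sample")
  if (C > 12) stop("C = ", C, " > 12: full 2^C state enumeration refused")
  bits <- (spins + 1) / 2
  codes <- as.integer(bits %*% 2^((C - 1):0))
  counts <- tabulate(codes + 1L, nbins = 2^C)
  act <- colMeans(spins)
  cooc <- crossprod(spins) / F_
  structure(list(Pe = counts / F_, counts = counts, act = act, cooc = cooc,
                 F = F_, C = C), class = "empirical_stats")
}

#' Moments of a full state distribution
#'
#' Activation rates and co-occurrences implied by a probability vector over
#' all 2^C states (enumeration); used both for model moments and to turn an
#' analytic distribution into fitting targets.
#'
#' @param P probability vector of length 2^C.
#' @param C number of channels.
#' @return an `empirical_stats` object with `F = NA` (analytic distribution).
#' @export
moments_from_distribution <- function(P, C) {
  stopifnot(length(P) == 2^C, all(P >= 0))
  if (abs(sum(P) - 1) > 1e-8) stop("P must sum to 1")
  S <- state_matrix(C)
  act <- as.vector(crossprod(S, P))
  cooc <- crossprod(S, S * P)
  cooc <- (cooc + t(cooc)) / 2
  diag(cooc) <- 1
  structure(list(Pe = P, counts = NULL, act = act, cooc = cooc,
                 F = NA_integer_, C = C), class = "empirical_stats")
}

#' Pairwise maximum-entropy (Ising/Boltzmann) model
#'
#' Builds the model object from fields `h` and couplings `J`: per-state
#' energies \eqn{E(s) = -\sum_m h_m \sigma_m - \frac12 \sum_{m \ne n}
#' J_{mn} \sigma_m \sigma_n} and Boltzmann probabilities
#' \eqn{P(s) \propto \exp(-E(s))} over all 2^C states.
#'
#' @param h field vector (length C), baseline activation tendency per channel.
#' @param J symmetric coupling matrix (`[C x C]`, zero diagonal), pairwise
#'   channel interactions.
#' @param method,iterations,final_update,converged fit metadata.
#' @return a `pmem_model` with `h`, `J`, `E` (length 2^C), `P` (sums to 1).
#' @export
pmem_model <- function(h, J = NULL, method = "direct", iterations = NA_integer_,
                       final_update = NA_real_, converged = NA) {
  C <- length(h)
  if (is.null(J)) J <- matrix(0, C, C)
  J <- as.matrix(J)
  stopifnot(nrow(J) == C, ncol(J) == C)
  if (max(abs(J - t(J))) > 1e-10) stop("J must be symmetric")
  if (max(abs(diag(J))) > 1e-10) stop("J must have zero diagonal")
  J <- (J + t(J)) / 2; diag(J) <- 0
  S <- state_matrix(C)
  E <- as.vector(-(S %*% h) - 0.5 * rowSums((S %*% J) * S))
  P <- exp(-(E - min(E)))
  P <- P / sum(P)
  structure(list(h = h, J = J, E = E, P = P, C = C, method = method,
                 iterations = iterations, final_update = final_update,
                 converged = converged),
            class = "pmem_model")
}

#' @export
print.pmem_model <- function(x, ...) {
  cat("pmem_model (", x$method, "): C =", x$C,
      "| iterations =", x$iterations,
      "| converged =", x$converged, "\n")
  cat("  h:", signif(x$h, 3), "\n")
  invisible(x)
}

#' Model-predicted moments
#'
#' Activation rates and pairwise co-occurrences under the model's Boltzmann
#' distribution, by enumeration over all 2^C states.
#'
#' @param model a `pmem_model`.
#' @export
model_moments <- function(model) {
  moments_from_distribution(model$P, model$C)
}

#' Independent maximum-entropy model (J = 0 baseline)
#'
#' Closed form: with couplings fixed at zero the maximum-entropy fit matching
#' the activation rates has `h_m = atanh(<sigma_m>)` and factorizes over
#' channels.  Serves as the baseline in the accuracy index.
#'
#' @param stats an `empirical_stats` object.
#' @return a `pmem_model` with zero `J`.
#' @export
fit_independent_mem <- function(stats) {
  stopifnot(inherits(stats, "empirical_stats"))
  if (any(abs(stats$act) >= 1)) {
    stop("saturated channel(s) with |<sigma>| = 1: ",
         paste(which(abs(stats$act) >= 1), collapse = ", "))
  }
  pmem_model(atanh(stats$act), method = "independent",
             iterations = 0L, final_update = 0, converged = TRUE)
}

#' Fit the pairwise maximum-entropy model
#'
#' Two fit modes sharing one result contract.  `method = "pl"` maximises the
#' log pseudo-likelihood (the sum over channels of the logistic conditional
#' of each spin given the others) by full-batch gradient ascent on the
#' samples.  `method = "exact"` performs moment matching with the exact
#' gradient: empirical minus model moments, the latter via enumeration over
#' all 2^C states.  Both use a fixed learning rate (default 0.1) and stop
#' when the largest absolute parameter update falls below `tol` (default
#' 5e-6) or after `max_iter` iterations; `h` and `J` start at zero (both
#' objectives are concave, so the optimum does not depend on the start).
#'
#' @param x a `binary_states` series, or an `empirical_stats` object
#'   (required for `method = "exact"`, sufficient for `"pl"` too since the
#'   pseudo-likelihood depends on the data only through state frequencies).
#' @param method `"exact"` (moment matching) or `"pl"` (pseudo-likelihood).
#' @param lr learning rate.
#' @param tol stopping threshold on the max absolute parameter update.
#' @param max_iter iteration cap; non-convergence returns the model with
#'   `converged = FALSE` and a warning.
#' @return a `pmem_model`.
#' @export
fit_pmem <- function(x, method = c("exact", "pl"), lr = 0.1, tol = 5e-6,
                     max_iter = 100000L) {
  method <- match.arg(method)
  if (inherits(x, "binary_states")) {
    stats <- empirical_stats(x)
  } else if (inherits(x, "empirical_stats")) {
    stats <- x
  } else if (is.matrix(x)) {
    stats <- empirical_stats(x)
  } else stop("x must be binary_states, empirical_stats, or a spin matrix")
  C <- stats$C
  if (C > 12) stop("C > 12 refused (2^C enumeration)")
  S <- state_matrix(C)
  if (method == "exact") {
    fit <- cpp_fit_exact(S, stats$act, stats$cooc, lr, tol, as.integer(max_iter))
  } else {
    keep <- stats$Pe > 0
    fit <- cpp_fit_pl(S[keep, , drop = FALSE], stats$Pe[keep], lr, tol,
                      as.integer(max_iter))
  }
  if (!fit$converged) {
    warning("fit_pmem (", method, ") did not converge after ", fit$iterations,
            " iterations (final update ", signif(fit$final_update, 3), ")")
  }
  pmem_model(as.vector(fit$h), fit$J, method = method,
             iterations = fit$iterations, final_update = fit$final_update,
             converged = fit$converged)
}

#' Accuracy index of the pairwise model
#'
#' Quantifies how much of the empirical state distribution the pairwise
#' couplings explain beyond independent channels: `r = (K1 - K2) / K1`,
#' where `K1` is the Kullback-Leibler divergence (base 2) of the empirical
#' distribution from the independent-MEM fit and `K2` from the pairwise fit.
#' `r = 1` when the pairwise model reproduces the empirical distribution
#' exactly; `r = 0` when pairwise interactions add nothing over the
#' independent baseline.
#'
#' @param Pe empirical probability vector over all 2^C states.
#' @param pmem fitted pairwise model (`pmem_model`).
#' @param mem fitted independent model (`pmem_model`, zero J).
#' @return an `accuracy_index` object with `K1`, `K2` (bits) and `r`.
#' @export
accuracy_index <- function(Pe, pmem, mem) {
  stopifnot(length(Pe) == length(pmem$P), length(Pe) == length(mem$P))
  K1 <- kl_bits(Pe, mem$P)
  K2 <- kl_bits(Pe, pmem$P)
  # guard: an empirical distribution the independent model fits exactly
  # leaves K1 at floating-point zero; r is then 0 by definition (pairwise
  # interactions contribute nothing)
  if (K1 <= 1e-10) {
    warning("K1 = 0: empirical distribution already independent-exact; r set to 0")
    r <- 0
  } else {
    r <- (K1 - K2) / K1
  }
  structure(list(K1 = K1, K2 = K2, r = r), class = "accuracy_index")
}

#' @export
print.accuracy_index <- function(x, ...) {
  cat(sprintf("accuracy index r = %.4f (K1 = %.4f, K2 = %.4f bits)\n",
              x$r, x$K1, x$K2))
  invisible(x)
}

# KL divergence in bits with the 0 log 0 = 0 convention; q is a Boltzmann
# distribution, hence strictly positive.
kl_bits <- function(p, q) {
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / q[nz]))
}
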