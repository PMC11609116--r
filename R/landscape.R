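#' Energy landscape on the state hypercube
#'
#' Views the per-state energies of a fitted pairwise maximum-entropy model
#' as a function on the hypercube graph: nodes are the 2^C states, edges
#' join states at Hamming distance 1.  Local minima (LMs) are states
#' strictly lower in energy than all C neighbours; the global minimum (GM)
#' is the lowest-energy state; every state is assigned to the basin of the
#' LM reached by steepest descent (move to the lowest-energy neighbour while
#' it improves; ties broken by lowest state code and flagged).
#'
#' @param x a `pmem_model` or a numeric vector of 2^C energies.
#' @param C number of channels (inferred from a model).
#' @return an `energy_landscape`: `energies`, `C`, `local_minima` and
#'   `global_minimum` (1-based positions, code = position - 1), `basin_of`
#'   (length 2^C, 1-based LM position owning each state), `basin_sizes`
#'   (named by LM position), `ties` flag.
#' @export
energy_landscape <- function(x, C = NULL) {
  if (inherits(x, "pmem_model")) {
    energies <- x$E
    C <- x$C
  } else {
    energies <- as.numeric(x)
    if (is.null(C)) {
      C <- round(log2(length(energies)))
    }
  }
  if (length(energies) != 2^C) stop("need 2^C energies")
  if (any(!is.finite(energies))) stop("non-finite energies")
  mins <- find_minima(energies, C)
  basins <- assign_basins(energies, C)
  structure(list(energies = energies, C = C,
                 local_minima = mins$local_minima,
                 global_minimum = mins$global_minimum,
                 gm_ties = mins$ties,
                 basin_of = basins$basin_of,
                 basin_sizes = basins$basin_sizes),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat("energy_landscape: C =", x$C, "|", length(x$local_minima),
      "local minima | GM =",
      state_string(decode_state(x$global_minimum - 1, x$C)), "\n")
  invisible(x)
}

#' Local and global minima of an energy vector
#'
#' @param energies numeric vector of 2^C finite energies.
#' @param C number of channels.
#' @return list with `local_minima` (1-based positions, ascending),
#'   `global_minimum` (1-based position; ties resolved to the lowest code
#'   and flagged via `ties`).  A landscape with no strict local minimum
#'   (e.g. constant energies) is degenerate and raises an error.
#' @export
find_minima <- function(energies, C) {
  if (length(energies) != 2^C) stop("need 2^C energies")
  if (any(!is.finite(energies))) stop("non-finite energies")
  nb <- neighbor_matrix(C)
  nbE <- matrix(energies[nb], nrow = 2^C)
  is_lm <- energies < apply(nbE, 1, min)
  lms <- which(is_lm)
  if (length(lms) == 0) {
    stop("degenerate landscape: no strict local minimum")
  }
  gmins <- which(energies == min(energies))
  list(local_minima = lms, global_minimum = gmins[1],
       ties = length(gmins) > 1)
}

#' Basin assignment by steepest descent
#'
#' From every state, repeatedly move to the lowest-energy neighbour while it
#' is strictly lower than the current state (ties among equally low
#' neighbours broken by lowest state code); the terminal state is a local
#' minimum and owns the starting state.  Basin sizes count owned states and
#' always sum to 2^C.
#'
#' @inheritParams find_minima
#' @return list with `basin_of` (length 2^C, 1-based LM position per state)
#'   and `basin_sizes` (named integer vector over LMs).
#' @export
assign_basins <- function(energies, C) {
  if (length(energies) != 2^C) stop("need 2^C energies")
  if (any(!is.finite(energies))) stop("non-finite energies")
  n <- 2^C
  nb <- neighbor_matrix(C)
  nbE <- matrix(energies[nb], nrow = n)
  # steepest-descent successor of each state (itself if local minimum);
  # which.min returns the first minimum, and neighbour columns are ordered
  # by flipped channel; break energy ties by lowest neighbour code instead.
  succ <- integer(n)
  for (i in seq_len(n)) {
    e_nb <- nbE[i, ]
    m <- min(e_nb)
    if (m < energies[i]) {
      cand <- nb[i, e_nb == m]
      succ[i] <- min(cand)
    } else {
      succ[i] <- i
    }
  }
  # pointer jumping: descent paths have length <= C * 2^C but collapse in
  # O(log) doubling steps
  owner <- succ
  repeat {
    nxt <- owner[owner]
    if (all(nxt == owner)) break
    owner <- nxt
  }
  stopifnot(all(owner == succ[owner]))  # owners are fixed points (LMs)
  sizes <- table(factor(owner, levels = sort(unique(owner))))
  basin_sizes <- as.integer(sizes)
  names(basin_sizes) <- names(sizes)
  list(basin_of = owner, basin_sizes = basin_sizes)
}

#' Metropolis random walk on the energy landscape
#'
#' Simulates state transitions by Markov chain Monte Carlo: at each of
#' `n_steps` iterations a Hamming-1 neighbour is proposed uniformly
#' (probability 1/C each); the walker moves if the proposed energy is lower
#' and otherwise moves with probability `exp(E_current - E_proposed)`,
#' staying put on rejection.  Each iteration advances time by one step
#' whether or not the proposal is accepted.  The stationary distribution is
#' the Boltzmann distribution of the energies.
#'
#' @param x an `energy_landscape`, `pmem_model`, or energy vector.
#' @param C number of channels (inferred when possible).
#' @param n_steps number of iterations (default 20000).
#' @param start 1-based starting state position, or `NULL` to draw uniformly
#'   over all 2^C states.
#' @param seed optional integer seed for reproducibility.
#' @param burn_in steps discarded from the front (default 0).
#' @return a `walk_result`: `trajectory` (1-based positions, length
#'   `n_steps - burn_in`), `start`, `n_steps`, `seed`.
#' @export
random_walk <- function(x, C = NULL, n_steps = 20000L, start = NULL,
                        seed = NULL, burn_in = 0L) {
  if (inherits(x, "energy_landscape") || inherits(x, "pmem_model")) {
    energies <- if (inherits(x, "pmem_model")) x$E else x$energies
    C <- x$C
  } else {
    energies <- as.numeric(x)
    if (is.null(C)) C <- round(log2(length(energies)))
  }
  stopifnot(length(energies) == 2^C, n_steps >= 1, burn_in >= 0,
            burn_in < n_steps)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start)) start <- sample.int(2^C, 1)
  stopifnot(start >= 1, start <= 2^C)
  traj <- cpp_random_walk(energies, C, as.integer(n_steps),
                          as.integer(start - 1L)) + 1L
  if (burn_in > 0) traj <- traj[-seq_len(burn_in)]
  structure(list(trajectory = traj, start = start,
                 n_steps = as.integer(n_steps), seed = seed),
            class = "walk_result")
}

#' Attractor features of one landscape and walk
#'
#' Extracts the participant-level energy-landscape features: the number of
#' local minima, the mean energy gap `E(LM) - E(GM)` over non-GM local
#' minima (0 when the GM is the only LM), the standard deviation of basin
#' sizes, and the walk's occupancy of the GM basin (`gm_duration`: total
#' steps whose state lies in the GM's basin).  For each requested major
#' state two dwell conventions are reported: the mean length of maximal
#' consecutive runs inside the state's basin (`mean_dwell`, "average
#' duration" per visit) and total occupancy (`total`).
#'
#' @param walk a `walk_result`.
#' @param landscape an `energy_landscape`.
#' @param major_states optional integer vector of 1-based state positions
#'   (or character display strings) whose basin dwell statistics are wanted;
#'   a major state that is not an LM of this landscape is mapped to the LM
#'   owning it, with a warning.
#' @return an `el_features` list: `n_LM`, `mean_gap`, `basin_size_sd`,
#'   `gm_duration`, `gm_mean_dwell`, and `major` (data frame with one row
#'   per major state: `state`, `basin_lm`, `mean_dwell`, `total`, `visits`).
#' @export
dwell_features <- function(walk, landscape, major_states = NULL) {
  stopifnot(inherits(walk, "walk_result"),
            inherits(landscape, "energy_landscape"))
  traj <- walk$trajectory
  owner <- landscape$basin_of[traj]
  gm <- landscape$global_minimum
  gm_duration <- sum(owner == gm)
  gm_mean_dwell <- mean_run_length(owner == gm)
  lm <- landscape$local_minima
  gaps <- landscape$energies[setdiff(lm, gm)] - landscape$energies[gm]
  major <- NULL
  if (!is.null(major_states) && length(major_states) > 0) {
    pos <- vapply(major_states, function(s) {
      if (is.character(s)) encode_state(parse_state(s)) + 1L else as.integer(s)
    }, integer(1))
    rows <- lapply(pos, function(p) {
      basin_lm <- landscape$basin_of[p]
      if (!(p %in% lm)) {
        warning("major state ", state_string(decode_state(p - 1, landscape$C)),
                " is not an LM here; using the basin of its owning LM")
      }
      inb <- owner == basin_lm
      data.frame(state = p, basin_lm = basin_lm,
                 mean_dwell = mean_run_length(inb),
                 total = sum(inb),
                 visits = n_runs(inb))
    })
    major <- do.call(rbind, rows)
    major$label <- vapply(major$state, function(p)
      state_string(decode_state(p - 1, landscape$C)), character(1))
  }
  structure(list(n_LM = length(lm),
                 mean_gap = if (length(gaps)) mean(gaps) else 0,
                 basin_size_sd = if (length(landscape$basin_sizes) > 1)
                   stats::sd(landscape$basin_sizes) else 0,
                 gm_duration = gm_duration,
                 gm_mean_dwell = gm_mean_dwell,
                 major = major,
                 n_steps = length(traj)),
            class = "el_features")
}

# mean length of maximal TRUE runs (0 if none); n_runs counts them
mean_run_length <- function(x) {
  r <- rle(x)
  lens <- r$lengths[r$values]
  if (length(lens) == 0) 0 else mean(lens)
}
n_runs <- function(x) {
  r <- rle(x)
  sum(r$values)
}

#' Major states across a collection of landscapes
#'
#' A major state is a state selected as a local minimum by every landscape
#' in the collection (the intersection of LM sets).  Also reports the most
#' frequently occurring LMs with their selection counts.
#'
#' @param landscapes list of `energy_landscape` objects (e.g. all
#'   participants under one stimulus).
#' @param top_n how many high-frequency LMs to report (default 6).
#' @return list with `major` (1-based positions present in every LM set;
#'   may be empty, with a warning), `major_labels`, and `top` (data frame
#'   of the `top_n` most frequent LMs: `state`, `label`, `count`).
#' @export
find_major_states <- function(landscapes, top_n = 6) {
  stopifnot(length(landscapes) >= 1)
  C <- landscapes[[1]]$C
  lm_sets <- lapply(landscapes, function(l) l$local_minima)
  major <- Reduce(intersect, lm_sets)
  if (length(major) == 0) warning("no state is an LM of every landscape")
  counts <- table(unlist(lm_sets))
  ord <- order(-as.integer(counts), as.integer(names(counts)))
  top_idx <- utils::head(ord, top_n)
  top <- data.frame(state = as.integer(names(counts))[top_idx],
                    count = as.integer(counts)[top_idx])
  top$label <- vapply(top$state, function(p)
    state_string(decode_state(p - 1, C)), character(1))
  major_labels <- vapply(sort(major), function(p)
    state_string(decode_state(p - 1, C)), character(1))
  list(major = sort(major), major_labels = major_labels, top = top)
}
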