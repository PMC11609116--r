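#' Binary brain states on the hypercube
#'
#' A brain state over `C` selected channels is a spin vector in
#' \{-1, +1\}^C.  States are indexed by the integer code obtained by reading
#' the spins as bits: the first (highest-ranked) channel is the leftmost,
#' most-significant bit, and spin +1 maps to bit "1".  Codes run from 0
#' (all channels inactive, "00...0") to 2^C - 1 (all active).  Most vector
#' APIs in this package use the 1-based position `code + 1` into length-2^C
#' vectors; functions documented as returning a "state index" return the
#' 0-based code.
#'
#' @param spins integer/numeric vector of +-1 spins, first channel first.
#' @return `encode_state`: the 0-based integer code of the state.
#' @examples
#' encode_state(c(-1, -1, 1))      # "001" -> 1
#' decode_state(6, C = 3)          # "110" -> c(1, 1, -1)
#' @export
encode_state <- function(spins) {
  if (!all(spins %in% c(-1, 1))) {
    stop("spins must be +1/-1, got: ", paste(unique(spins), collapse = ", "))
  }
  C <- length(spins)
  bits <- (spins + 1L) / 2L
  sum(bits * 2^((C - 1):0))
}

#' @rdname encode_state
#' @param code 0-based state code in `[0, 2^C - 1]`.
#' @param C number of channels.
#' @return `decode_state`: a +-1 spin vector of length `C`.
#' @export
decode_state <- function(code, C) {
  if (code < 0 || code >= 2^C) {
    stop("state code ", code, " out of range [0, ", 2^C - 1, "]")
  }
  bits <- as.integer(intToBits(as.integer(code)))[C:1]
  2L * bits - 1L
}

#' @rdname encode_state
#' @return `state_string`: the display string, e.g. `"0000111"`; the first
#'   selected channel is the leftmost character and "1" means active (+1).
#' @export
state_string <- function(spins) {
  paste0((spins + 1) / 2, collapse = "")
}

#' Parse a display string like "0000111" into a +-1 spin vector
#' @param x character scalar of 0/1 digits, leftmost = first channel.
#' @export
parse_state <- function(x) {
  bits <- as.integer(strsplit(x, "")[[1]])
  if (!all(bits %in% 0:1)) stop("state string must contain only 0/1: ", x)
  2L * bits - 1L
}

#' All 2^C spin vectors as a matrix
#'
#' Row `i` holds the spins of the state with code `i - 1`.
#'
#' @param C number of channels (C <= 20).
#' @return numeric matrix `[2^C x C]` with entries +-1.
#' @export
state_matrix <- function(C) {
  stopifnot(C >= 1, C <= 20)
  codes <- 0:(2^C - 1)
  m <- matrix(0, nrow = 2^C, ncol = C)
  for (ch in 1:C) {
    m[, ch] <- 2 * (codes %/% 2^(C - ch) %% 2) - 1
  }
  m
}

#' Hamming-1 neighbours of a state
#'
#' The energy landscape lives on the hypercube graph whose nodes are the
#' 2^C states and whose edges join states at Hamming distance 1; every state
#' therefore has exactly `C` neighbours.
#'
#' @param code 0-based state code.
#' @param C number of channels.
#' @return integer vector of the `C` neighbouring 0-based codes (the one
#'   obtained by flipping channel 1 first).
#' @export
neighbors <- function(code, C) {
  if (code < 0 || code >= 2^C) {
    stop("state code ", code, " out of range [0, ", 2^C - 1, "]")
  }
  vapply(1:C, function(ch) bitwXor(as.integer(code), 2L^(C - ch)), integer(1))
}

# 2^C x C integer matrix of 1-based neighbour positions; row i lists the
# neighbours of the state at position i (code i-1).
neighbor_matrix <- function(C) {
  codes <- 0:(2^C - 1)
  nb <- matrix(0L, nrow = 2^C, ncol = C)
  for (ch in 1:C) {
    nb[, ch] <- bitwXor(codes, 2L^(C - ch)) + 1L
  }
  nb
}
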