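# Bit-level helpers for network states.
#
# A state of an order-n network is an integer in [0, 2^n).  Node i is bit
# i-1 (little-endian: node 1 is the least-significant bit).  File formats
# write binary strings node-1-first; see read_truth_table().

#' Convert a state integer to a bit vector
#'
#' States are encoded little-endian: node 1 occupies the least-significant
#' bit, so state 3 of an order-3 network is `c(1, 1, 0)`.
#'
#' @param state Integer state code in `[0, 2^order)`.
#' @param order Number of nodes.
#' @return Integer vector of 0/1 bits, node 1 first.
#' @seealso [bits_to_state()]
#' @export
#' @examples
#' state_to_bits(5, 3)  # nodes 1 and 3 active
state_to_bits <- function(state, order) {
  stopifnot(length(state) == 1L, state >= 0, state < 2^order)
  bitwAnd(bitwShiftR(as.integer(state), 0:(order - 1L)), 1L)
}

#' Convert a bit vector to a state integer
#'
#' @param bits Integer vector of 0/1 values, node 1 first.
#' @return Integer state code.
#' @seealso [state_to_bits()]
#' @export
bits_to_state <- function(bits) {
  stopifnot(all(bits %in% c(0L, 1L)))
  as.integer(sum(bits * 2^(seq_along(bits) - 1L)))
}

# All states of an order-n network as a 2^n x n 0/1 matrix (row s+1 = state s).
state_matrix <- function(order) {
  s <- 0:(2^order - 1L)
  vapply(1:order, function(i) bitwAnd(bitwShiftR(s, i - 1L), 1L),
         integer(2^order))
}

# Format a state as a binary string, node 1 leftmost (file convention).
state_to_string <- function(state, order) {
  paste(state_to_bits(state, order), collapse = "")
}

string_to_state <- function(x) {
  bits_to_state(as.integer(strsplit(x, "")[[1]]))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
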