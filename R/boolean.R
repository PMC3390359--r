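# Synchronous Boolean-network engine.
#
# A genotype of an order-n network is an ordered list of n alleles; an
# allele is one node's update column: 2^n output bits, one per network
# state.  All nodes update simultaneously, so the genotype induces a
# deterministic transition map on the 2^n states, and every trajectory
# ends in an attractor: a fixed point or a periodic cycle.  Attractors are
# the phenotype unit of the package.

#' Construct a Boolean-network genotype
#'
#' @param alleles A list of `order` update columns, each an integer 0/1
#'   vector of length `2^order`: element `s + 1` is the node's next state
#'   when the network is in state `s` (states encoded little-endian, see
#'   [state_to_bits()]).  A `2^order x order` 0/1 matrix is also accepted.
#' @return An object of class `bn_genotype`.
#' @export
#' @examples
#' # 1-node negation: state 0 -> 1, state 1 -> 0
#' not1 <- bn_genotype(list(c(1L, 0L)))
#' trajectory_attractor(not1, 0)
bn_genotype <- function(alleles) {
  if (is.matrix(alleles))
    alleles <- lapply(seq_len(ncol(alleles)), function(i) alleles[, i])
  order <- length(alleles)
  if (order < 1L) stop("a genotype needs at least one allele")
  len <- lengths(alleles)
  if (any(len != 2^order))
    stop("each allele column must have length 2^order = ", 2^order)
  alleles <- lapply(alleles, function(a) {
    a <- as.integer(a)
    if (!all(a %in% c(0L, 1L))) stop("allele columns must be 0/1")
    a
  })
  structure(list(order = order, alleles = alleles), class = "bn_genotype")
}

#' @export
print.bn_genotype <- function(x, ...) {
  cat("Boolean-network genotype: order", x$order, "\n")
  tt <- transition_table(x)
  for (s in 0:(2^x$order - 1L))
    cat(" ", state_to_string(s, x$order), "->",
        state_to_string(tt[s + 1L], x$order), "\n")
  invisible(x)
}

#' Transition table of a genotype
#'
#' @param genotype A [bn_genotype].
#' @return Integer vector of length `2^order`; element `s + 1` is the
#'   successor state (0-based code) of state `s`.
#' @export
transition_table <- function(genotype) {
  stopifnot(inherits(genotype, "bn_genotype"))
  A <- do.call(cbind, genotype$alleles)
  as.integer(A %*% 2^(0:(genotype$order - 1L)))
}

#' Advance a network state by one synchronous step
#'
#' All nodes read the full current state and update simultaneously; node
#' i's next bit is entry `state + 1` of its allele column.
#'
#' @param genotype A [bn_genotype].
#' @param state Either an integer state code or a 0/1 bit vector of
#'   length `order` (node 1 first).  The result uses the same form.
#' @return The successor state.
#' @export
synchronous_step <- function(genotype, state) {
  stopifnot(inherits(genotype, "bn_genotype"))
  as_bits <- length(state) > 1L
  s <- if (as_bits) bits_to_state(state) else as.integer(state)
  if (s < 0 || s >= 2^genotype$order)
    stop("state out of range for order ", genotype$order)
  nxt <- vapply(genotype$alleles, function(a) a[s + 1L], 0L)
  if (as_bits) nxt else bits_to_state(nxt)
}

# Canonical form of a cyclic state sequence: rotate so the minimal state
# code comes first.  Successor order is preserved, so two attractors are
# identical iff their canonical sequences are identical.
canonical_cycle <- function(states) {
  k <- which.min(states)
  if (k > 1L) states <- c(states[k:length(states)], states[1:(k - 1L)])
  states
}

new_attractor <- function(states) {
  states <- as.integer(canonical_cycle(states))
  structure(list(kind = if (length(states) == 1L) "fixed" else "periodic",
                 states = states, period = length(states)),
            class = "bn_attractor")
}

#' @export
print.bn_attractor <- function(x, order = NULL, ...) {
  fmt <- if (is.null(order)) as.character(x$states) else
    vapply(x$states, state_to_string, "", order = order)
  cat(x$kind, "attractor, period", x$period, ":",
      paste(fmt, collapse = " -> "), "\n")
  invisible(x)
}

attractor_key <- function(states) paste(states, collapse = ",")

#' Run a trajectory to its attractor
#'
#' Follows the deterministic trajectory from `initial` until a state
#' repeats; transient states are discarded and the terminal cycle is
#' returned in canonical rotation (minimal state code first).
#'
#' @param genotype A [bn_genotype].
#' @param initial Initial state (integer code or bit vector).
#' @return A `bn_attractor` with fields `kind` (`"fixed"` or
#'   `"periodic"`), `states` (canonical cycle, 0-based codes) and
#'   `period`.
#' @export
trajectory_attractor <- function(genotype, initial) {
  tt <- transition_table(genotype)
  s <- if (length(initial) > 1L) bits_to_state(initial) else as.integer(initial)
  seen <- integer(0)
  pos <- rep(NA_integer_, length(tt))
  repeat {
    if (!is.na(pos[s + 1L])) break
    seen <- c(seen, s)
    pos[s + 1L] <- length(seen)
    s <- tt[s + 1L]
  }
  new_attractor(seen[pos[s + 1L]:length(seen)])
}

#' Derive the directed edge set of a genotype
#'
#' An edge j -> i exists iff node i's update rule depends essentially on
#' node j: flipping bit j changes node i's output in at least one state.
#' This is the criterion that defines network topology; inputs a column
#' happens to ignore contribute no edge.
#'
#' @param genotype A [bn_genotype].
#' @return An `order x order` 0/1 matrix `E` with `E[i, j] = 1` when an
#'   edge points from node j to node i.
#' @export
derive_edges <- function(genotype) {
  n <- genotype$order
  s <- 0:(2^n - 1L)
  E <- matrix(0L, n, n)
  for (i in 1:n) {
    f <- genotype$alleles[[i]]
    for (j in 1:n) {
      flipped <- bitwXor(s, bitwShiftL(1L, j - 1L))
      if (any(f != f[flipped + 1L])) E[i, j] <- 1L
    }
  }
  E
}

# Pooled attractor census over a matrix of transition tables (one row per
# genotype, 2^order columns of 0-based successors).  Used for libraries
# small enough to materialize in R; the exhaustive order-3 and threshold
# library censuses use the compiled path instead.
#
# Map-composition doubling brings every state into its attractor
# (transient <= 2^order - 1 < 2^order steps), then cycles are read off
# with the one-step table.
census_tmat <- function(tmat, order) {
  S <- 2^order
  G <- nrow(tmat)
  stopifnot(ncol(tmat) == S)
  B <- tmat
  rows <- rep.int(seq_len(G), S)
  for (k in seq_len(order))  # after this, 2^order steps
    B <- matrix(B[cbind(rows, as.vector(B) + 1L)], G, S)
  fixed_seen <- rep(FALSE, S)
  periodic <- new.env(parent = emptyenv())
  for (g in seq_len(G)) {
    att_states <- unique.default(B[g, ])
    tg <- tmat[g, ]
    is_fixed <- tg[att_states + 1L] == att_states
    fixed_seen[att_states[is_fixed] + 1L] <- TRUE
    for (s0 in att_states[!is_fixed]) {
      cyc <- s0
      s <- tg[s0 + 1L]
      while (s != s0) { cyc <- c(cyc, s); s <- tg[s + 1L] }
      cyc <- canonical_cycle(cyc)
      if (cyc[1L] == s0)  # record each cycle once, from its minimal state
        assign(attractor_key(cyc), cyc, envir = periodic)
    }
  }
  per <- mget(ls(periodic), envir = periodic)
  per <- per[base::order(vapply(per, `[`, 0L, 1L),
                         vapply(per, length, 0L))]
  names(per) <- NULL
  list(fixed = which(fixed_seen) - 1L, periodic = per,
       n_fixed = sum(fixed_seen), n_periodic = length(per),
       p = sum(fixed_seen) + length(per), n_genotypes = G)
}

#' Pooled attractor census of a genotype library
#'
#' Runs every genotype of the library from every initial state, pools the
#' resulting attractors across genotypes, and de-duplicates them by their
#' canonical state sequence.  The phenotype count is
#' `p = n_fixed + n_periodic`.
#'
#' @param library A [genotype_library], a list of [bn_genotype]s, or a
#'   single `bn_genotype`.
#' @param batch Number of genotypes materialized per block when censusing
#'   a lazily enumerated library.
#' @return A list with `fixed` (sorted 0-based fixed-point states),
#'   `periodic` (list of canonical cycles), `n_fixed`, `n_periodic`, `p`
#'   and `n_genotypes`.
#' @export
#' @examples
#' cls <- parse_topology_class("011 001 000")
#' attractor_census(topology_class_library(cls))
attractor_census <- function(library, batch = 65536L) {
  if (inherits(library, "bn_genotype")) library <- list(library)
  if (inherits(library, "genotype_library"))
    return(census_library(library, batch = batch))
  if (!is.list(library) || length(library) == 0L)
    stop("empty genotype library")
  ords <- vapply(library, function(g) g$order, 0L)
  if (length(unique(ords)) != 1L)
    stop("all genotypes in a library must share one order")
  tmat <- do.call(rbind, lapply(library, transition_table))
  census_tmat(tmat, ords[1L])
}

# Merge two census results (used for batched enumeration).
merge_census <- function(a, b) {
  if (is.null(a)) return(b)
  S_fixed <- sort(unique(c(a$fixed, b$fixed)))
  keys <- vapply(a$periodic, attractor_key, "")
  per <- a$periodic
  for (cyc in b$periodic) {
    k <- attractor_key(cyc)
    if (!(k %in% keys)) { per <- c(per, list(cyc)); keys <- c(keys, k) }
  }
  list(fixed = S_fixed, periodic = per, n_fixed = length(S_fixed),
       n_periodic = length(per), p = length(S_fixed) + length(per),
       n_genotypes = a$n_genotypes + b$n_genotypes)
}
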