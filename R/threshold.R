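# Threshold-network formalism and the yeast cell-cycle network (CCN).
#
# A threshold network specifies dynamics by signed unit-weight arrows:
# node i sums a_ij * S_j over the current state S and switches on (sum >
# 0), off (sum < 0), or -- on a tie -- holds its state unless it is
# self-degrading, in which case it switches off.  Self-degradation is
# metadata, not a signed arrow; in the truth-table formalism the
# conventions invert: a self-degrading node has NO self-edge, while a
# non-self-degrading node holds its state on ties and therefore DOES
# depend on itself.
#
# Each node of a threshold network admits three alleles: the wild-type
# update rule, a null allele (always off) and a constitutively active
# allele (always on).  The library of all 3^order allele assignments is
# the object whose attractor census defines the network's genetic
# complexity.

#' Construct a threshold network
#'
#' @param nodes Character vector of node names (defines the node order
#'   and the little-endian state encoding).
#' @param weights Integer matrix with `weights[i, j]` the sign (+1, -1,
#'   or 0) of the arrow from node j to node i.  Unit weights only; the
#'   diagonal must be zero -- self-influence is expressed through
#'   `self_degrading`, never through a signed self-arrow.
#' @param self_degrading Logical vector: does the node switch off when
#'   its inputs sum to zero?
#' @return An object of class `threshold_network`.
#' @export
threshold_network <- function(nodes, weights, self_degrading) {
  n <- length(nodes)
  weights <- as.matrix(weights)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (!all(dim(weights) == n))
    stop("weights must be an n x n matrix matching 'nodes'")
  if (!all(weights %in% c(-1L, 0L, 1L)))
    stop("unit weights only: entries must be -1, 0 or +1")
  if (any(diag(weights) != 0))
    stop("signed self-arrows are not allowed; use self_degrading")
  if (length(self_degrading) != n) stop("one self_degrading flag per node")
  storage.mode(weights) <- "integer"
  dimnames(weights) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = weights,
                 self_degrading = as.logical(self_degrading)),
            class = "threshold_network")
}

#' @export
print.threshold_network <- function(x, ...) {
  cat("Threshold network: ", length(x$nodes), " nodes, ",
      sum(x$weights == 1L), " positive / ", sum(x$weights == -1L),
      " negative arrows, ", sum(x$self_degrading),
      " self-degrading nodes\n", sep = "")
  invisible(x)
}

# Signed arrows as a data.frame (deterministic order: target, then source).
threshold_edges <- function(net) {
  idx <- which(net$weights != 0L, arr.ind = TRUE)
  idx <- idx[base::order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(source = net$nodes[idx[, 2L]], target = net$nodes[idx[, 1L]],
             weight = net$weights[idx], stringsAsFactors = FALSE)
}

#' Advance a threshold network one step
#'
#' @param net A [threshold_network].
#' @param state Integer state code or 0/1 bit vector (node 1 first).
#' @return Successor state in the same form.
#' @export
threshold_step <- function(net, state) {
  n <- length(net$nodes)
  as_bits <- length(state) > 1L
  bits <- if (as_bits) as.integer(state) else state_to_bits(state, n)
  if (length(bits) != n) stop("state length must match node count")
  sums <- as.vector(net$weights %*% bits)
  nxt <- ifelse(sums > 0, 1L,
         ifelse(sums < 0, 0L,
         ifelse(net$self_degrading, 0L, bits)))
  if (as_bits) as.integer(nxt) else bits_to_state(nxt)
}

# Wild-type update columns over all 2^n states: matrix 2^n x n, entry
# [s + 1, i] = next bit of node i from state s.
threshold_wild_columns <- function(net) {
  n <- length(net$nodes)
  Smat <- state_matrix(n)                       # 2^n x n
  sums <- Smat %*% t(net$weights)               # column i = input sum of node i
  hold <- matrix(rep(!net$self_degrading, each = nrow(Smat)), ncol = n)
  w <- (sums > 0) | (sums == 0 & hold & Smat == 1L)
  storage.mode(w) <- "integer"
  w
}

#' Convert a threshold network to a truth-table genotype
#'
#' Wild-type nodes get the threshold-rule update column evaluated over
#' all `2^order` states; null nodes an all-zero column; constitutive
#' nodes an all-one column (the overrides replace the whole rule,
#' including self-degradation).  Derived edges follow the self-edge
#' inversion convention: a self-degrading wild-type node has no
#' truth-table self-edge, a non-self-degrading one does.
#'
#' @param net A [threshold_network].
#' @param alleles Character vector, one of `"wild"`, `"null"`,
#'   `"constitutive"` per node (recycled scalar allowed).
#' @return A [bn_genotype].
#' @export
threshold_to_truth_table <- function(net, alleles = "wild") {
  n <- length(net$nodes)
  alleles <- rep_len(match.arg(alleles, c("wild", "null", "constitutive"),
                               several.ok = TRUE), n)
  w <- threshold_wild_columns(net)
  cols <- lapply(seq_len(n), function(i)
    switch(alleles[i],
           wild = w[, i],
           null = rep(0L, 2^n),
           constitutive = rep(1L, 2^n)))
  bn_genotype(cols)
}

#' The yeast cell-cycle threshold network
#'
#' The 11-node budding-yeast cell-cycle network in the threshold
#' formalism (Li et al.'s model): 15 positive and 14 negative unit
#' arrows, with Cln3, Cln1,2, Swi5, Cdc20&Cdc14 and Mcm1/SFF
#' self-degrading.  Loaded from the packaged edge/node tables
#' (`inst/extdata/ccn_edges.tsv`, `ccn_nodes.tsv`).
#'
#' @return A [threshold_network].
#' @export
#' @examples
#' net <- ccn()
#' sum(net$weights != 0)  # 29 signed arrows
ccn <- function() {
  read_threshold_network(
    system.file("extdata", "ccn_edges.tsv", package = "gpmcomplexity"),
    system.file("extdata", "ccn_nodes.tsv", package = "gpmcomplexity"))
}

#' Exhaustive census of a threshold network's allele library
#'
#' Enumerates all `3^order` assignments of wild/null/constitutive alleles,
#' runs each genotype from every initial state, pools attractors, and
#' computes the genetic complexity with `m^n = 3^order` (every node has
#' exactly three functionally distinct alleles).  Null/constitutive
#' alleles guarantee that every state is realized as a fixed point, so
#' the complexity is maximal exactly when no periodic attractor occurs.
#'
#' The census runs in compiled code: per-node wild-type columns are
#' precomputed once and per-genotype transition tables assembled
#' incrementally, with attractors found by functional-graph cycle
#' detection.
#'
#' @param net A [threshold_network] (at most `cap` nodes).
#' @param cap Guard on the node count (the census costs `3^n * 2^n`).
#' @param keep_attractors Keep the fixed-state list and periodic cycles
#'   in the result (attribute `census`)?
#' @return A `complexity_result`; attribute `census` holds the pooled
#'   attractor sets when requested.
#' @export
threshold_library_census <- function(net, cap = 12L, keep_attractors = TRUE) {
  n <- length(net$nodes)
  if (n > cap)
    stop("enumeration cap exceeded: ", n, " nodes imply 3^", n,
         " genotypes (cap ", cap, " nodes)")
  w <- threshold_wild_columns(net)
  raw <- cpp_threshold_census(w)
  G <- 3^n
  p <- length(raw$fixed) + length(raw$periodic)
  res <- new_complexity_result(
    n = n, m = 3, genotype_diversity = G, p = p,
    C = complexity_from_counts(G, p),
    n_fixed = length(raw$fixed), n_periodic = length(raw$periodic),
    source = "threshold library census")
  if (keep_attractors)
    attr(res, "census") <- list(fixed = raw$fixed, periodic = raw$periodic)
  res
}

#' @rdname threshold_library_census
#' @export
ccn_library_census <- function(net = ccn(), ...) {
  threshold_library_census(net, ...)
}
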