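# Enumeration of genotype libraries: by topology class, by order, and by
# size (edge count).
#
# A topology class is an order plus a directed edge set; its library is
# every genotype whose derived edges (essential dependence, see
# derive_edges) equal exactly that edge set.  Each node therefore draws
# its allele from the Boolean functions of its input set that depend
# essentially on every input; constants are available only to nodes with
# no inputs.

.fn_cache <- new.env(parent = emptyenv())

#' Parse a topology-class string
#'
#' The string notation writes one digit group per node: digit `b` of
#' group `a` is 1 when node `a` has an incoming edge from node `b`
#' (leftmost digit = node 1).  `"111 000 000"` is the 3-node class where
#' node 1 listens to all three nodes and nodes 2 and 3 have no inputs.
#'
#' @param text A class string such as `"011 001 000"`.
#' @return A `topology_class`: order plus 0/1 edge matrix `E` with
#'   `E[a, b] = 1` for an edge from node b into node a.
#' @seealso [format_topology_class()]
#' @export
parse_topology_class <- function(text) {
  groups <- strsplit(trimws(text), "\\s+")[[1]]
  n <- length(groups)
  if (n == 0L || any(nchar(groups) != n))
    stop("malformed topology-class string: need ", n,
         " groups of ", n, " digits each")
  digs <- lapply(groups, function(g) as.integer(strsplit(g, "")[[1]]))
  if (any(!unlist(digs) %in% c(0L, 1L)))
    stop("malformed topology-class string: digits must be 0/1")
  topology_class(do.call(rbind, digs))
}

#' Construct a topology class from an edge matrix
#'
#' @param E Square 0/1 matrix, `E[a, b] = 1` meaning an edge from node b
#'   into node a.
#' @return A `topology_class`.
#' @export
topology_class <- function(E) {
  E <- as.matrix(E)
  if (nrow(E) != ncol(E) || !all(E %in% c(0L, 1L)))
    stop("E must be a square 0/1 matrix")
  storage.mode(E) <- "integer"
  dimnames(E) <- NULL
  structure(list(order = nrow(E), E = E), class = "topology_class")
}

#' Serialize a topology class to its string notation
#'
#' @param cls A `topology_class`.
#' @return The class string; `parse_topology_class()` round-trips it.
#' @export
format_topology_class <- function(cls) {
  paste(apply(cls$E, 1, paste, collapse = ""), collapse = " ")
}

#' @export
print.topology_class <- function(x, ...) {
  cat("Topology class \"", format_topology_class(x), "\": order ", x$order,
      ", size ", sum(x$E), ", in-degrees (",
      paste(rowSums(x$E), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Number of Boolean functions essential in all inputs
#'
#' Counts the Boolean functions of `k` inputs that depend essentially on
#' every input, by inclusion-exclusion over ignored inputs:
#' `sum_j (-1)^j choose(k, j) 2^(2^(k-j))`.  This is the number of alleles
#' available to a node with in-degree `k` (2, 2, 10, 218 for k = 0..3).
#'
#' @param k In-degree, >= 0.
#' @return Exact count (double; exact for the supported range).
#' @export
count_essential_functions <- function(k) {
  stopifnot(is_count(k), k >= 0)
  j <- 0:k
  sum((-1)^j * choose(k, j) * 2^(2^(k - j)))
}

# Truth columns (2^k rows) of all essential k-input functions, cached.
# Column order follows the integer encoding of the function's truth
# column (little-endian), giving a deterministic lexicographic library
# iteration order.
essential_functions <- function(k) {
  stopifnot(is_count(k), k >= 0, k <= 4)
  key <- as.character(k)
  if (!is.null(.fn_cache[[key]])) return(.fn_cache[[key]])
  if (k == 0L) {
    out <- matrix(c(0L, 1L), nrow = 1L)
  } else {
    nf <- 2^(2^k)
    s <- 0:(2^k - 1L)
    cols <- vapply(0:(nf - 1L),
                   function(f) bitwAnd(bitwShiftR(f, s), 1L),
                   integer(2^k))
    essential <- rep(TRUE, nf)
    for (j in 1:k) {
      flipped <- bitwXor(s, bitwShiftL(1L, j - 1L)) + 1L
      essential <- essential & colSums(cols != cols[flipped, , drop = FALSE]) > 0L
    }
    out <- cols[, essential, drop = FALSE]
  }
  .fn_cache[[key]] <- out
  out
}

# Lift k-input truth columns to full update columns over all 2^order
# states, reading only the listed input bits.
allele_columns <- function(order, inputs) {
  F <- essential_functions(length(inputs))
  s <- 0:(2^order - 1L)
  sub <- integer(2^order)
  for (t in seq_along(inputs))
    sub <- sub + bitwShiftL(bitwAnd(bitwShiftR(s, inputs[t] - 1L), 1L), t - 1L)
  F[sub + 1L, , drop = FALSE]
}

new_genotype_library <- function(order, type, source, n_genotypes,
                                 node_alleles = NULL, genotypes = NULL,
                                 cls = NULL, n_edges = NULL) {
  structure(list(order = order, type = type, source = source,
                 n_genotypes = n_genotypes, node_alleles = node_alleles,
                 genotypes = genotypes, cls = cls, n_edges = n_edges),
            class = "genotype_library")
}

#' @export
print.genotype_library <- function(x, ...) {
  cat("Genotype library (", x$source, "): order ", x$order, ", |G| = ",
      format(x$n_genotypes, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' All genotypes of a topology class
#'
#' The library is the Cartesian product of per-node essential-function
#' alleles, so `|G|` is the product over nodes of
#' [count_essential_functions()] at their in-degrees.  Genotypes are
#' enumerated lazily (mixed-radix index, node 1 fastest); use
#' [library_genotype()] to materialize one member and
#' [attractor_census()] or [library_complexity()] to census the library.
#'
#' @param cls A `topology_class` (or class string).
#' @param cap Guard on the enumeration cost `|G| * 2^order`; exceeding it
#'   raises an error that reports the computed `|G|`.
#' @return A `genotype_library`.
#' @export
#' @examples
#' topology_class_library("111 000 000")$n_genotypes  # 872
topology_class_library <- function(cls,
                                   cap = getOption("gpmcomplexity.max_pairs", 1e8)) {
  if (is.character(cls)) cls <- parse_topology_class(cls)
  stopifnot(inherits(cls, "topology_class"))
  node_alleles <- lapply(seq_len(cls$order), function(i)
    allele_columns(cls$order, which(cls$E[i, ] == 1L)))
  n <- prod(vapply(node_alleles, ncol, 0L))
  if (n * 2^cls$order > cap)
    stop("enumeration cap exceeded: |G| = ", format(n, big.mark = ","),
         " genotypes x ", 2^cls$order, " states > cap ", cap)
  new_genotype_library(cls$order, "product",
                       paste0("topology class ", format_topology_class(cls)),
                       n, node_alleles = node_alleles, cls = cls)
}

#' Materialize one genotype of a library
#'
#' @param lib A `genotype_library` with explicit or product enumeration.
#' @param index 1-based genotype index in the library's deterministic
#'   (mixed-radix, node-1-fastest) order.
#' @return A [bn_genotype].
#' @export
library_genotype <- function(lib, index) {
  stopifnot(inherits(lib, "genotype_library"),
            is_count(index), index >= 1, index <= lib$n_genotypes)
  if (lib$type == "explicit") return(lib$genotypes[[index]])
  if (is.null(lib$node_alleles))
    stop("library of type '", lib$type, "' has no direct member access")
  idx <- index - 1
  alleles <- vector("list", lib$order)
  for (i in seq_len(lib$order)) {
    r <- ncol(lib$node_alleles[[i]])
    alleles[[i]] <- lib$node_alleles[[i]][, (idx %% r) + 1L]
    idx <- idx %/% r
  }
  bn_genotype(alleles)
}

#' The full genotype library of a given order
#'
#' Every possible truth-table assignment: each node may take any of the
#' `2^(2^order)` update columns, so `|G| = (2^(2^order))^order`.
#' Exhaustive censusing is tractable only up to order 3 (16,777,216
#' genotypes); larger orders are rejected.
#'
#' @param order Number of nodes, 1 to 3.
#' @return A `genotype_library`.
#' @export
full_order_library <- function(order) {
  stopifnot(is_count(order))
  if (order > 3)
    stop("full-order libraries are enumerable only for order <= 3")
  S <- 2^order
  s <- 0:(S - 1L)
  cols <- vapply(0:(2^S - 1L), function(f) bitwAnd(bitwShiftR(f, s), 1L),
                 integer(S))
  new_genotype_library(order, "full", paste0("full order-", order, " library"),
                       (2^S)^order,
                       node_alleles = rep(list(cols), order))
}

# Exact |G| for the size library: sum over in-degree assignments.
size_library_cardinality <- function(order, n_edges) {
  counts <- vapply(0:order, count_essential_functions, 0)
  per_node <- function(rem, nodes_left) {
    if (nodes_left == 0L) return(if (rem == 0L) 1 else 0)
    tot <- 0
    for (k in 0:min(order, rem))
      tot <- tot + choose(order, k) * counts[k + 1L] *
        per_node(rem - k, nodes_left - 1L)
    tot
  }
  per_node(n_edges, order)
}

#' The library of all genotypes with a given edge count
#'
#' Members are exactly the genotypes of the full order library whose
#' derived edge set has cardinality `n_edges`; topologies are pooled.
#' `|G|` is computed combinatorially (sum over in-degree assignments of
#' products of essential-function counts).
#'
#' @param order Number of nodes, 1 to 3.
#' @param n_edges Number of edges, 0 to `order^2`.
#' @return A `genotype_library` (censused by a single compiled pass over
#'   the full order library).
#' @export
size_library <- function(order, n_edges) {
  stopifnot(is_count(order), is_count(n_edges))
  if (order > 3) stop("size libraries are enumerable only for order <= 3")
  if (n_edges > order^2) stop("n_edges exceeds order^2 = ", order^2)
  new_genotype_library(order, "size",
                       paste0("order-", order, " size-", n_edges, " library"),
                       size_library_cardinality(order, n_edges),
                       n_edges = as.integer(n_edges))
}

#' Flip one column of a genotype's truth table
#'
#' Complementing node `node`'s entire update column reverses its
#' dependence on each input but changes no dependency, so the result lies
#' in the same topology class.  The operation is an involution and is the
#' constructive step behind fixed-point realizability.
#'
#' @param genotype A [bn_genotype].
#' @param node Node index whose column to flip.
#' @return A [bn_genotype] with identical derived edges.
#' @export
flip_column <- function(genotype, node) {
  stopifnot(inherits(genotype, "bn_genotype"),
            is_count(node), node >= 1, node <= genotype$order)
  alleles <- genotype$alleles
  alleles[[node]] <- 1L - alleles[[node]]
  bn_genotype(alleles)
}

#' Construct a class member fixing a given state
#'
#' Every topology class realizes every state as a fixed-point attractor:
#' take any member, look at where the state maps, and flip the columns of
#' the nodes whose bits change.  Column flips stay within the class, and
#' the state becomes a fixed point of the result.
#'
#' @param cls A `topology_class`, class string, or a representative
#'   [bn_genotype] whose class is used.
#' @param state State to fix (integer code or bit vector).
#' @return A [bn_genotype] in the same class with `state` fixed.
#' @export
#' @examples
#' g <- realize_fixed_point("100 100 100", 5)
#' synchronous_step(g, 5)  # 5
realize_fixed_point <- function(cls, state) {
  g <- if (inherits(cls, "bn_genotype")) cls
       else library_genotype(topology_class_library(cls), 1L)
  s <- if (length(state) > 1L) bits_to_state(state) else as.integer(state)
  bits <- state_to_bits(s, g$order)
  nxt <- state_to_bits(synchronous_step(g, s), g$order)
  for (i in which(bits != nxt)) g <- flip_column(g, i)
  g
}

# Batched census over a product library (mixed-radix enumeration).
census_product <- function(lib, batch = 65536L) {
  radix <- vapply(lib$node_alleles, ncol, 0L)
  total <- lib$n_genotypes
  S <- 2^lib$order
  res <- NULL
  start <- 0
  while (start < total) {
    idx <- start:min(start + batch - 1, total - 1)
    tm <- matrix(0L, length(idx), S)
    div <- 1
    for (i in seq_len(lib$order)) {
      choice <- (idx %/% div) %% radix[i]
      div <- div * radix[i]
      tm <- tm + t(lib$node_alleles[[i]][, choice + 1, drop = FALSE]) *
        bitwShiftL(1L, i - 1L)
    }
    res <- merge_census(res, census_tmat(tm, lib$order))
    start <- start + batch
  }
  res
}

census_library <- function(lib, batch = 65536L) {
  switch(lib$type,
    product = census_product(lib, batch),
    explicit = attractor_census(lib$genotypes),
    full = if (lib$order <= 2L) census_product(lib, batch) else
      full_order_census_cpp(lib$order)$total,
    size = {
      if (lib$order <= 2L) {
        res <- census_size_small(lib$order, lib$n_edges)
      } else {
        res <- full_order_census_cpp(lib$order)$per_size[[lib$n_edges + 1L]]
      }
      stopifnot(res$n_genotypes == lib$n_genotypes)
      res
    },
    stop("unknown library type ", lib$type))
}

# Size census for orders 1-2 by direct filtering of the full library.
census_size_small <- function(order, n_edges) {
  full <- full_order_library(order)
  keep <- integer(0)
  for (g in seq_len(full$n_genotypes)) {
    geno <- library_genotype(full, g)
    if (sum(derive_edges(geno)) == n_edges) keep <- c(keep, g)
  }
  res <- attractor_census(lapply(keep, library_genotype, lib = full))
  res
}

# Memoized compiled census of the full order-3 library, split by size.
full_order_census_cpp <- function(order) {
  key <- paste0("full_census_", order)
  if (!is.null(.fn_cache[[key]])) return(.fn_cache[[key]])
  raw <- cpp_full_order_census(as.integer(order))
  shape <- function(x) list(
    fixed = x$fixed, periodic = x$periodic,
    n_fixed = length(x$fixed), n_periodic = length(x$periodic),
    p = length(x$fixed) + length(x$periodic),
    n_genotypes = x$n_genotypes)
  out <- list(total = shape(raw$total),
              per_size = lapply(raw$per_size, shape))
  .fn_cache[[key]] <- out
  out
}

#' Census a library and compute its genetic complexity
#'
#' Composes [attractor_census()] with [complexity_from_counts()]: every
#' genotype is run from every initial state, attractors are pooled and
#' de-duplicated, `p = n_fixed + n_periodic`, and
#' `C = (|G| - p)/(p - 1)`.  For product (topology-class) libraries all
#' alleles are functionally unique, so `m^n = |G|`; size libraries pool
#' mixed topologies and use `|G|` directly.
#'
#' @param lib A `genotype_library`, `topology_class`, or class string.
#' @param batch Batch size for lazily enumerated libraries.
#' @return A `complexity_result` with the fixed/periodic split.
#' @export
#' @examples
#' library_complexity("111 000 000")  # C = 78.1818...
library_complexity <- function(lib, batch = 65536L) {
  if (is.character(lib)) lib <- parse_topology_class(lib)
  if (inherits(lib, "topology_class")) lib <- topology_class_library(lib)
  stopifnot(inherits(lib, "genotype_library"))
  cen <- census_library(lib, batch = batch)
  G <- lib$n_genotypes
  new_complexity_result(
    n = lib$order, m = G^(1 / lib$order), genotype_diversity = G,
    p = cen$p, C = complexity_from_counts(G, cen$p),
    n_fixed = cen$n_fixed, n_periodic = cen$n_periodic,
    source = lib$source)
}
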