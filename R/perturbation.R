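# Systematic perturbation scans of a threshold network.
#
# Every perturbed network is censused over its full 3^order allele
# library.  The null/constitutive alleles guarantee all 2^order fixed
# attractors in every census, so the change in complexity is entirely a
# function of the periodic attractors the perturbation lets in: C drops
# below baseline exactly when the perturbed census has more periodic
# attractors than the baseline census.

perturbation_row <- function(kind, source, target, sign, res, baseline_C) {
  data.frame(kind = kind, source = source, target = target, sign = sign,
             n_fixed = res$n_fixed, n_periodic = res$n_periodic,
             C = res$C, delta_C = res$C - baseline_C,
             stringsAsFactors = FALSE)
}

#' Single-edge deletion scan
#'
#' Removes each signed arrow in turn (self-degradation flags untouched)
#' and recomputes the full library census of the modified network.
#'
#' @param net A [threshold_network].
#' @param baseline Optional precomputed baseline `complexity_result`
#'   (computed if missing).
#' @return A data.frame with one row per signed arrow: the deleted
#'   arrow, the census split, `C` and `delta_C` against baseline.
#' @export
delete_edge_scan <- function(net, baseline = NULL) {
  baseline <- baseline %||% threshold_library_census(net, keep_attractors = FALSE)
  ed <- threshold_edges(net)
  rows <- lapply(seq_len(nrow(ed)), function(k) {
    mod <- net
    mod$weights[ed$target[k], ed$source[k]] <- 0L
    res <- threshold_library_census(mod, keep_attractors = FALSE)
    perturbation_row("delete", ed$source[k], ed$target[k], ed$weight[k],
                     res, baseline$C)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- baseline
  out
}

# Structure digraph of the signed arrows as an edge matrix for loop
# analytics (E[i, j] = 1 iff an arrow of either sign points j -> i).
arrow_topology <- function(net) {
  topology_class((net$weights != 0L) * 1L)
}

# Elementary cycles through a candidate arrow src -> tgt: simple paths
# tgt ~> src in the existing arrow digraph, closed by the new arrow.
cycles_through_new_edge <- function(net, source, target) {
  E <- (net$weights != 0L) * 1L
  n <- nrow(E)
  succ <- lapply(seq_len(n), function(j) which(E[, j] == 1L))
  src <- match(source, net$nodes)
  tgt <- match(target, net$nodes)
  lens <- integer(0)
  path <- integer(0)
  onpath <- rep(FALSE, n)
  dfs <- function(v) {
    path[length(path) + 1L] <<- v
    onpath[v] <<- TRUE
    if (v == src) lens[length(lens) + 1L] <<- length(path)
    else for (w in succ[[v]]) if (!onpath[w]) dfs(w)
    onpath[v] <<- FALSE
    path <<- path[-length(path)]
  }
  dfs(tgt)
  lens  # cycle lengths (path length incl. both endpoints = cycle length)
}

#' Single-edge addition scan
#'
#' Candidate arrows are the ordered node pairs (source != target) not
#' already carrying an arrow of either sign, each tried with both signs
#' -- self-arrows are excluded because self-influence is modeled by the
#' separate self-degradation mechanism.  For each candidate the scan
#' reports the elementary cycles the new arrow would create (grouped by
#' length) and, optionally, the full library census of the augmented
#' network.
#'
#' @param net A [threshold_network].
#' @param census Run the (expensive) full census for each candidate?
#'   With `census = FALSE` only the combinatorial and loop columns are
#'   filled.
#' @param candidates Optional integer vector of candidate indices to
#'   scan (useful for sampling the 2 x (n(n-1) - arrows) candidates).
#' @param baseline Optional precomputed baseline census.
#' @return A data.frame with one row per candidate: source, target,
#'   sign, `new_loops`, `new_loop_lengths` (comma-separated), and -- when
#'   censused -- the census split, `C` and `delta_C`.
#' @export
add_edge_scan <- function(net, census = TRUE, candidates = NULL,
                          baseline = NULL) {
  n <- length(net$nodes)
  pairs <- which(net$weights == 0L & !diag(n), arr.ind = TRUE)
  pairs <- pairs[base::order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  cand <- data.frame(
    source = net$nodes[rep(pairs[, 2L], each = 2L)],
    target = net$nodes[rep(pairs[, 1L], each = 2L)],
    sign = rep(c(1L, -1L), times = nrow(pairs)),
    stringsAsFactors = FALSE)
  if (!is.null(candidates)) cand <- cand[candidates, , drop = FALSE]
  if (census)
    baseline <- baseline %||% threshold_library_census(net, keep_attractors = FALSE)
  rows <- lapply(seq_len(nrow(cand)), function(k) {
    lens <- cycles_through_new_edge(net, cand$source[k], cand$target[k])
    row <- data.frame(kind = "add", source = cand$source[k],
                      target = cand$target[k], sign = cand$sign[k],
                      new_loops = length(lens),
                      new_loop_lengths = paste(sort(lens), collapse = ","),
                      stringsAsFactors = FALSE)
    if (census) {
      mod <- net
      mod$weights[cand$target[k], cand$source[k]] <- cand$sign[k]
      res <- threshold_library_census(mod, keep_attractors = FALSE)
      row$n_fixed <- res$n_fixed
      row$n_periodic <- res$n_periodic
      row$C <- res$C
      row$delta_C <- res$C - baseline$C
    }
    row
  })
  out <- do.call(rbind, rows)
  if (census) attr(out, "baseline") <- baseline
  out
}

# All reassignments of a node's incoming signed-arrow multiset to
# distinct sources among the other nodes, excluding the wild-type
# configuration.  Arrows of equal sign are interchangeable, so a
# configuration is (set of positive sources, disjoint set of negative
# sources).
input_reassignments <- function(net, node) {
  i <- match(node, net$nodes)
  if (is.na(i)) stop("unknown node '", node, "'")
  w <- net$weights[i, ]
  npos <- sum(w == 1L)
  nneg <- sum(w == -1L)
  if (npos + nneg == 0L)
    stop("node '", node, "' has no signed inputs to reassign")
  others <- setdiff(seq_along(net$nodes), i)
  pos_sets <- if (npos > 0) utils::combn(others, npos, simplify = FALSE)
              else list(integer(0))
  configs <- list()
  for (ps in pos_sets) {
    rest <- setdiff(others, ps)
    neg_sets <- if (nneg > 0) utils::combn(rest, nneg, simplify = FALSE)
                else list(integer(0))
    for (ns in neg_sets)
      configs[[length(configs) + 1L]] <- list(pos = ps, neg = ns)
  }
  wild <- list(pos = unname(which(w == 1L)), neg = unname(which(w == -1L)))
  keep <- !vapply(configs, function(cf)
    identical(sort(cf$pos), sort(wild$pos)) &&
    identical(sort(cf$neg), sort(wild$neg)), TRUE)
  configs[keep]
}

#' Per-node input reassignment scan
#'
#' Holds everything about the network fixed except the incoming arrows
#' of one node, and tries every reassignment of that node's multiset of
#' signed arrows to distinct source nodes drawn from the other nodes
#' (wild-type configuration excluded; arrows of equal sign are
#' interchangeable).  Each configuration gets a full library census; the
#' summary reports the mean periodic-attractor count per perturbation,
#' the quantity that ranks how much a node's inputs matter for keeping
#' complexity maximal.
#'
#' @param net A [threshold_network].
#' @param node Node name with in-degree >= 1 (a node without signed
#'   inputs has nothing to reassign).
#' @param census Run the censuses (`FALSE` returns the combinatorics
#'   only)?
#' @return A list with `node`, `n_perturbations`, per-perturbation
#'   data.frame `perturbations` (sources and, when censused, periodic
#'   counts) and `mean_periodic` (NA when not censused).
#' @export
reassign_inputs_scan <- function(net, node, census = TRUE) {
  configs <- input_reassignments(net, node)
  i <- match(node, net$nodes)
  per <- lapply(seq_along(configs), function(k) {
    cf <- configs[[k]]
    row <- data.frame(
      positive_sources = paste(net$nodes[cf$pos], collapse = ";"),
      negative_sources = paste(net$nodes[cf$neg], collapse = ";"),
      stringsAsFactors = FALSE)
    if (census) {
      mod <- net
      mod$weights[i, ] <- 0L
      mod$weights[i, cf$pos] <- 1L
      mod$weights[i, cf$neg] <- -1L
      res <- threshold_library_census(mod, keep_attractors = FALSE)
      row$n_periodic <- res$n_periodic
      row$C <- res$C
    }
    row
  })
  per <- do.call(rbind, per)
  list(node = node, n_perturbations = length(configs), perturbations = per,
       mean_periodic = if (census) mean(per$n_periodic) else NA_real_)
}
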