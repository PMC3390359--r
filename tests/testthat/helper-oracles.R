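# Independent brute-force oracles used to cross-check the engine.  They
# deliberately avoid the package's transition-table and census code
# paths: states are stepped by direct allele-column lookup, attractors
# found by plain walking, cycles by permutation search.

# Step a state (0-based) by reading each allele column directly.
naive_step <- function(alleles, s) {
  bits <- vapply(seq_along(alleles), function(i) alleles[[i]][s + 1L], 0L)
  sum(bits * 2^(seq_along(alleles) - 1L))
}

# Walk to the attractor; return the cycle rotated to start at its
# minimal state.
naive_attractor <- function(alleles, s0) {
  seen <- integer(0)
  s <- s0
  while (!(s %in% seen)) {
    seen <- c(seen, s)
    s <- naive_step(alleles, s)
  }
  cyc <- seen[which(seen == s):length(seen)]
  k <- which.min(cyc)
  if (k > 1L) cyc <- c(cyc[k:length(cyc)], cyc[1:(k - 1L)])
  cyc
}

# Pooled census of a list of bn_genotypes by naive walking.
naive_census <- function(genotypes) {
  keys <- character(0)
  fixed <- 0L
  for (g in genotypes) {
    for (s in 0:(2^g$order - 1L)) {
      cyc <- naive_attractor(g$alleles, s)
      keys <- union(keys, paste(cyc, collapse = ","))
    }
  }
  lens <- lengths(strsplit(keys, ","))
  list(p = length(keys), n_fixed = sum(lens == 1L),
       n_periodic = sum(lens > 1L))
}

# Brute-force elementary cycles of an edge matrix (E[i, j]: edge j -> i):
# try every node subset and every cyclic arrangement.
naive_cycles <- function(E) {
  n <- nrow(E)
  found <- list()
  for (k in 1:n) {
    for (sub in utils::combn(n, k, simplify = FALSE)) {
      base <- sub[1L]
      perms <- if (k == 1L) list(integer(0)) else
        combinat_perms(sub[-1L])
      for (pm in perms) {
        cyc <- c(base, pm)
        nxt <- c(cyc[-1L], cyc[1L])
        if (all(E[cbind(nxt, cyc)] == 1L))
          found[[length(found) + 1L]] <- cyc
      }
    }
  }
  found
}

combinat_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in combinat_perms(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

# Random genotype of a given order (uniform over all truth tables).
random_genotype <- function(order) {
  bn_genotype(lapply(1:order, function(i)
    sample(c(0L, 1L), 2^order, replace = TRUE)))
}

# A small 4-node threshold network with a feedback loop, used where the
# full CCN would be needlessly slow.
toy_threshold_net <- function() {
  W <- matrix(0L, 4, 4)
  W[2, 1] <- 1L   # A -> B
  W[3, 2] <- 1L   # B -> C
  W[1, 3] <- -1L  # C -| A
  W[4, 3] <- 1L   # C -> D
  threshold_network(c("A", "B", "C", "D"), W,
                    self_degrading = c(TRUE, FALSE, FALSE, TRUE))
}
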