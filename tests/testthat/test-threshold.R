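# Threshold formalism, truth-table conversion, the packaged cell-cycle
# network.

test_that("threshold network construction enforces the invariants", {
  W <- matrix(0L, 2, 2)
  W[1, 1] <- 1L
  expect_error(threshold_network(c("a", "b"), W, c(FALSE, FALSE)),
               "self-arrows")
  W2 <- matrix(c(0L, 2L, 0L, 0L), 2, 2)
  expect_error(threshold_network(c("a", "b"), W2, c(FALSE, FALSE)),
               "unit weights")
  expect_error(threshold_network(c("a", "a"), matrix(0L, 2, 2),
                                 c(FALSE, FALSE)), "duplicate")
})

test_that("the threshold rule thresholds, holds, and self-degrades", {
  net <- toy_threshold_net()
  # A on: A self-degrades to off, B switches on
  expect_equal(threshold_step(net, c(1L, 0L, 0L, 0L)), c(0L, 1L, 0L, 0L))
  # C on: represses A, activates D; B holds (zero input, not self-degrading)
  expect_equal(threshold_step(net, c(0L, 1L, 1L, 0L)), c(0L, 1L, 1L, 1L))
  # all-off is fixed
  expect_equal(threshold_step(net, 0L), 0L)
})

test_that("CCN anchors: G1 steady state and the Cln3 start signal", {
  net <- ccn()
  g1 <- rep(0L, 11)
  g1[match(c("Sic1", "Cdh1"), net$nodes)] <- 1L
  expect_equal(threshold_step(net, g1), g1)
  start <- rep(0L, 11)
  start[match("Cln3", net$nodes)] <- 1L
  nxt <- threshold_step(net, start)
  expect_equal(sort(net$nodes[nxt == 1L]), sort(c("MBF", "SBF")))
})

test_that("truth-table conversion follows the self-edge inversion convention", {
  lone_deg <- threshold_network("x", matrix(0L, 1, 1), TRUE)
  g <- threshold_to_truth_table(lone_deg)
  expect_equal(g$alleles[[1L]], c(0L, 0L))          # constant off
  expect_equal(sum(derive_edges(g)), 0L)            # no self-edge
  lone_hold <- threshold_network("x", matrix(0L, 1, 1), FALSE)
  g2 <- threshold_to_truth_table(lone_hold)
  expect_equal(g2$alleles[[1L]], c(0L, 1L))         # identity
  expect_equal(derive_edges(g2)[1L, 1L], 1L)        # hold-rule self-edge
})

test_that("the packaged CCN fixture matches its printed anchors", {
  net <- ccn()
  expect_equal(length(net$nodes), 11L)
  expect_equal(sum(net$weights != 0L), 29L)
  expect_equal(sum(net$weights == 1L), 15L)
  expect_equal(sum(net$weights == -1L), 14L)
  expect_equal(sum(net$self_degrading), 5L)
  expect_equal(net$nodes[net$self_degrading],
               c("Cln3", "Cln1,2", "Swi5", "Cdc20&Cdc14", "Mcm1/SFF"))
  # truth-table out-degrees, in fixture node order
  outdeg <- colSums(derive_edges(threshold_to_truth_table(net)))
  expect_equal(outdeg, c(2L, 2L, 2L, 2L, 2L, 1L, 5L, 5L, 3L, 8L, 3L))
})

test_that("conversion reproduces threshold trajectories for random alleles", {
  net <- ccn()
  n <- length(net$nodes)
  # independent construction of the update rule, one state at a time
  oracle_column <- function(alleles) {
    vapply(0:(2^n - 1L), function(s) {
      bits <- state_to_bits(s, n)
      nxt <- integer(n)
      for (i in 1:n) {
        nxt[i] <- switch(alleles[i],
          null = 0L, constitutive = 1L,
          wild = {
            tot <- 0L
            for (j in 1:n) tot <- tot + net$weights[i, j] * bits[j]
            if (tot > 0) 1L else if (tot < 0) 0L
            else if (net$self_degrading[i]) 0L else bits[i]
          })
      }
      bits_to_state(nxt)
    }, 0L)
  }
  set.seed(19)
  draws <- replicate(100, sample(c("wild", "null", "constitutive"), n,
                                 replace = TRUE, prob = c(0.6, 0.2, 0.2)),
                     simplify = FALSE)
  for (al in draws[1:8]) {   # full 2^11-state table comparison
    g <- threshold_to_truth_table(net, al)
    expect_equal(transition_table(g), oracle_column(al))
  }
  # remaining draws: spot-check 64 states each
  for (al in draws[-(1:8)]) {
    g <- threshold_to_truth_table(net, al)
    tt <- transition_table(g)
    for (s in sample(0:2047, 64)) {
      bits <- state_to_bits(s, n)
      nxt <- integer(n)
      for (i in 1:n) nxt[i] <- switch(al[i],
        null = 0L, constitutive = 1L,
        wild = {
          tot <- sum(net$weights[i, ] * bits)
          if (tot > 0) 1L else if (tot < 0) 0L
          else if (net$self_degrading[i]) 0L else bits[i]
        })
      expect_equal(tt[s + 1L], bits_to_state(nxt))
    }
  }
})

test_that("null/constitutive assignments pin any state as the sole attractor", {
  net <- toy_threshold_net()
  n <- length(net$nodes)
  for (s in c(0L, 5L, 15L)) {
    bits <- state_to_bits(s, n)
    al <- ifelse(bits == 1L, "constitutive", "null")
    g <- threshold_to_truth_table(net, al)
    expect_true(all(transition_table(g) == s))
  }
})

test_that("the toy library census realizes all fixed states", {
  net <- toy_threshold_net()
  res <- threshold_library_census(net)
  expect_equal(res$genotype_diversity, 3^4)
  expect_equal(res$n_fixed, 16L)
  expect_equal(res$C,
               complexity_from_counts(81, res$p))
  # cross-check against the R census over explicitly converted genotypes
  allele_grid <- expand.grid(rep(list(c("wild", "null", "constitutive")), 4),
                             stringsAsFactors = FALSE)
  genos <- lapply(seq_len(nrow(allele_grid)), function(k)
    threshold_to_truth_table(net, unlist(allele_grid[k, ])))
  cen <- attractor_census(genos)
  expect_equal(cen$n_fixed, res$n_fixed)
  expect_equal(cen$n_periodic, res$n_periodic)
  expect_equal(cen$p, res$p)
})

test_that("node-count cap guards the exhaustive census", {
  net <- ccn()
  expect_error(threshold_library_census(net, cap = 8L), "cap exceeded")
})
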