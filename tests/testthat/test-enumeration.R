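# Library enumeration: topology classes, order/size libraries,
# constructive operations.

test_that("topology-class strings round-trip and decode correctly", {
  cls <- parse_topology_class("111 000 000")
  expect_equal(cls$order, 3L)
  expect_equal(which(cls$E[1L, ] == 1L), 1:3)
  expect_equal(sum(cls$E[2:3, ]), 0L)
  expect_equal(format_topology_class(cls), "111 000 000")
  loops <- parse_topology_class("100 010 001")
  expect_equal(loops$E, diag(3L), ignore_attr = TRUE)
  two <- parse_topology_class("10 01")
  expect_equal(two$E, diag(2L), ignore_attr = TRUE)
  for (s in c("011 001 000", "110 000 100", "10 01"))
    expect_equal(format_topology_class(parse_topology_class(s)), s)
  expect_error(parse_topology_class("11 000 000"), "malformed")
  expect_error(parse_topology_class("121 000 000"), "malformed")
})

test_that("essential-function counts match the exhaustive enumeration", {
  expect_equal(count_essential_functions(0), 2)
  expect_equal(count_essential_functions(1), 2)
  expect_equal(count_essential_functions(2), 10)
  expect_equal(count_essential_functions(3), 218)
  # inclusion-exclusion vs direct filtering of all 2^(2^k) functions
  for (k in 0:3)
    expect_equal(ncol(gpmcomplexity:::essential_functions(k)),
                 count_essential_functions(k))
})

test_that("topology-class libraries have the product cardinality and stay in class", {
  expect_equal(topology_class_library("111 000 000")$n_genotypes, 872)
  expect_equal(topology_class_library("011 001 000")$n_genotypes, 40)
  expect_equal(topology_class_library("100 100 100")$n_genotypes, 8)
  # every member's derived edges equal the class edge set (exhaustive on
  # a small class, sampled on a larger one)
  cls <- parse_topology_class("100 100 100")
  lib <- topology_class_library(cls)
  for (g in seq_len(lib$n_genotypes))
    expect_equal(derive_edges(library_genotype(lib, g)), cls$E)
  cls2 <- parse_topology_class("111 000 000")
  lib2 <- topology_class_library(cls2)
  set.seed(9)
  for (g in sample(lib2$n_genotypes, 25))
    expect_equal(derive_edges(library_genotype(lib2, g)), cls2$E)
})

test_that("library members are pairwise distinct", {
  lib <- topology_class_library("011 001 000")
  keys <- vapply(seq_len(lib$n_genotypes), function(g)
    paste(unlist(library_genotype(lib, g)$alleles), collapse = ""), "")
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("full-order libraries have (2^(2^n))^n genotypes, order <= 3", {
  expect_equal(full_order_library(1)$n_genotypes, 4)
  expect_equal(full_order_library(2)$n_genotypes, 256)
  expect_equal(full_order_library(3)$n_genotypes, 16777216)
  expect_error(full_order_library(4), "order <= 3")
})

test_that("size libraries hold exactly the genotypes with that edge count", {
  expect_equal(size_library(1, 0)$n_genotypes, 2)   # two constants
  expect_equal(size_library(1, 1)$n_genotypes, 2)   # identity and NOT
  expect_equal(size_library(2, 4)$n_genotypes, 100) # 10 * 10
  expect_error(size_library(2, 5), "order")
  # order-1 censuses: constants give the two fixed states; identity/NOT
  # give both fixed states plus the 2-cycle
  cen0 <- attractor_census(size_library(1, 0))
  expect_equal(cen0$p, 2L)
  cen1 <- attractor_census(size_library(1, 1))
  expect_equal(cen1$n_fixed, 2L)
  expect_equal(cen1$n_periodic, 1L)
})

test_that("the size-library cardinality formula matches direct filtering", {
  for (ord in 1:2) {
    full <- full_order_library(ord)
    counts <- integer(ord^2 + 1L)
    for (g in seq_len(full$n_genotypes)) {
      k <- sum(derive_edges(library_genotype(full, g)))
      counts[k + 1L] <- counts[k + 1L] + 1L
    }
    for (k in 0:(ord^2))
      expect_equal(size_library(ord, k)$n_genotypes, counts[k + 1L])
  }
})

test_that("column flips preserve the topology class and are involutions", {
  g0 <- bn_genotype(list(rep(0L, 2)))
  expect_equal(flip_column(g0, 1)$alleles[[1L]], rep(1L, 2))
  set.seed(13)
  for (rep in 1:15) {
    g <- random_genotype(sample(2:4, 1))
    node <- sample(g$order, 1)
    flipped <- flip_column(g, node)
    expect_equal(derive_edges(flipped), derive_edges(g))
    expect_equal(flip_column(flipped, node)$alleles, g$alleles)
  }
})

test_that("any class realizes any state as a fixed point", {
  g <- realize_fixed_point("100 100 100", 5)
  expect_equal(synchronous_step(g, 5), 5)
  expect_equal(derive_edges(g), parse_topology_class("100 100 100")$E)
  for (cls in c("111 000 000", "011 001 000", "100 010 001"))
    for (s in 0:7) {
      g <- realize_fixed_point(cls, s)
      expect_equal(synchronous_step(g, s), s)
      expect_equal(derive_edges(g), parse_topology_class(cls)$E)
    }
})

test_that("classes sharing an in-degree multiset share |G|", {
  same <- c("110 001 000", "110 000 100", "110 000 010", "011 100 000",
            "110 100 000", "110 000 001", "110 010 000", "011 001 000",
            "100 101 000")
  sizes <- vapply(same, function(s)
    topology_class_library(s)$n_genotypes, 0)
  expect_true(all(sizes == 40))
  ones <- c("100 100 100", "010 100 100", "100 010 001")
  expect_true(all(vapply(ones, function(s)
    topology_class_library(s)$n_genotypes, 0) == 8))
})

test_that("alleles in a class library are functionally unique (m^n = |G|)", {
  # build the explicit GPM of a small class: loci = nodes, allele = the
  # update column chosen, phenotypes = the genotype's pooled attractors
  set.seed(17)
  for (cls in c("011 001 000", "100 100 100", "10 01")) {
    lib <- topology_class_library(cls)
    radix <- vapply(lib$node_alleles, ncol, 0L)
    rows <- lapply(seq_len(lib$n_genotypes), function(gi) {
      idx <- gi - 1L
      ch <- integer(lib$order)
      for (i in seq_len(lib$order)) {
        ch[i] <- idx %% radix[i]
        idx <- idx %/% radix[i]
      }
      ch
    })
    alleles <- as.data.frame(do.call(rbind, rows))
    names(alleles) <- paste0("node", seq_len(lib$order))
    alleles[] <- lapply(alleles, as.character)
    phen <- lapply(seq_len(lib$n_genotypes), function(gi) {
      g <- library_genotype(lib, gi)
      unique(vapply(0:(2^g$order - 1L), function(s)
        paste(trajectory_attractor(g, s)$states, collapse = ","), ""))
    })
    res <- gpm_complexity(gpm_table(alleles, phen))
    expect_equal(res$n, lib$order)
    expect_equal(res$genotype_diversity, lib$n_genotypes)
  }
})

test_that("the enumeration cap rejects oversized classes with the size", {
  dense <- topology_class(matrix(1L, 3, 3))
  expect_error(topology_class_library(dense, cap = 1000),
               "cap exceeded.*10,360,232")
})

test_that("library complexity reproduces the small-class references", {
  expect_equal(round(library_complexity("111 000 000")$C, 4), 78.1818)
  expect_equal(round(library_complexity("011 001 000")$C, 5), 4.57143)
  expect_equal(round(library_complexity("110 001 000")$C, 5), 2.54545)
})
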