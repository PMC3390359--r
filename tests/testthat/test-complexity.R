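# The complexity metric and the GPM table machinery.

test_that("complexity from counts matches hand-derived values", {
  expect_equal(complexity_from_counts(872, 12), (872 - 12) / 11)
  expect_equal(round(complexity_from_counts(872, 12), 4), 78.1818)
  expect_equal(round(complexity_from_counts(177147, 2048), 2), 85.54)
  expect_equal(complexity_from_counts(8, 12), -4 / 11)
  for (k in c(2, 5, 100, 177147))
    expect_identical(complexity_from_counts(k, k), 0)
})

test_that("degenerate and malformed count inputs are rejected", {
  expect_error(complexity_from_counts(10, 1), "degenerate phenotype set")
  expect_error(complexity_from_counts(10, 0), "degenerate phenotype set")
  expect_error(complexity_from_counts(10.5, 3), "whole numbers")
  expect_error(complexity_from_counts(0, 3), ">= 1")
})

test_that("C is strictly decreasing in p and zero exactly at p = G", {
  for (G in c(8, 40, 872, 177147)) {
    ps <- unique(pmin(G + 5, c(2:10, G - 1, G, G + 5)))
    Cs <- vapply(ps, complexity_from_counts, 0, genotype_diversity = G)
    expect_true(all(diff(Cs) < 0))
    expect_identical(Cs[ps == G], 0)
  }
})

test_that("phenotype counting pools observation sets", {
  expect_equal(distinct_phenotype_count(list("P1", "P1")), 1L)
  expect_equal(distinct_phenotype_count(list(c("P1", "P2"), "P2")), 2L)
})

test_that("a locus whose alleles never change the phenotype is uninformative", {
  tab <- gpm_table(
    alleles = data.frame(A = rep(c("A", "a"), each = 2),
                         B = rep(c("B", "b"), times = 2)),
    phenotypes = list("P1", "P1", "P2", "P2"))
  res <- gpm_complexity(tab)
  expect_equal(res$n, 1L)
  expect_equal(res$m, 2)
  expect_equal(res$genotype_diversity, 2)
  expect_true(tab$mendelian)
})

test_that("stochastic phenotypes can push C negative", {
  # |G| = 2 after collapse? no: both loci informative, G = p - 1 = 2
  tab <- gpm_table(
    alleles = data.frame(A = c("A", "a")),
    phenotypes = list(c("P1", "P2"), "P3"))
  res <- gpm_complexity(tab)
  expect_equal(res$genotype_diversity, res$p - 1)
  expect_lt(res$C, 0)
})

test_that("complexity is invariant under identifier relabeling", {
  base <- data.frame(A = rep(c("A", "a"), each = 2),
                     B = rep(c("B", "b"), times = 2))
  phen <- list("P1", "P2", "P2", "P3")
  r1 <- gpm_complexity(gpm_table(base, phen))
  relab <- base
  names(relab) <- c("locusX", "locusY")
  relab$locusX <- paste0("z", relab$locusX)
  phen2 <- lapply(phen, function(p) paste0("pheno_", p))
  r2 <- gpm_complexity(gpm_table(relab[, c(2, 1)], phen2))
  expect_equal(r1$C, r2$C)
  expect_equal(r1$n, r2$n)
  expect_equal(r1$p, r2$p)
})

test_that("equivalence detection agrees with a brute-force allele swap", {
  set.seed(42)
  for (rep in 1:20) {
    n_loci <- sample(2:3, 1)
    n_all <- sample(2:3, n_loci, replace = TRUE)
    grid <- expand.grid(lapply(n_all, function(k) letters[1:k]),
                        stringsAsFactors = FALSE)
    names(grid) <- paste0("L", seq_len(n_loci))
    # locus 1: make alleles "a" and "b" behave identically by keying the
    # phenotype on the other loci only, half the time
    collapse <- rep == 1 || runif(1) < 0.5
    phen <- if (collapse)
      lapply(seq_len(nrow(grid)), function(i)
        paste(unlist(grid[i, -1L]), collapse = "+"))
    else
      lapply(seq_len(nrow(grid)), function(i)
        paste0("ph", sample(3, 1)))
    tab <- gpm_table(grid, phen)
    res <- gpm_complexity(tab)
    # brute force: locus informative iff some allele pair differs in a
    # shared background
    informative <- vapply(seq_len(n_loci), function(l) {
      al <- grid[[l]]
      bg <- do.call(paste, grid[-l])
      pk <- vapply(phen, function(p) paste(sort(p), collapse = "|"), "")
      classes <- unique(al)
      distinct_pairs <- 0L
      for (u in classes) for (v in classes) if (u < v) {
        shared <- intersect(bg[al == u], bg[al == v])
        pu <- pk[al == u][match(shared, bg[al == u])]
        pv <- pk[al == v][match(shared, bg[al == v])]
        if (any(pu != pv)) distinct_pairs <- distinct_pairs + 1L
      }
      distinct_pairs > 0L
    }, TRUE)
    expect_equal(res$n, sum(informative))
    if (collapse) expect_false(informative[1L])
  }
})

test_that("continuous phenotypes discretize by single-linkage gaps", {
  expect_equal(discretize_phenotypes(c(0, 10, 20), 1), 3L)
  expect_equal(discretize_phenotypes(rep(3.7, 8), 0.5), 1L)
  # 8 measurements, exactly two pairs closer than the resolution
  x <- c(0, 1, 1.05, 2, 3, 4, 4.08, 5.5)
  expect_equal(discretize_phenotypes(x, 0.2), 6L)
  expect_error(discretize_phenotypes(numeric(0), 1), "empty")
  expect_error(discretize_phenotypes(1:3, 0), "positive")
})
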