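# Genetic complexity of genotype-to-phenotype maps.
#
# The central quantity of the package: a genotype-to-phenotype map (GPM)
# over a library of genotypes has genetic complexity
#
#     C = (m^n - p) / (p - 1)
#
# where n is the number of phenotypically informative loci, m the geometric
# mean number of phenotypically unique alleles per informative locus (so
# m^n is the genotypic diversity of the library), and p the number of
# measurably distinct phenotypes the library produces.  C measures the
# surplus of genotypic over phenotypic diversity; it is zero when the map
# is injective on phenotypes (p = m^n) and negative when phenotypes
# outnumber genotypes (possible under stochastic phenotypes).

#' Genetic complexity from diversity counts
#'
#' Evaluates `C = (G - p) / (p - 1)` where `G` is the genotypic diversity
#' (`m^n`; for non-product libraries the library cardinality `|G|`) and `p`
#' the number of distinct phenotypes.  The `(p - 1)` denominator is a
#' normalization that keeps C from growing linearly with system size.
#'
#' Both arguments must be whole numbers; `p = 1` is rejected because the
#' normalization is undefined for a degenerate (single-phenotype) set.
#'
#' @param genotype_diversity Count of genotypes (`m^n` or `|G|`), >= 1.
#' @param p Count of distinct phenotypes, >= 2.
#' @return The complexity `C`, a plain double (exact for counts below
#'   2^53; integer arithmetic throughout the numerator).
#' @export
#' @examples
#' complexity_from_counts(872, 12)      # 78.1818...
#' complexity_from_counts(177147, 2048) # 85.54 at two decimals
#' complexity_from_counts(8, 12)        # negative: phenotypes outnumber genotypes
complexity_from_counts <- function(genotype_diversity, p) {
  if (!is_count(genotype_diversity) || !is_count(p))
    stop("genotype_diversity and p must be whole numbers")
  if (genotype_diversity < 1) stop("genotype_diversity must be >= 1")
  if (p < 2)
    stop("degenerate phenotype set: p must be >= 2 (got ", p, ")")
  (genotype_diversity - p) / (p - 1)
}

# Constructor for the result container shared by the GPM and census paths.
new_complexity_result <- function(n, m, genotype_diversity, p, C,
                                  n_fixed = NA_integer_,
                                  n_periodic = NA_integer_,
                                  source = "gpm") {
  structure(
    list(n = n, m = m, genotype_diversity = genotype_diversity,
         p = p, C = C, n_fixed = n_fixed, n_periodic = n_periodic,
         source = source),
    class = "complexity_result")
}

#' @export
print.complexity_result <- function(x, digits = 6, ...) {
  cat("Genetic complexity (", x$source, ")\n", sep = "")
  cat("  informative loci n:  ", x$n, "\n", sep = "")
  cat("  alleles/locus m:     ", format(x$m, digits = digits), "\n", sep = "")
  cat("  genotypic diversity: ", format(x$genotype_diversity, big.mark = ","),
      "\n", sep = "")
  if (!is.na(x$n_fixed))
    cat("  phenotypes p:        ", x$p, " (", x$n_fixed, " fixed, ",
        x$n_periodic, " periodic attractors)\n", sep = "")
  else
    cat("  phenotypes p:        ", x$p, "\n", sep = "")
  cat("  complexity C:        ", format(x$C, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.complexity_result <- function(x, ...) {
  data.frame(n = x$n, m = x$m, genotype_diversity = x$genotype_diversity,
             p = x$p, n_fixed = x$n_fixed, n_periodic = x$n_periodic,
             C = x$C)
}

#' Construct a genotype-to-phenotype map table
#'
#' A GPM table records, for each genotype in a library, the set of
#' phenotypes observed for it.  A genotype assigns exactly one allele to
#' every locus.  The table is "Mendelian" when the genotype set is the
#' full Cartesian product of the per-locus allele sets.
#'
#' @param alleles A data.frame with one row per genotype and one character
#'   column per locus giving the allele carried at that locus.  Row names
#'   (or a `genotype_id` column) identify genotypes.
#' @param phenotypes A list, one element per genotype (same order as the
#'   rows of `alleles`), each a character vector of >= 1 phenotype
#'   identifiers observed for that genotype.
#' @return An object of class `gpm_table` with fields `loci`, `alleles`,
#'   `phenotypes`, `genotype_id` and logical `mendelian`.
#' @export
#' @examples
#' tab <- gpm_table(
#'   alleles = data.frame(A = c("A", "A", "a", "a"), B = c("B", "b", "B", "b")),
#'   phenotypes = list("P1", "P1", "P2", "P2"))
#' gpm_complexity(tab)
gpm_table <- function(alleles, phenotypes) {
  if (!is.data.frame(alleles) || nrow(alleles) == 0L)
    stop("empty table: 'alleles' must be a non-empty data.frame")
  if ("genotype_id" %in% names(alleles)) {
    ids <- as.character(alleles$genotype_id)
    alleles <- alleles[setdiff(names(alleles), "genotype_id")]
  } else {
    ids <- rownames(alleles) %||% as.character(seq_len(nrow(alleles)))
  }
  alleles[] <- lapply(alleles, as.character)
  if (length(phenotypes) != nrow(alleles))
    stop("need one phenotype set per genotype")
  phenotypes <- lapply(phenotypes, function(p) {
    p <- unique(as.character(p))
    if (length(p) < 1L) stop("every genotype needs >= 1 phenotype")
    p
  })
  if (anyDuplicated(ids)) stop("duplicate genotype identifiers")
  key <- do.call(paste, c(alleles, sep = "\r"))
  if (anyDuplicated(key)) stop("duplicate genotypes (same allele assignment)")
  n_product <- prod(vapply(alleles, function(a) length(unique(a)), 0))
  structure(
    list(loci = names(alleles), alleles = alleles, phenotypes = phenotypes,
         genotype_id = ids, mendelian = nrow(alleles) == n_product),
    class = "gpm_table")
}

#' @export
print.gpm_table <- function(x, ...) {
  cat("GPM table: ", nrow(x$alleles), " genotypes, ", length(x$loci),
      " loci (", paste(x$loci, collapse = ", "), "), ",
      distinct_phenotype_count(x$phenotypes), " distinct phenotypes",
      if (x$mendelian) "; Mendelian library" else "", "\n", sep = "")
  invisible(x)
}

#' Count measurably distinct phenotypes
#'
#' A genotype observed with several phenotypes (stochastic phenotypes,
#' repeated measurements) contributes each of them; `p` is the size of the
#' union of all observation sets.
#'
#' @param observations A list of character vectors of phenotype
#'   identifiers, or a `gpm_table`.
#' @return Integer count of distinct phenotype identifiers.
#' @export
distinct_phenotype_count <- function(observations) {
  if (inherits(observations, "gpm_table"))
    observations <- observations$phenotypes
  length(unique(unlist(observations, use.names = FALSE)))
}

# Per-locus phenotypic equivalence classes.  Two alleles at a locus are
# equivalent iff in every genetic background present in the table where
# both occur, swapping one for the other leaves the observed phenotype set
# unchanged.  Alleles that never share a background are kept distinct
# (they cannot be shown interchangeable).  Classes are connected
# components of the pairwise-equivalence graph.
locus_equivalence_classes <- function(gpm, locus) {
  alle <- gpm$alleles[[locus]]
  others <- setdiff(gpm$loci, locus)
  bg <- if (length(others))
    do.call(paste, c(gpm$alleles[others], sep = "\r")) else
    rep("", length(alle))
  pheno_key <- vapply(gpm$phenotypes,
                      function(p) paste(sort(p), collapse = "\r"), "")
  uniq <- sort(unique(alle))
  k <- length(uniq)
  if (k == 1L) return(list(uniq))
  # phenotype-set key per (background, allele), NA when absent
  tab <- matrix(NA_character_, nrow = length(unique(bg)), ncol = k,
                dimnames = list(unique(bg), uniq))
  tab[cbind(match(bg, rownames(tab)), match(alle, uniq))] <- pheno_key
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in 1:(k - 1)) for (b in (a + 1):k) {
    shared <- !is.na(tab[, a]) & !is.na(tab[, b])
    if (any(shared) && all(tab[shared, a] == tab[shared, b]))
      parent[find(b)] <- find(a)
  }
  roots <- vapply(seq_len(k), find, 0L)
  split(uniq, roots)
}

#' Genetic complexity of a GPM table
#'
#' Computes the full [complexity result][complexity_from_counts]: per-locus
#' allele equivalence classes (two alleles are equivalent iff swapping them
#' never changes the phenotype set in any shared background present in the
#' table), the number `n` of informative loci (>= 2 classes), the
#' geometric-mean allele count `m`, the genotypic diversity `m^n`, the
#' phenotype count `p` and `C`.
#'
#' @param gpm A [gpm_table].
#' @param assume_unique_alleles If `TRUE`, skip the exhaustive
#'   allele-swap check and treat every allele as phenotypically unique
#'   (appropriate for libraries where uniqueness is guaranteed by
#'   construction, e.g. Boolean-network topology-class libraries).
#' @return A `complexity_result`.
#' @export
gpm_complexity <- function(gpm, assume_unique_alleles = FALSE) {
  stopifnot(inherits(gpm, "gpm_table"))
  p <- distinct_phenotype_count(gpm)
  if (p < 2) stop("degenerate phenotype set: p must be >= 2 (got ", p, ")")
  m_i <- if (assume_unique_alleles)
    vapply(gpm$alleles, function(a) length(unique(a)), 0L)
  else
    vapply(gpm$loci, function(l) length(locus_equivalence_classes(gpm, l)), 0L)
  m_i <- m_i[m_i >= 2L]
  n <- length(m_i)
  G <- prod(m_i)
  m <- if (n > 0) G^(1 / n) else 1
  new_complexity_result(n = n, m = m, genotype_diversity = G, p = p,
                        C = complexity_from_counts(G, p), source = "gpm")
}

#' Discretize continuous phenotype measurements
#'
#' Single-linkage clustering on the measurement axis: two measurements
#' fall in the same phenotype cluster when they are connected by a chain
#' of gaps each strictly smaller than `resolution`.  Returns the number of
#' clusters, usable as `p`.  This is a documented pluggable hook for
#' continuous phenotypes, not a calibrated measurement model.
#'
#' @param values Numeric vector of phenotype measurements.
#' @param resolution Positive merge radius in measurement units.
#' @return Integer number of distinguishable phenotypes.
#' @export
#' @examples
#' discretize_phenotypes(c(0, 10, 20), resolution = 1)  # 3
discretize_phenotypes <- function(values, resolution) {
  if (length(values) == 0L) stop("empty measurement vector")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a positive number")
  1L + sum(diff(sort(values)) >= resolution)
}
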