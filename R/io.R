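# File formats.  The domain objects here have no community-standard
# format, so the package documents small bespoke TSV/JSON dialects:
#
#   * GPM TSV: one row per (genotype, phenotype) pair with columns
#     genotype_id, alleles ("locus=allele;locus=allele;..."), phenotype_id;
#     a JSON mirror carries the explicit loci list.
#   * Truth-table TSV: header `state` plus one column per node; one row
#     per state.  Binary state strings are written node-1-first, while
#     the in-memory integer encoding is little-endian (node 1 = bit 0);
#     the writer/reader pair keeps round-trips bit-exact.
#   * Threshold network: an edges file (source, target, weight in {-1,1})
#     and a nodes file (name, self_degrading in {0,1}).
#
# All readers fail with line-numbered diagnostics on malformed input.

#' Read / write a GPM table as TSV
#'
#' One row per (genotype, phenotype) observation; a genotype observed
#' with several phenotypes occupies several rows and contributes each of
#' them to its observation set.
#'
#' @param path File path.
#' @return `read_gpm_tsv()` returns a [gpm_table].
#' @export
read_gpm_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("genotype_id", "alleles", "phenotype_id")
  if (!all(need %in% names(df)))
    stop("GPM TSV needs columns: ", paste(need, collapse = ", "))
  parse_alleles <- function(x, line) {
    parts <- strsplit(x, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, "=", fixed = TRUE)
    if (any(lengths(kv) != 2L))
      stop("line ", line, ": malformed allele field '", x, "'")
    stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  }
  ids <- unique(df$genotype_id)
  first <- match(ids, df$genotype_id)
  assign_list <- lapply(seq_along(ids), function(k)
    parse_alleles(df$alleles[first[k]], first[k] + 1L))
  loci <- names(assign_list[[1L]])
  for (k in seq_along(ids)) {
    if (!identical(sort(names(assign_list[[k]])), sort(loci)))
      stop("line ", first[k] + 1L, ": genotype '", ids[k],
           "' does not assign exactly the loci ", paste(loci, collapse = ", "))
  }
  alleles <- as.data.frame(do.call(rbind,
    lapply(assign_list, function(a) a[loci])), stringsAsFactors = FALSE)
  names(alleles) <- loci
  phen <- lapply(ids, function(id) unique(df$phenotype_id[df$genotype_id == id]))
  # consistency: repeated rows for one genotype must repeat its alleles
  for (i in seq_len(nrow(df))) {
    k <- match(df$genotype_id[i], ids)
    if (!identical(parse_alleles(df$alleles[i], i + 1L)[loci],
                   assign_list[[k]][loci]))
      stop("line ", i + 1L, ": genotype '", ids[k],
           "' listed with conflicting alleles")
  }
  rownames(alleles) <- ids
  gpm_table(alleles, phen)
}

#' @rdname read_gpm_tsv
#' @param gpm A [gpm_table].
#' @export
write_gpm_tsv <- function(gpm, path) {
  rows <- do.call(rbind, lapply(seq_along(gpm$genotype_id), function(k) {
    al <- paste(gpm$loci, unlist(gpm$alleles[k, ]), sep = "=", collapse = ";")
    data.frame(genotype_id = gpm$genotype_id[k], alleles = al,
               phenotype_id = gpm$phenotypes[[k]], stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a GPM table as JSON
#'
#' JSON mirror of the TSV dialect with an explicit `loci` list:
#' `{"loci": [...], "genotypes": [{"id": ..., "alleles": {...},
#' "phenotypes": [...]}]}`.
#'
#' @param path File path.
#' @return `read_gpm_json()` returns a [gpm_table].
#' @export
read_gpm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  loci <- as.character(unlist(x$loci))
  alleles <- as.data.frame(do.call(rbind, lapply(x$genotypes, function(g)
    unlist(g$alleles)[loci])), stringsAsFactors = FALSE)
  names(alleles) <- loci
  rownames(alleles) <- vapply(x$genotypes, function(g) as.character(g$id), "")
  gpm_table(alleles, lapply(x$genotypes,
                            function(g) as.character(unlist(g$phenotypes))))
}

#' @rdname read_gpm_json
#' @param gpm A [gpm_table].
#' @export
write_gpm_json <- function(gpm, path) {
  out <- list(
    loci = gpm$loci,
    genotypes = lapply(seq_along(gpm$genotype_id), function(k) list(
      id = gpm$genotype_id[k],
      alleles = as.list(stats::setNames(unlist(gpm$alleles[k, ]), gpm$loci)),
      phenotypes = gpm$phenotypes[[k]])))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read / write a genotype's truth table as TSV
#'
#' Header `state` plus one column per node; one row per network state.
#' State strings are binary with node 1 leftmost.
#'
#' @param path File path.
#' @param node_names Optional node names for the header.
#' @return `read_truth_table()` returns a [bn_genotype].
#' @export
read_truth_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  if (names(df)[1L] != "state") stop("first column must be 'state'")
  order <- ncol(df) - 1L
  if (nrow(df) != 2^order)
    stop("truth table must have 2^order = ", 2^order, " rows, found ",
         nrow(df))
  states <- unname(vapply(df$state, string_to_state, 0L))
  if (!identical(sort(states), 0:(2^order - 1L)))
    stop("state column must enumerate every state exactly once")
  ord <- base::order(states)
  alleles <- lapply(2:(order + 1L), function(j) as.integer(df[[j]][ord]))
  bn_genotype(alleles)
}

#' @rdname read_truth_table
#' @param genotype A [bn_genotype].
#' @export
write_truth_table <- function(genotype, path, node_names = NULL) {
  n <- genotype$order
  node_names <- node_names %||% paste0("node", 1:n)
  df <- data.frame(state = vapply(0:(2^n - 1L), state_to_string, "", order = n),
                   stringsAsFactors = FALSE)
  for (i in 1:n) df[[node_names[i]]] <- genotype$alleles[[i]]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a threshold network as a TSV pair
#'
#' @param edges_path Edge table: columns `source`, `target`, `weight`
#'   (+1/-1).
#' @param nodes_path Node table: columns `name`, `self_degrading` (0/1);
#'   row order defines the node order.
#' @return `read_threshold_network()` returns a [threshold_network].
#' @export
read_threshold_network <- function(edges_path, nodes_path) {
  nd <- utils::read.delim(nodes_path, stringsAsFactors = FALSE)
  if (!all(c("name", "self_degrading") %in% names(nd)))
    stop("nodes file needs columns name, self_degrading")
  ed <- utils::read.delim(edges_path, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "weight") %in% names(ed)))
    stop("edges file needs columns source, target, weight")
  n <- nrow(nd)
  W <- matrix(0L, n, n)
  for (i in seq_len(nrow(ed))) {
    src <- match(ed$source[i], nd$name)
    tgt <- match(ed$target[i], nd$name)
    if (is.na(src) || is.na(tgt))
      stop("line ", i + 1L, " of edges file: unknown node '",
           if (is.na(src)) ed$source[i] else ed$target[i], "'")
    if (!ed$weight[i] %in% c(-1L, 1L))
      stop("line ", i + 1L, " of edges file: weight must be +1 or -1")
    if (W[tgt, src] != 0L)
      stop("line ", i + 1L, " of edges file: duplicate arrow ",
           ed$source[i], " -> ", ed$target[i])
    W[tgt, src] <- as.integer(ed$weight[i])
  }
  threshold_network(nd$name, W, nd$self_degrading == 1L)
}

#' @rdname read_threshold_network
#' @param net A [threshold_network].
#' @export
write_threshold_network <- function(net, edges_path, nodes_path) {
  utils::write.table(
    data.frame(name = net$nodes,
               self_degrading = as.integer(net$self_degrading)),
    nodes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(threshold_edges(net), edges_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(edges_path)
}

#' Write a complexity or census report as JSON
#'
#' The report carries the package version and the attractor-identity
#' convention tag so censuses from different versions are comparable.
#'
#' @param x A `complexity_result`, or any list/data.frame.
#' @param path Output path.
#' @export
write_report_json <- function(x, path) {
  body <- if (inherits(x, "complexity_result")) unclass(x) else x
  out <- list(package = "gpmcomplexity",
              version = as.character(utils::packageVersion("gpmcomplexity")),
              attractor_convention = "canonical-cyclic-state-sequence",
              report = body)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Sample a random genotype library
#'
#' Draws `n_genotypes` distinct genotypes uniformly from the full library
#' of the given order.  Deterministic under `seed`; the caller's RNG
#' state is left untouched.
#'
#' @param order Network order (1 to 3).
#' @param n_genotypes Number of distinct genotypes to draw, at most the
#'   full library size.
#' @param seed Integer seed.
#' @return A `genotype_library` of type `"explicit"`.
#' @export
random_library <- function(order, n_genotypes, seed) {
  stopifnot(is_count(order), order >= 1, order <= 3, is_count(n_genotypes))
  total <- (2^(2^order))^order
  if (n_genotypes > total)
    stop("cannot draw ", n_genotypes, " distinct genotypes from a library of ",
         total)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- sample.int(total, n_genotypes) - 1  # 0-based genotype codes
  S <- 2^order
  genos <- lapply(idx, function(g) {
    bn_genotype(lapply(1:order, function(i) {
      f <- (g %/% (2^S)^(i - 1)) %% (2^S)
      bitwAnd(bitwShiftR(as.integer(f), 0:(S - 1L)), 1L)
    }))
  })
  new_genotype_library(order, "explicit",
                       paste0("random library (seed ", seed, ")"),
                       n_genotypes, genotypes = genos)
}
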