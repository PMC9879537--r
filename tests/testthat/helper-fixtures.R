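# shared fixtures and independent oracles; everything is generated in code

tiny_map <- function(counts, species = "sp", genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(counts)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(counts)))
  dimnames(counts) <- list(genes, samples)
  expression_map(counts, species)
}

# deterministic small two-species comparison for classifier tests
small_sim <- function(seed = 42, n = 300, labels_a = 12, labels_b = 9) {
  simulate_species_pair(simulation_config(
    n_genes_a = n, n_genes_b = n, n_sample_labels_a = labels_a,
    n_sample_labels_b = labels_b, seed = seed))
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# --- union-find oracle for connected components --------------------------

uf_components <- function(n_nodes, edge_i, edge_j) {
  stopifnot(length(edge_i) == length(edge_j))
  edge_i <- edge_i[!is.na(edge_i)]; edge_j <- edge_j[!is.na(edge_j)]
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (e in seq_along(edge_i)) {
    ri <- find(edge_i[e]); rj <- find(edge_j[e])
    if (ri != rj) parent[rj] <- ri
  }
  vapply(seq_len(n_nodes), find, integer(1))
}

# canonical form of a partition (for comparing component structures)
partition_sets <- function(members, component) {
  sets <- split(members, component)
  sets <- lapply(sets, function(s) sort(s))
  unname(sets[order(vapply(sets, `[`, character(1), 1))])
}

# --- brute-force global affine-gap aligner (enumerates alignments) -------
# gap run of length L scores gap_open + (L - 1) * gap_extend

bf_align <- function(a, b, sub_mat, gap_open = -11, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, sub_mat[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(av)) {  # av[i] against a gap
      g <- if (last == "A") gap_extend else gap_open
      best <- max(best, g + rec(i + 1, j, "A"))
    }
    if (j <= length(bv)) {
      g <- if (last == "B") gap_extend else gap_open
      best <- max(best, g + rec(i, j + 1, "B"))
    }
    best
  }
  rec(1, 1, "start")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
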