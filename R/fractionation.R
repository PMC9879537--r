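#' Build the ES-weighted bipartite graph of an orthogroup
#'
#' Every interspecific gene pair within the orthogroup becomes an edge
#' whose weight is the pair's Expression Score, giving a complete weighted
#' bipartite graph between the two species' co-orthologs. Within-species
#' edges do not exist: expression similarity is only assessed across
#' species.
#'
#' @param group One orthogroup: a single row of the tibble returned by
#'   [read_orthogroups()] (or a list with `group_id`, `genes_a`, `genes_b`).
#' @param es An `es_table` (or any tibble with `gene_a`, `gene_b`, `es`).
#' @return A `bipartite_graph`: list with `group_id`, `nodes_a`, `nodes_b`
#'   and an `edges` tibble (`gene_a`, `gene_b`, `weight`).
#' @export
build_graph <- function(group, es) {
  if (is.data.frame(group)) {
    stopifnot(nrow(group) == 1)
    group <- list(group_id = group$group_id, genes_a = group$genes_a[[1]],
                  genes_b = group$genes_b[[1]])
  }
  edges <- tidyr::expand_grid(gene_a = group$genes_a, gene_b = group$genes_b)
  key <- pair_key(edges)
  idx <- match(key, pair_key(es))
  if (anyNA(idx)) {
    miss <- edges[is.na(idx), ]
    abort_lookup(paste0(
      "no ES for ", sum(is.na(idx)), " pair(s) of orthogroup ",
      group$group_id, ": ",
      paste(utils::head(paste(miss$gene_a, miss$gene_b, sep = "-"), 5),
            collapse = ", ")))
  }
  edges$weight <- es$es[idx]
  structure(list(group_id = group$group_id,
                 nodes_a = group$genes_a, nodes_b = group$genes_b,
                 edges = edges),
            class = "bipartite_graph")
}

#' Cut a weighted bipartite graph and list its connected components
#'
#' Removes every edge whose ES weight does not exceed the threshold, then
#' finds connected components of the remaining graph by depth-first
#' search. Each component is an expresso-group: a set of genes whose
#' expression profiles are mutually consistent across species. Genes left
#' without any retained edge become singleton expresso-groups. An edge
#' weight exactly equal to the threshold is removed (a pair with
#' ES = 0.5 is not classified as positive).
#'
#' @param graph A `bipartite_graph` from [build_graph()].
#' @param threshold ES threshold in \[0, 1\]; default 0.5.
#' @return A tibble with columns `group_id`, `expresso_group` (component
#'   index within the orthogroup), `gene`, `species` (`"A"`/`"B"`). Every
#'   input gene appears exactly once.
#' @export
cut_and_components <- function(graph, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  nodes <- c(paste0("A\r", graph$nodes_a), paste0("B\r", graph$nodes_b))
  n <- length(nodes)
  if (n == 0) {
    return(tibble::tibble(group_id = character(), expresso_group = integer(),
                          gene = character(), species = character()))
  }
  kept <- graph$edges[graph$edges$weight > threshold, , drop = FALSE]
  adj <- vector("list", n)
  if (nrow(kept) > 0) {
    ia <- match(paste0("A\r", kept$gene_a), nodes)
    ib <- match(paste0("B\r", kept$gene_b), nodes)
    for (e in seq_along(ia)) {
      adj[[ia[e]]] <- c(adj[[ia[e]]], ib[e])
      adj[[ib[e]]] <- c(adj[[ib[e]]], ia[e])
    }
  }
  comp <- integer(n)  # 0 = unvisited
  n_comp <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    n_comp <- n_comp + 1L
    stack <- start  # iterative depth-first search
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- n_comp
      nb <- adj[[v]]
      stack <- c(stack, nb[comp[nb] == 0L])
    }
  }
  tibble::tibble(
    group_id = rep(graph$group_id %||% NA_character_, n),
    expresso_group = comp,
    gene = sub("^[AB]\r", "", nodes),
    species = substr(nodes, 1, 1)
  )
}

#' Fractionate orthogroups into expresso-groups
#'
#' Applies [build_graph()] + [cut_and_components()] to every orthogroup.
#'
#' @param groups Orthogroup tibble from [read_orthogroups()].
#' @param es An `es_table` covering all interspecific pairs of the groups.
#' @param threshold ES threshold (default 0.5).
#' @return A tibble with columns `group_id`, `expresso_group`, `gene`,
#'   `species`.
#' @export
fractionate_orthogroups <- function(groups, es, threshold = 0.5) {
  es <- tibble::as_tibble(es)
  parts <- purrr::map(seq_len(nrow(groups)), function(i) {
    cut_and_components(build_graph(groups[i, ], es), threshold)
  })
  dplyr::bind_rows(parts)
}

#' Summarize fractionation patterns
#'
#' Global singleton statistics plus retention patterns for the 1 x n
#' orthogroup shapes: for an orthogroup with a single gene in one species
#' and `n` co-orthologs in the other, a co-ortholog is "retained" when it
#' lands in the same expresso-group as the single partner. Larger shapes
#' are summarized by their component-size histogram.
#'
#' @param fractions Output of [fractionate_orthogroups()].
#' @return A list with elements
#'   `singletons` (tibble: `n_genes`, `n_singletons`, `singleton_fraction`),
#'   `patterns` (tibble: `shape`, `n_retained`, `n_groups`, plus the
#'   per-shape retention fraction of co-orthologs), and
#'   `component_sizes` (tibble: `size`, `n_components`).
#' @export
summarize_patterns <- function(fractions) {
  per_comp <- fractions |>
    dplyr::group_by(.data$group_id, .data$expresso_group) |>
    dplyr::summarise(size = dplyr::n(), .groups = "drop")
  singleton_genes <- fractions |>
    dplyr::group_by(.data$group_id, .data$expresso_group) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup()
  singletons <- tibble::tibble(
    n_genes = nrow(fractions),
    n_singletons = nrow(singleton_genes),
    singleton_fraction = nrow(singleton_genes) / max(1, nrow(fractions))
  )

  shape_of <- fractions |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(n_a = sum(.data$species == "A"),
                     n_b = sum(.data$species == "B"), .groups = "drop")
  one_to_n <- shape_of |>
    dplyr::filter((.data$n_a == 1 & .data$n_b >= 2) |
                    (.data$n_b == 1 & .data$n_a >= 2)) |>
    dplyr::mutate(shape = paste0("1x", pmax(.data$n_a, .data$n_b)))

  patterns <- if (nrow(one_to_n)) {
    frac1 <- dplyr::inner_join(fractions, one_to_n, by = "group_id")
    frac1 |>
      dplyr::group_by(.data$group_id, .data$shape) |>
      dplyr::summarise(n_retained = retained_coorthologs(
        .data$expresso_group, .data$species, .data$n_a[1]), .groups = "drop") |>
      dplyr::count(.data$shape, .data$n_retained, name = "n_groups") |>
      dplyr::group_by(.data$shape) |>
      dplyr::mutate(
        fraction_of_groups = .data$n_groups / sum(.data$n_groups)) |>
      dplyr::ungroup()
  } else {
    tibble::tibble(shape = character(), n_retained = integer(),
                   n_groups = integer(), fraction_of_groups = numeric())
  }

  sizes <- per_comp |> dplyr::count(.data$size, name = "n_components")
  list(singletons = singletons, patterns = patterns,
       component_sizes = sizes)
}

# number of co-orthologs connected to the single-copy partner in a 1 x n
# orthogroup
retained_coorthologs <- function(component, species, n_a) {
  single_species <- if (n_a == 1) "A" else "B"
  partner_comp <- component[species == single_species][1]
  sum(species != single_species & component == partner_comp)
}

#' Fraction of co-orthologs with retained expression profiles
#'
#' For the 1 x n shapes in a pattern summary: the fraction of co-ortholog
#' genes that share an expresso-group with their single-copy partner.
#'
#' @param patterns The `patterns` element of [summarize_patterns()].
#' @return A tibble with columns `shape`, `retained_fraction`.
#' @export
retention_fractions <- function(patterns) {
  patterns |>
    dplyr::mutate(n = as.integer(sub("1x", "", .data$shape))) |>
    dplyr::group_by(.data$shape) |>
    dplyr::summarise(retained_fraction =
                       sum(.data$n_retained * .data$n_groups) /
                       sum(.data$n[1] * .data$n_groups))
}

#' Write fractionation results to TSV
#' @param fractions Output of [fractionate_orthogroups()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fractionation <- function(fractions, path) {
  readr::write_tsv(fractions, path, progress = FALSE)
  invisible(path)
}
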