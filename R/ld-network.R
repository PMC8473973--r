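#' LD network of SNPs in high linkage disequilibrium
#'
#' Builds a graph whose nodes are loci and whose edges connect pairs with
#' `r2 >= edge_min_r2` (pairs below the threshold are removed). Nodes in LD
#' with fewer than `min_degree` other SNPs are then excluded; pruning is
#' iterative — degrees are recomputed after each removal round until no node
#' violates the criterion — so the stated degree rule holds in the reported
#' network. Connected components of the retained nodes are reported with
#' their genomic spans; in a genome with a single segregating inversion the
#' expected outcome is one component spanning the inverted region.
#'
#' @param ld_tab LD table from [pairwise_ld()] / [chromosome_ld()].
#' @param edge_min_r2 Minimum r-squared for an edge (default 0.4).
#' @param min_degree Minimum number of LD partners for a node to be kept
#'   (default 4).
#' @return List of class `ld_network`: `graph` (an \pkg{igraph} object of
#'   the retained nodes), `components` (data frame: `component`, `n_loci`,
#'   `chrom`, `start`, `end` of the span on each chromosome touched), and
#'   `nodes` (data frame: `name`, `chrom`, `pos`, `degree`, `component`).
#'   An empty network is a valid result.
#' @export
ld_network <- function(ld_tab, edge_min_r2 = 0.4, min_degree = 4) {
  keep <- !is.na(ld_tab$r2) & ld_tab$r2 >= edge_min_r2
  et <- ld_tab[keep, , drop = FALSE]
  empty <- function() {
    structure(
      list(
        graph = igraph::make_empty_graph(directed = FALSE),
        components = data.frame(component = integer(), n_loci = integer(),
                                chrom = character(), start = integer(),
                                end = integer()),
        nodes = data.frame(name = character(), chrom = character(),
                           pos = integer(), degree = integer(),
                           component = integer())
      ),
      class = "ld_network"
    )
  }
  if (nrow(et) == 0) return(empty())
  key_a <- paste0(et$chrom_a, ":", et$pos_a)
  key_b <- paste0(et$chrom_b, ":", et$pos_b)
  g <- igraph::graph_from_data_frame(
    data.frame(from = key_a, to = key_b, r2 = et$r2),
    directed = FALSE
  )
  repeat {
    low <- igraph::V(g)[igraph::degree(g) < min_degree]
    if (length(low) == 0) break
    g <- igraph::delete_vertices(g, low)
  }
  if (igraph::vcount(g) == 0) return(empty())
  comp <- igraph::components(g)
  nm <- igraph::V(g)$name
  parts <- do.call(rbind, strsplit(nm, ":", fixed = TRUE))
  nodes <- data.frame(
    name = nm, chrom = parts[, 1], pos = as.integer(parts[, 2]),
    degree = as.integer(igraph::degree(g)),
    component = as.integer(comp$membership),
    stringsAsFactors = FALSE
  )
  spans <- do.call(rbind, lapply(split(nodes, nodes$component), function(d) {
    do.call(rbind, lapply(split(d, d$chrom), function(dc) {
      data.frame(component = dc$component[1], n_loci = nrow(d),
                 chrom = dc$chrom[1], start = min(dc$pos),
                 end = max(dc$pos), stringsAsFactors = FALSE)
    }))
  }))
  rownames(spans) <- NULL
  structure(list(graph = g, components = spans, nodes = nodes),
            class = "ld_network")
}

#' @export
print.ld_network <- function(x, ...) {
  cat(sprintf("<ld_network> %d nodes, %d edges, %d component(s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(unique(x$nodes$component))))
  if (nrow(x$components)) print(x$components)
  invisible(x)
}
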