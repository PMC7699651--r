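#' @include AllGenerics.R
NULL

# ---- constructors -----------------------------------------------------------

#' Construct a network layer
#'
#' Builds a [Layer-class] from an edge matrix, cleaning the input the way
#' the file loader does: self-loops are dropped, and duplicate edges
#' (including reverse duplicates for undirected layers) are collapsed; a
#' message reports each non-zero count. The node set is the union of edge
#' endpoints and `nodes`, so isolated nodes can be declared explicitly.
#'
#' @param name layer label.
#' @param edges two-column character matrix or data.frame of edges
#'   (regulator/target for a directed layer).
#' @param directed logical.
#' @param nodes optional character vector of additional (possibly
#'   isolated) node ids.
#' @return a validated [Layer-class].
#' @examples
#' Layer("ppi", cbind(c("p1", "p2"), c("p2", "p1")), directed = FALSE)
#' @export
Layer <- function(name, edges = NULL, directed = FALSE, nodes = NULL) {
  if (is.null(edges)) edges <- matrix(character(0), 0L, 2L)
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  edges <- matrix(as.character(edges), ncol = 2L,
                  dimnames = NULL)
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    message(sprintf("layer '%s': dropped %d self-loop(s)", name, sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (!directed && nrow(edges)) {
    a <- pmin(edges[, 1L], edges[, 2L])
    b <- pmax(edges[, 1L], edges[, 2L])
    edges <- cbind(a, b, deparse.level = 0L)
  }
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sprintf("layer '%s': collapsed %d duplicate edge(s)", name, sum(dup)))
    edges <- edges[!dup, , drop = FALSE]
  }
  allNodes <- sort(unique(c(as.character(edges), as.character(nodes))))
  new("Layer", name = name, directed = directed, nodes = allNodes,
      edges = edges)
}

#' @rdname InterdependencyMap-class
#' @param gene,protein parallel character vectors of paired ids.
#' @export
InterdependencyMap <- function(gene = character(0), protein = character(0)) {
  new("InterdependencyMap", gene = as.character(gene),
      protein = as.character(protein))
}

#' @rdname SupportMap-class
#' @param protein,metabolite parallel character vectors of support links.
#' @export
SupportMap <- function(protein = character(0), metabolite = character(0)) {
  new("SupportMap", protein = as.character(protein),
      metabolite = as.character(metabolite))
}

#' Assemble a multilayer network
#'
#' @param grn directed [Layer-class] (gene regulatory network).
#' @param ppi,met undirected [Layer-class] objects.
#' @param gp [InterdependencyMap-class] of gene/protein pairs.
#' @param pm [SupportMap-class] of protein-to-metabolite supports.
#' @param check validate the assembled network and fail on any violation
#'   (default). `check = FALSE` builds the object anyway, so
#'   [validateNetwork()] can be used to inspect a broken instance.
#' @return a [MultilayerNetwork-class].
#' @export
MultilayerNetwork <- function(grn, ppi, met,
                              gp = InterdependencyMap(),
                              pm = SupportMap(), check = TRUE) {
  net <- new("MultilayerNetwork", grn = grn, ppi = ppi, met = met,
             gp = gp, pm = pm)
  if (check) {
    bad <- validateNetwork(net)
    if (length(bad))
      stop("invalid multilayer network:\n  ", paste(bad, collapse = "\n  "),
           call. = FALSE)
  }
  net
}

# ---- accessors --------------------------------------------------------------

#' Accessors for layers and maps
#'
#' @param x a [Layer-class] or [MultilayerNetwork-class].
#' @name accessors
#' @aliases layerName isDirected layerNodes layerEdges grnLayer ppiLayer
#'   metLayer geneProteinMap proteinMetaboliteMap supportDegrees
NULL

#' @rdname accessors
setMethod("layerName", "Layer", function(x) x@name)
#' @rdname accessors
setMethod("isDirected", "Layer", function(x) x@directed)
#' @rdname accessors
setMethod("layerNodes", "Layer", function(x) x@nodes)
#' @rdname accessors
setMethod("layerEdges", "Layer", function(x) x@edges)
#' @rdname accessors
setMethod("grnLayer", "MultilayerNetwork", function(x) x@grn)
#' @rdname accessors
setMethod("ppiLayer", "MultilayerNetwork", function(x) x@ppi)
#' @rdname accessors
setMethod("metLayer", "MultilayerNetwork", function(x) x@met)
#' @rdname accessors
setMethod("geneProteinMap", "MultilayerNetwork", function(x) x@gp)
#' @rdname accessors
setMethod("proteinMetaboliteMap", "MultilayerNetwork", function(x) x@pm)

#' @rdname accessors
setMethod("supportDegrees", "MultilayerNetwork", function(x) {
  mets <- layerNodes(metLayer(x))
  ks <- tabulate(factor(x@pm@metabolite, levels = mets), nbins = length(mets))
  names(ks) <- mets
  ks
})

setMethod("show", "Layer", function(object) {
  cat(sprintf("Layer '%s' (%s): %d nodes, %d edges\n", object@name,
              if (object@directed) "directed" else "undirected",
              length(object@nodes), nrow(object@edges)))
})

setMethod("show", "MultilayerNetwork", function(object) {
  cat("MultilayerNetwork\n")
  for (l in list(object@grn, object@ppi, object@met)) {
    cat("  "); show(l)
  }
  cat(sprintf("  gene-protein pairs: %d\n", length(object@gp@gene)))
  cat(sprintf("  protein-metabolite supports: %d\n", length(object@pm@protein)))
})

# ---- validation -------------------------------------------------------------

#' Validate a multilayer network
#'
#' Returns a character vector of violations: dangling interlayer
#' endpoints, non-injective gene/protein matchings, duplicate support
#' links and malformed layers. An empty result means every invariant
#' holds.
#'
#' @param net a [MultilayerNetwork-class] (possibly built with
#'   `check = FALSE`).
#' @return character vector of violation descriptions (empty if valid).
#' @export
validateNetwork <- function(net) {
  msg <- character(0)
  for (l in list(net@grn, net@ppi, net@met)) {
    v <- validObject(l, test = TRUE)
    if (!isTRUE(v))
      msg <- c(msg, paste0("layer '", l@name, "': ", v))
  }
  g <- net@gp
  if (length(g@gene)) {
    if (length(g@gene) != length(g@protein))
      msg <- c(msg, "gene-protein map: ragged pair vectors")
    bad <- !g@gene %in% net@grn@nodes
    if (any(bad))
      msg <- c(msg, sprintf(
        "gene-protein map: dangling endpoint (gene %s not in GRN)",
        g@gene[bad][1L]))
    bad <- !g@protein %in% net@ppi@nodes
    if (any(bad))
      msg <- c(msg, sprintf(
        "gene-protein map: dangling endpoint (protein %s not in PPI)",
        g@protein[bad][1L]))
    if (anyDuplicated(g@gene))
      msg <- c(msg, "gene-protein map: non-injective matching (gene side)")
    if (anyDuplicated(g@protein))
      msg <- c(msg, "gene-protein map: non-injective matching (protein side)")
  }
  s <- net@pm
  if (length(s@protein)) {
    bad <- !s@protein %in% net@ppi@nodes
    if (any(bad))
      msg <- c(msg, sprintf(
        "support map: dangling endpoint (protein %s not in PPI)",
        s@protein[bad][1L]))
    bad <- !s@metabolite %in% net@met@nodes
    if (any(bad))
      msg <- c(msg, sprintf(
        "support map: dangling endpoint (metabolite %s not in metabolic layer)",
        s@metabolite[bad][1L]))
    if (anyDuplicated(paste(s@protein, s@metabolite, sep = "\r")))
      msg <- c(msg, "support map: duplicate support link")
  }
  msg
}

# ---- graph utilities --------------------------------------------------------

.layerIgraph <- function(layer) {
  n <- length(layer@nodes)
  g <- igraph::make_empty_graph(n = n, directed = layer@directed)
  if (nrow(layer@edges)) {
    idx <- rbind(match(layer@edges[, 1L], layer@nodes),
                 match(layer@edges[, 2L], layer@nodes))
    g <- igraph::add_edges(g, as.vector(idx))
  }
  g
}

#' Nodes of the largest connected component(s)
#'
#' Induces the subgraph of `layer` on `subset` and returns the union of
#' all components of maximum size. When several components tie for the
#' maximum, all of their nodes are returned (the inclusive tie rule used
#' throughout the cascade: every tied component counts as functional).
#' Intended for undirected layers; connectivity is evaluated ignoring
#' edge direction.
#'
#' @param layer a [Layer-class].
#' @param subset node ids to induce on (default: all nodes).
#' @return character vector of node ids (empty for an empty subset).
#' @export
largestComponent <- function(layer, subset = layerNodes(layer)) {
  subset <- as.character(subset)
  if (!all(subset %in% layer@nodes))
    stop("subset contains ids not in the layer", call. = FALSE)
  if (!length(subset)) return(character(0))
  ig <- .layerIgraph(layer)
  # induced_subgraph keeps vertices in increasing id order, whatever the
  # order of the input, so sort before mapping memberships back
  idx <- sort(match(subset, layer@nodes))
  sub <- igraph::induced_subgraph(ig, idx)
  cm <- igraph::components(sub, mode = "weak")
  layer@nodes[idx][cm$membership %in% which(cm$csize == max(cm$csize))]
}

# ---- degree statistics ------------------------------------------------------

.degreePmf <- function(deg) {
  if (!length(deg)) stop("empty layer", call. = FALSE)
  tabulate(deg + 1L, nbins = max(deg) + 1L) / length(deg)
}

#' Empirical degree distributions
#'
#' Computes the joint (in, out) degree pmf of the GRN, the degree pmfs of
#' the PPI and metabolic layers, and the support-degree pmf over all
#' metabolites (metabolites with no incoming support links contribute
#' mass at k_s = 0). These are the empirical inputs to the percolation
#' theory.
#'
#' @param net a [MultilayerNetwork-class].
#' @return a [DegreeDistributions-class].
#' @export
degreeDistributions <- function(net) {
  grn <- net@grn; ppi <- net@ppi; met <- net@met
  if (!length(grn@nodes) || !length(ppi@nodes) || !length(met@nodes))
    stop("empty layer", call. = FALSE)
  kIn <- tabulate(factor(grn@edges[, 2L], levels = grn@nodes),
                  nbins = length(grn@nodes))
  kOut <- tabulate(factor(grn@edges[, 1L], levels = grn@nodes),
                   nbins = length(grn@nodes))
  tab <- table(kIn, kOut)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0L, ]
  joint <- data.frame(kIn = as.integer(as.character(df$kIn)),
                      kOut = as.integer(as.character(df$kOut)),
                      prob = df$Freq / length(grn@nodes))
  undirDeg <- function(l) {
    tabulate(factor(c(l@edges[, 1L], l@edges[, 2L]), levels = l@nodes),
             nbins = length(l@nodes))
  }
  new("DegreeDistributions",
      grnJoint = joint,
      ppi = .degreePmf(undirDeg(ppi)),
      met = .degreePmf(undirDeg(met)),
      support = .degreePmf(unname(supportDegrees(net))))
}
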