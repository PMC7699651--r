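#' @include netmodel.R
NULL

# Read a whitespace/tab separated two-column file, '#' comments allowed.
# Reports the 1-based line number of any malformed line.
.readPairs <- function(path, what = "edge") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) return(matrix(character(0), 0L, 2L))
  parts <- strsplit(trimws(lines[idx]), "[\t ]+")
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop(sprintf("malformed %s line %d in %s: '%s'", what,
                 idx[bad][1L], path, lines[idx[bad][1L]]), call. = FALSE)
  t(vapply(parts, function(p) p[1:2], character(2L)))
}

#' Load a layer from a two-column TSV edge list
#'
#' Lines give one edge per row (`regulator<TAB>target` for a directed
#' layer); `#` comments are skipped. Self-loops are dropped and duplicate
#' (and, for undirected layers, reversed) edges collapsed, each with a
#' logged count. An optional one-column node-list file declares isolated
#' nodes.
#'
#' @param path edge-list file.
#' @param directed logical.
#' @param name layer label (defaults to the file name).
#' @param nodesPath optional one-column file of node ids.
#' @return a [Layer-class].
#' @export
loadLayer <- function(path, directed, name = basename(path),
                      nodesPath = NULL) {
  edges <- .readPairs(path)
  nodes <- NULL
  if (!is.null(nodesPath)) {
    if (!file.exists(nodesPath))
      stop("file not found: ", nodesPath, call. = FALSE)
    lines <- readLines(nodesPath, warn = FALSE)
    nodes <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  }
  Layer(name, edges, directed = directed, nodes = nodes)
}

#' @rdname loadLayer
#' @export
writeLayer <- function(layer, path) {
  e <- layerEdges(layer)
  writeLines(paste(e[, 1L], e[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Read / write a network bundle
#'
#' A bundle is a small YAML config naming the five TSV files (`grn`,
#' `ppi`, `met` edge lists, `gp` gene-protein pairs, `pm`
#' protein-metabolite supports), optional per-layer node lists
#' (`grn_nodes`, ...), and optional flags. Relative paths are resolved
#' against the config's directory.
#'
#' `prefix = "auto"` (default) prefixes node ids with `G:`/`P:`/`M:` only
#' when the three layers' id namespaces collide; `"always"` and `"never"`
#' force the behaviour. `restrictLcc` names undirected layers
#' (`"ppi"`, `"met"`) to restrict to their largest connected component
#' before assembly; the GRN is never restricted.
#'
#' @param path bundle YAML file.
#' @param prefix one of `"auto"`, `"always"`, `"never"`.
#' @param restrictLcc character vector among `c("ppi", "met")` (overrides
#'   any `restrict_lcc` entry in the config).
#' @return a [MultilayerNetwork-class].
#' @export
readNetworkBundle <- function(path, prefix = c("auto", "always", "never"),
                              restrictLcc = NULL) {
  prefix <- match.arg(prefix)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  dir <- dirname(normalizePath(path))
  f <- function(nm) {
    if (is.null(cfg[[nm]])) return(NULL)
    p <- cfg[[nm]]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(dir, p)
    p
  }
  for (nm in c("grn", "ppi", "met", "gp", "pm"))
    if (is.null(cfg[[nm]])) stop("bundle config lacks entry '", nm, "'",
                                 call. = FALSE)
  grn <- loadLayer(f("grn"), directed = TRUE, name = "grn",
                   nodesPath = f("grn_nodes"))
  ppi <- loadLayer(f("ppi"), directed = FALSE, name = "ppi",
                   nodesPath = f("ppi_nodes"))
  met <- loadLayer(f("met"), directed = FALSE, name = "met",
                   nodesPath = f("met_nodes"))
  gpPairs <- .readPairs(f("gp"), what = "gene-protein")
  pmPairs <- .readPairs(f("pm"), what = "protein-metabolite")
  if (is.null(restrictLcc) && !is.null(cfg$restrict_lcc))
    restrictLcc <- as.character(cfg$restrict_lcc)
  if ("ppi" %in% restrictLcc) ppi <- .restrictToLcc(ppi)
  if ("met" %in% restrictLcc) met <- .restrictToLcc(met)

  collide <- any(duplicated(c(unique(grn@nodes), unique(ppi@nodes),
                              unique(met@nodes))))
  doPrefix <- prefix == "always" || (prefix == "auto" && collide)
  if (doPrefix) {
    pre <- function(l, tag) {
      Layer(l@name, matrix(paste0(tag, l@edges), ncol = 2L),
            directed = l@directed, nodes = paste0(tag, l@nodes))
    }
    grn <- pre(grn, "G:"); ppi <- pre(ppi, "P:"); met <- pre(met, "M:")
    gpPairs <- cbind(paste0("G:", gpPairs[, 1L]), paste0("P:", gpPairs[, 2L]))
    pmPairs <- cbind(paste0("P:", pmPairs[, 1L]), paste0("M:", pmPairs[, 2L]))
  }
  # interlayer endpoints missing from edge files count as isolated nodes
  grn <- Layer("grn", grn@edges, TRUE, nodes = unique(c(grn@nodes, gpPairs[, 1L])))
  ppi <- Layer("ppi", ppi@edges, FALSE,
               nodes = unique(c(ppi@nodes, gpPairs[, 2L], pmPairs[, 1L])))
  met <- Layer("met", met@edges, FALSE, nodes = unique(c(met@nodes, pmPairs[, 2L])))
  MultilayerNetwork(grn, ppi, met,
                    gp = InterdependencyMap(gpPairs[, 1L], gpPairs[, 2L]),
                    pm = SupportMap(pmPairs[, 1L], pmPairs[, 2L]))
}

.restrictToLcc <- function(layer) {
  keep <- largestComponent(layer)
  e <- layer@edges
  e <- e[e[, 1L] %in% keep & e[, 2L] %in% keep, , drop = FALSE]
  Layer(layer@name, e, directed = layer@directed, nodes = keep)
}

#' @rdname readNetworkBundle
#' @param net a [MultilayerNetwork-class] to serialize.
#' @param dir output directory (created if needed).
#' @export
writeNetworkBundle <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLayer(net@grn, file.path(dir, "grn.tsv"))
  writeLayer(net@ppi, file.path(dir, "ppi.tsv"))
  writeLayer(net@met, file.path(dir, "met.tsv"))
  writeLines(paste(net@gp@gene, net@gp@protein, sep = "\t"),
             file.path(dir, "gp.tsv"))
  writeLines(paste(net@pm@protein, net@pm@metabolite, sep = "\t"),
             file.path(dir, "pm.tsv"))
  writeLines(net@grn@nodes, file.path(dir, "grn_nodes.txt"))
  writeLines(net@ppi@nodes, file.path(dir, "ppi_nodes.txt"))
  writeLines(net@met@nodes, file.path(dir, "met_nodes.txt"))
  cfg <- list(grn = "grn.tsv", ppi = "ppi.tsv", met = "met.tsv",
              gp = "gp.tsv", pm = "pm.tsv",
              grn_nodes = "grn_nodes.txt", ppi_nodes = "ppi_nodes.txt",
              met_nodes = "met_nodes.txt")
  yaml::write_yaml(cfg, file.path(dir, "bundle.yaml"))
  invisible(file.path(dir, "bundle.yaml"))
}
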