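# Directed social networks.
#
# An edge (a, b) means b follows a: a's expressed opinion is visible to b.
# The whole generated graph is used as-is, including disconnected
# subnetworks; no component filtering ever occurs.

NETWORK_KINDS <- c("erdos_renyi", "barabasi_albert", "scale_free", "complete")

new_network <- function(n_nodes, edges, kind) {
  edges <- matrix(as.integer(edges), ncol = 2,
                  dimnames = list(NULL, c("source", "target")))
  structure(list(n_nodes = as.integer(n_nodes), edges = edges, kind = kind),
            class = "soam_network")
}

validate_network <- function(net) {
  e <- net$edges
  if (nrow(e) > 0) {
    if (any(e < 1L) || any(e > net$n_nodes)) {
      stop("node id out of range [1, n_nodes]", call. = FALSE)
    }
    if (any(e[, 1] == e[, 2])) stop("self-loops are not allowed", call. = FALSE)
    if (anyDuplicated(paste(e[, 1], e[, 2]))) {
      stop("duplicate directed edges", call. = FALSE)
    }
  }
  net
}

#' Generate a directed social network
#'
#' Builds the directed influence graph the opinion dynamics run on. Node ids
#' are `1:n`. An edge `(a, b)` lets `a`'s expressed opinion influence `b`.
#'
#' Kinds:
#' \describe{
#'   \item{`erdos_renyi`}{Each ordered pair of distinct nodes carries an edge
#'     independently with probability `k / (n - 1)`, so expected in-degree and
#'     expected out-degree both equal `k`.}
#'   \item{`barabasi_albert`}{Undirected preferential attachment with
#'     `m = round(k / 2)` links per new node, then every undirected edge is
#'     replaced by both directed edges (mean total neighbor count about `k`).}
#'   \item{`scale_free`}{Undirected static power-law graph (degree exponent
#'     2.5) with `round(n * k / 2)` edges, symmetrized like `barabasi_albert`.}
#'   \item{`complete`}{All `n * (n - 1)` ordered pairs.}
#' }
#'
#' @param kind One of `"erdos_renyi"`, `"barabasi_albert"`, `"scale_free"`,
#'   `"complete"`.
#' @param n Number of nodes (at least 2).
#' @param k Target mean links per node, `0 <= k <= n - 1`. Ignored for
#'   `complete`.
#' @param seed Integer seed; the same arguments always give the same edge set.
#' @return A `soam_network`: list with `n_nodes`, integer `edges` matrix
#'   (columns `source`, `target`), and `kind`.
#' @examples
#' net <- generate_network("erdos_renyi", n = 100, k = 5, seed = 1)
#' nrow(net$edges) # close to 500
#' @export
generate_network <- function(kind, n, k = 5, seed = 1L) {
  kind <- match.arg(kind, NETWORK_KINDS)
  n <- as.integer(n)
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (kind != "complete" && (k < 0 || k > n - 1)) {
    stop("k must satisfy 0 <= k <= n - 1", call. = FALSE)
  }
  stream <- rng_stream(seed)
  edges <- with_stream(stream, switch(kind,
    complete = {
      idx <- expand.grid(target = seq_len(n), source = seq_len(n))
      idx <- idx[idx$source != idx$target, c("source", "target")]
      as.matrix(idx)
    },
    erdos_renyi = {
      g <- igraph::sample_gnp(n, p = k / (n - 1), directed = TRUE)
      igraph::as_edgelist(g, names = FALSE)
    },
    barabasi_albert = {
      m <- max(1L, as.integer(round(k / 2)))
      g <- igraph::sample_pa(n, m = m, directed = FALSE)
      symmetrize_edges(igraph::as_edgelist(g, names = FALSE))
    },
    scale_free = {
      n_edges <- max(1L, as.integer(round(n * k / 2)))
      g <- igraph::sample_fitness_pl(n, no.of.edges = n_edges,
                                     exponent.out = 2.5)
      g <- igraph::simplify(g)
      symmetrize_edges(igraph::as_edgelist(g, names = FALSE))
    }
  ))
  validate_network(new_network(n, edges, kind))
}

# undirected edge list -> both directed edges, deduplicated
symmetrize_edges <- function(e) {
  if (nrow(e) == 0) return(matrix(integer(0), ncol = 2))
  both <- rbind(e, e[, 2:1, drop = FALSE])
  unique(both)
}

#' In-neighborhood of a node
#'
#' The agents whose expressed opinions agent `i` can see: all `j` with a
#' directed edge `(j, i)`.
#'
#' @param net A `soam_network`.
#' @param i Node id in `1:n_nodes`.
#' @return Integer vector of node ids (possibly empty).
#' @export
in_neighbors <- function(net, i) {
  i <- as.integer(i)
  if (length(i) != 1 || is.na(i) || i < 1 || i > net$n_nodes) {
    stop("invalid node id", call. = FALSE)
  }
  e <- net$edges
  sort(e[e[, 2] == i, 1])
}

# list of in-neighbor id vectors, one per node (hot path for the engine)
in_adjacency <- function(net) {
  adj <- rep(list(integer(0)), net$n_nodes)
  e <- net$edges
  if (nrow(e) > 0) {
    sp <- split(e[, 1], e[, 2])
    adj[as.integer(names(sp))] <- sp
  }
  adj
}

#' Read and write directed networks
#'
#' Two on-disk formats: a plain-text directed edge list (header line
#' `n=<count>`, then one `source target` pair per line, 1-based ids) and
#' GraphML (via igraph; preserves the network kind as a graph attribute).
#' `read_network(write_network(net, path))` returns an identical node count
#' and edge set.
#'
#' @param net A `soam_network`.
#' @param path File path; a `.graphml` extension selects GraphML unless
#'   `format` is given.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `write_network` returns `path` invisibly; `read_network` returns a
#'   `soam_network` (kind `"custom"` for bare edge lists, which do not record
#'   a kind).
#' @export
write_network <- function(net, path, format = NULL) {
  format <- resolve_net_format(path, format)
  if (format == "graphml") {
    g <- igraph::graph_from_edgelist(net$edges, directed = TRUE)
    g <- igraph::add_vertices(g, max(0L, net$n_nodes - igraph::vcount(g)))
    g <- igraph::set_graph_attr(g, "kind", net$kind)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    lines <- c(sprintf("n=%d", net$n_nodes),
               sprintf("%d %d", net$edges[, 1], net$edges[, 2]))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = NULL) {
  format <- resolve_net_format(path, format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    kind <- igraph::graph_attr(g, "kind")
    if (is.null(kind)) kind <- "custom"
    net <- new_network(igraph::vcount(g),
                       igraph::as_edgelist(g, names = FALSE), kind)
  } else {
    lines <- readLines(path)
    if (length(lines) == 0 || !grepl("^n=\\d+$", lines[1])) {
      stop("malformed edge-list file: expected header 'n=<count>'",
           call. = FALSE)
    }
    n <- as.integer(sub("^n=", "", lines[1]))
    body <- lines[-1]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0) {
      edges <- matrix(integer(0), ncol = 2)
    } else {
      parts <- strsplit(trimws(body), "\\s+")
      if (any(lengths(parts) != 2)) {
        stop("malformed edge-list file: expected 'source target' lines",
             call. = FALSE)
      }
      edges <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
      if (anyNA(edges)) stop("malformed edge-list file: non-integer ids",
                             call. = FALSE)
    }
    net <- new_network(n, edges, "custom")
  }
  validate_network(net)
}

resolve_net_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("edgelist", "graphml")))
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "edgelist"
}

#' @export
print.soam_network <- function(x, ...) {
  cat(sprintf("<soam_network> kind=%s, %d nodes, %d directed edges\n",
              x$kind, x$n_nodes, nrow(x$edges)))
  invisible(x)
}
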