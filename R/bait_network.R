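NODE_STATUSES <- c("bait", "confirmed", "database_only", "experiment_only")

new_annotated_network <- function(nodes, edges, bait, report = NULL) {
  stopifnot(all(c("accession", "status", "depth") %in% names(nodes)))
  structure(list(nodes = nodes, edges = edges, bait = bait, report = report),
            class = "annotated_network")
}

#' @export
print.annotated_network <- function(x, ...) {
  counts <- table(factor(x$nodes$status, levels = NODE_STATUSES))
  cat(sprintf("<annotated_network> bait %s: %d node(s), %d edge(s)\n",
              x$bait, nrow(x$nodes), nrow(x$edges)))
  cat(sprintf("  bait %d | confirmed %d | database_only %d | experiment_only %d\n",
              counts["bait"], counts["confirmed"], counts["database_only"],
              counts["experiment_only"]))
  invisible(x)
}

#' @export
as_igraph.annotated_network <- function(net) {
  vertices <- data.frame(name = net$nodes$accession,
                         gene_name = net$nodes$gene_name %||% NA_character_,
                         status = net$nodes$status,
                         depth = net$nodes$depth,
                         stringsAsFactors = FALSE)
  if (all(c("x", "y") %in% names(net$nodes))) {
    vertices$x <- net$nodes$x
    vertices$y <- net$nodes$y
  }
  e <- net$edges
  if (nrow(e)) {
    d <- data.frame(from = e$acc_a, to = e$acc_b, sources = e$sources,
                    score = e$score, provisional = e$provisional,
                    stringsAsFactors = FALSE)
  } else {
    d <- data.frame(from = character(), to = character(), sources = character(),
                    score = numeric(), provisional = logical())
  }
  igraph::graph_from_data_frame(d, directed = FALSE, vertices = vertices)
}

#' Bait-centred focused network
#'
#' Extracts from the raw network the subgraph of all proteins within a given
#' unweighted shortest-path (breadth-first) distance of the bait, together
#' with every raw edge between included nodes (edges among same-depth nodes
#' are retained). Before experimental evidence is overlaid (see
#' [specialize()]), all non-bait nodes have status `database_only`.
#'
#' @param raw a `ppi_network` from [build_raw_network()].
#' @param bait accession of the protein of interest; must be a network node.
#' @param depth maximum path distance from the bait (`0` keeps the bait alone).
#' @return An `annotated_network` with per-node `status` and `depth`.
#' @export
focused_network <- function(raw, bait, depth = 2L) {
  stopifnot(inherits(raw, "ppi_network"))
  if (!is_count(depth, min = 0L)) config_error("'depth' must be a nonnegative integer")
  if (!bait %in% raw$nodes$accession) {
    config_error(sprintf("bait accession '%s' is not in the raw network", bait))
  }
  g <- as_igraph(raw)
  dist <- as.vector(igraph::distances(g, v = bait))
  names(dist) <- igraph::V(g)$name
  keep_acc <- names(dist)[is.finite(dist) & dist <= depth]

  nodes <- raw$nodes[raw$nodes$accession %in% keep_acc, , drop = FALSE]
  nodes$status <- ifelse(nodes$accession == bait, "bait", "database_only")
  nodes$depth <- as.integer(dist[nodes$accession])
  rownames(nodes) <- NULL

  edges <- raw$edges[raw$edges$acc_a %in% keep_acc &
                       raw$edges$acc_b %in% keep_acc, , drop = FALSE]
  edges$provisional <- rep(FALSE, nrow(edges))
  rownames(edges) <- NULL
  new_annotated_network(nodes, edges, bait)
}

#' Overlay experimental evidence: the specialized network
#'
#' Classifies every node of a focused network against the set of accessions
#' observed in the experiment: nodes found in both the database network and
#' the experiment become `confirmed`; database nodes absent from the
#' experiment stay `database_only`; experimental proteins absent from the
#' database network are added as `experiment_only` nodes attached to the bait
#' by a provisional evidence edge (flagged, score-free, so they render inside
#' the bait-centric view without claiming database support). The attached
#' report counts the experimental accessions found/not found in the database
#' network.
#'
#' @param focused an `annotated_network` from [focused_network()].
#' @param experimental_accessions character vector of accessions observed in
#'   the experiment (e.g. the significant candidate set).
#' @return An `annotated_network` with statuses assigned and a `report` list
#'   (`total`, `from_experiment`, `found_in_database`, `not_found`).
#' @export
specialize <- function(focused, experimental_accessions) {
  stopifnot(inherits(focused, "annotated_network"))
  exp_acc <- unique(as.character(experimental_accessions))
  nodes <- focused$nodes
  in_exp <- nodes$accession %in% exp_acc
  nodes$status <- ifelse(nodes$status == "bait", "bait",
                         ifelse(in_exp, "confirmed", "database_only"))
  new_acc <- setdiff(exp_acc, nodes$accession)
  edges <- focused$edges
  if (length(new_acc)) {
    add <- data.frame(accession = new_acc, gene_name = NA_character_,
                      taxonomy = nodes$taxonomy[nodes$status == "bait"][1],
                      status = "experiment_only", depth = 1L,
                      stringsAsFactors = FALSE)
    nodes <- rbind(nodes[, names(add)], add)
    prov <- data.frame(acc_a = pmin(focused$bait, new_acc),
                       acc_b = pmax(focused$bait, new_acc),
                       gene_a = NA_character_, gene_b = NA_character_,
                       taxonomy = add$taxonomy[1], sources = "experiment",
                       score = NA_real_, provisional = TRUE,
                       stringsAsFactors = FALSE)
    edges <- rbind(edges, prov)
  }
  rownames(nodes) <- rownames(edges) <- NULL
  report <- list(total = nrow(nodes),
                 from_experiment = length(exp_acc),
                 found_in_database = length(exp_acc) - length(new_acc),
                 not_found = length(new_acc))
  new_annotated_network(nodes, edges, focused$bait, report)
}

node_degrees <- function(nodes, edges) {
  deg <- setNames(integer(nrow(nodes)), nodes$accession)
  if (nrow(edges)) {
    t_a <- table(edges$acc_a)
    t_b <- table(edges$acc_b)
    deg[names(t_a)] <- deg[names(t_a)] + as.integer(t_a)
    deg[names(t_b)] <- deg[names(t_b)] + as.integer(t_b)
  }
  deg
}

#' Prune database-only leaves: the truncated network
#'
#' Iteratively removes every degree-1 node with status `database_only`,
#' starting at the outer leaves and repeating until no such node remains.
#' Confirmed, experiment-only and bait nodes are never removed, so the
#' truncated view keeps exactly the experimentally supported periphery plus
#' the database paths that connect it: it is informative precisely when
#' unconfirmed proteins are present. The operation is idempotent and the
#' result does not depend on removal order.
#'
#' @param specialized an `annotated_network` with statuses assigned (see
#'   [specialize()]).
#' @return The truncated `annotated_network`.
#' @export
truncate_network <- function(specialized) {
  stopifnot(inherits(specialized, "annotated_network"))
  nodes <- specialized$nodes
  edges <- specialized$edges
  repeat {
    deg <- node_degrees(nodes, edges)
    prune <- nodes$accession[nodes$status == "database_only" &
                               deg[nodes$accession] <= 1L]
    if (!length(prune)) break
    nodes <- nodes[!nodes$accession %in% prune, , drop = FALSE]
    edges <- edges[!(edges$acc_a %in% prune | edges$acc_b %in% prune), , drop = FALSE]
  }
  rownames(nodes) <- rownames(edges) <- NULL
  new_annotated_network(nodes, edges, specialized$bait, specialized$report)
}

#' Filter database edges by combined confidence score
#'
#' Removes every database edge whose combined score is below `min_score` or
#' absent, then drops all nodes left without a path to the bait. Provisional
#' experimental-evidence edges are exempt from the threshold (they carry no
#' database score by construction).
#'
#' @param net an `annotated_network`.
#' @param min_score threshold in [0, 1].
#' @return The filtered `annotated_network`.
#' @export
score_filter <- function(net, min_score) {
  stopifnot(inherits(net, "annotated_network"))
  if (!is.numeric(min_score) || length(min_score) != 1L ||
      is.na(min_score) || min_score < 0 || min_score > 1) {
    config_error("'min_score' must be a number in [0, 1]")
  }
  edges <- net$edges
  keep <- edges$provisional | (!is.na(edges$score) & edges$score >= min_score)
  edges <- edges[keep, , drop = FALSE]

  # connectivity to the bait over the surviving edges
  reach <- net$bait
  frontier <- net$bait
  while (length(frontier)) {
    nb <- c(edges$acc_b[edges$acc_a %in% frontier],
            edges$acc_a[edges$acc_b %in% frontier])
    frontier <- setdiff(unique(nb), reach)
    reach <- c(reach, frontier)
  }
  nodes <- net$nodes[net$nodes$accession %in% reach, , drop = FALSE]
  edges <- edges[edges$acc_a %in% reach & edges$acc_b %in% reach, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  new_annotated_network(nodes, edges, net$bait, net$report)
}

#' Static 2-D layout coordinates for a network
#'
#' Computes deterministic node positions for export or static plotting.
#' `"radial"` places the bait at the origin and every depth-`d` node on a
#' circle of radius `d` at equally spaced angles (ordered by accession);
#' `"hierarchic"` arranges depth layers top-down with nodes spread
#' horizontally; `"force"` runs Fruchterman-Reingold spring relaxation with a
#' fixed seed, so coordinates are reproducible bit-for-bit across runs.
#'
#' @param net an `annotated_network`.
#' @param style `"radial"`, `"hierarchic"` or `"force"`.
#' @param seed integer seed for the force layout.
#' @return Data frame with columns `accession`, `x`, `y`.
#' @export
layout_positions <- function(net, style = c("radial", "hierarchic", "force"),
                             seed = 1L) {
  stopifnot(inherits(net, "annotated_network"))
  style <- match.arg(style)
  nodes <- net$nodes
  if (!nrow(nodes)) config_error("network has no nodes")
  if (nrow(nodes) == 1L) {
    return(data.frame(accession = nodes$accession, x = 0, y = 0,
                      stringsAsFactors = FALSE))
  }
  if (style == "force") {
    g <- as_igraph(net)
    coords <- local({
      set.seed(seed)
      igraph::layout_with_fr(g)
    })
    return(data.frame(accession = igraph::V(g)$name,
                      x = coords[, 1], y = coords[, 2],
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(accession = nodes$accession, x = NA_real_, y = NA_real_,
                    stringsAsFactors = FALSE)
  for (d in sort(unique(nodes$depth))) {
    ring <- sort(nodes$accession[nodes$depth == d])
    idx <- match(ring, out$accession)
    if (style == "radial") {
      if (d == 0) {
        out$x[idx] <- 0
        out$y[idx] <- 0
      } else {
        theta <- 2 * pi * (seq_along(ring) - 1) / length(ring)
        out$x[idx] <- d * cos(theta)
        out$y[idx] <- d * sin(theta)
      }
    } else {
      out$x[idx] <- seq_along(ring) - (length(ring) + 1) / 2
      out$y[idx] <- -d
    }
  }
  out
}
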