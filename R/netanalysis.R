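# Bipartite network construction and degree topology. Networks here are
# two-sided by construction (compound-target, target-disease,
# target-pathway); degree is the only topological statistic computed, as in
# NetworkAnalyzer-style reporting. Node identity is (kind, id): the same
# accession in two networks is only the same logical node after an explicit
# join.

#' Build a bipartite network from an edge list
#'
#' Duplicate edges are collapsed to set semantics with a warning that counts
#' them; declared-but-isolated nodes are retained. The two endpoint kinds
#' must differ — a same-kind edge cannot exist in a bipartite layer.
#'
#' @param edges Data frame whose first two columns are left and right node
#'   identifiers (e.g. compound id, UniProt accession). May be empty.
#' @param left_kind,right_kind Node kinds, e.g. `"compound"` and `"target"`;
#'   must differ.
#' @param left_nodes,right_nodes Optional character vectors declaring the
#'   node sets; defaults to the ids seen in `edges`. Ids in `edges` missing
#'   from a declared set are an error.
#' @return An object of class `bipartite_network`: list with `left_kind`,
#'   `right_kind`, `left_nodes`, `right_nodes`, `edges` (two-column data
#'   frame `left`/`right`), `n_duplicates`.
#' @examples
#' net <- build_network(ct_edges_fixture(), "compound", "target")
#' nrow(net$edges)
#' @export
build_network <- function(edges, left_kind, right_kind,
                          left_nodes = NULL, right_nodes = NULL) {
  stopifnot(is.character(left_kind), is.character(right_kind))
  if (identical(left_kind, right_kind)) {
    stop("edge endpoints must have different kinds in a bipartite network (got '",
         left_kind, "' on both sides)", call. = FALSE)
  }
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0)) {
    e <- data.frame(left = character(0), right = character(0),
                    stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(edges), ncol(edges) >= 2)
    e <- data.frame(left = as.character(edges[[1]]),
                    right = as.character(edges[[2]]),
                    stringsAsFactors = FALSE)
  }
  if (anyNA(e$left) || anyNA(e$right) ||
      any(!nzchar(e$left)) || any(!nzchar(e$right))) {
    stop("edge list contains empty node identifiers", call. = FALSE)
  }
  key <- paste(e$left, e$right, sep = "\r")
  n_dup <- sum(duplicated(key))
  if (n_dup > 0) {
    warning(n_dup, " duplicate edge(s) collapsed", call. = FALSE)
    e <- e[!duplicated(key), , drop = FALSE]
    rownames(e) <- NULL
  }
  ln <- if (is.null(left_nodes)) unique(e$left) else as.character(left_nodes)
  rn <- if (is.null(right_nodes)) unique(e$right) else as.character(right_nodes)
  stray_l <- setdiff(e$left, ln)
  stray_r <- setdiff(e$right, rn)
  if (length(stray_l) || length(stray_r)) {
    stop("edge references undeclared node(s): ",
         paste(utils::head(c(stray_l, stray_r), 5), collapse = ", "),
         call. = FALSE)
  }
  structure(list(left_kind = left_kind, right_kind = right_kind,
                 left_nodes = ln, right_nodes = rn,
                 edges = e, n_duplicates = n_dup),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite %s-%s network: %d + %d nodes, %d edges\n",
              x$left_kind, x$right_kind,
              length(x$left_nodes), length(x$right_nodes), nrow(x$edges)))
  invisible(x)
}

#' Node degrees of one side of a bipartite network
#'
#' @param net A [build_network()] object.
#' @param side `"left"` or `"right"`.
#' @return Named integer vector over all nodes of that side (isolated nodes
#'   have degree 0), in node-set order.
#' @export
bipartite_degree <- function(net, side = c("left", "right")) {
  stopifnot(inherits(net, "bipartite_network"))
  side <- match.arg(side)
  nodes <- if (side == "left") net$left_nodes else net$right_nodes
  ends <- if (side == "left") net$edges$left else net$edges$right
  deg <- table(factor(ends, levels = nodes))
  stats::setNames(as.integer(deg), nodes)
}

#' Degree report with hub detection
#'
#' Computes per-node degrees on both sides, the maximum and its node, the
#' mean degree (kept unrounded; a 2-dp presentation value is also reported),
#' and the hub list at `hub_threshold`. The hub rule is parameterized:
#' `strict = TRUE` takes degree strictly greater than the threshold,
#' `strict = FALSE` takes degree at least the threshold. The report always
#' names the rule it used, because "degree > 10" and "degree >= 10" select
#' different hub sets on real tables.
#'
#' The handshake identity (left degree sum = right degree sum = edge count)
#' is asserted on every call.
#'
#' @param net A [build_network()] object.
#' @param hub_threshold Hub degree threshold (default 10).
#' @param strict Logical; `TRUE` for `> threshold`, `FALSE` for
#'   `>= threshold`.
#' @return An object of class `degree_report`: per-side list with `degree`
#'   (named vector), `max_degree`, `max_node`, `mean_degree`,
#'   `mean_degree_2dp`, `hubs` (named vector, decreasing degree, ties by
#'   id); plus `n_edges`, `hub_threshold`, `hub_rule`.
#' @examples
#' rep <- degree_report(ct_network_fixture(), hub_threshold = 10, strict = TRUE)
#' rep$right$max_node # ESR1's accession
#' @export
degree_report <- function(net, hub_threshold = 10, strict = TRUE) {
  stopifnot(inherits(net, "bipartite_network"),
            is.numeric(hub_threshold), length(hub_threshold) == 1)
  side_report <- function(side) {
    deg <- bipartite_degree(net, side)
    sel <- if (strict) deg > hub_threshold else deg >= hub_threshold
    hubs <- deg[sel]
    hubs <- hubs[order(-hubs, names(hubs))]
    if (length(deg) == 0) {
      return(list(degree = deg, max_degree = NA_integer_,
                  max_node = NA_character_, mean_degree = NA_real_,
                  mean_degree_2dp = NA_real_, hubs = hubs))
    }
    list(degree = deg,
         max_degree = max(deg),
         max_node = names(deg)[which.max(deg)],
         mean_degree = mean(deg),
         mean_degree_2dp = round(mean(deg), 2),
         hubs = hubs)
  }
  left <- side_report("left")
  right <- side_report("right")
  n_edges <- nrow(net$edges)
  stopifnot(sum(left$degree) == n_edges, sum(right$degree) == n_edges)
  structure(list(left = left, right = right, n_edges = n_edges,
                 hub_threshold = hub_threshold,
                 hub_rule = if (strict) paste0("degree > ", hub_threshold)
                            else paste0("degree >= ", hub_threshold)),
            class = "degree_report")
}

#' @export
print.degree_report <- function(x, ...) {
  cat(sprintf("degree report (%d edges; hub rule: %s)\n",
              x$n_edges, x$hub_rule))
  for (s in c("left", "right")) {
    r <- x[[s]]
    cat(sprintf("  %s: max %s = %s, mean %.2f, %d hub(s)\n", s,
                r$max_node, format(r$max_degree), r$mean_degree,
                length(r$hubs)))
  }
  invisible(x)
}

#' Merge a compound-target network with a target-to-module annotation
#'
#' Builds the three-layer compound / target / function-module network: the
#' union of the C-T edges and target-module membership edges. Targets may
#' belong to several modules (one edge per membership). Annotation rows that
#' reference targets absent from the C-T network are skipped with a warning
#' and counted. With an empty (or fully skipped) annotation the C-T network
#' is returned unchanged.
#'
#' @param ct_net A compound-target [build_network()] object.
#' @param target_to_module Annotation data frame with columns `subject_id`
#'   (target) and `term_id` (module).
#' @return An object of class `module_network`: list with `nodes` (data
#'   frame `id`, `type`), `edges` (data frame `from`, `to`, `kind` in
#'   `{ct, tm}`), `n_skipped`, and per-type counts in `counts`.
#' @export
merge_module_network <- function(ct_net, target_to_module) {
  stopifnot(inherits(ct_net, "bipartite_network"),
            is.data.frame(target_to_module))
  ann <- target_to_module
  if (nrow(ann)) {
    need <- c("subject_id", "term_id")
    miss <- setdiff(need, names(ann))
    if (length(miss)) {
      stop("annotation lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    ann <- unique(data.frame(subject_id = as.character(ann$subject_id),
                             term_id = as.character(ann$term_id),
                             stringsAsFactors = FALSE))
    known <- ann$subject_id %in% ct_net$right_nodes
    n_skipped <- sum(!known)
    if (n_skipped > 0) {
      warning(n_skipped, " annotation edge(s) to unknown targets skipped",
              call. = FALSE)
    }
    ann <- ann[known, , drop = FALSE]
  } else {
    n_skipped <- 0L
  }
  if (nrow(ann) == 0) return(ct_net)

  nodes <- rbind(
    data.frame(id = ct_net$left_nodes, type = ct_net$left_kind,
               stringsAsFactors = FALSE),
    data.frame(id = ct_net$right_nodes, type = ct_net$right_kind,
               stringsAsFactors = FALSE),
    data.frame(id = unique(ann$term_id), type = "function_module",
               stringsAsFactors = FALSE)
  )
  edges <- rbind(
    data.frame(from = ct_net$edges$left, to = ct_net$edges$right,
               kind = "ct", stringsAsFactors = FALSE),
    data.frame(from = ann$subject_id, to = ann$term_id,
               kind = "tm", stringsAsFactors = FALSE)
  )
  counts <- c(table(nodes$type), n_edges = nrow(edges),
              n_ct = sum(edges$kind == "ct"), n_tm = sum(edges$kind == "tm"))
  structure(list(nodes = nodes, edges = edges,
                 n_skipped = n_skipped, counts = counts),
            class = "module_network")
}

#' @export
print.module_network <- function(x, ...) {
  cat(sprintf("compound-target-function-module network: %d nodes, %d edges (%d ct + %d tm)\n",
              nrow(x$nodes), nrow(x$edges),
              x$counts[["n_ct"]], x$counts[["n_tm"]]))
  invisible(x)
}

# interaction labels for SIF emission, by right-side kind
.sif_labels <- c(target = "ct", disease = "td", pathway = "tp",
                 function_module = "tm")

#' Convert a network to an igraph object
#'
#' Vertices carry a `type` attribute with the node kind. Useful for layout
#' or for statistics beyond degree.
#'
#' @param net A `bipartite_network` or `module_network`.
#' @return An undirected [igraph::graph] with vertex attributes `name` and
#'   `type`.
#' @export
as_igraph <- function(net) {
  if (inherits(net, "bipartite_network")) {
    nodes <- rbind(
      data.frame(name = net$left_nodes,
                 type = rep(net$left_kind, length(net$left_nodes)),
                 stringsAsFactors = FALSE),
      data.frame(name = net$right_nodes,
                 type = rep(net$right_kind, length(net$right_nodes)),
                 stringsAsFactors = FALSE))
    edges <- data.frame(from = net$edges$left, to = net$edges$right,
                        stringsAsFactors = FALSE)
  } else if (inherits(net, "module_network")) {
    nodes <- data.frame(name = net$nodes$id, type = net$nodes$type,
                        stringsAsFactors = FALSE)
    edges <- net$edges[, c("from", "to")]
  } else {
    stop("unsupported network object of class ",
         paste(class(net), collapse = "/"), call. = FALSE)
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Export a network to an interchange format
#'
#' `"tsv"` writes a `left`/`right` edge table, `"sif"` a Cytoscape SIF file
#' with per-layer interaction labels (`ct`, `td`, `tp`, `tm`), and
#' `"graphml"` a GraphML document with node `type` attributes.
#'
#' @param net A `bipartite_network` or `module_network`.
#' @param path Output file path.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    stop("unknown format '", format[1],
         "'; supported formats: tsv, sif, graphml", call. = FALSE)
  })
  if (format == "graphml") {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  if (inherits(net, "bipartite_network")) {
    edges <- net$edges
    label <- .sif_labels[net$right_kind]
    if (is.na(label)) label <- "pp"
    write_edge_list(edges, path, dialect = format, interaction = unname(label))
  } else if (inherits(net, "module_network")) {
    if (format == "tsv") {
      write_edge_list(net$edges[, c("from", "to")], path, dialect = "tsv")
    } else {
      # per-kind interaction labels in one SIF file
      con <- file(path, open = "wb")
      on.exit(close(con))
      lines <- paste(net$edges$from, net$edges$kind, net$edges$to, sep = "\t")
      writeLines(lines, con, useBytes = TRUE)
    }
  } else {
    stop("unsupported network object", call. = FALSE)
  }
  invisible(path)
}

#' Feasibility of a bipartite degree sequence (Gale-Ryser)
#'
#' Tests whether two degree sequences can be realized as a simple bipartite
#' graph: the sums must agree and, with the left sequence sorted decreasingly
#' \eqn{a_1 \ge \dots \ge a_m}, every prefix must satisfy
#' \eqn{\sum_{i \le k} a_i \le \sum_j \min(b_j, k)}.
#'
#' @param left_degrees,right_degrees Non-negative integer vectors.
#' @return `TRUE` or `FALSE`.
#' @export
gale_ryser_feasible <- function(left_degrees, right_degrees) {
  a <- as.integer(left_degrees); b <- as.integer(right_degrees)
  stopifnot(all(a >= 0), all(b >= 0))
  if (sum(a) != sum(b)) return(FALSE)
  if (length(a) && max(a) > length(b)) return(FALSE)
  if (length(b) && max(b) > length(a)) return(FALSE)
  a <- sort(a, decreasing = TRUE)
  for (k in seq_along(a)) {
    if (sum(a[1:k]) > sum(pmin(b, k))) return(FALSE)
  }
  TRUE
}

#' Realize a bipartite graph from two degree sequences
#'
#' Deterministic greedy construction: left nodes are processed in decreasing
#' degree (ties broken by position), and each is connected to the right
#' nodes with the largest remaining residual degree (ties again by
#' position). For any feasible pair of sequences this greedy always
#' succeeds; the realized degrees are verified to equal the requested ones
#' exactly. Used to reconstruct a compound-target edge list from published
#' per-compound and per-target degree columns when the underlying likelihood
#' scores are not published.
#'
#' @param left_degrees,right_degrees Named non-negative integer vectors
#'   (names become node identifiers).
#' @return A data frame with columns `left`, `right`, one row per edge.
#' @examples
#' e <- realize_bipartite(c(a = 2, b = 1), c(x = 1, y = 1, z = 1))
#' nrow(e) # 3
#' @export
realize_bipartite <- function(left_degrees, right_degrees) {
  if (is.null(names(left_degrees)) || is.null(names(right_degrees))) {
    stop("degree sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(names(left_degrees)) || anyDuplicated(names(right_degrees))) {
    stop("node names must be unique within each side", call. = FALSE)
  }
  if (!gale_ryser_feasible(left_degrees, right_degrees)) {
    stop("degree sequences are not realizable as a simple bipartite graph ",
         "(Gale-Ryser condition fails)", call. = FALSE)
  }
  a <- as.integer(left_degrees)
  resid <- as.integer(right_degrees)
  rn <- names(right_degrees)
  order_left <- order(-a, seq_along(a))
  out_l <- character(0); out_r <- character(0)
  for (i in order_left) {
    d <- a[i]
    if (d == 0) next
    pick <- order(-resid, seq_along(resid))[seq_len(d)]
    if (resid[pick[d]] <= 0) {
      stop("internal error: greedy realization exhausted residual degrees",
           call. = FALSE)
    }
    out_l <- c(out_l, rep(names(left_degrees)[i], d))
    out_r <- c(out_r, rn[pick])
    resid[pick] <- resid[pick] - 1L
  }
  stopifnot(all(resid == 0))
  edges <- data.frame(left = out_l, right = out_r, stringsAsFactors = FALSE)
  # verify the realization reproduces both sequences exactly
  got_l <- table(factor(edges$left, levels = names(left_degrees)))
  got_r <- table(factor(edges$right, levels = names(right_degrees)))
  stopifnot(all(as.integer(got_l) == as.integer(left_degrees)),
            all(as.integer(got_r) == as.integer(right_degrees)))
  rownames(edges) <- NULL
  edges
}

#' Reconstructed compound-target edge list of the worked formula
#'
#' The study's compound-target likelihood scores are not published; what is
#' published is the per-compound and per-target degree columns of its two
#' tables (both summing to 367). `ct_edges_fixture()` returns the packaged
#' deterministic Gale-Ryser realization of those two degree sequences
#' (see [realize_bipartite()]); `ct_network_fixture()` wraps it as a
#' compound-target [build_network()] object with all 41 compounds and 94
#' targets declared. Degree-based topology statistics on this
#' reconstruction (degree sums, maxima, hub counts) match the published
#' network exactly; the individual edges are one consistent realization,
#' not the unpublished originals.
#'
#' @return For `ct_edges_fixture()`, a data frame with columns
#'   `compound_id`, `target_uniprot` (367 rows); for
#'   `ct_network_fixture()`, a `bipartite_network`.
#' @export
ct_edges_fixture <- function() {
  df <- read_edge_list(herbnet_extdata("ct_edges.tsv"))
  data.frame(compound_id = df$left, target_uniprot = df$right,
             stringsAsFactors = FALSE)
}

#' @rdname ct_edges_fixture
#' @export
ct_network_fixture <- function() {
  t1 <- table1_fixture()
  t2 <- table2_fixture()
  build_network(ct_edges_fixture(), "compound", "target",
                left_nodes = t1$ingredient_id, right_nodes = t2$uniprot_ac)
}
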