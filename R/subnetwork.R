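# Seed-anchored module extraction from a thresholded network.

# adjacency as a named list of character vectors (sorted, unique)
adjacency_from_edges <- function(el) {
  nodes <- sort(unique(c(el$from, el$to)))
  adj <- c(split(el$to, factor(el$from, levels = nodes)),
           split(el$from, factor(el$to, levels = nodes)))
  adj <- tapply(unlist(adj, use.names = FALSE),
                rep(names(adj), lengths(adj)), function(v) sort(unique(v)),
                simplify = FALSE)
  out <- stats::setNames(vector("list", length(nodes)), nodes)
  out[names(adj)] <- adj
  out[vapply(out, is.null, logical(1L))] <- list(character(0))
  out
}

check_seeds <- function(seeds, nodes) {
  missing <- setdiff(seeds, nodes)
  present <- intersect(seeds, nodes)
  if (length(present) == 0L) {
    stop("no seed gene found in the network; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(missing) > 0L) {
    warning("seed gene(s) absent from network: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  sort(present)
}

induced_edges <- function(el, nodes) {
  el[el$from %in% nodes & el$to %in% nodes, , drop = FALSE]
}

subnetwork_obj <- function(nodes, el, seeds, algorithm) {
  structure(list(nodes = sort(nodes),
                 edges = edge_list(induced_edges(el, nodes),
                                   cutoff = attr(el, "cutoff"),
                                   method = attr(el, "method")),
                 seeds = seeds, algorithm = algorithm),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("Subnetwork (", x$algorithm, "): ", length(x$nodes), " node(s), ",
      nrow(x$edges), " edge(s); seeds: ", paste(x$seeds, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Seed-neighborhood expansion (SNBuilder-style)
#'
#' Baits a module around seed genes. Round 1 admits the seeds' direct
#' neighbors (the first-degree neighborhood the seeds fish out of the
#' global network). Each later round admits every non-member that either
#' has at least `inclusion_fraction` of its network neighbors inside the
#' current member set or is adjacent to two or more seeds. Rounds use the
#' member set as of the round start, so the result does not depend on
#' candidate order; expansion stops at `expand_rounds` rounds or at a fixed
#' point. The returned module is the induced subnetwork on the members.
#'
#' @param net an `edge_list` (see [threshold_network()]).
#' @param seeds character vector of seed gene IDs; seeds absent from the
#'   network are dropped with a warning, and it is an error if none remain.
#' @param expand_rounds maximum number of expansion rounds (`>= 1`).
#' @param inclusion_fraction required fraction of a candidate's neighbors
#'   already inside the module, in `(0, 1]`.
#' @return a `subnetwork`: list with `nodes`, `edges` (induced
#'   `edge_list`), `seeds`, `algorithm`.
#' @export
snbuilder_extract <- function(net, seeds, expand_rounds = 2L,
                              inclusion_fraction = 0.5) {
  if (expand_rounds < 1L) stop("'expand_rounds' must be >= 1", call. = FALSE)
  if (!is.numeric(inclusion_fraction) || inclusion_fraction <= 0 ||
      inclusion_fraction > 1) {
    stop("'inclusion_fraction' must be in (0, 1]", call. = FALSE)
  }
  adj <- adjacency_from_edges(net)
  seeds <- check_seeds(seeds, names(adj))
  members <- seeds
  for (round in seq_len(expand_rounds)) {
    candidates <- setdiff(sort(unique(unlist(adj[members], use.names = FALSE))),
                          members)
    if (length(candidates) == 0L) break
    added <- if (round == 1L) {
      candidates  # first-degree neighborhood of the seeds
    } else {
      keep <- vapply(candidates, function(v) {
        nb <- adj[[v]]
        frac <- sum(nb %in% members) / length(nb)
        frac >= inclusion_fraction || sum(nb %in% seeds) >= 2L
      }, logical(1L))
      candidates[keep]
    }
    if (length(added) == 0L) break
    members <- sort(c(members, added))
  }
  subnetwork_obj(members, net, seeds, "snbuilder")
}

#' Cohesive greedy module growth (GeNa-style)
#'
#' Grows a module from the seeds by repeatedly adding the neighboring gene
#' that maximizes the cohesion of the resulting set, defined as
#' `W_in / (W_in + W_out)` where `W_in` is the total edge score inside the
#' set and `W_out` the total score crossing its boundary. Growth stops when
#' no addition strictly improves cohesion or when `max_size` is reached;
#' ties are broken by lexicographic gene ID. Tends to return small,
#' cohesive modules.
#'
#' @inheritParams snbuilder_extract
#' @param max_size maximum module size.
#' @return a `subnetwork`.
#' @export
gena_extract <- function(net, seeds, max_size = 100L) {
  if (max_size < 1L) stop("'max_size' must be >= 1", call. = FALSE)
  adj <- adjacency_from_edges(net)
  seeds <- check_seeds(seeds, names(adj))
  cohesion <- function(members) {
    inside <- net$from %in% members & net$to %in% members
    boundary <- xor(net$from %in% members, net$to %in% members)
    w_in <- sum(net$score[inside])
    w_out <- sum(net$score[boundary])
    if (w_in + w_out == 0) 0 else w_in / (w_in + w_out)
  }
  members <- seeds
  current <- cohesion(members)
  while (length(members) < max_size) {
    candidates <- setdiff(sort(unique(unlist(adj[members], use.names = FALSE))),
                          members)
    if (length(candidates) == 0L) break
    gains <- vapply(candidates, function(v) cohesion(c(members, v)),
                    numeric(1L))
    best <- which.max(gains)  # first max = lexicographically smallest
    if (gains[best] <= current) break
    members <- sort(c(members, candidates[best]))
    current <- gains[best]
  }
  subnetwork_obj(members, net, seeds, "gena")
}

#' Write a subnetwork to Cytoscape-compatible files
#'
#' Writes the induced edges with [write_edge_list()] and a node-list
#' sidecar (`<path>.nodes.tsv`) with a column marking seeds.
#'
#' @param sub a `subnetwork`.
#' @param path edge-file path; the node sidecar gets `.nodes.tsv` appended.
#' @param ... passed to [write_edge_list()].
#' @return `path`, invisibly.
#' @export
write_subnetwork <- function(sub, path, ...) {
  write_edge_list(sub$edges, path, ...)
  nodes <- data.frame(gene = sub$nodes,
                      is_seed = as.integer(sub$nodes %in% sub$seeds))
  utils::write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
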