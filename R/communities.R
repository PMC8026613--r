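# Modularity-based community detection within sub-networks.
#
# Each connected component is partitioned by multi-level (Louvain)
# modularity optimisation, followed by a node-level refinement pass that
# accepts single-node moves while they improve Q by more than 1e-7.
# Components whose best-partition modularity reaches the threshold
# (default 0.7) are flagged for splitting into their communities.

#' Detect communities in every sub-network
#'
#' Runs multi-level modularity optimisation per connected component, with a
#' deterministic seed-controlled node-order shuffle and a local refinement
#' pass. The best partition is always recorded; `split_applied` marks the
#' components whose modularity reaches `modularity_threshold` and which are
#' therefore split into individual communities downstream (see
#' [community_assignment()]). Singleton components have Q defined as 0.
#'
#' @param net `canvas_network`.
#' @param modularity_threshold minimum best-partition modularity for a
#'   component to be split (default 0.7).
#' @param seed integer seed controlling the node-order shuffle (recorded in
#'   the output attributes).
#' @param components optional precomputed [network_components()] table.
#' @return Tibble `fragment_id`, `component_id`, `community_id` (within
#'   component), `modularity`, `split_applied`; attributes `seed` and
#'   `modularity_threshold`.
#' @export
detect_communities <- function(net, modularity_threshold = 0.7, seed = 1L,
                               components = NULL) {
  comps <- components %||% network_components(net)
  g <- as_igraph_network(net)
  out <- vector("list", max(comps$component_id, 0))
  for (cid in unique(comps$component_id)) {
    members <- comps$fragment_id[comps$component_id == cid]
    sub <- igraph::induced_subgraph(g, members)
    part <- louvain_partition(sub, seed = seed + cid)
    out[[cid]] <- tibble(
      fragment_id = igraph::V(sub)$name,
      component_id = cid,
      community_id = part$membership,
      modularity = part$modularity,
      split_applied = part$modularity >= modularity_threshold
    )
  }
  res <- bind_rows(out) |> arrange(.data$component_id, .data$community_id,
                                   .data$fragment_id)
  attr(res, "seed") <- seed
  attr(res, "modularity_threshold") <- modularity_threshold
  res
}

#' Best Louvain partition of one (connected) graph (internal)
#'
#' Shuffles vertex order with the given seed (tie-breaking is order
#' dependent), runs igraph's multi-level algorithm, then applies local
#' single-node moves until the modularity gain per pass drops below 1e-7.
#' @noRd
louvain_partition <- function(sub, seed) {
  nv <- igraph::vcount(sub)
  if (nv <= 1 || igraph::ecount(sub) == 0) {
    return(list(membership = rep(1L, nv), modularity = 0))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  perm <- sample.int(nv)
  shuf <- igraph::permute(sub, perm)
  cl <- igraph::cluster_louvain(shuf)
  memb <- as.integer(igraph::membership(cl))[perm]
  memb <- refine_partition(sub, memb)
  memb <- as.integer(factor(memb, levels = unique(memb[order(igraph::V(sub)$name)])))
  list(membership = memb, modularity = igraph::modularity(sub, memb))
}

#' Greedy single-node refinement of a partition (internal)
#' @noRd
refine_partition <- function(sub, memb, tol = 1e-7) {
  adj <- igraph::as_adj_list(sub)
  repeat {
    q0 <- igraph::modularity(sub, memb)
    improved <- FALSE
    for (v in seq_along(memb)) {
      neigh <- as.integer(adj[[v]])
      cand <- unique(memb[neigh])
      cand <- cand[cand != memb[v]]
      if (length(cand) == 0) next
      best_q <- q0
      best_c <- memb[v]
      for (cc in cand) {
        trial <- memb
        trial[v] <- cc
        q <- igraph::modularity(sub, trial)
        if (q > best_q + tol) {
          best_q <- q
          best_c <- cc
        }
      }
      if (best_c != memb[v]) {
        memb[v] <- best_c
        q0 <- best_q
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  memb
}

#' Collapse community detection to the operative cluster assignment
#'
#' Components that met the modularity threshold are split into their
#' communities; the others remain whole. Cluster ids are
#' `"<component>"` or `"<component>.<community>"` accordingly.
#'
#' @param communities output of [detect_communities()].
#' @return Tibble `fragment_id`, `component_id`, `cluster`.
#' @export
community_assignment <- function(communities) {
  communities |>
    mutate(cluster = if_else(
      .data$split_applied,
      sprintf("%d.%d", .data$component_id, .data$community_id),
      sprintf("%d", .data$component_id)
    )) |>
    select("fragment_id", "component_id", "cluster")
}

#' Rand index between two labelings
#'
#' Fraction of node pairs on which two partitions agree (both together or
#' both apart); 1 means identical partitions.
#'
#' @param labels1,labels2 vectors of cluster labels over the same items.
#' @return Numeric in `[0, 1]`.
#' @export
rand_index <- function(labels1, labels2) {
  stopifnot(length(labels1) == length(labels2))
  n <- length(labels1)
  if (n < 2) return(1)
  same1 <- outer(labels1, labels1, `==`)
  same2 <- outer(labels2, labels2, `==`)
  ut <- upper.tri(same1)
  mean(same1[ut] == same2[ut])
}
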