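# Merged two-condition promoter-interaction network.
#
# Nodes are restriction fragments; edges are significant promoter
# interactions. An edge enters the merged network when its CHiCAGO score
# reaches `sig_threshold` (default 5) in at least one condition; an edge
# significant in one condition counts as shared when the other condition
# lends sub-threshold support above `support_threshold` (default 3).

#' Build the merged two-condition interaction network
#'
#' Merges per-condition significant-interaction calls into a single graph
#' keyed by unordered fragment pair. Edge inclusion and specificity follow
#' the score rule: an edge is kept iff its score reaches `sig_threshold` in
#' at least one condition; it is condition-specific when the other
#' condition's score is absent or `<= support_threshold`, and shared when
#' the other score exceeds `support_threshold`.
#'
#' @param calls_a,calls_b interaction-call tibbles from [read_interactions()]
#'   (columns `bait_id`, `other_id`, `score`, `read_count`, `condition`).
#' @param frags fragment map tibble; all call anchors must resolve in it.
#' @param sig_threshold significance cutoff on the CHiCAGO score (default 5).
#' @param support_threshold sub-threshold support cutoff (default 3); must
#'   not exceed `sig_threshold`.
#' @return A `canvas_network`: list with `nodes`, `edges`, `conditions`,
#'   `thresholds`. Edge specificity is one of `A_specific`, `B_specific`,
#'   `shared`; node specificity is derived from incident edges.
#' @export
build_merged_network <- function(calls_a, calls_b, frags,
                                 sig_threshold = 5, support_threshold = 3) {
  stopifnot(sig_threshold >= support_threshold)
  cond_a <- unique(calls_a$condition)
  cond_b <- unique(calls_b$condition)
  if (length(cond_a) == 0) cond_a <- "A"
  if (length(cond_b) == 0) cond_b <- "B"
  if (length(cond_a) != 1 || length(cond_b) != 1) {
    abort("each call set must carry exactly one condition label")
  }
  check_resolved <- function(calls) {
    unknown <- setdiff(c(calls$bait_id, calls$other_id), frags$fragment_id)
    if (length(unknown) > 0) {
      abort(sprintf("call references unknown fragment(s): %s",
                    paste(utils::head(unknown, 3), collapse = ", ")))
    }
  }
  check_resolved(calls_a)
  check_resolved(calls_b)

  keyed <- function(calls) {
    calls |>
      mutate(node1 = pmin(.data$bait_id, .data$other_id),
             node2 = pmax(.data$bait_id, .data$other_id))
  }
  a <- keyed(calls_a) |>
    select("node1", "node2", "bait_id", "other_id",
           score_A = "score", reads_A = "read_count")
  b <- keyed(calls_b) |>
    select("node1", "node2", bait_id_b = "bait_id", other_id_b = "other_id",
           score_B = "score", reads_B = "read_count")
  edges <- dplyr::full_join(a, b, by = c("node1", "node2")) |>
    mutate(
      bait_id = dplyr::coalesce(.data$bait_id, .data$bait_id_b),
      other_id = dplyr::coalesce(.data$other_id, .data$other_id_b)
    ) |>
    select(-"bait_id_b", -"other_id_b") |>
    mutate(specificity = edge_specificity(.data$score_A, .data$score_B,
                                          sig_threshold, support_threshold)) |>
    filter(!is.na(.data$specificity))

  fr <- frags |> mutate(midpoint = (.data$start + .data$end) / 2)
  e2 <- edges |>
    left_join(fr |> select("fragment_id", c1 = "chrom", m1 = "midpoint"),
              by = c(node1 = "fragment_id")) |>
    left_join(fr |> select("fragment_id", c2 = "chrom", m2 = "midpoint"),
              by = c(node2 = "fragment_id")) |>
    mutate(
      trans = .data$c1 != .data$c2,
      distance = if_else(.data$trans, NA_real_, abs(.data$m1 - .data$m2))
    ) |>
    select(-"c1", -"c2", -"m1", -"m2") |>
    arrange(.data$node1, .data$node2)

  node_ids <- sort(unique(c(e2$node1, e2$node2)))
  spec_by_node <- bind_rows(
    e2 |> select(fragment_id = "node1", "specificity"),
    e2 |> select(fragment_id = "node2", "specificity")
  ) |>
    group_by(.data$fragment_id) |>
    summarise(
      degree = n(),
      specificity = if (all(.data$specificity == "A_specific")) "A_specific"
      else if (all(.data$specificity == "B_specific")) "B_specific"
      else "shared",
      .groups = "drop"
    )
  nodes <- fr |>
    filter(.data$fragment_id %in% node_ids) |>
    left_join(spec_by_node, by = "fragment_id") |>
    arrange(.data$fragment_id)

  structure(
    list(
      nodes = nodes,
      edges = e2,
      conditions = c(A = cond_a, B = cond_b),
      thresholds = list(sig_threshold = sig_threshold,
                        support_threshold = support_threshold)
    ),
    class = "canvas_network"
  )
}

#' Edge specificity from a pair of scores
#'
#' Vectorised specificity rule. Returns `NA` when the edge does not reach
#' `sig_threshold` in either condition (no edge).
#'
#' @param score_a,score_b per-condition scores (`NA` = not called).
#' @param sig_threshold,support_threshold thresholds (defaults 5 and 3).
#' @return Character vector in `{A_specific, B_specific, shared, NA}`.
#' @export
edge_specificity <- function(score_a, score_b, sig_threshold = 5,
                             support_threshold = 3) {
  sa <- !is.na(score_a) & score_a >= sig_threshold
  sb <- !is.na(score_b) & score_b >= sig_threshold
  supp_a <- !is.na(score_a) & score_a > support_threshold
  supp_b <- !is.na(score_b) & score_b > support_threshold
  dplyr::case_when(
    sa & supp_b ~ "shared",
    sb & supp_a ~ "shared",
    sa ~ "A_specific",
    sb ~ "B_specific",
    TRUE ~ NA_character_
  )
}

#' @exportS3Method base::print
print.canvas_network <- function(x, ...) {
  cat(sprintf("<canvas_network> %d nodes, %d edges (conditions %s/%s)\n",
              nrow(x$nodes), nrow(x$edges), x$conditions[["A"]],
              x$conditions[["B"]]))
  cat(sprintf("  edge specificity: %s\n",
              paste(sprintf("%s=%d", names(table(x$edges$specificity)),
                            as.integer(table(x$edges$specificity))),
                    collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.canvas_network <- function(x, ...) x$edges

#' @exportS3Method generics::glance
glance.canvas_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_shared = sum(x$edges$specificity == "shared"),
    n_A_specific = sum(x$edges$specificity == "A_specific"),
    n_B_specific = sum(x$edges$specificity == "B_specific"),
    n_trans = sum(x$edges$trans),
    sig_threshold = x$thresholds$sig_threshold,
    support_threshold = x$thresholds$support_threshold
  )
}

#' Is an edge supported in a condition?
#'
#' A condition supports an edge when the edge is shared or specific to it.
#'
#' @param specificity edge specificity vector.
#' @param condition `"A"` or `"B"` (merged-network side, not the user label).
#' @return Logical vector.
#' @export
edge_supported <- function(specificity, condition = c("A", "B")) {
  condition <- match.arg(condition)
  specificity == "shared" | specificity == paste0(condition, "_specific")
}

#' Resolve a user condition label to side "A"/"B" (internal)
#' @noRd
cn_side <- function(net, condition) {
  if (condition %in% c("A", "B")) return(condition)
  side <- names(net$conditions)[net$conditions == condition]
  if (length(side) != 1) abort(sprintf("unknown condition '%s'", condition))
  side
}

#' Convert a merged network to igraph
#'
#' @param net `canvas_network`.
#' @param condition optional condition (side `"A"`/`"B"` or user label);
#'   when given, only edges supported in that condition are kept (their
#'   incident nodes form the vertex set).
#' @return An igraph graph whose vertex names are fragment ids.
#' @export
as_igraph_network <- function(net, condition = NULL) {
  edges <- net$edges
  if (!is.null(condition)) {
    edges <- edges |>
      filter(edge_supported(.data$specificity, cn_side(net, condition)))
  }
  verts <- if (is.null(condition)) net$nodes$fragment_id
           else sort(unique(c(edges$node1, edges$node2)))
  igraph::graph_from_data_frame(
    edges |> select(from = "node1", to = "node2", "specificity"),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE)
  )
}

#' Connected components (sub-networks) of the merged network
#'
#' Sub-networks are the maximal connected components of the merged graph.
#' Components are numbered deterministically: by size (descending), ties by
#' smallest member fragment id.
#'
#' @param net `canvas_network`.
#' @return Tibble `fragment_id`, `component_id` covering every network node.
#' @export
network_components <- function(net) {
  if (nrow(net$nodes) == 0) {
    return(tibble(fragment_id = character(), component_id = integer()))
  }
  g <- as_igraph_network(net)
  comp <- igraph::components(g)
  memb <- tibble(fragment_id = igraph::V(g)$name,
                 raw = as.integer(comp$membership))
  ord <- memb |>
    group_by(.data$raw) |>
    summarise(size = n(), lead = min(.data$fragment_id), .groups = "drop") |>
    arrange(dplyr::desc(.data$size), .data$lead) |>
    mutate(component_id = row_number())
  memb |>
    left_join(ord |> select("raw", "component_id"), by = "raw") |>
    select("fragment_id", "component_id") |>
    arrange(.data$component_id, .data$fragment_id)
}

#' Per-component differential census
#'
#' For each sub-network, counts the edges supported in each condition and
#' the nodes incident to at least one such edge, and assigns the quadrant
#' label used to compare sub-network size between conditions.
#'
#' @param net `canvas_network`.
#' @param components optional precomputed [network_components()] table.
#' @return Tibble with `component_id`, `n_nodes`, `nodes_A`, `nodes_B`,
#'   `edges_A`, `edges_B`, `quadrant`
#'   (`larger_in_A` / `larger_in_B` / `unchanged` / `mixed`).
#' @export
subnetwork_census <- function(net, components = NULL) {
  comps <- components %||% network_components(net)
  edges <- net$edges |>
    left_join(comps, by = c(node1 = "fragment_id")) |>
    rename(component_id1 = "component_id") |>
    left_join(comps, by = c(node2 = "fragment_id")) |>
    mutate(component_id = .data$component_id1) |>
    select(-"component_id1")
  per_edge <- edges |>
    mutate(in_A = edge_supported(.data$specificity, "A"),
           in_B = edge_supported(.data$specificity, "B"))
  edge_counts <- per_edge |>
    group_by(.data$component_id) |>
    summarise(edges_A = sum(.data$in_A), edges_B = sum(.data$in_B),
              .groups = "drop")
  node_counts <- bind_rows(
    per_edge |> select(fragment_id = "node1", "component_id", "in_A", "in_B"),
    per_edge |> select(fragment_id = "node2", "component_id", "in_A", "in_B")
  ) |>
    group_by(.data$component_id, .data$fragment_id) |>
    summarise(in_A = any(.data$in_A), in_B = any(.data$in_B), .groups = "drop") |>
    group_by(.data$component_id) |>
    summarise(n_nodes = n(), nodes_A = sum(.data$in_A),
              nodes_B = sum(.data$in_B), .groups = "drop")
  node_counts |>
    left_join(edge_counts, by = "component_id") |>
    mutate(
      d_edges = .data$edges_B - .data$edges_A,
      d_nodes = .data$nodes_B - .data$nodes_A,
      quadrant = dplyr::case_when(
        d_edges == 0 & d_nodes == 0 ~ "unchanged",
        d_edges >= 0 & d_nodes >= 0 ~ "larger_in_B",
        d_edges <= 0 & d_nodes <= 0 ~ "larger_in_A",
        TRUE ~ "mixed"
      )
    ) |>
    select(-"d_edges", -"d_nodes") |>
    arrange(.data$component_id)
}

#' Linear genomic distance between fragment midpoints
#'
#' @param frags fragment map tibble.
#' @param id1,id2 fragment id vectors.
#' @return Numeric bp distances; `NA` for trans (different-chromosome) pairs.
#' @export
interaction_distance <- function(frags, id1, id2) {
  i <- match(id1, frags$fragment_id)
  j <- match(id2, frags$fragment_id)
  m <- function(k) (frags$start[k] + frags$end[k]) / 2
  ifelse(frags$chrom[i] == frags$chrom[j], abs(m(i) - m(j)), NA_real_)
}

#' Assign interaction distances to range bands
#'
#' Bands are half-open on the left: with breakpoints `(b_short, b_long)` a
#' distance d is `short` when `d <= b_short`, `mid` when
#' `b_short < d <= b_long`, and `long` when `d > b_long`. The long-range
#' definition is strict: exactly 1 Mb is mid-range, anything above is long.
#'
#' @param distance numeric bp distances (non-negative).
#' @param bands named breakpoints `c(short = ..., long = ...)`; default
#'   short/mid at 250 kb and mid/long at 1 Mb.
#' @return Factor with levels `short`, `mid`, `long`.
#' @export
classify_distance_band <- function(distance,
                                   bands = c(short = 250000, long = 1000000)) {
  if (any(distance < 0, na.rm = TRUE)) abort("negative distance")
  stopifnot(bands[["short"]] < bands[["long"]])
  lab <- dplyr::case_when(
    is.na(distance) ~ NA_character_,
    distance <= bands[["short"]] ~ "short",
    distance <= bands[["long"]] ~ "mid",
    TRUE ~ "long"
  )
  factor(lab, levels = c("short", "mid", "long"))
}

#' Select the longest condition-supported cis interactions
#'
#' @param net `canvas_network`.
#' @param condition condition (side or label).
#' @param n number of edges (default 1000). When fewer condition-supported
#'   cis edges exist, all are returned with a warning.
#' @return Edge tibble sorted by distance (descending); ties broken by
#'   `(node1, node2)` ascending for determinism.
#' @export
select_top_longest <- function(net, condition, n = 1000) {
  side <- cn_side(net, condition)
  cand <- net$edges |>
    filter(!.data$trans, edge_supported(.data$specificity, side)) |>
    arrange(dplyr::desc(.data$distance), .data$node1, .data$node2)
  if (nrow(cand) < n) {
    warn(sprintf("only %d condition-supported cis edges available (n = %d requested)",
                 nrow(cand), n))
    return(cand)
  }
  cand |> slice(seq_len(n))
}

#' Extract the sub-graph induced by a node predicate
#'
#' Keeps the edges supported in `condition` whose both endpoints satisfy the
#' predicate (typically a chromatin-state membership such as bivalent or
#' Polycomb-associated), together with the genes baited on the retained
#' nodes.
#'
#' @param net `canvas_network`.
#' @param condition condition (side or label).
#' @param assignments fragment-state tibble (`fragment_id`, `state`) for the
#'   condition, from [assign_fragment_states()].
#' @param states character vector of qualifying states, or `predicate`, a
#'   function of the state vector returning logical.
#' @param baits optional bait annotation (`fragment_id`, `gene`) used to
#'   report the genes in the extracted sub-graph.
#' @return List with `edges` (tibble), `nodes` (character) and `genes`
#'   (character, empty if `baits` is `NULL`).
#' @export
extract_state_network <- function(net, condition, assignments,
                                  states = c("bivalent", "polycomb"),
                                  predicate = NULL, baits = NULL) {
  if (is.null(assignments) || nrow(assignments) == 0) {
    abort("fragment states missing for the requested condition")
  }
  side <- cn_side(net, condition)
  pred <- predicate %||% (function(s) s %in% states)
  st <- setNames(assignments$state, assignments$fragment_id)
  edges <- net$edges |>
    filter(edge_supported(.data$specificity, side)) |>
    filter(pred(st[.data$node1]) %in% TRUE & pred(st[.data$node2]) %in% TRUE)
  nodes <- sort(unique(c(edges$node1, edges$node2)))
  genes <- if (is.null(baits)) character() else
    sort(unique(baits$gene[baits$fragment_id %in% nodes]))
  list(edges = edges, nodes = nodes, genes = genes)
}
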