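# Fragment-level chromatin state annotation.
#
# Segmentation states are reduced to one label per restriction fragment by
# the supersession rules: any single state supersedes background, bivalent
# supersedes Polycomb-repressed, and any other mixture of distinct states
# is labelled "mixed". Bases not covered by the segmentation count as
# background.

#' Reduce a state set to a single fragment label
#'
#' The supersession rule applied to the set of non-background states
#' overlapping a fragment: empty set -> `background`; a single state -> that
#' state; exactly `{bivalent, polycomb}` -> `bivalent`; any other mixture of
#' two or more states -> `mixed`.
#'
#' @param states character vector of state labels overlapping one fragment
#'   (may include `background`; duplicates ignored).
#' @return Single state label.
#' @export
reduce_state_set <- function(states) {
  s <- setdiff(unique(states), "background")
  if (length(s) == 0) return("background")
  if (length(s) == 1) return(s)
  if (setequal(s, c("bivalent", "polycomb"))) return("bivalent")
  "mixed"
}

#' Assign one chromatin state per fragment
#'
#' Computes the bp overlap of each segmentation state with each fragment and
#' reduces it to a single label with [reduce_state_set()]. Fragments without
#' any qualifying overlap are background.
#'
#' @param segmentation tibble from [read_segmentation()].
#' @param frags fragment map tibble.
#' @param min_state_bp minimum bp overlap for a state to count toward a
#'   fragment (default 1).
#' @return Tibble `fragment_id`, `state`, `condition`; the per-fragment
#'   state -> bp overlap provenance table is attached as attribute
#'   `"overlap_table"`.
#' @export
assign_fragment_states <- function(segmentation, frags, min_state_bp = 1L) {
  bad <- setdiff(unique(segmentation$state), chromatin_states())
  if (length(bad) > 0) {
    abort(sprintf("unknown chromatin state label(s): %s",
                  paste(bad, collapse = ", ")))
  }
  condition <- unique(segmentation$condition) %||% NA_character_
  hits <- ov_find(gr_from_tbl(segmentation),
                                      gr_from_tbl(frags))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov_bp <- pmin(segmentation$end[qi], frags$end[si]) -
    pmax(segmentation$start[qi], frags$start[si])
  overlaps <- tibble(
    fragment_id = frags$fragment_id[si],
    state = segmentation$state[qi],
    bp = ov_bp
  ) |>
    group_by(.data$fragment_id, .data$state) |>
    summarise(bp = sum(.data$bp), .groups = "drop") |>
    filter(.data$bp >= min_state_bp)
  reduced <- overlaps |>
    group_by(.data$fragment_id) |>
    summarise(state = reduce_state_set(.data$state), .groups = "drop")
  out <- frags |>
    select("fragment_id") |>
    left_join(reduced, by = "fragment_id") |>
    mutate(state = dplyr::coalesce(.data$state, "background"),
           condition = condition[1])
  attr(out, "overlap_table") <- overlaps
  out
}

#' Cross-condition state transition matrix
#'
#' Counts fragments by (state in A, state in B) and reports percentages
#' normalised within each destination (condition-B) state.
#'
#' @param assignments_a,assignments_b fragment-state tibbles on the same
#'   fragment map.
#' @param fragment_subset optional fragment ids to restrict to (e.g. the
#'   anchors of long-range interactions).
#' @return Tibble `state_A`, `state_B`, `n`, `pct_within_B`.
#' @export
state_transition_matrix <- function(assignments_a, assignments_b,
                                    fragment_subset = NULL) {
  a <- assignments_a |> select("fragment_id", state_A = "state")
  b <- assignments_b |> select("fragment_id", state_B = "state")
  ab <- inner_join(a, b, by = "fragment_id")
  if (!is.null(fragment_subset)) {
    ab <- ab |> filter(.data$fragment_id %in% fragment_subset)
  }
  ab |>
    count(.data$state_A, .data$state_B, name = "n") |>
    group_by(.data$state_B) |>
    mutate(pct_within_B = 100 * .data$n / sum(.data$n)) |>
    ungroup()
}

#' Chromatin states at the ends of the longest interactions
#'
#' For the n longest condition-supported cis interactions, reports the state
#' of the bait (promoter) fragment and of the promoter-interacting region.
#' The bait side is the end carrying a gene annotation; when both ends are
#' baited the edge is counted once per direction.
#'
#' @param net `canvas_network`.
#' @param condition condition (side or label).
#' @param assignments fragment-state tibble for that condition.
#' @param baits bait annotation (`fragment_id`, `gene`).
#' @param n number of longest edges (default 1000).
#' @return List with `profile` (per-edge tibble: `node1`, `node2`,
#'   `bait_fragment`, `distance`, `bait_state`, `other_state`), `summary`
#'   (counts per state pair) and `bivalent_bait_fraction` plus
#'   `bivalent_both_fraction` (fractions over profile rows).
#' @export
longest_interaction_state_profile <- function(net, condition, assignments,
                                              baits, n = 1000) {
  top <- select_top_longest(net, condition, n)
  st <- setNames(assignments$state, assignments$fragment_id)
  baited <- unique(baits$fragment_id)
  rows <- list()
  for (i in seq_len(nrow(top))) {
    n1 <- top$node1[i]; n2 <- top$node2[i]
    b1 <- n1 %in% baited; b2 <- n2 %in% baited
    ends <- if (b1 && b2) list(c(n1, n2), c(n2, n1))
            else if (b2) list(c(n2, n1))
            else list(c(n1, n2))
    for (e in ends) {
      rows[[length(rows) + 1]] <- tibble(
        node1 = n1, node2 = n2, bait_fragment = e[1],
        distance = top$distance[i],
        bait_state = unname(st[e[1]]) %||% "background",
        other_state = unname(st[e[2]]) %||% "background"
      )
    }
  }
  profile <- if (length(rows) > 0) bind_rows(rows) else
    tibble(node1 = character(), node2 = character(),
           bait_fragment = character(), distance = numeric(),
           bait_state = character(), other_state = character())
  profile <- profile |>
    mutate(bait_state = dplyr::coalesce(.data$bait_state, "background"),
           other_state = dplyr::coalesce(.data$other_state, "background"))
  list(
    profile = profile,
    summary = profile |> count(.data$bait_state, .data$other_state, name = "n"),
    bivalent_bait_fraction = if (nrow(profile) == 0) NA_real_ else
      mean(profile$bait_state == "bivalent"),
    bivalent_both_fraction = if (nrow(profile) == 0) NA_real_ else
      mean(profile$bait_state == "bivalent" & profile$other_state == "bivalent")
  )
}

#' Expression change category per baited fragment
#'
#' A fragment is `up`/`down` when all of its significantly differential
#' genes agree in direction, `unchanged` when none is significant, and
#' `mixed` when significant genes disagree. Genes absent from the DE table
#' are treated as unchanged (logged).
#'
#' @param baits bait annotation (`fragment_id`, `gene`).
#' @param de_table tibble with `gene`, `log2fc`, `padj`.
#' @param alpha adjusted-p significance cutoff (default 0.05).
#' @return Tibble `fragment_id`, `category`.
#' @export
assign_expression_category <- function(baits, de_table, alpha = 0.05) {
  missing_genes <- setdiff(baits$gene, de_table$gene)
  if (length(missing_genes) > 0) {
    inform(sprintf("%d gene(s) absent from the DE table treated as unchanged",
                   length(missing_genes)))
  }
  baits |>
    left_join(de_table |> select("gene", "log2fc", "padj"), by = "gene") |>
    mutate(sig = !is.na(.data$padj) & .data$padj < alpha) |>
    group_by(.data$fragment_id) |>
    summarise(
      category = {
        dirs <- unique(sign(.data$log2fc[.data$sig]))
        dirs <- dirs[dirs != 0]
        if (length(dirs) == 0) "unchanged"
        else if (length(dirs) > 1) "mixed"
        else if (dirs > 0) "up" else "down"
      },
      .groups = "drop"
    )
}
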