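# Truth-table oracle for the edge rule, written independently of the
# package implementation: an edge exists iff one score reaches `sig`; it is
# shared iff the other score exceeds `support`.
specificity_oracle <- function(sa, sb, sig = 5, support = 3) {
  has_a <- !is.na(sa) && sa >= sig
  has_b <- !is.na(sb) && sb >= sig
  if (!has_a && !has_b) return(NA_character_)
  if (has_a && (!is.na(sb) && sb > support)) return("shared")
  if (has_b && (!is.na(sa) && sa > support)) return("shared")
  if (has_a) "A_specific" else "B_specific"
}

test_that("edge specificity matches the rule on an exhaustive threshold grid", {
  grid <- c(NA, 0, 1, 2.99, 3, 3.01, 4.99, 5, 5.01, 8, 20)
  for (sa in grid) {
    for (sb in grid) {
      expect_identical(
        edge_specificity(sa, sb),
        specificity_oracle(sa, sb),
        info = sprintf("score_A=%s score_B=%s", sa, sb)
      )
    }
  }
})

test_that("forced specificity examples hold at the thresholds", {
  expect_identical(edge_specificity(5.2, 1.0), "A_specific")
  expect_identical(edge_specificity(5.2, 3.5), "shared")
  expect_identical(edge_specificity(4.9, 4.9), NA_character_)
  expect_identical(edge_specificity(3.0, 5.0), "B_specific") # 3 is not >3
})

test_that("merged network equals brute-force set construction on random calls", {
  set.seed(101)
  fm <- make_frags(list(chr1 = rep(4000L, 30)))
  for (rep_i in 1:10) {
    pairs <- t(utils::combn(30, 2))
    pairs <- pairs[sample(nrow(pairs), 60), ]
    sa <- ifelse(runif(60) < 0.7, round(runif(60, 0, 10), 2), NA)
    sb <- ifelse(runif(60) < 0.7, round(runif(60, 0, 10), 2), NA)
    keep <- !(is.na(sa) & is.na(sb))
    pairs <- pairs[keep, ]; sa <- sa[keep]; sb <- sb[keep]
    net <- make_network(fm, pairs, sa, sb)
    expected <- purrr::map(seq_len(nrow(pairs)), function(k) {
      spec <- specificity_oracle(sa[k], sb[k])
      if (is.na(spec)) return(NULL)
      tibble::tibble(
        node1 = min(fm$fragment_id[pairs[k, ]]),
        node2 = max(fm$fragment_id[pairs[k, ]]),
        specificity = spec)
    }) |> dplyr::bind_rows() |> dplyr::arrange(node1, node2)
    got <- net$edges |> dplyr::select(node1, node2, specificity)
    expect_equal(got, expected)
    # no orphan nodes: every node is incident to >= 1 edge
    expect_setequal(net$nodes$fragment_id,
                    unique(c(net$edges$node1, net$edges$node2)))
    # recomputing specificity from the stored scores is idempotent
    expect_identical(
      edge_specificity(net$edges$score_A, net$edges$score_B),
      net$edges$specificity)
  }
})

test_that("components agree with a hand-rolled reachability oracle", {
  set.seed(7)
  fm <- make_frags(list(chr1 = rep(4000L, 25)))
  for (rep_i in 1:5) {
    pairs <- t(utils::combn(25, 2))
    pairs <- pairs[runif(nrow(pairs)) < 0.06, , drop = FALSE]
    if (nrow(pairs) == 0) next
    net <- make_network(fm, pairs, rep(6, nrow(pairs)), rep(6, nrow(pairs)))
    comps <- network_components(net)
    # oracle: boolean reachability by repeated adjacency expansion
    ids <- sort(unique(fm$fragment_id[c(pairs)]))
    n <- length(ids)
    adj <- diag(TRUE, n)
    for (k in seq_len(nrow(pairs))) {
      i <- match(fm$fragment_id[pairs[k, 1]], ids)
      j <- match(fm$fragment_id[pairs[k, 2]], ids)
      adj[i, j] <- adj[j, i] <- TRUE
    }
    repeat {
      nxt <- (adj %*% adj) > 0
      if (identical(nxt, adj)) break
      adj <- nxt
    }
    oracle_label <- apply(adj, 1, function(r) min(which(r)))
    got <- comps$component_id[match(ids, comps$fragment_id)]
    expect_equal(rand_index(got, oracle_label), 1)
    # partition covers all nodes exactly once
    expect_setequal(comps$fragment_id, ids)
    expect_equal(nrow(comps), n)
  }
})

test_that("two disjoint triangles form two 3-node components; empty network is empty", {
  fm <- make_frags(list(chr1 = rep(4000L, 6)))
  pairs <- rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))
  net <- make_network(fm, pairs, rep(6, 6), rep(NA, 6))
  comps <- network_components(net)
  expect_equal(as.integer(table(comps$component_id)), c(3L, 3L))
  empty <- build_merged_network(
    make_calls(fm, matrix(nrow = 0, ncol = 2), numeric(), "A"),
    make_calls(fm, matrix(nrow = 0, ncol = 2), numeric(), "B"), fm)
  expect_equal(nrow(network_components(empty)), 0)
})

test_that("subnetwork census counts per-condition support and assigns quadrants", {
  fm <- make_frags(list(chr1 = rep(4000L, 60)))
  # component 1: star with 10 A-only edges; component 2: star with 40 B-only
  p1 <- cbind(1, 2:11)
  p2 <- cbind(15, 16:55)
  net <- make_network(fm, rbind(p1, p2),
                      c(rep(6, 10), rep(NA, 40)),
                      c(rep(NA, 10), rep(6, 40)))
  census <- subnetwork_census(net)
  big <- census[census$n_nodes == 41, ]
  expect_equal(big$quadrant, "larger_in_B")
  expect_equal(big$edges_B, 40)
  expect_equal(big$edges_A, 0)
  small <- census[census$n_nodes == 11, ]
  expect_equal(small$quadrant, "larger_in_A")
  # all-shared component is unchanged
  net2 <- make_network(fm, p1, rep(6, 10), rep(6, 10))
  expect_equal(subnetwork_census(net2)$quadrant, "unchanged")
  # conservation: node counts across components sum to the node total
  expect_equal(sum(census$n_nodes), nrow(net$nodes))
})

test_that("interaction distance is midpoint arithmetic, symmetric, NA for trans", {
  fm <- make_frags(list(chr1 = c(4000L, 6000L, 4000L), chr2 = c(4000L)))
  frg <- fm$fragment_id
  expect_equal(interaction_distance(fm, frg[1], frg[3]), 10000)
  expect_equal(interaction_distance(fm, frg[3], frg[1]), 10000)
  expect_true(is.na(interaction_distance(fm, frg[1], frg[4])))
  set.seed(3)
  fm2 <- make_frags(list(chr1 = sample(1000:9000, 20)))
  i <- sample(20, 30, replace = TRUE)
  j <- sample(20, 30, replace = TRUE)
  mid <- (fm2$start + fm2$end) / 2
  expect_equal(interaction_distance(fm2, fm2$fragment_id[i], fm2$fragment_id[j]),
               abs(mid[i] - mid[j]))
})

test_that("distance bands are half-open with a strict >1 Mb long-range rule", {
  expect_equal(as.character(classify_distance_band(1000001)), "long")
  expect_equal(as.character(classify_distance_band(1000000)), "mid")
  expect_equal(as.character(classify_distance_band(250000)), "short")
  expect_equal(as.character(classify_distance_band(250001)), "mid")
  expect_error(classify_distance_band(-5), "negative")
  # sweep: labels consistent with the breakpoint definition
  bands <- c(short = 100, long = 1000)
  d <- 0:1500
  lab <- classify_distance_band(d, bands)
  expect_true(all(lab[d <= 100] == "short"))
  expect_true(all(lab[d > 100 & d <= 1000] == "mid"))
  expect_true(all(lab[d > 1000] == "long"))
})

test_that("top-longest selection matches sort-then-slice with deterministic ties", {
  fm <- make_frags(list(chr1 = rep(4000L, 40)))
  pairs <- cbind(1, c(3, 6, 10, 20, 35))
  net <- make_network(fm, pairs, rep(6, 5), rep(6, 5))
  top3 <- select_top_longest(net, "A", n = 3)
  expect_equal(nrow(top3), 3)
  expect_equal(top3$distance, sort(net$edges$distance, decreasing = TRUE)[1:3])
  # excluded distances never exceed included ones
  rest <- setdiff(net$edges$distance, top3$distance)
  expect_true(all(top3$distance >= max(rest)))
  # fewer edges than requested: return all with a warning
  expect_warning(all5 <- select_top_longest(net, "A", n = 10), "only 5")
  expect_equal(nrow(all5), 5)
  # ties at the cutoff resolve identically across runs
  pairs2 <- rbind(c(1, 11), c(2, 12), c(3, 13), c(4, 14))
  net2 <- make_network(fm, pairs2, rep(6, 4), rep(NA, 4))
  t1 <- select_top_longest(net2, "A", n = 2)
  t2 <- select_top_longest(net2, "A", n = 2)
  expect_identical(t1, t2)
  expect_equal(t1$node1, sort(t1$node1))
})

test_that("state-restricted sub-graphs keep only edges with qualifying endpoints", {
  fm <- make_frags(list(chr1 = rep(4000L, 12)))
  pairs <- rbind(c(1, 2), c(2, 3), c(4, 5), c(5, 6), c(7, 8), c(9, 10))
  net <- make_network(fm, pairs, rep(6, 6), rep(6, 6))
  states <- tibble::tibble(
    fragment_id = fm$fragment_id,
    state = c("bivalent", "bivalent", "bivalent", "polycomb", "bivalent",
              "polycomb", "active", "bivalent", "active", "active",
              "background", "background"),
    condition = "B")
  sub <- extract_state_network(net, "B", states)
  # qualifying edges: (1,2), (2,3), (4,5), (5,6); (7,8) has an active end
  expect_equal(nrow(sub$edges), 4)
  baits <- tibble::tibble(fragment_id = fm$fragment_id[2], gene = "HOXA1")
  sub2 <- extract_state_network(net, "B", states, baits = baits)
  expect_equal(sub2$genes, "HOXA1")
  # predicate TRUE keeps every supported edge
  all_e <- extract_state_network(net, "B", states, predicate = function(s) TRUE)
  expect_equal(nrow(all_e$edges), nrow(net$edges))
  expect_error(extract_state_network(net, "B", states[0, ]), "missing")
})
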