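# Independent truth table for the supersession rule over every subset of
# the seven reduced states.
supersession_oracle <- function(states_present) {
  s <- setdiff(states_present, "background")
  if (length(s) == 0) return("background")
  if (length(s) == 1) return(s)
  if (length(s) == 2 && all(sort(s) == c("bivalent", "polycomb"))) {
    return("bivalent")
  }
  "mixed"
}

test_that("state supersession matches the truth table on all 128 subsets", {
  states <- chromatin_states()
  for (mask in 0:(2^7 - 1)) {
    present <- states[bitwAnd(mask, 2^(0:6)) > 0]
    expect_identical(reduce_state_set(present), supersession_oracle(present),
                     info = paste(present, collapse = "+"))
  }
})

test_that("fragment state assignment applies supersession over real overlaps", {
  fm <- make_frags(list(chr1 = rep(4000L, 5)))
  seg <- tibble::tibble(
    chrom = "chr1",
    start = c(0L, 2000L, 4000L, 12000L, 13000L),
    end = c(2000L, 4000L, 8000L, 13000L, 16000L),
    state = c("bivalent", "polycomb", "active", "active", "heterochromatin"),
    condition = "X")
  st <- assign_fragment_states(seg, fm)
  lk <- function(i) st$state[st$fragment_id == fm$fragment_id[i]]
  expect_equal(lk(1), "bivalent")       # bivalent supersedes polycomb
  expect_equal(lk(2), "active")         # single state (background implicit)
  expect_equal(lk(3), "background")     # uncovered fragment
  expect_equal(lk(4), "mixed")          # active + heterochromatin
  # input order independence
  st2 <- assign_fragment_states(seg[sample(nrow(seg)), ], fm)
  expect_equal(dplyr::arrange(st, fragment_id), dplyr::arrange(st2, fragment_id))
  # label is reproducible from the provenance overlap table
  ov <- attr(st, "overlap_table")
  redo <- ov |>
    dplyr::group_by(fragment_id) |>
    dplyr::summarise(state = reduce_state_set(state))
  expect_equal(redo$state,
               st$state[match(redo$fragment_id, st$fragment_id)])
})

test_that("minimum-overlap threshold removes marginal states", {
  fm <- make_frags(list(chr1 = 4000L))
  seg <- tibble::tibble(chrom = "chr1", start = c(0L, 3990L),
                        end = c(3990L, 4000L),
                        state = c("active", "polycomb"), condition = "X")
  expect_equal(assign_fragment_states(seg, fm)$state, "mixed")
  expect_equal(assign_fragment_states(seg, fm, min_state_bp = 50)$state,
               "active")
})

test_that("unknown segmentation state labels are rejected by name", {
  fm <- make_frags(list(chr1 = 4000L))
  seg <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L,
                        state = "quiescent", condition = "X")
  expect_error(assign_fragment_states(seg, fm), "quiescent")
})

test_that("state transition matrix counts pairs and normalises within destination", {
  mk <- function(states) tibble::tibble(
    fragment_id = sprintf("f%02d", seq_along(states)), state = states,
    condition = "x")
  # identical assignments -> diagonal
  a <- mk(c("active", "bivalent", "polycomb", "active"))
  tm <- state_transition_matrix(a, a)
  expect_true(all(tm$state_A == tm$state_B))
  expect_equal(sum(tm$n), 4)
  # uniform off-diagonal block
  tm2 <- state_transition_matrix(mk(rep("active", 10)), mk(rep("bivalent", 10)))
  expect_equal(nrow(tm2), 1)
  expect_equal(tm2$n, 10)
  expect_equal(tm2$pct_within_B, 100)
  # random assignments vs direct pair counting
  set.seed(5)
  sa <- sample(chromatin_states(), 200, replace = TRUE)
  sb <- sample(chromatin_states(), 200, replace = TRUE)
  tm3 <- state_transition_matrix(mk(sa), mk(sb))
  expect_equal(sum(tm3$n), 200)
  direct <- table(sa, sb)
  for (r in seq_len(nrow(tm3))) {
    expect_equal(tm3$n[r], unname(direct[tm3$state_A[r], tm3$state_B[r]]))
  }
  # percentages are within-destination
  pct_sum <- tm3 |> dplyr::group_by(state_B) |>
    dplyr::summarise(s = sum(pct_within_B))
  expect_true(all(abs(pct_sum$s - 100) < 1e-9))
  # subset restriction
  tm4 <- state_transition_matrix(mk(sa), mk(sb),
                                 fragment_subset = sprintf("f%02d", 1:5))
  expect_equal(sum(tm4$n), 5)
})

test_that("longest-interaction profile reports bait/other-end states", {
  fm <- make_frags(list(chr1 = rep(4000L, 30)))
  pairs <- cbind(1:4, c(11, 14, 17, 20))
  net <- make_network(fm, pairs, rep(NA, 4), rep(6, 4))
  states <- tibble::tibble(fragment_id = fm$fragment_id,
                           state = "bivalent", condition = "B")
  baits <- tibble::tibble(fragment_id = fm$fragment_id[1:4],
                          gene = sprintf("G%d", 1:4))
  prof <- longest_interaction_state_profile(net, "B", states, baits, n = 4)
  expect_equal(nrow(prof$profile), 4)
  expect_equal(prof$bivalent_bait_fraction, 1)
  expect_equal(prof$bivalent_both_fraction, 1)
  expect_true(all(prof$profile$bait_fragment %in% baits$fragment_id))
  # both ends baited: the edge is counted once per direction
  baits2 <- dplyr::bind_rows(
    baits, tibble::tibble(fragment_id = fm$fragment_id[11], gene = "G11"))
  prof2 <- longest_interaction_state_profile(net, "B", states, baits2, n = 4)
  expect_equal(nrow(prof2$profile), 5)
})

test_that("expression categories aggregate per fragment with a mixed class", {
  baits <- tibble::tibble(
    fragment_id = c("f1", "f2", "f2", "f3", "f4"),
    gene = c("UP1", "UP2", "DOWN1", "NS1", "ABSENT"))
  de <- tibble::tibble(
    gene = c("UP1", "UP2", "DOWN1", "NS1"),
    log2fc = c(2, 1.5, -2, 3),
    padj = c(0.001, 0.01, 0.02, 0.4))
  expect_message(cat <- assign_expression_category(baits, de), "absent")
  lk <- function(f) cat$category[cat$fragment_id == f]
  expect_equal(lk("f1"), "up")
  expect_equal(lk("f2"), "mixed")     # significant genes disagree
  expect_equal(lk("f3"), "unchanged") # not significant
  expect_equal(lk("f4"), "unchanged") # absent from DE table
})

test_that("expression categories match brute-force aggregation on random tables", {
  set.seed(17)
  genes <- sprintf("g%03d", 1:150)
  baits <- tibble::tibble(
    fragment_id = sample(sprintf("f%02d", 1:40), 150, replace = TRUE),
    gene = genes)
  de <- tibble::tibble(gene = genes, log2fc = rnorm(150),
                       padj = runif(150))
  cat <- suppressMessages(assign_expression_category(baits, de, alpha = 0.3))
  for (f in unique(baits$fragment_id)) {
    g <- baits$gene[baits$fragment_id == f]
    rows <- de[de$gene %in% g & de$padj < 0.3, ]
    expected <- if (nrow(rows) == 0) "unchanged"
      else if (all(rows$log2fc > 0)) "up"
      else if (all(rows$log2fc < 0)) "down"
      else "mixed"
    expect_equal(cat$category[cat$fragment_id == f], expected, info = f)
  }
})
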