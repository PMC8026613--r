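mk_peaks <- function(starts, width = 400L) {
  tibble::tibble(chrom = "chr1", start = as.integer(starts),
                 end = as.integer(starts + width), signal = 1)
}

test_that("OSN peaks require all three factors and merge transitively", {
  # coincident peaks of all three factors -> one OSN peak
  osn <- build_osn_peaks(mk_peaks(1000), mk_peaks(1050), mk_peaks(1100))
  expect_equal(nrow(osn), 1)
  expect_equal(osn$centre, floor((osn$start + osn$end) / 2))
  # two factors only -> excluded
  osn2 <- build_osn_peaks(mk_peaks(c(1000, 9000)), mk_peaks(c(1050, 9050)),
                          mk_peaks(1100))
  expect_equal(nrow(osn2), 1)
  expect_true(osn2$start < 2000)
  # transitive merge across 50 bp gaps
  osn3 <- build_osn_peaks(mk_peaks(1000), mk_peaks(1450), mk_peaks(1900))
  expect_equal(nrow(osn3), 1)
  expect_equal(c(osn3$start, osn3$end), c(1000, 2300))
})

test_that("merge distance is a strict gap bound", {
  # gap exactly 100 bp: not merged, so no region carries all three factors
  osn <- build_osn_peaks(mk_peaks(1000), mk_peaks(1500), mk_peaks(2000))
  expect_equal(nrow(osn), 0)
  # gap 99 bp merges
  osn2 <- build_osn_peaks(mk_peaks(1000), mk_peaks(1499), mk_peaks(1998))
  expect_equal(nrow(osn2), 1)
})

test_that("OSN output is maximal and supported by every factor on random input", {
  set.seed(77)
  for (rep_i in 1:10) {
    po <- mk_peaks(sample(0:30000, 12), width = 300L)
    ps <- mk_peaks(sample(0:30000, 12), width = 300L)
    pn <- mk_peaks(sample(0:30000, 12), width = 300L)
    osn <- build_osn_peaks(po, ps, pn)
    if (nrow(osn) > 1) {
      gaps <- osn$start[-1] - osn$end[-nrow(osn)]
      expect_true(all(gaps >= 100))
    }
    for (pk in list(po, ps, pn)) {
      if (nrow(osn) == 0) break
      ov <- outer(seq_len(nrow(osn)), seq_len(nrow(pk)), function(i, j) {
        pmin(osn$end[i], pk$end[j]) - pmax(osn$start[i], pk$start[j]) > 0
      })
      expect_true(all(rowSums(ov) >= 1))
    }
  }
  expect_warning(empty <- build_osn_peaks(mk_peaks(1), mk_peaks(1), mk_peaks(integer(0))[0, ]),
                 "no peaks")
  expect_equal(nrow(empty), 0)
})

test_that("signal filtering keeps peaks over above-threshold windows only", {
  track <- tibble::tibble(chrom = "chr1", start = c(0L, 500L, 1000L),
                          end = c(500L, 1000L, 1500L),
                          value = c(0.2, -1, -0.5))
  pk <- mk_peaks(c(100, 600, 5000), width = 300L)
  kept <- filter_peaks_by_signal(pk, track)
  expect_equal(kept$start, 100L)  # window 0-500 has value 0.2 > 0
  # brute-force oracle on random tracks
  set.seed(8)
  track2 <- tibble::tibble(chrom = "chr1",
                           start = seq(0L, 19500L, by = 500L)) |>
    dplyr::mutate(end = start + 500L, value = rnorm(40))
  pk2 <- mk_peaks(sample(0:19000, 25), width = 350L)
  kept2 <- filter_peaks_by_signal(pk2, track2)
  oracle <- vapply(seq_len(25), function(i) {
    w <- track2$value[track2$start < pk2$end[i] & track2$end > pk2$start[i]]
    any(w > 0)
  }, logical(1))
  expect_equal(kept2, pk2[oracle, ])
})

test_that("OSN specificity is overlap-based against the other condition", {
  a <- mk_peaks(c(1000, 5000)) |> dplyr::mutate(osn_id = c("a1", "a2"))
  spec <- classify_osn_specificity(a, a)
  expect_true(all(spec$osn_a$specificity == "shared"))
  b <- mk_peaks(9000) |> dplyr::mutate(osn_id = "b1")
  spec2 <- classify_osn_specificity(a, b)
  expect_true(all(spec2$osn_a$specificity == "A_specific"))
  expect_equal(spec2$osn_b$specificity, "B_specific")
})

test_that("state composition uses the peak centre and sums to 100 per set", {
  seg <- tibble::tibble(chrom = "chr1", start = c(0L, 10000L),
                        end = c(10000L, 20000L),
                        state = c("active", "bivalent"), condition = "A")
  sets <- list(
    all_active = mk_peaks(c(1000, 4000, 7000)),
    split = mk_peaks(c(2000, 15000)),
    uncovered = mk_peaks(30000)
  )
  m <- state_overlap_matrix(sets, seg)
  expect_equal(m$pct[m$set == "all_active" & m$state == "active"], 100)
  expect_setequal(m$state[m$set == "split"], c("active", "bivalent"))
  expect_equal(m$state[m$set == "uncovered"], "background")
  sums <- m |> dplyr::group_by(set) |> dplyr::summarise(s = sum(pct))
  expect_true(all(abs(sums$s - 100) < 1e-9))
})

test_that("control-region sampling is deterministic, in-bounds and length-proportional", {
  genome <- tibble::tibble(chrom = c("chr1", "chr2"),
                           length = c(2e7, 1e7))
  r1 <- sample_control_regions(genome, n = 3000, width = 1200, seed = 5)
  r2 <- sample_control_regions(genome, n = 3000, width = 1200, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$end - r1$start == 1200))
  glen <- setNames(genome$length, genome$chrom)
  expect_true(all(r1$start >= 0 & r1$end <= glen[r1$chrom]))
  # chromosome allocation proportional to length (chr1 = 2/3), within 4 sd
  frac <- mean(r1$chrom == "chr1")
  expect_lt(abs(frac - 2 / 3), 4 * sqrt(2 / 9 / 3000))
  # distinct seeds overlap no more than 5x the uniform collision rate
  r3 <- sample_control_regions(genome, n = 500, width = 1200, seed = 6)
  r4 <- sample_control_regions(genome, n = 500, width = 1200, seed = 7)
  hit <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(r3$chrom, IRanges::IRanges(r3$start + 1, r3$end)),
    GenomicRanges::GRanges(r4$chrom, IRanges::IRanges(r4$start + 1, r4$end)))
  expected_rate <- 1 - exp(-500 * 2399 / 3e7)
  expect_lt(mean(hit > 0), 5 * expected_rate)
  # exclusion lists are honoured
  excl <- tibble::tibble(chrom = "chr1", start = 0L, end = 19000000L)
  r5 <- sample_control_regions(genome, n = 200, width = 1200, seed = 8,
                               exclude = excl)
  expect_false(any(r5$chrom == "chr1" & r5$start < 19000000))
  expect_error(sample_control_regions(genome, n = 1e6, width = 1200),
               "too short")
})

test_that("contingency odds ratios follow the cross-product rule and symmetries", {
  flat <- osn_interaction_contingency(tibble::tibble(
    fragment_id = sprintf("f%d", 1:40),
    osn_change = rep(c("lost", "retained"), each = 20),
    interaction_change = rep(rep(c("lost", "retained"), each = 10), 2)))
  ll <- flat$tests[flat$tests$osn_change == "lost" &
                     flat$tests$interaction_change == "lost", ]
  expect_equal(ll$odds_ratio, 1)
  expect_equal(ll$log2_odds_ratio, 0)
  # direct arithmetic example: [[20,5],[4,16]] -> OR 16, log2 OR 4
  direct <- fisher_or_chisq(matrix(c(20, 5, 4, 16), 2, byrow = TRUE))
  expect_equal(direct$odds_ratio, 16)
  expect_equal(direct$log2_odds_ratio, 4)
  # swapping both row and column labels preserves the OR; one label negates it
  swapped_both <- fisher_or_chisq(matrix(c(16, 4, 5, 20), 2, byrow = TRUE))
  expect_equal(swapped_both$odds_ratio, direct$odds_ratio)
  swapped_one <- fisher_or_chisq(matrix(c(5, 20, 16, 4), 2, byrow = TRUE))
  expect_equal(swapped_one$log2_odds_ratio, -direct$log2_odds_ratio)
  # row percentages sum to 100 within each OSN class present
  pr <- flat$matrix |> dplyr::filter(!is.na(row_pct)) |>
    dplyr::group_by(osn_change) |> dplyr::summarise(s = sum(row_pct))
  expect_true(all(abs(pr$s - 100) < 1e-9))
})

test_that("planted occupancy/interaction coupling yields a positive association", {
  set.seed(55)
  n <- 500
  osn_change <- sample(c("lost", "retained"), n, replace = TRUE)
  interaction_change <- ifelse(
    runif(n) < 0.9, osn_change,
    ifelse(osn_change == "lost", "retained", "lost"))
  res <- osn_interaction_contingency(tibble::tibble(
    fragment_id = sprintf("f%d", 1:n), osn_change = osn_change,
    interaction_change = interaction_change))
  ll <- res$tests[res$tests$osn_change == "lost" &
                    res$tests$interaction_change == "lost", ]
  expect_gt(ll$log2_odds_ratio, 0)
  expect_lt(ll$p_value, 0.05)
})

test_that("fragment change classes derive from peak overlap and edge support", {
  fm <- make_frags(list(chr1 = rep(4000L, 8)))
  net <- make_network(fm, rbind(c(1, 5), c(2, 6), c(3, 7)),
                      c(6, NA, 6), c(NA, 6, 6))
  frag_at <- function(i) fm[i, ]
  osn_a <- tibble::tibble(chrom = "chr1", start = c(100L, 8100L),
                          end = c(500L, 8500L))   # over fragments 1 and 3
  osn_b <- tibble::tibble(chrom = "chr1", start = c(4100L, 8200L),
                          end = c(4500L, 8600L))  # over fragments 2 and 3
  ch <- classify_fragment_changes(fm[1:4, ], osn_a, osn_b, net)
  expect_equal(ch$osn_change, c("lost", "gained", "retained", "never"))
  expect_equal(ch$interaction_change[1:3], c("lost", "gained", "retained"))
})
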