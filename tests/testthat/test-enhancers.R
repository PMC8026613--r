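# Hand-rolled interval-merge-with-gap oracle (single chromosome, sorted).
stitch_oracle <- function(starts, ends, gap) {
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  out <- list(c(starts[1], ends[1]))
  for (i in seq_along(starts)[-1]) {
    last <- out[[length(out)]]
    if (starts[i] - last[2] <= gap) {
      out[[length(out)]][2] <- max(last[2], ends[i])
    } else {
      out[[length(out) + 1]] <- c(starts[i], ends[i])
    }
  }
  do.call(rbind, out)
}

test_that("peak stitching merges gaps up to the stitch distance", {
  pk <- tibble::tibble(chrom = "chr1", start = c(0L, 1800L),
                       end = c(800L, 2500L), signal = c(2, 3))
  st <- stitch_peaks(pk, 1500)  # gap 1000 <= 1500
  expect_equal(nrow(st), 1)
  expect_equal(st$signal, 5)
  expect_equal(st$n_constituents, 2)
  pk2 <- tibble::tibble(chrom = "chr1", start = c(0L, 2800L),
                        end = c(800L, 3500L), signal = c(2, 3))
  expect_equal(nrow(stitch_peaks(pk2, 1500)), 2)  # gap 2000 > 1500
})

test_that("stitching matches the interval-merge oracle and is idempotent", {
  set.seed(31)
  for (rep_i in 1:40) {
    n <- sample(2:25, 1)
    starts <- sort(sample(0:50000, n))
    ends <- starts + sample(200:2500, n, replace = TRUE)
    gap <- sample(c(0, 500, 1500, 3000), 1)
    pk <- tibble::tibble(chrom = "chrX", start = starts, end = ends,
                         signal = runif(n, 1, 10))
    st <- stitch_peaks(pk, gap)
    oracle <- stitch_oracle(starts, ends, gap)
    expect_equal(cbind(st$start, st$end), unname(oracle))
    expect_equal(sum(st$signal), sum(pk$signal))
    st2 <- stitch_peaks(st |> dplyr::select(chrom, start, end, signal), gap)
    expect_equal(cbind(st2$start, st2$end), cbind(st$start, st$end))
  }
})

# Brute-force cutoff: evaluate x - y at every rank and take the argmax.
se_cutoff_oracle <- function(signal) {
  s <- sort(signal)
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  s[which.max(x - y)]
}

elements_from_signals <- function(signal) {
  n <- length(signal)
  tibble::tibble(element_id = sprintf("e%02d", 1:n), chrom = "chr1",
                 start = (1:n) * 10000L, end = (1:n) * 10000L + 1000L,
                 n_constituents = 1L, signal = signal)
}

test_that("super-enhancer cutoff sits at the rank-curve tangent point", {
  el <- call_super_enhancers(elements_from_signals(c(1, 2, 3, 4, 100)))
  expect_equal(el$signal[el$is_super], 100)
  expect_equal(attr(el, "cutoff_rank"), 4)  # scaled x - y maximal at rank 4
  expect_equal(attr(el, "cutoff_signal"), 4)
  el2 <- call_super_enhancers(elements_from_signals(c(1, 1, 1, 10, 10)))
  expect_equal(sort(el2$signal[el2$is_super]), c(10, 10))
  expect_warning(el3 <- call_super_enhancers(elements_from_signals(rep(4, 6))),
                 "no super-enhancers")
  expect_false(any(el3$is_super))
})

test_that("the cutoff matches brute force and is affine invariant", {
  set.seed(12)
  for (rep_i in 1:25) {
    sig <- round(rexp(sample(5:60, 1), 1 / 8), 4)
    if (diff(range(sig)) == 0) next
    el <- call_super_enhancers(elements_from_signals(sig))
    expect_equal(attr(el, "cutoff_signal"), se_cutoff_oracle(sig))
    # affine rescaling of the signal vector leaves the call set unchanged
    a <- runif(1, 0.1, 50); b <- runif(1, -5, 5)
    el2 <- call_super_enhancers(elements_from_signals(a * sig + b))
    expect_equal(el2$is_super[order(el2$element_id)],
                 el$is_super[order(el$element_id)])
    # ranks are unique
    expect_equal(sort(el$rank), seq_along(sig))
  }
})

test_that("element matching preserves one-to-many overlap pairs", {
  ea <- tibble::tibble(element_id = "A1", chrom = "chr1", start = 0L,
                       end = 10000L)
  eb <- tibble::tibble(element_id = c("B1", "B2"), chrom = "chr1",
                       start = c(1000L, 6000L), end = c(3000L, 8000L))
  m <- match_elements_across_conditions(ea, eb)
  expect_equal(m$elements_a$cross_condition, "shared")     # 1 shared in A
  expect_equal(m$elements_b$cross_condition, c("shared", "shared"))  # 2 in B
  expect_equal(nrow(m$pairs), 2)
  # disjoint sets are all specific
  eb2 <- eb |> dplyr::mutate(chrom = "chr2")
  m2 <- match_elements_across_conditions(ea, eb2)
  expect_equal(m2$elements_a$cross_condition, "specific")
  expect_true(all(m2$elements_b$cross_condition == "specific"))
})

test_that("element matching agrees with a pairwise overlap oracle", {
  set.seed(19)
  mk <- function(n, pre) tibble::tibble(
    element_id = sprintf("%s%02d", pre, 1:n), chrom = "chr1",
    start = sample(0:80000, n), width = sample(500:5000, n, replace = TRUE)) |>
    dplyr::mutate(end = start + width) |> dplyr::select(-width)
  ea <- mk(20, "a"); eb <- mk(25, "b")
  m <- match_elements_across_conditions(ea, eb)
  oracle <- outer(seq_len(20), seq_len(25), function(i, j) {
    pmin(ea$end[i], eb$end[j]) - pmax(ea$start[i], eb$start[j]) >= 1
  })
  expect_equal(m$elements_a$cross_condition,
               ifelse(rowSums(oracle) > 0, "shared", "specific"))
  expect_equal(m$elements_b$cross_condition,
               ifelse(colSums(oracle) > 0, "shared", "specific"))
  expect_equal(nrow(m$pairs), sum(oracle))
})

test_that("elements reach target genes through condition-supported edges", {
  fm <- make_frags(list(chr1 = rep(4000L, 10)))
  # element over fragment 5; G1's bait is fragment 2
  el <- tibble::tibble(element_id = "SE1", chrom = "chr1", start = 16500L,
                       end = 17500L)
  baits <- tibble::tibble(fragment_id = fm$fragment_id[2], gene = "G1")
  netA <- make_network(fm, rbind(c(2, 5)), 6, NA)      # A-specific edge
  tA <- map_elements_to_targets(el, netA, baits, "A", fm)
  expect_equal(tA$gene, "G1")
  expect_equal(nrow(map_elements_to_targets(el, netA, baits, "B", fm)), 0)
  netS <- make_network(fm, rbind(c(2, 5)), 6, 6)       # shared edge
  cls <- classify_target_genes(
    map_elements_to_targets(el, netS, baits, "A", fm),
    map_elements_to_targets(el, netS, baits, "B", fm))
  expect_equal(cls$class, "shared")
  # SE-contacted genes are removed from the enhancer gene list
  cls2 <- classify_target_genes(tA, tA[0, ], se_targets = "G1")
  expect_equal(nrow(cls2), 0)
})

test_that("target classes partition genes with no gene in two classes", {
  d <- default_fixture()$data
  net <- default_network()
  se_a <- call_super_enhancers(stitch_peaks(d$peaks$h3k27ac_A))
  se_b <- call_super_enhancers(stitch_peaks(d$peaks$h3k27ac_B))
  ta <- map_elements_to_targets(se_a[se_a$is_super, ], net, d$baits, "A", d$frags)
  tb <- map_elements_to_targets(se_b[se_b$is_super, ], net, d$baits, "B", d$frags)
  cls <- classify_target_genes(ta, tb)
  expect_equal(anyDuplicated(cls$gene), 0)
  expect_setequal(cls$gene, union(ta$gene, tb$gene))
})

test_that("contact-count distributions reflect the wiring", {
  asg <- tibble::tibble(element_id = c("SE1", "SE1", "SE1", "SE2"),
                        gene = c("G1", "G2", "G3", "G1"),
                        condition = "A")
  cc <- element_contact_counts(asg)
  expect_equal(cc$promoters_per_element$n_promoters[
    cc$promoters_per_element$element_id == "SE1"], 3)
  expect_equal(cc$elements_per_promoter$n_elements[
    cc$elements_per_promoter$gene == "G1"], 2)
  empty <- element_contact_counts(asg[0, ])
  expect_equal(nrow(empty$promoters_per_element), 0)
})

test_that("region methylation is the pooled call ratio", {
  reg <- tibble::tibble(element_id = c("E1", "E2"), chrom = "chr1",
                        start = c(0L, 10000L), end = c(1000L, 11000L))
  cpg <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L),
                        meth_count = c(2L, 2L), total_count = c(4L, 4L))
  q <- quantify_methylation(reg, cpg)
  expect_equal(q$pct_methylation[1], 50)
  expect_true(is.na(q$pct_methylation[2]))  # no covered CpG
  expect_error(
    quantify_methylation(reg, dplyr::mutate(cpg, meth_count = c(5L, 2L))),
    "exceed")
  # pooled ratio oracle on random calls
  set.seed(2)
  cpg2 <- tibble::tibble(chrom = "chr1", pos = sort(sample(0:999, 30)),
                         total_count = sample(5:30, 30, replace = TRUE)) |>
    dplyr::mutate(meth_count = rbinom(30, total_count, 0.4))
  q2 <- quantify_methylation(reg[1, ], cpg2)
  expect_equal(q2$pct_methylation,
               100 * sum(cpg2$meth_count) / sum(cpg2$total_count))
})

test_that("histone gain uses the per-region delta and linear median ratio", {
  reg <- tibble::tibble(region_id = c("r1", "r2", "r3"),
                        signal_A = c(0, 0, NA),
                        signal_B = c(1.5, 0.9, 2))
  expect_message(res <- histone_gain_classifier(reg), "non-finite")
  expect_equal(res$regions$gain, c(TRUE, FALSE))
  # set medians 1.0 vs 4.0 on the linear scale -> log2 fold change 2
  reg2 <- tibble::tibble(signal_A = rep(0, 5), signal_B = rep(2, 5))
  expect_equal(histone_gain_classifier(reg2)$log2fc_of_medians, 2)
})
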