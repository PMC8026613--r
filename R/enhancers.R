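# Enhancer and super-enhancer calling and target-gene assignment.
#
# H3K27ac peaks are stitched (gap <= 1.5 kb by default), ranked by total
# signal, and split into typical enhancers and super-enhancers at the
# rank-curve point where a slope-1 line is tangent to the scaled
# rank-signal curve (the ROSE geometry). Elements reach their target genes
# through the promoter-interaction network: element -> overlapped
# fragments -> condition-supported edges -> bait genes.

#' Stitch peaks into regulatory elements
#'
#' Merges peaks transitively whenever the gap between them is at most
#' `stitch_distance`; touching or overlapping peaks always merge. The
#' stitched region's signal is the sum of its constituents' signals.
#'
#' @param peaks tibble `chrom`, `start`, `end`, `signal`.
#' @param stitch_distance maximum gap in bp (default 1500).
#' @param condition optional condition label.
#' @return Tibble `element_id`, `chrom`, `start`, `end`, `n_constituents`,
#'   `signal`(, `condition`).
#' @export
stitch_peaks <- function(peaks, stitch_distance = 1500L, condition = NULL) {
  if (nrow(peaks) == 0) {
    out <- tibble(element_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  n_constituents = integer(), signal = numeric())
    if (!is.null(condition)) out$condition <- condition
    return(out)
  }
  gr <- gr_from_tbl(peaks)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = stitch_distance + 1L)
  hit <- ov_find(gr, merged, select = "first")
  agg <- tibble(region = hit, signal = peaks$signal) |>
    group_by(.data$region) |>
    summarise(n_constituents = n(), signal = sum(.data$signal),
              .groups = "drop") |>
    arrange(.data$region)
  out <- tbl_from_gr(merged) |>
    mutate(n_constituents = agg$n_constituents, signal = agg$signal) |>
    arrange(.data$chrom, .data$start) |>
    mutate(element_id = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end)) |>
    select("element_id", "chrom", "start", "end", "n_constituents", "signal")
  if (!is.null(condition)) out$condition <- condition
  out
}

#' Call super-enhancers on a stitched element set
#'
#' Ranks elements by ascending signal, scales ranks and signals to
#' `[0, 1]`, and places the cutoff at the element maximising
#' `x - y` (scaled rank minus scaled signal) — the point where a slope-1
#' line is tangent to the convex rank-signal curve. Elements with signal
#' strictly above the cutoff element's signal are super-enhancers. Rank-curve
#' ties are broken by genomic order so the cutoff is deterministic. The
#' cutoff is invariant to affine rescaling of the signal vector.
#'
#' @param elements stitched element tibble from [stitch_peaks()] (>= 2 rows).
#' @param condition optional condition label to stamp on the output.
#' @return The input with `rank` (ascending by signal), `is_super`, and
#'   attributes `cutoff_signal` and `cutoff_rank`. When all signals are
#'   equal no super-enhancer is called (warned).
#' @export
call_super_enhancers <- function(elements, condition = NULL) {
  stopifnot(nrow(elements) >= 2)
  el <- elements |> arrange(.data$chrom, .data$start)
  ord <- order(el$signal, seq_len(nrow(el)))
  ranked <- el[ord, ]
  nr <- nrow(ranked)
  if (diff(range(ranked$signal)) == 0) {
    warn("all element signals equal; no super-enhancers called")
    out <- ranked |> mutate(rank = row_number(), is_super = FALSE)
    attr(out, "cutoff_signal") <- ranked$signal[nr]
    attr(out, "cutoff_rank") <- nr
    if (!is.null(condition)) out$condition <- condition
    return(out)
  }
  x <- (seq_len(nr) - 1) / (nr - 1)
  y <- (ranked$signal - min(ranked$signal)) / diff(range(ranked$signal))
  cut_idx <- which.max(x - y)
  cutoff_signal <- ranked$signal[cut_idx]
  out <- ranked |>
    mutate(rank = row_number(), is_super = .data$signal > cutoff_signal)
  attr(out, "cutoff_signal") <- cutoff_signal
  attr(out, "cutoff_rank") <- cut_idx
  if (!is.null(condition)) out$condition <- condition
  out
}

#' Match elements across conditions by overlap
#'
#' An element is `shared` when it overlaps (>= `min_overlap` bp) at least
#' one element called in the other condition, otherwise condition-specific.
#' One-to-many overlaps are preserved as pairs, so shared counts may differ
#' between conditions.
#'
#' @param elements_a,elements_b element tibbles (columns `element_id`,
#'   `chrom`, `start`, `end`).
#' @param min_overlap minimum overlap in bp (default 1).
#' @return List with `elements_a`, `elements_b` (each gaining a
#'   `cross_condition` label `shared`/`specific`) and `pairs` (tibble
#'   `element_id_a`, `element_id_b`).
#' @export
match_elements_across_conditions <- function(elements_a, elements_b,
                                             min_overlap = 1L) {
  if (nrow(elements_a) == 0 || nrow(elements_b) == 0) {
    pairs <- tibble(element_id_a = character(), element_id_b = character())
  } else {
    hits <- ov_find(gr_from_tbl(elements_a),
                                        gr_from_tbl(elements_b),
                                        minoverlap = min_overlap)
    pairs <- tibble(
      element_id_a = elements_a$element_id[S4Vectors::queryHits(hits)],
      element_id_b = elements_b$element_id[S4Vectors::subjectHits(hits)]
    )
  }
  list(
    elements_a = elements_a |>
      mutate(cross_condition = if_else(
        .data$element_id %in% pairs$element_id_a, "shared", "specific")),
    elements_b = elements_b |>
      mutate(cross_condition = if_else(
        .data$element_id %in% pairs$element_id_b, "shared", "specific")),
    pairs = pairs
  )
}

#' Map regulatory elements to their target genes through the network
#'
#' Element -> fragments it overlaps -> edges supported in the condition
#' whose other end is one of those fragments -> genes baited on the
#' opposite end. Elements overlapping a bait fragment are still mapped
#' through edges only (no self-targets; logged).
#'
#' @param elements element tibble for one condition.
#' @param net `canvas_network`.
#' @param baits bait annotation (`fragment_id`, `gene`).
#' @param condition condition (side or label).
#' @param frags fragment map tibble.
#' @param min_overlap minimum element/fragment overlap in bp (default 1).
#' @return Tibble `element_id`, `gene`, `condition` (one row per
#'   element-gene contact).
#' @export
map_elements_to_targets <- function(elements, net, baits, condition, frags,
                                    min_overlap = 1L) {
  side <- cn_side(net, condition)
  if (nrow(elements) == 0) {
    return(tibble(element_id = character(), gene = character(),
                  condition = character()))
  }
  hits <- ov_find(gr_from_tbl(elements), gr_from_tbl(frags),
                                      minoverlap = min_overlap)
  el_frag <- tibble(
    element_id = elements$element_id[S4Vectors::queryHits(hits)],
    fragment_id = frags$fragment_id[S4Vectors::subjectHits(hits)]
  )
  n_self <- length(intersect(el_frag$fragment_id, baits$fragment_id))
  if (n_self > 0) {
    inform(sprintf("%d element-overlapped fragment(s) are themselves baited; mapped through edges only",
                   n_self))
  }
  edges <- net$edges |>
    filter(edge_supported(.data$specificity, side))
  both_dir <- bind_rows(
    edges |> select(element_frag = "node1", partner = "node2"),
    edges |> select(element_frag = "node2", partner = "node1")
  )
  el_frag |>
    inner_join(both_dir, by = c(fragment_id = "element_frag"),
               relationship = "many-to-many") |>
    inner_join(baits, by = c(partner = "fragment_id"),
               relationship = "many-to-many") |>
    distinct(.data$element_id, .data$gene) |>
    mutate(condition = net$conditions[[side]]) |>
    arrange(.data$element_id, .data$gene)
}

#' Classify target genes across conditions
#'
#' Genes contacted by elements in both conditions are `shared`; otherwise
#' `A_only`/`B_only`. When `se_targets` is supplied (the super-enhancer
#' target set), genes present in it are removed from the assignment, per
#' the convention that SE-contacted genes are excluded from the typical
#' enhancer gene list.
#'
#' @param targets_a,targets_b target tibbles from [map_elements_to_targets()].
#' @param se_targets optional tibble/vector of genes to exclude.
#' @return Tibble `gene`, `class` in `{A_only, B_only, shared}`.
#' @export
classify_target_genes <- function(targets_a, targets_b, se_targets = NULL) {
  ga <- unique(targets_a$gene)
  gb <- unique(targets_b$gene)
  out <- tibble(gene = sort(union(ga, gb))) |>
    mutate(class = dplyr::case_when(
      .data$gene %in% ga & .data$gene %in% gb ~ "shared",
      .data$gene %in% ga ~ "A_only",
      TRUE ~ "B_only"
    ))
  if (!is.null(se_targets)) {
    excl <- if (is.data.frame(se_targets)) unique(se_targets$gene) else se_targets
    out <- out |> filter(!(.data$gene %in% excl))
  }
  out
}

#' Contact-count distributions
#'
#' @param assignments target tibble (`element_id`, `gene`, `condition`).
#' @return List with `promoters_per_element` (per element, the number of
#'   distinct target genes) and `elements_per_promoter` (per gene, the
#'   number of distinct contacting elements).
#' @export
element_contact_counts <- function(assignments) {
  list(
    promoters_per_element = assignments |>
      distinct(.data$element_id, .data$gene, .data$condition) |>
      count(.data$condition, .data$element_id, name = "n_promoters"),
    elements_per_promoter = assignments |>
      distinct(.data$element_id, .data$gene, .data$condition) |>
      count(.data$condition, .data$gene, name = "n_elements")
  )
}

#' Percent DNA methylation per region
#'
#' Pooled percentage: 100 * sum(methylated calls) / sum(total calls) over
#' the CpGs inside each region; regions without covered CpGs get `NA`.
#'
#' @param regions tibble `element_id` (or `region_id`), `chrom`, `start`,
#'   `end`.
#' @param cpg_calls tibble from [read_methylation()].
#' @return Input regions with `pct_methylation` and `n_cpg` columns.
#' @export
quantify_methylation <- function(regions, cpg_calls) {
  id_col <- if ("element_id" %in% names(regions)) "element_id" else "region_id"
  if (nrow(cpg_calls) > 0 && any(cpg_calls$meth_count > cpg_calls$total_count)) {
    abort("methylated calls exceed total calls")
  }
  pts <- tibble(chrom = cpg_calls$chrom, start = cpg_calls$pos,
                end = cpg_calls$pos + 1L)
  hits <- ov_find(gr_from_tbl(pts), gr_from_tbl(regions))
  agg <- tibble(
    region = S4Vectors::subjectHits(hits),
    meth = cpg_calls$meth_count[S4Vectors::queryHits(hits)],
    total = cpg_calls$total_count[S4Vectors::queryHits(hits)]
  ) |>
    group_by(.data$region) |>
    summarise(pct_methylation = 100 * sum(.data$meth) / sum(.data$total),
              n_cpg = n(), .groups = "drop")
  regions$pct_methylation <- NA_real_
  regions$n_cpg <- 0L
  regions$pct_methylation[agg$region] <- agg$pct_methylation
  regions$n_cpg[agg$region] <- agg$n_cpg
  regions
}

#' Classify histone-mark gain per region
#'
#' Per region, gain iff `signal_b - signal_a > log2fc_threshold` (signals on
#' the log2 RPM scale). The set-level statistic, reported separately, is
#' log2 of the ratio of the two group medians on the linear scale.
#'
#' @param regions tibble with `signal_A` and `signal_B` columns (log2 RPM).
#' @param log2fc_threshold per-region gain threshold (default 1).
#' @return List with `regions` (input + `gain` logical; non-finite signals
#'   excluded with a message) and `log2fc_of_medians` (computed from linear
#'   medians).
#' @export
histone_gain_classifier <- function(regions, log2fc_threshold = 1) {
  finite <- is.finite(regions$signal_A) & is.finite(regions$signal_B)
  if (any(!finite)) {
    inform(sprintf("%d region(s) with non-finite signal excluded", sum(!finite)))
  }
  kept <- regions[finite, ]
  kept$gain <- (kept$signal_B - kept$signal_A) > log2fc_threshold
  med_a <- median(2^kept$signal_A)
  med_b <- median(2^kept$signal_B)
  list(regions = kept, log2fc_of_medians = log2(med_b / med_a))
}
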