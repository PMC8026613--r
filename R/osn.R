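# Composite OCT4/SOX2/NANOG (OSN) occupancy analysis.
#
# OSN peaks are the regions obtained by merging the union of the three
# factors' peaks whenever the gap is strictly below 100 bp, then keeping
# only merged regions that overlap at least one original peak of each
# factor. Peak-level chromatin state uses the state at the peak centre.

#' Build composite OSN peaks
#'
#' @param peaks_o,peaks_s,peaks_n peak tibbles (`chrom`, `start`, `end`,
#'   optional `signal`) for OCT4, SOX2 and NANOG.
#' @param merge_distance merge peaks closer than this many bp (strict gap
#'   `< merge_distance`; touching or overlapping peaks always merge;
#'   default 100).
#' @param condition optional condition label.
#' @return Tibble `osn_id`, `chrom`, `start`, `end`, `centre`, per-factor
#'   constituent counts `n_oct4`, `n_sox2`, `n_nanog`(, `condition`).
#' @export
build_osn_peaks <- function(peaks_o, peaks_s, peaks_n, merge_distance = 100L,
                            condition = NULL) {
  if (nrow(peaks_o) == 0 || nrow(peaks_s) == 0 || nrow(peaks_n) == 0) {
    warn("at least one factor has no peaks; OSN set is empty")
    out <- tibble(osn_id = character(), chrom = character(), start = integer(),
                  end = integer(), centre = numeric(), n_oct4 = integer(),
                  n_sox2 = integer(), n_nanog = integer())
    if (!is.null(condition)) out$condition <- condition
    return(out)
  }
  all_peaks <- bind_rows(
    peaks_o |> select("chrom", "start", "end") |> mutate(factor = "oct4"),
    peaks_s |> select("chrom", "start", "end") |> mutate(factor = "sox2"),
    peaks_n |> select("chrom", "start", "end") |> mutate(factor = "nanog")
  )
  merged <- GenomicRanges::reduce(gr_from_tbl(all_peaks),
                                  min.gapwidth = as.integer(merge_distance))
  hits <- ov_find(gr_from_tbl(all_peaks), merged)
  support <- tibble(
    region = S4Vectors::subjectHits(hits),
    factor = all_peaks$factor[S4Vectors::queryHits(hits)]
  ) |>
    count(.data$region, .data$factor) |>
    tidyr::pivot_wider(names_from = "factor", values_from = "n",
                       values_fill = 0L, names_prefix = "n_")
  for (col in c("n_oct4", "n_sox2", "n_nanog")) {
    if (!col %in% names(support)) support[[col]] <- 0L
  }
  out <- tbl_from_gr(merged) |>
    mutate(region = row_number()) |>
    inner_join(support, by = "region") |>
    filter(.data$n_oct4 > 0, .data$n_sox2 > 0, .data$n_nanog > 0) |>
    mutate(
      centre = floor((.data$start + .data$end) / 2),
      osn_id = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end)
    ) |>
    select("osn_id", "chrom", "start", "end", "centre",
           "n_oct4", "n_sox2", "n_nanog")
  if (!is.null(condition)) out$condition <- condition
  out
}

#' Filter peaks by binned signal
#'
#' Keeps peaks overlapping at least one fixed-width signal window whose
#' value exceeds the threshold. Windows absent from the track count as
#' below threshold.
#'
#' @param peaks peak tibble.
#' @param signal_track tibble `chrom`, `start`, `end`, `value` of tiled
#'   windows (500 bp by convention).
#' @param min_value threshold on the window value (strictly greater than;
#'   default 0, i.e. log2 RPM > 0).
#' @return The peaks that pass.
#' @export
filter_peaks_by_signal <- function(peaks, signal_track, min_value = 0) {
  if (nrow(peaks) == 0) return(peaks)
  keep_win <- signal_track |> filter(.data$value > min_value)
  if (nrow(keep_win) == 0) return(peaks[0, ])
  hits <- ov_find(gr_from_tbl(peaks), gr_from_tbl(keep_win))
  peaks[sort(unique(S4Vectors::queryHits(hits))), ]
}

#' Classify OSN-peak condition specificity
#'
#' A peak is shared when it overlaps (>= 1 bp) any OSN peak of the other
#' condition; otherwise condition-specific.
#'
#' @param osn_a,osn_b OSN peak tibbles for the two conditions.
#' @return List of the two tibbles, each with a `specificity` column
#'   (`shared`, `A_specific`/`B_specific`).
#' @export
classify_osn_specificity <- function(osn_a, osn_b) {
  lab <- function(x, other, specific) {
    if (nrow(x) == 0) {
      x$specificity <- character(0)
      return(x)
    }
    if (nrow(other) == 0) {
      x$specificity <- specific
      return(x)
    }
    hits <- ov_count(gr_from_tbl(x), gr_from_tbl(other))
    x$specificity <- if_else(hits > 0, "shared", specific)
    x
  }
  list(osn_a = lab(osn_a, osn_b, "A_specific"),
       osn_b = lab(osn_b, osn_a, "B_specific"))
}

#' Chromatin-state composition of peak sets
#'
#' Assigns each peak the chromatin state at its centre base (background when
#' the centre is uncovered) and tabulates the percentage of peaks per state
#' for each named set. Percentages sum to 100 within each set.
#'
#' @param peak_sets named list of peak tibbles (each with `chrom`, `start`,
#'   `end`; a `centre` column is used if present).
#' @param segmentation segmentation tibble for the matching condition.
#' @return Tibble `set`, `state`, `n`, `pct`.
#' @export
state_overlap_matrix <- function(peak_sets, segmentation) {
  purrr::imap(peak_sets, function(pk, nm) {
    if (nrow(pk) == 0) {
      return(tibble(set = character(), state = character(), n = integer()))
    }
    centre <- if ("centre" %in% names(pk)) pk$centre
              else floor((pk$start + pk$end) / 2)
    st <- state_at_point(segmentation, pk$chrom, centre)
    tibble(set = nm, state = st) |> count(.data$set, .data$state, name = "n")
  }) |>
    bind_rows() |>
    group_by(.data$set) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    ungroup()
}

#' State at single base positions
#'
#' @param segmentation segmentation tibble.
#' @param chrom,pos vectors of chromosome and 0-based position.
#' @return Character vector of states; uncovered positions are `background`.
#' @export
state_at_point <- function(segmentation, chrom, pos) {
  q <- tibble(chrom = as.character(chrom), start = as.integer(pos),
              end = as.integer(pos) + 1L)
  hit <- ov_find(gr_from_tbl(q), gr_from_tbl(segmentation),
                                     select = "first")
  st <- segmentation$state[hit]
  st[is.na(st)] <- "background"
  st
}

#' Sample random control regions
#'
#' Uniform, seed-reproducible sampling of fixed-width windows over the
#' genome (chromosome chosen proportional to length), optionally avoiding
#' an exclusion set by rejection sampling.
#'
#' @param genome tibble `chrom`, `length`.
#' @param n number of regions (default 10000).
#' @param width region width in bp (default 1200, the approximate average
#'   peak size).
#' @param seed RNG seed.
#' @param exclude optional interval tibble the samples must not overlap.
#' @return Tibble `region_id`, `chrom`, `start`, `end`, `centre`.
#' @export
sample_control_regions <- function(genome, n = 10000L, width = 1200L,
                                   seed = 1L, exclude = NULL) {
  if (sum(genome$length) < n * width) {
    abort("genome too short for the requested control set")
  }
  if (any(genome$length < width)) {
    abort("chromosome shorter than the control-region width")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  draw <- function(k) {
    ci <- sample.int(nrow(genome), k, replace = TRUE,
                     prob = genome$length - width + 1)
    start <- floor(runif(k) * (genome$length[ci] - width + 1))
    tibble(chrom = genome$chrom[ci], start = as.integer(start),
           end = as.integer(start) + as.integer(width))
  }
  out <- draw(n)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    for (iter in 1:50) {
      bad <- ov_count(gr_from_tbl(out),
                                          gr_from_tbl(exclude)) > 0
      if (!any(bad)) break
      out[bad, c("chrom", "start", "end")] <- draw(sum(bad))
    }
  }
  out |>
    mutate(region_id = sprintf("ctrl_%d", row_number()),
           centre = floor((.data$start + .data$end) / 2)) |>
    select("region_id", "chrom", "start", "end", "centre")
}

#' OSN-change x interaction-change association
#'
#' Cross-tabulates per-fragment OSN occupancy change (`lost`, `gained`,
#' `retained`, `never`) against interaction change (`lost`, `gained`,
#' `retained`) and, for every cell, collapses the table to 2x2
#' (this row x this column vs the rest) to compute an odds ratio, its log2,
#' and a chi-squared p-value (Fisher's exact test is substituted whenever
#' an expected cell is below 5, and noted in the `test` column). A 0.5
#' continuity correction is applied to the OR when any cell is 0 (flagged).
#'
#' @param changes tibble with columns `fragment_id`, `osn_change`,
#'   `interaction_change`.
#' @return List with `matrix` (counts + row-wise percentages) and `tests`
#'   (one row per OSN/interaction class pair).
#' @export
osn_interaction_contingency <- function(changes) {
  osn_levels <- c("lost", "gained", "retained", "never")
  int_levels <- c("lost", "gained", "retained")
  changes <- changes |>
    mutate(osn_change = factor(.data$osn_change, levels = osn_levels),
           interaction_change = factor(.data$interaction_change,
                                       levels = int_levels))
  counts <- table(changes$osn_change, changes$interaction_change)
  mat <- as_tibble(counts, .name_repair = "minimal")
  names(mat) <- c("osn_change", "interaction_change", "n")
  mat <- mat |>
    group_by(.data$osn_change) |>
    mutate(row_pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n)
           else rep(NA_real_, dplyr::n())) |>
    ungroup()
  tests <- purrr::map(osn_levels, function(oc) {
    purrr::map(int_levels, function(ic) {
      a <- sum(counts[oc, ic])
      b <- sum(counts[oc, ]) - a
      cc <- sum(counts[, ic]) - a
      d <- sum(counts) - a - b - cc
      res <- fisher_or_chisq(matrix(c(a, b, cc, d), 2, byrow = TRUE))
      res$osn_change <- oc
      res$interaction_change <- ic
      res
    }) |> bind_rows()
  }) |> bind_rows()
  list(matrix = mat,
       tests = tests |> relocate("osn_change", "interaction_change"))
}

#' Derive per-fragment OSN and interaction change classes
#'
#' Fragment-granularity classes for the contingency analysis: a fragment's
#' OSN change compares overlap with condition-A vs condition-B OSN peaks
#' (`never` = no OSN in either), and its interaction change summarises the
#' specificity of its incident edges (`lost` when it has A-supported but no
#' B-supported edges, `gained` for the converse, `retained` otherwise).
#'
#' @param fragments tibble of enhancer-bearing fragments (`fragment_id`,
#'   `chrom`, `start`, `end`).
#' @param osn_a,osn_b OSN peak tibbles per condition.
#' @param net `canvas_network`.
#' @return Tibble `fragment_id`, `osn_change`, `interaction_change`.
#' @export
classify_fragment_changes <- function(fragments, osn_a, osn_b, net) {
  ov <- function(osn) {
    if (nrow(osn) == 0) return(rep(FALSE, nrow(fragments)))
    ov_count(gr_from_tbl(fragments), gr_from_tbl(osn)) > 0
  }
  in_a <- ov(osn_a)
  in_b <- ov(osn_b)
  osn_change <- dplyr::case_when(
    in_a & in_b ~ "retained",
    in_a & !in_b ~ "lost",
    !in_a & in_b ~ "gained",
    TRUE ~ "never"
  )
  inc <- bind_rows(
    net$edges |> select(fragment_id = "node1", "specificity"),
    net$edges |> select(fragment_id = "node2", "specificity")
  ) |>
    group_by(.data$fragment_id) |>
    summarise(
      has_a = any(edge_supported(.data$specificity, "A")),
      has_b = any(edge_supported(.data$specificity, "B")),
      .groups = "drop"
    )
  fragments |>
    mutate(osn_change = osn_change) |>
    left_join(inc, by = "fragment_id") |>
    mutate(
      has_a = dplyr::coalesce(.data$has_a, FALSE),
      has_b = dplyr::coalesce(.data$has_b, FALSE),
      interaction_change = dplyr::case_when(
        .data$has_a & !.data$has_b ~ "lost",
        !.data$has_a & .data$has_b ~ "gained",
        TRUE ~ "retained"
      )
    ) |>
    select("fragment_id", "osn_change", "interaction_change")
}
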