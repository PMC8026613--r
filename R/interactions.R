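#' Read significant promoter-interaction calls
#'
#' Reads CHiCAGO-style significant-interaction calls in either of two text
#' dialects and resolves both anchors against the fragment map by exact
#' coordinate match (see [match_fragments_exact()]):
#'
#' * **ibed**: tab-separated with header `bait_chr, bait_start, bait_end,
#'   bait_name, otherEnd_chr, otherEnd_start, otherEnd_end, otherEnd_name,
#'   N_reads, score`.
#' * **washU**: three tab-separated fields `chr:start-end  chr:start-end
#'   score` (no header, no read counts).
#'
#' Duplicate rows for the same unordered fragment pair keep the maximum score
#' and sum read counts (logged as a message).
#'
#' @param path input file (gzip accepted).
#' @param frags fragment map tibble.
#' @param condition condition label attached to every call.
#' @param format `"auto"` (header sniffing), `"ibed"` or `"washU"`.
#' @param on_unmapped `"skip"` drops rows whose anchors match no fragment
#'   (with a warning reporting the count); `"error"` aborts.
#' @param tolerance bp tolerance for anchor matching (default 0 = exact).
#' @return Tibble of interaction calls: `bait_id`, `other_id`, `score`,
#'   `read_count`, `condition`.
#' @export
read_interactions <- function(path, frags, condition,
                              format = c("auto", "ibed", "washU"),
                              on_unmapped = c("skip", "error"),
                              tolerance = 0L) {
  format <- match.arg(format)
  on_unmapped <- match.arg(on_unmapped)
  con <- open_text(path)
  first <- readLines(con, n = 1)
  close(con)
  if (format == "auto") {
    format <- if (grepl("bait_chr", first)) "ibed" else "washU"
  }
  if (format == "ibed") {
    x <- read_delim_closed(path, header = TRUE, check.names = FALSE)
    calls <- tibble(
      bait_chrom = as.character(x$bait_chr),
      bait_start = as.integer(x$bait_start),
      bait_end = as.integer(x$bait_end),
      oe_chrom = as.character(x$otherEnd_chr),
      oe_start = as.integer(x$otherEnd_start),
      oe_end = as.integer(x$otherEnd_end),
      score = as.numeric(x$score),
      read_count = as.integer(x$N_reads)
    )
  } else {
    raw <- read_bedlike(path, min_cols = 3)
    a1 <- parse_anchor(raw[[1]])
    a2 <- parse_anchor(raw[[2]])
    calls <- tibble(
      bait_chrom = a1$chrom, bait_start = a1$start, bait_end = a1$end,
      oe_chrom = a2$chrom, oe_start = a2$start, oe_end = a2$end,
      score = as.numeric(raw[[3]]),
      read_count = NA_integer_
    )
  }
  if (any(is.na(calls$score) | calls$score < 0)) {
    abort(sprintf("negative or unparseable score at row %s of %s",
                  which(is.na(calls$score) | calls$score < 0)[1], path))
  }
  calls$bait_id <- match_fragments_exact(
    frags, tibble(chrom = calls$bait_chrom, start = calls$bait_start,
                  end = calls$bait_end), tolerance)
  calls$other_id <- match_fragments_exact(
    frags, tibble(chrom = calls$oe_chrom, start = calls$oe_start,
                  end = calls$oe_end), tolerance)
  unmapped <- is.na(calls$bait_id) | is.na(calls$other_id)
  if (any(unmapped)) {
    if (on_unmapped == "error") {
      abort(sprintf("%d interaction row(s) in %s match no fragment (first at row %d)",
                    sum(unmapped), path, which(unmapped)[1]))
    }
    warn(sprintf("skipped %d interaction row(s) in %s with unmappable anchors",
                 sum(unmapped), path))
    calls <- calls[!unmapped, ]
  }
  calls <- calls |> filter(.data$bait_id != .data$other_id)
  out <- calls |>
    mutate(
      pair_lo = pmin(.data$bait_id, .data$other_id),
      pair_hi = pmax(.data$bait_id, .data$other_id)
    ) |>
    group_by(.data$pair_lo, .data$pair_hi) |>
    summarise(
      bait_id = first(.data$bait_id),
      other_id = first(.data$other_id),
      score = max(.data$score),
      read_count = if (all(is.na(.data$read_count))) NA_integer_
                   else sum(.data$read_count, na.rm = TRUE),
      n_dup = n(),
      .groups = "drop"
    )
  ndup <- sum(out$n_dup > 1)
  if (ndup > 0) {
    inform(sprintf("%d duplicated fragment pair(s) collapsed (max score, summed reads)",
                   ndup))
  }
  out |>
    mutate(condition = condition) |>
    select("bait_id", "other_id", "score", "read_count", "condition")
}

#' @noRd
parse_anchor <- function(s) {
  m <- stringr::str_match(s, "^(.+):([0-9]+)-([0-9]+)$")
  if (anyNA(m[, 1])) {
    abort(sprintf("unparseable anchor '%s'", s[which(is.na(m[, 1]))[1]]))
  }
  list(chrom = m[, 2], start = as.integer(m[, 3]), end = as.integer(m[, 4]))
}

#' Assign promoters (baits) to fragments
#'
#' The promoter region of a gene is the 1 kb window upstream of its TSS
#' (strand-relative): `[tss - window, tss)` on the + strand and
#' `[tss + 1, tss + window + 1)` on the - strand, clipped at position 0.
#' A gene is annotated to every fragment its promoter overlaps, so promoters
#' spanning a fragment boundary annotate both fragments.
#'
#' @param tss tibble with columns `gene`, `chrom`, `tss` (0-based position)
#'   and `strand` (`"+"`, `"-"`; anything else is treated as `+` with a
#'   warning). May also be a path to a TSV file with those columns.
#' @param frags fragment map tibble.
#' @param window promoter window in bp upstream of the TSS (default 1000).
#' @return Bait annotation tibble: `fragment_id`, `gene`.
#' @export
read_promoters <- function(tss, frags, window = 1000L) {
  if (is.character(tss) && length(tss) == 1) {
    tss <- as_tibble(read_delim_closed(tss))
  }
  tss <- as_tibble(tss)
  unk <- !(tss$strand %in% c("+", "-"))
  if (any(unk)) {
    warn(sprintf("%d TSS row(s) without strand treated as '+'", sum(unk)))
    tss$strand[unk] <- "+"
  }
  prom <- tss |>
    mutate(
      start = if_else(.data$strand == "+",
                      pmax(0L, as.integer(.data$tss) - as.integer(window)),
                      as.integer(.data$tss) + 1L),
      end = if_else(.data$strand == "+",
                    as.integer(.data$tss),
                    as.integer(.data$tss) + as.integer(window) + 1L)
    ) |>
    filter(.data$start < .data$end)
  hits <- ov_find(gr_from_tbl(prom), gr_from_tbl(frags))
  tibble(
    fragment_id = frags$fragment_id[S4Vectors::subjectHits(hits)],
    gene = prom$gene[S4Vectors::queryHits(hits)]
  ) |>
    distinct() |>
    arrange(.data$fragment_id, .data$gene)
}
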