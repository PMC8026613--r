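# Shared constructors for in-code fixtures.

# A tiled fragment map: `sizes` are fragment widths per chromosome.
make_frags <- function(sizes_by_chrom) {
  purrr::imap(sizes_by_chrom, function(sizes, ch) {
    ends <- cumsum(sizes)
    starts <- c(0L, ends[-length(ends)])
    tibble::tibble(chrom = ch, start = as.integer(starts),
                   end = as.integer(ends))
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(fragment_id = sprintf("%s:%d-%d", chrom, start, end)) |>
    dplyr::select(fragment_id, chrom, start, end)
}

# Interaction calls straight from fragment ids.
make_calls <- function(frags, pairs, scores, condition,
                       read_count = 10L) {
  tibble::tibble(
    bait_id = frags$fragment_id[pairs[, 1]],
    other_id = frags$fragment_id[pairs[, 2]],
    score = scores,
    read_count = rep_len(read_count, nrow(pairs)),
    condition = condition
  )
}

# Merged network from explicit per-condition score vectors over id pairs.
make_network <- function(frags, pairs, score_a, score_b, ...) {
  ca <- make_calls(frags, pairs[!is.na(score_a), , drop = FALSE],
                   score_a[!is.na(score_a)], "A")
  cb <- make_calls(frags, pairs[!is.na(score_b), , drop = FALSE],
                   score_b[!is.na(score_b)], "B")
  build_merged_network(ca, cb, frags, ...)
}

# Cached default synthetic study (built once per test run).
default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_fixture(seed = 7)
    cache
  }
})

default_network <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- default_fixture()$data
      cache <<- build_merged_network(d$calls_A, d$calls_B, d$frags)
    }
    cache
  }
})
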