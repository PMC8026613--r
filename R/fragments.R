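# Coordinate convention (used by every function in the package):
# all intervals are 0-based, half-open [start, end), i.e. BED-native.
# washU "chr:start-end" anchors are treated as 0-based half-open too.
# GRanges conversion (1-based closed) happens only inside gr_from_tbl()/
# tbl_from_gr(); no other code shifts coordinates.

#' Convert an interval tibble to GRanges (internal)
#'
#' @param x tibble with chrom/start/end columns (0-based half-open).
#' @noRd
gr_from_tbl <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Overlap helpers that first harmonise sequence levels (internal)
#' @noRd
ov_find <- function(q, s, ...) {
  lv <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(s))
  GenomeInfoDb::seqlevels(q) <- lv
  GenomeInfoDb::seqlevels(s) <- lv
  GenomicRanges::findOverlaps(q, s, ...)
}

#' @noRd
ov_count <- function(q, s, ...) {
  lv <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(s))
  GenomeInfoDb::seqlevels(q) <- lv
  GenomeInfoDb::seqlevels(s) <- lv
  GenomicRanges::countOverlaps(q, s, ...)
}

#' @noRd
tbl_from_gr <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Read a restriction-fragment map from a BED file
#'
#' The fragment map is the node universe of the interaction network: a genome
#' partition into restriction fragments (e.g. a HindIII digest, ~4 kb average
#' fragment size). Fragments must tile each chromosome without overlaps.
#'
#' @param path BED3 or BED4 file (optionally gzip-compressed). When a name
#'   column is present it is used as the fragment id; otherwise ids are
#'   assigned as `"chrom:start-end"`.
#' @return A tibble with columns `fragment_id`, `chrom`, `start`, `end`,
#'   sorted by chromosome and start, validated to be non-overlapping.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t0\t4000", "chr1\t4000\t9000"), tf)
#' read_fragment_map(tf)
read_fragment_map <- function(path) {
  raw <- read_bedlike(path, min_cols = 3)
  frags <- tibble(
    chrom = raw[[1]],
    start = suppressWarnings(as.integer(raw[[2]])),
    end = suppressWarnings(as.integer(raw[[3]])),
    fragment_id = if (ncol(raw) >= 4) as.character(raw[[4]]) else NA_character_,
    line = seq_len(nrow(raw))
  )
  bad <- which(is.na(frags$start) | is.na(frags$end) | frags$start < 0 |
                 frags$start >= frags$end)
  if (length(bad) > 0) {
    abort(sprintf("malformed coordinates at line(s) %s of %s",
                  paste(utils::head(bad, 5), collapse = ", "), path))
  }
  frags <- frags |>
    mutate(fragment_id = if_else(
      is.na(.data$fragment_id) | .data$fragment_id == ".",
      sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end),
      .data$fragment_id
    ))
  validate_fragment_map(frags)
  frags |>
    arrange(.data$chrom, .data$start) |>
    select("fragment_id", "chrom", "start", "end")
}

#' Validate a fragment map
#'
#' Checks the fragment-map invariants: per chromosome, fragments sorted by
#' start must be non-overlapping; fragment ids must be unique.
#'
#' @param frags tibble with `fragment_id`, `chrom`, `start`, `end` (a `line`
#'   column, if present, is used to report offending input lines).
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_fragment_map <- function(frags) {
  dup <- frags$fragment_id[duplicated(frags$fragment_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate fragment_id: %s", paste(unique(dup), collapse = ", ")))
  }
  ord <- frags |> arrange(.data$chrom, .data$start)
  same <- ord$chrom[-1] == ord$chrom[-nrow(ord)]
  if (nrow(ord) > 1) {
    ov <- which(same & ord$start[-1] < ord$end[-nrow(ord)])
    if (length(ov) > 0) {
      i <- ov[1] + 1L
      where <- if ("line" %in% names(ord)) sprintf(" (input line %d)", ord$line[i]) else ""
      abort(sprintf("overlap at %s:%d%s", ord$chrom[i], ord$start[i], where))
    }
  }
  invisible(frags)
}

#' Write a fragment map to BED4
#'
#' @param frags fragment map tibble.
#' @param path output path (gzip if it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_fragment_map <- function(frags, path) {
  write_tsv_plain(
    frags |> select("chrom", "start", "end", "fragment_id") |>
      arrange(.data$chrom, .data$start),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Map base positions to fragments
#'
#' Point-to-fragment lookup is total over the covered genome: every base of a
#' tiled chromosome belongs to exactly one fragment.
#'
#' @param frags fragment map tibble.
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @return Character vector of fragment ids (`NA` for uncovered positions).
#' @export
lookup_fragment <- function(frags, chrom, pos) {
  q <- tibble(chrom = as.character(chrom), start = as.integer(pos),
              end = as.integer(pos) + 1L)
  hits <- ov_find(gr_from_tbl(q), gr_from_tbl(frags),
                                      select = "first")
  frags$fragment_id[hits]
}

#' Match intervals to fragments by exact coordinates
#'
#' Interaction anchors in promoter-capture Hi-C calls are fragment-resolved,
#' so anchors are matched to the fragment map by exact start/end equality.
#' A small tolerance (in bp) accommodates off-by-one dialects; silent
#' nearest-fragment snapping is deliberately not offered because it can
#' corrupt edges.
#'
#' @param frags fragment map tibble.
#' @param x tibble with `chrom`, `start`, `end`.
#' @param tolerance maximum absolute deviation allowed on each of start and
#'   end (default 0 = exact).
#' @return Character vector of fragment ids, `NA` where no fragment matches.
#' @export
match_fragments_exact <- function(frags, x, tolerance = 0L) {
  key <- paste(frags$chrom, frags$start, frags$end)
  idx <- match(paste(x$chrom, x$start, x$end), key)
  if (tolerance > 0L && anyNA(idx)) {
    miss <- which(is.na(idx))
    hits <- ov_find(gr_from_tbl(x[miss, ]), gr_from_tbl(frags))
    for (k in unique(S4Vectors::queryHits(hits))) {
      cand <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == k]
      i <- miss[k]
      ok <- cand[abs(frags$start[cand] - x$start[i]) <= tolerance &
                   abs(frags$end[cand] - x$end[i]) <= tolerance]
      if (length(ok) >= 1) idx[i] <- ok[1]
    }
  }
  frags$fragment_id[idx]
}

# -- low-level text helpers (gzip-aware) --------------------------------------

#' @noRd
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' @noRd
read_delim_closed <- function(path, ...) {
  con <- open_text(path)
  on.exit(close(con))
  utils::read.delim(con, stringsAsFactors = FALSE, ...)
}

#' @noRd
read_bedlike <- function(path, min_cols = 3, comment = "#") {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!startsWith(lines, comment) & nzchar(lines) &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) {
    return(tibble(V1 = character(), V2 = character(), V3 = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < min_cols)) {
    abort(sprintf("line %d of %s has fewer than %d tab-separated fields",
                  which(ncols < min_cols)[1], path, min_cols))
  }
  nc <- min(ncols)
  as_tibble(setNames(
    lapply(seq_len(nc), function(j) vapply(parts, `[[`, character(1), j)),
    paste0("V", seq_len(nc))
  ))
}

#' @noRd
write_tsv_plain <- function(x, path, col_names = TRUE) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col_names)
}
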