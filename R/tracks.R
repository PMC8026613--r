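# Readers for annotation tracks consumed by the network analyses:
# ChromHMM-style segmentations, signal peaks, binned signal tracks,
# CpG methylation calls, TAD calls and differential-expression tables.

#' Reduced chromatin state labels
#'
#' The seven reduced states used to annotate fragments, plus the derived
#' `mixed` label produced when a fragment overlaps several distinct states.
#' @export
chromatin_states <- function() {
  c("active", "h3k4me1_only", "bivalent", "polycomb", "heterochromatin",
    "unclassified", "background")
}

#' Read a chromatin-state segmentation (BED4)
#'
#' @param path BED4 file; the name column carries the state label.
#' @param condition condition label.
#' @param states allowed state labels (any subset of the seven reduced
#'   states is accepted; unknown labels are rejected by name).
#' @return Tibble `chrom`, `start`, `end`, `state`, `condition`, checked for
#'   within-chromosome non-overlap.
#' @export
read_segmentation <- function(path, condition, states = chromatin_states()) {
  raw <- read_bedlike(path, min_cols = 4)
  seg <- tibble(
    chrom = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    state = as.character(raw[[4]]),
    condition = condition
  )
  bad <- setdiff(unique(seg$state), states)
  if (length(bad) > 0) {
    abort(sprintf("unknown chromatin state label(s): %s",
                  paste(bad, collapse = ", ")))
  }
  ord <- seg |> arrange(.data$chrom, .data$start)
  if (nrow(ord) > 1) {
    same <- ord$chrom[-1] == ord$chrom[-nrow(ord)]
    if (any(same & ord$start[-1] < ord$end[-nrow(ord)])) {
      i <- which(same & ord$start[-1] < ord$end[-nrow(ord)])[1] + 1L
      abort(sprintf("overlapping segmentation intervals at %s:%d",
                    ord$chrom[i], ord$start[i]))
    }
  }
  ord
}

#' Read signal peaks (BED + signal column or narrowPeak)
#'
#' @param path BED file. narrowPeak (10 columns) uses `signalValue`
#'   (column 7); shorter BED uses the 5th column when numeric, otherwise
#'   signal is `NA`.
#' @param condition optional condition label.
#' @return Tibble `chrom`, `start`, `end`, `signal`(, `condition`).
#' @export
read_peaks <- function(path, condition = NULL) {
  raw <- read_bedlike(path, min_cols = 3)
  signal <- rep(NA_real_, nrow(raw))
  if (ncol(raw) >= 10) {
    signal <- suppressWarnings(as.numeric(raw[[7]]))
  } else if (ncol(raw) >= 5) {
    signal <- suppressWarnings(as.numeric(raw[[5]]))
  } else if (ncol(raw) >= 4) {
    s4 <- suppressWarnings(as.numeric(raw[[4]]))
    if (!anyNA(s4)) signal <- s4
  }
  out <- tibble(
    chrom = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    signal = signal
  ) |> arrange(.data$chrom, .data$start)
  if (!is.null(condition)) out$condition <- condition
  out
}

#' Read a binned signal track (bedGraph-like TSV)
#'
#' @param path TSV with columns chrom, start, end, value.
#' @return Tibble `chrom`, `start`, `end`, `value`.
#' @export
read_signal_track <- function(path) {
  raw <- read_bedlike(path, min_cols = 4)
  tibble(
    chrom = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    value = as.numeric(raw[[4]])
  )
}

#' Read per-CpG methylation calls
#'
#' @param path TSV with columns chrom, pos, meth_count, total_count.
#' @return Tibble `chrom`, `pos`, `meth_count`, `total_count`; rows with
#'   `meth_count > total_count` are rejected.
#' @export
read_methylation <- function(path) {
  raw <- read_bedlike(path, min_cols = 4)
  cpg <- tibble(
    chrom = raw[[1]],
    pos = as.integer(raw[[2]]),
    meth_count = as.integer(raw[[3]]),
    total_count = as.integer(raw[[4]])
  )
  bad <- which(cpg$meth_count > cpg$total_count | cpg$meth_count < 0)
  if (length(bad) > 0) {
    abort(sprintf("methylated calls exceed total at row %d of %s", bad[1], path))
  }
  cpg
}

#' Read a differential-expression table
#'
#' @param path TSV with columns gene, log2fc, padj (extra columns kept).
#' @return Tibble with at least `gene`, `log2fc`, `padj`.
#' @export
read_expression_table <- function(path) {
  x <- as_tibble(read_delim_closed(path))
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(x)))
  x
}

#' Write intervals as BED
#'
#' @param x tibble with `chrom`, `start`, `end` and optional extra columns
#'   appended after the name column.
#' @param path output path.
#' @param name optional column to use as BED name.
#' @param extra character vector of extra columns to append.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, name = NULL, extra = character()) {
  out <- x |> select("chrom", "start", "end")
  out$name <- if (!is.null(name)) as.character(x[[name]]) else "."
  for (e in extra) out[[e]] <- x[[e]]
  write_tsv_plain(out |> arrange(.data$chrom, .data$start), path,
                  col_names = FALSE)
  invisible(path)
}
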