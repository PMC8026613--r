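# Seeded generator of a miniature two-condition promoter-interaction study.
#
# The bundle emulates the statistical structure of a naive/primed
# comparison: a genome of restriction fragments, per-condition CHiCAGO-like
# interaction calls with planted communities and condition-B long-range
# bridges, chromatin-state segmentations with bivalent bridge anchors,
# H3K27ac peaks with planted super-enhancers wired to target genes,
# OCT4/SOX2/NANOG peaks whose occupancy changes are coupled to interaction
# changes at a known rate, expression, methylation and TAD tracks. The
# ground-truth manifest suffices to recompute every planted statistic.

#' Default generator parameters
#'
#' The study conditions of the synthetic fixture: 2 chromosomes x 20 Mb at
#' 4-kb fragment resolution, 60 bait fragments carrying 200 genes, 8
#' planted communities of 10-25 nodes (intra-community edge probability
#' 0.5, inter 0.02), 15 condition-B-specific bridges spanning more than
#' 1 Mb of which 80% have bivalent chromatin at both anchors (the rest have
#' one mixed anchor), 12 super-enhancers among typical enhancers, and 500
#' enhancer fragments whose OSN occupancy change is coupled to interaction
#' change at rate `osn_coupling`. Significant CHiCAGO scores are simulated
#' as 5 + Exponential(mean 4); sub-threshold support scores as
#' Uniform(3, 5).
#'
#' @return Named list of parameters.
#' @export
fixture_params <- function() {
  list(
    chrom_sizes = c(chr1 = 2e7, chr2 = 2e7),
    fragment_size = 4000L,
    n_genes = 200L,
    n_communities = 8L,
    community_size_range = c(10L, 25L),
    p_intra = 0.5,
    p_inter = 0.02,
    n_bridges = 15L,
    bridge_bivalent_fraction = 0.8,
    n_super_enhancers = 12L,
    n_enhancers = 20L,
    n_osn_fragments = 500L,
    osn_coupling = 0.9,
    expression_shift = 1.5,
    score_exp_mean = 4,
    null = FALSE
  )
}

#' @noRd
sim_sig_score <- function(n, mean = 4) 5 + rexp(n, rate = 1 / mean)

#' Generate the synthetic two-condition study
#'
#' @param seed integer seed; the whole bundle is a deterministic function of
#'   it and `params`.
#' @param params parameter list from [fixture_params()] (fields may be
#'   overridden).
#' @param dir optional directory; when given, the bundle is written as the
#'   plain-text files every reader in the package accepts, plus
#'   `manifest.json`.
#' @return List with `data` (in-memory tibbles: `frags`, `genome`,
#'   `calls_A`, `calls_B`, `tss`, `baits`, `segmentation_A/B`, `peaks`
#'   (named list), `signal_A/B`, `expression`, `methylation_A/B`, `tads`)
#'   and `manifest` (planted ground truth), plus `files` when `dir` is set.
#' @export
generate_fixture <- function(seed = 7L, params = fixture_params(), dir = NULL) {
  p <- utils::modifyList(fixture_params(), params)
  sizes <- p$community_size_range
  if (p$n_communities * sizes[2] > sum(p$chrom_sizes) / p$fragment_size / 10) {
    abort("infeasible parameters: communities exceed the available fragments")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  fs <- p$fragment_size
  genome <- tibble(chrom = names(p$chrom_sizes),
                   length = unname(p$chrom_sizes))
  frags <- purrr::map2(genome$chrom, genome$length, function(ch, len) {
    starts <- seq(0L, len - fs, by = fs)
    tibble(chrom = ch, start = starts, end = starts + fs)
  }) |>
    bind_rows() |>
    mutate(fragment_id = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end)) |>
    select("fragment_id", "chrom", "start", "end")
  fid <- function(ch, idx) sprintf("%s:%d-%d", ch, idx * fs, (idx + 1L) * fs)

  ## --- planted communities (chr1, fragments from index 100) ----------------
  comm_sizes <- sample(seq(sizes[1], sizes[2]), p$n_communities, replace = TRUE)
  comm_members <- list()
  cursor <- 100L
  for (k in seq_len(p$n_communities)) {
    comm_members[[k]] <- fid("chr1", cursor + seq_len(comm_sizes[k]) - 1L)
    cursor <- cursor + comm_sizes[k] + 2L
  }
  membership <- tibble(
    fragment_id = unlist(comm_members),
    community = rep(seq_len(p$n_communities), comm_sizes)
  )
  edges <- list()
  add_edge <- function(n1, n2, sA, sB) {
    edges[[length(edges) + 1]] <<- tibble(
      node1 = pmin(n1, n2), node2 = pmax(n1, n2),
      score_A = sA, score_B = sB)
  }
  for (k in seq_len(p$n_communities)) {
    m <- comm_members[[k]]
    pairs <- utils::combn(m, 2)
    keep <- runif(ncol(pairs)) < p$p_intra
    # guarantee connectivity with a spanning path
    chain <- cbind(m[-length(m)], m[-1])
    sel <- unique(rbind(t(pairs[, keep, drop = FALSE]), chain))
    ne <- nrow(sel)
    supp <- runif(ne) < 0.3
    sA <- sim_sig_score(ne, p$score_exp_mean)
    sB <- ifelse(supp, runif(ne, 3, 5), sim_sig_score(ne, p$score_exp_mean))
    add_edge(sel[, 1], sel[, 2], sA, sB)
  }
  for (k1 in seq_len(p$n_communities - 1)) {
    for (k2 in seq(k1 + 1, p$n_communities)) {
      pairs <- expand.grid(comm_members[[k1]], comm_members[[k2]],
                           stringsAsFactors = FALSE)
      keep <- runif(nrow(pairs)) < p$p_inter
      if (any(keep)) {
        ne <- sum(keep)
        add_edge(pairs[keep, 1], pairs[keep, 2],
                 sim_sig_score(ne, p$score_exp_mean),
                 sim_sig_score(ne, p$score_exp_mean))
      }
    }
  }

  ## --- condition-B long-range bridges (chr1, > 1 Mb) -----------------------
  anchor1 <- 600L + (seq_len(p$n_bridges) - 1L) * 40L
  anchor2 <- 2000L + (seq_len(p$n_bridges) - 1L) * 100L
  bridge <- tibble(
    bait = fid("chr1", anchor1),
    other = fid("chr1", anchor2),
    bivalent_both = seq_len(p$n_bridges) <=
      round(p$bridge_bivalent_fraction * p$n_bridges)
  )
  if (p$null) {
    # exchangeable conditions: bridges split evenly between A and B
    in_b <- rep(c(TRUE, FALSE), length.out = p$n_bridges)
    add_edge(bridge$bait, bridge$other,
             ifelse(in_b, NA_real_, sim_sig_score(p$n_bridges)),
             ifelse(in_b, sim_sig_score(p$n_bridges), NA_real_))
  } else {
    add_edge(bridge$bait, bridge$other, NA_real_,
             sim_sig_score(p$n_bridges, p$score_exp_mean))
  }

  ## --- super-enhancers and typical enhancers (chr2) ------------------------
  n_se <- p$n_super_enhancers
  se_fragidx <- 100L + (seq_len(n_se) - 1L) * 10L
  se_baitidx <- se_fragidx + 150L   # disjoint from the element grid
  se_class <- rep(c("A_only", "B_only", "shared"), length.out = n_se)
  if (p$null) se_class <- rep("shared", n_se)
  se <- tibble(
    se_fragment = fid("chr2", se_fragidx),
    bait_fragment = fid("chr2", se_baitidx),
    gene = sprintf("SEG%02d", seq_len(n_se)),
    class = se_class,
    peak_start = se_fragidx * fs + 500L
  )
  n_en <- p$n_enhancers
  en_fragidx <- 400L + (seq_len(n_en) - 1L) * 5L
  en_baitidx <- 600L + (seq_len(n_en) - 1L) * 5L
  en_class <- rep(c("A_only", "B_only", "shared"), length.out = n_en)
  if (p$null) en_class <- rep("shared", n_en)
  en <- tibble(
    en_fragment = fid("chr2", en_fragidx),
    bait_fragment = fid("chr2", en_baitidx),
    gene = sprintf("ENG%02d", seq_len(n_en)),
    class = en_class,
    peak_start = en_fragidx * fs + 800L
  )
  class_scores <- function(cls) {
    n <- length(cls)
    sA <- ifelse(cls %in% c("A_only", "shared"), sim_sig_score(n), NA_real_)
    sB <- ifelse(cls %in% c("B_only", "shared"), sim_sig_score(n), NA_real_)
    list(sA = sA, sB = sB)
  }
  cs <- class_scores(se$class)
  add_edge(se$se_fragment, se$bait_fragment, cs$sA, cs$sB)
  ce <- class_scores(en$class)
  add_edge(en$en_fragment, en$bait_fragment, ce$sA, ce$sB)
  # a gene contacted by an SE in A and by a typical enhancer in B: wire the
  # first A_only SE target to an extra enhancer through a B-supported edge
  extra_en_fragidx <- 165L
  fig4e_gene <- se$gene[se$class == "A_only"][1]
  if (!is.na(fig4e_gene)) {
    extra_bait <- se$bait_fragment[se$gene == fig4e_gene]
    add_edge(fid("chr2", extra_en_fragidx), extra_bait, NA_real_, sim_sig_score(1))
  }

  ## --- OSN fragments with planted occupancy/interaction coupling -----------
  n_osn <- p$n_osn_fragments
  osn_fragidx <- 1500L + (seq_len(n_osn) - 1L) * 4L
  osn_block <- (seq_len(n_osn) - 1L) %/% 50L
  osn_baitidx <- 1500L + osn_block * 200L + 1L
  osn_states <- sample(c("lost", "gained", "retained", "never"), n_osn,
                       replace = TRUE, prob = c(0.35, 0.1, 0.35, 0.2))
  rho <- p$osn_coupling
  int_change <- vapply(osn_states, function(s) {
    if (p$null) {
      sample(c("lost", "gained", "retained"), 1, prob = c(0.3, 0.3, 0.4))
    } else {
      switch(s,
        lost = if (runif(1) < rho) "lost" else "retained",
        gained = if (runif(1) < rho) "gained" else "retained",
        retained = if (runif(1) < rho) "retained"
                   else sample(c("lost", "gained"), 1),
        never = sample(c("lost", "gained", "retained"), 1,
                       prob = c(0.1, 0.1, 0.8))
      )
    }
  }, character(1))
  osn <- tibble(
    fragment_id = fid("chr2", osn_fragidx),
    bait_fragment = fid("chr2", osn_baitidx),
    gene = sprintf("OSNG%02d", osn_block + 1L),
    osn_change = unname(osn_states),
    interaction_change = unname(int_change),
    fragidx = osn_fragidx
  )
  add_edge(osn$fragment_id, osn$bait_fragment,
           ifelse(osn$interaction_change %in% c("lost", "retained"),
                  sim_sig_score(n_osn), NA_real_),
           ifelse(osn$interaction_change %in% c("gained", "retained"),
                  sim_sig_score(n_osn), NA_real_))

  ## --- genes, baits, expression --------------------------------------------
  comm_bait <- vapply(comm_members, `[`, character(1), 1)
  misc_baitidx <- 4600L + (0:4) * 3L
  misc_bait <- fid("chr2", misc_baitidx)
  gene_tbl <- bind_rows(
    tibble(gene = sprintf("COMG%02d", seq_len(p$n_communities)),
           fragment_id = comm_bait, role = "community"),
    tibble(gene = sprintf("BRG%02d", seq_len(p$n_bridges)),
           fragment_id = bridge$bait, role = "bridge"),
    tibble(gene = se$gene, fragment_id = se$bait_fragment, role = "se_target",
           class = se$class),
    tibble(gene = en$gene, fragment_id = en$bait_fragment, role = "en_target",
           class = en$class),
    tibble(gene = unique(osn$gene),
           fragment_id = osn$bait_fragment[!duplicated(osn$gene)],
           role = "osn_bait"),
    tibble(gene = c("MIXU1", "MIXD1", "UPG1", "DNG1", "NCG1"),
           fragment_id = misc_bait[c(1, 1, 2, 3, 4)], role = "misc")
  )
  n_extra <- p$n_genes - nrow(gene_tbl)
  if (n_extra > 0) {
    extra_idx <- 4700L + seq_len(n_extra) * 2L
    gene_tbl <- bind_rows(gene_tbl,
      tibble(gene = sprintf("BGG%03d", seq_len(n_extra)),
             fragment_id = fid("chr2", extra_idx), role = "background"))
  }
  frag_start <- setNames(frags$start, frags$fragment_id)
  tss <- gene_tbl |>
    mutate(
      chrom = sub(":.*", "", .data$fragment_id),
      strand = rep(c("+", "-"), length.out = n()),
      tss = unname(frag_start[.data$fragment_id]) +
        if_else(.data$strand == "+", 1500L, 500L)
    ) |>
    select("gene", "chrom", "tss", "strand")
  shift <- p$expression_shift
  expr <- gene_tbl |>
    mutate(
      base = rnorm(n(), mean = 2, sd = 1),
      up_A = !p$null & .data$role %in% c("se_target", "en_target") &
        dplyr::coalesce(.data$class, "") %in% c("A_only", "shared"),
      up_B = !p$null & ((.data$role %in% c("se_target", "en_target") &
        dplyr::coalesce(.data$class, "") %in% c("B_only", "shared")) |
        .data$gene %in% c("MIXU1", "UPG1")),
      down_B = !p$null & .data$gene %in% c("MIXD1", "DNG1"),
      value_A = .data$base + if_else(.data$up_A, shift, 0),
      value_B = .data$base + if_else(.data$up_B, shift, 0) -
        if_else(.data$down_B, shift, 0),
      log2fc = .data$value_B - .data$value_A + rnorm(n(), 0, 0.05),
      padj = if_else(.data$up_B != .data$up_A | .data$down_B,
                     10^runif(n(), -8, -3), runif(n(), 0.1, 1))
    ) |>
    select("gene", "value_A", "value_B", "log2fc", "padj")

  ## --- segmentations --------------------------------------------------------
  seg_interval <- function(ids, state) {
    k <- match(ids, frags$fragment_id)
    tibble(chrom = frags$chrom[k], start = frags$start[k],
           end = frags$end[k], state = state)
  }
  active_ids <- unique(c(membership$fragment_id, se$se_fragment,
                         en$en_fragment, osn$fragment_id,
                         se$bait_fragment, en$bait_fragment))
  seg_a <- bind_rows(
    seg_interval(active_ids, "active"),
    seg_interval(c(bridge$bait, bridge$other), "active")
  ) |> arrange(.data$chrom, .data$start) |> mutate(condition = "A")
  mixed_other <- bridge$other[!bridge$bivalent_both]
  biv_ids <- c(bridge$bait, bridge$other[bridge$bivalent_both])
  mix_k <- match(mixed_other, frags$fragment_id)
  seg_b <- bind_rows(
    seg_interval(active_ids, "active"),
    seg_interval(biv_ids, "bivalent"),
    # mixed anchors: a Polycomb block with an active patch inside
    tibble(chrom = frags$chrom[mix_k], start = frags$start[mix_k],
           end = frags$start[mix_k] + 2000L, state = "polycomb"),
    tibble(chrom = frags$chrom[mix_k], start = frags$start[mix_k] + 2000L,
           end = frags$start[mix_k] + 2500L, state = "active"),
    tibble(chrom = frags$chrom[mix_k], start = frags$start[mix_k] + 2500L,
           end = frags$end[mix_k], state = "polycomb")
  ) |> arrange(.data$chrom, .data$start) |> mutate(condition = "B")
  if (p$null) seg_b <- seg_a |> mutate(condition = "B")

  ## --- H3K27ac peaks (constituents of SEs and enhancers) -------------------
  k27_peaks <- bind_rows(
    purrr::map(seq_len(n_se), function(i) {
      s <- se$peak_start[i]
      tibble(chrom = "chr2",
             start = s + c(0L, 1100L, 2200L),
             end = s + c(800L, 1900L, 3000L),
             signal = round(runif(3, 18, 30), 2))
    }) |> bind_rows(),
    tibble(chrom = "chr2", start = en$peak_start,
           end = en$peak_start + 900L,
           signal = round(runif(n_en, 1, 5), 2)),
    tibble(chrom = "chr2", start = extra_en_fragidx * fs + 800L,
           end = extra_en_fragidx * fs + 1700L,
           signal = round(runif(1, 1, 5), 2))
  ) |> arrange(.data$chrom, .data$start)

  ## --- OSN factor peaks and binned signal ----------------------------------
  osn_present <- function(cond) {
    if (cond == "A") osn$osn_change %in% c("lost", "retained")
    else osn$osn_change %in% c("gained", "retained")
  }
  factor_peaks <- function(cond, off1, off2) {
    mid <- osn$fragidx[osn_present(cond)] * fs + 2000L
    tibble(chrom = "chr2", start = mid - off1, end = mid + off2,
           signal = round(runif(length(mid), 2, 8), 2))
  }
  peaks <- list(
    oct4_A = factor_peaks("A", 200L, 200L),
    sox2_A = factor_peaks("A", 150L, 250L),
    nanog_A = factor_peaks("A", 100L, 300L),
    oct4_B = factor_peaks("B", 200L, 200L),
    sox2_B = factor_peaks("B", 150L, 250L),
    nanog_B = factor_peaks("B", 100L, 300L),
    h3k27ac_A = k27_peaks,
    h3k27ac_B = k27_peaks
  )
  # weak decoy peaks whose 500-bp signal windows stay below log2 RPM 0
  decoy <- tibble(chrom = "chr2",
                  start = (4800L + (0:4) * 2L) * fs + 100L,
                  end = (4800L + (0:4) * 2L) * fs + 900L,
                  signal = round(runif(5, 1, 2), 2))
  for (f in c("oct4", "sox2", "nanog")) {
    peaks[[paste0(f, "_A")]] <- bind_rows(peaks[[paste0(f, "_A")]], decoy) |>
      arrange(.data$chrom, .data$start)
  }
  signal_windows <- function(cond) {
    mid <- osn$fragidx[osn_present(cond)] * fs + 2000L
    win0 <- (mid %/% 500L) * 500L
    good <- tibble(chrom = "chr2", start = win0, end = win0 + 500L,
                   value = round(runif(length(win0), 0.5, 2), 3))
    bad <- tibble(chrom = "chr2", start = (decoy$start %/% 500L) * 500L,
                  end = (decoy$start %/% 500L) * 500L + 500L,
                  value = round(runif(5, -2, -0.5), 3))
    bind_rows(good, bad) |> distinct(.data$chrom, .data$start, .keep_all = TRUE) |>
      arrange(.data$start)
  }
  signal_a <- signal_windows("A")
  signal_b <- signal_windows("B")

  ## --- methylation and TADs -------------------------------------------------
  meth_for <- function(high) {
    purrr::map2(seq_len(n_se), high, function(i, hi) {
      s <- se$peak_start[i]
      pos <- s + seq(100L, 2900L, by = 400L)
      total <- rbinom(length(pos), 20, 0.8) + 5L
      meth <- rbinom(length(pos), total, if (hi) 0.8 else 0.1)
      tibble(chrom = "chr2", pos = pos, meth_count = meth, total_count = total)
    }) |> bind_rows()
  }
  meth_a <- meth_for(rep(FALSE, n_se))
  meth_b <- meth_for(if (p$null) rep(FALSE, n_se) else se$class == "A_only")
  tads <- purrr::map(comm_members, function(m) {
    k <- match(m, frags$fragment_id)
    tibble(chrom = "chr1", start = min(frags$start[k]), end = max(frags$end[k]))
  }) |> bind_rows()

  ## --- assemble calls -------------------------------------------------------
  edge_tbl <- bind_rows(edges) |>
    distinct(.data$node1, .data$node2, .keep_all = TRUE)
  to_calls <- function(score_col, cond) {
    edge_tbl |>
      filter(!is.na(.data[[score_col]])) |>
      transmute(bait_id = .data$node1, other_id = .data$node2,
                score = .data[[score_col]],
                read_count = 5L + stats::rpois(n(), 40), condition = cond)
  }
  calls_a <- to_calls("score_A", "A")
  calls_b <- to_calls("score_B", "B")
  baits <- gene_tbl |> select("fragment_id", "gene")

  manifest <- list(
    seed = seed, params = p,
    genome = genome,
    community_membership = membership,
    community_sizes = comm_sizes,
    bridges = bridge,
    bivalent_anchor_fraction =
      round(p$bridge_bivalent_fraction * p$n_bridges) / p$n_bridges,
    se_targets = se |> select("gene", "class", "se_fragment", "bait_fragment"),
    enhancer_targets = en |> select("gene", "class", "en_fragment",
                                    "bait_fragment"),
    fig4e_gene = fig4e_gene,
    osn_changes = osn |> select("fragment_id", "osn_change",
                                "interaction_change"),
    osn_coupling = rho,
    expression_shift = shift
  )
  data <- list(
    frags = frags, genome = genome,
    calls_A = calls_a, calls_B = calls_b,
    tss = tss, baits = baits,
    segmentation_A = seg_a, segmentation_B = seg_b,
    peaks = peaks, signal_A = signal_a, signal_B = signal_b,
    expression = expr, methylation_A = meth_a, methylation_B = meth_b,
    tads = tads
  )
  out <- list(data = data, manifest = manifest)
  if (!is.null(dir)) out$files <- write_fixture_bundle(out, dir)
  out
}

#' Generate a null fixture with no planted structure
#'
#' Conditions are statistically exchangeable: bridges are split evenly
#' between conditions, all elements are shared, expression carries no
#' shift, and OSN occupancy change is independent of interaction change.
#'
#' @inheritParams generate_fixture
#' @export
generate_null_fixture <- function(seed = 7L, params = fixture_params(),
                                  dir = NULL) {
  params$null <- TRUE
  generate_fixture(seed = seed, params = params, dir = dir)
}

#' Write the fixture bundle to disk
#'
#' @param fixture result of [generate_fixture()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_fixture_bundle <- function(fixture, dir) {
  d <- fixture$data
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(name) file.path(dir, name)
  files <- c(fragments = fp("fragments.bed"))
  write_fragment_map(d$frags, files[["fragments"]])
  coords <- setNames(
    lapply(seq_len(nrow(d$frags)), function(i) d$frags[i, ]),
    d$frags$fragment_id)
  write_ibed <- function(calls, path) {
    k1 <- match(calls$bait_id, d$frags$fragment_id)
    k2 <- match(calls$other_id, d$frags$fragment_id)
    write_tsv_plain(tibble(
      bait_chr = d$frags$chrom[k1], bait_start = d$frags$start[k1],
      bait_end = d$frags$end[k1], bait_name = calls$bait_id,
      otherEnd_chr = d$frags$chrom[k2], otherEnd_start = d$frags$start[k2],
      otherEnd_end = d$frags$end[k2], otherEnd_name = calls$other_id,
      N_reads = calls$read_count, score = calls$score
    ), path)
    path
  }
  files[["interactions_A"]] <- write_ibed(d$calls_A, fp("interactions_A.ibed"))
  files[["interactions_B"]] <- write_ibed(d$calls_B, fp("interactions_B.ibed"))
  files[["promoters"]] <- fp("promoters.tsv")
  write_tsv_plain(d$tss, files[["promoters"]])
  for (cond in c("A", "B")) {
    nm <- paste0("segmentation_", cond)
    files[[nm]] <- fp(paste0(nm, ".bed"))
    write_bed(d[[nm]], files[[nm]], name = "state")
  }
  for (nm in names(d$peaks)) {
    files[[nm]] <- fp(paste0(nm, ".bed"))
    pk <- d$peaks[[nm]] |> mutate(name = ".", score5 = .data$signal)
    write_tsv_plain(pk |> select("chrom", "start", "end", "name", "score5"),
                    files[[nm]], col_names = FALSE)
  }
  for (cond in c("A", "B")) {
    nm <- paste0("signal_", cond)
    files[[nm]] <- fp(paste0("osn_", nm, ".bedgraph"))
    write_tsv_plain(d[[nm]], files[[nm]], col_names = FALSE)
    nm2 <- paste0("methylation_", cond)
    files[[nm2]] <- fp(paste0(nm2, ".tsv"))
    write_tsv_plain(d[[nm2]], files[[nm2]], col_names = FALSE)
  }
  files[["tads"]] <- fp("tads.bed")
  write_tsv_plain(d$tads, files[["tads"]], col_names = FALSE)
  files[["expression"]] <- fp("expression.tsv")
  write_tsv_plain(d$expression |> mutate(
    value_A = round(.data$value_A, 6), value_B = round(.data$value_B, 6),
    log2fc = round(.data$log2fc, 6), padj = signif(.data$padj, 6)),
    files[["expression"]])
  files[["manifest"]] <- fp("manifest.json")
  jsonlite::write_json(fixture$manifest, files[["manifest"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files
}
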