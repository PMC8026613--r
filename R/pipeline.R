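# Pipeline orchestration: build -> annotate -> census/communities ->
# long-range state profiles -> SE calling -> targets -> OSN -> stats ->
# layouts, each stage skippable, every output stamped with version, config
# hash and seeds.

#' Read or normalise a pipeline configuration
#'
#' @param config a YAML file path or a named list. Recognised fields:
#'   `inputs` (paths: fragments, interactions_A/B, promoters,
#'   segmentation_A/B, h3k27ac_A/B, oct4/sox2/nanog_A/B, tads, expression),
#'   `thresholds` (sig, support, modularity, stitch, osn_merge, log2fc),
#'   `seed`, `out_dir`, `skip` (character vector of stage names),
#'   `conditions` (labels, default A/B), `top_n` (longest-edge count).
#' @return Normalised config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    thresholds = list(sig = 5, support = 3, modularity = 0.7,
                      stitch = 1500, osn_merge = 100, log2fc = 1),
    seed = 1L, skip = character(), conditions = c(A = "A", B = "B"),
    top_n = 1000L
  )
  cfg <- utils::modifyList(defaults, config)
  cfg$thresholds <- utils::modifyList(defaults$thresholds,
                                      config$thresholds %||% list())
  cfg
}

#' @noRd
config_hash <- function(cfg) rlang::hash(cfg[setdiff(names(cfg), "out_dir")])

#' @noRd
stamp_lines <- function(cfg) {
  c(sprintf("# canvasnet %s",
            as.character(utils::packageVersion("canvasnet"))),
    sprintf("# config_hash %s", config_hash(cfg)),
    sprintf("# seed %d", cfg$seed))
}

#' @noRd
write_stamped_tsv <- function(x, path, cfg) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(stamp_lines(cfg), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the staged analysis over a configuration of input paths (or an
#' in-memory fixture), writing census, community, state-profile,
#' element/target, OSN and layout outputs into `out_dir`. Stages listed in
#' `config$skip` are skipped; a stage whose prerequisite was skipped aborts
#' with a stage-labelled message.
#'
#' @param config see [read_run_config()].
#' @param fixture optional result of [generate_fixture()]; when supplied its
#'   in-memory tables stand in for the `inputs` paths.
#' @return Invisibly, a list with the main in-memory results (`network`,
#'   `census`, `communities`, `se`, `targets`, `osn`, `contingency`,
#'   `files`).
#' @export
run_pipeline <- function(config, fixture = NULL) {
  cfg <- read_run_config(config)
  out_dir <- cfg$out_dir %||% abort("config must name an out_dir")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  skip <- cfg$skip
  th <- cfg$thresholds
  need <- function(stage, value, from) {
    if (is.null(value)) {
      abort(sprintf("stage '%s' requires output of skipped stage '%s'",
                    stage, from))
    }
    value
  }
  res <- list(files = character())
  addfile <- function(nm, path) res$files[[nm]] <<- path

  ## inputs
  if (!is.null(fixture)) {
    d <- fixture$data
    frags <- d$frags
    calls_a <- d$calls_A
    calls_b <- d$calls_B
    baits <- d$baits
    seg_a <- d$segmentation_A
    seg_b <- d$segmentation_B
    k27_a <- d$peaks$h3k27ac_A
    k27_b <- d$peaks$h3k27ac_B
    osn_in <- lapply(c(oct4_A = "oct4_A", sox2_A = "sox2_A", nanog_A = "nanog_A",
                       oct4_B = "oct4_B", sox2_B = "sox2_B", nanog_B = "nanog_B"),
                     function(nm) d$peaks[[nm]])
    sig_a <- d$signal_A
    sig_b <- d$signal_B
    tads <- d$tads
    genome <- d$genome
  } else {
    inp <- cfg$inputs %||% abort("config must provide inputs or a fixture")
    frags <- read_fragment_map(need("build", inp$fragments, "inputs"))
    calls_a <- read_interactions(inp$interactions_A, frags,
                                 cfg$conditions[["A"]])
    calls_b <- read_interactions(inp$interactions_B, frags,
                                 cfg$conditions[["B"]])
    baits <- read_promoters(inp$promoters, frags)
    seg_a <- if (!is.null(inp$segmentation_A))
      read_segmentation(inp$segmentation_A, cfg$conditions[["A"]])
    seg_b <- if (!is.null(inp$segmentation_B))
      read_segmentation(inp$segmentation_B, cfg$conditions[["B"]])
    k27_a <- if (!is.null(inp$h3k27ac_A)) read_peaks(inp$h3k27ac_A)
    k27_b <- if (!is.null(inp$h3k27ac_B)) read_peaks(inp$h3k27ac_B)
    osn_in <- lapply(c(oct4_A = "oct4_A", sox2_A = "sox2_A",
                       nanog_A = "nanog_A", oct4_B = "oct4_B",
                       sox2_B = "sox2_B", nanog_B = "nanog_B"),
                     function(nm) if (!is.null(inp[[nm]])) read_peaks(inp[[nm]]))
    sig_a <- if (!is.null(inp$signal_A)) read_signal_track(inp$signal_A)
    sig_b <- if (!is.null(inp$signal_B)) read_signal_track(inp$signal_B)
    tads <- if (!is.null(inp$tads)) read_peaks(inp$tads)
    genome <- if (!is.null(inp$genome)) {
      g <- utils::read.delim(inp$genome, header = FALSE)
      tibble(chrom = g[[1]], length = as.numeric(g[[2]]))
    }
  }

  ## build
  net <- NULL
  if (!"build" %in% skip) {
    net <- build_merged_network(calls_a, calls_b, frags,
                                sig_threshold = th$sig,
                                support_threshold = th$support)
    res$network <- net
    addfile("network_gexf", file.path(out_dir, "network.gexf"))
    write_network_export(net, res$files[["network_gexf"]], format = "gexf")
  }

  ## annotate
  states_a <- states_b <- NULL
  if (!"annotate" %in% skip && !is.null(seg_a) && !is.null(seg_b)) {
    states_a <- assign_fragment_states(seg_a, frags)
    states_b <- assign_fragment_states(seg_b, frags)
    res$states <- list(A = states_a, B = states_b)
  }

  ## census + communities
  if (!"census" %in% skip) {
    netx <- need("census", net, "build")
    comps <- network_components(netx)
    res$components <- comps
    res$census <- subnetwork_census(netx, comps)
    addfile("census", file.path(out_dir, "census.tsv"))
    write_stamped_tsv(res$census, res$files[["census"]], cfg)
    comm <- detect_communities(netx, modularity_threshold = th$modularity,
                               seed = cfg$seed, components = comps)
    res$communities <- comm
    addfile("communities", file.path(out_dir, "communities.tsv"))
    write_stamped_tsv(comm, res$files[["communities"]], cfg)
  }

  ## long-range state profiles
  if (!"longrange" %in% skip && !is.null(states_b)) {
    netx <- need("longrange", net, "build")
    prof <- longest_interaction_state_profile(netx, "B", states_b, baits,
                                              n = cfg$top_n)
    res$longrange_profile <- prof
    addfile("longrange", file.path(out_dir, "longrange_state_profile.tsv"))
    write_stamped_tsv(prof$profile, res$files[["longrange"]], cfg)
    res$transition <- state_transition_matrix(
      need("longrange", states_a, "annotate"), states_b)
    addfile("transition", file.path(out_dir, "state_transitions.tsv"))
    write_stamped_tsv(res$transition, res$files[["transition"]], cfg)
  }

  ## SE calling
  se_a <- se_b <- NULL
  if (!"se" %in% skip && !is.null(k27_a) && !is.null(k27_b)) {
    se_a <- call_super_enhancers(stitch_peaks(k27_a, th$stitch), "A")
    se_b <- call_super_enhancers(stitch_peaks(k27_b, th$stitch), "B")
    res$se <- list(A = se_a, B = se_b)
    addfile("elements_A", file.path(out_dir, "elements_A.tsv"))
    addfile("elements_B", file.path(out_dir, "elements_B.tsv"))
    write_stamped_tsv(se_a, res$files[["elements_A"]], cfg)
    write_stamped_tsv(se_b, res$files[["elements_B"]], cfg)
  }

  ## targets
  if (!"targets" %in% skip) {
    netx <- need("targets", net, "build")
    se_ax <- need("targets", se_a, "se")
    t_se_a <- map_elements_to_targets(se_ax |> filter(.data$is_super),
                                      netx, baits, "A", frags)
    t_se_b <- map_elements_to_targets(se_b |> filter(.data$is_super),
                                      netx, baits, "B", frags)
    t_en_a <- map_elements_to_targets(se_ax |> filter(!.data$is_super),
                                      netx, baits, "A", frags)
    t_en_b <- map_elements_to_targets(se_b |> filter(!.data$is_super),
                                      netx, baits, "B", frags)
    se_classes <- classify_target_genes(t_se_a, t_se_b)
    en_classes <- classify_target_genes(t_en_a, t_en_b,
                                        se_targets = se_classes$gene)
    res$targets <- list(se = se_classes, enhancer = en_classes,
                        se_contacts = bind_rows(t_se_a, t_se_b),
                        enhancer_contacts = bind_rows(t_en_a, t_en_b))
    addfile("se_targets", file.path(out_dir, "se_target_genes.tsv"))
    write_stamped_tsv(se_classes, res$files[["se_targets"]], cfg)
    addfile("enhancer_targets", file.path(out_dir, "enhancer_target_genes.tsv"))
    write_stamped_tsv(en_classes, res$files[["enhancer_targets"]], cfg)
  }

  ## OSN
  if (!"osn" %in% skip && !is.null(osn_in$oct4_A)) {
    netx <- need("osn", net, "build")
    filt <- function(pk, sig) {
      if (is.null(sig)) pk else filter_peaks_by_signal(pk, sig)
    }
    osn_a <- build_osn_peaks(filt(osn_in$oct4_A, sig_a),
                             filt(osn_in$sox2_A, sig_a),
                             filt(osn_in$nanog_A, sig_a),
                             merge_distance = th$osn_merge, condition = "A")
    osn_b <- build_osn_peaks(filt(osn_in$oct4_B, sig_b),
                             filt(osn_in$sox2_B, sig_b),
                             filt(osn_in$nanog_B, sig_b),
                             merge_distance = th$osn_merge, condition = "B")
    res$osn <- classify_osn_specificity(osn_a, osn_b)
    enh_frag_ids <- sort(unique(c(
      lookup_fragment(frags, osn_a$chrom, osn_a$centre),
      lookup_fragment(frags, osn_b$chrom, osn_b$centre))))
    enh_frags <- frags |> filter(.data$fragment_id %in% enh_frag_ids)
    changes <- classify_fragment_changes(enh_frags, osn_a, osn_b, netx)
    res$contingency <- osn_interaction_contingency(changes)
    addfile("contingency", file.path(out_dir, "osn_contingency.tsv"))
    write_stamped_tsv(res$contingency$tests, res$files[["contingency"]], cfg)
  }

  ## stats: community/TAD overlap
  if (!"stats" %in% skip && !is.null(tads) && !is.null(genome) &&
      !is.null(res$communities)) {
    assign <- community_assignment(res$communities)
    cl_regions <- assign |>
      left_join(frags, by = "fragment_id") |>
      group_by(.data$cluster) |>
      summarise(chrom = first(.data$chrom), start = min(.data$start),
                end = max(.data$end), .groups = "drop") |>
      filter(!is.na(.data$chrom))
    res$tad_overlap <- permutation_overlap_test(
      cl_regions |> select("chrom", "start", "end"),
      tads |> select("chrom", "start", "end"),
      genome, n_perm = 200L, seed = cfg$seed)
    addfile("tad_overlap", file.path(out_dir, "tad_overlap.tsv"))
    write_stamped_tsv(res$tad_overlap, res$files[["tad_overlap"]], cfg)
  }

  ## layouts
  if (!"layout" %in% skip && !is.null(net)) {
    lay <- layout_force_directed(net, iterations = 150L, seed = cfg$seed)
    res$layout <- lay
    addfile("layout", file.path(out_dir, "layout.tsv"))
    write_layout(lay, res$files[["layout"]])
  }

  invisible(res)
}
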