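# Deterministic network layouts: a simplified ForceAtlas2-style
# force-directed layout and a metric MDS embedding of genomic distances
# with Kruskal stress-1.

#' Force-directed layout (simplified ForceAtlas2)
#'
#' Iterative layout with linear attraction along edges, degree-weighted
#' pairwise repulsion and central gravity, with an adaptive global step
#' that shrinks when total displacement oscillates. Fully deterministic
#' given the seed (which controls only the initial positions). Repulsion is
#' computed exactly over all node pairs in vectorised form.
#'
#' @param net `canvas_network`, or an igraph graph with vertex names.
#' @param iterations maximum iterations (default 300, must be > 0).
#' @param seed RNG seed for the initial placement.
#' @param repulsion,gravity scaling constants of the repulsive and gravity
#'   forces (defaults 10 and 1).
#' @param edge_weight_influence exponent applied to edge weights in the
#'   attraction term (default 0 = unweighted).
#' @param tolerance convergence threshold on mean displacement per node
#'   (default 1e-4).
#' @return A `canvas_layout`: tibble `node`, `x`, `y` with attributes
#'   `algorithm`, `params`, `seed`, `iterations`.
#' @export
layout_force_directed <- function(net, iterations = 300L, seed = 1L,
                                  repulsion = 10, gravity = 1,
                                  edge_weight_influence = 0,
                                  tolerance = 1e-4) {
  if (iterations <= 0) abort("iterations must be positive")
  g <- if (inherits(net, "igraph")) net else as_igraph_network(net)
  nv <- igraph::vcount(g)
  if (nv == 0) abort("network is empty")
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- rep(1, nrow(el))
  if (edge_weight_influence != 0 && !is.null(igraph::E(g)$weight)) {
    w <- igraph::E(g)$weight^edge_weight_influence
  }
  deg <- igraph::degree(g)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  pos <- matrix(runif(2 * nv, -1, 1), ncol = 2)
  step <- 0.1
  used_iter <- 0L
  for (it in seq_len(iterations)) {
    used_iter <- it
    disp <- matrix(0, nv, 2)
    # repulsion: k_r * (deg_i+1)(deg_j+1) / d, exact over all pairs
    dx <- outer(pos[, 1], pos[, 1], `-`)
    dy <- outer(pos[, 2], pos[, 2], `-`)
    d2 <- dx^2 + dy^2
    diag(d2) <- Inf
    d2[d2 < 1e-8] <- 1e-8
    dw <- outer(deg + 1, deg + 1)
    f <- repulsion * dw / d2
    disp[, 1] <- rowSums(f * dx)
    disp[, 2] <- rowSums(f * dy)
    # attraction: linear in distance along edges
    if (nrow(el) > 0) {
      vx <- pos[el[, 2], 1] - pos[el[, 1], 1]
      vy <- pos[el[, 2], 2] - pos[el[, 1], 2]
      ax <- w * vx
      ay <- w * vy
      for (k in seq_len(nrow(el))) {
        i <- el[k, 1]; j <- el[k, 2]
        disp[i, 1] <- disp[i, 1] + ax[k]
        disp[i, 2] <- disp[i, 2] + ay[k]
        disp[j, 1] <- disp[j, 1] - ax[k]
        disp[j, 2] <- disp[j, 2] - ay[k]
      }
    }
    # gravity toward the origin, proportional to degree mass
    disp <- disp - gravity * (deg + 1) * pos
    norm <- sqrt(rowSums(disp^2))
    norm[norm < 1e-12] <- 1e-12
    limited <- pmin(norm, 10)
    pos <- pos + step * disp / norm * limited
    mean_disp <- mean(step * limited)
    step <- step * 0.97
    if (mean_disp < tolerance) break
  }
  out <- tibble(node = igraph::V(g)$name, x = pos[, 1], y = pos[, 2])
  structure(out,
            class = c("canvas_layout", class(out)),
            algorithm = "force_directed",
            params = list(repulsion = repulsion, gravity = gravity,
                          edge_weight_influence = edge_weight_influence,
                          tolerance = tolerance),
            seed = seed, iterations = used_iter)
}

#' Kruskal stress-1 of a 2-D configuration
#'
#' `sqrt(sum((d - delta)^2) / sum(delta^2))` over all point pairs, where
#' `delta` are the target dissimilarities and `d` the layout distances.
#'
#' @param coords matrix/tibble with columns x, y.
#' @param delta dissimilarity matrix.
#' @return Numeric stress value (>= 0).
#' @export
kruskal_stress <- function(coords, delta) {
  xy <- as.matrix(coords[, c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  ut <- upper.tri(delta)
  sqrt(sum((d[ut] - delta[ut])^2) / sum(delta[ut]^2))
}

#' MDS layout from linear genomic distance
#'
#' Embeds a node set in 2-D so that layout distances approximate the linear
#' genomic distances between fragment midpoints, by classical scaling
#' followed by metric SMACOF stress majorisation. Trans pairs (different
#' chromosomes) are given the maximum observed cis distance and flagged.
#' Kruskal stress-1 is computed over all node pairs. Fewer than 3 nodes
#' are placed analytically with stress 0.
#'
#' @param frags fragment map tibble.
#' @param node_ids fragment ids to embed.
#' @param max_iter majorisation iterations (default 200).
#' @param tol relative stress-improvement tolerance (default 1e-10).
#' @return A `canvas_layout` tibble `node`, `x`, `y` with attributes
#'   `algorithm = "mds"`, `stress`, `n_trans_pairs`, `iterations`.
#' @export
layout_mds <- function(frags, node_ids, max_iter = 200L, tol = 1e-10) {
  k <- length(node_ids)
  i <- match(node_ids, frags$fragment_id)
  if (anyNA(i)) abort("unknown fragment id(s) in node set")
  mid <- (frags$start[i] + frags$end[i]) / 2
  chr <- frags$chrom[i]
  delta <- abs(outer(mid, mid, `-`))
  trans <- outer(chr, chr, `!=`)
  n_trans <- sum(trans[upper.tri(trans)])
  if (n_trans > 0) {
    max_cis <- max(delta[!trans & upper.tri(delta, diag = FALSE)], 0)
    delta[trans] <- max_cis
    warn(sprintf("%d trans pair(s) assigned the maximum cis distance", n_trans))
  }
  emb <- mds_embed(delta, max_iter = max_iter, tol = tol)
  out <- tibble(node = node_ids, x = emb$coords[, 1], y = emb$coords[, 2])
  structure(out,
            class = c("canvas_layout", class(out)),
            algorithm = "mds", stress = emb$stress, n_trans_pairs = n_trans,
            iterations = emb$iterations, seed = NA_integer_)
}

#' Metric 2-D MDS of a dissimilarity matrix
#'
#' Classical scaling initialisation followed by SMACOF stress majorisation
#' (Guttman transform); deterministic, no random restarts. Configurations
#' with fewer than 3 points are placed analytically with stress 0.
#'
#' @param delta symmetric non-negative dissimilarity matrix.
#' @param max_iter majorisation iterations (default 200).
#' @param tol relative raw-stress improvement tolerance (default 1e-10).
#' @return List with `coords` (n x 2 matrix), `stress` (Kruskal stress-1
#'   over all pairs) and `iterations`.
#' @export
mds_embed <- function(delta, max_iter = 200L, tol = 1e-10) {
  delta <- as.matrix(delta)
  k <- nrow(delta)
  if (k == 1) {
    coords <- matrix(0, 1, 2)
  } else if (k == 2) {
    coords <- rbind(c(0, 0), c(delta[1, 2], 0))
  } else {
    xy <- stats::cmdscale(stats::as.dist(delta), k = 2)
    if (ncol(xy) < 2) xy <- cbind(xy, 0)
    best <- sum((as.matrix(stats::dist(xy)) - delta)^2) / 2
    for (it in seq_len(max_iter)) {
      d <- as.matrix(stats::dist(xy))
      ratio <- ifelse(d > 1e-12, delta / d, 0)
      bmat <- -ratio
      diag(bmat) <- 0
      diag(bmat) <- -rowSums(bmat)
      xy_new <- bmat %*% xy / k
      sigma <- sum((as.matrix(stats::dist(xy_new)) - delta)^2) / 2
      if (best - sigma < tol * max(best, 1e-300)) {
        xy <- xy_new
        break
      }
      xy <- xy_new
      best <- sigma
    }
    coords <- xy
  }
  colnames(coords) <- c("x", "y")
  stress <- if (k < 3) 0 else
    kruskal_stress(tibble(x = coords[, 1], y = coords[, 2]), delta)
  list(coords = coords, stress = stress,
       iterations = if (k < 3) 0L else max_iter)
}

#' @exportS3Method generics::glance
glance.canvas_layout <- function(x, ...) {
  tibble(
    algorithm = attr(x, "algorithm"),
    n_nodes = nrow(x),
    stress = attr(x, "stress") %||% NA_real_,
    seed = attr(x, "seed") %||% NA_integer_,
    iterations = attr(x, "iterations") %||% NA_integer_
  )
}

#' Write layout coordinates as TSV
#'
#' @param layout `canvas_layout`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  write_tsv_plain(
    tibble(node = layout$node,
           x = sprintf("%.10g", layout$x),
           y = sprintf("%.10g", layout$y)),
    path
  )
  invisible(path)
}
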