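# Glomerular capillary network anatomy: construction, validation, I/O,
# summaries, and a parametric synthetic generator constrained to published
# morphometric statistics of the rat glomerulus (320 segments, 193 nodes,
# mean D 8.3 um, mean L 20.9 um, total surface area 1.76e5 um^2).

#' Construct a glomerular capillary network
#'
#' @param nodes data.frame with columns \code{id} (integer) and \code{kind}
#'   (one of \code{"interior"}, \code{"afferent_inlet"},
#'   \code{"efferent_outlet"}).
#' @param segments data.frame with columns \code{id}, \code{i}, \code{j}
#'   (endpoint node ids), \code{L_um}, \code{D_um}, and optionally
#'   \code{junction} (logical; merged-efferent junction stubs).
#' @param metadata free-form named list.
#' @param validate check invariants (connectivity, unique inlet/outlet,
#'   dangling endpoints).
#' @return an object of class \code{glom_network}.
#' @export
glom_network <- function(nodes, segments, metadata = list(), validate = TRUE) {
  nodes <- as.data.frame(nodes)
  segments <- as.data.frame(segments)
  if (is.null(segments$junction)) segments$junction <- FALSE
  net <- structure(list(nodes = nodes, segments = segments,
                        metadata = metadata),
                   class = "glom_network")
  if (validate) validate_network(net)
  net
}

validate_network <- function(net) {
  nd <- net$nodes; sg <- net$segments
  if (!all(c("id", "kind") %in% names(nd)))
    stop("nodes must have columns 'id' and 'kind'")
  need <- c("id", "i", "j", "L_um", "D_um")
  if (!all(need %in% names(sg)))
    stop("segments must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(nd$id)) stop("node ids are not unique")
  if (anyDuplicated(sg$id)) stop("segment ids are not unique")
  bad <- !nd$kind %in% c("interior", "afferent_inlet", "efferent_outlet")
  if (any(bad)) stop("unknown node kind: ", nd$kind[bad][1])
  if (sum(nd$kind == "afferent_inlet") != 1)
    stop("network must have exactly one afferent_inlet node")
  n_out <- sum(nd$kind == "efferent_outlet")
  if (n_out < 1) stop("network must have at least one efferent_outlet node")
  dangling <- setdiff(c(sg$i, sg$j), nd$id)
  if (length(dangling))
    stop("segment endpoint references missing node ", dangling[1])
  if (any(sg$i == sg$j)) stop("segment endpoints must differ (self-loop)")
  if (any(sg$L_um <= 0)) stop("segment lengths must be positive")
  if (any(sg$D_um <= 0)) stop("segment diameters must be positive")
  g <- as_igraph_net(net)
  if (!igraph::is_connected(g, mode = "weak"))
    stop("network is not connected")
  deg <- igraph::degree(g)
  term <- nd$id[nd$kind != "interior"]
  if (any(deg[match(as.character(term), igraph::V(g)$name)] < 1))
    stop("inlet/outlet must attach to at least one segment")
  invisible(net)
}

as_igraph_net <- function(net) {
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(net$segments$i),
                   to = as.character(net$segments$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes$id),
                          kind = net$nodes$kind))
}

inlet_id <- function(net) net$nodes$id[net$nodes$kind == "afferent_inlet"]
outlet_id <- function(net) net$nodes$id[net$nodes$kind == "efferent_outlet"]

#' @export
print.glom_network <- function(x, ...) {
  cat(sprintf("glomerular capillary network: %d nodes, %d segments\n",
              nrow(x$nodes), nrow(x$segments)))
  s <- summarize_network(x)
  cat(sprintf("  D [um]: mean %.2f (%.2f-%.2f); L [um]: mean %.2f (%.2f-%.2f)\n",
              s$d_mean, s$d_min, s$d_max, s$l_mean, s$l_min, s$l_max))
  cat(sprintf("  total surface area: %.4g um^2\n", s$total_surface_area))
  invisible(x)
}

#' Read a network document
#'
#' Accepts either a JSON file following the schema
#' \code{{"nodes": [...], "segments": [...], "metadata": {}}} or a character
#' vector of two CSV paths \code{c(nodes, segments)} with the same columns.
#' Networks with multiple efferent outlets are merged at a newly created
#' junction node (see \code{\link{merge_efferent_outlets}}).
#'
#' @param source path to a \code{.json} network document, or length-2 vector
#'   of CSV paths (nodes, segments).
#' @param merge_outlets join multiple efferent outlets at a created node.
#' @return a validated \code{\link{glom_network}}.
#' @export
load_network <- function(source, merge_outlets = TRUE) {
  if (length(source) == 2) {
    nodes <- utils::read.csv(source[1])
    segments <- utils::read.csv(source[2])
    meta <- list()
  } else {
    doc <- jsonlite::fromJSON(source, simplifyDataFrame = TRUE)
    if (is.null(doc$nodes) || is.null(doc$segments))
      stop("network document must contain 'nodes' and 'segments'")
    nodes <- doc$nodes
    segments <- doc$segments
    meta <- if (is.null(doc$metadata)) list() else doc$metadata
  }
  net <- glom_network(nodes, segments, meta, validate = FALSE)
  if (merge_outlets && sum(net$nodes$kind == "efferent_outlet") > 1)
    net <- merge_efferent_outlets(net)
  validate_network(net)
  net
}

#' Write a network document
#'
#' @param net a \code{\link{glom_network}}.
#' @param path output path; \code{.json}, or a length-2 vector of CSV paths.
#' @export
write_network <- function(net, path) {
  if (length(path) == 2) {
    utils::write.csv(net$nodes, path[1], row.names = FALSE)
    utils::write.csv(net$segments, path[2], row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(nodes = net$nodes, segments = net$segments,
           metadata = net$metadata),
      path, digits = I(17), auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Export a network to GraphML (for external visualisation)
#' @param net a \code{\link{glom_network}}.
#' @param path output \code{.graphml} path.
#' @export
write_network_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(
    d = cbind(data.frame(from = as.character(net$segments$i),
                         to = as.character(net$segments$j)),
              net$segments[c("id", "L_um", "D_um", "junction")]),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes$id),
                          kind = net$nodes$kind))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Join multiple efferent outlets at a created node
#'
#' When the anatomy reports more than one efferent vessel, they are joined at
#' a newly created node by short, wide junction stubs of negligible hydraulic
#' resistance (flagged \code{junction = TRUE} and excluded from anatomical
#' summaries and stress reports), leaving exactly one efferent outlet.
#'
#' @param net a \code{\link{glom_network}}.
#' @param junction_L_um,junction_D_um stub dimensions; the defaults give a
#'   resistance several orders of magnitude below any capillary segment.
#' @return a \code{\link{glom_network}} with a single efferent outlet.
#' @export
merge_efferent_outlets <- function(net, junction_L_um = 1, junction_D_um = 40) {
  outs <- net$nodes$id[net$nodes$kind == "efferent_outlet"]
  if (length(outs) == 0) stop("network has no efferent_outlet node")
  if (length(outs) == 1) return(net)
  new_id <- max(net$nodes$id) + 1L
  nodes <- net$nodes
  nodes$kind[nodes$id %in% outs] <- "interior"
  nodes <- rbind(nodes, data.frame(id = new_id, kind = "efferent_outlet"))
  stubs <- data.frame(id = max(net$segments$id) + seq_along(outs),
                      i = outs, j = new_id,
                      L_um = junction_L_um, D_um = junction_D_um,
                      junction = TRUE)
  segments <- rbind(net$segments[names(stubs)], stubs)
  glom_network(nodes, segments,
               c(net$metadata, list(merged_outlets = length(outs))))
}

#' Summarise a network's anatomy
#'
#' Counts and diameter/length moments, plus the total lateral surface area
#' \eqn{\sum \pi D L}. Junction stubs created by
#' \code{\link{merge_efferent_outlets}} (and the created junction node) are
#' excluded.
#'
#' @param net a \code{\link{glom_network}}.
#' @return a list of class \code{network_summary}.
#' @export
summarize_network <- function(net) {
  sg <- net$segments[!net$segments$junction, ]
  if (nrow(sg) == 0) stop("network has no (non-junction) segments")
  n_nodes <- nrow(net$nodes) -
    if (isTRUE(net$metadata$merged_outlets > 1)) 1L else 0L
  structure(list(
    n_segments = nrow(sg), n_nodes = n_nodes,
    d_mean = mean(sg$D_um), d_min = min(sg$D_um), d_max = max(sg$D_um),
    l_mean = mean(sg$L_um), l_min = min(sg$L_um), l_max = max(sg$L_um),
    total_surface_area = sum(pi * sg$D_um * sg$L_um)),
    class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(paste0("%d segments, %d nodes\n",
                     "D [um]: mean %.3f, range [%.2f, %.2f]\n",
                     "L [um]: mean %.3f, range [%.2f, %.2f]\n",
                     "total surface area: %.5g um^2\n"),
              x$n_segments, x$n_nodes, x$d_mean, x$d_min, x$d_max,
              x$l_mean, x$l_min, x$l_max, x$total_surface_area))
  invisible(x)
}

#' Parameters of the synthetic anatomy generator
#'
#' Targets and distributional assumptions for
#' \code{\link{generate_shea_like_network}}. The defaults reproduce the
#' published morphometric statistics of a perfusion-fixed rat glomerulus.
#' Diameters and lengths are drawn from truncated log-normal distributions
#' (right-skewed, matching the printed min/mean/max asymmetry).
#'
#' @param n_segments,n_nodes target counts.
#' @param d_mean,d_min,d_max diameter targets, um.
#' @param l_mean,l_min,l_max length targets, um.
#' @param total_area target total lateral surface area, um^2.
#' @param lobules number of parallel lobules fed by the afferent inlet.
#' @param anastomosis_frac fraction of segments that are cross-lobule
#'   anastomoses.
#' @param d_sdlog,l_sdlog log-normal shape parameters.
#' @return a list of class \code{generator_params}.
#' @export
generator_params <- function(n_segments = 320, n_nodes = 193,
                             d_mean = 8.3, d_min = 2, d_max = 21.3,
                             l_mean = 20.9, l_min = 2.5, l_max = 109,
                             total_area = 1.76e5,
                             lobules = 5, anastomosis_frac = 0.1,
                             d_sdlog = 0.32, l_sdlog = 0.6) {
  stopifnot(d_min < d_mean, d_mean < d_max, l_min < l_mean, l_mean < l_max,
            n_segments >= n_nodes - 1, lobules >= 1,
            anastomosis_frac >= 0, anastomosis_frac < 1)
  structure(as.list(environment()), class = "generator_params")
}

#' @rdname generator_params
#' @export
shea_params <- function() generator_params()

# run expr with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# truncated log-normal sample whose mean is matched exactly (multiplicative
# rescale with resampling of out-of-bounds values)
rtrunc_lnorm_mean <- function(n, mean, lo, hi, sdlog, max_retry = 200) {
  meanlog <- log(mean) - sdlog^2 / 2
  draw <- function(m) {
    x <- stats::rlnorm(m, meanlog, sdlog)
    while (any(bad <- x < lo | x > hi))
      x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
    x
  }
  x <- draw(n)
  for (it in seq_len(max_retry)) {
    x <- x * (mean / mean(x))
    bad <- x < lo | x > hi
    if (!any(bad)) {
      if (abs(mean(x) - mean) / mean < 1e-12) return(x)
    } else {
      x[bad] <- draw(sum(bad))
    }
  }
  stop("could not match target mean within bounds; widen [min, max] or reduce sdlog")
}

# lobule layer widths: expand 1,2,3 -> plateau of 4s -> contract 3,2,1
lobule_widths <- function(m) {
  if (m < 13) { # small lobules: simple diamond
    head <- c(1, 2); tail <- c(2, 1)
    mid <- m - 6
    w <- c(head, rep(3, mid %/% 3), if (mid %% 3) mid %% 3, tail)
    return(w[w > 0])
  }
  head <- c(1, 2, 3); tail <- c(3, 2, 1)
  mid <- m - 12
  w <- c(head, rep(4, mid %/% 4), if (mid %% 4) mid %% 4, tail)
  w[w > 0]
}

#' Generate a synthetic glomerular capillary network
#'
#' Builds a connected network with exactly the target segment and node
#' counts: a single afferent inlet feeds \code{lobules} parallel lobules,
#' each an expand-then-contract layered graph of bifurcations and
#' coalescences, converging on a single efferent outlet, with cross-lobule
#' anastomoses added at the configured fraction. Diameters and lengths are
#' drawn from truncated log-normal distributions and rescaled so the sample
#' means match the targets exactly; length-diameter pairing is then adjusted
#' (preserving both marginals) and lengths globally rescaled (well within
#' 0.5\%) so the total surface area \eqn{\sum \pi D L} matches its target to
#' machine precision. Deterministic for a fixed seed.
#'
#' @param params a \code{\link{generator_params}} object.
#' @param seed integer random seed.
#' @return a validated \code{\link{glom_network}}.
#' @export
generate_shea_like_network <- function(params = shea_params(), seed = 1) {
  stopifnot(inherits(params, "generator_params"))
  with_local_seed(seed, generate_impl(params, seed))
}

generate_impl <- function(p, seed) {
  n <- p$n_nodes
  inlet <- 1L; outlet <- n
  interior <- seq(2L, n - 1L)
  n_int <- length(interior)
  if (n_int < 2 * p$lobules) stop("infeasible counts: too few interior nodes")

  # --- partition interior nodes into lobules, assign layers -------------
  sizes <- rep(n_int %/% p$lobules, p$lobules)
  sizes[seq_len(n_int %% p$lobules)] <- sizes[seq_len(n_int %% p$lobules)] + 1L
  if (any(sizes < 6))
    stop("infeasible counts: each lobule needs at least 6 interior nodes")
  lob_nodes <- split(interior, rep(seq_len(p$lobules), sizes))

  edges <- list()
  add_edge <- function(a, b) edges[[length(edges) + 1L]] <<- c(a, b)
  deg <- integer(n) # degree ledger, cap interior at 4
  bump <- function(a, b) { deg[a] <<- deg[a] + 1L; deg[b] <<- deg[b] + 1L }

  layer_of <- integer(n)
  lob_of <- integer(n)
  for (l in seq_len(p$lobules)) {
    nodes_l <- lob_nodes[[l]]
    w <- lobule_widths(length(nodes_l))
    layers <- split(nodes_l, rep(seq_along(w), w))
    for (t in seq_along(layers)) {
      layer_of[layers[[t]]] <- t
      lob_of[layers[[t]]] <- l
    }
    # inlet feeds the lobule entry; exit drains to the outlet
    add_edge(inlet, layers[[1]][1]); bump(inlet, layers[[1]][1])
    add_edge(layers[[length(layers)]][1], outlet)
    bump(layers[[length(layers)]][1], outlet)
    # base inter-layer connections: every child has a parent, every parent
    # a child (cyclic pairing), giving max(|A|,|B|) edges per layer pair
    for (t in seq_len(length(layers) - 1)) {
      A <- layers[[t]]; B <- layers[[t + 1]]
      m <- max(length(A), length(B))
      for (q in seq_len(m)) {
        a <- A[(q - 1) %% length(A) + 1]
        b <- B[(q - 1) %% length(B) + 1]
        add_edge(a, b); bump(a, b)
      }
    }
  }

  existing <- new.env(hash = TRUE)
  key <- function(a, b) paste(min(a, b), max(a, b))
  for (e in edges) assign(key(e[1], e[2]), TRUE, envir = existing)
  has_edge <- function(a, b) !is.null(existing[[key(a, b)]])

  n_base <- length(edges)
  n_ana <- round(p$anastomosis_frac * p$n_segments)
  n_extra <- p$n_segments - n_base - n_ana
  if (n_extra < 0)
    stop("infeasible counts: base topology already exceeds the segment budget")

  # --- extra intra-lobule links (coalescence/bifurcation richness) ------
  depth_norm <- function(v) layer_of[v] / max(layer_of[lob_of == lob_of[v]])
  added <- 0L; tries <- 0L
  while (added < n_extra && tries < 50000L) {
    tries <- tries + 1L
    a <- sample(interior, 1)
    cand <- interior[lob_of[interior] == lob_of[a] &
                       layer_of[interior] == layer_of[a] + 1L]
    cand <- cand[deg[cand] < 4L]
    if (deg[a] >= 4L || !length(cand)) next
    b <- if (length(cand) == 1) cand else sample(cand, 1)
    if (has_edge(a, b)) next
    add_edge(a, b); bump(a, b)
    assign(key(a, b), TRUE, envir = existing)
    added <- added + 1L
  }
  if (added < n_extra)
    stop("could not place all intra-lobule segments under the degree cap")

  # --- cross-lobule anastomoses at matching relative depth --------------
  added <- 0L; tries <- 0L
  while (added < n_ana && tries < 50000L) {
    tries <- tries + 1L
    a <- sample(interior, 1)
    if (deg[a] >= 4L) next
    cand <- interior[lob_of[interior] != lob_of[a] & deg[interior] < 4L]
    cand <- cand[abs(vapply(cand, depth_norm, 1) - depth_norm(a)) < 0.2]
    if (!length(cand)) next
    b <- if (length(cand) == 1) cand else sample(cand, 1)
    if (has_edge(a, b)) next
    add_edge(a, b); bump(a, b)
    assign(key(a, b), TRUE, envir = existing)
    added <- added + 1L
  }
  if (added < n_ana)
    stop("could not place all anastomoses under the degree cap")

  em <- do.call(rbind, edges)
  stopifnot(nrow(em) == p$n_segments)

  # --- dimensions: truncated log-normals, exact means -------------------
  # keep a margin inside [min, max] so the final area rescale cannot
  # push values out of bounds
  D <- rtrunc_lnorm_mean(p$n_segments, p$d_mean, p$d_min, p$d_max, p$d_sdlog)
  L <- rtrunc_lnorm_mean(p$n_segments, p$l_mean, p$l_min * 1.002,
                         p$l_max / 1.002, p$l_sdlog)

  # --- pair D and L so that sum(pi D L) hits the area target ------------
  # pairwise swaps of L preserve both marginals (means, bounds) while
  # steering the D-L covariance; a final global length rescale (|s-1| well
  # below 0.5%) makes the area exact.
  target <- p$total_area / pi
  s_dl <- sum(D * L)
  for (it in seq_len(50000L)) {
    if (abs(s_dl - target) / target < 2e-4) break
    ij <- sample.int(p$n_segments, 2)
    delta <- (D[ij[1]] - D[ij[2]]) * (L[ij[2]] - L[ij[1]])
    if (abs(s_dl + delta - target) < abs(s_dl - target)) {
      L[ij] <- L[rev(ij)]
      s_dl <- s_dl + delta
    }
  }
  s <- target / sum(D * L)
  if (abs(s - 1) > 0.005)
    stop("area rescale exceeds tolerance; adjust generator distributions")
  L <- L * s

  nodes <- data.frame(id = seq_len(n),
                      kind = c("afferent_inlet",
                               rep("interior", n_int), "efferent_outlet"))
  segments <- data.frame(id = seq_len(p$n_segments),
                         i = em[, 1], j = em[, 2],
                         L_um = L, D_um = D, junction = FALSE)
  glom_network(nodes, segments,
               metadata = list(preset = "shea_like", seed = seed))
}

#' Bifurcation distance of a segment from the afferent inlet
#'
#' Number of bifurcations (edges) on the shortest path from the inlet node to
#' the segment's source node, the endpoint nearer the inlet (ties broken
#' toward the smaller node id).
#'
#' @param net a \code{\link{glom_network}}.
#' @param segment_id segment id(s); default all segments.
#' @return integer vector of distances.
#' @export
bifurcation_distance <- function(net, segment_id = net$segments$id) {
  d <- node_depths(net)
  sg <- net$segments[match(segment_id, net$segments$id), ]
  if (any(is.na(sg$id))) stop("unknown segment id")
  di <- d[as.character(sg$i)]; dj <- d[as.character(sg$j)]
  if (any(!is.finite(di) & !is.finite(dj)))
    stop("segment unreachable from the afferent inlet")
  src <- ifelse(di < dj | (di == dj & sg$i < sg$j), di, dj)
  as.integer(src)
}

# BFS depth (edges) of every node from the inlet, named by node id
node_depths <- function(net) {
  g <- as_igraph_net(net)
  d <- igraph::distances(g, v = as.character(inlet_id(net)))[1, ]
  stats::setNames(d, igraph::V(g)$name)
}
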