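# Airway lumen segmentation (threshold-adaptive region growing with leak
# detection) and centerline extraction (geodesic wavefront clustering).

# 6-connected flood fill over `inside` (logical vector on the grid) from a
# flat seed index. Returns a logical vector.
flood_fill6 <- function(inside, dm, seed_flat) {
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  nxy <- nx * ny
  visited <- logical(length(inside))
  if (!inside[seed_flat]) return(visited)
  visited[seed_flat] <- TRUE
  frontier <- seed_flat
  while (length(frontier)) {
    i <- (frontier - 1L) %% nx + 1L
    j <- ((frontier - 1L) %/% nx) %% ny + 1L
    k <- (frontier - 1L) %/% nxy + 1L
    nb <- c(frontier[i > 1L] - 1L, frontier[i < nx] + 1L,
            frontier[j > 1L] - nx, frontier[j < ny] + nx,
            frontier[k > 1L] - nxy, frontier[k < nz] + nxy)
    nb <- unique(nb)
    nb <- nb[inside[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

#' Segment an airway lumen by adaptive region growing
#'
#' Grows a 6-connected region of low-attenuation voxels from a seed point
#' placed inside an air-filled lumen. The HU threshold is raised from
#' `base_threshold_hu` in doubling steps; when a step makes the region
#' volume explode (grow by more than `leak_factor` times) the step is
#' rejected and the last safe threshold is kept -- a single-threshold
#' simplification of tree-oriented optimal-threshold growing.
#'
#' @param vol a [ct_volume()] (inspiratory).
#' @param seed_point world coordinates (mm) of a point inside the lumen.
#' @param base_threshold_hu starting (most conservative) threshold.
#' @param step_hu initial threshold increment (doubles each round).
#' @param max_threshold_hu never grow beyond this threshold.
#' @param leak_factor volume-explosion criterion: a step is a leak when the
#'   region grows by more than this factor.
#' @param max_volume_frac if even the base threshold captures more than this
#'   fraction of the grid, segmentation is flagged failed (leak at minimum).
#' @return Logical array (lumen mask) with attributes `threshold_hu`,
#'   `leak_detected`, `failed` and `seed_flat`.
#' @export
segment_lumen <- function(vol, seed_point,
                          base_threshold_hu = -950, step_hu = 8,
                          max_threshold_hu = -500, leak_factor = 3,
                          max_volume_frac = 0.25) {
  stopifnot(inherits(vol, "ct_volume"))
  dm <- dim(vol$voxels)
  sp <- vol$spacing
  ci <- pmin(dm, pmax(1L, ceiling(as.numeric(seed_point) / sp)))
  seed_flat <- ci[1] + (ci[2] - 1L) * dm[1] + (ci[3] - 1L) * dm[1] * dm[2]
  if (vol$voxels[seed_flat] >= -900)
    stop_copdct(sprintf("seed voxel is not air-filled (HU = %.0f >= -900)",
                        vol$voxels[seed_flat]), "copdct_seed_error")

  hu <- as.vector(vol$voxels)
  grow <- function(thr) flood_fill6(hu < thr, dm, seed_flat)

  thr <- base_threshold_hu
  mask <- grow(thr)
  failed <- sum(mask) > max_volume_frac * length(hu)
  leak <- FALSE
  step <- step_hu
  while (!failed && thr + step <= max_threshold_hu) {
    cand_thr <- thr + step
    cand <- grow(cand_thr)
    if (sum(cand) > leak_factor * sum(mask)) { leak <- TRUE; break }
    thr <- cand_thr
    mask <- cand
    step <- step * 2
  }
  out <- array(mask, dim = dm)
  attr(out, "threshold_hu") <- thr
  attr(out, "leak_detected") <- leak
  attr(out, "failed") <- failed
  attr(out, "seed_flat") <- seed_flat
  out
}

# 26-neighbourhood flat-index offsets with wrap-safe validity.
neighbors26 <- function(flat, dm) {
  nx <- dm[1]; ny <- dm[2]; nxy <- dm[1] * dm[2]; nz <- dm[3]
  i <- (flat - 1L) %% nx + 1L
  j <- ((flat - 1L) %/% nx) %% ny + 1L
  k <- (flat - 1L) %/% nxy + 1L
  res <- integer(0)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0L && dy == 0L && dz == 0L) next
    ok <- i + dx >= 1L & i + dx <= nx & j + dy >= 1L & j + dy <= ny &
      k + dz >= 1L & k + dz <= nz
    res <- c(res, flat[ok] + dx + dy * nx + dz * nxy)
  }
  res
}

#' Extract an airway centerline tree from a lumen mask
#'
#' Converts a binary lumen mask into a centerline model by geodesic
#' wavefront propagation from the root: mask voxels are binned by their
#' 26-connected breadth-first distance from the root voxel, each connected
#' component of a distance shell becomes a centerline node at its centroid,
#' and nodes are linked across consecutive shells by voxel adjacency.
#' Maximal non-branching chains form branch segments; leaf branches shorter
#' than `spur_mm` are pruned; generations count bifurcations from the root
#' (0 = trachea).
#'
#' @param mask logical array (from [segment_lumen()]).
#' @param spacing voxel spacing in mm.
#' @param seed_point world coordinates (mm) of the tree root (trachea end);
#'   defaults to the mask's stored seed.
#' @param spur_mm prune leaf branches shorter than this (mm).
#' @return An object of class `airway_tree`: `nodes` (data.frame with
#'   world position, unit tangent, `branch_id`, `generation_label`),
#'   `branches` (data.frame with `branch_id`, `parent`, `generation_label`,
#'   `length_mm`) and `bifurcations` (matrix of bifurcation positions).
#' @export
extract_centerline <- function(mask, spacing, seed_point = NULL,
                               spur_mm = 3) {
  dm <- dim(mask)
  sp <- rep_len(as.numeric(spacing), 3L)
  flat_mask <- as.vector(mask)
  idx_all <- which(flat_mask)
  if (!length(idx_all))
    stop_copdct("empty lumen mask", "copdct_degenerate_input_error")

  # interior check: at least one voxel with all six face neighbours in-mask
  has_interior <- FALSE
  nx <- dm[1]; ny <- dm[2]; nxy <- dm[1] * dm[2]; nz <- dm[3]
  i <- (idx_all - 1L) %% nx + 1L
  j <- ((idx_all - 1L) %/% nx) %% ny + 1L
  k <- (idx_all - 1L) %/% nxy + 1L
  inner <- idx_all[i > 1L & i < nx & j > 1L & j < ny & k > 1L & k < nz]
  if (length(inner)) {
    has_interior <- any(flat_mask[inner - 1L] & flat_mask[inner + 1L] &
                        flat_mask[inner - nx] & flat_mask[inner + nx] &
                        flat_mask[inner - nxy] & flat_mask[inner + nxy])
  }
  if (!has_interior)
    stop_copdct("lumen mask has no interior (one voxel thin)",
                "copdct_degenerate_mask_error")

  if (is.null(seed_point)) {
    sf <- attr(mask, "seed_flat")
    if (is.null(sf))
      stop_copdct("no seed stored in mask; supply 'seed_point'",
                  "copdct_input_error")
    root_flat <- sf
  } else {
    ctr <- cbind(((idx_all - 1L) %% nx + 0.5) * sp[1],
                 (((idx_all - 1L) %/% nx) %% ny + 0.5) * sp[2],
                 ((idx_all - 1L) %/% nxy + 0.5) * sp[3])
    d2 <- (ctr[, 1] - seed_point[1])^2 + (ctr[, 2] - seed_point[2])^2 +
      (ctr[, 3] - seed_point[3])^2
    root_flat <- idx_all[which.min(d2)]
  }

  # BFS geodesic distance (26-connectivity)
  dist <- rep(NA_integer_, length(flat_mask))
  dist[root_flat] <- 0L
  frontier <- root_flat
  d <- 0L
  shells <- list()  # per distance: flat indices
  shells[[1L]] <- frontier
  while (length(frontier)) {
    nb <- unique(neighbors26(frontier, dm))
    nb <- nb[flat_mask[nb] & is.na(dist[nb])]
    if (!length(nb)) break
    d <- d + 1L
    dist[nb] <- d
    shells[[d + 1L]] <- nb
    frontier <- nb
  }

  # cluster each shell into 26-connected components -> candidate nodes
  node_pos <- list(); node_shell <- integer(0); node_voxels <- list()
  comp_of <- rep(NA_integer_, length(flat_mask))
  nid <- 0L
  for (s in seq_along(shells)) {
    vox <- shells[[s]]
    remaining <- vox
    inshell <- logical(length(flat_mask)); inshell[vox] <- TRUE
    while (length(remaining)) {
      comp <- remaining[1L]
      grown <- comp
      repeat {
        nb <- unique(neighbors26(grown, dm))
        nb <- nb[inshell[nb] & is.na(comp_of[nb])]
        nb <- setdiff(nb, comp)
        if (!length(nb)) break
        comp <- c(comp, nb)
        grown <- nb
        comp_of[nb] <- -1L  # provisional
      }
      nid <- nid + 1L
      comp_of[comp] <- nid
      ii <- (comp - 1L) %% nx; jj <- ((comp - 1L) %/% nx) %% ny
      kk <- (comp - 1L) %/% nxy
      node_pos[[nid]] <- c(mean((ii + 0.5) * sp[1]), mean((jj + 0.5) * sp[2]),
                           mean((kk + 0.5) * sp[3]))
      node_shell[nid] <- s - 1L
      node_voxels[[nid]] <- comp
      remaining <- setdiff(remaining, comp)
    }
  }

  # parent links: a node's voxels touch voxels of a node one shell closer
  parent <- rep(NA_integer_, nid)
  for (v in seq_len(nid)) {
    if (node_shell[v] == 0L) next
    nb <- unique(neighbors26(node_voxels[[v]], dm))
    nb <- nb[flat_mask[nb]]
    cand <- comp_of[nb]
    cand <- cand[!is.na(cand) & cand > 0L]
    cand <- cand[node_shell[cand] == node_shell[v] - 1L]
    if (length(cand)) {
      tab <- table(cand)
      parent[v] <- as.integer(names(tab)[which.max(tab)])
    }
  }
  keep <- node_shell == 0L | !is.na(parent)
  # (nodes disconnected from the root lineage are dropped)

  children <- vector("list", nid)
  for (v in which(keep)) if (!is.na(parent[v]))
    children[[parent[v]]] <- c(children[[parent[v]]], v)
  n_child <- lengths(children)

  pos <- do.call(rbind, node_pos)

  # walk root->leaves splitting into branches at multi-child nodes
  root_node <- which(node_shell == 0L)[1L]
  branches <- list()
  walk <- list(list(start = root_node, parent_branch = NA_integer_, gen = 0L))
  while (length(walk)) {
    w <- walk[[1L]]; walk <- walk[-1L]
    chain <- w$start
    v <- w$start
    while (n_child[v] == 1L) {
      v <- children[[v]][1L]
      chain <- c(chain, v)
    }
    bid <- length(branches) + 1L
    branches[[bid]] <- list(nodes = chain, parent = w$parent_branch,
                            gen = w$gen, bif_end = n_child[v] > 1L)
    if (n_child[v] > 1L) {
      for (ch in children[[v]]) {
        walk <- c(walk, list(list(start = ch, parent_branch = bid,
                                  gen = w$gen + 1L)))
      }
    }
  }

  arc_len <- function(chain) {
    if (length(chain) < 2L) return(0)
    sum(sqrt(rowSums((pos[chain[-1L], , drop = FALSE] -
                      pos[chain[-length(chain)], , drop = FALSE])^2)))
  }

  # prune short leaf branches (skeleton spurs), repeatedly
  repeat {
    parent_ids <- vapply(branches, function(b) b$parent %||% NA_integer_,
                         integer(1))
    leaf <- !(seq_along(branches) %in% parent_ids)
    lens <- vapply(branches, function(b) arc_len(b$nodes), numeric(1))
    drop <- which(leaf & lens < spur_mm & !is.na(parent_ids))
    if (!length(drop)) break
    keep_ids <- setdiff(seq_along(branches), drop)
    remap <- match(seq_along(branches), keep_ids)
    branches <- branches[keep_ids]
    for (b in seq_along(branches)) {
      if (!is.na(branches[[b]]$parent))
        branches[[b]]$parent <- remap[branches[[b]]$parent]
    }
    # merge a parent with a now-single child into one branch
    repeat {
      parent_ids <- vapply(branches, function(b) b$parent %||% NA_integer_,
                           integer(1))
      counts <- tabulate(parent_ids[!is.na(parent_ids)], length(branches))
      merge_p <- which(counts == 1L)
      if (!length(merge_p)) break
      p <- merge_p[1L]
      ch <- which(!is.na(parent_ids) & parent_ids == p)[1L]
      branches[[p]]$nodes <- c(branches[[p]]$nodes, branches[[ch]]$nodes)
      branches[[p]]$bif_end <- branches[[ch]]$bif_end
      keep_ids <- setdiff(seq_along(branches), ch)
      remap <- match(seq_along(branches), keep_ids)
      for (b in seq_along(branches)) {
        if (!is.na(branches[[b]]$parent) && branches[[b]]$parent == ch)
          branches[[b]]$parent <- p
      }
      branches <- branches[keep_ids]
      for (b in seq_along(branches)) {
        if (!is.na(branches[[b]]$parent))
          branches[[b]]$parent <- remap[branches[[b]]$parent]
      }
    }
  }

  # regenerate generation labels after pruning
  gens <- rep(NA_integer_, length(branches))
  parent_ids <- vapply(branches, function(b) b$parent %||% NA_integer_,
                       integer(1))
  roots <- which(is.na(parent_ids))
  gens[roots] <- 0L
  repeat {
    todo <- which(is.na(gens) & !is.na(gens[parent_ids]))
    if (!length(todo)) break
    gens[todo] <- gens[parent_ids[todo]] + 1L
  }

  node_rows <- list()
  bif_pts <- list()
  for (b in seq_along(branches)) {
    chain <- branches[[b]]$nodes
    p <- pos[chain, , drop = FALSE]
    tg <- polyline_tangents(p)
    node_rows[[b]] <- data.frame(
      x = p[, 1], y = p[, 2], z = p[, 3],
      tx = tg[, 1], ty = tg[, 2], tz = tg[, 3],
      branch_id = b, generation_label = gens[b]
    )
    if (isTRUE(branches[[b]]$bif_end))
      bif_pts[[length(bif_pts) + 1L]] <- p[nrow(p), ]
  }
  nodes <- do.call(rbind, node_rows)
  br_df <- data.frame(
    branch_id = seq_along(branches),
    parent = parent_ids,
    generation_label = gens,
    length_mm = vapply(branches, function(b) arc_len(b$nodes), numeric(1))
  )
  bifs <- if (length(bif_pts)) do.call(rbind, bif_pts) else
    matrix(numeric(0), ncol = 3L)
  structure(list(nodes = nodes, branches = br_df, bifurcations = bifs),
            class = "airway_tree")
}

# Unit tangents along a polyline: central differences, one-sided at the ends.
polyline_tangents <- function(p) {
  n <- nrow(p)
  if (n == 1L) return(matrix(c(0, 0, 1), 1L))
  d <- matrix(0, n, 3L)
  d[1L, ] <- p[2L, ] - p[1L, ]
  d[n, ] <- p[n, ] - p[n - 1L, ]
  if (n > 2L) d[2:(n - 1L), ] <- p[3:n, , drop = FALSE] - p[1:(n - 2L), , drop = FALSE]
  nr <- sqrt(rowSums(d^2))
  nr[nr == 0] <- 1
  d / nr
}

#' Build an airway tree from explicit centerline polylines
#'
#' Constructs an [extract_centerline()]-compatible tree directly from known
#' centerline polylines (e.g. phantom ground truth), bypassing image
#' segmentation. Polylines are independent branches; supply `parent` links
#' and bifurcation points explicitly if the tree has them.
#'
#' @param polylines list of numeric matrices (columns x,y,z in mm).
#' @param generation_labels integer per polyline (default all 2).
#' @param parents integer parent branch per polyline (NA = root).
#' @param bifurcations optional matrix of bifurcation positions (mm).
#' @return An `airway_tree`.
#' @export
airway_tree_from_polylines <- function(polylines, generation_labels = NULL,
                                       parents = NULL, bifurcations = NULL) {
  nb <- length(polylines)
  generation_labels <- generation_labels %||% rep(2L, nb)
  parents <- parents %||% rep(NA_integer_, nb)
  rows <- vector("list", nb)
  lens <- numeric(nb)
  for (b in seq_len(nb)) {
    p <- matrix(as.numeric(polylines[[b]]), ncol = 3L)
    tg <- polyline_tangents(p)
    rows[[b]] <- data.frame(x = p[, 1], y = p[, 2], z = p[, 3],
                            tx = tg[, 1], ty = tg[, 2], tz = tg[, 3],
                            branch_id = b,
                            generation_label = generation_labels[b])
    lens[b] <- sum(sqrt(rowSums((p[-1L, , drop = FALSE] -
                                 p[-nrow(p), , drop = FALSE])^2)))
  }
  structure(list(
    nodes = do.call(rbind, rows),
    branches = data.frame(branch_id = seq_len(nb), parent = parents,
                          generation_label = generation_labels,
                          length_mm = lens),
    bifurcations = bifurcations %||% matrix(numeric(0), ncol = 3L)
  ), class = "airway_tree")
}

#' @export
print.airway_tree <- function(x, ...) {
  cat(sprintf("<airway_tree> %d branches, %d nodes, %d bifurcation(s)\n",
              nrow(x$branches), nrow(x$nodes), nrow(x$bifurcations)))
  invisible(x)
}
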