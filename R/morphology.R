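## Compartmental morphology: a tree of cylindrical segments.

REGION_TAGS <- c("soma", "AIS", "axon_node", "axon_myelin",
                 "dendrite_proximal", "dendrite_distal", "tuft")

#' Cylinder geometry of a segment
#'
#' Computes the lateral (membrane) area, volume and cross-sectional area of a
#' cylindrical segment. All arguments are vectorised.
#'
#' @param length segment length in um
#' @param diam segment diameter in um
#' @return a list with components `lateral_area` (um^2), `volume` (um^3) and
#'   `cross_section` (um^2)
#' @examples
#' segment_geometry(100, 2)
#' @export
segment_geometry <- function(length, diam) {
  if (any(!is.finite(length)) || any(!is.finite(diam)) ||
      any(length <= 0) || any(diam <= 0)) {
    stop("invalid geometry: segment length and diameter must be positive")
  }
  list(lateral_area = pi * diam * length,
       volume = pi * diam^2 * length / 4,
       cross_section = pi * diam^2 / 4)
}

#' Construct a morphology
#'
#' A morphology is a tree of cylindrical segments. `segments` must have
#' columns `id`, `parent` (NA for the single root), `length` (um), `diam`
#' (um) and `region` (one of soma, AIS, axon_node, axon_myelin,
#' dendrite_proximal, dendrite_distal, tuft).
#'
#' @param segments data.frame of segments
#' @param spatial_resolution subdivision factor applied on construction;
#'   each segment is split into this many equal pieces (geometry-preserving)
#' @return an object of class `morphology`
#' @export
morphology <- function(segments, spatial_resolution = 1L) {
  stopifnot(is.data.frame(segments))
  req <- c("id", "parent", "length", "diam", "region")
  if (!all(req %in% names(segments))) {
    stop("segments must have columns: ", paste(req, collapse = ", "))
  }
  segments$id <- as.integer(segments$id)
  segments$parent <- as.integer(segments$parent)
  segments$region <- as.character(segments$region)
  if (anyDuplicated(segments$id)) stop("duplicate segment id")
  if (any(!segments$region %in% REGION_TAGS)) {
    stop("unknown region tag: ",
         paste(setdiff(segments$region, REGION_TAGS), collapse = ", "))
  }
  segment_geometry(segments$length, segments$diam)  # validates positivity
  root <- which(is.na(segments$parent))
  if (length(root) != 1L) stop("morphology must have exactly one root segment")
  known <- segments$id
  bad <- !is.na(segments$parent) & !(segments$parent %in% known)
  if (any(bad)) {
    stop("parent id ", segments$parent[which(bad)[1]], " of segment ",
         segments$id[which(bad)[1]], " does not exist")
  }
  ## cycle / connectivity check: walk up from every segment
  idx <- match(segments$parent, segments$id)
  n <- nrow(segments)
  for (i in seq_len(n)) {
    j <- i; steps <- 0L
    while (!is.na(idx[j])) {
      j <- idx[j]; steps <- steps + 1L
      if (steps > n) stop("cyclic parent reference involving segment ",
                          segments$id[i])
    }
    if (j != root) stop("segment ", segments$id[i], " is not connected to the root")
  }
  m <- structure(list(segments = segments, spatial_resolution = 1L),
                 class = "morphology")
  if (spatial_resolution > 1L) m <- subdivide(m, spatial_resolution)
  m
}

#' @export
print.morphology <- function(x, ...) {
  s <- x$segments
  cat("<morphology> ", nrow(s), " segments, total area ",
      format(total_area(x), digits = 6), " um^2, total volume ",
      format(total_volume(x), digits = 6), " um^3\n", sep = "")
  print(table(s$region))
  invisible(x)
}

n_segments <- function(m) nrow(m$segments)

#' Total membrane area of a morphology (um^2)
#' @param m a morphology
#' @export
total_area <- function(m) sum(segment_geometry(m$segments$length, m$segments$diam)$lateral_area)

#' Total intracellular volume of a morphology (um^3)
#' @param m a morphology
#' @export
total_volume <- function(m) sum(segment_geometry(m$segments$length, m$segments$diam)$volume)

#' Subdivide every segment
#'
#' Splits each segment into `n` serial pieces of equal length and identical
#' diameter. Total membrane area and volume are unchanged; only the spatial
#' discretisation of the cable and of longitudinal diffusion is refined.
#'
#' @param m a morphology
#' @param n subdivision factor (integer >= 1)
#' @export
subdivide <- function(m, n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (n == 1L) return(m)
  s <- m$segments
  out <- vector("list", nrow(s))
  next_id <- max(s$id) + 1L
  ## first piece of each segment keeps the original id so that parent
  ## references from other segments keep pointing at the proximal end
  last_piece <- stats::setNames(s$id, s$id)
  for (i in seq_len(nrow(s))) {
    ids <- c(s$id[i], seq.int(next_id, length.out = n - 1L))
    next_id <- next_id + n - 1L
    out[[i]] <- data.frame(id = ids,
                           parent = c(s$parent[i], ids[-n]),
                           length = s$length[i] / n,
                           diam = s$diam[i],
                           region = s$region[i])
    last_piece[as.character(s$id[i])] <- ids[n]
  }
  seg <- do.call(rbind, out)
  ## children must attach to the *distal* piece of their original parent
  orig_ids <- s$id
  is_orig_first <- seg$id %in% orig_ids
  fix <- !is.na(seg$parent) & is_orig_first & seg$parent %in% orig_ids
  seg$parent[fix] <- as.integer(last_piece[as.character(seg$parent[fix])])
  m2 <- morphology(seg)
  m2$spatial_resolution <- m$spatial_resolution * n
  m2
}

#' Path distance from the root to each segment centre (um)
#' @param m a morphology
#' @return numeric vector aligned with `m$segments`
#' @export
path_distance <- function(m) {
  s <- m$segments
  idx <- match(s$parent, s$id)
  d <- rep(NA_real_, nrow(s))
  ## segments are in tree order after ordering parents before children
  ord <- tree_order(m)
  for (i in ord) {
    d[i] <- if (is.na(idx[i])) s$length[i] / 2
            else d[idx[i]] + s$length[idx[i]] / 2 + s$length[i] / 2
  }
  d
}

## topological order: parents before children (row indices)
tree_order <- function(m) {
  s <- m$segments
  idx <- match(s$parent, s$id)
  n <- nrow(s)
  depth <- integer(n)
  for (i in seq_len(n)) {
    j <- i
    while (!is.na(idx[j])) { depth[i] <- depth[i] + 1L; j <- idx[j] }
  }
  order(depth)
}

#' Drop all segments with the given region tags
#'
#' Used e.g. to remove the dendritic tree before measuring the effective
#' somatic capacitance of a strongly loaded cell. Children of removed
#' segments are removed as well.
#'
#' @param m a morphology
#' @param tags character vector of region tags to drop
#' @export
remove_region <- function(m, tags) {
  s <- m$segments
  drop <- s$region %in% tags
  idx <- match(s$parent, s$id)
  repeat {
    more <- !drop & !is.na(idx) & drop[idx]
    if (!any(more)) break
    drop <- drop | more
  }
  if (all(drop)) stop("removing these regions would leave no segments")
  keep <- s[!drop, , drop = FALSE]
  if (any(!is.na(keep$parent) & !(keep$parent %in% keep$id))) {
    stop("removal disconnects the tree (root region removed?)")
  }
  m2 <- morphology(keep)
  m2$spatial_resolution <- m$spatial_resolution
  m2
}

## ---------------------------------------------------------------------------
## SWC input/output

.swc_type_to_region <- function(type) {
  ifelse(type == 1, "soma",
  ifelse(type == 2, "AIS",
  ifelse(type == 3, "dendrite_proximal",
  ifelse(type == 4, "dendrite_distal", "dendrite_distal"))))
}

.region_to_swc_type <- function(region) {
  c(soma = 1L, AIS = 2L, axon_node = 2L, axon_myelin = 2L,
    dendrite_proximal = 3L, dendrite_distal = 4L, tuft = 4L)[region]
}

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`, `#` comments).
#' Each non-root sample becomes one cylindrical segment whose length is the
#' Euclidean distance to its parent sample and whose diameter is twice the
#' sample radius. Contiguous type-1 (soma) samples are collapsed into a
#' single equivalent cylinder of equal membrane area, since the models used
#' here have lumped somata; an isolated type-1 root sample of radius r maps
#' to a cylinder with length = diameter = 2r (equal area to the sphere).
#'
#' @param path path to an SWC file
#' @return a `morphology`
#' @export
load_swc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("SWC format error: empty file '", path, "'")
  parse_one <- function(ln) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[ln]), "\\s+")[[1]]))
    if (length(f) != 7 || any(is.na(f))) {
      stop("SWC format error at line ", ln, ": expected 7 numeric fields")
    }
    f
  }
  raw <- t(vapply(keep, parse_one, numeric(7)))
  sm <- data.frame(id = as.integer(raw[, 1]), type = as.integer(raw[, 2]),
                   x = raw[, 3], y = raw[, 4], z = raw[, 5],
                   radius = raw[, 6], parent = as.integer(raw[, 7]),
                   line = keep)
  if (anyDuplicated(sm$id)) {
    dup <- sm$line[duplicated(sm$id)][1]
    stop("SWC format error at line ", dup, ": duplicate sample id")
  }
  root <- which(sm$parent == -1L)
  if (length(root) != 1L) stop("SWC format error: need exactly one root sample")
  pidx <- match(sm$parent, sm$id)
  orphan <- which(sm$parent != -1L & is.na(pidx))
  if (length(orphan)) {
    stop("SWC format error at line ", sm$line[orphan[1]],
         ": parent ", sm$parent[orphan[1]], " does not exist")
  }
  ## cycle detection
  for (i in seq_len(nrow(sm))) {
    j <- i; steps <- 0L
    while (!is.na(pidx[j])) {
      j <- pidx[j]; steps <- steps + 1L
      if (steps > nrow(sm))
        stop("SWC format error at line ", sm$line[i], ": cyclic parent chain")
    }
  }
  dist_to_parent <- function(i) {
    j <- pidx[i]
    sqrt((sm$x[i] - sm$x[j])^2 + (sm$y[i] - sm$y[j])^2 + (sm$z[i] - sm$z[j])^2)
  }

  ## collapse the contiguous chain of type-1 samples containing the root
  soma_chain <- integer(0)
  if (sm$type[root] == 1L) {
    soma_chain <- root
    repeat {
      nxt <- which(sm$type == 1L & !is.na(pidx) & pidx %in% soma_chain &
                   !(seq_len(nrow(sm)) %in% soma_chain))
      if (!length(nxt)) break
      soma_chain <- c(soma_chain, nxt)
    }
  }
  if (length(soma_chain) >= 2L) {
    lens <- vapply(setdiff(soma_chain, root), dist_to_parent, numeric(1))
    if (any(lens <= 0)) stop("SWC format error: coincident soma samples")
    areas <- 2 * pi * sm$radius[setdiff(soma_chain, root)] * lens
    L <- sum(lens)
    d_eq <- sum(areas) / (pi * L)
    soma_row <- data.frame(id = sm$id[root], parent = NA_integer_,
                           length = L, diam = d_eq, region = "soma")
  } else if (length(soma_chain) == 1L || sm$type[root] != 1L) {
    r <- sm$radius[root]
    soma_row <- data.frame(id = sm$id[root], parent = NA_integer_,
                           length = 2 * r, diam = 2 * r,
                           region = .swc_type_to_region(sm$type[root]))
    soma_chain <- root
  }
  rest <- setdiff(seq_len(nrow(sm)), soma_chain)
  seg_rows <- lapply(rest, function(i) {
    L <- dist_to_parent(i)
    if (L <= 0) stop("SWC format error at line ", sm$line[i],
                     ": zero distance to parent sample")
    par <- if (pidx[i] %in% soma_chain) sm$id[root] else sm$parent[i]
    data.frame(id = sm$id[i], parent = par, length = L,
               diam = 2 * sm$radius[i], region = .swc_type_to_region(sm$type[i]))
  })
  morphology(do.call(rbind, c(list(soma_row), seg_rows)))
}

#' Write a morphology to an SWC file
#'
#' Inverse of [load_swc()] up to coordinate placement: samples are laid out
#' along the x axis (one branch per parent direction), which preserves all
#' inter-sample distances and therefore all segment geometry on re-read.
#' The root is written as a two-sample soma chain so the equal-area collapse
#' in [load_swc()] reconstructs its cylinder exactly.
#'
#' @param m a morphology
#' @param path output path
#' @export
write_swc <- function(m, path) {
  s <- m$segments
  ord <- tree_order(m)
  s <- s[ord, , drop = FALSE]
  root_i <- which(is.na(s$parent))
  ## sample ids: root start sample gets a fresh id, every segment's distal
  ## end sample reuses the segment id
  start_id <- max(s$id) + 1L
  xs <- stats::setNames(numeric(nrow(s)), s$id)  # x of distal sample
  rows <- character(0)
  rt <- .region_to_swc_type(s$region[root_i])
  rows <- c(rows,
            sprintf("%d %d %.9g 0 0 %.9g -1", start_id, rt, 0, s$diam[root_i] / 2),
            sprintf("%d %d %.9g 0 0 %.9g %d", s$id[root_i], rt,
                    s$length[root_i], s$diam[root_i] / 2, start_id))
  xs[as.character(s$id[root_i])] <- s$length[root_i]
  for (i in seq_len(nrow(s))) {
    if (i == root_i) next
    px <- xs[as.character(s$parent[i])]
    x <- px + s$length[i]
    xs[as.character(s$id[i])] <- x
    rows <- c(rows, sprintf("%d %d %.9g 0 0 %.9g %d", s$id[i],
                            .region_to_swc_type(s$region[i]), x,
                            s$diam[i] / 2, s$parent[i]))
  }
  writeLines(c("# written by nadyn", rows), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Reduced archetypes

#' Build a reduced archetype morphology
#'
#' Constructs a lumped soma + AIS + proximal/distal dendrite morphology of
#' one of three flavours. `purkinje_like` additionally carries a myelinated
#' axon with three nodes of Ranvier, and its proximal dendrites are thick
#' (> 2.2 um) so that climbing-fiber volleys have targets. `pyramidal_like`
#' ends in a thin apical tuft that doubles as the distal synaptic site and,
#' at its proximal edge, a calcium-channel hot zone. The printed dimensions
#' of the original lumped models are not public; these defaults are the
#' package's own reduced geometries and are freely overridable.
#'
#' @param kind one of `"mitral_like"`, `"pyramidal_like"`, `"purkinje_like"`
#' @param params named list overriding individual dimensions; see the
#'   function body for the parameter names and defaults (all um)
#' @param spatial_resolution subdivision factor (see [subdivide()])
#' @return a `morphology`
#' @export
build_archetype <- function(kind = c("mitral_like", "pyramidal_like", "purkinje_like"),
                            params = list(), spatial_resolution = 1L) {
  kind <- match.arg(kind)
  p <- switch(kind,
    mitral_like = list(soma_L = 25, soma_d = 20, ais_L = 30, ais_d = 1.5,
                       prox_L = 150, prox_d = 3.5, prox_n = 3,
                       dist_L = 150, dist_d = 1.5, dist_n = 3,
                       tuft_L = 100, tuft_d = 1.0, tuft_n = 2),
    pyramidal_like = list(soma_L = 30, soma_d = 25, ais_L = 40, ais_d = 1.5,
                          prox_L = 200, prox_d = 3.0, prox_n = 4,
                          dist_L = 300, dist_d = 1.2, dist_n = 6,
                          tuft_L = 150, tuft_d = 0.9, tuft_n = 3),
    purkinje_like = list(soma_L = 25, soma_d = 25, ais_L = 20, ais_d = 1.5,
                         prox_L = 120, prox_d = 3.0, prox_n = 3,
                         dist_L = 150, dist_d = 1.2, dist_n = 3,
                         tuft_L = 0, tuft_d = 1, tuft_n = 0,
                         myelin_L = 100, myelin_d = 1.2, node_L = 1.5,
                         node_d = 1.2, n_nodes = 3))
  p[names(params)] <- params
  rows <- list(data.frame(id = 1L, parent = NA_integer_, length = p$soma_L,
                          diam = p$soma_d, region = "soma"),
               data.frame(id = 2L, parent = 1L, length = p$ais_L,
                          diam = p$ais_d, region = "AIS"))
  nid <- 3L
  chain <- function(n, parent, L, d, region, nid) {
    if (n == 0L) return(list(rows = NULL, last = parent, nid = nid))
    if (L <= 0 || d <= 0) {
      stop("invalid geometry: ", region, " length and diameter must be positive")
    }
    ids <- seq.int(nid, length.out = n)
    list(rows = data.frame(id = ids, parent = c(parent, ids[-n]),
                           length = L / n, diam = d, region = region),
         last = ids[n], nid = nid + n)
  }
  pr <- chain(p$prox_n, 1L, p$prox_L, p$prox_d, "dendrite_proximal", nid)
  nid <- pr$nid
  di <- chain(p$dist_n, pr$last, p$dist_L, p$dist_d, "dendrite_distal", nid)
  nid <- di$nid
  rows <- c(rows, list(pr$rows, di$rows))
  if (p$tuft_n > 0 && p$tuft_L > 0) {
    tu <- chain(p$tuft_n, di$last, p$tuft_L, p$tuft_d, "tuft", nid)
    nid <- tu$nid
    rows <- c(rows, list(tu$rows))
  }
  if (kind == "purkinje_like") {
    par <- 2L  # axon hangs off the AIS
    for (k in seq_len(p$n_nodes)) {
      my <- chain(1L, par, p$myelin_L, p$myelin_d, "axon_myelin", nid)
      nid <- my$nid
      no <- chain(1L, my$last, p$node_L, p$node_d, "axon_node", nid)
      nid <- no$nid
      rows <- c(rows, list(my$rows, no$rows))
      par <- no$last
    }
  }
  morphology(do.call(rbind, rows), spatial_resolution = spatial_resolution)
}
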