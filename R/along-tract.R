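#' Fiber bundle container
#'
#' A bundle is a list of streamlines (each an m x 3 matrix of ordered
#' points in scanner mm coordinates, consistently oriented) plus the voxel
#' geometry of the source image grid.
#'
#' @param streamlines List of m x 3 numeric matrices (m >= 2 each).
#' @param voxel_dim Length-3 voxel size, mm.
#' @param origin Length-3 position of the grid corner (edge of voxel
#'   (1,1,1)), mm.
#' @return Object of class `bundle`.
#' @export
new_bundle <- function(streamlines, voxel_dim = c(2.5, 2.5, 2.5),
                       origin = c(0, 0, 0)) {
  stopifnot(length(streamlines) >= 1)
  ok <- vapply(streamlines, function(s)
    is.matrix(s) && ncol(s) == 3 && nrow(s) >= 2 && all(is.finite(s)),
    logical(1))
  if (!all(ok)) stop("streamlines must be finite m x 3 matrices, m >= 2",
                     call. = FALSE)
  structure(list(streamlines = streamlines, voxel_dim = voxel_dim,
                 origin = origin),
            class = "bundle")
}

#' @export
print.bundle <- function(x, ...) {
  cat(sprintf("<bundle> %d streamlines, voxel %.2f x %.2f x %.2f mm\n",
              length(x$streamlines), x$voxel_dim[1], x$voxel_dim[2],
              x$voxel_dim[3]))
  invisible(x)
}

# arc-length resampling of one polyline to given target arc positions
.resample_polyline <- function(pts, s_target) {
  seg <- diff(pts)
  arc <- c(0, cumsum(sqrt(rowSums(seg^2))))
  cbind(approx(arc, pts[, 1], s_target)$y,
        approx(arc, pts[, 2], s_target)$y,
        approx(arc, pts[, 3], s_target)$y)
}

.polyline_length <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))

#' Resample streamlines to bounded node spacing
#'
#' Linear arc-length resampling of every streamline so that consecutive
#' nodes are spaced at most `max_step` apart (the along-tract procedure
#' requires node spacing below the voxel size). Endpoints are preserved;
#' zero-length streamlines are dropped with a message.
#'
#' @param bundle A [new_bundle()] object.
#' @param max_step Maximum node spacing, mm.
#' @return The resampled bundle.
#' @export
resample_streamlines <- function(bundle, max_step = min(bundle$voxel_dim)) {
  stopifnot(inherits(bundle, "bundle"), max_step > 0)
  lens <- vapply(bundle$streamlines, .polyline_length, numeric(1))
  dropped <- sum(lens <= 0)
  if (dropped > 0) {
    message(sprintf("dropping %d zero-length streamline(s)", dropped))
  }
  keep <- bundle$streamlines[lens > 0]
  lens <- lens[lens > 0]
  bundle$streamlines <- purrr::map2(keep, lens, function(pts, L) {
    n <- ceiling(L / max_step) + 1
    .resample_polyline(pts, seq(0, L, length.out = n))
  })
  bundle
}

#' Trilinear interpolation of voxel maps at streamline nodes
#'
#' Interpolates a 3-D (or 4-D, last dimension = shell) array defined on a
#' regular voxel grid at arbitrary mm coordinates. Voxel (i,j,k) is centred
#' at `origin + (c(i,j,k) - 0.5) * voxel_dim`. Nodes outside the grid are
#' flagged `NA` and reported via the `n_out_of_bounds` attribute.
#'
#' @param field 3-D or 4-D numeric array.
#' @param nodes n x 3 matrix of mm coordinates.
#' @param voxel_dim,origin Grid geometry (mm).
#' @return n-vector (3-D field) or n x n_shell matrix (4-D field) of
#'   interpolated values; attribute `n_out_of_bounds` counts excluded nodes.
#' @export
interpolate_at_nodes <- function(field, nodes, voxel_dim, origin = c(0, 0, 0)) {
  dims <- dim(field)
  stopifnot(length(dims) %in% c(3, 4))
  n_shell <- if (length(dims) == 4) dims[4] else 1L
  # continuous voxel-centre coordinates
  u <- sweep(sweep(nodes, 2, origin, `-`), 2, voxel_dim, `/`) - 0.5
  i0 <- floor(u)
  fr <- u - i0
  oob <- rep(FALSE, nrow(nodes))
  for (d in 1:3) {
    oob <- oob | i0[, d] < 0 | i0[, d] > dims[d] - 2 &
      !(i0[, d] == dims[d] - 1 & fr[, d] < 1e-9)
  }
  # clamp boundary-exact nodes onto the last cell
  for (d in 1:3) {
    at_edge <- i0[, d] == dims[d] - 1 & fr[, d] < 1e-9
    i0[at_edge, d] <- dims[d] - 2
    fr[at_edge, d] <- 1
  }
  out <- matrix(NA_real_, nrow(nodes), n_shell)
  ok <- which(!oob)
  if (length(ok) == 0) stop("all nodes fall outside the field", call. = FALSE)
  ii <- i0[ok, , drop = FALSE] + 1L
  ff <- fr[ok, , drop = FALSE]
  for (s in seq_len(n_shell)) {
    vol <- if (length(dims) == 4) field[, , , s] else field
    acc <- numeric(length(ok))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (dx * ff[, 1] + (1 - dx) * (1 - ff[, 1])) *
           (dy * ff[, 2] + (1 - dy) * (1 - ff[, 2])) *
           (dz * ff[, 3] + (1 - dz) * (1 - ff[, 3]))
      idx <- cbind(ii[, 1] + dx, ii[, 2] + dy, ii[, 3] + dz)
      acc <- acc + w * vol[idx]
    }
    out[ok, s] <- acc
  }
  res <- if (n_shell == 1) drop(out) else out
  attr(res, "n_out_of_bounds") <- sum(oob)
  res
}

#' Bundle centerline
#'
#' Deterministic centerline estimate: every streamline is resampled to
#' `n_points` equally spaced arc-length positions, the pointwise mean
#' across streamlines is taken (permutation invariant), and the result is
#' smoothed with a moving average (window 5, shrinking at the ends). The
#' strategy assumes a consistently oriented bundle and is deliberately the
#' simplest swappable choice.
#'
#' @param bundle A bundle.
#' @param n_points Number of centerline points.
#' @return An `n_points` x 3 matrix.
#' @export
compute_centerline <- function(bundle, n_points = 100) {
  stopifnot(inherits(bundle, "bundle"))
  mats <- lapply(bundle$streamlines, function(pts) {
    L <- .polyline_length(pts)
    .resample_polyline(pts, seq(0, L, length.out = n_points))
  })
  m <- Reduce(`+`, mats) / length(mats)
  # symmetric shrinking window: no inward bias at the endpoints
  sm <- sapply(1:3, function(d) {
    vapply(seq_len(n_points), function(i) {
      w <- min(2L, i - 1L, n_points - i)
      mean(m[(i - w):(i + w), d])
    }, numeric(1))
  })
  sm
}

#' Divide a centerline into equal-length segments and assign nodes
#'
#' Splits the centerline into `N` segments of equal arc length `L_N`. Each
#' segment is represented by the tangent line through its midpoint; a node
#' belongs to the first segment (lowest index wins at boundaries) whose
#' tangent-axis projection interval of half-width `L_N/2` contains it. The
#' segment cylinder radius is the maximal perpendicular node distance to
#' the axis; per-streamline mean perpendicular distances give the
#' inverse-distance averaging weights (floored at `eps` mm).
#'
#' @param bundle A resampled bundle.
#' @param centerline Matrix from [compute_centerline()].
#' @param N Number of segments.
#' @param eps Distance floor for weights, mm.
#' @return Tibble with one row per node: `segment`, `streamline`, `node`,
#'   coordinates, `dist` (perpendicular distance to the segment axis),
#'   `weight`; attributes `segments` (tibble of midpoints, tangents,
#'   lengths, cylinder radii), `n_unassigned`.
#' @export
segment_bundle <- function(bundle, centerline, N = 20, eps = 0.1) {
  stopifnot(inherits(bundle, "bundle"), N >= 1)
  seg <- diff(centerline)
  arc <- c(0, cumsum(sqrt(rowSums(seg^2))))
  L <- arc[length(arc)]
  if (L <= 0) stop("degenerate centerline", call. = FALSE)
  L_N <- L / N
  mid_s <- (seq_len(N) - 0.5) * L_N
  mids <- .resample_polyline(centerline, mid_s)
  tangent_at <- function(s) {
    h <- L / 200
    p1 <- .resample_polyline(centerline, max(s - h, 0))
    p2 <- .resample_polyline(centerline, min(s + h, L))
    t <- p2 - p1
    t / sqrt(sum(t^2))
  }
  tans <- t(vapply(mid_s, function(s) drop(tangent_at(s)), numeric(3)))
  nodes <- purrr::imap_dfr(bundle$streamlines, function(pts, sl) {
    tibble::tibble(streamline = sl, node = seq_len(nrow(pts)),
                   x = pts[, 1], y = pts[, 2], z = pts[, 3])
  })
  P <- as.matrix(nodes[, c("x", "y", "z")])
  assigned <- rep(NA_integer_, nrow(P))
  dist_ax <- rep(NA_real_, nrow(P))
  for (i in seq_len(N)) {
    rel <- sweep(P, 2, mids[i, ], `-`)
    tproj <- drop(rel %*% tans[i, ])
    inside <- is.na(assigned) & abs(tproj) <= L_N / 2
    if (any(inside)) {
      perp2 <- rowSums(rel[inside, , drop = FALSE]^2) - tproj[inside]^2
      assigned[inside] <- i
      dist_ax[inside] <- sqrt(pmax(perp2, 0))
    }
  }
  nodes$segment <- assigned
  nodes$dist <- dist_ax
  n_unassigned <- sum(is.na(assigned))
  nodes <- nodes[!is.na(nodes$segment), , drop = FALSE]
  # per-streamline mean distance within each segment -> weights
  nodes <- nodes |>
    dplyr::group_by(.data$segment, .data$streamline) |>
    dplyr::mutate(weight = 1 / pmax(mean(.data$dist), eps)) |>
    dplyr::ungroup()
  seg_tbl <- nodes |>
    dplyr::group_by(segment = .data$segment) |>
    dplyr::summarise(cyl_radius = max(.data$dist), n_nodes = dplyr::n(),
                     .groups = "drop") |>
    dplyr::right_join(
      tibble::tibble(segment = seq_len(N), mid_s = mid_s,
                     mid_x = mids[, 1], mid_y = mids[, 2], mid_z = mids[, 3],
                     tan_x = tans[, 1], tan_y = tans[, 2], tan_z = tans[, 3],
                     length = L_N),
      by = "segment") |>
    dplyr::arrange(.data$segment)
  seg_tbl$n_nodes[is.na(seg_tbl$n_nodes)] <- 0L
  attr(nodes, "segments") <- seg_tbl
  attr(nodes, "n_unassigned") <- n_unassigned
  nodes
}

#' Distance-weighted segment averages of node values
#'
#' Averages per-node values (one column per shell) within each segment,
#' weighting each streamline by the inverse of its mean distance to the
#' centerline axis. Empty segments yield `NA` rows (flagged, not errors).
#'
#' @param nodes Node tibble from [segment_bundle()].
#' @param values n_nodes-vector or n_nodes x n_shell matrix aligned with
#'   the rows of `nodes` (e.g. from [interpolate_at_nodes()] on the kept
#'   nodes).
#' @param N Total number of segments.
#' @return Tibble: `segment`, `shell`, `sbar`, `n_nodes`, `missing`.
#' @export
segment_average <- function(nodes, values, N = 20) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  stopifnot(nrow(values) == nrow(nodes))
  purrr::map_dfr(seq_len(N), function(i) {
    sel <- nodes$segment == i
    purrr::map_dfr(seq_len(ncol(values)), function(s) {
      v <- values[sel, s]
      w <- nodes$weight[sel]
      ok <- is.finite(v)
      if (!any(ok)) {
        return(tibble::tibble(segment = i, shell = s, sbar = NA_real_,
                              n_nodes = 0L, missing = TRUE))
      }
      tibble::tibble(segment = i, shell = s,
                     sbar = sum(w[ok] * v[ok]) / sum(w[ok]),
                     n_nodes = sum(ok), missing = FALSE)
    })
  })
}

#' Along-tract effective-radius profile
#'
#' Runs the full five-step along-tract compression and fits the effective
#' radius per segment: (1) take the oriented bundle, (2) resample
#' streamlines below the voxel size and interpolate the per-shell
#' spherical-mean maps at the nodes, (3) compute the bundle centerline,
#' (4) cut it into `N` equal-length segments with cylindrical node
#' membership, (5) average node signals with inverse-distance streamline
#' weights, then estimate (beta, r) per segment from the averaged
#' spherical means.
#'
#' @param bundle A bundle (raw; resampling is applied internally).
#' @param smean 4-D array (x, y, z, shell) of spherical-mean maps.
#' @param shells Pulse tibble, one row per shell of `smean` (b >= 6).
#' @param voxel_dim,origin Grid geometry of `smean`, mm.
#' @param N Number of segments.
#' @param D0 Axoplasmic diffusivity.
#' @param flip Reverse the segment order (to honour a
#'   posterior-to-anterior or inferior-to-superior convention).
#' @param sigma Optional per-direction noise level for precision columns.
#' @return Tibble of class `tract_profile`: per segment, arc-length
#'   midpoint `mid_s` (mm), per-shell averaged signals (list-column
#'   `series`), `r`, `beta`, `flag`, `n_nodes`.
#' @export
tract_profile <- function(bundle, smean, shells, voxel_dim,
                          origin = c(0, 0, 0), N = 20,
                          D0 = mraxon_constants()$D0, flip = FALSE,
                          sigma = NULL) {
  bundle <- resample_streamlines(bundle, max_step = min(voxel_dim))
  centerline <- compute_centerline(bundle)
  nodes <- segment_bundle(bundle, centerline, N = N)
  vals <- interpolate_at_nodes(smean, as.matrix(nodes[, c("x", "y", "z")]),
                               voxel_dim, origin)
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1)
  avg <- segment_average(nodes, vals, N = N)
  seg_tbl <- attr(nodes, "segments")
  out <- purrr::map_dfr(seq_len(N), function(i) {
    ser <- dplyr::filter(avg, .data$segment == i)
    row <- tibble::tibble(segment = i, mid_s = seg_tbl$mid_s[i],
                          n_nodes = seg_tbl$n_nodes[i],
                          series = list(ser), r = NA_real_,
                          beta = NA_real_, flag = NA)
    if (any(ser$missing) || any(!is.finite(ser$sbar)) || any(ser$sbar <= 0)) {
      row$flag <- TRUE
      return(row)
    }
    fit <- fit_radius(tibble::tibble(b = shells$b, sbar = ser$sbar,
                                     n_dirs = shells$n_dirs),
                      shells, D0 = D0, sigma = sigma)
    row$r <- fit$r
    row$beta <- fit$beta
    row$flag <- fit$at_resolution_limit
    row
  })
  if (flip) {
    out <- out[rev(seq_len(N)), ]
    out$segment <- seq_len(N)
  }
  class(out) <- c("tract_profile", class(out))
  out
}
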