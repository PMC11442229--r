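# Berry-shape chimera synthesis and quantitative shape descriptors.
#
# Categorical per-upright shape scores are replaced by canonical silhouette
# templates, normalised to common area and centre, combined through their
# differential distance transforms (DDT), and thresholded on positive values
# to give one "chimera" silhouette per genotype-year. Six descriptors are then
# measured on the chimera: ellipse eccentricity (UKEC), length:width ratio
# (UKLvW), slope-chain-code tortuosity (UKTO), solidity (UKSO), and log10
# unsigned Manhattan chain-code step counts per axis (UKUX, UKUY).

# Images are plain 0/1 integer matrices; [row, col] indexes (y, x).

.check_binary <- function(img) {
  if (!is.matrix(img) || !all(img %in% c(0L, 1L, 0, 1)))
    stop("image must be a binary 0/1 matrix")
  invisible(TRUE)
}

.fg_coords <- function(img) which(img > 0, arr.ind = TRUE)

#' Generate the five berry-shape class templates
#'
#' Synthetic silhouettes standing in for the canonical shape-scoring card
#' (the published card's bitmaps are not available): round, oval, oblong,
#' pyriform (pear/bell) and spindle. Each template is rendered on a common
#' grid and normalised to the target area with its centroid at the grid
#' centre.
#'
#' @param size raster side length in pixels (default 256).
#' @param target_area common foreground area in pixels (default 12000).
#' @return named list of 5 binary matrices (names from
#'   \code{\link{SHAPE_CLASSES}}).
#' @export
shape_templates <- function(size = 256, target_area = 12000) {
  cx <- (size + 1) / 2
  grid <- expand.grid(y = seq_len(size), x = seq_len(size))
  u <- (grid$x - cx) / (size / 2)   # [-1, 1]
  v <- (grid$y - cx) / (size / 2)
  render <- function(inside) {
    m <- matrix(0L, size, size)
    m[cbind(grid$y[inside], grid$x[inside])] <- 1L
    m
  }
  # half-width profile w(t) along the long axis t in [-1,1]; fg iff |u| <= w(v/a)
  profile_shape <- function(a, wfun) {
    t <- v / a
    inside <- abs(t) <= 1 & abs(u) <= wfun(t)
    render(inside)
  }
  ellipse <- function(a, b) render((u / b)^2 + (v / a)^2 <= 1)
  templates <- list(
    round    = ellipse(0.42, 0.42),
    oval     = ellipse(0.48, 0.38),
    oblong   = profile_shape(0.52, function(t) 0.33 * (1 - t^6)^(1 / 6)),
    # pear: bulbous base tapering toward the stem end
    pyriform = profile_shape(0.52, function(t)
      pmax(0, (0.36 - 0.14 * t) * sqrt(pmax(0, 1 - t^2)))),
    # pointed at both ends
    spindle  = profile_shape(0.55, function(t) 0.30 * (1 - t^2))
  )
  lapply(templates, normalize_shape, target_area = target_area)
}

#' Normalise a binary shape
#'
#' Centres the silhouette's centroid at the grid centre and rescales it so the
#' foreground area matches \code{target_area}. The geometric rescaling is
#' nearest-neighbour; the residual area error is then removed exactly by
#' taking the \code{target_area} pixels with the largest differential distance
#' transform value (an erosion/dilation level set), so the output area is
#' within one pixel of the target and topology is preserved.
#'
#' @param img binary matrix with nonzero foreground.
#' @param target_area target foreground pixel count.
#' @return binary matrix of the same dimensions.
#' @export
normalize_shape <- function(img, target_area = 12000) {
  .check_binary(img)
  area <- sum(img)
  if (area == 0) stop("empty foreground")
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cxx <- (w + 1) / 2
  fg <- .fg_coords(img)
  cen <- colMeans(fg)                       # (row, col)
  s <- sqrt(target_area / area)
  bbox <- c(diff(range(fg[, 1])), diff(range(fg[, 2]))) + 1
  if (any(bbox * s > c(h, w) - 2))
    stop("shape does not fit the grid at target_area; use a larger grid")
  # inverse-map each output pixel to the source and nearest-neighbour sample
  gy <- matrix(seq_len(h), h, w)
  gx <- matrix(seq_len(w), h, w, byrow = TRUE)
  sy <- round(cen[1] + (gy - cy) / s)
  sx <- round(cen[2] + (gx - cxx) / s)
  ok <- sy >= 1 & sy <= h & sx >= 1 & sx <= w
  out <- matrix(0L, h, w)
  out[ok] <- img[cbind(sy[ok], sx[ok])]
  if (sum(out) == 0) stop("shape scaled out of frame; use a larger grid")
  # exact-area correction on the DDT level set
  ddt <- differential_distance_transform(out)
  ord <- order(ddt, decreasing = TRUE)
  sel <- ord[seq_len(min(target_area, h * w))]
  out2 <- matrix(0L, h, w)
  out2[sel] <- 1L
  # recentre by the best integer shift
  fg2 <- .fg_coords(out2)
  cen2 <- colMeans(fg2)
  dy <- round(cy - cen2[1]); dx <- round(cxx - cen2[2])
  ny <- fg2[, 1] + dy; nx <- fg2[, 2] + dx
  keep <- ny >= 1 & ny <= h & nx >= 1 & nx <= w
  out3 <- matrix(0L, h, w)
  out3[cbind(ny[keep], nx[keep])] <- 1L
  out3
}

#' Differential distance transform
#'
#' Euclidean distance transform of the foreground minus that of the inverted
#' image: DDT(p) = EDT_to_background(p) - EDT_to_foreground(p). Strictly
#' positive exactly on foreground pixels and strictly negative on background,
#' growing toward each region's interior.
#'
#' @param img binary matrix.
#' @return numeric matrix of signed distances.
#' @export
differential_distance_transform <- function(img) {
  .check_binary(img)
  storage.mode(img) <- "integer"
  d_fg <- EBImage::distmap(img, metric = "euclidean")
  d_bg <- EBImage::distmap(1L - img, metric = "euclidean")
  as.matrix(d_fg) - as.matrix(d_bg)
}

#' Synthesise a chimera silhouette
#'
#' Sums the differential distance transforms of the per-upright silhouettes
#' and keeps pixels where the sum is strictly positive. With a single input
#' (or N identical inputs) the chimera is exactly that silhouette; with mixed
#' inputs it is a majority-like blend.
#'
#' @param uprights non-empty list of binary matrices on a common grid.
#' @return binary matrix.
#' @export
synthesize_chimera <- function(uprights) {
  if (length(uprights) == 0) stop("need at least one silhouette")
  dims <- lapply(uprights, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all silhouettes must share one grid")
  acc <- Reduce(`+`, lapply(uprights, differential_distance_transform))
  out <- matrix(0L, nrow(acc), ncol(acc))
  out[acc > 0] <- 1L
  out
}

# Second central moments of the foreground pixel set; returns list with
# eigenvalues (l1 >= l2) of the covariance matrix.
.shape_moments <- function(img) {
  fg <- .fg_coords(img)
  if (nrow(fg) == 0) stop("empty foreground")
  cen <- colMeans(fg)
  dy <- fg[, 1] - cen[1]; dx <- fg[, 2] - cen[2]
  m20 <- mean(dx^2); m02 <- mean(dy^2); m11 <- mean(dx * dy)
  tr <- m20 + m02
  det <- m20 * m02 - m11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  list(l1 = tr / 2 + disc, l2 = max(0, tr / 2 - disc))
}

#' Ellipse eccentricity of a silhouette (UKEC)
#'
#' Eccentricity sqrt(1 - b^2/a^2) of the ellipse with the same second central
#' moments; 0 for a circle, approaching 1 for elongated shapes. Degenerate
#' (line-like) shapes return the sentinel 1 with a warning.
#' @param img binary matrix.
#' @return eccentricity in [0, 1].
#' @export
eccentricity <- function(img) {
  .check_binary(img)
  m <- .shape_moments(img)
  if (m$l1 <= 0) stop("degenerate shape: no spatial extent")
  if (m$l2 / m$l1 < 1e-12) {
    warning("degenerate line-like shape; eccentricity sentinel 1")
    return(1)
  }
  sqrt(1 - m$l2 / m$l1)
}

#' Length-to-width ratio of a silhouette (UKLvW)
#'
#' Major/minor axis length of the moment-matched ellipse; >= 1 by definition.
#' @param img binary matrix.
#' @return ratio >= 1.
#' @export
length_width <- function(img) {
  .check_binary(img)
  m <- .shape_moments(img)
  if (m$l2 <= 0) stop("degenerate shape: zero minor axis")
  sqrt(m$l1 / m$l2)
}

#' Solidity of a silhouette (UKSO)
#'
#' Foreground area divided by the area of the convex hull of the foreground
#' pixel squares (corners at half-integer offsets), so solidity <= 1 always,
#' with equality (up to rasterisation) for convex shapes.
#' @param img binary matrix.
#' @return solidity in (0, 1].
#' @export
solidity <- function(img) {
  .check_binary(img)
  fg <- .fg_coords(img)
  if (nrow(fg) == 0) stop("empty foreground")
  corners <- rbind(cbind(fg[, 1] - 0.5, fg[, 2] - 0.5),
                   cbind(fg[, 1] - 0.5, fg[, 2] + 0.5),
                   cbind(fg[, 1] + 0.5, fg[, 2] - 0.5),
                   cbind(fg[, 1] + 0.5, fg[, 2] + 0.5))
  hull <- corners[grDevices::chull(corners), , drop = FALSE]
  x <- hull[, 2]; y <- hull[, 1]
  hull_area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  min(1, nrow(fg) / hull_area)
}

# Outer contour as a closed polyline (n x 2, columns x, y), from EBImage's
# contour tracer on the largest component.
.outer_contour <- function(img) {
  .check_binary(img)
  storage.mode(img) <- "integer"
  oc <- EBImage::ocontour(EBImage::bwlabel(img))
  if (length(oc) == 0) stop("no contour found")
  oc[[which.max(vapply(oc, nrow, integer(1)))]]
}

# Resample a closed polyline into m points equally spaced in arc length.
.resample_contour <- function(pts, m) {
  pts <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(pts)^2))
  if (sum(seg) <= 0) stop("degenerate contour")
  s <- c(0, cumsum(seg))
  target <- seq(0, s[length(s)], length.out = m + 1)[-(m + 1)]
  cbind(stats::approx(s, pts[, 1], xout = target)$y,
        stats::approx(s, pts[, 2], xout = target)$y)
}

# Turning angles (radians, wrapped to (-pi, pi]) between consecutive segments
# of the m-segment resampled contour.
.turning_angles <- function(img, m) {
  p <- .resample_contour(.outer_contour(img), m)
  d <- diff(rbind(p, p[1, , drop = FALSE]))
  ang <- atan2(d[, 2], d[, 1])
  turn <- diff(c(ang, ang[1]))
  ((turn + pi) %% (2 * pi)) - pi
}

#' Slope-chain-code tortuosity (UKTO)
#'
#' The outer contour is resampled into \code{m} equal-length segments; the
#' tortuosity is the sum of absolute slope changes between consecutive
#' segments, each normalised by pi (so a convex contour gives exactly 2, one
#' full turn, and waviness adds on top).
#'
#' @param img binary matrix with a closed outer contour.
#' @param m number of chain segments (default 64).
#' @return tortuosity >= 0 (dimensionless).
#' @export
tortuosity <- function(img, m = 64) {
  sum(abs(.turning_angles(img, m))) / pi
}

#' Total signed contour turning
#'
#' Net turning of the resampled outer contour in full turns; +/-1 for a simple
#' closed contour (sign follows trace orientation). Used to sanity-check the
#' slope-chain normalisation.
#' @inheritParams tortuosity
#' @return signed number of full turns.
#' @export
total_turning <- function(img, m = 64) {
  sum(.turning_angles(img, m)) / (2 * pi)
}

#' Unsigned Manhattan chain code step counts (UKUX, UKUY)
#'
#' Traces the silhouette boundary as unit moves along pixel edges (crack
#' code) and counts horizontal and vertical unit moves. Returns their log10:
#' UKUX = log10(#horizontal moves), UKUY = log10(#vertical moves). For an
#' axis-aligned w x h rectangle these are log10(2w) and log10(2h).
#'
#' @param img binary matrix, hole-free foreground.
#' @return named numeric vector c(UKUX, UKUY).
#' @export
umcc <- function(img) {
  .check_binary(img)
  h <- nrow(img); w <- ncol(img)
  # horizontal boundary edges separate vertically adjacent discordant pixels
  n_horiz <- sum(img[-h, ] != img[-1, ]) + sum(img[1, ]) + sum(img[h, ])
  n_vert <- sum(img[, -w] != img[, -1]) + sum(img[, 1]) + sum(img[, w])
  if (n_horiz + n_vert < 4) stop("contour shorter than 4 moves")
  c(UKUX = log10(n_horiz), UKUY = log10(n_vert))
}

#' All six chimera shape descriptors
#'
#' @param img binary matrix (typically a chimera).
#' @param m slope-chain segment count passed to \code{\link{tortuosity}}.
#' @return one-row data.frame with UKEC, UKLvW, UKTO, UKSO, UKUX, UKUY.
#' @export
shape_descriptors <- function(img, m = 64) {
  u <- umcc(img)
  data.frame(UKEC = eccentricity(img), UKLvW = length_width(img),
             UKTO = tortuosity(img, m), UKSO = solidity(img),
             UKUX = unname(u["UKUX"]), UKUY = unname(u["UKUY"]))
}

#' Chimera descriptors for a table of categorical shape scores
#'
#' For each genotype-year, replaces the per-upright shape classes by their
#' templates, synthesises the chimera, and computes the six descriptors.
#'
#' @param scores data.frame(genotype, year, upright, shape_class) as from
#'   \code{\link{simulate_shape_scores}}.
#' @param templates template list from \code{\link{shape_templates}} (built
#'   with defaults when NULL).
#' @param m slope-chain segment count.
#' @return tidy data.frame (genotype, year, UKEC, UKLvW, UKTO, UKSO, UKUX,
#'   UKUY).
#' @export
chimera_descriptors <- function(scores, templates = NULL, m = 64) {
  stopifnot(all(c("genotype", "year", "shape_class") %in% names(scores)))
  if (is.null(templates)) templates <- shape_templates()
  bad <- setdiff(unique(scores$shape_class), names(templates))
  if (length(bad)) stop("unknown shape classes: ", paste(bad, collapse = ", "))
  keys <- unique(scores[, c("genotype", "year")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- scores$genotype == keys$genotype[i] & scores$year == keys$year[i]
    chim <- synthesize_chimera(templates[scores$shape_class[sel]])
    cbind(keys[i, , drop = FALSE], shape_descriptors(chim, m))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
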