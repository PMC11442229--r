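# Synthetic four-way-cross data with known ground truth.
#
# The generator mirrors the structure of the field data the downstream stages
# expect: a composite linkage map, AC/AD/BC/BD progeny genotype classes, and
# multi-year per-upright phenotypes with genetic, genotype-by-year, spatial and
# residual components. Every stochastic component is returned in a ground-truth
# sidecar so parameter recovery can be tested.

#' Four-way genotype class labels
#'
#' Progeny classes of an outbred four-way cross: maternal alleles A/B crossed
#' with paternal alleles C/D.
#' @export
GENOTYPE_CLASSES <- c("AC", "AD", "BC", "BD")

#' Berry shape class labels
#'
#' The five categorical berry-shape classes used by trait evaluators. These are
#' synthetic stand-ins for the canonical scoring card (round through spindle);
#' each has a programmatically generated silhouette template (see
#' \code{\link{shape_templates}}).
#' @export
SHAPE_CLASSES <- c("round", "oval", "oblong", "pyriform", "spindle")

# Run code under a seed without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Haldane map function
#'
#' Recombination fraction between two loci d centimorgans apart under no
#' crossover interference: r = (1 - exp(-2d/100)) / 2.
#'
#' @param d map distance in centimorgans (cM), non-negative.
#' @return recombination fraction in [0, 0.5).
#' @export
haldane_r <- function(d) {
  stopifnot(all(d >= 0))
  (1 - exp(-2 * d / 100)) / 2
}

#' Simulate a linkage map
#'
#' Builds a marker map over \code{n_lg} linkage groups. Defaults match the
#' scale of the cranberry composite map (12 linkage groups, 130 markers each,
#' 1560 markers total, ~90 cM per group).
#'
#' @param n_lg number of linkage groups (>= 1).
#' @param markers_per_lg markers per linkage group (>= 2).
#' @param length_cm linkage group length in cM.
#' @param seed integer seed (used when \code{spacing = "random"}).
#' @param spacing \code{"uniform"} for equal spacing spanning [0, length_cm],
#'   \code{"random"} for sorted uniform-random positions with the ends pinned.
#' @return data.frame with columns \code{marker_id}, \code{linkage_group},
#'   \code{position} (cM, non-decreasing within group).
#' @export
simulate_map <- function(n_lg = 12, markers_per_lg = 130, length_cm = 90,
                         seed = 1, spacing = c("uniform", "random")) {
  spacing <- match.arg(spacing)
  if (n_lg < 1 || markers_per_lg < 2 || length_cm <= 0)
    stop("need n_lg >= 1, markers_per_lg >= 2, length_cm > 0")
  pos_one <- function(lg) {
    if (spacing == "uniform") seq(0, length_cm, length.out = markers_per_lg)
    else sort(c(0, runif(markers_per_lg - 2, 0, length_cm), length_cm))
  }
  with_seed(seed, {
    lgs <- rep(seq_len(n_lg), each = markers_per_lg)
    pos <- unlist(lapply(seq_len(n_lg), pos_one))
    data.frame(
      marker_id = sprintf("M%02d_%03d", lgs, sequence(rep(markers_per_lg, n_lg))),
      linkage_group = lgs,
      position = pos,
      stringsAsFactors = FALSE
    )
  })
}

# Simulate one parental gamete (two alleles) for all progeny along ordered
# positions of a single linkage group: a two-state Markov chain with Haldane
# transition probabilities. Returns n x length(pos) matrix of 1/2 allele codes.
.sim_gamete_chain <- function(positions, n, alleles) {
  m <- length(positions)
  out <- matrix(0L, n, m)
  out[, 1] <- sample(1:2, n, replace = TRUE)
  if (m > 1) {
    r <- haldane_r(diff(positions))
    for (j in 2:m) {
      swap <- runif(n) < r[j - 1]
      out[, j] <- ifelse(swap, 3L - out[, j - 1], out[, j - 1])
    }
  }
  matrix(alleles[out], n, m)
}

#' Simulate four-way-cross progeny genotypes
#'
#' Maternal (A/B) and paternal (C/D) gametes are simulated independently per
#' linkage group as Markov chains with Haldane recombination fractions between
#' adjacent markers; each progeny's genotype class at a marker is the gamete
#' pair (AC, AD, BC or BD).
#'
#' @param map linkage map from \code{\link{simulate_map}}.
#' @param n_progeny number of progeny (>= 1).
#' @param seed integer seed.
#' @return character matrix (progeny x marker) of genotype classes, with
#'   dimnames; progeny ids are \code{P001}, \code{P002}, ...
#' @export
simulate_cross <- function(map, n_progeny, seed = 1) {
  if (n_progeny < 1) stop("n_progeny must be >= 1")
  check_map(map)
  with_seed(seed, {
    geno <- matrix(NA_character_, n_progeny, nrow(map),
                   dimnames = list(sprintf("P%03d", seq_len(n_progeny)),
                                   map$marker_id))
    for (lg in unique(map$linkage_group)) {
      idx <- which(map$linkage_group == lg)
      mat <- .sim_gamete_chain(map$position[idx], n_progeny, c("A", "B"))
      pat <- .sim_gamete_chain(map$position[idx], n_progeny, c("C", "D"))
      geno[, idx] <- paste0(mat, pat)
    }
    geno
  })
}

# Validate a linkage map data.frame.
check_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("marker_id", "linkage_group", "position") %in% names(map)))
  if (anyDuplicated(map$marker_id)) stop("duplicate marker_ids in map")
  for (lg in unique(map$linkage_group)) {
    p <- map$position[map$linkage_group == lg]
    if (length(p) < 2) stop("each linkage group needs >= 2 markers")
    if (is.unsorted(p)) stop("positions must be non-decreasing within a linkage group")
  }
  invisible(TRUE)
}

#' Simulate a rectangular field layout
#'
#' Assigns each progeny a (row, column) plot on a near-square grid, in a
#' seeded random order. The real trial's plot geometry is not published; a
#' compact rectangular grid is used as a neutral stand-in.
#'
#' @param progeny_ids character vector of progeny identifiers.
#' @param n_rows number of field rows; default ceiling(sqrt(n)).
#' @param seed integer seed.
#' @return data.frame(genotype, row, col), one row per progeny.
#' @export
simulate_layout <- function(progeny_ids, n_rows = NULL, seed = 1) {
  n <- length(progeny_ids)
  if (is.null(n_rows)) n_rows <- ceiling(sqrt(n))
  n_cols <- ceiling(n / n_rows)
  with_seed(seed, {
    ord <- sample(n)
    data.frame(genotype = progeny_ids,
               row = ((ord - 1) %/% n_cols) + 1L,
               col = ((ord - 1) %% n_cols) + 1L,
               stringsAsFactors = FALSE)
  })
}

#' Define a trait architecture
#'
#' Ground-truth generative parameters for one quantitative trait.
#'
#' @param qtl data.frame with columns \code{linkage_group}, \code{position},
#'   \code{maternal}, \code{paternal}, \code{interaction} (effect sizes in
#'   trait units; a maternal effect e means A-carriers average e more than
#'   B-carriers), or NULL for no QTL.
#' @param polygenic_variance additive background variance (trait units^2).
#' @param residual_variance per-upright residual variance.
#' @param gxy_variance genotype-by-year interaction variance.
#' @param spatial_amplitude amplitude (trait units) of the smooth 2-D field
#'   surface (polynomial + sinusoid).
#' @param row_variance,col_variance variances of iid row / column effects.
#' @param mu trait grand mean.
#' @param year_effects named numeric vector of fixed year effects, or NULL for
#'   all-zero.
#' @return list of class \code{trait_architecture}.
#' @export
trait_architecture <- function(qtl = NULL, polygenic_variance = 0,
                               residual_variance = 1, gxy_variance = 0,
                               spatial_amplitude = 0, row_variance = 0,
                               col_variance = 0, mu = 0, year_effects = NULL) {
  v <- c(polygenic_variance, residual_variance, gxy_variance,
         row_variance, col_variance)
  if (any(v < 0)) stop("variances must be >= 0")
  structure(list(qtl = qtl, polygenic_variance = polygenic_variance,
                 residual_variance = residual_variance,
                 gxy_variance = gxy_variance,
                 spatial_amplitude = spatial_amplitude,
                 row_variance = row_variance, col_variance = col_variance,
                 mu = mu, year_effects = year_effects),
            class = "trait_architecture")
}

# Smooth 2-D field surface on the unit square: a first-order polynomial tilt
# plus a sinusoidal bump, so both straight-line and non-polynomial spatial
# variation are exercised. Standardised to roughly unit range.
.spatial_surface <- function(row, col, n_rows, n_cols) {
  x <- (row - 1) / max(1, n_rows - 1)
  y <- (col - 1) / max(1, n_cols - 1)
  0.5 * (x + y - 1) + 0.5 * sin(2 * pi * x) * cos(pi * y)
}

#' Simulate multi-year per-upright phenotypes
#'
#' Generates observations y = mu + year effect + QTL contrast effects +
#' polygenic value + genotype-by-year deviation + row + column + smooth 2-D
#' spatial surface + per-upright residual. QTL effects are applied through the
#' genotype class at the marker nearest each QTL position (the truth sidecar
#' records which). All ground-truth components are returned alongside the
#' observations and sum exactly to them.
#'
#' @param geno genotype matrix from \code{\link{simulate_cross}}.
#' @param map linkage map.
#' @param arch \code{\link{trait_architecture}}.
#' @param layout field layout from \code{\link{simulate_layout}}.
#' @param years vector of year labels (non-empty).
#' @param uprights_per_genotype uprights sampled per genotype-year (default 10,
#'   the traditional sampling intensity).
#' @param seed integer seed.
#' @param trait trait name recorded in the output.
#' @param polygenic_K optional genotype covariance for the polygenic term
#'   (e.g. the genomic relationship matrix, giving a GBLUP-consistent
#'   generative model); iid when NULL. Dimnames must cover the progeny.
#' @return list with \code{phenotypes} (long data.frame: genotype, year, row,
#'   col, upright, trait, value, rot_flag) and \code{truth} (per genotype-year
#'   component table plus per-observation residuals and the realised QTL
#'   marker classes).
#' @export
simulate_traits <- function(geno, map, arch, layout, years,
                            uprights_per_genotype = 10, seed = 1,
                            trait = "Y", polygenic_K = NULL) {
  if (length(years) == 0) stop("years must be non-empty")
  if (!inherits(arch, "trait_architecture")) stop("arch must be a trait_architecture")
  ids <- rownames(geno)
  if (!all(ids %in% layout$genotype)) stop("all progeny must be present in layout")
  lay <- layout[match(ids, layout$genotype), ]
  n <- length(ids)
  yrs <- as.character(years)
  ny <- length(yrs)
  year_eff <- stats::setNames(rep(0, ny), yrs)
  if (!is.null(arch$year_effects)) {
    if (!all(yrs %in% names(arch$year_effects)))
      stop("year_effects must name every year")
    year_eff[yrs] <- arch$year_effects[yrs]
  }

  with_seed(seed, {
    # genotype-level genetic components
    qtl_eff <- rep(0, n)
    qtl_classes <- NULL
    if (!is.null(arch$qtl) && nrow(arch$qtl) > 0) {
      qtl_classes <- matrix(NA_character_, n, nrow(arch$qtl))
      for (k in seq_len(nrow(arch$qtl))) {
        q <- arch$qtl[k, ]
        idx <- which(map$linkage_group == q$linkage_group)
        if (length(idx) == 0) stop("QTL linkage group not on map")
        mk <- idx[which.min(abs(map$position[idx] - q$position))]
        cls <- geno[, mk]
        qtl_classes[, k] <- cls
        mat <- ifelse(substr(cls, 1, 1) == "A", 0.5, -0.5) * q$maternal
        pat <- ifelse(substr(cls, 2, 2) == "C", 0.5, -0.5) * q$paternal
        int <- ifelse(cls %in% c("AC", "BD"), 0.5, -0.5) * q$interaction
        qtl_eff <- qtl_eff + mat + pat + int
      }
    }
    poly_eff <- if (arch$polygenic_variance > 0) {
      if (is.null(polygenic_K)) rnorm(n, 0, sqrt(arch$polygenic_variance))
      else {
        K <- polygenic_K[ids, ids]
        L <- t(chol(K + diag(1e-8, n)))
        drop(L %*% rnorm(n, 0, sqrt(arch$polygenic_variance)))
      }
    } else rep(0, n)
    gxy <- if (arch$gxy_variance > 0)
      matrix(rnorm(n * ny, 0, sqrt(arch$gxy_variance)), n, ny) else
      matrix(0, n, ny)

    rows <- sort(unique(lay$row)); cols <- sort(unique(lay$col))
    row_eff <- if (arch$row_variance > 0)
      stats::setNames(rnorm(length(rows), 0, sqrt(arch$row_variance)), rows) else
      stats::setNames(rep(0, length(rows)), rows)
    col_eff <- if (arch$col_variance > 0)
      stats::setNames(rnorm(length(cols), 0, sqrt(arch$col_variance)), cols) else
      stats::setNames(rep(0, length(cols)), cols)
    spat <- arch$spatial_amplitude *
      .spatial_surface(lay$row, lay$col, max(lay$row), max(lay$col))

    comp <- expand.grid(genotype = ids, year = yrs,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gi <- match(comp$genotype, ids)
    yi <- match(comp$year, yrs)
    comp$mu <- arch$mu
    comp$year_effect <- year_eff[yi]
    comp$qtl_effect <- qtl_eff[gi]
    comp$polygenic <- poly_eff[gi]
    comp$gxy <- gxy[cbind(gi, yi)]
    comp$row_effect <- unname(row_eff[as.character(lay$row[gi])])
    comp$col_effect <- unname(col_eff[as.character(lay$col[gi])])
    comp$spatial <- spat[gi]
    comp$genetic_value <- comp$qtl_effect + comp$polygenic
    base <- comp$mu + comp$year_effect + comp$qtl_effect + comp$polygenic +
      comp$gxy + comp$row_effect + comp$col_effect + comp$spatial

    nu <- uprights_per_genotype
    obs <- comp[rep(seq_len(nrow(comp)), each = nu), ]
    obs$upright <- rep(seq_len(nu), nrow(comp))
    resid <- if (arch$residual_variance > 0)
      rnorm(nrow(obs), 0, sqrt(arch$residual_variance)) else rep(0, nrow(obs))
    phen <- data.frame(
      genotype = obs$genotype, year = obs$year,
      row = lay$row[match(obs$genotype, ids)],
      col = lay$col[match(obs$genotype, ids)],
      upright = obs$upright, trait = trait,
      value = rep(base, each = nu) + resid,
      rot_flag = FALSE, stringsAsFactors = FALSE)
    truth <- list(components = comp, residuals = resid,
                  qtl_marker_classes = qtl_classes)
    list(phenotypes = phen, truth = truth)
  })
}

#' Simulate categorical berry-shape scores
#'
#' Each (genotype, year, upright) is assigned one of the five shape classes,
#' drawn from that genotype's class distribution.
#'
#' @param n_genotypes number of genotypes.
#' @param uprights_per_genotype uprights per genotype-year.
#' @param class_bias numeric vector of 5 probabilities (recycled to all
#'   genotypes) or an n_genotypes x 5 matrix of per-genotype distributions.
#' @param years vector of year labels.
#' @param seed integer seed.
#' @return data.frame(genotype, year, upright, shape_class).
#' @export
simulate_shape_scores <- function(n_genotypes, uprights_per_genotype = 10,
                                  class_bias = rep(0.2, 5),
                                  years = "2011", seed = 1) {
  if (is.null(dim(class_bias)))
    class_bias <- matrix(class_bias, n_genotypes, 5, byrow = TRUE)
  if (ncol(class_bias) != 5) stop("class_bias needs 5 classes")
  if (any(class_bias < 0)) stop("class_bias must be non-negative")
  if (any(abs(rowSums(class_bias) - 1) > 1e-8))
    stop("class_bias rows must sum to 1")
  ids <- sprintf("P%03d", seq_len(n_genotypes))
  with_seed(seed, {
    out <- expand.grid(upright = seq_len(uprights_per_genotype),
                       year = as.character(years), genotype = ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gi <- match(out$genotype, ids)
    u <- runif(nrow(out))
    cum <- t(apply(class_bias, 1, cumsum))
    cls <- SHAPE_CLASSES[max.col(cum[gi, , drop = FALSE] >= u, "first")]
    out$shape_class <- cls
    out[, c("genotype", "year", "upright", "shape_class")]
  })
}
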