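# Independent oracles and fixture builders used across the suite.

# Brute-force differential distance transform: per-pixel nearest-neighbour
# search (O(n^2)), independent of the EDT implementation under test.
brute_ddt <- function(img) {
  fg <- which(img > 0, arr.ind = TRUE)
  bg <- which(img == 0, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(img), ncol(img))
  for (k in seq_len(nrow(fg)))
    out[fg[k, 1], fg[k, 2]] <-
      sqrt(min((fg[k, 1] - bg[, 1])^2 + (fg[k, 2] - bg[, 2])^2))
  for (k in seq_len(nrow(bg)))
    out[bg[k, 1], bg[k, 2]] <-
      -sqrt(min((bg[k, 1] - fg[, 1])^2 + (bg[k, 2] - fg[, 2])^2))
  out
}

# Rasterise a disc / axis-aligned ellipse on an s x s grid.
raster_disc <- function(s, r, cy = (s + 1) / 2, cx = (s + 1) / 2) {
  y <- matrix(seq_len(s), s, s); x <- t(y)
  m <- matrix(0L, s, s)
  m[(y - cy)^2 + (x - cx)^2 <= r^2] <- 1L
  m
}
raster_ellipse <- function(s, a, b) {   # a: semi-axis along x, b: along y
  y <- matrix(seq_len(s), s, s); x <- t(y)
  c0 <- (s + 1) / 2
  m <- matrix(0L, s, s)
  m[((x - c0) / a)^2 + ((y - c0) / b)^2 <= 1] <- 1L
  m
}

# Random connected-ish binary blob (union of random discs), plus pure noise.
random_blob <- function(s = 24) {
  m <- matrix(0L, s, s)
  for (i in seq_len(sample(1:3, 1)))
    m <- m | raster_disc(s, runif(1, 2, s / 4),
                         runif(1, s / 4, 3 * s / 4),
                         runif(1, s / 4, 3 * s / 4))
  storage.mode(m) <- "integer"
  m
}
random_binary <- function(s = 24, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.2, 0.8)
  matrix(rbinom(s * s, 1, p), s, s)
}

# Exhaustive maximal-clique enumeration over interval overlap, for <= ~15
# intervals: checks every vertex subset for cliqueness and maximality.
brute_force_cliques <- function(lo, hi, lg = rep(1, length(lo))) {
  n <- length(lo)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    lg[i] == lg[j] & pmax(lo[i], lo[j]) <= pmin(hi[i], hi[j]))
  diag(adj) <- TRUE
  is_clique <- function(v) all(adj[v, v])
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    v <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!is_clique(v)) next
    ext <- setdiff(seq_len(n), v)
    maximal <- !any(vapply(ext, function(w) all(adj[w, v]), logical(1)))
    if (maximal) out[[length(out) + 1]] <- v
  }
  out[order(vapply(out, paste, character(1), collapse = ","))]
}

# QTL-table row builder.
qtl_row <- function(lg, lo, hi, trait = "t", population = "p", study = "s",
                    model = "m", method = "scanone", r2 = 0.2,
                    am = 0, ap = 0, ai = 0, lod = 5) {
  data.frame(trait = trait, population = population, study = study,
             model = model, method = method, linkage_group = as.character(lg),
             position = (lo + hi) / 2, lod = lod, marker_r2 = r2,
             lo = lo, hi = hi, effect_maternal = am, effect_paternal = ap,
             effect_interaction = ai, stringsAsFactors = FALSE)
}

make_qtl_table <- function(lo, hi, lg = rep(1, length(lo)), ...) {
  do.call(rbind, lapply(seq_along(lo), function(i)
    qtl_row(lg[i], lo[i], hi[i], model = paste0("m", i), ...)))
}

# Simulate one single-QTL trait on an existing cross: effect e on the
# maternal contrast at a chosen marker, residual sd chosen for a target PVE
# (theoretical variance of the +/- e/2 contrast is e^2/4).
single_qtl_phenotype <- function(geno, marker, effect = 1, pve = 0.2) {
  xm <- ifelse(substr(geno[, marker], 1, 1) == "A", 0.5, -0.5)
  gvar <- effect^2 / 4
  effect * xm + rnorm(nrow(geno), 0, sqrt(gvar * (1 - pve) / pve))
}
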