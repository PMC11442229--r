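# Haley-Knott genome scans for a four-way outbred cross.
#
# Genotype-class probabilities (AC/AD/BC/BD) are computed at markers and
# pseudomarkers by conditioning each parental gamete on its nearest informative
# flanking markers under the Haldane map function. Scans regress the phenotype
# (genotype BLUPs) on the expected class contrasts; significance comes from
# permutation thresholds, support from 1.5-LOD intervals, and effect sizes
# from the three parental contrasts of the fitted class means.

# Conditional P(allele = first) at position p for one gamete, given observed
# 1/2 codes at flanking typed markers (two-flank Markov conditioning).
.flank_prob <- function(p, pos, obs) {
  n <- nrow(obs)
  out <- rep(0.5, n)
  m <- length(pos)
  for (i in seq_len(n)) {
    typed <- which(!is.na(obs[i, ]))
    if (length(typed) == 0) next
    lf <- typed[pos[typed] <= p]
    rf <- typed[pos[typed] >= p]
    lf <- if (length(lf)) lf[length(lf)] else NA
    rf <- if (length(rf)) rf[1] else NA
    if (!is.na(lf) && pos[lf] == p) { out[i] <- as.numeric(obs[i, lf] == 1); next }
    if (!is.na(rf) && pos[rf] == p) { out[i] <- as.numeric(obs[i, rf] == 1); next }
    if (!is.na(lf) && !is.na(rf)) {
      rl <- haldane_r(p - pos[lf]); rr <- haldane_r(pos[rf] - p)
      # path probabilities through latent allele 1 vs 2
      pl <- if (obs[i, lf] == 1) c(1 - rl, rl) else c(rl, 1 - rl)
      pr <- if (obs[i, rf] == 1) c(1 - rr, rr) else c(rr, 1 - rr)
      num <- pl * pr
      out[i] <- num[1] / sum(num)
    } else if (!is.na(lf)) {
      rl <- haldane_r(p - pos[lf])
      out[i] <- if (obs[i, lf] == 1) 1 - rl else rl
    } else {
      rr <- haldane_r(pos[rf] - p)
      out[i] <- if (obs[i, rf] == 1) 1 - rr else rr
    }
  }
  out
}

# Vectorised fast path for progeny with no missing calls on the linkage group.
.flank_prob_complete <- function(p, pos, obs) {
  m <- length(pos)
  lf <- findInterval(p, pos)
  if (lf >= 1 && pos[lf] == p) return(as.numeric(obs[, lf] == 1))
  rf <- lf + 1
  if (lf >= 1 && rf <= m) {
    rl <- haldane_r(p - pos[lf]); rr <- haldane_r(pos[rf] - p)
    # joint path probabilities through latent allele 1 vs 2
    a1 <- ifelse(obs[, lf] == 1, 1 - rl, rl) * ifelse(obs[, rf] == 1, 1 - rr, rr)
    a2 <- ifelse(obs[, lf] == 1, rl, 1 - rl) * ifelse(obs[, rf] == 1, rr, 1 - rr)
    return(a1 / (a1 + a2))
  }
  if (lf >= 1) {
    rl <- haldane_r(p - pos[lf])
    return(ifelse(obs[, lf] == 1, 1 - rl, rl))
  }
  rr <- haldane_r(pos[rf] - p)
  ifelse(obs[, rf] == 1, 1 - rr, rr)
}

#' Genotype-class probabilities at markers and pseudomarkers
#'
#' For each linkage group, lays a grid of positions (the markers plus
#' pseudomarkers every \code{step} cM) and computes, per progeny, the
#' probability of each four-way class. The maternal (A/B) and paternal (C/D)
#' gametes are conditioned independently on their nearest informative flanking
#' markers with Haldane recombination; class probability is the product of
#' gamete probabilities. At a typed marker the observed class has probability
#' one.
#'
#' @param geno genotype matrix from \code{\link{simulate_cross}} (NAs allowed).
#' @param map linkage map.
#' @param step pseudomarker spacing in cM (default 1); a step larger than the
#'   group length yields markers only.
#' @return object of class \code{genoprob}: per-LG list with \code{pos},
#'   \code{is_marker} and \code{prob} (progeny x position x 4 classes), plus
#'   the progeny ids.
#' @export
calc_genoprob <- function(geno, map, step = 1) {
  check_map(map)
  if (step <= 0) stop("step must be positive")
  stopifnot(all(colnames(geno) == map$marker_id))
  mat_all <- ifelse(substr(geno, 1, 1) == "A", 1L, 2L)
  pat_all <- ifelse(substr(geno, 2, 2) == "C", 1L, 2L)
  lgs <- unique(map$linkage_group)
  out <- list()
  for (lg in lgs) {
    idx <- which(map$linkage_group == lg)
    pos <- map$position[idx]
    grid <- sort(unique(c(pos, seq(min(pos), max(pos), by = step))))
    is_marker <- grid %in% pos
    obs_m <- mat_all[, idx, drop = FALSE]
    obs_p <- pat_all[, idx, drop = FALSE]
    complete <- !anyNA(obs_m) && !anyNA(obs_p)
    n <- nrow(geno)
    prob <- array(NA_real_, c(n, length(grid), 4),
                  dimnames = list(rownames(geno), NULL, GENOTYPE_CLASSES))
    for (gidx in seq_along(grid)) {
      p <- grid[gidx]
      pA <- if (complete) .flank_prob_complete(p, pos, obs_m) else
        .flank_prob(p, pos, obs_m)
      pC <- if (complete) .flank_prob_complete(p, pos, obs_p) else
        .flank_prob(p, pos, obs_p)
      prob[, gidx, "AC"] <- pA * pC
      prob[, gidx, "AD"] <- pA * (1 - pC)
      prob[, gidx, "BC"] <- (1 - pA) * pC
      prob[, gidx, "BD"] <- (1 - pA) * (1 - pC)
    }
    out[[as.character(lg)]] <- list(pos = grid, is_marker = is_marker,
                                    prob = prob)
  }
  structure(list(lg = out, progeny = rownames(geno), step = step),
            class = "genoprob")
}

# Haley-Knott design matrix at one grid position: intercept plus the expected
# maternal, paternal and interaction contrasts (each in [-1, 1]).
.hk_design <- function(pr) {
  pA <- pr[, "AC"] + pr[, "AD"]
  pC <- pr[, "AC"] + pr[, "BC"]
  xi <- pr[, "AC"] + pr[, "BD"] - pr[, "AD"] - pr[, "BC"]
  cbind(intercept = 1, xm = 2 * pA - 1, xp = 2 * pC - 1, xi = xi)
}

# Residual sum of squares of Y (n x k) on design X, rank-tolerant.
.rss <- function(X, Y) {
  q <- qr(X)
  res <- qr.resid(q, Y)
  colSums(as.matrix(res)^2)
}

#' Haley-Knott single-QTL genome scan
#'
#' At every grid position, regresses the phenotype on the expected class
#' contrasts and reports LOD = (n/2) log10(RSS0 / RSS1), RSS0 being the
#' intercept-only fit. \code{y} may be a matrix (phenotypes in columns), in
#' which case all columns are scanned in one pass -- this is how permutation
#' and null-replicate scans stay fast.
#'
#' @param probs \code{genoprob} object.
#' @param y numeric vector, or matrix with one phenotype per column, aligned
#'   with the progeny of \code{probs}.
#' @return list of class \code{scan_result}: \code{map} (data.frame lg,
#'   position, is_marker) and \code{lod} (positions x phenotypes matrix).
#' @export
scanone_hk <- function(probs, y) {
  Y <- as.matrix(y)
  n <- nrow(Y)
  if (n != length(probs$progeny)) stop("phenotype length mismatch")
  keep <- stats::complete.cases(Y)
  Yk <- Y[keep, , drop = FALSE]
  nk <- nrow(Yk)
  if (nk < 8) stop("need >= 8 phenotyped genotypes")
  rss0 <- .rss(matrix(1, nk, 1), Yk)
  maps <- list(); lods <- list()
  for (lg in names(probs$lg)) {
    pl <- probs$lg[[lg]]
    np <- length(pl$pos)
    lod <- matrix(0, np, ncol(Yk))
    for (i in seq_len(np)) {
      X <- .hk_design(pl$prob[keep, i, ])
      rss1 <- .rss(X, Yk)
      lod[i, ] <- pmax(0, (nk / 2) * log10(rss0 / pmax(rss1, 1e-300)))
    }
    maps[[lg]] <- data.frame(lg = lg, position = pl$pos,
                             is_marker = pl$is_marker,
                             stringsAsFactors = FALSE)
    lods[[lg]] <- lod
  }
  structure(list(map = do.call(rbind, maps), lod = do.call(rbind, lods),
                 n = nk), class = "scan_result")
}

#' Genome-wide permutation threshold
#'
#' Permutes the phenotype across genotypes \code{n_perm} times, records each
#' permutation's genome-wide maximum LOD, and returns the requested
#' percentile of that null distribution (80th for single-QTL significance,
#' 95th for the stepwise penalty).
#'
#' @param probs \code{genoprob} object.
#' @param y phenotype vector.
#' @param n_perm number of permutations (default 1000).
#' @param percentile percentile of the max-LOD null distribution, in (0, 100).
#' @param seed integer seed; same seed, same threshold.
#' @return list of class \code{perm_threshold}: \code{threshold},
#'   \code{max_lod} (per permutation), \code{n_perm}, \code{percentile},
#'   \code{seed}.
#' @export
permutation_threshold <- function(probs, y, n_perm = 1000, percentile = 80,
                                  seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (percentile <= 0 || percentile >= 100) stop("percentile must be in (0,100)")
  Yp <- with_seed(seed,
                  vapply(seq_len(n_perm), function(i) sample(y), y))
  sc <- scanone_hk(probs, Yp)
  mx <- apply(sc$lod, 2, max)
  structure(list(threshold = unname(stats::quantile(mx, percentile / 100)),
                 max_lod = mx, n_perm = n_perm, percentile = percentile,
                 seed = seed), class = "perm_threshold")
}

#' 1.5-LOD support interval
#'
#' Outermost grid positions, on the peak's linkage group, whose LOD stays
#' within \code{drop} of the peak. Ties for the peak are broken leftmost.
#'
#' @param scan \code{scan_result} (single phenotype).
#' @param lg linkage group to profile (default: the genome-wide peak's).
#' @param drop LOD drop defining the support interval (default 1.5).
#' @return list: \code{lo}, \code{hi}, \code{peak} (position), \code{lod}
#'   (peak LOD), \code{lg}, \code{flat} (TRUE when the curve is flat and the
#'   whole group is returned).
#' @export
lod_interval <- function(scan, lg = NULL, drop = 1.5) {
  lod <- scan$lod[, 1]
  if (is.null(lg)) lg <- scan$map$lg[which.max(lod)]
  sel <- scan$map$lg == lg
  lodl <- lod[sel]; posl <- scan$map$position[sel]
  pk <- which.max(lodl)   # leftmost maximum
  flat <- diff(range(lodl)) == 0
  ok <- lodl >= lodl[pk] - drop
  list(lo = min(posl[ok]), hi = max(posl[ok]), peak = posl[pk],
       lod = lodl[pk], lg = lg, flat = flat)
}

#' Parental effect contrasts and marker R-squared at a fitted position
#'
#' Fits the Haley-Knott regression at one position and reports the three
#' contrasts of the fitted class means -- maternal AvB = (AC+AD)-(BC+BD),
#' paternal CvD = (AC+BC)-(AD+BD), interaction Int = (AC+BD)-(AD+BC) -- and
#' the marker variance explained R2 = 1 - 10^(-2 LOD / n).
#'
#' @param probs \code{genoprob} object.
#' @param lg linkage group (name) of the position.
#' @param pos grid position in cM.
#' @param y phenotype vector.
#' @param lod LOD at the position (for R2).
#' @return list: \code{AvB}, \code{CvD}, \code{Int}, \code{marker_r2},
#'   \code{class_means}.
#' @export
effects_and_r2 <- function(probs, lg, pos, y, lod) {
  pl <- probs$lg[[as.character(lg)]]
  i <- which.min(abs(pl$pos - pos))
  keep <- !is.na(y)
  X <- .hk_design(pl$prob[keep, i, ])
  b <- qr.coef(qr(X), y[keep])
  b[is.na(b)] <- 0
  cm <- c(AC = b[1] + b[2] + b[3] + b[4], AD = b[1] + b[2] - b[3] - b[4],
          BC = b[1] - b[2] + b[3] - b[4], BD = b[1] - b[2] - b[3] + b[4])
  names(cm) <- GENOTYPE_CLASSES
  list(AvB = unname(4 * b[2]), CvD = unname(4 * b[3]),
       Int = unname(4 * b[4]),
       marker_r2 = 1 - 10^(-2 * lod / sum(keep)), class_means = cm)
}

# Assemble one QtlHit row.
.qtl_hit <- function(trait, population, study, model, method, lg, iv, eff) {
  data.frame(trait = trait, population = population, study = study,
             model = model, method = method, linkage_group = lg,
             position = iv$peak, lod = iv$lod, marker_r2 = eff$marker_r2,
             lo = iv$lo, hi = iv$hi, effect_maternal = eff$AvB,
             effect_paternal = eff$CvD, effect_interaction = eff$Int,
             stringsAsFactors = FALSE)
}

#' Single-QTL scan summary above a threshold
#'
#' Runs the Haley-Knott scan and reports, per linkage group whose maximum LOD
#' reaches \code{threshold}, one QTL with its 1.5-LOD interval, effects and
#' marker R2 (the scanone summary convention).
#'
#' @param probs \code{genoprob} object.
#' @param y phenotype (BLUP) vector.
#' @param threshold LOD significance threshold (from
#'   \code{\link{permutation_threshold}} at the 80th percentile).
#' @param trait,population,study,model provenance labels for the QTL table.
#' @param drop LOD support drop (default 1.5).
#' @return data.frame of QTL hits (possibly empty) in the shared QTL-table
#'   schema.
#' @export
scan_summary <- function(probs, y, threshold, trait = "trait",
                         population = "pop", study = "this", model = "all years",
                         drop = 1.5) {
  sc <- scanone_hk(probs, y)
  hits <- list()
  for (lg in unique(sc$map$lg)) {
    sel <- sc$map$lg == lg
    if (max(sc$lod[sel, 1]) < threshold) next
    iv <- lod_interval(sc, lg = lg, drop = drop)
    eff <- effects_and_r2(probs, lg, iv$peak, y, iv$lod)
    hits[[lg]] <- .qtl_hit(trait, population, study, model, "scanone",
                           lg, iv, eff)
  }
  if (length(hits) == 0) return(empty_qtl_table())
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

# Joint Haley-Knott design for a set of (lg, grid index) QTL positions.
.multi_design <- function(probs, qtl_idx, keep) {
  Xs <- lapply(qtl_idx, function(q)
    .hk_design(probs$lg[[q$lg]]$prob[keep, q$i, ])[, -1, drop = FALSE])
  cbind(1, do.call(cbind, Xs))
}

#' Stepwise additive multiple-QTL search
#'
#' Forward selection of additive QTL maximising the penalised LOD
#' pLOD = LOD(model) - penalty * (number of QTL), followed by backward
#' pruning, stopping when pLOD no longer improves. Per-QTL support intervals
#' come from profile LOD curves (all other QTL fixed); per-QTL LOD and marker
#' R2 from the drop-one LOD difference.
#'
#' @param probs \code{genoprob} object.
#' @param y phenotype (BLUP) vector.
#' @param penalty main-effect penalty in LOD units (the 95th-percentile
#'   permutation threshold).
#' @param max_qtl cap on model size (default 6).
#' @param trait,population,study,model provenance labels.
#' @param drop LOD support drop (default 1.5).
#' @return data.frame of QTL hits (possibly empty).
#' @export
stepwise_scan <- function(probs, y, penalty, max_qtl = 6, trait = "trait",
                          population = "pop", study = "this",
                          model = "all years", drop = 1.5) {
  keep <- !is.na(y)
  yk <- y[keep]
  n <- length(yk)
  rss0 <- sum((yk - mean(yk))^2)
  lod_of <- function(qtl) {
    if (length(qtl) == 0) return(0)
    X <- .multi_design(probs, qtl, keep)
    (n / 2) * log10(rss0 / max(sum(qr.resid(qr(X), yk)^2), 1e-300))
  }
  grid <- do.call(rbind, lapply(names(probs$lg), function(lg)
    data.frame(lg = lg, i = seq_along(probs$lg[[lg]]$pos),
               stringsAsFactors = FALSE)))
  model_q <- list()
  plod <- 0
  repeat {
    if (length(model_q) >= max_qtl) break
    # forward: best single addition
    best <- NULL; best_lod <- -Inf
    for (r in seq_len(nrow(grid))) {
      cand <- c(model_q, list(list(lg = grid$lg[r], i = grid$i[r])))
      l <- lod_of(cand)
      if (l > best_lod) { best_lod <- l; best <- cand }
    }
    cand_plod <- best_lod - penalty * length(best)
    if (!is.finite(cand_plod) || cand_plod <= plod + 1e-9) break
    model_q <- best; plod <- cand_plod
    # backward pruning
    repeat {
      if (length(model_q) <= 1) break
      drops <- vapply(seq_along(model_q), function(k)
        lod_of(model_q[-k]) - penalty * (length(model_q) - 1), numeric(1))
      if (max(drops) > plod + 1e-9) {
        k <- which.max(drops)
        model_q <- model_q[-k]; plod <- drops[k]
      } else break
    }
  }
  if (length(model_q) == 0) return(empty_qtl_table())

  full_lod <- lod_of(model_q)
  hits <- list()
  for (k in seq_along(model_q)) {
    q <- model_q[[k]]
    pl <- probs$lg[[q$lg]]
    others <- model_q[-k]
    prof <- vapply(seq_along(pl$pos), function(i)
      lod_of(c(others, list(list(lg = q$lg, i = i)))), numeric(1))
    pk <- which.max(prof)
    ok <- prof >= prof[pk] - drop
    iv <- list(lo = min(pl$pos[ok]), hi = max(pl$pos[ok]),
               peak = pl$pos[pk], lod = full_lod - lod_of(others), lg = q$lg)
    eff <- effects_and_r2(probs, q$lg, pl$pos[pk], y, iv$lod)
    hits[[k]] <- .qtl_hit(trait, population, study, model, "stepwiseqtl",
                          q$lg, iv, eff)
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}
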