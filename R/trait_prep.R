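# Phenotype curation: categorical encoding, outlier trimming, upright means,
# and correlation clustering of traits.

#' Default ordinal encoding for categorical traits
#'
#' A generic low/mid/high style mapping used when no trait-specific encoding
#' table is supplied; higher values represent more favourable characteristics.
#' Fully overridable via the \code{encoding} argument of
#' \code{\link{encode_categorical}}.
#' @export
default_encoding <- function(levels) {
  stats::setNames(seq_along(levels) - 1, levels)
}

#' Encode categorical traits to numeric values
#'
#' Applies a per-trait category-to-number mapping. Berry-shape classes are not
#' encoded: rows whose trait is in \code{shape_traits} are returned separately
#' for chimera synthesis.
#'
#' @param raw data.frame with at least columns \code{trait}, \code{value}
#'   (character or numeric).
#' @param encoding named list: trait -> named numeric vector (category ->
#'   value). Traits absent from the list are assumed already numeric.
#' @param shape_traits trait names passed through unencoded (default
#'   \code{"UBS"}, the categorical largest-berry-shape score).
#' @return list with \code{numeric} (encoded table, \code{value} numeric) and
#'   \code{shape} (the untouched shape-score rows).
#' @export
encode_categorical <- function(raw, encoding = list(), shape_traits = "UBS") {
  stopifnot(all(c("trait", "value") %in% names(raw)))
  is_shape <- raw$trait %in% shape_traits
  shape <- raw[is_shape, , drop = FALSE]
  num <- raw[!is_shape, , drop = FALSE]
  for (tr in intersect(names(encoding), unique(num$trait))) {
    sel <- num$trait == tr
    map <- encoding[[tr]]
    vals <- as.character(num$value[sel])
    unknown <- setdiff(unique(vals), names(map))
    if (length(unknown))
      stop("trait '", tr, "': no encoding for categories: ",
           paste(unknown, collapse = ", "))
    num$value[sel] <- unname(map[vals])
  }
  suppressWarnings(num$value <- as.numeric(num$value))
  if (anyNA(num$value))
    stop("non-numeric values remain after encoding; supply encodings for: ",
         paste(unique(num$trait[is.na(num$value)]), collapse = ", "))
  list(numeric = num, shape = shape)
}

#' Trim phenotype outliers
#'
#' Three-stage curation, applied per trait: (1) rows flagged as rotten are
#' removed; (2) a linear model value ~ population + genotype + year is fitted
#' and the observation with the largest externally studentised residual is
#' removed while its Bonferroni-adjusted two-sided p-value is below
#' \code{alpha} (via \code{car::outlierTest}, iterated to convergence);
#' (3) observations beyond \code{sd_cut} standard deviations of the trait
#' mean are culled. If the model is rank-deficient or otherwise unusable the
#' studentised step is skipped and logged.
#'
#' @param tbl phenotype data.frame with columns \code{trait}, \code{value},
#'   and (when present) \code{population}, \code{genotype}, \code{year},
#'   \code{rot_flag}.
#' @param alpha Bonferroni-adjusted p cutoff for the studentised test.
#' @param sd_cut standard-deviation multiplier for the tail cull.
#' @param max_iter safety cap on studentised-removal iterations.
#' @return list with \code{data} (curated table) and \code{log} (one row per
#'   removal: rule, trait, statistic, p).
#' @export
trim_outliers <- function(tbl, alpha = 0.05, sd_cut = 3, max_iter = 50) {
  stopifnot(all(c("trait", "value") %in% names(tbl)))
  log <- data.frame(rule = character(), trait = character(),
                    row_id = integer(), statistic = numeric(), p = numeric(),
                    stringsAsFactors = FALSE)
  tbl$.rid <- seq_len(nrow(tbl))
  if ("rot_flag" %in% names(tbl)) {
    rot <- which(tbl$rot_flag %in% TRUE)
    if (length(rot)) {
      log <- rbind(log, data.frame(rule = "rotten", trait = tbl$trait[rot],
                                   row_id = tbl$.rid[rot], statistic = NA,
                                   p = NA))
      tbl <- tbl[-rot, , drop = FALSE]
    }
  }
  terms <- intersect(c("population", "genotype", "year"), names(tbl))
  for (tr in unique(tbl$trait)) {
    # stage 2: iterated studentised-residual test
    for (it in seq_len(max_iter)) {
      sub <- tbl[tbl$trait == tr, , drop = FALSE]
      if (nrow(sub) < 10) break
      use <- terms[vapply(terms, function(v) length(unique(sub[[v]])) > 1,
                          logical(1))]
      if (length(use) == 0 || stats::var(sub$value) == 0) break
      fm <- tryCatch(
        stats::lm(stats::reformulate(use, "value"),
                  data = data.frame(value = sub$value,
                                    lapply(sub[use], as.factor))),
        error = function(e) NULL)
      if (is.null(fm)) {
        log <- rbind(log, data.frame(rule = "model_skipped", trait = tr,
                                     row_id = NA, statistic = NA, p = NA))
        break
      }
      ot <- tryCatch(car::outlierTest(fm, cutoff = alpha, n.max = 1),
                     error = function(e) NULL)
      if (is.null(ot) || all(is.na(ot$bonf.p)) || min(ot$bonf.p) >= alpha)
        break
      worst <- as.integer(names(ot$rstudent)[which.min(ot$bonf.p)])
      rid <- sub$.rid[worst]
      log <- rbind(log, data.frame(rule = "studentized", trait = tr,
                                   row_id = rid,
                                   statistic = unname(ot$rstudent[1]),
                                   p = unname(min(ot$bonf.p))))
      tbl <- tbl[tbl$.rid != rid, , drop = FALSE]
    }
    # stage 3: SD cull
    sel <- tbl$trait == tr
    v <- tbl$value[sel]
    s <- stats::sd(v)
    if (is.finite(s) && s > 0) {
      z <- abs(v - mean(v)) / s
      bad <- which(z > sd_cut)
      if (length(bad)) {
        rid <- tbl$.rid[sel][bad]
        log <- rbind(log, data.frame(rule = "sd_cut", trait = tr,
                                     row_id = rid, statistic = z[bad], p = NA))
        tbl <- tbl[!(tbl$.rid %in% rid), , drop = FALSE]
      }
    }
  }
  tbl$.rid <- NULL
  rownames(tbl) <- NULL
  list(data = tbl, log = log)
}

#' Per genotype-year upright means
#'
#' Arithmetic mean over available uprights for each (genotype, year, trait),
#' with the contributing upright count retained.
#'
#' @param tbl curated phenotype data.frame.
#' @return data.frame(genotype, year, trait, mean_value, n_uprights).
#' @export
upright_means <- function(tbl) {
  stopifnot(all(c("genotype", "year", "trait", "value") %in% names(tbl)))
  agg <- stats::aggregate(value ~ genotype + year + trait, data = tbl,
                          FUN = mean)
  cnt <- stats::aggregate(value ~ genotype + year + trait, data = tbl,
                          FUN = length)
  names(agg)[names(agg) == "value"] <- "mean_value"
  agg$n_uprights <- cnt$value
  agg[order(agg$trait, agg$year, agg$genotype), , drop = FALSE]
}

#' Trait correlations and correlation cliques
#'
#' Pairwise Pearson correlations are computed within each year from the
#' genotype-year means, then averaged across years; two-sided p-values come
#' from the t statistic of each per-year correlation (the smallest per pair
#' is reported, unadjusted). Traits are then clustered by complete-linkage
#' hierarchical agglomeration on the distance 1 - |mean r|, cut at
#' \code{cut_height}; singleton clusters are dropped from the report.
#'
#' @param means data.frame from \code{\link{upright_means}}.
#' @param cut_height tree cut height on 1 - |mean r| (default 0.6, i.e. traits
#'   cluster together when |mean r| >= 0.4 under complete linkage).
#' @return list: \code{r} (mean correlation matrix), \code{p} (p-value
#'   matrix), \code{clusters} (named membership vector, non-singletons only),
#'   \code{dropped} (traits excluded as constant).
#' @export
correlation_cliques <- function(means, cut_height = 0.6) {
  stopifnot(all(c("genotype", "year", "trait", "mean_value") %in% names(means)))
  traits <- sort(unique(means$trait))
  if (length(traits) < 3) stop("need >= 3 traits")
  years <- unique(means$year)
  wide_by_year <- lapply(years, function(yr) {
    sub <- means[means$year == yr, ]
    stats::reshape(sub[, c("genotype", "trait", "mean_value")],
                   idvar = "genotype", timevar = "trait",
                   direction = "wide")
  })
  # drop constant traits (undefined correlations)
  dropped <- character()
  for (tr in traits) {
    vals <- means$mean_value[means$trait == tr]
    if (stats::sd(vals) == 0 || all(is.na(vals))) dropped <- c(dropped, tr)
  }
  traits <- setdiff(traits, dropped)
  k <- length(traits)
  if (k < 3) stop("fewer than 3 non-constant traits")
  r_sum <- p_min <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  n_sum <- matrix(0, k, k)
  for (wy in wide_by_year) {
    for (i in seq_len(k)) for (j in seq_len(k)) {
      xi <- wy[[paste0("mean_value.", traits[i])]]
      xj <- wy[[paste0("mean_value.", traits[j])]]
      if (is.null(xi) || is.null(xj)) next
      ok <- stats::complete.cases(xi, xj)
      n <- sum(ok)
      if (n < 4) next
      r <- suppressWarnings(stats::cor(xi[ok], xj[ok]))
      if (!is.finite(r)) next
      tt <- if (abs(r) < 1) r * sqrt((n - 2) / (1 - r^2)) else Inf
      p <- 2 * stats::pt(-abs(tt), n - 2)
      r_sum[i, j] <- sum(r_sum[i, j], r, na.rm = TRUE)
      n_sum[i, j] <- n_sum[i, j] + 1
      p_min[i, j] <- min(p_min[i, j], p, na.rm = TRUE)
    }
  }
  r_bar <- r_sum / n_sum
  diag(r_bar) <- 1
  d <- stats::as.dist(1 - abs(r_bar))
  hc <- stats::hclust(d, method = "complete")
  memb <- stats::cutree(hc, h = cut_height)
  sizes <- table(memb)
  memb <- memb[memb %in% as.integer(names(sizes)[sizes > 1])]
  list(r = r_bar, p = p_min, clusters = memb, dropped = dropped)
}
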