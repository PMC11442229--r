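# Genomic relationship matrix, REML variance components, BLUPs (GEBVs) and
# narrow-sense genomic heritability.
#
# The mixed models are
#   within-year :  y = mu            + Zg g + Zr r + Zc c + Zs s + e
#   across-year :  y = mu + Xe year  + Zg g + Zge ge + Zr r + Zc c + Zs s + e
# with g ~ N(0, A sigma_a^2) and every other random term iid. Variance
# components are estimated by average-information REML with EM fallback,
# components floored at zero; BLUPs come from the mixed-model equations at
# the optimum.

#' Marker dosages from four-way genotype classes
#'
#' Codes each marker as a biallelic dosage: one dose for the maternal A allele
#' plus one for the paternal C allele, giving 0/1/2 per progeny. This is the
#' marker representation consumed by \code{\link{compute_A}}.
#'
#' @param geno character matrix of AC/AD/BC/BD classes.
#' @return integer matrix (progeny x marker) of dosages in 0..2.
#' @export
fourway_dosage <- function(geno) {
  d <- (substr(geno, 1, 1) == "A") + (substr(geno, 2, 2) == "C")
  matrix(as.integer(d), nrow(geno), ncol(geno), dimnames = dimnames(geno))
}

#' Additive genomic relationship matrix
#'
#' VanRaden method-1 relationship matrix from biallelic dosages:
#' A = W W' / (2 sum p_k (1 - p_k)) with W the column-centred dosage matrix
#' and p_k the observed allele frequency of marker k. Monomorphic markers are
#' dropped with a warning.
#'
#' @param M numeric matrix (genotypes x markers) of dosages 0/1/2.
#' @return symmetric positive semidefinite genotype x genotype matrix.
#' @export
compute_A <- function(M) {
  if (nrow(M) < 2) stop("need >= 2 genotypes")
  p <- colMeans(M) / 2
  mono <- p <= 0 | p >= 1
  if (all(mono)) stop("all markers monomorphic")
  if (any(mono)) {
    warning(sum(mono), " monomorphic markers dropped")
    M <- M[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  if (ncol(M) < 10) warning("fewer than 10 polymorphic markers; A will be noisy")
  W <- sweep(M, 2, 2 * p)
  A <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  (A + t(A)) / 2
}

#' REML fit of a Gaussian mixed model
#'
#' Estimates variance components of y = X b + sum_i Z_i u_i + e with
#' u_i ~ N(0, K_i sigma_i^2) and e ~ N(0, I sigma_e^2) by restricted maximum
#' likelihood, using average-information updates with EM fallback and
#' step-halving; components are floored at zero. BLUPs and their standard
#' errors (from prediction error variance) are computed at the optimum.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (full column rank); default intercept.
#' @param random named list of random terms, each a list with \code{Z}
#'   (n x q incidence) and optional \code{K} (q x q covariance, identity when
#'   NULL).
#' @param tol convergence tolerance on the restricted log-likelihood.
#' @param max_iter iteration cap; non-convergence is flagged, never silent.
#' @param init optional named numeric vector of starting values (terms then
#'   "residual").
#' @return object of class \code{reml_fit}: \code{vc} (named variance
#'   components incl. residual), \code{loglik} (restricted), \code{aic}
#'   (-2 loglik + 2k, k = fixed effects + variance components),
#'   \code{beta}, \code{blup} and \code{blup_se} (lists per term),
#'   \code{converged}, \code{n_iter}, \code{n}.
#' @export
fit_reml <- function(y, X = NULL, random, tol = 1e-8, max_iter = 200,
                     init = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design not full column rank")
  if (length(random) == 0) stop("need at least one random term")
  terms <- names(random)
  if (is.null(terms) || any(terms == "")) stop("random terms must be named")
  Vi <- lapply(random, function(r) {
    Z <- as.matrix(r$Z)
    if (nrow(Z) != n) stop("Z row mismatch")
    if (is.null(r$K)) tcrossprod(Z) else Z %*% r$K %*% t(Z)
  })
  Vi <- c(Vi, list(residual = diag(n)))
  nv <- length(Vi)
  vy <- stats::var(y)
  if (vy == 0) vy <- 1
  theta <- rep(vy / nv, nv)
  names(theta) <- names(Vi)
  if (!is.null(init)) theta[names(init)] <- init
  floor_v <- 1e-10 * vy

  restricted_ll <- function(th) {
    V <- Reduce(`+`, Map(`*`, Vi, th))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    XtVX <- crossprod(X, Vinv %*% X)
    chx <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    P <- Vinv - Vinv %*% X %*% chol2inv(chx) %*% crossprod(X, Vinv)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    list(ll = ll, P = P, Py = Py)
  }

  st <- restricted_ll(theta)
  if (is.null(st)) stop("initial covariance not positive definite")
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    P <- st$P; Py <- st$Py
    VPy <- lapply(Vi, function(v) v %*% Py)
    score <- vapply(seq_len(nv), function(i)
      -0.5 * (sum(P * Vi[[i]]) - sum(Py * VPy[[i]])), numeric(1))
    AI <- matrix(0, nv, nv)
    PVPy <- lapply(VPy, function(v) P %*% v)
    for (i in seq_len(nv)) for (j in i:nv)
      AI[i, j] <- AI[j, i] <- 0.5 * sum(VPy[[i]] * PVPy[[j]])
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    if (is.null(step)) {  # EM fallback
      step <- theta^2 * vapply(seq_len(nv), function(i)
        (sum(Py * VPy[[i]]) - sum(P * Vi[[i]])) / n, numeric(1))
    }
    improved <- FALSE
    for (half in 0:10) {
      cand <- pmax(theta + step / 2^half, 0)
      cand[cand < floor_v] <- floor_v
      if (sum(cand) <= 0) next
      stc <- restricted_ll(cand)
      if (!is.null(stc) && stc$ll >= st$ll - 1e-12) {
        delta <- stc$ll - st$ll
        theta <- cand; st <- stc; improved <- TRUE
        break
      }
    }
    if (!improved) { converged <- TRUE; break }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("REML did not converge in ", max_iter, " iterations")

  theta[theta <= 2 * floor_v] <- 0
  stf <- restricted_ll(pmax(theta, ifelse(theta == 0, floor_v, theta)))
  P <- stf$P; Py <- stf$Py
  V <- Reduce(`+`, Map(`*`, Vi, pmax(theta, floor_v)))
  Vinv <- chol2inv(chol(V))
  XtVXi <- solve(crossprod(X, Vinv %*% X))
  beta <- drop(XtVXi %*% crossprod(X, Vinv %*% y))
  blup <- blup_se <- list()
  for (tm in terms) {
    Z <- as.matrix(random[[tm]]$Z)
    K <- random[[tm]]$K
    KZt <- if (is.null(K)) t(Z) else K %*% t(Z)
    u <- theta[tm] * (KZt %*% Py)
    Kd <- if (is.null(K)) rep(1, ncol(Z)) else diag(K)
    pev <- theta[tm] * Kd - theta[tm]^2 *
      rowSums((KZt %*% P) * KZt)
    blup[[tm]] <- drop(u)
    blup_se[[tm]] <- sqrt(pmax(pev, 0))
    if (!is.null(colnames(Z))) {
      names(blup[[tm]]) <- colnames(Z)
      names(blup_se[[tm]]) <- colnames(Z)
    }
  }
  k <- ncol(X) + nv
  structure(list(vc = theta, loglik = stf$ll, aic = -2 * stf$ll + 2 * k,
                 beta = beta, blup = blup, blup_se = blup_se,
                 converged = converged, n_iter = it, n = n,
                 terms = terms), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit (n =", x$n, ")\n")
  cat("variance components:\n")
  print(round(x$vc, 6))
  cat("logLik:", x$loglik, " AIC:", x$aic,
      " converged:", x$converged, "\n")
  invisible(x)
}

#' AIC model search over optional random terms
#'
#' Fits every subset of \code{optional} random terms on top of the forced
#' \code{base} terms and returns the fit with the lowest AIC; ties are broken
#' toward fewer terms.
#'
#' @param y,X response and fixed design as in \code{\link{fit_reml}}.
#' @param base named list of random terms present in every candidate (the
#'   genotype term, and GxY when gated in).
#' @param optional named list of optional random terms (row, column, spline).
#' @param ... passed to \code{\link{fit_reml}}.
#' @return list: \code{fit} (best \code{reml_fit}), \code{terms} (optional
#'   terms included), \code{aic_table} (candidate summary).
#' @export
select_model_aic <- function(y, X = NULL, base, optional = list(), ...) {
  opt_names <- names(optional)
  subsets <- list(character(0))
  for (nm in opt_names)
    subsets <- c(subsets, lapply(subsets, c, nm))
  fits <- vector("list", length(subsets))
  aic <- rep(NA_real_, length(subsets))
  for (i in seq_along(subsets)) {
    rnd <- c(base, optional[subsets[[i]]])
    fits[[i]] <- tryCatch(fit_reml(y, X, rnd, ...), error = function(e) NULL)
    if (!is.null(fits[[i]])) aic[i] <- fits[[i]]$aic
  }
  if (all(is.na(aic))) stop("no candidate model converged")
  sizes <- lengths(subsets)
  ord <- order(aic, sizes)
  best <- ord[1]
  list(fit = fits[[best]], terms = subsets[[best]],
       aic_table = data.frame(
         terms = vapply(subsets, function(s)
           if (length(s)) paste(s, collapse = "+") else "(none)",
           character(1)),
         n_terms = sizes, aic = aic))
}

#' Likelihood-ratio gate for the genotype-by-year term
#'
#' Tests the GxY variance component with a likelihood ratio statistic
#' 2(l_full - l_reduced) against the boundary null mixture
#' 0.5 chi2_0 + 0.5 chi2_1 (correct for a variance component tested at zero).
#' The term is kept iff p < alpha.
#'
#' @param fit_with,fit_without nested \code{reml_fit}s on identical data,
#'   differing only by the GxY term.
#' @param alpha significance level (default 0.05).
#' @return list: \code{keep} (logical), \code{statistic}, \code{p}.
#' @export
gate_gxy <- function(fit_with, fit_without, alpha = 0.05) {
  if (fit_with$n != fit_without$n)
    stop("fits are not on identical data")
  if (!all(fit_without$terms %in% fit_with$terms))
    stop("models are not nested")
  stat <- 2 * (fit_with$loglik - fit_without$loglik)
  p <- if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)
  list(keep = p < alpha, statistic = max(0, stat), p = p)
}

#' Narrow-sense genomic heritability
#'
#' Within-year: h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2). Across years
#' (n years): h2 = sigma_a^2 / (sigma_a^2 + sigma_ge^2 / n + sigma_e^2 / n).
#'
#' @param sigma_a2 additive genomic variance.
#' @param sigma_e2 residual variance.
#' @param sigma_ge2 genotype-by-year variance (across-year only).
#' @param n_years number of distinct years (across-year only).
#' @param across_year logical.
#' @return heritability in [0, 1], or NA with a warning when the denominator
#'   is zero.
#' @export
heritability <- function(sigma_a2, sigma_e2, sigma_ge2 = 0, n_years = 1,
                         across_year = FALSE) {
  if (any(c(sigma_a2, sigma_e2, sigma_ge2) < 0)) stop("components must be >= 0")
  if (across_year && n_years < 1) stop("n_years must be >= 1")
  den <- if (across_year)
    sigma_a2 + sigma_ge2 / n_years + sigma_e2 / n_years
  else sigma_a2 + sigma_e2
  if (den == 0) {
    warning("all variance components zero; heritability undefined")
    return(NA_real_)
  }
  sigma_a2 / den
}

# ---- design helpers -------------------------------------------------------

# 0/1 incidence matrix of a factor, columns in level order.
incidence <- function(f) {
  f <- factor(f)
  Z <- stats::model.matrix(~ f - 1)
  colnames(Z) <- levels(f)
  Z
}

# Tensor-product B-spline basis over (row, col), iid coefficients; models
# smooth 2-D spatial variation beyond straight-line row/column trends.
spline_basis <- function(row, col, df = 6) {
  br <- splines::bs(row, df = df, intercept = TRUE)
  bc <- splines::bs(col, df = df, intercept = TRUE)
  out <- matrix(0, length(row), df * df)
  for (i in seq_len(df)) for (j in seq_len(df))
    out[, (i - 1) * df + j] <- br[, i] * bc[, j]
  out
}

#' Fit the BLUP model for one trait
#'
#' High-level driver for the within-year and across-year mixed models on
#' genotype-year means: builds the design, runs the AIC search over the
#' optional spatial terms (row, column, 2-D spline), gates GxY by likelihood
#' ratio in the across-year model, and returns variance components, genomic
#' heritability and genotype BLUPs (GEBVs).
#'
#' @param means data.frame(genotype, year, mean_value) for one trait, with
#'   \code{row}, \code{col} columns when spatial terms are wanted.
#' @param A genomic relationship matrix with dimnames covering the genotypes
#'   (identity used when NULL).
#' @param model \code{"across"} or a single year label for a within-year fit.
#' @param spatial_terms which optional terms to search over; any of
#'   \code{"row"}, \code{"col"}, \code{"spline"}.
#' @param spline_df marginal B-spline basis dimension (default 6, i.e. a 6x6
#'   tensor product).
#' @param gxy_alpha level of the GxY likelihood-ratio gate.
#' @param ... passed to \code{\link{fit_reml}}.
#' @return list: \code{fit}, \code{h2}, \code{vc}, \code{blup} (named
#'   genotype vector), \code{blup_se}, \code{spearman} (BLUP vs genotype raw
#'   means), \code{gxy} (gate result or NULL), \code{spatial_terms} kept,
#'   \code{n_years}.
#' @export
fit_blup_model <- function(means, A = NULL, model = "across",
                           spatial_terms = c("row", "col", "spline"),
                           spline_df = 6, gxy_alpha = 0.05, ...) {
  stopifnot(all(c("genotype", "year", "mean_value") %in% names(means)))
  dat <- means
  if (model != "across") {
    dat <- dat[as.character(dat$year) == as.character(model), , drop = FALSE]
    if (nrow(dat) == 0) stop("no data for year ", model)
  }
  dat <- dat[stats::complete.cases(dat$mean_value), , drop = FALSE]
  y <- dat$mean_value
  gid <- factor(dat$genotype)
  Zg <- incidence(gid)
  K <- NULL
  if (!is.null(A)) {
    if (is.null(dimnames(A)) || !all(levels(gid) %in% rownames(A)))
      stop("A must have dimnames covering all genotypes")
    K <- A[levels(gid), levels(gid)]
  }
  across <- model == "across"
  n_years <- length(unique(dat$year))
  X <- if (across && n_years > 1)
    stats::model.matrix(~ factor(year), dat) else matrix(1, length(y), 1)

  base <- list(genotype = list(Z = Zg, K = K))
  optional <- list()
  if (all(c("row", "col") %in% names(dat))) {
    if ("row" %in% spatial_terms)
      optional$row <- list(Z = incidence(dat$row))
    if ("col" %in% spatial_terms)
      optional$col <- list(Z = incidence(dat$col))
    if ("spline" %in% spatial_terms)
      optional$spline <- list(Z = spline_basis(dat$row, dat$col, spline_df))
  }

  gxy <- NULL
  cell_reps <- max(table(interaction(dat$genotype, dat$year, drop = TRUE)))
  # GxY is only separable from the residual with replicate observations per
  # genotype-year cell; on cell means it is absorbed into the residual.
  if (across && n_years > 1 && cell_reps > 1) {
    Zge <- incidence(interaction(dat$genotype, dat$year, drop = TRUE))
    sel_with <- select_model_aic(y, X, c(base, list(gxy = list(Z = Zge))),
                                 optional, ...)
    sel_without <- select_model_aic(y, X, base, optional, ...)
    gxy <- gate_gxy(sel_with$fit, sel_without$fit, gxy_alpha)
    sel <- if (gxy$keep) sel_with else sel_without
  } else {
    sel <- select_model_aic(y, X, base, optional, ...)
  }
  fit <- sel$fit
  vc <- fit$vc
  h2 <- heritability(vc["genotype"],
                     vc["residual"],
                     sigma_ge2 = if ("gxy" %in% names(vc)) vc["gxy"] else 0,
                     n_years = n_years,
                     across_year = across && n_years > 1)
  blup <- fit$blup$genotype
  raw <- tapply(y, gid, mean)
  rho <- suppressWarnings(
    stats::cor(blup[names(raw)], raw, method = "spearman"))
  list(fit = fit, h2 = unname(h2), vc = vc, blup = blup,
       blup_se = fit$blup_se$genotype, spearman = unname(rho), gxy = gxy,
       spatial_terms = sel$terms, n_years = n_years,
       aic_table = sel$aic_table)
}
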