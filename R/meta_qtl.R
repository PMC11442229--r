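# Meta-QTL synthesis: interval-overlap graphs, maximal cliques, extent
# intersection and filter sets.
#
# Primary QTL within a trait group are nodes of an undirected graph; an edge
# joins two QTL on the same linkage group whose 1.5-LOD support intervals
# intersect (closed intervals -- touching endpoints count). Each maximal
# clique becomes one meta-QTL: its extents are the maximum of the members'
# left extents and the minimum of their right extents (non-empty by the Helly
# property of intervals on a line), its position the midpoint of the extents,
# and its summary statistics the means/distinct counts over members.

#' Round half away from zero
#'
#' Report rounding for cM positions: 55.75 -> 55.8 at one decimal (base R's
#' \code{round} would give 55.7 under round-half-even).
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Columns of the shared QTL table schema
#' @export
QTL_COLUMNS <- c("trait", "population", "study", "model", "method",
                 "linkage_group", "position", "lod", "marker_r2", "lo", "hi",
                 "effect_maternal", "effect_paternal", "effect_interaction")

#' Empty QTL table in the shared schema
#' @export
empty_qtl_table <- function() {
  out <- data.frame(trait = character(), population = character(),
                    study = character(), model = character(),
                    method = character(), linkage_group = character(),
                    position = numeric(), lod = numeric(),
                    marker_r2 = numeric(), lo = numeric(), hi = numeric(),
                    effect_maternal = numeric(), effect_paternal = numeric(),
                    effect_interaction = numeric(), stringsAsFactors = FALSE)
  out
}

.check_hits <- function(hits) {
  miss <- setdiff(QTL_COLUMNS, names(hits))
  if (length(miss)) stop("QTL table missing columns: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Build the QTL interval-overlap graph
#'
#' Nodes are QTL (rows of \code{hits}); an undirected edge joins two QTL on
#' the same linkage group whose closed [lo, hi] support intervals intersect.
#' Rows with missing extents are excluded with a warning.
#'
#' @param hits QTL table (shared schema) for one trait group.
#' @return igraph undirected graph whose vertex attribute \code{row} indexes
#'   back into \code{hits}.
#' @export
build_graph <- function(hits) {
  .check_hits(hits)
  bad <- which(is.na(hits$lo) | is.na(hits$hi))
  if (length(bad)) {
    warning(length(bad), " QTL with missing extents excluded from graph")
    hits <- hits[-bad, , drop = FALSE]
  }
  n <- nrow(hits)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$row <- if (length(bad)) setdiff(seq_len(n + length(bad)), bad)
    else seq_len(n)
  if (n > 1) {
    pairs <- utils::combn(n, 2)
    same_lg <- hits$linkage_group[pairs[1, ]] == hits$linkage_group[pairs[2, ]]
    ovl <- pmax(hits$lo[pairs[1, ]], hits$lo[pairs[2, ]]) <=
      pmin(hits$hi[pairs[1, ]], hits$hi[pairs[2, ]])
    sel <- same_lg & ovl
    if (any(sel)) g <- igraph::add_edges(g, as.vector(pairs[, sel]))
  }
  g
}

#' Maximal cliques of the overlap graph
#'
#' Exact maximal-clique enumeration (per-linkage-group overlap graphs are
#' interval graphs, so this is cheap), in a deterministic order: sorted by
#' linkage group, then by the smallest member left extent, then by members.
#'
#' @param graph overlap graph from \code{\link{build_graph}}.
#' @param hits the QTL table the graph was built from (for ordering).
#' @return list of integer vectors of row indices into \code{hits}; isolated
#'   QTL yield singleton cliques.
#' @export
cliques_of <- function(graph, hits) {
  cl <- igraph::max_cliques(graph)
  rows <- igraph::V(graph)$row
  out <- lapply(cl, function(v) sort(rows[as.integer(v)]))
  if (length(out) == 0) return(out)
  key_lg <- vapply(out, function(v) as.character(hits$linkage_group[v[1]]),
                   character(1))
  key_lo <- vapply(out, function(v) min(hits$lo[v]), numeric(1))
  key_id <- vapply(out, function(v) paste(v, collapse = ","), character(1))
  out[order(key_lg, key_lo, key_id)]
}

#' Synthesise a meta-QTL from one clique
#'
#' Extents are the maximal member left extent and the minimal member right
#' extent; the synthetic position is their midpoint (kept at full precision in
#' \code{position}, with \code{position_report} rounded half-up to 0.1 cM).
#' Mean marker R2 and mean effects are arithmetic means over members; counts
#' are distinct-value counts.
#'
#' @param hits QTL table.
#' @param members integer row indices forming one maximal clique (one linkage
#'   group).
#' @return one-row data.frame describing the meta-QTL.
#' @export
synthesize_meta <- function(hits, members) {
  if (length(members) == 0) stop("empty clique")
  h <- hits[members, , drop = FALSE]
  if (length(unique(h$linkage_group)) != 1)
    stop("clique spans multiple linkage groups")
  lo <- max(h$lo); hi <- min(h$hi)
  stopifnot(lo <= hi)  # Helly property of pairwise-overlapping intervals
  pos <- (lo + hi) / 2
  data.frame(
    linkage_group = h$linkage_group[1], lo = lo, hi = hi,
    position = pos, position_report = round_half_up(pos, 1),
    n_members = length(members),
    traits = paste(sort(unique(h$trait)), collapse = "+"),
    models = paste(sort(unique(h$model)), collapse = "+"),
    methods = paste(sort(unique(h$method)), collapse = "+"),
    populations = paste(sort(unique(h$population)), collapse = "+"),
    studies = paste(sort(unique(h$study)), collapse = "+"),
    mean_marker_r2 = mean(h$marker_r2),
    mean_effect_maternal = mean(h$effect_maternal),
    mean_effect_paternal = mean(h$effect_paternal),
    mean_effect_interaction = mean(h$effect_interaction),
    n_traits = length(unique(h$trait)),
    n_models = length(unique(h$model)),
    n_methods = length(unique(h$method)),
    n_populations = length(unique(h$population)),
    n_studies = length(unique(h$study)),
    member_rows = paste(members, collapse = ","),
    stringsAsFactors = FALSE)
}

.empty_meta_table <- function() {
  data.frame(linkage_group = character(), lo = numeric(), hi = numeric(),
             position = numeric(), position_report = numeric(),
             n_members = integer(), traits = character(), models = character(),
             methods = character(), populations = character(),
             studies = character(), mean_marker_r2 = numeric(),
             mean_effect_maternal = numeric(),
             mean_effect_paternal = numeric(),
             mean_effect_interaction = numeric(), n_traits = integer(),
             n_models = integer(), n_methods = integer(),
             n_populations = integer(), n_studies = integer(),
             member_rows = character(), stringsAsFactors = FALSE)
}

#' Meta-QTL for one trait group
#'
#' Builds the overlap graph over the group's QTL, enumerates maximal cliques
#' and synthesises one meta-QTL per clique.
#'
#' @param hits QTL table restricted to one trait group.
#' @return data.frame of meta-QTL (possibly zero rows).
#' @export
meta_qtl <- function(hits) {
  .check_hits(hits)
  if (nrow(hits) == 0) return(.empty_meta_table())
  g <- build_graph(hits)
  cl <- cliques_of(g, hits)
  out <- do.call(rbind, lapply(cl, function(v) synthesize_meta(hits, v)))
  rownames(out) <- NULL
  out
}

#' Within-trait stability filter
#'
#' Assembles within-trait meta-QTL (each trait its own group) and keeps those
#' stable in at least \code{min_models} of the year/all-years models with mean
#' marker R2 at least \code{min_r2} (boundary values kept: >= comparisons).
#'
#' @param hits QTL table across models for one population.
#' @param min_models minimum distinct model count (default 3 of the four
#'   models: three single years plus all-years).
#' @param min_r2 major-QTL threshold on mean marker R2 (default 0.10).
#' @return data.frame of stable within-trait meta-QTL with a \code{trait}
#'   column.
#' @export
stability_filter <- function(hits, min_models = 3, min_r2 = 0.10) {
  .check_hits(hits)
  res <- list()
  for (tr in unique(hits$trait)) {
    m <- meta_qtl(hits[hits$trait == tr, , drop = FALSE])
    if (nrow(m) == 0) next
    # member_rows index the per-trait subset; relabel to the trait
    m <- m[m$n_models >= min_models & m$mean_marker_r2 >= min_r2, ,
           drop = FALSE]
    if (nrow(m)) { m$trait <- tr; res[[tr]] <- m }
  }
  if (length(res) == 0) {
    out <- meta_qtl(hits[0, , drop = FALSE]); out$trait <- character(0)
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(-out$mean_marker_r2), , drop = FALSE]
}

#' Define a trait group
#'
#' A set of synonymous/correlated traits analysed together, with the AND-ed
#' filter rules applied to its meta-QTL (the filter statistics are
#' \code{mean_marker_r2}, \code{n_models}, \code{n_traits},
#' \code{n_populations}, \code{n_studies}).
#'
#' @param group_id label.
#' @param traits member trait names (synonym sets across studies).
#' @param filters list of lists with \code{statistic}, \code{comparator}
#'   (one of ">=", ">", "<=", "<", "=="), \code{value}.
#' @return list of class \code{trait_group}.
#' @export
trait_group <- function(group_id, traits, filters = list()) {
  if (length(traits) == 0) stop("traits must be non-empty")
  ok_stats <- c("mean_marker_r2", "n_models", "n_traits", "n_populations",
                "n_studies", "n_methods")
  for (f in filters) {
    if (!all(c("statistic", "comparator", "value") %in% names(f)))
      stop("each filter needs statistic, comparator, value")
    if (!f$statistic %in% ok_stats)
      stop("unknown filter statistic: ", f$statistic)
    if (!f$comparator %in% c(">=", ">", "<=", "<", "=="))
      stop("unknown comparator: ", f$comparator)
  }
  structure(list(group_id = group_id, traits = traits, filters = filters),
            class = "trait_group")
}

#' Apply a trait group's filters to its meta-QTL
#'
#' AND-combines the group's rules; returns the surviving meta-QTL and a
#' pass/fail log.
#'
#' @param metas meta-QTL data.frame from \code{\link{meta_qtl}}.
#' @param group \code{\link{trait_group}}.
#' @return list: \code{kept} (filtered metas), \code{log} (per-meta pass/fail
#'   per rule).
#' @export
apply_group_filters <- function(metas, group) {
  stopifnot(inherits(group, "trait_group"))
  if (nrow(metas) == 0) return(list(kept = metas, log = data.frame()))
  pass <- rep(TRUE, nrow(metas))
  logs <- list()
  for (f in group$filters) {
    v <- metas[[f$statistic]]
    ok <- switch(f$comparator,
                 ">=" = v >= f$value, ">" = v > f$value,
                 "<=" = v <= f$value, "<" = v < f$value, "==" = v == f$value)
    logs[[length(logs) + 1]] <- data.frame(
      meta = seq_len(nrow(metas)), group = group$group_id,
      rule = paste(f$statistic, f$comparator, f$value), pass = ok)
    pass <- pass & ok
  }
  list(kept = metas[pass, , drop = FALSE],
       log = if (length(logs)) do.call(rbind, logs) else data.frame())
}

#' Grouped meta-QTL analysis
#'
#' For each trait group, restricts the QTL table to the group's traits, runs
#' the clique synthesis and applies the group's filters.
#'
#' @param hits QTL table (may span populations and studies).
#' @param groups list of \code{\link{trait_group}}s.
#' @return data.frame of surviving meta-QTL with a \code{group} column.
#' @export
grouped_meta_qtl <- function(hits, groups) {
  res <- list()
  for (g in groups) {
    sub <- hits[hits$trait %in% g$traits, , drop = FALSE]
    m <- meta_qtl(sub)
    keep <- apply_group_filters(m, g)$kept
    if (nrow(keep)) { keep$group <- g$group_id; res[[g$group_id]] <- keep }
  }
  if (length(res) == 0) return(data.frame())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
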