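#' Fisher's exact enrichment between target and annotation gene sets
#'
#' One-sided hypergeometric enrichment for every target x annotation pair
#' against a shared background universe, with either Bonferroni-across-
#' targets or Holm-Sidak step-down multiplicity control (applied within each
#' annotation, across targets — the convention of dividing the 0.05
#' threshold by the number of target sets).
#'
#' @param targets named list of target gene sets (e.g. module gene lists).
#' @param annotations named list of annotation gene sets.
#' @param background character vector; must contain all set members (members
#'   outside it are dropped with a message).
#' @param correction `"bonferroni_across_targets"` or `"holm_sidak"`.
#' @param alpha pairwise significance level.
#' @return An `enrichment_table` data frame: target, annotation, overlap,
#'   odds_ratio (Haldane-corrected only when a zero cell makes it undefined,
#'   flagged in `or_corrected`), p, p_adjusted, significant_pairwise,
#'   significant_corrected, overlap_genes.
#' @export
fisher_enrichment <- function(targets, annotations, background,
                              correction = c("bonferroni_across_targets",
                                             "holm_sidak"),
                              alpha = 0.05) {
  correction <- match.arg(correction)
  background <- unique(background)
  n_bg <- length(background)
  clean <- function(sets) {
    lapply(sets, function(s) {
      s2 <- intersect(unique(s), background)
      if (length(s2) < length(unique(s))) {
        message(sprintf("%d set members outside the background dropped",
                        length(unique(s)) - length(s2)))
      }
      s2
    })
  }
  targets <- clean(targets)
  annotations <- clean(annotations)
  rows <- list()
  for (ti in seq_along(targets)) {
    for (ai in seq_along(annotations)) {
      tset <- targets[[ti]]
      aset <- annotations[[ai]]
      ov <- intersect(tset, aset)
      a <- length(ov)
      b <- length(tset) - a
      c0 <- length(aset) - a
      d <- n_bg - a - b - c0
      p <- stats::phyper(a - 1, length(aset), n_bg - length(aset),
                         length(tset), lower.tail = FALSE)
      undef <- b == 0 || c0 == 0 # OR undefined (division by zero)
      if (undef) {
        or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c0 + 0.5))
      } else {
        or <- (a * d) / (b * c0)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        target = names(targets)[ti], annotation = names(annotations)[ai],
        overlap = a, odds_ratio = or, or_corrected = undef, p = p,
        overlap_genes = paste(ov, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  m <- length(targets)
  tab$p_adjusted <- NA_real_
  for (ai in seq_along(annotations)) {
    sel <- tab$annotation == names(annotations)[ai]
    p <- tab$p[sel]
    adj <- if (correction == "bonferroni_across_targets") {
      pmin(1, p * m)
    } else {
      # Holm-Sidak step-down
      o <- order(p)
      padj <- numeric(length(p))
      padj[o] <- cummax(1 - (1 - p[o])^(length(p) - seq_along(p) + 1))
      pmax(pmin(1, padj), p) # guard the p_adjusted >= p invariant
    }
    tab$p_adjusted[sel] <- adj
  }
  tab$significant_pairwise <- tab$p < alpha
  tab$significant_corrected <- tab$p_adjusted < alpha
  class(tab) <- c("enrichment_table", class(tab))
  tab
}

#' Top-fraction marker sets from group-level expression
#'
#' For each group (column), the genes in the top `fraction` of that group's
#' expression vector. Ties at the cut are all included (the set may slightly
#' exceed the nominal fraction; a message notes it).
#'
#' @param expr genes x groups matrix with gene-id rownames.
#' @param fraction top fraction per group.
#' @return Named list of marker gene sets (one per column).
#' @export
make_top_fraction_markers <- function(expr, fraction = 0.05) {
  expr <- as.matrix(expr)
  ng <- nrow(expr)
  k <- max(1L, floor(ng * fraction))
  out <- lapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    cut <- sort(x, decreasing = TRUE)[k]
    set <- rownames(expr)[x >= cut]
    if (length(set) > k) {
      message(sprintf("group %d: %d ties at the cut included",
                      j, length(set) - k))
    }
    set
  })
  names(out) <- colnames(expr)
  out
}

#' Intramodular PPI connectivity against degree-matched nulls
#'
#' Computes each module gene's degree within the module-induced subgraph of
#' the protein-protein interaction network; the median intramodular degree
#' is tested against null modules resampled within global-degree deciles
#' matching the module's decile profile.
#'
#' @param module_genes character vector of gene ids.
#' @param ppi_edges two-column matrix/data frame of undirected edges.
#' @param n_resample null modules.
#' @param seed integer seed.
#' @return List with `observed` (median intramodular degree), `p`, `null`,
#'   `n_in_ppi`, `underpowered` (fewer than 5 module genes in the network).
#' @export
ppi_module_test <- function(module_genes, ppi_edges, n_resample = 10000,
                            seed = 1) {
  ppi_edges <- as.matrix(ppi_edges)
  nodes <- unique(c(ppi_edges[, 1], ppi_edges[, 2]))
  g <- igraph::graph_from_edgelist(ppi_edges, directed = FALSE)
  g <- igraph::simplify(g)
  deg <- igraph::degree(g)
  present <- intersect(module_genes, nodes)
  n_absent <- length(module_genes) - length(present)
  if (n_absent > 0) {
    message(sprintf("%d module genes absent from the PPI network", n_absent))
  }
  underpowered <- length(present) < 5
  if (length(present) == 0) {
    return(list(observed = NA_real_, p = NA_real_, null = NULL,
                n_in_ppi = 0, underpowered = TRUE))
  }
  qs <- unique(stats::quantile(deg, seq(0, 1, 0.1), type = 7))
  decile <- cut(deg, qs, include.lowest = TRUE, labels = FALSE)
  names(decile) <- names(deg)
  median_intra <- function(genes) {
    sub <- igraph::induced_subgraph(g, genes)
    stats::median(igraph::degree(sub))
  }
  observed <- median_intra(present)
  profile <- table(decile[present])
  pools <- split(names(decile), decile)
  null <- with_seed(seed, vapply(seq_len(n_resample), function(i) {
    draw <- unlist(lapply(names(profile), function(dl) {
      sample(pools[[dl]], profile[[dl]])
    }), use.names = FALSE)
    median_intra(draw)
  }, numeric(1)))
  list(
    observed = observed,
    p = (1 + sum(null >= observed)) / (1 + n_resample),
    null = null, n_in_ppi = length(present), underpowered = underpowered
  )
}

# per-gene smooth developmental trajectories evaluated on a common log-age
# grid, z-normalised per gene
trajectory_profiles <- function(trajectories, n_points = 20) {
  genes <- unique(trajectories$gene)
  lr <- range(log(trajectories$age))
  grid <- seq(lr[1], lr[2], length.out = n_points)
  prof <- t(vapply(genes, function(g) {
    d <- trajectories[trajectories$gene == g, ]
    la <- log(d$age)
    fit <- if (length(unique(la)) >= 6) {
      kk <- min(8, length(unique(la)) - 1)
      mgcv::gam(value ~ s(la, bs = "cr", k = kk), data = data.frame(la = la, value = d$value))
    } else {
      stats::lm(value ~ la, data = data.frame(la = la, value = d$value))
    }
    stats::predict(fit, newdata = data.frame(la = grid))
  }, numeric(n_points)))
  sds <- apply(prof, 1, stats::sd)
  sds[sds == 0] <- 1
  prof <- (prof - rowMeans(prof)) / sds
  rownames(prof) <- genes
  prof
}

#' Temporal coherence of a module's developmental trajectories
#'
#' Each gene's expression trajectory over age is smoothed (penalized spline
#' over log age), resampled at equally spaced log-age points, and
#' z-normalised; the module statistic is the median pairwise Pearson
#' correlation between member trajectories, tested against size-matched
#' random gene sets.
#'
#' @param module_genes character vector of gene ids.
#' @param trajectories long-form data frame with columns `gene`, `age`
#'   (same time units for all genes), `value`.
#' @param n_resample random gene sets.
#' @param n_points resampled time points.
#' @param seed integer seed.
#' @return List with `observed` (median pairwise r), `p`, `null`,
#'   `profiles` (the module's z-normalised trajectory matrix).
#' @export
trajectory_coherence_test <- function(module_genes, trajectories,
                                      n_resample = 1000, n_points = 20,
                                      seed = 1) {
  prof <- trajectory_profiles(trajectories, n_points)
  idx <- match(module_genes, rownames(prof))
  idx <- idx[!is.na(idx)]
  if (length(idx) < 2) stop("need >= 2 module genes with trajectories")
  med_pair_r <- function(rows) {
    cm <- stats::cor(t(prof[rows, , drop = FALSE]))
    stats::median(cm[upper.tri(cm)])
  }
  observed <- med_pair_r(idx)
  ng <- nrow(prof)
  null <- with_seed(seed, vapply(seq_len(n_resample), function(i) {
    med_pair_r(sample.int(ng, length(idx)))
  }, numeric(1)))
  list(
    observed = observed,
    p = (1 + sum(null >= observed)) / (1 + n_resample),
    null = null, profiles = prof[idx, , drop = FALSE]
  )
}

#' Community structure of an annotation similarity network
#'
#' Builds a weighted graph over gene sets from a pairwise enrichment p-value
#' matrix: p-values above 0.1 are set to 1, weights are `-log10(p)`, nodes
#' in the bottom decile of degree (edges counted at p < 0.05) are dropped,
#' and Louvain communities are found on the remaining weighted graph (best
#' modularity over restarts).
#'
#' @param p_matrix symmetric matrix of pairwise enrichment p-values with
#'   set names as dimnames.
#' @param p_ceiling p-values above this are set to 1 (zero weight).
#' @param degree_alpha edge threshold for the degree filter.
#' @param drop_quantile degree quantile below which nodes are dropped.
#' @param n_restarts Louvain restarts.
#' @param seed integer seed.
#' @return List with `weights` (filtered weight matrix), `kept` (set
#'   names), `communities` (named membership vector), `modularity`.
#' @export
annotation_graph <- function(p_matrix, p_ceiling = 0.1, degree_alpha = 0.05,
                             drop_quantile = 0.1, n_restarts = 10, seed = 1) {
  p <- as.matrix(p_matrix)
  diag(p) <- 1
  p[p > p_ceiling] <- 1
  w <- -log10(p)
  w[!is.finite(w)] <- max(w[is.finite(w)], 0)
  deg <- rowSums(p < degree_alpha)
  if (all(deg == 0)) {
    return(list(weights = w * 0, kept = character(0),
                communities = integer(0), modularity = NA_real_))
  }
  n_drop <- floor(drop_quantile * length(deg))
  keep <- rep(TRUE, length(deg))
  if (n_drop > 0) keep[order(deg)[seq_len(n_drop)]] <- FALSE
  w2 <- w[keep, keep, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(w2, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_restarts)) {
      cl <- igraph::cluster_louvain(g)
      if (is.null(best) || igraph::modularity(cl) > igraph::modularity(best)) {
        best <- cl
      }
    }
  })
  memb <- igraph::membership(best)
  list(
    weights = w2, kept = rownames(w2),
    communities = stats::setNames(as.integer(memb), rownames(w2)),
    modularity = igraph::modularity(best)
  )
}
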