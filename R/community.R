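#' Community matrix of percent covers
#'
#' Units (samples, quadrats or transects) by taxa percent-cover values with
#' optional per-unit metadata and a transform state that only moves
#' forward: raw -> pruned+standardized -> sqrt.
#'
#' @param cover numeric matrix, rows = units (rownames required), cols =
#'   taxa
#' @param metadata optional data.frame keyed by \code{unit} column
#' @param transform one of "raw", "pruned_standardized", "sqrt"
#' @export
community_matrix <- function(cover, metadata = NULL, transform = "raw") {
  stopifnot(is.matrix(cover), !is.null(rownames(cover)))
  if (is.null(colnames(cover)))
    colnames(cover) <- paste0("taxon", seq_len(ncol(cover)))
  if (any(cover < 0)) stop("covers must be >= 0")
  transform <- match.arg(transform, c("raw", "pruned_standardized", "sqrt"))
  structure(list(cover = cover, metadata = metadata, transform = transform),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d units x %d taxa (%s)\n",
              nrow(x$cover), ncol(x$cover), x$transform))
  invisible(x)
}

#' Percent cover from point-intercept records
#'
#' cover(label) = 100 * count(label) / total points per unit. Pooling the
#' six 100-point quadrats of a sample gives 600-point denominators.
#'
#' @param points data.frame with a \code{label} column and the unit key
#' @param unit_key column naming the aggregation unit (e.g. "quadrat_id",
#'   "sample_id", "transect_id")
#' @param metadata optional per-unit metadata data.frame with a column
#'   matching \code{unit_key}
#' @return a \code{community_matrix} (raw)
#' @export
percent_cover_from_points <- function(points, unit_key = "quadrat_id",
                                      metadata = NULL) {
  stopifnot("label" %in% names(points), unit_key %in% names(points))
  if (any(is.na(points$label))) stop("every point needs a label")
  tab <- table(points[[unit_key]], points$label)
  tot <- rowSums(tab)
  if (any(tot == 0)) stop("unit with zero points: ",
                          paste(rownames(tab)[tot == 0], collapse = ", "))
  cover <- 100 * sweep(unclass(tab), 1L, tot, "/")
  community_matrix(as.matrix(cover), metadata = metadata)
}

#' Prune non-valid/non-living categories and standardize
#'
#' Drops the excluded columns (shadow/frame as non-valid; sand, rock,
#' rubble as non-living by default) and renormalizes each unit to 100.
#'
#' @param raw a raw \code{community_matrix}
#' @param exclude_nonvalid,exclude_nonliving category names to drop
#' @return \code{community_matrix} in state "pruned_standardized"
#' @export
prepare_community_matrix <- function(raw,
                                     exclude_nonvalid = c("shadow", "frame"),
                                     exclude_nonliving = c("sand", "rock",
                                                           "rubble")) {
  stopifnot(inherits(raw, "community_matrix"))
  if (raw$transform != "raw") stop("expected a raw matrix")
  drop <- union(exclude_nonvalid, exclude_nonliving)
  keep <- setdiff(colnames(raw$cover), drop)
  if (length(keep) == 0) stop("no taxa left after pruning")
  m <- raw$cover[, keep, drop = FALSE]
  rs <- rowSums(m)
  if (any(rs == 0)) stop("unit(s) with zero living cover: ",
                         paste(rownames(m)[rs == 0], collapse = ", "))
  m <- 100 * sweep(m, 1L, rs, "/")
  community_matrix(m, metadata = raw$metadata,
                   transform = "pruned_standardized")
}

#' Square-root transform a community matrix
#' @param cm a pruned+standardized \code{community_matrix}
#' @export
transform_sqrt <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  if (cm$transform == "sqrt") stop("matrix already sqrt-transformed")
  community_matrix(sqrt(cm$cover), metadata = cm$metadata,
                   transform = "sqrt")
}

#' Bray-Curtis similarity matrix
#'
#' S_jk = 100 * 2 sum_i min(y_ij, y_ik) / sum_i (y_ij + y_ik). A pair of
#' all-zero units is defined as similarity 0 (with a warning).
#'
#' @param cm a \code{community_matrix} or non-negative numeric matrix
#' @return a \code{distance_matrix} with metric
#'   \code{"bray_curtis_similarity"}
#' @export
bray_curtis <- function(cm) {
  m <- if (inherits(cm, "community_matrix")) cm$cover else cm
  if (!is.matrix(m) || nrow(m) < 2) stop("need a matrix with >= 2 units")
  if (any(m < 0)) stop("negative values")
  if (any(rowSums(m) == 0)) warning("all-zero unit(s): similarity set to 0")
  s <- cpp_bray_curtis(m)
  dimnames(s) <- list(rownames(m), rownames(m))
  structure(list(values = s, metric = "bray_curtis_similarity",
                 labels = rownames(m)), class = "distance_matrix")
}

#' Euclidean distance matrix in the same container
#' @param m numeric matrix (rows = units)
#' @export
euclidean_distance <- function(m) {
  d <- as.matrix(stats::dist(m))
  structure(list(values = d, metric = "euclidean_distance",
                 labels = rownames(m)), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix (%s): %d units\n", x$metric,
              length(x$labels)))
  invisible(x)
}

# dissimilarity (0..100 for Bray-Curtis) from either container state
as_dissimilarity <- function(d) {
  stopifnot(inherits(d, "distance_matrix"))
  if (d$metric == "bray_curtis_similarity") 100 - d$values else d$values
}

# ---------------------------------------------------------------------------
# SIMPROF + UPGMA grouping

#' Hierarchical clustering with similarity-profile (SIMPROF) testing
#'
#' Builds a group-average (UPGMA) dendrogram on Bray-Curtis
#' dissimilarities and tests nodes top-down for multivariate structure:
#' at each node the departure pi of the ordered observed similarities from
#' the mean ordered profile of taxon-wise permutations is compared to its
#' permutation distribution. Descent continues only into significant nodes
#' (p <= alpha); the leaves of testing are the returned groups, labelled
#' a, b, c, ... in dendrogram order.
#'
#' @param cm transformed \code{community_matrix} (the permutations operate
#'   on the data, not the resemblance matrix)
#' @param n_perm permutations for the mean profile and for the test
#' @param alpha significance level for descending
#' @param seed RNG seed
#' @return an \code{assemblage_grouping}: named group vector
#'   (\code{$groups}), dendrogram (\code{$hclust}) and node test log
#'   (\code{$tests})
#' @export
cluster_simprof <- function(cm, n_perm = 999, alpha = 0.05, seed = 1) {
  stopifnot(inherits(cm, "community_matrix"))
  m <- cm$cover
  n <- nrow(m)
  if (n < 3) stop("need at least 3 units")
  set.seed(seed)
  sim <- cpp_bray_curtis(m)
  hc <- stats::hclust(stats::as.dist(100 - sim), method = "average")
  members <- function(node) {
    # leaves under merge-row node (node > 0) or single leaf (-i)
    if (node < 0) return(-node)
    c(members(hc$merge[node, 1]), members(hc$merge[node, 2]))
  }
  tests <- list()
  groups <- rep(NA_character_, n)
  group_sets <- list()
  descend <- function(node) {
    leaves <- sort(members(node))
    if (node < 0 || length(leaves) < 2) {
      group_sets[[length(group_sets) + 1L]] <<- leaves
      return(invisible())
    }
    res <- cpp_simprof_test(m[leaves, , drop = FALSE], n_perm, n_perm)
    tests[[length(tests) + 1L]] <<- data.frame(
      node = node, size = length(leaves), pi = res$pi, p = res$p)
    if (res$p <= alpha) {
      descend(hc$merge[node, 1])
      descend(hc$merge[node, 2])
    } else {
      group_sets[[length(group_sets) + 1L]] <<- leaves
    }
  }
  descend(nrow(hc$merge))
  # label groups a, b, c, ... by dendrogram display order
  pos <- match(seq_len(n), hc$order)
  ord <- order(vapply(group_sets, function(g) min(pos[g]), 0))
  for (k in seq_along(ord))
    groups[group_sets[[ord[k]]]] <- letters[k]
  grouping <- setNames(groups, rownames(m))
  structure(list(groups = grouping, hclust = hc,
                 tests = do.call(rbind, tests), alpha = alpha,
                 n_perm = n_perm, seed = seed),
            class = "assemblage_grouping")
}

#' @export
print.assemblage_grouping <- function(x, ...) {
  cat("assemblage_grouping:", length(unique(x$groups)), "group(s)\n")
  print(table(x$groups))
  invisible(x)
}

# ---------------------------------------------------------------------------
# SIMPER

#' Similarity percentages (SIMPER)
#'
#' Decomposes average within-group Bray-Curtis similarity into per-taxon
#' contributions: for each within-group pair the taxon term is
#' 100 * 2 min(y_ij, y_ik) / sum_i (y_ij + y_ik), which sums exactly to the
#' pairwise similarity. Also reports between-group average dissimilarity
#' decompositions. Average abundance is taken from the untransformed
#' matrix when supplied.
#'
#' @param cm transformed (sqrt) \code{community_matrix}
#' @param grouping named group vector or \code{assemblage_grouping}
#' @param raw optional raw/standardized \code{community_matrix} for the
#'   abundance column
#' @return list with \code{$within} (per-group tables: Av.Abundance,
#'   Av.Sim, Ind.Cont, Cum.Cont) and \code{$between} (per-pair
#'   dissimilarity tables)
#' @export
simper <- function(cm, grouping, raw = NULL) {
  stopifnot(inherits(cm, "community_matrix"))
  g <- if (inherits(grouping, "assemblage_grouping")) grouping$groups else grouping
  m <- cm$cover
  if (!all(rownames(m) %in% names(g))) stop("grouping must cover all units")
  g <- g[rownames(m)]
  rawm <- if (is.null(raw)) m else raw$cover[rownames(m), , drop = FALSE]
  taxa <- colnames(m)
  pair_terms <- function(rows, diss = FALSE) {
    # matrix: pairs x taxa of similarity (or dissimilarity) terms
    pr <- utils::combn(rows, 2)
    t(apply(pr, 2L, function(jk) {
      y1 <- m[jk[1], ]; y2 <- m[jk[2], ]
      den <- sum(y1 + y2)
      if (den == 0) return(rep(0, length(taxa)))
      if (diss) 100 * abs(y1 - y2) / den else 100 * 2 * pmin(y1, y2) / den
    }))
  }
  within <- list()
  for (gr in sort(unique(g))) {
    rows <- which(g == gr)
    av_ab <- colMeans(rawm[rows, , drop = FALSE])
    if (length(rows) < 2) {
      within[[gr]] <- data.frame(taxon = taxa, av_abundance = av_ab,
                                 av_sim = NA_real_, ind_contrib = NA_real_,
                                 cum_contrib = NA_real_, row.names = NULL)
      next
    }
    terms <- pair_terms(rows)
    contrib <- colMeans(terms)
    av_sim <- sum(contrib)     # = mean over pairs of pairwise similarity
    ind <- 100 * contrib / av_sim
    ord <- order(ind, decreasing = TRUE)
    within[[gr]] <- data.frame(taxon = taxa[ord],
                               av_abundance = av_ab[ord],
                               av_sim = contrib[ord],
                               ind_contrib = ind[ord],
                               cum_contrib = cumsum(ind[ord]),
                               row.names = NULL)
  }
  between <- list()
  gl <- sort(unique(g))
  if (length(gl) >= 2) {
    for (i in seq_len(length(gl) - 1)) for (j in (i + 1):length(gl)) {
      r1 <- which(g == gl[i]); r2 <- which(g == gl[j])
      pr <- expand.grid(a = r1, b = r2)
      terms <- t(apply(pr, 1L, function(jk) {
        y1 <- m[jk[1], ]; y2 <- m[jk[2], ]
        den <- sum(y1 + y2)
        if (den == 0) rep(0, length(taxa)) else 100 * abs(y1 - y2) / den
      }))
      contrib <- colMeans(terms)
      av_diss <- sum(contrib)
      ind <- 100 * contrib / av_diss
      ord <- order(ind, decreasing = TRUE)
      between[[paste(gl[i], gl[j], sep = "_vs_")]] <-
        data.frame(taxon = taxa[ord], av_diss = contrib[ord],
                   ind_contrib = ind[ord], cum_contrib = cumsum(ind[ord]),
                   row.names = NULL)
    }
  }
  list(within = within, between = between)
}

# ---------------------------------------------------------------------------
# ANOSIM

multiset_perms <- function(v) {
  # all distinct arrangements of the label vector v
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (u in unique(v)) {
    rest <- v[-match(u, v)]
    for (p in multiset_perms(rest)) out[[length(out) + 1L]] <- c(u, p)
  }
  out
}

anosim_R <- function(dr, g) {
  # dr: rank matrix of dissimilarities; g: group labels
  n <- length(g)
  same <- outer(g, g, "==")
  ut <- upper.tri(dr)
  rw <- mean(dr[ut & same])
  rb <- mean(dr[ut & !same])
  M <- n * (n - 1) / 2
  (rb - rw) / (M / 2)
}

#' Analysis of similarities (one-way ANOSIM)
#'
#' Rank-based permutation test of separation between a priori groups:
#' R = (mean between-group rank - mean within-group rank) / (M/2) with
#' M = n(n-1)/2, so R is 1 when all between-group dissimilarities exceed
#' all within-group ones. When the number of distinct relabelings is at
#' most \code{n_perm} the null distribution is enumerated completely
#' (exact p); otherwise p uses random permutations with the
#' (1+count)/(1+n_perm) estimator.
#'
#' @param d a \code{distance_matrix}
#' @param grouping named group labels (or \code{assemblage_grouping})
#' @param n_perm number of permutations
#' @param seed RNG seed
#' @return a \code{permutation_test_result} with statistic R
#' @export
anosim <- function(d, grouping, n_perm = 999, seed = 1) {
  g <- if (inherits(grouping, "assemblage_grouping")) grouping$groups else grouping
  diss <- as_dissimilarity(d)
  if (!is.null(names(g)) && !is.null(d$labels)) g <- g[d$labels]
  g <- as.character(g)
  if (length(unique(g)) < 2) stop("ANOSIM needs at least two groups")
  n <- length(g)
  ut <- upper.tri(diss)
  dr <- diss
  dr[ut] <- rank(diss[ut])
  dr[lower.tri(dr)] <- t(dr)[lower.tri(dr)]
  R_obs <- anosim_R(dr, g)
  n_arrange <- factorial(n) / prod(factorial(table(g)))
  set.seed(seed)
  if (is.finite(n_arrange) && n_arrange <= n_perm) {
    perms <- multiset_perms(g)
    Rs <- vapply(perms, function(p) anosim_R(dr, p), 0)
    p <- mean(Rs >= R_obs - 1e-12)
    exact <- TRUE
    n_used <- length(perms)
  } else {
    cnt <- 0L
    for (b in seq_len(n_perm))
      if (anosim_R(dr, g[sample.int(n)]) >= R_obs - 1e-12) cnt <- cnt + 1L
    p <- (1 + cnt) / (1 + n_perm)
    exact <- FALSE
    n_used <- n_perm
  }
  structure(list(statistic = R_obs, p_value = p, n_permutations = n_used,
                 exact = exact, seed = seed, method = "ANOSIM"),
            class = "permutation_test_result")
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s, %d permutations)\n",
              x$method, x$statistic, x$p_value,
              if (isTRUE(x$exact)) "exact" else "sampled",
              x$n_permutations))
  invisible(x)
}

# ---------------------------------------------------------------------------
# nMDS

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimization over monotone regression (via
#' \code{vegan::monoMDS}), taking the best of \code{n_restarts} random
#' starts plus a metric-scaling start.
#'
#' @param d a \code{distance_matrix}
#' @param n_dim embedding dimension (< number of units)
#' @param n_restarts random restarts
#' @param seed RNG seed
#' @return list(points, stress, n_dim)
#' @export
nmds <- function(d, n_dim = 2, n_restarts = 20, seed = 1) {
  diss <- as_dissimilarity(d)
  n <- nrow(diss)
  if (n_dim >= n) stop("n_dim must be smaller than the number of units")
  dd <- stats::as.dist(diss)
  set.seed(seed)
  best <- vegan::monoMDS(dd, k = n_dim, model = "global",
                         maxit = 500, smin = 1e-7, sratmax = 0.999999)
  for (r in seq_len(n_restarts)) {
    init <- matrix(stats::rnorm(n * n_dim), n, n_dim)
    fit <- vegan::monoMDS(dd, y = init, k = n_dim, model = "global",
                          maxit = 500, smin = 1e-7, sratmax = 0.999999)
    if (fit$stress < best$stress) best <- fit
  }
  pts <- best$points
  rownames(pts) <- d$labels
  list(points = pts, stress = best$stress, n_dim = n_dim)
}

# ---------------------------------------------------------------------------
# DistLM / dbRDA

expand_predictors <- function(predictors, normalise = TRUE) {
  # categorical -> indicator columns; each column centered, unit SD
  cols <- list()
  assign <- integer(0)
  for (j in seq_along(predictors)) {
    v <- predictors[[j]]
    nm <- names(predictors)[j]
    if (is.numeric(v)) {
      cols[[nm]] <- v
      assign <- c(assign, j)
    } else {
      f <- factor(v)
      for (lv in levels(f)) {
        cols[[paste(nm, lv, sep = ".")]] <- as.numeric(f == lv)
        assign <- c(assign, j)
      }
    }
  }
  X <- do.call(cbind, cols)
  if (normalise) {
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0
  }
  list(X = as.matrix(X), assign = assign)
}

gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  list(H = tcrossprod(Q), rank = q$rank, dropped = q$rank < ncol(X))
}

distlm_fit_stats <- function(G, X) {
  h <- hat_matrix(X)
  H <- h$H
  n <- nrow(G)
  m <- h$rank
  HGH <- H %*% G %*% H
  IH <- diag(n) - H
  RGR <- IH %*% G %*% IH
  trG <- sum(diag(G))
  r2 <- sum(diag(HGH)) / trG
  Fstat <- (sum(diag(HGH)) / m) / (sum(diag(RGR)) / (n - m - 1))
  list(r2 = r2, F = Fstat, m = m, dropped = h$dropped)
}

#' Distance-based linear modelling with dbRDA ordination
#'
#' McArdle-Anderson partitioning of a resemblance matrix on coded
#' predictors: with G the Gower-centered matrix of -D^2/2 and H the hat
#' matrix of the predictors, R^2 = tr(HGH)/tr(G) and
#' pseudo-F = [tr(HGH)/m] / [tr((I-H)G(I-H))/(n-m-1)]. P-values come from
#' permuting units. Reports marginal and sequential tests per predictor,
#' the best subset by adjusted R^2, and dbRDA axes (eigenvectors of HGH
#' scaled by the square roots of their eigenvalues) with predictor
#' correlations.
#'
#' @param d a \code{distance_matrix}
#' @param predictors data.frame of predictors (factors expanded to
#'   indicator columns and normalised)
#' @param n_perm permutations for the p-values
#' @param seed RNG seed
#' @export
distlm_dbrda <- function(d, predictors, n_perm = 999, seed = 1) {
  diss <- as_dissimilarity(d)
  n <- nrow(diss)
  ex <- expand_predictors(predictors)
  X <- ex$X
  if (n < ncol(X) + 2)
    warning("few units relative to predictor columns")
  G <- gower_center(diss)
  full <- distlm_fit_stats(G, X)
  # indicator expansions of factors are redundant by construction (each
  # factor's columns are collinear with the intercept); only warn when the
  # rank falls below what the factor structure itself implies
  expected_rank <- sum(vapply(predictors, function(v)
    if (is.numeric(v)) 1L else nlevels(factor(v)) - 1L, 0L))
  if (full$m < min(expected_rank, nrow(X) - 1))
    warning("rank-deficient predictors: aliased columns dropped")
  set.seed(seed)
  perm_p <- function(Xs, obsF) {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      pi <- sample.int(n)
      st <- distlm_fit_stats(G[pi, pi], Xs)
      if (st$F >= obsF - 1e-12) cnt <- cnt + 1L
    }
    (1 + cnt) / (1 + n_perm)
  }
  p_full <- perm_p(X, full$F)
  # marginal per predictor
  marg <- lapply(seq_along(predictors), function(j) {
    Xj <- X[, ex$assign == j, drop = FALSE]
    st <- distlm_fit_stats(G, Xj)
    data.frame(predictor = names(predictors)[j], r2 = st$r2,
               pseudo_F = st$F, p = perm_p(Xj, st$F))
  })
  # sequential in given order
  seqt <- list()
  r2_prev <- 0
  for (j in seq_along(predictors)) {
    Xj <- X[, ex$assign <= j, drop = FALSE]
    st <- distlm_fit_stats(G, Xj)
    seqt[[j]] <- data.frame(predictor = names(predictors)[j],
                            r2_added = st$r2 - r2_prev, r2_cum = st$r2)
    r2_prev <- st$r2
  }
  # best subset by adjusted R^2
  subsets <- unlist(lapply(seq_along(predictors), function(k)
    utils::combn(seq_along(predictors), k, simplify = FALSE)),
    recursive = FALSE)
  best <- NULL
  subset_tab <- do.call(rbind, lapply(subsets, function(ss) {
    Xs <- X[, ex$assign %in% ss, drop = FALSE]
    st <- distlm_fit_stats(G, Xs)
    adj <- 1 - (1 - st$r2) * (n - 1) / (n - st$m - 1)
    data.frame(subset = paste(names(predictors)[ss], collapse = "+"),
               r2 = st$r2, adj_r2 = adj, m = st$m)
  }))
  best <- subset_tab$subset[which.max(subset_tab$adj_r2)]
  # dbRDA axes
  H <- hat_matrix(X)$H
  HGH <- H %*% G %*% H
  eg <- eigen((HGH + t(HGH)) / 2, symmetric = TRUE)
  pos <- which(eg$values > 1e-8 * max(abs(eg$values)))
  axes <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), length(pos))
  rownames(axes) <- d$labels
  colnames(axes) <- paste0("dbRDA", seq_along(pos))
  pred_cor <- stats::cor(X, axes)
  structure(list(r2 = full$r2, pseudo_F = full$F, p_value = p_full,
                 m = full$m, n = n, marginal = do.call(rbind, marg),
                 sequential = do.call(rbind, seqt),
                 subsets = subset_tab, best_subset = best,
                 axes = axes, eigenvalues = eg$values[pos],
                 predictor_correlations = pred_cor,
                 n_permutations = n_perm, seed = seed),
            class = "distlm_result")
}

#' @export
print.distlm_result <- function(x, ...) {
  cat(sprintf("DistLM: R2 = %.3f, pseudo-F = %.3f (m = %d, n = %d), p = %.4g\n",
              x$r2, x$pseudo_F, x$m, x$n, x$p_value))
  cat("  best subset:", x$best_subset, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# CAP (canonical analysis of principal coordinates)

#' Canonical analysis of principal coordinates
#'
#' Discriminant analysis in principal-coordinate space: the resemblance
#' matrix is decomposed into PCo axes, the number m of retained axes is
#' chosen (when not given) to maximize leave-one-out allocation success of
#' a linear discriminant on the first m axes (capped at
#' n - groups - 1), and canonical axes plus LOO allocation success are
#' reported, with optional predictor/axis correlations.
#'
#' @param d a \code{distance_matrix}
#' @param grouping named group labels (or \code{assemblage_grouping})
#' @param m_axes number of PCo axes; chosen automatically when NULL
#' @param predictors optional data.frame; correlations of its normalised
#'   coding with the canonical axes are reported
#' @param seed RNG seed (LDA itself is deterministic; kept for API
#'   symmetry)
#' @export
cap_analysis <- function(d, grouping, m_axes = NULL, predictors = NULL,
                         seed = 1) {
  g <- if (inherits(grouping, "assemblage_grouping")) grouping$groups else grouping
  diss <- as_dissimilarity(d)
  if (!is.null(names(g)) && !is.null(d$labels)) g <- g[d$labels]
  g <- factor(as.character(g))
  if (nlevels(g) < 2) stop("need at least two groups")
  n <- nrow(diss)
  G <- gower_center(diss)
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- which(eg$values > 1e-8 * max(abs(eg$values)))
  scores <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), length(pos))
  m_max <- min(length(pos), n - nlevels(g) - 1)
  if (m_max < 1) stop("too few units for CAP")
  loo_success <- function(m) {
    ok <- 0L
    for (i in seq_len(n)) {
      fit <- tryCatch(suppressWarnings(
        MASS::lda(scores[-i, seq_len(m), drop = FALSE],
                  grouping = g[-i])), error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      pr <- stats::predict(fit, scores[i, seq_len(m), drop = FALSE])$class
      if (pr == g[i]) ok <- ok + 1L
    }
    ok / n
  }
  if (is.null(m_axes)) {
    succ <- vapply(seq_len(m_max), loo_success, 0)
    m_axes <- which.max(succ)           # ties -> smallest m
    allocation <- succ[m_axes]
  } else {
    if (m_axes >= n) stop("m must be < n")
    allocation <- loo_success(m_axes)
  }
  fit <- suppressWarnings(MASS::lda(scores[, seq_len(m_axes), drop = FALSE],
                                    grouping = g))
  ax <- stats::predict(fit)$x
  rownames(ax) <- d$labels
  colnames(ax) <- paste0("CAP", seq_len(ncol(ax)))
  pred_cor <- NULL
  if (!is.null(predictors)) {
    X <- expand_predictors(predictors)$X
    pred_cor <- stats::cor(X, ax)
  }
  structure(list(axes = ax, m = m_axes, allocation_success = allocation,
                 groups = g, predictor_correlations = pred_cor,
                 n_canonical = ncol(ax), seed = seed),
            class = "cap_result")
}

#' @export
print.cap_result <- function(x, ...) {
  cat(sprintf("CAP: m = %d PCo axes, %d canonical axes, LOO allocation %.1f%%\n",
              x$m, x$n_canonical, 100 * x$allocation_success))
  invisible(x)
}
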