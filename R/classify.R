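#' Z-score feature columns
#'
#' Centres each feature to mean 0 and scales to population SD 1 so that every
#' feature contributes equally to the embedding. Zero-variance columns are
#' uninformative and dropped (with a message).
#'
#' @param fm an `sst_features` object.
#' @return `sst_features` with standardized `values`.
#' @export
zscore_features <- function(fm) {
  x <- fm$values
  if (nrow(x) < 2L) stop("z-scoring needs at least 2 cells")
  mu <- colMeans(x)
  s <- apply(x, 2L, pop_sd)
  keep <- s > 0
  if (any(!keep))
    message(sum(!keep), " zero-variance feature column(s) dropped")
  z <- sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep]), 2L, s[keep], `/`)
  structure(list(values = z, specs = fm$specs[keep, , drop = FALSE],
                 cells = fm$cells, excluded = fm$excluded),
            class = "sst_features")
}

# Fit the (a, b) low-dimensional similarity curve 1 / (1 + a d^(2b)) to the
# target shape exp(-(d - min_dist)) beyond min_dist (1 inside it).
ab_params <- function(min_dist) {
  d <- seq(0, 3, length.out = 301)
  y <- ifelse(d <= min_dist, 1, exp(-(d - min_dist)))
  fit <- tryCatch(
    stats::nls(y ~ 1 / (1 + a * d^(2 * b)), start = list(a = 1.6, b = 0.9),
               control = list(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(c(a = 1.58, b = 0.90))
  cf <- stats::coef(fit)
  c(a = unname(cf["a"]), b = unname(cf["b"]))
}

# Smooth-kNN graph: per-point adaptive kernel calibrated so the effective
# neighbourhood size is log2(k), then symmetrized by fuzzy union.
fuzzy_knn_graph <- function(x, n_neighbors) {
  n <- nrow(x)
  D <- as.matrix(dist(x))
  k <- min(n_neighbors, n - 1L)
  P <- matrix(0, n, n)
  target <- log2(k)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    nn <- order(d)[seq_len(k)]
    dn <- d[nn]
    rho <- if (any(dn > 0)) min(dn[dn > 0]) else 0
    f <- function(sigma) sum(exp(-pmax(dn - rho, 0) / sigma)) - target
    lo <- 1e-6; hi <- max(dn) + 1
    if (f(hi) < 0) hi <- hi * 64
    sigma <- tryCatch(stats::uniroot(f, c(lo, hi))$root, error = function(e) 1)
    w <- exp(-pmax(dn - rho, 0) / sigma)
    cols <- seq_len(n)[-i][nn]
    P[i, cols] <- w
  }
  P + t(P) - P * t(P)
}

#' Neighbour-graph embedding of the feature matrix
#'
#' Two-dimensional embedding of the z-scored top-feature matrix built from a
#' fuzzy k-nearest-neighbour graph: per-point adaptive Gaussian weights
#' calibrated to an effective neighbourhood of `n_neighbors`, symmetrized,
#' initialised by the graph Laplacian's leading non-trivial eigenvectors, and
#' refined by full-batch gradient descent on the graph cross-entropy with a
#' low-dimensional similarity kernel whose flat core is set by `min_dist`.
#' Deterministic given `seed`.
#'
#' @param x numeric matrix (cells x features), typically z-scored top-30.
#' @param n_neighbors neighbourhood size (>= 2, < number of cells).
#' @param min_dist minimum separation scale in embedding space, in [0, 1).
#' @param n_components embedding dimension (2).
#' @param seed integer seed.
#' @param n_epochs optimisation epochs.
#' @return cells x `n_components` coordinate matrix.
#' @export
embed_features <- function(x, n_neighbors = 15L, min_dist = 0.1,
                           n_components = 2L, seed = 42L, n_epochs = 200L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n_neighbors < 2L) stop("n_neighbors must be >= 2")
  if (n <= n_neighbors) stop("fewer cells than n_neighbors")
  if (min_dist < 0 || min_dist >= 1) stop("min_dist must be in [0, 1)")
  set.seed(seed)
  P <- fuzzy_knn_graph(x, n_neighbors)
  ab <- ab_params(min_dist)
  a <- ab["a"]; b <- ab["b"]
  # spectral initialisation on the normalized Laplacian (tiny uniform term
  # keeps disconnected components bound)
  W <- P + 1e-8
  dg <- rowSums(W)
  L <- diag(n) - diag(1 / sqrt(dg)) %*% W %*% diag(1 / sqrt(dg))
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  y <- ev$vectors[, (n - 1L):(n - n_components), drop = FALSE]
  y <- apply(y, 2L, function(v) {
    s <- pop_sd(v)
    if (s > 0) v / s else v
  }) * 3
  y <- y + matrix(rnorm(n * n_components, sd = 1e-3), n)
  # full-batch cross-entropy layout; repulsion balanced against total edge
  # weight (the negative-sampling ratio of the stochastic formulation)
  gamma <- 5 * sum(P) / max(1, n * (n - 1L) - sum(P > 0))
  eps <- 1e-3
  for (epoch in seq_len(n_epochs)) {
    alpha <- 0.3 * (1 - (epoch - 1L) / n_epochs)
    d2 <- as.matrix(dist(y))^2
    denom <- 1 + a * d2^b
    catt <- P * (2 * a * b * pmax(d2, eps)^(b - 1)) / denom
    crep <- (1 - P) * (2 * b) / ((d2 + eps) * denom)
    C <- catt - gamma * crep
    diag(C) <- 0
    grad <- (diag(rowSums(C)) - C) %*% y
    grad <- pmin(pmax(grad, -4), 4)
    y <- y - alpha * grad
  }
  dimnames(y) <- list(rownames(x), paste0("dim", seq_len(n_components)))
  y
}

#' Density-based clustering (DBSCAN)
#'
#' Standard DBSCAN on the embedding coordinates: core points have at least
#' `min_pts` neighbours within `eps`; clusters are the connected components
#' of core points plus their border points; remaining points are noise
#' (label 0).
#'
#' @param x numeric matrix of points.
#' @param eps neighbourhood radius.
#' @param min_pts core-point threshold (including the point itself).
#' @return Integer cluster labels (0 = noise).
#' @export
dbscan_cluster <- function(x, eps, min_pts = 5L) {
  D <- as.matrix(dist(x))
  n <- nrow(D)
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, 0L) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0L) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (q in nb[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

mean_silhouette <- function(points, labels) {
  keep <- labels != 0L
  if (sum(keep) < 3L || length(unique(labels[keep])) < 2L) return(NA_real_)
  sil <- cluster::silhouette(labels[keep], dist(points[keep, , drop = FALSE]))
  mean(sil[, "sil_width"])
}

#' Default embedding / clustering hyperparameter grid
#'
#' @param full if `TRUE`, the expanded search (~5000 combinations) used to
#'   stress the cluster-count choice; otherwise a grid sized to run in
#'   minutes.
#' @return List with `n_neighbors`, `min_dist`, `k`, `eps`, `methods`.
#' @export
default_grid <- function(full = FALSE) {
  if (full) {
    list(n_neighbors = c(3, 5, 8, 10, 15, 20, 30, 50),
         min_dist = c(0, 0.05, 0.1, 0.25, 0.5, 0.8),
         k = 2:10, eps = exp(seq(log(0.05), log(8), length.out = 16)),
         methods = c("kmeans", "spectral", "dbscan"))
  } else {
    list(n_neighbors = c(5, 10, 15, 30), min_dist = c(0, 0.1, 0.25, 0.5),
         k = 2:8, eps = exp(seq(log(0.1), log(5), length.out = 10)),
         methods = c("kmeans", "spectral", "dbscan"))
  }
}

#' Grid search over embeddings and clusterings
#'
#' Evaluates every combination of embedding hyperparameters with every
#' clustering configuration (k-means and spectral clustering over cluster
#' counts `k`; DBSCAN over radii `eps`), scoring each solution by the mean
#' silhouette width in embedding space. Degenerate solutions (fewer than two
#' clusters, silhouette undefined, or density solutions leaving more than
#' `max_noise_frac` of cells unassigned) are kept in the table but excluded
#' from ranking.
#'
#' @param z numeric matrix (cells x features), z-scored.
#' @param grid hyperparameter grid from [default_grid()].
#' @param seed integer seed controlling the embeddings and cluster
#'   initialisations.
#' @param n_epochs embedding optimisation epochs.
#' @param max_noise_frac largest tolerated fraction of noise points in a
#'   ranked density-method solution.
#' @return List of class `sst_gridsearch`: `solutions` (data.frame, ranked),
#'   `best` (list: `embedding`, `labels`, silhouette and parameters),
#'   `embeddings` (list of coordinate matrices), `selection` (silhouette
#'   summary by cluster count supporting the cluster-count choice).
#' @export
grid_search <- function(z, grid = default_grid(), seed = 42L,
                        n_epochs = 150L, max_noise_frac = 0.2) {
  emb_cfg <- expand.grid(n_neighbors = grid$n_neighbors,
                         min_dist = grid$min_dist)
  embeddings <- vector("list", nrow(emb_cfg))
  sols <- list()
  labels_store <- list()
  for (e in seq_len(nrow(emb_cfg))) {
    emb <- embed_features(z, emb_cfg$n_neighbors[e], emb_cfg$min_dist[e],
                          seed = seed, n_epochs = n_epochs)
    embeddings[[e]] <- emb
    add <- function(method, param, labels) {
      nc <- length(unique(labels[labels != 0L]))
      sil <- mean_silhouette(emb, labels)
      # a solution must cover the population: density solutions that leave
      # more than max_noise_frac of cells unassigned are degenerate
      noise_frac <- mean(labels == 0L)
      sols[[length(sols) + 1L]] <<- data.frame(
        embedding_id = e, n_neighbors = emb_cfg$n_neighbors[e],
        min_dist = emb_cfg$min_dist[e], method = method, param = param,
        n_clusters = nc, n_noise = sum(labels == 0L), silhouette = sil,
        degenerate = nc < 2L || !is.finite(sil) ||
          noise_frac > max_noise_frac)
      labels_store[[length(sols)]] <<- labels
    }
    if ("kmeans" %in% grid$methods) {
      for (k in grid$k) {
        set.seed(seed + k)
        km <- kmeans(emb, centers = k, nstart = 10L, iter.max = 50L)
        add("kmeans", k, km$cluster)
      }
    }
    if ("spectral" %in% grid$methods) {
      for (k in grid$k) {
        set.seed(seed + k)
        lab <- tryCatch(
          as.integer(kernlab::specc(emb, centers = k)),
          error = function(err) NULL)
        if (!is.null(lab)) add("spectral", k, lab)
      }
    }
    if ("dbscan" %in% grid$methods) {
      for (eps in grid$eps) add("dbscan", eps, dbscan_cluster(emb, eps))
    }
  }
  solutions <- do.call(rbind, sols)
  solutions$solution_id <- seq_len(nrow(solutions))
  ok <- !solutions$degenerate
  ord <- order(ifelse(ok, -solutions$silhouette, Inf))
  solutions <- solutions[ord, ]
  rownames(solutions) <- NULL
  if (!any(ok)) stop("no non-degenerate clustering solution found")
  best_row <- solutions[1L, ]
  best <- list(embedding = embeddings[[best_row$embedding_id]],
               labels = labels_store[[best_row$solution_id]],
               method = best_row$method, param = best_row$param,
               n_neighbors = best_row$n_neighbors,
               min_dist = best_row$min_dist,
               n_clusters = best_row$n_clusters,
               silhouette = best_row$silhouette)
  sel <- stats::aggregate(silhouette ~ n_clusters,
                          data = solutions[!solutions$degenerate, ],
                          FUN = function(v) c(best = max(v), mean = mean(v),
                                              n = length(v)))
  structure(list(solutions = solutions, best = best,
                 embeddings = embeddings, selection = sel),
            class = "sst_gridsearch")
}

#' Assign the putative SST-Calb2 cluster
#'
#' Operationalises the heuristic cluster-to-subtype assignment: the cluster
#' whose cells have the highest mean stimulus-response probability and mean
#' evoked peak (rank-sum over the two criteria) is designated putative
#' SST-Calb2; all other clusters, and density-method noise points, become
#' putative SST-O. Ties break to the lower cluster id with a warning. A
#' manual override is available.
#'
#' @param best a `best` solution from [grid_search()].
#' @param fm the full `sst_features` matrix (used for the response-probability
#'   and evoked-peak criteria).
#' @param manual optional cluster id to designate as putative SST-Calb2,
#'   bypassing the heuristic.
#' @return List of class `sst_assignment`: `putative_calb2_cluster`,
#'   `predicted` (named per-cell `"putative-Calb2"`/`"putative-O"`), `noise`
#'   (logical), `criteria` (per-cluster means and ranks).
#' @export
assign_putative_subtype <- function(best, fm, manual = NULL) {
  labels <- best$labels
  clusters <- sort(unique(labels[labels != 0L]))
  if (length(clusters) < 2L)
    stop("assignment undefined for a single-cluster solution")
  rp_cols <- fm$specs$category == "response_probability" &
    fm$specs$trial_type == "stimulus"
  pk_col <- fm$specs$category == "in_trial" &
    fm$specs$trial_type == "stimulus" & fm$specs$period == "response" &
    fm$specs$metric == "peak"
  if (!any(rp_cols) || !any(pk_col))
    stop("feature matrix lacks the assignment criteria columns")
  rp <- rowMeans(fm$values[, rp_cols, drop = FALSE])
  pk <- rowMeans(fm$values[, pk_col, drop = FALSE])
  crit <- data.frame(
    cluster = clusters,
    mean_response_prob = vapply(clusters, function(cl)
      mean(rp[labels == cl]), 0),
    mean_evoked_peak = vapply(clusters, function(cl)
      mean(pk[labels == cl]), 0))
  crit$rank_prob <- rank(-crit$mean_response_prob, ties.method = "min")
  crit$rank_peak <- rank(-crit$mean_evoked_peak, ties.method = "min")
  crit$rank_sum <- crit$rank_prob + crit$rank_peak
  if (is.null(manual)) {
    winners <- crit$cluster[crit$rank_sum == min(crit$rank_sum)]
    if (length(winners) > 1L)
      warning("tie on the assignment heuristic; choosing cluster ",
              min(winners))
    calb2_cluster <- min(winners)
  } else {
    if (!manual %in% clusters) stop("manual cluster id not in solution")
    calb2_cluster <- manual
  }
  predicted <- ifelse(labels == calb2_cluster, "putative-Calb2", "putative-O")
  names(predicted) <- fm$cells
  structure(list(putative_calb2_cluster = calb2_cluster,
                 predicted = predicted, noise = labels == 0L,
                 criteria = crit), class = "sst_assignment")
}

#' Evaluate predictions against genetic labels
#'
#' Confusion-matrix evaluation with SST-Calb2 as the positive class:
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = 2PR/(P+R),
#' accuracy = (TP+TN)/total, and the analogous per-class precision/recall for
#' SST-O. Cells with unknown truth are ignored.
#'
#' @param predicted per-cell `"putative-Calb2"`/`"putative-O"`, named by cell.
#' @param truth per-cell `"SST-Calb2"`/`"SST-O"` (named; other values
#'   ignored).
#' @return List of class `sst_eval`: `confusion` (TP, FP, TN, FN) and
#'   `metrics` (precision/recall per class, f1, accuracy).
#' @export
evaluate_classification <- function(predicted, truth) {
  if (!is.null(names(predicted)) && !is.null(names(truth)))
    truth <- truth[names(predicted)]
  use <- truth %in% c("SST-Calb2", "SST-O")
  if (sum(truth[use] == "SST-Calb2") < 1L || sum(truth[use] == "SST-O") < 1L)
    stop("need at least one labelled cell per class")
  p <- predicted[use] == "putative-Calb2"
  y <- truth[use] == "SST-Calb2"
  tp <- sum(p & y); fp <- sum(p & !y); tn <- sum(!p & !y); fn <- sum(!p & y)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  prec_o <- tn / (tn + fn)
  rec_o <- tn / (tn + fp)
  structure(list(
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    metrics = list(precision_calb2 = prec, recall_calb2 = rec, f1 = f1,
                   accuracy = (tp + tn) / (tp + fp + tn + fn),
                   precision_o = prec_o, recall_o = rec_o)),
    class = "sst_eval")
}

#' @export
print.sst_eval <- function(x, ...) {
  cat(sprintf("<sst_eval> TP=%d FP=%d TN=%d FN=%d | F1=%.3f acc=%.1f%%\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"], x$metrics$f1, 100 * x$metrics$accuracy))
  cat(sprintf("  SST-Calb2: precision %.0f%%, recall %.0f%% | SST-O: precision %.0f%%, recall %.0f%%\n",
              100 * x$metrics$precision_calb2, 100 * x$metrics$recall_calb2,
              100 * x$metrics$precision_o, 100 * x$metrics$recall_o))
  invisible(x)
}

#' End-to-end clustering-informed classification
#'
#' Convenience pipeline: build the feature matrix over the pretraining days,
#' rank features by class separability, z-score the top `n_top`, grid-search
#' embeddings and clusterings, assign the putative SST-Calb2 cluster, and
#' evaluate against the genetic labels.
#'
#' @param preprocessed result of [preprocess_experiment()].
#' @param labels named per-cell truth labels (`"SST-Calb2"`/`"SST-O"`).
#' @param days pretraining days for the feature matrix.
#' @param n_top number of ranked features to embed (30).
#' @param grid hyperparameter grid.
#' @param seed integer seed.
#' @param n_epochs embedding optimisation epochs.
#' @return List: `features`, `ranking`, `search`, `assignment`, `evaluation`.
#' @export
classify_experiment <- function(preprocessed, labels,
                                days = paste0("ACC", 4:6), n_top = 30L,
                                grid = default_grid(), seed = 42L,
                                n_epochs = 150L) {
  fm <- build_feature_matrix(preprocessed, days = days)
  ranking <- rank_features(fm, labels)
  z <- zscore_features(top_features(fm, ranking, n_top))
  search <- grid_search(z$values, grid = grid, seed = seed,
                        n_epochs = n_epochs)
  assignment <- assign_putative_subtype(search$best, fm)
  evaluation <- evaluate_classification(assignment$predicted, labels)
  list(features = fm, ranking = ranking, search = search,
       assignment = assignment, evaluation = evaluation)
}
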