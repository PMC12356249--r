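make_fm <- function(vals, specs = NULL) {
  if (is.null(specs))
    specs <- data.frame(spec_id = colnames(vals), category = "in_trial",
                        trial_type = "stimulus", period = "response",
                        metric = "peak", threshold_k = NA_real_)
  structure(list(values = vals, specs = specs, cells = rownames(vals),
                 excluded = character(0)), class = "sst_features")
}

test_that("z-scoring yields exact column contracts and drops constants", {
  v <- cbind(a = c(1, 3), b = c(5, 5))
  rownames(v) <- c("c1", "c2")
  expect_message(z <- zscore_features(make_fm(v)), "zero-variance")
  expect_equal(unname(z$values[, "a"]), c(-1, 1))
  expect_false("b" %in% colnames(z$values))

  set.seed(21)
  v2 <- matrix(rnorm(200), 20, dimnames = list(paste0("c", 1:20), NULL))
  colnames(v2) <- paste0("f", 1:10)
  z2 <- zscore_features(make_fm(v2))
  expect_true(all(abs(colMeans(z2$values)) < 1e-12))
  expect_true(all(abs(apply(z2$values, 2, function(x)
    sqrt(mean((x - mean(x))^2))) - 1) < 1e-12))

  expect_error(zscore_features(make_fm(v[1, , drop = FALSE])), "2 cells")
})

test_that("embedding is deterministic, 2-D, and separates feature blobs", {
  set.seed(22)
  n <- 40L
  x <- rbind(matrix(rnorm(20 * 10, 0), 20),
             matrix(rnorm(20 * 10, 6), 20))
  rownames(x) <- paste0("c", 1:n)
  e1 <- embed_features(x, n_neighbors = 10, min_dist = 0.1, seed = 5)
  e2 <- embed_features(x, n_neighbors = 10, min_dist = 0.1, seed = 5)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(n, 2L))
  # the two blobs are linearly separable along some embedding axis
  grp <- rep(1:2, each = 20)
  gap_ok <- vapply(1:2, function(d) {
    r1 <- range(e1[grp == 1, d]); r2 <- range(e1[grp == 2, d])
    r1[2] < r2[1] || r2[2] < r1[1]
  }, TRUE)
  expect_true(any(gap_ok))
  expect_error(embed_features(x, n_neighbors = 50), "fewer cells")
  expect_error(embed_features(x, n_neighbors = 1), ">= 2")
  expect_error(embed_features(x, min_dist = 1.2), "min_dist")
})

test_that("dbscan finds dense groups and marks outliers as noise", {
  pts <- rbind(matrix(rnorm(40, 0, 0.05), 20),
               matrix(rnorm(40, 5, 0.05), 20),
               c(50, 50))
  lab <- dbscan_cluster(pts, eps = 0.5, min_pts = 5)
  expect_equal(length(unique(lab[lab != 0])), 2L)
  expect_equal(lab[41], 0L)
  expect_length(unique(lab[1:20]), 1L)
  expect_length(unique(lab[21:40]), 1L)
})

test_that("grid search enumerates the full grid and ranks by silhouette", {
  set.seed(23)
  x <- rbind(matrix(rnorm(60, 0, 0.3), 10), matrix(rnorm(60, 4, 0.3), 10),
             matrix(rnorm(60, c(0, 8), 0.3), 10))
  rownames(x) <- paste0("c", 1:30)
  g <- list(n_neighbors = c(5, 8), min_dist = 0.1, k = 2:4,
            eps = numeric(0), methods = "kmeans")
  gs <- grid_search(x, grid = g, seed = 3, n_epochs = 60)
  # 2 embeddings x 3 k values -> 6 solutions
  expect_equal(nrow(gs$solutions), 6L)
  expect_equal(sort(table(gs$solutions$n_neighbors), decreasing = TRUE),
               sort(table(c(5, 5, 5, 8, 8, 8)), decreasing = TRUE))
  ok <- !gs$solutions$degenerate
  expect_true(all(diff(gs$solutions$silhouette[ok]) <= 0))
  expect_equal(gs$best$silhouette, max(gs$solutions$silhouette[ok]))
  # three well-separated blobs: the best solution has three clusters
  expect_equal(gs$best$n_clusters, 3L)
  # a two-point-per-cluster perfect separation scores silhouette 1
  tiny <- rbind(c(0, 0), c(0, 0.001), c(9, 9), c(9, 9.001))
  sil <- mean_silhouette(tiny, c(1L, 1L, 2L, 2L))
  expect_gt(sil, 0.99)
})

test_that("putative-Calb2 assignment follows the rank-sum heuristic", {
  spec2 <- data.frame(
    spec_id = c("rp", "pk"),
    category = c("response_probability", "in_trial"),
    trial_type = "stimulus", period = "response",
    metric = c("probability", "peak"), threshold_k = c(1, NA))
  vals <- rbind(matrix(c(0.9, 1.5), 4, 2, byrow = TRUE),
                matrix(c(0.3, 0.4), 4, 2, byrow = TRUE))
  colnames(vals) <- spec2$spec_id
  rownames(vals) <- paste0("c", 1:8)
  fm <- make_fm(vals, spec2)
  best <- list(labels = c(rep(2L, 4), rep(1L, 4)))
  asg <- assign_putative_subtype(best, fm)
  expect_equal(asg$putative_calb2_cluster, 2L)
  expect_equal(unname(asg$predicted[1:4]), rep("putative-Calb2", 4))
  expect_equal(unname(asg$predicted[5:8]), rep("putative-O", 4))

  # identical clusters tie-break to the lower id with a warning
  vals_tie <- rbind(matrix(c(0.5, 1), 4, 2, byrow = TRUE),
                    matrix(c(0.5, 1), 4, 2, byrow = TRUE))
  dimnames(vals_tie) <- dimnames(vals)
  expect_warning(
    asg_tie <- assign_putative_subtype(best, make_fm(vals_tie, spec2)),
    "tie")
  expect_equal(asg_tie$putative_calb2_cluster, 1L)

  # single-cluster solutions cannot be assigned
  expect_error(
    assign_putative_subtype(list(labels = rep(1L, 8)), fm),
    "single-cluster")

  # manual override bypasses the heuristic
  asg_man <- assign_putative_subtype(best, fm, manual = 1L)
  expect_equal(asg_man$putative_calb2_cluster, 1L)

  # density-method noise points are never putative-Calb2
  best_noise <- list(labels = c(rep(2L, 4), rep(1L, 3), 0L))
  asg_n <- assign_putative_subtype(best_noise, fm)
  expect_equal(unname(asg_n$predicted[8]), "putative-O")
  expect_true(asg_n$noise[8])
})

test_that("confusion metrics agree with a brute-force tally on random labels", {
  set.seed(24)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    truth <- sample(c("SST-Calb2", "SST-O"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    pred <- sample(c("putative-Calb2", "putative-O"), n, replace = TRUE)
    names(pred) <- names(truth) <- paste0("c", seq_len(n))
    ev <- evaluate_classification(pred, truth)
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in seq_len(n)) {
      if (pred[i] == "putative-Calb2" && truth[i] == "SST-Calb2") tp <- tp + 1
      if (pred[i] == "putative-Calb2" && truth[i] == "SST-O") fp <- fp + 1
      if (pred[i] == "putative-O" && truth[i] == "SST-O") tn <- tn + 1
      if (pred[i] == "putative-O" && truth[i] == "SST-Calb2") fn <- fn + 1
    }
    expect_equal(unname(ev$confusion), c(tp, fp, tn, fn))
    expect_equal(ev$confusion[["TP"]] + ev$confusion[["FP"]] +
                 ev$confusion[["TN"]] + ev$confusion[["FN"]], n)
    if (tp + fp > 0) expect_equal(ev$metrics$precision_calb2, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(ev$metrics$recall_calb2, tp / (tp + fn))
    expect_equal(ev$metrics$accuracy, (tp + tn) / n)
  }
  # perfect prediction
  truth <- setNames(rep(c("SST-Calb2", "SST-O"), 3), paste0("c", 1:6))
  pred <- setNames(ifelse(truth == "SST-Calb2", "putative-Calb2",
                          "putative-O"), names(truth))
  ev <- evaluate_classification(pred, truth)
  expect_equal(ev$metrics$f1, 1)
  expect_equal(ev$metrics$accuracy, 1)
})

test_that("classification beats chance on the default two-class population", {
  # scaled-down population, full pipeline, binomial test against chance
  wins <- 0L
  n_seeds <- 3L
  for (s in seq_len(n_seeds)) {
    cls <- default_classes()
    cls[[1]]$n <- 10L; cls[[2]]$n <- 20L
    cfg <- generator_config(classes = cls, days = paste0("ACC", 4:6),
                            seed = 30 + s)
    exp1 <- generate_experiment(cfg)
    pp <- preprocess_experiment(exp1$sessions)
    labs <- setNames(exp1$registry$true_label, exp1$registry$cell_id)
    g <- list(n_neighbors = c(5, 10), min_dist = c(0, 0.1), k = 2:4,
              eps = exp(seq(log(0.3), log(3), length.out = 4)),
              methods = c("kmeans", "dbscan"))
    res <- suppressWarnings(suppressMessages(
      classify_experiment(pp, labs, grid = g, seed = 40 + s,
                          n_epochs = 80)))
    cm <- res$evaluation$confusion
    n_lab <- sum(cm)
    correct <- cm[["TP"]] + cm[["TN"]]
    # chance = always guessing the majority class
    p_chance <- max(table(labs)) / n_lab
    p <- stats::binom.test(correct, n_lab, p_chance,
                           alternative = "greater")$p.value
    if (p < 0.01) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
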