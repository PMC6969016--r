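# Native k-nearest-neighbour classification of raw tri-axial accelerometer
# records. No feature engineering: each record is a single (x, y, z) sample in
# g and distance is plain Euclidean distance in those units.

#' Build a training set from an annotated trace
#'
#' Samples, uniformly at random without replacement, `n_scent` raw tri-axial
#' records from each scent-marking class present in the annotation and
#' `n_other` records from the general "other" class (fine labels collapsed).
#' The deliberately small scent-class sample emulates field conditions where
#' only a few marking events are observed before release.
#'
#' @param trace an [accel_trace()].
#' @param labels a [label_track()] annotating the trace.
#' @param n_scent records per scent class (default 50).
#' @param n_other records for the "other" class (default 500).
#' @param seed RNG seed for the sampling.
#' @return A `training_set`: data.frame with columns `x`, `y`, `z`, `class`,
#'   `index` (sample index into the trace); attributes `provenance` and
#'   `sample_classes` (the per-sample collapsed label vector, reused when
#'   building the complementary testing set).
#' @export
build_training_set <- function(trace, labels, n_scent = 50, n_other = 500,
                               seed = 1L) {
  cls <- collapse_other(labels_at(labels, trace$t, default = "other"))
  present_scent <- intersect(scent_classes(), unique(cls))
  if (!length(present_scent)) stop("no scent-marking class present in labels")
  counts <- table(cls)
  for (sc in present_scent) {
    if (counts[[sc]] < n_scent) {
      stop(sprintf("class '%s' has %d samples, fewer than n_scent = %d",
                   sc, counts[[sc]], n_scent))
    }
  }
  if (is.na(counts["other"]) || counts[["other"]] < n_other) {
    stop(sprintf("class 'other' has %d samples, fewer than n_other = %d",
                 if (is.na(counts["other"])) 0L else counts[["other"]], n_other))
  }
  with_sim_seed(seed, {
    idx <- integer(0)
    for (sc in present_scent) {
      idx <- c(idx, sample(which(cls == sc), n_scent))
    }
    idx <- c(idx, sample(which(cls == "other"), n_other))
    ts <- data.frame(x = trace$x[idx], y = trace$y[idx], z = trace$z[idx],
                     class = cls[idx], index = idx, stringsAsFactors = FALSE)
    attr(ts, "provenance") <- list(n_scent = n_scent, n_other = n_other,
                                   seed = seed, classes = c(present_scent, "other"))
    attr(ts, "sample_classes") <- cls
    class(ts) <- c("training_set", "data.frame")
    ts
  })
}

#' Build the complementary testing set
#'
#' All scent-marking records not used for training, plus `n_other_test`
#' randomly selected "other" records disjoint from the training rows (capped
#' at availability with a warning). The capped random "other" sample prevents
#' the abundant non-marking class from driving the performance metrics.
#'
#' @param trace,labels as in [build_training_set()].
#' @param training the `training_set` built from the same trace.
#' @param n_other_test "other" records in the testing set (default 3000).
#' @param seed RNG seed.
#' @return A `training_set`-shaped data.frame of testing records, disjoint
#'   from `training` by construction.
#' @export
build_testing_set <- function(trace, labels, training, n_other_test = 3000,
                              seed = 2L) {
  cls <- attr(training, "sample_classes")
  if (is.null(cls)) cls <- collapse_other(labels_at(labels, trace$t, default = "other"))
  avail <- setdiff(seq_along(cls), training$index)
  scent_idx <- avail[cls[avail] %in% scent_classes()]
  other_avail <- avail[cls[avail] == "other"]
  with_sim_seed(seed, {
    n_take <- min(n_other_test, length(other_avail))
    if (n_take < n_other_test) {
      warning(sprintf("only %d 'other' records available for testing (requested %d)",
                      n_take, n_other_test))
    }
    other_idx <- if (n_take > 0) sample(other_avail, n_take) else integer(0)
    idx <- c(scent_idx, other_idx)
    ts <- data.frame(x = trace$x[idx], y = trace$y[idx], z = trace$z[idx],
                     class = cls[idx], index = idx, stringsAsFactors = FALSE)
    class(ts) <- c("training_set", "data.frame")
    ts
  })
}

#' Construct a KNN classifier
#'
#' @param training a `training_set` (or any data.frame with `x`, `y`, `z`,
#'   `class`).
#' @param k odd positive neighbour count, `k <= nrow(training)`. Odd k avoids
#'   vote deadlocks in the two-class case.
#' @param vote `"majority"` or `"distance_weighted"` (votes weighted by
#'   1/distance; an exact-match neighbour at distance 0 wins outright).
#' @return A `knn_classifier`.
#' @export
knn_classifier <- function(training, k = 3L, vote = c("majority", "distance_weighted")) {
  vote <- match.arg(vote)
  k <- as.integer(k)
  if (k < 1 || k %% 2 == 0) stop("k must be a positive odd integer")
  if (k > nrow(training)) stop("k exceeds the number of training records")
  structure(list(training = training, k = k, vote = vote),
            class = "knn_classifier")
}

#' @export
print.knn_classifier <- function(x, ...) {
  cat(sprintf("<knn_classifier> k = %d, %s vote, %d training records (%s)\n",
              x$k, x$vote, nrow(x$training),
              paste(names(table(x$training$class)), collapse = ", ")))
  invisible(x)
}

#' Predict behaviour classes for raw tri-axial records
#'
#' For each query the `k` training records at smallest Euclidean distance
#' vote. Distance ties at the k-th neighbour are resolved toward the
#' lowest-index training record; a vote deadlock (possible with three or more
#' classes despite odd k) is broken in favour of the tied class whose nearest
#' representative is closest, since nearer points hold more relevant
#' information.
#'
#' @param model a [knn_classifier()].
#' @param queries matrix/data.frame with columns x, y, z (or an
#'   [accel_trace()]).
#' @param return_scores also return per-class vote fractions (used for
#'   one-vs-rest AUC).
#' @return Character vector of predicted classes, or (with scores) a list
#'   `list(class = ..., scores = matrix)`.
#' @export
knn_predict <- function(model, queries, return_scores = FALSE) {
  Q <- as_query_matrix(queries)
  Tm <- as.matrix(model$training[, c("x", "y", "z")])
  tcl <- model$training$class
  classes <- sort(unique(tcl))
  m <- nrow(Q)
  if (m == 0) {
    out <- character(0)
    if (return_scores) {
      return(list(class = out,
                  scores = matrix(numeric(0), 0, length(classes),
                                  dimnames = list(NULL, classes))))
    }
    return(out)
  }
  k <- model$k
  t2 <- rowSums(Tm^2)
  cls_id <- match(tcl, classes)
  nc <- length(classes)
  pred <- character(m)
  scores <- if (return_scores) matrix(0, m, nc, dimnames = list(NULL, classes))
  chunk <- max(1L, floor(2e6 / nrow(Tm)))
  for (lo in seq(1L, m, by = chunk)) {
    hi <- min(lo + chunk - 1L, m)
    Qc <- Q[lo:hi, , drop = FALSE]
    mc <- nrow(Qc)
    d2 <- sweep(-2 * Qc %*% t(Tm), 2, t2, "+") + rowSums(Qc^2)
    rows <- seq_len(mc)
    # k smallest per row by iterated max.col; ties -> lowest training index
    nn_cls <- matrix(0L, mc, k)
    nn_d2 <- matrix(0, mc, k)
    for (j in seq_len(k)) {
      jmin <- max.col(-d2, ties.method = "first")
      nn_cls[, j] <- cls_id[jmin]
      nn_d2[, j] <- d2[cbind(rows, jmin)]
      d2[cbind(rows, jmin)] <- Inf
    }
    res <- vote_chunk(nn_cls, nn_d2, model$vote, nc)
    pred[lo:hi] <- classes[res$winner]
    if (return_scores) scores[lo:hi, ] <- res$score
  }
  if (return_scores) list(class = pred, scores = scores) else pred
}

# Vectorised voting over a chunk. nn_cls/nn_d2: m x k class ids and squared
# distances in neighbour order. A vote deadlock (tied top score) is broken in
# favour of the tied class whose nearest representative comes first.
vote_chunk <- function(nn_cls, nn_d2, vote, nc) {
  m <- nrow(nn_cls); k <- ncol(nn_cls)
  rows <- seq_len(m)
  if (vote == "distance_weighted") {
    w <- 1 / sqrt(pmax(nn_d2, 0))
    w[!is.finite(w)] <- 0              # exact matches handled below
    sc <- vapply(seq_len(nc),
                 function(cl) rowSums(w * (nn_cls == cl)), numeric(m))
    sc <- matrix(sc, m, nc)
    tot <- rowSums(sc)
    sc[tot > 0, ] <- sc[tot > 0, , drop = FALSE] / tot[tot > 0]
  } else {
    sc <- vapply(seq_len(nc),
                 function(cl) rowSums(nn_cls == cl) / k, numeric(m))
    sc <- matrix(sc, m, nc)
  }
  # first neighbour-order position of each class (large if absent)
  first_pos <- matrix(k + 1, m, nc)
  for (cl in seq_len(nc)) {
    eqc <- nn_cls == cl
    val <- eqc * rep((k + 1) - seq_len(k), each = m)   # earlier -> larger
    pos <- max.col(val, ties.method = "first")
    has <- val[cbind(rows, pos)] > 0
    first_pos[has, cl] <- pos[has]
  }
  top <- do.call(pmax, as.data.frame(sc))
  key <- first_pos
  key[sc < top - 1e-12] <- k + 2       # non-leaders never win
  winner <- max.col(-key, ties.method = "first")
  if (vote == "distance_weighted") {
    exact <- which(nn_d2[, 1] <= 0)
    if (length(exact)) {               # a distance-0 neighbour wins outright
      winner[exact] <- nn_cls[exact, 1]
      sc[exact, ] <- 0
      sc[cbind(exact, winner[exact])] <- 1
    }
  }
  list(winner = winner, score = sc)
}

as_query_matrix <- function(queries) {
  if (inherits(queries, "accel_trace")) {
    return(cbind(x = queries$x, y = queries$y, z = queries$z))
  }
  q <- as.matrix(as.data.frame(queries)[, c("x", "y", "z")])
  storage.mode(q) <- "double"
  q
}

#' Grid-search k by stratified cross-validation
#'
#' Builds the training set with the stated design, deals each class
#' round-robin into `folds` stratified folds, and evaluates every odd k in
#' `k_grid` by mean held-out fold accuracy. Ties are broken toward the
#' smallest k because nearer points hold more relevant information.
#'
#' @param trace,labels annotated trace.
#' @param k_grid candidate k values (default odd 1..21).
#' @param folds number of CV folds (default 5).
#' @param seed RNG seed (training-set sampling and fold shuffling).
#' @param n_scent,n_other training design, see [build_training_set()].
#' @param vote vote scheme passed to [knn_classifier()].
#' @return List with `k_best`, `cv_table` (data.frame k / mean_accuracy), and
#'   `training` (the sampled training set).
#' @export
tune_k <- function(trace, labels, k_grid = seq(1L, 21L, by = 2L), folds = 5L,
                   seed = 1L, n_scent = 50, n_other = 500,
                   vote = "majority") {
  training <- build_training_set(trace, labels, n_scent, n_other, seed)
  counts <- table(training$class)
  if (folds > min(counts)) {
    stop(sprintf("folds = %d exceeds the smallest class count (%d)",
                 folds, min(counts)))
  }
  fold_id <- integer(nrow(training))
  with_sim_seed(seed + 13L, {
    for (cl in names(counts)) {
      rows <- sample(which(training$class == cl))
      fold_id[rows] <- rep_len(seq_len(folds), length(rows))
    }
  })
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid %% 2 == 0)) stop("k_grid must contain odd values only")
  acc <- matrix(NA_real_, length(k_grid), folds)
  for (f in seq_len(folds)) {
    tr <- training[fold_id != f, , drop = FALSE]
    te <- training[fold_id == f, , drop = FALSE]
    for (ki in seq_along(k_grid)) {
      if (k_grid[ki] > nrow(tr)) next
      mdl <- knn_classifier(tr, k_grid[ki], vote)
      acc[ki, f] <- mean(knn_predict(mdl, te) == te$class)
    }
  }
  mean_acc <- rowMeans(acc)
  k_best <- k_grid[which.max(mean_acc)]   # which.max -> first max -> smallest k
  list(k_best = k_best,
       cv_table = data.frame(k = k_grid, mean_accuracy = mean_acc),
       training = training)
}

#' Cross-individual surrogate transfer matrix
#'
#' Trains a classifier on each individual and evaluates it on every
#' individual's testing set, emulating the use of captive surrogates for
#' model training. Entry (i, j) is the metrics report for the model trained
#' on individual i applied to individual j's testing set; the diagonal is
#' self-evaluation.
#'
#' @param datasets list of `list(trace = , labels = )` per individual, all
#'   sharing a class vocabulary.
#' @param k neighbour count; `NULL` tunes k per training individual via
#'   [tune_k()].
#' @param n_scent,n_other,n_other_test sampling design.
#' @param seed RNG seed.
#' @param vote vote scheme.
#' @return List with `reports` (n x n list-matrix of [evaluate()] reports)
#'   and `accuracy` (n x n numeric matrix).
#' @export
cross_individual_matrix <- function(datasets, k = NULL, n_scent = 50,
                                    n_other = 500, n_other_test = 3000,
                                    seed = 1L, vote = "majority") {
  n <- length(datasets)
  if (n < 2) stop("need at least 2 datasets")
  vocab <- lapply(datasets, function(d) {
    sort(unique(collapse_other(labels_at(d$labels, d$trace$t, default = "other"))))
  })
  for (i in seq_len(n)[-1]) {
    if (!identical(vocab[[i]], vocab[[1]])) {
      stop("class vocabulary mismatch between datasets 1 and ", i, ": ",
           paste(union(setdiff(vocab[[1]], vocab[[i]]),
                       setdiff(vocab[[i]], vocab[[1]])), collapse = ", "))
    }
  }
  models <- vector("list", n)
  tests <- vector("list", n)
  for (i in seq_len(n)) {
    d <- datasets[[i]]
    if (is.null(k)) {
      tk <- tune_k(d$trace, d$labels, seed = seed + i, n_scent = n_scent,
                   n_other = n_other, vote = vote)
      training <- tk$training
      ki <- tk$k_best
    } else {
      training <- build_training_set(d$trace, d$labels, n_scent, n_other,
                                     seed + i)
      ki <- k
    }
    models[[i]] <- knn_classifier(training, ki, vote)
    tests[[i]] <- build_testing_set(d$trace, d$labels, training,
                                    n_other_test, seed + 100L + i)
  }
  reports <- matrix(list(), n, n)
  accuracy <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      pr <- knn_predict(models[[i]], tests[[j]], return_scores = TRUE)
      rep_ij <- evaluate(tests[[j]]$class, pr$class, pr$scores)
      reports[[i, j]] <- rep_ij
      accuracy[i, j] <- rep_ij$accuracy
    }
  }
  list(reports = reports, accuracy = accuracy)
}
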