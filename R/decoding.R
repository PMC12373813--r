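## Pairwise identity decoding from instantaneous 3D position.
##
## Each classifier distinguishes one pair of individuals from single-sample
## (x, y, z) features using an RBF-kernel support vector machine with the
## regularization constant C = 1. Features are z-scored with statistics
## fitted on the training data only (the RBF kernel is scale-sensitive);
## the kernel bandwidth is gamma = 1/3 on standardized features. Three
## protocols mirror the study: random 90/10 within-session splits,
## train-on-one-session / test-on-others, and quadruple-to-triplet
## generalization. Significance comes from shuffled-label nulls with
## p = (1 + #null >= observed) / (1 + #shuffles).

#' Train a pairwise position classifier
#'
#' RBF-kernel SVM (cost 1) on 3D position samples of two individuals.
#' Features are standardized using training-set statistics. Degenerate
#' input where every sample of both classes is identical yields a flagged
#' majority classifier instead of an SVM fit.
#'
#' @param positionsA,positionsB n x 3 matrices of non-missing positions
#'   (at least 10 rows each).
#' @param labels length-2 character vector of class labels.
#' @param standardize z-score features on training statistics (default TRUE).
#' @param gamma RBF kernel bandwidth (default 1/3, i.e. 1/n_features on
#'   standardized data).
#' @param cost SVM box constraint (default 1).
#' @return An object of class \code{"pairClassifier"} with a
#'   \code{predict} method.
#' @export
trainPairClassifier <- function(positionsA, positionsB,
                                labels = c("A", "B"), standardize = TRUE,
                                gamma = 1 / 3, cost = 1) {
  positionsA <- as.matrix(positionsA); positionsB <- as.matrix(positionsB)
  if (nrow(positionsA) < 10L || nrow(positionsB) < 10L)
    stop("each class needs at least 10 samples (got ", nrow(positionsA),
         " and ", nrow(positionsB), ")", call. = FALSE)
  x <- rbind(positionsA, positionsB)
  y <- factor(rep(labels, c(nrow(positionsA), nrow(positionsB))),
              levels = labels)
  degenerate <- nrow(unique(x)) == 1L
  if (degenerate) {
    warning("degenerate training data (all samples identical); ",
            "falling back to a majority classifier", call. = FALSE)
    maj <- labels[which.max(tabulate(y, 2L))]
    obj <- list(type = "majority", majorityLabel = maj, labels = labels,
                degenerate = TRUE)
    class(obj) <- "pairClassifier"
    return(obj)
  }
  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
    scale[scale == 0] <- 1
  } else {
    center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  fit <- e1071::svm(xs, y, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  obj <- list(type = "svm", model = fit, center = center, scale = scale,
              labels = labels, degenerate = FALSE)
  class(obj) <- "pairClassifier"
  obj
}

#' @describeIn trainPairClassifier Predict class labels for new positions.
#' @param object a fitted \code{pairClassifier}.
#' @param newdata m x 3 matrix of positions.
#' @param ... ignored.
#' @export
predict.pairClassifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$type == "majority")
    return(factor(rep(object$majorityLabel, nrow(newdata)),
                  levels = object$labels))
  xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  predict(object$model, xs)
}

# per-individual non-missing samples, capped by uniform subsampling
decodingSamples <- function(t, individual, maxPerClass) {
  p <- positions(t, individual)
  p <- p[stats::complete.cases(p), , drop = FALSE]
  if (nrow(p) > maxPerClass)
    p <- p[sample.int(nrow(p), maxPerClass), , drop = FALSE]
  p
}

shuffleNullRefit <- function(x, y, nShuffles, testFrac = 0.1) {
  # refit on label-shuffled data, one random split per shuffle
  vapply(seq_len(nShuffles), function(s) {
    yp <- sample(y)
    test <- sample.int(nrow(x), max(1L, round(testFrac * nrow(x))))
    fit <- trainPairClassifier(x[-test, , drop = FALSE][yp[-test] == levels(y)[1L], , drop = FALSE],
                               x[-test, , drop = FALSE][yp[-test] == levels(y)[2L], , drop = FALSE],
                               labels = levels(y))
    mean(predict(fit, x[test, , drop = FALSE]) == yp[test])
  }, numeric(1))
}

#' Within-session cross-validated identity decoding
#'
#' Ten random 90/10 sample-level splits (non-contiguous in time): each fold
#' draws 10 percent of each individual's samples as the test set, trains the
#' pairwise SVM on the rest, and scores the held-out samples. The
#' shuffled-label null refits the classifier on label-permuted data (one
#' random split per shuffle).
#'
#' @param t a \linkS4class{TrajectorySet}.
#' @param pair length-2 character vector of individuals.
#' @param nFolds number of random splits (default 10).
#' @param nShuffles shuffled-label refits for the null (default 100).
#' @param maxPerClass per-class subsample cap for SVM tractability
#'   (default 5000).
#' @param nullMaxPerClass tighter per-class cap for the null refits
#'   (default 1500): label-shuffled data is inseparable, which makes SVM
#'   training cost grow steeply with n, while the null's location at chance
#'   level does not depend on n.
#' @param seed integer seed for splits, subsampling and shuffles.
#' @return A \linkS4class{DecodingResult} with protocol "within_cv".
#' @export
withinSessionCV <- function(t, pair, nFolds = 10L, nShuffles = 100L,
                            maxPerClass = 5000L, nullMaxPerClass = 1500L,
                            seed = 1L) {
  stopifnot(is(t, "TrajectorySet"), length(pair) == 2L)
  set.seed(seed)
  pa <- decodingSamples(t, pair[1L], maxPerClass)
  pb <- decodingSamples(t, pair[2L], maxPerClass)
  if (min(nrow(pa), nrow(pb)) < 100L)
    stop("too few samples for cross-validated decoding (need >= 100 ",
         "per individual)", call. = FALSE)
  acc <- vapply(seq_len(nFolds), function(f) {
    ta <- sample.int(nrow(pa), max(1L, round(0.1 * nrow(pa))))
    tb <- sample.int(nrow(pb), max(1L, round(0.1 * nrow(pb))))
    fit <- trainPairClassifier(pa[-ta, , drop = FALSE],
                               pb[-tb, , drop = FALSE], labels = pair)
    pred <- predict(fit, rbind(pa[ta, , drop = FALSE],
                               pb[tb, , drop = FALSE]))
    truth <- rep(pair, c(length(ta), length(tb)))
    mean(as.character(pred) == truth)
  }, numeric(1))
  nullAcc <- numeric(0)
  if (nShuffles > 0L) {
    na <- pa[sample.int(nrow(pa), min(nrow(pa), nullMaxPerClass)), ,
             drop = FALSE]
    nb <- pb[sample.int(nrow(pb), min(nrow(pb), nullMaxPerClass)), ,
             drop = FALSE]
    x <- rbind(na, nb)
    y <- factor(rep(pair, c(nrow(na), nrow(nb))), levels = pair)
    nullAcc <- shuffleNullRefit(x, y, nShuffles)
  }
  obs <- mean(acc)
  p <- if (length(nullAcc)) (1 + sum(nullAcc >= obs)) / (1 + length(nullAcc))
       else NA_real_
  new("DecodingResult", pair = pair, protocol = "within_cv",
      accuracies = acc, meanAccuracy = obs, nullAccuracies = nullAcc,
      pValue = p)
}

#' Cross-session identity decoding
#'
#' Trains the pairwise SVM on one entire session and scores every test
#' session separately; test sessions missing a pair member are skipped with
#' a warning. The null permutes the concatenated test labels against the
#' fixed predictions (no refit needed since the classifier is unchanged).
#'
#' @param train a \linkS4class{TrajectorySet} used for training.
#' @param tests list of \linkS4class{TrajectorySet} test sessions.
#' @param pair length-2 character vector of individuals.
#' @param nShuffles label permutations for the null (default 100).
#' @param maxPerClass per-class subsample cap (default 5000).
#' @param seed integer seed.
#' @param protocol result label (default "cross_session").
#' @return A \linkS4class{DecodingResult}; accuracies are named by test
#'   session.
#' @export
crossSessionDecode <- function(train, tests, pair, nShuffles = 100L,
                               maxPerClass = 5000L, seed = 1L,
                               protocol = "cross_session") {
  stopifnot(is(train, "TrajectorySet"), length(pair) == 2L)
  set.seed(seed)
  fit <- trainPairClassifier(decodingSamples(train, pair[1L], maxPerClass),
                             decodingSamples(train, pair[2L], maxPerClass),
                             labels = pair)
  acc <- numeric(0)
  allPred <- character(0); allTruth <- character(0)
  for (ts in tests) {
    if (!all(pair %in% roster(ts))) {
      warning("session '", sessionId(ts), "' skipped: pair member absent",
              call. = FALSE)
      next
    }
    xa <- decodingSamples(ts, pair[1L], maxPerClass)
    xb <- decodingSamples(ts, pair[2L], maxPerClass)
    pred <- as.character(predict(fit, rbind(xa, xb)))
    truth <- rep(pair, c(nrow(xa), nrow(xb)))
    acc <- c(acc, stats::setNames(mean(pred == truth), sessionId(ts)))
    allPred <- c(allPred, pred); allTruth <- c(allTruth, truth)
  }
  nullAcc <- numeric(0)
  if (length(allTruth) && nShuffles > 0L)
    nullAcc <- vapply(seq_len(nShuffles), function(s)
      mean(allPred == sample(allTruth)), numeric(1))
  obs <- if (length(acc)) mean(acc) else NA_real_
  p <- if (length(nullAcc) && !is.na(obs))
    (1 + sum(nullAcc >= obs)) / (1 + length(nullAcc)) else NA_real_
  new("DecodingResult", pair = pair, protocol = protocol,
      accuracies = acc, meanAccuracy = obs, nullAccuracies = nullAcc,
      pValue = p)
}

#' Cross-context identity decoding (quadruple to triplet)
#'
#' Trains on a quadruple session and tests on triplet sessions that still
#' contain both pair members; otherwise identical to
#' \code{\link{crossSessionDecode}}.
#'
#' @param trainQuadruple quadruple-context training session.
#' @param testTriplets list of triplet-context test sessions.
#' @inheritParams crossSessionDecode
#' @return A \linkS4class{DecodingResult} with protocol "cross_context".
#' @export
crossContextDecode <- function(trainQuadruple, testTriplets, pair,
                               nShuffles = 100L, maxPerClass = 5000L,
                               seed = 1L) {
  keep <- vapply(testTriplets, function(ts) all(pair %in% roster(ts)),
                 logical(1))
  crossSessionDecode(trainQuadruple, testTriplets[keep], pair,
                     nShuffles = nShuffles, maxPerClass = maxPerClass,
                     seed = seed, protocol = "cross_context")
}

#' Pairwise decoding accuracy matrix
#'
#' Runs within-session CV for every unordered pair of roster members of one
#' session and arranges mean accuracies in symmetric matrix form.
#'
#' @param t a \linkS4class{TrajectorySet}.
#' @param nFolds,nShuffles,maxPerClass,seed passed to
#'   \code{\link{withinSessionCV}} (the null defaults to 0 shuffles here;
#'   raise \code{nShuffles} for significance).
#' @return List with \code{matrix} (pairs x pairs mean accuracy, NA
#'   diagonal) and \code{results} (list of \linkS4class{DecodingResult}).
#' @export
decodingMatrix <- function(t, nFolds = 10L, nShuffles = 0L,
                           maxPerClass = 5000L, seed = 1L) {
  ids <- roster(t)
  m <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  results <- list()
  prs <- utils::combn(ids, 2L)
  for (c in seq_len(ncol(prs))) {
    pair <- prs[, c]
    res <- withinSessionCV(t, pair, nFolds = nFolds,
                           nShuffles = nShuffles,
                           maxPerClass = maxPerClass, seed = seed + c)
    m[pair[1L], pair[2L]] <- m[pair[2L], pair[1L]] <- meanAccuracy(res)
    results[[paste(pair, collapse = "-")]] <- res
  }
  list(matrix = m, results = results)
}
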