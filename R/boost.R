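# Multinomial gradient boosting on motif counts with per-feature relative
# influence.  The boosting loop, multinomial-deviance gradients, leaf updates
# and influence bookkeeping are implemented here; each boosting round fits a
# small regression tree with rpart.

#' Motif enrichment in a dynamics class
#'
#' Per motif, a one-sided Fisher test of motif presence (count >= 1) in
#' target-class peaks versus background-class peaks, BH-adjusted across
#' motifs.  Odds ratios use the Haldane correction (+0.5 per cell) so they
#' stay finite for degenerate tables.
#'
#' @param counts peaks x motifs count matrix.
#' @param class_labels dynamics class per peak (row).
#' @param target_class,background_class the two compared classes.
#' @return data frame per motif: `motif`, `n_target`, `n_background`,
#'   `odds_ratio`, `p`, `q`, sorted by q then p.
#' @export
motif_enrichment <- function(counts, class_labels, target_class,
                             background_class) {
  ti <- class_labels == target_class
  bi <- class_labels == background_class
  if (!any(ti)) stop("no peaks in target class ", target_class)
  if (!any(bi)) stop("no peaks in background class ", background_class)
  pres <- counts >= 1
  rows <- lapply(colnames(counts), function(m) {
    a <- sum(pres[ti, m]); b <- sum(ti) - a
    c_ <- sum(pres[bi, m]); d <- sum(bi) - c_
    data.frame(motif = m, n_target = a, n_background = c_,
               odds_ratio = ((a + 0.5) * (d + 0.5)) /
                            ((b + 0.5) * (c_ + 0.5)),
               p = fisher_one_sided(matrix(c(a, c_, b, d), 2)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$q, out$p, -out$odds_ratio), ]
}

# deviance (SS) reduction per feature of one anova rpart tree
tree_influence <- function(tree, features) {
  fr <- tree$frame
  infl <- setNames(numeric(length(features)), features)
  if (nrow(fr) < 3) return(infl)
  nodes <- as.integer(rownames(fr))
  for (r in which(fr$var != "<leaf>")) {
    n <- nodes[r]
    l <- match(2L * n, nodes); rg <- match(2L * n + 1L, nodes)
    if (is.na(l) || is.na(rg)) next
    red <- fr$dev[r] - fr$dev[l] - fr$dev[rg]
    v <- as.character(fr$var[r])
    infl[v] <- infl[v] + max(red, 0)
  }
  infl
}

#' Fit a multinomial gradient-boosting model on motif counts
#'
#' One-vs-rest multinomial deviance boosting: at every iteration, for every
#' class, a depth-limited regression tree is fit to the gradient
#' (`y_k - p_k`) and its leaves updated with the standard multinomial gamma
#' step.  Peaks are split into a stratified training set
#' (`train_fraction`) and a held-out test set used for evaluation.
#'
#' @param counts peaks x motifs count matrix.
#' @param labels dynamics class per peak.
#' @param train_fraction fraction of peaks used for training (stratified by
#'   class).
#' @param seed RNG seed for the split.
#' @param n_trees boosting iterations.
#' @param depth maximal tree depth.
#' @param learning_rate shrinkage per iteration.
#' @param min_split minimal node size rpart is allowed to split.
#' @return an object of class `boost_model` with held-out predictions in
#'   `$test` and per-feature influence in `$influence_raw`.
#' @export
fit_boost <- function(counts, labels, train_fraction = 0.7, seed = 1,
                      n_trees = 200, depth = 3, learning_rate = 0.05,
                      min_split = 20) {
  stopifnot(nrow(counts) == length(labels))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 3) stop("need >= 3 classes present")
  if (nrow(counts) < 50) stop("need >= 50 peaks")
  set.seed(seed)
  train <- unlist(lapply(classes, function(cl) {
    i <- which(labels == cl)
    sample(i, max(1, round(train_fraction * length(i))))
  }))
  train <- sort(train)
  test <- setdiff(seq_len(nrow(counts)), train)
  if (!all(classes %in% labels[train]))
    stop("a class is absent from the training split")
  feat <- colnames(counts)
  safe <- make.names(feat, unique = TRUE)
  df_all <- as.data.frame(counts)
  names(df_all) <- safe
  dtrain <- df_all[train, , drop = FALSE]
  n <- length(train); K <- length(classes)
  Y <- outer(labels[train], classes, `==`) * 1
  prior <- colMeans(Y)
  F0 <- log(pmax(prior, 1e-6))
  Fm <- matrix(F0, n, K, byrow = TRUE)
  trees <- vector("list", n_trees)
  infl <- setNames(numeric(length(safe)), safe)
  ctrl <- rpart::rpart.control(maxdepth = depth, cp = 0,
                               minsplit = min_split, minbucket = 5,
                               maxcompete = 0, maxsurrogate = 0, xval = 0)
  for (m in seq_len(n_trees)) {
    eF <- exp(Fm - apply(Fm, 1, max))
    P <- eF / rowSums(eF)
    round_trees <- vector("list", K)
    for (k in seq_len(K)) {
      r <- Y[, k] - P[, k]
      d <- dtrain
      d$.r <- r
      tr <- rpart::rpart(.r ~ ., data = d, method = "anova",
                         control = ctrl)
      infl <- infl + tree_influence(tr, safe)
      # replace leaf values by the multinomial gamma step
      leaf_of <- tr$where
      gam <- vapply(unique(leaf_of), function(lf) {
        ri <- r[leaf_of == lf]
        den <- sum(abs(ri) * (1 - abs(ri)))
        if (den < 1e-12) 0 else (K - 1) / K * sum(ri) / den
      }, numeric(1))
      names(gam) <- as.character(unique(leaf_of))
      tr$frame$yval <- ifelse(tr$frame$var == "<leaf>",
                              unname(gam[as.character(seq_len(nrow(tr$frame)))]),
                              0)
      tr$frame$yval[is.na(tr$frame$yval)] <- 0
      Fm[, k] <- Fm[, k] + learning_rate * tr$frame$yval[leaf_of]
      tr$where <- NULL; tr$y <- NULL; tr$call <- NULL
      round_trees[[k]] <- tr
    }
    trees[[m]] <- round_trees
  }
  model <- structure(list(classes = classes, F0 = F0, trees = trees,
                          learning_rate = learning_rate, n_trees = n_trees,
                          features = feat, safe_features = safe,
                          influence_raw = infl, train = train, test = test,
                          seed = seed),
                     class = "boost_model")
  model$test_predicted <- predict_boost(model, counts[test, , drop = FALSE])
  model$test_labels <- labels[test]
  model$balanced_accuracy <- balanced_accuracy(model$test_predicted,
                                               model$test_labels)
  model
}

#' @export
print.boost_model <- function(x, ...) {
  cat("boost_model:", x$n_trees, "rounds x", length(x$classes),
      "classes; held-out balanced accuracy",
      sprintf("%.3f", x$balanced_accuracy), "\n")
  invisible(x)
}

#' Predict dynamics classes with a boosting model
#'
#' @param model a [fit_boost()] result.
#' @param counts peaks x motifs count matrix (same features).
#' @param type `"class"` or `"prob"`.
#' @return class labels, or a probability matrix.
#' @export
predict_boost <- function(model, counts, type = c("class", "prob")) {
  type <- match.arg(type)
  df <- as.data.frame(counts)
  names(df) <- model$safe_features
  K <- length(model$classes)
  Fm <- matrix(model$F0, nrow(df), K, byrow = TRUE)
  for (round in model$trees)
    for (k in seq_len(K))
      Fm[, k] <- Fm[, k] +
        model$learning_rate * predict(round[[k]], newdata = df)
  eF <- exp(Fm - apply(Fm, 1, max))
  P <- eF / rowSums(eF)
  colnames(P) <- model$classes
  if (type == "prob") return(P)
  model$classes[max.col(P, ties.method = "first")]
}

#' Balanced accuracy
#'
#' Unweighted mean of per-class recalls; chance level is 1/K for K balanced
#' classes.
#'
#' @param predicted,truth label vectors of equal length.
#' @return a number in `[0, 1]`.
#' @export
balanced_accuracy <- function(predicted, truth) {
  if (!length(truth) || length(predicted) != length(truth))
    stop("predicted and truth labels must be non-empty and equal length")
  classes <- unique(truth)
  mean(vapply(classes, function(cl)
    mean(predicted[truth == cl] == cl), numeric(1)))
}

#' Relative influence of motifs in a boosting model
#'
#' Per feature, the summed squared-error reduction over all splits using
#' that feature across all trees, normalised to total 100, descending.
#'
#' @param model a [fit_boost()] result.
#' @return data frame: `motif`, `influence`.
#' @export
relative_influence <- function(model) {
  infl <- model$influence_raw
  if (sum(infl) <= 0) stop("model has no splits; influence undefined")
  out <- data.frame(motif = model$features,
                    influence = 100 * unname(infl) / sum(infl),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$influence), ]
  rownames(out) <- NULL
  out
}
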