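.classifier_names <- c("svm", "rf", "nb", "knn", "dt")

.default_params <- function() {
  list(cost = 1, gamma = NULL,      # svm: RBF kernel, gamma defaults to 1/d
       ntree = 100,                 # rf
       k = 5,                       # knn (odd: no vote ties in two classes)
       cp = 0, maxdepth = 30)       # dt: gini, effectively unlimited depth
}

#' Train one classifier and predict on held-out samples
#'
#' Supports the five classifiers \code{svm} (RBF support vector machine),
#' \code{rf} (random forest), \code{nb} (Gaussian naive Bayes), \code{knn}
#' (k-nearest neighbors) and \code{dt} (decision tree). Features are
#' standardized with training-set statistics only. Each call returns hard
#' labels and a continuous score per test sample (probability of the
#' positive class, or the decision margin for \code{svm}); the random seed
#' makes stochastic learners deterministic.
#'
#' @param X_train,X_test numeric matrices (rows = samples).
#' @param y_train vector of class labels coded 0/1 (1 = positive = ILFS).
#' @param classifier one of \code{"svm", "rf", "nb", "knn", "dt"}.
#' @param seed integer seed set before fitting.
#' @param params named list overriding the default hyperparameters
#'   (\code{cost}, \code{gamma}, \code{ntree}, \code{k}, \code{cp},
#'   \code{maxdepth}).
#' @return List with \code{labels} (integer 0/1) and \code{scores}
#'   (numeric, larger = more ILFS-like).
#' @export
fit_predict <- function(X_train, y_train, X_test, classifier = "rf",
                        seed = 1L, params = list()) {
  if (!classifier %in% .classifier_names)
    stop("unknown classifier '", classifier, "'; valid names: ",
         paste(.classifier_names, collapse = ", "))
  if (length(unique(y_train)) < 2)
    stop("y_train must contain both classes")
  p <- utils::modifyList(.default_params(), params)
  X_train <- as.matrix(X_train)
  X_test <- matrix(as.matrix(X_test), ncol = ncol(X_train))
  ctr <- colMeans(X_train)
  scl <- apply(X_train, 2, sd)
  scl[scl == 0] <- 1
  X_train <- sweep(sweep(X_train, 2, ctr), 2, scl, "/")
  X_test <- sweep(sweep(X_test, 2, ctr), 2, scl, "/")
  colnames(X_train) <- colnames(X_test) <- paste0("f", seq_len(ncol(X_train)))
  yf <- factor(y_train, levels = c(0, 1))
  set.seed(seed)
  if (classifier == "svm") {
    gamma <- if (is.null(p$gamma)) 1 / ncol(X_train) else p$gamma
    fit <- e1071::svm(X_train, yf, kernel = "radial", cost = p$cost,
                      gamma = gamma, scale = FALSE)
    pred <- predict(fit, X_test, decision.values = TRUE)
    dv <- drop(attr(pred, "decision.values"))
    # orient the margin so that larger means class "1"
    if (grepl("^0/1$", colnames(attr(pred, "decision.values"))[1]))
      dv <- -dv
    labels <- as.integer(as.character(pred))
    scores <- dv
  } else if (classifier == "rf") {
    fit <- randomForest::randomForest(X_train, yf, ntree = p$ntree)
    prob <- predict(fit, X_test, type = "prob")[, "1"]
    labels <- as.integer(prob > 0.5)
    scores <- prob
  } else if (classifier == "nb") {
    fit <- e1071::naiveBayes(X_train, yf)
    prob <- predict(fit, X_test, type = "raw")[, "1"]
    labels <- as.integer(prob > 0.5)
    scores <- prob
  } else if (classifier == "knn") {
    pred <- class::knn(X_train, X_test, yf, k = p$k, prob = TRUE)
    win <- attr(pred, "prob")
    scores <- ifelse(pred == "1", win, 1 - win)
    labels <- as.integer(as.character(pred))
  } else { # dt
    df_tr <- data.frame(y = yf, X_train)
    fit <- rpart::rpart(y ~ ., df_tr, method = "class",
                        control = rpart::rpart.control(
                          cp = p$cp, maxdepth = p$maxdepth))
    prob <- predict(fit, data.frame(X_test), type = "prob")[, "1"]
    labels <- as.integer(prob > 0.5)
    scores <- prob
  }
  list(labels = labels, scores = as.numeric(scores))
}

#' Stratified cross-validation folds
#'
#' Deals the indices of each class round-robin into k folds after a seeded
#' shuffle, so every fold holds both classes whenever the class sizes allow
#' it. If the smaller class has fewer members than \code{k}, the fold count
#' is reduced to that size.
#'
#' @param y class labels.
#' @param k requested number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold assignments (1..k), same length as
#'   \code{y}.
#' @export
make_folds <- function(y, k = 10, seed = 1L) {
  k <- min(k, min(table(y)))
  if (k < 2) stop("need at least 2 members in each class for CV")
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  folds
}
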