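# Detection pipeline: fused feature vectors, SMOTE balancing, truncated-SVD
# reduction, feature normalization, classifier training, evaluation metrics,
# stratified cross-validation and the configuration grid.

REDUCE_FRACTIONS <- c(0.10, 0.50, 0.75, 1.00)
NORMALIZATIONS <- c("MinMax", "Standard", "Robust", "Unscaled")
CLASSIFIERS <- c("SVM", "RF", "LR")
CLASS_LEVELS <- c("healthy", "dysphonic")

#' Pipeline configuration
#'
#' Fixes one instance of the detection framework: the cepstral technique
#' set (possibly empty), the mapping set, whether the noncepstral block is
#' used, the balancing strategy, the SVD reduction fraction, the
#' normalization, the classifier and the seed controlling all randomness.
#'
#' @param techniques A [technique_set()] / alias / character vector, or
#'   `NULL` for no cepstral features (then `use_noncepstral` must be TRUE).
#' @param mappings A [mapping_set()] / alias / character vector.
#' @param use_noncepstral Include the 28-coordinate noncepstral block?
#' @param balance `"SMOTE"` or `"none"`.
#' @param reduce_fraction One of 0.10, 0.50, 0.75, 1.00.
#' @param normalization One of `"MinMax"`, `"Standard"`, `"Robust"`,
#'   `"Unscaled"`.
#' @param classifier One of `"SVM"` (Gaussian kernel, C = 1, kernel width
#'   from the median pairwise-distance heuristic), `"RF"` (100 trees),
#'   `"LR"` (L2-regularized logistic regression). All are fitted with
#'   class weights inversely proportional to class frequencies.
#' @param seed Integer seed for SMOTE, fold shuffling and the classifier.
#' @param nceps Cepstral coefficients per technique (default 20).
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(techniques = "MFCC", mappings = "M8",
                            use_noncepstral = TRUE, balance = "SMOTE",
                            reduce_fraction = 0.5,
                            normalization = "Standard", classifier = "SVM",
                            seed = 1L, nceps = 20) {
  techniques <- if (is.null(techniques) || length(techniques) == 0L) NULL
                else technique_set(techniques)
  mappings <- mapping_set(mappings)
  if (is.null(techniques) && !use_noncepstral)
    stop("a representation must exist: enable noncepstral features or ",
         "supply cepstral techniques")
  balance <- match.arg(balance, c("SMOTE", "none"))
  if (!any(abs(reduce_fraction - REDUCE_FRACTIONS) < 1e-9))
    stop("reduce_fraction must be one of ",
         paste(REDUCE_FRACTIONS, collapse = ", "))
  normalization <- match.arg(normalization, NORMALIZATIONS)
  classifier <- match.arg(classifier, CLASSIFIERS)
  structure(list(techniques = techniques, mappings = mappings,
                 use_noncepstral = use_noncepstral, balance = balance,
                 reduce_fraction = reduce_fraction,
                 normalization = normalization, classifier = classifier,
                 seed = as.integer(seed), nceps = nceps),
            class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat(sprintf(
    "<detector_config> P={%s} M={%s}%s | %s | SVD %.0f%% | %s | %s | seed %d\n",
    paste(x$techniques %||% "", collapse = ","),
    paste(x$mappings, collapse = ","),
    if (x$use_noncepstral) " + nonceps" else "",
    x$balance, 100 * x$reduce_fraction, x$normalization, x$classifier,
    x$seed))
  invisible(x)
}

# ---- feature construction ---------------------------------------------------

#' Build the fused feature vector of one signal
#'
#' Concatenation of the fused multiprojected cepstral vector (when
#' techniques are configured) and the noncepstral vector (when enabled).
#'
#' @param signal A [voice_signal()].
#' @param config A [detector_config()].
#' @param aux Fitted [fit_acoustic_stats()] statistics (needed for the
#'   corpus-dependent noncepstral coordinates; `NULL` gives zeros there).
#' @return Named numeric vector.
#' @export
build_feature_vector <- function(signal, config, aux = NULL) {
  parts <- list()
  if (!is.null(config$techniques))
    parts$cep <- fuse_cepstral(signal, config$techniques, config$mappings,
                               nceps = config$nceps)
  if (config$use_noncepstral)
    parts$noncep <- noncepstral_vector(signal, aux)
  unlist(parts, use.names = TRUE)
}

#' Precompute signal-level raw features for a corpus
#'
#' Computes, per signal, the multiprojection blocks of every requested
#' cepstral technique and the raw acoustic measures. These quantities
#' depend only on the signal (never on a training partition), so the
#' result can be passed to [dysphonia_detector()], [kfold_cv()] and
#' [run_grid()] to avoid recomputing them across folds and grid rows.
#'
#' @param corpus A [labeled_corpus()].
#' @param techniques Character vector of technique names to precompute
#'   (or `NULL` for none).
#' @param nceps Cepstral coefficients per technique.
#' @param use_noncepstral Also compute the raw acoustic measures?
#' @param verbose Report progress?
#' @return An opaque feature cache (list).
#' @export
corpus_features <- function(corpus, techniques = "MFCC", nceps = 20,
                            use_noncepstral = TRUE, verbose = FALSE) {
  .corpus_features(corpus, techniques, nceps, use_noncepstral, verbose)
}

# Signal-level raw features for a whole corpus. These depend only on the
# signal (never on the training partition), so they are computed once and
# reused across folds and grid rows. Per technique and mapping we store the
# 3*nceps projection block of every signal.
.corpus_features <- function(corpus, techniques, nceps = 20,
                             use_noncepstral = TRUE, verbose = FALSE) {
  n <- length(corpus$signals)
  cep <- list()
  if (length(techniques) > 0L) {
    for (tech in techniques) cep[[tech]] <- list()
    for (i in seq_len(n)) {
      sig <- corpus$signals[[i]]
      for (tech in techniques) {
        cc <- extract_cc(sig, tech, nceps = nceps)
        for (m in MAPPING_NAMES) {
          block <- multiproject(cc, m)
          if (is.null(cep[[tech]][[m]]))
            cep[[tech]][[m]] <- matrix(0, n, length(block))
          cep[[tech]][[m]][i, ] <- block
        }
      }
      if (verbose && i %% 25L == 0L)
        message(sprintf("  cepstral features: %d/%d signals", i, n))
    }
  }
  measures <- NULL
  if (use_noncepstral) {
    measures <- t(vapply(corpus$signals, acoustic_measures,
                         numeric(length(NONCEPSTRAL_LAYOUT))))
  }
  list(cep = cep, measures = measures, labels = corpus_labels(corpus))
}

# Assemble the design matrix rows `idx` from cached raw features and fitted
# auxiliary statistics, in the canonical layout (techniques, then mappings,
# then C/D1/D2; noncepstral block last).
.assemble_features <- function(feats, config, aux, idx) {
  parts <- list()
  for (tech in config$techniques) {
    for (m in config$mappings) {
      parts[[paste(tech, m, sep = ".")]] <-
        feats$cep[[tech]][[m]][idx, , drop = FALSE]
    }
  }
  if (config$use_noncepstral) {
    nc <- t(vapply(idx, function(i)
      .assemble_noncepstral(feats$measures[i, ], aux),
      numeric(length(NONCEPSTRAL_LAYOUT))))
    parts$noncep <- nc
  }
  do.call(cbind, parts)
}

# ---- balancing, reduction, normalization -----------------------------------

#' SMOTE oversampling of the minority class
#'
#' Oversamples the minority class to the majority count: each synthetic
#' point is `x + u * (x_nn - x)` with `x` a random minority point, `x_nn`
#' one of its k nearest minority neighbours (Euclidean) and `u` uniform on
#' `[0, 1]`. Originals are retained; deterministic given the seed. Already
#' balanced input is returned unchanged; if fewer than `k + 1` minority
#' samples exist, `k` is lowered.
#'
#' @param x Feature matrix (samples x features).
#' @param y Label vector (two classes).
#' @param k Number of neighbours (default 5).
#' @param seed Integer seed.
#' @return List with balanced `x` and `y`.
#' @export
smote_balance <- function(x, y, k = 5, seed = 1L) {
  x <- as.matrix(x)
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) < 2L) stop("SMOTE needs two classes")
  if (tab[1] == tab[2]) return(list(x = x, y = y))
  minority <- names(tab)[which.min(tab)]
  need <- as.integer(max(tab) - min(tab))
  mi <- which(y == minority)
  Xm <- x[mi, , drop = FALSE]
  k_eff <- min(k, nrow(Xm) - 1L)
  if (k_eff < 1L) stop("SMOTE needs at least 2 minority samples")
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- apply(d, 1L, function(row) order(row)[seq_len(k_eff)])
  nn <- matrix(nn, nrow = k_eff)
  synth <- with_seed(seed, {
    base_i <- sample.int(nrow(Xm), need, replace = TRUE)
    nn_j <- vapply(base_i, function(b) nn[sample.int(k_eff, 1L), b],
                   integer(1))
    u <- stats::runif(need)
    Xm[base_i, , drop = FALSE] +
      u * (Xm[nn_j, , drop = FALSE] - Xm[base_i, , drop = FALSE])
  })
  list(x = rbind(x, synth), y = c(y, rep(minority, need)))
}

#' Fit a truncated-SVD reducer
#'
#' Truncated singular value decomposition of the *uncentered* training
#' matrix; the leading `m = round(fraction * d)` right singular vectors
#' (rounded half away from zero, at least 1) form the projection basis.
#' `fraction = 1` keeps a full orthonormal basis, so projection is an
#' isometry.
#'
#' @param x Training feature matrix (samples x features).
#' @param fraction Fraction of coordinates to keep, in (0, 1].
#' @return An object of class `svd_reducer` with orthonormal `basis`
#'   (d x m), `fraction`, `input_dim`, `output_dim`.
#' @export
fit_reducer <- function(x, fraction) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2L, ncol(x) >= 1L, fraction > 0, fraction <= 1)
  d <- ncol(x)
  m <- max(1L, as.integer(floor(fraction * d + 0.5)))  # half away from zero
  m <- min(m, d)
  V <- svd(x, nu = 0, nv = d)$v
  structure(list(basis = V[, seq_len(m), drop = FALSE], fraction = fraction,
                 input_dim = d, output_dim = m),
            class = "svd_reducer")
}

#' Apply a fitted reducer
#' @param reducer An [fit_reducer()] object.
#' @param x Matrix (samples x features) or a single feature vector.
#' @return Reduced matrix / vector.
#' @export
apply_reducer <- function(reducer, x) {
  if (is.null(dim(x))) drop(matrix(x, 1L) %*% reducer$basis)
  else as.matrix(x) %*% reducer$basis
}

#' Fit a per-coordinate normalizer
#'
#' `MinMax` maps the training minimum/maximum of each coordinate to 0/1;
#' `Standard` centres by the mean and scales by the population standard
#' deviation; `Robust` centres by the median and scales by the
#' interquartile range (linear-interpolation quantiles); `Unscaled` is the
#' identity. Zero-range coordinates map to 0.
#'
#' @param x Training feature matrix (samples x features).
#' @param strategy One of `"MinMax"`, `"Standard"`, `"Robust"`,
#'   `"Unscaled"`.
#' @return An object of class `feature_normalizer`.
#' @export
fit_normalizer <- function(x, strategy) {
  x <- as.matrix(x)
  strategy <- match.arg(strategy, NORMALIZATIONS)
  d <- ncol(x)
  prm <- switch(strategy,
    MinMax = {
      mn <- apply(x, 2L, min); mx <- apply(x, 2L, max)
      list(center = mn, scale = mx - mn)
    },
    Standard = {
      mu <- colMeans(x)
      sdv <- sqrt(colMeans(sweep(x, 2L, mu)^2))  # population sd
      list(center = mu, scale = sdv)
    },
    Robust = {
      med <- apply(x, 2L, stats::median)
      iqr <- apply(x, 2L, function(col)
        diff(stats::quantile(col, c(0.25, 0.75), names = FALSE)))
      list(center = med, scale = iqr)
    },
    Unscaled = list(center = rep(0, d), scale = rep(1, d))
  )
  # zero-scale coordinates map to 0
  prm$scale[prm$scale < 1e-12] <- Inf
  structure(list(strategy = strategy, center = prm$center,
                 scale = prm$scale), class = "feature_normalizer")
}

#' Apply a fitted normalizer
#' @param normalizer A [fit_normalizer()] object.
#' @param x Matrix (samples x features) or a single feature vector.
#' @return Normalized matrix / vector.
#' @export
apply_normalizer <- function(normalizer, x) {
  if (is.null(dim(x)))
    (x - normalizer$center) / normalizer$scale
  else
    sweep(sweep(as.matrix(x), 2L, normalizer$center), 2L,
          normalizer$scale, "/")
}

# ---- classifiers ------------------------------------------------------------

.class_weights <- function(y) {
  tab <- table(factor(y, levels = CLASS_LEVELS))
  w <- sum(tab) / (2 * tab)
  stats::setNames(as.numeric(w), names(tab))
}

.fit_classifier <- function(x, y, type, seed) {
  y <- factor(y, levels = CLASS_LEVELS)
  w <- .class_weights(y)
  if (type == "SVM") {
    # RBF width from the median pairwise squared distance of the training
    # set (the standard median heuristic); robust when many coordinates
    # carry no class signal
    d2 <- stats::median(stats::dist(x)^2)
    gamma <- if (is.finite(d2) && d2 > 0) 1 / (2 * d2) else 1 / ncol(x)
    fit <- e1071::svm(x = x, y = y, kernel = "radial", cost = 1,
                      gamma = gamma, class.weights = w, scale = FALSE)
  } else if (type == "RF") {
    fit <- with_seed(seed,
      randomForest::randomForest(x = x, y = y, ntree = 100,
                                 classwt = w))
  } else {
    obs_w <- as.numeric(w[as.character(y)])
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = 1 / nrow(x), weights = obs_w)
  }
  list(type = type, fit = fit)
}

.predict_classifier <- function(clf, x) {
  x <- as.matrix(x)
  if (clf$type == "LR") {
    p <- stats::predict(clf$fit, newx = x, type = "class")
    factor(as.character(p), levels = CLASS_LEVELS)
  } else {
    stats::predict(clf$fit, x)
  }
}

# ---- model fitting ----------------------------------------------------------

# Fit reducer/normalizer/classifier (and the noncepstral auxiliaries) on the
# training rows of cached raw features.
.fit_on_features <- function(feats, config, train_idx) {
  y <- feats$labels[train_idx]
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  aux <- if (config$use_noncepstral)
    fit_acoustic_stats(feats$measures[train_idx, , drop = FALSE]) else NULL
  X <- .assemble_features(feats, config, aux, train_idx)
  if (config$balance == "SMOTE") {
    bal <- smote_balance(X, y, k = 5, seed = child_seed(config$seed, 1L))
    X <- bal$x; y <- bal$y
  }
  reducer <- fit_reducer(X, config$reduce_fraction)
  Xr <- apply_reducer(reducer, X)
  normalizer <- fit_normalizer(Xr, config$normalization)
  Xn <- apply_normalizer(normalizer, Xr)
  clf <- .fit_classifier(Xn, y, config$classifier,
                         seed = child_seed(config$seed, 2L))
  list(aux = aux, reducer = reducer, normalizer = normalizer,
       classifier = clf, input_dim = reducer$input_dim,
       output_dim = reducer$output_dim)
}

.predict_on_features <- function(model, feats, idx) {
  X <- .assemble_features(feats, model$config, model$aux, idx)
  Xn <- apply_normalizer(model$normalizer, apply_reducer(model$reducer, X))
  as.character(.predict_classifier(model$classifier, Xn))
}

#' Fit a dysphonia detector
#'
#' The main fitting function of the package. Builds the fused feature
#' vector of every training signal (fitting the noncepstral auxiliaries on
#' the training corpus only), optionally balances the classes with SMOTE,
#' fits a truncated-SVD reducer and a feature normalizer on the balanced
#' set, and trains the configured classifier with class weights inversely
#' proportional to class frequencies. Deterministic given `config$seed`.
#'
#' @param corpus A [labeled_corpus()] containing both classes.
#' @param config A [detector_config()].
#' @param features Optional precomputed raw features (internal use).
#' @return An object of class `dysphonia_detector` with components
#'   `config`, `aux`, `reducer`, `normalizer`, `classifier` and fit
#'   summaries; supports [predict()], [print()] and [summary()].
#' @export
dysphonia_detector <- function(corpus, config = detector_config(),
                               features = NULL) {
  stopifnot(inherits(corpus, "labeled_corpus"),
            inherits(config, "detector_config"))
  feats <- features %||%
    .corpus_features(corpus, config$techniques, config$nceps,
                     config$use_noncepstral)
  fit <- .fit_on_features(feats, config, seq_along(feats$labels))
  structure(
    c(list(config = config), fit,
      list(n_train = length(feats$labels),
           class_counts = table(feats$labels))),
    class = "dysphonia_detector")
}

#' @export
print.dysphonia_detector <- function(x, ...) {
  cat("Dysphonia detector\n")
  print(x$config)
  cat(sprintf("  feature dimension: %d -> %d after SVD reduction\n",
              x$input_dim, x$output_dim))
  cat(sprintf("  trained on %d signals (%s)\n", x$n_train,
              paste(sprintf("%s: %d", names(x$class_counts),
                            x$class_counts), collapse = ", ")))
  invisible(x)
}

#' @export
summary.dysphonia_detector <- function(object, ...) {
  print(object)
  cat(sprintf("  classifier: %s; normalization: %s; balancing: %s\n",
              object$config$classifier, object$config$normalization,
              object$config$balance))
  invisible(object)
}

#' Predict labels for new signals
#'
#' Builds each signal's feature vector with the fitted auxiliaries, applies
#' the fitted reducer and normalizer, and classifies. No test-set
#' statistics are used.
#'
#' @param object A fitted [dysphonia_detector()].
#' @param newdata A [voice_signal()] or [labeled_corpus()].
#' @param ... Unused.
#' @return Character vector of predicted labels (`"healthy"` /
#'   `"dysphonic"`).
#' @export
predict.dysphonia_detector <- function(object, newdata, ...) {
  if (inherits(newdata, "voice_signal")) {
    v <- build_feature_vector(newdata, object$config, object$aux)
    Xn <- apply_normalizer(object$normalizer,
                           apply_reducer(object$reducer, v))
    return(as.character(.predict_classifier(object$classifier,
                                            matrix(Xn, 1L))))
  }
  stopifnot(inherits(newdata, "labeled_corpus"))
  feats <- .corpus_features(newdata, object$config$techniques,
                            object$config$nceps,
                            object$config$use_noncepstral)
  .predict_on_features(object, feats, seq_along(feats$labels))
}

# ---- metrics ----------------------------------------------------------------

# Metrics from label vectors; dysphonic is the positive class.
.compute_metrics <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  n_h <- sum(truth == "healthy"); n_d <- sum(truth == "dysphonic")
  EH <- if (n_h > 0) 100 * sum(truth == "healthy" &
                                 pred == "dysphonic") / n_h else NA_real_
  EP <- if (n_d > 0) 100 * sum(truth == "dysphonic" &
                                 pred == "healthy") / n_d else NA_real_
  EER <- if (is.na(EH) || is.na(EP)) NA_real_ else (EH + EP) / 2
  ACC <- 100 * mean(truth == pred)
  tp <- sum(truth == "dysphonic" & pred == "dysphonic")
  fp <- sum(truth == "healthy" & pred == "dysphonic")
  fn <- sum(truth == "dysphonic" & pred == "healthy")
  F1 <- if (tp + fp == 0 || tp + fn == 0) {
    if (tp == 0 && fn == 0) NA_real_ else 0
  } else {
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  list(EH = EH, EP = EP, EER = EER, ACC = ACC, F1 = F1)
}

#' Evaluate a fitted detector on a test corpus
#'
#' Reports EH (% healthy signals classified as dysphonic), EP (% dysphonic
#' classified as healthy), EER = (EH + EP)/2, ACC (% correct) and the F1
#' score with dysphonic as the positive class.
#'
#' @param model A fitted [dysphonia_detector()].
#' @param test A non-empty [labeled_corpus()].
#' @return Named list `EH`, `EP`, `EER`, `ACC`, `F1` (percentages except
#'   F1 in `[0, 1]`).
#' @export
evaluate_detector <- function(model, test) {
  pred <- predict(model, test)
  .compute_metrics(corpus_labels(test), pred)
}

# Stratified k-fold assignment, shuffled with `seed`.
.stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation accuracy
#'
#' Stratified k-fold split shuffled with `config$seed`; in each fold the
#' full pipeline (noncepstral auxiliaries, SMOTE, reducer, normalizer,
#' classifier) is refitted on the training folds only and accuracy is
#' measured on the held-out fold. Returns the mean of the k accuracies
#' (the KFCV score, in `[0, 1]`).
#'
#' @param corpus A [labeled_corpus()]; each class needs at least `k`
#'   members.
#' @param config A [detector_config()].
#' @param k Number of folds (default 5).
#' @param features Optional precomputed raw features (internal use).
#' @return Mean held-out accuracy in `[0, 1]`.
#' @export
kfold_cv <- function(corpus, config = detector_config(), k = 5,
                     features = NULL) {
  labels <- corpus_labels(corpus)
  if (any(table(labels) < k)) stop("each class needs at least k members")
  feats <- features %||%
    .corpus_features(corpus, config$techniques, config$nceps,
                     config$use_noncepstral)
  feats$labels <- labels
  fold <- .stratified_folds(labels, k, config$seed)
  accs <- vapply(seq_len(k), function(f) {
    tr <- which(fold != f); te <- which(fold == f)
    fit <- .fit_on_features(feats, config, tr)
    fit$config <- config
    pred <- .predict_on_features(fit, feats, te)
    mean(pred == labels[te])
  }, numeric(1))
  mean(accs)
}

# ---- experiment grid --------------------------------------------------------

# Table-style descriptor "value|techniques|normalization|dim|clf|bal|maps".
.descriptor <- function(value, row) {
  techs <- if (is.na(row$technique_set) || row$technique_set == "") {
    if (row$noncepstral) "nonceps" else ""
  } else {
    paste0(row$technique_set, if (row$noncepstral) ", nonceps" else "")
  }
  parts <- c(sprintf("%.2f", value), techs, row$normalization,
             row$dimension, row$classifier,
             if (row$balancing == "SMOTE") "SMOTE" else "-")
  if (!is.na(row$technique_set) && row$technique_set != "")
    parts <- c(parts, row$mapping_set)
  paste(parts, collapse = "|")
}

#' Run a configuration grid
#'
#' Evaluates the Cartesian product of the requested technique sets, mapping
#' sets, noncepstral on/off, normalizations, reduction fractions,
#' classifiers and balancing options. The corpus is split once into
#' stratified train/test partitions; every configuration is fitted on the
#' training partition and scored on the test partition. Signal-level raw
#' features are computed once and shared across rows.
#'
#' @param corpus A [labeled_corpus()].
#' @param techniques List of technique sets (aliases/character vectors);
#'   use `NA` for "no cepstral features".
#' @param mappings List of mapping sets (aliases/character vectors).
#' @param noncepstral Logical values to cross (default TRUE).
#' @param normalizations,fractions,classifiers,balancing Vectors of values
#'   to cross.
#' @param holdout Test fraction for the stratified split (default 0.25).
#' @param kfcv Also compute the 5-fold KFCV score per row? (slower)
#' @param seed Integer seed for the split and all fits.
#' @param nceps Cepstral coefficients per technique.
#' @param features Optional precomputed [corpus_features()] cache covering
#'   every requested technique.
#' @return A data.frame with one row per configuration (columns
#'   technique_set, mapping_set, noncepstral, normalization, fraction,
#'   dimension, classifier, balancing, EH, EP, EER, ACC, F1, KFCV, seed)
#'   with a `best` attribute holding per-metric descriptor strings.
#' @export
run_grid <- function(corpus, techniques = list("MFCC"),
                     mappings = list("M8"), noncepstral = TRUE,
                     normalizations = "Standard", fractions = 0.5,
                     classifiers = "SVM", balancing = "SMOTE",
                     holdout = 0.25, kfcv = FALSE, seed = 1L, nceps = 20,
                     features = NULL) {
  labels <- corpus_labels(corpus)
  tech_names <- vapply(techniques, function(t) {
    if (length(t) == 1L && is.na(t)) "" else
      paste(technique_set(t), collapse = ", ")
  }, character(1))
  map_names <- vapply(mappings, function(m)
    paste(mapping_set(m), collapse = ", "), character(1))

  all_techs <- unique(unlist(lapply(techniques, function(t)
    if (length(t) == 1L && is.na(t)) NULL else as.character(technique_set(t)))))
  feats <- features %||%
    .corpus_features(corpus, all_techs, nceps,
                     use_noncepstral = any(noncepstral))
  feats$labels <- labels

  # stratified holdout split
  test_idx <- integer(0)
  with_seed(child_seed(seed, 99L), {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      test_idx <- c(test_idx, sample(idx, max(1L, round(holdout * length(idx)))))
    }
  })
  train_idx <- setdiff(seq_along(labels), test_idx)

  grid <- expand.grid(ti = seq_along(techniques), mi = seq_along(mappings),
                      nc = noncepstral, norm = normalizations,
                      fr = fractions, clf = classifiers, bal = balancing,
                      stringsAsFactors = FALSE)
  # drop invalid rows: no representation at all
  valid <- !(tech_names[grid$ti] == "" & !grid$nc)
  grid <- grid[valid, , drop = FALSE]

  rows <- lapply(seq_len(nrow(grid)), function(g) {
    row <- grid[g, ]
    cfg <- detector_config(
      techniques = if (tech_names[row$ti] == "") NULL else techniques[[row$ti]],
      mappings = mappings[[row$mi]], use_noncepstral = row$nc,
      balance = if (row$bal == "SMOTE") "SMOTE" else "none",
      reduce_fraction = row$fr, normalization = row$norm,
      classifier = row$clf, seed = seed, nceps = nceps)
    fit <- .fit_on_features(feats, cfg, train_idx)
    fit$config <- cfg
    pred <- .predict_on_features(fit, feats, test_idx)
    met <- .compute_metrics(labels[test_idx], pred)
    kf <- if (kfcv) kfold_cv(corpus, cfg, features = feats) else NA_real_
    data.frame(technique_set = tech_names[row$ti],
               mapping_set = map_names[row$mi], noncepstral = row$nc,
               normalization = row$norm, fraction = row$fr,
               dimension = fit$output_dim, classifier = row$clf,
               balancing = if (row$bal == "SMOTE") "SMOTE" else "none",
               EH = met$EH, EP = met$EP, EER = met$EER, ACC = met$ACC,
               F1 = met$F1, KFCV = kf, seed = seed,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  best <- list(
    ACC = .descriptor(max(res$ACC), res[which.max(res$ACC), ]),
    EER = .descriptor(min(res$EER), res[which.min(res$EER), ]),
    F1  = .descriptor(max(res$F1), res[which.max(res$F1), ])
  )
  if (kfcv && any(!is.na(res$KFCV)))
    best$KFCV <- .descriptor(max(res$KFCV, na.rm = TRUE),
                             res[which.max(res$KFCV), ])
  attr(res, "best") <- best
  res
}
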