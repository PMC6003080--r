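#' Stratified k-fold assignment
#'
#' Shuffles samples within each class and deals them round-robin into k
#' folds, so class proportions per fold are preserved within one sample.
#' Reproducible for a fixed seed.
#'
#' @param labels named factor/character, sample id -> class.
#' @param k fold count (default 10).
#' @param seed integer seed.
#' @param stratified logical; FALSE shuffles without regard to class.
#' @return A [FoldPlan-class].
#' @export
makeFolds <- function(labels, k = 10, seed = 1, stratified = TRUE) {
  labels <- droplevels(factor(labels))
  if (is.null(names(labels))) stop("labels must be named by sample id")
  if (k < 2) stop("k must be >= 2")
  small <- table(labels) < k
  if (stratified && any(small))
    stop("class(es) smaller than k: ",
         paste(names(small)[small], collapse = ", "),
         "; use a smaller k")
  if (!stratified && length(labels) < k)
    stop("fewer samples than folds")
  assign <- integer(length(labels))
  names(assign) <- names(labels)
  hadSeed <- exists(".Random.seed", envir = globalenv())
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  groups <- if (stratified) split(names(labels), labels) else
    list(all = names(labels))
  for (g in groups) {
    ord <- sample(g)
    assign[ord] <- rep_len(seq_len(k), length(ord))
  }
  if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
  methods::new("FoldPlan", k = as.integer(k), assignments = assign,
               seed = as.integer(seed), stratified = stratified)
}

#' Built-in classifier adapters
#'
#' Pluggable classifiers for [evaluateCV()]: `"dt"` (decision tree,
#' rpart), `"rf"` (random forest, randomForest) and `"nb"` (naive
#' Bayes, e1071), each used with its host library's default settings.
#' An adapter is a list with `fit(X, y)` and `prob(model, X)` returning
#' a samples x classes probability matrix. When the training feature
#' set is empty the harness falls back to predicting class priors.
#'
#' @param name one of `"dt"`, `"rf"`, `"nb"`, or a custom adapter list.
#' @return adapter list with elements `name`, `fit`, `prob`.
#' @export
hfeClassifier <- function(name = c("rf", "dt", "nb")) {
  if (is.list(name)) {
    stopifnot(all(c("name", "fit", "prob") %in% names(name)))
    return(name)
  }
  name <- match.arg(name)
  switch(name,
    dt = list(name = "dt",
      fit = function(X, y) rpart::rpart(y ~ ., data = data.frame(X, y = y),
                                        method = "class"),
      prob = function(m, X) predict(m, data.frame(X), type = "prob")),
    rf = list(name = "rf",
      fit = function(X, y) randomForest::randomForest(X, y),
      prob = function(m, X) predict(m, X, type = "prob")),
    nb = list(name = "nb",
      fit = function(X, y) e1071::naiveBayes(X, y),
      prob = function(m, X) predict(m, X, type = "raw")))
}

#' Macro one-vs-rest AUC
#' @noRd
.macroAUC <- function(truth, prob) {
  classes <- colnames(prob)
  aucs <- vapply(classes, function(cl) {
    resp <- factor(truth == cl, levels = c(FALSE, TRUE))
    if (nlevels(droplevels(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, prob[, cl], quiet = TRUE,
                                   direction = "<", levels = c(FALSE, TRUE))))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Support-weighted precision/recall/F from truth and predicted classes
#' @noRd
.weightedPRF <- function(truth, pred) {
  classes <- levels(truth)
  n <- length(truth)
  prf <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    p <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else 0
    r <- if (sum(truth == cl) > 0) tp / sum(truth == cl) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f) * sum(truth == cl) / n
  }, numeric(3))
  rowSums(prf)
}

#' Per-fold cross-validated evaluation of HFE + classifier
#'
#' For every fold, HFE is run on the training partitions only, both
#' train and test samples are projected onto the selected features (the
#' internal-taxon columns of test samples come from the same per-sample
#' aggregation, so no test label or value influences selection), a
#' classifier is trained and scored, and AUC / precision / recall /
#' F-measure are accumulated. Multi-class AUC is macro-averaged
#' one-vs-rest; precision/recall/F are support-weighted. With
#' `baseline = TRUE` selection is disabled and the raw OTU features are
#' used, giving the no-feature-engineering reference.
#'
#' @param table an [AbundanceTable-class] over the tree's OTUs.
#' @param labels named factor/character of per-sample classes.
#' @param tree a [TaxonomyTree-class].
#' @param classifier adapter name or list; see [hfeClassifier()].
#' @param plan a [FoldPlan-class] from [makeFolds()]; default 10-fold
#'   stratified with seed 1.
#' @param theta correlation threshold for HFE.
#' @param baseline logical; TRUE evaluates raw OTU features instead.
#' @param phase3Average passed to [runHFE()].
#' @return An [EvaluationReport-class].
#' @export
evaluateCV <- function(table, labels, tree, classifier = "rf", plan = NULL,
                       theta = 0.7, baseline = FALSE,
                       phase3Average = c("per-path", "global")) {
  phase3Average <- match.arg(phase3Average)
  table <- normalizeRelative(table)
  labels <- .alignLabels(table, labels)
  names(labels) <- sampleIds(table)
  if (is.null(plan)) plan <- makeFolds(labels, k = 10, seed = 1)
  adapter <- hfeClassifier(classifier)
  extended <- if (baseline) table else aggregateTaxa(table, tree)
  assign <- foldAssignments(plan)
  miss <- setdiff(sampleIds(table), names(assign))
  if (length(miss)) stop("fold plan does not cover sample(s): ",
                         paste(utils::head(miss, 3), collapse = ", "))
  X <- abundances(extended)
  rows <- lapply(seq_len(plan@k), function(fold) {
    testIds <- names(assign)[assign == fold]
    trainIds <- setdiff(sampleIds(table), testIds)
    sel <- if (baseline) featureIds(table) else
      selectedFeatures(.hfeOnExtended(extended, labels, tree, theta,
                                      samples = trainIds, phase3Average))
    yTr <- droplevels(labels[trainIds]); yTe <- labels[testIds]
    if (length(sel) == 0L || nlevels(yTr) < 2) {
      # nothing informative survived: predict training class priors
      pri <- prop.table(base::table(labels[trainIds]))
      prob <- matrix(rep(as.numeric(pri), each = length(testIds)),
                     nrow = length(testIds),
                     dimnames = list(testIds, names(pri)))
    } else {
      set.seed(plan@seed * 1000L + fold)  # classifier RNG tied to the plan
      model <- adapter$fit(X[trainIds, sel, drop = FALSE], yTr)
      prob <- adapter$prob(model, X[testIds, sel, drop = FALSE])
      if (!all(levels(labels) %in% colnames(prob))) {
        full <- matrix(0, nrow(prob), nlevels(labels),
                       dimnames = list(rownames(prob), levels(labels)))
        full[, colnames(prob)] <- prob
        prob <- full
      }
    }
    pred <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                   levels = levels(labels))
    prf <- .weightedPRF(yTe, pred)
    list(metrics = data.frame(fold = fold, auc = .macroAUC(yTe, prob),
                              precision = prf[1], recall = prf[2], f = prf[3],
                              nFeatures = length(sel)),
         selection = sel)
  })
  methods::new("EvaluationReport",
    metrics = do.call(rbind, lapply(rows, `[[`, "metrics")),
    selections = lapply(rows, `[[`, "selection"),
    classifier = adapter$name,
    theta = if (baseline) NA_real_ else theta,
    baseline = baseline)
}

#' Cross-fold feature intersection
#'
#' The set of features selected in every fold; a measure of how stable
#' the engineered feature set is across training partitions.
#'
#' @param selections list of per-fold feature id vectors, or an
#'   [EvaluationReport-class].
#' @return character vector.
#' @export
featureIntersection <- function(selections) {
  if (methods::is(selections, "EvaluationReport"))
    selections <- selections@selections
  if (length(selections) < 2) stop("need selections from >= 2 folds")
  Reduce(intersect, selections)
}
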