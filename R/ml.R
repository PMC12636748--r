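#' Generate a synthetic printability dataset
#'
#' Physics-informed generator emulating the schema of the study-style
#' printability tables: one row per (material, nozzle) combination with
#' yield stress (Pa), reference viscosity at shear rate 0.01 1/s (Pa s)
#' and nozzle diameter (um), plus a binary printable label. Ground truth
#' follows the plastocapillary rule: printable iff the yield-capillary
#' number computed with the nozzle radius reaches \code{Y_crit} and the
#' reference viscosity stays below the tearing (M3) threshold. Features
#' are drawn log-uniformly over ranges bracketing soft embedded-printing
#' baths and practical nozzle sizes; labels can be flipped with a given
#' noise probability.
#'
#' @param n number of records (>= 20)
#' @param seed integer RNG seed
#' @param Y_crit plastocapillary stability threshold (default 0.1)
#' @param tear_viscosity_threshold Pa s; reference viscosities above this
#'   mark tearing-regime (non-printable) materials
#' @param label_noise flip probability in [0, 0.5)
#' @param sigma surface tension used in the rule, N/m
#' @param tau_y_range,viscosity_range,diameter_range feature ranges
#'   (Pa, Pa s, um)
#' @return data frame of class \code{printability_data}: columns
#'   \code{yield_stress_Pa}, \code{viscosity_Pa_s},
#'   \code{nozzle_diameter_um}, \code{printable} (factor)
#' @export
generate_printability_data <- function(n, seed = 1L, Y_crit = 0.1,
                                       tear_viscosity_threshold = 3e4,
                                       label_noise = 0, sigma = 0.025,
                                       tau_y_range = c(1, 1e3),
                                       viscosity_range = c(10, 1e6),
                                       diameter_range = c(100, 2000)) {
  if (n < 20) stop("n must be >= 20")
  if (label_noise < 0 || label_noise >= 0.5) stop("label_noise must be in [0, 0.5)")
  rng <- function(r) {
    if (r[1] <= 0 || r[2] <= r[1]) stop("degenerate feature range")
    exp(stats::runif(n, log(r[1]), log(r[2])))
  }
  set.seed(as.integer(seed))
  tau_y <- rng(tau_y_range)
  mu <- rng(viscosity_range)
  d_um <- rng(diameter_range)
  lab <- printability_rule(tau_y, mu, d_um, Y_crit = Y_crit,
                           tear_viscosity_threshold = tear_viscosity_threshold,
                           sigma = sigma)
  if (label_noise > 0) {
    flip <- stats::runif(n) < label_noise
    lab[flip] <- !lab[flip]
  }
  out <- data.frame(yield_stress_Pa = tau_y, viscosity_Pa_s = mu,
                    nozzle_diameter_um = d_um,
                    printable = factor(ifelse(lab, "printable", "not-printable"),
                                       levels = c("not-printable", "printable")))
  class(out) <- c("printability_data", class(out))
  attr(out, "rule") <- list(Y_crit = Y_crit,
                            tear_viscosity_threshold = tear_viscosity_threshold,
                            sigma = sigma)
  out
}

#' Ground-truth printability rule
#'
#' @inheritParams generate_printability_data
#' @param tau_y yield stress, Pa
#' @param mu reference viscosity, Pa s
#' @param d_um nozzle diameter, um
#' @return logical vector: printable under the generating rule
#' @export
printability_rule <- function(tau_y, mu, d_um, Y_crit = 0.1,
                               tear_viscosity_threshold = 3e4, sigma = 0.025) {
  R <- d_um * 1e-6 / 2
  Y <- tau_y * R / sigma
  Y >= Y_crit & mu < tear_viscosity_threshold
}

.ml_families <- c("random_forest", "xgboost", "neural_network", "knn",
                  "logistic", "svm", "naive_bayes")

# log10-transformed, train-fold-standardized design matrix
.ml_design <- function(df) {
  x <- cbind(log_tau_y = log10(df$yield_stress_Pa),
             log_mu = log10(df$viscosity_Pa_s),
             log_d = log10(df$nozzle_diameter_um))
  x
}

.ml_fit <- function(family, x, y, seed) {
  set.seed(seed)
  switch(family,
    random_forest = randomForest::randomForest(x, y, ntree = 300),
    xgboost = xgboost::xgboost(x, y, nrounds = 60, max_depth = 3,
                               learning_rate = 0.3, nthread = 1,
                               verbosity = 0),
    neural_network = nnet::nnet(x, stats::model.matrix(~ y - 1)[, 2, drop = FALSE],
                                size = 6, decay = 1e-3, maxit = 400,
                                trace = FALSE, entropy = TRUE),
    knn = list(train_x = x, train_y = y, k = 7),
    logistic = suppressWarnings(
      stats::glm.fit(cbind(1, x), as.integer(y) - 1L,
                     family = stats::binomial())),
    svm = e1071::svm(x, y, kernel = "radial", probability = TRUE),
    naive_bayes = e1071::naiveBayes(x, y),
    stop("unknown family: ", family))
}

.ml_score <- function(family, fit, x) {
  switch(family,
    random_forest = stats::predict(fit, x, type = "prob")[, "printable"],
    xgboost = stats::predict(fit, x),
    neural_network = as.numeric(stats::predict(fit, x)),
    knn = {
      pr <- class::knn(fit$train_x, x, fit$train_y, k = fit$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "printable", p, 1 - p)
    },
    logistic = as.numeric(stats::plogis(cbind(1, x) %*% fit$coefficients)),
    svm = {
      pr <- stats::predict(fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "printable"]
    },
    naive_bayes = stats::predict(fit, x, type = "raw")[, "printable"])
}

#' Train the printability classifier bank
#'
#' Trains the seven model families used for printability prediction
#' (random forest, XGBoost, a small feed-forward neural network,
#' k-nearest neighbors, logistic regression, an RBF support vector
#' machine and naive Bayes) on log10-transformed features with
#' stratified k-fold cross-validation; standardization statistics are
#' estimated on the training folds only. Each family yields a
#' \code{classifier_report} (per-fold accuracy/precision/recall/F1 and a
#' pooled confusion matrix) plus a final model refitted on the full
#' data for prediction.
#'
#' @param records \code{printability_data} (or a data frame with the
#'   same columns)
#' @param families subset of
#'   \code{c("random_forest", "xgboost", "neural_network", "knn",
#'   "logistic", "svm", "naive_bayes")}, or \code{"all"}
#' @param cv_folds number of stratified folds (>= 2)
#' @param seed integer seed controlling folds and stochastic learners
#' @return object of class \code{classifier_bank}: named list of
#'   \code{printability_model} objects, each carrying its
#'   \code{report}
#' @export
train_classifiers <- function(records, families = "all", cv_folds = 5,
                              seed = 1L) {
  if (identical(families, "all")) families <- .ml_families
  families <- match.arg(families, .ml_families, several.ok = TRUE)
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  y <- records$printable
  if (!is.factor(y)) y <- factor(y, levels = c("not-printable", "printable"))
  if (nlevels(droplevels(y)) < 2) stop("training data has a single class")
  if (min(table(y)) < 10) stop("need >= 10 records per class")
  x_raw <- .ml_design(records)
  set.seed(as.integer(seed))
  # stratified fold assignment
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(cv_folds), length(idx))
  }
  out <- lapply(families, function(fam) {
    per_fold <- lapply(seq_len(cv_folds), function(f) {
      tr <- fold != f; te <- !tr
      if (nlevels(droplevels(y[tr])) < 2 || !any(te))
        stop("fold without both classes; reduce cv_folds")
      ctr <- colMeans(x_raw[tr, , drop = FALSE])
      scl <- apply(x_raw[tr, , drop = FALSE], 2, stats::sd)
      scl[scl == 0] <- 1
      xt <- scale(x_raw[tr, , drop = FALSE], ctr, scl)
      xe <- scale(x_raw[te, , drop = FALSE], ctr, scl)
      fit <- .ml_fit(fam, xt, y[tr], seed + f)
      sc <- .ml_score(fam, fit, xe)
      pred <- factor(ifelse(sc >= 0.5, "printable", "not-printable"),
                     levels = levels(y))
      tab <- table(truth = y[te], pred = pred)
      tp <- tab["printable", "printable"]; fp <- tab["not-printable", "printable"]
      fn <- tab["printable", "not-printable"]
      prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
        2 * prec * rec / (prec + rec) else NA_real_
      list(accuracy = mean(pred == y[te]), precision = prec, recall = rec,
           f1 = f1, confusion = tab)
    })
    conf <- Reduce(`+`, lapply(per_fold, `[[`, "confusion"))
    ctr <- colMeans(x_raw); scl <- apply(x_raw, 2, stats::sd); scl[scl == 0] <- 1
    final <- .ml_fit(fam, scale(x_raw, ctr, scl), y, seed)
    boundary <- if (fam == "logistic")
      stats::setNames(final$coefficients, c("intercept", colnames(x_raw)))
    else if (fam == "random_forest") randomForest::importance(final)[, 1]
    else NULL
    report <- structure(list(
      family = fam, cv_folds = cv_folds,
      accuracy = vapply(per_fold, `[[`, 0, "accuracy"),
      precision = vapply(per_fold, `[[`, 0, "precision"),
      recall = vapply(per_fold, `[[`, 0, "recall"),
      f1 = vapply(per_fold, `[[`, 0, "f1"),
      confusion = conf, boundary = boundary), class = "classifier_report")
    structure(list(family = fam, fit = final, center = ctr, scale = scl,
                   levels = levels(y), feature_range = apply(x_raw, 2, range),
                   seed = seed, report = report),
              class = "printability_model")
  })
  names(out) <- families
  structure(out, class = "classifier_bank")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("%s: %d-fold CV accuracy %.3f (sd %.3f), F1 %.3f\n",
              x$family, x$cv_folds, mean(x$accuracy), stats::sd(x$accuracy),
              mean(x$f1, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.classifier_bank <- function(x, ...) {
  cat("printability classifier bank:\n")
  for (m in x) print(m$report)
  invisible(x)
}

#' @export
print.printability_model <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Summarize cross-validated accuracy of a classifier bank
#' @param object \code{classifier_bank}
#' @param ... unused
#' @return data frame: family, mean/min accuracy, mean F1
#' @export
summary.classifier_bank <- function(object, ...) {
  do.call(rbind, lapply(object, function(m)
    data.frame(family = m$family, mean_accuracy = mean(m$report$accuracy),
               min_accuracy = min(m$report$accuracy),
               mean_f1 = mean(m$report$f1, na.rm = TRUE))))
}

#' Predict printability for new material/nozzle combinations
#'
#' @param model a \code{printability_model} (one element of a
#'   \code{\link{train_classifiers}} bank)
#' @param newdata data frame with \code{yield_stress_Pa},
#'   \code{viscosity_Pa_s}, \code{nozzle_diameter_um}
#' @return data frame: \code{label} (factor) and \code{score} in [0, 1]
#'   (probability of printable)
#' @export
predict_printability <- function(model, newdata) {
  stopifnot(inherits(model, "printability_model"))
  need <- c("yield_stress_Pa", "viscosity_Pa_s", "nozzle_diameter_um")
  miss <- setdiff(need, names(newdata))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(newdata[need]))) || any(newdata[need] <= 0))
    stop("features must be positive and finite")
  x <- .ml_design(newdata)
  fr <- model$feature_range  # log10 units: +-1 is a factor of 10
  if (any(sweep(x, 2, fr[1, ] - 1, "<") | sweep(x, 2, fr[2, ] + 1, ">")))
    warning("features beyond 10x the training range; extrapolating")
  xs <- scale(x, model$center, model$scale)
  sc <- .ml_score(model$family, model$fit, xs)
  data.frame(label = factor(ifelse(sc >= 0.5, "printable", "not-printable"),
                            levels = model$levels),
             score = as.numeric(sc))
}

#' Read / write printability tables as CSV
#'
#' Expected columns: \code{yield_stress_Pa}, \code{viscosity_Pa_s},
#' \code{nozzle_diameter_um}, \code{printable} (label text or 0/1).
#' Malformed rows (non-numeric, non-positive or missing values, unknown
#' labels) are dropped with per-row reasons recorded in the
#' \code{"rejections"} attribute.
#'
#' @param path CSV file
#' @return validated \code{printability_data}; inspect
#'   \code{attr(x, "rejections")} for the rejection report
#' @export
read_printability_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty printability table: ", path)
  need <- c("yield_stress_Pa", "viscosity_Pa_s", "nozzle_diameter_um", "printable")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  num <- function(v) suppressWarnings(as.numeric(v))
  f <- data.frame(yield_stress_Pa = num(df$yield_stress_Pa),
                  viscosity_Pa_s = num(df$viscosity_Pa_s),
                  nozzle_diameter_um = num(df$nozzle_diameter_um))
  lab_raw <- tolower(as.character(df$printable))
  lab <- ifelse(lab_raw %in% c("printable", "1", "true", "yes"), "printable",
         ifelse(lab_raw %in% c("not-printable", "0", "false", "no"),
                "not-printable", NA))
  reasons <- character(nrow(df))
  bad_num <- !stats::complete.cases(f) | apply(f, 1, function(r) any(r <= 0))
  reasons[bad_num] <- "non-numeric or non-positive feature"
  reasons[is.na(lab) & !nzchar(reasons)] <- "unrecognized label"
  keep <- !nzchar(reasons)
  if (!any(keep)) stop("no valid rows in ", path)
  out <- cbind(f[keep, , drop = FALSE],
               printable = factor(lab[keep],
                                  levels = c("not-printable", "printable")))
  rownames(out) <- NULL
  class(out) <- c("printability_data", class(out))
  attr(out, "rejections") <- data.frame(row = which(!keep),
                                        reason = reasons[!keep])
  out
}

#' @rdname read_printability_csv
#' @param records \code{printability_data}
#' @export
write_printability_csv <- function(records, path) {
  df <- as.data.frame(records)[, c("yield_stress_Pa", "viscosity_Pa_s",
                                   "nozzle_diameter_um", "printable")]
  utils::write.csv(format(df, digits = 12), path, row.names = FALSE)
  invisible(path)
}
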