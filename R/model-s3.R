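# The user-facing fitted model object. fit_preference_model() runs the
# leave-one-out logistic protocol over the contact positions, optimizes
# the per-type thresholds on the pooled LOO activations, and returns a
# classed object with the usual modelling methods.

#' Fit the CDR amino-acid preference model
#'
#' Trains, for every amino-acid type, one logistic regression per held-out
#' contact position on the (X, Y, Z) features and deltaW labels of the
#' remaining positions (leave-one-out over positions), pools the LOO
#' activations, and optimizes one MCC-maximal threshold per type.
#'
#' @param score_table long table with columns position, aa, X, Y and
#'   optionally Z (see \code{\link{score_positions}} and
#'   \code{\link{structural_propensity}}).
#' @param preference_table long table with columns position, aa, deltaW
#'   and optionally W (see \code{\link{preference_profile}}).
#' @param positions contact positions to model (default all shared
#'   positions).
#' @param objective regression objective: \code{"binary"} cross-entropy on
#'   the deltaW labels (default) or \code{"least_squares"} against
#'   min-max rescaled W.
#' @return A \code{cdr_pref_model} with components \code{pW},
#'   \code{deltaW}, \code{thresholds}, \code{weights}, \code{evaluation}
#'   and the aligned feature matrices.
#' @export
fit_preference_model <- function(score_table, preference_table,
                                 positions = NULL,
                                 objective = c("binary", "least_squares")) {
  objective <- match.arg(objective)
  loo <- loo_train_predict(score_table, preference_table, positions,
                           objective = objective)
  th <- optimize_thresholds(loo$pW, loo$deltaW)
  pred <- predict_binary(loo$pW, th$t)
  ev <- evaluate_predictions(pred, loo$deltaW)
  structure(list(pW = loo$pW, deltaW = loo$deltaW, predicted = pred,
                 thresholds = th$t, threshold_mcc = th$mcc,
                 degenerate_types = th$degenerate, weights = loo$weights,
                 features = loo$features, evaluation = ev,
                 objective = objective,
                 call = match.call()), class = "cdr_pref_model")
}

#' @export
print.cdr_pref_model <- function(x, ...) {
  cat("CDR amino-acid preference model (leave-one-out logistic regression)\n")
  cat(sprintf("  positions: %d, amino-acid types: %d, objective: %s\n",
              nrow(x$pW), ncol(x$pW), x$objective))
  cat(sprintf("  overall LOO MCC %.3f (accuracy %.3f, recall %.3f)\n",
              x$evaluation$mcc, x$evaluation$accuracy, x$evaluation$recall))
  invisible(x)
}

#' @export
summary.cdr_pref_model <- function(object, ...) {
  ev <- object$evaluation
  per_pos <- vapply(rownames(object$pW), function(j) {
    evp <- evaluate_predictions(object$predicted[j, ], object$deltaW[j, ])
    c(positives = sum(object$deltaW[j, ]),
      predicted = sum(object$predicted[j, ]),
      true_pos = evp$TP)
  }, numeric(3))
  out <- list(evaluation = ev, per_position = t(per_pos),
              thresholds = object$thresholds,
              mean_positives = mean(colSums(t(object$deltaW))),
              model = object)
  class(out) <- "summary.cdr_pref_model"
  out
}

#' @export
print.summary.cdr_pref_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  mean positive types per position: %.2f\n", x$mean_positives))
  cat("  confusion: "); print(x$evaluation)
  cat("per-position counts (positives / predicted / true positives):\n")
  print(x$per_position)
  invisible(x)
}

#' @export
coef.cdr_pref_model <- function(object, ...) {
  # average the per-fold weights per type: one (a, x, y, z) row per type
  apply(object$weights, c(2L, 3L), mean)
}

#' Predict preference activations for new score rows
#'
#' Applies, for each amino-acid type, the mean of the fitted per-fold
#' models to new (X, Y, Z) feature rows.
#'
#' @param object a \code{cdr_pref_model}.
#' @param newdata data.frame with columns position, aa, X, Y and
#'   optionally Z. Default: refit activations of the training positions.
#' @param type \code{"activation"} for pW, \code{"binary"} for thresholded
#'   deltapW, \code{"margin"} for pW - t.
#' @param ... unused.
#' @return data.frame position, aa plus the requested prediction column.
#' @export
predict.cdr_pref_model <- function(object, newdata = NULL,
                                   type = c("activation", "binary", "margin"),
                                   ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    pW <- object$pW
    long <- data.frame(position = rep(rownames(pW), ncol(pW)),
                       aa = rep(colnames(pW), each = nrow(pW)),
                       pW = as.vector(pW), stringsAsFactors = FALSE)
  } else {
    nd <- as.data.frame(newdata)
    if (!("Z" %in% names(nd))) nd$Z <- 0
    w <- coef(object)  # types x (a, x, y, z)
    long <- nd[, c("position", "aa")]
    long$pW <- NA_real_
    for (i in seq_len(nrow(nd))) {
      aa <- nd$aa[i]
      if (!(aa %in% rownames(w))) stop(sprintf("unknown type '%s'", aa))
      eta <- w[aa, "a"] + w[aa, "x"] * nd$X[i] + w[aa, "y"] * nd$Y[i] +
        w[aa, "z"] * nd$Z[i]
      long$pW[i] <- sigmoid(eta)
    }
  }
  t_i <- object$thresholds[long$aa]
  if (type == "binary") long$deltapW <- (long$pW >= t_i) * 1L
  if (type == "margin") long$margin <- long$pW - t_i
  long
}

#' Ranking of the 20 types at each modelled position
#'
#' @param object a \code{cdr_pref_model}.
#' @return Integer rank matrix (positions x types) by activation margin.
#' @export
model_rankings <- function(object) {
  stopifnot(inherits(object, "cdr_pref_model"))
  margin <- sweep(object$pW, 2L, object$thresholds[colnames(object$pW)])
  rank_amino_acids(margin)
}

#' Serialize a fitted model to JSON
#'
#' @param object a \code{cdr_pref_model}.
#' @param path output file.
#' @export
write_model_json <- function(object, path) {
  payload <- list(objective = object$objective,
                  positions = rownames(object$pW),
                  types = colnames(object$pW),
                  thresholds = as.list(object$thresholds),
                  mean_weights = apply(object$weights, c(2L, 3L), mean),
                  pW = object$pW, deltaW = object$deltaW,
                  evaluation = unclass(object$evaluation))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
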