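# Logistic-regression preference models: per-(position, type) activation
# pW from the X/Y/Z features, leave-one-out training over positions,
# MCC-optimal per-type thresholds, confusion metrics and the closed-form
# random-prediction baseline.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fit a ridge-regularized logistic regression
#'
#' Deterministic iteratively reweighted least squares with a small L2
#' penalty (lambda = 1e-6 on the slopes, none on the intercept) and
#' convergence tolerance 1e-8. Features are z-scored with the training
#' statistics (constant features get unit scale). With all labels
#' identical the fit falls back to an intercept-only model with a
#' lightly shrunk empirical log-odds.
#'
#' @param features numeric matrix (rows = training cases, columns =
#'   features, e.g. X, Y, Z).
#' @param labels 0/1 vector.
#' @param lambda L2 penalty.
#' @param tol convergence tolerance on the coefficient change.
#' @param max_iter iteration cap.
#' @return list with \code{coef} (intercept + slopes on the original
#'   feature scale), \code{coef_std}, \code{center}, \code{scale},
#'   \code{converged}.
#' @export
fit_logistic <- function(features, labels, lambda = 1e-6, tol = 1e-8,
                         max_iter = 100L) {
  X <- as.matrix(features)
  if (any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite feature at row %d, column %d", bad[1L], bad[2L]))
  }
  y <- as.numeric(labels)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)), nrow(X) >= 2L)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  p_feat <- ncol(Xs)
  if (length(unique(y)) == 1L) {
    phat <- (sum(y) + 0.5) / (length(y) + 1)
    b <- c(log(phat / (1 - phat)), rep(0, p_feat))
    coef <- back_transform_coef(b, ctr, scl)
    return(list(coef = coef, coef_std = b, center = ctr, scale = scl,
                converged = TRUE, intercept_only = TRUE))
  }
  Z <- cbind(1, Xs)
  b <- rep(0, p_feat + 1L)
  pen <- diag(c(0, rep(lambda, p_feat)), p_feat + 1L)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% b)
    mu <- sigmoid(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Z, Z * w) + pen
    g <- crossprod(Z, y - mu) - pen %*% b
    step <- solve(H, g)
    b_new <- b + drop(step)
    if (max(abs(b_new - b)) < tol) {
      b <- b_new
      converged <- TRUE
      break
    }
    b <- b_new
  }
  list(coef = back_transform_coef(b, ctr, scl), coef_std = b, center = ctr,
       scale = scl, converged = converged, intercept_only = FALSE)
}

back_transform_coef <- function(b, ctr, scl) {
  slopes <- b[-1L] / scl
  c(b[1L] - sum(slopes * ctr), slopes)
}

predict_logistic <- function(fit, features) {
  X <- as.matrix(features)
  sigmoid(drop(cbind(1, X) %*% fit$coef))
}

# Assemble aligned (positions x types) matrices of X, Y, Z and deltaW from
# long score/preference tables.
align_tables <- function(score_table, preference_table, positions = NULL) {
  st <- as.data.frame(score_table)
  pt <- as.data.frame(preference_table)
  if (!("Z" %in% names(st))) st$Z <- 0
  m <- merge(st[, c("position", "aa", "X", "Y", "Z")],
             pt[, c("position", "aa", intersect(c("W", "deltaW"), names(pt)))],
             by = c("position", "aa"))
  if (is.null(positions)) positions <- sort(unique(m$position))
  m <- m[m$position %in% positions, , drop = FALSE]
  types <- sort(unique(m$aa))
  shape <- function(col) {
    out <- matrix(NA_real_, length(positions), length(types),
                  dimnames = list(positions, types))
    out[cbind(match(m$position, positions), match(m$aa, types))] <- m[[col]]
    out
  }
  res <- list(X = shape("X"), Y = shape("Y"), Z = shape("Z"),
              deltaW = if ("deltaW" %in% names(m)) shape("deltaW"),
              W = if ("W" %in% names(m)) shape("W"))
  if (any(is.na(res$X)) || (!is.null(res$deltaW) && any(is.na(res$deltaW))))
    stop("score/preference tables do not cover all positions x types")
  res
}

#' Leave-one-out training and prediction of preference activations
#'
#' For each amino-acid type i and each held-out position j, a logistic
#' model is trained on the (X, Y, Z, deltaW) rows of all other positions
#' for that type and applied to the held-out features, yielding the
#' activation pW_ji.
#'
#' @param score_table long table with position, aa, X, Y (and optionally
#'   Z) columns.
#' @param preference_table long table with position, aa, deltaW (and
#'   optionally W).
#' @param positions contact positions to use (default: all shared).
#' @param objective \code{"binary"} (cross-entropy on deltaW; default) or
#'   \code{"least_squares"} (squared error against min-max rescaled W).
#' @return list with \code{pW} (positions x types), \code{deltaW},
#'   \code{weights} (per type x held-out position coefficient array) and
#'   the aligned feature matrices.
#' @export
loo_train_predict <- function(score_table, preference_table,
                              positions = NULL,
                              objective = c("binary", "least_squares")) {
  objective <- match.arg(objective)
  al <- align_tables(score_table, preference_table, positions)
  if (is.null(al$deltaW)) stop("preference table lacks deltaW labels")
  npos <- nrow(al$X)
  types <- colnames(al$X)
  if (npos < 2L) stop("need at least 2 positions for leave-one-out")
  pW <- matrix(NA_real_, npos, length(types),
               dimnames = dimnames(al$X))
  weights <- array(NA_real_, dim = c(npos, length(types), 4L),
                   dimnames = list(rownames(al$X), types,
                                   c("a", "x", "y", "z")))
  if (objective == "least_squares" && is.null(al$W))
    stop("least_squares objective needs a W column")
  for (t in seq_along(types)) {
    feats <- cbind(X = al$X[, t], Y = al$Y[, t], Z = al$Z[, t])
    for (j in seq_len(npos)) {
      tr <- setdiff(seq_len(npos), j)
      if (length(tr) < 2L) {
        # degenerate 2-position protocol: train on the single other row
        tr <- rep(tr, 2L)
      }
      if (objective == "binary") {
        fit <- fit_logistic(feats[tr, , drop = FALSE], al$deltaW[tr, t])
      } else {
        wtr <- al$W[tr, t]
        rng <- range(wtr)
        target <- if (diff(rng) < 1e-12) rep(0.5, length(wtr)) else
          (wtr - rng[1L]) / diff(rng)
        fit <- fit_least_squares_sigmoid(feats[tr, , drop = FALSE], target)
      }
      pW[j, t] <- predict_logistic(fit, feats[j, , drop = FALSE])
      weights[j, t, ] <- c(fit$coef[1L], fit$coef[-1L])
    }
  }
  list(pW = pW, deltaW = al$deltaW, weights = weights,
       features = al, objective = objective)
}

# Least-squares mode: sigmoid output fitted to a rescaled continuous
# target by damped Gauss-Newton; shares the ridge and tolerances of the
# logistic mode.
fit_least_squares_sigmoid <- function(features, target, lambda = 1e-6,
                                      tol = 1e-8, max_iter = 200L) {
  X <- as.matrix(features)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  Z <- cbind(1, Xs)
  b <- rep(0, ncol(Z))
  pen <- diag(c(0, rep(lambda, ncol(Xs))), ncol(Z))
  for (it in seq_len(max_iter)) {
    mu <- sigmoid(drop(Z %*% b))
    J <- Z * (mu * (1 - mu))
    g <- crossprod(J, target - mu) - pen %*% b
    H <- crossprod(J) + pen + diag(1e-8, ncol(Z))
    step <- drop(solve(H, g))
    b_new <- b + step
    if (max(abs(b_new - b)) < tol) {
      b <- b_new
      break
    }
    b <- b_new
  }
  list(coef = back_transform_coef(b, ctr, scl), coef_std = b,
       center = ctr, scale = scl, converged = TRUE)
}

#' Matthews correlation coefficient and companion metrics
#'
#' @param TP,FP,TN,FN confusion counts.
#' @return list with accuracy, specificity, recall, precision, mcc (the
#'   0/0 MCC convention is 0).
#' @export
confusion_metrics <- function(TP, FP, TN, FN) {
  n <- TP + FP + TN + FN
  den <- sqrt((TP + FP)) * sqrt((TP + FN)) * sqrt((TN + FP)) * sqrt((TN + FN))
  mcc <- if (den == 0) {
    0
  } else if (FP == 0 && FN == 0) {
    1  # perfect prediction, exactly (TP, TN > 0 since den > 0)
  } else if (TP == 0 && TN == 0) {
    -1
  } else {
    (TP * TN - FP * FN) / den
  }
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       accuracy = if (n > 0) (TP + TN) / n else NA_real_,
       specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
       recall = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
       mcc = mcc)
}

#' Evaluate binary predictions against experimental labels
#'
#' @param pred,obs 0/1 matrices or vectors of equal shape.
#' @return An \code{evaluation_summary} (confusion counts + metrics).
#' @export
evaluate_predictions <- function(pred, obs) {
  pred <- as.vector(pred)
  obs <- as.vector(obs)
  if (length(pred) == 0L) stop("empty input")
  stopifnot(length(pred) == length(obs), all(pred %in% c(0, 1)),
            all(obs %in% c(0, 1)))
  res <- confusion_metrics(TP = sum(pred == 1 & obs == 1),
                           FP = sum(pred == 1 & obs == 0),
                           TN = sum(pred == 0 & obs == 0),
                           FN = sum(pred == 0 & obs == 1))
  structure(res, class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("accuracy %.3f  precision %.3f  recall %.3f  specificity %.3f  MCC %.3f\n",
              x$accuracy, x$precision, x$recall, x$specificity, x$mcc))
  invisible(x)
}

#' MCC-optimal per-type activation thresholds
#'
#' For each amino-acid type the threshold t_i maximizing the MCC of the
#' pooled leave-one-out predictions is chosen over the candidate grid of
#' midpoints between sorted unique activations plus \{0, 1\}; ties are
#' broken toward the larger threshold. Types without both a positive and
#' a negative label fall back to t_i = 0.5 (flagged degenerate).
#'
#' @param pW activation matrix (positions x types).
#' @param deltaW 0/1 label matrix of the same shape.
#' @return list with \code{t} (named per-type thresholds), \code{mcc}
#'   (per-type optimum) and \code{degenerate} (logical).
#' @export
optimize_thresholds <- function(pW, deltaW) {
  stopifnot(all(dim(pW) == dim(deltaW)))
  types <- colnames(pW)
  t_out <- stats::setNames(rep(0.5, length(types)), types)
  mcc_out <- stats::setNames(rep(NA_real_, length(types)), types)
  degen <- stats::setNames(rep(FALSE, length(types)), types)
  for (t in seq_along(types)) {
    p <- pW[, t]
    y <- deltaW[, t]
    if (length(unique(y)) < 2L) {
      degen[t] <- TRUE
      next
    }
    u <- sort(unique(p))
    cand <- sort(unique(c(0, 1, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2)))
    best_mcc <- -Inf
    best_t <- 0.5
    for (tc in cand) {
      pred <- (p >= tc) * 1L
      m <- confusion_metrics(sum(pred & y), sum(pred & !y),
                             sum(!pred & !y), sum(!pred & y))$mcc
      if (m > best_mcc || (m == best_mcc && tc > best_t)) {
        best_mcc <- m
        best_t <- tc
      }
    }
    t_out[t] <- best_t
    mcc_out[t] <- best_mcc
  }
  list(t = t_out, mcc = mcc_out, degenerate = degen)
}

#' Threshold activations into binary predictions
#'
#' deltapW = 1 exactly when pW >= t (boundary counts as positive).
#'
#' @param pW activation matrix (positions x types).
#' @param t per-type thresholds (named vector or scalar).
#' @return 0/1 matrix of the same shape.
#' @export
predict_binary <- function(pW, t) {
  if (length(t) == 1L) t <- stats::setNames(rep(t, ncol(pW)), colnames(pW))
  out <- sweep(pW, 2L, t[colnames(pW)], ">=") * 1L
  dimnames(out) <- dimnames(pW)
  out
}

#' Closed-form metrics of a size-k random prediction
#'
#' A predictor marking k of n types positive uniformly at random at each
#' of the positions, against an average of m experimentally positive types
#' per position, has E[TP] = k m / n per position, hence
#' accuracy = (E[TP] + (n - m - k + E[TP])) / n,
#' precision = E[TP]/k, recall = E[TP]/m,
#' specificity = (n - m - k + E[TP]) / (n - m).
#'
#' @param n_positions number of interface positions (enters only the
#'   Monte-Carlo cross-check scale, not the expectations).
#' @param n_types number of amino-acid types n.
#' @param mean_positives mean positives per position m.
#' @param k_predicted predicted positives per position k.
#' @return list with accuracy, precision, recall, specificity.
#' @export
random_baseline <- function(n_positions = 24, n_types = 20,
                            mean_positives = 5.7, k_predicted = 5.7) {
  n <- n_types
  m <- mean_positives
  k <- k_predicted
  if (k > n || m > n || k < 0 || m < 0) stop("k and m must lie in [0, n]")
  etp <- k * m / n
  list(accuracy = (etp + (n - m - k + etp)) / n,
       precision = etp / k,
       recall = etp / m,
       specificity = (n - m - k + etp) / (n - m))
}

#' Rank the 20 amino acids by activation margin at each position
#'
#' @param activation matrix (positions x types) of pW - t margins.
#' @return Integer matrix of ranks 1..n_types per position (1 = best);
#'   ties broken alphabetically by type.
#' @export
rank_amino_acids <- function(activation) {
  out <- activation
  for (j in seq_len(nrow(activation))) {
    ord <- order(-activation[j, ], colnames(activation))
    out[j, ord] <- seq_len(ncol(activation))
  }
  storage.mode(out) <- "integer"
  out
}

#' Rank of the native residue at each position
#'
#' @param ranks rank matrix from \code{\link{rank_amino_acids}}.
#' @param native named character vector (position -> native 1-letter
#'   code).
#' @return Named integer vector of native ranks.
#' @export
rank_of_native <- function(ranks, native) {
  pos <- intersect(rownames(ranks), names(native))
  stats::setNames(ranks[cbind(match(pos, rownames(ranks)),
                              match(native[pos], colnames(ranks)))], pos)
}

#' Distribution of predicted ranks by interface class
#'
#' @param ranks named integer vector of per-position native ranks.
#' @param classes named character vector of core/rim labels for the same
#'   positions.
#' @param n_types number of rank bins.
#' @return data.frame rank x class percentage table (each class sums to
#'   100) plus the uniform reference (100 / n_types per rank).
#' @export
ranking_distribution <- function(ranks, classes, n_types = 20L) {
  pos <- intersect(names(ranks), names(classes))
  stopifnot(length(pos) > 0L)
  cls <- unique(classes[pos])
  out <- data.frame(rank = seq_len(n_types))
  for (cl in cls) {
    r <- ranks[pos][classes[pos] == cl]
    h <- table(factor(r, levels = seq_len(n_types)))
    out[[cl]] <- 100 * as.numeric(h) / length(r)
  }
  out$random <- 100 / n_types
  out
}

#' Per-position report of experimental and predicted preferences
#'
#' Left column: experimentally positive types sorted by W descending.
#' Right column: predicted-positive types sorted by activation margin
#' pW - t descending (ties alphabetical); true positives flagged.
#'
#' @param pW,deltaW,W aligned (positions x types) matrices.
#' @param t per-type thresholds.
#' @param position position label (row name).
#' @return list with \code{experimental} and \code{predicted} data.frames.
#' @export
report_position <- function(pW, deltaW, W, t, position) {
  stopifnot(position %in% rownames(pW))
  margin <- pW[position, ] - t[colnames(pW)]
  dpw <- (pW[position, ] >= t[colnames(pW)]) * 1L
  exp_pos <- names(which(deltaW[position, ] == 1))
  exp_df <- data.frame(aa = exp_pos, W = W[position, exp_pos],
                       stringsAsFactors = FALSE)
  exp_df <- exp_df[order(-exp_df$W, exp_df$aa), , drop = FALSE]
  pred_pos <- names(which(dpw == 1))
  pred_df <- data.frame(aa = pred_pos, margin = margin[pred_pos],
                        pW = pW[position, pred_pos],
                        true_positive = pred_pos %in% exp_pos,
                        stringsAsFactors = FALSE)
  pred_df <- pred_df[order(-pred_df$margin, pred_df$aa), , drop = FALSE]
  rownames(exp_df) <- rownames(pred_df) <- NULL
  list(experimental = exp_df, predicted = pred_df)
}
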