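# Total Reading Score: two-class multivariate-Gaussian classifier over the
# twelve retained reading parameters.

#' The twelve screening parameters
#'
#' Column names of the parameter vector fed to the total-score classifier,
#' for the basic-text configuration: the ex-Gaussian tail tau, the three
#' saccade-length quartiles, refixations R, fixation count Fix, word classes
#' F0 and Fge2, and the four gaze-difficulty bins. (F1 is excluded: it is
#' fully determined by F0 and Fge2.)
#'
#' @param bins Named list of length bins; the names supply the X columns.
#' @return Character vector of 12 column names.
#' @export
trs_parameters <- function(bins = radar_text_bins("basic")) {
  c("tau", "q25", "q50", "q75", "R", "Fix", "F0", "Fge2", names(bins))
}

#' Bin definitions of the built-in texts
#' @param text `"basic"` or `"easy"`.
#' @return Named list of `c(min_L, max_L)` ranges.
#' @export
radar_text_bins <- function(text = c("basic", "easy")) {
  text <- match.arg(text)
  if (text == "basic")
    list(X_le3 = c(1, 3), X_45 = c(4, 5), X_67 = c(6, 7), X_ge8 = c(8, Inf))
  else
    list(X_le3 = c(1, 3), X_4 = c(4, 4), X_5 = c(5, 5), X_ge6 = c(6, Inf))
}

#' Standardise parameter vectors
#'
#' Standardises each parameter to zero mean and unit SD using statistics
#' from the training set only ((P - mu)/sigma normalisation).
#'
#' @param x Numeric matrix or data.frame of parameter vectors (rows =
#'   participants).
#' @param stats List with `center` and `scale` (from a fitted model); if
#'   NULL, computed from `x`.
#' @return List: `x` (standardised matrix), `center`, `scale`.
#' @export
normalize_params <- function(x, stats = NULL) {
  x <- as.matrix(x)
  if (is.null(stats)) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
  } else {
    center <- stats$center; scale <- stats$scale
  }
  if (any(!is.finite(scale)) || any(scale <= 0))
    stop("zero or non-finite SD in normalization: ",
         paste(colnames(x)[!is.finite(scale) | scale <= 0], collapse = ", "))
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' Fit the Total Reading Score classifier
#'
#' Fits a two-class multivariate-Gaussian model on parameter vectors: after
#' standardising all training vectors, each class gets its sample mean and a
#' shrunk covariance \eqn{\hat\Sigma = (1-w) S + w\,\mathrm{diag}(S)} (plus a
#' tiny ridge for numerical definiteness). The Total Reading Score of a
#' vector v is the posterior probability of the control class,
#' \eqn{\pi_c g_c(v) / (\pi_c g_c(v) + \pi_d g_d(v))}, evaluated in log
#' space; scores above 0.5 classify as control, below as dyslexic.
#'
#' `trs()` is generic: the formula method expects `group ~ .` style input
#' with a two-level grouping factor (levels containing "control"/"dyslexic"
#' or the first level taken as control).
#'
#' @param x Parameter matrix/data.frame (rows = participants), or a formula.
#' @param group Factor or character vector of class labels.
#' @param shrinkage Covariance shrinkage weight w, between 0 and 1.
#' @param priors Named class priors, summing to 1.
#' @param data data.frame for the formula method.
#' @param ... Passed on between methods.
#' @return Object of class `trs`: class means and covariances on the
#'   standardised scale, Cholesky factors, normalisation statistics, priors,
#'   shrinkage, training scores.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60, 0), 20), matrix(rnorm(60, 2), 20))
#' colnames(x) <- c("a", "b", "c")
#' g <- rep(c("control", "dyslexic"), each = 20)
#' fit <- trs(x, g)
#' predict(fit, x[1:3, ])
#' @export
trs <- function(x, ...) UseMethod("trs")

#' @rdname trs
#' @export
trs.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  group <- mf[[1]]
  pred <- mf[, -1, drop = FALSE]
  trs.default(pred, group, ...)
}

#' @rdname trs
#' @export
trs.default <- function(x, group, shrinkage = 0.2,
                        priors = c(control = 0.5, dyslexic = 0.5), ...) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("parameter vectors must be complete and finite")
  group <- .as_group(group)
  stopifnot(nrow(x) == length(group), abs(sum(priors) - 1) < 1e-8,
            shrinkage >= 0, shrinkage <= 1)
  if (min(table(group)) < 2) stop("need at least 2 participants per class")

  norm <- normalize_params(x)
  z <- norm$x
  fit_class <- function(cls) {
    zi <- z[group == cls, , drop = FALSE]
    mu <- colMeans(zi)
    S <- stats::cov(zi)
    Sh <- (1 - shrinkage) * S + shrinkage * diag(diag(S), ncol(z))
    # ridge floor keeps the shrunk covariance positive definite even when a
    # count parameter is (near) constant within a class
    Sh <- Sh + diag(1e-6 * mean(diag(Sh)) + 1e-12, ncol(z))
    ch <- tryCatch(chol(Sh), error = function(e)
      stop("singular covariance for class ", cls,
           " after shrinkage; increase `shrinkage`"))
    list(mean = mu, cov = Sh, chol = ch,
         logdet = 2 * sum(log(diag(ch))))
  }
  model <- structure(list(classes = c("control", "dyslexic"),
                          control = fit_class("control"),
                          dyslexic = fit_class("dyslexic"),
                          priors = priors, shrinkage = shrinkage,
                          center = norm$center, scale = norm$scale,
                          parameters = colnames(x),
                          n = c(control = sum(group == "control"),
                                dyslexic = sum(group == "dyslexic"))),
                     class = "trs")
  model$training <- data.frame(group = group,
                               score = trs_score(model, x),
                               stringsAsFactors = FALSE)
  model
}

.as_group <- function(group) {
  g <- as.character(group)
  gl <- tolower(g)
  if (all(gl %in% c("control", "dyslexic"))) return(gl)
  lev <- unique(g)
  if (length(lev) != 2) stop("group must have exactly two classes")
  ifelse(g == lev[1], "control", "dyslexic")
}

.log_gauss <- function(z, cls) {
  d <- length(cls$mean)
  diff <- sweep(z, 2, cls$mean)
  u <- backsolve(cls$chol, t(diff), transpose = TRUE)
  -0.5 * (d * log(2 * pi) + cls$logdet + colSums(u^2))
}

#' Total Reading Score of parameter vectors
#'
#' Posterior probability of the control class under a fitted [trs()] model,
#' computed in log space so extreme vectors never produce NaN.
#'
#' @param model A fitted `trs` object.
#' @param x Parameter matrix/data.frame (raw scale, same columns as
#'   training).
#' @return Numeric vector of scores in (0, 1).
#' @export
trs_score <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(model$parameters) && !is.null(colnames(x)))
    x <- x[, model$parameters, drop = FALSE]
  z <- normalize_params(x, stats = list(center = model$center,
                                        scale = model$scale))$x
  lc <- .log_gauss(z, model$control) + log(model$priors[["control"]])
  ld <- .log_gauss(z, model$dyslexic) + log(model$priors[["dyslexic"]])
  # score = exp(lc) / (exp(lc) + exp(ld)), stably
  1 / (1 + exp(pmin(pmax(ld - lc, -745), 745)))
}

#' @export
print.trs <- function(x, ...) {
  cat(sprintf("Total Reading Score model: %d parameters, n = %d control / %d dyslexic, shrinkage %.2f\n",
              length(x$parameters), x$n[["control"]], x$n[["dyslexic"]],
              x$shrinkage))
  if (!is.null(x$training)) {
    acc <- mean((x$training$score > 0.5) == (x$training$group == "control"))
    cat(sprintf("Training (resubstitution) accuracy: %.1f%%\n", 100 * acc))
  }
  invisible(x)
}

#' @export
summary.trs <- function(object, ...) {
  sep <- (object$control$mean - object$dyslexic$mean)
  out <- data.frame(parameter = object$parameters,
                    control_mean = object$center +
                      object$scale * object$control$mean,
                    dyslexic_mean = object$center +
                      object$scale * object$dyslexic$mean,
                    std_separation = sep)
  rownames(out) <- NULL
  structure(list(model = object, table = out), class = "summary.trs")
}

#' @export
print.summary.trs <- function(x, ...) {
  print(x$model)
  cat("\nClass means (raw scale) and standardised separation:\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' @export
coef.trs <- function(object, ...) {
  rbind(control = object$center + object$scale * object$control$mean,
        dyslexic = object$center + object$scale * object$dyslexic$mean)
}

#' @export
#' @rdname trs_score
#' @param object A fitted `trs` model.
#' @param newdata Parameter vectors to score.
#' @param type `"score"` for the posterior probability of control,
#'   `"class"` for the 0.5-threshold label.
#' @param ... Unused; for method consistency.
predict.trs <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  s <- trs_score(object, newdata)
  if (type == "score") s else ifelse(s > 0.5, "control", "dyslexic")
}

#' @export
simulate.trs <- function(object, nsim = 1, seed = NULL,
                         n_per_class = c(control = 10, dyslexic = 10), ...) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function(cls, n) {
    d <- length(cls$mean)
    z <- matrix(stats::rnorm(n * d), n, d) %*% cls$chol
    z <- sweep(z, 2, cls$mean, "+")
    sweep(sweep(z, 2, object$scale, "*"), 2, object$center, "+")
  }
  out <- lapply(seq_len(nsim), function(k) {
    x <- rbind(draw(object$control, n_per_class[["control"]]),
               draw(object$dyslexic, n_per_class[["dyslexic"]]))
    colnames(x) <- object$parameters
    list(x = x, group = rep(c("control", "dyslexic"), n_per_class))
  })
  if (nsim == 1) out[[1]] else out
}

#' @export
plot.trs <- function(x, ...) {
  if (is.null(x$training)) stop("no training scores stored")
  g <- x$training$group
  graphics::plot(seq_along(g), x$training$score,
                 col = ifelse(g == "control", "dodgerblue3", "firebrick3"),
                 pch = 19, ylim = c(0, 1), xlab = "participant",
                 ylab = "Total Reading Score p(control | parameters)", ...)
  graphics::abline(h = 0.5, lty = 2)
  graphics::legend("right", legend = c("control", "dyslexic"), pch = 19,
                   col = c("dodgerblue3", "firebrick3"), bty = "n")
  invisible(x)
}

#' Leave-one-out ("circular") validation of the TRS classifier
#'
#' For each participant in turn, the normalisation statistics and the
#' two-class Gaussian model are refitted on the remaining participants and
#' the held-out vector is scored; sensitivity is the dyslexic recall,
#' specificity the control recall, at the 0.5 score threshold.
#'
#' @inheritParams trs.default
#' @return Object of class `trs_cv`: data.frame `scores` (participant row,
#'   group, score, predicted), sensitivity, specificity, accuracy.
#' @export
trs_loocv <- function(x, group, shrinkage = 0.2,
                      priors = c(control = 0.5, dyslexic = 0.5)) {
  x <- as.matrix(x)
  group <- .as_group(group)
  n <- nrow(x)
  score <- numeric(n)
  for (i in seq_len(n)) {
    fit <- trs.default(x[-i, , drop = FALSE], group[-i],
                       shrinkage = shrinkage, priors = priors)
    score[i] <- trs_score(fit, x[i, , drop = FALSE])
  }
  predicted <- ifelse(score > 0.5, "control", "dyslexic")
  sens <- mean(predicted[group == "dyslexic"] == "dyslexic")
  spec <- mean(predicted[group == "control"] == "control")
  structure(list(scores = data.frame(row = seq_len(n), group = group,
                                     score = score, predicted = predicted,
                                     stringsAsFactors = FALSE),
                 sensitivity = sens, specificity = spec,
                 accuracy = mean(predicted == group)),
            class = "trs_cv")
}

#' @export
print.trs_cv <- function(x, ...) {
  cat(sprintf("Leave-one-out validation (n = %d): accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              nrow(x$scores), 100 * x$accuracy, 100 * x$sensitivity,
              100 * x$specificity))
  invisible(x)
}

#' Principal components of normalised parameter vectors
#'
#' Eigen-decomposition of the sample covariance of the standardised
#' parameter vectors; returns the projections onto the maximum- and
#' minimum-variance components, a 2-D view in which the two reader groups
#' separate.
#'
#' @param x Parameter matrix/data.frame.
#' @return List: `pc_first`, `pc_last` (projections), `sdev` (all component
#'   SDs), `rotation`.
#' @export
pca_projection <- function(x) {
  z <- normalize_params(x)$x
  p <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  k <- ncol(p$x)
  list(pc_first = p$x[, 1], pc_last = p$x[, k], sdev = p$sdev,
       rotation = p$rotation)
}
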