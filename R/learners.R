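# Learner registry. Each learner is fitted on a labelled predictor table and
# exposes scores in [0,1] via predict(); all are deterministic given a seed.
#
#   sre      envelope membership scored 1/0
#   linear   additive logistic regression on standardized predictors
#   flexible random-forest tree committee
#   smooth   spline additive logistic model (GAM)

learner_registry <- function() c("sre", "linear", "flexible", "smooth")

#' Fit one registered learner
#'
#' @param name one of `"sre"`, `"linear"`, `"flexible"`, `"smooth"`.
#' @param train data frame of predictor columns plus a `label` factor with
#'   levels `presence`, `pseudo_absence` (both present).
#' @param predictors predictor column names; defaults to all columns except
#'   `label` and the coordinate bookkeeping columns.
#' @param seed integer seed (tree committee and any other stochastic fit).
#' @param sre_q trim quantile for the `"sre"` learner's envelope.
#' @return An `sdm_learner` with a `predict()` method returning scores in
#'   \[0,1\].
#' @export
fit_learner <- function(name, train, predictors = NULL, seed = 1L,
                        sre_q = 0.025) {
  if (!name %in% learner_registry())
    stop("unknown learner '", name, "'; registry: ",
         paste(learner_registry(), collapse = ", "))
  if (is.null(predictors))
    predictors <- setdiff(names(train), c("label", "row", "col", "x", "y"))
  if (!"label" %in% names(train) || nlevels(droplevels(train$label)) < 2)
    stop("degenerate training data: both classes are required")
  X <- as.matrix(train[, predictors, drop = FALSE])
  y <- train$label == "presence"
  set.seed(seed)
  fit <- switch(
    name,
    sre = {
      b <- apply(X[y, , drop = FALSE], 2, stats::quantile,
                 probs = c(sre_q, 1 - sre_q), names = FALSE)
      env <- structure(list(bounds = data.frame(variable = predictors,
                                                lower = b[1, ], upper = b[2, ],
                                                row.names = NULL),
                            q = sre_q),
                       class = "sre_envelope")
      list(envelope = env)
    },
    linear = {
      mu <- colMeans(X); sd <- apply(X, 2, stats::sd)
      sd[sd == 0] <- 1
      Z <- scale(X, mu, sd)
      df <- data.frame(Z, y = y)
      list(mu = mu, sd = sd,
           glm = suppressWarnings(stats::glm(y ~ ., data = df,
                                             family = stats::binomial())))
    },
    flexible = {
      list(rf = randomForest::randomForest(
        x = as.data.frame(X), y = factor(y, levels = c(FALSE, TRUE)),
        ntree = 500))
    },
    smooth = {
      df <- data.frame(X, y = y)
      k <- vapply(predictors,
                  function(p) min(4L, length(unique(X[, p])) - 1L), 1L)
      usable <- predictors[k >= 3]
      rhs <- if (length(usable)) {
        paste(sprintf("s(%s, k = %d)", usable, k[usable]), collapse = " + ")
      } else "1"
      list(gam = mgcv::gam(stats::as.formula(paste("y ~", rhs)),
                           data = df, family = stats::binomial(),
                           method = "REML"))
    })
  structure(list(name = name, predictors = predictors, fit = fit, seed = seed),
            class = "sdm_learner")
}

#' Score new data with a fitted learner
#'
#' @param object an `sdm_learner`.
#' @param newdata data frame or matrix containing the learner's predictors.
#' @param ... unused.
#' @return Numeric scores in \[0,1\], `NA` for incomplete rows.
#' @export
predict.sdm_learner <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$predictors, drop = FALSE])
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  if (!any(ok)) return(out)
  Xk <- X[ok, , drop = FALSE]
  s <- switch(
    object$name,
    sre = as.numeric(in_envelope(object$fit$envelope, Xk)),
    linear = {
      Z <- scale(Xk, object$fit$mu, object$fit$sd)
      as.numeric(stats::predict(object$fit$glm, newdata = as.data.frame(Z),
                                type = "response"))
    },
    flexible = stats::predict(object$fit$rf, newdata = as.data.frame(Xk),
                              type = "prob")[, "TRUE"],
    smooth = as.numeric(stats::predict(object$fit$gam,
                                       newdata = as.data.frame(Xk),
                                       type = "response")))
  out[ok] <- pmin(pmax(s, 0), 1)
  out
}

#' @export
print.sdm_learner <- function(x, ...) {
  cat("<sdm_learner> '", x$name, "' on ", length(x$predictors),
      " predictor(s)\n", sep = "")
  invisible(x)
}
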