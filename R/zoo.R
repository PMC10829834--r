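#' Base-learner registry for the stacked ensemble
#'
#' The aging clock stacks a zoo of heterogeneous regressors per view.
#' Each learner is identified by a short name; [fit_base_learner()] and
#' [predict_base_learner()] provide a uniform fit/predict surface so the
#' stacking code never touches library-specific interfaces.
#'
#' Available learners:
#' \describe{
#'   \item{lr}{ordinary least squares}
#'   \item{lasso, ridge, enet}{glmnet with alpha 1, 0 and 0.5; lambda chosen
#'     by internal 5-fold cross-validation on the learner's training data}
#'   \item{bridge}{Bayesian ridge regression (evidence maximization)}
#'   \item{knn}{k-nearest-neighbour regression (k = 5, Euclidean)}
#'   \item{svml, svmr}{support vector regression, linear / radial kernel}
#'   \item{tree}{CART regression tree}
#'   \item{rf}{random forest (ranger, 150 trees)}
#'   \item{gbt}{gradient-boosted regression trees (xgboost)}
#' }
#'
#' @return `zoo_registry()` returns the character vector of learner names;
#'   `default_zoo()` the default selection used by [fit_ensemble()].
#' @export
zoo_registry <- function() {
  c("lr", "lasso", "ridge", "bridge", "enet", "knn",
    "svml", "svmr", "tree", "rf", "gbt")
}

#' @rdname zoo_registry
#' @export
default_zoo <- function() {
  # a diverse but fast subset: four linear-family and three tree-family
  # learners; the remaining registry members can be requested explicitly
  c("lr", "lasso", "ridge", "enet", "tree", "rf", "gbt")
}

#' Fit one base learner
#'
#' @param name learner name from [zoo_registry()].
#' @param x numeric matrix (samples x features), already standardized by the
#'   caller.
#' @param y numeric response (age in years).
#' @param seed integer seed controlling any stochastic component.
#' @param lambda optional fixed glmnet penalty; when `NULL` the glmnet
#'   learners select lambda by internal cross-validation.
#' @return an object of class `gc_learner` carrying the fitted model.
#' @export
fit_base_learner <- function(name, x, y, seed = 1L, lambda = NULL) {
  name <- match.arg(name, zoo_registry())
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  fit <- switch(name,
    lr = {
      co <- stats::lm.fit(cbind(1, x), y)$coefficients
      co[is.na(co)] <- 0
      list(coef = co)
    },
    lasso = fit_glmnet_learner(x, y, alpha = 1, seed, lambda),
    ridge = fit_glmnet_learner(x, y, alpha = 0, seed, lambda),
    enet = fit_glmnet_learner(x, y, alpha = 0.5, seed, lambda),
    bridge = fit_bayes_ridge(x, y),
    knn = list(x = x, y = y, k = min(5L, nrow(x))),
    svml = e1071::svm(x = x, y = y, kernel = "linear", scale = FALSE),
    svmr = e1071::svm(x = x, y = y, kernel = "radial", scale = FALSE),
    tree = {
      df <- as.data.frame(x)
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "anova",
                   control = rpart::rpart.control(xval = 0))
    },
    rf = ranger::ranger(x = x, y = y, num.trees = 150, num.threads = 1,
                        seed = seed, respect.unordered.factors = TRUE),
    gbt = xgboost::xgboost(x, y, nrounds = 80, max_depth = 3,
                           learning_rate = 0.1, nthreads = 1,
                           seed = seed, verbosity = 0)
  )
  structure(list(name = name, fit = fit, features = colnames(x)),
            class = "gc_learner")
}

fit_glmnet_learner <- function(x, y, alpha, seed, lambda) {
  if (!is.null(lambda)) {
    m <- glmnet::glmnet(x, y, alpha = alpha, lambda = lambda)
    return(list(model = m, lambda = lambda))
  }
  foldid <- fold_assignments(nrow(x), k = 5, seed = seed)
  cv <- glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid)
  list(model = cv$glmnet.fit, lambda = cv$lambda.min)
}

# Bayesian ridge by evidence maximization (MacKay's iterative update of the
# prior precision alpha and noise precision beta); returns posterior-mean
# coefficients on the given scale.
fit_bayes_ridge <- function(x, y, max_iter = 50, tol = 1e-6) {
  n <- nrow(x); p <- ncol(x)
  xm <- colMeans(x); ym <- mean(y)
  xc <- sweep(x, 2, xm); yc <- y - ym
  s <- svd(xc)
  d2 <- s$d^2
  uty <- crossprod(s$u, yc)
  alpha <- 1; beta <- 1 / max(stats::var(yc), 1e-8)
  for (i in seq_len(max_iter)) {
    coef_d <- s$d * uty / (d2 + alpha / beta)
    gamma <- sum(d2 / (d2 + alpha / beta))
    w2 <- max(sum(coef_d^2), 1e-12)
    fitted <- s$u %*% coef_d
    sse <- sum((yc - fitted)^2)
    alpha_new <- gamma / w2
    beta_new <- max(n - gamma, 1e-6) / max(sse, 1e-12)
    if (abs(alpha_new - alpha) < tol * alpha && abs(beta_new - beta) < tol * beta) {
      alpha <- alpha_new; beta <- beta_new
      break
    }
    alpha <- alpha_new; beta <- beta_new
  }
  ridge_coef <- s$v %*% (s$d * uty / (d2 + alpha / beta))
  list(coef = c(ym - sum(xm * ridge_coef), ridge_coef))
}

#' @rdname fit_base_learner
#' @param object a fitted `gc_learner`.
#' @param newx matrix of samples to predict, same columns as training.
#' @export
predict_base_learner <- function(object, newx) {
  stopifnot(inherits(object, "gc_learner"))
  newx <- as.matrix(newx)
  storage.mode(newx) <- "double"
  colnames(newx) <- object$features
  name <- object$name
  fit <- object$fit
  if (name %in% c("lr", "bridge")) {
    return(drop(cbind(1, newx) %*% fit$coef))
  }
  if (name %in% c("lasso", "ridge", "enet")) {
    return(drop(glmnet::predict.glmnet(fit$model, newx, s = fit$lambda)))
  }
  if (name == "knn") {
    return(knn_predict(fit$x, fit$y, newx, fit$k))
  }
  if (name %in% c("svml", "svmr")) {
    return(unname(stats::predict(fit, newx)))
  }
  if (name == "tree") {
    return(unname(stats::predict(fit, as.data.frame(newx))))
  }
  if (name == "rf") {
    return(stats::predict(fit, data = newx, num.threads = 1)$predictions)
  }
  if (name == "gbt") {
    return(stats::predict(fit, newx))
  }
  stop("unknown learner: ", name)
}

# chunked Euclidean kNN regression; O(n_train * n_new) memory per chunk
knn_predict <- function(xtr, ytr, xnew, k, chunk = 2000L) {
  n <- nrow(xnew)
  out <- numeric(n)
  tr2 <- rowSums(xtr^2)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    xn <- xnew[idx, , drop = FALSE]
    d2 <- outer(tr2, rowSums(xn^2), "+") - 2 * xtr %*% t(xn)
    out[idx] <- apply(d2, 2, function(col) {
      mean(ytr[order(col)[seq_len(k)]])
    })
  }
  out
}

# deterministic balanced fold assignment
fold_assignments <- function(n, k, seed) {
  r <- rng_local(seed)
  on.exit(r())
  sample(rep_len(seq_len(k), n))
}

# set the RNG to a reproducible state and return a restorer
rng_local <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# derive a stage-specific 31-bit seed from a master seed
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(offset)) %% 2147483647L)
}
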