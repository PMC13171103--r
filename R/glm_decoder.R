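#' L2-penalized logistic regression
#'
#' Maximizes the Bernoulli log-likelihood with an L2 penalty on the
#' non-intercept weights by Newton iterations (IRLS), converging when the
#' gradient norm falls below `tol`. The small default penalty guarantees a
#' finite unique optimum on linearly separable bootstrap samples.
#'
#' @param X trials x dims feature matrix.
#' @param y binary outcomes (0/1 or logical), both classes present.
#' @param l2 penalty strength (default 1e-3).
#' @param max_iter maximum Newton iterations (default 100).
#' @param tol gradient-norm convergence tolerance (default 1e-8).
#' @return List of class `"logistic_model"`: `weights` (intercept first),
#'   `converged`.
#' @export
fit_logistic <- function(X, y, l2 = 1e-3, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("training outcomes are single-class")
  Xa <- cbind(1, X)
  d <- ncol(Xa)
  pen <- diag(c(0, rep(l2, d - 1)), d)
  w <- numeric(d)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% w)
    p <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(Xa, y - p)) - pen %*% w
    if (sqrt(sum(grad^2)) < tol) {
      converged <- TRUE
      break
    }
    wts <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Xa, Xa * wts) + pen
    step <- solve(H, grad)
    w <- w + drop(step)
  }
  structure(list(weights = drop(w), converged = converged), class = "logistic_model")
}

#' Predict binary choices from a logistic model
#'
#' Label 1 (correct) iff the model probability exceeds 0.5, i.e. the linear
#' score is strictly positive; an exact 0.5 maps to 0.
#'
#' @param model a `logistic_model`.
#' @param X trials x dims feature matrix.
#' @return Integer 0/1 labels.
#' @export
predict_choice <- function(model, X) {
  score <- drop(cbind(1, as.matrix(X)) %*% model$weights)
  as.integer(score > 0)
}

#' Bootstrap logistic decoding of trial outcomes
#'
#' Per iteration: subsample a fraction of neurons, balance trials by
#' adjacent upsampling, compute 5 s pre-choice means, refit PCA to the
#' leading components on the subsample, split trials 90/10 stratified by
#' outcome, fit the penalized logistic model on the training split, and
#' score held-out accuracy at the 0.5 threshold. Iterations whose training
#' split is single-class or whose held-out split is empty are invalid.
#'
#' @inheritParams decode_bootstrap
#' @param l2 penalty passed to [fit_logistic()].
#' @return List of class `"glm_decode"`: `per_iteration` (valid, accuracy)
#'   and `summary`.
#' @export
choice_decode_bootstrap <- function(session, n_iterations = 1000,
                                    neuron_fraction = 0.4, train_fraction = 0.9,
                                    balance_target = 31, n_components = 3,
                                    l2 = 1e-3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- prechoice_means(session)
  N <- ncol(M)
  n_trials <- nrow(M)
  y_all <- as.integer(session$trials$outcome == "correct")
  if (length(unique(y_all)) < 2) stop("session has single-class outcomes")
  n_sub <- max(n_components, floor(neuron_fraction * N))
  res <- data.frame(iteration = seq_len(n_iterations), valid = FALSE,
                    accuracy = NA_real_)
  for (b in seq_len(n_iterations)) {
    idx_n <- sample.int(N, n_sub)
    bal <- balance_trials(n_trials, balance_target)
    y <- y_all[bal]
    out <- tryCatch({
      X <- pca_scores(M[bal, idx_n, drop = FALSE], n_components)
      train <- sort(unlist(lapply(unique(y), function(cl) {
        ix <- which(y == cl)
        sample(ix, floor(train_fraction * length(ix)))
      })))
      heldout <- setdiff(seq_len(nrow(X)), train)
      if (!length(heldout) || length(unique(y[train])) < 2) {
        list(valid = FALSE, accuracy = NA_real_)
      } else {
        model <- fit_logistic(X[train, , drop = FALSE], y[train], l2 = l2)
        pred <- predict_choice(model, X[heldout, , drop = FALSE])
        list(valid = TRUE, accuracy = mean(pred == y[heldout]))
      }
    }, error = function(e) list(valid = FALSE, accuracy = NA_real_))
    res$valid[b] <- out$valid
    res$accuracy[b] <- out$accuracy
  }
  ok <- res[res$valid, , drop = FALSE]
  summary <- list(
    n_valid = nrow(ok), failure_rate = 1 - nrow(ok) / n_iterations,
    accuracy_mean = mean(ok$accuracy),
    accuracy_median = stats::median(ok$accuracy),
    accuracy_sem = stats::sd(ok$accuracy) / sqrt(nrow(ok))
  )
  structure(list(per_iteration = res, summary = summary), class = "glm_decode")
}
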