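# Chemometrics stage for metabolite bucket tables: orthogonal signal
# correction, Pareto scaling, PLS-DA by NIPALS latent-variable extraction,
# seven-fold Q2 cross-validation, permutation validation, VIP scores and
# discriminant-bucket selection with Kruskal-Wallis confirmation.
#
# Matrices are samples x buckets throughout this file (the chemometrics
# convention); use t(tcm$values) when coming from a time_course.

#' Pareto scaling
#'
#' Column-wise centering followed by division by the square root of the
#' standard deviation, the usual compromise between no scaling and unit
#' variance for spectral buckets. Zero-variance columns are centered only
#' and flagged.
#'
#' @param X numeric matrix, samples x buckets.
#' @return list: `values` (scaled matrix), `center`, `divisor`, `constant`
#'   (logical flag per column).
#' @export
pareto_scale <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  constant <- s == 0
  div <- sqrt(s)
  div[constant] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, div, "/")
  list(values = Xs, center = mu, divisor = div, constant = constant)
}

.class_indicator <- function(y) {
  y <- factor(y)
  Y <- stats::model.matrix(~ 0 + y)
  colnames(Y) <- levels(y)
  attr(Y, "assign") <- NULL
  attr(Y, "contrasts") <- NULL
  Y
}

#' Orthogonal signal correction
#'
#' Removes from a (centered) data matrix `n_osc` components of structured
#' variation orthogonal to the class structure: each iteration starts from
#' the dominant principal-component score of the current matrix, projects
#' out the class-indicator column space (so the score is exactly orthogonal
#' to every class column), recomputes the weight vector by regressing the
#' matrix on the orthogonalised score, re-orthogonalises the resulting
#' score, and deflates the matrix by the component. With `n_osc = 0` the
#' input is returned unchanged.
#'
#' @param X numeric matrix, samples x buckets.
#' @param classes class labels (e.g. ZT), one per row.
#' @param n_osc number of components to remove.
#' @return list: `values` (filtered matrix, original offset restored),
#'   `scores`, `loadings`, `weights` (one column per removed component),
#'   `center`.
#' @export
osc_filter <- function(X, classes, n_osc = 1) {
  X <- as.matrix(X)
  y <- factor(classes)
  if (nlevels(y) < 2) stop("need >= 2 classes")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (n_osc == 0)
    return(list(values = X, scores = NULL, loadings = NULL, weights = NULL,
                center = mu))
  Yq <- qr(cbind(1, .class_indicator(y)))
  Ts <- Ps <- Ws <- list()
  for (i in seq_len(n_osc)) {
    sv <- svd(Xc, nu = 1, nv = 0)
    t0 <- sv$u[, 1] * sv$d[1]
    t_orth <- qr.resid(Yq, t0)
    w <- crossprod(Xc, t_orth)
    w <- w / sqrt(sum(w^2))
    tt <- qr.resid(Yq, Xc %*% w)       # removed score exactly Y-orthogonal
    p <- crossprod(Xc, tt) / sum(tt^2)
    Xc <- Xc - tcrossprod(tt, p)
    Ts[[i]] <- tt; Ps[[i]] <- p; Ws[[i]] <- w
  }
  list(values = sweep(Xc, 2, mu, "+"),
       scores = do.call(cbind, Ts), loadings = do.call(cbind, Ps),
       weights = do.call(cbind, Ws), center = mu)
}

#' Fit a PLS-DA model by NIPALS
#'
#' Regresses a centered class-indicator matrix on the (scaled) data matrix
#' by iterative NIPALS extraction: for each component, `w = X'u`
#' (normalised), `t = Xw`, `c = Y't / t't`, `u = Yc / c'c`, iterated until
#' the score converges, then X and Y are deflated by the component. Scores
#' of different components are mutually orthogonal and the per-component
#' explained Y sum-of-squares is recorded, giving cumulative R2X and R2Y.
#'
#' @param X numeric matrix, samples x buckets, already scaled as desired
#'   (the fit centers columns internally).
#' @param classes class labels, one per row.
#' @param A number of latent components.
#' @param tol relative convergence tolerance on the score vector.
#' @param max_iter iteration cap per component; exceeding it is an error
#'   naming the component.
#' @return object of class `plsda`: weights `W` (unit columns), scores `T`,
#'   X-loadings `P`, Y-loadings `C`, `ssy` (per-component explained Y SS),
#'   cumulative `r2x`/`r2y`, coefficient matrix `B`, centers, class levels.
#' @export
plsda_fit <- function(X, classes, A, tol = 1e-10, max_iter = 1e4) {
  X <- as.matrix(X)
  y <- factor(classes)
  Y0 <- .class_indicator(y)
  y_center <- colMeans(Y0)
  x_center <- colMeans(X)
  Xd <- sweep(X, 2, x_center)
  Yd <- sweep(Y0, 2, y_center)
  ssx0 <- sum(Xd^2); ssy0 <- sum(Yd^2)
  if (A < 1) stop("A must be >= 1")
  p <- ncol(Xd)
  W <- P <- matrix(0, p, A, dimnames = list(colnames(Xd), NULL))
  C <- matrix(0, ncol(Yd), A, dimnames = list(levels(y), NULL))
  Tm <- matrix(0, nrow(Xd), A, dimnames = list(rownames(Xd), NULL))
  ssy <- r2x <- r2y <- numeric(A)
  for (a in seq_len(A)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    t_old <- rep(Inf, nrow(Xd))
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      nw <- sqrt(sum(w^2))
      if (nw == 0) stop("degenerate component ", a, ": zero weight vector")
      w <- w / nw
      tt <- Xd %*% w
      cc <- crossprod(Yd, tt) / sum(tt^2)
      u <- Yd %*% cc / sum(cc^2)
      if (sqrt(sum((tt - t_old)^2)) <= tol * sqrt(sum(tt^2))) break
      t_old <- tt
      if (it == max_iter)
        stop("NIPALS did not converge for component ", a)
    }
    pp <- crossprod(Xd, tt) / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, pp)
    ssy[a] <- sum(tt^2) * sum(cc^2)
    Yd <- Yd - tcrossprod(tt, cc)
    W[, a] <- w; P[, a] <- pp; C[, a] <- cc; Tm[, a] <- tt
    r2x[a] <- 1 - sum(Xd^2) / ssx0
    r2y[a] <- 1 - sum(Yd^2) / ssy0
  }
  Wstar <- W %*% solve(crossprod(P, W))
  B <- tcrossprod(Wstar, C)
  structure(list(A = A, W = W, T = Tm, P = P, C = C, ssy = ssy,
                 r2x = r2x, r2y = r2y, B = B,
                 x_center = x_center, y_center = y_center,
                 levels = levels(y), classes = y),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat("PLS-DA: ", x$A, " components, ", length(x$levels), " classes (",
      paste(x$levels, collapse = ", "), ")\n", sep = "")
  cat("  cumulative R2X: ", paste(signif(x$r2x, 3), collapse = " "), "\n", sep = "")
  cat("  cumulative R2Y: ", paste(signif(x$r2y, 3), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Predict classes or responses from a PLS-DA model
#'
#' @param object a `plsda` model.
#' @param newdata samples x buckets matrix on the same scale as the
#'   training data.
#' @param type `"class"` for labels, `"response"` for the predicted
#'   indicator values.
#' @param ncomp number of components to use (default all fitted).
#' @param ... unused.
#' @return factor of class labels or a numeric response matrix.
#' @export
predict.plsda <- function(object, newdata, type = c("class", "response"),
                          ncomp = object$A, ...) {
  type <- match.arg(type)
  Xn <- sweep(as.matrix(newdata), 2, object$x_center)
  if (ncomp < object$A) {
    W <- object$W[, seq_len(ncomp), drop = FALSE]
    P <- object$P[, seq_len(ncomp), drop = FALSE]
    C <- object$C[, seq_len(ncomp), drop = FALSE]
    B <- tcrossprod(W %*% solve(crossprod(P, W)), C)
  } else B <- object$B
  Yhat <- sweep(Xn %*% B, 2, object$y_center, "+")
  colnames(Yhat) <- object$levels
  if (type == "response") return(Yhat)
  factor(object$levels[max.col(Yhat, ties.method = "first")],
         levels = object$levels)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a ssy_a * w_aj^2 / sum_a ssy_a)` with unit-norm
#' weight vectors; the squared scores average to 1 over the `p` variables.
#'
#' @param model a `plsda` model with total explained Y SS > 0.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda"))
  if (sum(model$ssy) <= 0) stop("degenerate model: no explained Y variance")
  p <- nrow(model$W)
  v <- sqrt(p * as.numeric(model$W^2 %*% model$ssy) / sum(model$ssy))
  names(v) <- rownames(model$W)
  v
}

.stratified_folds <- function(y, n_folds, seed) {
  y <- factor(y)
  fold <- integer(length(y))
  with_seed(seed, {
    offset <- 0L
    for (lev in levels(y)) {
      idx <- sample(which(y == lev))
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

#' Cross-validated Q2 of a PLS-DA model
#'
#' Stratified n-fold cross-validation: for each fold the model is refit on
#' the training samples and the held-out rows of the class-indicator matrix
#' are predicted; `Q2(a) = 1 - PRESS(a) / SS` where PRESS aggregates the
#' squared prediction error over folds at `a` components and SS is the
#' error of predicting the training class means. The chosen component
#' count follows the sequential rule: keep adding components while the Q2
#' increment is at least `q2_increment`. A validity heuristic flags models
#' with `R2Y > 0.5` and `Q2 > 0.4`.
#'
#' @param X samples x buckets matrix (scaled as desired).
#' @param classes class labels.
#' @param A_max maximum number of components to evaluate.
#' @param n_folds number of folds (classes are spread over folds so every
#'   training set keeps all classes).
#' @param seed integer seed for the fold assignment.
#' @param q2_increment minimum Q2 gain to accept one more component.
#' @return list of class `plsda_cv`: `q2` (per component count), `A`
#'   (chosen), `press`, `folds`, `r2y` (of the full-data fit at `A`),
#'   `valid`.
#' @export
q2_crossval <- function(X, classes, A_max, n_folds = 7, seed = 1,
                        q2_increment = 0.01) {
  X <- as.matrix(X)
  y <- factor(classes)
  if (n_folds > nrow(X)) stop("more folds than samples")
  fold <- .stratified_folds(y, n_folds, seed)
  Yind <- .class_indicator(y)
  press <- numeric(A_max)
  ss <- 0
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- fold == f
    if (nlevels(droplevels(y[tr])) < nlevels(y))
      stop("a training fold lost a class; use fewer folds")
    fit <- plsda_fit(X[tr, , drop = FALSE], y[tr], A = A_max)
    Yte <- Yind[te, , drop = FALSE]
    ss <- ss + sum(sweep(Yte, 2, colMeans(Yind[tr, , drop = FALSE]))^2)
    for (a in seq_len(A_max)) {
      Yhat <- predict(fit, X[te, , drop = FALSE], type = "response", ncomp = a)
      press[a] <- press[a] + sum((Yte - Yhat)^2)
    }
  }
  q2 <- 1 - press / ss
  inc <- diff(c(0, q2))
  A <- 0L
  for (a in seq_len(A_max)) {
    if (inc[a] >= q2_increment) A <- a else break
  }
  if (A == 0L) A <- 1L
  full <- plsda_fit(X, y, A = A)
  res <- list(q2 = q2, A = A, press = press, folds = fold,
              r2y = full$r2y[A],
              valid = full$r2y[A] > 0.5 && q2[A] > 0.4)
  class(res) <- "plsda_cv"
  res
}

#' @export
print.plsda_cv <- function(x, ...) {
  cat("PLS-DA cross-validation: Q2 =",
      paste(signif(x$q2, 3), collapse = " "),
      "| chosen A =", x$A, "| R2Y =", signif(x$r2y, 3),
      "| valid:", x$valid, "\n")
  invisible(x)
}

#' Permutation validation of a PLS-DA model
#'
#' Refits the model `n_perm` times with permuted class labels and reports
#' empirical p-values `(1 + #{perm >= observed}) / (n_perm + 1)` for both
#' Q2 (cross-validated, same fold scheme) and R2Y.
#'
#' @param X samples x buckets matrix.
#' @param classes class labels.
#' @param A fixed number of components.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param n_folds folds for the Q2 of each refit.
#' @return list: `q2_observed`, `r2_observed`, `p_q2`, `p_r2`,
#'   `q2_perm`, `r2_perm`.
#' @export
permutation_validation <- function(X, classes, A, n_perm = 200, seed = 1,
                                   n_folds = 7) {
  X <- as.matrix(X)
  y <- factor(classes)
  cv <- q2_crossval(X, y, A_max = A, n_folds = n_folds, seed = seed)
  q2_obs <- cv$q2[A]
  r2_obs <- plsda_fit(X, y, A = A)$r2y[A]
  q2_perm <- r2_perm <- numeric(n_perm)
  with_seed(seed + 1L, {
    for (i in seq_len(n_perm)) {
      yp <- sample(y)
      cvp <- tryCatch(
        q2_crossval(X, yp, A_max = A, n_folds = n_folds,
                    seed = seed + 1L + i),
        error = function(e) NULL)
      q2_perm[i] <- if (is.null(cvp)) -Inf else cvp$q2[A]
      r2_perm[i] <- tryCatch(plsda_fit(X, yp, A = A)$r2y[A],
                             error = function(e) -Inf)
    }
  })
  list(q2_observed = q2_obs, r2_observed = r2_obs,
       p_q2 = (1 + sum(q2_perm >= q2_obs)) / (n_perm + 1),
       p_r2 = (1 + sum(r2_perm >= r2_obs)) / (n_perm + 1),
       q2_perm = q2_perm, r2_perm = r2_perm)
}

#' Select discriminant buckets by VIP and Kruskal-Wallis
#'
#' A bucket is selected when its VIP is strictly greater than `vip_cut`
#' and its Kruskal-Wallis p across the classes is below `kw_alpha`.
#'
#' @param vips named VIP vector (from [vip_scores()]).
#' @param X samples x buckets matrix of the (unscaled or scaled) bucket
#'   values used for the rank test.
#' @param classes class labels.
#' @param vip_cut VIP threshold (strict).
#' @param kw_alpha Kruskal-Wallis threshold.
#' @return data.frame: `bucket`, `vip`, `kw_p`, `selected`.
#' @export
select_discriminant <- function(vips, X, classes, vip_cut = 1.5,
                                kw_alpha = 0.05) {
  X <- as.matrix(X)
  stopifnot(length(vips) == ncol(X))
  y <- factor(classes)
  kw_p <- vapply(seq_len(ncol(X)), function(j)
    kruskal_wallis(split(X[, j], y))$p, numeric(1))
  data.frame(bucket = if (!is.null(names(vips))) names(vips) else colnames(X),
             vip = as.numeric(vips), kw_p = kw_p,
             selected = vips > vip_cut & kw_p < kw_alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hotelling 95 percent ellipse for a score plot
#'
#' Semi-axes of the T2 confidence ellipse for a pair of score vectors:
#' `sqrt(var(t_i) * 2 (n - 1) / (n - 2) * qF(level; 2, n - 2))`.
#'
#' @param model a `plsda` model.
#' @param comps length-2 component indices.
#' @param level confidence level.
#' @return list: `semi_axes` (length 2), `comps`, `level`.
#' @export
hotelling_ellipse <- function(model, comps = c(1, 2), level = 0.95) {
  stopifnot(inherits(model, "plsda"), length(comps) == 2,
            max(comps) <= model$A)
  n <- nrow(model$T)
  lim <- 2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2)
  v <- apply(model$T[, comps, drop = FALSE], 2, stats::var)
  list(semi_axes = sqrt(v * lim), comps = comps, level = level)
}
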