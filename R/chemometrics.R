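#' Mean-centre and autoscale a data matrix
#'
#' Standard chemometric preprocessing: every column is mean-centred and
#' scaled to unit variance.  Constant columns cannot be autoscaled; they
#' are dropped and recorded.
#'
#' @param X Numeric matrix (samples x variables), >= 2 rows.
#' @param tol Standard deviations below `tol` count as constant.
#' @return List with `scaled` (matrix), `means`, `sds` (named vectors for
#'   the retained columns) and `dropped` (labels of constant columns).
#' @export
autoscale <- function(X, tol = 1e-12) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("autoscaling needs at least two rows")
  means <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > tol
  if (!any(keep)) stop("all columns are constant; nothing to autoscale")
  dropped <- colnames(X)[!keep]
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, means[keep], "-"),
              2, sds[keep], "/")
  list(scaled = Xs, means = means[keep], sds = sds[keep], dropped = dropped)
}

apply_scaling <- function(X, means, sds) {
  X <- as.matrix(X)
  if (!is.null(names(means)) && !is.null(colnames(X)))
    X <- X[, names(means), drop = FALSE]
  if (ncol(X) != length(means))
    stop("column mismatch between data and scaling parameters")
  sweep(sweep(X, 2, means, "-"), 2, sds, "/")
}

#' Principal component analysis of an autoscaled matrix
#'
#' Thin wrapper over the singular value decomposition for the prescreening
#' step: components are ordered by decreasing explained variance and
#' loadings are orthonormal.  If the matrix rank is below the requested
#' number of components, the available components are returned with a
#' message.
#'
#' @param Xs Autoscaled matrix (see [autoscale()]).
#' @param n_components Number of components requested.
#' @return List with `scores`, `loadings`, `explained` (fractions of total
#'   variance) and `n_components` actually returned.
#' @export
pca_profiles <- function(Xs, n_components = 2L) {
  Xs <- as.matrix(Xs)
  max_comp <- min(nrow(Xs) - 1L, ncol(Xs))
  if (n_components > max_comp)
    stop("n_components exceeds min(rows - 1, cols)")
  sv <- svd(Xs)
  ev <- sv$d^2
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  k <- min(n_components, rank)
  if (k < n_components)
    message("rank deficiency: returning ", k, " of ", n_components,
            " requested components")
  list(scores = Xs %*% sv$v[, seq_len(k), drop = FALSE],
       loadings = sv$v[, seq_len(k), drop = FALSE],
       explained = ev[seq_len(k)] / sum(ev),
       n_components = k)
}

#' PLS1 regression by sequential latent-variable extraction
#'
#' Fits a single-response partial least squares regression on an already
#' autoscaled predictor block and a centred response, extracting
#' components one at a time: the weight vector is the normalised
#' covariance `X'y`, scores are `X w`, x- and y-loadings are least-squares
#' projections on the score, and both blocks are deflated before the next
#' component.  Regression coefficients on the scaled space are composed as
#' `B = W (P'W)^-1 q`.
#'
#' @param Xs Autoscaled predictor matrix.
#' @param yc Centred response vector.
#' @param n_components Number of latent variables (<= rank of `Xs`).
#' @return A `pls1_fit` list with `coefficients` (per variable, scaled
#'   space), `weights`, `x_loadings`, `y_loadings`, `scores`,
#'   `n_components` and the per-component cumulative `r_squared` on the
#'   training data.
#' @export
fit_pls1 <- function(Xs, yc, n_components) {
  Xs <- as.matrix(Xs); yc <- as.numeric(yc)
  stopifnot(nrow(Xs) == length(yc))
  if (stats::sd(yc) == 0) stop("response has zero variance")
  p <- ncol(Xs)
  n_components <- min(n_components, p, nrow(Xs) - 1L)
  W <- P <- matrix(0, p, n_components)
  Q <- numeric(n_components)
  Tm <- matrix(0, nrow(Xs), n_components)
  Xd <- Xs; yd <- yc
  r2 <- numeric(n_components)
  ss_tot <- sum(yc^2)
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { n_components <- a - 1L; break }
    w <- w / nw
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(Xd, t_)) / tt
    q_ <- sum(yd * t_) / tt
    Xd <- Xd - tcrossprod(t_, p_)
    yd <- yd - t_ * q_
    W[, a] <- w; P[, a] <- p_; Q[a] <- q_; Tm[, a] <- t_
    r2[a] <- 1 - sum(yd^2) / ss_tot
  }
  if (n_components == 0L) stop("no usable PLS component (X'y is zero)")
  W <- W[, seq_len(n_components), drop = FALSE]
  P <- P[, seq_len(n_components), drop = FALSE]
  Q <- Q[seq_len(n_components)]
  Tm <- Tm[, seq_len(n_components), drop = FALSE]
  B <- W %*% solve(crossprod(P, W), Q)
  structure(list(coefficients = drop(B), weights = W, x_loadings = P,
                 y_loadings = Q, scores = Tm,
                 n_components = n_components,
                 r_squared = r2[seq_len(n_components)]),
            class = "pls1_fit")
}

# Coefficients for every component count 1..A in one pass (columns = A).
pls1_coef_path <- function(Xs, yc, max_components) {
  fit <- fit_pls1(Xs, yc, max_components)
  A <- fit$n_components
  out <- matrix(0, ncol(Xs), A)
  for (a in seq_len(A)) {
    W <- fit$weights[, seq_len(a), drop = FALSE]
    P <- fit$x_loadings[, seq_len(a), drop = FALSE]
    out[, a] <- W %*% solve(crossprod(P, W), fit$y_loadings[seq_len(a)])
  }
  out
}

#' Full cross-validation of a PLS1 model
#'
#' Leave-one-out ("full") cross-validation by default, or k segments
#' (consecutive, or random under a seed).  For every candidate component
#' count the root mean square error of cross-validation (RMSECV) is
#' computed from the held-out predictions; the suggested component count
#' is the RMSECV minimum, relaxed toward fewer components by the
#' one-standard-error parsimony rule.
#'
#' @param X Raw predictor matrix (autoscaling is refitted inside every
#'   training split).
#' @param y Response vector.
#' @param max_components Largest component count to try.
#' @param segments Number of segments; `NULL` (default) means leave-one-out.
#' @param segment_type `"consecutive"` or `"random"`.
#' @param seed Seed used when `segment_type = "random"`.
#' @return A `pls_cv` list: `rmsecv` (per component count), `suggested`
#'   (component count), `press` (matrix of held-out squared errors),
#'   `sub_coefficients` (segments x variables x components array, scaled
#'   space) and `segments` (the index sets).
#' @export
cross_validate <- function(X, y, max_components, segments = NULL,
                           segment_type = c("consecutive", "random"),
                           seed = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  segment_type <- match.arg(segment_type)
  n <- nrow(X)
  if (is.null(segments)) {
    seg <- as.list(seq_len(n))
  } else {
    idx <- seq_len(n)
    if (segment_type == "random") {
      if (!is.null(seed)) {
        idx <- withr_seed(seed, sample(n))
      } else idx <- sample(n)
    }
    seg <- split(idx, cut(seq_len(n), segments, labels = FALSE))
  }
  M <- length(seg)
  if (M < 2L) stop("cross-validation needs at least two segments")
  max_components <- min(max_components, ncol(X), n - max(lengths(seg)) - 1L)
  press <- matrix(NA_real_, n, max_components)
  subB <- array(NA_real_, c(M, ncol(X), max_components),
                dimnames = list(NULL, colnames(X), NULL))
  for (m in seq_len(M)) {
    out <- seg[[m]]
    Xtr <- X[-out, , drop = FALSE]; ytr <- y[-out]
    if (stats::sd(ytr) == 0) stop("a training segment has zero response variance")
    sc <- autoscale(Xtr)
    if (length(sc$dropped) > 0)
      stop("constant predictor inside a cross-validation segment: ",
           paste(sc$dropped, collapse = ", "))
    ym <- mean(ytr)
    Bpath <- pls1_coef_path(sc$scaled, ytr - ym, max_components)
    A <- ncol(Bpath)
    Xout <- apply_scaling(X[out, , drop = FALSE], sc$means, sc$sds)
    for (a in seq_len(A)) {
      pred <- ym + drop(Xout %*% Bpath[, a])
      press[out, a] <- (y[out] - pred)^2
      subB[m, , a] <- Bpath[, a]
    }
  }
  rmsecv <- sqrt(colMeans(press, na.rm = TRUE))
  best <- which.min(rmsecv)
  # one-standard-error rule (delta method on the mean squared error)
  se_best <- stats::sd(press[, best]) / sqrt(n) / (2 * rmsecv[best])
  suggested <- which(rmsecv <= rmsecv[best] + se_best)[1]
  structure(list(rmsecv = rmsecv, suggested = suggested, press = press,
                 sub_coefficients = subB, segments = seg),
            class = "pls_cv")
}

withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Martens' uncertainty test
#'
#' Jackknife significance test of PLS regression coefficients.  The
#' stability of each variable is the spread of its coefficient over the
#' cross-validation submodels around the full-model value:
#' `s2_b = sum_m (b_m - b)^2 * (M - 1) / M` over the `M` submodels.  A
#' variable is significant at the 5 percent level when the interval
#' `b +/- t(0.975, M - 1) * s_b` excludes zero (its uncertainty limits do
#' not cross the zero line).
#'
#' @param full_coefficients Full-model coefficient vector (scaled space).
#' @param sub_coefficients Matrix (submodels x variables) of submodel
#'   coefficients at the same component count.
#' @param conf_level Confidence level (default 0.95).
#' @return An `uncertainty_result` data frame with columns `variable`,
#'   `coefficient`, `jackknife_sd`, `t_crit`, `significant`.
#' @export
martens_uncertainty <- function(full_coefficients, sub_coefficients,
                                conf_level = 0.95) {
  B <- as.matrix(sub_coefficients)
  M <- nrow(B)
  if (M < 3L) stop("Martens' test needs at least three submodels")
  b <- as.numeric(full_coefficients)
  if (length(b) != ncol(B))
    stop("full model and submodels disagree on the number of variables")
  s2 <- colSums(sweep(B, 2, b, "-")^2) * (M - 1) / M
  s <- sqrt(s2)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = M - 1)
  vars <- colnames(B)
  if (is.null(vars)) vars <- paste0("V", seq_along(b))
  structure(data.frame(variable = vars, coefficient = b, jackknife_sd = s,
                       t_crit = tcrit,
                       significant = abs(b) > tcrit * s,
                       stringsAsFactors = FALSE),
            class = c("uncertainty_result", "data.frame"))
}

#' Variable reduction by cross-validated PLS and Martens' test
#'
#' Composition of [cross_validate()] and [martens_uncertainty()]: a PLS1
#' model is cross-validated on the candidate variables, the component
#' count is selected, submodel coefficients at that count feed the
#' jackknife test, and only significant variables survive.  Survivors are
#' returned ordered by decreasing coefficient magnitude; the coefficient
#' sign indicates the marker direction (positive = associated with high
#' response).
#'
#' @param X Predictor matrix over the candidate variables.
#' @param y Response vector.
#' @param max_components Largest component count to try.
#' @param conf_level Confidence level of the jackknife test.
#' @return List with `survivors` (data frame `variable`, `coefficient`,
#'   ordered by `abs(coefficient)`), `uncertainty` (full test table),
#'   `suggested_components` and `rmsecv`.
#' @export
reduce_variables <- function(X, y, max_components = min(ncol(X), 10L),
                             conf_level = 0.95) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("variable reduction needs at least two candidates")
  cv <- cross_validate(X, y, max_components)
  a <- cv$suggested
  sc <- autoscale(X)
  full <- fit_pls1(sc$scaled, y - mean(y), a)
  b <- stats::setNames(full$coefficients, colnames(sc$scaled))
  unc <- martens_uncertainty(b, cv$sub_coefficients[, , a], conf_level)
  surv <- unc[unc$significant, c("variable", "coefficient")]
  if (nrow(surv) == 0L)
    stop(paste0("no variable passed the uncertainty test; a model on these ",
                "candidates is not supported"))
  surv <- surv[order(-abs(surv$coefficient)), ]
  rownames(surv) <- NULL
  list(survivors = surv, uncertainty = unc,
       suggested_components = a, rmsecv = cv$rmsecv)
}
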