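#' Analysis of covariance with a region main effect
#'
#' Least-squares fit of \code{response ~ group + covariates} with partial
#' (type II, default) or marginal (type III) sums of squares, F statistics
#' and p values per term, plus adjusted group means evaluated at the
#' covariate means. This is the design used to compare standardized PD or
#' MPD between two continents while holding climate and topography fixed.
#'
#' @param response Numeric response per unit (e.g. standardized PD).
#' @param group Region/continent label per unit (coerced to factor).
#' @param covariates Data frame or matrix of numeric covariates (e.g. six
#'   PC scores and log10 elevation range); \code{NULL} reduces the model to
#'   a one-way ANOVA.
#' @param ss_type \code{"II"} (default) or \code{"III"}.
#' @return An object of class \code{"pd_ancova"}: list with \code{table}
#'   (term, ss, df, statistic, p), \code{error_ss}, \code{error_df},
#'   \code{adjusted_means} and the underlying \code{fit}.
#' @export
ancova <- function(response, group, covariates = NULL,
                   ss_type = c("II", "III")) {
  ss_type <- match.arg(ss_type)
  n <- length(response)
  covariates <- if (is.null(covariates)) {
    as.data.frame(matrix(numeric(0), nrow = n, ncol = 0))
  } else {
    as.data.frame(covariates)
  }
  if (nrow(covariates) != n || length(group) != n) {
    stop("response, group and covariates must describe the same units")
  }
  if (anyNA(response) || anyNA(covariates) || anyNA(group)) {
    stop("missing values are not allowed")
  }
  p <- ncol(covariates) + 1L
  if (n <= p + 2L) stop("too few units (n = ", n, ") for ", p, " terms")
  dat <- data.frame(.y = response, .group = factor(group), covariates)
  fit <- if (ss_type == "III") {
    stats::lm(.y ~ ., data = dat,
              contrasts = list(.group = "contr.sum"))
  } else {
    stats::lm(.y ~ ., data = dat)
  }
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  A <- car::Anova(fit, type = if (ss_type == "II") 2 else 3)
  A <- as.data.frame(A)
  keep <- !rownames(A) %in% c("(Intercept)", "Residuals")
  tab <- data.frame(
    term = sub("^\\.group$", "region", rownames(A)[keep]),
    ss = A[keep, "Sum Sq"], df = A[keep, "Df"],
    statistic = A[keep, "F value"], p = A[keep, "Pr(>F)"],
    stringsAsFactors = FALSE
  )
  err <- A["Residuals", ]
  nd <- data.frame(.group = factor(levels(dat$.group),
                                   levels = levels(dat$.group)))
  if (ncol(covariates)) {
    nd <- cbind(nd, as.list(colMeans(covariates)))
    names(nd)[-1L] <- names(covariates)
  }
  adj <- stats::setNames(stats::predict(fit, newdata = nd),
                         levels(dat$.group))
  structure(
    list(table = tab, error_ss = err[["Sum Sq"]], error_df = err[["Df"]],
         adjusted_means = adj, ss_type = ss_type, fit = fit),
    class = "pd_ancova"
  )
}

#' @export
print.pd_ancova <- function(x, ...) {
  cat("ANCOVA (type", x$ss_type, "SS)\n")
  tab <- x$table
  tab$ss <- signif(tab$ss, 4)
  tab$statistic <- signif(tab$statistic, 4)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat("Error: SS =", signif(x$error_ss, 4), ", df =", x$error_df, "\n")
  cat("Adjusted means:",
      paste(names(x$adjusted_means), signif(x$adjusted_means, 5),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.pd_ancova <- function(object, ...) stats::coef(object$fit)

#' @export
residuals.pd_ancova <- function(object, ...) stats::residuals(object$fit)

# Row-standardized spatial weights from point coordinates. k-nearest
# neighbours are symmetrized (i~j if either is among the other's k nearest)
# so the weight matrix has real eigenvalues via the similar symmetric form
# D^-1/2 A D^-1/2.
spatial_weights <- function(coords, k = 8, scheme = c("knn", "idw")) {
  scheme <- match.arg(scheme)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  if (scheme == "knn") {
    if (k >= n) stop("'k' must be smaller than the number of units")
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nn <- order(D[i, -i])[seq_len(k)]
      idx <- seq_len(n)[-i][nn]
      A[i, idx] <- 1
    }
    A <- pmax(A, t(A))
  } else {
    if (any(D[upper.tri(D)] == 0)) stop("duplicate coordinates in 'idw' scheme")
    A <- 1 / D
    diag(A) <- 0
  }
  rs <- rowSums(A)
  if (any(rs == 0)) stop("weight matrix has all-zero row(s)")
  list(A = A, W = A / rs, rs = rs, scheme = scheme, k = k)
}

connected_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(A[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  cur
}

#' Spatial autoregressive error model
#'
#' Maximum-likelihood fit of \eqn{y = X\beta + u}, \eqn{u = \lambda W u +
#' \varepsilon}, with a row-standardized spatial weight matrix built from
#' unit centroids (symmetrized k-nearest-neighbour by default, inverse
#' distance as an alternative, or a user-supplied matrix). The spatial
#' error coefficient is profiled out with the eigenvalue form of the
#' log-determinant; coefficients are the GLS solution at the ML
#' \eqn{\hat\lambda}.
#'
#' @param response Numeric response per unit.
#' @param covariates Data frame or matrix of covariates.
#' @param coords Two-column matrix/data frame of unit centroids.
#' @param k Number of nearest neighbours (default 8).
#' @param scheme \code{"knn"} or \code{"idw"}.
#' @param W Optional pre-built (non-negative, zero-diagonal) weight matrix;
#'   it is row-standardized internally and overrides \code{coords}.
#' @return An object of class \code{"sar_error"}: list with \code{lambda},
#'   \code{coefficients}, \code{sigma2}, \code{loglik}, \code{residuals}
#'   (raw, \eqn{y - X\hat\beta}), \code{residuals_filtered} (spatially
#'   filtered innovations) and fit metadata.
#' @export
sar_error <- function(response, covariates, coords = NULL, k = 8,
                      scheme = c("knn", "idw"), W = NULL) {
  scheme <- match.arg(scheme)
  y <- as.numeric(response)
  X <- cbind(`(Intercept)` = 1, as.matrix(as.data.frame(covariates)))
  n <- length(y)
  if (nrow(X) != n) stop("response and covariates must have equal length")
  if (n < 20L) stop("spatial error model needs at least 20 units, got ", n)
  if (is.null(W)) {
    if (is.null(coords)) stop("either 'coords' or 'W' must be supplied")
    sw <- spatial_weights(coords, k = k, scheme = scheme)
  } else {
    W <- as.matrix(W)
    if (nrow(W) != n || ncol(W) != n) stop("'W' must be n x n")
    if (any(W < 0)) stop("'W' must be non-negative")
    rs <- rowSums(W)
    if (any(rs == 0)) stop("weight matrix has all-zero row(s)")
    sw <- list(A = W, W = W / rs, rs = rs, scheme = "user", k = NA)
  }
  if (connected_components(sw$A) > 1L) {
    warning("spatial weight graph is disconnected")
  }
  # eigenvalues of row-standardized W via the similar symmetric matrix
  if (max(abs(sw$A - t(sw$A))) < 1e-12) {
    S <- sw$A / sqrt(outer(sw$rs, sw$rs))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  } else {
    ev <- Re(eigen(sw$W, only.values = TRUE)$values)
  }
  Wm <- sw$W
  Wy <- Wm %*% y
  WX <- Wm %*% X
  prof <- function(lambda) {
    ys <- y - lambda * Wy
    Xs <- X - lambda * WX
    fit <- stats::lm.fit(Xs, ys)
    rss <- sum(fit$residuals^2)
    -n / 2 * (log(2 * pi) + 1) - n / 2 * log(rss / n) +
      sum(log(1 - lambda * ev))
  }
  lo <- if (min(ev) < 0) 1 / min(ev) + 1e-6 else -1 + 1e-6
  hi <- 1 / max(ev) - 1e-6
  opt <- stats::optimize(prof, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  lambda <- opt$maximum
  if (lambda - lo < 1e-4 || hi - lambda < 1e-4) {
    warning("lambda estimate at the boundary of the search interval (",
            signif(lo, 3), ", ", signif(hi, 3), ")")
  }
  ys <- y - lambda * Wy
  Xs <- X - lambda * WX
  gls <- stats::lm.fit(Xs, ys)
  beta <- stats::setNames(gls$coefficients, colnames(X))
  raw <- as.numeric(y - X %*% beta)
  filt <- as.numeric(ys - Xs %*% beta)
  structure(
    list(lambda = lambda, coefficients = beta,
         sigma2 = sum(filt^2) / n, loglik = opt$objective,
         residuals = raw, residuals_filtered = filt,
         fitted = as.numeric(X %*% beta), n = n,
         weights = list(scheme = sw$scheme, k = sw$k),
         eigen_range = range(ev)),
    class = "sar_error"
  )
}

#' @export
print.sar_error <- function(x, ...) {
  cat("Spatial autoregressive error model (", x$weights$scheme,
      " weights), n = ", x$n, "\n", sep = "")
  cat("lambda =", signif(x$lambda, 4), "; log-likelihood =",
      signif(x$loglik, 6), "\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.sar_error <- function(object, ...) object$coefficients

#' @export
residuals.sar_error <- function(object, type = c("raw", "filtered"), ...) {
  type <- match.arg(type)
  if (type == "raw") object$residuals else object$residuals_filtered
}

#' Contrast of regression residuals between two regions
#'
#' Welch two-sample t test on the residuals of a fitted spatial error model,
#' split by region. Answers: after accounting for climate and topography
#' (and spatial autocorrelation), is the response still higher in one
#' region?
#'
#' @param fit A \code{"sar_error"} fit.
#' @param group Region label per unit (exactly two levels, each with at
#'   least two units).
#' @param type Which residuals to contrast: \code{"raw"} (default,
#'   \eqn{y - X\hat\beta}) or \code{"filtered"}.
#' @return A list with \code{statistic}, \code{df}, \code{p.value} and the
#'   per-group residual \code{means}.
#' @export
residual_contrast <- function(fit, group, type = c("raw", "filtered")) {
  stopifnot(inherits(fit, "sar_error"))
  type <- match.arg(type)
  r <- residuals(fit, type = type)
  group <- as.character(group)
  if (length(group) != length(r)) stop("'group' must label every unit")
  levs <- unique(group)
  if (length(levs) != 2L) stop("residual contrast needs exactly two groups")
  x <- r[group == levs[1L]]
  y <- r[group == levs[2L]]
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 units")
  tt <- two_sample_t(x, y, variant = "welch")
  list(statistic = tt$statistic, df = tt$df, p.value = tt$p.value,
       means = stats::setNames(c(mean(x), mean(y)), levs))
}

#' Spearman rank correlation
#'
#' Pearson correlation of ranks, with average ranks for ties.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return The correlation coefficient rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("'x' and 'y' must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for a constant vector")
  }
  stats::cor(x, y, method = "spearman")
}

#' Two-sample t test
#'
#' Welch (default) or pooled-variance two-sample t test, two-sided. When
#' both samples have zero variance and equal means the test is reported as
#' t = 0, p = 1 (a documented convention; \code{stats::t.test} would
#' error); zero variance with different means yields p = 0.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @param variant \code{"welch"} or \code{"pooled"}.
#' @return A list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{estimate} (the two means).
#' @export
two_sample_t <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs >= 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2L,
                p.value = if (eq) 1 else 0,
                estimate = c(mean(x), mean(y))))
  }
  tt <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, estimate = unname(tt$estimate))
}
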