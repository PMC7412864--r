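# NIPALS partial least squares regression of drug-uptake ratios on polymer
# descriptors, with per-component variance bookkeeping, scree-based
# component selection, loading maps and descriptor-response correlation
# profiles. This is the modelling core of the package and is implemented
# from scratch (no PLS library is used).

#' Fit a PLS regression by NIPALS
#'
#' PLS2 regression of `q` responses on `p` descriptors for `n` polymers.
#' Both blocks are autoscaled (centred, unit sample variance) — descriptors
#' span incompatible units, and the variance-share bookkeeping below assumes
#' unit-variance columns. Components are extracted one at a time by the
#' NIPALS inner iteration
#' `u -> w = X'u / ||X'u|| -> t = X w -> q = Y't / t't -> u = Y q / q'q`
#' until the weight vector stabilises, after which both blocks are deflated
#' by the score: `X <- X - t p'`, `Y <- Y - t q'` with `p = X't / t't`.
#' Per-component explained-variance shares are Frobenius-norm fractions of
#' the initial standardized blocks, so the per-component columns sum exactly
#' to the cumulative columns.
#'
#' Each weight vector's largest-magnitude element is made positive, fixing
#' the sign indeterminacy so scores and loadings are reproducible across
#' platforms.
#'
#' @param x Numeric descriptor matrix (n x p), or a `standardized_table`.
#' @param y Numeric response matrix or vector (n x q, q in \{1, 2\} for the
#'   two end-capping agents, though any q >= 1 is accepted). Uptake ratios
#'   should normally be supplied on the log scale (see the vignette).
#' @param ncomp Number of components H, `H <= min(n - 1, p)`.
#' @param tol Convergence tolerance on the change in the weight vector
#'   (default 1e-12).
#' @param max_iter Maximum NIPALS iterations per component (default 500).
#' @return An object of class `pls_model`: standardization constants
#'   (`x_means`, `x_sds`, `y_means`, `y_sds`), `weights` W (p x H),
#'   `x_loadings` P (p x H), `y_loadings` Q (q x H), `scores` T (n x H),
#'   `r2x`, `r2x_cum`, `r2y`, `r2y_cum`, `ncomp`, and the standardized
#'   training blocks `X0`, `Y0`.
#' @export
fit_pls <- function(x, y, ncomp, tol = 1e-12, max_iter = 500L) {
  if (inherits(x, "standardized_table")) x <- x$z_values
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x); p <- ncol(x); q <- ncol(y)
  if (nrow(y) != n) stop("x and y must have the same number of rows")
  if (n < 3L) stop("PLS needs at least 3 polymers")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(n - 1L, p)) {
    stop("ncomp must be in [1, min(n - 1, p)] = [1, ", min(n - 1L, p), "]")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (is.null(colnames(y))) {
    colnames(y) <- if (q == 1L) "y" else paste0("y", seq_len(q))
  }

  x_means <- colMeans(x); x_sds <- apply(x, 2L, stats::sd)
  y_means <- colMeans(y); y_sds <- apply(y, 2L, stats::sd)
  if (any(x_sds == 0)) {
    stop("constant descriptor column(s): ",
         paste(colnames(x)[x_sds == 0], collapse = ", "),
         " (drop via standardize_descriptors first)")
  }
  if (any(y_sds == 0)) stop("constant response column")
  X0 <- sweep(sweep(x, 2L, x_means, "-"), 2L, x_sds, "/")
  Y0 <- sweep(sweep(y, 2L, y_means, "-"), 2L, y_sds, "/")

  ssx0 <- sum(X0^2); ssy0 <- sum(Y0^2)
  X <- X0; Y <- Y0
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp); Tm <- matrix(0, n, ncomp)
  r2x <- numeric(ncomp); r2y <- numeric(ncomp)
  h_fit <- 0L

  for (h in seq_len(ncomp)) {
    ssx_rem <- sum(X^2)
    if (ssx_rem < ssx0 * 1e-24) {
      warning("X exhausted after ", h - 1L,
              " components; truncating (requested ", ncomp, ")")
      break
    }
    u <- Y[, which.max(apply(Y, 2L, stats::var)), drop = FALSE]
    if (sum(u^2) == 0) u <- Y[, 1L, drop = FALSE] + 0  # fully deflated Y
    w_old <- rep(0, p)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- crossprod(X, u)
      nw <- sqrt(sum(w^2))
      if (nw == 0) stop("NIPALS breakdown at component ", h,
                        ": X'u vanished")
      w <- w / nw
      tt <- X %*% w
      qh <- crossprod(Y, tt) / sum(tt^2)
      if (q == 1L) { converged <- TRUE; break }
      u <- Y %*% qh / sum(qh^2)
      if (sqrt(sum((w - w_old)^2)) < tol) { converged <- TRUE; break }
      w_old <- w
    }
    if (!converged) {
      stop("NIPALS did not converge at component ", h,
           " within ", max_iter, " iterations")
    }
    # sign convention: largest-|.| weight element positive
    imax <- which.max(abs(w))
    if (w[imax] < 0) { w <- -w; tt <- -tt; qh <- -qh }
    ph <- crossprod(X, tt) / sum(tt^2)
    X <- X - tt %*% t(ph)
    Y <- Y - tt %*% t(qh)
    W[, h] <- w; P[, h] <- ph; Q[, h] <- qh; Tm[, h] <- tt
    r2x[h] <- sum(tt^2) * sum(ph^2) / ssx0
    r2y[h] <- sum(tt^2) * sum(qh^2) / ssy0
    h_fit <- h
  }
  if (h_fit == 0L) stop("no PLS component could be extracted")
  keep <- seq_len(h_fit)
  dimnames(W) <- list(colnames(x), paste0("comp", seq_len(ncomp)))
  dimnames(P) <- dimnames(W)
  dimnames(Q) <- list(colnames(y), colnames(W))
  dimnames(Tm) <- list(rownames(x), colnames(W))

  structure(
    list(x_means = x_means, x_sds = x_sds,
         y_means = y_means, y_sds = y_sds,
         weights = W[, keep, drop = FALSE],
         x_loadings = P[, keep, drop = FALSE],
         y_loadings = Q[, keep, drop = FALSE],
         scores = Tm[, keep, drop = FALSE],
         r2x = r2x[keep], r2x_cum = cumsum(r2x[keep]),
         r2y = r2y[keep], r2y_cum = cumsum(r2y[keep]),
         ncomp = h_fit,
         X0 = X0, Y0 = Y0),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> NIPALS PLS,", nrow(x$X0), "polymers x",
      ncol(x$X0), "descriptors ->", ncol(x$Y0), "response(s),",
      x$ncomp, "components\n")
  cat(sprintf("  X-R2 cum: %s\n",
              paste(sprintf("%.3f", x$r2x_cum), collapse = " ")))
  cat(sprintf("  Y-R2 cum: %s\n",
              paste(sprintf("%.3f", x$r2y_cum), collapse = " ")))
  invisible(x)
}

# regression coefficients (standardized scales) for the first h components:
# B_h = W_h (P_h' W_h)^{-1} Q_h'
pls_coefficients <- function(model, h) {
  W <- model$weights[, seq_len(h), drop = FALSE]
  P <- model$x_loadings[, seq_len(h), drop = FALSE]
  Q <- model$y_loadings[, seq_len(h), drop = FALSE]
  W %*% solve(crossprod(P, W), t(Q))
}

#' Predict uptake responses from a fitted PLS model
#'
#' Standardizes new descriptor rows with the training constants, applies the
#' h-component regression coefficients, and back-transforms to original
#' response units. `h = 0` predicts the training response means.
#'
#' @param object A `pls_model`.
#' @param newdata Descriptor matrix with the training columns (any order, if
#'   named); defaults to the training matrix.
#' @param h Number of components to use (default all fitted).
#' @param ... Unused.
#' @return Matrix of predictions (rows of `newdata` x responses).
#' @export
predict.pls_model <- function(object, newdata = NULL, h = object$ncomp, ...) {
  h <- as.integer(h)
  if (h < 0L || h > object$ncomp) stop("h must be in [0, ", object$ncomp, "]")
  if (is.null(newdata)) {
    Xs <- object$X0
  } else {
    newdata <- as.matrix(newdata)
    nm <- names(object$x_means)
    if (!is.null(colnames(newdata))) {
      missing_cols <- setdiff(nm, colnames(newdata))
      if (length(missing_cols)) {
        stop("newdata lacks descriptor column(s): ",
             paste(missing_cols, collapse = ", "))
      }
      newdata <- newdata[, nm, drop = FALSE]
    } else if (ncol(newdata) != length(nm)) {
      stop("newdata has ", ncol(newdata), " columns; training had ",
           length(nm))
    }
    Xs <- sweep(sweep(newdata, 2L, object$x_means, "-"),
                2L, object$x_sds, "/")
  }
  q <- length(object$y_means)
  if (h == 0L) {
    out <- matrix(object$y_means, nrow(Xs), q, byrow = TRUE)
  } else {
    B <- pls_coefficients(object, h)
    out <- sweep(sweep(Xs %*% B, 2L, object$y_sds, "*"),
                 2L, object$y_means, "+")
  }
  dimnames(out) <- list(rownames(Xs), names(object$y_means))
  out
}

#' In-sample RMSE scree curve
#'
#' Root-mean-squared prediction error, in standardized response units, over
#' all `n x q` residuals at each component count `h = 1..H`. The curve is
#' nonincreasing; its inflection ("elbow") is one of the two
#' component-selection criteria (see [select_components()]).
#'
#' @param model A `pls_model`.
#' @param x,y Optional evaluation data in original units; default is the
#'   training data.
#' @param cv `"none"` (default, in-sample) or `"loo"`: leave-one-out
#'   refitting of the model at every component count. LOO is informative as
#'   an overfitting diagnostic but is not used for component selection by
#'   default.
#' @return Object of class `scree_curve`: data frame with columns `h`,
#'   `rmse`.
#' @export
rmse_scree <- function(model, x = NULL, y = NULL, cv = c("none", "loo")) {
  stopifnot(inherits(model, "pls_model"))
  cv <- match.arg(cv)
  if (is.null(x) != is.null(y)) stop("supply both x and y, or neither")
  if (cv == "loo") {
    if (!is.null(x)) stop("LOO mode refits on the training data only")
    return(rmse_scree_loo(model))
  }
  if (is.null(y)) {
    Ys <- model$Y0
    newd <- NULL
  } else {
    Ys <- sweep(sweep(as.matrix(y), 2L, model$y_means, "-"),
                2L, model$y_sds, "/")
    newd <- x
  }
  rmse <- vapply(seq_len(model$ncomp), function(h) {
    pred <- predict(model, newdata = newd, h = h)
    preds <- sweep(sweep(pred, 2L, model$y_means, "-"), 2L, model$y_sds, "/")
    sqrt(mean((Ys - preds)^2))
  }, 0)
  structure(data.frame(h = seq_len(model$ncomp), rmse = rmse),
            class = c("scree_curve", "data.frame"))
}

# leave-one-out scree: refit without each row, predict it, pool residuals
# (standardized with the full-model constants so curves are comparable)
rmse_scree_loo <- function(model) {
  X <- sweep(sweep(model$X0, 2L, model$x_sds, "*"), 2L, model$x_means, "+")
  Y <- sweep(sweep(model$Y0, 2L, model$y_sds, "*"), 2L, model$y_means, "+")
  n <- nrow(X)
  H <- model$ncomp
  res2 <- matrix(NA_real_, n, H)
  for (i in seq_len(n)) {
    mi <- fit_pls(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                  ncomp = min(H, n - 2L), max_iter = 10000L)
    for (h in seq_len(mi$ncomp)) {
      pred <- predict(mi, X[i, , drop = FALSE], h = h)
      z <- (Y[i, ] - pred) / model$y_sds
      res2[i, h] <- mean(z^2)
    }
  }
  rmse <- sqrt(colMeans(res2, na.rm = TRUE))
  structure(data.frame(h = seq_len(H), rmse = rmse),
            class = c("scree_curve", "data.frame"))
}

#' Locate the elbow of a decreasing curve
#'
#' The inflection ("knee") of a scree-like curve: the interior index h
#' maximising the discrete second difference
#' `curve[h-1] - 2 curve[h] + curve[h+1]`, i.e. where a steep decline turns
#' into a plateau.
#'
#' @param curve Numeric vector (length >= 3) of a nonincreasing diagnostic,
#'   e.g. RMSE or unexplained variance per component count.
#' @return Integer index of the elbow.
#' @export
scree_elbow <- function(curve) {
  H <- length(curve)
  if (H < 3L) stop("need at least 3 points for an interior elbow")
  interior <- 2L:(H - 1L)
  d2 <- curve[interior - 1L] - 2 * curve[interior] + curve[interior + 1L]
  interior[which.max(d2)]
}

#' Select the number of PLS components
#'
#' Two criteria are computed, mirroring standard chemometric practice for
#' these models: (1) the smallest h whose cumulative X-variance share reaches
#' `threshold` (default 80%), and (2) the scree-plot inflection. The
#' inflection is located with [scree_elbow()] on the unexplained-X-variance
#' curve `1 - r2x_cum`: once the latent chemical structure of the descriptor
#' block is exhausted, per-component X-variance gains collapse, and that kink
#' identifies the effective dimensionality even when the prediction-error
#' curve has already flattened (with one or two responses the RMSE curve
#' levels off at the response rank, well before the descriptor structure is
#' spanned — see the vignette). The RMSE elbow is reported alongside as a
#' diagnostic (`h_elbow_rmse`).
#'
#' The inflection is taken as the selected count — on real polymer libraries
#' the variance rule can demand more components than the data support — and
#' a warning is logged when the selected h falls short of the variance
#' threshold, so both criteria stay visible.
#'
#' @param scree A `scree_curve` from [rmse_scree()].
#' @param r2x_cum Cumulative X-variance shares, one per component.
#' @param threshold Cumulative X-variance threshold (default 0.80).
#' @return Object of class `component_selection`: list with `h_selected`,
#'   `h_elbow` (X-variance inflection), `h_elbow_rmse`, `h_variance` (NA if
#'   the threshold is never reached), `threshold`, `rationale`.
#' @export
select_components <- function(scree, r2x_cum, threshold = 0.80) {
  rmse <- scree$rmse
  H <- length(rmse)
  if (H < 3L) stop("need H >= 3 components for an interior elbow")
  if (length(r2x_cum) != H) stop("r2x_cum length must match the scree curve")
  h_elbow <- scree_elbow(1 - r2x_cum)
  h_elbow_rmse <- scree_elbow(rmse)
  h_variance <- if (any(r2x_cum >= threshold)) {
    which(r2x_cum >= threshold)[1L]
  } else NA_integer_
  h_selected <- h_elbow
  rationale <- sprintf(
    "inflection of the X-variance curve at h=%d (RMSE elbow at h=%d); variance criterion (X-R2 cum >= %.0f%%) gives h=%s",
    h_elbow, h_elbow_rmse, 100 * threshold,
    ifelse(is.na(h_variance), "none", as.character(h_variance)))
  if (is.na(h_variance) || r2x_cum[h_selected] < threshold) {
    warning(sprintf(
      "selected h=%d carries %.0f%% of X variance, below the %.0f%% threshold",
      h_selected, 100 * r2x_cum[h_selected], 100 * threshold))
  }
  structure(list(h_selected = h_selected, h_elbow = h_elbow,
                 h_elbow_rmse = h_elbow_rmse,
                 h_variance = h_variance, threshold = threshold,
                 rationale = rationale),
            class = "component_selection")
}

#' @export
print.component_selection <- function(x, ...) {
  cat("<component_selection>", x$rationale, "\n")
  invisible(x)
}

#' Per-component and cumulative variance table
#'
#' The standard four-column report for a fitted PLS model: per-component and
#' cumulative variance shares of the descriptor block (X-R2) and the response
#' block (Y-R2). Cumulative columns are exact running sums of the
#' per-component columns.
#'
#' @param model A `pls_model`.
#' @return Data frame with columns `h`, `x_r2`, `x_r2_cum`, `y_r2`,
#'   `y_r2_cum`.
#' @export
variance_tables <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  data.frame(h = seq_len(model$ncomp),
             x_r2 = model$r2x, x_r2_cum = model$r2x_cum,
             y_r2 = model$r2y, y_r2_cum = model$r2y_cum)
}

#' Loading map on the first two components
#'
#' Correlation-scaled loading plot ("circle of correlations"): every
#' descriptor and every response is placed at its Pearson correlation with
#' the first two score vectors. Descriptors adjacent to a response on the map
#' drive it positively; diametrically opposite ones drive it negatively;
#' perpendicular ones have little influence. All coordinates lie in
#' `[-1, 1]`.
#'
#' @param model A `pls_model` with at least 2 components.
#' @return Data frame with columns `name`, `role` (`"descriptor"` or
#'   `"response"`), `comp1`, `comp2`.
#' @export
loading_map <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (model$ncomp < 2L) stop("loading map needs at least 2 components")
  t12 <- model$scores[, 1:2, drop = FALSE]
  cx <- stats::cor(model$X0, t12)
  cy <- stats::cor(model$Y0, t12)
  out <- data.frame(
    name = c(rownames(cx), rownames(cy)),
    role = rep(c("descriptor", "response"), c(nrow(cx), nrow(cy))),
    comp1 = c(cx[, 1L], cy[, 1L]),
    comp2 = c(cx[, 2L], cy[, 2L]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Descriptor-response correlation profile
#'
#' Signed importance of each descriptor for each response: the Pearson
#' correlation between the (standardized) descriptor column and the
#' h-component model prediction of the response — the bar-profile view of
#' which polymer characteristics drive uptake and in which direction.
#' Correlating with the observed responses instead is available via
#' `against = "observed"`.
#'
#' @param model A `pls_model`.
#' @param h Components used for the predictions (default all fitted).
#' @param against Correlate descriptors with model predictions (default) or
#'   with the observed responses.
#' @return Data frame with one row per descriptor x response: `descriptor`,
#'   `response`, `correlation`, `degenerate` (TRUE where the prediction was
#'   constant and the correlation is reported as 0).
#' @export
variable_response_correlations <- function(model, h = model$ncomp,
                                           against = c("fitted", "observed")) {
  stopifnot(inherits(model, "pls_model"))
  against <- match.arg(against)
  h <- as.integer(h)
  if (h < 1L || h > model$ncomp) stop("h must be in [1, ", model$ncomp, "]")
  target <- if (against == "fitted") {
    pred <- predict(model, h = h)
    sweep(sweep(pred, 2L, model$y_means, "-"), 2L, model$y_sds, "/")
  } else {
    model$Y0
  }
  X0 <- model$X0
  out <- expand.grid(descriptor = colnames(X0), response = colnames(target),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$correlation <- NA_real_
  out$degenerate <- FALSE
  for (k in seq_len(ncol(target))) {
    tk <- target[, k]
    rows <- out$response == colnames(target)[k]
    if (stats::sd(tk) == 0) {
      out$correlation[rows] <- 0
      out$degenerate[rows] <- TRUE
    } else {
      out$correlation[rows] <- as.numeric(stats::cor(X0, tk))
    }
  }
  out
}

#' Plot an RMSE scree curve
#'
#' @param x A `scree_curve`.
#' @param selection Optional `component_selection` whose chosen h is marked.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scree_curve <- function(x, selection = NULL, ...) {
  graphics::plot(x$h, x$rmse, type = "b", pch = 16,
                 xlab = "number of PLS components",
                 ylab = "RMSE of prediction (standardized)", ...)
  if (!is.null(selection)) {
    graphics::abline(v = selection$h_selected, lty = 2)
  }
  invisible(x)
}

#' Plot a loading map
#'
#' @param map Data frame from [loading_map()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_loading_map <- function(map, ...) {
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 xlab = "component 1", ylab = "component 2", ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th), col = "grey70")
  graphics::abline(h = 0, v = 0, col = "grey85")
  is_y <- map$role == "response"
  graphics::points(map$comp1[!is_y], map$comp2[!is_y], pch = 16,
                   col = "darkgreen")
  graphics::points(map$comp1[is_y], map$comp2[is_y], pch = 17,
                   col = "darkblue")
  graphics::text(map$comp1, map$comp2, map$name, pos = 3, cex = 0.6)
  invisible(map)
}

#' Serialize a PLS model to JSON
#'
#' All matrices are written row-major with named axes, so the document is
#' self-describing and re-loadable.
#'
#' @param model A `pls_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  mat <- function(m) list(rows = rownames(m), cols = colnames(m),
                          values = unname(apply(m, 1L, as.numeric,
                                                simplify = FALSE)))
  doc <- list(
    ncomp = model$ncomp,
    x_means = as.list(model$x_means), x_sds = as.list(model$x_sds),
    y_means = as.list(model$y_means), y_sds = as.list(model$y_sds),
    weights = mat(model$weights), x_loadings = mat(model$x_loadings),
    y_loadings = mat(model$y_loadings), scores = mat(model$scores),
    r2x = model$r2x, r2x_cum = model$r2x_cum,
    r2y = model$r2y, r2y_cum = model$r2y_cum
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
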