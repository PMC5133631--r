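# Reference-based leukocyte deconvolution and the linear epigenetic-age
# clock.

#' Build a cell-type reference profile
#'
#' @param means Matrix of mean beta values, discriminating probes as rows
#'   and cell types as columns; all values in \[0, 1\], at least two cell
#'   types.
#' @return Object of class `ReferenceProfile`.
#' @export
reference_profile <- function(means) {
  if (!is.matrix(means) || ncol(means) < 2)
    stop("reference must be a matrix with at least two cell-type columns")
  if (any(means < 0 | means > 1)) stop("reference means must lie in [0,1]")
  if (is.null(rownames(means)) || is.null(colnames(means)))
    stop("reference needs probe rownames and cell-type colnames")
  structure(list(means = means), class = "ReferenceProfile")
}

#' Estimate leukocyte proportions by constrained least squares
#'
#' For each sample solves `min || beta_sample - R w ||^2` subject to
#' `w >= 0` and `sum(w) <= 1` (the Houseman-style quadratic program,
#' via `quadprog::solve.QP`), then renormalizes to `sum(w) = 1` so the
#' proportions can serve directly as model covariates.
#'
#' @param meth `MethylationMatrix`.
#' @param ref A [reference_profile()].
#' @return Object of class `CellProportions`: list with `proportions`
#'   (samples x cell types, rows summing to 1), `raw` (pre-renormalization
#'   solutions) and `residual` (per-sample residual norm).
#' @export
estimate_cell_proportions <- function(meth, ref) {
  shared <- intersect(rownames(meth$beta), rownames(ref$means))
  if (length(shared) == 0)
    stop("no probes shared between matrix and reference")
  if (length(shared) < 50)
    warning("only ", length(shared), " probes shared with the reference; ",
            "estimates may be unstable")
  R <- ref$means[shared, , drop = FALSE]
  K <- ncol(R)
  if (qr(R)$rank < K)
    warning("reference profiles are collinear (non-identifiable); ",
            "proportions reported with residuals, interpret with care")
  D <- crossprod(R)
  D <- D + diag(1e-10, K)  # ridge for numerical positive definiteness
  # constraints: w_k >= 0 (K rows), -sum(w) >= -1
  A <- cbind(diag(K), -rep(1, K))
  b0 <- c(rep(0, K), -1)
  Y <- meth$beta[shared, , drop = FALSE]
  W <- matrix(NA_real_, ncol(Y), K,
              dimnames = list(colnames(Y), colnames(R)))
  resid <- numeric(ncol(Y))
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    ok <- !is.na(y)
    Rj <- R[ok, , drop = FALSE]
    sol <- quadprog::solve.QP(crossprod(Rj) + diag(1e-10, K),
                              crossprod(Rj, y[ok]), A, b0)
    w <- pmax(sol$solution, 0)
    W[j, ] <- w
    resid[j] <- sqrt(sum((y[ok] - Rj %*% w)^2))
  }
  raw <- W
  s <- rowSums(W)
  s[s == 0] <- 1
  W <- W / s
  structure(list(proportions = W, raw = raw, residual = resid,
                 n_probes = length(shared)),
            class = "CellProportions")
}

#' @exportS3Method base::print
print.CellProportions <- function(x, ...) {
  cat(sprintf("CellProportions: %d samples x %d cell types (%d probes)\n",
              nrow(x$proportions), ncol(x$proportions), x$n_probes))
  invisible(x)
}

#' Define a linear epigenetic-age clock
#'
#' Predicted age is `transform(a0 + sum_j a_j * beta_j)` over the clock's
#' CpGs. No published coefficient set is bundled; coefficients are
#' supplied by the user (or the synthetic generator).
#'
#' @param intercept Clock intercept `a0`.
#' @param weights Named numeric vector of per-probe weights `a_j`.
#' @param transform Optional function applied to the linear predictor
#'   (default identity); e.g. the log-linear young-age anti-transform.
#' @return Object of class `ClockModel`.
#' @export
clock_model <- function(intercept, weights, transform = identity) {
  if (is.null(names(weights))) stop("clock weights must be named by probe id")
  structure(list(intercept = intercept, weights = weights,
                 transform = transform), class = "ClockModel")
}

#' Predict epigenetic age
#'
#' Clock probes absent from the matrix are imputed at the cohort mean of
#' the available clock probes. Absences are tolerated up to 20\% of the
#' clock; beyond that the prediction is refused.
#'
#' @param meth `MethylationMatrix`.
#' @param clock A [clock_model()].
#' @return Named numeric vector of predicted ages (years).
#' @export
predict_epigenetic_age <- function(meth, clock) {
  probes <- names(clock$weights)
  present <- probes %in% rownames(meth$beta)
  if (mean(present) < 0.8)
    stop(sprintf("only %.0f%% of clock probes present (need >= 80%%)",
                 100 * mean(present)))
  if (!all(present))
    warning("clock probes absent, imputed at cohort mean: ",
            paste(probes[!present], collapse = ", "))
  B <- matrix(NA_real_, length(probes), ncol(meth$beta),
              dimnames = list(probes, colnames(meth$beta)))
  B[probes[present], ] <- meth$beta[probes[present], , drop = FALSE]
  if (!all(present)) {
    cohort_mean <- mean(B, na.rm = TRUE)
    B[is.na(B)] <- cohort_mean
  }
  lp <- clock$intercept + drop(crossprod(B, clock$weights))
  clock$transform(lp)
}

#' Epigenetic age acceleration
#'
#' Residuals of the least-squares regression of predicted on
#' chronological age; by construction the residual mean is zero, so a
#' clock that is globally shifted or rescaled still yields comparable
#' per-sample acceleration.
#'
#' @param predicted,actual Numeric vectors of equal length (>= 3 samples).
#' @return Numeric vector of residuals (years).
#' @export
age_acceleration <- function(predicted, actual) {
  if (length(predicted) < 3) stop("need at least 3 samples")
  if (stats::var(actual) == 0)
    stop("chronological age is constant; acceleration undefined")
  stats::residuals(stats::lm(predicted ~ actual))
}
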