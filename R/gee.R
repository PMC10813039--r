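#' Gaussian GEE with exchangeable working correlation
#'
#' Fits a marginal linear model to clustered observations (two eyes per
#' subject) by generalized estimating equations with Gaussian family,
#' identity link and an exchangeable working correlation, the standard way
#' to correct eye-level analyses for intra-subject inter-eye correlation.
#' The algorithm alternates (i) the weighted estimating-equation update of
#' the coefficients under working covariance `phi * R(rho)` with `R`
#' exchangeable, and (ii) moment re-estimation of the dispersion `phi` and
#' correlation `rho` from Pearson residuals, until the largest coefficient
#' change is below `tol` (default `1e-8`) or `max_iter` iterations.
#' Standard errors are the robust sandwich estimate
#' `B^-1 (sum_i X_i' V_i^-1 r_i r_i' V_i^-1 X_i) B^-1` with
#' `B = sum_i X_i' V_i^-1 X_i`; 95% confidence limits are
#' `beta +/- 1.96 * SE` and p-values are two-sided from the robust Wald z.
#' With all clusters of size one the fit reduces exactly to ordinary least
#' squares.
#'
#' Rows with missing values in any model column are dropped (the count is
#' messaged). The moment estimate of `rho` is clamped to `[0, 0.99]`.
#'
#' @param data data frame with outcome, covariates and the cluster id.
#' @param formula model formula, e.g. `log_vh ~ age + sex`.
#' @param id name of the cluster id column (default `"subject_id"`).
#' @param tol,max_iter convergence tolerance on `max(abs(delta beta))` and
#'   iteration cap.
#' @return Object of class `gee_fit`: `coefficients`, `robust_se`,
#'   `ci95_low`, `ci95_high`, `p_values` (named vectors), `rho_hat`,
#'   `phi_hat`, `n_clusters`, `n_obs`, `n_dropped`, `converged`, `vcov`.
#' @export
fit_gee <- function(data, formula, id = "subject_id",
                    tol = 1e-8, max_iter = 100L) {
  stopifnot(is.data.frame(data))
  if (!id %in% names(data)) stop("cluster id column not found: ", id)
  vars <- all.vars(formula)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("model columns not found: ", paste(missing_cols, collapse = ", "))
  }
  sub <- data[, unique(c(vars, id)), drop = FALSE]
  keep <- stats::complete.cases(sub)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("fit_gee: dropped %d row(s) with missing model values",
                    n_dropped))
  }
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no complete rows to fit")

  mf <- stats::model.frame(formula, data = sub)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  n <- nrow(X); p <- ncol(X)
  f <- factor(sub[[id]])
  m <- nlevels(f)
  if (m < 2L) stop("at least 2 clusters are required")

  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("singular design; collinear column(s): ", paste(bad, collapse = ", "))
  }

  ni <- as.vector(table(f))          # aligned with rowsum() row order
  npairs_tot <- sum(ni * (ni - 1) / 2)

  beta <- qr.coef(qx, y)
  rho <- 0; phi <- 1
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    r <- as.vector(y - X %*% beta)
    phi <- sum(r^2) / (n - p)
    if (npairs_tot > p) {
      Sr <- rowsum(r, f)[, 1]
      Sr2 <- rowsum(r^2, f)[, 1]
      rho <- sum((Sr^2 - Sr2) / 2) / phi / (npairs_tot - p)
      rho <- min(max(rho, 0), 0.99)
    } else {
      rho <- 0
    }
    # closed-form exchangeable inverse:
    # V_i^-1 = [I - c_i J] / (phi (1 - rho)), c_i = rho / (1 + (n_i - 1) rho)
    ci <- rho / (1 + (ni - 1) * rho)
    SX <- rowsum(X, f)
    Sy <- rowsum(y, f)[, 1]
    w <- sqrt(ci)
    A <- (crossprod(X) - crossprod(SX * w)) / (phi * (1 - rho))
    b <- (crossprod(X, y) - crossprod(SX * w, Sy * w)) / (phi * (1 - rho))
    beta_new <- solve(A, b)[, 1]
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }

  # robust sandwich covariance at the final iterate
  r <- as.vector(y - X %*% beta)
  ci <- rho / (1 + (ni - 1) * rho)
  SX <- rowsum(X, f)
  Sr <- rowsum(r, f)[, 1]
  A <- (crossprod(X) - crossprod(SX * sqrt(ci))) / (phi * (1 - rho))
  U <- (rowsum(X * r, f) - (ci * Sr) * SX) / (phi * (1 - rho))
  Ainv <- solve(A)
  V <- Ainv %*% crossprod(U) %*% Ainv
  se <- sqrt(diag(V))
  z <- beta / se
  names(beta) <- names(se) <- colnames(X)
  structure(
    list(
      coefficients = beta,
      robust_se = se,
      ci95_low = beta - 1.96 * se,
      ci95_high = beta + 1.96 * se,
      p_values = 2 * stats::pnorm(-abs(z)),
      rho_hat = rho,
      phi_hat = phi,
      n_clusters = m,
      n_obs = n,
      n_dropped = n_dropped,
      converged = converged,
      vcov = V,
      formula = formula
    ),
    class = "gee_fit"
  )
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf(
    "gee_fit (exchangeable): %d obs in %d clusters, rho_hat %.3f, phi_hat %.4f%s\n",
    x$n_obs, x$n_clusters, x$rho_hat, x$phi_hat,
    if (x$converged) "" else " [NOT CONVERGED]"
  ))
  tab <- data.frame(
    beta = round(x$coefficients, 4),
    robust_se = round(x$robust_se, 4),
    ci_low = round(x$ci95_low, 4),
    ci_high = round(x$ci95_high, 4),
    p = signif(x$p_values, 3)
  )
  print(tab)
  invisible(x)
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' Percent group difference from a log-scale fit
#'
#' Back-transforms a coefficient of a model for log haze to the percent
#' difference on the original scale: `(exp(beta) - 1) * 100`.
#'
#' @param fit a [fit_gee()] result on the log-VH scale.
#' @param term coefficient name (e.g. the group indicator).
#' @return Percent difference.
#' @export
group_contrast <- function(fit, term) {
  stopifnot(inherits(fit, "gee_fit"))
  if (!term %in% names(fit$coefficients)) {
    stop("coefficient not in model: ", term)
  }
  (exp(fit$coefficients[[term]]) - 1) * 100
}
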