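# Generalized estimating equations, identity link, Gaussian working
# variance, exchangeable working correlation, robust (sandwich) standard
# errors clustered on patient. Written for the marginal group-over-time
# comparison of repeated assay metrics; handles unbalanced clusters
# (missing blood draws are simply absent rows).

#' Fit a marginal (GEE) model for one metric
#'
#' Regresses the metric on group (plus day as a categorical covariate, and
#' optionally their interaction) with an exchangeable working correlation
#' within patient, and reports the group effect with its robust standard
#' error and Wald p-value. With a single time point the model degenerates,
#' by design, to the group-mean difference.
#'
#' @param data Cohort table: data frame with columns `patient_id`,
#'   `group`, `day`, `metric`, `value` (long format, one row per
#'   patient x day x metric).
#' @param metric Metric name to model.
#' @param groups Length-2 character: reference group first; the reported
#'   coefficient is the second group's effect.
#' @param include_day Include day as a categorical covariate.
#' @param interaction Add the group x day interaction (the reported group
#'   effect is then the main effect at the reference day).
#' @param max_iter,tol Fisher-scoring iteration control.
#' @return A `GeeResult` list: `beta` (group effect), `se` (robust),
#'   `p`, `structure`, `rho` (estimated exchangeable correlation),
#'   `phi` (dispersion), `coefficients` (full vector), `robust_se`
#'   (full vector), `n_patients`, `n_obs`, `converged`, `n_iter`.
#' @export
fit_gee <- function(data, metric,
                    groups = c("no_infection", "infection"),
                    include_day = TRUE, interaction = FALSE,
                    max_iter = 50, tol = 1e-8) {
  d <- data[data$metric == metric & data$group %in% groups, , drop = FALSE]
  d <- d[stats::complete.cases(d[, c("patient_id", "group", "day", "value")]), ]
  if (nrow(d) == 0) stop("no rows for metric '", metric, "'", call. = FALSE)
  if (length(unique(d$patient_id[d$group == groups[1]])) < 2 ||
      length(unique(d$patient_id[d$group == groups[2]])) < 2) {
    stop("need at least 2 patients per group", call. = FALSE)
  }
  d$group <- factor(d$group, levels = groups)
  d <- d[order(d$patient_id, d$day), , drop = FALSE]

  n_days <- length(unique(d$day))
  degenerate <- n_days < 2
  use_day <- include_day && !degenerate
  fml <- if (use_day && interaction) value ~ group * factor(day)
         else if (use_day) value ~ group + factor(day)
         else value ~ group
  X <- stats::model.matrix(fml, data = d)
  y <- d$value
  id <- as.character(d$patient_id)
  clusters <- split(seq_along(y), id)
  p <- ncol(X)
  N <- length(y)

  beta <- stats::coef(stats::lm.fit(X, y))
  rho <- 0
  phi <- 1
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    r <- y - as.vector(X %*% beta)
    phi <- sum(r^2) / max(N - p, 1)
    if (phi < 1e-12) {  # zero-variance degenerate data: OLS solution stands
      converged <- TRUE
      phi <- 0
      break
    }
    rs <- r / sqrt(phi)
    num <- 0; n_pairs <- 0
    for (idx in clusters) {
      ni <- length(idx)
      if (ni > 1) {
        s <- sum(rs[idx])
        num <- num + (s^2 - sum(rs[idx]^2)) / 2
        n_pairs <- n_pairs + ni * (ni - 1) / 2
      }
    }
    rho <- if (n_pairs > p) num / (n_pairs - p) else 0
    rho <- min(max(rho, 0), 0.99)

    A <- matrix(0, p, p)
    b <- numeric(p)
    for (idx in clusters) {
      ni <- length(idx)
      Xi <- X[idx, , drop = FALSE]
      yi <- y[idx]
      Ri_inv <- exch_inverse(ni, rho)
      Wi <- Ri_inv / phi
      XtW <- crossprod(Xi, Wi)
      A <- A + XtW %*% Xi
      b <- b + XtW %*% yi
    }
    beta_new <- solve(A, b)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- as.vector(beta_new)
      converged <- TRUE
      break
    }
    beta <- as.vector(beta_new)
    if (iter >= max_iter) break
  }
  if (!converged && phi > 0) {
    stop("GEE did not converge in ", max_iter,
         " iterations (last max coefficient change above tolerance)",
         call. = FALSE)
  }

  # robust (sandwich) covariance
  r <- y - as.vector(X %*% beta)
  A <- matrix(0, p, p)
  B <- matrix(0, p, p)
  phi_w <- if (phi > 0) phi else 1
  for (idx in clusters) {
    ni <- length(idx)
    Xi <- X[idx, , drop = FALSE]
    Wi <- exch_inverse(ni, rho) / phi_w
    XtW <- crossprod(Xi, Wi)
    A <- A + XtW %*% Xi
    u <- XtW %*% r[idx]
    B <- B + tcrossprod(u)
  }
  A_inv <- solve(A)
  V <- A_inv %*% B %*% A_inv
  se <- sqrt(pmax(diag(V), 0))

  cn <- colnames(X)
  g_idx <- which(cn == paste0("group", groups[2]))
  z <- if (se[g_idx] > 0) beta[g_idx] / se[g_idx] else NA_real_
  structure(list(
    beta = unname(beta[g_idx]),
    se = unname(se[g_idx]),
    p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
    structure = "exchangeable",
    rho = rho, phi = phi,
    coefficients = stats::setNames(beta, cn),
    robust_se = stats::setNames(se, cn),
    n_patients = length(clusters), n_obs = N,
    degenerate = degenerate, converged = converged, n_iter = iter
  ), class = "GeeResult")
}

# inverse of the ni x ni exchangeable correlation matrix
exch_inverse <- function(ni, rho) {
  if (ni == 1) return(matrix(1, 1, 1))
  a <- 1 - rho
  denom <- a * (1 + (ni - 1) * rho)
  M <- matrix(-rho / denom, ni, ni)
  diag(M) <- (1 + (ni - 2) * rho) / denom
  M
}

#' @export
print.GeeResult <- function(x, ...) {
  cat(sprintf(
    "GEE (%s working correlation, robust SE): beta = %.4g, SE = %.4g, p = %.4g\n",
    x$structure, x$beta, x$se, x$p))
  cat(sprintf("  rho = %.3f, phi = %.4g, %d patients, %d observations\n",
              x$rho, x$phi, x$n_patients, x$n_obs))
  invisible(x)
}
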