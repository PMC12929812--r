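# Single-cell random-intercept linear mixed model:
#   y_ij = beta0 + beta1 * x_i + u_i + e_ij,
#   u_i ~ N(0, sigma_u^2), e_ij ~ N(0, sigma_e^2),
# fit by maximum likelihood with a profile likelihood over the variance
# ratio lambda = sigma_u^2 / sigma_e^2. Because the covariate is constant
# within patient, the GLS fixed-effect solve reduces to a weighted
# regression of patient means with weights n_i / (1 + lambda * n_i), which
# keeps each likelihood evaluation O(number of patients).

lmm_sufficient <- function(y_cells, patient_of_cell, x_patient_z) {
  if (length(y_cells) != length(patient_of_cell))
    abort_tme("y_cells and patient_of_cell lengths differ")
  pats <- sort(unique(as.character(patient_of_cell)))
  if (length(pats) < 2) abort_tme("need >= 2 patients")
  if (is.null(names(x_patient_z)))
    abort_tme("x_patient_z must be named by patient")
  if (!all(pats %in% names(x_patient_z)))
    abort_tme("every cell's patient needs an x value")
  f <- factor(as.character(patient_of_cell), levels = pats)
  n_i <- as.vector(table(f))
  ybar <- as.vector(tapply(y_cells, f, mean))
  ssw <- sum((y_cells - ybar[as.integer(f)])^2)
  list(pats = pats, n_i = n_i, ybar = ybar, ssw = ssw,
       x = unname(x_patient_z[pats]), N = length(y_cells))
}

# Profile -2 log-likelihood pieces at a given lambda >= 0.
lmm_profile_at <- function(suf, lambda) {
  w <- suf$n_i / (1 + lambda * suf$n_i)
  sw <- sum(w); swx <- sum(w * suf$x); swxx <- sum(w * suf$x^2)
  det_m <- sw * swxx - swx^2
  swy <- sum(w * suf$ybar); swxy <- sum(w * suf$x * suf$ybar)
  beta1 <- (sw * swxy - swx * swy) / det_m
  beta0 <- (swy - swx * beta1) / sw
  resid <- suf$ybar - beta0 - beta1 * suf$x
  q <- suf$ssw + sum(w * resid^2)
  sigma_e2 <- q / suf$N
  m2ll <- suf$N * (log(2 * pi * sigma_e2) + 1) + sum(log(1 + lambda * suf$n_i))
  list(beta0 = beta0, beta1 = beta1, sigma_e2 = sigma_e2, m2ll = m2ll,
       var_beta = sigma_e2 * solve(matrix(c(sw, swx, swx, swxx), 2)))
}

# -2 log-likelihood as a function of the variance components themselves
# (beta profiled out); used for the observed information of (su2, se2).
lmm_m2ll_vc <- function(suf, su2, se2) {
  lambda <- su2 / se2
  w <- suf$n_i / (1 + lambda * suf$n_i)
  sw <- sum(w); swx <- sum(w * suf$x); swxx <- sum(w * suf$x^2)
  det_m <- sw * swxx - swx^2
  swy <- sum(w * suf$ybar); swxy <- sum(w * suf$x * suf$ybar)
  beta1 <- (sw * swxy - swx * swy) / det_m
  beta0 <- (swy - swx * beta1) / sw
  resid <- suf$ybar - beta0 - beta1 * suf$x
  q <- suf$ssw + sum(w * resid^2)
  suf$N * log(2 * pi * se2) + sum(log(1 + lambda * suf$n_i)) + q / se2
}

# var(beta1_hat) as a function of (su2, se2); gradient feeds Satterthwaite.
lmm_varb1_vc <- function(suf, su2, se2) {
  lambda <- su2 / se2
  w <- suf$n_i / (1 + lambda * suf$n_i)
  sw <- sum(w); swx <- sum(w * suf$x); swxx <- sum(w * suf$x^2)
  se2 * sw / (sw * swxx - swx^2)
}

#' Fit the random-intercept linear mixed model
#'
#' Maximum-likelihood fit of \code{y_ij = beta0 + beta1 x_i + u_i + e_ij}
#' for single-cell expression \code{y} with a patient-level covariate
#' \code{x} (typically the z-scored patient mean of an anchor gene). The
#' fixed-effect p-value uses a t reference distribution with Satterthwaite
#' degrees of freedom derived from the observed information of the variance
#' components.
#'
#' @param y_cells Numeric vector of per-cell normalized expression.
#' @param patient_of_cell Patient id per cell.
#' @param x_patient_z Named numeric vector: one covariate value per patient
#'   (see \code{\link{zscore_patients}}).
#' @return Object of class \code{lmm_fit}: beta0, beta1, se_beta1,
#'   sigma_u2, sigma_e2, df_satt, t_value, p_value, loglik, n_cells,
#'   n_patients, boundary (TRUE when sigma_u2 is clamped at 0) and
#'   fallback_df (TRUE when the information matrix was singular and
#'   df = n_patients - 2 was used).
#' @export
fit_random_intercept_lmm <- function(y_cells, patient_of_cell, x_patient_z) {
  suf <- lmm_sufficient(y_cells, patient_of_cell, x_patient_z)
  if (sd(suf$x) == 0) abort_tme("patient covariate has zero variance")

  obj <- function(t) lmm_profile_at(suf, exp(t))$m2ll
  # profile over log(lambda); compare the interior optimum with the
  # lambda = 0 boundary (OLS limit)
  opt <- optimize(obj, interval = c(-25, 12), tol = 1e-10)
  at0 <- lmm_profile_at(suf, 0)
  if (at0$m2ll <= opt$objective + 1e-10) {
    lambda <- 0
    sol <- at0
    boundary <- TRUE
  } else {
    lambda <- exp(opt$minimum)
    sol <- lmm_profile_at(suf, lambda)
    boundary <- FALSE
  }
  sigma_e2 <- sol$sigma_e2
  sigma_u2 <- lambda * sigma_e2
  se_beta1 <- sqrt(sol$var_beta[2, 2])

  # Satterthwaite df: g = var(beta1_hat)(su2, se2); df = 2 g^2 / (grad' A^-1 grad)
  # with A = observed information (finite-difference Hessian of -log L).
  p <- length(suf$pats)
  df <- p - 2
  fallback <- TRUE
  g0 <- lmm_varb1_vc(suf, sigma_u2, sigma_e2)
  h_u <- max(sigma_u2, sigma_e2) * 1e-4 + 1e-10
  h_e <- sigma_e2 * 1e-4 + 1e-10
  grad <- c(
    (lmm_varb1_vc(suf, sigma_u2 + h_u, sigma_e2) -
       lmm_varb1_vc(suf, max(sigma_u2 - h_u, 0), sigma_e2)) /
      (h_u + min(sigma_u2, h_u)),
    (lmm_varb1_vc(suf, sigma_u2, sigma_e2 + h_e) -
       lmm_varb1_vc(suf, sigma_u2, sigma_e2 - h_e)) / (2 * h_e))
  f <- function(su2, se2) 0.5 * lmm_m2ll_vc(suf, max(su2, 0), se2)
  hess <- tryCatch({
    H <- matrix(NA_real_, 2, 2)
    s0 <- c(sigma_u2, sigma_e2)
    h <- c(h_u, h_e)
    for (a in 1:2) for (b in 1:2) {
      ea <- eb <- c(0, 0); ea[a] <- h[a]; eb[b] <- h[b]
      H[a, b] <- (f(s0[1] + ea[1] + eb[1], s0[2] + ea[2] + eb[2]) -
                  f(s0[1] + ea[1] - eb[1], s0[2] + ea[2] - eb[2]) -
                  f(s0[1] - ea[1] + eb[1], s0[2] - ea[2] + eb[2]) +
                  f(s0[1] - ea[1] - eb[1], s0[2] - ea[2] - eb[2])) /
        (4 * h[a] * h[b])
    }
    (H + t(H)) / 2
  }, error = function(e) NULL)
  if (!is.null(hess) && !boundary && all(is.finite(hess)) &&
      det(hess) > 1e-12) {
    denom <- drop(t(grad) %*% solve(hess, grad))
    if (is.finite(denom) && denom > 0) {
      df_try <- 2 * g0^2 / denom
      if (is.finite(df_try) && df_try > 0) {
        df <- df_try
        fallback <- FALSE
      }
    }
  }
  if (boundary) {
    # sigma_u2 on the 0 boundary: residual-like df
    df <- suf$N - 2
    fallback <- FALSE
  }

  t_val <- sol$beta1 / se_beta1
  structure(
    list(beta0 = sol$beta0, beta1 = sol$beta1, se_beta1 = se_beta1,
         sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
         df_satt = df, t_value = t_val,
         p_value = 2 * pt(-abs(t_val), df),
         loglik = -0.5 * sol$m2ll,
         n_cells = suf$N, n_patients = p,
         boundary = boundary, fallback_df = fallback),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("lmm_fit: beta1 = %.4f (SE %.4f), df = %.1f, p = %.3g\n",
              x$beta1, x$se_beta1, x$df_satt, x$p_value))
  cat(sprintf("  sigma_u2 = %.4f, sigma_e2 = %.4f, %d cells / %d patients%s\n",
              x$sigma_u2, x$sigma_e2, x$n_cells, x$n_patients,
              if (x$boundary) " (sigma_u2 at 0 boundary)" else ""))
  invisible(x)
}
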