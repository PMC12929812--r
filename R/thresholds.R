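# Normalization and GMM-based high/low marker thresholding.
#
# Markers such as CEBPB in epithelial cells and CTLA4 in T cells show bimodal
# expression; cells (and patients) are dichotomized at the first point above
# zero where the two weighted component densities of a fitted 2-component
# Gaussian mixture are equal.

#' Library-size normalize a count matrix
#'
#' Counts are divided by the cell's total, scaled (counts-per-10,000 by
#' default), and log2(1 + x) transformed. Base 2 is used so that downstream
#' differences of group mean expression are literally log2 fold changes.
#'
#' @param table A \code{\link{cell_expression_table}}.
#' @param scale Scale factor applied after library-size division.
#' @return An object of class \code{normalized_matrix}: list with
#'   \code{values} (sparse genes x cells, zero wherever the count is zero),
#'   \code{cell_meta}, \code{zero_cells} (barcodes with zero total count) and
#'   a \code{normalization} record (scale, log base).
#' @export
normalize_expression <- function(table, scale = 10000) {
  stopifnot(inherits(table, "cell_expression_table"))
  check_number(scale, "scale", lower = 1e-12)
  counts <- table$counts
  totals <- Matrix::colSums(counts)
  zero_cells <- table$cell_ids[totals == 0]
  if (length(zero_cells))
    warning(sprintf("%d cell(s) with zero total count left all-zero",
                    length(zero_cells)), call. = FALSE)
  denom <- ifelse(totals == 0, 1, totals)
  values <- counts %*% Matrix::Diagonal(x = scale / denom)
  values@x <- log2(1 + values@x)
  dimnames(values) <- dimnames(counts)
  values <- as(as(values, "generalMatrix"), "CsparseMatrix")
  structure(
    list(values = values, cell_meta = table$cell_meta,
         zero_cells = zero_cells,
         normalization = list(scale = scale, log_base = 2)),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells (CP%g, log%d)\n",
              nrow(x$values), ncol(x$values),
              x$normalization$scale, x$normalization$log_base))
  invisible(x)
}

# log of w * N(x; mu, sd^2), vectorized over x
log_wdnorm <- function(x, w, mu, sd) log(w) + dnorm(x, mu, sd, log = TRUE)

gmm2_loglik <- function(x, w1, mu1, sd1, mu2, sd2) {
  a <- log_wdnorm(x, w1, mu1, sd1)
  b <- log_wdnorm(x, 1 - w1, mu2, sd2)
  m <- pmax(a, b)
  sum(m + log(exp(a - m) + exp(b - m)))
}

#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Maximum-likelihood EM with several k-means-style initializations;
#' components are relabeled so \code{mu1 <= mu2}. A variance floor prevents
#' component collapse on zero-inflated expression data.
#'
#' @param values Numeric vector (>= 4 finite values, nonzero variance).
#' @param max_iter Maximum EM iterations per start.
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @param n_init Number of random initializations; the best final
#'   log-likelihood wins.
#' @param seed Integer seed controlling the initializations (determinism).
#' @param var_floor Lower bound on component variances.
#' @param nonzero_only Fit on the strictly positive values only. With
#'   heavily zero-inflated markers the zero spike otherwise absorbs one
#'   component, pushing the first intersection to an uninformative point
#'   just above zero; restricting the fit to expressed cells targets the
#'   bimodality of the expressing population instead.
#' @return Object of class \code{gmm_fit}: weights \code{w1,w2}, means
#'   \code{mu1 <= mu2}, sds \code{sd1,sd2}, \code{loglik_trace} of the
#'   winning start (non-decreasing), \code{converged}, \code{n}, and the
#'   derived \code{cutoff} (see \code{\link{gmm_cutoff}}; may be NA).
#' @export
fit_gmm2 <- function(values, max_iter = 500, tol = 1e-8, n_init = 5,
                     seed = 1, var_floor = 1e-6, nonzero_only = FALSE) {
  x <- values[is.finite(values)]
  if (nonzero_only) x <- x[x > 0]
  if (length(x) < 4) abort_tme("degenerate input: need >= 4 finite values")
  if (var(x) == 0) abort_tme("degenerate input: zero variance")
  check_count(n_init, "n_init", lower = 1)

  em_run <- function(mu1, mu2, sd1, sd2, w1) {
    trace <- numeric(0)
    prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      la <- pmax(log_wdnorm(x, w1, mu1, sd1), -745)
      lb <- pmax(log_wdnorm(x, 1 - w1, mu2, sd2), -745)
      m <- pmax(la, lb)
      ll <- sum(m + log(exp(la - m) + exp(lb - m)))
      trace <- c(trace, ll)
      if (!is.finite(ll)) break                # collapsed component
      if (is.finite(prev) && abs(ll - prev) < tol) {
        converged <- TRUE
        break
      }
      prev <- ll
      g1 <- 1 / (1 + exp(lb - la))             # responsibilities, component 1
      n1 <- sum(g1); n2 <- length(x) - n1
      if (n1 < 1e-8 || n2 < 1e-8) break        # empty component
      w1 <- n1 / length(x)
      w1 <- min(max(w1, 1e-10), 1 - 1e-10)
      mu1 <- sum(g1 * x) / n1
      mu2 <- sum((1 - g1) * x) / n2
      sd1 <- sqrt(max(sum(g1 * (x - mu1)^2) / n1, var_floor))
      sd2 <- sqrt(max(sum((1 - g1) * (x - mu2)^2) / n2, var_floor))
    }
    list(w1 = w1, mu1 = mu1, sd1 = sd1, mu2 = mu2, sd2 = sd2,
         loglik = trace[length(trace)], trace = trace, converged = converged)
  }

  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_init)) {
      # k-means-style split of the data for initial means/sds
      km <- tryCatch(
        suppressWarnings(kmeans(x, centers = 2, nstart = 1)),
        error = function(e) NULL)
      if (is.null(km) || min(km$size) < 2) {
        q <- quantile(x, c(0.25, 0.75), names = FALSE)
        init <- list(mu = q + rnorm(2, 0, sd(x) / 10),
                     sd = rep(max(sd(x) / 2, sqrt(var_floor)), 2),
                     w = 0.5)
      } else {
        o <- order(km$centers)
        s <- vapply(o, function(k) {
          xi <- x[km$cluster == k]
          max(sd(xi), sqrt(var_floor))
        }, numeric(1))
        init <- list(mu = km$centers[o] + rnorm(2, 0, sd(x) / 20),
                     sd = s, w = km$size[o[1]] / length(x))
      }
      fit <- em_run(init$mu[1], init$mu[2], init$sd[1], init$sd[2], init$w)
      if (!is.finite(fit$loglik)) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  if (is.null(best)) abort_tme("EM failed: every initialization collapsed")

  # relabel so mu1 <= mu2
  if (best$mu1 > best$mu2) {
    best <- list(w1 = 1 - best$w1, mu1 = best$mu2, sd1 = best$sd2,
                 mu2 = best$mu1, sd2 = best$sd1, loglik = best$loglik,
                 trace = best$trace, converged = best$converged)
  }
  fit <- structure(
    list(w1 = best$w1, w2 = 1 - best$w1,
         mu1 = best$mu1, sd1 = best$sd1,
         mu2 = best$mu2, sd2 = best$sd2,
         loglik = best$loglik, loglik_trace = best$trace,
         converged = best$converged, n = length(x), cutoff = NA_real_),
    class = "gmm_fit")
  fit$cutoff <- gmm_cutoff(fit)
  fit
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("gmm_fit: w=(%.3f, %.3f), mu=(%.3f, %.3f), sd=(%.3f, %.3f)\n",
              x$w1, x$w2, x$mu1, x$mu2, x$sd1, x$sd2))
  cat(sprintf("  n=%d, loglik=%.3f, converged=%s, cutoff=%s\n",
              x$n, x$loglik, x$converged,
              if (is.na(x$cutoff)) "undefined" else sprintf("%.4f", x$cutoff)))
  invisible(x)
}

#' Expression cutoff from a fitted two-component mixture
#'
#' Solves \code{w1 N(x; mu1, sd1^2) = w2 N(x; mu2, sd2^2)} and returns the
#' smallest real root strictly greater than zero (the first intersection of
#' the two weighted curves above zero). With unequal sds the equation is a
#' quadratic (at most two real roots); with equal sds it is linear.
#'
#' @param fit A converged \code{gmm_fit}.
#' @return The cutoff (> 0), or \code{NA_real_} when no intersection above
#'   zero exists (e.g. identical components).
#' @export
gmm_cutoff <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  if (!isTRUE(fit$converged)) abort_tme("gmm_cutoff requires a converged fit")
  w1 <- fit$w1; w2 <- fit$w2
  m1 <- fit$mu1; m2 <- fit$mu2
  s1 <- fit$sd1; s2 <- fit$sd2
  # log w1 - log s1 - (x-m1)^2/(2 s1^2) = log w2 - log s2 - (x-m2)^2/(2 s2^2)
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log(w1 / w2) + log(s2 / s1)
  eps <- 1e-12
  if (abs(a) < eps) {
    if (abs(b) < eps) return(NA_real_)      # identical densities: no crossing
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(NA_real_)
    roots <- c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
  }
  roots <- sort(roots[roots > 0])
  if (!length(roots)) return(NA_real_)
  roots[1]
}

#' Dichotomize expression values at a cutoff
#'
#' Strictly-greater convention: a value above the cutoff is "high", a value
#' at or below it is "low".
#'
#' @param values Numeric vector.
#' @param cutoff A single finite cutoff.
#' @return Character vector of "high"/"low" labels (NA values stay NA).
#' @export
assign_high_low <- function(values, cutoff) {
  check_number(cutoff, "cutoff")
  out <- ifelse(values > cutoff, "high", "low")
  out[is.na(values)] <- NA_character_
  out
}

#' Per-patient high/low grouping from a pseudobulk profile
#'
#' Each patient is labeled by whether their mean expression of \code{gene}
#' within cells of \code{cell_type} exceeds the cutoff. Patients with no
#' (retained) cells of that type are unlabeled (dropped).
#'
#' @param profile A \code{\link{pseudobulk}} profile.
#' @param gene,cell_type The marker and the compartment to threshold on.
#' @param cutoff Expression cutoff (typically \code{\link{gmm_cutoff}}).
#' @return data.frame with columns patient_id, mean_expr, group.
#' @export
patient_group <- function(profile, gene, cell_type, cutoff) {
  stopifnot(inherits(profile, "pseudobulk_profile"))
  sub <- profile[profile$gene == gene & profile$cell_type == cell_type, ,
                 drop = FALSE]
  if (!nrow(sub))
    abort_tme("gene '%s' / cell_type '%s' absent from profile", gene, cell_type)
  data.frame(patient_id = sub$patient_id,
             mean_expr = sub$mean_norm_expr,
             group = assign_high_low(sub$mean_norm_expr, cutoff),
             stringsAsFactors = FALSE)
}
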