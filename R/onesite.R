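#' Specific binding by subtraction of nonspecific counts
#'
#' Elementwise `total - nonspecific` for concentration-matched series.
#' Negative differences (nonspecific exceeding total, as can happen at low
#' specific signal) are retained, not clipped, and flagged with a warning
#' and a `"negative"` attribute.
#'
#' @param total,nonspecific Equal-length numeric count vectors.
#' @return Numeric vector of specific counts with a logical attribute
#'   `negative` marking below-zero entries.
#' @export
specific_binding <- function(total, nonspecific) {
  if (length(total) != length(nonspecific)) {
    stop("'total' and 'nonspecific' must have equal length", call. = FALSE)
  }
  out <- total - nonspecific
  neg <- out < 0
  if (any(neg)) {
    warning(sprintf("%d specific-binding value(s) are negative", sum(neg)),
            call. = FALSE)
  }
  attr(out, "negative") <- neg
  out
}

#' Fit a one-site saturation-binding hyperbola
#'
#' Nonlinear least-squares fit of \eqn{y = B_{max}\,x / (K_d + x)} to
#' specific-binding counts. The standard error of Kd comes from the
#' asymptotic covariance at the optimum. A warning is issued when the
#' concentration series does not bracket the fitted Kd (no point below or
#' above it), since the estimate is then poorly constrained.
#'
#' @param concs Ligand concentrations (nM), non-negative; at least 4 distinct
#'   values.
#' @param specific Specific-binding counts matched to `concs` (e.g. from
#'   [specific_binding()]).
#' @return An object of class `fit_one_site` with components `kd`, `kd_se`,
#'   `bmax`, `bmax_se`, `residual_ss`, `sigma`, `df.residual`, `converged`,
#'   `n_points` and the fitting data.
#' @examples
#' x <- seq(0.1, 1.6, by = 0.1)
#' fit <- fit_one_site(x, 100 * x / (0.5 + x))
#' coef(fit)
#' @export
fit_one_site <- function(concs, specific) {
  if (length(concs) != length(specific)) {
    stop("'concs' and 'specific' must have equal length", call. = FALSE)
  }
  if (any(!is.finite(concs)) || any(concs < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
  if (length(unique(concs)) < 4) {
    stop("at least 4 distinct concentrations are required", call. = FALSE)
  }
  dat <- data.frame(x = concs, y = as.numeric(specific))
  mu <- tapply(dat$y, dat$x, mean)
  xs <- as.numeric(names(mu))
  bmax0 <- max(mu)
  half_x <- xs[which.min(abs(mu - bmax0 / 2))]
  start <- list(bmax = bmax0, kd = max(half_x, min(xs[xs > 0])))
  do_fit <- function(start) tryCatch(
    minpack.lm::nlsLM(y ~ bmax * x / (kd + x), data = dat, start = start,
                      lower = c(bmax = 0, kd = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e
  )
  fit <- do_fit(start)
  if (inherits(fit, "error")) {
    # deterministic fallback: seed kd from a log-spaced grid by residual SS
    xpos <- min(xs[xs > 0])
    kd_grid <- 10^seq(log10(xpos / 100), log10(max(xs) * 10),
                      length.out = 25)
    ss <- vapply(kd_grid, function(k)
      sum((dat$y - bmax0 * dat$x / (k + dat$x))^2), numeric(1))
    fit <- do_fit(list(bmax = bmax0, kd = kd_grid[which.min(ss)]))
  }
  if (inherits(fit, "error")) {
    return(structure(list(converged = FALSE,
                          message = conditionMessage(fit),
                          n_points = nrow(dat), data = dat,
                          call = match.call()),
                     class = "fit_one_site"))
  }
  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(diag(vc))
  if (cf[["kd"]] < min(concs[concs > 0]) || cf[["kd"]] > max(concs)) {
    warning("concentration series does not bracket the fitted Kd",
            call. = FALSE)
  }
  rss <- deviance(fit)
  dfres <- nrow(dat) - 2L
  structure(list(
    kd = cf[["kd"]], kd_se = se[[which(names(cf) == "kd")]],
    bmax = cf[["bmax"]], bmax_se = se[[which(names(cf) == "bmax")]],
    residual_ss = rss, sigma = sqrt(rss / dfres),
    df.residual = dfres, converged = TRUE, n_points = nrow(dat),
    data = dat, call = match.call()
  ), class = "fit_one_site")
}

#' @export
coef.fit_one_site <- function(object, ...) {
  if (!object$converged) return(c(kd = NA_real_, bmax = NA_real_))
  c(kd = object$kd, bmax = object$bmax)
}

#' @export
print.fit_one_site <- function(x, digits = 4, ...) {
  cat("One-site saturation binding fit\n")
  if (!x$converged) {
    cat("  did not converge:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  Kd: %.*g +/- %.*g nM   Bmax: %.*g +/- %.*g counts\n",
              digits, x$kd, digits, x$kd_se, digits, x$bmax, digits,
              x$bmax_se))
  cat(sprintf("  n = %d tubes, residual SS = %.*g\n", x$n_points, digits,
              x$residual_ss))
  invisible(x)
}

#' @export
summary.fit_one_site <- function(object, ...) {
  print(object)
  if (object$converged) {
    est <- c(object$kd, object$bmax)
    se <- c(object$kd_se, object$bmax_se)
    tab <- cbind(Estimate = est, `Std. Error` = se, `t value` = est / se,
                 `Pr(>|t|)` = 2 * pt(-abs(est / se), object$df.residual))
    rownames(tab) <- c("kd", "bmax")
    cat("\nCoefficients:\n")
    stats::printCoefmat(tab, digits = 4)
    invisible(tab)
  } else invisible(object)
}

#' @export
predict.fit_one_site <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit",
                              call. = FALSE)
  x <- if (is.null(newdata)) object$data$x
       else if (is.list(newdata)) newdata$conc_nM else newdata
  object$bmax * x / (object$kd + x)
}

#' @export
fitted.fit_one_site <- function(object, ...) predict(object)

#' @export
residuals.fit_one_site <- function(object, ...) {
  object$data$y - fitted(object)
}

#' @export
confint.fit_one_site <- function(object, parm = c("kd", "bmax"),
                                 level = 0.95, ...) {
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  tcrit <- qt(1 - (1 - level) / 2, object$df.residual)
  est <- c(kd = object$kd, bmax = object$bmax)[parm]
  se <- c(kd = object$kd_se, bmax = object$bmax_se)[parm]
  out <- cbind(est - tcrit * se, est + tcrit * se)
  dimnames(out) <- list(parm, sprintf("%g %%", 100 * c((1 - level) / 2,
                                                       1 - (1 - level) / 2)))
  out
}

#' @export
plot.fit_one_site <- function(x, n_curve = 200, xlab = "[ligand] (nM)",
                              ylab = "specific binding (counts)", ...) {
  graphics::plot(x$data$x, x$data$y, xlab = xlab, ylab = ylab, ...)
  if (x$converged) {
    xx <- seq(0, max(x$data$x), length.out = n_curve)
    graphics::lines(xx, predict(x, xx))
    graphics::abline(v = x$kd, lty = 3)
  }
  invisible(x)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Classical one-way analysis of variance across assay groups followed by
#' Tukey's honestly-significant-difference test on all unordered group
#' pairs, using the studentized range distribution with the pooled
#' within-group mean square (Tukey-Kramer correction for unequal group
#' sizes). The degenerate case of identical constant values in every group
#' is reported as F = 0, p = 1, all adjusted p = 1.
#'
#' @param groups Named list mapping a group label to a numeric vector of
#'   fold-activation values; at least 2 groups with >= 2 values each.
#' @return An object of class `anova_tukey`: list with `f_stat`, `p_value`,
#'   `df` (between, within) and a `pairwise` data frame (`group_a`,
#'   `group_b`, `mean_diff`, `adjusted_p`).
#' @examples
#' anova_tukey(list(a = c(1, 2, 1.5), b = c(3, 3.5, 4), c = c(1, 1.2, 0.9)))
#' @export
anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 || is.null(names(groups))) {
    stop("'groups' must be a named list with >= 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop("every group needs >= 2 values (offending: ",
         paste(names(groups)[sizes < 2], collapse = ", "), ")", call. = FALSE)
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups))
  )
  labs <- names(groups)
  pairs <- t(combn(labs, 2))
  means <- vapply(groups, mean, numeric(1))
  if (var(df$value) == 0) {
    pw <- data.frame(group_a = pairs[, 1], group_b = pairs[, 2],
                     mean_diff = 0, adjusted_p = 1,
                     stringsAsFactors = FALSE)
    return(structure(list(f_stat = 0, p_value = 1,
                          df = c(length(groups) - 1,
                                 nrow(df) - length(groups)),
                          pairwise = pw), class = "anova_tukey"))
  }
  fit <- aov(value ~ group, data = df)
  an <- anova(fit)
  tk <- TukeyHSD(fit)$group
  key <- paste(pairs[, 2], pairs[, 1], sep = "-")  # TukeyHSD order: later-earlier
  pw <- data.frame(group_a = pairs[, 1], group_b = pairs[, 2],
                   mean_diff = means[pairs[, 2]] - means[pairs[, 1]],
                   adjusted_p = tk[key, "p adj"],
                   stringsAsFactors = FALSE, row.names = NULL)
  structure(list(f_stat = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
                 df = c(an$Df[1], an$Df[2]), pairwise = pw),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, digits = 4, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.*g, p = %.*g\n",
              x$df[1], x$df[2], digits, x$f_stat, digits, x$p_value))
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$pairwise, digits = digits)
  invisible(x)
}

#' @importFrom utils combn
NULL
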