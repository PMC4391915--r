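#' Fit a variable-slope sigmoidal concentration-response model
#'
#' Nonlinear least-squares fit of the four-parameter logistic (4PL)
#'
#' \deqn{f(d) = bottom + \frac{emax - bottom}{1 + 10^{hill\,(\log_{10} EC_{50} - \log_{10} d)}}}
#'
#' to fold-activation data, in log10-dose space. Vehicle wells (dose 0) are
#' excluded from the fit — log dose is undefined there; they belong to the
#' upstream normalization. The 95% confidence interval for EC50 is computed
#' on the log10 scale from the asymptotic standard error at the optimum and
#' back-transformed to nM, so it is asymmetric around EC50 in concentration
#' units.
#'
#' Initialization is deterministic: log10 EC50 at the dose whose mean
#' response is nearest half-maximal, hill = 1, top at the maximal mean fold,
#' bottom at 1 (fold scale). If the optimizer fails from there, a bounded
#' multi-start over a small deterministic grid is tried; persistent failure
#' returns an object with `converged = FALSE` and diagnostics rather than an
#' error.
#'
#' @param doses Ligand concentrations (nM); at least 5 distinct nonzero
#'   values are required.
#' @param folds Fold-activation values, finite and positive, matched to
#'   `doses`.
#' @return An object of class `fit_4pl` with components `ec50`, `log_ec50`,
#'   `ec50_ci95`, `emax` (fitted top plateau), `emax_observed` (largest mean
#'   fold seen), `bottom`, `hill`, coefficient standard errors, `residual_ss`,
#'   `sigma`, `df.residual`, `converged`, `n_points`, and the fitting data.
#' @examples
#' d <- rep(c(0.2, 1, 5, 25, 125, 625), each = 2)
#' y <- 1 + 50 / (1 + 5 / d)
#' fit <- fit_4pl(d, y)
#' coef(fit)
#' confint(fit)
#' @seealso [fit_one_site()] for saturation binding.
#' @export
fit_4pl <- function(doses, folds) {
  if (length(doses) != length(folds)) {
    stop("'doses' and 'folds' must have equal length", call. = FALSE)
  }
  keep <- doses > 0
  doses <- doses[keep]
  folds <- folds[keep]
  if (!all(is.finite(folds)) || any(folds <= 0)) {
    stop("'folds' must be finite and positive", call. = FALSE)
  }
  if (length(unique(doses)) < 5) {
    stop("at least 5 distinct nonzero doses are required", call. = FALSE)
  }
  if (diff(range(folds)) <= 1e-9 * max(abs(folds))) {
    stop("no dose dependence: response is flat across doses", call. = FALSE)
  }
  logd <- log10(doses)
  # mean response per dose, used for deterministic starting values
  mu <- tapply(folds, logd, mean)
  lev <- as.numeric(names(mu))
  half <- (max(mu) + min(mu)) / 2
  start0 <- list(bottom = 1,
                 emax = max(mu),
                 hill = 1,
                 logec50 = lev[which.min(abs(mu - half))])

  dat <- data.frame(logd = logd, fold = folds)
  form <- fold ~ bottom + (emax - bottom) / (1 + 10^(hill * (logec50 - logd)))
  try_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e
    )
  }
  fit <- try_fit(start0)
  if (inherits(fit, "error")) {
    # deterministic bounded multi-start fallback
    starts <- expand.grid(logec50 = quantile(lev, c(0.25, 0.5, 0.75),
                                             names = FALSE),
                          hill = c(0.5, 1, 2),
                          bottom = c(1, min(mu)),
                          emax = c(max(mu), 1.2 * max(mu)))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      cand <- try_fit(as.list(starts[i, ]))
      if (!inherits(cand, "error")) {
        if (is.null(best) || deviance(cand) < deviance(best)) best <- cand
      }
    }
    fit <- best
  }
  if (is.null(fit) || inherits(fit, "error")) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else
      "all starting values failed"
    return(structure(list(converged = FALSE, message = msg,
                          n_points = nrow(dat), data = dat,
                          call = match.call()),
                     class = "fit_4pl"))
  }

  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 4, 4,
                  dimnames = list(names(cf), names(cf))))
  se <- sqrt(diag(vc))
  dfres <- nrow(dat) - length(cf)
  tcrit <- qt(0.975, dfres)
  ci_log <- cf[["logec50"]] + c(-1, 1) * tcrit * se[["logec50"]]
  rss <- deviance(fit)
  structure(list(
    ec50 = 10^cf[["logec50"]],
    log_ec50 = cf[["logec50"]],
    ec50_ci95 = 10^ci_log,
    emax = cf[["emax"]],
    emax_observed = max(mu),
    bottom = cf[["bottom"]],
    hill = cf[["hill"]],
    se = c(bottom = se[["bottom"]], emax = se[["emax"]],
           hill = se[["hill"]], log_ec50 = se[["logec50"]]),
    vcov = vc,
    residual_ss = rss,
    sigma = sqrt(rss / dfres),
    df.residual = dfres,
    converged = TRUE,
    n_points = nrow(dat),
    data = dat,
    call = match.call()
  ), class = "fit_4pl")
}

#' @importFrom stats deviance
#' @export
coef.fit_4pl <- function(object, ...) {
  if (!object$converged) return(c(bottom = NA, emax = NA, hill = NA,
                                  ec50 = NA))
  c(bottom = object$bottom, emax = object$emax, hill = object$hill,
    ec50 = object$ec50)
}

#' @export
print.fit_4pl <- function(x, digits = 4, ...) {
  cat("Four-parameter logistic concentration-response fit\n")
  if (!x$converged) {
    cat("  did not converge:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  EC50: %.*g nM (95%% CI %.*g-%.*g)\n", digits, x$ec50,
              digits, x$ec50_ci95[1], digits, x$ec50_ci95[2]))
  cat(sprintf("  E_MAX (top plateau): %.*g-fold  bottom: %.*g  hill: %.*g\n",
              digits, x$emax, digits, x$bottom, digits, x$hill))
  cat(sprintf("  n = %d wells, residual SS = %.*g\n", x$n_points, digits,
              x$residual_ss))
  invisible(x)
}

#' @export
summary.fit_4pl <- function(object, ...) {
  if (!object$converged) {
    cat("fit_4pl: not converged (", object$message, ")\n", sep = "")
    return(invisible(object))
  }
  est <- c(object$bottom, object$emax, object$hill, object$log_ec50)
  se <- object$se[c("bottom", "emax", "hill", "log_ec50")]
  tab <- cbind(Estimate = est, `Std. Error` = se,
               `t value` = est / se,
               `Pr(>|t|)` = 2 * pt(-abs(est / se), object$df.residual))
  rownames(tab) <- c("bottom", "emax", "hill", "log10(EC50)")
  print(object)
  cat("\nCoefficients:\n")
  stats::printCoefmat(tab, digits = 4)
  invisible(tab)
}

#' @export
predict.fit_4pl <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit",
                              call. = FALSE)
  d <- if (is.null(newdata)) 10^object$data$logd
       else if (is.list(newdata)) newdata$dose_nM else newdata
  fourpl_response(d, object$bottom, object$emax, object$hill, object$ec50)
}

#' @export
fitted.fit_4pl <- function(object, ...) predict(object)

#' @export
residuals.fit_4pl <- function(object, ...) {
  object$data$fold - fitted(object)
}

#' @export
confint.fit_4pl <- function(object, parm = "ec50", level = 0.95, ...) {
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  tcrit <- qt(1 - (1 - level) / 2, object$df.residual)
  rows <- lapply(parm, function(p) {
    if (p == "ec50") {
      10^(object$log_ec50 + c(-1, 1) * tcrit * object$se[["log_ec50"]])
    } else if (p %in% c("bottom", "emax", "hill")) {
      unname(object[[p]] + c(-1, 1) * tcrit * object$se[[p]])
    } else stop("unknown parameter: ", p, call. = FALSE)
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(parm, sprintf("%g %%", 100 * c((1 - level) / 2,
                                                       1 - (1 - level) / 2)))
  out
}

#' @export
plot.fit_4pl <- function(x, n_curve = 200, xlab = "dose (nM)",
                         ylab = "fold activation", ...) {
  d <- 10^x$data$logd
  graphics::plot(d, x$data$fold, log = "x", xlab = xlab, ylab = ylab, ...)
  if (x$converged) {
    dd <- 10^seq(min(x$data$logd), max(x$data$logd), length.out = n_curve)
    graphics::lines(dd, predict(x, dd))
    graphics::abline(v = x$ec50, lty = 3)
  }
  invisible(x)
}
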