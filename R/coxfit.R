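#' Single-covariate Cox proportional-hazards fit
#'
#' Maximizes the Breslow-ties partial likelihood for one covariate by
#' Newton-Raphson (tolerance 1e-8 on the score, at most 50 iterations, with
#' step-halving whenever a step would decrease the log partial likelihood).
#' This is the machinery behind the calibration slope: the coefficient of the
#' centred prognostic index refit on the validation data.
#'
#' @param data A data frame.
#' @param covariate Column holding the single covariate (tidy-eval).
#' @param time,event Follow-up time and 0/1 event indicator columns.
#' @param tol Convergence tolerance on the absolute score.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `survalid_cox` with elements `beta`,
#'   `std_error`, `conf_low`, `conf_high`, `log_partial_likelihood`,
#'   `iterations`, `converged`, `n`, `n_events`.
#' @export
fit_cox_single_covariate <- function(data, covariate, time = time,
                                     event = event, tol = 1e-8,
                                     max_iter = 50) {
  x <- dplyr::pull(data, {{ covariate }})
  t <- dplyr::pull(data, {{ time }})
  d <- dplyr::pull(data, {{ event }})
  cox_core(t, d, x, tol = tol, max_iter = max_iter)
}

cox_core <- function(t, d, x, tol = 1e-8, max_iter = 50) {
  if (any(t <= 0)) abort("All follow-up times must be strictly positive.")
  if (!all(d %in% c(0, 1))) abort("Event indicator must be 0/1.")
  if (sum(d) < 2) abort("At least 2 events are required to fit the model.")
  if (length(unique(x)) < 2) {
    abort("Covariate is constant; the partial likelihood is degenerate.")
  }
  n <- length(t)
  xc <- x - mean(x) # location shift leaves beta unchanged; stabilises exp()
  ord <- order(t, decreasing = TRUE)
  ts <- t[ord]; ds <- d[ord]; xs <- xc[ord]
  # risk set of a subject = all with time >= its time; with times sorted
  # decreasing these are positions 1..(last index of its tie group)
  grp <- rle(ts)
  risk_end <- rep(cumsum(grp$lengths), grp$lengths)
  ev <- ds == 1

  eval_pl <- function(beta) {
    w <- exp(beta * xs)
    s0 <- cumsum(w)[risk_end]
    s1 <- cumsum(w * xs)[risk_end]
    s2 <- cumsum(w * xs^2)[risk_end]
    xbar <- s1 / s0
    list(ll = sum(beta * xs[ev] - log(s0[ev])),
         score = sum(xs[ev] - xbar[ev]),
         info = sum((s2 / s0 - xbar^2)[ev]))
  }

  beta <- 0
  cur <- eval_pl(beta)
  iter <- 0L
  converged <- abs(cur$score) < tol
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    step <- cur$score / cur$info
    cand <- beta + step
    nxt <- eval_pl(cand)
    halvings <- 0L
    while (nxt$ll < cur$ll && halvings < 30L) { # never accept a downhill step
      step <- step / 2
      cand <- beta + step
      nxt <- eval_pl(cand)
      halvings <- halvings + 1L
    }
    beta <- cand
    cur <- nxt
    converged <- abs(cur$score) < tol
  }
  if (!converged) {
    warn(sprintf("Cox fit did not converge in %d iterations (|score| = %.3g).",
                 max_iter, abs(cur$score)))
  }
  se <- 1 / sqrt(cur$info)
  structure(
    list(beta = beta, std_error = se,
         conf_low = beta - stats::qnorm(0.975) * se,
         conf_high = beta + stats::qnorm(0.975) * se,
         log_partial_likelihood = cur$ll, iterations = iter,
         converged = converged, n = n, n_events = sum(d)),
    class = "survalid_cox")
}

#' @export
print.survalid_cox <- function(x, ...) {
  cat(sprintf("<survalid_cox> beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$beta, x$std_error, x$conf_low, x$conf_high))
  cat(sprintf("  n = %d, events = %d, logPL = %.4f, %d iteration(s)%s\n",
              x$n, x$n_events, x$log_partial_likelihood, x$iterations,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
tidy.survalid_cox <- function(x, ...) {
  tibble::tibble(
    term = "covariate", estimate = x$beta, std.error = x$std_error,
    conf.low = x$conf_low, conf.high = x$conf_high,
    statistic = x$beta / x$std_error,
    p.value = 2 * stats::pnorm(-abs(x$beta / x$std_error)))
}

#' @export
glance.survalid_cox <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_partial_likelihood, nobs = x$n, nevent = x$n_events,
    iterations = x$iterations, converged = x$converged)
}
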