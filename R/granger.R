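#' Granger model specification
#'
#' Settings for the pairwise bivariate autoregressive (Granger causality)
#' network. Coefficients are estimated by ordinary least squares.
#'
#' @param order Model order `p`: the maximum number of lags in the
#'   autoregression. Must satisfy `p >= 1` and `p < n_timepoints / 4`.
#' @param check_stationarity Apply the covariance-stationarity safeguard:
#'   each series is demeaned and linearly detrended; if any region still
#'   shows a lag-1 autocorrelation above 0.99 (unit-root heuristic), all
#'   series are first-differenced with a warning.
#' @return An object of class `granger_spec`.
#' @export
granger_spec <- function(order = 1L, check_stationarity = TRUE) {
  order <- as.integer(order)
  if (order < 1L) stop("model order p must be at least 1")
  structure(list(order = order, check_stationarity = isTRUE(check_stationarity)),
            class = "granger_spec")
}

# lag-embedding: columns x(t-1) ... x(t-p) aligned to y = x[(p+1):T]
lag_design <- function(x, p) {
  T <- length(x)
  vapply(seq_len(p), function(l) x[(p + 1L - l):(T - l)], numeric(T - p))
}

#' Pairwise bivariate Granger causality network
#'
#' For every ordered region pair (j, k), fits the bivariate AR(p) model of
#' region k by least squares and computes the log variance ratio
#' `F(j -> k) = ln(var(e_R) / var(e_U))`, where the restricted model predicts
#' k from its own past only and the unrestricted model adds the past of j.
#' Entry (j, k) of the returned matrix holds `F(j -> k)`; the diagonal is 0.
#' Nested OLS guarantees nonnegative F up to numerical noise.
#'
#' Degenerate (near-noiseless) fits are capped by flooring the unrestricted
#' residual variance at `1e-12`, so a perfect lagged copy yields a large
#' finite F rather than an infinity.
#'
#' @param ts A [region_ts] (or bare matrix).
#' @param spec A [granger_spec].
#' @return A [conn_matrix] with `method = "granger"` and `lag` set to the
#'   model order.
#' @export
granger_matrix <- function(ts, spec = granger_spec()) {
  ts <- as_region_ts(ts)
  p <- spec$order
  N <- n_timepoints(ts)
  if (p >= N / 4)
    stop(sprintf("model order p = %d too large for %d time points (need p < N/4)", p, N))
  x <- ts$data
  n <- nrow(x)
  # demean + linear detrend each series
  tt <- seq_len(N)
  x <- t(apply(x, 1L, function(r) stats::lm.fit(cbind(1, tt), r)$residuals))
  if (spec$check_stationarity) {
    ac1 <- apply(x, 1L, function(r) {
      v <- stats::var(r)
      if (v == 0) 0 else stats::cor(r[-1L], r[-length(r)])
    })
    if (any(ac1 > 0.99)) {
      warning("unit-root heuristic triggered (lag-1 autocorrelation > 0.99); first-differencing all series")
      x <- t(apply(x, 1L, diff))
      N <- ncol(x)
      if (p >= N / 4) stop("model order too large after differencing")
    }
  }
  eps_floor <- 1e-12
  designs <- lapply(seq_len(n), function(i) lag_design(x[i, ], p))
  targets <- lapply(seq_len(n), function(i) x[i, (p + 1L):N])
  # restricted residual variance per region (own past only)
  var_r <- numeric(n)
  for (k in seq_len(n)) {
    fit <- stats::lm.fit(cbind(1, designs[[k]]), targets[[k]])
    var_r[k] <- mean(fit$residuals^2)
  }
  F <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j == k) next
      X <- cbind(1, designs[[k]], designs[[j]])
      fit <- tryCatch(stats::lm.fit(X, targets[[k]]), error = function(e) NULL)
      if (is.null(fit) || fit$rank < ncol(X)) {
        warning(sprintf("singular design for pair (%s, %s); entry set to 0",
                        ts$region_labels[j], ts$region_labels[k]))
        next
      }
      var_u <- max(mean(fit$residuals^2), eps_floor)
      F[j, k] <- log(max(var_r[k], eps_floor) / var_u)
    }
  }
  F[F < 0 & F > -1e-10] <- 0   # numerical noise only; nested OLS keeps F >= 0
  conn_matrix(F, "granger", lag = p, clipped = TRUE,
              region_labels = ts$region_labels, subject_id = ts$subject_id)
}
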