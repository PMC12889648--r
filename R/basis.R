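#' Raised-cosine basis for temporal filters
#'
#' Builds a bank of raised-cosine bumps covering lags `(0, support_ms]`, the
#' standard parameterisation for post-spike and coupling filters in
#' point-process GLMs.  Each column is a single bump with peak value 1, zero
#' outside its own support.  With `log_stretch > 0` the bump centres are
#' spaced uniformly in `log(t + log_stretch)`, concentrating resolution at
#' short lags where filters change fastest.
#'
#' @param n_basis number of basis functions (>= 1).
#' @param support_ms maximum lag covered by the basis, in ms.
#' @param log_stretch non-negative stretch constant (ms); 0 gives linearly
#'   spaced centres, larger values approach linear spacing again.
#' @param bin_ms lag grid resolution in ms.
#' @return numeric matrix with one row per lag `seq(bin_ms, support_ms, by =
#'   bin_ms)` and one column per basis function; the lag grid is attached as
#'   attribute `"lag_ms"`.
#' @seealso [eval_raised_cosine()] for evaluation at arbitrary lags.
#' @export
#' @examples
#' B <- raised_cosine_basis(8, 100)
#' matplot(attr(B, "lag_ms"), B, type = "l")
raised_cosine_basis <- function(n_basis, support_ms, log_stretch = 0, bin_ms = 1) {
  if (length(n_basis) != 1L || is.na(n_basis) || n_basis < 1)
    stop("`n_basis` must be a positive integer")
  if (length(support_ms) != 1L || is.na(support_ms) || support_ms <= 0)
    stop("`support_ms` must be positive")
  lags <- seq(bin_ms, support_ms, by = bin_ms)
  B <- eval_raised_cosine(lags, n_basis, support_ms, log_stretch)
  attr(B, "lag_ms") <- lags
  attr(B, "support_ms") <- support_ms
  attr(B, "log_stretch") <- log_stretch
  B
}

#' Evaluate raised-cosine basis functions at arbitrary points
#'
#' Values are exactly zero for `x < 0` (causality) and `x > support`.
#'
#' @param x evaluation points (lags in ms, or any basis domain).
#' @param n_basis,support,log_stretch as in [raised_cosine_basis()].
#' @return matrix `length(x)` x `n_basis`.
#' @export
eval_raised_cosine <- function(x, n_basis, support, log_stretch = 0) {
  n_basis <- as.integer(n_basis)
  if (n_basis < 1) stop("`n_basis` must be >= 1")
  if (support <= 0) stop("`support` must be positive")
  if (log_stretch < 0) stop("`log_stretch` must be non-negative")
  u <- function(t) if (log_stretch > 0) log(t + log_stretch) else t
  u0 <- u(0)
  u1 <- u(support)
  if (n_basis == 1L) {
    centers <- (u0 + u1) / 2
    halfwidth <- (u1 - u0) / 2
  } else {
    centers <- seq(u0, u1, length.out = n_basis)
    halfwidth <- 2 * (centers[2] - centers[1])
  }
  inside <- x >= 0 & x <= support
  ux <- u(pmax(x, 0))
  B <- matrix(0, length(x), n_basis)
  for (k in seq_len(n_basis)) {
    arg <- (ux - centers[k]) / halfwidth
    v <- ifelse(abs(arg) <= 1, 0.5 * (1 + cos(pi * arg)), 0)
    B[, k] <- ifelse(inside, v, 0)
  }
  B
}

# B-spline (order 4) design over `range`, with `df` columns including the
# constant; interior knots are equally spaced.  Used for baseline templates.
bspline_basis <- function(times, df, range) {
  if (df < 4) stop("baseline needs at least 4 B-spline coefficients")
  n_interior <- df - 4L
  interior <- if (n_interior > 0)
    seq(range[1], range[2], length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  else numeric(0)
  knots <- c(rep(range[1], 4L), interior, rep(range[2], 4L))
  bad <- times < range[1] | times > range[2]
  if (any(bad)) stop("B-spline evaluation outside [", range[1], ", ", range[2], "]")
  splines::splineDesign(knots, x = times, ord = 4L)
}

# Least-squares projection of a function (values on a lag grid) onto a basis
# matrix; returns list(coef, fitted, rel_l2).  Small utility used in tests and
# for summarising filters.
project_onto_basis <- function(values, basis) {
  coef <- qr.coef(qr(basis), values)
  coef[is.na(coef)] <- 0
  fitted <- drop(basis %*% coef)
  rel <- sqrt(sum((values - fitted)^2) / sum(values^2))
  list(coef = coef, fitted = fitted, rel_l2 = rel)
}
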