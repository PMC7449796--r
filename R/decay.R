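#' Parameters of the decaying-exponential oxygenation model
#'
#' The oxygenation proxy (ratio^-1 = RFP / GFP-ODD) as a function of the
#' minimum distance `x` to the tracheal system is modelled as
#' `y(x) = y0 + A * exp(-(x - x0) / lambda)`: `A` spans the full range of
#' the decay, `y0` is the asymptotic (minimum) oxygenation value, `lambda`
#' is the decay constant -- the distance over which the exponential term
#' falls to 37 percent (1/e) of its initial value -- and `x0` is a fixed
#' reference distance (by convention the smallest distance in the fitted
#' data set).
#'
#' @param A amplitude (dimensionless).
#' @param y0 offset (asymptotic ratio^-1).
#' @param lambda_um decay constant, um; must be > 0.
#' @param x0_um reference distance, um.
#' @return Object of class `decay_params`.
#' @export
decay_params <- function(A, y0, lambda_um, x0_um = 0) {
  if (!is.na(lambda_um) && lambda_um <= 0) stop("lambda must be > 0")
  structure(list(A = A, y0 = y0, lambda_um = lambda_um, x0_um = x0_um),
            class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  cat(sprintf("decay_params: y(x) = %.4g + %.4g * exp(-(x - %.4g) / %.4g)\n",
              x$y0, x$A, x$x0_um, x$lambda_um))
  invisible(x)
}

new_decay_fit <- function(params, se, residual_rms, n, method, converged,
                          lambda_identifiable = TRUE) {
  structure(list(params = params, se = se, residual_rms = residual_rms,
                 n = n, method = method, converged = converged,
                 lambda_identifiable = lambda_identifiable),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "decay_fit (%s): A=%.4g y0=%.4g lambda=%.4g um x0=%.4g um\n",
    x$method, x$params$A, x$params$y0, x$params$lambda_um, x$params$x0_um))
  cat(sprintf("  n=%d rms=%.4g converged=%s lambda identifiable=%s\n",
              x$n, x$residual_rms, x$converged, x$lambda_identifiable))
  invisible(x)
}

#' Fit the decaying-exponential oxygenation model
#'
#' Fits `y = y0 + A * exp(-(x - x0) / lambda)` to (distance, ratio^-1)
#' points. The default minimises vertical least-squares residuals
#' (Levenberg-Marquardt); `method = "odr"` minimises orthogonal distances
#' to the curve, refining the least-squares solution. `x0` is not a free
#' parameter: by default it is fixed at the minimum observed distance
#' (`x0_policy = "min"`); a numeric `x0_policy` fixes it explicitly.
#'
#' Initialisation: `y0` at the 5 percent quantile of `y`, `A` at
#' `max(y) - y0`, `lambda` at half the x-range, with `lambda` bounded in
#' `[1e-3, 10 * x-range]`. A fit whose amplitude is smaller than twice the
#' residual RMS is flagged as having an unidentifiable decay constant
#' (e.g. distance-independent oxygenation).
#'
#' @param dist_um distances, um.
#' @param inv_ratio oxygenation proxy values (ratio^-1), > 0.
#' @param method `"least_squares"` or `"odr"`.
#' @param x0_policy `"min"` or a fixed numeric x0 (um).
#' @return A `decay_fit`: fitted [decay_params()], standard errors,
#'   residual RMS, `n`, `method`, `converged` and `lambda_identifiable`.
#' @export
fit_decay <- function(dist_um, inv_ratio,
                      method = c("least_squares", "odr"),
                      x0_policy = "min") {
  method <- match.arg(method)
  ok <- is.finite(dist_um) & is.finite(inv_ratio)
  x <- dist_um[ok]; y <- inv_ratio[ok]
  if (length(x) < 10) stop("need at least 10 finite points to fit")
  if (any(y <= 0)) stop("inv_ratio values must be > 0")
  x0 <- if (identical(x0_policy, "min")) min(x) else as.numeric(x0_policy)
  xrange <- max(diff(range(x)), 1e-6)
  y0_init <- as.numeric(stats::quantile(y, 0.05))
  A_init <- max(max(y) - y0_init, 1e-6)
  start <- list(A = A_init, y0 = y0_init, lambda = xrange / 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + A * exp(-(x - x0) / lambda),
                      start = start,
                      lower = c(A = 0, y0 = -Inf, lambda = 1e-3),
                      upper = c(A = Inf, y0 = Inf, lambda = 10 * xrange),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate data (e.g. constant y): report a flat model
    rms <- stats::sd(y)
    if (is.na(rms)) rms <- 0
    return(new_decay_fit(decay_params(0, mean(y), NA_real_, x0),
                         se = c(A = NA, y0 = NA, lambda = NA),
                         residual_rms = rms, n = length(x),
                         method = method, converged = TRUE,
                         lambda_identifiable = FALSE))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(A = NA, y0 = NA, lambda = NA))
  rms <- sqrt(mean(stats::resid(fit)^2))
  params <- decay_params(unname(cf["A"]), unname(cf["y0"]),
                         unname(cf["lambda"]), x0)
  if (method == "odr") {
    od <- odr_refine(x, y, params)
    params <- od$params
    rms <- od$rms
  }
  identifiable <- is.finite(params$lambda_um) && params$A >= 2 * rms &&
    params$A > 1e-6 * max(abs(params$y0), 1)
  new_decay_fit(params,
                se = c(A = unname(se["A"]), y0 = unname(se["y0"]),
                       lambda = unname(se["lambda"])),
                residual_rms = rms, n = length(x), method = method,
                converged = TRUE, lambda_identifiable = identifiable)
}

# orthogonal-distance refinement: minimise the sum of squared Euclidean
# distances from each (x, y) point to the curve, starting from the
# vertical-least-squares solution
odr_refine <- function(x, y, params) {
  obj <- function(th) {
    p <- decay_params(th[1], th[2], exp(th[3]), params$x0_um)
    sum(orth_dist2(x, y, p))
  }
  th0 <- c(params$A, params$y0, log(params$lambda_um))
  opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  p <- decay_params(opt$par[1], opt$par[2], exp(opt$par[3]), params$x0_um)
  list(params = p, rms = sqrt(opt$value / length(x)))
}

# squared orthogonal distance from points to the curve, via a per-point
# 1D minimisation over the curve parameter t (Newton steps from t = x_i)
orth_dist2 <- function(x, y, p) {
  f <- function(t) p$y0 + p$A * exp(-(t - p$x0_um) / p$lambda_um)
  fp <- function(t) -(p$A / p$lambda_um) * exp(-(t - p$x0_um) / p$lambda_um)
  t <- x
  for (it in 1:8) {
    ft <- f(t); dft <- fp(t)
    # minimise g(t) = (x-t)^2 + (y-f(t))^2 ; g'(t)/2 = (t-x) - (y-f)*f'
    g1 <- (t - x) - (y - ft) * dft
    d2f <- dft / p$lambda_um * -1  # second derivative of f
    g2 <- 1 + dft^2 - (y - ft) * d2f
    step <- g1 / pmax(g2, 1e-8)
    t <- t - pmin(pmax(step, -p$lambda_um), p$lambda_um)
  }
  (x - t)^2 + (y - f(t))^2
}

#' Average several decay fits into one curve
#'
#' Computes the pointwise mean of the predicted `ratio^-1` curves of the
#' converged fits on a distance grid (the "average fit" across brains), and
#' refits a single set of [decay_params()] to the averaged curve so the
#' average can be used wherever a single fit is expected.
#'
#' @param fits list of `decay_fit` objects.
#' @param distance_grid distances (um) on which curves are averaged.
#' @return list with `distance_grid`, `mean_inv_ratio` (averaged curve) and
#'   `params` (equivalent [decay_params()] refit to the curve).
#' @export
average_fit <- function(fits, distance_grid = seq(0, 150, by = 1)) {
  if (length(fits) == 0) stop("no fits to average")
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0) stop("no converged fits to average")
  curves <- vapply(conv, function(f) {
    true_inverse_ratio(distance_grid, f$params)
  }, numeric(length(distance_grid)))
  mean_curve <- rowMeans(curves)
  eq <- fit_decay(distance_grid, mean_curve, method = "least_squares",
                  x0_policy = min(distance_grid))
  list(distance_grid = distance_grid, mean_inv_ratio = mean_curve,
       params = eq$params)
}

#' Predict the hypoxia-response ratio from tracheole distance
#'
#' Inverts the fitted oxygenation model: the predicted ratio at distance
#' `d` is `1 / (y0 + A * exp(-(d - x0) / lambda))`, strictly increasing in
#' `d` for `A > 0` (cells farther from a tracheole are predicted more
#' hypoxic).
#'
#' @param fit a converged `decay_fit`.
#' @param dist_um distance(s), um.
#' @return predicted ratio(s).
#' @export
predict_ratio <- function(fit, dist_um) {
  stopifnot(inherits(fit, "decay_fit"))
  if (!isTRUE(fit$converged)) stop("cannot predict from a non-converged fit")
  1 / true_inverse_ratio(dist_um, fit$params)
}

#' Render a predicted-hypoxia heatmap
#'
#' Fills every voxel of each nucleus with the ratio predicted from that
#' nucleus's tracheole distance, background 0 -- the model-predicted
#' counterpart of the measured ratiometric image.
#'
#' @param fit a converged `decay_fit`.
#' @param labels a [label_volume()].
#' @param table nucleus table with `id` and `dist_um` for every label.
#' @param voxel_size um per voxel (z, y, x).
#' @return A single-channel [image_stack()] named `"predicted_ratio"`.
#' @export
render_prediction_map <- function(fit, labels, table, voxel_size) {
  stopifnot(inherits(labels, "label_volume"))
  ids <- seq_len(labels$n_labels)
  d <- table$dist_um[match(ids, table$id)]
  missing <- ids[is.na(d)]
  if (length(missing) > 0) {
    stop("missing dist_um for label id(s): ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  pred <- predict_ratio(fit, d)
  lab <- labels$labels
  vol <- array(0, dim(lab))
  idx <- which(lab > 0)
  vol[idx] <- pred[lab[idx]]
  image_stack(array(vol, c(1, dim(lab))), voxel_size, "predicted_ratio")
}

#' Simulate (distance, ratio^-1) points from a decay model
#'
#' Draws distances uniformly on a range, evaluates the oxygenation model
#' and applies multiplicative noise: `"gaussian"` multiplies by
#' `1 + cv * N(0, 1)`, `"lognormal"` by a mean-1 log-normal with the given
#' CV. Used for parameter-recovery experiments.
#'
#' @param n number of points.
#' @param model a [decay_params()].
#' @param dist_range range of distances, um.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param noise `"gaussian"` or `"lognormal"`.
#' @param seed RNG seed (optional).
#' @return data frame with `dist_um` and `inv_ratio`.
#' @export
simulate_decay_data <- function(n, model, dist_range = c(0, 150),
                                noise_cv = 0.08,
                                noise = c("gaussian", "lognormal"),
                                seed = NULL) {
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::runif(n, dist_range[1], dist_range[2])
  y <- true_inverse_ratio(x, model)
  if (noise_cv > 0) {
    fac <- if (noise == "gaussian") {
      1 + noise_cv * stats::rnorm(n)
    } else {
      sdlog <- sqrt(log(1 + noise_cv^2))
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    y <- y * fac
  }
  data.frame(dist_um = x, inv_ratio = pmax(y, 1e-6))
}
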