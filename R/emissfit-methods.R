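#' @export
print.emissfit <- function(x, ...) {
  est <- x$estimates
  ok <- !est$degenerate & !is.na(est$epsilon_solver)
  cat(sprintf("Floral emissivity fit (%s protocol)\n", x$protocol))
  cat(sprintf("  %d measurement points (%d flagged degenerate)\n",
              nrow(est), x$n_flagged))
  if (any(ok)) {
    m <- mean(est$epsilon_solver[ok])
    s <- if (sum(ok) > 1) stats::sd(est$epsilon_solver[ok]) else 0
    cat(sprintf("  solver emissivity: mean %.4f, sd %.4f (n = %d)\n",
                m, s, sum(ok)))
  }
  if (!is.null(x$method_comparison))
    cat(sprintf("  solver - calculated: mean %.2g +/- %.2g (SEM), n = %d\n",
                x$method_comparison$mean, x$method_comparison$sem,
                x$method_comparison$n))
  d <- x$deltas$delta[!is.na(x$deltas$delta)]
  if (length(d))
    cat(sprintf("  T_obj - T_%.2f retrieval delta: mean %.3f K (n = %d)\n",
                x$epsilon_used, mean(d), length(d)))
  invisible(x)
}

#' Summarise an emissivity fit
#'
#' Grouped emissivity summaries (mean, SD, n, SEM of the solver estimates)
#' and grouped retrieval-delta summaries, by species and location (and bath
#' temperature for water-bath fits).
#'
#' @param object an \code{emissfit}.
#' @param by grouping columns; default species x location (x bath for the
#'   water-bath protocol).
#' @param ... passed to \code{\link{summarize_estimates}}.
#' @return a list of class \code{"summary.emissfit"} with elements
#'   \code{emissivity}, \code{deltas}, \code{method_comparison}.
#' @export
summary.emissfit <- function(object, by = NULL, ...) {
  if (is.null(by)) {
    by <- c("species", "location")
    if (object$protocol == "water_bath") by <- c(by, "bath_set")
  }
  structure(list(
    emissivity = summarize_estimates(object, by = by, ...),
    deltas = summarize_deltas(object, by = by),
    method_comparison = object$method_comparison,
    protocol = object$protocol,
    n_flagged = object$n_flagged),
    class = "summary.emissfit")
}

#' @export
print.summary.emissfit <- function(x, digits = 4, ...) {
  cat(sprintf("Emissivity estimates by group (%s protocol, %d flagged)\n",
              x$protocol, x$n_flagged))
  print(format(x$emissivity, digits = digits), row.names = FALSE)
  cat("\nRetrieval deltas T_obj - T_eps (K):\n")
  print(format(x$deltas, digits = digits), row.names = FALSE)
  if (!is.null(x$method_comparison))
    cat(sprintf("\nSolver vs calculated: mean %.2g +/- %.2g (SEM), n = %d\n",
                x$method_comparison$mean, x$method_comparison$sem,
                x$method_comparison$n))
  invisible(x)
}

#' Group-mean emissivity coefficients
#'
#' @param object an \code{emissfit}.
#' @param by grouping columns (default species x location).
#' @param ... unused.
#' @return named numeric vector of group mean solver emissivities.
#' @export
coef.emissfit <- function(object, by = c("species", "location"), ...) {
  s <- summarize_estimates(object, by = by)
  stats::setNames(s$mean, do.call(paste, c(s[intersect(by, names(s))],
                                           sep = ":")))
}

#' Residuals of an emissivity fit
#'
#' \code{type = "delta_e"} (default): per-point difference between the two
#' resolutions (solver minus calculated), near zero everywhere by
#' construction on clean data. \code{type = "radiance"}: per-point radiance
#' misfit \code{W_obs - W_exp} at the solver emissivity, which the solver
#' drives to ~0. \code{type = "temperature"}: the retrieval deltas
#' \code{t_obj - t_098}.
#'
#' @param object an \code{emissfit}.
#' @param type residual type.
#' @param ... unused.
#' @export
residuals.emissfit <- function(object, type = c("delta_e", "radiance",
                                                "temperature"), ...) {
  type <- match.arg(type)
  est <- object$estimates
  if (type == "delta_e") return(est$delta_e)
  if (type == "temperature") return(object$deltas$delta)
  sc <- object$scene
  out <- rep(NA_real_, nrow(est))
  for (i in seq_len(nrow(est))) {
    if (est$degenerate[i] || is.na(est$epsilon_solver[i])) next
    sc_i <- scene_conditions(t_ref = est$t_ref[i], t_env = sc$t_env,
                             rho = sc$rho, sigma = sc$sigma)
    out[i] <- est$w_obs[i] -
      total_radiance(est$t_obj[i], est$epsilon_solver[i], sc_i)
  }
  out
}

#' Predict camera temperature retrievals at an assumed emissivity
#'
#' Applies the fixed-emissivity retrieval to the fit's measurement points
#' (or to new points) at any assumed emissivity, returning the retrieved
#' temperatures and their deltas from the known object temperatures. With
#' the default \code{epsilon = 0.98} this reproduces the fit's own
#' \code{$deltas} component.
#'
#' @param object an \code{emissfit}.
#' @param epsilon assumed emissivity.
#' @param newdata optional measurement-point data frame; defaults to the
#'   fitted points.
#' @param ... unused.
#' @return a data frame with \code{t_098} and \code{delta} columns.
#' @export
predict.emissfit <- function(object, epsilon = object$epsilon_used,
                             newdata = NULL, ...) {
  pts <- if (is.null(newdata)) object$points else newdata
  compute_t098_deltas(pts, epsilon_used = epsilon, scene = object$scene)
}

#' Plot group-mean emissivity estimates
#'
#' Mean solver emissivity per species and measurement location with +/- 1 SD
#' error bars, one panel layout shared across locations, and a dashed line
#' at the theoretical upper limit of 1.
#'
#' @param x an \code{emissfit}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.emissfit <- function(x, ...) {
  s <- summarize_estimates(x, by = c("species", "location"))
  sp <- sort(unique(s$species))
  locs <- intersect(LOCATIONS, unique(s$location))
  pch <- stats::setNames(c(19, 17, 15)[seq_along(locs)], locs)
  off <- stats::setNames(seq_along(locs) * 0.15 - 0.3, locs)
  xi <- match(s$species, sp) + off[s$location]
  ylim <- range(s$mean - s$sd, s$mean + s$sd, 1)
  graphics::plot(xi, s$mean, pch = pch[s$location], xaxt = "n",
                 xlab = "", ylab = "Emissivity estimate",
                 ylim = ylim, ...)
  graphics::arrows(xi, s$mean - s$sd, xi, s$mean + s$sd, angle = 90,
                   code = 3, length = 0.03)
  graphics::abline(h = 1, lty = 2)
  graphics::axis(1, at = seq_along(sp), labels = sp, las = 2,
                 cex.axis = 0.7)
  graphics::legend("topleft", legend = locs, pch = pch, bty = "n",
                   cex = 0.8)
  invisible(x)
}
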