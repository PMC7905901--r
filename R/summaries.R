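#' Grouped summaries of emissivity estimates
#'
#' Mean, sample standard deviation (n-1 denominator), count and standard
#' error of the mean of the solver emissivity estimates, grouped by any
#' subset of species, location, bath temperature and protocol. Degenerate
#' records are excluded from the summaries but counted. Single-record groups
#' report sd and sem of 0 and are flagged.
#'
#' @param estimates output of \code{\link{solve_emissivity_batch}} or an
#'   \code{emissfit} object.
#' @param by grouping columns, a subset of \code{c("species", "location",
#'   "bath_set", "protocol")}.
#' @param value which estimate to summarise: "epsilon_solver" (default,
#'   matching the analysed quantity), "epsilon_calc", or
#'   "epsilon_calc_raw" (the unscreened closed form, wild outliers and
#'   all).
#' @param include_degenerate if \code{TRUE}, degenerate records with a
#'   finite raw closed-form value are kept, reproducing the outlier-bearing
#'   summaries of the retain-everything convention. Default \code{FALSE}.
#' @return a data frame with the grouping columns plus \code{mean},
#'   \code{sd}, \code{n}, \code{sem}, \code{n_flagged},
#'   \code{single_record}, sorted by group key.
#' @export
summarize_estimates <- function(estimates, by = c("species", "location"),
                                value = c("epsilon_solver", "epsilon_calc",
                                          "epsilon_calc_raw"),
                                include_degenerate = FALSE) {
  if (inherits(estimates, "emissfit")) estimates <- estimates$estimates
  value <- match.arg(value)
  allowed <- c("species", "location", "bath_set", "protocol")
  if (!length(by) || !all(by %in% allowed))
    stop("grouping must be a non-empty subset of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  by <- by[by %in% names(estimates)]
  if (!length(by)) stop("no grouping columns present in data", call. = FALSE)
  v <- estimates[[value]]
  if (include_degenerate && value == "epsilon_solver" &&
      "epsilon_calc_raw" %in% names(estimates)) {
    fill <- is.na(v) & !is.na(estimates$epsilon_calc_raw)
    v[fill] <- estimates$epsilon_calc_raw[fill]
  }
  keep <- if (include_degenerate) !is.na(v) & is.finite(v) else
    !estimates$degenerate & !is.na(v)
  .group_summary(estimates[keep, by, drop = FALSE], v[keep],
                 n_flagged_total = sum(!keep))
}

.group_summary <- function(keys, v, n_flagged_total = 0L) {
  if (!nrow(keys) || !length(v))
    stop("no records to summarise", call. = FALSE)
  key <- interaction(keys, drop = TRUE, lex.order = TRUE, sep = "\r")
  idx <- split(seq_along(v), key)
  out <- do.call(rbind, lapply(names(idx), function(kk) {
    i <- idx[[kk]]
    parts <- strsplit(kk, "\r", fixed = TRUE)[[1L]]
    g <- as.data.frame(as.list(parts), stringsAsFactors = FALSE)
    names(g) <- names(keys)
    n <- length(i)
    s <- if (n > 1L) stats::sd(v[i]) else 0
    cbind(g, data.frame(mean = mean(v[i]), sd = s, n = n,
                        sem = if (n > 1L) s / sqrt(n) else 0,
                        single_record = n == 1L))
  }))
  out <- out[do.call(order, out[names(keys)]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_flagged") <- n_flagged_total
  out
}

#' Grouped summaries of fixed-emissivity retrieval deltas
#'
#' Per-group mean +/- SEM of the temperature difference between the known
#' object temperature and the temperature retrieved at the assumed
#' emissivity (T_obj - T_0.98), plus a pooled "Average" row per protocol
#' (and bath temperature where applicable). By default the Average row pools
#' all measurement points; \code{average = "species_means"} instead averages
#' the per-species means (both conventions exist because pooled and
#' mean-of-means averages differ whenever replication is unbalanced).
#'
#' @param deltas output of \code{\link{compute_t098_deltas}} or an
#'   \code{emissfit} object.
#' @param by grouping columns, as in \code{\link{summarize_estimates}}.
#' @param average pooling convention for the Average row.
#' @return a data frame as in \code{\link{summarize_estimates}}, with
#'   species \code{"Average"} rows appended.
#' @export
summarize_deltas <- function(deltas, by = c("species", "location"),
                             average = c("points", "species_means")) {
  if (inherits(deltas, "emissfit")) deltas <- deltas$deltas
  average <- match.arg(average)
  allowed <- c("species", "location", "bath_set", "protocol")
  if (!length(by) || !all(by %in% allowed))
    stop("grouping must be a non-empty subset of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  by <- by[by %in% names(deltas)]
  keep <- !is.na(deltas$delta)
  if ("flag" %in% names(deltas))
    keep <- keep & (deltas$flag %in% c("", "water_temp_crosscheck",
                                       "bath_temp_deviation"))
  out <- .group_summary(deltas[keep, by, drop = FALSE],
                        deltas$delta[keep], sum(!keep))
  # pooled Average row(s) across species, per remaining grouping
  if ("species" %in% by) {
    rest <- setdiff(by, "species")
    d <- deltas[keep, , drop = FALSE]
    if (average == "points") {
      keys <- if (length(rest)) d[, rest, drop = FALSE]
        else data.frame(.all = rep("all", nrow(d)))
      avg <- .group_summary(keys, d$delta)
    } else {
      per_sp <- .group_summary(d[, by, drop = FALSE], d$delta)
      keys <- if (length(rest)) per_sp[, rest, drop = FALSE]
        else data.frame(.all = rep("all", nrow(per_sp)))
      avg <- .group_summary(keys, per_sp$mean)
    }
    avg$.all <- NULL
    avg$species <- "Average"
    missing_cols <- setdiff(names(out), names(avg))
    for (mc in missing_cols) avg[[mc]] <- NA
    out <- rbind(out, avg[names(out)])
    rownames(out) <- NULL
  }
  out
}
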