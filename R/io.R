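# Header normalisation for the deposited-table dialects. Spreadsheet exports
# of the protocol tables vary in case, spacing and punctuation; names are
# folded (lowercase, alphanumerics only) and matched against the known
# semantic columns. Unknown columns are preserved untouched.
.fold_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.canonical_header <- function(nm) {
  f <- .fold_header(nm)
  out <- nm
  for (i in seq_along(f)) {
    h <- f[i]
    out[i] <-
      if (grepl("individualwithinspecies", h)) "individual_within_species"
      else if (h == "individual") "individual"
      else if (h == "species") "species"
      else if (grepl("measurementlocation", h)) "measurement_location"
      else if (h == "measurement") "measurement"
      else if (grepl("thermometer", h)) "thermometer_c"
      else if (grepl("thermocouple", h)) "thermocouple_c"
      else if (grepl("settemp", h) || grepl("bathset", h)) "bath_set"
      else if (grepl("watertapp", h)) "water_tapp_k"
      else if (grepl("irttemp", h) || grepl("watert098", h)) "water_t098_k"
      else if (grepl("deltatobj", h)) "delta_t098"
      else if (grepl("deltae", h)) "deltae"
      else if (grepl("^tobj", h)) "tobj_k"
      else if (grepl("^tref", h)) "tref_k"
      else if (grepl("e1d0", h) || grepl("uncorrected", h) ||
               grepl("^tapp", h)) "tapp_k"
      else if (grepl("e098", h)) "t_e098_k"
      else if (h == "ecal") "ecal"
      else if (h == "esolve") "esolve"
      else nm[i]
  }
  out
}

.detect_delim <- function(path) {
  line1 <- readLines(path, n = 1L)
  if (!length(line1)) stop("empty file: ", path, call. = FALSE)
  if (lengths(regmatches(line1, gregexpr("\t", line1))) >=
      lengths(regmatches(line1, gregexpr(",", line1)))) "\t" else ","
}

.numeric_cols <- c("thermocouple_c", "tobj_k", "tref_k", "tapp_k",
                   "water_tapp_k", "water_t098_k", "t_e098_k", "delta_t098",
                   "thermometer_c", "ecal", "esolve", "deltae",
                   "individual", "individual_within_species")

#' Read a protocol measurement table
#'
#' Reads a delimiter-separated measurement table in either protocol dialect.
#' Header names are normalised case-insensitively with whitespace and
#' punctuation folding, so both this package's canonical headers and the
#' verbose spreadsheet-export headers of deposited datasets are accepted;
#' unknown extra columns are preserved. The delimiter (comma or tab) is
#' auto-detected unless given. Location codes such as "A: repro struc" are
#' kept verbatim here and mapped by the point builders.
#'
#' @param path file path.
#' @param dialect "auto" (infer from columns), "thermocouple" or
#'   "water_bath"; a named dialect enforces that protocol's required
#'   columns.
#' @param delim field delimiter; \code{NULL} auto-detects comma vs tab.
#' @return a data frame with canonical column names. Cells that failed
#'   numeric parsing are \code{NA} and recorded (row and column) in the
#'   \code{"bad_cells"} attribute.
#' @export
read_measurement_table <- function(path,
                                   dialect = c("auto", "thermocouple",
                                               "water_bath"),
                                   delim = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- .detect_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  names(raw) <- .canonical_header(names(raw))
  bad <- NULL
  for (cc in intersect(.numeric_cols, names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    miss <- which(is.na(v) & nzchar(trimws(raw[[cc]])))
    if (length(miss))
      bad <- rbind(bad, data.frame(row = miss, column = cc,
                                   stringsAsFactors = FALSE))
    raw[[cc]] <- v
  }
  if (dialect == "thermocouple") {
    .require_cols(raw, c("species", "measurement_location", "tapp_k"))
    if (!any(c("tobj_k", "thermocouple_c") %in% names(raw)))
      stop("missing required column(s): tobj_k (or thermocouple_c)",
           call. = FALSE)
  } else if (dialect == "water_bath") {
    .require_cols(raw, c("species", "measurement_location", "bath_set",
                         "tapp_k", "tref_k"))
    if (!any(c("water_tapp_k", "water_t098_k") %in% names(raw)))
      stop("missing required column(s): water_tapp_k (or water_t098_k)",
           call. = FALSE)
  }
  attr(raw, "bad_cells") <- bad
  attr(raw, "dialect") <- if (dialect != "auto") dialect
    else if ("bath_set" %in% names(raw)) "water_bath" else "thermocouple"
  raw
}

#' Write a measurement or estimate table
#'
#' Writes a data frame as delimiter-separated text with canonical headers;
#' the exact inverse of \code{\link{read_measurement_table}} for canonical
#' tables (write-then-read round trips are identical up to numeric
#' printing, which uses full precision).
#'
#' @param x data frame.
#' @param path output path.
#' @param delim field delimiter.
#' @export
write_measurement_table <- function(x, path, delim = ",") {
  utils::write.table(x, path, sep = delim, row.names = FALSE, quote = TRUE,
                     qmethod = "double")
  invisible(path)
}

#' Write a grouped summary table in the deposited-summary dialect
#'
#' Emits the column dialect of the published summary tables: species,
#' measurement.location, then \code{<prefix>.mean}, \code{<prefix>.SD},
#' \code{<prefix>.Count}, \code{<prefix>.SEM}, plus
#' Set.temperature.of.waterbath when a bath column is present.
#'
#' @param s a summary data frame from \code{\link{summarize_estimates}} or
#'   \code{\link{summarize_deltas}}.
#' @param path output path.
#' @param prefix estimate-column prefix, e.g. "Esolve" or "Ecal".
#' @param delim field delimiter.
#' @export
write_summary_table <- function(s, path, prefix = "Esolve", delim = ",") {
  out <- list()
  if ("species" %in% names(s)) out$species <- s$species
  if ("location" %in% names(s)) {
    codes <- c(reproductive_structures = "A: repro struc",
               petal_base = "B: petal base", petal_edge = "C: petal edge")
    lab <- s$location
    mapped <- !is.na(lab) & lab %in% names(codes)
    lab[mapped] <- codes[lab[mapped]]
    out$measurement.location <- lab
  }
  if ("bath_set" %in% names(s))
    out$Set.temperature.of.waterbath <- s$bath_set
  out[[paste0(prefix, ".mean")]] <- s$mean
  out[[paste0(prefix, ".SD")]] <- s$sd
  out[[paste0(prefix, ".Count")]] <- s$n
  out[[paste0(prefix, ".SEM")]] <- s$sem
  out <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = TRUE, qmethod = "double")
  invisible(path)
}
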