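#' Assay time course container
#'
#' One trace from a kinetic assay: sampling times, the measured signal and
#' bookkeeping metadata. Times are minutes for the enzymology assays and
#' seconds for SPR; the unit travels with the object and with its CSV form.
#'
#' @param times Strictly increasing numeric vector, first element >= 0.
#' @param values Numeric signal, same length as `times` (cpm-equivalent nM for
#'   radioligand assays, mol Pi / mol Galpha for turnover, relative
#'   fluorescence units, or RU for SPR).
#' @param assay_kind One of `"gtpgs_binding"`, `"single_turnover"`,
#'   `"steady_state"`, `"fluorescence"`, `"spr"`.
#' @param unit Time unit, `"min"` or `"s"`.
#' @param meta Named list of free-form metadata (protein concentration,
#'   specific activity, noise sd, seed, replicate id, ...).
#' @return An object of class `time_course`.
#' @export
time_course <- function(times, values,
                        assay_kind = c("gtpgs_binding", "single_turnover",
                                       "steady_state", "fluorescence", "spr"),
                        unit = c("min", "s"), meta = list()) {
  assay_kind <- match.arg(assay_kind)
  unit <- match.arg(unit)
  check_times(times)
  if (!is.numeric(values) || length(values) != length(times))
    stop("values must be numeric and the same length as times", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 assay_kind = assay_kind, unit = unit, meta = meta),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> %s: %d points over [%g, %g] %s\n",
              x$assay_kind, length(x$times), min(x$times), max(x$times),
              x$unit))
  invisible(x)
}

#' Write / read assay time courses as CSV
#'
#' The on-disk dialect is a plain CSV with columns `time`, `value`,
#' `replicate`, preceded by comment lines `# unit=<min|s>` and
#' `# assay=<kind>`. Replicate traces of one assay share a file.
#'
#' @param tcs A `time_course` or list of them (replicates of one assay).
#' @param path Output CSV path.
#' @return `write_time_course_csv` returns `path` invisibly;
#'   `read_time_course_csv` returns a list of `time_course` objects.
#' @export
write_time_course_csv <- function(tcs, path) {
  if (inherits(tcs, "time_course")) tcs <- list(tcs)
  stopifnot(length(tcs) >= 1L, all(vapply(tcs, inherits, TRUE, "time_course")))
  unit <- tcs[[1]]$unit
  kind <- tcs[[1]]$assay_kind
  rows <- do.call(rbind, lapply(seq_along(tcs), function(i) {
    data.frame(time = tcs[[i]]$times, value = tcs[[i]]$values, replicate = i)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# unit=%s", unit), sprintf("# assay=%s", kind)), con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_time_course_csv
#' @export
read_time_course_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_tag <- function(tag, default) {
    m <- grep(sprintf("^#\\s*%s=", tag), hdr, value = TRUE)
    if (length(m)) sub(sprintf("^#\\s*%s=", tag), "", m[1]) else default
  }
  unit <- get_tag("unit", "min")
  kind <- get_tag("assay", "gtpgs_binding")
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path, call. = FALSE)
  if (is.null(df$replicate)) df$replicate <- 1L
  lapply(split(df, df$replicate), function(d) {
    d <- d[order(d$time), ]
    time_course(d$time, d$value, assay_kind = kind, unit = unit,
                meta = list(source = path, replicate = d$replicate[1]))
  })
}

#' SPR sensorgram container
#'
#' Response trace of one analyte concentration over an association phase
#' followed by a dissociation phase.
#'
#' @param times Seconds from injection start, strictly increasing.
#' @param response Response units (RU), same length as `times`.
#' @param conc Analyte concentration, M.
#' @param t_assoc End of the association phase, s; later times are
#'   dissociation.
#' @param meta Named list of metadata.
#' @return An object of class `sensorgram`.
#' @export
sensorgram <- function(times, response, conc, t_assoc, meta = list()) {
  check_times(times)
  if (length(response) != length(times))
    stop("response must match times in length", call. = FALSE)
  if (!is.numeric(conc) || length(conc) != 1L || conc <= 0)
    stop("conc must be a single positive concentration in M", call. = FALSE)
  if (t_assoc <= 0) stop("t_assoc must be positive", call. = FALSE)
  structure(list(times = as.numeric(times), response = as.numeric(response),
                 conc = as.numeric(conc), t_assoc = as.numeric(t_assoc),
                 meta = meta),
            class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("<sensorgram> C = %.3g M, %d points, assoc 0-%g s\n",
              x$conc, length(x$times), x$t_assoc))
  invisible(x)
}

#' Write / read SPR sensorgram series as CSV
#'
#' Columns: `time_s`, `response_RU`, `conc_M`, `phase` (`assoc`/`dissoc`).
#' All concentrations of one series share a file.
#'
#' @param series A `sensorgram` or list of them.
#' @param path CSV path.
#' @return `write_sensorgram_csv` returns `path` invisibly;
#'   `read_sensorgram_csv` returns a list of `sensorgram` objects sorted by
#'   concentration.
#' @export
write_sensorgram_csv <- function(series, path) {
  if (inherits(series, "sensorgram")) series <- list(series)
  stopifnot(all(vapply(series, inherits, TRUE, "sensorgram")))
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(time_s = s$times, response_RU = s$response, conc_M = s$conc,
               phase = ifelse(s$times <= s$t_assoc, "assoc", "dissoc"))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensorgram_csv
#' @export
read_sensorgram_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("time_s", "response_RU", "conc_M", "phase")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(df, df$conc_M), function(d) {
    d <- d[order(d$time_s), ]
    t_assoc <- max(d$time_s[d$phase == "assoc"])
    sensorgram(d$time_s, d$response_RU, conc = d$conc_M[1], t_assoc = t_assoc,
               meta = list(source = path))
  })
  out[order(vapply(out, function(s) s$conc, 0))]
}
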