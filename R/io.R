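# CSV dialect: comment-style header lines "# key: value" carrying the
# metadata, then a standard header row "frequency_MHz,R1_per_s[,sigma_per_s]".
# Frequencies are serialized in MHz, rates in s^-1, times in s, angles in
# degrees and dipolar constants in rad^2 s^-2 throughout, and the units are
# echoed in the header to keep the rad^2-vs-Hz^2 ambiguity out of the files.

.schema_version <- "1"

#' Read / write relaxation profiles
#'
#' `write_profile()` serializes a [relaxation_profile()] to a CSV file with
#' `# key: value` metadata headers; `read_profile()` parses it back.  The
#' round trip is lossless for values and metadata.  Rows are checked and
#' malformed ones reported with their line numbers; decreasing frequency
#' grids are rejected unless the rows merely need re-sorting (then they are
#' sorted with a message).
#'
#' @param path file path
#' @param profile a [relaxation_profile()]
#' @return `read_profile()` returns a [relaxation_profile()];
#'   `write_profile()` returns `path` invisibly.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      key <- trimws(m[2]); val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  cols <- strsplit(body[1], ",")[[1]]
  if (!("frequency_MHz" %in% cols))
    stop("missing column 'frequency_MHz' in ", path, call. = FALSE)
  if (!("R1_per_s" %in% cols))
    stop("missing column 'R1_per_s' in ", path, call. = FALSE)
  rows <- strsplit(body[-1], ",")
  bad <- which(lengths(rows) != length(cols))
  if (length(bad))
    stop(sprintf("malformed row(s) at data line(s) %s of %s",
                 paste(bad + 1, collapse = ", "), path), call. = FALSE)
  d <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(d) <- cols
  num <- lapply(d, function(v) suppressWarnings(as.numeric(v)))
  for (cn in c("frequency_MHz", "R1_per_s"))
    if (any(is.na(num[[cn]])))
      stop(sprintf("non-numeric value in column '%s' at data line(s) %s of %s",
                   cn, paste(which(is.na(num[[cn]])) + 1, collapse = ", "),
                   path), call. = FALSE)
  f <- num$frequency_MHz; r <- num$R1_per_s
  s <- num$sigma_per_s
  if (is.unsorted(f, strictly = TRUE)) {
    o <- order(f)
    if (any(duplicated(f)))
      stop("duplicated frequencies in ", path, call. = FALSE)
    message("re-sorting profile rows by increasing frequency")
    f <- f[o]; r <- r[o]; if (!is.null(s)) s <- s[o]
  }
  # strip bookkeeping keys that are not profile metadata
  meta$schema_version <- NULL
  meta$units <- NULL
  relaxation_profile(f, r, uncertainties = s, metadata = meta)
}

#' @rdname read_profile
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "relaxation_profile"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# schema_version: %s", .schema_version), con)
  writeLines("# units: frequency_MHz, R1 s^-1", con)
  for (k in names(profile$metadata))
    writeLines(sprintf("# %s: %s", k,
                       format(profile$metadata[[k]], digits = 15)), con)
  d <- as.data.frame(profile)
  writeLines(paste(names(d), collapse = ","), con)
  # %.17g guarantees an exact double round trip
  rows <- do.call(paste, c(lapply(d, function(col) sprintf("%.17g", col)),
                           sep = ","))
  writeLines(rows, con)
  invisible(path)
}

#' Serialize fit results and validity scans
#'
#' `write_fit_result()` writes an `nmrd_fit` as JSON (schema version,
#' input checksum, configuration echo, fixed and fitted parameters with
#' relative uncertainties, per-component decomposition on the fitted
#' grid).  `read_fit_result()` reloads it.  `write_validity_scan()` writes
#' the per-(x, frequency) curves of an [sle_validity_scan()] as CSV with
#' `# key: value` headers, one row per (x, frequency) pair, with the per-x
#' summary embedded in the header.
#'
#' @param fit an `nmrd_fit`
#' @param path output path
#' @param profile optional profile the fit was computed from (adds an
#'   input checksum and the decomposition on the profile grid)
#' @param config_echo optional list echoed verbatim into the output
#' @return the path, invisibly (`read_fit_result()`: a list)
#' @export
write_fit_result <- function(fit, path, profile = NULL, config_echo = NULL) {
  stopifnot(inherits(fit, "nmrd_fit"))
  obj <- list(
    schema_version = .schema_version,
    generator = "nmrdfit",
    config_echo = config_echo,
    fixed = list(a_Q_MHz = fit$fixed$a_Q, eta = fit$fixed$eta),
    parameters = list(
      C_s = fit$hh$slow$C, tau_s = fit$hh$slow$tau,
      C_i = fit$hh$intermediate$C, tau_i = fit$hh$intermediate$tau,
      C_f = fit$hh$fast$C, tau_f = fit$hh$fast$tau,
      A = fit$hh$A, C_HN = fit$hn$C_HN, tau_Q = fit$hn$tau_Q,
      theta_deg = fit$hn$theta, phi_deg = fit$hn$phi),
    units = list(C = "rad^2 s^-2", tau = "s", A = "s^-1",
                 angles = "degrees"),
    rel_uncertainty = as.list(fit$rel_uncertainty),
    relative_error_percent = fit$relative_error,
    tau_Q_init = fit$tau_Q_init,
    tau_Q_at_bound = fit$tau_Q_at_bound,
    converged = fit$converged,
    n_points = fit$n_points)
  if (!is.null(profile)) {
    obj$input_checksum <- .profile_checksum(profile)
    obj$decomposition <- decompose(fit, profile$frequencies)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_result
#' @export
read_fit_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname write_fit_result
#' @param scan an [sle_validity_scan()]
#' @export
write_validity_scan <- function(scan, path, config_echo = NULL) {
  stopifnot(inherits(scan, "sle_validity_scan"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# schema_version: %s", .schema_version), con)
  writeLines(sprintf("# a_Q_MHz: %g", scan$quad$a_Q), con)
  writeLines(sprintf("# eta: %g", scan$quad$eta), con)
  writeLines(sprintf("# C_HN: %g", scan$C_HN), con)
  writeLines(sprintf("# L_max: %d", scan$L_max), con)
  if (!is.null(config_echo))
    for (k in names(config_echo))
      writeLines(sprintf("# %s: %s", k, format(config_echo[[k]])), con)
  for (i in seq_len(nrow(scan$summary)))
    writeLines(sprintf(
      "# summary_x_%g: tau_Q=%g max_rel_dev=%.6g mean_rel_dev=%.6g",
      scan$summary$x[i], scan$summary$tau_Q[i],
      scan$summary$max_rel_dev[i], scan$summary$mean_rel_dev[i]), con)
  utils::write.table(scan$curves, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.profile_checksum <- function(profile) {
  v <- c(profile$frequencies, profile$rates)
  # order-sensitive FNV-style hash over the rounded decimal representation
  s <- paste(sprintf("%.10e", v), collapse = ",")
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
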