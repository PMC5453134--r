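#' Read and write stress-stretch curves as CSV
#'
#' Curves are exchanged as plain CSV with columns
#' \code{stretch,stress,phase,cycle} (\code{phase}/\code{cycle} optional:
#' missing phases are inferred by monotonicity segmentation of the strain
#' intensity, exactly as the cycle simulator labels them). Metadata (stress
#' kind and unit) is stored in leading \code{#} comment lines and round-trips.
#'
#' @param path file path.
#' @return \code{read_curve} returns a \code{"stress_stretch_curve"};
#'   \code{write_curve} invisibly returns \code{path}.
#' @name curve-io
NULL

#' @rdname curve-io
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("no such file: %s", path))
  lines <- readLines(path)
  meta_n <- 0L
  stress_kind <- "engineering"; unit <- "unknown"
  while (meta_n < length(lines) && startsWith(lines[meta_n + 1L], "#")) {
    meta_n <- meta_n + 1L
    ln <- sub("^#\\s*", "", lines[meta_n])
    if (grepl("^stress_kind:", ln))
      stress_kind <- trimws(sub("^stress_kind:", "", ln))
    if (grepl("^unit:", ln)) unit <- trimws(sub("^unit:", "", ln))
  }
  body <- lines[(meta_n + 1L):length(lines)]
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE),
    error = function(e) stop_domain(sprintf("cannot parse CSV %s: %s",
                                            path, conditionMessage(e))))
  if (!all(c("stretch", "stress") %in% names(df)))
    stop_domain(sprintf(
      "%s: required columns `stretch` and `stress` not found (got: %s)",
      path, paste(names(df), collapse = ", ")))
  # data row i lives on file line meta_n + 1 (header) + i
  line_of <- function(i) meta_n + 1L + i
  for (col in c("stretch", "stress")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop_domain(sprintf("%s: non-numeric `%s` entry at line %d",
                          path, col, line_of(bad)))
    }
    if (anyNA(v))
      stop_domain(sprintf("%s: missing `%s` value at line %d",
                          path, col, line_of(which(is.na(v))[1])))
  }
  if (any(df$stretch <= 0))
    stop_domain(sprintf("%s: non-positive stretch at line %d",
                        path, line_of(which(df$stretch <= 0)[1])))
  if (is.null(df$phase)) df$phase <- infer_phases(df$stretch)
  if (is.null(df$cycle)) df$cycle <- infer_cycles(df$phase)
  new_curve(df[, c("stretch", "stress", "phase", "cycle")],
            stress_kind = stress_kind, unit = unit)
}

#' @rdname curve-io
#' @param curve a \code{"stress_stretch_curve"} (or any data frame with
#'   \code{stretch} and \code{stress} columns).
#' @export
write_curve <- function(curve, path) {
  kind <- attr(curve, "stress_kind"); if (is.null(kind)) kind <- "engineering"
  unit <- attr(curve, "unit"); if (is.null(unit)) unit <- "unknown"
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# stress_kind: %s", kind),
               sprintf("# unit: %s", unit)), con)
  df <- as.data.frame(curve)
  for (col in c("stretch", "stress"))
    df[[col]] <- format(df[[col]], digits = 15, trim = TRUE,
                        scientific = FALSE)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# label samples loading/unloading/reloading from the stretch path alone,
# mirroring the simulator's rule: primary path = running max of m
infer_phases <- function(stretch) {
  m <- strain_intensity(stretch)
  runmax <- cummax(m)
  virgin <- m >= runmax * (1 - 1e-12)
  phase <- character(length(stretch))
  for (i in seq_along(stretch)) {
    if (virgin[i]) phase[i] <- "loading"
    else phase[i] <- if (i > 1L && m[i] < m[i - 1L]) "unloading" else "reloading"
  }
  phase
}

infer_cycles <- function(phase) {
  cycle <- integer(length(phase)); cyc <- 1L
  for (i in seq_along(phase)) {
    if (i > 1L && phase[i - 1L] == "unloading" && phase[i] != "unloading")
      cyc <- cyc + 1L
    cycle[i] <- cyc
  }
  cycle
}
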