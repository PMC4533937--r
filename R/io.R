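# Plain-text I/O: sparse kernel export as coordinate triplets, flat
# key-value configuration files, and TSV tables with '#' provenance
# headers. A single dialect (tab-separated, header row, '#' comments)
# keeps every output diff-able and dataframe-friendly.

#' Export a transition kernel as coordinate-format triplets
#'
#' Writes the sparse kernel as tab-separated `(row, col, probability)`
#' triplets (1-based indices), preceded by `#` header lines recording the
#' capacity `n`, the parameters, and the state-ordering convention
#' (lexicographic in `(i1, j1, i2, j2)`), so the file is self-describing
#' and bit-reproducible.
#'
#' @param kernel A `"kmt_kernel"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kernel_triplets <- function(kernel, path) {
  kernel <- as_kmt_kernel(kernel)
  tm <- methods::as(kernel$matrix, "TsparseMatrix")
  ord <- order(tm@i, tm@j)
  df <- data.frame(row = tm@i[ord] + 1L, col = tm@j[ord] + 1L,
                   probability = tm@x[ord])
  pars <- kernel$params
  hdr <- c(
    sprintf("# kMT attachment transition kernel, %d x %d",
            kernel$space$S, kernel$space$S),
    sprintf("# n=%d p=%g q=%g alpha=%g beta=%g gamma=%g mode=%s",
            pars$n, pars$p, pars$q, pars$alpha, pars$beta, pars$gamma,
            pars$mode),
    "# state order: lexicographic in (i1, j1, i2, j2), 1-based indices")
  write_tsv(df, path, hdr)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Parses lines of the form `key = value` (or `key value`), ignoring
#' blank lines and `#` comments. Recognised keys: `n, p, q, alpha, beta,
#' gamma, mode, seed, horizon, k`; numeric values are converted.
#'
#' @param path Path to the configuration file.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=[:space:]]+")[[1]]
    kv <- kv[nzchar(kv)]
    if (length(kv) != 2L)
      stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    val <- kv[2]
    num <- suppressWarnings(as.numeric(val))
    out[[kv[1]]] <- if (is.na(num)) val else num
  }
  out
}

#' Write a flat key-value configuration file
#'
#' @param config Named list (e.g. from [read_config()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  lines <- vapply(names(config), function(k)
    sprintf("%s = %s", k, format(config[[k]], digits = 17)), character(1))
  writeLines(lines, path)
  invisible(path)
}

# TSV with '#' provenance header; path "" or NULL writes to stdout
write_tsv <- function(df, path, header_lines = character(0)) {
  con <- if (is.null(path) || identical(path, "") || identical(path, "-"))
    stdout() else file(path, open = "wt")
  if (!identical(con, stdout())) on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
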