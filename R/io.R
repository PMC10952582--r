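## Text formats: traces are tab-separated with "# key = value" metadata
## headers; schemes/rate sets are YAML; dose-response tables are CSV.

.metaScalar <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

#' Write / read a current trace as delimited text
#'
#' Traces are stored as tab-separated `time_s` / `current` columns preceded
#' by `# key = value` metadata lines (scheme id, rate provenance, protocol
#' epochs, sampling interval, noise seed, ...). A write -> read round trip
#' preserves the samples exactly and the metadata key-values.
#'
#' @param trace a [CurrentTrace-class].
#' @param path file path.
#' @return `writeTrace()` returns `path` invisibly; `readTrace()` returns a
#'   [CurrentTrace-class].
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "CurrentTrace"))
  md <- trace@metadata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# gabakin trace v1", con)
  ep <- md$epochs
  for (nm in setdiff(names(md), "epochs")) {
    val <- md[[nm]]
    if (is.null(val) || length(val) != 1L) next
    writeLines(sprintf("# %s = %s", nm, .metaScalar(val)), con)
  }
  if (!is.null(ep)) {
    for (i in seq_len(nrow(ep)))
      writeLines(sprintf("# epoch = %s,%s,%s,%s", ep$label[i],
                         .metaScalar(ep$duration_s[i]),
                         .metaScalar(ep$gaba_M[i]),
                         .metaScalar(ep$analogue_M[i])), con)
  }
  writeLines("time_s\tcurrent", con)
  writeLines(sprintf("%.17g\t%.17g", trace@time, trace@current), con)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  lines <- readLines(path)
  meta <- list()
  ep <- list()
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    body <- sub("^#\\s*", "", lines[i])
    if (grepl("=", body, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", body))
      val <- trimws(sub("^[^=]*=", "", body))
      if (key == "epoch") {
        parts <- strsplit(val, ",", fixed = TRUE)[[1]]
        if (length(parts) != 4L)
          stop(sprintf("malformed epoch metadata at line %d", i))
        ep[[length(ep) + 1L]] <- data.frame(
          label = parts[1], duration_s = as.numeric(parts[2]),
          gaba_M = as.numeric(parts[3]), analogue_M = as.numeric(parts[4]),
          stringsAsFactors = FALSE)
      } else {
        num <- suppressWarnings(as.numeric(val))
        meta[[key]] <- if (!is.na(num)) num else val
      }
    }
    i <- i + 1L
  }
  if (i > length(lines))
    stop("no column header found in trace file")
  header <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
  for (needed in c("time_s", "current"))
    if (!(needed %in% header))
      stop(sprintf("trace file is missing the '%s' column (line %d)",
                   needed, i))
  body <- lines[seq.int(i + 1L, length.out = length(lines) - i)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(header))
  if (length(bad))
    stop(sprintf("ragged row in trace file at line %d", i + bad[1]))
  m <- matrix(as.numeric(unlist(fields)), ncol = length(header),
              byrow = TRUE, dimnames = list(NULL, header))
  if (any(!is.finite(m)))
    stop("non-numeric sample values in trace file")
  if (length(ep)) {
    epdf <- do.call(rbind, ep)
    epdf$start_s <- c(0, cumsum(epdf$duration_s))[seq_len(nrow(epdf))]
    meta$epochs <- epdf
  }
  new("CurrentTrace", time = m[, "time_s"], current = m[, "current"],
      metadata = meta)
}

#' Write / read a kinetic scheme + rate set as a YAML config
#'
#' The config schema has keys `id`, `resting`, `states`, `conducting`,
#' `transitions` (list of `from`/`to`/`rate`/`ligand` records) and `rates`
#' (map rate id -> `value`/`units`). Packaged models ship in exactly this
#' schema, so user-defined schemes are first-class. Validation is strict and
#' errors name the offending key.
#'
#' @param scheme a [KineticScheme-class].
#' @param rates a [RateSet-class].
#' @param path file path.
#' @return `writeSchemeConfig()` returns `path` invisibly;
#'   `readSchemeConfig()` returns `list(scheme =, rates =)`.
#' @export
writeSchemeConfig <- function(scheme, rates, path) {
  stopifnot(is(scheme, "KineticScheme"), is(rates, "RateSet"))
  tr <- scheme@transitions
  u <- rates@units
  cfg <- list(
    id = scheme@id, resting = scheme@resting,
    states = as.list(scheme@states),
    conducting = as.list(scheme@conducting),
    transitions = lapply(seq_len(nrow(tr)), function(i)
      list(from = tr$from[i], to = tr$to[i], rate = tr$rate[i],
           ligand = tr$ligand[i])),
    rates = lapply(stats::setNames(names(rates@values), names(rates@values)),
      function(nm) list(value = unname(rates@values[[nm]]),
                        units = if (length(u)) unname(u[[nm]]) else ""))
  )
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

#' @rdname writeSchemeConfig
#' @export
readSchemeConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such scheme config: %s", path))
  cfg <- yaml::read_yaml(path)
  for (key in c("id", "resting", "states", "conducting", "transitions",
                "rates"))
    if (is.null(cfg[[key]]))
      stop(sprintf("scheme config %s is missing required key '%s'",
                   path, key))
  tr <- do.call(rbind, lapply(seq_along(cfg$transitions), function(i) {
    t1 <- cfg$transitions[[i]]
    for (key in c("from", "to", "rate", "ligand"))
      if (is.null(t1[[key]]))
        stop(sprintf("transition %d in %s is missing '%s'", i, path, key))
    data.frame(from = t1$from, to = t1$to, rate = t1$rate,
               ligand = t1$ligand, stringsAsFactors = FALSE)
  }))
  vals <- vapply(cfg$rates, function(r) {
    if (is.null(r$value) || !is.numeric(r$value))
      stop(sprintf("rate entries in %s need a numeric 'value'", path))
    r$value
  }, numeric(1))
  units <- vapply(cfg$rates, function(r)
    if (is.null(r$units)) "" else r$units, character(1))
  scheme <- kineticScheme(
    states = unlist(cfg$states), conducting = unlist(cfg$conducting),
    transitions = tr, resting = cfg$resting, id = cfg$id)
  rates <- rateSet(vals, units, provenance = sprintf("config %s", basename(path)))
  list(scheme = scheme, rates = rates)
}

#' Write / read a dose-response table as CSV
#'
#' Columns `concentration_M`, `response` and optionally `response_se`;
#' `#`-prefixed lines carry metadata and are ignored on read.
#'
#' @param table `data.frame` with at least `concentration_M` and `response`.
#' @param path file path.
#' @param meta optional named list written as comment headers.
#' @return `writeDoseResponse()` returns `path` invisibly;
#'   `readDoseResponse()` returns a `data.frame`.
#' @export
writeDoseResponse <- function(table, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s = %s", nm, .metaScalar(meta[[nm]])), con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDoseResponse
#' @export
readDoseResponse <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (needed in c("concentration_M", "response"))
    if (!(needed %in% names(tab)))
      stop(sprintf("dose-response table is missing the '%s' column", needed))
  tab
}
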