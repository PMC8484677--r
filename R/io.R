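## File I/O and the staged pipeline. Delimited format: comma-separated,
## period decimal mark, optional single header row of feature labels.
## The binary container for large runs is R's native serialization
## (RDS), which round-trips doubles bit-exactly.

#' Read / write a timeseries matrix
#'
#' `read_timeseries` parses a delimited text file (rows = timepoints,
#' columns = features, comma separator, optional header) or an RDS
#' binary container into a numeric matrix, with row/column diagnostics
#' on malformed input. `write_timeseries` is its inverse.
#'
#' @param path File path.
#' @param format `"delimited"` or `"binary"`.
#' @param header Does the delimited file carry a header row of feature
#'   labels? Default `TRUE`.
#' @return A numeric `T x K` matrix (timepoints are reported 1-based in
#'   all diagnostics).
#' @export
read_timeseries <- function(path, format = c("delimited", "binary"),
                            header = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "binary") {
    X <- readRDS(path)
    if (!is.matrix(X) || !is.numeric(X))
      stop("binary container does not hold a numeric matrix: ", path,
           call. = FALSE)
    return(X)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  cells <- strsplit(lines, ",", fixed = TRUE)
  start <- 1L
  labels <- NULL
  if (header) {
    labels <- trimws(cells[[1L]])
    start <- 2L
    if (length(cells) < 2L)
      stop("no data rows below the header in ", path, call. = FALSE)
  }
  widths <- lengths(cells[start:length(cells)])
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop("ragged row ", bad, " in ", path, ": ", widths[bad],
         " cells, expected ", widths[1L], call. = FALSE)
  }
  rows <- lapply(seq.int(start, length(cells)), function(i) {
    v <- suppressWarnings(as.numeric(trimws(cells[[i]])))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop("non-numeric cell at data row ", i - start + 1L, ", column ",
           j, " in ", path, call. = FALSE)
    }
    v
  })
  X <- do.call(rbind, rows)
  if (!is.null(labels) && length(labels) == ncol(X)) colnames(X) <- labels
  X
}

#' @rdname read_timeseries
#' @param X Numeric matrix to write.
#' @export
write_timeseries <- function(X, path, format = c("delimited", "binary")) {
  format <- match.arg(format)
  if (format == "binary") {
    saveRDS(X, path)
  } else {
    hdr <- if (!is.null(colnames(X))) paste(colnames(X), collapse = ",")
    body <- apply(X, 1L, function(r)
      paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
            collapse = ","))
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Read / write a vectorized correlation stream
#'
#' The stream is stored as a delimited matrix (or RDS) plus a JSON
#' sidecar (`<path>.json`) recording `K`, the vectorization convention,
#' and the kernel/mode that produced it, so projections are
#' reproducible.
#'
#' @param Y A `corr_series`.
#' @inheritParams read_timeseries
#' @export
write_corr_series <- function(Y, path, format = c("delimited", "binary")) {
  format <- match.arg(format)
  stopifnot(inherits(Y, "corr_series"))
  write_timeseries(unclass(Y), path, format)
  meta <- list(K = attr(Y, "K"),
               ordering = "row-major upper triangle including diagonal",
               kernel = if (!is.null(attr(Y, "kernel")))
                 format(attr(Y, "kernel")) else NULL,
               mode = attr(Y, "mode"))
  writeLines(to_json(meta), paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_corr_series
#' @export
read_corr_series <- function(path, format = c("delimited", "binary")) {
  format <- match.arg(format)
  X <- read_timeseries(path, format, header = FALSE)
  K <- as.integer(round((sqrt(8 * ncol(X) + 1) - 1) / 2))
  new_corr_series(X, K = K)
}

## minimal JSON writer for flat manifests (scalars, vectors, one level
## of nesting); avoids a hard dependency for metadata sidecars
to_json <- function(x, indent = "") {
  esc <- function(s) gsub("\"", "\\\\\"", s)
  render <- function(v) {
    if (is.null(v)) return("null")
    if (is.list(v)) return(to_json(v, paste0(indent, "  ")))
    if (is.character(v)) out <- paste0("\"", esc(v), "\"")
    else if (is.logical(v)) out <- ifelse(v, "true", "false")
    else out <- format(v, digits = 15, trim = TRUE)
    if (length(out) == 1L) out else
      paste0("[", paste(out, collapse = ", "), "]")
  }
  body <- vapply(seq_along(x), function(i)
    paste0(indent, "  \"", esc(names(x)[i]), "\": ", render(x[[i]])),
    character(1L))
  paste0("{\n", paste(body, collapse = ",\n"), "\n", indent, "}")
}

#' Read a directory of per-participant timeseries
#'
#' Reads every `*.csv` file in `dir` (alphabetical order), or the files
#' listed (one per line) in `manifest`, into a [participant_group()].
#'
#' @param dir Directory of delimited matrices.
#' @param manifest Optional path to a text manifest of file names
#'   relative to `dir`.
#' @param header Passed to [read_timeseries()].
#' @return A [participant_group()].
#' @export
read_group <- function(dir, manifest = NULL, header = TRUE) {
  files <- if (!is.null(manifest)) {
    file.path(dir, readLines(manifest))
  } else {
    list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  }
  if (!length(files)) stop("no timeseries files found in ", dir,
                           call. = FALSE)
  participant_group(lapply(files, read_timeseries, header = header))
}

#' Run one pipeline stage from a declarative configuration
#'
#' Dispatches on `config$stage`:
#' \describe{
#'   \item{`simulate`}{Writes `reps` synthetic datasets (observations +
#'     per-order truth streams) under `config$out`.}
#'   \item{`orders`}{Reads a timeseries, fits [hocorr()], writes one
#'     matrix per order.}
#'   \item{`disfc`}{Reads a participant directory, writes the group
#'     DISFC stream.}
#'   \item{`recover`}{Runs [recovery_sweep()] and writes the tidy
#'     table.}
#'   \item{`decode`}{Reads a participant directory, runs
#'     [run_decoding()], writes the records and by-order summary.}
#' }
#' Every stage writes a `manifest.json` echoing the resolved
#' configuration, the package version, and the seed, and never mutates
#' its inputs.
#'
#' @param config Named list; common fields: `stage`, `input`, `out`,
#'   `seed`, `kernel` (list with `family`, `width`), `mode`, plus
#'   stage-specific fields (`category`, `order`, `K`, `T`, `reps`,
#'   `max_order`, `folds`, `projection`).
#' @return Invisibly, the list of files written.
#' @export
run_stage <- function(config) {
  stage <- config$stage
  if (is.null(stage) ||
      !stage %in% c("simulate", "orders", "disfc", "recover", "decode"))
    stop("unknown stage: ", if (is.null(stage)) "<missing>" else stage,
         call. = FALSE)
  out_dir <- config$out
  if (is.null(out_dir)) stop("config$out is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  kern <- if (is.null(config$kernel)) laplace_kernel(20) else
    kernel_spec(config$kernel$family, config$kernel$width)
  mode <- if (is.null(config$mode)) "as_printed" else config$mode
  written <- character(0)
  emit <- function(path) written <<- c(written, path)

  if (stage == "simulate") {
    reps <- if (is.null(config$reps)) 1L else as.integer(config$reps)
    ord <- if (is.null(config$order)) 1L else as.integer(config$order)
    for (r in seq_len(reps)) {
      sp <- regime_spec(config$category,
                        K = if (is.null(config$K)) (if (ord > 1) 10L else 50L)
                            else as.integer(config$K),
                        T = if (is.null(config$T)) 300L else
                          as.integer(config$T),
                        order = ord, seed = seed + r)
      ds <- if (ord > 1L) simulate_higher_order(sp) else
        simulate_first_order(sp)
      d <- file.path(out_dir, sprintf("dataset_%03d", r))
      dir.create(d, showWarnings = FALSE)
      write_timeseries(ds$observations, file.path(d, "observations.csv"))
      emit(file.path(d, "observations.csv"))
      for (o in names(ds$truth)) {
        write_corr_series(ds$truth[[o]],
                          file.path(d, paste0("truth_order", o, ".csv")))
        emit(file.path(d, paste0("truth_order", o, ".csv")))
      }
    }
  } else if (stage == "orders") {
    X <- read_timeseries(config$input)
    fit <- hocorr(X, max_order = config$max_order, kernel = kern,
                  mode = mode,
                  projection = if (is.null(config$projection)) "pca"
                               else config$projection)
    for (o in names(fit$stack)) {
      p <- file.path(out_dir, paste0("order_", o, ".csv"))
      write_timeseries(fit$stack[[o]], p); emit(p)
    }
  } else if (stage == "disfc") {
    g <- read_group(config$input)
    Y <- disfc(g, kern, mode)
    p <- file.path(out_dir, "disfc.csv")
    write_corr_series(Y, p); emit(p)
  } else if (stage == "recover") {
    tab <- recovery_sweep(categories = config$category,
                          kernels = list(kern),
                          orders = if (is.null(config$order)) 1L else
                            as.integer(config$order),
                          reps = if (is.null(config$reps)) 1L else
                            as.integer(config$reps),
                          K = if (is.null(config$K)) 50L else
                            as.integer(config$K),
                          T = if (is.null(config$T)) 300L else
                            as.integer(config$T),
                          mode = mode, seed = seed)
    p <- file.path(out_dir, "recovery.csv")
    utils::write.csv(tab, p, row.names = FALSE); emit(p)
  } else if (stage == "decode") {
    g <- read_group(config$input)
    res <- run_decoding(g,
                        max_order = if (is.null(config$max_order)) 1L else
                          as.integer(config$max_order),
                        kernel_bank = list(kern), mode = mode,
                        folds = if (is.null(config$folds)) 10L else
                          as.integer(config$folds),
                        seed = seed)
    p1 <- file.path(out_dir, "decode_records.csv")
    utils::write.csv(res$records, p1, row.names = FALSE); emit(p1)
    p2 <- file.path(out_dir, "decode_by_order.csv")
    utils::write.csv(res$by_order, p2, row.names = FALSE); emit(p2)
  }

  manifest <- list(stage = stage, seed = seed,
                   kernel = format(kern), mode = mode,
                   package_version =
                     as.character(utils::packageVersion("hocorr")),
                   config = config[setdiff(names(config), "kernel")],
                   files = basename(written))
  mpath <- file.path(out_dir, "manifest.json")
  writeLines(to_json(manifest), mpath)
  emit(mpath)
  invisible(written)
}
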