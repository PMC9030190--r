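#' Write an `nmr_dataset` to disk
#'
#' The on-disk container is a directory holding `header.json` (format tag
#' `"ndnmr/1"`, dimension names, shape, axis descriptors, metadata,
#' provenance) and `data.bin`, a little-endian blob of 64-bit floats: the
#' values as interleaved real/imaginary pairs with the first-listed (direct)
#' dimension fastest-varying, followed by each coordinate axis in dimension
#' order. Numerics live in the blob so the round trip is bit-exact; the
#' header stays human-inspectable.
#'
#' @param ds a valid [nmr_dataset()].
#' @param path directory to create (must not already contain a dataset
#'   unless `overwrite = TRUE`).
#' @param overwrite replace an existing dataset directory.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, overwrite = FALSE) {
  validate_nmr_dataset(ds)
  if (length(ds$values) == 0L) stop("refusing to write empty dataset",
                                    call. = FALSE)
  if (dir.exists(path) && file.exists(file.path(path, "header.json")) &&
      !overwrite) {
    stop("dataset already exists at '", path, "'", call. = FALSE)
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)

  shape <- dim(ds$values)
  header <- list(
    format = "ndnmr/1",
    dims = as.list(ds$dims),
    shape = as.list(as.integer(shape)),
    axes = lapply(ds$dims, function(d) {
      ax <- ds$coords[[d]]
      list(dim = d, length = length(ax),
           units = ds$attrs$units[[d]],
           domain = ds$attrs$domain[[d]],
           first = ax[1], last = ax[length(ax)])
    }),
    attrs = ds$attrs[setdiff(names(ds$attrs),
                             c("units", "domain", "provenance"))],
    provenance = ds$attrs$provenance
  )
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  v <- as.vector(ds$values)
  payload <- numeric(2 * length(v))
  payload[c(TRUE, FALSE)] <- Re(v)
  payload[c(FALSE, TRUE)] <- Im(v)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(payload, con, size = 8L, endian = "little")
  for (d in ds$dims) {
    writeBin(as.numeric(ds$coords[[d]]), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read an `nmr_dataset` written by [write_dataset()]
#'
#' @param path dataset directory.
#' @return the reconstructed [nmr_dataset()]; the round trip is lossless
#'   (values and axes bit-identical, metadata and provenance preserved).
#' @export
read_dataset <- function(path) {
  hpath <- file.path(path, "header.json")
  if (!file.exists(hpath)) {
    stop("no header.json under '", path, "'", call. = FALSE)
  }
  header <- tryCatch(jsonlite::read_json(hpath),
                     error = function(e) stop("malformed header: ",
                                              conditionMessage(e),
                                              call. = FALSE))
  for (k in c("format", "dims", "shape", "axes")) {
    if (is.null(header[[k]])) {
      stop("malformed header: missing field '", k, "'", call. = FALSE)
    }
  }
  if (!identical(header$format, "ndnmr/1")) {
    stop("unknown format version '", header$format, "'", call. = FALSE)
  }
  dims <- unlist(header$dims)
  shape <- as.integer(unlist(header$shape))
  if (length(dims) != length(shape) || length(header$axes) != length(dims)) {
    stop("header shape/axis mismatch: ", length(dims), " dims, ",
         length(shape), " extents, ", length(header$axes), " axes",
         call. = FALSE)
  }

  n_val <- prod(shape)
  n_total <- 2 * n_val + sum(shape)
  raw <- readBin(file.path(path, "data.bin"), what = "double", n = n_total + 1,
                 size = 8L, endian = "little")
  if (length(raw) != n_total) {
    stop("data blob length ", length(raw), " != expected ", n_total,
         call. = FALSE)
  }
  vals <- complex(real = raw[seq(1, 2 * n_val, by = 2)],
                  imaginary = raw[seq(2, 2 * n_val, by = 2)])
  values <- array(vals, dim = shape)

  coords <- list()
  offset <- 2 * n_val
  units <- character(0)
  domain <- character(0)
  for (i in seq_along(dims)) {
    ax_desc <- header$axes[[i]]
    n_ax <- shape[i]
    coords[[dims[i]]] <- raw[(offset + 1):(offset + n_ax)]
    offset <- offset + n_ax
    units[dims[i]] <- ax_desc$units
    domain[dims[i]] <- ax_desc$domain
  }

  attrs <- header$attrs
  attrs <- lapply(attrs, function(a) if (is.list(a)) unlist(a) else a)
  attrs$units <- units
  attrs$domain <- domain
  attrs$provenance <- lapply(header$provenance, function(e) {
    list(op = e$op, params = lapply(e$params, function(p) {
      if (is.list(p)) unlist(p) else p
    }))
  })
  nmr_dataset(values, dims, coords, attrs)
}
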