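#' Read and write triplet choice tables
#'
#' The on-disk format is a UTF-8, LF-terminated, tab-separated file with
#' header `objA objB objC choice` and 0-based integer object indices, one
#' trial per row.  In R, triplet tables use 1-based indices; the converters
#' translate on the way in and out.
#'
#' @param trials Triplet table with columns `a`, `b`, `c`, `choice`.
#' @param path File path.
#' @param n_objects Optional object count recorded on read (defaults to the
#'   largest index seen).
#' @return `read_triplets()` returns a tibble with columns `a`, `b`, `c`,
#'   `choice` and attribute `n_objects`; `write_triplets()` returns `path`
#'   invisibly.
#' @export
write_triplets <- function(trials, path) {
  trials <- as_triplet_df(trials)
  out <- tibble::tibble(objA = trials$a - 1L, objB = trials$b - 1L,
                        objC = trials$c - 1L, choice = trials$choice - 1L)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_triplets
#' @export
read_triplets <- function(path, n_objects = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "i"))
  need <- c("objA", "objB", "objC", "choice")
  if (!all(need %in% names(raw))) {
    abort(sprintf("Triplet file must have columns %s.", toString(need)))
  }
  as_triplet_df(
    tibble::tibble(a = raw$objA + 1L, b = raw$objB + 1L, c = raw$objC + 1L,
                   choice = raw$choice + 1L),
    n_objects = n_objects
  )
}

#' Read and write embedding matrices
#'
#' Embeddings are stored as plain-text whitespace-delimited matrices, one
#' object per row, with an optional key-value sidecar (`<path>.meta`)
#' carrying object ids and training metadata.
#'
#' @param embedding A `spose_embedding`, `gt_embedding` or weight matrix.
#' @param path File path for the matrix.
#' @param sidecar Write/read the `.meta` sidecar?
#' @return `read_embedding()` returns the weight matrix (rownames set from
#'   the sidecar when present); `write_embedding()` returns `path`
#'   invisibly.
#' @export
write_embedding <- function(embedding, path, sidecar = TRUE) {
  w <- embedding_weights(embedding)
  utils::write.table(w, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  if (sidecar) {
    meta <- c(
      sprintf("n_objects: %d", nrow(w)),
      sprintf("n_dims: %d", ncol(w)),
      if (!is.null(rownames(w))) {
        sprintf("object_ids: %s", paste(rownames(w), collapse = ","))
      },
      if (inherits(embedding, "spose_embedding")) c(
        sprintf("lambda: %.10g", embedding$config$lambda),
        sprintf("seed: %d", embedding$config$seed)
      ),
      if (inherits(embedding, "gt_embedding")) c(
        sprintf("sparsity: %.10g", embedding$sparsity),
        sprintf("seed: %d", embedding$seed)
      )
    )
    writeLines(meta, paste0(path, ".meta"))
  }
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path, sidecar = TRUE) {
  w <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(w) <- NULL
  meta_path <- paste0(path, ".meta")
  if (sidecar && file.exists(meta_path)) {
    meta <- readLines(meta_path)
    ids <- sub("^object_ids: ", "", grep("^object_ids: ", meta, value = TRUE))
    if (length(ids) == 1) rownames(w) <- strsplit(ids, ",")[[1]]
  }
  w
}

#' Read and write measurement containers as plain-text directories
#'
#' `repeated_measures` and `fusion_data` objects are serialized to a
#' directory of named datasets: one TSV per array (multi-dimensional arrays
#' are flattened with their dimensions recorded) plus a `meta.json` with
#' ids, axes and generating parameters.
#'
#' @param x A `repeated_measures` or `fusion_data` object.
#' @param dir Directory to create/read.
#' @return Readers return the reconstructed object; writers return `dir`
#'   invisibly.
#' @export
write_repeated_measures <- function(x, dir) {
  stopifnot(inherits(x, "repeated_measures"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(matrix(x$responses, nrow = dim(x$responses)[1]),
                     file.path(dir, "responses.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(kind = "repeated_measures", dim = dim(x$responses),
               channel_ids = x$channel_ids, image_ids = x$image_ids,
               signal_sd = x$signal_sd, noise_sd = x$noise_sd, seed = x$seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_repeated_measures
#' @export
read_repeated_measures <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file.path(dir, "responses.tsv"),
                                      sep = "\t"))
  structure(
    list(responses = array(flat, dim = meta$dim),
         channel_ids = meta$channel_ids, image_ids = meta$image_ids,
         signal_sd = meta$signal_sd, noise_sd = meta$noise_sd,
         seed = meta$seed),
    class = "repeated_measures"
  )
}

#' @rdname write_repeated_measures
#' @export
write_fusion_dataset <- function(x, dir) {
  stopifnot(inherits(x, "fusion_data"))
  dir.create(file.path(dir, "roi"), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(matrix(x$sensor_data, nrow = dim(x$sensor_data)[1]),
                     file.path(dir, "sensor_data.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  for (nm in names(x$roi_responses)) {
    utils::write.table(x$roi_responses[[nm]],
                       file.path(dir, "roi", paste0(nm, ".tsv")), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(x$session_labels, file.path(dir, "sessions.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(x$time_ms, file.path(dir, "time_ms.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(kind = "fusion_data", dim = dim(x$sensor_data),
               rois = names(x$roi_responses),
               baseline_window = x$baseline_window,
               roi_onsets = as.list(x$roi_onsets %||% NULL),
               snr = x$snr %||% NULL, seed = x$seed %||% NULL)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_repeated_measures
#' @export
read_fusion_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file.path(dir, "sensor_data.tsv"),
                                      sep = "\t"))
  rois <- lapply(meta$rois, function(nm) {
    utils::read.table(file.path(dir, "roi", paste0(nm, ".tsv")))[[1]]
  })
  names(rois) <- meta$rois
  out <- fusion_dataset(
    array(flat, dim = meta$dim), rois,
    utils::read.table(file.path(dir, "sessions.tsv"))[[1]],
    utils::read.table(file.path(dir, "time_ms.tsv"))[[1]],
    meta$baseline_window
  )
  if (length(meta$roi_onsets)) out$roi_onsets <- unlist(meta$roi_onsets)
  out$snr <- meta$snr
  out$seed <- meta$seed
  out
}
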