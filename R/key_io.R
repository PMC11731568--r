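# Key files and triplet files: the on-disk form of a fingerprint and of
# its key -> triangle back-mapping.  Tab-delimited with a '#'-prefixed
# header block recording mode, config hash and bin boundaries so key
# values are self-describing.

key_file_header <- function(kv, config = NULL) {
  c("# tsrkeys key data",
    paste0("# mode=", kv$mode),
    paste0("# config_hash=", kv$config_hash),
    if (!is.null(config)) c(
      paste0("# theta_bins=", paste(config$theta_bins, collapse = ",")),
      paste0("# dist_bins=", paste(config$dist_bins, collapse = ",")),
      paste0("# label_map=", paste(names(config$label_map),
                                   config$label_map,
                                   sep = ":", collapse = ","))),
    paste0("# provenance=", paste(unlist(kv$provenance), collapse = "|")))
}

#' Write / read a key file
#'
#' A key file is the serialised key-frequency vector: one `key TAB
#' frequency` row per distinct key, preceded by a header block recording
#' mode, configuration hash and provenance.
#'
#' @param kv A `tsr_keyvector`.
#' @param path File path.
#' @param config Optional [tsr_config()]; when given, bin boundaries and
#'   the label map are recorded in the header.
#' @return `path` invisibly (write); a `tsr_keyvector` (read).
#' @export
write_key_file <- function(kv, path, config = NULL) {
  stopifnot(inherits(kv, "tsr_keyvector"))
  if (length(kv$counts) == 0) stop("empty key vector", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(key_file_header(kv, config), con)
  writeLines("key\tfrequency", con)
  writeLines(paste(names(kv$counts),
                   format(kv$counts, scientific = FALSE, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

read_header_field <- function(lines, field) {
  pat <- paste0("^# ", field, "=")
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) == 0) return(NULL)
  sub(pat, "", hit[1])
}

#' @rdname write_key_file
#' @export
read_key_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) < 2 || body[1] != "key\tfrequency") {
    stop("not a key file: ", path, call. = FALSE)
  }
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 2)
  if (length(bad) > 0) {
    stop("malformed key file row at line ",
         which(lines == body[bad[1] + 1])[1], " of ", path, call. = FALSE)
  }
  mat <- matrix(unlist(rows), ncol = 2, byrow = TRUE)
  counts <- suppressWarnings(as.numeric(mat[, 2]))
  keys <- suppressWarnings(as.numeric(mat[, 1]))
  if (anyNA(counts) || anyNA(keys)) {
    stop("non-numeric key or frequency in ", path, call. = FALSE)
  }
  names(counts) <- mat[, 1]
  prov <- read_header_field(lines, "provenance")
  structure(list(
    counts = counts[order(keys)],
    mode = read_header_field(lines, "mode"),
    config_hash = read_header_field(lines, "config_hash"),
    provenance = if (is.null(prov)) list() else
      as.list(strsplit(prov, "|", fixed = TRUE)[[1]])
  ), class = "tsr_keyvector")
}

#' Write / read a triplet file
#'
#' A triplet file lists every retained triangle with its three vertex
#' identifiers and labels, MaxDist, Theta, bin indices and key, so any
#' key can be mapped back to the triangle(s) it came from.
#'
#' @param keys A `tsr_keys` result from [generate_keys()] (write).
#' @param path File path.
#' @param config Optional [tsr_config()] recorded in the header.
#' @return `path` invisibly (write); a data frame of triangles with a
#'   `provenance` attribute (read).
#' @export
write_triplet_file <- function(keys, path, config = NULL) {
  stopifnot(inherits(keys, "tsr_keys"))
  tr <- keys$triplets
  if (nrow(tr) == 0) stop("no triangles to write", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(key_file_header(keys$key_vector, config), con)
  tr$maxdist <- format(tr$maxdist, digits = 15, scientific = FALSE,
                       trim = TRUE)
  tr$theta <- format(tr$theta, digits = 15, scientific = FALSE,
                     trim = TRUE)
  utils::write.table(tr, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_triplet_file
#' @export
read_triplet_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#")]
  tr <- tryCatch(
    utils::read.delim(text = body, stringsAsFactors = FALSE),
    error = function(e) stop("malformed triplet file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  needed <- c("v1", "v2", "v3", "l1", "l2", "l3", "maxdist", "theta",
              "theta_bin", "dist_bin", "key")
  if (!all(needed %in% names(tr))) {
    stop("triplet file ", path, " lacks columns: ",
         paste(setdiff(needed, names(tr)), collapse = ", "),
         call. = FALSE)
  }
  prov <- read_header_field(lines, "provenance")
  attr(tr, "provenance") <- prov
  attr(tr, "config_hash") <- read_header_field(lines, "config_hash")
  tr
}

#' Map a key back to its triangles
#'
#' Searches a triplet store (a list of triplet data frames, typically
#' from [read_triplet_file()] or `generate_keys()$triplets`) for every
#' triangle bearing the key, tagging each match with the provenance of
#' the molecule it came from.
#'
#' @param key A single integer key.
#' @param store List of triplet data frames.
#' @return Data frame of matching triangles with a `provenance` column;
#'   zero rows when the key is absent.
#' @export
map_key_to_triangles <- function(key, store) {
  stopifnot(length(key) == 1)
  if (inherits(store, "data.frame")) store <- list(store)
  out <- lapply(seq_along(store), function(i) {
    tr <- store[[i]]
    hit <- tr[tr$key == key, , drop = FALSE]
    if (nrow(hit) == 0) return(NULL)
    prov <- attr(tr, "provenance")
    if (is.null(prov)) prov <- names(store)[i]
    if (is.null(prov) || !nzchar(prov)) prov <- paste0("store_", i)
    hit$provenance <- prov
    hit
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    empty <- data.frame(v1 = character(), v2 = character(),
                        v3 = character(), l1 = integer(), l2 = integer(),
                        l3 = integer(), maxdist = numeric(),
                        theta = numeric(), theta_bin = integer(),
                        dist_bin = integer(), key = numeric(),
                        provenance = character(),
                        stringsAsFactors = FALSE)
    return(empty)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
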