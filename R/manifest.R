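manifest_required_cols <- c("image_path", "mask_path", "emitted_label",
                            "true_label", "patient_id", "site_id", "mislabeled")

#' Read and validate a dataset manifest
#'
#' CSV, comma-separated, UTF-8, header required; image/mask paths are
#' interpreted relative to the manifest's directory.  Rows are validated:
#' required columns present, image ids unique, referenced files exist.
#'
#' @param path manifest CSV path.
#' @param check_files verify that referenced image/mask files exist.
#' @return data.frame with an `active` column added (all `TRUE`).
#' @export
read_manifest <- function(path, check_files = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(manifest_required_cols, names(m))
  if (length(missing_cols)) {
    stop("manifest is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"image_id" %in% names(m)) {
    m$image_id <- sub("\\.png$", "", basename(m$image_path))
  }
  dup <- m$image_id[duplicated(m$image_id)]
  if (length(dup)) {
    stop("duplicate image_id in manifest: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", m$image_path)
  m$image_path[rel] <- file.path(base, m$image_path[rel])
  relm <- !grepl("^(/|[A-Za-z]:)", m$mask_path)
  m$mask_path[relm] <- file.path(base, m$mask_path[relm])
  if (check_files) {
    gone <- m$image_path[!file.exists(m$image_path)]
    if (length(gone)) {
      stop("manifest references missing files: ", paste(gone, collapse = ", "),
           call. = FALSE)
    }
  }
  m$mislabeled <- as.logical(m$mislabeled)
  m$active <- TRUE
  m
}

#' Write a manifest CSV
#' @param manifest data.frame as returned by [read_manifest()] or
#'   [generate_dataset()].
#' @param path output CSV path; image/mask paths are written relative to
#'   its directory where possible.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest[, c("image_id", manifest_required_cols)]
  base <- normalizePath(dirname(path))
  relativize <- function(p) {
    ifelse(dirname(normalizePath(p, mustWork = FALSE)) == base, basename(p), p)
  }
  out$image_path <- relativize(out$image_path)
  out$mask_path <- relativize(out$mask_path)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Load the images and masks referenced by a manifest
#' @param manifest validated manifest data.frame.
#' @return list with `images` and `masks`, lists of matrices in `[0,1]` /
#'   binary, named by `image_id`.
#' @export
load_dataset <- function(manifest) {
  images <- lapply(manifest$image_path, function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    a
  })
  masks <- lapply(manifest$mask_path, function(p) {
    if (is.na(p) || !nzchar(p) || !file.exists(p)) return(NULL)
    a <- png::readPNG(p)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    (a > 0.5) + 0L
  })
  names(images) <- manifest$image_id
  names(masks) <- manifest$image_id
  list(images = images, masks = masks)
}
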