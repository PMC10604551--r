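#' Load / save images as PNG
#'
#' Images are arrays `H x W x 3` with values in `[0, 1]`. Grayscale files
#' are expanded to three channels; an alpha channel is dropped.
#'
#' @param path file path.
#' @param img array `H x W x 3` in `[0, 1]`.
#' @return `load_image_png()` returns the image array.
#' @export
load_image_png <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3]
  if (dim(img)[3] != 3) stop("unsupported channel count in ", path)
  img
}

#' @rdname load_image_png
#' @export
save_image_png <- function(img, path) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read / write circle annotations as CSV
#'
#' Flat interchange format with one row per circle: columns `file`, `cx`,
#' `cy`, `r`, plus optional `class_id` (defaults to 1 on read) and, for
#' predictions, `score`. Numeric values round-trip at full double
#' precision.
#'
#' @param path CSV path.
#' @param anns annotation/detection data frame.
#' @param strict if `TRUE` (default) malformed rows are an error; otherwise
#'   they are dropped with a warning.
#' @return `read_annotations_csv()` returns the annotation data frame.
#' @export
read_annotations_csv <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  d <- as.data.frame(data.table::fread(path))
  missing_cols <- setdiff(c("file", "cx", "cy", "r"), names(d))
  if (length(missing_cols))
    stop("annotation CSV ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(d)) {
    bad <- !is.finite(d$cx) | !is.finite(d$cy) | !is.finite(d$r) | d$r < 0
    if (any(bad)) {
      msg <- paste0(sum(bad), " malformed rows in ", path)
      if (strict) stop(msg) else { warning(msg, "; dropped"); d <- d[!bad, , drop = FALSE] }
    }
  }
  if (is.null(d$class_id)) d$class_id <- rep(1L, nrow(d))
  d$class_id <- as.integer(d$class_id)
  d
}

#' @rdname read_annotations_csv
#' @export
write_annotations_csv <- function(anns, path) {
  cols <- intersect(c("file", "cx", "cy", "r", "class_id", "score"), names(anns))
  out <- anns[, cols, drop = FALSE]
  # %.17g guarantees an exact double round trip (fwrite stops at 15 digits)
  for (nm in intersect(c("cx", "cy", "r", "score"), cols))
    out[[nm]] <- sprintf("%.17g", out[[nm]])
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read / write a dataset manifest
#'
#' One row per image: `file` (unique relative path), `label`
#' (`positive`/`negative`), and optionally `split` (`train`/`test`),
#' `n_cells` and `seed`.
#'
#' @param path CSV path.
#' @param man manifest data frame.
#' @return `read_manifest()` returns the manifest data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- as.data.frame(data.table::fread(path))
  if (!"file" %in% names(man)) stop("manifest must have a 'file' column")
  if (anyDuplicated(man$file)) stop("manifest paths must be unique")
  if ("split" %in% names(man) && !all(man$split %in% c("train", "test")))
    stop("manifest split values must be 'train' or 'test'")
  man
}

#' @rdname read_manifest
#' @export
write_manifest <- function(man, path) {
  data.table::fwrite(man, path)
  invisible(path)
}

via_format_version <- "circlenet-via-2.0"

#' Read circle annotations from a VIA-style JSON project
#'
#' Parses the VIA 2.x dialect: a map from image key to an entry with a
#' `filename` and a list of `regions`; circle regions carry
#' `shape_attributes` `{name: "circle", cx, cy, r}` and the class under
#' `region_attributes$class`. Non-circle regions are skipped with a warning
#' (or an error when `strict = TRUE`). Coordinates are 0-based pixels.
#'
#' @param path JSON path.
#' @param strict error on non-circle regions instead of skipping.
#' @return Annotation data frame with columns `file`, `cx`, `cy`, `r`,
#'   `label`, `class_id` (1-based by sorted label).
#' @export
read_via_json <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("VIA project not found: ", path)
  pj <- jsonlite::read_json(path)
  entries <- if (!is.null(pj$images)) pj$images else
    pj[setdiff(names(pj), grep("^_", names(pj), value = TRUE))]
  rows <- list()
  for (key in names(entries)) {
    e <- entries[[key]]
    fname <- if (!is.null(e$filename)) e$filename else key
    for (ri in seq_along(e$regions)) {
      reg <- e$regions[[ri]]
      sa <- reg$shape_attributes
      if (is.null(sa$name) || sa$name != "circle") {
        msg <- paste0("region ", ri, " of '", fname, "' in ", path,
                      " is not a circle (", if (is.null(sa$name)) "?" else sa$name, ")")
        if (strict) stop(msg)
        warning(msg, "; skipped")
        next
      }
      if (is.null(sa$cx) || is.null(sa$cy) || is.null(sa$r))
        stop("region ", ri, " of '", fname, "' in ", path,
             " is missing circle attributes cx/cy/r")
      lab <- reg$region_attributes$class
      rows[[length(rows) + 1]] <- data.frame(
        file = fname, cx = as.numeric(sa$cx), cy = as.numeric(sa$cy),
        r = as.numeric(sa$r), label = if (is.null(lab)) "SRC" else lab)
    }
  }
  if (length(rows) == 0)
    return(data.frame(file = character(0), cx = numeric(0), cy = numeric(0),
                      r = numeric(0), label = character(0), class_id = integer(0)))
  d <- do.call(rbind, rows)
  d$class_id <- as.integer(factor(d$label, levels = sort(unique(d$label))))
  d
}

#' Write circle annotations as a VIA-style JSON project
#'
#' Emits the dialect read by [read_via_json()]; image keys and field order
#' are sorted so output is byte-stable.
#'
#' @param anns annotation data frame (`file`, `cx`, `cy`, `r`, and `label`
#'   or `class_id`).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_via_json <- function(anns, path) {
  if (is.null(anns$label))
    anns$label <- if (is.null(anns$class_id)) "SRC" else paste0("class_", anns$class_id)
  images <- list()
  for (f in sort(unique(as.character(anns$file)))) {
    sub <- anns[anns$file == f, , drop = FALSE]
    regions <- lapply(seq_len(nrow(sub)), function(i) list(
      shape_attributes = list(name = "circle", cx = sub$cx[i], cy = sub$cy[i],
                              r = sub$r[i]),
      region_attributes = list(class = as.character(sub$label[i]))))
    images[[f]] <- list(filename = f, regions = regions)
  }
  jsonlite::write_json(list(`_via_format` = via_format_version, images = images),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
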