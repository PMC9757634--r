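#' @include AllClasses.R
NULL

writeGrayPNG <- function(pixels, path) {
  png::writePNG(pixels, path)
  invisible(path)
}

readGrayPNG <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Read a dataset manifest
#'
#' Parses a CSV with header `filename,label,modality,style`.  Empty label
#' fields mean unlabeled; present labels must be integers in `[1, 30]`
#' (chambers with more than 30 cells are excluded upstream).  Malformed
#' rows raise an error naming the row number.
#'
#' @param path CSV file path.
#' @param split `"train"` or `"test"` tag for the returned manifest.
#' @return a [DatasetManifest-class] rooted at the CSV's directory.
#' @export
readManifest <- function(path, split = "train") {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- read.csv(path, colClasses = "character")
  need <- c("filename", "label", "modality", "style")
  if (!identical(names(df)[seq_along(need)], need))
    stop("manifest must have header: ", paste(need, collapse = ","))
  lab <- rep(NA_integer_, nrow(df))
  present <- !is.na(df$label) & nzchar(df$label)
  if (any(present)) {
    parsed <- suppressWarnings(as.numeric(df$label[present]))
    bad <- which(present)[is.na(parsed) | parsed != round(parsed)]
    if (length(bad))
      stop("row ", bad[1], ": label '", df$label[bad[1]], "' is not an integer")
    out <- which(present)[parsed < 1 | parsed > 30]
    if (length(out))
      stop("row ", out[1], ": label ", df$label[out[1]],
           " outside the allowed range [1, 30]")
    lab[present] <- as.integer(parsed)
  }
  badMod <- which(!df$modality %in% MODALITIES)
  if (length(badMod))
    stop("row ", badMod[1], ": modality must be 'natural' or 'synthetic'")
  badSty <- which(!df$style %in% STYLES)
  if (length(badSty))
    stop("row ", badSty[1], ": style must be 'bf' or 'pc'")
  new("DatasetManifest",
      data = data.frame(filename = df$filename, label = lab,
                        modality = df$modality, style = df$style,
                        stringsAsFactors = FALSE),
      root = dirname(path), split = split)
}

#' Write a dataset manifest
#'
#' Serializes in canonical form: rows sorted by filename, unlabeled rows
#' with an empty label field, UTF-8 CSV with header.  Reading the file
#' back reproduces the manifest exactly.
#'
#' @param manifest a [DatasetManifest-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(is(manifest, "DatasetManifest"))
  df <- manifest@data[order(manifest@data$filename), , drop = FALSE]
  out <- data.frame(filename = df$filename,
                    label = ifelse(is.na(df$label), "", as.character(df$label)),
                    modality = df$modality, style = df$style,
                    stringsAsFactors = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load the images of a manifest into memory
#'
#' Reads every referenced PNG (8-bit grayscale; for RGB files the first
#' channel is used) and checks that all images are square and equally
#' sized.
#'
#' @param manifest a [DatasetManifest-class], or a path to a manifest CSV.
#' @return an [ImageSet-class].
#' @export
loadImageSet <- function(manifest) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  stopifnot(is(manifest, "DatasetManifest"))
  df <- manifest@data
  if (nrow(df) == 0) stop("manifest is empty")
  imgs <- lapply(file.path(manifest@root, df$filename), readGrayPNG)
  sides <- vapply(imgs, nrow, 1L)
  if (any(vapply(imgs, ncol, 1L) != sides) || length(unique(sides)) != 1)
    stop("all images must be square and equally sized")
  arr <- array(0, c(sides[1], sides[1], nrow(df)))
  for (i in seq_along(imgs)) arr[, , i] <- imgs[[i]]
  new("ImageSet", images = arr, label = df$label, modality = df$modality,
      style = df$style, id = sub("\\.png$", "", df$filename))
}
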