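#' Quantize an RGB image to a coarse color palette
#'
#' Reduces an image to at most `palette_size` colors and tabulates the pixel
#' count of each resulting palette code, emulating the coarse-palette (GIF
#' style) color tables that canopy image analysis tools report. Quantization
#' uses median-cut without dithering, so pixel counts stay concentrated on
#' genuine palette codes instead of being scattered across fabricated ones.
#' Alternatively a fixed palette can be supplied and every pixel is mapped to
#' its nearest palette entry (Euclidean distance in RGB space, ties broken by
#' the lowest palette index), which is how a known device palette is forced.
#'
#' @param image Either a numeric array (`H x W x 3` RGB, `H x W x 4` RGBA with
#'   the alpha channel dropped, or `H x W` grayscale promoted to RGB) with
#'   values in `[0, 1]` or 8-bit integers in `[0, 255]`, or the path to a PNG
#'   file (read with \pkg{png}); JPEG/TIFF paths are read through
#'   \pkg{EBImage} when that package is installed.
#' @param palette_size Maximum number of palette colors, integer in `[2, 256]`.
#'   Default 256, the GIF palette size. Ignored when `palette` is given.
#' @param palette Optional fixed palette: a matrix or data frame with columns
#'   `r`, `g`, `b` (8-bit integers). When supplied, median-cut is skipped.
#' @param image_id Optional identifier stored on the returned table.
#'
#' @return A `color_table`: a data frame with integer columns `r`, `g`, `b`
#'   and `pixels`, one row per distinct palette code, rows ordered by
#'   `(r, g, b)`. Pixel counts always sum to the number of image pixels.
#'
#' @details When the image already contains no more than `palette_size`
#'   distinct colors the table lists exactly those colors and counts
#'   (quantization is the identity on already-quantized images).
#'
#' @examples
#' img <- array(0, dim = c(10, 10, 3))
#' img[, , 2] <- 43 / 255        # uniform dark green (0,43,0)
#' quantize_image(img, palette_size = 256)
#' @export
quantize_image <- function(image, palette_size = 256, palette = NULL,
                           image_id = NULL) {
  if (is.character(image)) image <- load_image(image)
  image <- as_rgb255(image)
  if (length(image) == 0L) stop("image has no pixels", call. = FALSE)

  if (is.null(palette)) {
    if (length(palette_size) != 1L || is.na(palette_size) ||
        palette_size < 2 || palette_size > 256 ||
        palette_size != round(palette_size)) {
      stop("`palette_size` must be a single integer in [2, 256]", call. = FALSE)
    }
  }

  npx <- dim(image)[1] * dim(image)[2]
  cols <- matrix(as.integer(image), ncol = 3L,
                 dimnames = list(NULL, c("r", "g", "b")))
  key <- cols[, 1] * 65536L + cols[, 2] * 256L + cols[, 3]
  tab <- table_counts(key)
  uniq <- cbind(r = tab$key %/% 65536L,
                g = (tab$key %/% 256L) %% 256L,
                b = tab$key %% 256L)
  counts <- tab$count

  if (!is.null(palette)) {
    pal <- as_palette_matrix(palette)
    idx <- nearest_palette_index(uniq, pal)
    mapped <- pal[idx, , drop = FALSE]
  } else if (nrow(uniq) > palette_size) {
    pal <- median_cut_palette(uniq, counts, palette_size)
    mapped <- pal$palette[pal$assignment, , drop = FALSE]
  } else {
    mapped <- uniq
  }

  out <- aggregate_codes(mapped, counts)
  stopifnot(sum(out$pixels) == npx)
  new_color_table(out, image_id = image_id)
}

#' Read color tables with sample metadata from CSV
#'
#' Reads a long-format CSV of palette color tables, one row per
#' `(image, RGB code)` pair, and validates it: channel values must be 8-bit
#' integers, pixel counts strictly positive integers, codes unique within an
#' image, and the metadata (`plot_id`, `treatment`, `month`, `year`) constant
#' within an image and not shared by two images.
#'
#' @param path Path to a CSV file with header
#'   `image_id,plot_id,treatment,month,year,r,g,b,pixels`.
#' @return A data frame with those columns, rows ordered by `image_id` then
#'   `(r, g, b)`, of class `color_table_set`.
#' @seealso [write_color_table()]
#' @export
read_color_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_color_table_set(df)
}

#' Write color tables with sample metadata to CSV
#'
#' Writes tables in the format read by [read_color_table()], with a
#' deterministic row order (`image_id`, then `r`, `g`, `b` ascending) so the
#' write/read round trip is the identity. An empty set writes a header-only
#' file.
#'
#' @param tables A data frame as returned by [read_color_table()] or
#'   assembled from [quantize_image()] output plus metadata columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_color_table <- function(tables, path) {
  cols <- c("image_id", "plot_id", "treatment", "month", "year",
            "r", "g", "b", "pixels")
  if (nrow(tables) > 0L) {
    tables <- validate_color_table_set(tables)
  } else {
    missing <- setdiff(cols, names(tables))
    for (m in missing) tables[[m]] <- character(0)
  }
  ok <- tryCatch({
    write.csv(tables[, cols, drop = FALSE], path, row.names = FALSE,
              quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

validate_color_table_set <- function(df) {
  cols <- c("image_id", "plot_id", "treatment", "month", "year",
            "r", "g", "b", "pixels")
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("color table CSV is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (ch in c("r", "g", "b")) {
    v <- df[[ch]]
    if (any(is.na(v)) || any(v != round(v)) || any(v < 0 | v > 255)) {
      stop("channel `", ch, "` must hold integers in [0, 255]", call. = FALSE)
    }
    df[[ch]] <- as.integer(v)
  }
  px <- df$pixels
  if (any(is.na(px)) || any(px != round(px)) || any(px < 1)) {
    stop("`pixels` must hold positive integer counts (>= 1)", call. = FALSE)
  }
  df$pixels <- as.numeric(px)
  key <- paste(df$image_id, df$r, df$g, df$b)
  if (anyDuplicated(key)) {
    stop("duplicate (image_id, r, g, b) rows: ",
         paste(head(unique(key[duplicated(key)]), 3L), collapse = "; "),
         call. = FALSE)
  }
  meta <- unique(df[, c("image_id", "plot_id", "treatment", "month", "year")])
  if (anyDuplicated(meta$image_id)) {
    stop("inconsistent metadata within image_id: ",
         paste(unique(meta$image_id[duplicated(meta$image_id)]),
               collapse = ", "), call. = FALSE)
  }
  unit <- paste(meta$plot_id, meta$month, meta$year)
  if (anyDuplicated(unit)) {
    stop("two images share the same (plot_id, month, year)", call. = FALSE)
  }
  df <- df[order(df$image_id, df$r, df$g, df$b), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("color_table_set", "data.frame")
  df
}

new_color_table <- function(df, image_id = NULL) {
  rownames(df) <- NULL
  attr(df, "image_id") <- image_id
  class(df) <- c("color_table", "data.frame")
  df
}

# --- internals -------------------------------------------------------------

load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return(png::readPNG(path))
  if (ext %in% c("jpg", "jpeg", "tif", "tiff")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading ", ext, " files requires the EBImage package",
           call. = FALSE)
    }
    img <- EBImage::imageData(EBImage::readImage(path))
    # EBImage stores images x-major; transpose to row (y) major
    if (length(dim(img)) == 2L) return(t(img))
    return(aperm(img, c(2L, 1L, 3L)))
  }
  stop("unsupported image format: .", ext,
       " (supply a PNG/JPEG/TIFF path or an RGB array)", call. = FALSE)
}

as_rgb255 <- function(image) {
  if (!is.numeric(image)) stop("image must be a numeric array", call. = FALSE)
  d <- dim(image)
  if (is.null(d) || length(d) < 2L) {
    stop("image must be an H x W (x channels) array", call. = FALSE)
  }
  if (length(d) == 2L) image <- array(rep(image, 3L), dim = c(d, 3L))
  d <- dim(image)
  if (d[3] == 4L) image <- image[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(image)[3] != 3L) {
    stop("image must have 1, 3 or 4 channels", call. = FALSE)
  }
  if (max(image) <= 1 + 1e-12) image <- image * 255
  image <- round(image)
  if (min(image) < 0 || max(image) > 255) {
    stop("image values outside [0, 255]", call. = FALSE)
  }
  image
}

table_counts <- function(key) {
  o <- order(key)
  k <- key[o]
  new <- c(TRUE, k[-1] != k[-length(k)])
  starts <- which(new)
  counts <- diff(c(starts, length(k) + 1L))
  list(key = k[starts], count = as.numeric(counts))
}

as_palette_matrix <- function(palette) {
  if (is.data.frame(palette)) {
    palette <- as.matrix(palette[, c("r", "g", "b")])
  }
  palette <- matrix(as.numeric(palette), ncol = 3L)
  if (any(is.na(palette)) || any(palette != round(palette)) ||
      any(palette < 0 | palette > 255)) {
    stop("palette entries must be integers in [0, 255]", call. = FALSE)
  }
  colnames(palette) <- c("r", "g", "b")
  palette
}

nearest_palette_index <- function(cols, pal) {
  # squared Euclidean distances, n_colors x n_palette
  cross <- cols %*% t(pal)
  d2 <- outer(rowSums(cols^2), rowSums(pal^2), "+") - 2 * cross
  # max.col on negated distances with ties.method = "first" -> lowest index
  max.col(-d2, ties.method = "first")
}

# Median-cut: repeatedly split the box with the widest channel range at the
# pixel-weighted median along that channel, until `k` boxes or all boxes are
# single colors. Deterministic throughout.
median_cut_palette <- function(cols, counts, k) {
  n <- nrow(cols)
  boxes <- list(seq_len(n))
  box_range <- function(idx) {
    if (length(idx) < 2L) return(c(0, 0))
    r <- apply(cols[idx, , drop = FALSE], 2L, function(x) max(x) - min(x))
    c(max(r), which.max(r))
  }
  info <- lapply(boxes, box_range)
  while (length(boxes) < k) {
    widths <- vapply(info, `[`, numeric(1), 1L)
    if (all(widths == 0)) break
    bi <- which.max(widths)
    idx <- boxes[[bi]]
    ch <- info[[bi]][2L]
    o <- idx[order(cols[idx, ch], cols[idx, 1], cols[idx, 2], cols[idx, 3])]
    cum <- cumsum(counts[o])
    half <- cum[length(cum)] / 2
    split_at <- min(max(1L, sum(cum < half)), length(o) - 1L)
    left <- o[seq_len(split_at)]
    right <- o[-seq_len(split_at)]
    boxes[[bi]] <- left
    boxes[[length(boxes) + 1L]] <- right
    info[[bi]] <- box_range(left)
    info[[length(boxes)]] <- box_range(right)
  }
  palette <- t(vapply(boxes, function(idx) {
    w <- counts[idx] / sum(counts[idx])
    round(colSums(cols[idx, , drop = FALSE] * w))
  }, numeric(3)))
  colnames(palette) <- c("r", "g", "b")
  assignment <- integer(n)
  for (bi in seq_along(boxes)) assignment[boxes[[bi]]] <- bi
  list(palette = palette, assignment = assignment)
}

aggregate_codes <- function(codes, counts) {
  key <- codes[, 1] * 65536 + codes[, 2] * 256 + codes[, 3]
  agg <- rowsum(counts, group = key)
  k <- as.numeric(rownames(agg))
  df <- data.frame(r = as.integer(k %/% 65536),
                   g = as.integer((k %/% 256) %% 256),
                   b = as.integer(k %% 256),
                   pixels = as.numeric(agg[, 1]))
  df[order(df$r, df$g, df$b), , drop = FALSE]
}
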