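#' Classify RGB codes as green
#'
#' A palette code is classified as green when its G channel strictly exceeds
#' both R and B. Equality on either channel is non-green: gray tones such as
#' (50,50,50) are excluded.
#'
#' @param r,g,b Integer channel vectors in `[0, 255]`, recycled to a common
#'   length.
#' @return Logical vector.
#' @examples
#' is_green(0, 43, 0)       # TRUE, the canonical dark green
#' is_green(135, 120, 100)  # FALSE
#' @export
is_green <- function(r, g, b) {
  g > r & g > b
}

#' Darkness index of a green code
#'
#' Computes `(R + B) / G`. Green codes are darker the closer this index is to
#' zero: the dark green (0,43,0) scores 0 while the light green (102,128,102)
#' scores 204/128 = 1.59375.
#'
#' @inheritParams is_green
#' @return Numeric vector of darkness indices (small = dark).
#' @export
darkness_index <- function(r, g, b) {
  if (any(g <= 0)) {
    stop("darkness index requires G > 0 (a code with G = 0 cannot be green)",
         call. = FALSE)
  }
  (r + b) / g
}

#' Build a weight-normalized green profile from a color table
#'
#' Filters a color table to its green codes (see [is_green()]), optionally
#' keeps the `top_k` codes by pixel count or restricts to an explicit list of
#' codes, and attaches normalized weights `W_i = A_i / sum(A_j)` where `A_i`
#' is the pixel count of the i-th retained green code. Codes are ordered dark
#' to light by the darkness index `(R+B)/G`.
#'
#' If rows for several images are passed (or `table` carries duplicate codes)
#' the pixel counts of identical codes are summed first, so the same function
#' also pools plot-level tables into a treatment-level profile.
#'
#' @param table Data frame with columns `r`, `g`, `b`, `pixels` (extra
#'   columns are ignored), e.g. a [quantize_image()] result or a subset of a
#'   [read_color_table()] set.
#' @param top_k Optional positive integer: keep only the `top_k` green codes
#'   with the largest pixel counts (ties broken by darkness index, then RGB
#'   lexicographic order) and renormalize the weights. The field convention
#'   is `top_k = 5`, the number of common green codes retained by visual
#'   palette inspection.
#' @param codes Optional explicit code list (matrix or data frame with
#'   columns `r`, `g`, `b`): keep exactly these codes (those present), in
#'   place of a `top_k` cut.
#' @param label Optional label stored on the profile.
#' @return A `green_profile`: data frame with columns `r`, `g`, `b`,
#'   `pixels`, `weight`, `darkness`, rows ordered dark to light; weights sum
#'   to 1.
#' @examples
#' tab <- data.frame(r = c(0, 102, 200), g = c(43, 128, 10),
#'                   b = c(0, 102, 10), pixels = c(300, 100, 500))
#' build_profile(tab)   # the red code is dropped; weights 0.75 / 0.25
#' @export
build_profile <- function(table, top_k = NULL, codes = NULL, label = NULL) {
  stopifnot(all(c("r", "g", "b", "pixels") %in% names(table)))
  df <- aggregate_codes(as.matrix(table[, c("r", "g", "b")]), table$pixels)
  green <- is_green(df$r, df$g, df$b)
  if (!any(green)) {
    nong <- df[order(-df$pixels), , drop = FALSE]
    top <- head(sprintf("(%d,%d,%d): %g px", nong$r, nong$g, nong$b,
                        nong$pixels), 3L)
    stop("no green codes (G > R and G > B) in table; dominant codes: ",
         paste(top, collapse = ", "), call. = FALSE)
  }
  df <- df[green, , drop = FALSE]
  df$darkness <- darkness_index(df$r, df$g, df$b)

  if (!is.null(codes)) {
    pal <- as_palette_matrix(codes)
    keep <- paste(df$r, df$g, df$b) %in% paste(pal[, 1], pal[, 2], pal[, 3])
    if (!any(keep)) {
      stop("none of the requested codes are present among the green codes",
           call. = FALSE)
    }
    df <- df[keep, , drop = FALSE]
  } else if (!is.null(top_k)) {
    if (length(top_k) != 1L || is.na(top_k) || top_k < 1 ||
        top_k != round(top_k)) {
      stop("`top_k` must be a single positive integer", call. = FALSE)
    }
    o <- order(-df$pixels, df$darkness, df$r, df$g, df$b)
    df <- df[o[seq_len(min(top_k, nrow(df)))], , drop = FALSE]
  }

  df$weight <- df$pixels / sum(df$pixels)
  df <- df[order(df$darkness, df$r, df$g, df$b), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "label") <- label
  class(df) <- c("green_profile", "data.frame")
  df
}

#' Pixel-weighted color statistics of a green profile
#'
#' Computes the five pixel-weighted statistics of a green profile: the
#' weighted channel means `sum(W_i R_i)`, `sum(W_i G_i)`, `sum(W_i B_i)` and
#' the weighted ratio means `sum(W_i R_i/G_i)` and `sum(W_i B_i/G_i)`. The
#' ratio statistics are means of per-code ratios, not ratios of means; they
#' are strictly below 1 because G strictly dominates in every green code, and
#' they approach 0 for dark canopies.
#'
#' @param profile A `green_profile` from [build_profile()] or
#'   [pool_profiles()].
#' @return A one-row data frame with columns `m` (number of codes), `mean_r`,
#'   `mean_g`, `mean_b`, `mean_rg`, `mean_bg`.
#' @examples
#' p <- build_profile(data.frame(r = 102, g = 128, b = 102, pixels = 1))
#' weighted_stats(p)  # mean_rg = mean_bg = 0.796875, i.e. 0.80
#' @export
weighted_stats <- function(profile) {
  stopifnot(inherits(profile, "green_profile"), nrow(profile) >= 1L)
  w <- profile$weight
  data.frame(
    m       = nrow(profile),
    mean_r  = sum(w * profile$r),
    mean_g  = sum(w * profile$g),
    mean_b  = sum(w * profile$b),
    mean_rg = sum(w * profile$r / profile$g),
    mean_bg = sum(w * profile$b / profile$g)
  )
}

#' Pool green profiles
#'
#' Sums pixel counts per code across profiles and rebuilds the weights, e.g.
#' to pool the four replicate plots of a treatment into one treatment-level
#' profile. Pooling is scale invariant: pooling a profile with itself doubles
#' every pixel count but leaves weights and all weighted statistics unchanged.
#'
#' @param profiles A list of `green_profile` objects.
#' @param label Optional label for the pooled profile.
#' @return A `green_profile`.
#' @export
pool_profiles <- function(profiles, label = NULL) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  ok <- vapply(profiles, inherits, logical(1), "green_profile")
  if (!all(ok)) stop("all elements must be green_profile objects", call. = FALSE)
  combined <- do.call(rbind, lapply(profiles, function(p) {
    as.data.frame(p)[, c("r", "g", "b", "pixels")]
  }))
  build_profile(combined, label = label)
}

#' The five common green palette codes
#'
#' The canonical coarse-palette green codes observed in quantized strawberry
#' canopy images, listed dark to light: (0,43,0), (51,85,51), (51,85,0),
#' (102,128,51), (102,128,102). The first is the designated dark green and
#' the last the designated light green used for the dark:light area ratio.
#' Note the conventional dark-to-light listing of the middle pair does not
#' follow the `(R+B)/G` index, which ranks (51,85,0) darker than (51,85,51);
#' [build_profile()] orders by the index.
#'
#' @return A 5-row data frame with columns `r`, `g`, `b`.
#' @export
common_green_codes <- function() {
  data.frame(
    r = c(0L, 51L, 51L, 102L, 102L),
    g = c(43L, 85L, 85L, 128L, 128L),
    b = c(0L, 51L, 0L, 51L, 102L)
  )
}
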