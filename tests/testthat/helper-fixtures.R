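# Fixture builders shared across the test files. All randomness is seeded at
# the call site.

five_codes <- common_green_codes()

# a color table over the five common green codes (+ optional non-green rows)
make_green_table <- function(pixels, extra = NULL) {
  tab <- data.frame(five_codes[seq_along(pixels), ], pixels = pixels)
  if (!is.null(extra)) tab <- rbind(tab, extra)
  tab
}

# random green table: k codes drawn under the green constraint, counts <= max_px
random_green_table <- function(k = 5, max_px = 1e4) {
  g <- sample(1:255, k, replace = TRUE)
  r <- vapply(g, function(x) sample.int(x, 1) - 1L, integer(1))
  b <- vapply(g, function(x) sample.int(x, 1) - 1L, integer(1))
  tab <- unique(data.frame(r = r, g = g, b = b))
  n <- nrow(tab)
  # split a random total across the codes, every count >= 1
  total <- sample(n:max_px, 1)
  w <- as.numeric(rgamma(n, 1)) + 1e-9
  px <- pmax(1, floor(total * w / sum(w)))
  tab$pixels <- px
  tab
}

# independent oracle: plain per-pixel means after expanding each code to rows
per_pixel_stats <- function(tab) {
  tab <- tab[is_green(tab$r, tab$g, tab$b), ]
  idx <- rep(seq_len(nrow(tab)), times = tab$pixels)
  data.frame(
    mean_r  = mean(tab$r[idx]),
    mean_g  = mean(tab$g[idx]),
    mean_b  = mean(tab$b[idx]),
    mean_rg = mean(tab$r[idx] / tab$g[idx]),
    mean_bg = mean(tab$b[idx] / tab$g[idx])
  )
}

# uniform-color test image as an H x W x 3 array on the [0,1] scale
solid_image <- function(code, h = 10, w = 10) {
  arr <- array(0, dim = c(h, w, 3))
  arr[, , 1] <- code[1] / 255
  arr[, , 2] <- code[2] / 255
  arr[, , 3] <- code[3] / 255
  arr
}

# small valid color-table set with metadata, two images
example_table_set <- function() {
  data.frame(
    image_id = rep(c("img1", "img2"), each = 2),
    plot_id = rep(c("p1", "p2"), each = 2),
    treatment = rep(c("control", "steam"), each = 2),
    month = "May", year = "Y1",
    r = c(0, 102, 0, 102), g = c(43, 128, 43, 128), b = c(0, 102, 0, 102),
    pixels = c(300, 100, 80, 20)
  )
}

# expected canonical form of a table set after a CSV round trip
validate_set_for_test <- function(df) {
  df <- df[order(df$image_id, df$r, df$g, df$b), ]
  for (ch in c("r", "g", "b")) df[[ch]] <- as.integer(df[[ch]])
  df$pixels <- as.numeric(df$pixels)
  rownames(df) <- NULL
  df
}
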