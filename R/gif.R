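# Native GIF89a writer (own LZW implementation) used as the animation
# container, plus a minimal structural parser for round-trip checks and a
# 3x5 bitmap font for frame captions.

# fixed 252-color quantization cube (6 x 7 x 6 levels of r, g, b)
.cr_gif_levels <- c(r = 6L, g = 7L, b = 6L)

cr_gif_palette <- function() {
  lv <- .cr_gif_levels
  grid <- expand.grid(b = seq_len(lv["b"]) - 1L, g = seq_len(lv["g"]) - 1L,
                      r = seq_len(lv["r"]) - 1L)
  pal <- cbind(grid$r / (lv["r"] - 1L), grid$g / (lv["g"] - 1L),
               grid$b / (lv["b"] - 1L))
  pal <- rbind(pal, matrix(0, 256L - nrow(pal), 3L))
  pal
}

cr_gif_quantize <- function(rgb_arr) {
  lv <- .cr_gif_levels
  r <- round(rgb_arr[, , 1] * (lv["r"] - 1L))
  g <- round(rgb_arr[, , 2] * (lv["g"] - 1L))
  b <- round(rgb_arr[, , 3] * (lv["b"] - 1L))
  idx <- b + lv["b"] * g + lv["b"] * lv["g"] * r   # row-major within cube
  matrix(as.integer(idx), nrow(r), ncol(r))
}

# GIF-flavoured LZW: 8-bit symbols, clear code 256, EOI 257, codes grow from
# 9 to 12 bits, table reset on overflow
cr_lzw_encode <- function(pix) {
  clear <- 256L; eoi <- 257L
  codes <- integer(length(pix) + 16L)
  nc <- 0L
  emit <- function(code) { nc <<- nc + 1L; codes[nc] <<- code }
  nxt <- matrix(0L, 4096L, 256L)
  next_code <- 258L
  emit(clear)
  cur <- pix[1] + 1L   # 1-based row into nxt; codes 0..255 map to rows 1..256
  for (i in seq_along(pix)[-1]) {
    p <- pix[i]
    hit <- nxt[cur, p + 1L]
    if (hit > 0L) {
      cur <- hit
    } else {
      emit(cur - 1L)
      if (next_code < 4096L) {
        nxt[cur, p + 1L] <- next_code + 1L
        next_code <- next_code + 1L
      } else {
        emit(clear)
        nxt[] <- 0L
        next_code <- 258L
      }
      cur <- p + 1L
    }
  }
  emit(cur - 1L)
  emit(eoi)
  codes <- codes[seq_len(nc)]
  # pack: code width tracks the encoder table size, LSB first
  bytes <- raw(length(codes) * 2L)
  nb <- 0L
  bitbuf <- 0; nbits <- 0L
  width <- 9L
  next_code <- 258L
  for (code in codes) {
    bitbuf <- bitbuf + code * 2^nbits
    nbits <- nbits + width
    while (nbits >= 8L) {
      nb <- nb + 1L
      bytes[nb] <- as.raw(bitbuf %% 256)
      bitbuf <- bitbuf %/% 256
      nbits <- nbits - 8L
    }
    if (code == clear) {
      width <- 9L; next_code <- 258L
    } else if (code != eoi) {
      # decoder adds one table entry per emitted code (after the first
      # following a clear); mirror its width growth
      if (next_code < 4096L) next_code <- next_code + 1L
      if (next_code > 2^width && width < 12L) width <- width + 1L
    }
  }
  if (nbits > 0L) { nb <- nb + 1L; bytes[nb] <- as.raw(bitbuf %% 256) }
  bytes[seq_len(nb)]
}

cr_u16 <- function(x) as.raw(c(x %% 256L, x %/% 256L))

cr_sub_blocks <- function(bytes) {
  out <- list()
  i <- 1L
  while (i <= length(bytes)) {
    j <- min(i + 254L, length(bytes))
    out[[length(out) + 1L]] <- c(as.raw(j - i + 1L), bytes[i:j])
    i <- j + 1L
  }
  out[[length(out) + 1L]] <- as.raw(0L)
  do.call(c, out)
}

#' Write an animated GIF
#'
#' Encodes RGB frames with the package's GIF89a/LZW writer, using a fixed
#' 252-color quantization palette. Deterministic: identical frames yield
#' byte-identical files.
#'
#' @param frames list of RGB arrays `(H, W, 3)` in \[0, 1\], all equal dims.
#' @param path output path.
#' @param delay_cs per-frame delay in centiseconds.
#' @param loop number of animation loops (0 = forever).
#' @return invisibly, `path`.
#' @export
write_gif <- function(frames, path, delay_cs = 10L, loop = 0L) {
  stopifnot(length(frames) >= 1L)
  d <- dim(frames[[1]])
  h <- d[1]; w <- d[2]
  pal <- cr_gif_palette()
  pal_bytes <- as.raw(as.integer(round(t(pal) * 255)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GIF89a"), con)
  writeBin(c(cr_u16(w), cr_u16(h), as.raw(0xF7), as.raw(0), as.raw(0)), con)
  writeBin(pal_bytes, con)
  writeBin(c(as.raw(c(0x21, 0xFF, 0x0B)), charToRaw("NETSCAPE2.0"),
             as.raw(c(0x03, 0x01)), cr_u16(loop), as.raw(0)), con)
  for (f in frames) {
    stopifnot(identical(dim(f), d))
    idx <- cr_gif_quantize(f)
    writeBin(c(as.raw(c(0x21, 0xF9, 0x04, 0x04)), cr_u16(delay_cs),
               as.raw(c(0, 0))), con)
    writeBin(c(as.raw(0x2C), cr_u16(0L), cr_u16(0L), cr_u16(w), cr_u16(h),
               as.raw(0)), con)
    writeBin(as.raw(8L), con)
    # pixel stream is row-major (left-to-right, top-to-bottom)
    writeBin(cr_sub_blocks(cr_lzw_encode(as.integer(t(idx)))), con)
  }
  writeBin(as.raw(0x3B), con)
  invisible(path)
}

#' Count the image frames inside a GIF file
#'
#' Structural parse of the block stream (no pixel decoding); used to verify
#' that an encoded animation carries the expected number of frames.
#'
#' @param path GIF file path.
#' @return integer frame count.
#' @export
gif_frame_count <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (!identical(rawToChar(bytes[1:6]), "GIF89a")) {
    stop("not a GIF89a file", call. = FALSE)
  }
  packed <- as.integer(bytes[11])
  i <- 14L
  if (bitwAnd(packed, 0x80L) > 0L) {
    i <- i + 3L * 2L^(bitwAnd(packed, 0x07L) + 1L)
  }
  skip_sub_blocks <- function(i) {
    repeat {
      n <- as.integer(bytes[i])
      i <- i + 1L + n
      if (n == 0L) return(i)
    }
  }
  frames <- 0L
  while (i <= length(bytes)) {
    b <- as.integer(bytes[i])
    if (b == 0x3B) break
    if (b == 0x21) {                     # extension
      i <- skip_sub_blocks(i + 2L)
    } else if (b == 0x2C) {              # image descriptor
      frames <- frames + 1L
      pk <- as.integer(bytes[i + 9L])
      i <- i + 10L
      if (bitwAnd(pk, 0x80L) > 0L) {
        i <- i + 3L * 2L^(bitwAnd(pk, 0x07L) + 1L)
      }
      i <- skip_sub_blocks(i + 1L)       # skip LZW min code size + data
    } else {
      stop("malformed GIF block at offset ", i, call. = FALSE)
    }
  }
  frames
}

## ---- caption font ----------------------------------------------------------

.cr_font <- local({
  g <- c(
    "0" = "111101101101111", "1" = "010110010010111", "2" = "111001111100111",
    "3" = "111001111001111", "4" = "101101111001001", "5" = "111100111001111",
    "6" = "111100111101111", "7" = "111001001010010", "8" = "111101111101111",
    "9" = "111101111001111", "A" = "010101111101101", "B" = "110101110101110",
    "C" = "011100100100011", "D" = "110101101101110", "E" = "111100110100111",
    "F" = "111100110100100", "G" = "011100101101011", "H" = "101101111101101",
    "I" = "111010010010111", "J" = "001001001101010", "K" = "101110100110101",
    "L" = "100100100100111", "M" = "101111111101101", "N" = "101111111111101",
    "O" = "010101101101010", "P" = "110101110100100", "Q" = "111101101111001",
    "R" = "110101110110101", "S" = "011100010001110", "T" = "111010010010010",
    "U" = "101101101101111", "V" = "101101101101010", "W" = "101101111111101",
    "X" = "101101010101101", "Y" = "101101010010010", "Z" = "111001010100111",
    "." = "000000000000010", "-" = "000000111000000", "_" = "000000000000111",
    ":" = "000010000010000", " " = "000000000000000")
  lapply(g, function(s) {
    matrix(as.integer(strsplit(s, "")[[1]]) == 1L, 5L, 3L, byrow = TRUE)
  })
})

# stamp caption pixels (white on darkened strip) into an RGB array
cr_stamp_text <- function(rgb_arr, text, x0 = 2L, y0 = 2L) {
  chars <- strsplit(text, "")[[1]]
  h <- dim(rgb_arr)[1]; w <- dim(rgb_arr)[2]
  strip_w <- min(w, x0 + length(chars) * 4L)
  if (y0 + 5L <= h) {
    rgb_arr[y0:(y0 + 5L), 1:strip_w, ] <- rgb_arr[y0:(y0 + 5L), 1:strip_w, ] * 0.35
  }
  x <- x0
  for (ch in chars) {
    glyph <- .cr_font[[ch]]
    if (is.null(glyph)) glyph <- .cr_font[[" "]]
    if (x + 2L > w || y0 + 4L > h) break
    for (gy in 1:5) for (gx in 1:3) {
      if (glyph[gy, gx]) rgb_arr[y0 + gy - 1L, x + gx - 1L, ] <- 1
    }
    x <- x + 4L
  }
  rgb_arr
}
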