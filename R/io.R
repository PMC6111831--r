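# Raster I/O. PNG/JPEG/TIFF decode through EBImage; PPM (P2/P3/P5/P6) is
# parsed directly since EBImage does not handle it. All readers return values
# in [0, 1] in the package's [row = y, col = x] convention.

#' Read an image file as an RGB image
#'
#' Accepts PNG, JPEG, TIFF, or PPM/PGM. Values are rescaled to `[0, 1]`;
#' greyscale inputs are replicated across three identical channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path Path to the image file.
#' @return An [rgb_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("ppm", "pgm")) {
    read_pnm(path)
  } else {
    x <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
    a <- EBImage::imageData(x)  # dims: (x, y[, channel])
    if (length(dim(a)) == 2) {
      t(a)
    } else {
      nc <- dim(a)[3]
      if (nc >= 3) {
        array(c(t(a[, , 1]), t(a[, , 2]), t(a[, , 3])),
              c(dim(a)[2], dim(a)[1], 3))
      } else {
        t(a[, , 1])
      }
    }
  }
  arr <- pmin(pmax(arr, 0), 1)
  rgb_image(arr)
}

# Minimal PPM/PGM (P2/P3/P5/P6) parser.
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic '", magic, "' in ", path, call. = FALSE)
  tok <- pnm_tokens(con, 3)
  w <- as.integer(tok[1]); h <- as.integer(tok[2]); mx <- as.numeric(tok[3])
  if (is.na(w) || is.na(h) || w < 1 || h < 1 || is.na(mx) || mx < 1)
    stop("malformed PNM header in ", path, call. = FALSE)
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    if (mx > 255) {
      v <- readBin(con, "integer", n, size = 2, signed = FALSE,
                   endian = "big")
    } else {
      v <- as.integer(readBin(con, "raw", n))
    }
    if (length(v) < n) stop("truncated PNM data in ", path, call. = FALSE)
    v
  } else {
    v <- scan(con, what = numeric(), n = n, quiet = TRUE)
    if (length(v) < n) stop("truncated PNM data in ", path, call. = FALSE)
    v
  }
  vals <- vals / mx
  if (nch == 1L) {
    matrix(vals, h, w, byrow = TRUE)
  } else {
    # interleaved r,g,b per pixel, row-major
    a <- array(vals, c(3, w, h))
    array(c(t(a[1, , ]), t(a[2, , ]), t(a[3, , ])), c(h, w, 3))
  }
}

# Read whitespace-separated PNM header tokens, skipping '#' comments.
pnm_tokens <- function(con, n) {
  out <- character(0)
  buf <- ""
  while (length(out) < n) {
    ch <- rawToChar(readBin(con, "raw", 1))
    if (!length(ch) || !nzchar(ch)) stop("truncated PNM header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1))
        if (ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(buf)) { out <- c(out, buf); buf <- "" }
    } else buf <- paste0(buf, ch)
  }
  out
}

#' Write an image or response map as PNG
#'
#' @param x An [rgb_image()], or a numeric matrix in `[0, 1]` (written as
#'   greyscale).
#' @param path Output path (PNG).
#' @param bits Bit depth, 8 (default) or 16; 16-bit preserves fine response
#'   gradations in dumped intermediate maps.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path, bits = 8) {
  if (!bits %in% c(8, 16)) stop("'bits' must be 8 or 16", call. = FALSE)
  a <- if (inherits(x, "rgb_image")) x$pixels else x
  if (min(a) < 0 || max(a) > 1)
    stop("values must lie in [0, 1]; rescale before writing", call. = FALSE)
  if (bits == 8) {
    png::writePNG(a, path)
  } else {
    if (!is.matrix(a))
      stop("16-bit output is for greyscale response maps only", call. = FALSE)
    write_png16_grey(a, path)
  }
  invisible(path)
}

# Minimal 16-bit greyscale PNG encoder (no installed package writes 16-bit
# PNG). The zlib stream uses stored (uncompressed) deflate blocks, which the
# format permits; response maps are small, so size is irrelevant.
write_png16_grey <- function(mat, path) {
  h <- nrow(mat); w <- ncol(mat)
  v <- as.integer(round(t(mat) * 65535))
  px <- matrix(0L, nrow = 2 * w, ncol = h)
  px[seq(1, 2 * w, 2), ] <- v %/% 256L
  px[seq(2, 2 * w, 2), ] <- v %% 256L
  raw_rows <- rbind(0L, px)  # filter byte 0 per scanline
  dat <- as.raw(as.vector(raw_rows))
  u32 <- function(x) as.raw(c(x %/% 16777216, (x %/% 65536) %% 256,
                              (x %/% 256) %% 256, x %% 256))
  adler <- function(d) {
    a <- 1; b <- 0
    for (chunk in split(as.integer(d), ceiling(seq_along(d) / 4096))) {
      for (x in chunk) { a <- (a + x) %% 65521; b <- (b + a) %% 65521 }
    }
    u32(b * 65536 + a)
  }
  zlib <- c(as.raw(c(0x78, 0x01)), local({
    out <- raw(0); i <- 1; n <- length(dat)
    while (i <= n) {
      len <- min(65535L, n - i + 1L)
      fin <- if (i + len > n) as.raw(1) else as.raw(0)
      out <- c(out, fin,
               as.raw(c(len %% 256, len %/% 256,
                        255 - len %% 256, 255 - len %/% 256)),
               dat[i:(i + len - 1)])
      i <- i + len
    }
    out
  }), adler(dat))
  # table-driven CRC-32 in double arithmetic (values stay below 2^32)
  xor32 <- function(a, b) {
    hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
    lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
    as.numeric(hi) * 65536 + lo
  }
  crc_table <- local({
    tab <- numeric(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8)
        c <- if (c %% 2) xor32(3988292384, c %/% 2) else c %/% 2
      tab[n + 1] <- c
    }
    tab
  })
  crc32r <- function(d) {
    c <- 4294967295
    for (x in as.integer(d))
      c <- xor32(crc_table[(xor32(c, x) %% 256) + 1], c %/% 256)
    u32(xor32(c, 4294967295))
  }
  png_chunk <- function(type, payload) {
    body <- c(charToRaw(type), payload)
    c(u32(length(payload)), body, crc32r(body))
  }
  sig <- as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))
  ihdr <- c(u32(w), u32(h), as.raw(c(16, 0, 0, 0, 0)))
  out <- c(sig, png_chunk("IHDR", ihdr), png_chunk("IDAT", zlib),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read boundary ground truth
#'
#' Each annotator map is either a PNG (binarised at 0.5) or a
#' whitespace-separated 0/1 text matrix. Multiple annotators are either given
#' as an explicit vector of paths, or found by a shared stem
#' (`stem.png` / `stem_1.png`, `stem_2.txt`, ...).
#'
#' @param paths Character vector of mask files, or a single stem.
#' @return A [boundary_gt()].
#' @export
read_boundary_gt <- function(paths) {
  if (length(paths) == 1 && !file.exists(paths)) {
    hits <- Sys.glob(c(paste0(paths, ".png"), paste0(paths, ".txt"),
                       paste0(paths, "_*.png"), paste0(paths, "_*.txt")))
    if (!length(hits))
      stop("no ground-truth files match stem: ", paths, call. = FALSE)
    paths <- sort(hits)
  }
  maps <- lapply(paths, function(p) {
    if (tolower(tools::file_ext(p)) %in% c("png", "jpg", "jpeg", "tif",
                                           "tiff", "ppm", "pgm")) {
      m <- greyscale(read_image(p))
      (m >= 0.5) * 1
    } else {
      m <- as.matrix(utils::read.table(p))
      dimnames(m) <- NULL
      if (!all(m %in% c(0, 1)))
        stop("text mask must contain only 0/1: ", p, call. = FALSE)
      m
    }
  })
  boundary_gt(maps)
}

#' Write a binary boundary mask as a 0/1 text matrix
#'
#' @param mask `H x W` matrix in `{0, 1}`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundary_mask <- function(mask, path) {
  utils::write.table(mask, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
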