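# Image I/O (PNG / TIFF / PGM grayscale), the seeded synthetic phantom
# generator, bilinear pixel<->node resampling and quality metrics.

#' Seeded synthetic phantoms
#'
#' Generates a clean test scene in \[0,1\] plus a noisy version with seeded
#' additive Gaussian noise (clipped back to \[0,1\]). Scenes: `disks` —
#' sharp-contoured shapes on a dark background (exercises ringing and edge
#' preservation at strong contours); `step_edge` — a single straight
#' intensity step; `microgrooves` — fine parallel low-contrast ridges
#' without sharp boundaries; `sine` — a single smooth cosine mode (Neumann
#' compatible), useful for diffusion-rate checks. All synthetic: these stand
#' in for real medical imagery with comparable edge structure.
#'
#' @param size integer pair `(rows, cols)` (a scalar is squared).
#' @param scene one of `"disks"`, `"step_edge"`, `"microgrooves"`, `"sine"`.
#' @param contrast amplitude of the scene features, in (0, 1\].
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param seed RNG seed; identical specs give identical images. The global
#'   RNG state is restored on exit.
#' @return list with matrices `clean` and `noisy` (rows y, columns x) and
#'   the spec fields.
#' @export
generate_phantom <- function(size = 129L, scene = c("disks", "step_edge",
                                                    "microgrooves", "sine"),
                             contrast = 0.6, noise_sigma = 0.05, seed = 42L) {
  scene <- match.arg(scene)
  if (length(size) == 1L) size <- c(size, size)
  if (any(size < 8)) stop("invalid size: need at least 8 pixels per side")
  stopifnot(contrast > 0, contrast <= 1, noise_sigma >= 0)
  nr <- size[1]; nc <- size[2]
  x <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
  y <- matrix(rep(seq(0, 1, length.out = nr), nc), nr, nc)
  base <- 0.5 - contrast / 2
  clean <- switch(scene,
    disks = {
      img <- matrix(base, nr, nc)
      disks <- list(c(0.35, 0.4, 0.22, 1.0), c(0.7, 0.65, 0.14, 0.75),
                    c(0.3, 0.75, 0.09, 0.55))
      for (d in disks) {
        inside <- (x - d[1])^2 + (y - d[2])^2 <= d[3]^2
        img[inside] <- base + contrast * d[4]
      }
      img
    },
    step_edge = base + contrast * (x >= 0.5),
    microgrooves = {
      ph <- 2 * pi * 14 * (x + 0.35 * y)
      0.5 + (contrast / 2) * tanh(2.5 * sin(ph)) / tanh(2.5) *
        (0.35 + 0.65 * y)                  # ridge contrast grows along y
    },
    sine = 0.5 + (contrast / 2) * cos(2 * pi * x) * cos(2 * pi * y))
  clean <- pmin(pmax(clean, 0), 1)
  noisy <- clean
  if (noise_sigma > 0) {
    old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    noisy <- clean + matrix(stats::rnorm(nr * nc, sd = noise_sigma), nr, nc)
    noisy <- pmin(pmax(noisy, 0), 1)
  }
  list(clean = clean, noisy = noisy, scene = scene, contrast = contrast,
       noise_sigma = noise_sigma, seed = seed, size = size)
}

#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(1 / \mathrm{MSE})} in dB on the \[0,1\] intensity
#' scale; `Inf` for identical images.
#'
#' @param reference,test image matrices of equal shape.
#' @return PSNR in dB.
#' @examples
#' psnr(matrix(0, 2, 2), matrix(0.1, 2, 2))   # 20
#' @export
psnr <- function(reference, test) {
  if (!all(dim(reference) == dim(test))) stop("shape mismatch")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

# separable bilinear resampling between pixel grids (used for the
# pixel <-> collocation-node mapping when the block edge is not 2^J + 1)
resample_bilinear <- function(m, nr, nc) {
  if (nrow(m) == nr && ncol(m) == nc) return(m)
  interp_1d <- function(mat, nout) {       # resample rows
    nin <- nrow(mat)
    if (nin == nout) return(mat)
    t <- seq(0, 1, length.out = nout) * (nin - 1) + 1
    i0 <- pmin(floor(t), nin - 1)
    w <- t - i0
    mat[i0, , drop = FALSE] * (1 - w) + mat[i0 + 1, , drop = FALSE] * w
  }
  t(interp_1d(t(interp_1d(m, nr)), nc))
}

#' Read a grayscale image as an intensity field
#'
#' Reads an 8- or 16-bit grayscale PNG, TIFF or PGM file and rescales to
#' \[0,1\]. Color inputs are rejected rather than silently converted.
#'
#' @param path file path; format inferred from the extension.
#' @return matrix of intensities in \[0,1\] with attribute `bit_depth`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    depth <- 8L
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path)
    depth <- 8L
  } else if (ext == "pgm") {
    return(read_pgm(path))
  } else stop("format error: unsupported extension '", ext, "'")
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] > 1L)
      stop("format error: multi-channel (color) input; grayscale required")
    a <- a[, , 1]
  }
  structure(a, bit_depth = depth)
}

#' Write an intensity field as a grayscale image
#'
#' Clamps to \[0,1\] and writes PNG, TIFF or PGM at the requested bit depth,
#' rounding half to even. A read-write-read trip is idempotent at the stored
#' depth.
#'
#' @param field intensity matrix in \[0,1\].
#' @param path output path; format from the extension.
#' @param bit_depth 8 or 16 (PGM and PNG; TIFF is written 8-bit).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(field, path, bit_depth = 8L) {
  f <- pmin(pmax(field, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(f, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(f, path)
  } else if (ext == "pgm") {
    write_pgm(f, path, bit_depth)
  } else stop("format error: unsupported extension '", ext, "'")
  invisible(path)
}

# minimal PGM (P2 ascii / P5 binary) support; maxval 255 or 65535
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0) stop("format error: truncated PGM header")
      if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE)
        if (length(c2) == 0 || c2 == "\n") break } ; next }
      if (!grepl("[[:space:]]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0 || grepl("[[:space:]]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P5")) stop("format error: not a PGM file (", magic, ")")
  nc <- as.integer(tok()); nr <- as.integer(tok()); maxv <- as.integer(tok())
  n <- nr * nc
  vals <- if (magic == "P2") {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (maxv < 256L) {
    as.integer(readBin(con, "raw", n))
  } else {
    readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
  }
  structure(matrix(vals / maxv, nr, nc, byrow = TRUE),
            bit_depth = if (maxv < 256L) 8L else 16L)
}

write_pgm <- function(field, path, bit_depth = 8L) {
  stopifnot(bit_depth %in% c(8L, 16L))
  maxv <- 2L^bit_depth - 1L
  q <- matrix(as.integer(round(field * maxv)), nrow(field), ncol(field))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(field), nrow(field), maxv),
            con, eos = NULL)
  v <- as.vector(t(q))                     # row-major raster order
  if (bit_depth == 8L) {
    writeBin(as.raw(v), con)
  } else {
    writeBin(as.integer(v), con, size = 2L, endian = "big")
  }
  invisible(path)
}
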