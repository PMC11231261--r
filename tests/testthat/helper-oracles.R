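# Independent brute-force oracles and shared fixtures. Oracles here never
# call the code paths they check.

# all-pairs voxel-center distance oracle for shell partitions
brute_shell_index <- function(ref_mask, spacing, K, w) {
  d <- dim(ref_mask)
  refs <- which(ref_mask, arr.ind = TRUE)
  out <- array(0L, dim = d)
  for (i in seq_len(prod(d))) {
    ai <- arrayInd(i, d)
    dsq <- Inf
    for (r in seq_len(nrow(refs))) {
      s <- 0
      for (a in seq_along(d)) s <- s + ((ai[a] - refs[r, a]) * spacing[a])^2
      dsq <- min(dsq, s)
    }
    if (dsq == 0) next
    for (k in seq_len(K)) {
      if (dsq > ((k - 1) * w)^2 && dsq <= (k * w)^2) {
        out[i] <- k
        break
      }
    }
  }
  out
}

# direct grayscale morphological opening with a disc, ignore-outside padding
brute_opening_disc <- function(img, radius) {
  br <- EBImage::makeBrush(2L * radius + 1L, "disc")
  ctr <- radius + 1L
  off <- which(br > 0, arr.ind = TRUE) - ctr
  n <- nrow(img); m <- ncol(img)
  sweep_minmax <- function(x, f, fill) {
    acc <- matrix(fill, n, m)
    for (k in seq_len(nrow(off))) {
      sh <- matrix(fill, n, m)
      yy <- (1:n) + off[k, 1]; xx <- (1:m) + off[k, 2]
      vy <- yy >= 1 & yy <= n; vx <- xx >= 1 & xx <= m
      sh[vy, vx] <- x[yy[vy], xx[vx]]
      acc <- f(acc, sh)
    }
    acc
  }
  er <- sweep_minmax(img, pmin, Inf)
  sweep_minmax(er, pmax, -Inf)
}

# mask with separated square blobs of the requested pixel counts (raster
# order = given order); counts must be perfect squares or small
blob_mask <- function(counts, side = 40L) {
  m <- array(FALSE, dim = c(side, max(40L, 12L * length(counts))))
  x0 <- 2L
  for (i in seq_along(counts)) {
    c_i <- counts[i]
    w <- ceiling(sqrt(c_i))
    cells <- arrayInd(seq_len(c_i), c(w, w))
    m[cbind(2L + cells[, 1], x0 + cells[, 2])] <- TRUE
    x0 <- x0 + w + 3L
  }
  m
}

# minimal uncompressed little-endian single-strip TIFF with an
# ImageDescription tag: builds the OME-TIFF fixture for metadata parsing
# (binary fixtures cannot be stored in the repository)
write_minimal_ome_tiff <- function(path, img16, description) {
  img16 <- as.matrix(img16)
  h <- nrow(img16); w <- ncol(img16)
  desc <- c(charToRaw(description), as.raw(0L)) # nul-terminated
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  n_entries <- 10L
  # layout: 8-byte header, pixel data, description, then IFD
  pix_off <- 8L
  pix_len <- h * w * 2L
  desc_off <- pix_off + pix_len
  ifd_off <- desc_off + length(desc)
  writeBin(ifd_off, con, size = 4, endian = "little")
  # pixel data, row-major (TIFF rows = image rows)
  writeBin(as.integer(t(img16)), con, size = 2, endian = "little")
  writeBin(desc, con)
  writeBin(n_entries, con, size = 2, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  entry(256, 4, 1, w)              # ImageWidth
  entry(257, 4, 1, h)              # ImageLength
  entry(258, 3, 1, 16)             # BitsPerSample
  entry(259, 3, 1, 1)              # Compression: none
  entry(262, 3, 1, 1)              # Photometric: BlackIsZero
  entry(270, 2, length(desc), desc_off) # ImageDescription
  entry(273, 4, 1, pix_off)        # StripOffsets
  entry(277, 3, 1, 1)              # SamplesPerPixel
  entry(278, 4, 1, h)              # RowsPerStrip
  entry(279, 4, 1, pix_len)        # StripByteCounts
  writeBin(0L, con, size = 4, endian = "little") # next IFD
  invisible(path)
}
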