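# Shared fixtures and independent oracles for the test suite.

small_geometry <- function(n = 10) device_geometry(n_channels_per_side = n)

# Independent connected-component oracle: plain BFS flood fill, written
# without reference to the package's union-find labeller.
bfs_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 4) {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5, ]
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        r <- p[1] + nbr[k, 1]; c <- p[2] + nbr[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Shift an image by (dr, dc) with zero padding (for registration tests).
shift_matrix <- function(m, dr, dc) {
  out <- matrix(0L, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dr
  src_c <- seq_len(ncol(m)) - dc
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

shift_image <- function(img, dr, dc) {
  out <- lapply(img, shift_matrix, dr = dr, dc = dc)
  class(out) <- "rendered_image"
  out
}

# Sorted-interpolation quantile oracle (linear between order statistics).
quantile_oracle <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
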