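# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package internals.

oracle_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# window of size w covers offsets -(w-1)%/%2 .. w%/%2
oracle_rank_filter <- function(img, wy, wx, fun) {
  ny <- nrow(img)
  nx <- ncol(img)
  ly <- -((wy - 1) %/% 2)
  hy <- wy %/% 2
  lx <- -((wx - 1) %/% 2)
  hx <- wx %/% 2
  out <- matrix(0, ny, nx)
  for (y in seq_len(ny)) {
    for (x in seq_len(nx)) {
      vals <- numeric(0)
      for (dy in ly:hy) {
        for (dx in lx:hx) {
          vals <- c(vals, img[oracle_reflect(y + dy, ny),
                              oracle_reflect(x + dx, nx)])
        }
      }
      out[y, x] <- fun(vals)
    }
  }
  out
}

oracle_laplacian <- function(img) {
  ny <- nrow(img)
  nx <- ncol(img)
  out <- matrix(0, ny, nx)
  for (y in seq_len(ny)) {
    for (x in seq_len(nx)) {
      out[y, x] <- img[oracle_reflect(y - 1, ny), x] +
        img[oracle_reflect(y + 1, ny), x] +
        img[y, oracle_reflect(x - 1, nx)] +
        img[y, oracle_reflect(x + 1, nx)] -
        4 * img[y, x]
    }
  }
  out
}

oracle_label <- function(mask, connectivity = 8L) {
  ny <- nrow(mask)
  nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  nbr <- if (connectivity == 4L) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    as.matrix(expand.grid(dy = -1:1, dx = -1:1))[-5, ]
  }
  cur <- 0L
  for (x in seq_len(nx)) {
    for (y in seq_len(ny)) {
      if (!mask[y, x] || lab[y, x] > 0L) next
      cur <- cur + 1L
      queue <- list(c(y, x))
      lab[y, x] <- cur
      while (length(queue)) {
        p <- queue[[1L]]
        queue <- queue[-1L]
        for (j in seq_len(nrow(nbr))) {
          yy <- p[1L] + nbr[j, 1L]
          xx <- p[2L] + nbr[j, 2L]
          if (yy >= 1 && yy <= ny && xx >= 1 && xx <= nx &&
              mask[yy, xx] && lab[yy, xx] == 0L) {
            lab[yy, xx] <- cur
            queue[[length(queue) + 1L]] <- c(yy, xx)
          }
        }
      }
    }
  }
  lab
}

# same partition? (labels may be numbered differently)
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  ia <- a[a > 0]
  ib <- b[b > 0]
  length(unique(paste(ia, ib))) == length(unique(ia)) &&
    length(unique(ia)) == length(unique(ib))
}

# flat-background image with one or more Gaussian spots (loop construction)
oracle_spot_image <- function(ny, nx, centres, amplitude, sigma,
                              background = 0) {
  img <- matrix(background, ny, nx)
  for (y in seq_len(ny)) {
    for (x in seq_len(nx)) {
      for (i in seq_len(nrow(centres))) {
        img[y, x] <- img[y, x] + amplitude[min(i, length(amplitude))] *
          exp(-((x - 1 - centres[i, 1])^2 + (y - 1 - centres[i, 2])^2) /
                (2 * sigma^2))
      }
    }
  }
  img
}

# greedy one-to-one matching of detections to ground truth within max_dist
match_spots <- function(det_x, det_y, true_x, true_y, max_dist) {
  used <- rep(FALSE, length(true_x))
  hits <- 0L
  for (i in seq_along(det_x)) {
    if (!length(true_x)) break
    d <- sqrt((true_x - det_x[i])^2 + (true_y - det_y[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= max_dist) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  hits
}
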