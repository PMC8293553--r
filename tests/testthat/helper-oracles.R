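# Brute-force reference implementations, deliberately independent of the
# package's labelling code: plain queue-based flood fills on small masks.

# number of 8-connected foreground components
oracle_count_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  n <- 0L
  for (y0 in seq_len(h)) for (x0 in seq_len(w)) {
    if (mask[y0, x0] && !seen[y0, x0]) {
      n <- n + 1L
      queue <- list(c(y0, x0)); seen[y0, x0] <- TRUE
      while (length(queue)) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (dy in -1:1) for (dx in -1:1) {
          ny <- p[1L] + dy; nx <- p[2L] + dx
          if ((dy || dx) && ny >= 1 && ny <= h && nx >= 1 && nx <= w &&
              mask[ny, nx] && !seen[ny, nx]) {
            seen[ny, nx] <- TRUE
            queue[[length(queue) + 1L]] <- c(ny, nx)
          }
        }
      }
    }
  }
  n
}

# hole filling: background flood-filled from the border (4-connectivity);
# anything not reached becomes foreground
oracle_fill_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  outside <- matrix(FALSE, h, w)
  queue <- list()
  for (x in seq_len(w)) for (y in c(1L, h)) {
    if (!mask[y, x] && !outside[y, x]) { outside[y, x] <- TRUE; queue[[length(queue) + 1L]] <- c(y, x) }
  }
  for (y in seq_len(h)) for (x in c(1L, w)) {
    if (!mask[y, x] && !outside[y, x]) { outside[y, x] <- TRUE; queue[[length(queue) + 1L]] <- c(y, x) }
  }
  steps <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  while (length(queue)) {
    p <- queue[[1L]]; queue <- queue[-1L]
    for (s in steps) {
      ny <- p[1L] + s[1L]; nx <- p[2L] + s[2L]
      if (ny >= 1 && ny <= h && nx >= 1 && nx <= w &&
          !mask[ny, nx] && !outside[ny, nx]) {
        outside[ny, nx] <- TRUE
        queue[[length(queue) + 1L]] <- c(ny, nx)
      }
    }
  }
  mask | !outside
}

random_mask <- function(h, w, p = 0.3) matrix(runif(h * w) < p, h, w)

# disc mask centred in an h x w canvas
disc_mask <- function(h, w, cy, cx, r) {
  yy <- matrix(seq_len(h) - 1, h, w)
  xx <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}
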