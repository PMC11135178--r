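# Independent oracles and small fixtures shared across tests.

# exhaustive minimum-cost path through an error surface: enumerate every
# column sequence whose steps are in {-1, 0, +1}
bruteForceCutCost <- function(e) {
  N <- nrow(e); M <- ncol(e)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + e[i, j]
    if (acc >= best) return(invisible(NULL))
    if (i == N) {
      best <<- acc
      return(invisible(NULL))
    }
    for (nj in (j - 1L):(j + 1L))
      if (nj >= 1L && nj <= M) recurse(i + 1L, nj, acc)
    invisible(NULL)
  }
  for (j0 in seq_len(M)) recurse(1L, j0, 0)
  best
}

# brute-force 4-connected flood fill; labels assigned in column-major
# first-encounter order (the same canonical order the package uses)
floodFillLabel <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nextl <- 0L
  for (c in seq_len(W)) for (r in seq_len(H)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    nextl <- nextl + 1L
    queue <- list(c(r, c))
    lab[r, c] <- nextl
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- p[1L] + d[1L]; cc <- p[2L] + d[2L]
        if (rr >= 1L && rr <= H && cc >= 1L && cc <= W &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nextl
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# canonical relabeling in column-major first-encounter order, so two
# labelings can be compared as partitions
canonicalLabels <- function(lab) {
  ids <- unique(lab[lab > 0L])
  seen <- integer(0)
  out <- lab
  k <- 0L
  for (i in seq_along(lab)) {
    v <- lab[i]
    if (v > 0L && !(v %in% seen)) {
      seen <- c(seen, v)
    }
  }
  remap <- stats::setNames(seq_along(seen), seen)
  out[lab > 0L] <- remap[as.character(lab[lab > 0L])]
  out
}

# small gridded page with a single smooth trace, used by extraction tests.
# cosine phase (flat start) and a sub-pixel-per-column slope keep the
# rendered rows a |step| <= 1 staircase, the regime where column-wise
# extraction is exact
smoothTracePage <- function(dpi = 200, amp_mv = 0.4, freq_hz = 1,
                            show_grid = TRUE) {
  spec <- renderSpec(dpi = dpi, paper_size = c(4, 2), show_grid = show_grid)
  img <- renderGrid(spec)
  W <- dim(imagePixels(img))[2L]
  baseline <- round(dim(imagePixels(img))[1L] / 2)
  cols <- round(0.1 * W):round(0.9 * W)
  tt <- (cols - cols[1L]) / spec$px_per_s
  mv <- amp_mv * cos(2 * pi * freq_hz * tt)
  rows <- baseline - round(mv * spec$px_per_mv)
  img <- drawPolyline(img, cols, rows, color = c(0, 0, 0))
  list(image = img, cols = cols, rows = rows, baseline = baseline,
       spec = spec, mv = mv)
}
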