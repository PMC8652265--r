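# Independent brute-force implementations used as oracles. These are kept
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can serve as a second route to the same quantities.

bf_label <- function(x, connectivity = 8) {
  x <- matrix(as.logical(x), nrow(x))
  nr <- nrow(x); nc <- ncol(x)
  lab <- matrix(0L, nr, nc); nxt <- 0L
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  if (connectivity == 4) offs <- offs[offs$di == 0 | offs$dj == 0, ]
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!x[i, j] || lab[i, j] > 0) next
    nxt <- nxt + 1L
    stack <- list(c(i, j)); lab[i, j] <- nxt
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        ni <- cur[1] + offs$di[k]; nj <- cur[2] + offs$dj[k]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
            x[ni, nj] && lab[ni, nj] == 0) {
          lab[ni, nj] <- nxt
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# the four landscape metrics by explicit per-cell edge/area counting
bf_metrics <- function(high, cell_size = 10, connectivity = 8,
                       count_boundary = TRUE) {
  high <- matrix(as.logical(high), nrow(high))
  lab <- bf_label(high, connectivity)
  np <- max(lab)
  A_land <- length(high) * cell_size^2 / 1e4
  if (np == 0)
    return(list(pland = 0, area_mn = NA_real_, shape_mn = NA_real_, ed = 0,
                n_patches = 0L))
  area <- numeric(np); per <- numeric(np)
  nr <- nrow(high); nc <- ncol(high)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    p <- lab[i, j]
    if (p == 0) next
    area[p] <- area[p] + cell_size^2
    for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ni <- i + s[1]; nj <- j + s[2]
      outside <- ni < 1 || ni > nr || nj < 1 || nj > nc
      if (outside) {
        if (count_boundary) per[p] <- per[p] + cell_size
      } else if (!high[ni, nj]) {
        per[p] <- per[p] + cell_size
      }
    }
  }
  list(pland = 100 * sum(area) / (A_land * 1e4),
       area_mn = mean(area) / 1e4,
       shape_mn = mean(0.25 * per / sqrt(area)),
       ed = sum(per) / A_land,
       n_patches = np)
}

# park-effect heat mitigation by an all-pairs loop over pixels
bf_heat_mitigation <- function(cc, green, res, params) {
  green <- matrix(as.logical(green), nrow(green))
  lab <- bf_label(green, 8)
  big <- matrix(FALSE, nrow(green), ncol(green))
  if (max(lab) > 0) {
    min_cells <- params$green_area_min * 1e4 / res^2
    for (p in seq_len(max(lab)))
      if (sum(lab == p) >= min_cells) big[lab == p] <- TRUE
  }
  nr <- nrow(cc); nc <- ncol(cc)
  hm <- cc
  gi <- which(big, arr.ind = TRUE)
  if (nrow(gi) == 0) return(hm)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    d <- sqrt((gi[, 1] - i)^2 + (gi[, 2] - j)^2) * res
    keep <- d <= params$d_cool
    if (!any(keep)) next
    w <- exp(-d[keep] / params$d_cool)
    gam <- sum(w * cc[gi[keep, , drop = FALSE]]) / sum(w)
    hm[i, j] <- max(cc[i, j], gam)
  }
  pmin(pmax(hm, 0), 1)
}
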