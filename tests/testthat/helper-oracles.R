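# Independent brute-force oracles and small fixture builders. These never
# call the implementation paths they are used to check.

# flood-fill connected-component labeling (queue-based, pure R)
oracle_flood_fill <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 8) {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  nxt <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      cur <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (k in seq_len(nrow(nbr))) {
        r <- cur[1] + nbr[k, 1]; cc <- cur[2] + nbr[k, 2]
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- nxt
          queue[[length(queue) + 1]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# all-pairs proximity count: a-cells with any b-cell within r
oracle_prox_count <- function(ax, ay, bx, by, r) {
  if (!length(ax) || !length(bx)) return(0L)
  d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
  sum(apply(d2, 1, min) <= r^2)
}

# BH step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# exhaustive agglomerative complete-linkage clustering cut at height h
oracle_complete_linkage <- function(d, h) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- c(NA, NA); bestd <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      dd <- max(d[clusters[[i]], clusters[[j]]])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    if (bestd > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  assign <- integer(n)
  for (i in seq_along(clusters)) assign[clusters[[i]]] <- i
  assign
}

# brute-force grid box count over a pixel set
oracle_box_count <- function(x, y, eps) {
  length(unique(paste(floor(x / eps), floor(y / eps))))
}

# filled disk mask of radius r in an n x n raster
disk_mask <- function(n, r, cx = n / 2, cy = n / 2) {
  xy <- expand.grid(row = seq_len(n), col = seq_len(n))
  matrix((xy$row - cy)^2 + (xy$col - cx)^2 <= r^2, n, n)
}

# tiny two-region slide: left half CT, right half CAS
half_half_slide <- function(n = 40, mpp = 4, cells = empty_cell_table()) {
  r <- matrix(1L, n, n)
  r[, (n / 2 + 1):n] <- 2L
  slide_map(r, cells, slide_id = "half", mpp = mpp)
}

random_slide <- function(seed, n = 64, mpp = 4, n_cells = 30) {
  set.seed(seed)
  r <- matrix(sample(0:3, n * n, replace = TRUE, prob = c(.4, .3, .2, .1)), n, n)
  cells <- data.frame(
    x_um = runif(n_cells, 0, n * mpp), y_um = runif(n_cells, 0, n * mpp),
    cell_class = sample(c("lymphocyte", "plasma", "fibroblast", "macrophage",
                          "cancer"), n_cells, replace = TRUE),
    stringsAsFactors = FALSE)
  slide_map(r, cells, slide_id = paste0("rand", seed), mpp = mpp)
}
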