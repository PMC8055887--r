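# Independent reference implementations used to cross-check the package.
# These are deliberately naive (enumeration / repeated scans) and share no
# code with the implementations they verify.

# --- watershed: exhaustive level-by-level flooding -------------------------
# Semantics: seed all regional minima (plateau-aware). Then repeatedly pick,
# among unlabeled pixels adjacent to the labeled region, the one with the
# smallest (value, row, col); it takes the label of its labeled neighbour
# with the smallest (value, row, col).
oracle_watershed <- function(relief, connectivity = 8, mask = NULL) {
  H <- nrow(relief); W <- ncol(relief)
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  lab <- matrix(0L, H, W)
  nb <- function(r, c) {
    d <- if (connectivity == 8)
      rbind(c(-1,0), c(1,0), c(0,-1), c(0,1), c(-1,-1), c(-1,1), c(1,-1), c(1,1))
    else rbind(c(-1,0), c(1,0), c(0,-1), c(0,1))
    out <- cbind(r + d[,1], c + d[,2])
    out[out[,1] >= 1 & out[,1] <= H & out[,2] >= 1 & out[,2] <= W, , drop = FALSE]
  }
  # regional minima via plateau flood fill
  seen <- matrix(FALSE, H, W)
  next_lab <- 0L
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    v <- relief[r0, c0]
    plateau <- list(); queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    is_min <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      plateau[[length(plateau) + 1L]] <- p
      for (k in seq_len(nrow(nb(p[1], p[2])))) {
        q <- nb(p[1], p[2])[k, ]
        if (!mask[q[1], q[2]]) next
        w <- relief[q[1], q[2]]
        if (w < v) is_min <- FALSE
        else if (w == v && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    if (is_min) {
      next_lab <- next_lab + 1L
      for (p in plateau) lab[p[1], p[2]] <- next_lab
    }
  }
  # flood one pixel at a time
  repeat {
    frontier <- NULL
    for (c in seq_len(W)) for (r in seq_len(H)) {
      if (!mask[r, c] || lab[r, c] != 0L) next
      nn <- nb(r, c)
      if (any(lab[nn] != 0L))
        frontier <- rbind(frontier, c(relief[r, c], r, c))
    }
    if (is.null(frontier)) break
    o <- order(frontier[, 1], frontier[, 2], frontier[, 3])[1]
    r <- frontier[o, 2]; c <- frontier[o, 3]
    nn <- nb(r, c)
    nn <- nn[lab[nn] != 0L, , drop = FALSE]
    o2 <- order(relief[nn], nn[, 1], nn[, 2])[1]
    lab[r, c] <- lab[nn[o2, 1], nn[o2, 2]]
  }
  lab
}

# canonical relabeling by first occurrence (column-major) so two label
# images can be compared up to label permutation
canon_labels <- function(lab) {
  v <- as.vector(lab)
  ids <- unique(v[v != 0])
  out <- v
  for (i in seq_along(ids)) out[v == ids[i]] <- i
  matrix(out, nrow(lab), ncol(lab))
}

# --- matching: repeated full-scan greedy -----------------------------------
# Applies the matching rule by exhaustive search: repeatedly scan the full
# distance matrix for the smallest remaining distance < R (ties by
# prediction index then truth index), accept, remove both points.
oracle_match <- function(px, py, tx, ty, R) {
  np <- length(px); nt <- length(tx)
  pairs <- NULL
  if (np > 0 && nt > 0) {
    dmat <- sqrt(outer(px, tx, "-")^2 + outer(py, ty, "-")^2)
    used_p <- logical(np); used_t <- logical(nt)
    repeat {
      best <- NULL
      for (i in seq_len(np)) for (j in seq_len(nt)) {
        if (used_p[i] || used_t[j] || dmat[i, j] >= R) next
        if (is.null(best) || dmat[i, j] < best$d ||
            (dmat[i, j] == best$d && (i < best$i || (i == best$i && j < best$j))))
          best <- list(i = i, j = j, d = dmat[i, j])
      }
      if (is.null(best)) break
      used_p[best$i] <- TRUE; used_t[best$j] <- TRUE
      pairs <- rbind(pairs, c(best$i, best$j))
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  list(pairs = pairs, tp = tp, fp = np - tp, fn = nt - tp)
}

# --- shared fixtures --------------------------------------------------------
random_annotation_set <- function(n, width = 128, height = 128, seed = 1,
                                  image_id = "rand") {
  withr::with_seed(seed, {
    annotation_set(
      data.frame(x = sample(0:(width - 1), n, replace = TRUE),
                 y = sample(0:(height - 1), n, replace = TRUE),
                 class = sample(0:2, n, replace = TRUE)),
      image_id, width, height)
  })
}

# connectivity check used by watershed partition properties
is_connected_region <- function(lab, id, connectivity = 8) {
  px <- which(lab == id, arr.ind = TRUE)
  if (nrow(px) <= 1) return(TRUE)
  visited <- rep(FALSE, nrow(px))
  visited[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    dr <- abs(px[, 1] - px[i, 1]); dc <- abs(px[, 2] - px[i, 2])
    adj <- if (connectivity == 8) dr <= 1 & dc <= 1 & (dr + dc > 0)
           else dr + dc == 1
    new <- which(adj & !visited)
    visited[new] <- TRUE
    queue <- c(queue, new)
  }
  all(visited)
}
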