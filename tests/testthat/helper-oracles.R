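# Exhaustive flood-fill labeling of a logical (T, H, W) array, written
# independently of the package's labeling path: dense scan over the whole
# array, depth-first fill over coordinate triples.
flood_fill_labels <- function(mask, connectivity = 26) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  off <- as.matrix(expand.grid(dt = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  n_off <- nrow(off)
  nxt <- 0L
  for (x0 in seq_len(d[3])) for (y0 in seq_len(d[2])) for (t0 in seq_len(d[1])) {
    if (!mask[t0, y0, x0] || labels[t0, y0, x0] != 0L) next
    nxt <- nxt + 1L
    stack <- matrix(0L, nrow = sum(mask), ncol = 3)
    stack[1, ] <- c(t0, y0, x0)
    top <- 1L
    labels[t0, y0, x0] <- nxt
    while (top > 0L) {
      cur <- stack[top, ]; top <- top - 1L
      for (k in seq_len(n_off)) {
        p1 <- cur[1] + off[k, 1]; p2 <- cur[2] + off[k, 2]; p3 <- cur[3] + off[k, 3]
        if (p1 < 1L || p2 < 1L || p3 < 1L || p1 > d[1] || p2 > d[2] || p3 > d[3]) next
        if (mask[p1, p2, p3] && labels[p1, p2, p3] == 0L) {
          labels[p1, p2, p3] <- nxt
          top <- top + 1L
          stack[top, ] <- c(p1, p2, p3)
        }
      }
    }
  }
  labels
}

# voxel sets (sorted linear indices) per component from a label array
label_voxel_sets <- function(labels) {
  idx <- which(labels > 0)
  unname(lapply(split(idx, labels[idx]), sort))
}

# voxel sets from an event_catalog
catalog_voxel_sets <- function(catalog) {
  d <- catalog$dims
  unname(lapply(catalog$events, function(ev) {
    sort(ev$voxels[, "t"] + d[1] * (ev$voxels[, "y"] - 1L) +
           d[1] * d[2] * (ev$voxels[, "x"] - 1L))
  }))
}

# set equality between two lists of voxel sets, order-free
same_voxel_sets <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  key <- function(s) paste(s, collapse = ",")
  setequal(vapply(a, key, character(1)), vapply(b, key, character(1)))
}

# wrap a dff array in a minimal dff_movie-like object
as_dff <- function(arr, frame_rate_hz = 20, pixel_size_um = 7.68) {
  structure(list(dff = arr, baseline_window_frames = NA_integer_,
                 frame_rate_hz = frame_rate_hz, pixel_size_um = pixel_size_um),
            class = "dff_movie")
}

# small random logical stack with tunable density
random_stack <- function(d = c(12, 12, 12), p = 0.2) {
  array(runif(prod(d)) < p, dim = d)
}
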