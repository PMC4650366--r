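# Brute-force flood-fill component labelling: the independent oracle for
# everything segmentation-shaped. Deliberately naive (pixel queue, explicit
# neighbour list); only for small test images.
flood_label <- function(fg, connectivity = 8L) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8L)
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  cur <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!fg[rr, cc] || lab[rr, cc] > 0L) next
    cur <- cur + 1L
    queue <- list(c(rr, cc))
    lab[rr, cc] <- cur
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (k in seq_len(nrow(nb))) {
        q <- p + nb[k, ]
        if (q[1L] >= 1L && q[1L] <= nr && q[2L] >= 1L && q[2L] <= nc &&
            fg[q[1L], q[2L]] && lab[q[1L], q[2L]] == 0L) {
          lab[q[1L], q[2L]] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# geometry covering an entire small square image (radius = half-diagonal)
full_geometry <- function(n, rim_fraction = 0.05) {
  ctr <- (n + 1) / 2
  PlateGeometry(c(ctr, ctr), sqrt(2) * n, rim_fraction)
}

# a frame that is uniform background except for explicitly set dark pixels
dark_pixels <- function(n, px, depth = 0.5, bg = 0.9) {
  img <- matrix(bg, n, n)
  for (k in seq_len(nrow(px))) img[px[k, 1L], px[k, 2L]] <- bg - depth
  img
}

# brute-force steady-level oracle: evaluate every window directly from the
# printed criteria (floating-point form, independent of the scan under test)
steady_oracle <- function(cnt, times) {
  for (i in seq_len(length(cnt) - 2L)) {
    c0 <- cnt[i]; c1 <- cnt[i + 1L]; c2 <- cnt[i + 2L]
    if (c0 < 1) next
    ok <- if (c0 > 100) abs(c1 - c0) <= c0 / 100 && abs(c2 - c1) <= c1 / 100
          else abs(c1 - c0) <= 1 && abs(c2 - c1) <= 1
    if (ok) return(list(found = TRUE, i = i, n_stdy = c2, t = times[i + 2L]))
  }
  list(found = FALSE, i = NA_integer_, n_stdy = NA_integer_, t = NA_real_)
}

# exhaustive minimum-total-distance assignment of detections to tracks:
# enumerate every injective map detection -> track-or-NA within the gate,
# prefer more links, then lower total distance (<= 4 objects)
exhaustive_assignment <- function(track_pos, det_pos, gate) {
  nt <- nrow(track_pos); nd <- nrow(det_pos)
  d <- sqrt(outer(track_pos[, 1L], det_pos[, 1L], "-")^2 +
            outer(track_pos[, 2L], det_pos[, 2L], "-")^2)
  best <- rep(NA_integer_, nd); best_n <- -1L; best_cost <- Inf
  recurse <- function(di, asg, used, cost) {
    if (di > nd) {
      n_linked <- sum(!is.na(asg))
      if (n_linked > best_n ||
          (n_linked == best_n && cost < best_cost)) {
        best <<- asg; best_n <<- n_linked; best_cost <<- cost
      }
      return(invisible())
    }
    recurse(di + 1L, asg, used, cost)  # leave detection unassigned
    for (ti in seq_len(nt)) {
      if (!used[ti] && d[ti, di] <= gate) {
        asg[di] <- ti; used[ti] <- TRUE
        recurse(di + 1L, asg, used, cost + d[ti, di])
        asg[di] <- NA_integer_; used[ti] <- FALSE
      }
    }
  }
  recurse(1L, rep(NA_integer_, nd), rep(FALSE, nt), 0)
  best
}

# standard small simulation used across tests (fast, noise-free)
quick_config <- function(...) {
  defaults <- list(sensor_px = 512L, n_viable = 8L, n_debris = 5L,
                   n_frames = 16L, r_max_um = 800, noise_sd = 0,
                   lag_mean_h = 5, lag_sd_h = 1.5,
                   growth_rate_um_per_h_mean = 60,
                   growth_rate_um_per_h_sd = 10, rng_seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(SimulationConfig, args)
}
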