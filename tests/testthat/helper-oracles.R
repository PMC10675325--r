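# Independent oracles and small scene builders shared across the suite.

# Brute-force pixel-in-circle count under the shared rasterization rule:
# a pixel (row i, col j) belongs to the disc iff its center, the integer
# point (j, i), lies inside the closed circle. Deliberately a double loop,
# independent of the renderer's vectorized geometry.
oracle_circle_count <- function(nr, nc, cx, cy, r) {
  n <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if ((j - cx)^2 + (i - cy)^2 <= r^2) n <- n + 1L
    }
  }
  n
}

# Reference 8-connected labeling: explicit stack-based flood fill in pure R,
# scanning in raster order so labels follow first encounter.
oracle_flood_fill <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (i0 in seq_len(nr)) {
    for (j0 in seq_len(nc)) {
      if (mask[i0, j0] == 0 || lab[i0, j0] != 0) next
      nxt <- nxt + 1L
      stack <- matrix(c(i0, j0), ncol = 2)
      lab[i0, j0] <- nxt
      while (nrow(stack) > 0) {
        i <- stack[nrow(stack), 1]
        j <- stack[nrow(stack), 2]
        stack <- stack[-nrow(stack), , drop = FALSE]
        for (di in -1:1) {
          for (dj in -1:1) {
            qi <- i + di
            qj <- j + dj
            if (qi >= 1 && qi <= nr && qj >= 1 && qj <= nc &&
                mask[qi, qj] != 0 && lab[qi, qj] == 0) {
              lab[qi, qj] <- nxt
              stack <- rbind(stack, c(qi, qj))
            }
          }
        }
      }
    }
  }
  lab
}

random_mask <- function(nr, nc, p = 0.4) {
  matrix(stats::rbinom(nr * nc, 1L, p), nr, nc)
}

# One disc of radius r_px centered on a pixel inside a single well,
# rendered from a real simulator truth (enzyme 0, so the radius is static).
render_single_disc <- function(r_px, px_per_mm = 10, well_r_px = 110,
                               noise_sd = 0, debris_rate = 0, seed = 1) {
  disc <- disc_spec(radius0 = r_px / px_per_mm)
  truth <- simulate_kinetics(list(well_condition("A", 0)), disc,
                             duration = 1, step = 1, seed = seed)
  layout <- well_layout(data.frame(well_id = "A",
                                   cx_px = well_r_px + 5,
                                   cy_px = well_r_px + 5,
                                   r_px = well_r_px))
  cfg <- render_config(px_per_mm = px_per_mm, frame_interval = 60,
                       noise_sd = noise_sd, debris_rate = debris_rate,
                       seed = seed)
  out <- render_frames(truth, layout, cfg)
  list(truth = truth, layout = layout, cfg = cfg,
       frames = out$frames, manifest = out$manifest,
       center = c(x = well_r_px + 5, y = well_r_px + 5))
}

# Random RGB frame for pixelwise-property tests.
random_frame <- function(nr = 12, nc = 17, seed = 1) {
  withr::with_seed(seed, {
    frame_image(array(sample(0:255, nr * nc * 3, replace = TRUE),
                      dim = c(nr, nc, 3L)))
  })
}

# Exact standards on a known line.
exact_standards <- function(slope = 0.002, intercept = 0.10,
                            conc = c(0, 10, 25, 50, 100)) {
  data.frame(conc_ug_ml = conc, absorbance = slope * conc + intercept)
}
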