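# Shared fixtures, built in code. Phantoms are cached per parameter set so
# repeated tests do not re-rasterize them.

.phantom_cache <- new.env(parent = emptyenv())

test_phantom <- function(pitch = 0.3, noise_sd = 0, seed = 1L,
                         cis = 0.8, trans = 1.2,
                         cis_density = 700, trans_density = 650) {
  key <- paste(pitch, noise_sd, seed, cis, trans, cis_density, trans_density,
               sep = "_")
  if (!is.null(.phantom_cache[[key]])) return(.phantom_cache[[key]])
  comps <- list()
  if (cis > 0) comps <- c(comps, list(callus_compartment("cis", cis,
                                                         cis_density)))
  if (trans > 0) comps <- c(comps, list(callus_compartment("trans", trans,
                                                           trans_density)))
  spec <- phantom_spec(voxel_pitch = pitch, noise_sd = noise_sd, seed = seed,
                       callus_compartments = comps)
  ph <- generate_phantom(spec)
  .phantom_cache[[key]] <- ph
  ph
}

truth_callus_count <- function(ph) sum(ph$truth$labels %in% c(3L, 4L))

# A small calibrated volume holding an axis-aligned hollow cylinder
# (cortex density), optionally tilted by a rotation about the y axis.
cylinder_volume <- function(n_xy = 40, n_z = 60, pitch = 0.4,
                            outer_r = 5, inner_r = 3, tilt_deg = 0,
                            density = 1200) {
  xs <- (seq_len(n_xy) - 0.5) * pitch - n_xy * pitch / 2
  zs <- (seq_len(n_z) - 0.5) * pitch - n_z * pitch / 2
  vals <- array(0, c(n_xy, n_xy, n_z))
  th <- tilt_deg * pi / 180
  for (k in seq_len(n_z)) {
    # rotate coordinates about y: radial distance from the tilted axis
    xk <- outer(xs * cos(th) - zs[k] * sin(th), rep(1, n_xy))
    yk <- outer(rep(1, n_xy), xs)
    r2 <- xk^2 + yk^2
    sl <- vals[, , k]
    sl[r2 <= outer_r^2 & r2 > inner_r^2] <- density
    vals[, , k] <- sl
  }
  calibrated_volume(vals, pitch)
}
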