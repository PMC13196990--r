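# Shared fixtures. Everything is generated in code; sizes are desk-scale
# (tens of sensors, 10 um segments) so the full suite stays fast.

# straight chain of segments along +x carrying a constant axial current,
# used as a wire stand-in for field oracles
wire_currents <- function(length_um, n_seg, I_nA = 1) {
  brk <- seq(-length_um / 2, length_um / 2, length.out = n_seg + 1L)
  neuromag:::new_compartment_currents(
    starts = cbind(brk[-(n_seg + 1L)], 0, 0),
    ends = cbind(brk[-1L], 0, 0),
    radii = rep(1, n_seg),
    I_a = matrix(I_nA, n_seg, 1),
    I_m = matrix(0, n_seg, 1),
    dt = NA_real_, t = 0, check = FALSE
  )
}

# point transmembrane sources at given positions (one time step)
point_sources <- function(positions, I_m) {
  positions <- as.matrix(positions)
  neuromag:::new_compartment_currents(
    starts = positions, ends = positions,
    radii = rep(1, nrow(positions)),
    I_a = matrix(0, nrow(positions), 1),
    I_m = matrix(I_m, ncol = 1),
    dt = NA_real_, t = 0, check = FALSE
  )
}

# small template on a grid with prescribed values
grid_template <- function(values, nx, ny, pitch = 10, signal_type = "phi",
                          dt = 0.03125) {
  sens <- make_sensor_grid(nx, ny, pitch)
  neuromag:::new_spike_template(values, sens, dt, signal_type)
}

# canonical reconstruction fixture: tapered straight axon with a hillock
recon_ball_stick <- function() {
  make_ball_stick(axon_length = 600, segment_length = 10, taper_ratio = 3,
                  hillock_factor = 2.5)
}

# opposing-dendrite fixture exercising the CNBE near-soma correction
recon_branched <- function(seed) {
  make_branched_cell(trunk_length = 600, n_minor_branches = 2,
                     branch_length = 200, seed = seed,
                     branch_diameter = 1.5)
}
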