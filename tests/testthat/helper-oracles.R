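# Shared oracles and builders for the test suite.

# VSE parameters derived independently from two (field, frequency) pairs by
# solving the 2x2 linear system nu = nu0 + dmu * F.
derived_vse <- local({
  A <- rbind(c(1, -78), c(1, -64.9))
  sol <- solve(A, c(2215.5, 2219.1))
  vse_params(nu0 = sol[1], dmu = sol[2])
})

canonical_blue <- blueshift_params()

# Geometry whose bound-state blueshift is ~26 cm^-1 (head-on, near 3 A),
# used by the two-state narrowing constructions.
narrow_geom <- list(d = 3.002, theta = 175)

# Strict two-state trajectory: constant field, fixed bound geometry.
two_state_traj <- function(tau_ps, n_frames, seed, dt_fs = 20,
                           d = narrow_geom$d, theta = narrow_geom$theta,
                           field = -64.9) {
  spec <- dynamics_spec(mean_residence_hb = tau_ps,
                        mean_residence_free = tau_ps,
                        hb_d_mean = d, hb_d_sd = 0,
                        hb_theta_mean = theta, hb_theta_sd = 0,
                        field_mean = field, field_sd = 0,
                        dt_fs = dt_fs, n_frames = n_frames, seed = seed)
  map_trajectory(simulate_hb_trajectory(spec))
}
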