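# Small analytic field builders shared across test files.

# isotropic test grid
isoGrid <- function(n = 16L, h = 2, nFrames = 1L)
  FlowGrid(rep(n, 3), spacing = rep(h, 3), nFrames = nFrames)

# velocity array from a function of physical position (mm) -> m/s
fieldFromFun <- function(grid, fun) {
  xs <- grid@origin[1] + (seq_len(grid@shape[1]) - 1) * grid@spacing[1]
  ys <- grid@origin[2] + (seq_len(grid@shape[2]) - 1) * grid@spacing[2]
  zs <- grid@origin[3] + (seq_len(grid@shape[3]) - 1) * grid@spacing[3]
  P <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  v <- fun(P)
  array(v, c(grid@shape, 3L))
}

# rigid rotation about the z axis through the grid center, omega in rad/s;
# positions are converted to metres so velocities are m/s
rigidRotation <- function(grid, omega = 1) {
  ctr <- grid@origin + (grid@shape - 1) * grid@spacing / 2
  fieldFromFun(grid, function(P) {
    Pm <- sweep(P, 2, ctr, "-") / 1000
    cbind(-omega * Pm[, 2], omega * Pm[, 1], 0)
  })
}

# a small analytic vortex ring centred in an isotropic grid, plus its spec
ringFixture <- function(n = 32L, h = 2, R = 10, a = 3, gamma = 0.008,
                        nFrames = 1L, amplitude = 1) {
  grid <- isoGrid(n, h, nFrames)
  ctr <- grid@origin + (grid@shape - 1) * grid@spacing / 2
  spec <- RingSpec(center = ctr, normal = c(0, 0, 1), radius = R,
                   coreRadius = a, circulation = gamma,
                   amplitudeCurve = rep(amplitude, nFrames))
  list(grid = grid, spec = spec,
       field = ringVelocityField(spec, grid, frame = 1L))
}

# confusion counts from two logical vectors, as a 2x2 matrix for cohenKappa
presenceMatrix <- function(auto, ref) {
  rbind(c(sum(!auto & !ref), sum(!auto & ref)),
        c(sum(auto & !ref), sum(auto & ref)))
}
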