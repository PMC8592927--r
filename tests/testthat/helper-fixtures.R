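# in-code fixtures shared across test files

# a bare topology of n dummy carbon-like atoms with explicit vdW radii
dummyTopology <- function(n, vdw = 1.7, chain = "A") {
  channelTopology(name = rep("C", n), resname = rep("DUM", n),
                  resno = seq_len(n), chain = rep_len(chain, n),
                  element = rep("C", n), vdw = vdw)
}

# dense ring of nAtoms sphere centres at the given radius and height
ringCoords <- function(nAtoms, radius, z, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(nAtoms) - 1) / nAtoms
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th), z)
}

zAxis <- function(center = c(0, 0, 0)) {
  new("PoreAxis", center = center, direction = c(0, 0, 1))
}

# random atom cloud in a cylindrical shell (keeps a pore-like cavity)
randomConfig <- function(nAtoms, seed, rMin = 2.5, rMax = 7, zHalf = 3,
                         vdwChoices = c(1.5, 1.7, 2.0)) {
  set.seed(seed)
  r <- runif(nAtoms, rMin, rMax)
  th <- runif(nAtoms, 0, 2 * pi)
  co <- cbind(r * cos(th), r * sin(th), runif(nAtoms, -zHalf, zHalf))
  vdw <- sample(vdwChoices, nAtoms, replace = TRUE)
  list(topology = dummyTopology(nAtoms, vdw = vdw), coords = co)
}

# proper rotation matrix + translation
randomRigid <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 5))
}

applyRigid <- function(coords, rigid) {
  sweep(coords %*% t(rigid$R), 2, -rigid$t)
}

# rotation about the z axis by deg degrees plus xy translation
rotateAboutZ <- function(coords, deg, shift = c(0, 0, 0)) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  sweep(coords %*% t(R), 2, -shift)
}

# tiny noise-free synthetic spec used across files
quietSpec <- function(nFrames, ...) {
  syntheticChannelSpec(nFrames, noiseSigma = 0, ...)
}

proteinOnly <- "not resname TIP3 TIP3P SOL WAT HOH SOD NA CLA CL"
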