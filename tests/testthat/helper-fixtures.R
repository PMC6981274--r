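# Shared fixtures, all built in code.

# Analytic scattering curve of a uniform sphere of radius R (form factor
# squared), the classic closed-form oracle.
sphere_profile <- function(R = 50, q = seq(0.004, 0.3, length.out = 280),
                           i0 = 1, rel_sigma = 0.01, noise_seed = NULL) {
  u <- q * R
  I <- i0 * (3 * (sin(u) - u * cos(u)) / u^3)^2
  sig <- pmax(I * rel_sigma, 1e-14)
  if (!is.null(noise_seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(noise_seed)
    I <- I + rnorm(length(q), 0, sig)
  }
  saxs_profile(q, I, sigma = sig, label = "sphere")
}

# Synthetic C-alpha-only protein chain: a regular alpha-helix (2.3 A
# radius, 1.5 A rise, 100 degrees per residue), residue types cycled,
# with optional residue gaps (disordered stretches) and per-domain
# B-factors.
helix_model <- function(n = 60, chain = "A", start_res = 1, gaps = integer(0),
                        b = 20) {
  resno <- setdiff(start_res + seq_len(n) - 1L, gaps)
  i <- resno - start_res
  aa <- c("ALA", "GLY", "LEU", "SER", "LYS", "GLU", "VAL", "THR", "PHE", "ASP")
  atoms <- data.frame(
    chain = chain, resno = resno, resid = aa[(resno %% 10) + 1],
    atom = "CA", elem = "C",
    x = 2.3 * cos(i * 100 * pi / 180),
    y = 2.3 * sin(i * 100 * pi / 180),
    z = 1.5 * i,
    b = if (length(b) == 1) rep(b, length(resno)) else b)
  atom_model(atoms, source = "synthetic helix")
}

# Non-periodic smooth 3D chain for correspondence tests: unlike an ideal
# helix it has no internal translational symmetry, so residue matchings
# are unambiguous.
curve_chain <- function(n = 80, drop = integer(0)) {
  keep <- setdiff(seq_len(n), drop)
  t <- keep * 0.35
  out <- cbind(30 * cos(t) + 10 * cos(2.3 * t),
               30 * sin(t) + 10 * sin(1.7 * t),
               6 * t)
  attr(out, "resno") <- keep
  out
}

rotation_about_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# Uniform random points in a sphere (for MC pair-distance oracles).
runif_sphere <- function(n, R, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  v * R * runif(n)^(1 / 3)
}

toy_q_grid <- function(n = 120) seq(0.008, 0.12, length.out = n)
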