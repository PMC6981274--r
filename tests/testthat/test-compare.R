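random_cloud <- function(n, seed, sd = 10) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = sd), ncol = 3)
}

test_that("kabsch recovers exact rigid motions", {
  P <- random_cloud(50, 1)
  sp0 <- kabsch(P, P)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-9)

  R <- rotation_about_z(63) %*%
    matrix(c(1, 0, 0, 0, cos(0.4), -sin(0.4), 0, sin(0.4), cos(0.4)), 3, 3,
           byrow = TRUE)
  t0 <- c(4, -7, 2)
  Q <- P %*% t(solve(R)) - matrix(as.numeric(solve(R) %*% t0), 50, 3,
                                  byrow = TRUE)
  sp <- kabsch(P, Q)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(apply_superposition(sp, Q), P, tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch RMSD under isotropic noise matches expectation and bio3d", {
  P <- random_cloud(200, 2, sd = 15)
  set.seed(3)
  Q <- P + matrix(rnorm(600, sd = 0.5), ncol = 3)
  sp <- kabsch(P, Q)
  expect_equal(sp$rmsd, 0.5 * sqrt(3), tolerance = 0.10)

  # independent cross-check: bio3d's least-squares fit gives the same RMSD
  xyz_p <- as.vector(t(P)); xyz_q <- as.vector(t(Q))
  rmsd_bio3d <- bio3d::rmsd(xyz_p, xyz_q, fit = TRUE)
  expect_equal(sp$rmsd, rmsd_bio3d, tolerance = 1e-3)
})

test_that("kabsch rejects degenerate input and RMSD is pre-rotation invariant", {
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(kabsch(line, line), "degenerate")

  P <- random_cloud(40, 4)
  set.seed(5)
  Q <- P + matrix(rnorm(120, sd = 0.3), ncol = 3)
  r1 <- kabsch(P, Q)$rmsd
  R <- rotation_about_z(119)
  r2 <- kabsch(P %*% t(R), Q %*% t(R))$rmsd
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("align_domains matches identical and rotated-deleted copies", {
  A <- curve_chain(80)
  spA <- align_domains(A, A)
  expect_equal(spA$n_matched, 80)
  expect_equal(spA$rmsd, 0, tolerance = 1e-9)
  expect_equal(spA$correspondence$a, spA$correspondence$b)

  # rotated copy with 10 residues deleted: all surviving residues match
  B <- curve_chain(80, drop = 31:40)
  R <- rotation_about_z(75)
  Brot <- B %*% t(R) + matrix(c(10, 5, -8), nrow(B), 3, byrow = TRUE)
  attr(Brot, "resno") <- attr(B, "resno")
  sp <- align_domains(A, Brot)
  expect_equal(sp$n_matched, 70)
  expect_lt(sp$rmsd, 0.01)
  expect_error(align_domains(A[1:10, ], A[1:10, ]), "at least 20")
})

test_that("ligand transplantation moves atoms by the transform and back", {
  acceptor <- helix_model(n = 30)
  lig <- atom_model(data.frame(
    chain = "L", resno = 1, resid = "LIG",
    atom = c("C1", "C2", "C3", "O1"), elem = c("C", "C", "C", "O"),
    x = c(5, 6, 7, 8), y = c(0, 1, 0, 1), z = c(20, 21, 22, 23), b = 30),
    source = "ligand")

  ident <- kabsch(random_cloud(10, 7), random_cloud(10, 7))
  placed <- transplant_ligand(acceptor, lig, ident)
  lig_rows <- placed$chain == "Z"
  expect_equal(as.matrix(placed[lig_rows, c("x", "y", "z")]),
               as.matrix(lig[, c("x", "y", "z")]), tolerance = 1e-9,
               ignore_attr = TRUE)

  # min heavy-atom contact equals a brute-force minimum
  d_brute <- min(pracma::distmat(as.matrix(acceptor[, c("x", "y", "z")]),
                                 as.matrix(lig[, c("x", "y", "z")])))
  expect_equal(attr(placed, "min_contact"), d_brute, tolerance = 1e-9)

  # transform then inverse-transform restores coordinates
  P <- random_cloud(30, 8); Q <- random_cloud(30, 9)
  sp <- kabsch(P, Q)
  inv <- kabsch(Q, P)
  xyz <- as.matrix(lig[, c("x", "y", "z")])
  expect_equal(apply_superposition(inv, apply_superposition(sp, xyz)),
               xyz, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(transplant_ligand(acceptor, lig[0, ], ident), "empty")
})

test_that("per-domain B-factor summaries match brute-force statistics", {
  d <- domain_decomposition(
    groups = list(core = data.frame(chain = "A", start = 1, end = 30),
                  mobile = data.frame(chain = "A", start = 31, end = 60)))
  m <- helix_model(n = 60, b = c(rep(20, 30), rep(40, 30)))
  s <- domain_bfactor_summary(m, d)
  expect_equal(s$mean, c(20, 40))
  expect_equal(s$sd, c(0, 0))
  expect_gt(s$mean[s$group == "mobile"], s$mean[s$group == "core"])

  # brute-force recomputation over raw records
  expect_equal(s$mean[1], mean(m$b[m$resno <= 30]))
  expect_equal(s$median[2], median(m$b[m$resno > 30]))

  d_bad <- domain_decomposition(
    groups = list(none = data.frame(chain = "B", start = 1, end = 5)))
  expect_error(domain_bfactor_summary(m, d_bad), "no atoms")
})
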