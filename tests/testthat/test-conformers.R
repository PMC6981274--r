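test_that("default decomposition has three rigid groups and a free hinge loop", {
  d <- default_decomposition()
  expect_named(d$groups, c("CARF-dimer", "nuclease-like", "nuclease"))
  expect_equal(nrow(d$groups[["CARF-dimer"]]), 2)  # union of two CARF domains

  # resolve against a model covering 3-638: hinge residues 423-428 end up
  # in no rigid group, and no residue is covered twice
  m <- helix_model(n = 636, start_res = 3)
  beads <- coarse_grain(m)
  res <- saxsens:::resolve_decomposition(d, beads)
  all_idx <- unlist(res$groups)
  expect_equal(anyDuplicated(all_idx), 0L)
  resno_in_groups <- as.integer(sub(".* (\\d+) .*", "\\1",
                                    beads$labels[all_idx]))
  expect_false(any(423:428 %in% resno_in_groups))
  # tethers join the residues flanking each linker
  expect_true(all(c(422, 429) %in%
    as.integer(sub(".* (\\d+) .*", "\\1",
                   beads$labels[unlist(res$tethers[c("i", "j")])]))))
})

test_that("restraint windows are pi/q_max around ground distances, capped at dmax", {
  toy <- make_two_state_toy(seed = 1)
  rs <- build_restraints(toy$decomposition, toy$closed, dmax = 120,
                         q_max = 0.25, mode = "unconstrained")
  half <- pi / 0.25
  expect_equal(rs$pairs$upper - rs$pairs$d0,
               pmin(rep(half, nrow(rs$pairs)), 120 - rs$pairs$d0),
               tolerance = 1e-9)
  expect_equal(rs$pairs$d0 - rs$pairs$lower,
               pmin(rep(half, nrow(rs$pairs)), rs$pairs$d0),
               tolerance = 1e-9)
  # ground state satisfies its own restraints; upper bounds never exceed dmax
  expect_true(all(rs$pairs$d0 >= rs$pairs$lower & rs$pairs$d0 <= rs$pairs$upper))
  expect_true(all(rs$pairs$upper <= 120))

  # window modes add displacement anchors; dmax smaller than a ground
  # distance is inconsistent
  rs5 <- build_restraints(toy$decomposition, toy$closed, dmax = 120,
                          q_max = 0.25, mode = "window:5")
  expect_equal(rs5$anchors$max_disp, c(5, 5))
  expect_error(build_restraints(toy$decomposition, toy$closed, dmax = 50,
                                q_max = 0.25), "exceeds dmax")
})

test_that("null moves reproduce the ground state; n = 0 gives an empty ensemble", {
  toy <- make_two_state_toy(n_domains = 2, beads_per_domain = 40, seed = 2)
  rs <- build_restraints(toy$decomposition, toy$closed, dmax = 100,
                         q_max = 0.25, mode = "unconstrained")
  expect_length(sample_conformations(toy$closed, toy$decomposition, rs,
                                     n = 0, seed = 1), 0)
  ens <- sample_conformations(toy$closed, toy$decomposition, rs, n = 5,
                              seed = 1, max_rot = 0, max_trans = 0)
  for (cf in ens)
    expect_equal(cf$positions, toy$closed$positions, tolerance = 1e-12)
})

test_that("sampling is reproducible and transforms reconstruct coordinates", {
  toy <- make_two_state_toy(n_domains = 3, beads_per_domain = 50, seed = 3)
  rs <- build_restraints(toy$decomposition, toy$closed, dmax = 120,
                         q_max = 0.2, mode = "unconstrained")
  e1 <- sample_conformations(toy$closed, toy$decomposition, rs, n = 10,
                             seed = 7, stride = 5)
  e2 <- sample_conformations(toy$closed, toy$decomposition, rs, n = 10,
                             seed = 7, stride = 5)
  expect_identical(lapply(e1, `[[`, "positions"),
                   lapply(e2, `[[`, "positions"))

  groups <- attr(e1, "groups")
  cf <- e1[[10]]
  for (g in names(groups)) {
    idx <- groups[[g]]
    tr <- cf$transforms[[g]]
    rebuilt <- toy$closed$positions[idx, ] %*% t(tr$R) +
      matrix(tr$t, length(idx), 3, byrow = TRUE)
    expect_equal(rebuilt, cf$positions[idx, ], tolerance = 1e-9)
    expect_equal(det(tr$R), 1, tolerance = 1e-9)
  }
})

test_that("every emitted conformation passes an independent constraint check", {
  toy <- make_two_state_toy(seed = 4)
  rs <- build_restraints(toy$decomposition, toy$closed, dmax = 115,
                         q_max = 0.12, mode = "unconstrained")
  ens <- sample_conformations(toy$closed, toy$decomposition, rs, n = 50,
                              seed = 11)
  groups <- attr(ens, "groups")
  tet <- attr(ens, "tethers")
  f <- attr(ens, "f")
  # brute-force verifier, written independently of the sampler internals
  for (cf in ens) {
    pos <- cf$positions
    coms <- lapply(groups, function(idx)
      colSums(pos[idx, , drop = FALSE] * (f[idx] / sum(f[idx]))))
    for (r in seq_len(nrow(rs$pairs))) {
      d <- sqrt(sum((coms[[rs$pairs$a[r]]] - coms[[rs$pairs$b[r]]])^2))
      expect_gte(d, rs$pairs$lower[r] - 1e-6)
      expect_lte(d, rs$pairs$upper[r] + 1e-6)
    }
    for (r in seq_len(nrow(tet))) {
      gap <- sqrt(sum((pos[tet$i[r], ] - pos[tet$j[r], ])^2))
      expect_lte(gap, 3.8 * (tet$len[r] + 1) + 1e-6)
    }
    # inter-group clashes: never tighter than the ground state's own contacts
    gn <- names(groups)
    for (a in seq_along(gn)) for (b in seq_len(a - 1)) {
      dmin_ground <- min(as.matrix(
        pracma::distmat(toy$closed$positions[groups[[a]], ],
                        toy$closed$positions[groups[[b]], ])))
      dmin <- min(as.matrix(pracma::distmat(pos[groups[[a]], ],
                                            pos[groups[[b]], ])))
      expect_gte(dmin, min(3.0, dmin_ground * 0.999) - 1e-6)
    }
  }
  # the fixed group never moves
  fixed_idx <- groups[[attr(ens, "fixed")]]
  for (cf in ens)
    expect_equal(cf$positions[fixed_idx, ], toy$closed$positions[fixed_idx, ],
                 tolerance = 1e-12)
})

test_that("anchor windows bound domain excursions; unconstrained mode explores", {
  toy <- make_two_state_toy(seed = 5)
  rs5 <- build_restraints(toy$decomposition, toy$closed, dmax = 115,
                          q_max = 0.12, mode = "window:5")
  e5 <- sample_conformations(toy$closed, toy$decomposition, rs5, n = 40,
                             seed = 13)
  disp5 <- t(vapply(e5, `[[`, numeric(3), "com_displacement"))
  expect_true(all(disp5[, c("domain2", "domain3")] <= 5 + 1e-6))

  rs0 <- build_restraints(toy$decomposition, toy$closed, dmax = 115,
                          q_max = 0.12, mode = "unconstrained")
  e0 <- sample_conformations(toy$closed, toy$decomposition, rs0, n = 40,
                             seed = 13)
  disp0 <- t(vapply(e0, `[[`, numeric(3), "com_displacement"))
  expect_gt(max(disp0[, "domain3"]), 5)
})
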