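#' Domain decomposition into rigid groups and linkers
#'
#' Describes which residues move together during rigid-body sampling.
#' `groups` is a named list of residue-range tables (see [as_ranges]); a
#' residue interval may appear split across entries so a group can be a
#' union of discontinuous segments (e.g. a dimer of two domains kept as one
#' rigid unit). `linkers` are intervals treated as unconstrained tethers:
#' they belong to no rigid group (linker residues are stripped from any
#' group that nominally covers them) and only constrain how far the flanking
#' residues may separate.
#'
#' @param groups named list; each element coerced by [as_ranges].
#' @param linkers residue ranges coerced by [as_ranges], or `NULL`.
#' @return An object of class `domain_decomposition`.
#' @export
domain_decomposition <- function(groups, linkers = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)), all(nzchar(names(groups))))
  groups <- lapply(groups, as_ranges)
  linkers <- if (!is.null(linkers)) as_ranges(linkers)
  structure(list(groups = groups, linkers = linkers),
            class = "domain_decomposition")
}

#' Default decomposition for a two-CARF effector nuclease
#'
#' The experimentally motivated decomposition for Can1-like architectures:
#' the two CARF domains (residues 3-151 and 293-422) form one rigid unit
#' because their mutual arrangement is conserved; domain 2, the
#' nuclease-like domain (168-276), and the nuclease domain (426-638) are
#' separate rigid bodies. Inter-domain loops (152-167, 277-292 and the
#' hinge loop 423-428) are unconstrained tethers.
#'
#' @param chain chain identifier (default "A").
#' @return A [domain_decomposition] with three rigid groups.
#' @export
default_decomposition <- function(chain = "A") {
  rngs <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(chain = chain, start = m[, 1], end = m[, 2])
  }
  domain_decomposition(
    groups = list(
      "CARF-dimer"    = rngs(3, 151, 293, 422),
      "nuclease-like" = rngs(168, 276),
      "nuclease"      = rngs(426, 638)),
    linkers = rngs(152, 167, 277, 292, 423, 428))
}

#' @export
print.domain_decomposition <- function(x, ...) {
  cat(sprintf("Domain decomposition: %d rigid group(s)\n", length(x$groups)))
  for (nm in names(x$groups)) {
    rg <- x$groups[[nm]]
    cat(sprintf("  %-14s %s\n", nm,
                paste(sprintf("%s:%d-%d", rg$chain, rg$start, rg$end),
                      collapse = ", ")))
  }
  if (!is.null(x$linkers))
    cat(sprintf("  linkers        %s\n",
                paste(sprintf("%s:%d-%d", x$linkers$chain, x$linkers$start,
                              x$linkers$end), collapse = ", ")))
  invisible(x)
}

# Resolve a decomposition against a bead model into integer bead indices.
# Residue-based decompositions require beads carrying "chain resno resid"
# labels (as produced by coarse_grain). Linker residues are removed from
# rigid groups; each linker contributes one tether between the beads
# flanking it (when both flanks are modelled). Index-based decompositions
# (named list of integer vectors, `tethers` data frame with columns i, j,
# len) pass through unchanged.
resolve_decomposition <- function(decomp, beads) {
  if (!inherits(decomp, "domain_decomposition")) {
    stopifnot(is.list(decomp$groups))
    return(list(groups = decomp$groups,
                tethers = decomp$tethers))
  }
  lab <- strsplit(beads$labels, " ")
  key <- vapply(lab, function(v) paste(v[1], v[2]), "")
  in_linker <- rep(FALSE, length(key))
  lk <- decomp$linkers
  if (!is.null(lk)) {
    for (i in seq_len(nrow(lk)))
      in_linker <- in_linker |
        key %in% paste(lk$chain[i], lk$start[i]:lk$end[i])
  }
  groups <- lapply(decomp$groups, function(rg) {
    idx <- integer(0)
    for (i in seq_len(nrow(rg)))
      idx <- c(idx, which(key %in% paste(rg$chain[i], rg$start[i]:rg$end[i]) &
                            !in_linker))
    sort(unique(idx))
  })
  empty <- names(groups)[vapply(groups, length, 1L) == 0]
  if (length(empty))
    stop("rigid group(s) empty in this model: ", paste(empty, collapse = ", "))
  tethers <- NULL
  if (!is.null(lk)) {
    rows <- lapply(seq_len(nrow(lk)), function(i) {
      pre <- which(key == paste(lk$chain[i], lk$start[i] - 1L))
      post <- which(key == paste(lk$chain[i], lk$end[i] + 1L))
      if (length(pre) == 1 && length(post) == 1)
        data.frame(i = pre, j = post, len = lk$end[i] - lk$start[i] + 1L)
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) tethers <- do.call(rbind, rows)
  }
  list(groups = groups, tethers = tethers)
}

group_com <- function(positions, f, idx) {
  w <- f[idx] / sum(f[idx])
  colSums(positions[idx, , drop = FALSE] * w)
}

#' Build centre-of-mass distance restraints
#'
#' For every pair of rigid groups with ground-state centre-of-mass (COM)
#' separation d0, the restraint window is
#' `[max(0, d0 - pi/q_max), min(dmax, d0 + pi/q_max)]`: pi/q_max is the
#' nominal real-space resolution of the measurement, and no inter-domain
#' distance may exceed the particle's maximum dimension from the P(r)
#' analysis. The window modes additionally cap each mobile group's COM
#' displacement from its crystallographic position at 5 or 10 Angstrom,
#' encoded as anchor restraints to fixed points.
#'
#' @param decomp a [domain_decomposition] (or resolved index decomposition).
#' @param ground ground-state model: an `atom_model` or [bead_model].
#' @param dmax maximum particle dimension from the experimental P(r), A.
#' @param q_max highest measured momentum transfer, 1/A.
#' @param mode `"unconstrained"`, `"window:5"` or `"window:10"`.
#' @param fixed name of the group held fixed (no anchor needed); default
#'   the first group.
#' @return An object of class `restraint_set`: pair windows, anchors, and
#'   the provenance of every bound.
#' @export
build_restraints <- function(decomp, ground, dmax, q_max,
                             mode = c("unconstrained", "window:5", "window:10"),
                             fixed = NULL) {
  mode <- match.arg(mode)
  beads <- if (inherits(ground, "atom_model")) coarse_grain(ground) else ground
  stopifnot(inherits(beads, "bead_model"))
  res <- resolve_decomposition(decomp, beads)
  gn <- names(res$groups)
  if (is.null(fixed)) fixed <- gn[1]
  coms <- t(vapply(res$groups, function(idx)
    group_com(beads$positions, beads$f, idx), numeric(3)))
  half <- pi / q_max
  pairs <- utils::combn(gn, 2, simplify = FALSE)
  ptab <- do.call(rbind, lapply(pairs, function(pp) {
    d0 <- sqrt(sum((coms[pp[1], ] - coms[pp[2], ])^2))
    if (d0 > dmax)
      stop(sprintf("ground-state COM distance %s-%s (%.1f A) exceeds dmax (%.1f A)",
                   pp[1], pp[2], d0, dmax))
    data.frame(a = pp[1], b = pp[2], d0 = d0,
               lower = max(0, d0 - half), upper = min(dmax, d0 + half))
  }))
  anchors <- NULL
  if (mode != "unconstrained") {
    cap <- if (mode == "window:5") 5 else 10
    mob <- setdiff(gn, fixed)
    anchors <- data.frame(group = mob,
                          x = coms[mob, 1], y = coms[mob, 2],
                          z = coms[mob, 3], max_disp = cap)
  }
  structure(list(pairs = ptab, anchors = anchors, mode = mode,
                 dmax = dmax, q_max = q_max, fixed = fixed),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("Restraint set (mode %s, dmax %.1f A, pi/q_max %.2f A):\n",
              x$mode, x$dmax, pi / x$q_max))
  for (i in seq_len(nrow(x$pairs)))
    cat(sprintf("  %s -- %s: d0 %.1f, window [%.1f, %.1f] A\n",
                x$pairs$a[i], x$pairs$b[i], x$pairs$d0[i], x$pairs$lower[i],
                x$pairs$upper[i]))
  if (!is.null(x$anchors))
    cat(sprintf("  anchors: %s within %.0f A of crystallographic COM\n",
                paste(x$anchors$group, collapse = ", "), x$anchors$max_disp[1]))
  invisible(x)
}

# Validity check used by the sampler (and by the brute-force test oracle):
# positions must satisfy every pair window, every anchor, every tether, and
# no inter-group contact closer than the clash threshold. Thresholds are
# never applied more strictly than the ground state's own geometry.
check_conformation <- function(positions, f, groups, restraints, tethers,
                               clash_floor, stretch_limit) {
  coms <- t(vapply(groups, function(idx) group_com(positions, f, idx),
                   numeric(3)))
  pt <- restraints$pairs
  for (i in seq_len(nrow(pt))) {
    d <- sqrt(sum((coms[pt$a[i], ] - coms[pt$b[i], ])^2))
    if (d < pt$lower[i] - 1e-9 || d > pt$upper[i] + 1e-9) return(FALSE)
  }
  an <- restraints$anchors
  if (!is.null(an)) {
    for (i in seq_len(nrow(an))) {
      d <- sqrt(sum((coms[an$group[i], ] - c(an$x[i], an$y[i], an$z[i]))^2))
      if (d > an$max_disp[i] + 1e-9) return(FALSE)
    }
  }
  if (!is.null(tethers)) {
    for (i in seq_len(nrow(tethers))) {
      gap <- sqrt(sum((positions[tethers$i[i], ] - positions[tethers$j[i], ])^2))
      if (gap > stretch_limit[i] + 1e-9) return(FALSE)
    }
  }
  gn <- names(groups)
  for (a in seq_along(gn)) for (b in seq_len(a - 1L)) {
    key <- paste(gn[b], gn[a])
    if (cpp_min_cross_dist(positions[groups[[a]], , drop = FALSE],
                           positions[groups[[b]], , drop = FALSE]) <
        clash_floor[[key]] - 1e-9) return(FALSE)
  }
  TRUE
}

random_rotation <- function(max_deg) {
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, 0, max_deg) * pi / 180
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

#' Sample restrained rigid-body conformations
#'
#' Constant-temperature Metropolis random walk over rigid-body placements.
#' Each proposal rotates every mobile group about its current centre of
#' mass by at most `max_rot` degrees and translates it by at most
#' `max_trans` Angstrom; proposals violating any restraint window, anchor
#' cap, linker tether, or inter-group clash are rejected, and the current
#' state is recorded every `stride` accepted moves until `n` conformations
#' have been emitted. All constraints are hard (the target density is
#' uniform over the allowed region), and the walk is fully reproducible
#' from `seed`.
#'
#' The linker tether limits the gap between the residues flanking each
#' linker to `3.8 * (linker length + 1) * max_linker_stretch` Angstrom (a
#' fully extended chain at 3.8 A per peptide). The clash criterion rejects
#' inter-group C-alpha contacts closer than `clash_dist`, relaxed per group
#' pair to the ground state's own closest contact where that is already
#' tighter.
#'
#' @param ground ground-state `atom_model` or [bead_model].
#' @param decomp a [domain_decomposition] (or resolved index groups).
#' @param restraints a `restraint_set` from [build_restraints].
#' @param n number of conformations to emit.
#' @param seed integer seed.
#' @param max_rot maximum proposal rotation, degrees.
#' @param max_trans maximum proposal translation, Angstrom.
#' @param clash_dist inter-group clash threshold, Angstrom.
#' @param max_linker_stretch linker extensibility factor (1 = fully
#'   extended chain).
#' @param stride record every this-many accepted moves.
#' @param mobile names of groups allowed to move; default all but `fixed`.
#' @param fixed group held fixed as the frame of reference; default taken
#'   from the restraint set.
#' @return A list of class `conformation_ensemble`; each element is a
#'   `conformation` with `id`, per-group `transforms` (rotation,
#'   translation relative to ground), full bead `positions`,
#'   `com_displacement` per group, `restraint_ok` and `max_linker_gap`.
#' @export
sample_conformations <- function(ground, decomp, restraints, n, seed,
                                 max_rot = 15, max_trans = 5,
                                 clash_dist = 3.0, max_linker_stretch = 1.0,
                                 stride = 10, mobile = NULL, fixed = NULL) {
  stopifnot(n >= 0)
  beads <- if (inherits(ground, "atom_model")) coarse_grain(ground) else ground
  res <- resolve_decomposition(decomp, beads)
  gn <- names(res$groups)
  if (is.null(fixed)) fixed <- if (!is.null(restraints$fixed)) restraints$fixed else gn[1]
  if (is.null(mobile)) mobile <- setdiff(gn, fixed)
  stopifnot(all(mobile %in% gn), !(fixed %in% mobile))

  pos0 <- beads$positions
  f <- beads$f
  coms0 <- t(vapply(res$groups, function(idx) group_com(pos0, f, idx),
                    numeric(3)))

  # per-pair clash floor: never stricter than the ground state itself
  clash_floor <- list()
  for (a in seq_along(gn)) for (b in seq_len(a - 1L)) {
    gmin <- cpp_min_cross_dist(pos0[res$groups[[a]], , drop = FALSE],
                               pos0[res$groups[[b]], , drop = FALSE])
    clash_floor[[paste(gn[b], gn[a])]] <- min(clash_dist, gmin * 0.999)
  }
  stretch_limit <- if (!is.null(res$tethers))
    3.8 * (res$tethers$len + 1) * max_linker_stretch

  if (!check_conformation(pos0, f, res$groups, restraints, res$tethers,
                          clash_floor, stretch_limit))
    stop("ground state violates its own restraint set; check inputs")
  if (n == 0) return(structure(list(), class = "conformation_ensemble"))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  transforms <- stats::setNames(lapply(gn, function(g)
    list(R = diag(3), t = c(0, 0, 0))), gn)
  cur <- pos0
  out <- vector("list", n)
  emitted <- 0L; accepted <- 0L; proposed <- 0L
  max_proposals <- max(1e4, n * stride * 500)

  linker_gap <- function(positions) {
    if (is.null(res$tethers)) return(0)
    max(vapply(seq_len(nrow(res$tethers)), function(i)
      sqrt(sum((positions[res$tethers$i[i], ] -
                  positions[res$tethers$j[i], ])^2)), numeric(1)))
  }

  while (emitted < n) {
    proposed <- proposed + 1L
    if (proposed > max_proposals)
      stop("sampler exhausted its proposal budget; loosen max_rot/max_trans or the restraints")
    cand <- cur
    cand_tr <- transforms
    for (g in mobile) {
      idx <- res$groups[[g]]
      com <- group_com(cand, f, idx)
      Rs <- random_rotation(max_rot)
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      ts <- dir * stats::runif(1, 0, max_trans)
      cand[idx, ] <- sweep(sweep(cand[idx, , drop = FALSE], 2, com) %*% t(Rs),
                           2, -(com + ts))
      bs <- com + ts - as.numeric(Rs %*% com)
      Rc <- cand_tr[[g]]$R; bc <- cand_tr[[g]]$t
      cand_tr[[g]] <- list(R = Rs %*% Rc, t = as.numeric(Rs %*% bc) + bs)
    }
    if (check_conformation(cand, f, res$groups, restraints, res$tethers,
                           clash_floor, stretch_limit)) {
      cur <- cand
      transforms <- cand_tr
      accepted <- accepted + 1L
      if (accepted %% stride == 0L) {
        emitted <- emitted + 1L
        disp <- vapply(gn, function(g)
          sqrt(sum((group_com(cur, f, res$groups[[g]]) - coms0[g, ])^2)),
          numeric(1))
        out[[emitted]] <- structure(list(
          id = sprintf("conf_%04d", emitted),
          transforms = transforms,
          positions = cur,
          com_displacement = disp,
          restraint_ok = TRUE,
          max_linker_gap = linker_gap(cur)), class = "conformation")
      }
    }
    if (proposed == 1e4L && accepted / proposed < 0.01)
      stop("acceptance rate below 1% over 10000 proposals; loosen max_rot/max_trans or the restraints")
  }
  structure(out, class = "conformation_ensemble",
            acceptance = accepted / proposed, groups = res$groups,
            tethers = res$tethers, f = f, fixed = fixed)
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat(sprintf("Conformational ensemble: %d conformations (acceptance %.1f%%)\n",
              length(x), 100 * attr(x, "acceptance")))
  invisible(x)
}

#' Bead model of one sampled conformation
#'
#' @param conf a `conformation` from [sample_conformations].
#' @param ground_beads the [bead_model] the ensemble was sampled from
#'   (supplies form factors and labels).
#' @return A [bead_model] with the conformation's coordinates.
#' @export
conformation_beads <- function(conf, ground_beads) {
  bead_model(conf$positions, f = ground_beads$f, labels = ground_beads$labels)
}
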