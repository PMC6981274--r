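#' Kabsch least-squares superposition
#'
#' Finds the proper rotation R and translation t minimising the RMSD of
#' `Q` onto `P` (so `Q %*% t(R) + t` best matches `P`), via the SVD of the
#' cross-covariance with reflection correction.
#'
#' @param P,Q n x 3 coordinate matrices in correspondence, n >= 3.
#' @param correspondence optional label pairs stored in the result.
#' @return An object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation`, `rmsd`, `n_matched`, `correspondence`.
#' @export
kabsch <- function(P, Q, correspondence = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("P and Q must have equal length")
  if (nrow(P) < 3) stop("need at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  for (M in list(Pc, Qc)) {
    sv <- svd(M)$d
    if (sv[2] < 1e-8 * max(sv[1], 1e-12))
      stop("degenerate (collinear) coordinates; superposition undefined")
  }
  H <- t(Qc) %*% Pc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(cp - R %*% cq)
  Qfit <- Q %*% t(R) + matrix(t_vec, nrow(Q), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((P - Qfit)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 n_matched = nrow(P), correspondence = correspondence),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition: RMSD %.3f A over %d matched positions\n",
              x$rmsd, x$n_matched))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sp a `superposition`.
#' @param coords n x 3 matrix (coordinates in the mobile frame).
#' @return Transformed coordinates.
#' @export
apply_superposition <- function(sp, coords) {
  as.matrix(coords) %*% t(sp$rotation) +
    matrix(sp$translation, nrow(coords), 3, byrow = TRUE)
}

# Local-shape descriptor for seeding a sequence-independent alignment: for
# each residue, the distances to residues at fixed sequence offsets. NA at
# chain ends.
distance_profile <- function(X, lags = c(-8L, -4L, 4L, 8L)) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, length(lags))
  for (k in seq_along(lags)) {
    j <- seq_len(n) + lags[k]
    ok <- j >= 1 & j <= n
    out[ok, k] <- sqrt(rowSums((X[which(ok), , drop = FALSE] -
                                  X[j[ok], , drop = FALSE])^2))
  }
  out
}

# Longest increasing subsequence (indices) -- O(n^2) DP, n is modest.
lis_indices <- function(v) {
  n <- length(v)
  if (n == 0) return(integer(0))
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    if (v[j] < v[i] && len[j] + 1L > len[i]) {
      len[i] <- len[j] + 1L; prev[i] <- j
    }
  }
  i <- which.max(len)
  path <- integer(0)
  while (i > 0L) { path <- c(i, path); i <- prev[i] }
  path
}

#' Sequence-independent domain alignment by iterative trimming
#'
#' Aligns two C-alpha traces without using sequence identity: the initial
#' correspondence is the best gapless sequence-offset alignment of local
#' distance profiles, and the procedure then alternates a Kabsch fit on the
#' current pairs with re-pairing each residue of `A` to its nearest residue
#' of `B` within `d_cut` (sequence order preserved via a longest increasing
#' subsequence), until the pair set is stable or `max_iter` is reached.
#' A deliberately simple stand-in for distance-matrix aligners such as
#' DALI: matched counts and RMSDs are comparable, not identical.
#'
#' @param A,B C-alpha coordinate matrices (>= 20 rows), e.g. from
#'   [select_calpha]; `resno` attributes, when present, label the
#'   correspondence.
#' @param d_cut pairing distance cutoff, Angstrom.
#' @param max_iter maximum refinement iterations.
#' @return A `superposition` whose `correspondence` is a data frame of
#'   matched residue labels (or row indices) of A and B.
#' @export
align_domains <- function(A, B, d_cut = 4.0, max_iter = 20L) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) < 20 || nrow(B) < 20) stop("need at least 20 residues per set")
  labA <- attr(A, "resno"); labB <- attr(B, "resno")
  if (is.null(labA)) labA <- seq_len(nrow(A))
  if (is.null(labB)) labB <- seq_len(nrow(B))

  # seed: the best gapless window of matching local distance profiles --
  # a short clean correspondence beats a long contaminated one, because the
  # first Kabsch fit only needs one correctly matched stretch
  pa <- distance_profile(A); pb <- distance_profile(B)
  win <- min(20L, nrow(A), nrow(B))
  offsets <- seq(-(nrow(B) - win), nrow(A) - win)
  best <- NULL
  for (o in offsets) {
    ia <- seq_len(nrow(A)); ib <- ia - o
    ok <- which(ib >= 1 & ib <= nrow(B))
    if (length(ok) < win) next
    rowcost <- rowMeans((pa[ok, , drop = FALSE] -
                           pb[ib[ok], , drop = FALSE])^2, na.rm = TRUE)
    roll <- stats::filter(rowcost, rep(1 / win, win), sides = 1)
    i_end <- which.min(roll)
    if (is.null(best) || roll[i_end] < best$cost) {
      rows <- ok[(i_end - win + 1L):i_end]
      best <- list(cost = roll[i_end], pairs = cbind(a = rows, b = rows - o))
    }
  }
  if (is.null(best)) stop("no seed window found; inputs too short")
  pairs <- best$pairs

  for (iter in seq_len(max_iter)) {
    sp <- kabsch(A[pairs[, "a"], , drop = FALSE],
                 B[pairs[, "b"], , drop = FALSE])
    Bt <- apply_superposition(sp, B)
    # nearest B residue for each A residue, then enforce sequence order
    nb <- vapply(seq_len(nrow(A)), function(i) {
      d2 <- rowSums(sweep(Bt, 2, A[i, ])^2)
      j <- which.min(d2)
      if (sqrt(d2[j]) <= d_cut) j else NA_integer_
    }, integer(1))
    cand <- which(!is.na(nb))
    keep <- cand[lis_indices(nb[cand])]
    new_pairs <- cbind(a = keep, b = nb[keep])
    if (nrow(new_pairs) < 10)
      stop("fewer than 10 structurally equivalent residues; folds appear non-homologous")
    if (nrow(new_pairs) == nrow(pairs) && all(new_pairs == pairs)) break
    pairs <- new_pairs
  }
  sp <- kabsch(A[pairs[, "a"], , drop = FALSE], B[pairs[, "b"], , drop = FALSE])
  sp$correspondence <- data.frame(a = labA[pairs[, "a"]], b = labB[pairs[, "b"]])
  sp$n_matched <- nrow(pairs)
  sp
}

#' Transplant a ligand into a homologous acceptor structure
#'
#' Moves the ligand atoms by the transform of a donor-to-acceptor protein
#' superposition and appends them to the acceptor model, so a binding mode
#' observed in one structure can be visualised in a homologue. No clash
#' relief is attempted; the closest acceptor-ligand heavy-atom distance is
#' reported in the `min_contact` attribute.
#'
#' @param acceptor `atom_model` receiving the ligand.
#' @param ligand `atom_model` of the ligand atoms (in donor coordinates).
#' @param transform `superposition` mapping donor coordinates onto the
#'   acceptor frame.
#' @param ligand_chain chain id assigned to the transplanted ligand.
#' @return The acceptor `atom_model` with ligand atoms appended.
#' @export
transplant_ligand <- function(acceptor, ligand, transform,
                              ligand_chain = "Z") {
  stopifnot(inherits(acceptor, "atom_model"), inherits(transform, "superposition"))
  if (!inherits(ligand, "atom_model") || nrow(ligand) == 0)
    stop("ligand selection is empty")
  moved <- ligand
  xyz <- apply_superposition(transform, as.matrix(ligand[, c("x", "y", "z")]))
  moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
  moved$chain <- ligand_chain
  dmat_min <- cpp_min_cross_dist(as.matrix(acceptor[, c("x", "y", "z")]), xyz)
  out <- atom_model(rbind(as.data.frame(acceptor), as.data.frame(moved)),
                    source = paste0(attr(acceptor, "source"), "+ligand"))
  attr(out, "min_contact") <- dmat_min
  out
}

#' Per-domain temperature-factor summary
#'
#' Mean, median and standard deviation of the crystallographic temperature
#' factors over each rigid group of a decomposition -- higher averages flag
#' the more mobile domains.
#'
#' @param model an `atom_model` with temperature factors.
#' @param decomp a [domain_decomposition]; group ranges are used as given
#'   (linkers are not stripped here).
#' @param calpha_only restrict to C-alpha atoms.
#' @return Data frame with one row per group: `group`, `n_atoms`, `mean`,
#'   `median`, `sd`.
#' @export
domain_bfactor_summary <- function(model, decomp, calpha_only = FALSE) {
  stopifnot(inherits(model, "atom_model"),
            inherits(decomp, "domain_decomposition"))
  m <- if (calpha_only) model[model$atom == "CA", , drop = FALSE] else model
  rows <- lapply(names(decomp$groups), function(nm) {
    rg <- decomp$groups[[nm]]
    sel <- rep(FALSE, nrow(m))
    for (i in seq_len(nrow(rg)))
      sel <- sel | (m$chain == rg$chain[i] & m$resno >= rg$start[i] &
                      m$resno <= rg$end[i])
    if (!any(sel)) stop("group '", nm, "' selects no atoms")
    b <- m$b[sel]
    data.frame(group = nm, n_atoms = sum(sel), mean = mean(b),
               median = stats::median(b), sd = stats::sd(b))
  })
  do.call(rbind, rows)
}
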