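# Synthetic-data generators: every input the analysis pipeline consumes,
# with known ground truth, so the whole chain is testable without any
# measured data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Two-state (closed/open) toy particle
#'
#' Builds a multi-domain bead particle in two conformations with known
#' geometry: each domain is a dense cluster of beads drawn uniformly from a
#' sphere, domains are packed in contact along a line for the closed state,
#' and the open state translates the last (terminal) domain outward by
#' `hinge_translation` along the line of centres. This mimics a hinged
#' domain opening: the open state has strictly larger radius of gyration
#' and maximum dimension, the increase in d_max being close to the hinge
#' translation itself.
#'
#' @param n_domains number of domains (>= 2).
#' @param beads_per_domain beads per domain.
#' @param hinge_translation opening displacement of the terminal domain, A.
#' @param domain_radius radius of each domain's bead sphere, A.
#' @param seed integer seed.
#' @return List with `closed` and `open` [bead_model]s, `decomposition`
#'   (index-based, with generous inter-domain tethers), and
#'   `hinge_translation`.
#' @export
make_two_state_toy <- function(n_domains = 3, beads_per_domain = 120,
                               hinge_translation = 25, domain_radius = 15,
                               seed = 1) {
  stopifnot(n_domains >= 2)
  with_seed(seed, {
    centres <- cbind((seq_len(n_domains) - 1) * 2 * domain_radius, 0, 0)
    clusters <- lapply(seq_len(n_domains), function(i) {
      # uniform in a sphere: normalise gaussians, cube-root radius
      v <- matrix(stats::rnorm(3 * beads_per_domain), ncol = 3)
      v <- v / sqrt(rowSums(v^2))
      r <- domain_radius * stats::runif(beads_per_domain)^(1 / 3)
      sweep(v * r, 2, -centres[i, ])
    })
    closed_pos <- do.call(rbind, clusters)
    open_pos <- closed_pos
    last <- (n_domains - 1) * beads_per_domain + seq_len(beads_per_domain)
    open_pos[last, 1] <- open_pos[last, 1] + hinge_translation
    groups <- stats::setNames(
      lapply(seq_len(n_domains), function(i)
        (i - 1L) * beads_per_domain + seq_len(beads_per_domain)),
      paste0("domain", seq_len(n_domains)))
    # tethers between consecutive domain centres-of-mass proxies: join the
    # bead of each domain closest to the next domain's centre, with an
    # effective linker length of 10 residues so the hinge can open
    tethers <- do.call(rbind, lapply(seq_len(n_domains - 1L), function(i) {
      a <- groups[[i]]; b <- groups[[i + 1L]]
      da <- colSums((t(closed_pos[a, ]) - centres[i + 1L, ])^2)
      db <- colSums((t(closed_pos[b, ]) - centres[i, ])^2)
      data.frame(i = a[which.min(da)], j = b[which.min(db)], len = 10L)
    }))
    list(closed = bead_model(closed_pos),
         open = bead_model(open_pos),
         decomposition = list(groups = groups, tethers = tethers),
         hinge_translation = hinge_translation)
  })
}

#' Simulate a noisy measured profile from a bead model
#'
#' Computes the exact Debye intensity and applies multiplicative Gaussian
#' noise whose relative standard deviation grows toward high q,
#' sd(q) = noise_level * (1 + 5 q / q_max), as in real scattering data
#' where the signal falls orders of magnitude below the low-q level. The
#' sigma column carries the true per-point standard deviation, so
#' chi-square against the generating model is calibrated to ~1.
#'
#' @param model a [bead_model].
#' @param q_grid ascending q grid, 1/A.
#' @param noise_level relative noise at q = 0 (0.01 = 1%).
#' @param seed integer seed.
#' @return A [saxs_profile] with sigma.
#' @export
simulate_profile <- function(model, q_grid, noise_level = 0.01, seed = 1) {
  stopifnot(noise_level >= 0)
  ideal <- debye_intensity(model, q_grid)
  rel_sd <- noise_level * (1 + 5 * q_grid / max(q_grid))
  sig <- pmax(ideal$intensity * rel_sd, .Machine$double.eps)
  obs <- with_seed(seed,
    ideal$intensity * (1 + stats::rnorm(length(q_grid), 0, rel_sd)))
  saxs_profile(q_grid, obs, sigma = sig, label = "simulated")
}

#' Simulate a measured profile of a conformational mixture
#'
#' Applies the noise model of [simulate_profile] to the weighted sum of
#' the members' Debye intensities.
#'
#' @param models list of [bead_model]s.
#' @param weights non-negative fractions summing to 1, one per model.
#' @param q_grid ascending q grid, 1/A.
#' @param noise_level relative noise at q = 0.
#' @param seed integer seed.
#' @return A [saxs_profile] with sigma.
#' @export
simulate_mixture <- function(models, weights, q_grid, noise_level = 0.01,
                             seed = 1) {
  if (length(models) != length(weights))
    stop("one weight per model required")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  I <- Reduce(`+`, Map(function(m, w)
    w * debye_intensity(m, q_grid)$intensity, models, weights))
  rel_sd <- noise_level * (1 + 5 * q_grid / max(q_grid))
  sig <- pmax(I * rel_sd, .Machine$double.eps)
  obs <- with_seed(seed, I * (1 + stats::rnorm(length(q_grid), 0, rel_sd)))
  saxs_profile(q_grid, obs, sigma = sig, label = "simulated mixture")
}

#' Simulate replicate nicking time courses
#'
#' Fractions follow A (1 - exp(-k t)) with additive Gaussian noise,
#' clamped to `[0, 1]`.
#'
#' @param k rate constant, 1/min (> 0).
#' @param amplitude reaction end point.
#' @param times sampling times, min.
#' @param noise_sd additive noise standard deviation.
#' @param replicates number of replicate series.
#' @param seed integer seed.
#' @return A [time_course].
#' @export
simulate_timecourse <- function(k = 0.81, amplitude = 0.95,
                                times = c(0, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10),
                                noise_sd = 0.05, replicates = 3, seed = 1) {
  stopifnot(k > 0)
  mu <- amplitude * (1 - exp(-k * times))
  frac <- with_seed(seed, {
    m <- matrix(stats::rnorm(length(times) * replicates, 0, noise_sd),
                ncol = replicates)
    pmin(pmax(mu + m, 0), 1)
  })
  time_course(times, frac)
}
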