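#' Run the full apo-state conformational analysis
#'
#' One reproducible run of the whole chain: model-free invariants for every
#' input curve (Guinier, dimensionless Kratky, Moore P(r), d_max, Porod
#' volume), then for the apo analysis the restraint table, restrained
#' rigid-body sampling from the ground state, Debye profiles for every
#' conformation, the chi-square table, and the best single-state and best
#' two-state ensemble fits. Every numerical convention used (Guinier limit,
#' Moore terms, Porod cut, clash distance, chi-square normalisation) is
#' recorded in the report so two analyses can diff their assumptions.
#'
#' @param config a list (see Details) or the result of [pipeline_config].
#' @details Config fields: `apo_profile` (path or [saxs_profile],
#'   required), `complex_profile` (optional), `ground` (path,
#'   `atom_model`, or [bead_model], required), `decomposition`
#'   ([domain_decomposition] or index decomposition; default
#'   [default_decomposition]), `mode` (restraint mode, default
#'   `"unconstrained"`), `n_conformations` (default 2430), `seed`
#'   (default 1), `k` (multi-state size, default 2), `qrg_limit`,
#'   `q_cut`, `dmax` (fixed value or `"auto"`), `dmax_grid`
#'   (candidates for the auto scan), sampler settings `max_rot`,
#'   `max_trans`, `clash_dist`, `stride`, `mobile`, `fixed`, and
#'   `out_dir` (optional; report JSON and P(r) TSVs are written there).
#' @return A report list of class `saxs_pipeline_report`; deterministic
#'   given the seed.
#' @export
run_conformational_analysis <- function(config) {
  cfg <- if (is.null(attr(config, "validated"))) do.call(pipeline_config, config)
         else config
  stage <- "input"
  report <- list(schema = "saxsens-report/1",
                 package_version = as.character(utils::packageVersion("saxsens")),
                 config = cfg[!vapply(cfg, is.object, TRUE)],
                 seed = cfg$seed)
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  load_prof <- function(x) if (inherits(x, "saxs_profile")) x else read_profile(x)
  apo <- run_stage("read apo profile", load_prof(cfg$apo_profile))
  cplx <- if (!is.null(cfg$complex_profile))
    run_stage("read complex profile", load_prof(cfg$complex_profile))
  ground <- run_stage("read ground-state structure", {
    g <- cfg$ground
    if (is.character(g)) g <- read_structure(g)
    g
  })
  beads <- if (inherits(ground, "bead_model")) ground else coarse_grain(ground)

  curve_block <- function(profile, label) run_stage(paste("invariants:", label), {
    gf <- guinier_fit(profile, qrg_limit = cfg$qrg_limit)
    kr <- dimensionless_kratky(profile, gf)
    dmax <- cfg$dmax
    dmax_scan <- NULL
    if (identical(dmax, "auto")) {
      grid <- cfg$dmax_grid
      if (is.null(grid)) grid <- seq(2 * gf$rg, 4.5 * gf$rg, by = 2.5)
      sel <- estimate_dmax(profile, grid)
      dmax <- sel$dmax
      dmax_scan <- sel$scores
    }
    pr <- moore_pr(profile, dmax)
    pv <- porod_volume(profile, gf, q_cut = cfg$q_cut)
    list(label = label, guinier = gf, kratky = kr, pofr = pr, dmax = dmax,
         dmax_scan = dmax_scan, porod_volume = as.numeric(pv),
         porod_q_cut = attr(pv, "q_cut"))
  })

  report$apo <- curve_block(apo, "apo")
  if (!is.null(cplx)) report$complex <- curve_block(cplx, "complex")

  decomp <- cfg$decomposition
  restraints <- run_stage("restraints", build_restraints(
    decomp, beads, dmax = report$apo$dmax, q_max = max(apo$q),
    mode = cfg$mode, fixed = cfg$fixed))
  report$restraints <- restraints

  ens <- run_stage("sampling", sample_conformations(
    beads, decomp, restraints, n = cfg$n_conformations, seed = cfg$seed,
    max_rot = cfg$max_rot, max_trans = cfg$max_trans,
    clash_dist = cfg$clash_dist, stride = cfg$stride,
    mobile = cfg$mobile, fixed = cfg$fixed))
  report$n_conformations <- length(ens)

  pool <- run_stage("profiles", {
    p <- lapply(ens, function(cf)
      debye_intensity(conformation_beads(cf, beads), apo$q))
    names(p) <- vapply(ens, `[[`, "", "id")
    p
  })
  report$ground_chi2 <- run_stage("ground-state fit",
    as.numeric(chi2(apo, debye_intensity(beads, apo$q))))
  report$single_state <- run_stage("single-state fit",
    best_single_state(apo, pool))
  report$multi_state <- run_stage("multi-state fit",
    multi_state_fit(apo, pool, k = cfg$k))
  best_conf <- ens[[match(report$single_state$member_ids[1], names(pool))]]
  report$best_displacement <- best_conf$com_displacement
  report$ensemble <- ens

  if (!is.null(cfg$out_dir)) run_stage("write outputs", {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      data.frame(r = report$apo$pofr$r, p = report$apo$pofr$p),
      file.path(cfg$out_dir, "apo_pr.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report_json(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  class(report) <- "saxs_pipeline_report"
  report
}

#' Validated pipeline configuration
#'
#' @param apo_profile path or [saxs_profile] of the apo curve.
#' @param ground path, `atom_model` or [bead_model] of the ground state.
#' @param complex_profile optional second curve.
#' @param decomposition rigid-group decomposition; default
#'   [default_decomposition].
#' @param mode restraint mode (see [build_restraints]).
#' @param n_conformations,seed,max_rot,max_trans,clash_dist,stride sampler
#'   settings (see [sample_conformations]).
#' @param k ensemble size for [multi_state_fit].
#' @param qrg_limit,q_cut,dmax,dmax_grid invariant settings.
#' @param mobile,fixed group mobility overrides.
#' @param out_dir optional output directory.
#' @return The validated config list.
#' @export
pipeline_config <- function(apo_profile, ground, complex_profile = NULL,
                            decomposition = default_decomposition(),
                            mode = "unconstrained", n_conformations = 2430,
                            seed = 1, max_rot = 15, max_trans = 5,
                            clash_dist = 3.0, stride = 10, k = 2,
                            qrg_limit = 1.3, q_cut = NULL, dmax = "auto",
                            dmax_grid = NULL, mobile = NULL, fixed = NULL,
                            out_dir = NULL) {
  for (p in list(apo_profile, complex_profile, ground))
    if (is.character(p) && !file.exists(p)) stop("path not found: ", p)
  structure(
    list(apo_profile = apo_profile, ground = ground,
         complex_profile = complex_profile, decomposition = decomposition,
         mode = mode, n_conformations = n_conformations, seed = seed,
         max_rot = max_rot, max_trans = max_trans, clash_dist = clash_dist,
         stride = stride, k = k, qrg_limit = qrg_limit, q_cut = q_cut,
         dmax = dmax, dmax_grid = dmax_grid, mobile = mobile, fixed = fixed,
         out_dir = out_dir),
    validated = TRUE)
}

# Numeric core of a report for JSON serialisation (drops bulky ensembles).
report_json <- function(report) {
  curve <- function(b) if (is.null(b)) NULL else list(
    rg = b$guinier$rg, rg_err = b$guinier$rg_err, i0 = b$guinier$i0,
    guinier_window = b$guinier$q_window, guinier_points = b$guinier$n_points,
    qrg_limit = b$guinier$qrg_limit,
    dmax = b$dmax, pr_rg = b$pofr$rg_real, pr_i0 = b$pofr$i0_real,
    pr_terms = b$pofr$n_terms, pr_chi2 = b$pofr$chi2_fit,
    porod_volume = b$porod_volume, porod_q_cut = b$porod_q_cut)
  list(schema = report$schema, package_version = report$package_version,
       seed = report$seed,
       apo = curve(report$apo), complex = curve(report$complex),
       restraints = list(mode = report$restraints$mode,
                         dmax = report$restraints$dmax,
                         q_max = report$restraints$q_max,
                         pairs = report$restraints$pairs,
                         anchors = report$restraints$anchors),
       n_conformations = report$n_conformations,
       ground_chi2 = report$ground_chi2,
       single_state = list(id = report$single_state$member_ids,
                           chi2 = report$single_state$chi2,
                           scale = report$single_state$scale),
       multi_state = list(ids = report$multi_state$member_ids,
                          weights = report$multi_state$weights,
                          chi2 = report$multi_state$chi2),
       best_displacement = as.list(report$best_displacement))
}

#' @export
print.saxs_pipeline_report <- function(x, ...) {
  cat("SAXS conformational-analysis report\n")
  cat(sprintf("  apo: Rg %.2f A, dmax %.1f A, Porod volume %.4g A^3\n",
              x$apo$guinier$rg, x$apo$dmax, x$apo$porod_volume))
  if (!is.null(x$complex))
    cat(sprintf("  complex: Rg %.2f A, dmax %.1f A, Porod volume %.4g A^3\n",
                x$complex$guinier$rg, x$complex$dmax, x$complex$porod_volume))
  cat(sprintf("  ground-state (closed) chi2: %.2f\n", x$ground_chi2))
  cat(sprintf("  best single state: %s, chi2 %.2f\n",
              x$single_state$member_ids[1], x$single_state$chi2))
  cat(sprintf("  best %d-state: chi2 %.2f (weights %s)\n",
              length(x$multi_state$member_ids), x$multi_state$chi2,
              paste(sprintf("%.2f", x$multi_state$weights), collapse = "/")))
  invisible(x)
}
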