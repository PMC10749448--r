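#' Configuration for the full hydration-shell analysis
#'
#' @param box_edge Cubic box edge (Å); required when reading a trajectory
#'   from file.
#' @param dt Frame spacing (ps); required when reading from file.
#' @param ion Ion label in the XYZ file.
#' @param lp_label Lone-pair pseudo-atom label.
#' @param bin_width g(r) and P(eta) bin width (Å).
#' @param r_cut Conventional first-shell cutoff (Å), or `"auto"` to take the
#'   first minimum of the ion-oxygen g(r) inside `r_cut_window`.
#' @param eta_cut Tight/loose eta cutoff (Å), or `"auto"` for the
#'   rank-distribution intersection.
#' @param r_cut_window Search window (Å) for the automatic first minimum.
#' @param threshold Exchange transient-filter time (ps).
#' @param sdf_voxel,sdf_half_extent SDF grid voxel size and half extent (Å).
#' @return A list of class `lp_run_config`.
#' @export
run_config <- function(box_edge = NULL, dt = NULL, ion = "Cl", lp_label = "X",
                       bin_width = 0.02, r_cut = "auto", eta_cut = "auto",
                       r_cut_window = c(3.0, 5.5), threshold = 0.1,
                       sdf_voxel = 0.2, sdf_half_extent = 5) {
  for (nm in c("r_cut", "eta_cut")) {
    v <- get(nm)
    if (!identical(v, "auto") && !(is.numeric(v) && v > 0)) {
      stop(sprintf("%s must be a positive number or \"auto\"", nm), call. = FALSE)
    }
  }
  structure(list(box_edge = box_edge, dt = dt, ion = ion, lp_label = lp_label,
                 bin_width = bin_width, r_cut = r_cut, eta_cut = eta_cut,
                 r_cut_window = r_cut_window, threshold = threshold,
                 sdf_voxel = sdf_voxel, sdf_half_extent = sdf_half_extent),
            class = "lp_run_config")
}

#' Run the full lone-pair hydration-shell analysis
#'
#' Chains every stage on one trajectory: ion-oxygen and ion-hydrogen g(r)
#' with the first-shell cutoff, the eta table and its distributions (all
#' pairs, rank 1-4, rank 5-7) with the intersection cutoff, oxygen and
#' hydrogen SDFs in the lone-pair frame, tight/loose/bulk classification with
#' coordination-number distributions and the tight/rest g(r) decomposition,
#' and the exchange-event analysis with residence times. Deterministic:
#' identical input and configuration give an identical report.
#'
#' @param traj An [lp_trajectory()], or a path to an extended XYZ file (then
#'   `config$box_edge` and `config$dt` are required).
#' @param config An [run_config()].
#' @param out_dir Optional output directory; when given, writes `gr_XO.dat`,
#'   `gr_XH.dat`, `p_eta.dat`, `p_eta_rank14.dat`, `p_eta_rank57.dat`,
#'   `sdf_O.cube`, `sdf_H.cube`, `labels.tsv`, `exchange.tsv` and
#'   `report.json`.
#' @return Invisibly, a list with all intermediate objects and `report`, the
#'   scalar summary (cutoffs, peak positions, coordination numbers, event
#'   counts, residence times).
#' @export
run_full_analysis <- function(traj, config = run_config(), out_dir = NULL) {
  if (is.character(traj)) {
    if (is.null(config$box_edge) || is.null(config$dt)) {
      stop("box_edge and dt are required to read a trajectory from file",
           call. = FALSE)
    }
    traj <- read_xyz_trajectory(
      traj, species_map(ion = config$ion, lp = config$lp_label),
      dt = config$dt, box_edge = config$box_edge)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  gr_xo <- stage("rdf", compute_rdf(traj, "XO", config$bin_width))
  gr_xh <- stage("rdf", compute_rdf(traj, "XH", config$bin_width))
  r_cut <- if (identical(config$r_cut, "auto")) {
    stage("rdf", as.numeric(first_minimum(gr_xo, config$r_cut_window)))
  } else config$r_cut

  tab <- stage("eta", eta_table(traj))
  p_all <- stage("eta", eta_distribution(tab, "all", config$bin_width))
  rank_cut <- stage("eta", eta_rank_cutoff(tab, config$bin_width))
  eta_cut <- if (identical(config$eta_cut, "auto")) rank_cut$eta_cut
             else config$eta_cut

  labels <- stage("shells", classify_shells(traj, shell_cutoffs(r_cut, eta_cut)))
  cnd_tight <- stage("shells", cn_distribution(labels, "tight"))
  dec <- stage("shells", decomposed_rdf(traj, labels, config$bin_width))
  # a short trajectory can have a shell with no committed events; its NMRT
  # is then reported as Inf rather than aborting the run
  ev <- stage("exchange", exchange_events(labels, config$threshold))
  occ0 <- shell_occupancy(labels)
  exch_sum <- tryCatch(
    nmrt_from_counts(event_counts(ev), t_sim = traj$t_sim,
                     n_tight = occ0["tight"], n_loose = occ0["loose"]),
    error = function(e) {
      warning("a shell has zero committed exchange events; NMRT reported as Inf",
              call. = FALSE)
      cnt <- event_counts(ev)
      n_ex <- c(tight = unname(cnt["T-L"] + cnt["T-B"] + cnt["T-L-B"]),
                loose = unname(cnt["T-L"] + cnt["L-B"] + cnt["T-L-B"]))
      structure(list(counts = cnt, n_ex = n_ex,
                     mrt = ifelse(n_ex > 0,
                                  traj$t_sim * c(occ0["tight"], occ0["loose"]) / n_ex,
                                  Inf),
                     nmrt = ifelse(n_ex > 0, traj$t_sim / n_ex, Inf),
                     n_bar = c(tight = unname(occ0["tight"]),
                               loose = unname(occ0["loose"])),
                     t_sim = traj$t_sim),
                class = "lp_exchange_summary")
    })
  exch <- list(events = ev, summary = exch_sum)

  sdf_o <- stage("sdf", accumulate_sdf(traj, config$sdf_voxel,
                                       config$sdf_half_extent, "O",
                                       distance_window = c(0, r_cut)))
  sdf_h <- stage("sdf", accumulate_sdf(traj, config$sdf_voxel,
                                       config$sdf_half_extent, "H",
                                       distance_window = c(0, r_cut)))
  occ <- shell_occupancy(labels)
  report <- list(
    n_frames = n_frames(traj), dt = traj$dt, t_sim = traj$t_sim,
    box_edge = traj$box_edge, n_waters = n_waters(traj$frames[[1]]),
    r_cut = r_cut, eta_cut = eta_cut,
    gr_xo_peak = gr_xo$r_centers[which.max(smooth_ma(gr_xo$g, 5L))],
    eta_peak_all = eta_peak(p_all),
    eta_peak_rank14 = eta_peak(rank_cut$d14),
    coordination_number = coordination_number(traj, r_cut),
    n_bar = as.list(occ),
    cn_mode_tight = cn_mode(cnd_tight),
    event_counts = as.list(event_counts(exch$events)),
    n_ex = as.list(exch$summary$n_ex),
    mrt = as.list(exch$summary$mrt),
    nmrt = as.list(exch$summary$nmrt),
    config = unclass(config))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_curve(gr_xo$r_centers, gr_xo$g, file.path(out_dir, "gr_XO.dat"),
                "r [Ang]", "g_XO(r) [-]")
    write_curve(gr_xh$r_centers, gr_xh$g, file.path(out_dir, "gr_XH.dat"),
                "r [Ang]", "g_XH(r) [-]")
    write_curve(p_all$eta_centers, p_all$p, file.path(out_dir, "p_eta.dat"),
                "eta [Ang]", "P(eta) [1/Ang]")
    write_curve(rank_cut$d14$eta_centers, rank_cut$d14$p,
                file.path(out_dir, "p_eta_rank14.dat"), "eta [Ang]", "P(eta) [1/Ang]")
    write_curve(rank_cut$d57$eta_centers, rank_cut$d57$p,
                file.path(out_dir, "p_eta_rank57.dat"), "eta [Ang]", "P(eta) [1/Ang]")
    write_cube(sdf_o, file.path(out_dir, "sdf_O.cube"))
    write_cube(sdf_h, file.path(out_dir, "sdf_H.cube"))
    utils::write.table(labels, file.path(out_dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(exch$events, file.path(out_dir, "exchange.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(traj = traj, gr_xo = gr_xo, gr_xh = gr_xh, eta_table = tab,
                 p_eta = p_all, rank_cutoff = rank_cut, labels = labels,
                 cn_tight = cnd_tight, decomposed = dec, sdf_o = sdf_o,
                 sdf_h = sdf_h, exchange = exch, report = report))
}
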