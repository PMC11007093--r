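# cache of per-scheme dictionary tables (keyed by shell b-values + grid)
.dwidown_cache <- new.env(parent = emptyenv())

.cached_shell_tables <- function(scheme, grid, quad) {
  key <- paste(c(shell_bvalues(scheme), grid$v_ic, grid$kappa,
                 nrow(quad$points)), collapse = "|")
  if (is.null(.dwidown_cache[[key]]))
    .dwidown_cache[[key]] <- .noddi_shell_tables(scheme, grid, quad)
  .dwidown_cache[[key]]
}

#' Study configuration
#'
#' @param phantom a [phantom_spec()].
#' @param rates down-sampling rates to evaluate (fractions removed).
#' @param alpha repulsion-energy weight for subset selection.
#' @param grid NODDI dictionary grid.
#' @param metrics which metric maps to profile.
#' @param fa_threshold FA threshold used to re-derive each arm's bundle
#'   segmentation masks (within the truth mask dilated by one voxel), so
#'   volume loss reflects the arm's own maps as a segmentation re-run
#'   would.
#' @return A `study_config` list.
#' @export
study_config <- function(phantom = phantom_spec(), rates = c(0.1, 0.3, 0.5),
                         alpha = 0.5, grid = noddi_grid(),
                         metrics = c("FA", "MD", "ICvf"),
                         fa_threshold = 0.2) {
  stopifnot(all(rates >= 0 & rates < 1))
  structure(list(phantom = phantom, rates = rates, alpha = alpha,
                 grid = grid, metrics = metrics,
                 fa_threshold = fa_threshold),
            class = "study_config")
}

# group bundles into joined left/right pairs + unpaired singles
.bundle_groups <- function(bundles) {
  names_ <- names(bundles)
  groups <- list()
  for (nm in names_) {
    b <- bundles[[nm]]
    g <- if (b$side %in% c("left", "right"))
      sub("_(left|right)$", "", nm) else nm
    groups[[g]] <- c(groups[[g]], nm)
  }
  groups
}

#' Run the full reference-vs-downsampled phantom study
#'
#' Orchestrates the complete pipeline on a synthetic phantom: subsample
#' the gradient scheme at each rate, slice each subject/session dataset
#' to the retained volumes, fit DTI and NODDI on every arm, profile each
#' bundle along 98 segments per side (196 joined for left/right pairs),
#' and compute the agreement statistics: relative L1 distance of bundle
#' averages across subjects/sessions, per-segment KS tests with BH-FDR,
#' Bland-Altman bias and limits of agreement, and white-matter volume
#' loss from FA-threshold re-segmentation.
#'
#' A rate of 0 is always evaluated implicitly as the reference arm; rates
#' listed in the config are compared against it. Identical seeds yield
#' bit-identical reports.
#'
#' @param config a [study_config()].
#' @param verbose print stage progress.
#' @return An `agreement_report`: list of data.frames `bundle_average`
#'   (per bundle/metric/rate: median and 2.5/97.5 percentiles of the
#'   relative L1 distance, plus per-observation rows in
#'   `bundle_average_raw`), `profiles_ks`, `bland_altman`, `volume_loss`,
#'   and a `manifest` with the configuration.
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(...)
  say("generating phantom")
  ph <- make_phantom(config$phantom)
  scheme <- ph$scheme
  spec <- config$phantom

  rates <- sort(unique(config$rates))
  arms <- list(`0` = seq_len(n_volumes(scheme)))
  for (r in rates[rates > 0]) {
    sub <- subsample_scheme(scheme, subsample_plan(r),
                            energy_config(config$alpha))
    arms[[as.character(r)]] <- attr(sub, "retained_volumes")
  }
  groups <- .bundle_groups(ph$bundles)
  n_sub <- spec$n_subjects; n_ses <- spec$n_sessions

  # fit every arm of every subject/session, collect profiles + volumes
  obs <- list()       # obs[[rate]][[subject]][[session]]
  for (ri in seq_along(arms)) {
    rate_name <- names(arms)[ri]
    say("fitting arm rate=", rate_name)
    obs[[rate_name]] <- vector("list", n_sub)
    for (sj in seq_len(n_sub)) {
      obs[[rate_name]][[sj]] <- vector("list", n_ses)
      for (ss in seq_len(n_ses)) {
        ds <- slice_dataset(ph$data[[sj]][[ss]], arms[[ri]])
        tf <- fit_tensor(ds)
        tm <- tensor_metrics(tf)
        nm <- fit_noddi(ds, tf, config$grid,
                        quad = watson_quadrature())
        maps <- list(FA = tm$FA, MD = tm$MD, RD = tm$RD,
                     ICvf = nm$ICvf, ISOvf = nm$ISOvf, OD = nm$OD)
        # arm-specific re-segmentation: FA threshold inside the truth
        # neighbourhood
        segs <- lapply(ph$bundles, function(b) {
          region <- .dilate_mask(b$mask, 1)
          region & !is.na(maps$FA) & maps$FA > config$fa_threshold
        })
        profs <- list()
        for (g in names(groups)) {
          members <- groups[[g]]
          for (m in config$metrics) {
            map <- maps[[m]]
            map[is.na(map)] <- 0
            pr <- lapply(members, function(nm_)
              profile_bundle(ph$bundles[[nm_]], map))
            profs[[paste(g, m, sep = ".")]] <-
              if (length(pr) == 2) join_profiles(pr[[1]], pr[[2]])
              else pr[[1]]
          }
        }
        obs[[rate_name]][[sj]][[ss]] <-
          list(profiles = profs,
               volumes = vapply(segs, sum, numeric(1)))
      }
    }
  }

  say("computing agreement statistics")
  ref <- obs[["0"]]
  keys <- names(ref[[1]][[1]]$profiles)
  avg_rows <- raw_rows <- ks_rows <- ba_rows <- vl_rows <- list()
  for (rate_name in names(arms)) {
    rate_pct <- 100 * as.numeric(rate_name)
    arm <- obs[[rate_name]]
    for (key in keys) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      gname <- parts[1]; metric <- parts[2]
      ref_avg <- ds_avg <- c()
      ref_mat <- ds_mat <- NULL
      for (sj in seq_len(n_sub)) for (ss in seq_len(n_ses)) {
        pr <- ref[[sj]][[ss]]$profiles[[key]]
        pd <- arm[[sj]][[ss]]$profiles[[key]]
        ref_avg <- c(ref_avg, bundle_average(pr))
        ds_avg <- c(ds_avg, bundle_average(pd))
        ref_mat <- rbind(ref_mat, pr$values)
        ds_mat <- rbind(ds_mat, pd$values)
      }
      l1 <- rel_l1(ref_avg, ds_avg)
      sm <- summarize_distribution(l1)
      avg_rows[[length(avg_rows) + 1]] <- data.frame(
        bundle = gname, metric = metric, rate_pct = rate_pct,
        median_rel_l1 = sm$median, p2.5 = sm$lo, p97.5 = sm$hi)
      raw_rows[[length(raw_rows) + 1]] <- data.frame(
        bundle = gname, metric = metric, rate_pct = rate_pct,
        obs = seq_along(l1), rel_l1 = l1)
      if (nrow(ref_mat) >= 2) {
        ks <- ks_profile_test(ref_mat, ds_mat)
        ks_rows[[length(ks_rows) + 1]] <- data.frame(
          bundle = gname, metric = metric, rate_pct = rate_pct, ks)
      }
      if (length(ref_avg) >= 2) {
        ba <- bland_altman(ref_avg, ds_avg)
        ba_rows[[length(ba_rows) + 1]] <- data.frame(
          bundle = gname, metric = metric, rate_pct = rate_pct,
          bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
          sd = ba$sd, n = ba$n)
      }
    }
    for (sj in seq_len(n_sub)) for (ss in seq_len(n_ses)) {
      v_ref <- sum(ref[[sj]][[ss]]$volumes)
      v_ds <- sum(arm[[sj]][[ss]]$volumes)
      vl_rows[[length(vl_rows) + 1]] <- data.frame(
        rate_pct = rate_pct, subject = sj, session = ss,
        loss_pct = 100 * (v_ref - v_ds) / v_ref)
    }
  }

  structure(list(
    bundle_average = do.call(rbind, avg_rows),
    bundle_average_raw = do.call(rbind, raw_rows),
    profiles_ks = do.call(rbind, ks_rows),
    bland_altman = do.call(rbind, ba_rows),
    volume_loss = do.call(rbind, vl_rows),
    manifest = list(seed = spec$seed, protocol = spec$protocol,
                    n_subjects = n_sub, n_sessions = n_ses,
                    snr = spec$snr, rates = rates,
                    alpha = config$alpha, metrics = config$metrics,
                    fa_threshold = config$fa_threshold)),
    class = "agreement_report")
}

#' Write an agreement report to CSV/JSON files
#'
#' @param report an `agreement_report` from [run_study()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "agreement_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("bundle_average", "bundle_average_raw", "profiles_ks",
               "bland_altman", "volume_loss"))
    utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report:",
      length(unique(x$bundle_average$bundle)), "bundles,",
      length(unique(x$bundle_average$metric)), "metrics, rates",
      paste(unique(x$bundle_average$rate_pct), collapse = "/"),
      "%\n")
  print(utils::head(x$bundle_average, 12))
  invisible(x)
}
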